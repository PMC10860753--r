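#' Initialize centroids by k-means
#'
#' Seeds `k` centers with the k-means++ rule (distance-proportional sampling)
#' and refines them by Lloyd iterations (at most 300); the whole procedure is
#' restarted `nstart` times (default 10, the conventional k-means default)
#' and the solution with the lowest within-cluster sum of squares is kept.
#' The result is deterministic given `seed` and becomes the free centroid
#' parameters of the clustering head.
#'
#' @param embeddings `M x d` matrix of (encoder-space) embeddings, `M >= k`.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param df Student-t degrees of freedom stored with the centroids
#'   (default 1).
#' @param nstart number of independent k-means++ restarts.
#' @return An object of class `mcc_centroids`: list with `mu` (`k x d`), `df`,
#'   `k`.
#' @export
init_centroids <- function(embeddings, k, seed = 0L, df = 1, nstart = 10L) {
  embeddings <- as.matrix(embeddings)
  m <- nrow(embeddings)
  k <- as.integer(k)
  if (k < 1) stop_mixcc("'k' must be at least 1")
  if (m < k) stop_mixcc(sprintf("need at least k = %d points, got %d", k, m))
  if (!all(is.finite(embeddings))) stop_mixcc("embeddings must be finite")
  if (df <= 0) stop_mixcc("'df' must be positive")
  ndistinct <- nrow(unique(embeddings))
  if (ndistinct < k)
    stop_mixcc(sprintf(
      "only %d distinct points for k = %d clusters (%d short)",
      ndistinct, k, k - ndistinct))
  mu <- with_seed(seed, {
    if (k == m) {
      embeddings
    } else if (k == 1) {
      matrix(colMeans(embeddings), nrow = 1)
    } else {
      best <- NULL
      for (r in seq_len(max(1L, nstart))) {
        centers <- kmeanspp_centers(embeddings, k)
        km <- suppressWarnings(
          stats::kmeans(embeddings, centers = centers, iter.max = 300L,
                        algorithm = "Lloyd"))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      best$centers
    }
  })
  mu <- matrix(as.numeric(mu), nrow = k)
  structure(list(mu = mu, df = df, k = k), class = "mcc_centroids")
}

# k-means++ seeding: first center uniform, then distance^2-proportional.
kmeanspp_centers <- function(x, k) {
  m <- nrow(x)
  centers <- matrix(0, nrow = k, ncol = ncol(x))
  centers[1, ] <- x[sample.int(m, 1L), ]
  if (k == 1) return(centers)
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    pick <- if (sum(d2) <= 0) sample.int(m, 1L) else sample.int(m, 1L, prob = d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' @export
print.mcc_centroids <- function(x, ...) {
  cat(sprintf("<mcc_centroids> k = %d, dim = %d, df = %g\n",
              x$k, ncol(x$mu), x$df))
  invisible(x)
}

# Student-t kernel forward with cache for the backward pass.
soft_assign_forward <- function(E, centroids) {
  mu <- centroids$mu; a <- centroids$df
  d2 <- pmax(outer(rowSums(E^2), rowSums(mu^2), "+") - 2 * tcrossprod(E, mu), 0)
  if (!all(is.finite(d2))) stop_mixcc("non-finite distance in soft assignment")
  u <- 1 + d2 / a
  t_ <- u^(-(a + 1) / 2)
  t_ <- pmax(t_, 1e-300)
  Tn <- rowSums(t_)
  list(q = t_ / Tn, t = t_, u = u, Tn = Tn, E = E, mu = mu, a = a)
}

# Backward through the Student-t soft assignment: given dL/dq, return
# gradients w.r.t. embeddings and centroids.
soft_assign_backward <- function(cache, Gq) {
  q <- cache$q
  # dL/dt_il = (Gq_il - sum_l' Gq_il' q_il') / T_i
  Gt <- (Gq - rowSums(Gq * q)) / cache$Tn
  # dt/dd2 = -((a+1)/(2a)) * u^(-(a+3)/2)
  a <- cache$a
  A <- Gt * (-(a + 1) / (2 * a)) * cache$u^(-(a + 3) / 2)
  gE <- 2 * (rowSums(A) * cache$E - A %*% cache$mu)
  gMu <- 2 * (colSums(A) * cache$mu - crossprod(A, cache$E))
  list(gE = gE, gMu = gMu)
}

#' Student-t soft cluster assignment
#'
#' Probability that each embedding belongs to each centroid under a Student-t
#' kernel with `df` degrees of freedom:
#' \deqn{q_{ik} \propto (1 + \|e_i - \mu_k\|^2 / \alpha)^{-(\alpha+1)/2},}
#' rows normalized to sum to 1. As \eqn{\alpha \to \infty} the kernel
#' approaches a Gaussian \eqn{\exp(-\|e_i-\mu_k\|^2/2)}.
#'
#' @param E `N x d` embedding matrix.
#' @param centroids an [init_centroids()] object (or list with `mu`, `df`).
#' @return `N x K` row-stochastic matrix of assignment probabilities.
#' @export
soft_assign <- function(E, centroids) {
  E <- as.matrix(E)
  if (ncol(E) != ncol(centroids$mu))
    stop_mixcc("embedding and centroid dimensions differ")
  soft_assign_forward(E, centroids)$q
}

#' Sharpen soft assignments into a target distribution
#'
#' The auxiliary target raises assignments to the second power and normalizes
#' by the soft cluster frequencies \eqn{f_k = \sum_i q_{ik}}:
#' \deqn{p_{ik} = \frac{q_{ik}^2 / f_k}{\sum_{k'} q_{ik'}^2 / f_{k'}},}
#' boosting high-confidence clusters while counteracting imbalance. During
#' training the target is treated as a constant (no gradient flows through it
#' unless explicitly requested).
#'
#' @param q `N x K` row-stochastic assignment matrix.
#' @return A list of class `mcc_target` with `p` (`N x K`, row-stochastic) and
#'   `f` (length-`K` soft frequencies). Empty clusters (`f_k = 0`) contribute
#'   zero with a warning.
#' @export
sharpen_targets <- function(q) {
  q <- as.matrix(q)
  f <- colSums(q)
  w <- q^2
  if (any(f <= 0)) {
    warning("cluster(s) with zero soft frequency: ",
            paste(which(f <= 0), collapse = ", "), call. = FALSE)
    nz <- f > 0
    w[, nz] <- sweep(w[, nz, drop = FALSE], 2, f[nz], "/")
    w[, !nz] <- 0
  } else {
    w <- sweep(w, 2, f, "/")
  }
  p <- w / rowSums(w)
  structure(list(p = p, f = f), class = "mcc_target")
}

# Backward through sharpening: given dL/dp, return dL/dq.
sharpen_backward <- function(q, Gp) {
  f <- colSums(q)
  w <- sweep(q^2, 2, f, "/")
  Wn <- rowSums(w)
  p <- w / Wn
  Gw <- (Gp - rowSums(Gp * p)) / Wn
  Gq <- Gw * 2 * sweep(q, 2, f, "/")
  Gf <- -colSums(Gw * sweep(q^2, 2, f^2, "/"))
  sweep(Gq, 2, Gf, "+")
}

# Rowwise KL(p || q) with the 0 log 0 = 0 convention.
kl_rows <- function(p, q) {
  if (any(q <= 0 & p > 0))
    stop_mixcc("KL divergence undefined: q has zero mass where p > 0")
  x <- ifelse(p > 0, p * (log(p) - log(q)), 0)
  rowSums(x)
}

#' Anchor clustering loss
#'
#' Kullback-Leibler loss of the clustering head. In the default
#' `anchor_to_children` mode the anchor's sharpened assignment `p =
#' sharpen(q_anchor)` is the (constant) target for the three augmented views:
#' \deqn{\mathcal{L} = \frac{1}{3}\,\mathrm{mean}_i\left[
#'   KL(p_i \| q^1_i) + KL(p_i \| q^2_i) + KL(p_i \| q^3_i)\right].}
#' `self_paired` lets each view sharpen its own target
#' (`mean KL(sharpen(q^k) || q^k)` over the three views); `single_anchor`
#' uses only the anchor (`mean KL(p || q_anchor)`).
#'
#' @param q_anchor `N x K` soft assignment of the anchor embeddings.
#' @param q1,q2,q3 soft assignments of the three views (ignored for
#'   `single_anchor`).
#' @param variant `"anchor_to_children"` (default), `"self_paired"`, or
#'   `"single_anchor"`.
#' @return A non-negative scalar loss.
#' @export
anchor_cluster_loss <- function(q_anchor, q1 = NULL, q2 = NULL, q3 = NULL,
                                variant = c("anchor_to_children",
                                            "self_paired", "single_anchor")) {
  variant <- match.arg(variant)
  q_anchor <- as.matrix(q_anchor)
  if (variant == "single_anchor") {
    p <- sharpen_targets(q_anchor)$p
    return(mean(kl_rows(p, q_anchor)))
  }
  for (qv in list(q1, q2, q3))
    if (is.null(qv) || !all(dim(as.matrix(qv)) == dim(q_anchor)))
      stop_mixcc("q1, q2, q3 must share the shape of q_anchor")
  if (variant == "anchor_to_children") {
    p <- sharpen_targets(q_anchor)$p
    mean(kl_rows(p, as.matrix(q1)) + kl_rows(p, as.matrix(q2)) +
           kl_rows(p, as.matrix(q3))) / 3
  } else {
    (mean(kl_rows(sharpen_targets(as.matrix(q1))$p, as.matrix(q1))) +
       mean(kl_rows(sharpen_targets(as.matrix(q2))$p, as.matrix(q2))) +
       mean(kl_rows(sharpen_targets(as.matrix(q3))$p, as.matrix(q3)))) / 3
  }
}
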