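#' Control parameters for model fitting
#'
#' Collects every tunable of [mcc()]. Defaults follow the method's reference
#' settings: mixing weight `lambda = 0.8`, temperature `tau = 0.5`, loss
#' balance `gamma = 10`, Student-t degrees of freedom `df = 1` (use 10 for
#' biomedical-style corpora), Adam learning rate `5e-4` for the heads and
#' centroids, batch size 400 and 2000 iterations (desk-scale runs typically
#' use 16-128 documents per batch and a few hundred iterations). The encoder
#' learning rate defaults to `NULL` = automatic: `5e-6` — a fine-tuning
#' rate — for user-supplied (typically pretrained) encoders, and `1e-3` for
#' the built-in from-scratch [reference_encoder()], which has no pretrained
#' structure to preserve and learns nothing at a fine-tuning rate.
#'
#' @param batch_size documents per mini-batch (capped at the corpus size).
#' @param iterations number of optimizer steps `L` (0 = no training: the model
#'   reduces to k-means-initialized soft assignment).
#' @param gamma weight of the clustering loss in the joint objective.
#' @param lambda fixed mixup weight; ignored when `beta_shape` is set.
#' @param beta_shape optional Beta(a, a) shape for a per-batch mixup draw.
#' @param tau contrastive temperature (> 0).
#' @param df Student-t degrees of freedom of the clustering kernel (> 0).
#' @param variant contrastive variant, `"sibling"` or `"infonce"`.
#' @param denominator denominator convention, see [contrastive_config()].
#' @param cluster_variant clustering-head mode, see [anchor_cluster_loss()].
#' @param grad_through_target also propagate gradients through the sharpened
#'   target (default `FALSE`: the target is a constant per step).
#' @param instance_weight weight of the contrastive loss (1; set 0 for a
#'   cluster-loss-only ablation).
#' @param lr_encoder Adam learning rate for the encoder parameters, or `NULL`
#'   (default) to resolve automatically as described above.
#' @param lr_heads Adam learning rate for the projection head and centroids.
#' @param aug1,aug2 [augmenter()] specifications for the two views.
#' @param encoder_dim,buckets,max_len reference-encoder settings (used when
#'   no encoder is supplied to [mcc()]).
#' @param projection_dim,hidden_dim projection-head output and hidden widths
#'   (`hidden_dim = NULL` means equal to the encoder width).
#' @param init_sample at most this many documents are used for the k-means
#'   centroid initialization.
#' @param predict_mode `"argmax_q"` (default) or `"kmeans_features"`.
#' @param seed integer seed governing every stochastic component.
#' @param verbose print progress every 100 iterations.
#' @return A list of class `mcc_control`.
#' @export
mcc_control <- function(batch_size = 400L, iterations = 2000L, gamma = 10,
                        lambda = 0.8, beta_shape = NULL, tau = 0.5, df = 1,
                        variant = c("sibling", "infonce"),
                        denominator = c("literal_all", "exclude_self",
                                        "exclude_siblings"),
                        cluster_variant = c("anchor_to_children",
                                            "self_paired", "single_anchor"),
                        grad_through_target = FALSE, instance_weight = 1,
                        lr_encoder = NULL, lr_heads = 5e-4,
                        aug1 = augmenter("word_deletion", 0.15),
                        aug2 = augmenter("char_noise", 0.10),
                        encoder_dim = 64L, buckets = 1024L, max_len = 32L,
                        projection_dim = 128L, hidden_dim = NULL,
                        init_sample = 2048L,
                        predict_mode = c("argmax_q", "kmeans_features"),
                        seed = 0L, verbose = FALSE) {
  if (batch_size < 2) stop_mixcc("'batch_size' must be at least 2")
  if (iterations < 0) stop_mixcc("'iterations' must be non-negative")
  if (gamma < 0) stop_mixcc("'gamma' must be non-negative")
  if (instance_weight < 0) stop_mixcc("'instance_weight' must be non-negative")
  if (!is.null(lr_encoder) && lr_encoder <= 0)
    stop_mixcc("'lr_encoder' must be positive (or NULL for automatic)")
  if (lr_heads <= 0) stop_mixcc("'lr_heads' must be positive")
  if (df <= 0) stop_mixcc("'df' must be positive")
  structure(list(
    batch_size = as.integer(batch_size), iterations = as.integer(iterations),
    gamma = gamma, lambda = lambda, beta_shape = beta_shape, tau = tau,
    df = df, variant = match.arg(variant),
    denominator = match.arg(denominator),
    cluster_variant = match.arg(cluster_variant),
    grad_through_target = isTRUE(grad_through_target),
    instance_weight = instance_weight,
    lr_encoder = lr_encoder, lr_heads = lr_heads,
    aug1 = aug1, aug2 = aug2,
    encoder_dim = as.integer(encoder_dim), buckets = as.integer(buckets),
    max_len = as.integer(max_len),
    projection_dim = as.integer(projection_dim),
    hidden_dim = if (!is.null(hidden_dim)) as.integer(hidden_dim),
    init_sample = as.integer(init_sample),
    predict_mode = match.arg(predict_mode),
    seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "mcc_control")
}

#' Joint training objective
#'
#' `instance + gamma * cluster`, the scalar optimized at every step.
#'
#' @param instance instance-level contrastive loss.
#' @param cluster clustering (KL) loss.
#' @param gamma balance weight.
#' @return A single number.
#' @export
total_loss <- function(instance, cluster, gamma) {
  if (!all(is.finite(c(instance, cluster, gamma))))
    stop_mixcc("non-finite loss component")
  instance + gamma * cluster
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(par) lapply(par, function(p) list(m = p * 0, v = p * 0))

adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(par)) {
    g <- grad[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(par = par, state = state)
}

# --- cluster loss with gradients -------------------------------------------

cluster_loss_grad <- function(E, E1, E2, E3, mu_set, ctl) {
  n <- nrow(E)
  c0 <- soft_assign_forward(E, mu_set)
  out <- list(gE = E * 0, gE1 = E * 0, gE2 = E * 0, gE3 = E * 0,
              gMu = mu_set$mu * 0)
  views <- list(E1, E2, E3)
  if (ctl$cluster_variant == "single_anchor") {
    p <- sharpen_targets(c0$q)$p
    out$loss <- mean(kl_rows(p, c0$q))
    Gq0 <- -(p / c0$q) / n
    if (ctl$grad_through_target) {
      Gp <- (log(pmax(p, 1e-300)) - log(c0$q) + 1) / n
      Gq0 <- Gq0 + sharpen_backward(c0$q, Gp)
    }
    bk <- soft_assign_backward(c0, Gq0)
    out$gE <- bk$gE; out$gMu <- bk$gMu
    return(out)
  }
  caches <- lapply(views, soft_assign_forward, centroids = mu_set)
  if (ctl$cluster_variant == "anchor_to_children") {
    p <- sharpen_targets(c0$q)$p
    loss <- 0
    Gp <- NULL
    for (k in 1:3) {
      qk <- caches[[k]]$q
      loss <- loss + mean(kl_rows(p, qk))
      bk <- soft_assign_backward(caches[[k]], -(p / qk) / (3 * n))
      out[[paste0("gE", k)]] <- bk$gE
      out$gMu <- out$gMu + bk$gMu
      if (ctl$grad_through_target) {
        term <- (log(pmax(p, 1e-300)) - log(qk) + 1) / (3 * n)
        Gp <- if (is.null(Gp)) term else Gp + term
      }
    }
    if (ctl$grad_through_target) {
      bk0 <- soft_assign_backward(c0, sharpen_backward(c0$q, Gp))
      out$gE <- bk0$gE
      out$gMu <- out$gMu + bk0$gMu
    }
    out$loss <- loss / 3
  } else {  # self_paired
    loss <- 0
    for (k in 1:3) {
      qk <- caches[[k]]$q
      pk <- sharpen_targets(qk)$p
      loss <- loss + mean(kl_rows(pk, qk))
      Gqk <- -(pk / qk) / (3 * n)
      if (ctl$grad_through_target) {
        Gpk <- (log(pmax(pk, 1e-300)) - log(qk) + 1) / (3 * n)
        Gqk <- Gqk + sharpen_backward(qk, Gpk)
      }
      bk <- soft_assign_backward(caches[[k]], Gqk)
      out[[paste0("gE", k)]] <- bk$gE
      out$gMu <- out$gMu + bk$gMu
    }
    out$loss <- loss / 3
  }
  out
}

# --- fitting ----------------------------------------------------------------

#' Fit a mixup contrastive clustering model
#'
#' Jointly trains a text encoder, a contrastive projection head, and a
#' Student-t clustering head on an unlabeled short-text corpus. Each step
#' samples a mini-batch, builds two augmented views and a mixed third view of
#' the embeddings, and takes one Adam step on
#' `instance_loss + gamma * cluster_loss` (the encoder at `lr_encoder`; the
#' projection head and centroids at `lr_heads`). Centroids are initialized by
#' k-means on the initial embeddings. The run is fully reproducible given
#' `control$seed`.
#'
#' @param x an [mcc_corpus()].
#' @param k number of clusters (at most the corpus size).
#' @param control an [mcc_control()] list.
#' @param encoder optional [mcc_encoder()]; defaults to the
#'   [reference_encoder()] configured by `control`.
#' @return An object of class `mcc`: list with the trained `encoder`, `head`,
#'   `centroids`, per-iteration `losses` (data frame with columns
#'   `iteration`, `total`, `instance`, `cluster`), final `assignments`
#'   (named integer vector, clusters `1..k`), plus `corpus`, `k`, `control`,
#'   `call`.
#' @seealso [predict.mcc()], [evaluate_clustering()], [synthetic_corpus()]
#' @examples
#' corp <- synthetic_corpus(2, 10, vocab_per_topic = 20, doc_len = 8, seed = 1)
#' fit <- mcc(corp, k = 2, control = mcc_control(batch_size = 8, iterations = 20))
#' table(fitted(fit), corp$label)
#' @export
mcc <- function(x, k, control = mcc_control(), encoder = NULL) {
  stopifnot(inherits(x, "mcc_corpus"), inherits(control, "mcc_control"))
  n <- length(x$id)
  k <- as.integer(k)
  if (k < 1 || k > n) stop_mixcc("'k' must be between 1 and the corpus size")
  if (n < 2) stop_mixcc("corpus must contain at least 2 documents")
  ctl <- control
  if (is.null(encoder))
    encoder <- reference_encoder(ctl$encoder_dim, ctl$buckets, ctl$max_len)
  stopifnot(inherits(encoder, "mcc_encoder"))
  # fine-tuning rate for supplied (pretrained) encoders, training rate for
  # the built-in from-scratch reference encoder
  ctl$lr_encoder <- ctl$lr_encoder %||%
    (if (startsWith(encoder$kind, "reference")) 1e-3 else 5e-6)
  enc_par <- encoder$params
  if (is.null(enc_par)) {
    if (!is.function(encoder$init))
      stop_mixcc("encoder has no parameters and no init function")
    enc_par <- encoder$init(derive_seed(ctl$seed, 1L))
  }
  head <- projection_head(encoder$dim,
                          hidden_dim = ctl$hidden_dim %||% encoder$dim,
                          out_dim = ctl$projection_dim, normalize = TRUE,
                          seed = derive_seed(ctl$seed, 2L))
  trunc_toks <- function(tl)
    lapply(tl, function(t) if (length(t) > ctl$max_len) t[seq_len(ctl$max_len)] else t)
  all_tokens <- trunc_toks(x$tokens)

  # centroid initialization on initial encoder outputs (optionally subsampled)
  E_init <- encoder$forward(enc_par, all_tokens)
  init_idx <- if (n > ctl$init_sample)
    with_seed(derive_seed(ctl$seed, 3L), sample.int(n, ctl$init_sample))
  else seq_len(n)
  cent <- init_centroids(E_init[init_idx, , drop = FALSE], k,
                         seed = derive_seed(ctl$seed, 4L), df = ctl$df)
  mu <- cent$mu

  ccfg <- contrastive_config(ctl$tau, ctl$variant, ctl$denominator)
  mixcfg <- mixup_config(lambda = if (is.null(ctl$beta_shape)) ctl$lambda,
                         beta_shape = ctl$beta_shape,
                         seed = derive_seed(ctl$seed, 5L))

  head_par <- head[c("W1", "b1", "W2", "b2")]
  head_par$mu <- mu
  st_enc <- if (encoder$trainable) adam_init(enc_par)
  st_head <- adam_init(head_par)

  L <- ctl$iterations
  losses <- matrix(NA_real_, nrow = L, ncol = 3,
                   dimnames = list(NULL, c("total", "instance", "cluster")))
  bs <- min(ctl$batch_size, n)
  ord <- integer(0); pos <- 1L; epoch <- 0L
  iw <- ctl$instance_weight

  for (it in seq_len(L)) {
    if (pos + 1L > length(ord)) {  # need >= 2 docs; otherwise start new epoch
      epoch <- epoch + 1L
      ord <- with_seed(derive_seed(ctl$seed, 10L, epoch), sample.int(n))
      pos <- 1L
    }
    idx <- ord[pos:min(pos + bs - 1L, length(ord))]
    pos <- pos + length(idx)
    nb <- length(idx)

    u1 <- ctl$aug1; u1$seed <- derive_seed(ctl$seed, 20L, it)
    u2 <- ctl$aug2; u2$seed <- derive_seed(ctl$seed, 21L, it)
    vp <- make_view_pair(subset_corpus(x, idx), u1, u2, indices = idx)

    E  <- encoder$forward(enc_par, trunc_toks(vp$original))
    E1 <- encoder$forward(enc_par, trunc_toks(vp$view1))
    E2 <- encoder$forward(enc_par, trunc_toks(vp$view2))
    lam <- draw_lambda(mixcfg, it)
    E3 <- lam * E + ((1 - lam) / 2) * (E1 + E2)

    f1 <- project_forward(head, E1)
    f2 <- project_forward(head, E2)
    f3 <- project_forward(head, E3)
    inst <- instance_loss_impl(list(Z1 = f1$Z, Z2 = f2$Z, Z3 = f3$Z), ccfg,
                               want_grad = iw > 0)

    mu_set <- list(mu = head_par$mu, df = ctl$df, k = k)
    clu <- cluster_loss_grad(E, E1, E2, E3, mu_set, ctl)

    tot <- iw * inst$loss + ctl$gamma * clu$loss
    if (!is.finite(tot))
      stop_mixcc(sprintf(
        "non-finite loss at iteration %d (instance = %g, cluster = %g)",
        it, inst$loss, clu$loss))
    losses[it, ] <- c(tot, inst$loss, clu$loss)

    # backward: projection head (contrastive branch)
    hg <- list(W1 = head$W1 * 0, b1 = head$b1 * 0,
               W2 = head$W2 * 0, b2 = head$b2 * 0)
    gE1p <- gE2p <- gE3p <- E * 0
    if (iw > 0) {
      b1p <- project_backward(head, f1$cache, iw * inst$gZ1)
      b2p <- project_backward(head, f2$cache, iw * inst$gZ2)
      b3p <- project_backward(head, f3$cache, iw * inst$gZ3)
      for (nm in names(hg))
        hg[[nm]] <- b1p$grads[[nm]] + b2p$grads[[nm]] + b3p$grads[[nm]]
      gE1p <- b1p$gE; gE2p <- b2p$gE; gE3p <- b3p$gE
    }
    g <- ctl$gamma
    gE3_tot <- gE3p + g * clu$gE3
    gE1_tot <- gE1p + g * clu$gE1 + ((1 - lam) / 2) * gE3_tot
    gE2_tot <- gE2p + g * clu$gE2 + ((1 - lam) / 2) * gE3_tot
    gE0_tot <- lam * gE3_tot + g * clu$gE

    hg$mu <- g * clu$gMu
    up <- adam_step(head_par, hg, st_head, ctl$lr_heads, it)
    head_par <- up$par; st_head <- up$state
    head$W1 <- head_par$W1; head$b1 <- head_par$b1
    head$W2 <- head_par$W2; head$b2 <- head_par$b2

    if (encoder$trainable) {
      ge0 <- encoder$backward(enc_par, trunc_toks(vp$original), gE0_tot)
      ge1 <- encoder$backward(enc_par, trunc_toks(vp$view1), gE1_tot)
      ge2 <- encoder$backward(enc_par, trunc_toks(vp$view2), gE2_tot)
      genc <- ge0
      for (nm in names(genc)) genc[[nm]] <- ge0[[nm]] + ge1[[nm]] + ge2[[nm]]
      upe <- adam_step(enc_par, genc, st_enc, ctl$lr_encoder, it)
      enc_par <- upe$par; st_enc <- upe$state
    }
    if (ctl$verbose && it %% 100L == 0L)
      message(sprintf("iter %d/%d  total %.4f  instance %.4f  cluster %.4f",
                      it, L, tot, inst$loss, clu$loss))
  }

  encoder$params <- enc_par
  cent$mu <- head_par$mu
  fit <- structure(list(call = match.call(), corpus = x, k = k, control = ctl,
                        encoder = encoder, head = head, centroids = cent,
                        losses = data.frame(iteration = seq_len(L),
                                            total = losses[, 1],
                                            instance = losses[, 2],
                                            cluster = losses[, 3]),
                        assignments = NULL),
                   class = "mcc")
  fit$assignments <- predict(fit, mode = ctl$predict_mode,
                             seed = derive_seed(ctl$seed, 30L))
  fit
}

# Anchor embeddings of a corpus under the fitted encoder.
anchor_embeddings <- function(object, corpus) {
  ml <- object$control$max_len
  toks <- lapply(corpus$tokens,
                 function(t) if (length(t) > ml) t[seq_len(ml)] else t)
  object$encoder$forward(object$encoder$params, toks)
}

#' Predict cluster assignments
#'
#' Assigns documents to clusters with the fitted model, either by the argmax
#' of the Student-t soft assignment against the trained centroids
#' (`"argmax_q"`, the default) or by a fresh seeded k-means on the final
#' anchor embeddings (`"kmeans_features"`).
#'
#' @param object a fitted [mcc()] model.
#' @param newdata an [mcc_corpus()]; defaults to the training corpus.
#' @param mode `"argmax_q"` or `"kmeans_features"`.
#' @param seed seed for the `"kmeans_features"` mode.
#' @param ... unused.
#' @return Named integer vector of cluster assignments in `1..k`.
#' @export
predict.mcc <- function(object, newdata = NULL,
                        mode = c("argmax_q", "kmeans_features"),
                        seed = NULL, ...) {
  mode <- match.arg(mode[1], c("argmax_q", "kmeans_features"))
  corpus <- newdata %||% object$corpus
  stopifnot(inherits(corpus, "mcc_corpus"))
  if (length(corpus$id) == 0) stop_mixcc("empty corpus")
  E <- anchor_embeddings(object, corpus)
  if (mode == "argmax_q") {
    q <- soft_assign(E, object$centroids)
    cl <- max.col(q, ties.method = "first")
  } else {
    seed <- seed %||% derive_seed(object$control$seed, 31L)
    cl <- with_seed(seed, {
      centers <- kmeanspp_centers(E, object$k)
      if (object$k == 1) rep(1L, nrow(E)) else
        suppressWarnings(stats::kmeans(E, centers = centers, iter.max = 300L,
                                       algorithm = "Lloyd"))$cluster
    })
  }
  stats::setNames(as.integer(cl), corpus$id)
}

#' @export
fitted.mcc <- function(object, ...) object$assignments

#' @export
coef.mcc <- function(object, ...) object$centroids$mu

#' @export
print.mcc <- function(x, ...) {
  n <- length(x$corpus$id)
  cat(sprintf("Mixup contrastive clustering fit: %d documents, k = %d\n",
              n, x$k))
  cat(sprintf("  encoder: %s; %s contrastive loss (tau = %g), gamma = %g\n",
              x$encoder$kind, x$control$variant, x$control$tau,
              x$control$gamma))
  L <- nrow(x$losses)
  if (L > 0)
    cat(sprintf("  %d iterations; final loss %.4f (instance %.4f, cluster %.4f)\n",
                L, x$losses$total[L], x$losses$instance[L],
                x$losses$cluster[L]))
  else cat("  no training iterations (k-means initialization only)\n")
  cat("  cluster sizes:",
      paste(tabulate(x$assignments, nbins = x$k), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.mcc <- function(object, ...) {
  out <- list(k = object$k, n = length(object$corpus$id),
              iterations = nrow(object$losses),
              sizes = tabulate(object$assignments, nbins = object$k),
              final_losses = if (nrow(object$losses) > 0)
                unlist(object$losses[nrow(object$losses),
                                     c("total", "instance", "cluster")]),
              control = object$control,
              eval = if (!is.null(object$corpus$label))
                evaluate_clustering(object$assignments, object$corpus))
  class(out) <- "summary.mcc"
  out
}

#' @export
print.summary.mcc <- function(x, ...) {
  cat(sprintf("Mixup contrastive clustering: %d documents in k = %d clusters\n",
              x$n, x$k))
  cat("  cluster sizes:", paste(x$sizes, collapse = " "), "\n")
  if (!is.null(x$final_losses))
    cat(sprintf("  after %d iterations: total %.4f, instance %.4f, cluster %.4f\n",
                x$iterations, x$final_losses["total"],
                x$final_losses["instance"], x$final_losses["cluster"]))
  if (!is.null(x$eval))
    cat(sprintf("  against gold labels: ACC %.4f, NMI %.4f\n",
                x$eval$acc, x$eval$nmi))
  invisible(x)
}

#' Plot the training loss trace
#'
#' Line plot of the total, instance (contrastive), and clustering loss
#' against the iteration number.
#'
#' @param x a fitted [mcc()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mcc <- function(x, ...) {
  if (nrow(x$losses) == 0) stop_mixcc("model was fitted with 0 iterations")
  graphics::matplot(x$losses$iteration,
                    cbind(x$losses$total, x$losses$instance, x$losses$cluster),
                    type = "l", lty = 1, col = c("black", "steelblue", "firebrick"),
                    xlab = "iteration", ylab = "loss", ...)
  graphics::legend("topright", c("total", "instance", "cluster"),
                   lty = 1, col = c("black", "steelblue", "firebrick"),
                   bty = "n")
  invisible(x)
}
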