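#' Contrastive loss configuration
#'
#' Settings for the instance-level objective over the three projected views.
#' `variant` selects standard two-sided InfoNCE or the simplified sibling loss
#' whose denominator is anchored at the third (sibling) view of the pair.
#' `denominator` controls which of the `3N` similarity terms enter the
#' normalizer:
#' \describe{
#'   \item{`literal_all`}{all `3N` terms, including the denominator anchor's
#'     own self- and sibling-similarities (the printed form of the loss).}
#'   \item{`exclude_self`}{drops only the anchor's self-similarity term.}
#'   \item{`exclude_siblings`}{drops all three same-index terms and places the
#'     positive-pair similarity itself in the denominator, i.e. the positive
#'     against exactly `3N - 3` cross-index negatives.}
#' }
#'
#' @param tau temperature (> 0) dividing cosine similarities; default 0.5.
#' @param variant `"sibling"` (default) or `"infonce"`.
#' @param denominator `"literal_all"` (default), `"exclude_self"`, or
#'   `"exclude_siblings"`.
#' @return An object of class `mcc_contrastive`.
#' @export
contrastive_config <- function(tau = 0.5,
                               variant = c("sibling", "infonce"),
                               denominator = c("literal_all", "exclude_self",
                                               "exclude_siblings")) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    stop_mixcc("'tau' must be a positive number")
  structure(list(tau = tau, variant = match.arg(variant),
                 denominator = match.arg(denominator)),
            class = "mcc_contrastive")
}

#' Cosine similarity
#'
#' `dot(a, b) / (||a|| ||b||)`; errors on zero vectors.
#'
#' @param a,b numeric vectors of equal length.
#' @return A number in \code{[-1, 1]}.
#' @examples
#' cosine_sim(c(1, 1), c(1, 0))  # 1/sqrt(2)
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-300 || nb < 1e-300) stop_mixcc("cosine similarity of a zero vector")
  sum(a * b) / (na * nb)
}

check_quad <- function(quad) {
  if (!all(c("Z1", "Z2", "Z3") %in% names(quad)))
    stop_mixcc("projected quad must contain matrices Z1, Z2, Z3")
  n <- nrow(quad$Z1)
  if (nrow(quad$Z2) != n || nrow(quad$Z3) != n)
    stop_mixcc("Z1, Z2, Z3 must have equal row counts")
  if (n < 2) stop_mixcc("contrastive losses require N >= 2 (no negatives exist)")
  n
}

# Stacked similarity logits: row/col index (k-1)*N + i for view k, doc i.
stack_logits <- function(quad, tau) tcrossprod(rbind(quad$Z1, quad$Z2, quad$Z3)) / tau

# Denominator term for anchor row `r` (doc i) with positive logit `pos`:
# value of log-sum-exp plus, if requested, softmax weights for the gradient.
denom_logsumexp <- function(Grow, r, i, n, pos, denominator) {
  sib <- c(i, i + n, i + 2L * n)
  extra <- NULL
  keep <- rep(TRUE, 3L * n)
  if (denominator == "exclude_self") keep[r] <- FALSE
  if (denominator == "exclude_siblings") { keep[sib] <- FALSE; extra <- pos }
  logits <- c(Grow[keep], extra)
  lse <- logsumexp(logits)
  list(lse = lse, keep = keep, extra = extra)
}

# One per-pair loss term; optionally accumulates logit-space coefficients
# into the environment `acc` (matrix C) for the analytic gradient.
pair_term <- function(G, n, i, a, b, cfg, acc = NULL) {
  ia <- i + (a - 1L) * n; ib <- i + (b - 1L) * n
  add_denom <- function(r, pos, w, ia, ib) {
    d <- denom_logsumexp(G[r, ], r, i, n, pos, cfg$denominator)
    if (!is.null(acc)) {
      soft <- exp(c(G[r, d$keep], d$extra) - d$lse)
      nk <- sum(d$keep)
      acc$C[r, which(d$keep)] <- acc$C[r, which(d$keep)] + w * soft[seq_len(nk)]
      if (!is.null(d$extra))
        acc$C[ia, ib] <- acc$C[ia, ib] + w * soft[nk + 1L]
      acc$C[ia, ib] <- acc$C[ia, ib] - w
    }
    d$lse
  }
  if (cfg$variant == "sibling") {
    cc <- 6L - a - b
    r <- i + (cc - 1L) * n
    pos <- G[ia, ib]
    lse <- add_denom(r, pos, 1, ia, ib)
    -pos + lse
  } else {
    pos <- G[ia, ib]
    l1 <- add_denom(ia, pos, 0.5, ia, ib)
    l2 <- add_denom(ib, pos, 0.5, ib, ia)
    0.5 * (-pos + l1) + 0.5 * (-pos + l2)
  }
}

#' Per-pair InfoNCE loss
#'
#' Symmetric two-term InfoNCE for document `i` and view pair `pair`: minus the
#' mean of the two log-softmax terms of the positive similarity against the
#' configured denominator, each anchored at one member of the pair.
#'
#' @param quad list with unit-row matrices `Z1`, `Z2`, `Z3` (`N >= 2`).
#' @param i document index in `1..N`.
#' @param pair integer pair of view indices: `c(1,2)`, `c(1,3)` or `c(2,3)`.
#' @param cfg an [contrastive_config()] (the `variant` field is ignored here).
#' @return A single loss value.
#' @export
infonce_pair_loss <- function(quad, i, pair, cfg = contrastive_config()) {
  n <- check_quad(quad)
  cfg$variant <- "infonce"
  pair_term(stack_logits(quad, cfg$tau), n, as.integer(i),
            as.integer(pair[1]), as.integer(pair[2]), cfg)
}

#' Per-pair sibling contrastive loss
#'
#' Simplified one-term loss for document `i` and view pair `pair`: the
#' positive similarity of the pair, normalized by denominator terms anchored
#' at the third (sibling) view of the same document.
#'
#' @inheritParams infonce_pair_loss
#' @return A single loss value.
#' @export
sibling_pair_loss <- function(quad, i, pair, cfg = contrastive_config()) {
  n <- check_quad(quad)
  cfg$variant <- "sibling"
  pair_term(stack_logits(quad, cfg$tau), n, as.integer(i),
            as.integer(pair[1]), as.integer(pair[2]), cfg)
}

.pairs3 <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))

# Loss and (optionally) gradients w.r.t. Z1, Z2, Z3.
instance_loss_impl <- function(quad, cfg, want_grad = FALSE) {
  n <- check_quad(quad)
  S <- rbind(quad$Z1, quad$Z2, quad$Z3)
  G <- tcrossprod(S) / cfg$tau
  acc <- NULL
  if (want_grad) {
    acc <- new.env(parent = emptyenv())
    acc$C <- matrix(0, 3L * n, 3L * n)
  }
  total <- 0
  w <- 1 / (3 * n)
  for (i in seq_len(n))
    for (p in 1:3)
      total <- total + pair_term(G, n, i, .pairs3[p, 1], .pairs3[p, 2], cfg, acc)
  loss <- w * total
  if (!want_grad) return(list(loss = loss))
  gS <- (acc$C + t(acc$C)) %*% S * (w / cfg$tau)
  list(loss = loss,
       gZ1 = gS[seq_len(n), , drop = FALSE],
       gZ2 = gS[n + seq_len(n), , drop = FALSE],
       gZ3 = gS[2L * n + seq_len(n), , drop = FALSE])
}

#' Total instance-level contrastive loss
#'
#' Mean of the configured per-pair loss over all documents and the three view
#' pairs (1,2), (1,3), (2,3), scaled by `1/(3N)`.
#'
#' @param quad list with unit-row matrices `Z1`, `Z2`, `Z3` (`N >= 2`), e.g.
#'   from [project_batch()].
#' @param cfg an [contrastive_config()].
#' @return A single loss value.
#' @export
instance_loss_total <- function(quad, cfg = contrastive_config()) {
  instance_loss_impl(quad, cfg, want_grad = FALSE)$loss
}
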