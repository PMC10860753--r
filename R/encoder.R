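#' Define a pluggable text encoder
#'
#' An encoder maps a batch of token sequences to an `N x dim` matrix of
#' document embeddings. The fitting routine only relies on this contract, so
#' any sentence encoder (including wrappers around pretrained transformers)
#' can be supplied; a trainable encoder additionally provides `init` and
#' `backward` so the optimizer can update its parameters.
#'
#' @param dim embedding width.
#' @param forward `function(params, tokens_list)` returning an `N x dim`
#'   matrix (finite values; one row per input document).
#' @param init optional `function(seed)` returning the initial parameter list.
#' @param backward optional `function(params, tokens_list, grad_out)`
#'   returning gradients with the same shapes as `params`; when absent the
#'   encoder is treated as frozen.
#' @param kind label for printing.
#' @param max_len token sequences are truncated to this many leading tokens
#'   before encoding.
#' @return An object of class `mcc_encoder`.
#' @seealso [reference_encoder()]
#' @export
mcc_encoder <- function(dim, forward, init = NULL, backward = NULL,
                        kind = "plugin", max_len = 32L) {
  stopifnot(is.function(forward), dim >= 1)
  structure(list(kind = kind, dim = as.integer(dim),
                 max_len = as.integer(max_len),
                 forward = forward, init = init, backward = backward,
                 trainable = is.function(backward) && is.function(init),
                 params = NULL),
            class = "mcc_encoder")
}

#' @export
print.mcc_encoder <- function(x, ...) {
  cat(sprintf("<mcc_encoder> %s, dim %d%s\n", x$kind, x$dim,
              if (x$trainable) ", trainable" else ", frozen"))
  invisible(x)
}

# Deterministic polynomial string hash into 1..buckets (feature hashing).
# Kept exact in double arithmetic: intermediate values stay below 2^53.
hash_bucket <- function(token, buckets) {
  cp <- utf8ToInt(token)
  h <- 0
  for (b in cp) h <- (h * 131 + b) %% 1000000007
  as.integer(h %% buckets) + 1L
}

# Memoized bucket lookup for a batch of token lists.
bucket_indices <- function(tokens_list, buckets, cache) {
  lapply(tokens_list, function(toks) {
    vapply(toks, function(tk) {
      hit <- cache[[tk]]
      if (is.null(hit)) {
        hit <- hash_bucket(tk, buckets)
        cache[[tk]] <- hit
      }
      hit
    }, integer(1), USE.NAMES = FALSE)
  })
}

#' Reference hashed-embedding encoder
#'
#' The built-in trainable encoder used for desk-scale experiments: a token
#' embedding table addressed by feature hashing (a deterministic string hash
#' into `buckets` rows) followed by mean pooling over the document's tokens.
#' Hashing gives every token — including tokens first created by character
#' noise at training time — a stable embedding row without any vocabulary
#' bookkeeping. Parameters are the `buckets x dim` table, initialized
#' standard normal so that document embeddings (and their pairwise distances)
#' live on the order-one scale the head learning rates assume.
#'
#' @param dim embedding width (default 64).
#' @param buckets number of hash buckets (default 1024).
#' @param max_len leading tokens kept per document (default 32).
#' @return A trainable [mcc_encoder()].
#' @export
reference_encoder <- function(dim = 64L, buckets = 1024L, max_len = 32L) {
  dim <- as.integer(dim); buckets <- as.integer(buckets)
  cache <- new.env(parent = emptyenv())
  trunc_tokens <- function(tokens_list, max_len)
    lapply(tokens_list, function(t) if (length(t) > max_len) t[seq_len(max_len)] else t)
  forward <- function(params, tokens_list) {
    tokens_list <- trunc_tokens(tokens_list, max_len)
    idx <- bucket_indices(tokens_list, buckets, cache)
    W <- params$W
    E <- matrix(0, nrow = length(idx), ncol = dim)
    for (i in seq_along(idx))
      E[i, ] <- .colMeans(W[idx[[i]], , drop = FALSE], length(idx[[i]]), dim)
    E
  }
  backward <- function(params, tokens_list, grad_out) {
    tokens_list <- trunc_tokens(tokens_list, max_len)
    idx <- bucket_indices(tokens_list, buckets, cache)
    lens <- lengths(idx)
    rows <- unlist(idx, use.names = FALSE)
    gext <- grad_out[rep.int(seq_along(idx), lens), , drop = FALSE] /
      rep.int(lens, lens)
    part <- rowsum(gext, rows)
    gW <- matrix(0, nrow = buckets, ncol = dim)
    gW[as.integer(rownames(part)), ] <- part
    list(W = gW)
  }
  init <- function(seed) {
    with_seed(seed, list(W = matrix(stats::rnorm(buckets * dim),
                                    nrow = buckets, ncol = dim)))
  }
  enc <- mcc_encoder(dim, forward, init = init, backward = backward,
                     kind = sprintf("reference (hashed, %d buckets)", buckets),
                     max_len = max_len)
  enc
}

#' Encode the three aligned batches of a view pair
#'
#' Runs the encoder over the original batch and both augmented views with the
#' same parameters, yielding the index-aligned embedding matrices `E`, `E1`,
#' `E2`.
#'
#' @param encoder an [mcc_encoder()] with non-`NULL` `params` (set
#'   `encoder$params <- encoder$init(seed)` for a fresh trainable encoder).
#' @param view_pair an `mcc_view_pair` from [make_view_pair()].
#' @return A list of class `mcc_quad` with matrices `E`, `E1`, `E2` (rows
#'   aligned with `view_pair`).
#' @export
encode_batch <- function(encoder, view_pair) {
  stopifnot(inherits(encoder, "mcc_encoder"), inherits(view_pair, "mcc_view_pair"))
  if (is.null(encoder$params) && is.function(encoder$init))
    stop_mixcc("encoder parameters not initialized; set encoder$params <- encoder$init(seed)")
  enc1 <- function(tl) {
    E <- encoder$forward(encoder$params, tl)
    bad <- which(!apply(is.finite(E), 1, all))
    if (length(bad) > 0)
      stop_mixcc("non-finite encoder output at row(s): ",
                 paste(bad, collapse = ", "))
    E
  }
  structure(list(E = enc1(view_pair$original),
                 E1 = enc1(view_pair$view1),
                 E2 = enc1(view_pair$view2)),
            class = "mcc_quad")
}

#' Mixup configuration
#'
#' The mixing weight of the virtual third view: either a fixed
#' \eqn{\lambda \in [0,1]} or a per-batch draw from Beta(`beta_shape`,
#' `beta_shape`). Exactly one of the two must be given.
#'
#' @param lambda fixed mixing weight in \code{[0, 1]} (default 0.8).
#' @param beta_shape positive shape for a per-batch Beta(a, a) draw, or `NULL`.
#' @param seed integer seed for Beta draws.
#' @return An object of class `mcc_mixup`.
#' @export
mixup_config <- function(lambda = 0.8, beta_shape = NULL, seed = 0L) {
  if (!is.null(beta_shape)) {
    if (beta_shape <= 0) stop_mixcc("'beta_shape' must be positive")
    lambda <- NULL
  } else {
    check_prob(lambda, "lambda")
  }
  structure(list(lambda = lambda, beta_shape = beta_shape,
                 seed = as.integer(seed)),
            class = "mcc_mixup")
}

# Resolve the batch mixing weight (fixed, or one Beta draw per batch).
draw_lambda <- function(cfg, draw_index = 0L) {
  if (!is.null(cfg$lambda)) return(cfg$lambda)
  with_seed(derive_seed(cfg$seed, draw_index),
            stats::rbeta(1, cfg$beta_shape, cfg$beta_shape))
}

#' Build the mixed third view
#'
#' Representation-level mixup: rowwise
#' \deqn{e^3_i = \lambda e_i + \frac{1-\lambda}{2} e^1_i +
#'       \frac{1-\lambda}{2} e^2_i,}
#' a convex combination of the anchor and the two augmented views (the
#' coefficients sum to 1). With `beta_shape` set, one \eqn{\lambda} is drawn
#' per call.
#'
#' @param quad an `mcc_quad` with `E`, `E1`, `E2` (from [encode_batch()]).
#' @param cfg an [mixup_config()], or a single numeric \eqn{\lambda}.
#' @param draw_index integer distinguishing successive Beta draws.
#' @return The quad with `E3` added and the used weight in
#'   `attr(, "lambda")`.
#' @export
mix_representations <- function(quad, cfg = mixup_config(), draw_index = 0L) {
  stopifnot(!is.null(quad$E), !is.null(quad$E1), !is.null(quad$E2))
  if (is.numeric(cfg)) cfg <- mixup_config(lambda = cfg)
  lam <- draw_lambda(cfg, draw_index)
  if (lam < 0 || lam > 1) stop_mixcc("mixing weight must lie in [0, 1]")
  quad$E3 <- lam * quad$E + ((1 - lam) / 2) * (quad$E1 + quad$E2)
  attr(quad, "lambda") <- lam
  quad
}

#' Projection head for the contrastive branch
#'
#' A two-layer perceptron with rectified-linear activation,
#' `z = normalize(W2 relu(W1 e + b1) + b2)`, mapping encoder space to the
#' low-dimensional unit sphere on which cosine similarities are computed.
#' Weights use He-style initialization; biases start at zero.
#'
#' @param in_dim encoder width `d`.
#' @param hidden_dim hidden width (default `in_dim`).
#' @param out_dim output width `d'` (default 128).
#' @param normalize unit-normalize output rows (default `TRUE`; the
#'   contrastive loss assumes it).
#' @param seed integer seed for initialization.
#' @return An object of class `mcc_projection`.
#' @export
projection_head <- function(in_dim, hidden_dim = in_dim, out_dim = 128L,
                            normalize = TRUE, seed = 0L) {
  stopifnot(in_dim >= 1, hidden_dim >= 1, out_dim >= 1)
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(in_dim * hidden_dim, sd = sqrt(2 / in_dim)),
                 nrow = in_dim)
    W2 <- matrix(stats::rnorm(hidden_dim * out_dim, sd = sqrt(2 / hidden_dim)),
                 nrow = hidden_dim)
    structure(list(W1 = W1, b1 = numeric(hidden_dim),
                   W2 = W2, b2 = numeric(out_dim),
                   in_dim = as.integer(in_dim),
                   hidden_dim = as.integer(hidden_dim),
                   out_dim = as.integer(out_dim),
                   normalize = isTRUE(normalize)),
              class = "mcc_projection")
  })
}

# Forward pass for one matrix; keeps the cache needed by the backward pass.
project_forward <- function(head, E) {
  A <- sweep(E %*% head$W1, 2, head$b1, "+")
  H <- pmax(A, 0)
  Y <- sweep(H %*% head$W2, 2, head$b2, "+")
  if (head$normalize) {
    nrm <- sqrt(rowSums(Y^2))
    if (any(nrm < 1e-12))
      stop_mixcc("zero vector reached normalization in the projection head ",
                 "(degenerate parameters) at row(s): ",
                 paste(which(nrm < 1e-12), collapse = ", "))
    Z <- Y / nrm
  } else {
    nrm <- rep(1, nrow(Y)); Z <- Y
  }
  list(Z = Z, cache = list(E = E, H = H, Z = Z, nrm = nrm))
}

# Backward pass: returns gradient w.r.t. inputs and head parameters.
project_backward <- function(head, cache, gZ) {
  if (head$normalize) {
    gY <- (gZ - cache$Z * rowSums(gZ * cache$Z)) / cache$nrm
  } else gY <- gZ
  gW2 <- crossprod(cache$H, gY)
  gb2 <- colSums(gY)
  gH <- gY %*% t(head$W2)
  gA <- gH * (cache$H > 0)
  gW1 <- crossprod(cache$E, gA)
  gb1 <- colSums(gA)
  gE <- gA %*% t(head$W1)
  list(gE = gE, grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

#' Project the three views for the contrastive loss
#'
#' Applies the projection head to `E1`, `E2`, `E3`, returning the
#' unit-normalized projections used by the instance-level objective (the
#' anchor embedding `E` is consumed by the clustering head, not projected).
#'
#' @param head an [projection_head()].
#' @param quad an `mcc_quad` containing `E1`, `E2`, `E3`.
#' @return A list of class `mcc_projected` with matrices `Z1`, `Z2`, `Z3`.
#' @export
project_batch <- function(head, quad) {
  stopifnot(inherits(head, "mcc_projection"))
  if (is.null(quad$E3))
    stop_mixcc("quad has no mixed view E3; call mix_representations() first")
  if (ncol(quad$E1) != head$in_dim)
    stop_mixcc(sprintf("projection head expects %d input dims, got %d",
                       head$in_dim, ncol(quad$E1)))
  structure(list(Z1 = project_forward(head, quad$E1)$Z,
                 Z2 = project_forward(head, quad$E2)$Z,
                 Z3 = project_forward(head, quad$E3)$Z),
            class = "mcc_projected")
}
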