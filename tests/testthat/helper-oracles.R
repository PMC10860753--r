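# Independent oracles used across the suite. These deliberately re-derive
# every quantity with plain loops and textbook formulas, sharing no code with
# the package internals they check.

oracle_cos <- function(a, b) sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)))

# Brute-force per-pair contrastive loss over a list of three N x d matrices.
oracle_pair_loss <- function(Z, i, pair, tau, variant, denominator) {
  N <- nrow(Z[[1]])
  a <- pair[1]; b <- pair[2]
  pos <- oracle_cos(Z[[a]][i, ], Z[[b]][i, ])
  denom <- function(anchor_vec, anchor_view) {
    s <- 0
    for (j in seq_len(N)) {
      for (k in 1:3) {
        if (denominator == "exclude_self" && j == i && k == anchor_view) next
        if (denominator == "exclude_siblings" && j == i) next
        s <- s + exp(oracle_cos(anchor_vec, Z[[k]][j, ]) / tau)
      }
    }
    if (denominator == "exclude_siblings") s <- s + exp(pos / tau)
    s
  }
  if (variant == "sibling") {
    cc <- setdiff(1:3, pair)
    -log(exp(pos / tau) / denom(Z[[cc]][i, ], cc))
  } else {
    0.5 * (-log(exp(pos / tau) / denom(Z[[a]][i, ], a)) +
             -log(exp(pos / tau) / denom(Z[[b]][i, ], b)))
  }
}

oracle_total_loss <- function(Z, tau, variant, denominator) {
  N <- nrow(Z[[1]])
  tot <- 0
  for (i in seq_len(N))
    for (pr in list(c(1, 2), c(1, 3), c(2, 3)))
      tot <- tot + oracle_pair_loss(Z, i, pr, tau, variant, denominator)
  tot / (3 * N)
}

# Random projected quad with unit-norm rows.
random_quad <- function(n, d, seed) {
  set.seed(seed)
  one <- function() {
    m <- matrix(rnorm(n * d), n)
    m / sqrt(rowSums(m^2))
  }
  list(Z1 = one(), Z2 = one(), Z3 = one())
}

# Central finite differences of a scalar function of a matrix/vector.
num_grad <- function(f, X, h = 1e-6) {
  G <- X
  for (i in seq_along(X)) {
    xp <- X; xp[i] <- xp[i] + h
    xm <- X; xm[i] <- xm[i] - h
    G[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  G
}

# Exhaustive-permutation clustering accuracy (feasible for <= 6 clusters).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

brute_force_acc <- function(pred, gold) {
  pu <- unique(pred); gu <- unique(gold)
  m <- max(length(pu), length(gu))
  best <- 0
  for (perm in all_perms(seq_len(m))) {
    matched <- 0
    for (j in seq_along(pu)) {
      g <- perm[j]
      if (g <= length(gu))
        matched <- matched + sum(pred == pu[j] & gold == gu[g])
    }
    best <- max(best, matched)
  }
  best / length(pred)
}
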