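test_that("k-means initialization recovers blob structure and edge cases", {
  set.seed(1)
  blob <- rbind(matrix(rnorm(40, 0, 0.1), 20),
                matrix(rnorm(40, 10, 0.1), 20))
  cent <- init_centroids(blob, 2, seed = 3)
  mu <- cent$mu[order(cent$mu[, 1]), ]
  expect_lt(max(abs(mu[1, ] - colMeans(blob[1:20, ]))), 0.5)
  expect_lt(max(abs(mu[2, ] - colMeans(blob[21:40, ]))), 0.5)
  # K = M: every point its own centroid; K = 1: the grand mean
  x <- matrix(rnorm(12), 4)
  expect_equal(sort(init_centroids(x, 4, seed = 1)$mu[, 1]), sort(x[, 1]))
  expect_equal(init_centroids(x, 1, seed = 1)$mu[1, ], colMeans(x))
  expect_error(init_centroids(x, 5, seed = 1), "at least")
  dupl <- x[c(1, 1, 2, 2), ]
  expect_error(init_centroids(dupl, 3, seed = 1), "distinct")
  expect_identical(init_centroids(blob, 2, seed = 9),
                   init_centroids(blob, 2, seed = 9))
})

test_that("soft assignment matches the Student-t kernel by hand", {
  # K = 1: all mass on the single cluster
  e <- matrix(rnorm(10), 5)
  q1 <- soft_assign(e, list(mu = matrix(0, 1, 2), df = 1))
  expect_equal(as.vector(q1), rep(1, 5))
  # equidistant point splits evenly
  qeq <- soft_assign(matrix(c(0.5, 1), 1),
                     list(mu = rbind(c(0, 0), c(1, 0)), df = 2))
  expect_equal(as.vector(qeq), c(0.5, 0.5), tolerance = 1e-12)
  # df = 1, e = origin, mu1 = origin, mu2 = (1,0): kernels (1, 1/2) -> (2/3, 1/3)
  qh <- soft_assign(matrix(0, 1, 2), list(mu = rbind(c(0, 0), c(1, 0)), df = 1))
  expect_equal(as.vector(qh), c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("soft assignments are row-stochastic and distance-monotone", {
  set.seed(4)
  for (r in 1:25) {
    E <- matrix(rnorm(8 * 3, sd = 2), 8)
    mu <- matrix(rnorm(4 * 3, sd = 2), 4)
    q <- soft_assign(E, list(mu = mu, df = 0.5 + r / 10))
    expect_equal(rowSums(q), rep(1, 8), tolerance = 1e-8)
    expect_true(all(q > 0 & q <= 1))
  }
  # q_ik strictly decreases as e_i moves away from mu_k, all else fixed
  mu <- rbind(c(0, 0), c(4, 0))
  qs <- vapply(seq(0, 3, by = 0.5), function(x)
    soft_assign(matrix(c(x, 0), 1), list(mu = mu, df = 1))[1, 1], numeric(1))
  expect_true(all(diff(qs) < 0))
})

test_that("the Student-t kernel approaches the Gaussian kernel for large df", {
  dists <- seq(0, 3, by = 0.25)
  mu <- cbind(dists, 0)  # centroids on a line, query at the origin
  q <- soft_assign(matrix(0, 1, 2), list(mu = mu, df = 1e6))
  qg <- exp(-dists^2 / 2) / sum(exp(-dists^2 / 2))
  expect_lt(max(abs(q[1, ] - qg) / qg), 1e-3)
})

test_that("target sharpening matches hand arithmetic and preserves argmax", {
  # N = 1: frequencies cancel, p = q
  q1 <- matrix(c(0.3, 0.7), 1)
  expect_equal(sharpen_targets(q1)$p, q1, tolerance = 1e-12)
  # worked fixture
  q <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  tg <- sharpen_targets(q)
  expect_equal(tg$f, c(1.4, 0.6), tolerance = 1e-12)
  expect_equal(tg$p, rbind(c(0.9720, 0.0280), c(0.3000, 0.7000)),
               tolerance = 1e-4)
  # hard assignments are fixed points (both clusters occupied)
  qh <- rbind(c(1, 0), c(0, 1))
  expect_equal(sharpen_targets(qh)$p, qh)
  # with equal frequencies, sharpening keeps argmax and raises its mass
  qb <- rbind(c(0.6, 0.4), c(0.4, 0.6))
  pb <- sharpen_targets(qb)$p
  expect_equal(max.col(pb), max.col(qb))
  expect_true(all(apply(pb, 1, max) >= apply(qb, 1, max)))
})

test_that("sharpening backward matches finite differences", {
  set.seed(5)
  q <- matrix(runif(12, 0.05, 1), 4); q <- q / rowSums(q)
  C <- matrix(rnorm(12), 4)
  g <- mixcc:::sharpen_backward(q, C)
  gn <- num_grad(function(x) sum(C * sharpen_targets(x)$p), q)
  expect_lt(max(abs(g - gn)), 1e-5)
})

test_that("anchor KL loss: identity, hand fixture, and non-negativity", {
  q <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  p <- sharpen_targets(q)$p
  # views already matching the target give zero loss
  expect_equal(anchor_cluster_loss(q, p, p, p), 0, tolerance = 1e-12)
  # p = (1,0) against uniform views: ln 2 (the empty second column warns)
  expect_warning(
    l <- anchor_cluster_loss(matrix(c(1, 0), 1), matrix(0.5, 1, 2),
                             matrix(0.5, 1, 2), matrix(0.5, 1, 2)),
    "zero soft frequency")
  expect_equal(l, log(2), tolerance = 1e-12)
  set.seed(6)
  for (r in 1:30) {
    qa <- matrix(runif(8, 0.05, 1), 2); qa <- qa / rowSums(qa)
    qs <- replicate(3, { m <- matrix(runif(8, 0.05, 1), 2); m / rowSums(m) },
                    simplify = FALSE)
    expect_gte(anchor_cluster_loss(qa, qs[[1]], qs[[2]], qs[[3]]), 0)
    expect_gte(anchor_cluster_loss(qa, qs[[1]], qs[[2]], qs[[3]],
                                   variant = "self_paired"), 0)
    expect_gte(anchor_cluster_loss(qa, variant = "single_anchor"), 0)
  }
})

test_that("cluster-head variants compose as documented", {
  set.seed(7)
  qa <- matrix(runif(12, 0.05, 1), 3); qa <- qa / rowSums(qa)
  qs <- replicate(3, { m <- matrix(runif(12, 0.05, 1), 3); m / rowSums(m) },
                  simplify = FALSE)
  p <- sharpen_targets(qa)$p
  kl <- function(p, q) rowSums(p * (log(p) - log(q)))
  expect_equal(anchor_cluster_loss(qa, qs[[1]], qs[[2]], qs[[3]]),
               mean(kl(p, qs[[1]]) + kl(p, qs[[2]]) + kl(p, qs[[3]])) / 3)
  expect_equal(anchor_cluster_loss(qa, qs[[1]], qs[[2]], qs[[3]],
                                   variant = "self_paired"),
               mean(vapply(qs, function(qk)
                 mean(kl(sharpen_targets(qk)$p, qk)), numeric(1))))
  expect_equal(anchor_cluster_loss(qa, variant = "single_anchor"),
               mean(kl(p, qa)))
})

test_that("cluster loss gradients match finite differences", {
  set.seed(42)
  n <- 5; d <- 3; K <- 2
  E <- matrix(rnorm(n * d), n)
  E1 <- E + 0.1 * matrix(rnorm(n * d), n)
  E2 <- E + 0.1 * matrix(rnorm(n * d), n)
  E3 <- 0.8 * E + 0.1 * (E1 + E2)
  mu <- matrix(rnorm(K * d), K)
  ms <- list(mu = mu, df = 1, k = K)
  lossf <- function(E, E1, E2, E3, mu) {
    q0 <- soft_assign(E, list(mu = mu, df = 1))
    p <- sharpen_targets(q0)$p
    kl <- function(p, q) rowSums(p * (log(p) - log(q)))
    mean(kl(p, soft_assign(E1, list(mu = mu, df = 1))) +
           kl(p, soft_assign(E2, list(mu = mu, df = 1))) +
           kl(p, soft_assign(E3, list(mu = mu, df = 1)))) / 3
  }
  # stop-gradient mode: exact for the view embeddings
  ctl <- list(cluster_variant = "anchor_to_children", grad_through_target = FALSE)
  g <- mixcc:::cluster_loss_grad(E, E1, E2, E3, ms, ctl)
  expect_equal(g$loss, lossf(E, E1, E2, E3, mu), tolerance = 1e-12)
  gn1 <- num_grad(function(x) lossf(E, x, E2, E3, mu), E1)
  expect_lt(max(abs(g$gE1 - gn1)), 1e-7)
  expect_equal(g$gE, E * 0)  # target is constant: no anchor gradient
  # literal mode: full gradient, including through the sharpened target
  ctlT <- list(cluster_variant = "anchor_to_children", grad_through_target = TRUE)
  gt <- mixcc:::cluster_loss_grad(E, E1, E2, E3, ms, ctlT)
  gnmu <- num_grad(function(m) lossf(E, E1, E2, E3, m), mu)
  gnE <- num_grad(function(x) lossf(x, E1, E2, E3, mu), E)
  expect_lt(max(abs(gt$gMu - gnmu)), 1e-7)
  expect_lt(max(abs(gt$gE - gnE)), 1e-7)
})

test_that("a descent step moves view assignments toward the target", {
  set.seed(11)
  n <- 6; d <- 3; K <- 3
  E <- matrix(rnorm(n * d), n)
  E1 <- E + 0.3 * matrix(rnorm(n * d), n)
  mu <- E[c(1, 3, 5), ] + 0.1
  ms <- list(mu = mu, df = 1, k = K)
  ctl <- list(cluster_variant = "anchor_to_children", grad_through_target = FALSE)
  g <- mixcc:::cluster_loss_grad(E, E1, E1, E1, ms, ctl)
  p <- sharpen_targets(soft_assign(E, ms))$p
  tv <- function(q) mean(rowSums(abs(q - p))) / 2
  q_before <- soft_assign(E1, ms)
  q_after <- soft_assign(E1 - 0.5 * g$gE1, ms)
  expect_lt(tv(q_after), tv(q_before))
})
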