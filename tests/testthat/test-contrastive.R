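# Symmetric two-document fixture: every view of doc 1 is (1,0), of doc 2 is
# (0,1). With tau = 0.5 the per-pair loss under the full denominator is
# log(3 e^2 + 3) - 2 for every pair and both variants.
sym_quad <- function() {
  Z <- rbind(c(1, 0), c(0, 1))
  list(Z1 = Z, Z2 = Z, Z3 = Z)
}
sym_expected <- log(3 * exp(2) + 3) - 2   # 1.2255...

test_that("cosine similarity matches hand arithmetic", {
  expect_equal(cosine_sim(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 1), c(1, 0)), 0.7071, tolerance = 1e-4)
  expect_error(cosine_sim(c(0, 0), c(1, 0)), "zero")
})

test_that("worked symmetric fixture reproduces log(3e^2 + 3) - 2", {
  q <- sym_quad()
  cfg <- contrastive_config(tau = 0.5, denominator = "literal_all")
  expect_equal(sibling_pair_loss(q, 1, c(1, 2), cfg), sym_expected,
               tolerance = 1e-6)
  expect_equal(infonce_pair_loss(q, 1, c(1, 2), cfg), sym_expected,
               tolerance = 1e-6)
  # all six per-pair terms are equal here, so the total matches too
  expect_equal(instance_loss_total(q, cfg), sym_expected, tolerance = 1e-6)
})

test_that("limits: infinite temperature and identical projections", {
  q <- sym_quad()
  # tau -> Inf: every exponential -> 1, loss -> log(3N) = log 6
  cfg <- contrastive_config(tau = 1e6)
  expect_equal(instance_loss_total(q, cfg), log(6), tolerance = 1e-3)
  # all 3N projections identical: loss = log(3N) for any tau
  same <- matrix(rep(c(1, 0), each = 2), 2)
  qq <- list(Z1 = same, Z2 = same, Z3 = same)
  for (tau in c(0.3, 1, 5))
    expect_equal(sibling_pair_loss(qq, 1, c(1, 2), contrastive_config(tau)),
                 log(6), tolerance = 1e-9)
})

test_that("perfect separation drives the sibling loss to zero as tau -> 0", {
  n <- 3
  Z <- diag(n)  # orthogonal documents, identical views
  q <- list(Z1 = Z, Z2 = Z, Z3 = Z)
  cfg <- contrastive_config(tau = 1e-3, denominator = "exclude_siblings")
  expect_lt(instance_loss_total(q, cfg), 1e-6)
})

test_that("losses match the brute-force oracle across variants and denominators", {
  cases <- expand.grid(variant = c("sibling", "infonce"),
                       denominator = c("literal_all", "exclude_self",
                                       "exclude_siblings"),
                       stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cases))) {
    v <- cases$variant[r]; dn <- cases$denominator[r]
    for (s in 1:5) {
      q <- random_quad(n = 2 + s %% 3, d = 2 + s %% 2, seed = 100 * r + s)
      cfg <- contrastive_config(tau = 0.4 + 0.2 * s, variant = v,
                                denominator = dn)
      expect_equal(instance_loss_total(q, cfg),
                   oracle_total_loss(list(q$Z1, q$Z2, q$Z3), cfg$tau, v, dn),
                   tolerance = 1e-9,
                   info = sprintf("%s/%s seed %d", v, dn, s))
      expect_equal(sibling_pair_loss(q, 1, c(2, 3), cfg),
                   oracle_pair_loss(list(q$Z1, q$Z2, q$Z3), 1, c(2, 3),
                                    cfg$tau, "sibling", dn),
                   tolerance = 1e-9)
      expect_equal(infonce_pair_loss(q, 2, c(1, 3), cfg),
                   oracle_pair_loss(list(q$Z1, q$Z2, q$Z3), 2, c(1, 3),
                                    cfg$tau, "infonce", dn),
                   tolerance = 1e-9)
    }
  }
})

test_that("per-pair losses ignore relabeling of other documents", {
  q <- random_quad(5, 3, seed = 42)
  cfg <- contrastive_config()
  base <- sibling_pair_loss(q, 1, c(1, 2), cfg)
  perm <- c(1, 4, 2, 5, 3)  # fixes document 1
  qp <- list(Z1 = q$Z1[perm, ], Z2 = q$Z2[perm, ], Z3 = q$Z3[perm, ])
  expect_equal(sibling_pair_loss(qp, 1, c(1, 2), cfg), base, tolerance = 1e-12)
})

test_that("loss is non-negative whenever the self term is in the denominator", {
  for (s in 1:20) {
    q <- random_quad(3, 3, seed = s)
    cfg <- contrastive_config(tau = 0.5, denominator = "literal_all")
    expect_gte(sibling_pair_loss(q, 1, c(1, 2), cfg), 0)
    expect_gte(infonce_pair_loss(q, 2, c(1, 3), cfg), 0)
    expect_gte(instance_loss_total(q, cfg), 0)
  }
})

test_that("loss grows as temperature shrinks when negatives crowd positives", {
  # cross-document similarity (0.2 rad apart) exceeds the positive
  # similarity (views rotated 0.7 rad)
  z1 <- c(1, 0); z2 <- c(cos(0.2), sin(0.2))
  Z1 <- rbind(z1, z2)
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  Z2 <- rbind(rot(z1, 0.7), rot(z2, 0.7))
  q <- list(Z1 = Z1, Z2 = Z2, Z3 = Z1)
  losses <- vapply(c(1, 0.5, 0.25, 0.1), function(tau)
    instance_loss_total(q, contrastive_config(tau)), numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("analytic loss gradients match finite differences", {
  for (cfgspec in list(list("sibling", "literal_all"),
                       list("infonce", "exclude_self"),
                       list("sibling", "exclude_siblings"))) {
    cfg <- contrastive_config(0.7, cfgspec[[1]], cfgspec[[2]])
    q <- random_quad(3, 2, seed = 77)
    res <- mixcc:::instance_loss_impl(q, cfg, want_grad = TRUE)
    for (nm in c("Z1", "Z2", "Z3")) {
      gn <- num_grad(function(x) {
        qq <- q; qq[[nm]] <- x
        mixcc:::instance_loss_impl(qq, cfg)$loss
      }, q[[nm]])
      expect_lt(max(abs(res[[paste0("g", nm)]] - gn)), 1e-6)
    }
  }
})

test_that("a gradient step pulls positive pairs together", {
  set.seed(12)
  q <- random_quad(4, 3, seed = 12)
  cfg <- contrastive_config(0.5)
  res <- mixcc:::instance_loss_impl(q, cfg, want_grad = TRUE)
  pos_cos <- function(qq) mean(vapply(seq_len(4), function(i)
    cosine_sim(qq$Z1[i, ], qq$Z2[i, ]), numeric(1)))
  step <- function(Z, G) {
    Zn <- Z - 0.2 * G
    Zn / sqrt(rowSums(Zn^2))
  }
  q2 <- list(Z1 = step(q$Z1, res$gZ1), Z2 = step(q$Z2, res$gZ2),
             Z3 = step(q$Z3, res$gZ3))
  expect_gt(pos_cos(q2), pos_cos(q))
  expect_lt(mixcc:::instance_loss_impl(q2, cfg)$loss, res$loss)
})

test_that("duplicating the batch only enlarges the denominator", {
  q <- sym_quad()
  qdup <- lapply(q, function(Z) rbind(Z, Z))
  cfg <- contrastive_config(0.5)
  expect_gt(instance_loss_total(qdup, cfg), instance_loss_total(q, cfg))
})

test_that("degenerate inputs are rejected", {
  one <- list(Z1 = matrix(1, 1), Z2 = matrix(1, 1), Z3 = matrix(1, 1))
  expect_error(instance_loss_total(one), "N >= 2")
  expect_error(contrastive_config(tau = 0), "positive")
})
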