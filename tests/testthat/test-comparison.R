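test_that("WAIC matches the hand-evaluated formulas", {
  # 1 observation, 2 draws with likelihoods 0.5 and 0.25:
  # lppd = log(0.375), p_waic = var(log 0.5, log 0.25), waic = -2(lppd - p)
  ll <- matrix(log(c(0.5, 0.25)), ncol = 1)
  w <- waic(ll)
  expect_equal(w$lppd, log(0.375), tolerance = 1e-12)
  expect_equal(w$p_waic, var(log(c(0.5, 0.25))), tolerance = 1e-12)
  expect_equal(w$waic, 2.4421, tolerance = 1e-4)
})

test_that("degenerate constant draws give waic = loo = -2 * total loglik", {
  ll <- matrix(rep(c(-1.2, -0.4, -2.2), each = 5), nrow = 5)
  w <- waic(ll); l <- loo(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * sum(ll[1, ]))
  expect_equal(l$loo, w$waic)
  expect_equal(l$p_loo, 0, tolerance = 1e-10)
})

test_that("duplicating observation columns doubles WAIC", {
  set.seed(71)
  ll <- matrix(rnorm(200, -1, 0.3), 20, 10)
  expect_equal(waic(cbind(ll, ll))$waic, 2 * waic(ll)$waic, tolerance = 1e-10)
})

test_that("indices are invariant to draw and observation ordering", {
  set.seed(72)
  ll <- matrix(rnorm(400, -1, 0.5), 40, 10)
  perm_d <- sample(40); perm_o <- sample(10)
  expect_equal(waic(ll[perm_d, perm_o])$waic, waic(ll)$waic, tolerance = 1e-10)
  l1 <- loo(ll); l2 <- loo(ll[perm_d, perm_o])
  expect_equal(l2$loo, l1$loo, tolerance = 1e-10)
  expect_equal(sort(l2$pareto_k), sort(l1$pareto_k), tolerance = 1e-10)
})

test_that("PSIS-LOO tracks exact leave-one-out on a conjugate model", {
  # Normal-mean model with known variance 1 and N(0, 1) prior: the
  # leave-one-out posterior and predictive density are available in closed
  # form, giving an independent oracle for elpd_loo.
  set.seed(73)
  n <- 30
  y <- rnorm(n, 0.4, 1)
  exact_elpd <- vapply(seq_len(n), function(i) {
    yi <- y[-i]
    post_var <- 1 / (1 + length(yi))
    post_mean <- sum(yi) * post_var
    dnorm(y[i], post_mean, sqrt(post_var + 1), log = TRUE)
  }, numeric(1))
  # posterior draws from the full-data posterior
  S <- 4000
  post_var <- 1 / (1 + n)
  mu_draws <- rnorm(S, sum(y) * post_var, sqrt(post_var))
  ll <- vapply(seq_len(n), function(i) dnorm(y[i], mu_draws, 1, log = TRUE),
               numeric(S))
  l <- loo(ll)
  expect_equal(l$loo, -2 * sum(exact_elpd), tolerance = 0.02)
  expect_true(all(is.na(l$pareto_k) | l$pareto_k < 0.7))
  expect_gte(l$p_loo, 0)
  # LOO penalizes at least as much as WAIC on this well-behaved case
  expect_gte(l$loo, waic(ll)$waic - 0.5)
})

test_that("single-draw matrices are rejected", {
  expect_error(waic(matrix(-1, 1, 3)), "at least 2")
  expect_error(loo(matrix(-1, 1, 3)), "at least 2")
})

test_that("model selection picks the smaller criterion with ties to fewer dimensions", {
  f1 <- structure(list(waic = 100, loo = 101, n_obs = 50), class = "fit_indices")
  f2 <- structure(list(waic = 90, loo = 102, n_obs = 50), class = "fit_indices")
  sel <- select_model(list(`1d` = f1, `2d` = f2))
  expect_identical(sel$waic, "2d")
  expect_identical(sel$loo, "1d")
  tie <- select_model(list(`1d` = f1, `2d` = f1))
  expect_identical(tie$waic, "1d")
  expect_identical(tie$loo, "1d")
  f3 <- structure(list(waic = 80, loo = 80, n_obs = 60), class = "fit_indices")
  expect_error(select_model(list(`1d` = f1, `2d` = f3)), "not comparable")
})
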