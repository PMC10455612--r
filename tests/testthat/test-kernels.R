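test_that("category probabilities match the hand-evaluated kernel", {
  # theta = delta = 0, alpha = 1, C = 1, tau1 = -1:
  # numerator(z=1) = 2e, denominator = 2 + 2e, so P(1) = e / (1 + e)
  p <- ggum_category_probabilities(0, 1, 0, tau = -1)
  expect_equal(p[2], exp(1) / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # brute-force oracle agreement over a parameter sweep
  set.seed(1)
  for (rep in 1:25) {
    C <- sample(1:4, 1)
    th <- runif(1, -6, 6); al <- runif(1, 0.1, 5)
    de <- runif(1, -6, 6); ta <- runif(C, -3, 1)
    p <- ggum_category_probabilities(th, al, de, ta)
    expect_equal(p, oracle_ggum_probs(th, al, de, ta), tolerance = 1e-10)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0))
  }
})

test_that("probabilities are symmetric about the item location", {
  set.seed(2)
  for (rep in 1:10) {
    al <- runif(1, 0.3, 3); de <- runif(1, -2, 2); ta <- runif(2, -3, 0)
    t_off <- runif(1, 0, 4)
    expect_equal(ggum_category_probabilities(de + t_off, al, de, ta),
                 ggum_category_probabilities(de - t_off, al, de, ta),
                 tolerance = 1e-12)
  }
})

test_that("kernel is overflow-safe at extreme trait-location distances", {
  p <- ggum_category_probabilities(50, 1, 0, c(-2, -1)) # alpha*(theta-delta) = 50
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-10)
  p2 <- ggum_category_probabilities(-30, 5, 20, -2)
  expect_true(all(is.finite(p2)))
  expect_equal(sum(p2), 1, tolerance = 1e-10)
})

test_that("invalid kernel inputs are rejected", {
  expect_error(ggum_category_probabilities(0, -1, 0, -1), "positive")
  expect_error(ggum_category_probabilities(0, 1, 0, c(-2, -1),
                                           scale = response_scale(2)),
               "exactly C")
})

test_that("multidimensional kernel reduces to the unidimensional one", {
  set.seed(3)
  for (rep in 1:20) {
    D <- sample(2:5, 1); C <- sample(c(1, 3), 1)
    th <- rnorm(D, 0, 2)
    it <- list(trait = sample(D, 1), alpha = runif(1, 0.2, 3),
               delta = runif(1, -2, 2), tau = sort(runif(C, -3, -0.5)))
    pm <- mggum_category_probabilities(th, it)
    pu <- ggum_category_probabilities(th[it$trait], it$alpha, it$delta, it$tau)
    expect_equal(pm, pu, tolerance = 1e-10)
    expect_equal(sum(pm), 1, tolerance = 1e-10)
  }
})

test_that("multidimensional kernel is invariant to off-dimension traits and rejects zero loadings", {
  it <- list(trait = 1, alpha = 1, delta = 0, tau = -1)
  p1 <- mggum_category_probabilities(c(0, -7), it)
  p2 <- mggum_category_probabilities(c(0, 3), it)
  expect_equal(p1, p2)
  expect_equal(p1[2], exp(1) / (1 + exp(1)), tolerance = 1e-12)
  bad <- list(trait = 1, alpha = 0, delta = 0, tau = -1)
  expect_error(mggum_category_probabilities(c(0, 0), bad), "zero loadings")
})

test_that("latent mean is the covariate-by-coefficient product", {
  expect_equal(latent_mean(matrix(c(1, 2), 1), rbind(c(0.5, 0), c(0, -1))),
               matrix(c(0.5, -2), 1))
  X <- matrix(rnorm(6), 3, 2)
  expect_equal(latent_mean(X, matrix(0, 2, 4)), matrix(0, 3, 4))
  expect_equal(latent_mean(diag(2), diag(2)), diag(2))
  expect_error(latent_mean(X, matrix(0, 3, 2)), "shape")
})

test_that("joint log-likelihood equals the brute-force cell sum", {
  # 2 persons x 2 items at the hand-oracle configuration, all responses 1
  bank <- item_bank(trait = c(1, 2), alpha = c(1, 1), delta = c(0, 0),
                    tau = matrix(-1, 2, 1))
  Z <- matrix(1L, 2, 2)
  theta <- matrix(0, 2, 2)
  expect_equal(joint_log_likelihood(Z, bank, theta),
               4 * log(exp(1) / (1 + exp(1))), tolerance = 1e-12)

  # random small instances against the independent loop
  set.seed(4)
  for (rep in 1:10) {
    C <- sample(c(1, 3), 1)
    bank <- toy_bank(C = C, I = 5, D = 2)
    theta <- matrix(rnorm(8), 4, 2)
    Z <- matrix(sample(0:C, 20, replace = TRUE), 4, 5)
    Z[sample(20, 4)] <- NA
    expect_equal(joint_log_likelihood(Z, bank, theta),
                 oracle_loglik(Z, theta, bank$trait, bank$alpha, bank$delta,
                               bank$tau),
                 tolerance = 1e-10)
  }
})

test_that("fully missing data contributes zero log-likelihood", {
  bank <- toy_bank(C = 1, I = 3, D = 1)
  Z <- matrix(NA_integer_, 2, 3)
  expect_equal(joint_log_likelihood(Z, bank, matrix(0, 2, 1)), 0)
})

test_that("out-of-range responses are rejected", {
  bank <- toy_bank(C = 1, I = 3, D = 1)
  Z <- matrix(2L, 2, 3)
  expect_error(joint_log_likelihood(Z, bank, matrix(0, 2, 1)), "0..1")
})

test_that("response scale derives M from C", {
  sc <- response_scale(4)
  expect_identical(sc$C, 3L)
  expect_identical(sc$M, 7L)
  expect_error(response_scale(1), ">= 2")
})
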