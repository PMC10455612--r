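test_that("item direction classification matches the location rule", {
  expect_identical(classify_item_direction(-2), "negative")
  expect_identical(classify_item_direction(0), "neutral")
  expect_identical(classify_item_direction(1.5), "neutral")   # boundary
  expect_identical(classify_item_direction(-1.5), "neutral")  # boundary
  expect_identical(classify_item_direction(1.6), "positive")
  expect_error(classify_item_direction(NaN), "finite")
})

test_that("Gelman-Rubin statistic matches the hand-evaluated formula", {
  # chain1 = (0, 2), chain2 = (1, 3): W = 2, B = 1, Rhat = sqrt(0.75)
  expect_equal(gelman_rubin(rbind(c(0, 2), c(1, 3))), sqrt(0.75),
               tolerance = 1e-12)
  # long chains from one distribution approach 1
  set.seed(91)
  x <- rbind(rnorm(20000), rnorm(20000))
  expect_equal(gelman_rubin(x), 1, tolerance = 0.01)
  # zero within-chain variance is flagged, not silently passed
  expect_true(is.na(gelman_rubin(rbind(c(1, 1), c(2, 2)))))
  expect_error(gelman_rubin(matrix(1:3, 1)), "at least 2 chains")
})

test_that("priors follow the documented defaults", {
  p2 <- mggum_priors(2)
  expect_equal(p2$tau_mean, -2)
  p4 <- mggum_priors(4)
  expect_equal(p4$tau_mean, c(-3, -2, -1))
  expect_equal(p4$tau_sd, 2)
  expect_equal(p4$alpha_logsd, 0.5)
  expect_equal(unname(p4$delta_mean), c(-1, 0, 1))
})

test_that("model construction validates inputs", {
  Z <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  im <- data.frame(trait = c(1, 2), direction = c("neutral", "neutral"))
  m <- build_model(Z, im, n_options = 2)
  expect_s3_class(m, "mggum_model")
  expect_identical(m$D, 2L)
  expect_error(build_model(Z, im[1, ], n_options = 2), "one row per")
  expect_error(build_model(matrix(c(0L, 3L, 1L, 0L), 2, 2), im,
                           n_options = 2), "0..1")
  expect_error(build_model(Z, im, X = matrix(c(1, NA), 2, 1), n_options = 2),
               "missing covariate")
  Zm <- Z; Zm[, 2] <- NA_integer_
  expect_error(build_model(Zm, im, n_options = 2), "entirely missing")
})

test_that("fitting is deterministic and honors the draw-count contract", {
  cond <- sim_condition(40, 2, 5, 2, trait_cor = 0.5)
  sim <- simulate_mggum_data(cond, seed = 15)
  m <- build_model(sim$responses,
                   data.frame(trait = sim$items$trait,
                              direction = sim$items$direction),
                   n_options = 2)
  cfg <- mcmc_config(n_iterations = 200, n_burnin = 80, seed = 3,
                      n_warmup_extra = 100)
  f1 <- mggum_fit(m, cfg)
  f2 <- mggum_fit(m, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(dim(f1$draws$alpha), c(120L, 2L, 10L))
  expect_identical(f1$n_draws, 240L)
  expect_identical(ncol(f1$pointwise_loglik), sum(!is.na(sim$responses)))
  expect_identical(nrow(f1$pointwise_loglik), 240L)
})

test_that("posterior draws respect the sign and support constraints", {
  set.seed(16)
  bank <- item_bank(trait = rep(1:2, each = 4),
                    alpha = runif(8, 0.5, 2),
                    delta = c(-1.9, 0.2, 1.8, 0.5, -1.7, 1.9, 0.1, -0.3),
                    tau = matrix(runif(8, -3, -1), 8, 1))
  theta <- MASS::mvrnorm(120, c(0, 0), diag(2))
  Z <- generate_responses(theta, bank, seed = 17)
  m <- build_model(Z, data.frame(trait = bank$trait,
                                 direction = bank$direction), n_options = 2)
  fit <- mggum_fit(m, mcmc_config(n_iterations = 250, n_burnin = 100, seed = 4,
                                  n_warmup_extra = 100))
  pos <- which(bank$direction == "positive")
  neg <- which(bank$direction == "negative")
  expect_true(all(fit$draws$delta[, , pos] >= 0))
  expect_true(all(fit$draws$delta[, , neg] <= 0))
  expect_true(all(fit$draws$alpha > 0))
  expect_true(all(abs(fit$draws$omega) < 1))
  # theta draws stay on the identified unit scale
  expect_lt(abs(mean(fit$draws$theta)), 0.25)
  expect_lt(abs(sd(fit$draws$theta) - 1), 0.35)
})

test_that("covariate significance needs covariates and reads the intervals", {
  cond <- sim_condition(40, 2, 5, 2)
  sim <- simulate_mggum_data(cond, seed = 18)
  m <- build_model(sim$responses,
                   data.frame(trait = sim$items$trait,
                              direction = sim$items$direction),
                   n_options = 2)
  fit <- mggum_fit(m, mcmc_config(n_iterations = 120, n_burnin = 60, seed = 5,
                              n_warmup_extra = 50))
  expect_error(covariate_significance(fit), "without covariates")

  mX <- build_model(sim$responses,
                    data.frame(trait = sim$items$trait,
                               direction = sim$items$direction),
                    X = sim$persons$X, n_options = 2)
  fitX <- mggum_fit(mX, mcmc_config(n_iterations = 120, n_burnin = 60, seed = 5,
                                    n_warmup_extra = 50))
  sig <- covariate_significance(fitX)
  expect_identical(dim(sig), c(2L, 2L))
  ci <- fitX$ci95[dimnames(fitX$draws$beta)[[3]], , drop = FALSE]
  expect_identical(unname(as.vector(sig)),
                   unname(ci[, "lower"] > 0 | ci[, "upper"] < 0))
})

test_that("summary and trait-score tables expose every parameter once", {
  cond <- sim_condition(25, 2, 4, 2)
  sim <- simulate_mggum_data(cond, seed = 19)
  m <- build_model(sim$responses,
                   data.frame(trait = sim$items$trait,
                              direction = sim$items$direction),
                   n_options = 2)
  fit <- mggum_fit(m, mcmc_config(n_iterations = 120, n_burnin = 60, seed = 6,
                              n_warmup_extra = 50))
  sm <- summary(fit)
  expect_identical(nrow(sm), length(fit$estimates))
  ts <- trait_scores(fit)
  expect_identical(nrow(ts), 25L * 2L)
  dir <- withr::local_tempdir()
  write_fit(fit, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "trait_scores.csv")))
})
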