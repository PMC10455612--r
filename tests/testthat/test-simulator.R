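test_that("item parameters respect the generating intervals", {
  cond <- sim_condition(100, 2, 10, 4)
  set.seed(11)
  draws <- replicate(50, draw_item_parameters(cond), simplify = FALSE)
  alpha <- unlist(lapply(draws, `[[`, "alpha"))
  delta <- unlist(lapply(draws, `[[`, "delta"))
  expect_true(all(alpha >= 0.5 & alpha <= 2))
  expect_true(all(delta >= -2 & delta <= 2))
  # disjoint threshold intervals force the ordering tau1 < tau2 < tau3
  for (b in draws) {
    expect_true(all(b$tau[, 1] < b$tau[, 2]))
    expect_true(all(b$tau[, 2] < b$tau[, 3]))
    expect_true(all(b$tau[, 1] >= -3.5 & b$tau[, 1] <= -2.5))
    expect_true(all(b$tau[, 3] >= -1.5 & b$tau[, 3] <= -0.5))
  }
  # two-option conditions use a single U(-3, -1) threshold
  cond2 <- sim_condition(100, 2, 5, 2)
  b2 <- draw_item_parameters(cond2, seed = 5)
  expect_identical(ncol(b2$tau), 1L)
  expect_true(all(b2$tau >= -3 & b2$tau <= -1))
  expect_error(draw_item_parameters(sim_condition(100, 2, 5, 3)),
               "unsupported")
})

test_that("items load traits in blocks and directions follow true locations", {
  cond <- sim_condition(50, 3, 4, 2)
  bank <- draw_item_parameters(cond, seed = 21)
  expect_identical(bank$trait, rep(1:3, each = 4))
  expect_identical(bank$direction, classify_item_direction(bank$delta))
})

test_that("item draws are reproducible from the seed", {
  cond <- sim_condition(100, 2, 5, 4)
  a <- draw_item_parameters(cond, seed = 123)
  b <- draw_item_parameters(cond, seed = 123)
  expect_identical(a, b)
  sim1 <- simulate_mggum_data(cond, seed = 7)
  sim2 <- simulate_mggum_data(cond, seed = 7)
  expect_identical(sim1, sim2)
})

test_that("person and covariate draws reproduce the target moments", {
  cond <- sim_condition(100000, 2, 5, 2, trait_cor = 0.5,
                        trait_covariate_cor = 0.25)
  ps <- draw_persons_and_covariates(cond, seed = 31)
  expect_equal(unname(colMeans(ps$theta)), c(0, 0), tolerance = 0.01)
  expect_equal(unname(apply(ps$theta, 2, var)), c(1, 1), tolerance = 0.02)
  expect_equal(cor(ps$theta)[1, 2], 0.5, tolerance = 0.01)
  expect_equal(unname(cor(ps$X)[1, 2]), 0, tolerance = 0.015)
  cc <- cor(ps$theta, ps$X)
  expect_true(all(abs(cc - 0.25) < 0.01))

  # independence when the trait-covariate factor is zero
  cond0 <- sim_condition(100000, 2, 5, 2)
  ps0 <- draw_persons_and_covariates(cond0, seed = 32)
  expect_true(all(abs(cor(ps0$theta, ps0$X)) < 0.015))
})

test_that("impossible correlation structures are rejected early", {
  expect_error(sim_condition(100, 5, 5, 2, trait_cor = -0.9),
               "positive semi-definite")
})

test_that("generated responses follow the kernel frequencies", {
  bank <- item_bank(trait = 1, alpha = 1, delta = 0,
                    tau = matrix(-1, 1, 1))
  theta <- matrix(0, 200000, 1)
  set.seed(41)
  Z <- generate_responses(theta, bank)
  expect_true(all(Z %in% 0:1))
  expect_equal(mean(Z), exp(1) / (1 + exp(1)), tolerance = 0.005)
})

test_that("high discrimination at the item location concentrates responses", {
  bank <- item_bank(trait = 1, alpha = 40, delta = 0.5,
                    tau = matrix(c(-2, -1), 1, 2, byrow = TRUE))
  theta <- matrix(0.5, 500, 1)
  set.seed(42)
  Z <- generate_responses(theta, bank)
  expect_true(mean(Z == 2) > 0.99) # highest-agreement category
})

test_that("missingness masks the exact cell count reproducibly", {
  Z <- matrix(0L, 40, 25) # 1000 cells
  Zm <- apply_missingness(Z, 0.2, seed = 51)
  expect_identical(sum(is.na(Zm)), 200L)
  expect_identical(apply_missingness(Z, 0.2, seed = 51), Zm)
  expect_identical(apply_missingness(Z, 0), Z)
  expect_error(apply_missingness(Z, 1), "\\[0, 1\\)")
})

test_that("datasets round-trip through the CSV layout", {
  cond <- sim_condition(30, 2, 5, 4, missing_prop = 0.2,
                        trait_covariate_cor = 0.25)
  sim <- simulate_mggum_data(cond, seed = 61)
  dir <- withr::local_tempdir()
  write_mggum_data(sim, dir)
  back <- read_mggum_data(dir)
  expect_identical(unname(back$responses), unname(sim$responses))
  expect_equal(unname(back$X), unname(sim$persons$X), tolerance = 1e-12)
  expect_identical(back$item_map$trait, sim$items$trait)
  expect_identical(back$item_map$direction, sim$items$direction)
  expect_equal(back$item_map$delta, sim$items$delta, tolerance = 1e-12)
})

test_that("covariate missingness is rejected", {
  expect_error(person_sample(matrix(0, 2, 1), matrix(c(1, NA), 2, 1)),
               "missing")
})
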