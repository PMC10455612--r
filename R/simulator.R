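# Synthetic-data generator for the simulation studies: item parameters from
# the generating uniforms, persons and covariates from one joint multivariate
# normal, responses from the unfolding kernel, and exact-count MCAR masking.

#' Person sample
#'
#' Latent traits and (optionally) covariates for `J` persons.  Covariates may
#' not contain missing values; only response data may be missing.
#'
#' @param theta Numeric `J x D` trait matrix.
#' @param X Optional numeric `J x P` covariate matrix.
#' @return An object of class `person_sample`.
#' @export
person_sample <- function(theta, X = NULL) {
  theta <- as.matrix(theta)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (anyNA(X)) stop("covariates may not contain missing values")
    if (nrow(X) != nrow(theta)) stop("theta and X row counts differ")
  }
  structure(list(theta = theta, X = X), class = "person_sample")
}

#' Simulation condition
#'
#' One cell of the study design: sample size, number of traits, items per
#' trait, response options, missing-data proportion, between-trait
#' correlation, and trait-covariate correlation (two covariates, mutually
#' uncorrelated, each correlated equally with every trait when the factor is
#' nonzero).
#'
#' @param n_persons Number of respondents.
#' @param n_traits Number of latent traits `D`.
#' @param items_per_trait Items loading on each trait.
#' @param n_options Number of response options (2 or 4 in the study designs).
#' @param missing_prop Proportion of response cells masked, in `[0, 1)`.
#' @param trait_cor Correlation between every pair of traits.
#' @param trait_covariate_cor Correlation between every trait and every
#'   covariate.
#' @param n_covariates Number of covariates (0 disables the covariate block).
#' @return An object of class `sim_condition`.
#' @export
sim_condition <- function(n_persons, n_traits, items_per_trait, n_options,
                          missing_prop = 0, trait_cor = 0,
                          trait_covariate_cor = 0, n_covariates = 2) {
  stopifnot(n_persons >= 1, n_traits >= 1, items_per_trait >= 1,
            n_options >= 2)
  if (missing_prop < 0 || missing_prop >= 1)
    stop("`missing_prop` must be in [0, 1)")
  if (abs(trait_cor) > 1) stop("|trait_cor| must be <= 1")
  cond <- structure(list(n_persons = as.integer(n_persons),
                         n_traits = as.integer(n_traits),
                         items_per_trait = as.integer(items_per_trait),
                         n_options = as.integer(n_options),
                         missing_prop = missing_prop,
                         trait_cor = trait_cor,
                         trait_covariate_cor = trait_covariate_cor,
                         n_covariates = as.integer(n_covariates)),
                    class = "sim_condition")
  # fail early if the implied joint correlation matrix is not PSD
  joint_correlation(cond)
  cond
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf(paste0("condition: J=%d, D=%d, %d items/trait, %d options, ",
                     "missing=%.2f, r=%.2f, r(theta,X)=%.2f, P=%d\n"),
              x$n_persons, x$n_traits, x$items_per_trait, x$n_options,
              x$missing_prop, x$trait_cor, x$trait_covariate_cor,
              x$n_covariates))
  invisible(x)
}

# Joint correlation matrix of (theta_1..theta_D, X_1..X_P): unit variances,
# trait_cor within the trait block, identity within the covariate block,
# trait_covariate_cor across blocks.
joint_correlation <- function(cond) {
  D <- cond$n_traits; P <- cond$n_covariates
  S <- diag(D + P)
  if (D > 1) S[1:D, 1:D][upper.tri(diag(D))] <- cond$trait_cor
  S[1:D, 1:D][lower.tri(diag(D))] <- t(S[1:D, 1:D])[lower.tri(diag(D))]
  if (P > 0) {
    S[1:D, D + seq_len(P)] <- cond$trait_covariate_cor
    S[D + seq_len(P), 1:D] <- cond$trait_covariate_cor
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    message("implied joint correlation matrix (traits then covariates):")
    print(S)
    stop("implied correlation matrix of traits and covariates is not ",
         "positive semi-definite")
  }
  S
}

#' Draw generating item parameters
#'
#' Discriminations from `U(0.5, 2)`, locations from `U(-2, 2)`; thresholds
#' from `U(-3, -1)` for two response options, and from `U(-3.5, -2.5)`,
#' `U(-2.5, -1.5)`, `U(-1.5, -0.5)` for four.  Items are assigned to traits
#' in consecutive blocks of `items_per_trait`, and direction labels are set
#' from the true locations via [classify_item_direction()].
#'
#' @param condition A [sim_condition()].
#' @param seed Optional integer; when given, seeds R's RNG locally.
#' @return An [item_bank()].
#' @export
draw_item_parameters <- function(condition, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  I <- condition$n_traits * condition$items_per_trait
  C <- condition$n_options - 1L
  alpha <- runif(I, 0.5, 2.0)
  delta <- runif(I, -2.0, 2.0)
  tau <- switch(as.character(condition$n_options),
    "2" = matrix(runif(I, -3, -1), ncol = 1),
    "4" = cbind(runif(I, -3.5, -2.5), runif(I, -2.5, -1.5),
                runif(I, -1.5, -0.5)),
    stop("unsupported number of response options: ", condition$n_options,
         " (2 or 4 are supported)"))
  stopifnot(ncol(tau) == C)
  trait <- rep(seq_len(condition$n_traits), each = condition$items_per_trait)
  item_bank(trait, alpha, delta, tau,
            direction = classify_item_direction(delta))
}

#' Draw persons and covariates
#'
#' One joint multivariate-normal draw of traits and covariates with zero
#' means, unit variances, `trait_cor` between traits, zero correlation
#' between covariates, and `trait_covariate_cor` between every trait and
#' every covariate.
#'
#' @inheritParams draw_item_parameters
#' @return A [person_sample()]; `X` is `NULL` when `n_covariates = 0`.
#' @export
draw_persons_and_covariates <- function(condition, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- condition$n_traits; P <- condition$n_covariates
  S <- joint_correlation(condition)
  Y <- MASS::mvrnorm(condition$n_persons, mu = rep(0, D + P), Sigma = S)
  Y <- matrix(Y, ncol = D + P)
  person_sample(theta = Y[, seq_len(D), drop = FALSE],
                X = if (P > 0) Y[, D + seq_len(P), drop = FALSE] else NULL)
}

#' Generate responses
#'
#' Draws each response cell from the MGGUM category probabilities of the
#' person-item pair (equivalent to the unidimensional kernel on the item's
#' loading dimension under simple structure).  No missingness is applied.
#'
#' @param persons A [person_sample()] or `J x D` trait matrix.
#' @param items An [item_bank()].
#' @param scale Optional [response_scale()] (validated against the bank).
#' @param seed Optional integer; when given, seeds R's RNG locally.
#' @return Integer `J x I` response matrix with entries in `0..C`.
#' @export
generate_responses <- function(persons, items, scale = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- if (inherits(persons, "person_sample")) persons$theta else
    as.matrix(persons)
  if (!is.null(scale) && scale$C != items$C)
    stop("response scale and item bank disagree on C")
  Z <- cpp_generate_responses(theta, items$trait - 1L, items$alpha,
                              items$delta, items$tau)
  dimnames(Z) <- list(NULL, paste0("item", seq_along(items$alpha)))
  Z
}

#' Apply completely-at-random missingness
#'
#' Masks exactly `round(missing_prop * J * I)` cells, drawn uniformly without
#' replacement, so small instances hit the nominal proportion exactly.
#'
#' @param responses Integer response matrix.
#' @param missing_prop Proportion of cells to mask, in `[0, 1)`.
#' @param seed Optional integer; when given, seeds R's RNG locally.
#' @return The response matrix with masked cells set to `NA`.
#' @export
apply_missingness <- function(responses, missing_prop, seed = NULL) {
  if (missing_prop < 0 || missing_prop >= 1)
    stop("`missing_prop` must be in [0, 1)")
  if (missing_prop == 0) return(responses)
  if (!is.null(seed)) set.seed(seed)
  n <- length(responses)
  k <- round(missing_prop * n)
  idx <- sample.int(n, k)
  responses[idx] <- NA_integer_
  responses
}

#' Simulate one complete dataset
#'
#' Runs the full generating pipeline for one condition: item parameters,
#' persons and covariates, responses, and missingness.  With a fixed seed the
#' result is reproducible byte-for-byte.
#'
#' @param condition A [sim_condition()].
#' @param seed Optional integer seed for the whole pipeline.
#' @return A list with elements `items`, `persons`, `responses`, `scale`,
#'   and `condition`, of class `mggum_simulation`.
#' @export
simulate_mggum_data <- function(condition, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  items <- draw_item_parameters(condition)
  persons <- draw_persons_and_covariates(condition)
  scale <- response_scale(condition$n_options)
  Z <- generate_responses(persons, items, scale)
  Z <- apply_missingness(Z, condition$missing_prop)
  structure(list(items = items, persons = persons, responses = Z,
                 scale = scale, condition = condition),
            class = "mggum_simulation")
}

#' Write a simulated dataset as delimited text
#'
#' Writes `responses.csv` (persons by items, missing as `NA`),
#' `covariates.csv` (when present), `itemmap.csv` (item id, trait, direction,
#' and the true generating parameters for recovery scoring), and
#' `condition.csv` (key-value manifest).
#'
#' @param sim A [simulate_mggum_data()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mggum_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sim$responses, file.path(dir, "responses.csv"),
            row.names = FALSE)
  if (!is.null(sim$persons$X)) {
    X <- sim$persons$X
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    write.csv(X, file.path(dir, "covariates.csv"), row.names = FALSE)
  }
  tau <- sim$items$tau
  colnames(tau) <- paste0("tau", seq_len(ncol(tau)))
  im <- data.frame(item = colnames(sim$responses), trait = sim$items$trait,
                   direction = sim$items$direction, alpha = sim$items$alpha,
                   delta = sim$items$delta, tau)
  write.csv(im, file.path(dir, "itemmap.csv"), row.names = FALSE)
  cond <- sim$condition
  write.csv(data.frame(key = names(cond),
                       value = unlist(lapply(cond, as.character))),
            file.path(dir, "condition.csv"), row.names = FALSE)
  invisible(dir)
}
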