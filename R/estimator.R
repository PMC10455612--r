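# Bayesian estimation of the MGGUM: model construction, the MCMC driver,
# Gelman-Rubin convergence gating, and posterior summaries.

#' Classify item direction from the location parameter
#'
#' Items with location below -1.5 are `negative`, above 1.5 `positive`, and
#' `neutral` in between (boundaries inclusive to neutral).  Direction labels
#' select the location prior and its sign bound at estimation time.
#'
#' @param delta Numeric vector of item locations.
#' @return Character vector in `negative`, `neutral`, `positive`.
#' @examples
#' classify_item_direction(c(-2, 0, 1.5, 1.6))
#' @export
classify_item_direction <- function(delta) {
  if (any(!is.finite(delta))) stop("`delta` must be finite")
  ifelse(delta < -1.5, "negative", ifelse(delta > 1.5, "positive", "neutral"))
}

#' Prior specification
#'
#' Default priors: location `N(-1, 1)` bounded above by 0 for negative
#' items, `N(1, 1)` bounded below by 0 for positive items, `N(0, 1)`
#' unbounded for neutral items; thresholds `N(-2, 2)` with two response
#' options and `N(-3, 2)`, `N(-2, 2)`, `N(-1, 2)` with four; discrimination
#' `logN(0, 0.5)`; regression coefficients independent `N(0, 1)`; trait
#' correlation matrix LKJ with shape 1 (uniform over correlation matrices).
#' All second arguments are standard deviations.
#'
#' @param n_options Number of response options.
#' @return A list of class `mggum_priors`.
#' @export
mggum_priors <- function(n_options) {
  C <- as.integer(n_options) - 1L
  tau_mean <- if (C == 1L) -2 else if (C == 3L) c(-3, -2, -1) else -(C:1)
  structure(list(
    delta_mean = c(negative = -1, neutral = 0, positive = 1),
    delta_sd = 1,
    tau_mean = tau_mean, tau_sd = 2,
    alpha_logmean = 0, alpha_logsd = 0.5,
    beta_sd = 1, lkj_eta = 1
  ), class = "mggum_priors")
}

#' MCMC configuration
#'
#' @param n_chains Number of chains (at least 2, so that the Gelman-Rubin
#'   diagnostic is defined).
#' @param n_iterations Total iterations per chain, including burn-in.
#' @param n_burnin Iterations discarded per chain.
#' @param seed Integer seed; chain `c` runs under `seed + c - 1`.
#' @param rhat_threshold Convergence gate: converged iff the largest
#'   Gelman-Rubin statistic over all parameters is below this value.
#' @param n_person_scans Person-trait update sweeps per iteration.
#' @param n_item_scans Item-block update sweeps per iteration.
#' @param n_warmup_extra Additional adaptation-only iterations run before
#'   the counted iterations begin (never stored; lets proposal adaptation
#'   settle before burn-in ends).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_iterations = 2000, n_burnin = 1000,
                        seed = 1, rhat_threshold = 1.05,
                        n_person_scans = 1, n_item_scans = 4,
                        n_warmup_extra = 600) {
  stopifnot(n_chains >= 2, n_burnin < n_iterations, n_burnin >= 0,
            n_person_scans >= 1, n_item_scans >= 1, n_warmup_extra >= 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold,
                 n_person_scans = as.integer(n_person_scans),
                 n_item_scans = as.integer(n_item_scans),
                 n_warmup_extra = as.integer(n_warmup_extra)),
            class = "mcmc_config")
}

#' Build an MGGUM model object
#'
#' Assembles and validates everything the sampler needs: the response
#' matrix, the item-to-trait map with direction labels, optional covariates,
#' and priors.  The posterior is proportional to the response likelihood
#' times the priors, with traits distributed `MVN(X beta, omega)` where
#' `omega` is restricted to a correlation matrix (unit variances) for
#' identification; without covariates the trait prior is `MVN(0, omega)`.
#'
#' @param responses Integer `J x I` matrix, categories `0..C`, `NA` missing.
#' @param item_map Data frame with columns `trait` and `direction` (one row
#'   per item), or an [item_bank()].
#' @param X Optional numeric `J x P` covariate matrix (no missing values).
#' @param n_options Number of response options; defaults to
#'   `max(responses) + 1`.
#' @param priors An [mggum_priors()] list.
#' @return An object of class `mggum_model`.
#' @export
build_model <- function(responses, item_map, X = NULL, n_options = NULL,
                        priors = NULL) {
  Z <- as.matrix(responses)
  if (inherits(item_map, "item_bank"))
    item_map <- data.frame(trait = item_map$trait,
                           direction = item_map$direction)
  if (!all(c("trait", "direction") %in% names(item_map)))
    stop("`item_map` needs columns `trait` and `direction`")
  if (nrow(item_map) != ncol(Z))
    stop("`item_map` must have one row per response column")
  if (is.null(n_options)) n_options <- max(Z, na.rm = TRUE) + 1L
  C <- as.integer(n_options) - 1L
  vals <- Z[!is.na(Z)]
  if (any(vals < 0) || any(vals > C) || any(vals != round(vals)))
    stop("responses must be integers in 0..", C)
  if (any(colSums(!is.na(Z)) == 0))
    stop("at least one item column is entirely missing")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (anyNA(X))
      stop("missing covariate values are not supported; only response ",
           "data may be missing")
    if (nrow(X) != nrow(Z)) stop("covariate and response row counts differ")
  }
  if (is.null(priors)) priors <- mggum_priors(n_options)
  dir <- match.arg(as.character(item_map$direction),
                   c("negative", "neutral", "positive"), several.ok = TRUE)
  storage.mode(Z) <- "integer"
  structure(list(responses = Z, trait = as.integer(item_map$trait),
                 direction = dir, X = X, C = C,
                 D = max(as.integer(item_map$trait)), priors = priors),
            class = "mggum_model")
}

# Random initial values for one chain: mild jitter around prior centers,
# respecting the sign bounds on directional items.
chain_inits <- function(model) {
  I <- ncol(model$responses); J <- nrow(model$responses)
  D <- model$D; C <- model$C
  P <- if (is.null(model$X)) 0L else ncol(model$X)
  dircode <- c(negative = -1, neutral = 0, positive = 1)[model$direction]
  delta0 <- rnorm(I, mean = dircode, sd = 0.3)
  delta0[model$direction == "positive"] <-
    abs(delta0[model$direction == "positive"])
  delta0[model$direction == "negative"] <-
    -abs(delta0[model$direction == "negative"])
  list(alpha = exp(rnorm(I, 0, 0.2)),
       delta = delta0,
       tau = matrix(rep(model$priors$tau_mean, each = I) + rnorm(I * C, 0, 0.3),
                    nrow = I),
       theta = matrix(rnorm(J * D, 0, 0.5), J, D),
       beta = matrix(0, max(P, 1), D),
       omega = diag(D))
}

#' Fit an MGGUM model by MCMC
#'
#' Runs an adaptive Metropolis-within-Gibbs sampler: slice-sampling and
#' prior-independence updates for person traits; joint adaptive-covariance
#' and slice updates for each item's parameter block (on the log
#' discrimination, location and alpha-scaled threshold scale), with the
#' location sign-bounded by the item's direction; a conjugate Gibbs draw
#' for the latent-regression coefficients; element-wise Metropolis updates
#' of the trait correlation matrix under the flat LKJ(1) prior; and
#' reflection moves that handle the sign symmetries of the unfolding
#' kernel.  Proposal adaptation runs during burn-in only, so the retained
#' draws form a valid Markov chain.  After sampling, Gelman-Rubin
#' statistics are computed for every scalar parameter and the fit is
#' flagged converged iff all are below the configured threshold.
#'
#' @param model An [build_model()] object.
#' @param config An [mcmc_config()].
#' @param store_loglik Keep the draws-by-observations pointwise
#'   log-likelihood matrix (needed for [waic()] / [loo()]).
#' @return An object of class `mggum_fit` with elements `draws` (per-family
#'   arrays of dimension draws x chains x parameters), `rhat`, `converged`,
#'   `estimates`, `ses`, `ci95`, `pointwise_loglik`, and metadata.
#' @export
mggum_fit <- function(model, config = mcmc_config(), store_loglik = TRUE) {
  stopifnot(inherits(model, "mggum_model"))
  J <- nrow(model$responses); I <- ncol(model$responses)
  D <- model$D; C <- model$C
  P <- if (is.null(model$X)) 0L else ncol(model$X)
  Xm <- if (P > 0) model$X else matrix(0, J, 0)
  dircode <- as.integer(c(negative = -1, neutral = 0,
                          positive = 1)[model$direction])
  pr <- model$priors
  delta_pm <- as.numeric(pr$delta_mean[model$direction])
  S <- config$n_iterations - config$n_burnin
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    ini <- chain_inits(model)
    chains[[ch]] <- cpp_run_chain(
      model$responses, model$trait - 1L, dircode, Xm, C,
      config$n_iterations, config$n_burnin,
      pr$tau_mean, pr$tau_sd, pr$alpha_logmean, pr$alpha_logsd,
      delta_pm, pr$delta_sd, pr$beta_sd,
      ini$alpha, ini$delta, ini$tau, ini$theta, ini$beta, ini$omega,
      config$n_person_scans, config$n_item_scans, config$n_warmup_extra,
      store_loglik)
  }

  fam_names <- list(
    alpha = paste0("alpha[", seq_len(I), "]"),
    delta = paste0("delta[", seq_len(I), "]"),
    tau = paste0("tau[", rep(seq_len(I), each = C), ",",
                 rep(seq_len(C), I), "]"),
    theta = paste0("theta[", rep(seq_len(J), D), ",",
                   rep(seq_len(D), each = J), "]"),
    beta = if (P > 0) paste0("beta[", rep(seq_len(P), D), ",",
                             rep(seq_len(D), each = P), "]") else character(),
    omega = if (D > 1) {
      idx <- which(upper.tri(diag(D)), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      paste0("omega[", idx[, 1], ",", idx[, 2], "]")
    } else character())
  # note: C++ emits omega pairs in row-major (a<b) order, matching idx above
  draws <- list()
  for (fam in c("alpha", "delta", "tau", "theta", "beta", "omega")) {
    k <- length(fam_names[[fam]])
    if (k == 0) next
    a <- array(NA_real_, c(S, config$n_chains, k),
               dimnames = list(NULL, NULL, fam_names[[fam]]))
    for (ch in seq_len(config$n_chains))
      a[, ch, ] <- chains[[ch]][[fam]][, seq_len(k), drop = FALSE]
    draws[[fam]] <- a
  }

  flat <- do.call(cbind, lapply(draws, function(a) {
    m <- matrix(a, nrow = S * config$n_chains)
    colnames(m) <- dimnames(a)[[3]]
    m
  }))
  rhat <- unlist(lapply(draws, function(a)
    apply(a, 3, function(m) gelman_rubin(t(m)))))
  names(rhat) <- colnames(flat)
  converged <- all(is.finite(rhat)) && max(rhat) < config$rhat_threshold

  est <- colMeans(flat)
  ses <- apply(flat, 2, sd)
  ci <- t(apply(flat, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lower", "upper")

  ll <- NULL
  if (store_loglik)
    ll <- do.call(rbind, lapply(chains, `[[`, "loglik"))

  structure(list(draws = draws, rhat = rhat, converged = converged,
                 estimates = est, ses = ses, ci95 = ci,
                 pointwise_loglik = ll,
                 model = model, config = config,
                 n_draws = S * config$n_chains,
                 dims = list(J = J, I = I, D = D, C = C, P = P)),
            class = "mggum_fit")
}

#' @export
print.mggum_fit <- function(x, ...) {
  cat(sprintf(paste0("MGGUM fit: J=%d persons, I=%d items, D=%d traits, ",
                     "C=%d, %d covariates\n"),
              x$dims$J, x$dims$I, x$dims$D, x$dims$C, x$dims$P))
  cat(sprintf("%d retained draws (%d chains); max Rhat = %.3f -> %s\n",
              x$n_draws, x$config$n_chains, max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `Rhat = sqrt(((n - 1) / n * W + B / n) / W)` where `W` is the mean
#' within-chain variance and `B` is `n` times the variance of the chain
#' means.  Chains with zero within-chain variance yield `NA` (flagged as
#' nonconverged by the fitting gate).
#'
#' @param x Matrix of draws for one parameter, chains in rows.
#' @return The potential scale reduction factor (scalar).
#' @examples
#' gelman_rubin(rbind(c(0, 2), c(1, 3))) # sqrt(0.75)
#' @export
gelman_rubin <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 chains with at least 2 draws each")
  n <- ncol(x)
  W <- mean(apply(x, 1, var))
  B <- n * var(rowMeans(x))
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior trait-score table
#'
#' @param fit An [mggum_fit()].
#' @return Data frame with person, trait, posterior mean, sd, and 95%
#'   interval bounds.
#' @export
trait_scores <- function(fit) {
  stopifnot(inherits(fit, "mggum_fit"))
  nm <- dimnames(fit$draws$theta)[[3]]
  idx <- do.call(rbind, regmatches(nm, regexec("theta\\[(\\d+),(\\d+)\\]", nm)))
  data.frame(person = as.integer(idx[, 2]), trait = as.integer(idx[, 3]),
             estimate = unname(fit$estimates[nm]), se = unname(fit$ses[nm]),
             lower = unname(fit$ci95[nm, "lower"]),
             upper = unname(fit$ci95[nm, "upper"]))
}

# Posterior-mean theta as a J x D matrix.
theta_estimates <- function(fit) {
  ts <- trait_scores(fit)
  m <- matrix(NA_real_, fit$dims$J, fit$dims$D)
  m[cbind(ts$person, ts$trait)] <- ts$estimate
  m
}

#' Covariate-effect significance
#'
#' A regression coefficient is flagged significant iff its central 95%
#' credible interval excludes zero.
#'
#' @param fit An [mggum_fit()] estimated with covariates.
#' @return Logical `P x D` matrix.
#' @export
covariate_significance <- function(fit) {
  stopifnot(inherits(fit, "mggum_fit"))
  if (fit$dims$P == 0)
    stop("model was fitted without covariates; significance is not applicable")
  nm <- dimnames(fit$draws$beta)[[3]]
  sig <- fit$ci95[nm, "lower"] > 0 | fit$ci95[nm, "upper"] < 0
  matrix(sig, fit$dims$P, fit$dims$D,
         dimnames = list(paste0("x", seq_len(fit$dims$P)),
                         paste0("trait", seq_len(fit$dims$D))))
}

#' Posterior summary table
#'
#' @param object An [mggum_fit()].
#' @param ... Unused.
#' @return Data frame with parameter, estimate, se, 95% interval, and Rhat.
#' @export
summary.mggum_fit <- function(object, ...) {
  data.frame(parameter = names(object$estimates),
             estimate = unname(object$estimates),
             se = unname(object$ses),
             ci2.5 = unname(object$ci95[, "lower"]),
             ci97.5 = unname(object$ci95[, "upper"]),
             rhat = unname(object$rhat[names(object$estimates)]),
             row.names = NULL)
}

#' Write fit outputs as CSV
#'
#' Writes `summary.csv` (parameter, estimate, se, interval, Rhat) and
#' `trait_scores.csv` under `dir`.
#'
#' @param fit An [mggum_fit()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(summary(fit), file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(trait_scores(fit), file.path(dir, "trait_scores.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a responses / covariates / item-map CSV triple
#'
#' Companion reader for datasets written by [write_mggum_data()] or prepared
#' by hand in the same layout.
#'
#' @param dir Directory containing `responses.csv`, `itemmap.csv`, and
#'   optionally `covariates.csv`.
#' @return List with `responses` (integer matrix), `item_map` (data frame),
#'   and `X` (matrix or `NULL`).
#' @export
read_mggum_data <- function(dir) {
  Z <- as.matrix(read.csv(file.path(dir, "responses.csv")))
  storage.mode(Z) <- "integer"
  im <- read.csv(file.path(dir, "itemmap.csv"), stringsAsFactors = FALSE)
  xf <- file.path(dir, "covariates.csv")
  X <- if (file.exists(xf)) as.matrix(read.csv(xf)) else NULL
  list(responses = Z, item_map = im, X = X)
}
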