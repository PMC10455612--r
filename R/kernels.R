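# Pure model kernels: category probabilities, latent-regression mean, and the
# joint log-likelihood.  These are shared by the simulator and the estimator.

#' Response scale descriptor
#'
#' Describes a polytomous response scale with categories `0..C`.  `C` is the
#' number of response options minus one; the unfolding kernel additionally
#' uses `M = 2C + 1`, which is always derived, never stored independently.
#'
#' @param n_options Number of response options (at least 2).
#' @return An object of class `response_scale` with elements `C` and `M`.
#' @examples
#' response_scale(4) # C = 3, M = 7
#' @export
response_scale <- function(n_options) {
  if (!is.numeric(n_options) || length(n_options) != 1L || n_options < 2)
    stop("`n_options` must be a single integer >= 2")
  C <- as.integer(n_options) - 1L
  structure(list(C = C, M = 2L * C + 1L), class = "response_scale")
}

#' @export
print.response_scale <- function(x, ...) {
  cat("response scale: categories 0..", x$C, " (M = ", x$M, ")\n", sep = "")
  invisible(x)
}

#' Item bank for a simple-structure MGGUM
#'
#' Holds per-item discrimination (`alpha`), location (`delta`), the `C`
#' subjective response category thresholds (`tau`, with the implicit
#' `tau_0 = 0` never stored), the single loading trait of each item
#' (between-item simple structure), and a direction label used to set the
#' location prior at estimation time.
#'
#' @param trait Integer vector, the loading dimension of each item (1..D).
#' @param alpha Positive numeric vector of discriminations.
#' @param delta Numeric vector of item locations.
#' @param tau Numeric matrix, items in rows, `C` threshold columns.
#' @param direction Optional character vector in `negative`, `neutral`,
#'   `positive`; defaults to [classify_item_direction()] applied to `delta`.
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(trait, alpha, delta, tau, direction = NULL) {
  tau <- as.matrix(tau)
  I <- length(alpha)
  if (length(delta) != I || nrow(tau) != I || length(trait) != I)
    stop("item parameter lengths are inconsistent")
  if (any(alpha <= 0)) stop("`alpha` must be positive")
  if (is.null(direction)) direction <- classify_item_direction(delta)
  direction <- match.arg(direction, c("negative", "neutral", "positive"),
                         several.ok = TRUE)
  if (length(direction) == 1L) direction <- rep(direction, I)
  structure(list(trait = as.integer(trait), alpha = as.numeric(alpha),
                 delta = as.numeric(delta), tau = tau,
                 direction = direction,
                 D = max(as.integer(trait)), C = ncol(tau)),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat("item bank:", length(x$alpha), "items,", x$D, "traits,",
      x$C, "thresholds per item\n")
  invisible(x)
}

#' GGUM category probabilities
#'
#' Probability of each response category `0..C` under the unidimensional
#' generalized graded unfolding model.  The kernel for category `z` sums two
#' exponential terms, at `z` and its mirror `M - z`, of
#' `alpha * (w * (theta - delta) - sum_{k<=z} tau_k)` with `tau_0 = 0` and
#' `M = 2C + 1`; probabilities are normalized over categories.  Computation is
#' carried out in log space with max-subtraction, so extreme
#' `alpha * (theta - delta)` values do not overflow.
#'
#' @param theta Scalar latent trait value.
#' @param alpha Positive scalar discrimination.
#' @param delta Scalar item location.
#' @param tau Numeric vector of `C` thresholds.
#' @param scale Optional [response_scale()]; when supplied, `length(tau)`
#'   must equal `scale$C`.
#' @return Numeric vector of `C + 1` probabilities summing to 1.
#' @examples
#' ggum_category_probabilities(0, 1, 0, tau = -1) # c(1, e) / (1 + e)
#' @export
ggum_category_probabilities <- function(theta, alpha, delta, tau,
                                        scale = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("`alpha` must be a positive scalar")
  if (!is.null(scale) && length(tau) != scale$C)
    stop("`tau` must have exactly C = ", scale$C, " entries")
  if (length(tau) < 1L) stop("`tau` must have at least one entry")
  cpp_ggum_probs(theta, alpha, delta, as.numeric(tau))
}

#' MGGUM category probabilities
#'
#' Multidimensional unfolding kernel: the signed distance of the
#' unidimensional model is replaced by the weighted Euclidean distance
#' `sqrt(sum_d alpha_d^2 (theta_d - delta_d)^2)` and the thresholds by the
#' multidimensional thresholds `psi_k = sum_d alpha_d tau_k`.  Under
#' between-item simple structure (one nonzero loading) this reduces exactly
#' to [ggum_category_probabilities()] on the loading dimension, because the
#' unidimensional kernel is symmetric about `delta`.
#'
#' @param theta_row Numeric vector of length `D`, one person's traits.
#' @param item A single-item list with elements `trait` (loading dimension),
#'   `alpha`, `delta`, `tau`; or an [item_bank()] together with `which`.
#' @param scale Optional [response_scale()] for threshold-count validation.
#' @param which Item index when `item` is an [item_bank()].
#' @return Numeric vector of `C + 1` probabilities summing to 1.
#' @export
mggum_category_probabilities <- function(theta_row, item, scale = NULL,
                                         which = 1L) {
  if (inherits(item, "item_bank"))
    item <- list(trait = item$trait[which], alpha = item$alpha[which],
                 delta = item$delta[which], tau = item$tau[which, ])
  D <- length(theta_row)
  if (item$trait < 1L || item$trait > D)
    stop("item loading dimension outside 1..D")
  alpha_d <- numeric(D)
  alpha_d[item$trait] <- item$alpha
  if (all(alpha_d == 0)) stop("item has all-zero loadings")
  if (!is.null(scale) && length(item$tau) != scale$C)
    stop("`tau` must have exactly C = ", scale$C, " entries")
  C <- length(item$tau)
  M <- 2L * C + 1L
  dist <- sqrt(sum(alpha_d^2 * (theta_row - item$delta)^2))
  psi <- sum(alpha_d) * as.numeric(item$tau)
  ct <- c(0, cumsum(psi))
  z <- 0:C
  l1 <- z * dist - ct[z + 1L]
  l2 <- (M - z) * dist - ct[z + 1L]
  lp <- pmax(l1, l2) + log1p(exp(-abs(l1 - l2)))
  m <- max(lp)
  p <- exp(lp - m)
  p / sum(p)
}

#' Latent-regression mean
#'
#' Systematic part of the latent regression, `sum_p beta[p, d] * X[j, p]`:
#' the conditional mean of each trait given the person covariates.  The
#' normal residual is handled by the caller (simulator or estimator).
#'
#' @param X Numeric `J x P` covariate matrix.
#' @param beta Numeric `P x D` coefficient matrix.
#' @return Numeric `J x D` matrix of trait means.
#' @export
latent_mean <- function(X, beta) {
  X <- as.matrix(X); beta <- as.matrix(beta)
  if (ncol(X) != nrow(beta))
    stop("shape mismatch: ncol(X) = ", ncol(X), " but nrow(beta) = ",
         nrow(beta))
  X %*% beta
}

#' Joint log-likelihood of a response matrix
#'
#' Sum over non-missing person-by-item cells of the log category probability
#' of the observed response.  Missing cells (coded `NA`) contribute zero:
#' missingness is assumed completely at random and is ignorable in the
#' likelihood.
#'
#' @param responses Integer `J x I` matrix with entries in `0..C`, `NA` for
#'   missing.
#' @param items An [item_bank()].
#' @param persons A [person_sample()] or a plain `J x D` trait matrix.
#' @param scale Optional [response_scale()] used to validate entries.
#' @return Scalar log-likelihood.
#' @export
joint_log_likelihood <- function(responses, items, persons, scale = NULL) {
  theta <- if (inherits(persons, "person_sample")) persons$theta else
    as.matrix(persons)
  Z <- as.matrix(responses)
  C <- items$C
  if (!is.null(scale)) C <- scale$C
  vals <- Z[!is.na(Z)]
  if (length(vals) && (any(vals < 0) || any(vals > C) || any(vals != round(vals))))
    stop("responses must be integers in 0..", C)
  if (nrow(Z) != nrow(theta) || ncol(Z) != length(items$alpha))
    stop("responses, items and persons have inconsistent shapes")
  storage.mode(Z) <- "integer"
  sum(cpp_pointwise_loglik(Z, theta, items$trait - 1L, items$alpha,
                           items$delta, items$tau))
}
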