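#' Gaussian-process surrogate settings
#'
#' The surrogate is a zero-mean Gaussian process (after centering the
#' responses on their mean) with a squared-exponential kernel
#' `k(x, x') = amplitude^2 * exp(-||x - x'||^2 / (2 * lengthscale^2))`,
#' a single length-scale shared across feature dimensions, Gaussian
#' observation noise, and a fixed diagonal jitter for numerical stability.
#'
#' @param lengthscale Kernel length-scale on the feature scale (features are
#'   generated on \[0, 1\]; default 0.2).
#' @param amplitude Kernel amplitude (prior standard deviation of the
#'   latent function). `NULL` (default) uses the standard deviation of the
#'   training responses.
#' @param noise_sd Observation noise standard deviation; default 0.1,
#'   matching the default synthetic library's measurement noise. Set to 0
#'   for exact interpolation.
#' @param jitter Diagonal jitter added to the kernel matrix for numerical
#'   stability; default 1e-8, small enough that noiseless fits interpolate
#'   their training data to within about 1e-6 on modest sample sizes.
#' @param optimize If `TRUE`, amplitude, length-scale and noise are refit by
#'   maximizing the log marginal likelihood (L-BFGS-B on log parameters,
#'   started from the values above).
#' @return A list of class `helo_gp_control`.
#' @export
gp_control <- function(lengthscale = 0.2, amplitude = NULL, noise_sd = 0.1,
                       jitter = 1e-8, optimize = FALSE) {
  stopifnot(lengthscale > 0, is.null(amplitude) || amplitude > 0,
            noise_sd >= 0, jitter >= 0)
  structure(
    list(lengthscale = lengthscale, amplitude = amplitude,
         noise_sd = noise_sd, jitter = jitter, optimize = isTRUE(optimize)),
    class = "helo_gp_control"
  )
}

sqexp_kernel <- function(X1, X2, amplitude, lengthscale) {
  # squared distances via the expansion ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  amplitude^2 * exp(-0.5 * d2 / lengthscale^2)
}

gp_chol <- function(K) {
  tryCatch(
    chol(K),
    error = function(e) {
      stop("kernel matrix is singular or not positive definite; ",
           "increase `jitter` in gp_control()", call. = FALSE)
    }
  )
}

gp_log_marginal <- function(X, yc, amplitude, lengthscale, noise_sd, jitter) {
  n <- length(yc)
  K <- sqexp_kernel(X, X, amplitude, lengthscale) +
    diag(noise_sd^2 + jitter, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  -0.5 * sum(yc * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
}

#' Fit a Gaussian-process QSAR surrogate
#'
#' Fits the predictive model used by the active-learning loop: given the
#' features and activities measured so far, the surrogate returns a Normal
#' predictive distribution (mean and standard deviation) for the activity
#' of any untested compound, which the acquisition functions turn into
#' probabilities of improvement.
#'
#' @param X Numeric matrix (or data frame) of measured compounds' features,
#'   one row per measurement; at least 2 rows, all finite.
#' @param y Numeric vector of measured activities (e.g. pGI50 values).
#' @param control A [gp_control()] list of kernel hyperparameters.
#' @return An object of class `helo_gp` with a [predict()][predict.helo_gp]
#'   method.
#' @examples
#' x <- matrix(seq(0, 1, length.out = 8))
#' fit <- fit_surrogate(x, sin(2 * pi * x[, 1]), gp_control(noise_sd = 0))
#' predict(fit, matrix(0.25))
#' @export
fit_surrogate <- function(X, y, control = gp_control()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(inherits(control, "helo_gp_control"))
  if (nrow(X) < 2L) {
    stop("at least 2 measurements are required to fit the surrogate",
         call. = FALSE)
  }
  if (length(y) != nrow(X)) stop("`y` must match rows of `X`", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("features and activities must be finite", call. = FALSE)
  }
  mean_y <- mean(y)
  yc <- y - mean_y
  amplitude <- control$amplitude %||% max(stats::sd(y), 1e-8)
  lengthscale <- control$lengthscale
  noise_sd <- control$noise_sd

  if (control$optimize) {
    obj <- function(par) {
      -gp_log_marginal(X, yc, exp(par[1]), exp(par[2]), exp(par[3]),
                       control$jitter)
    }
    fit <- stats::optim(
      log(c(amplitude, lengthscale, max(noise_sd, 1e-4))), obj,
      method = "L-BFGS-B", lower = log(1e-4), upper = log(1e3)
    )
    amplitude <- exp(fit$par[1])
    lengthscale <- exp(fit$par[2])
    noise_sd <- exp(fit$par[3])
  }

  K <- sqexp_kernel(X, X, amplitude, lengthscale) +
    diag(noise_sd^2 + control$jitter, nrow(X))
  L <- gp_chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(
    list(X = X, y = y, mean_y = mean_y, L = L, alpha = alpha,
         amplitude = amplitude, lengthscale = lengthscale,
         noise_sd = noise_sd, jitter = control$jitter),
    class = "helo_gp"
  )
}

#' Predictive distribution of a fitted surrogate
#'
#' Returns the Normal predictive distribution of the latent activity at the
#' query rows. Far from all training data the mean reverts to the training
#' mean and the standard deviation approaches the prior amplitude; at a
#' training point with zero noise the mean interpolates the measurement and
#' the standard deviation collapses to (numerically) zero.
#'
#' @param object A `helo_gp`.
#' @param newdata Matrix or data frame of query feature rows.
#' @param ... Unused.
#' @return A tibble with columns `.pred_mean` and `.pred_sd`.
#' @export
predict.helo_gp <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  storage.mode(Xs) <- "double"
  Ks <- sqexp_kernel(Xs, object$X, object$amplitude, object$lengthscale)
  mu <- object$mean_y + as.numeric(Ks %*% object$alpha)
  V <- forwardsolve(t(object$L), t(Ks))
  var <- pmax(object$amplitude^2 - colSums(V^2), 0)
  tibble::tibble(.pred_mean = mu, .pred_sd = sqrt(var))
}

#' @export
print.helo_gp <- function(x, ...) {
  cat("<GP surrogate> n =", nrow(x$X), " d =", ncol(x$X),
      "\n  amplitude =", format(x$amplitude, digits = 4),
      " lengthscale =", format(x$lengthscale, digits = 4),
      " noise_sd =", format(x$noise_sd, digits = 4), "\n")
  invisible(x)
}

#' @exportS3Method
glance.helo_gp <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$X), d = ncol(x$X),
    amplitude = x$amplitude, lengthscale = x$lengthscale,
    noise_sd = x$noise_sd,
    log_marginal = gp_log_marginal(x$X, x$y - x$mean_y, x$amplitude,
                                   x$lengthscale, x$noise_sd, x$jitter)
  )
}

#' Acquisition scores for candidate compounds
#'
#' Given the surrogate's Normal predictive distribution `N(mu, sigma^2)`
#' for a compound's activity and the current k-th best measured activity
#' `y_kbest`, the three informed selection strategies score the compound as:
#'
#' * `acq_mpi()` — most probable improvement: the probability
#'   `P(Y > y_kbest) = pnorm((mu - y_kbest) / sigma)`, in \[0, 1\].
#' * `acq_mei()` — maximum expected improvement:
#'   `E[max(Y - y_kbest, 0)] = (mu - y_kbest) * pnorm(z) + sigma * dnorm(z)`
#'   with `z = (mu - y_kbest) / sigma`, always nonnegative.
#' * `acq_optimistic()` — the confidence-bound criterion oriented for
#'   maximization: `mu + beta * sigma` (optimism under uncertainty).
#'
#' When `sigma` is 0 the predictive is a point mass and the stated limits
#' are used directly (no division): MPI becomes the indicator
#' `mu > y_kbest`, MEI becomes `max(mu - y_kbest, 0)`.
#'
#' All three are vectorized over `mu` and `sigma`.
#'
#' @param mu Predictive mean(s).
#' @param sigma Predictive standard deviation(s), `>= 0`.
#' @param y_kbest Current k-th best measured activity.
#' @param beta Optimism multiplier for the confidence bound, `>= 0`
#'   (default 2).
#' @return Numeric vector of scores.
#' @name acquisition
#' @examples
#' acq_mpi(1, 2, 0)          # P(N(1, 4) > 0)
#' acq_mei(0, 1, 0)          # dnorm(0)
#' acq_optimistic(1, 0.5, 2) # 2.0
NULL

#' @rdname acquisition
#' @export
acq_mpi <- function(mu, sigma, y_kbest) {
  stopifnot(all(sigma >= 0))
  out <- ifelse(sigma > 0,
                stats::pnorm((mu - y_kbest) / ifelse(sigma > 0, sigma, 1)),
                as.numeric(mu > y_kbest))
  as.numeric(out)
}

#' @rdname acquisition
#' @export
acq_mei <- function(mu, sigma, y_kbest) {
  stopifnot(all(sigma >= 0))
  d <- mu - y_kbest
  z <- d / ifelse(sigma > 0, sigma, 1)
  out <- ifelse(sigma > 0,
                d * stats::pnorm(z) + sigma * stats::dnorm(z),
                pmax(d, 0))
  pmax(as.numeric(out), 0)
}

#' @rdname acquisition
#' @export
acq_optimistic <- function(mu, sigma, beta = 2) {
  stopifnot(all(sigma >= 0), all(beta >= 0))
  as.numeric(mu + beta * sigma)
}
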