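#' Fit the PEST-MLE psychometric threshold
#'
#' Maximum-likelihood estimate of the resting-motor-threshold parameter
#' of a cumulative-Gaussian psychometric function from binary trial
#' outcomes. The model is
#' \deqn{P(\mathrm{MEP} > \mathrm{target} \mid x) = \Phi\!\left(\frac{x - t}{\sigma}\right)}
#' with a single free parameter, the threshold \eqn{t}; the spread
#' \eqn{\sigma} is fixed (absolute, in \%MSO) or proportional to \eqn{t}
#' (relative mode). Two virtual anchor trials — an assumed failure at
#' 0 \%MSO and an assumed success at 100 \%MSO — regularise the
#' likelihood so the fit is defined even before both outcome classes
#' have been observed.
#'
#' The negative log-likelihood is minimised over `[lower, upper]` by a
#' coarse bracketing grid followed by bounded scalar minimisation
#' ([stats::optimize()]); if the optimiser fails, a fine grid search is
#' used instead and the result is flagged (`$fallback`). For absolute
#' spread the objective is convex in `t` (the Gaussian CDF is
#' log-concave), so the minimiser is the global one.
#'
#' @param x for the default method, a numeric vector of tested
#'   intensities (\%MSO); for the formula method, a formula such as
#'   `outcome ~ intensity`.
#' @param ... passed between methods.
#' @return an object of class `"pest_mle"`: a list with components
#'   `threshold` (the ML estimate, \%MSO), `spread`, `spread_mode`,
#'   `trials` (data frame of `intensity`, `outcome`, `weight`),
#'   `anchors`, `anchor_weight`, `nll` (minimised value), `bounds`,
#'   `epsilon`, `fallback`, and `call`. Supported methods: `print`,
#'   `summary`, `coef`, `logLik`, `predict`, `fitted`, `residuals`,
#'   `simulate`, and `plot`.
#' @examples
#' fit <- pest_mle(c(40, 60), c(FALSE, TRUE))
#' coef(fit)                         # 50 by symmetry
#' predict(fit, newdata = c(45, 55)) # response probabilities
#' @export
pest_mle <- function(x, ...) UseMethod("pest_mle")

#' @rdname pest_mle
#' @param outcome logical vector of trial outcomes (`TRUE` =
#'   supra-target MEP), same length as `x`.
#' @param weights optional nonnegative per-trial weights.
#' @param spread psychometric spread: `sigma` in \%MSO (absolute mode,
#'   default 3.5) or the dimensionless factor `s` with `sigma = s * t`
#'   (relative mode, a typical value is 0.07).
#' @param spread_mode `"absolute"` (default) or `"relative"`.
#' @param anchors include the virtual boundary trials (failure at
#'   0 \%MSO, success at 100 \%MSO)? Default `TRUE`.
#' @param anchor_weight likelihood weight of each anchor pseudo-trial.
#' @param lower,upper threshold search interval (\%MSO). The default
#'   upper bound of 150 lets "threshold above device maximum" estimates
#'   exist before any capping at 100 \%MSO downstream.
#' @param epsilon probability clipping bound for likelihood stability.
#' @export
pest_mle.default <- function(x, outcome, weights = NULL, spread = 3.5,
                             spread_mode = c("absolute", "relative"),
                             anchors = TRUE, anchor_weight = 1,
                             lower = 1, upper = 150, epsilon = 1e-12,
                             ...) {
  spread_mode <- match.arg(spread_mode)
  intensity <- as.numeric(x)
  outcome <- as.logical(outcome)
  if (length(intensity) != length(outcome)) {
    stop("'x' and 'outcome' must have the same length", call. = FALSE)
  }
  if (anyNA(intensity) || anyNA(outcome)) {
    stop("missing values in trial data", call. = FALSE)
  }
  if (any(intensity < 0 | intensity > 100)) {
    stop("intensities must lie in [0, 100] %MSO", call. = FALSE)
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(intensity), all(weights >= 0))
  }
  if (!is.numeric(spread) || length(spread) != 1L || spread <= 0) {
    stop("'spread' must be a single positive number", call. = FALSE)
  }
  stopifnot(lower > 0, lower < upper)
  if (!anchors && (all(outcome) || !any(outcome))) {
    warning("without anchors the likelihood may be monotone; ",
            "estimate may sit on a search bound", call. = FALSE)
  }

  f <- function(t) .nll_grid(t, intensity, outcome, weights = weights,
                             spread = spread, spread_mode = spread_mode,
                             anchors = anchors,
                             anchor_weight = anchor_weight,
                             epsilon = epsilon)
  # coarse bracket (one vectorised evaluation), then refine
  tgrid <- seq(lower, upper, by = 1)
  coarse <- f(tgrid)
  i <- which.min(coarse)
  lo <- max(lower, tgrid[i] - 1)
  hi <- min(upper, tgrid[i] + 1)
  fallback <- FALSE
  opt <- tryCatch(stats::optimize(f, c(lo, hi), tol = 1e-7),
                  error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    fine <- seq(lo, hi, by = 1e-4)
    v <- f(fine)
    opt <- list(minimum = fine[which.min(v)], objective = min(v))
    fallback <- TRUE
  }
  # guard against a bracket that missed the optimum (non-convex cases)
  if (min(coarse) < opt$objective - 1e-9) {
    fine <- seq(lower, upper, by = 1e-3)
    v <- f(fine)
    opt <- list(minimum = fine[which.min(v)], objective = min(v))
    fallback <- TRUE
  }

  structure(list(
    threshold = opt$minimum,
    spread = spread,
    spread_mode = spread_mode,
    trials = data.frame(
      intensity = intensity, outcome = outcome,
      weight = if (is.null(weights)) rep(1, length(intensity)) else weights
    ),
    anchors = anchors,
    anchor_weight = anchor_weight,
    nll = opt$objective,
    bounds = c(lower = lower, upper = upper),
    epsilon = epsilon,
    fallback = fallback,
    call = match.call()
  ), class = "pest_mle")
}

#' @rdname pest_mle
#' @param formula a two-sided formula, `outcome ~ intensity`.
#' @param data a data frame holding the formula variables.
#' @export
pest_mle.formula <- function(formula, data = parent.frame(), ...) {
  mf <- stats::model.frame(formula, data = data)
  if (ncol(mf) != 2L) {
    stop("formula must be of the form outcome ~ intensity", call. = FALSE)
  }
  out <- pest_mle.default(mf[[2L]], as.logical(mf[[1L]]), ...)
  out$call <- match.call()
  out
}

# ---- methods -------------------------------------------------------------

#' @export
print.pest_mle <- function(x, digits = 4, ...) {
  cat("PEST-MLE psychometric threshold fit\n")
  cat("  threshold:", format(x$threshold, digits = digits), "%MSO\n")
  sig <- if (x$spread_mode == "absolute") {
    paste0(format(x$spread, digits = digits), " %MSO (absolute)")
  } else {
    paste0(format(x$spread, digits = digits), " * t (relative)")
  }
  cat("  spread:   ", sig, "\n")
  cat("  trials:   ", nrow(x$trials),
      if (x$anchors) " (+ 2 virtual anchors)" else "", "\n", sep = "")
  if (x$fallback) cat("  note: grid-search fallback used\n")
  invisible(x)
}

#' @export
coef.pest_mle <- function(object, ...) c(threshold = object$threshold)

#' @export
logLik.pest_mle <- function(object, ...) {
  structure(-object$nll, df = 1L, nobs = nrow(object$trials),
            class = "logLik")
}

#' Predict response probabilities from a fitted threshold
#'
#' @param object a [pest_mle()] fit.
#' @param newdata intensities (\%MSO) to predict at: a numeric vector or
#'   a data frame with an `intensity` column. Defaults to the observed
#'   trial intensities.
#' @param ... unused.
#' @return numeric vector of probabilities of a supra-target MEP.
#' @export
predict.pest_mle <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) {
    object$trials$intensity
  } else if (is.data.frame(newdata)) {
    newdata$intensity
  } else {
    as.numeric(newdata)
  }
  response_probability(xv, object$threshold, object$spread,
                       object$spread_mode, epsilon = 0)
}

#' @export
fitted.pest_mle <- function(object, ...) predict(object)

#' @export
residuals.pest_mle <- function(object,
                               type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  p <- fitted(object)
  y <- as.numeric(object$trials$outcome)
  r <- y - p
  if (type == "pearson") r <- r / sqrt(p * (1 - p))
  r
}

#' @export
simulate.pest_mle <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- fitted(object)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p) == 1))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.pest_mle <- function(object, ...) {
  p <- fitted(object)
  y <- object$trials$outcome
  structure(list(
    fit = object,
    n_trials = nrow(object$trials),
    n_success = sum(y),
    deviance = -2 * as.numeric(logLik(object)),
    mean_abs_resid = if (length(p)) mean(abs(as.numeric(y) - p)) else NA_real_
  ), class = "summary.pest_mle")
}

#' @export
print.summary.pest_mle <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  successes:", x$n_success, "of", x$n_trials, "trials\n")
  cat("  deviance: ", format(x$deviance, digits = digits), "\n")
  if (is.finite(x$mean_abs_resid)) {
    cat("  mean |response residual|:",
        format(x$mean_abs_resid, digits = digits), "\n")
  }
  invisible(x)
}

#' Plot a fitted psychometric function
#'
#' Draws the fitted cumulative-Gaussian response curve with the observed
#' trials as points at 0/1 (jittered vertically if `jitter > 0`).
#'
#' @param x a [pest_mle()] fit.
#' @param xlim intensity range to draw; defaults to the data range
#'   padded by 3 spreads.
#' @param jitter vertical jitter applied to the outcome points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pest_mle <- function(x, xlim = NULL, jitter = 0.02, ...) {
  sig <- if (x$spread_mode == "absolute") x$spread else x$spread * x$threshold
  if (is.null(xlim)) {
    rng <- range(x$trials$intensity, x$threshold)
    xlim <- c(max(0, rng[1] - 3 * sig), min(150, rng[2] + 3 * sig))
  }
  xv <- seq(xlim[1], xlim[2], length.out = 200)
  graphics::plot(xv, predict(x, xv), type = "l",
                 xlab = "intensity (%MSO)",
                 ylab = "P(MEP > target)", ylim = c(-0.05, 1.05), ...)
  y <- as.numeric(x$trials$outcome)
  if (jitter > 0) y <- y + stats::runif(length(y), -jitter, jitter)
  graphics::points(x$trials$intensity, y, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.6))
  graphics::abline(v = x$threshold, lty = 2, col = "grey40")
  graphics::abline(h = 0.5, lty = 3, col = "grey70")
  invisible(x)
}
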