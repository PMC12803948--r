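#' Cumulative-Gaussian response probability
#'
#' Probability that a TMS pulse at intensity `x` evokes a motor evoked
#' potential (MEP) larger than the target amplitude, under the
#' one-parameter psychometric model `Phi((x - threshold) / sigma)` with
#' `Phi` the standard normal CDF.
#'
#' The spread `sigma` is either fixed in \%MSO units
#' (`spread_mode = "absolute"`, the default) or proportional to the
#' threshold, `sigma = spread * threshold`
#' (`spread_mode = "relative"`, as in the original PEST literature where
#' the slope scales with intensity). Probabilities are clipped to
#' `[epsilon, 1 - epsilon]` so that log-likelihood terms stay finite even
#' for the virtual anchor trials at 0 and 100 \%MSO.
#'
#' @param x stimulation intensity (\%MSO), numeric vector.
#' @param threshold psychometric threshold `t` (\%MSO), scalar, the
#'   intensity at which the response probability is exactly 0.5.
#' @param spread curve spread: `sigma` in \%MSO (absolute mode) or the
#'   dimensionless slope factor `s` (relative mode). Must be positive.
#' @param spread_mode `"absolute"` or `"relative"`.
#' @param epsilon clipping bound keeping probabilities away from 0 and 1;
#'   set to 0 for the raw CDF value.
#' @return numeric vector of probabilities, same length as `x`.
#' @examples
#' response_probability(50, threshold = 50, spread = 3.5)    # 0.5
#' response_probability(53.5, threshold = 50, spread = 3.5)  # pnorm(1)
#' @seealso [pest_mle()], [negative_log_likelihood()]
#' @export
response_probability <- function(x, threshold, spread = 3.5,
                                 spread_mode = c("absolute", "relative"),
                                 epsilon = 1e-12) {
  spread_mode <- match.arg(spread_mode)
  stopifnot(is.numeric(x), all(is.finite(x)),
            is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  if (!is.numeric(spread) || length(spread) != 1L || !is.finite(spread) ||
      spread <= 0) {
    stop("'spread' must be a single positive number", call. = FALSE)
  }
  sigma <- if (spread_mode == "absolute") spread else spread * abs(threshold)
  if (sigma <= 0) stop("effective spread is not positive", call. = FALSE)
  p <- stats::pnorm((x - threshold) / sigma)
  if (epsilon > 0) p <- pmin(pmax(p, epsilon), 1 - epsilon)
  p
}

# Vectorised NLL over a grid of candidate thresholds.
# intensity/outcome/weights describe the observed trials; anchors add the
# virtual failure at 0 %MSO and success at 100 %MSO.
.nll_grid <- function(tgrid, intensity, outcome, weights = NULL,
                      spread = 3.5, spread_mode = "absolute",
                      anchors = TRUE, anchor_weight = 1,
                      epsilon = 1e-12) {
  if (anchors) {
    intensity <- c(intensity, 0, 100)
    outcome <- c(outcome, FALSE, TRUE)
    weights <- c(if (is.null(weights)) rep(1, length(outcome) - 2L) else weights,
                 anchor_weight, anchor_weight)
  } else if (is.null(weights)) {
    weights <- rep(1, length(intensity))
  }
  n <- length(intensity)
  if (n == 0L) return(rep(0, length(tgrid)))
  sigma <- if (spread_mode == "absolute") spread else spread * abs(tgrid)
  # z: n x length(tgrid)
  z <- outer(intensity, tgrid, "-") /
    rep(sigma, each = n)
  # log-scale tail probabilities: symmetric in accuracy for p and 1-p,
  # then clipped below at log(epsilon) (== clipping p into [eps, 1-eps])
  logp <- stats::pnorm(z, log.p = TRUE)
  log1mp <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  if (epsilon > 0) {
    leps <- log(epsilon)
    logp <- pmax(logp, leps)
    log1mp <- pmax(log1mp, leps)
  }
  y <- as.numeric(outcome)
  ll <- y * logp + (1 - y) * log1mp
  -colSums(ll * weights)
}

#' Negative log-likelihood of a candidate threshold
#'
#' Bernoulli negative log-likelihood of the observed trial outcomes under
#' the cumulative-Gaussian psychometric model, evaluated at one or more
#' candidate thresholds. By default the two virtual anchor trials are
#' included: an assumed failure at 0 \%MSO and an assumed success at
#' 100 \%MSO, each entering as a pseudo-trial with weight
#' `anchor_weight`.
#'
#' @param intensity tested intensities (\%MSO), numeric vector (may be
#'   empty; the anchors still apply).
#' @param outcome logical vector, `TRUE` for a supra-target MEP.
#' @param threshold candidate threshold(s) `t` (\%MSO); vectorised.
#' @param weights optional per-trial weights (default all 1).
#' @param anchors include the virtual boundary trials? Default `TRUE`.
#' @param anchor_weight weight of each anchor pseudo-trial.
#' @inheritParams response_probability
#' @return numeric vector of NLL values, one per element of `threshold`.
#' @examples
#' # anchors only: both anchor probabilities are ~1, so NLL ~ 0
#' negative_log_likelihood(numeric(0), logical(0), threshold = 50)
#' # a single success at the threshold adds -log(0.5)
#' negative_log_likelihood(50, TRUE, threshold = 50)
#' @export
negative_log_likelihood <- function(intensity, outcome, threshold,
                                    spread = 3.5,
                                    spread_mode = c("absolute", "relative"),
                                    weights = NULL,
                                    anchors = TRUE, anchor_weight = 1,
                                    epsilon = 1e-12) {
  spread_mode <- match.arg(spread_mode)
  stopifnot(length(intensity) == length(outcome),
            is.numeric(threshold), length(threshold) >= 1L)
  if (any(!is.finite(threshold)) || any(threshold <= 0)) {
    stop("'threshold' must be finite and positive", call. = FALSE)
  }
  if (!is.numeric(spread) || spread <= 0) {
    stop("'spread' must be positive", call. = FALSE)
  }
  .nll_grid(threshold, as.numeric(intensity), as.logical(outcome),
            weights = weights, spread = spread, spread_mode = spread_mode,
            anchors = anchors, anchor_weight = anchor_weight,
            epsilon = epsilon)
}

#' Exhaustive grid search for the ML threshold
#'
#' Evaluates the negative log-likelihood on a regular grid over
#' `[lower, upper]` and returns the global minimiser, breaking ties
#' toward the lower intensity. This is the brute-force reference
#' minimiser against which [pest_mle()] is validated; it is exact to the
#' grid resolution but slow at fine resolutions.
#'
#' @inheritParams negative_log_likelihood
#' @param resolution grid step in \%MSO (> 0).
#' @param lower,upper search interval bounds (\%MSO).
#' @return list with `threshold` (the argmin), `nll` (its NLL), and
#'   `resolution`.
#' @examples
#' grid_search_threshold(c(60, 40), c(TRUE, FALSE), resolution = 0.01)
#' @export
grid_search_threshold <- function(intensity, outcome, spread = 3.5,
                                  spread_mode = c("absolute", "relative"),
                                  weights = NULL, anchors = TRUE,
                                  anchor_weight = 1, epsilon = 1e-12,
                                  resolution = 0.01,
                                  lower = 1, upper = 150) {
  spread_mode <- match.arg(spread_mode)
  stopifnot(is.numeric(resolution), length(resolution) == 1L,
            resolution > 0, lower < upper)
  tgrid <- seq(lower, upper, by = resolution)
  nll <- .nll_grid(tgrid, as.numeric(intensity), as.logical(outcome),
                   weights = weights, spread = spread,
                   spread_mode = spread_mode, anchors = anchors,
                   anchor_weight = anchor_weight, epsilon = epsilon)
  i <- which.min(nll)  # which.min returns the first (lowest-t) minimiser
  list(threshold = tgrid[i], nll = nll[i], resolution = resolution)
}
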