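#' Time-averaged mean squared displacement of a track
#'
#' Computes the time-averaged MSD over all ordered same-lag sample pairs:
#' `MSD(k * dt) = mean_i |r(i + k) - r(i)|^2`. MSD(0) = 0 by convention and
#' is not returned as a row. The number of lags is
#' `max(min_lags, floor(max_lag_fraction * (n - 1)))`, capped at `n - 1`;
#' the `min_lags` floor guarantees that even the shortest analyzable tracks
#' (8 frames) provide the 4 points the power-law and directed fits need.
#'
#' @param track A [gc_track()] with at least 2 samples.
#' @param max_lag_fraction Fraction of the track length up to which lags are
#'   computed.
#' @param min_lags Minimum number of lags, track length permitting.
#' @return An `msd_curve` data frame with columns `lag` (frames), `tau` (s),
#'   `msd` (um^2) and `n_pairs`.
#' @examples
#' tr <- gc_track(1, t = seq(0, 5, 0.5), x = 0.1 * seq(0, 5, 0.5), y = 0)
#' compute_msd(tr)
#' @export
compute_msd <- function(track, max_lag_fraction = 0.25, min_lags = 4L) {
  n <- n_frames(track)
  if (n < 2L) stop("cannot compute an MSD from fewer than 2 samples",
                   call. = FALSE)
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("max_lag_fraction must be in (0, 1]", call. = FALSE)
  max_lag <- min(n - 1L, max(as.integer(min_lags),
                             floor(max_lag_fraction * (n - 1L))))
  lags <- seq_len(max_lag)
  msd <- numeric(max_lag)
  np <- integer(max_lag)
  for (k in lags) {
    dx <- track$x[(1L + k):n] - track$x[1L:(n - k)]
    dy <- track$y[(1L + k):n] - track$y[1L:(n - k)]
    msd[k] <- mean(dx * dx + dy * dy)
    np[k] <- n - k
  }
  structure(data.frame(lag = lags, tau = lags * track$frame_interval,
                       msd = msd, n_pairs = np),
            class = c("msd_curve", "data.frame"))
}

#' Anomalous-diffusion power-law fit of an MSD curve
#'
#' Fits `MSD = 4 D tau^alpha` by ordinary least squares in log-log space
#' (zero MSD values are excluded; the exponent is clamped to `[0, 2]`). The
#' exponent alpha separates confined (low alpha), Brownian (alpha near 1)
#' and directed (high alpha) motion.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @return A `motion_fit` list with elements `D` (um^2/s), `alpha`, `model =
#'   "power"`, `V = NA`, `fit_window` (number of lags used) and `degenerate`
#'   (TRUE when fewer than 2 positive MSD values were available, in which
#'   case `D = 0` and `alpha = NA`).
#' @export
fit_msd_power <- function(msd) {
  ok <- msd$msd > 0
  if (sum(ok) < 2L)
    return(motion_fit(D = 0, alpha = NA_real_, model = "power",
                      fit_window = sum(ok), degenerate = TRUE))
  fit <- stats::lm.fit(cbind(1, log(msd$tau[ok])), log(msd$msd[ok]))
  alpha <- min(max(fit$coefficients[2], 0), 2)
  motion_fit(D = exp(fit$coefficients[1]) / 4, alpha = unname(alpha),
             model = "power", fit_window = sum(ok))
}

#' Directed-motion fit of an MSD curve
#'
#' Fits `MSD = 4 D tau + V^2 tau^2` by nonnegative least squares on the
#' regressors `(4 tau, tau^2)` and reports the drift speed `V` (um/s). A
#' negative unconstrained coefficient is clamped to zero and flagged.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @return A `motion_fit` with `model = "directed"`, elements `D`, `V`,
#'   `fit_window`, and `clamped` (TRUE when a coefficient hit the bound).
#' @export
fit_msd_directed <- function(msd) {
  X <- cbind(4 * msd$tau, msd$tau^2)
  y <- msd$msd
  beta <- nnls2(X, y)
  motion_fit(D = beta$coef[1], alpha = NA_real_, model = "directed",
             V = sqrt(beta$coef[2]), fit_window = nrow(msd),
             clamped = beta$clamped)
}

# exact nonnegative least squares for two regressors: try the unconstrained
# solution, else the best single-regressor fit with a nonnegative coefficient
nnls2 <- function(X, y) {
  b <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) c(NA, NA))
  if (!anyNA(b) && all(b >= 0)) return(list(coef = unname(b), clamped = FALSE))
  cand <- list(c(max(0, sum(X[, 1] * y) / sum(X[, 1]^2)), 0),
               c(0, max(0, sum(X[, 2] * y) / sum(X[, 2]^2))),
               c(0, 0))
  sse <- vapply(cand, function(cf) sum((y - X %*% cf)^2), numeric(1))
  list(coef = cand[[which.min(sse)]], clamped = TRUE)
}

motion_fit <- function(D, alpha, model, V = NA_real_, fit_window = NA_integer_,
                       degenerate = FALSE, clamped = FALSE) {
  structure(list(D = unname(D), alpha = alpha, model = model, V = unname(V),
                 fit_window = fit_window, degenerate = degenerate,
                 clamped = clamped),
            class = "motion_fit")
}

#' @export
print.motion_fit <- function(x, ...) {
  cat(sprintf("<motion_fit [%s]: D = %.4g um^2/s", x$model, x$D))
  if (!is.na(x$alpha)) cat(sprintf(", alpha = %.3g", x$alpha))
  if (!is.na(x$V)) cat(sprintf(", V = %.4g um/s", x$V))
  if (isTRUE(x$degenerate)) cat(" (degenerate)")
  cat(">\n")
  invisible(x)
}

#' Classify a trajectory by its anomalous exponent
#'
#' Motion classes follow the simulation-calibrated thresholds: confined for
#' `alpha < alpha_confined` (0.5), Brownian for intermediate alpha, directed
#' for `alpha >= alpha_directed` (1.5, boundary inclusive).
#'
#' @param fit A `motion_fit` from [fit_msd_power()], or a numeric alpha
#'   vector.
#' @param th A [class_thresholds()].
#' @return Character vector in `{"confined", "brownian", "directed"}`
#'   (`NA` for degenerate fits).
#' @export
classify_alpha <- function(fit, th = class_thresholds()) {
  alpha <- if (inherits(fit, "motion_fit")) fit$alpha else fit
  out <- ifelse(alpha >= th$alpha_directed, "directed",
                ifelse(alpha < th$alpha_confined, "confined", "brownian"))
  out[is.na(alpha)] <- NA_character_
  out
}

#' Diffusion coefficient from the initial MSD slope
#'
#' `D = slope / 4` from a straight-line fit (with intercept, absorbing the
#' localization-error offset) through the first `n_points` MSD lags -- the
#' convention of fitting the first 4 points (80 ms at 20 Hz). A non-positive
#' slope means the molecule explored less area than the localization
#' accuracy; such trajectories are arbitrarily assigned the sentinel
#' `th$D_sentinel` (1e-5 um^2/s) and classify as confined.
#'
#' @param msd An `msd_curve` with at least `n_points` lags.
#' @param n_points Number of initial lags in the fit.
#' @param th A [class_thresholds()] supplying the sentinel.
#' @return Diffusion coefficient (um^2/s).
#' @export
diffusion_from_initial_slope <- function(msd, n_points = 4L,
                                         th = class_thresholds()) {
  if (nrow(msd) < n_points)
    stop("MSD curve has fewer than ", n_points, " lags", call. = FALSE)
  i <- seq_len(n_points)
  fit <- stats::lm.fit(cbind(1, msd$tau[i]), msd$msd[i])
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope <= 0) return(th$D_sentinel)
  slope / 4
}

#' Classify mobility from the diffusion coefficient
#'
#' Confined if `D < D_confined` (strict, so a molecule exactly at the
#' threshold counts as mobile); the sentinel value always classifies as
#' confined.
#'
#' @param D Numeric vector of diffusion coefficients (um^2/s).
#' @param th A [class_thresholds()].
#' @return Character vector in `{"confined", "mobile"}`.
#' @export
classify_mobility <- function(D, th = class_thresholds()) {
  ifelse(D < th$D_confined, "confined", "mobile")
}

#' Fit and classify every track of a set
#'
#' Runs the per-trajectory analysis chain on each track: MSD, power-law fit
#' (D, alpha), motion class, and -- for directed trajectories -- the
#' directed-model drift speed V.
#'
#' @param ts A [trackset()] (normally already length-filtered with
#'   [filter_tracks()]).
#' @param th A [class_thresholds()].
#' @param max_lag_fraction,min_lags Passed to [compute_msd()].
#' @return A data frame with one row per track: `id`, `n_frames`, `D`,
#'   `alpha`, `class`, `V` (NA unless directed).
#' @export
classify_tracks <- function(ts, th = class_thresholds(),
                            max_lag_fraction = 0.25, min_lags = 4L) {
  rows <- lapply(ts$tracks, function(tr) {
    msd <- compute_msd(tr, max_lag_fraction, min_lags)
    pf <- fit_msd_power(msd)
    cls <- classify_alpha(pf, th)
    V <- NA_real_
    if (identical(cls, "directed")) V <- fit_msd_directed(msd)$V
    data.frame(id = as.character(tr$id), n_frames = n_frames(tr),
               D = pf$D, alpha = pf$alpha, class = cls, V = V,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(0), n_frames = integer(0),
                      D = numeric(0), alpha = numeric(0),
                      class = character(0), V = numeric(0))
  out
}

#' Motion-class fractions of a classified set
#'
#' @param fits Data frame from [classify_tracks()].
#' @return Named numeric vector `(confined, brownian, directed)` summing
#'   to 1 (over non-degenerate fits).
#' @export
class_fractions <- function(fits) {
  cls <- fits$class[!is.na(fits$class)]
  n <- length(cls)
  if (!n) return(c(confined = NA_real_, brownian = NA_real_,
                   directed = NA_real_))
  c(confined = sum(cls == "confined") / n,
    brownian = sum(cls == "brownian") / n,
    directed = sum(cls == "directed") / n)
}
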