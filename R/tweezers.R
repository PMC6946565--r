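#' Stokes drag force on a trapped microsphere
#'
#' `F = 6 * pi * eta * R * V` for a sphere of radius `R` in a fluid of
#' viscosity `eta` moving at relative velocity `V`. With R in um, V in um/s
#' and eta in Pa.s the numeric product is already in pN (the 1e-12 factors
#' from the um conversions cancel the N -> pN factor).
#'
#' @param R Bead radius (um).
#' @param eta Fluid viscosity (Pa.s).
#' @param V Flow velocity (um/s).
#' @return Drag force (pN).
#' @examples
#' stokes_drag(R = 0.5, eta = 1e-3, V = 60)  # ~0.57 pN
#' @export
stokes_drag <- function(R = 0.5, eta = 1e-3, V = 60) {
  if (any(R <= 0) || any(eta <= 0) || any(V < 0))
    stop("R and eta must be > 0 and V >= 0", call. = FALSE)
  6 * pi * eta * R * V
}

#' Calibrate trap stiffness from force and displacement
#'
#' For a single (force, displacement) pair returns `kappa = F / delta`. For
#' vectors of measurements at several laser powers or flow speeds, fits the
#' zero-intercept regression `F = kappa * delta` by least squares (the trap
#' is linear over the working range).
#'
#' @param F Applied force(s) (pN), e.g. from [stokes_drag()].
#' @param delta Steady-state bead displacement(s) from the trap center (um).
#' @return Trap stiffness kappa (pN/um).
#' @export
calibrate_trap <- function(F, delta) {
  if (length(F) != length(delta))
    stop("F and delta must have equal length", call. = FALSE)
  if (any(delta <= 0)) stop("delta must be > 0", call. = FALSE)
  if (length(F) == 1L) return(F / delta)
  sum(F * delta) / sum(delta^2)
}

#' Minimal escape force of the optical trap
#'
#' The force needed to pull the bead out of the trap, reached when the bead
#' displacement equals the escape distance (taken as the bead radius):
#' `F_escape = kappa * R`. At the study's maximal laser power
#' (kappa = 4.7 pN/um, R = 0.5 um) this is about 2.3 pN.
#'
#' @param kappa Trap stiffness (pN/um).
#' @param R Escape distance = bead radius (um).
#' @return Escape force (pN).
#' @examples
#' escape_force(kappa = 4.7, R = 0.5)
#' @export
escape_force <- function(kappa, R = 0.5) kappa * R

#' Bead displacement track
#'
#' @param t Times (s), strictly increasing.
#' @param displacement Distance from the trap center (um), or `NULL` when
#'   `x`/`y` positions are given (displacement is then measured from the
#'   first sample).
#' @param x,y Optional raw bead positions (um).
#' @return A `bead_track` data frame with columns `t`, `displacement`.
#' @export
bead_track <- function(t, displacement = NULL, x = NULL, y = NULL) {
  if (is.null(displacement)) {
    if (is.null(x) || is.null(y))
      stop("give either displacement or x and y", call. = FALSE)
    displacement <- sqrt((x - x[1])^2 + (y - y[1])^2)
  }
  if (any(diff(t) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(displacement < 0))
    stop("displacement must be >= 0", call. = FALSE)
  structure(data.frame(t = t, displacement = displacement),
            class = c("bead_track", "data.frame"))
}

#' Detect trap escape and post-escape velocity of a bead
#'
#' A bead has escaped when its displacement from the trap center first
#' exceeds `escape_radius` (the bead radius) and stays above it for
#' `persistence` consecutive samples (rejecting single-frame noise spikes).
#' The post-escape velocity is the ordinary-least-squares slope of
#' displacement versus time restricted to the peripheral displacement band
#' `velocity_window` (1--4 um), after escape.
#'
#' @param track A [bead_track()].
#' @param escape_radius Escape distance (um).
#' @param velocity_window Displacement band (um) for the velocity fit.
#' @param persistence Consecutive above-threshold samples required.
#' @return An `escape_result` list: `escaped`, `escape_time` (s, NA if
#'   never), `post_escape_velocity` (um/s, NA when undefined, flagged by
#'   `velocity_defined`).
#' @export
analyze_bead_track <- function(track, escape_radius = 0.5,
                               velocity_window = c(1, 4),
                               persistence = 2L) {
  d <- track$displacement; t <- track$t
  n <- length(d)
  above <- d > escape_radius
  esc_i <- NA_integer_
  if (n >= persistence) {
    run <- stats::filter(as.numeric(above), rep(1, persistence),
                         sides = 1)
    hits <- which(run == persistence)
    if (length(hits)) esc_i <- hits[1] - persistence + 1L
  }
  escaped <- !is.na(esc_i)
  vel <- NA_real_; vel_def <- FALSE
  if (escaped) {
    sel <- seq_len(n) >= esc_i & d >= velocity_window[1] &
      d <= velocity_window[2]
    if (sum(sel) >= 2L) {
      cf <- stats::lm.fit(cbind(1, t[sel]), d[sel])$coefficients
      vel <- unname(cf[2]); vel_def <- TRUE
    }
  }
  structure(list(escaped = escaped,
                 escape_time = if (escaped) t[esc_i] else NA_real_,
                 post_escape_velocity = vel, velocity_defined = vel_def),
            class = "escape_result")
}

#' Escape probability over an observation window
#'
#' Fraction of beads that escaped the trap within the first `window` seconds
#' of their recordings (60 s, i.e. the first half of a 2 min recording).
#'
#' @param results List of `escape_result` objects from
#'   [analyze_bead_track()].
#' @param window Observation window (s).
#' @return Fraction in `[0, 1]`.
#' @export
escape_probability <- function(results, window = 60) {
  if (!length(results)) stop("no escape results given", call. = FALSE)
  hits <- vapply(results, function(r)
    isTRUE(r$escaped) && r$escape_time <= window, logical(1))
  mean(hits)
}

#' Mean escape time of the beads that escaped
#'
#' Averages `escape_time` over escaped beads only, the convention used when
#' reporting the time needed to leave the trap (beads that never escape are
#' excluded, not censored).
#'
#' @param results List of `escape_result` objects.
#' @return Mean escape time (s), NA if no bead escaped.
#' @export
mean_escape_time <- function(results) {
  et <- vapply(results, function(r)
    if (isTRUE(r$escaped)) r$escape_time else NA_real_, numeric(1))
  if (all(is.na(et))) NA_real_ else mean(et, na.rm = TRUE)
}

#' Simulate a trapped-then-escaping bead track
#'
#' Synthetic dwell-then-drift displacement series emulating a 2 min, 5 Hz
#' DIC recording: bounded jitter around the trap center until
#' `escape_time`, then linear drift with the retrograde flow at `flow_V`
#' from the escape radius outward, plus optional Gaussian noise.
#'
#' @param escape_time Constructed escape time (s); values beyond `duration`
#'   mean the bead never escapes.
#' @param flow_V Post-escape drift speed (um/s).
#' @param noise Jitter / measurement noise SD (um).
#' @param duration Recording length (s).
#' @param rate Sampling rate (Hz).
#' @param escape_radius Escape distance (um).
#' @param seed Optional RNG seed.
#' @return A [bead_track()].
#' @examples
#' tr <- simulate_bead_track(escape_time = 30, flow_V = 0.12)
#' analyze_bead_track(tr)$post_escape_velocity
#' @export
simulate_bead_track <- function(escape_time = 30, flow_V = 0.12,
                                noise = 0, duration = 120, rate = 5,
                                escape_radius = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / rate)
  d <- numeric(length(t))
  pre <- t <= escape_time
  if (noise > 0)
    d[pre] <- pmin(abs(stats::rnorm(sum(pre), sd = noise)),
                   0.8 * escape_radius)
  post <- !pre
  if (any(post)) {
    d[post] <- escape_radius + flow_V * (t[post] - escape_time)
    if (noise > 0)
      d[post] <- pmax(d[post] + stats::rnorm(sum(post), sd = noise), 0)
  }
  bead_track(t, displacement = d)
}
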