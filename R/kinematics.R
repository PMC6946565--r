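#' Growth-cone centroid kinematics
#'
#' Summarizes a growth-cone centroid trajectory from a DIC time lapse
#' (typically 1 frame/min for 45 min). The global velocity is the total path
#' length divided by the total recording time. A pause is a maximal run of at
#' least `pause_min` seconds during which every position stays within
#' `pause_eps` of the run's first position ("no movement of the centroid for
#' one minute or more"); the velocity excluding pauses uses only path length
#' and time accumulated outside pauses.
#'
#' @param centroid A [gc_track()] of centroid positions (um, s).
#' @param pause_min Minimum pause duration (s).
#' @param pause_eps Maximum centroid excursion that still counts as "no
#'   movement" (um).
#' @return A `kinematics_result` list: `mean_velocity` (um/min), `pauses`
#'   (data frame of start s / duration s), `total_pause_time` (s),
#'   `velocity_excluding_pauses` (um/min).
#' @examples
#' t <- seq(0, 45 * 60, by = 60)
#' tr <- gc_track("gc", t, x = t / 60, y = 0)  # 1 um/min, no pauses
#' growth_cone_kinematics(tr)$mean_velocity
#' @export
growth_cone_kinematics <- function(centroid, pause_min = 60,
                                   pause_eps = 0.5) {
  n <- n_frames(centroid)
  if (n < 2L) stop("need at least 2 centroid samples", call. = FALSE)
  if (pause_eps <= 0) stop("pause_eps must be > 0", call. = FALSE)
  x <- centroid$x; y <- centroid$y; t <- centroid$t
  step <- sqrt(diff(x)^2 + diff(y)^2)
  total_time <- t[n] - t[1]
  mean_velocity <- sum(step) / (total_time / 60)

  # greedy scan for maximal anchored runs of immobility
  pauses <- list()
  in_pause <- rep(FALSE, n - 1L)  # marks intervals inside a pause
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n &&
           sqrt((x[j + 1L] - x[i])^2 + (y[j + 1L] - y[i])^2) <= pause_eps)
      j <- j + 1L
    if (j > i && t[j] - t[i] >= pause_min) {
      pauses[[length(pauses) + 1L]] <-
        data.frame(start = t[i], duration = t[j] - t[i])
      in_pause[i:(j - 1L)] <- TRUE
      i <- j
    } else i <- i + 1L
  }
  pauses <- if (length(pauses)) do.call(rbind, pauses) else
    data.frame(start = numeric(0), duration = numeric(0))
  total_pause <- sum(pauses$duration)
  time_moving <- total_time - total_pause
  vel_ex <- if (time_moving > 0)
    sum(step[!in_pause]) / (time_moving / 60) else NA_real_
  structure(list(mean_velocity = mean_velocity, pauses = pauses,
                 total_pause_time = total_pause,
                 velocity_excluding_pauses = vel_ex),
            class = "kinematics_result")
}

#' @export
print.kinematics_result <- function(x, ...) {
  cat(sprintf("<kinematics: %.3g um/min overall, %d pause(s) totalling %g s, %.3g um/min excluding pauses>\n",
              x$mean_velocity, nrow(x$pauses), x$total_pause_time,
              x$velocity_excluding_pauses))
  invisible(x)
}

#' EB3 comet velocity and lifetime
#'
#' The velocity of a microtubule plus-end (EB3) comet comes from the
#' directed-motion MSD fit `4 D tau + V^2 tau^2`; its lifetime is the number
#' of time points divided by the acquisition rate (2 Hz by default, i.e.
#' frames / 2 seconds).
#'
#' @param track A [gc_track()] of one comet.
#' @param rate_hz Acquisition rate (frames/s).
#' @param max_lag_fraction Passed to [compute_msd()].
#' @return A list with `V` (um/s) and `lifetime` (s).
#' @export
eb3_metrics <- function(track, rate_hz = 2, max_lag_fraction = 0.5) {
  msd <- compute_msd(track, max_lag_fraction = max_lag_fraction)
  fit <- fit_msd_directed(msd)
  list(V = fit$V, lifetime = n_frames(track) / rate_hz)
}
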