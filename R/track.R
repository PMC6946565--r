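#' Single-molecule track
#'
#' A track is the time-stamped 2D trajectory of one molecule: strictly
#' increasing, evenly spaced times `t` (s) and positions `x`, `y` (um), with
#' an optional per-sample state label (`"FREE"`, `"FLOW"` or `"BOUND"`) when
#' produced by the simulator.
#'
#' @param id Track identifier (integer or character).
#' @param t Numeric vector of times (s), strictly increasing, constant
#'   spacing.
#' @param x,y Numeric position vectors (um), same length as `t`.
#' @param state Optional character vector of per-sample molecule states.
#' @param frame_interval Frame interval (s); inferred from `t` when missing.
#' @return An object of class `gc_track`.
#' @seealso [trackset()], [compute_msd()]
#' @export
gc_track <- function(id, t, x, y, state = NULL, frame_interval = NULL) {
  n <- length(t)
  if (length(x) == 1L) x <- rep(x, n)
  if (length(y) == 1L) y <- rep(y, n)
  if (length(x) != n || length(y) != n)
    stop("t, x, y must have equal length", call. = FALSE)
  if (n >= 2L) {
    dts <- diff(t)
    if (any(dts <= 0))
      stop("track ", id, ": times must be strictly increasing", call. = FALSE)
    if (max(dts) - min(dts) > 1e-6 * max(dts))
      stop("track ", id, ": times must be evenly spaced", call. = FALSE)
    if (is.null(frame_interval)) frame_interval <- dts[1]
  }
  if (!is.null(state)) {
    state <- as.character(state)
    if (length(state) != n)
      stop("state must match t in length", call. = FALSE)
    bad <- setdiff(unique(state), c("FREE", "FLOW", "BOUND"))
    if (length(bad))
      stop("unknown molecule state(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(list(id = id, t = as.numeric(t), x = as.numeric(x),
                 y = as.numeric(y), state = state,
                 frame_interval = frame_interval),
            class = "gc_track")
}

#' Number of samples in a track
#' @param track A [gc_track()].
#' @return Integer sample count.
#' @export
n_frames <- function(track) length(track$t)

#' @export
print.gc_track <- function(x, ...) {
  cat(sprintf("<gc_track '%s': %d samples at %s s interval>\n", x$id,
              n_frames(x),
              if (is.null(x$frame_interval)) "?" else
                format(x$frame_interval)))
  invisible(x)
}

#' @export
as.data.frame.gc_track <- function(x, ...) {
  d <- data.frame(track_id = rep(x$id, n_frames(x)), t = x$t,
                  x = x$x, y = x$y)
  if (!is.null(x$state)) d$state <- x$state
  d
}

#' Collection of tracks sharing a frame interval
#'
#' @param tracks List of [gc_track()] objects.
#' @param frame_interval Common frame interval (s); inferred from the first
#'   track when missing.
#' @param metadata Free-form provenance list (configuration, seed, ...).
#' @return An object of class `gc_trackset`.
#' @export
trackset <- function(tracks, frame_interval = NULL, metadata = list()) {
  if (!all(vapply(tracks, inherits, logical(1), "gc_track")))
    stop("tracks must be a list of gc_track objects", call. = FALSE)
  if (is.null(frame_interval) && length(tracks))
    frame_interval <- tracks[[1]]$frame_interval
  if (!is.null(frame_interval)) {
    fi <- vapply(tracks, function(tr)
      if (is.null(tr$frame_interval)) frame_interval else tr$frame_interval,
      numeric(1))
    if (length(fi) && any(abs(fi - frame_interval) > 1e-9 * frame_interval))
      stop("all tracks must share the frame interval", call. = FALSE)
  }
  structure(list(tracks = tracks, frame_interval = frame_interval,
                 metadata = metadata),
            class = "gc_trackset")
}

#' @export
length.gc_trackset <- function(x) length(x$tracks)

#' @export
print.gc_trackset <- function(x, ...) {
  nf <- vapply(x$tracks, n_frames, integer(1))
  cat(sprintf("<gc_trackset: %d tracks at %s s interval", length(x),
              if (is.null(x$frame_interval)) "?" else
                format(x$frame_interval)))
  if (length(nf)) cat(sprintf(", %d-%d frames", min(nf), max(nf)))
  cat(">\n")
  invisible(x)
}

#' @export
as.data.frame.gc_trackset <- function(x, ...) {
  if (!length(x$tracks))
    return(data.frame(track_id = character(0), t = numeric(0),
                      x = numeric(0), y = numeric(0)))
  do.call(rbind, lapply(x$tracks, as.data.frame))
}

#' Filter tracks by minimum length
#'
#' Keeps tracks strictly longer than `min_frames` samples, mirroring the
#' sptPALM convention of analyzing only trajectories longer than seven frames
#' (so the default keeps tracks of 8 or more frames). Idempotent.
#'
#' @param ts A [trackset()].
#' @param min_frames Tracks must have strictly more samples than this.
#' @return A [trackset()] containing the surviving tracks.
#' @export
filter_tracks <- function(ts, min_frames = 7L) {
  keep <- vapply(ts$tracks, n_frames, integer(1)) > min_frames
  trackset(ts$tracks[keep], frame_interval = ts$frame_interval,
           metadata = c(ts$metadata, list(min_frames = min_frames)))
}

#' Pool the localizations of a track set
#'
#' Flattens every sample of every track into one (x, y) point table, the
#' input expected by [render_superres()]. Optionally restricted to samples in
#' given molecule states (e.g. only slowly moving, adhesion-bound molecules).
#'
#' @param ts A [trackset()].
#' @param states Optional character vector of states to keep.
#' @return A data frame with columns `x`, `y` (um).
#' @export
track_localizations <- function(ts, states = NULL) {
  d <- as.data.frame(ts)
  if (!is.null(states)) {
    if (is.null(d$state))
      stop("tracks carry no state labels", call. = FALSE)
    d <- d[d$state %in% states, , drop = FALSE]
  }
  data.frame(x = d$x, y = d$y)
}
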