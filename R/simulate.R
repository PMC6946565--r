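#' Random draws for one simulated molecule
#'
#' The per-step stochastic state machine consumes a fixed budget of random
#' numbers per time step regardless of the molecule's state (two standard
#' normals for the motion update and three uniforms for the polymerization,
#' coupling/uncoupling and depolymerization tests), plus two uniforms for the
#' initial position. Drawing them up front makes a molecule's path a pure
#' function of its draw set, which keeps seeded runs reproducible and lets an
#' independent re-integration replay the exact same path.
#'
#' @param n_steps Number of simulation steps (samples) of the track.
#' @return A list with components `r0u`, `th0u` (uniforms for the initial
#'   position), `n1`, `n2` (standard normals) and `u_poly`, `u_bind`, `u_dep`
#'   (uniforms), each step-indexed.
#' @export
sim_draws <- function(n_steps) {
  list(r0u = stats::runif(1), th0u = stats::runif(1),
       n1 = stats::rnorm(n_steps), n2 = stats::rnorm(n_steps),
       u_poly = stats::runif(n_steps), u_bind = stats::runif(n_steps),
       u_dep = stats::runif(n_steps))
}

#' Simulate one actin molecule in the virtual growth cone
#'
#' Integrates the stochastic three-state dynamics of a single actin molecule
#' inside a 2D conical growth cone (apex at the origin, leading edge at
#' `r = cone_radius`, half angle `cone_half_angle`). A molecule is either
#' freely diffusing (FREE, diffusivity `D_free`), incorporated in the
#' retrograde actin flow (FLOW, radial drift `-V_flow * dt` plus lateral
#' noise `D_flow_lateral`), or bound to a substrate adhesion (BOUND,
#' diffusivity `D_bound`).
#'
#' Per-step event order (fixed, so seeded runs are reproducible): (1) a FREE
#' molecule within `edge_band` of the leading edge polymerizes into the flow
#' with probability `k_poly * dt`; (2) motion update for the current state;
#' (3) a FLOW molecule binds an adhesion if `k_c * dt` exceeds a fresh
#' uniform draw, a BOUND molecule releases if `k_u * dt` does; (4) a FLOW
#' molecule depolymerizes to FREE with probability `k_d * dt`, and a FLOW
#' molecule that has reached the basal region (`r < base_band`) is forced to
#' disassemble. Free monomers never bind adhesions. FREE moves are reflected
#' at the cone's leading edge and straight sides; the small FLOW/BOUND wobble
#' is clamped to the cone.
#'
#' @param config A [sim_config()].
#' @param id Track identifier.
#' @param draws Optional [sim_draws()] list; generated from the current RNG
#'   state when missing.
#' @param start Optional fixed initial position `c(r, theta)` (um, degrees);
#'   drawn uniformly in `[0, cone_radius] x [-half_angle, +half_angle]`
#'   when missing.
#' @param initial_state Initial molecule state, normally `"FREE"`.
#' @return A [gc_track()] of `floor(duration/dt)` samples with per-sample
#'   states, sampled at `t = 0, dt, 2*dt, ...`.
#' @examples
#' set.seed(7)
#' tr <- simulate_molecule(sim_config(duration = 10))
#' tr
#' @export
simulate_molecule <- function(config, id = 1L, draws = NULL, start = NULL,
                              initial_state = c("FREE", "FLOW", "BOUND")) {
  validate_sim_config(config)
  initial_state <- match.arg(initial_state)
  n <- floor(config$duration / config$dt)
  if (n < 1L) stop("duration shorter than one time step", call. = FALSE)
  if (is.null(draws)) draws <- sim_draws(n)

  dt <- config$dt
  R <- config$cone_radius
  A <- config$cone_half_angle * pi / 180
  sf <- sqrt(2 * config$D_free * dt)
  sl <- sqrt(2 * config$D_flow_lateral * dt)
  sb <- sqrt(2 * config$D_bound * dt)
  V <- config$V_flow
  p_poly <- config$k_poly * dt
  p_bind <- config$k_c * dt
  p_unbind <- config$k_u * dt
  p_dep <- config$k_d * dt
  edge_r <- R - config$edge_band
  base_r <- config$base_band

  if (is.null(start)) {
    r0 <- draws$r0u * R
    th0 <- (2 * draws$th0u - 1) * A
  } else {
    r0 <- start[[1]]
    th0 <- start[[2]] * pi / 180
  }

  x <- numeric(n); y <- numeric(n); st <- integer(n)
  xx <- r0 * cos(th0); yy <- r0 * sin(th0)
  s <- match(initial_state, c("FREE", "FLOW", "BOUND"))
  x[1] <- xx; y[1] <- yy; st[1] <- s

  n1 <- draws$n1; n2 <- draws$n2
  u_poly <- draws$u_poly; u_bind <- draws$u_bind; u_dep <- draws$u_dep

  if (n >= 2L) for (i in 2:n) {
    rr <- sqrt(xx * xx + yy * yy)
    # 1. polymerization: FREE molecules in the leading-edge band join the flow
    if (s == 1L && rr >= edge_r && p_poly > u_poly[i]) s <- 2L
    # 2. motion update
    if (s == 1L) {
      xx <- xx + sf * n1[i]; yy <- yy + sf * n2[i]
      rr <- sqrt(xx * xx + yy * yy); tt <- atan2(yy, xx)
      if (rr > R) rr <- 2 * R - rr          # reflect at the leading edge
      if (tt > A) tt <- 2 * A - tt          # reflect at the straight sides
      else if (tt < -A) tt <- -2 * A - tt
      if (rr > R) rr <- R                    # double bounce: clamp
      if (tt > A) tt <- A else if (tt < -A) tt <- -A
      xx <- rr * cos(tt); yy <- rr * sin(tt)
    } else if (s == 2L) {
      tt <- atan2(yy, xx)
      rr <- rr - V * dt
      if (rr < 0) rr <- 0
      xx <- rr * cos(tt) + sl * n1[i]
      yy <- rr * sin(tt) + sl * n2[i]
      tmp <- clamp_to_cone(xx, yy, R, A); xx <- tmp[1]; yy <- tmp[2]
    } else {
      xx <- xx + sb * n1[i]; yy <- yy + sb * n2[i]
      tmp <- clamp_to_cone(xx, yy, R, A); xx <- tmp[1]; yy <- tmp[2]
    }
    # 3. clutch coupling / uncoupling
    if (s == 2L) {
      if (p_bind > u_bind[i]) s <- 3L
    } else if (s == 3L) {
      if (p_unbind > u_bind[i]) s <- 2L
    }
    # 4. depolymerization and forced disassembly at the base
    if (s == 2L) {
      if (p_dep > u_dep[i]) s <- 1L
      else if (sqrt(xx * xx + yy * yy) < base_r) s <- 1L
    }
    x[i] <- xx; y[i] <- yy; st[i] <- s
  }

  gc_track(id = id, t = (seq_len(n) - 1) * dt, x = x, y = y,
           state = c("FREE", "FLOW", "BOUND")[st], frame_interval = dt)
}

# clamp a point to the cone {r <= R, |theta| <= A}; used for the small
# FLOW/BOUND wobble, which is too short-ranged to warrant reflection
clamp_to_cone <- function(x, y, R, A) {
  r <- sqrt(x * x + y * y)
  th <- atan2(y, x)
  if (r > R) r <- R
  if (th > A) th <- A else if (th < -A) th <- -A
  c(r * cos(th), r * sin(th))
}

#' Simulate an ensemble of molecules
#'
#' Runs [simulate_molecule()] for `config$n_molecules` independent molecules.
#' Molecule `i` draws its randomness from a sub-seed `config$seed + i`, so an
#' ensemble is reproducible bit-exactly for a fixed seed and individual
#' molecules can be regenerated in isolation.
#'
#' @param config A [sim_config()].
#' @return A [trackset()] with the configuration and seed in `metadata`.
#' @examples
#' ts <- simulate_ensemble(sim_config(n_molecules = 5, duration = 10))
#' length(ts)
#' @export
simulate_ensemble <- function(config) {
  validate_sim_config(config)
  n <- config$n_molecules
  tracks <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((config$seed + i) %% 2147483647L)
    tracks[[i]] <- simulate_molecule(config, id = i)
  }
  trackset(tracks, frame_interval = config$dt,
           metadata = list(config = config, seed = config$seed))
}

#' Apply fluorophore photophysics to tracks
#'
#' Truncates each ground-truth trajectory to its fluorescent window: the
#' molecule turns on at a time drawn uniformly from `photo$on_window` and
#' bleaches after an exponential on-time of mean `photo$off_lifetime_mean`.
#' Only samples inside `[t_on, t_on + t_off]` are kept, so the observable
#' track is a contiguous sub-track (possibly empty when the window misses
#' the recording).
#'
#' @param x A [gc_track()] or [trackset()].
#' @param photo A [photo_config()].
#' @param ... Unused.
#' @return An object of the same class as `x`. The trackset method seeds the
#'   RNG from `photo$seed` (when set) and drops tracks left with zero
#'   samples.
#' @export
apply_photophysics <- function(x, photo, ...) UseMethod("apply_photophysics")

#' @export
apply_photophysics.gc_track <- function(x, photo, ...) {
  if (!n_frames(x)) stop("track is empty", call. = FALSE)
  t_on <- stats::runif(1, photo$on_window[1], photo$on_window[2])
  t_off <- if (is.finite(photo$off_lifetime_mean))
    stats::rexp(1, rate = 1 / photo$off_lifetime_mean) else Inf
  keep <- x$t >= t_on & x$t <= t_on + t_off
  gc_track(id = x$id, t = x$t[keep], x = x$x[keep], y = x$y[keep],
           state = if (is.null(x$state)) NULL else x$state[keep],
           frame_interval = x$frame_interval)
}

#' @export
apply_photophysics.gc_trackset <- function(x, photo, ...) {
  if (!is.null(photo$seed)) set.seed(photo$seed)
  out <- lapply(x$tracks, apply_photophysics, photo = photo)
  out <- out[vapply(out, n_frames, integer(1)) > 0L]
  trackset(out, frame_interval = x$frame_interval,
           metadata = c(x$metadata, list(photo = photo)))
}

#' Down-sample tracks to the camera time lapse
#'
#' Converts simulation-rate tracks to the experimental acquisition rate:
#' positions in each group of `sum_group` consecutive samples are averaged
#' (the trajectory-level equivalent of summing camera exposures), then one
#' group out of `keep_every` is retained. With the defaults this turns a
#' 3200-frame track at 50 ms into a 320-frame track at 0.5 s, i.e. the 2 Hz
#' movie with 250 ms exposure used for actin-mEos2. For a molecule that is
#' detectable throughout, the output frame count is
#' `floor(floor(n / sum_group) / keep_every)`; tracks shorter than one full
#' group are dropped with a warning. Group states, when present, are the
#' group's majority state.
#'
#' When `cam$blur_radius` is set (the default), camera frames during which
#' the molecule strayed further than that from its exposure-mean position
#' produce no localization -- this is how the summation eliminates
#' fast-diffusing monomers, which blur over the image -- and the returned
#' track is the longest contiguous run of detected frames (`NULL` when the
#' molecule is never detected).
#'
#' @param x A [gc_track()] or [trackset()].
#' @param cam A [camera_config()].
#' @param ... Unused.
#' @return Down-sampled object of the same class; the frame interval becomes
#'   `frame_interval * sum_group * keep_every`.
#' @export
downsample_to_camera <- function(x, cam, ...) UseMethod("downsample_to_camera")

#' @export
downsample_to_camera.gc_track <- function(x, cam, ...) {
  n <- n_frames(x)
  g <- n %/% cam$sum_group
  keep <- seq_len(g %/% cam$keep_every) * cam$keep_every
  if (!length(keep)) return(NULL)
  idx <- seq_len(g * cam$sum_group)
  xm <- matrix(x$x[idx], nrow = cam$sum_group)
  ym <- matrix(x$y[idx], nrow = cam$sum_group)
  gx <- colMeans(xm)[keep]
  gy <- colMeans(ym)[keep]
  gt <- colMeans(matrix(x$t[idx], nrow = cam$sum_group))[keep]
  gs <- NULL
  if (!is.null(x$state)) {
    sm <- matrix(x$state[idx], nrow = cam$sum_group)
    gs <- apply(sm, 2, function(s) names(which.max(table(s))))[keep]
  }
  run <- seq_along(keep)
  if (!is.null(cam$blur_radius)) {
    # within-exposure excursion from the group mean; a molecule that moved
    # further than the blur radius leaves no localizable spot
    spread <- sqrt(sweep(xm, 2, colMeans(xm))^2 +
                     sweep(ym, 2, colMeans(ym))^2)
    detected <- (apply(spread, 2, max))[keep] <= cam$blur_radius
    run <- longest_true_run(detected)
    if (!length(run)) return(NULL)
  }
  fi <- x$frame_interval * cam$sum_group * cam$keep_every
  gc_track(id = x$id, t = gt[run], x = gx[run], y = gy[run],
           state = if (is.null(gs)) NULL else gs[run],
           frame_interval = fi)
}

# indices of the longest run of TRUE values (first one on ties)
longest_true_run <- function(flags) {
  if (!any(flags)) return(integer(0))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  best <- which(r$values)[which.max(r$lengths[r$values])]
  (ends[best] - r$lengths[best] + 1L):ends[best]
}

#' @export
downsample_to_camera.gc_trackset <- function(x, cam, ...) {
  out <- lapply(x$tracks, downsample_to_camera, cam = cam)
  short <- vapply(out, is.null, logical(1))
  if (any(short))
    warning(sum(short),
            " track(s) dropped (shorter than one camera group or never",
            " detected)", call. = FALSE)
  out <- out[!short]
  fi <- if (is.null(x$frame_interval)) NULL else
    x$frame_interval * cam$sum_group * cam$keep_every
  trackset(out, frame_interval = fi,
           metadata = c(x$metadata, list(camera = cam)))
}
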