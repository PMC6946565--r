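test_that("MSD of a stationary track is zero at every lag", {
  tr <- gc_track("m", t = (0:19) * 0.5, x = 1, y = 2)
  msd <- compute_msd(tr)
  expect_true(all(msd$msd == 0))
})

test_that("MSD of uniform motion is exactly v^2 tau^2", {
  v <- 0.1
  tr <- linear_track("m", v = v, dt = 0.5, n = 40)
  msd <- compute_msd(tr, max_lag_fraction = 0.5)
  expect_equal(msd$msd, v^2 * msd$tau^2, tolerance = 1e-12)
})

test_that("MSD equals the brute-force pair-sum oracle on short tracks", {
  set.seed(21)
  for (n in c(5, 10, 23, 50)) {
    tr <- brownian_track(n, D = 0.05, dt = 0.5, n = n)
    msd <- compute_msd(tr, max_lag_fraction = 1)
    expect_equal(msd$msd, brute_msd(tr, nrow(msd)), tolerance = 1e-12)
    expect_equal(msd$n_pairs, n - seq_len(nrow(msd)))
  }
})

test_that("power-law fit recovers noiseless closed forms", {
  tau <- (1:10) * 0.5
  drift <- structure(data.frame(lag = 1:10, tau = tau,
                                msd = (0.1 * tau)^2, n_pairs = 10),
                     class = c("msd_curve", "data.frame"))
  f <- fit_msd_power(drift)
  expect_equal(f$alpha, 2, tolerance = 1e-6)
  brown <- structure(data.frame(lag = 1:10, tau = tau,
                                msd = 4 * 0.05 * tau, n_pairs = 10),
                     class = c("msd_curve", "data.frame"))
  f <- fit_msd_power(brown)
  expect_equal(f$alpha, 1, tolerance = 1e-6)
  expect_equal(f$D, 0.05, tolerance = 1e-6)
  # all-zero MSD flags a degenerate fit with D = 0
  zero <- structure(data.frame(lag = 1:5, tau = tau[1:5], msd = 0,
                               n_pairs = 5),
                    class = c("msd_curve", "data.frame"))
  expect_true(fit_msd_power(zero)$degenerate)
  expect_equal(fit_msd_power(zero)$D, 0)
})

test_that("power-law fit recovers Brownian generative parameters", {
  set.seed(33)
  fits <- vapply(1:200, function(i) {
    tr <- brownian_track(i, D = 0.05, dt = 0.05, n = 200)
    f <- fit_msd_power(compute_msd(tr))
    c(f$D, f$alpha)
  }, numeric(2))
  expect_gt(median(fits[2, ]), 0.9)
  expect_lt(median(fits[2, ]), 1.1)
  expect_lt(abs(median(fits[1, ]) - 0.05) / 0.05, 0.1)
})

test_that("directed fit recovers (D, V) exactly from its own model", {
  tau <- (1:10) * 0.5
  msd <- structure(data.frame(lag = 1:10, tau = tau,
                              msd = 4 * 0.01 * tau + 0.01 * tau^2,
                              n_pairs = 10),
                   class = c("msd_curve", "data.frame"))
  f <- fit_msd_directed(msd)
  expect_equal(f$D, 0.01, tolerance = 1e-6)
  expect_equal(f$V, 0.1, tolerance = 1e-6)
  zero <- structure(data.frame(lag = 1:5, tau = tau[1:5], msd = 0,
                               n_pairs = 5),
                    class = c("msd_curve", "data.frame"))
  fz <- fit_msd_directed(zero)
  expect_equal(fz$D, 0)
  expect_equal(fz$V, 0)
})

test_that("initial-slope D matches the closed-form OLS slope and the
           negative-slope sentinel applies", {
  tau <- (1:6) * 0.05
  msd <- structure(data.frame(lag = 1:6, tau = tau, msd = 4 * 0.1 * tau,
                              n_pairs = 6),
                   class = c("msd_curve", "data.frame"))
  expect_equal(diffusion_from_initial_slope(msd), 0.1, tolerance = 1e-9)
  # noisy curve: compare against an independent closed-form OLS slope
  set.seed(4)
  noisy <- msd
  noisy$msd <- noisy$msd + rnorm(6, 0, 0.002)
  i <- 1:4
  sl <- cov(noisy$tau[i], noisy$msd[i]) / var(noisy$tau[i])
  expect_equal(diffusion_from_initial_slope(noisy), sl / 4,
               tolerance = 1e-9)
  dec <- msd
  dec$msd <- rev(4 * 0.1 * tau)
  expect_equal(diffusion_from_initial_slope(dec), 1e-5)
})

test_that("alpha classes use an inclusive directed boundary", {
  th <- class_thresholds()
  expect_equal(classify_alpha(1.6, th), "directed")
  expect_equal(classify_alpha(1.5, th), "directed")
  expect_equal(classify_alpha(0.5, th), "brownian")
  expect_equal(classify_alpha(0.49, th), "confined")
})

test_that("mobility classes use a strict confined threshold", {
  th <- class_thresholds()
  expect_equal(classify_mobility(0.01, th), "confined")
  expect_equal(classify_mobility(1e-5, th), "confined")
  expect_equal(classify_mobility(0.015, th), "mobile")
})

test_that("track filtering keeps > min_frames and is idempotent", {
  mk <- function(n) linear_track(paste0("t", n), 0.01, 0.5, n)
  ts <- trackset(lapply(c(3, 7, 8, 20), mk))
  out <- filter_tracks(ts)
  expect_equal(vapply(out$tracks, n_frames, integer(1)), c(8L, 20L))
  again <- filter_tracks(out)
  expect_equal(length(again), length(out))
  expect_equal(length(filter_tracks(trackset(list()))), 0L)
})

test_that("pure simulated regimes classify as expected and fractions sum
           to one", {
  cam <- camera_config()
  mk_regime <- function(state, cfg, n, start_r) {
    trackset(lapply(seq_len(n), function(i) {
      set.seed(1000 + i)
      tr <- simulate_molecule(cfg, id = i,
                              start = c(start_r, runif(1, -30, 30)),
                              initial_state = state)
      downsample_to_camera(tr, cam)
    }), frame_interval = cfg$dt * cam$sum_group * cam$keep_every)
  }
  # FLOW only: no binding, no depolymerization, stays clear of the base;
  # the anomalous exponent calls these directed
  flow_cfg <- sim_config(k_c = 0, k_d = 0, V_flow = 0.1, duration = 50,
                         k_poly = 0)
  flow <- classify_tracks(mk_regime("FLOW", flow_cfg, 30, 11.5))
  expect_gt(class_fractions(flow)["directed"], 0.5)
  expect_equal(sum(class_fractions(flow)), 1)
  # BOUND only (never unbinds): the initial-slope diffusion coefficient
  # sits far below the 0.015 um^2/s cut-off, i.e. confined mobility
  bound_cfg <- sim_config(k_u = 0, duration = 50, k_poly = 0)
  bound <- mk_regime("BOUND", bound_cfg, 30, 8)
  D_bound <- vapply(bound$tracks, function(tr)
    diffusion_from_initial_slope(compute_msd(tr, max_lag_fraction = 1)),
    numeric(1))
  expect_gt(mean(classify_mobility(D_bound) == "confined"), 0.8)
  # FREE only at the simulation frame rate: Brownian exponents
  free_cfg <- sim_config(k_poly = 0, duration = 2)
  free <- trackset(lapply(1:30, function(i) {
    set.seed(2000 + i)
    simulate_molecule(free_cfg, id = i, start = c(6, runif(1, -30, 30)))
  }), frame_interval = free_cfg$dt)
  ffree <- classify_tracks(free)
  expect_gt(class_fractions(ffree)["brownian"], 0.5)
})
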