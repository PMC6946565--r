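test_that("a default-length simulation yields 3200 frames at 50 ms", {
  set.seed(1)
  tr <- simulate_molecule(sim_config())
  expect_equal(n_frames(tr), 3200L)
  expect_equal(tr$frame_interval, 0.05)
  expect_equal(diff(tr$t)[1], 0.05)
})

test_that("a molecule with no noise sources and no events never moves", {
  cfg <- sim_config(D_free = 0, k_poly = 0, duration = 20)
  set.seed(2)
  tr <- simulate_molecule(cfg, start = c(6, 0))
  expect_true(all(tr$x == tr$x[1]))
  expect_true(all(tr$y == tr$y[1]))
  expect_true(all(tr$state == "FREE"))
})

test_that("a flowing molecule drifts rearward at V and matches a replayed
           Euler integration with the same draws", {
  cfg <- sim_config(k_c = 0, k_d = 0, V_flow = 0.1, duration = 10)
  n <- floor(cfg$duration / cfg$dt)
  set.seed(31)
  draws <- sim_draws(n)
  tr <- simulate_molecule(cfg, draws = draws, start = c(10, 0),
                          initial_state = "FLOW")
  # net radial displacement ~ -V * t within 3 sigma of the lateral noise
  r_end <- sqrt(tr$x[n]^2 + tr$y[n]^2)
  sigma <- sqrt(2 * cfg$D_flow_lateral * cfg$duration)
  expect_lt(abs((r_end - 10) - (-0.1 * 10)), 3 * sigma)
  expect_true(all(tr$state == "FLOW"))

  # independent step-by-step replay of the flow update rule
  sl <- sqrt(2 * cfg$D_flow_lateral * cfg$dt)
  xx <- 10; yy <- 0
  for (i in 2:n) {
    r <- sqrt(xx^2 + yy^2) - cfg$V_flow * cfg$dt
    th <- atan2(yy, xx)
    xx <- r * cos(th) + sl * draws$n1[i]
    yy <- r * sin(th) + sl * draws$n2[i]
  }
  expect_equal(c(tr$x[n], tr$y[n]), c(xx, yy), tolerance = 1e-12)
})

test_that("every simulated position stays inside the cone", {
  cfg <- sim_config(n_molecules = 30, duration = 20, seed = 7)
  ts <- simulate_ensemble(cfg)
  for (tr in ts$tracks) {
    r <- sqrt(tr$x^2 + tr$y^2)
    th <- atan2(tr$y, tr$x) * 180 / pi
    expect_true(all(r <= cfg$cone_radius + 1e-9))
    expect_true(all(abs(th) <= cfg$cone_half_angle + 1e-9))
  }
})

test_that("state transitions never leave the allowed graph", {
  # BOUND is only entered from FLOW and only left to FLOW
  cfg <- sim_config(n_molecules = 40, duration = 40, k_u = 0.2, seed = 11)
  ts <- simulate_ensemble(cfg)
  allowed <- c("FREE>FREE", "FLOW>FLOW", "BOUND>BOUND",
               "FREE>FLOW", "FLOW>FREE", "FLOW>BOUND", "BOUND>FLOW")
  seen <- character(0)
  for (tr in ts$tracks) {
    s <- tr$state
    trans <- paste(s[-length(s)], s[-1], sep = ">")
    expect_true(all(trans %in% allowed))
    seen <- union(seen, trans)
  }
  # the interesting transitions actually occur in this ensemble
  expect_true(all(c("FREE>FLOW", "FLOW>BOUND", "BOUND>FLOW") %in% seen))
})

test_that("ensembles are reproducible bit-exactly and sized as configured", {
  cfg <- sim_config(n_molecules = 5, duration = 10, seed = 123)
  a <- simulate_ensemble(cfg)
  b <- simulate_ensemble(cfg)
  expect_equal(length(a), 5L)
  expect_identical(lapply(a$tracks, `[`, c("t", "x", "y", "state")),
                   lapply(b$tracks, `[`, c("t", "x", "y", "state")))
  expect_equal(length(simulate_ensemble(sim_config(n_molecules = 0))), 0L)
})

test_that("forced disassembly returns flowing molecules at the base to
           free diffusion", {
  # no depolymerization, no binding: the only FLOW -> FREE route left is
  # the forced disassembly in the 4 um base region
  cfg <- sim_config(k_c = 0, k_d = 0, V_flow = 0.15, duration = 60,
                    D_flow_lateral = 0, k_poly = 0)
  set.seed(5)
  tr <- simulate_molecule(cfg, start = c(6, 0), initial_state = "FLOW")
  i_free <- which(tr$state == "FREE")[1]
  expect_false(is.na(i_free))
  r_at <- sqrt(tr$x[i_free]^2 + tr$y[i_free]^2)
  expect_lt(r_at, cfg$base_band + 0.01)
})
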