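test_that("rendering conserves localization counts exactly", {
  expect_error(render_superres(data.frame(x = numeric(0), y = numeric(0))),
               "localization")
  one <- render_superres(data.frame(x = 1.01, y = 2.02))
  expect_equal(sum(one$grid), 1)
  expect_equal(sum(one$grid > 0), 1)
  set.seed(5)
  locs <- data.frame(x = runif(777, 0, 8), y = runif(777, 0, 3))
  m <- render_superres(locs)
  expect_equal(sum(m$grid), 777)
})

test_that("a 10 um extent at 25 nm pixels gives a 400-pixel axis", {
  m <- render_superres(data.frame(x = 5, y = 5), pixel_size = 0.025,
                       extent = list(xlim = c(0, 10), ylim = c(0, 10)))
  expect_equal(dim(m$grid), c(400L, 400L))
})

test_that("uniform background below threshold yields no domains", {
  set.seed(6)
  locs <- data.frame(x = runif(500, 0, 5), y = runif(500, 0, 5))
  m <- render_superres(locs, pixel_size = 0.1)
  doms <- detect_domains(m, k_sd = 6)
  expect_equal(nrow(doms), 0L)
})

test_that("a single synthetic cluster is found at its true center", {
  set.seed(7)
  locs <- rbind(gauss_cluster(200, 2.5, 2.5, 0.05),
                data.frame(x = runif(150, 0, 5), y = runif(150, 0, 5)))
  m <- render_superres(locs, extent = list(xlim = c(0, 5), ylim = c(0, 5)))
  doms <- detect_domains(m, k_sd = 4)
  expect_equal(nrow(doms), 1L)
  expect_lt(abs(doms$center_x - 2.5), 0.025)
  expect_lt(abs(doms$center_y - 2.5), 0.025)
})

test_that("five well-separated clusters give five domains with sizes near
           the generative extent", {
  set.seed(8)
  centers <- data.frame(cx = c(1, 3, 1, 3, 2), cy = c(1, 1, 3, 3, 2))
  sigma <- 0.05
  locs <- do.call(rbind, lapply(1:5, function(i)
    gauss_cluster(250, centers$cx[i], centers$cy[i], sigma)))
  m <- render_superres(locs, extent = list(xlim = c(0, 4), ylim = c(0, 4)))
  doms <- detect_domains(m, k_sd = 2)
  expect_equal(nrow(doms), 5L)
  # size ~ full width at half maximum of the Gaussian profile
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  expect_lt(abs(mean(doms$mean_size) - fwhm) / fwhm, 0.25)
})

test_that("domain counts are invariant under global intensity scaling when
           the threshold is relative", {
  set.seed(9)
  locs <- do.call(rbind, lapply(1:3, function(i)
    gauss_cluster(200, i, i, 0.04)))
  m <- render_superres(locs, extent = list(xlim = c(0, 4), ylim = c(0, 4)))
  m10 <- m
  m10$grid <- m$grid * 10
  expect_equal(nrow(detect_domains(m10, k_sd = 2)),
               nrow(detect_domains(m, k_sd = 2)))
})

test_that("domain density and periphery enrichment follow the counts", {
  m <- render_superres(data.frame(x = 1, y = 1), pixel_size = 0.1,
                       extent = list(xlim = c(0, 10), ylim = c(0, 10)))
  mask <- matrix(TRUE, 100, 100)  # 10 x 10 um at 0.1 um/px... 1 um^2/100px
  # use a synthetic 5 um^2 mask: 500 pixels
  mask5 <- matrix(FALSE, 100, 100); mask5[1:50, 1:10] <- TRUE
  doms <- data.frame(center_x = runif(10, 0.1, 4.9),
                     center_y = runif(10, 0.1, 0.9))
  st <- domain_stats(doms, mask5, m)
  expect_equal(st$density, 10 / (sum(mask5) * 0.01))
  # all domains inside a periphery band covering half the mask area
  half <- mask5; half[26:50, ] <- FALSE
  doms2 <- data.frame(center_x = runif(8, 0.1, 2.4),
                      center_y = runif(8, 0.1, 0.9))
  st2 <- domain_stats(doms2, mask5, m, periphery = half)
  expect_equal(st2$periphery_ratio, 2)
  expect_error(domain_stats(doms, mask5 & FALSE, m), "zero area")
})

test_that("uniformly placed domains show no periphery enrichment", {
  m <- render_superres(data.frame(x = 5, y = 5), pixel_size = 0.1,
                       extent = list(xlim = c(0, 10), ylim = c(0, 10)))
  msk <- cone_mask(m, radius = 9, half_angle = 45, apex = c(0.5, 5))
  per <- periphery_mask(m, radius = 9, half_angle = 45, apex = c(0.5, 5))
  set.seed(10)
  ratios <- replicate(300, {
    # rejection-sample uniform points inside the cone mask
    pts <- matrix(runif(400, 0, 10), ncol = 2)
    ix <- pmin(floor(pts[, 1] / 0.1) + 1, 100)
    iy <- pmin(floor(pts[, 2] / 0.1) + 1, 100)
    keep <- msk[cbind(ix, iy)]
    doms <- data.frame(center_x = pts[keep, 1][1:60],
                       center_y = pts[keep, 2][1:60])
    domain_stats(doms, msk, m, periphery = per)$periphery_ratio
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("shape index is 1 for a disk, pi/4 for a square, and analytic
           for an elongated ellipse", {
  d <- shape_index(disk_mask(50))
  expect_lt(abs(d$shape_index - 1), 0.03)
  sq <- matrix(FALSE, 120, 120); sq[30:90, 30:90] <- TRUE
  s <- shape_index(sq)
  expect_lt(abs(s$shape_index - pi / 4) / (pi / 4), 0.05)
  # 5:1 ellipse against Ramanujan's perimeter approximation
  a <- 100; b <- 20
  e <- shape_index(ellipse_mask(a, b))
  h <- ((a - b) / (a + b))^2
  P <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  si_true <- 4 * pi * (pi * a * b) / P^2
  expect_lt(abs(e$shape_index - si_true) / si_true, 0.05)
})

test_that("shape index never exceeds the isoperimetric bound and falls
           with elongation", {
  set.seed(11)
  sis <- vapply(1:8, function(i) {
    a <- sample(20:60, 1); b <- sample(10:a, 1)
    shape_index(ellipse_mask(a, b))$shape_index
  }, numeric(1))
  expect_true(all(sis <= 1.03))
  fam <- vapply(c(1, 2, 4, 8), function(k)
    shape_index(ellipse_mask(24 * k, 24 / ifelse(k > 1, k, 1)))$shape_index,
    numeric(1))
  expect_true(all(diff(fam) < 0))
  expect_error(shape_index(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 20, 20); two[2:5, 2:5] <- TRUE; two[10:15, 10:15] <- TRUE
  expect_error(shape_index(two), "2")
})

test_that("strongly coupled (bound-heavy) ensembles form denser domain
           maps than weakly coupled ones", {
  mk_density <- function(k_u, seed) {
    cfg <- sim_config(k_u = k_u, n_molecules = 60, duration = 80,
                      seed = seed)
    ts <- simulate_ensemble(cfg)
    ts <- suppressWarnings(downsample_to_camera(ts, camera_config()))
    locs <- track_localizations(ts, states = c("FLOW", "BOUND"))
    m <- render_superres(locs, pixel_size = 0.05,
                         extent = list(xlim = c(-1, 13), ylim = c(-10, 10)))
    msk <- cone_mask(m)
    doms <- detect_domains(m, k_sd = 3, mask = msk, min_pixels = 3)
    domain_stats(doms, msk, m)$density
  }
  expect_gt(mk_density(0.001, 21), mk_density(0.8, 21))
})
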