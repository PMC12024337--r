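# Poiseuille WSS surrogate: tau field, TAWSS, OSI, high-WSS fractions.

test_that("Poiseuille WSS matches the hand evaluation and its scaling laws", {
  # 4 * 0.04 * 5 / (pi * 0.2^3) dyn/cm^2
  tau <- wss_profile(5, 0.2, mu = 0.04)
  expect_equal(tau[1, 1], 0.8 / (pi * 0.008), tolerance = 1e-12)
  expect_equal(tau[1, 1] * 0.1, 3.1831, tolerance = 1e-4)  # in Pa
  expect_equal(wss_profile(-5, 0.2), -wss_profile(5, 0.2))
  expect_equal(wss_profile(5, 0.1)[1, 1], 8 * wss_profile(5, 0.2)[1, 1],
               tolerance = 1e-12)
})

test_that("TAWSS is the cycle-average of |tau|", {
  times <- seq(0, 1, by = 1e-3)
  expect_equal(tawss(rep(20, length(times)), times), 2)  # 20 dyn = 2 Pa
  # +1 Pa for half the cycle, -1 Pa for the other half: TAWSS = 1 Pa
  sq <- ifelse(times < 0.5, 10, -10)
  expect_equal(tawss(sq, times), 1, tolerance = 0.01)
  expect_equal(tawss(-3 * sq, times), 3 * tawss(sq, times), tolerance = 1e-12)
  expect_error(tawss(numeric(0), numeric(0)), "full cycle")
})

test_that("OSI reproduces the worked values and stays in [0, 0.5]", {
  times <- seq(0, 1, by = 1e-3)
  expect_equal(osi(rep(5, length(times)), times), 0)
  expect_equal(osi(ifelse(times < 0.5, 1, -1), times), 0.5, tolerance = 0.01)
  expect_equal(osi(ifelse(times < 0.75, 1, -1), times), 0.25, tolerance = 0.01)
  set.seed(7)
  for (i in 1:25) {
    tau <- stats::rnorm(length(times), mean = runif(1, -2, 2))
    v <- osi(tau, times)
    expect_gte(v, 0); expect_lte(v, 0.5)
  }
  # TAWSS always dominates the magnitude of the signed mean
  for (i in 1:10) {
    tau <- stats::rnorm(length(times))
    expect_gte(tawss(tau, times) + 1e-12,
               abs(sum(diff(times) * (head(tau, -1) + tail(tau, -1)) / 2)) * 0.1)
  }
})

test_that("profile-based high-WSS fraction matches hand counts", {
  expect_equal(high_wss_fraction(rep(2, 50)), 0)
  expect_equal(high_wss_fraction(c(rep(1, 9), 41)), 0.10)  # mean 5, one > 20
  expect_equal(high_wss_fraction(c(rep(1, 9), 41), k = 1e6), 0)
  expect_error(high_wss_fraction(numeric(0)), "empty")
})

test_that("exposure-based fraction responds to pulsatility, profile-based does not", {
  times <- seq(0, 1, by = 1e-3)
  r <- c(rep(0.2, 10), seq(0.2, 0.08, length.out = 10))
  steady <- rep(2, length(times))
  pulsatile <- 2 + 1.8 * sin(2 * pi * times)
  tau_s <- wss_profile(steady, r)
  tau_p <- wss_profile(pulsatile, r)
  # same mean flow: identical TAWSS profile, hence identical profile fraction
  expect_equal(tawss(tau_s, times), tawss(tau_p, times), tolerance = 0.01)
  expect_identical(high_wss_fraction(tawss(tau_s, times)),
                   high_wss_fraction(tawss(tau_p, times)))
  # but the pulsatile flow exposes at least as many elements instantaneously
  expect_gte(high_wss_exposure(tau_p, times), high_wss_exposure(tau_s, times))
})

test_that("radius profile tapers smoothly into the throat", {
  seg <- vessel_segment("LAD", radius = 0.18, length = 10, side = "left",
                        lesion_start = 2)
  sten <- stenosis_spec(0.57, 15, 0.18)
  prof <- stenosis_radius_profile(seg, sten)
  expect_true(all(diff(prof$x) > 0))
  expect_true(all(prof$radius > 0))
  expect_equal(min(prof$radius), sten$throat_radius, tolerance = 1e-3)
  # reference radius upstream of the lesion
  expect_true(all(prof$radius[prof$x < 2] == 0.18))
  # region spans 15 mm upstream through the lesion end
  expect_equal(max(prof$x), 2 + 1.5, tolerance = 0.03)
  expect_equal(min(prof$x), 0.5, tolerance = 0.03)
})

test_that("the WSS report on a simulated patient is internally consistent", {
  run <- ref_run()
  wr <- wss_report(run$sim_rest)
  expect_true(all(wr$osi_profile >= 0 & wr$osi_profile <= 0.5))
  expect_true(all(wr$tawss_profile > 0))
  expect_gte(wr$high_frac, 0); expect_lte(wr$high_frac, 1)
  expect_equal(wr$tawss_mean, mean(wr$tawss_profile), tolerance = 1e-12)
  # peak TAWSS sits at the throat
  expect_equal(wr$x[which.max(wr$tawss_profile)],
               wr$x[which.min(wr$radius)], tolerance = 1e-9)
  # axial refinement changes the regional summaries by less than 2%
  wr2 <- wss_report(run$sim_rest, dx = 0.0125)
  expect_lt(abs(wr$tawss_mean - wr2$tawss_mean) / wr2$tawss_mean, 0.02)
  expect_lt(abs(wr$high_frac - wr2$high_frac), 0.02)
})
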