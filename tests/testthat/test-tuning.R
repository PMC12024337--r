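# Boundary-condition tuning: systemic RCR, coronary resistances and
# compliances.

test_that("total systemic resistance is mean pressure over cardiac output", {
  # 99 mmHg at 5 L/min: 99 * 1333.22 / 83.33
  expect_equal(total_systemic_resistance(99, 83.33), 99 * 1333.22 / 83.33,
               tolerance = 1e-12)
  expect_equal(total_systemic_resistance(99, 2 * 83.33),
               total_systemic_resistance(99, 83.33) / 2, tolerance = 1e-12)
  expect_equal(total_systemic_resistance(0, 83.33), 0)
  expect_error(total_systemic_resistance(99, 0), "cardiac output")
})

test_that("RCR split is exact and validated", {
  s <- split_rcr(1000, 0.09)
  expect_equal(unname(s), c(90, 910))
  expect_identical(sum(s), 1000)
  expect_equal(unname(split_rcr(500, 0.5)), c(250, 250))
  expect_error(split_rcr(1000, 0), "rp_fraction")
  expect_error(split_rcr(1000, 1), "rp_fraction")
})

test_that("coronary resistance distribution follows the mode ratios exactly", {
  rest <- distribute_coronary(100000, resistance_distribution("rest"))
  expect_equal(unname(rest), c(32000, 52000, 16000))
  stress <- distribute_coronary(100000, resistance_distribution("stress"))
  expect_equal(unname(stress), c(41000, 28000, 31000))
  expect_equal(unname(distribute_coronary(0)), c(0, 0, 0))
  set.seed(21)
  for (r in runif(20, 1e3, 1e6))
    expect_identical(sum(distribute_coronary(r)), r)  # exact closure
  expect_error(resistance_distribution(ra_frac = 0.5, ramicro_frac = 0.5,
                                       rv_frac = 0.5), "sum to 1")
})

test_that("compliance distribution honours area shares and the 89/11 split", {
  d <- distribute_compliance(2e-5, c(1, 1))
  expect_equal(d$ca, c(1.1e-6, 1.1e-6), tolerance = 1e-12)
  expect_equal(d$cim, c(8.9e-6, 8.9e-6), tolerance = 1e-12)
  d1 <- distribute_compliance(3.6e-5, 0.1)
  expect_equal(d1$ca + d1$cim, 3.6e-5, tolerance = 1e-15)
  d0 <- distribute_compliance(0, c(1, 2))
  expect_true(all(d0 == 0))
})

test_that("RCR tuning recovers pressure targets generated by a known network", {
  pt <- reference_patient()
  targets <- tuning_targets(pt$pre)
  net <- build_network(pt, "pre", "rest", targets = targets)
  # simulate a known RCR, take its pressures as targets, re-tune from a
  # perturbed start: the fitted network must reproduce them
  sim0 <- simulate_network(net, n_cycles = 4)
  sm0 <- sim_summary(sim0)
  targets2 <- tuning_targets(pt$pre, p_sys = sm0$p_sys, p_dia = sm0$p_dia)
  net_pert <- net
  s <- split_rcr((net$systemic$rp + net$systemic$rd) * 1.3, 0.07)
  net_pert$systemic <- rcr_params(s[["rp"]], 0.001, s[["rd"]])
  fit <- tune_rcr(targets2, net_pert)
  expect_true(fit$converged)
  expect_lte(abs(fit$p_sys - sm0$p_sys), targets2$tol_pressure)
  expect_lte(abs(fit$p_dia - sm0$p_dia), targets2$tol_pressure)
})

test_that("infinite pressure tolerance returns after one iteration", {
  pt <- reference_patient()
  targets <- tuning_targets(pt$pre, tol_pressure = Inf)
  net <- build_network(pt, "pre", "rest", targets = targets)
  fit <- tune_rcr(targets, net)
  expect_true(fit$converged)
  expect_identical(fit$iterations, 1L)
})

test_that("inverted pressure targets are rejected", {
  expect_error(tuning_targets(p_sys = 80, p_dia = 100, cardiac_output = 90))
})

test_that("rest tuning hits the 4% fraction and 3:1 velocity ratio", {
  run <- ref_run()
  sim <- run$sim_rest
  qin <- cycle_mean(sim, sim$q_inflow)
  q_cor <- sum(vapply(sim$branches, function(b) cycle_mean(sim, b$q), 0))
  expect_lt(abs(q_cor / qin - 0.04), 0.005)
  expect_true(run$cor_rest$converged)
  # velocity ratio within 15% of 3:1
  net <- sim$network
  q_l <- cycle_mean(sim, sim$branches$LAD$q) + cycle_mean(sim, sim$branches$LCx$q)
  q_r <- cycle_mean(sim, sim$branches$RCA$q)
  vr <- (q_l / (pi * net$ostial_radii[["left"]]^2)) /
        (q_r / (pi * net$ostial_radii[["right"]]^2))
  expect_lt(abs(vr - 3) / 3, 0.15)
})

test_that("hyperemic tuning lands in the 10-12% band with lower resistance", {
  run <- ref_run()
  sim <- run$sim_hyper
  qin <- cycle_mean(sim, sim$q_inflow)
  frac <- sum(vapply(sim$branches, function(b) cycle_mean(sim, b$q), 0)) / qin
  expect_gte(frac, 0.10 - 0.005)
  expect_lte(frac, 0.12 + 0.005)
  r_tot <- function(cor) sum(vapply(cor, function(o) o$ra + o$ra_micro + o$rv, 0))
  expect_lt(r_tot(run$cor_hyper$coronary), r_tot(run$cor_rest$coronary))
})

test_that("equal ostial areas turn the 3:1 velocity target into a 3:1 flow split", {
  pt <- reference_patient()
  net <- build_network(pt, "pre", "rest")
  net$ostial_radii <- c(left = 0.17, right = 0.17)
  q <- target_branch_flows(net, 8, 3)
  q_l <- sum(q[c("LAD", "LCx")])
  expect_equal(q_l / q[["RCA"]], 3, tolerance = 1e-12)
  expect_equal(sum(q), 8, tolerance = 1e-12)
})
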