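# Shared, lazily-computed fixtures. Tuning and simulation of the reference
# patient are moderately expensive, so each fixture is built once per test
# session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# fully tuned + simulated reference patient (rest & hyperemia)
ref_run <- function() with_cache("ref_run", {
  tune_patient_state(reference_patient(), "pre")
})

# the same patient with the stenosis degree set to `degree`
degree_run <- function(degree) {
  key <- paste0("degree_run_", degree)
  with_cache(key, tune_patient_state(reference_patient(degree = degree), "pre"))
}

# full default cohort run (n = 26, seed 0) + statistics
cohort_run <- function() with_cache("cohort_run", {
  res <- run_cohort(run_config(n = 26, seed = 0))
  list(res = res, stats = cohort_stats(res))
})

# a minimal network with no coronary branches (bare aortic RCR), driven by
# a constant inflow; used for closed-form Windkessel checks
rcr_only_network <- function(q0 = 80, rp = 100, c = 0.0008, rd = 1300,
                             period = 0.8) {
  times <- seq(0, period, by = 0.001)
  structure(list(
    inflow = waveform(times, rep(q0, length(times)), "flow"),
    systemic = rcr_params(rp, c, rd),
    branches = list(),
    fluid = fluid_properties(),
    murray_exponent = 3,
    ostial_radii = c(left = 0.225, right = 0.17),
    state = "pre", mode = "rest", targets = NULL,
    period = period, cardiac_state = NULL
  ), class = "network_spec")
}

# a fake minimal coro_sim carrying constant pressure series, for index and
# residual plumbing checks
constant_sim <- function(pa = 100, pd = 90, n_cycles = 2, period = 1,
                         mode = "rest", hr = 70, et = 336) {
  m <- 100
  time <- seq(0, n_cycles * period, length.out = n_cycles * m + 1)
  cs <- cardiac_state(heart_rate = hr, stroke_volume = 79.1,
                      ejection_time = et, aortic_valve_area = 0.6,
                      p_sys = 141, p_dia = 78.5)
  structure(list(
    time = time, cycle = pmax(ceiling(time / period), 1),
    n_cycles = n_cycles, period = period, dt = period / m,
    p_aorta = rep(pa, length(time)),
    q_inflow = rep(5, length(time)),
    q_systemic = rep(5, length(time)), q_systemic_out = rep(5, length(time)),
    branches = list(LAD = list(q = rep(1, length(time)),
                               p_prox = rep(pa, length(time)),
                               p_dist = rep(pd, length(time)),
                               p_outlet = rep(pd, length(time)),
                               p_cim = rep(20, length(time)),
                               q_venous = rep(1, length(time)))),
    mode = mode, state = "pre",
    network = list(cardiac_state = cs,
                   branches = list(LAD = list(stenosis = list(degree = 0.5))))
  ), class = "coro_sim")
}

expect_rel_equal <- function(object, expected, tol = 1e-6) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-12), tol)
}
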