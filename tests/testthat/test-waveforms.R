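# Inflow and ventricular pressure waveform generation.

pre_state <- function() cardiac_state(stroke_volume = 79.1, ejection_time = 336,
                                      aortic_valve_area = 0.6,
                                      p_sys = 141, p_dia = 78.5)
post_state <- function() cardiac_state(stroke_volume = 81.4, ejection_time = 252,
                                       aortic_valve_area = 2.4,
                                       p_sys = 143, p_dia = 78.3)

test_that("half-sine inflow matches the closed-form peak and integrates to SV", {
  # closed form for a half-sine pulse: Qp = pi * SV / (2 * ET)
  cases <- list(c(sv = 79.1, et = 336), c(sv = 81.4, et = 252))
  for (cs in cases) {
    st <- cardiac_state(stroke_volume = cs[["sv"]], ejection_time = cs[["et"]],
                        aortic_valve_area = 0.6, p_sys = 141, p_dia = 78.5)
    wf <- make_inflow(st, inflow_shape(skew_per_ava = 0))
    qp_expected <- pi * cs[["sv"]] / (2 * cs[["et"]] / 1000)
    expect_lt(abs(max(wf$values) - qp_expected) / qp_expected, 1e-3)
    # independent quadrature of the generated samples recovers SV
    sv_num <- sum(diff(wf$times) * (head(wf$values, -1) + tail(wf$values, -1)) / 2)
    expect_lt(abs(sv_num - cs[["sv"]]) / cs[["sv"]], 1e-6)
  }
})

test_that("inflow is zero in diastole, periodic, and zero for SV = 0", {
  st <- pre_state()
  wf <- make_inflow(st)
  et <- st$ejection_time / 1000
  expect_true(all(wf$values[wf$times > et + 1e-9] == 0))
  expect_equal(wf$values[1], wf$values[length(wf$values)], tolerance = 1e-9)
  st0 <- cardiac_state(stroke_volume = 0, ejection_time = 336,
                       aortic_valve_area = 0.6, p_sys = 141, p_dia = 78.5)
  expect_true(all(make_inflow(st0)$values == 0))
})

test_that("smaller valve area skews the inflow peak later in systole", {
  peak_frac <- function(ava) {
    st <- cardiac_state(stroke_volume = 80, ejection_time = 300,
                        aortic_valve_area = ava, p_sys = 141, p_dia = 78.5)
    wf <- make_inflow(st)
    wf$times[which.max(wf$values)] / (st$ejection_time / 1000)
  }
  fr <- vapply(c(3, 1.5, 0.9, 0.6), peak_frac, 0)
  expect_true(all(diff(fr) > 0))
})

test_that("post-AVR state yields a strictly higher peak inflow", {
  q_pre <- max(make_inflow(pre_state())$values)
  q_post <- max(make_inflow(post_state())$values)
  expect_gt(q_post, q_pre)
})

test_that("LV pressure template hits its extrema and scales linearly", {
  st <- cardiac_state(stroke_volume = 79.1, ejection_time = 336,
                      aortic_valve_area = 0.6, p_sys = 141, p_dia = 78.5,
                      lv_peak = 141, lv_edp = 10)
  wf <- make_lv_pressure(st)
  expect_equal(max(wf$values), 141, tolerance = 1e-9)
  expect_equal(min(wf$values), 10, tolerance = 1e-9)
  expect_equal(wf$values[1], wf$values[length(wf$values)], tolerance = 1e-9)
  # near-degenerate state stays near-flat
  st_eps <- cardiac_state(stroke_volume = 79.1, ejection_time = 336,
                          aortic_valve_area = 0.6, p_sys = 141, p_dia = 78.5,
                          lv_peak = 10.01, lv_edp = 10)
  wf_eps <- make_lv_pressure(st_eps)
  expect_lte(max(wf_eps$values) - min(wf_eps$values), 0.01 + 1e-12)
  # doubling the peak doubles the systolic excursion above baseline
  st2 <- cardiac_state(stroke_volume = 79.1, ejection_time = 336,
                       aortic_valve_area = 0.6, p_sys = 141, p_dia = 78.5,
                       lv_peak = 282, lv_edp = 10)
  wf2 <- make_lv_pressure(st2)
  expect_equal(max(wf2$values) - 10, 272, tolerance = 1e-9)
  sys_idx <- wf$values > 10 + 1e-6
  expect_equal((wf2$values[sys_idx] - 10) / (wf$values[sys_idx] - 10),
               rep(272 / 131, sum(sys_idx)), tolerance = 1e-9)
})

test_that("RV pressure peak follows the simplified Bernoulli relation", {
  st <- function(tr) cardiac_state(stroke_volume = 79.1, ejection_time = 336,
                                   aortic_valve_area = 0.6, p_sys = 141,
                                   p_dia = 78.5, tr_velocity = tr)
  expect_equal(max(make_rv_pressure(st(2.5), rap = 5)$values), 4 * 6.25 + 5,
               tolerance = 1e-9)
  expect_equal(max(make_rv_pressure(st(0), rap = 5)$values), 5, tolerance = 1e-9)
  # doubling the TR velocity quadruples the gradient term (peak - RAP)
  g1 <- max(make_rv_pressure(st(1.5), rap = 5)$values) - 5
  g2 <- max(make_rv_pressure(st(3.0), rap = 5)$values) - 5
  expect_equal(g2 / g1, 4, tolerance = 1e-9)
})

test_that("invalid cardiac states are rejected", {
  expect_error(cardiac_state(heart_rate = 70, stroke_volume = 80,
                             ejection_time = 900, aortic_valve_area = 0.6,
                             p_sys = 141, p_dia = 78.5),
               "ejection_time")
  expect_error(cardiac_state(stroke_volume = 80, ejection_time = 300,
                             aortic_valve_area = 0.6, p_sys = 80, p_dia = 100),
               "p_dia")
  expect_error(cardiac_state(stroke_volume = 80, ejection_time = 300,
                             aortic_valve_area = 0.6, p_sys = 141, p_dia = 78.5,
                             lv_peak = 5, lv_edp = 10),
               "lv_peak")
})

test_that("default mean pressure and Gorlin gradient are consistent", {
  st <- pre_state()
  expect_equal(st$p_mean, 78.5 + (141 - 78.5) / 3, tolerance = 1e-12)
  # Gorlin: dP = (SV/ET / (44.3 AVA))^2
  expect_equal(transvalvular_gradient(79.1, 336, 0.6),
               (79.1 / 0.336 / (44.3 * 0.6))^2, tolerance = 1e-12)
  expect_equal(st$lv_peak, 141 + transvalvular_gradient(79.1, 336, 0.6),
               tolerance = 1e-12)
})

test_that("waveform CSV round-trips on the decimal text", {
  wf <- make_inflow(pre_state())
  path <- tempfile(fileext = ".csv")
  write_waveform_csv(wf, path)
  wf2 <- read_waveform_csv(path, "flow")
  expect_identical(readLines(path)[1], "time_s,value")
  expect_equal(wf2$times, wf$times)
  expect_equal(wf2$values, wf$values)
  unlink(path)
})
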