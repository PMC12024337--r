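# Synthetic cohort generator: virtual patients with the statistical
# structure of an aortic-stenosis + coronary-artery-disease TAVI cohort
# (n = 26, paired pre/post valve-replacement states, one lesion per
# patient), plus a noisy "invasive FFR" channel for the agreement analysis.

# Truncated-normal sampler (inverse-CDF) and its analytic mean.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# lognormal sdlog from a median and interquartile range
sdlog_from_iqr <- function(q25, q75) log(q75 / q25) / (2 * stats::qnorm(0.75))

#' Cohort distribution parameters
#'
#' Defaults emulate the study population: age 79.6 (10.1) years in
#' [50, 89]; stenosis degree 0.568 (0.0853) truncated to [0.40, 0.71];
#' lesion length 15.1 (4.36) mm in [8, 23]; lesion vessel LAD 62% / RCA
#' 23% / LCx 12% / ramus 3.8%; pre-AVR stroke volume 79.1 (17.0) mL,
#' ejection time 336 (27.3) ms, AVA median 0.60 IQR [0.542, 0.700] cm^2
#' (lognormal), systolic/diastolic pressure 141 (19.2) / 78.5 (10.2) mmHg;
#' post-AVR AVA median 2.40 IQR [2.17, 2.80], ejection time shortened by
#' 83.9 ms and stroke volume increased by 2.31 mL on average, aortic
#' pressures resampled with near-zero mean shift.
#'
#' Paired-variability channels (within-pair noise not derivable from the
#' summary tables; see the methods vignette): the per-state *effective*
#' stenosis degree adds N(0, `sd_degree_state`) re-measurement noise to the
#' shared QCA degree; per-state rest and hyperemic coronary-flow fractions
#' are drawn inside their physiologic bands; the post-AVR TR velocity falls
#' by `tr_drop` m/s on average.
#'
#' @param ... overrides of any listed element.
#' @export
cohort_params <- function(...) {
  p <- list(
    heart_rate = 70,
    age = c(mean = 79.6, sd = 10.1, lo = 50, hi = 89),
    lvef = c(mean = 0.578, sd = 0.066, lo = 0.45, hi = 0.70),
    degree = c(mean = 0.568, sd = 0.0853, lo = 0.40, hi = 0.71),
    length_mm = c(mean = 15.1, sd = 4.36, lo = 8, hi = 23),
    vessel_prob = c(LAD = 0.62, RCA = 0.23, LCx = 0.12, ramus = 0.038),
    sv_pre = c(mean = 79.1, sd = 17.0, lo = 40, hi = 130),
    et_pre = c(mean = 336, sd = 27.3, lo = 250, hi = 420),
    ava_pre = c(meanlog = log(0.60), sdlog = sdlog_from_iqr(0.542, 0.700)),
    ava_post = c(meanlog = log(2.40), sdlog = sdlog_from_iqr(2.17, 2.80)),
    p_dia_pre = c(mean = 78.5, sd = 10.2, lo = 50, hi = 110),
    pp_pre = c(mean = 62.5, sd = 16.3, lo = 25, hi = 110),
    d_sv = c(mean = 2.31, sd = 3),
    d_et = c(mean = 83.9, sd = 15, lo = 40, hi = 140),
    d_p_dia = c(mean = -0.231, sd = 3),
    d_p_sys = c(mean = 2.04, sd = 4),
    tr_pre = c(mean = 2.5, sd = 0.3, lo = 1.5, hi = 3.5),
    tr_drop = c(mean = 0.25, sd = 0.15, lo = 0, hi = 0.6),
    lv_edp = 10,
    sd_degree_state = 0.02,
    frac_rest = c(mean = 0.04, sd = 0.002, lo = 0.035, hi = 0.045),
    frac_hyper = c(mean = 0.11, sd = 0.0075, lo = 0.10, hi = 0.12),
    comorbidity_prob = c(ckd = 0.15, diabetes = 0.23, dyslipidemia = 0.77,
                         htn = 0.92, cad_history = 0.15, lvh = 0.96,
                         mitral_vd = 0.15, smoking = 0.31)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(p)) stop("unknown cohort parameter: ", nm)
    p[[nm]] <- over[[nm]]
  }
  p
}

#' Construct a virtual patient
#'
#' Container for all per-patient physiology and lesion parameters with
#' paired pre/post valve-replacement cardiac states. The lesion fields
#' (vessel, QCA degree, length) are shared between states;
#' `effective_degree` holds the per-state effective stenosis degree (equal
#' to the QCA degree unless re-measurement noise is modelled).
#'
#' @param id patient identifier.
#' @param lesion_vessel `"LAD"`, `"RCA"`, `"LCx"` or `"ramus"`.
#' @param stenosis_degree QCA diameter-reduction fraction in `[0, 1)`.
#' @param stenosis_length mm.
#' @param pre,post [cardiac_state()] objects (`post` may be `NULL` for a
#'   single-state patient).
#' @param age,lvef optional descriptors (inert in the model).
#' @param effective_degree named list `pre`/`post`; defaults to the QCA
#'   degree for both.
#' @param frac_rest,frac_hyper per-state coronary flow-fraction targets
#'   (named lists `pre`/`post`).
#' @param branch_radii optional named radii overrides, cm.
#' @param comorbidities optional named logical vector (inert).
#' @export
virtual_patient <- function(id, lesion_vessel, stenosis_degree,
                            stenosis_length, pre, post = NULL,
                            age = NA, lvef = NA,
                            effective_degree = NULL,
                            frac_rest = NULL, frac_hyper = NULL,
                            branch_radii = NULL, comorbidities = NULL) {
  stopifnot(inherits(pre, "cardiac_state"))
  if (stenosis_degree < 0 || stenosis_degree >= 1)
    stop("stenosis_degree must be in [0, 1)")
  stopifnot(stenosis_length > 0)
  lesion_vessel <- match.arg(lesion_vessel, c("LAD", "RCA", "LCx", "ramus"))
  if (!is.null(post)) {
    stopifnot(inherits(post, "cardiac_state"))
    if (!(post$ejection_time < pre$ejection_time))
      stop("post-AVR ejection time must be shorter than pre-AVR")
    if (!(post$aortic_valve_area > pre$aortic_valve_area))
      stop("post-AVR valve area must exceed pre-AVR")
  }
  if (is.null(effective_degree))
    effective_degree <- list(pre = stenosis_degree, post = stenosis_degree)
  if (is.null(frac_rest)) frac_rest <- list(pre = 0.04, post = 0.04)
  if (is.null(frac_hyper)) frac_hyper <- list(pre = 0.11, post = 0.11)
  structure(list(id = id, lesion_vessel = lesion_vessel,
                 stenosis_degree = stenosis_degree,
                 stenosis_length = stenosis_length,
                 pre = pre, post = post, age = age, lvef = lvef,
                 effective_degree = effective_degree,
                 frac_rest = frac_rest, frac_hyper = frac_hyper,
                 branch_radii = branch_radii,
                 comorbidities = comorbidities),
            class = "virtual_patient")
}

#' Sample one virtual patient
#'
#' Draws a patient from the cohort distributions of [cohort_params()] using
#' the current RNG state (seed via [generate_cohort()] or `set.seed()`).
#'
#' @param id patient identifier.
#' @param params from [cohort_params()].
#' @return A [virtual_patient()].
#' @export
sample_patient <- function(id = 1L, params = cohort_params()) {
  p <- params
  tn <- function(v, n = 1) rtruncnorm(n, v[["mean"]], v[["sd"]], v[["lo"]], v[["hi"]])
  age <- tn(p$age)
  lvef <- tn(p$lvef)
  degree <- tn(p$degree)
  len <- tn(p$length_mm)
  vessel <- sample(names(p$vessel_prob), 1,
                   prob = p$vessel_prob / sum(p$vessel_prob))

  sv_pre <- tn(p$sv_pre)
  et_pre <- tn(p$et_pre)
  ava_pre <- stats::rlnorm(1, p$ava_pre[["meanlog"]], p$ava_pre[["sdlog"]])
  p_dia_pre <- tn(p$p_dia_pre)
  pp_pre <- tn(p$pp_pre)
  tr_pre <- tn(p$tr_pre)

  sv_post <- max(sv_pre + stats::rnorm(1, p$d_sv[["mean"]], p$d_sv[["sd"]]), 30)
  d_et <- tn(p$d_et)
  et_post <- max(et_pre - d_et, 140)
  if (et_post >= et_pre) et_post <- et_pre - 10
  ava_post <- stats::rlnorm(1, p$ava_post[["meanlog"]], p$ava_post[["sdlog"]])
  ava_post <- max(ava_post, ava_pre + 0.5)
  p_dia_post <- p_dia_pre + stats::rnorm(1, p$d_p_dia[["mean"]], p$d_p_dia[["sd"]])
  p_sys_post <- p_dia_pre + pp_pre +
    stats::rnorm(1, p$d_p_sys[["mean"]], p$d_p_sys[["sd"]])
  pp_post <- max(p_sys_post - p_dia_post, 25)
  tr_post <- max(tr_pre - tn(p$tr_drop), 0.5)

  mk_state <- function(sv, et, ava, dia, pp, tr) {
    cardiac_state(heart_rate = p$heart_rate, stroke_volume = sv,
                  ejection_time = et, aortic_valve_area = ava,
                  p_sys = dia + pp, p_dia = dia,
                  lv_edp = p$lv_edp, tr_velocity = tr)
  }
  pre <- mk_state(sv_pre, et_pre, ava_pre, p_dia_pre, pp_pre, tr_pre)
  post <- mk_state(sv_post, et_post, ava_post, p_dia_post, pp_post, tr_post)

  eff <- pmin(pmax(degree + stats::rnorm(2, 0, p$sd_degree_state), 0.05), 0.92)
  fr <- rtruncnorm(2, p$frac_rest[["mean"]], p$frac_rest[["sd"]],
                   p$frac_rest[["lo"]], p$frac_rest[["hi"]])
  fh <- rtruncnorm(2, p$frac_hyper[["mean"]], p$frac_hyper[["sd"]],
                   p$frac_hyper[["lo"]], p$frac_hyper[["hi"]])
  com <- stats::setNames(
    stats::runif(length(p$comorbidity_prob)) < p$comorbidity_prob,
    names(p$comorbidity_prob))

  virtual_patient(id = id, lesion_vessel = vessel, stenosis_degree = degree,
                  stenosis_length = len, pre = pre, post = post,
                  age = age, lvef = lvef,
                  effective_degree = list(pre = eff[1], post = eff[2]),
                  frac_rest = list(pre = fr[1], post = fr[2]),
                  frac_hyper = list(pre = fh[1], post = fh[2]),
                  comorbidities = com)
}

#' Generate a virtual cohort
#'
#' `n` independent patients from one seeded stream (default n = 26, the
#' study size).
#'
#' @param n cohort size.
#' @param seed RNG seed (integer) or `NULL` to use the current stream.
#' @param params [cohort_params()].
#' @return List of [virtual_patient()]s.
#' @export
generate_cohort <- function(n = 26, seed = 0, params = cohort_params()) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), sample_patient, params = params)
}

#' Synthetic invasive FFR measurement
#'
#' Adds a relative measurement error to a model-derived FFR:
#' `ffr * (1 + eps/100)` with `eps ~ N(bias_pct, noise_sd_pct)`, clipped to
#' `(0, 1.1]`. The default scale mirrors the published model-vs-invasive
#' agreement (bias -1.486%, SD 1.938%).
#'
#' @param model_ffr model FFR in `(0, 1]` (vectorised).
#' @param bias_pct mean percentage difference.
#' @param noise_sd_pct SD of the percentage difference.
#' @return Synthetic invasive FFR values.
#' @export
synth_invasive_ffr <- function(model_ffr, bias_pct = -1.486,
                               noise_sd_pct = 1.938) {
  stopifnot(all(model_ffr > 0), all(model_ffr <= 1 + 1e-9))
  eps <- stats::rnorm(length(model_ffr), bias_pct, noise_sd_pct)
  pmin(pmax(model_ffr * (1 + eps / 100), 1e-6), 1.1)
}

#' Write / read a virtual patient as JSON
#'
#' Plain-text patient configuration with unit-suffixed keys
#' (`radius_cm`, `stenosis_length_mm`, `p_sys_mmhg`, ...).
#'
#' @param patient a [virtual_patient()].
#' @param path file path.
#' @export
write_patient_json <- function(patient, path) {
  st <- function(s) if (is.null(s)) NULL else list(
    heart_rate_bpm = s$heart_rate, stroke_volume_ml = s$stroke_volume,
    ejection_time_ms = s$ejection_time, ava_cm2 = s$aortic_valve_area,
    p_sys_mmhg = s$p_sys, p_dia_mmhg = s$p_dia, p_mean_mmhg = s$p_mean,
    lv_peak_mmhg = s$lv_peak, lv_edp_mmhg = s$lv_edp,
    tr_velocity_m_s = s$tr_velocity)
  obj <- list(id = patient$id, lesion_vessel = patient$lesion_vessel,
              stenosis_degree = patient$stenosis_degree,
              stenosis_length_mm = patient$stenosis_length,
              age_years = patient$age, lvef = patient$lvef,
              effective_degree = patient$effective_degree,
              frac_rest = patient$frac_rest, frac_hyper = patient$frac_hyper,
              branch_radii_cm = patient$branch_radii,
              comorbidities = as.list(patient$comorbidities),
              pre = st(patient$pre), post = st(patient$post))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_patient_json
#' @export
read_patient_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- function(s) if (is.null(s)) NULL else
    cardiac_state(heart_rate = s$heart_rate_bpm,
                  stroke_volume = s$stroke_volume_ml,
                  ejection_time = s$ejection_time_ms,
                  aortic_valve_area = s$ava_cm2,
                  p_sys = s$p_sys_mmhg, p_dia = s$p_dia_mmhg,
                  p_mean = s$p_mean_mmhg, lv_peak = s$lv_peak_mmhg,
                  lv_edp = s$lv_edp_mmhg, tr_velocity = s$tr_velocity_m_s)
  virtual_patient(id = o$id, lesion_vessel = o$lesion_vessel,
                  stenosis_degree = o$stenosis_degree,
                  stenosis_length = o$stenosis_length_mm,
                  pre = st(o$pre), post = st(o$post),
                  age = o$age_years, lvef = o$lvef,
                  effective_degree = as.list(o$effective_degree),
                  frac_rest = as.list(o$frac_rest),
                  frac_hyper = as.list(o$frac_hyper),
                  branch_radii = o$branch_radii_cm,
                  comorbidities = unlist(o$comorbidities))
}
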