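# Orchestration: tune and simulate each patient-state in both modes,
# collect indices and WSS summaries for the whole cohort, then run the
# paired statistics and the Bland-Altman validation.

#' Pipeline run configuration
#'
#' @param n cohort size (default 26).
#' @param seed RNG seed for cohort generation and the synthetic invasive
#'   channel.
#' @param dt solver output interval, s.
#' @param n_cycles cycles for the reported (final) simulations.
#' @param tune_cycles cycles per in-loop (first-order) tuning simulation.
#' @param dx WSS axial grid spacing, cm.
#' @param k_high high-WSS threshold multiple.
#' @param n_validation number of patients in the synthetic invasive-FFR
#'   validation subset.
#' @param params cohort distribution parameters, [cohort_params()].
#' @export
run_config <- function(n = 26, seed = 0, dt = 0.001, n_cycles = 7,
                       tune_cycles = 2, dx = 0.025, k_high = 4,
                       n_validation = 10, params = cohort_params()) {
  stopifnot(n >= 1, dt > 0, n_cycles >= 2, tune_cycles >= 2)
  list(n = n, seed = seed, dt = dt, n_cycles = n_cycles,
       tune_cycles = tune_cycles, dx = dx, k_high = k_high,
       n_validation = n_validation, params = params)
}

#' Tune and simulate one patient-state in both modes
#'
#' The per-state workflow: (1) tune the aortic RCR to the state's pressure
#' targets on the rest network; (2) tune the rest-mode coronary outlets to
#' the state's resting flow fraction and the 3:1 velocity ratio and run the
#' full-length rest simulation; (3) rebuild for hyperemia (stress
#' resistance distribution), tune to the hyperemic fraction, and run the
#' full-length hyperemic simulation.
#'
#' @param patient a [virtual_patient()].
#' @param state `"pre"` or `"post"`.
#' @param cfg a [run_config()].
#' @return List: `sim_rest`, `sim_hyper` (converged `coro_sim`s),
#'   `rcr_fit`, `cor_rest`, `cor_hyper`, `targets`.
#' @export
tune_patient_state <- function(patient, state = c("pre", "post"),
                               cfg = run_config()) {
  state <- match.arg(state)
  cs <- patient[[state]]
  targets <- tuning_targets(
    cs,
    rest_coronary_fraction = patient$frac_rest[[state]],
    stress_coronary_fraction = patient$frac_hyper[[state]])

  net_rest <- build_network(patient, state, "rest", targets = targets)
  rcr_fit <- tune_rcr(targets, net_rest, n_cycles = cfg$tune_cycles)
  net_rest$systemic <- rcr_fit$rcr
  cor_rest <- tune_coronary(targets, net_rest, "rest",
                            n_cycles = cfg$tune_cycles)
  sim_rest <- simulate_network(cor_rest$network, n_cycles = cfg$n_cycles,
                               dt = cfg$dt)

  hyp <- hyperemic_outlets(cor_rest$coronary,
                           f_rest = targets$rest_coronary_fraction,
                           f_hyper = targets$stress_coronary_fraction)
  net_hyper <- build_network(patient, state, "hyper", rcr = rcr_fit$rcr,
                             coronary = hyp$coronary, targets = targets)
  cor_hyper <- tune_coronary(targets, net_hyper, "hyper",
                             r_floor = hyp$r_floor,
                             n_cycles = cfg$tune_cycles)
  sim_hyper <- simulate_network(cor_hyper$network, n_cycles = cfg$n_cycles,
                                dt = cfg$dt)

  list(sim_rest = sim_rest, sim_hyper = sim_hyper, rcr_fit = rcr_fit,
       cor_rest = cor_rest, cor_hyper = cor_hyper, targets = targets)
}

#' Run the full workflow for one patient
#'
#' Both states (pre/post), both modes (rest/hyperemia): tuned parameters,
#' converged simulations, the index set, and the WSS report of the
#' rest-mode lesion branch.
#'
#' @param patient a [virtual_patient()].
#' @param cfg a [run_config()].
#' @param keep_sims keep the full simulation objects (memory-heavy).
#' @return List with `rows` (a two-row data frame, one per state) and,
#'   if requested, `runs`.
#' @export
run_patient <- function(patient, cfg = run_config(), keep_sims = FALSE) {
  rows <- list()
  runs <- list()
  for (state in c("pre", "post")) {
    if (is.null(patient[[state]])) next
    run <- tune_patient_state(patient, state, cfg)
    idx <- compute_indices(run$sim_rest, run$sim_hyper)
    wr <- wss_report(run$sim_rest, dx = cfg$dx, k = cfg$k_high)
    rows[[state]] <- cbind(
      data.frame(id = patient$id, state = state,
                 lesion_vessel = patient$lesion_vessel,
                 stenosis_degree = patient$stenosis_degree,
                 effective_degree = patient$effective_degree[[state]]),
      idx,
      data.frame(tawss_mean = wr$tawss_mean, tawss_median = wr$tawss_median,
                 osi_mean = wr$osi_mean, high_frac = wr$high_frac,
                 high_frac_profile = wr$high_frac_profile,
                 rcr_converged = run$rcr_fit$converged,
                 cor_rest_converged = run$cor_rest$converged,
                 cor_hyper_converged = run$cor_hyper$converged))
    if (keep_sims) runs[[state]] <- run
  }
  out <- list(rows = do.call(rbind, rows))
  if (keep_sims) out$runs <- runs
  out
}

#' Run the full cohort analysis
#'
#' Generates (or accepts) a cohort, runs every patient through tuning,
#' simulation, indices and WSS, and attaches a synthetic invasive-FFR
#' channel to the validation subset. Per-patient failures are caught and
#' reported; the cohort run continues.
#'
#' @param cfg a [run_config()].
#' @param patients optional pre-generated list of [virtual_patient()]s
#'   (otherwise generated from `cfg`).
#' @param progress print one line per patient.
#' @return Object of class `cohort_result`: `table` (one row per
#'   patient-state), `validation` (invasive vs model FFR pairs),
#'   `failures`, `cfg`.
#' @export
run_cohort <- function(cfg = run_config(), patients = NULL, progress = FALSE) {
  if (is.null(patients))
    patients <- generate_cohort(cfg$n, seed = cfg$seed, params = cfg$params)
  rows <- list()
  failures <- list()
  for (i in seq_along(patients)) {
    res <- tryCatch(run_patient(patients[[i]], cfg), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(id = patients[[i]]$id, message = conditionMessage(res))
      if (progress) message("patient ", patients[[i]]$id, " FAILED: ",
                            conditionMessage(res))
      next
    }
    rows[[length(rows) + 1]] <- res$rows
    if (progress) message("patient ", patients[[i]]$id, " done")
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  # synthetic invasive validation subset (pre-AVR model FFR); reseeded so
  # the channel is reproducible whether or not patients were supplied
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1)
  pre_tab <- tab[tab$state == "pre", ]
  nv <- min(cfg$n_validation, nrow(pre_tab))
  validation <- NULL
  if (nv >= 2) {
    sub <- pre_tab[seq_len(nv), ]
    validation <- data.frame(id = sub$id, model_ffr = sub$ffr,
                             invasive_ffr = synth_invasive_ffr(sub$ffr))
  }
  structure(list(table = tab, validation = validation,
                 failures = if (length(failures)) do.call(rbind, failures) else NULL,
                 completed = length(rows), attempted = length(patients),
                 cfg = cfg),
            class = "cohort_result")
}

#' Paired pre/post statistics for a cohort run
#'
#' Runs the distribution-gated paired test for every index and WSS summary
#' and the Bland-Altman agreement of model vs synthetic invasive FFR on
#' the validation subset.
#'
#' @param cohort a `cohort_result` from [run_cohort()].
#' @param variables columns of the cohort table to compare.
#' @return List: `paired` (data frame, one row per variable),
#'   `bland_altman` (or `NULL` without a validation subset).
#' @export
cohort_stats <- function(cohort,
                         variables = c("ffr", "ifr", "pd_pa_rest", "cfr",
                                       "q_rest", "q_hyper", "tawss_mean",
                                       "tawss_median", "osi_mean",
                                       "high_frac")) {
  tab <- cohort$table
  ids <- intersect(tab$id[tab$state == "pre"], tab$id[tab$state == "post"])
  pre <- tab[tab$state == "pre" & tab$id %in% ids, ]
  post <- tab[tab$state == "post" & tab$id %in% ids, ]
  pre <- pre[order(pre$id), ]
  post <- post[order(post$id), ]
  paired <- do.call(rbind, lapply(variables, function(v)
    paired_compare(pre[[v]], post[[v]], variable = v)))
  ba <- NULL
  if (!is.null(cohort$validation))
    ba <- bland_altman(cohort$validation$invasive_ffr,
                       cohort$validation$model_ffr, type = "percent")
  list(paired = paired, bland_altman = ba)
}

#' Write cohort outputs as CSV/JSON
#'
#' Writes the per-patient-state table, the paired-test table, and the
#' Bland-Altman summary under `dir`.
#'
#' @param cohort a `cohort_result`.
#' @param stats result of [cohort_stats()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_cohort_results <- function(cohort, stats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    table = file.path(dir, "cohort_table.csv"),
    paired = file.path(dir, "paired_tests.csv"),
    ba = file.path(dir, "bland_altman.json"),
    manifest = file.path(dir, "manifest.json"))
  utils::write.csv(cohort$table, paths[["table"]], row.names = FALSE)
  utils::write.csv(stats$paired, paths[["paired"]], row.names = FALSE)
  if (!is.null(stats$bland_altman)) {
    ba <- stats$bland_altman
    jsonlite::write_json(list(bias = ba$bias, sd = ba$sd,
                              loa_low = ba$loa_low, loa_high = ba$loa_high,
                              pct_within_loa = ba$pct_within_loa,
                              type = ba$type, n = ba$n),
                         paths[["ba"]], auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(list(seed = cohort$cfg$seed, n = cohort$cfg$n,
                            dt = cohort$cfg$dt, n_cycles = cohort$cfg$n_cycles,
                            completed = cohort$completed,
                            attempted = cohort$attempted),
                       paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Reference synthetic patient
#'
#' A deterministic single patient at the cohort's central values: LAD
#' lesion of degree 0.57 and length 15 mm, stroke volume 79.1 mL, ejection
#' time 336 ms, AVA 0.6 cm^2, aortic pressures 141/78.5 (mean 99.3) mmHg,
#' heart rate 70, TR velocity 2.5 m/s. Used by the worked examples and as
#' the model-verification fixture.
#'
#' @param degree stenosis degree override.
#' @return A [virtual_patient()] (pre-state only).
#' @export
reference_patient <- function(degree = 0.57) {
  pre <- cardiac_state(heart_rate = 70, stroke_volume = 79.1,
                       ejection_time = 336, aortic_valve_area = 0.6,
                       p_sys = 141, p_dia = 78.5, tr_velocity = 2.5)
  virtual_patient(id = "ref", lesion_vessel = "LAD",
                  stenosis_degree = degree, stenosis_length = 15, pre = pre)
}
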