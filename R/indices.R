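# Coronary physiology indices computed from converged simulations:
# FFR (hyperemic mean Pd/Pa), iFR (resting wave-free-period Pd/Pa),
# resting whole-cycle Pd/Pa, and CFR (hyperemic over resting flow).

#' Fractional flow reserve
#'
#' Ratio of the cycle-mean pressure distal to the stenosis (`Pd`, sampled
#' at the node immediately distal to the stenosis element) to the
#' cycle-mean pressure at the branch ostium (`Pa`), on the final cycle of a
#' hyperemic-mode simulation.
#'
#' @param sim_hyper a `coro_sim` run in hyperemic mode.
#' @param branch branch name carrying the lesion (default: the network's
#'   stenotic branch).
#' @param pa_at `"ostium"` (branch proximal node) or `"aorta"` (aortic
#'   root); the two are one (negligible) node apart here.
#' @return FFR, dimensionless.
#' @export
compute_ffr <- function(sim_hyper, branch = lesion_branch(sim_hyper),
                        pa_at = c("ostium", "aorta")) {
  pa_at <- match.arg(pa_at)
  if (!identical(sim_hyper$mode, "hyper"))
    stop("mode mismatch: FFR must be computed on a hyperemic-mode simulation")
  b <- sim_hyper$branches[[branch]]
  pa <- if (pa_at == "aorta") sim_hyper$p_aorta else b$p_prox
  cycle_mean(sim_hyper, b$p_dist) / cycle_mean(sim_hyper, pa)
}

#' Resting whole-cycle distal-to-proximal pressure ratio
#'
#' @param sim_rest a rest-mode `coro_sim`.
#' @inheritParams compute_ffr
#' @export
compute_pd_pa <- function(sim_rest, branch = lesion_branch(sim_rest),
                          pa_at = c("ostium", "aorta")) {
  pa_at <- match.arg(pa_at)
  b <- sim_rest$branches[[branch]]
  pa <- if (pa_at == "aorta") sim_rest$p_aorta else b$p_prox
  cycle_mean(sim_rest, b$p_dist) / cycle_mean(sim_rest, pa)
}

# name of the branch carrying a stenosis (first one, if several)
lesion_branch <- function(sim) {
  net <- if (inherits(sim, "coro_sim")) sim$network else sim
  has <- vapply(net$branches, function(b) !is.null(b$stenosis), NA)
  if (!any(has)) stop("network has no stenotic branch")
  names(net$branches)[which(has)[1]]
}

#' Diastolic wave-free window
#'
#' Diastole is taken as `[ejection_time, cycle_end]` (the inflow is
#' prescribed and returns to zero at end-ejection, so no dicrotic-notch
#' detection is needed); the wave-free window runs from 25% into diastole
#' to 5 ms before end-diastole, the usual convention for resting
#' wave-free-period indices.
#'
#' @param state a [cardiac_state()].
#' @return `c(t_start, t_end)` in seconds within the cycle.
#' @export
wave_free_window <- function(state) {
  T <- state$period
  et <- state$ejection_time / 1000
  dia <- T - et
  if (dia <= 0.05) stop("diastole shorter than 50 ms; wave-free window undefined")
  w <- c(et + 0.25 * dia, T - 0.005)
  if (w[1] >= w[2]) stop("empty wave-free window")
  w
}

#' Instantaneous wave-free ratio
#'
#' Mean distal pressure over mean ostial pressure within the diastolic
#' wave-free window, on the final cycle of a rest-mode simulation.
#'
#' @param sim_rest a rest-mode `coro_sim`.
#' @param branch lesion branch name.
#' @param window `c(t_start, t_end)` within the cycle, from
#'   [wave_free_window()]; defaults to the simulation's own cardiac state.
#' @inheritParams compute_ffr
#' @export
compute_ifr <- function(sim_rest, branch = lesion_branch(sim_rest),
                        window = wave_free_window(sim_rest$network$cardiac_state),
                        pa_at = c("ostium", "aorta")) {
  pa_at <- match.arg(pa_at)
  if (!identical(sim_rest$mode, "rest"))
    stop("mode mismatch: iFR must be computed on a rest-mode simulation")
  T <- sim_rest$period
  if (any(window < 0) || any(window > T) || window[1] >= window[2])
    stop("wave-free window outside the cycle")
  t0 <- (sim_rest$n_cycles - 1) * T
  i <- which(sim_rest$time >= t0 + window[1] - 1e-12 &
             sim_rest$time <= t0 + window[2] + 1e-12)
  if (length(i) < 2) stop("wave-free window contains too few samples")
  b <- sim_rest$branches[[branch]]
  pa <- if (pa_at == "aorta") sim_rest$p_aorta else b$p_prox
  tt <- sim_rest$time[i]
  trapz(tt, b$p_dist[i]) / trapz(tt, pa[i])
}

#' Coronary flow reserve
#'
#' Cycle-mean hyperemic branch flow over cycle-mean resting branch flow
#' (final cycles). With `branch = "total"` the summed coronary flow is
#' used.
#'
#' @param sim_rest,sim_hyper rest- and hyperemic-mode simulations of the
#'   same patient-state.
#' @param branch branch name or `"total"`.
#' @export
compute_cfr <- function(sim_rest, sim_hyper, branch = lesion_branch(sim_rest)) {
  qb <- function(sim) {
    if (identical(branch, "total"))
      sum(vapply(sim$branches, function(b) cycle_mean(sim, b$q), 0))
    else cycle_mean(sim, sim$branches[[branch]]$q)
  }
  q_rest <- qb(sim_rest)
  q_hyper <- qb(sim_hyper)
  if (abs(q_rest) < 1e-12) stop("zero resting flow; CFR undefined")
  q_hyper / q_rest
}

#' Full index set for one patient-state
#'
#' @param sim_rest,sim_hyper converged rest and hyperemic simulations.
#' @param branch lesion branch.
#' @return One-row data frame: `ffr`, `ifr`, `pd_pa_rest`, `cfr`
#'   (lesion-branch), `cfr_total`, `q_rest`, `q_hyper` (total coronary,
#'   cm^3/s), `pa_mean`, `pd_mean` (hyperemic cycle means, mmHg).
#' @export
compute_indices <- function(sim_rest, sim_hyper,
                            branch = lesion_branch(sim_rest)) {
  b <- sim_hyper$branches[[branch]]
  data.frame(
    branch = branch,
    ffr = compute_ffr(sim_hyper, branch),
    ifr = compute_ifr(sim_rest, branch),
    pd_pa_rest = compute_pd_pa(sim_rest, branch),
    cfr = compute_cfr(sim_rest, sim_hyper, branch),
    cfr_total = compute_cfr(sim_rest, sim_hyper, "total"),
    q_rest = sum(vapply(sim_rest$branches, function(x) cycle_mean(sim_rest, x$q), 0)),
    q_hyper = sum(vapply(sim_hyper$branches, function(x) cycle_mean(sim_hyper, x$q), 0)),
    pa_mean = cycle_mean(sim_hyper, b$p_prox),
    pd_mean = cycle_mean(sim_hyper, b$p_dist)
  )
}
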