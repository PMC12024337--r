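#' Trans-stenotic pressure drop
#'
#' Constitutive law of the stenosis element: a viscous (Poiseuille) term in
#' the narrowed throat plus a turbulent expansion-loss term,
#' \deqn{\Delta P = R_v q + k_t \frac{\rho}{2 A_0^2}\left(\frac{A_0}{A_s} -
#' 1\right)^2 q |q|,}
#' with \eqn{A_0 = \pi r_0^2} the reference area, \eqn{A_s} the throat area
#' at diameter reduction `degree`, and \eqn{R_v = 8 \mu L / (\pi r_s^4)}.
#' The drop carries the sign of the flow and vanishes at `q = 0`; with
#' `degree = 0` only the viscous term remains.
#'
#' @param q flow, cm^3/s (vectorised).
#' @param sten a [stenosis_spec()].
#' @param fluid [fluid_properties()].
#' @return Pressure drop, mmHg, with the sign of `q`.
#' @export
stenosis_dp <- function(q, sten, fluid = fluid_properties()) {
  co <- stenosis_coefs(sten, fluid)
  dyn2mmhg(co$b * q + co$a * q * abs(q))
}

# Linear (b, dyn s/cm^5) and quadratic (a, dyn s^2/cm^8) coefficients of the
# stenosis law, in CGS.
stenosis_coefs <- function(sten, fluid) {
  a0 <- pi * sten$ref_radius^2
  as <- pi * sten$throat_radius^2
  len_cm <- sten$length / 10
  b <- poiseuille_resistance(sten$throat_radius, max(len_cm, 1e-9), fluid)
  if (sten$length <= 0) b <- 0
  a <- sten$kt * fluid$rho / (2 * a0^2) * (a0 / as - 1)^2
  list(a = a, b = b)
}

#' Assemble the ODE system of a network
#'
#' Reduces the network to a stiff ODE in the capacitor pressures: one state
#' for the systemic Windkessel capacitor and two per coronary branch (the
#' arterial-compliance node and the intramyocardial-compliance node, the
#' latter carried relative to its `Pim` source so no `dPim/dt` is needed).
#' Branch flows are algebraic in the nodal pressures; the aortic root
#' pressure is resolved at every evaluation by a safeguarded Newton solve of
#' the (monotone) nodal flow balance, which is nonlinear only through the
#' quadratic stenosis term.
#'
#' @param network a `network_spec` from [build_network()] (or assembled by
#'   hand with the same structure).
#' @return Object of class `ode_system`: state layout, derivative closure
#'   and per-branch coefficient tables.
#' @export
assemble_system <- function(network) {
  nb <- length(network$branches)
  fl <- network$fluid
  sys <- network$systemic
  p_ref <- mmhg2dyn(sys$p_ref)
  qin_f <- wf_fun(network$inflow)

  if (nb > 0) {
    res <- lapply(network$branches, branch_series_resistance, fluid = fl)
    b_lin <- a_quad <- r_prox <- r_sten_v <- numeric(nb)
    ramicro <- rv <- ca <- cim <- numeric(nb)
    pim_f <- vector("list", nb)
    for (i in seq_len(nb)) {
      br <- network$branches[[i]]
      out <- br$outlet
      co <- if (is.null(br$stenosis)) list(a = 0, b = 0) else
        stenosis_coefs(br$stenosis, fl)
      b_lin[i] <- res[[i]]$r_prox + co$b + res[[i]]$r_dist + out$ra
      a_quad[i] <- co$a
      r_prox[i] <- res[[i]]$r_prox
      r_sten_v[i] <- co$b
      ramicro[i] <- out$ra_micro
      rv[i] <- out$rv
      ca[i] <- out$ca
      cim[i] <- out$cim
      pim_f[[i]] <- wf_fun(br$pim)
    }
  } else {
    b_lin <- a_quad <- r_prox <- r_sten_v <- ramicro <- rv <- ca <- cim <- numeric(0)
    pim_f <- list()
  }

  env <- new.env(parent = emptyenv())
  env$p_ao_last <- mmhg2dyn(80)

  # flow through a branch chain for a given driving pressure (dyn)
  branch_q <- function(dp) {
    q <- dp / b_lin
    nl <- a_quad > 0
    if (any(nl)) {
      aa <- a_quad[nl]; bb <- b_lin[nl]; d <- dp[nl]
      q[nl] <- sign(d) * (-bb + sqrt(bb^2 + 4 * aa * abs(d))) / (2 * aa)
    }
    q
  }

  solve_p_ao <- function(qin, pc, p_ca) {
    if (nb == 0) return(pc + sys$rp * qin)
    p <- env$p_ao_last
    for (it in 1:60) {
      dp <- p - p_ca
      q <- branch_q(dp)
      f <- (p - pc) / sys$rp + sum(q) - qin
      fp <- 1 / sys$rp + sum(1 / sqrt(b_lin^2 + 4 * a_quad * abs(dp)))
      step <- f / fp
      p <- p - step
      if (abs(step) < 1e-6) break
    }
    env$p_ao_last <- p
    p
  }

  derivs <- function(t, y, parms) {
    qin <- qin_f(t)
    pc <- y[1]
    if (nb == 0) {
      p_ao <- pc + sys$rp * qin
      dpc <- (qin - (pc - p_ref) / sys$rd) / sys$c
      return(list(dpc, c(p_ao = p_ao)))
    }
    p_ca <- y[2:(1 + nb)]
    pic <- y[(2 + nb):(1 + 2 * nb)]
    pim <- mmhg2dyn(vapply(pim_f, function(f) f(t), 0))
    p_cim <- pic + pim
    p_ao <- solve_p_ao(qin, pc, p_ca)
    q_br <- branch_q(p_ao - p_ca)
    q_mid <- (p_ca - p_cim) / ramicro
    q_v <- p_cim / rv
    dpc <- (((p_ao - pc) / sys$rp) - (pc - p_ref) / sys$rd) / sys$c
    dp_ca <- (q_br - q_mid) / ca
    dpic <- (q_mid - q_v) / cim
    list(c(dpc, dp_ca, dpic), c(p_ao = p_ao, q_br))
  }

  structure(list(
    derivs = derivs, n_state = 1L + 2L * nb, n_branches = nb,
    branch_names = names(network$branches),
    b_lin = b_lin, a_quad = a_quad, r_prox = r_prox, r_sten_v = r_sten_v,
    ramicro = ramicro, rv = rv, ca = ca, cim = cim,
    pim_f = pim_f, network = network
  ), class = "ode_system")
}

#' Integrate a lumped circulation network over repeated cardiac cycles
#'
#' Runs the assembled ODE system with an adaptive stiffness-switching
#' integrator (`deSolve::lsoda`) and dense output on a uniform grid of
#' approximately `dt` spacing that lands exactly on every cycle boundary.
#' Results are reported in user units (mmHg, cm^3/s); by convention the
#' quantities of interest are read from the final cycle.
#'
#' @param network a `network_spec`.
#' @param n_cycles number of cardiac cycles to integrate (default 7).
#' @param dt target output interval, s (default 1 ms).
#' @param y0 initial state (dyn/cm^2); the default is the pressure-primed
#'   state of [initial_state()] (capacitors pre-charged near the mean
#'   pressure target), the standard practice that lets a cyclic state be
#'   reached within a handful of cycles. Pass `numeric(n_state)` (zeros)
#'   for a cold start: with a physiologic arterial time constant
#'   (`tau = R C` of order 1.5 s) a cold start needs roughly 10 cycles to
#'   settle below a 1% cycle-to-cycle residual.
#' @param rtol,atol integrator tolerances.
#' @return Object of class `coro_sim`: `time`, `cycle`, `p_aorta` (mmHg),
#'   `q_systemic`, `q_systemic_out` (cm^3/s), and per-branch lists `q`,
#'   `p_prox`, `p_dist`, `p_outlet`, `p_cim` (mmHg), plus bookkeeping.
#' @export
simulate_network <- function(network, n_cycles = 7, dt = 0.001, y0 = NULL,
                             rtol = 1e-6, atol = 1e-2) {
  stopifnot(n_cycles >= 1, dt > 0)
  system <- assemble_system(network)
  simulate_system(system, n_cycles = n_cycles, dt = dt, y0 = y0,
                  rtol = rtol, atol = atol)
}

#' @rdname simulate_network
#' @param system an `ode_system` from [assemble_system()].
#' @export
simulate_system <- function(system, n_cycles = 7, dt = 0.001, y0 = NULL,
                            rtol = 1e-6, atol = 1e-2) {
  network <- system$network
  T <- network$period
  m <- max(2L, as.integer(round(T / dt)))
  tc <- (0:m) * (T / m)
  times <- c(0, as.vector(outer(tc[-1], (0:(n_cycles - 1)) * T, "+")))
  cycle <- c(1L, rep(seq_len(n_cycles), each = m))

  if (is.null(y0)) y0 <- initial_state(system)
  stopifnot(length(y0) == system$n_state)

  sol <- deSolve::lsoda(y = y0, times = times, func = system$derivs,
                        parms = NULL, rtol = rtol, atol = atol,
                        hmax = T / 40, maxsteps = 50000)
  bad <- !stats::complete.cases(sol) | apply(!is.finite(sol), 1, any)
  if (any(bad))
    stop("integration failure: non-finite state first at t = ",
         signif(times[which(bad)[1]], 6), " s")

  nb <- system$n_branches
  pc <- sol[, 2]
  if (nb > 0) {
    p_ca <- sol[, 2 + seq_len(nb), drop = FALSE]
    pic <- sol[, 2 + nb + seq_len(nb), drop = FALSE]
    p_ao <- sol[, 2 + 2 * nb + 1]
    q_br <- sol[, 2 + 2 * nb + 1 + seq_len(nb), drop = FALSE]
  } else {
    p_ao <- sol[, 3]
    p_ca <- pic <- q_br <- matrix(0, nrow(sol), 0)
  }

  qin <- wf_fun(network$inflow)(times)
  q_sys <- (p_ao - pc) / network$systemic$rp
  q_sys_out <- (pc - mmhg2dyn(network$systemic$p_ref)) / network$systemic$rd

  branches <- list()
  for (i in seq_len(nb)) {
    q <- q_br[, i]
    pim <- mmhg2dyn(system$pim_f[[i]](times))
    p_prox <- p_ao - system$r_prox[i] * q
    p_dist <- p_prox - (system$r_sten_v[i] * q + system$a_quad[i] * q * abs(q))
    branches[[system$branch_names[i]]] <- list(
      q = q,
      p_prox = dyn2mmhg(p_prox),
      p_dist = dyn2mmhg(p_dist),
      p_outlet = dyn2mmhg(p_ca[, i]),
      p_cim = dyn2mmhg(pic[, i] + pim),
      q_venous = (pic[, i] + pim) / system$rv[i]
    )
  }

  structure(list(
    time = times, cycle = cycle, n_cycles = n_cycles, period = T, dt = T / m,
    p_aorta = dyn2mmhg(p_ao),
    q_inflow = qin, q_systemic = q_sys, q_systemic_out = q_sys_out,
    branches = branches,
    mode = network$mode, state = network$state,
    network = network, y_final = sol[nrow(sol), 1 + seq_len(system$n_state)]
  ), class = "coro_sim")
}

#' Pressure-primed initial state for a network
#'
#' Capacitor pressures pre-charged toward the periodic state: the systemic
#' capacitor at the mean-pressure target less the proximal drop, the
#' coronary arterial nodes slightly below it, and the intramyocardial
#' states at their diastolic offset (zero relative to `Pim`). Falls back
#' to zeros when the network carries no pressure targets.
#'
#' @param system an `ode_system` (or a `network_spec`).
#' @return State vector in dyn/cm^2.
#' @export
initial_state <- function(system) {
  if (inherits(system, "network_spec")) system <- assemble_system(system)
  y0 <- numeric(system$n_state)
  tg <- system$network$targets
  if (is.null(tg)) return(y0)
  p0 <- mmhg2dyn(tg$p_mean)
  y0[1] <- p0 - system$network$systemic$rp * tg$cardiac_output *
    (1 - tg$rest_coronary_fraction)
  nb <- system$n_branches
  if (nb > 0) y0[1 + seq_len(nb)] <- 0.95 * p0
  y0
}

# indices of samples belonging to cycle k (inclusive of both boundaries)
cycle_idx <- function(sim, k) {
  stopifnot(k >= 1, k <= sim$n_cycles)
  which(sim$time >= (k - 1) * sim$period - 1e-12 &
        sim$time <= k * sim$period + 1e-12)
}

#' Cycle-mean of a simulated series
#'
#' Trapezoidal time-average of one series over one cardiac cycle.
#'
#' @param sim a `coro_sim`.
#' @param x numeric series on the simulation grid.
#' @param k cycle number (default: final cycle).
#' @return scalar mean.
#' @export
cycle_mean <- function(sim, x, k = sim$n_cycles) {
  i <- cycle_idx(sim, k)
  trapz(sim$time[i], x[i]) / sim$period
}

#' Cycle-to-cycle periodicity residual
#'
#' Maximum, over the monitored pressure nodes (aortic root and every
#' coronary outlet node), of the relative change in cycle-mean pressure
#' between cycle `k` and cycle `k - 1`. The simulation is considered
#' cyclically converged once this falls below a tolerance (1% by default in
#' [cycles_to_converge()]).
#'
#' @param sim a `coro_sim`.
#' @param k cycle number, `k >= 2`.
#' @return Dimensionless residual (fraction).
#' @export
periodicity_residual <- function(sim, k) {
  if (k < 2) stop("periodicity residual needs k >= 2")
  if (k > sim$n_cycles) stop("k exceeds the number of simulated cycles")
  series <- c(list(sim$p_aorta), lapply(sim$branches, `[[`, "p_outlet"))
  resid <- vapply(series, function(x) {
    mk <- cycle_mean(sim, x, k)
    mk1 <- cycle_mean(sim, x, k - 1)
    abs(mk - mk1) / abs(mk)
  }, 0)
  max(resid)
}

#' @rdname periodicity_residual
#' @param tol residual tolerance (default 0.01).
#' @return `cycles_to_converge`: the first cycle `k >= 2` whose residual is
#'   below `tol`, or `NA` if never reached.
#' @export
cycles_to_converge <- function(sim, tol = 0.01) {
  for (k in 2:sim$n_cycles)
    if (periodicity_residual(sim, k) < tol) return(k)
  NA_integer_
}

#' Cycle-mean flow balance of a simulation
#'
#' In the periodic state the cycle-mean inflow equals the cycle-mean
#' systemic outflow plus the summed cycle-mean coronary outflow (capacitor
#' storage nets to zero over a cycle).
#'
#' @param sim a `coro_sim`.
#' @param k cycle (default final).
#' @return List with the mean inflow, outflows, and the relative imbalance.
#' @export
flow_balance <- function(sim, k = sim$n_cycles) {
  q_in <- cycle_mean(sim, sim$q_inflow, k)
  q_sys <- cycle_mean(sim, sim$q_systemic_out, k)
  q_cor <- sum(vapply(sim$branches, function(b) cycle_mean(sim, b$q_venous, k), 0))
  list(inflow = q_in, systemic = q_sys, coronary = q_cor,
       imbalance = abs(q_in - q_sys - q_cor) / q_in)
}

#' Summary quantities of a simulation's final cycle
#'
#' @param sim a `coro_sim`.
#' @return List: aortic systolic/diastolic/mean pressure (mmHg), mean
#'   inflow, per-branch mean flows (cm^3/s) and the coronary flow fraction.
#' @export
sim_summary <- function(sim) {
  k <- sim$n_cycles
  i <- cycle_idx(sim, k)
  q_in <- cycle_mean(sim, sim$q_inflow, k)
  q_br <- vapply(sim$branches, function(b) cycle_mean(sim, b$q, k), 0)
  list(p_sys = max(sim$p_aorta[i]), p_dia = min(sim$p_aorta[i]),
       p_mean = cycle_mean(sim, sim$p_aorta, k),
       q_inflow = q_in, q_branches = q_br,
       coronary_fraction = sum(q_br) / q_in)
}
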