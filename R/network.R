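#' Blood fluid properties
#'
#' Newtonian blood in CGS units: density 1.06 g/cm^3 and dynamic viscosity
#' 0.04 poise by default.
#'
#' @param rho density, g/cm^3.
#' @param mu viscosity, poise (dyn s/cm^2).
#' @export
fluid_properties <- function(rho = 1.06, mu = 0.04) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Epicardial vessel segment
#'
#' One straight epicardial conduit from the aortic root (ostium) to its
#' coronary outlet. `lesion_start` locates the proximal end of a stenosis
#' along the segment when one is attached. Wall thickness, when not given,
#' follows the usual 1/10-of-radius rule.
#'
#' @param name label, unique within a network.
#' @param radius lumen radius, cm.
#' @param length segment length, cm.
#' @param side `"left"` or `"right"` coronary tree (selects the LV- or
#'   RV-derived intramyocardial pressure).
#' @param lesion_start distance from the ostium to the lesion's proximal
#'   end, cm.
#' @param wall_thickness cm; default `radius/10`.
#' @export
vessel_segment <- function(name, radius, length, side = c("left", "right"),
                           lesion_start = length / 3,
                           wall_thickness = NULL) {
  side <- match.arg(side)
  stopifnot(radius > 0, length > 0, lesion_start >= 0, lesion_start < length)
  if (is.null(wall_thickness)) wall_thickness <- wall_thickness_rule(radius)
  structure(list(name = name, radius = radius, length = length, side = side,
                 lesion_start = lesion_start, wall_thickness = wall_thickness),
            class = "vessel_segment")
}

#' Wall thickness rule
#'
#' Vessel wall thickness assumed to be one tenth of the mean lumen radius.
#'
#' @param radius cm.
#' @return thickness, cm.
#' @export
wall_thickness_rule <- function(radius) {
  if (any(radius <= 0)) stop("radius must be > 0")
  radius / 10
}

#' Stenosis specification
#'
#' A focal stenosis described by its QCA diameter-reduction fraction,
#' length, reference (healthy) radius, and the turbulent-loss coefficient
#' of the pressure-drop law (see [stenosis_dp()]).
#'
#' @param degree diameter reduction fraction in `[0, 1)`.
#' @param length lesion length, mm.
#' @param ref_radius reference lumen radius, cm.
#' @param kt dimensionless turbulent (expansion) loss coefficient.
#' @export
stenosis_spec <- function(degree, length, ref_radius, kt = 1.52) {
  stopifnot(length > 0, ref_radius > 0, kt >= 0)
  if (degree < 0 || degree >= 1) stop("stenosis degree must be in [0, 1)")
  structure(list(degree = degree, length = length, ref_radius = ref_radius,
                 kt = kt, throat_radius = ref_radius * (1 - degree)),
            class = "stenosis_spec")
}

#' Aortic RCR (three-element Windkessel) parameters
#'
#' @param rp proximal resistance, dyn s/cm^5.
#' @param c compliance, cm^5/dyn.
#' @param rd distal resistance, dyn s/cm^5.
#' @param p_ref distal reference pressure, mmHg.
#' @export
rcr_params <- function(rp, c, rd, p_ref = 0) {
  stopifnot(rp > 0, rd > 0, c > 0)
  structure(list(rp = rp, c = c, rd = rd, p_ref = p_ref), class = "rcr_params")
}

#' Coronary outlet (coronary Windkessel) parameters
#'
#' The coronary outlet model: small-artery resistance `ra`, microcirculatory
#' resistance `ra_micro`, venous resistance `rv` (with the micro-venous
#' resistance fixed at zero), arterial compliance `ca`, and intramyocardial
#' compliance `cim` compressed by the ventricular pressure source `Pim`.
#'
#' @param ra,ra_micro,rv resistances, dyn s/cm^5.
#' @param ca,cim compliances, cm^5/dyn.
#' @param rv_micro fixed at 0 by convention.
#' @export
coronary_outlet_params <- function(ra, ra_micro, rv, ca, cim, rv_micro = 0) {
  stopifnot(ra >= 0, ra_micro >= 0, rv >= 0, ca > 0, cim > 0)
  if (rv_micro != 0) stop("rv_micro is fixed at 0")
  structure(list(ra = ra, ra_micro = ra_micro, rv = rv, rv_micro = 0,
                 ca = ca, cim = cim), class = "coronary_outlet_params")
}

#' Murray's-law flow allocation
#'
#' Splits a total flow among branches in proportion to `radius^m`
#' (generalised Murray's law, classically `m = 3`). The last element takes
#' the closure remainder so the split sums to `q_total` exactly.
#'
#' @param radii branch radii, cm.
#' @param m Murray exponent.
#' @param q_total total flow, cm^3/s.
#' @return Per-branch flows, cm^3/s.
#' @examples
#' murray_split(c(0.2, 0.1), 3, 9)  # 8:1
#' @export
murray_split <- function(radii, m = 3, q_total) {
  if (length(radii) == 0) stop("murray_split: empty radii list")
  stopifnot(all(radii > 0), q_total >= 0)
  w <- radii^m
  q <- q_total * w / sum(w)
  q[length(q)] <- q_total - sum(q[-length(q)])
  q
}

#' Poiseuille resistance of a cylindrical segment
#'
#' `R = 8 mu L / (pi r^4)` in CGS units.
#'
#' @param radius cm.
#' @param length cm.
#' @param fluid [fluid_properties()].
#' @return Resistance, dyn s/cm^5.
#' @export
poiseuille_resistance <- function(radius, length, fluid = fluid_properties()) {
  stopifnot(all(radius > 0), all(length > 0))
  8 * fluid$mu * length / (pi * radius^4)
}

#' Default coronary branch geometry
#'
#' Literature-typical epicardial radii and lengths for a right-dominant
#' tree: LAD, LCx and RCA (plus a ramus intermedius when a patient's lesion
#' sits there). The left main is represented as a virtual common left
#' ostium whose radius enters only the left ostial velocity; its Poiseuille
#' resistance is negligible against the coronary outlet resistances.
#'
#' @param with_ramus include a ramus intermedius branch.
#' @return List with `branches` (list of [vessel_segment()]) and
#'   `ostial_radii` (named cm: left, right).
#' @export
default_branch_geometry <- function(with_ramus = FALSE) {
  br <- list(
    LAD = vessel_segment("LAD", radius = 0.18, length = 10, side = "left",
                         lesion_start = 2.0),
    LCx = vessel_segment("LCx", radius = 0.17, length = 8, side = "left",
                         lesion_start = 2.0),
    RCA = vessel_segment("RCA", radius = 0.17, length = 11, side = "right",
                         lesion_start = 2.0)
  )
  if (with_ramus)
    br$ramus <- vessel_segment("ramus", radius = 0.14, length = 6,
                               side = "left", lesion_start = 2.0)
  list(branches = br, ostial_radii = c(left = 0.225, right = 0.17))
}

#' Assemble a lumped circulation network for one patient-state
#'
#' Builds the open-loop aorto-coronary network: prescribed aortic inflow,
#' one systemic RCR outlet, and one coronary branch per epicardial vessel,
#' each a series chain of proximal segment resistance, optional stenosis
#' element, distal segment resistance and a coronary Windkessel outlet.
#' Left branches are compressed by the LV-derived intramyocardial pressure,
#' the right branch by the RV-derived one (right-dominant convention).
#'
#' @param patient a [virtual_patient()].
#' @param state `"pre"` or `"post"` (before/after valve replacement).
#' @param mode `"rest"` or `"hyper"` (adenosine hyperemia).
#' @param rcr tuned [rcr_params()]; default from [init_rcr()].
#' @param coronary named list of [coronary_outlet_params()] per branch;
#'   default from [init_coronary()].
#' @param fluid [fluid_properties()].
#' @param murray_exponent generalised Murray exponent in `[2, 3]`.
#' @param shape inflow shape, [inflow_shape()].
#' @param targets [tuning_targets()] used for default initialisation.
#' @return Object of class `network_spec`.
#' @export
build_network <- function(patient, state = c("pre", "post"),
                          mode = c("rest", "hyper"),
                          rcr = NULL, coronary = NULL,
                          fluid = fluid_properties(),
                          murray_exponent = 3,
                          shape = inflow_shape(),
                          targets = NULL) {
  state <- match.arg(state)
  mode <- match.arg(mode)
  stopifnot(inherits(patient, "virtual_patient"))
  cs <- patient[[state]]
  geom <- default_branch_geometry(with_ramus = patient$lesion_vessel == "ramus")
  if (!is.null(patient$branch_radii))
    for (nm in intersect(names(patient$branch_radii), names(geom$branches)))
      geom$branches[[nm]]$radius <- patient$branch_radii[[nm]]
  if (!patient$lesion_vessel %in% names(geom$branches))
    stop("lesion vessel '", patient$lesion_vessel, "' not among network branches")

  degree <- patient$effective_degree[[state]]
  seg <- geom$branches[[patient$lesion_vessel]]
  sten <- stenosis_spec(degree = degree, length = patient$stenosis_length,
                        ref_radius = seg$radius)

  inflow <- make_inflow(cs, shape)
  pim_l <- make_lv_pressure(cs)
  pim_r <- make_rv_pressure(cs)

  if (is.null(targets)) targets <- tuning_targets(cs)
  if (is.null(rcr)) rcr <- init_rcr(targets)

  branches <- lapply(names(geom$branches), function(nm) {
    s <- geom$branches[[nm]]
    list(segment = s,
         stenosis = if (nm == patient$lesion_vessel) sten else NULL,
         outlet = NULL,
         pim = if (s$side == "left") pim_l else pim_r)
  })
  names(branches) <- names(geom$branches)

  net <- structure(list(
    inflow = inflow, systemic = rcr, branches = branches,
    fluid = fluid, murray_exponent = murray_exponent,
    ostial_radii = geom$ostial_radii,
    state = state, mode = mode, targets = targets,
    period = cs$period, cardiac_state = cs
  ), class = "network_spec")

  if (is.null(coronary)) coronary <- init_coronary(net, targets, mode)
  for (nm in names(net$branches)) net$branches[[nm]]$outlet <- coronary[[nm]]
  net
}

# Series linear resistance of a branch up to its outlet node: proximal
# segment + stenosis viscous part + distal segment + Ra.
branch_series_resistance <- function(br, fluid) {
  seg <- br$segment
  r_prox <- poiseuille_resistance(seg$radius, seg$lesion_start, fluid)
  len_sten_cm <- if (is.null(br$stenosis)) 0 else br$stenosis$length / 10
  r_dist <- poiseuille_resistance(
    seg$radius, max(seg$length - seg$lesion_start - len_sten_cm, 1e-6), fluid)
  r_sten <- if (is.null(br$stenosis)) 0 else
    poiseuille_resistance(br$stenosis$throat_radius, len_sten_cm, fluid)
  list(r_prox = r_prox, r_sten = r_sten, r_dist = r_dist)
}
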