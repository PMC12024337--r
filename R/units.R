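# Internal unit system is CGS (cm, g, s, dyn). mmHg appears only at the
# user-facing surface; WSS is reported in Pa.

#' Unit conversion constants
#'
#' The package works internally in CGS units (cm, g, s, dyn). Pressures are
#' accepted and reported in mmHg, wall shear stress in pascal.
#'
#' @format `MMHG_TO_DYN` is the number of dyn/cm^2 in one mmHg (1333.22);
#'   `DYN_TO_PA` converts dyn/cm^2 to Pa (0.1).
#' @name units
#' @keywords internal
NULL

MMHG_TO_DYN <- 1333.22
DYN_TO_PA <- 0.1

mmhg2dyn <- function(p) p * MMHG_TO_DYN
dyn2mmhg <- function(p) p / MMHG_TO_DYN
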