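#' Physical constants and unit conversions
#'
#' All energies inside the package are handled in units of kBT (thermal
#' energy at the temperature of the physical parameter set, default 298 K),
#' lengths in micrometres and pressures in pascal.  This table centralises
#' the conversions.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K.}
#'   \item{R_gas}{Molar gas constant, J/(mol K).}
#'   \item{J_per_Pa_um3}{Joule per (pascal x cubic micrometre), i.e. 1e-18.}
#' }
#' @export
endofuse_constants <- list(
  kB           = 1.380649e-23,
  R_gas        = 8.31446261815324,
  J_per_Pa_um3 = 1e-18
)

#' Thermal energy in joule
#'
#' @param T_K absolute temperature in kelvin.
#' @return kBT in joule.
#' @export
kBT_joule <- function(T_K = 298) {
  stopifnot(is.numeric(T_K), T_K > 0)
  endofuse_constants$kB * T_K
}

## 1 Pa * um^3 expressed in kBT at temperature T_K
pa_um3_in_kBT <- function(T_K = 298) {
  endofuse_constants$J_per_Pa_um3 / kBT_joule(T_K)
}

#' Physical parameter set for the membrane model
#'
#' Bundles the membrane bending modulus, the minimum bending radius used to
#' regularise the neck region, the osmotic pressure difference across the
#' membrane and the temperature defining the kBT energy scale.
#'
#' @param kappa bending modulus in kBT (default 10).
#' @param R0_nm minimum bending radius in nanometres (default 100).
#' @param delta_p_Pa osmotic pressure difference in pascal (inside minus
#'   outside; default 10, the midpoint decade of the 2.5--25 Pa range
#'   estimated for late-endosome ion differences).
#' @param T_K absolute temperature in kelvin (default 298).
#' @return An object of class \code{physical_params}.
#' @export
physical_params <- function(kappa = 10, R0_nm = 100, delta_p_Pa = 10, T_K = 298) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0)
    stop("'kappa' must be a single positive number (kBT)")
  if (!is.numeric(R0_nm) || length(R0_nm) != 1 || R0_nm <= 0)
    stop("'R0_nm' must be a single positive number (nm)")
  if (!is.numeric(delta_p_Pa) || length(delta_p_Pa) != 1 || delta_p_Pa < 0)
    stop("'delta_p_Pa' must be a single non-negative number (Pa)")
  if (!is.numeric(T_K) || length(T_K) != 1 || T_K <= 0)
    stop("'T_K' must be a single positive number (K)")
  structure(list(kappa = kappa, R0_nm = R0_nm, R0_um = R0_nm / 1000,
                 delta_p_Pa = delta_p_Pa, T_K = T_K),
            class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Membrane physical parameters\n")
  cat(sprintf("  bending modulus kappa : %g kBT\n", x$kappa))
  cat(sprintf("  minimum bending radius: %g nm\n", x$R0_nm))
  cat(sprintf("  osmotic pressure diff : %g Pa\n", x$delta_p_Pa))
  cat(sprintf("  temperature           : %g K\n", x$T_K))
  invisible(x)
}

#' Osmotic pressure range used for late endosomes
#'
#' The pressure range adopted for late-endosome-sized vesicles, derived from
#' an assumed 1--10 mM total ion difference between the endosomal lumen and
#' the cytoplasm.  Note that an ideal van't Hoff conversion of the same
#' concentration range gives pressures about three orders of magnitude
#' larger (see \code{\link{vant_hoff_pressure}}); both are exposed and never
#' silently reconciled.
#'
#' @return Numeric vector \code{c(2.5, 25)} in Pa.
#' @export
default_osmotic_range <- function() c(2.5, 25)
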