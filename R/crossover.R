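## Closed-form estimates around the bending-versus-osmotic energy balance:
## the sphere volume at a given projected area, the crossover vesicle size
## at which the osmotic energy overtakes a reference bending energy, and the
## van't Hoff osmotic-pressure utility.

#' Sphere volume from projected area
#'
#' Microscopy reports vesicle size as the projected (cross-sectional) area
#' \code{A_p}; the corresponding sphere has radius \code{R = sqrt(A_p/pi)}
#' and volume \code{V = (4 A_p / 3) sqrt(A_p / pi)}.
#'
#' @param A_p projected area in um^2 (vectorised).
#' @return Volume in um^3.
#' @export
sphere_volume_from_projected_area <- function(A_p) {
  if (!is.numeric(A_p) || any(!is.finite(A_p)) || any(A_p <= 0))
    stop("'A_p' must be positive (um^2)")
  (4 * A_p / 3) * sqrt(A_p / pi)
}

#' Crossover vesicle size between fusion modes
#'
#' Solves \code{delta_p * V(A*) = b} for the projected area \code{A*} at
#' which the osmotic energy of a spherical vesicle equals a reference
#' bending energy \code{b}: below \code{A*} bending dominates (explosive
#' fusion), above it the osmotic term dominates (bridge fusion).  In closed
#' form \code{A* = (3 b sqrt(pi) / (4 delta_p))^(2/3)}.
#'
#' With the typical bending energy \code{b = 2e-18} J and pressures 2.5--25
#' Pa this gives the switching range of about 1.0 down to 0.22 um^2.
#'
#' @param b reference bending energy in joule.
#' @param delta_p_Pa osmotic pressure difference in pascal.
#' @return A list of class \code{crossover_result} with \code{b_J},
#'   \code{delta_p_Pa}, \code{A_star_um2} and \code{V_star_um3}.
#' @export
crossover_area <- function(b = 2e-18, delta_p_Pa) {
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b <= 0)
    stop("'b' must be a single positive energy in joule")
  if (!is.numeric(delta_p_Pa) || length(delta_p_Pa) != 1 ||
      !is.finite(delta_p_Pa) || delta_p_Pa <= 0)
    stop("'delta_p_Pa' must be a single positive pressure in pascal")
  V_star_m3 <- b / delta_p_Pa                    # m^3
  A_star_m2 <- (3 * sqrt(pi) * V_star_m3 / 4)^(2 / 3)
  structure(list(b_J = b, delta_p_Pa = delta_p_Pa,
                 A_star_um2 = A_star_m2 * 1e12,
                 V_star_um3 = V_star_m3 * 1e18),
            class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  cat("Fusion-mode crossover size\n")
  cat(sprintf("  b = %g J, delta_p = %g Pa\n", x$b_J, x$delta_p_Pa))
  cat(sprintf("  A* = %.4g um^2 (V* = %.4g um^3)\n", x$A_star_um2, x$V_star_um3))
  invisible(x)
}

#' Van't Hoff osmotic pressure of a dilute solute difference
#'
#' Ideal dilute-solution law \code{delta_p = delta_C * R_gas * T}.  Note
#' that for the 1--10 mM ion differences considered for endosomes this gives
#' pressures of order kPa, roughly a thousandfold larger than the 2.5--25 Pa
#' working range adopted for the landscapes
#' (\code{\link{default_osmotic_range}}); the package exposes both and never
#' silently reconciles them, treating the working range as an effective
#' given input.
#'
#' @param delta_C_mM solute concentration difference in mM (= mol/m^3).
#' @param T_K absolute temperature in kelvin.
#' @return Pressure in pascal.
#' @export
vant_hoff_pressure <- function(delta_C_mM, T_K = 298) {
  if (!is.numeric(delta_C_mM) || any(delta_C_mM < 0))
    stop("'delta_C_mM' must be non-negative")
  if (!is.numeric(T_K) || any(T_K <= 0)) stop("'T_K' must be positive")
  delta_C_mM * endofuse_constants$R_gas * T_K
}
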