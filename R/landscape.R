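## Free-energy landscapes over the (w, a) shape space.
##
## Three landscape modes are supported, matching the two asymptotic regimes
## of the model plus the full expression:
##   small: F = b                (bending energy; scale free, no R0 floor)
##   large: F = B_neck - dp * V  (neck energy of the R0-floored family)
##   full : F = b - dp * V       (same shapes as mode small)
## Shapes are always the constrained minimum-bending-energy members of the
## cap+collar family; the osmotic term is evaluated on that shape afterwards,
## so mode-large F is exactly linear in dp with slope -V.

#' Default neck-width grid
#'
#' 31 points over [0, 0.6] with doubled density over the corridor
#' w = 0--0.15 where mode selection happens.
#' @return Ascending numeric vector.
#' @export
default_w_grid <- function() {
  sort(unique(c(seq(0, 0.6, by = 0.02), seq(0.01, 0.15, by = 0.02))))
}

#' Default area-fraction grid
#'
#' 25 points over [0.02, 0.5] with doubled density over a = 0.25--0.35
#' (the region around the canonical initial condition a = 0.3).
#' @return Ascending numeric vector.
#' @export
default_a_grid <- function() {
  sort(unique(c(seq(0.02, 0.5, by = 0.02), seq(0.25, 0.35, by = 0.02))))
}

#' Characteristic neck bending-energy scale
#'
#' \code{Gamma = 2 pi kappa sqrt(A_p / pi) / R0}, with kappa in kBT, used
#' only as a reported diagnostic to contextualise fluctuation magnitudes
#' (never to rescale free energies).
#'
#' @param A_p projected area, um^2.
#' @param phys a \code{\link{physical_params}}.
#' @return Energy scale in kBT.
#' @export
neck_energy_scale <- function(A_p, phys = physical_params()) {
  2 * pi * phys$kappa * sqrt(A_p / pi) / phys$R0_um
}

#' Compute a free-energy landscape on a (w, a) grid
#'
#' Evaluates the free energy of the constrained minimum-bending-energy
#' two-lobed shape at every grid node.  Infeasible nodes (neck wider than
#' the smaller lobe can accommodate, \code{w^2 >= 2 a}) are masked, never
#' silently interpolated; for interpolation stencils they are filled with
#' the nearest feasible value in the same a-column.
#'
#' @param w_grid ascending neck-width grid in [0, 1].
#' @param a_grid ascending area-fraction grid in (0, 0.5].
#' @param A_p projected area in um^2.
#' @param phys a \code{\link{physical_params}} (supplies kappa, R0 and the
#'   osmotic pressure difference).
#' @param mode one of \code{"small"} (bending only, scale free),
#'   \code{"large"} (neck bending minus osmotic energy, R0-floored family)
#'   or \code{"full"} (total bending minus osmotic energy).
#' @return An object of class \code{fusion_landscape} with the axis vectors,
#'   the free-energy matrix \code{F_kBT} (rows = w, cols = a), the underlying
#'   energy and volume matrices, the feasibility mask and the diagnostic
#'   \code{Gamma}.
#' @export
compute_landscape <- function(w_grid = default_w_grid(),
                              a_grid = default_a_grid(),
                              A_p = 10,
                              phys = physical_params(),
                              mode = c("large", "small", "full")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(w_grid), is.numeric(a_grid), length(w_grid) >= 4,
            length(a_grid) >= 4)
  if (any(diff(w_grid) <= 0) || any(diff(a_grid) <= 0))
    stop("grids must be strictly ascending")
  if (min(w_grid) < 0 || max(w_grid) > 1 || min(a_grid) <= 0 || max(a_grid) > 0.5)
    stop("grids must lie within [0,1] x (0, 0.5]")
  if (!is.numeric(A_p) || A_p <= 0) stop("'A_p' must be positive (um^2)")

  nw <- length(w_grid); na <- length(a_grid)
  mask <- outer(w_grid, a_grid, feasible_wa)
  if (!any(mask)) stop("empty feasible region for the given grids")

  Req <- sqrt(A_p / pi)
  kappa <- phys$kappa
  r0u <- phys$R0_um / Req
  floored <- mode == "large"
  E <- matrix(NA_real_, nw, na)      # bending (small/full) or neck (large), kBT
  V <- matrix(NA_real_, nw, na)      # enclosed volume, um^3
  conv <- mask

  for (j in seq_len(na)) {
    a <- a_grid[j]
    for (i in seq_len(nw)) {
      if (!mask[i, j]) next
      w <- w_grid[i]
      if (w == 0 && !floored) {
        E[i, j] <- 16 * pi * kappa
        V[i, j] <- 4 * pi / 3 * (a^1.5 + (1 - a)^1.5) * Req^3
        next
      }
      ## in the floored (large-vesicle) family the whole region w R_eq < R0
      ## shares the limit geometry at waist radius R0, including w = 0
      rn <- if (floored) max(w, r0u) else w
      fe <- .minimise_family(rn, a,
                             rho_lo = if (floored) max(r0u, 1e-4) else 1e-4,
                             allow_catenoid = !floored)
      if (is.null(fe)) { conv[i, j] <- FALSE; next }
      E[i, j] <- kappa * (if (floored) fe$E_neck_unit else fe$E_bend_unit)
      V[i, j] <- fe$V * Req^3
    }
  }

  bad <- mask & !conv
  if (sum(bad) > 0.1 * sum(mask)) {
    idx <- which(bad, arr.ind = TRUE)
    stop(sprintf("landscape error: %d of %d feasible cells failed to converge (first: w=%g, a=%g)",
                 sum(bad), sum(mask), w_grid[idx[1, 1]], a_grid[idx[1, 2]]))
  }

  dp_kBT <- phys$delta_p_Pa * pa_um3_in_kBT(phys$T_K)
  Fmat <- switch(mode,
                 small = E,
                 large = E - dp_kBT * V,
                 full  = E - dp_kBT * V)
  L <- structure(list(
    w = w_grid, a = a_grid, F_kBT = Fmat, E_kBT = E, V_um3 = V,
    mask = mask & conv, mode = mode, phys = phys, A_p = A_p,
    Gamma = neck_energy_scale(A_p, phys)),
    class = "fusion_landscape")
  L$F_fill <- .fill_masked(L$F_kBT, L$mask)
  L
}

## Rebuild a landscape at a different osmotic pressure without redoing the
## geometry (F is linear in dp with slope -V).
.with_delta_p <- function(L, delta_p_Pa) {
  phys <- L$phys; phys$delta_p_Pa <- delta_p_Pa
  dp_kBT <- delta_p_Pa * pa_um3_in_kBT(phys$T_K)
  L$phys <- phys
  L$F_kBT <- if (L$mode == "small") L$E_kBT else L$E_kBT - dp_kBT * L$V_um3
  L$F_fill <- .fill_masked(L$F_kBT, L$mask)
  L
}

## Constant fill of masked/unconverged nodes from the nearest feasible node
## in the same column (used only to complete interpolation stencils).
.fill_masked <- function(Fmat, mask) {
  out <- Fmat
  for (j in seq_len(ncol(out))) {
    col <- out[, j]
    ok <- which(mask[, j] & is.finite(col))
    if (!length(ok)) { out[, j] <- 0; next }
    bad <- which(!(mask[, j] & is.finite(col)))
    if (length(bad)) {
      nearest <- vapply(bad, function(i) ok[which.min(abs(ok - i))], integer(1))
      out[bad, j] <- col[nearest]
    }
  }
  out
}

#' @export
print.fusion_landscape <- function(x, ...) {
  cat(sprintf("Free-energy landscape (mode = %s)\n", x$mode))
  cat(sprintf("  grid: %d x %d (w in [%g, %g], a in [%g, %g])\n",
              length(x$w), length(x$a), min(x$w), max(x$w), min(x$a), max(x$a)))
  cat(sprintf("  A_p = %g um^2, delta_p = %g Pa, kappa = %g kBT\n",
              x$A_p, x$phys$delta_p_Pa, x$phys$kappa))
  cat(sprintf("  F range (feasible): [%.4g, %.4g] kBT; Gamma = %.4g kBT\n",
              min(x$F_kBT[x$mask], na.rm = TRUE),
              max(x$F_kBT[x$mask], na.rm = TRUE), x$Gamma))
  cat(sprintf("  %d of %d nodes feasible\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Contour plot of a landscape
#'
#' @param x a \code{fusion_landscape}.
#' @param nlevels number of contour levels.
#' @param ... passed to \code{\link[graphics]{contour}}.
#' @export
plot.fusion_landscape <- function(x, nlevels = 20, ...) {
  graphics::contour(x$w, x$a, x$F_fill, nlevels = nlevels,
                    xlab = "neck width w", ylab = "area fraction a", ...)
  graphics::title(main = sprintf("F (%s mode), A_p = %g um^2", x$mode, x$A_p))
  invisible(x)
}

## ---- local cubic (4-point Lagrange) interpolation --------------------------

## Stencil start index for query x in grid g (interior cells use the two
## nodes on each side; edge cells a one-sided stencil).
.stencil_start <- function(x, g) {
  n <- length(g)
  i <- findInterval(x, g, all.inside = TRUE)
  max(1L, min(i - 1L, n - 3L))
}

## Lagrange cubic basis (and derivative) at x for 4 nodes xs.
.lagrange4 <- function(x, xs, deriv = FALSE) {
  b <- numeric(4); db <- numeric(4)
  for (k in 1:4) {
    others <- xs[-k]
    denom <- prod(xs[k] - others)
    b[k] <- prod(x - others) / denom
    if (deriv) {
      db[k] <- sum(vapply(1:3, function(m) prod((x - others)[-m]), numeric(1))) / denom
    }
  }
  if (deriv) list(b = b, db = db) else list(b = b)
}

.interp_point <- function(L, w, a, deriv = FALSE) {
  iw <- .stencil_start(w, L$w); ia <- .stencil_start(a, L$a)
  xs <- L$w[iw:(iw + 3)]; ys <- L$a[ia:(ia + 3)]
  Bw <- .lagrange4(w, xs, deriv); Ba <- .lagrange4(a, ys, deriv)
  sub <- L$F_fill[iw:(iw + 3), ia:(ia + 3)]
  val <- drop(crossprod(Bw$b, sub %*% Ba$b))
  if (!deriv) return(list(F = val))
  list(F = val,
       dw = drop(crossprod(Bw$db, sub %*% Ba$b)),
       da = drop(crossprod(Bw$b, sub %*% Ba$db)))
}

.check_in_hull <- function(L, point) {
  w <- point[1]; a <- point[2]
  if (w < min(L$w) - 1e-12 || w > max(L$w) + 1e-12 ||
      a < min(L$a) - 1e-12 || a > max(L$a) + 1e-12)
    stop(sprintf("point (w=%g, a=%g) outside the landscape grid hull", w, a))
  if (!feasible_wa(w, min(a, 0.5)))
    stop(sprintf("point (w=%g, a=%g) lies in the infeasible region", w, a))
  invisible(TRUE)
}

#' Interpolated free energy at a point
#'
#' Local bicubic (tensor-product 4-point Lagrange) interpolation; exact at
#' grid nodes, smooth within cells.
#'
#' @param L a \code{fusion_landscape}.
#' @param point numeric \code{c(w, a)}.
#' @return Free energy in kBT.
#' @export
landscape_value <- function(L, point) {
  .check_in_hull(L, point)
  .interp_point(L, point[1], point[2])$F
}

#' Gradient of the interpolated landscape
#'
#' @param L a \code{fusion_landscape}.
#' @param point numeric \code{c(w, a)} inside the grid hull and feasible.
#' @return Numeric \code{c(dF_dw, dF_da)} in kBT per unit shape coordinate.
#' @export
landscape_gradient <- function(L, point) {
  .check_in_hull(L, point)
  g <- .interp_point(L, point[1], point[2], deriv = TRUE)
  c(dF_dw = g$dw, dF_da = g$da)
}

#' Export a landscape to JSON
#'
#' Writes axis vectors, the free-energy matrix, the feasibility mask and a
#' parameter block as plain-text JSON (readable back with
#' \code{\link{read_landscape}}).
#'
#' @param L a \code{fusion_landscape}.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_landscape <- function(L, file) {
  x <- list(w = L$w, a = L$a, F_kBT = L$F_kBT, E_kBT = L$E_kBT,
            V_um3 = L$V_um3, mask = L$mask, mode = L$mode, A_p = L$A_p,
            Gamma = L$Gamma,
            phys = list(kappa = L$phys$kappa, R0_nm = L$phys$R0_nm,
                        delta_p_Pa = L$phys$delta_p_Pa, T_K = L$phys$T_K))
  jsonlite::write_json(x, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Read a landscape written by \code{\link{write_landscape}}
#'
#' @param file path to the JSON file.
#' @return A \code{fusion_landscape}.
#' @export
read_landscape <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  phys <- physical_params(kappa = x$phys$kappa, R0_nm = x$phys$R0_nm,
                          delta_p_Pa = x$phys$delta_p_Pa, T_K = x$phys$T_K)
  L <- structure(list(
    w = x$w, a = x$a, F_kBT = as.matrix(x$F_kBT), E_kBT = as.matrix(x$E_kBT),
    V_um3 = as.matrix(x$V_um3), mask = as.matrix(x$mask), mode = x$mode,
    phys = phys, A_p = x$A_p, Gamma = x$Gamma),
    class = "fusion_landscape")
  L$F_fill <- .fill_masked(L$F_kBT, L$mask)
  L
}
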