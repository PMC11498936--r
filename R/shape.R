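## Axisymmetric two-lobed vesicle shapes: two spherical caps joined by a
## toroidal collar with tangent matching.  All internal geometry is done in
## dimensionless units with R_eq = sqrt(S_total / 4 pi) = 1, so the total
## membrane area is 4 pi; physical quantities are recovered by scaling with
## R_eq (lengths), R_eq^2 (areas) and R_eq^3 (volumes).  Bending energies are
## scale free and carry a factor kappa.

#' Shape parameters of a two-lobed vesicle
#'
#' @param w dimensionless neck width: waist radius divided by R_eq, the
#'   radius of the sphere whose surface equals the total membrane area;
#'   in [0, 1].
#' @param a area fraction of the smaller lobe, in (0, 0.5].
#' @param A_p projected area of the fused system's equivalent sphere in
#'   square micrometres; the total membrane area is fixed at 4 * A_p.
#' @return An object of class \code{shape_params}.
#' @export
shape_params <- function(w, a, A_p) {
  if (!is.numeric(w) || length(w) != 1 || is.na(w) || w < 0 || w > 1)
    stop("'w' must be a single number in [0, 1]")
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a <= 0 || a > 0.5)
    stop("'a' must be a single number in (0, 0.5]")
  if (!is.numeric(A_p) || length(A_p) != 1 || is.na(A_p) || A_p <= 0)
    stop("'A_p' must be a single positive number (um^2)")
  if (!feasible_wa(w, a))
    stop(sprintf(paste0("infeasible (w, a) = (%g, %g): the neck radius may not",
                        " exceed the smaller lobe's cap radius (requires w < sqrt(2 a))"),
                 w, a))
  structure(list(w = w, a = a, A_p = A_p), class = "shape_params")
}

#' Geometric feasibility of a (w, a) combination
#'
#' A neck of dimensionless radius \code{w} can only connect to a lobe
#' carrying an area fraction \code{a} of the total membrane if the lobe's
#' spherical cap can close around the neck: the cap area (at least a
#' hemisphere of rim radius w R_eq) must fit into the side's area budget,
#' giving the bound \code{w^2 < 2 a}.
#'
#' @param w neck width(s), dimensionless.
#' @param a smaller-lobe area fraction(s), in (0, 0.5].
#' @return Logical vector.
#' @export
feasible_wa <- function(w, a) {
  w^2 < 2 * a * (1 - 1e-9) & w >= 0 & a > 0 & a <= 0.5
}

## ---- closed-form pieces (dimensionless, R_eq = 1, total area 4 pi) --------

## Side geometry for one lobe: given waist radius rn, collar tube radius rho
## and cap sphere radius R, return opening angle phi and the side's membrane
## area (cap plus its collar half).
.side_area <- function(R, rn, rho) {
  rc  <- rn + rho
  cph <- rc / (rho + R)          # cos(phi), <= 1 because R >= rn
  cph <- min(cph, 1)
  phi <- acos(cph)
  area_cap <- 2 * pi * R^2 * (1 + sin(phi))
  area_col <- 2 * pi * rho * (rc * phi - rho * sin(phi))
  list(phi = phi, area = area_cap + area_col,
       area_cap = area_cap, area_col = area_col)
}

## Solve the cap radius R for one side so that its area equals frac * 4 pi.
## Returns NULL if infeasible.
.solve_side <- function(frac, rn, rho) {
  target <- 4 * pi * frac
  if (2 * pi * rn^2 >= target) return(NULL)    # cap cannot close around neck
  lo <- rn * (1 + 1e-12)
  hi <- sqrt(target / (2 * pi))
  g  <- function(R) .side_area(R, rn, rho)$area - target
  glo <- g(lo); ghi <- g(hi)
  if (is.na(glo) || is.na(ghi) || glo > 0) return(NULL)
  if (ghi < 0) {                               # collar consumed no area yet: widen
    hi2 <- hi * 2
    if (g(hi2) < 0) return(NULL)
    hi <- hi2
  }
  root <- tryCatch(
    stats::uniroot(g, c(lo, hi), tol = 1e-12)$root,
    error = function(e) NULL)
  root
}

## Collar bending energy integral (closed form), in units of kappa:
##   E_col / kappa = pi * rho * int_{-phi2}^{phi1} (cos f / r - 1/rho)^2 r df
## with r = rc - rho cos f.  Uses the partial-fraction decomposition
##   cos^2 f / (A - B cos f) = -(cos f)/B - A/B^2 + (A^2/B^2)/(A - B cos f).
.collar_bend <- function(rn, rho, phi1, phi2) {
  A <- rn + rho; B <- rho
  s1 <- sin(phi1) + sin(phi2)
  ph <- phi1 + phi2
  ## J = int df / (A - B cos f), A > B since rn > 0
  Jfun <- function(phi) {
    k <- sqrt((A + B) / (A - B))
    2 / sqrt(A^2 - B^2) * atan(k * tan(phi / 2))
  }
  J <- Jfun(phi1) + Jfun(phi2)
  I_cos2_over_r <- -s1 / B - A / B^2 * ph + A^2 / B^2 * J
  I_cos  <- s1
  I_r    <- A * ph - B * s1
  pi * rho * (I_cos2_over_r - 2 * I_cos / rho + I_r / rho^2)
}

## Collar volume contribution (closed form): pi * int r^2 dz over the collar.
.collar_vol <- function(rn, rho, phi1, phi2) {
  rc <- rn + rho
  Fv <- function(phi) {
    rc^2 * sin(phi) - 2 * rc * rho * (phi / 2 + sin(2 * phi) / 4) +
      rho^2 * (sin(phi) - sin(phi)^3 / 3)
  }
  pi * rho * (Fv(phi1) + Fv(phi2))
}

## Cap volume contribution: pi * R^3 * int sin^3 t dt over the cap's polar range.
.cap_vol <- function(R, th_lo, th_hi) {
  G <- function(th) -cos(th) + cos(th)^3 / 3
  pi * R^3 * (G(th_hi) - G(th_lo))
}

## ---- catenoid collar branch -----------------------------------------------
## A catenoid patch r = c cosh(t), z = c t has zero mean curvature, hence a
## zero-cost collar; its waist radius equals the catenoid parameter c, so the
## neck radius pins c = rn and there is no free collar variable.  Tangency to
## a cap sphere of radius R requires R = c cosh^2(t_j) at the junction, which
## gives cos(phi) = 1/cosh(t_j) in the cap-angle convention used above.

.side_area_cat <- function(t, rn) {
  R <- rn * cosh(t)^2
  area_cap <- 2 * pi * R^2 * (1 + tanh(t))
  area_col <- pi * rn^2 * (t + sinh(t) * cosh(t))
  list(R = R, area = area_cap + area_col, area_col = area_col)
}

.solve_side_cat <- function(frac, rn) {
  target <- 4 * pi * frac
  if (2 * pi * rn^2 >= target) return(NULL)
  g <- function(t) .side_area_cat(t, rn)$area - target
  hi <- 1
  while (g(hi) < 0 && hi < 50) hi <- hi + 1
  if (g(hi) < 0) return(NULL)
  tryCatch(stats::uniroot(g, c(0, hi), tol = 1e-12)$root,
           error = function(e) NULL)
}

.family_eval_catenoid <- function(rn, a) {
  t1 <- .solve_side_cat(a, rn)
  if (is.null(t1)) return(NULL)
  t2 <- .solve_side_cat(1 - a, rn)
  if (is.null(t2)) return(NULL)
  R1 <- rn * cosh(t1)^2; R2 <- rn * cosh(t2)^2
  E_cap <- 4 * pi * (1 + tanh(t1)) + 4 * pi * (1 + tanh(t2))
  Gv <- function(t) t / 2 + sinh(2 * t) / 4
  V <- .cap_vol(R2, 0, pi / 2 + asin(tanh(t2))) +
       .cap_vol(R1, pi / 2 - asin(tanh(t1)), pi) +
       pi * rn^3 * (Gv(t1) + Gv(t2))
  area <- .side_area_cat(t1, rn)$area + .side_area_cat(t2, rn)$area
  list(R1 = R1, R2 = R2, t1 = t1, t2 = t2, rn = rn,
       phi1 = asin(tanh(t1)), phi2 = asin(tanh(t2)),
       E_bend_unit = E_cap, E_neck_unit = 0, V = V, area = area,
       branch = "catenoid")
}

## Evaluate the cap+collar family at fixed (rn, a, rho).  Returns NULL when
## the side constraints cannot be satisfied.  All values dimensionless
## (energies in units of kappa).
.family_eval <- function(rn, a, rho) {
  R1 <- .solve_side(a, rn, rho)          # smaller lobe, top
  if (is.null(R1)) return(NULL)
  R2 <- .solve_side(1 - a, rn, rho)      # larger lobe, bottom
  if (is.null(R2)) return(NULL)
  g1 <- .side_area(R1, rn, rho)
  g2 <- .side_area(R2, rn, rho)
  phi1 <- g1$phi; phi2 <- g2$phi
  E_cap <- 4 * pi * (1 + sin(phi1)) + 4 * pi * (1 + sin(phi2))
  E_col <- .collar_bend(rn, rho, phi1, phi2)
  V <- .cap_vol(R2, 0, pi / 2 + phi2) +
       .cap_vol(R1, pi / 2 - phi1, pi) +
       .collar_vol(rn, rho, phi1, phi2)
  list(R1 = R1, R2 = R2, phi1 = phi1, phi2 = phi2, rho = rho, rn = rn,
       E_bend_unit = E_cap + E_col, E_neck_unit = E_col, V = V,
       area = g1$area + g2$area)
}

## Minimise the (dimensionless) objective over the collar tube radius rho.
## objective: bending energy, optionally minus dp_unit * V (dp_unit is the
## osmotic pressure in units of kappa per unit volume at R_eq = 1).
.minimise_family <- function(rn, a, rho_lo, rho_hi = 1.5, dp_unit = 0,
                             allow_catenoid = FALSE) {
  obj <- function(rho) {
    fe <- .family_eval(rn, a, rho)
    if (is.null(fe)) return(Inf)
    fe$E_bend_unit - dp_unit * fe$V
  }
  grid <- exp(seq(log(rho_lo), log(rho_hi), length.out = 25))
  vals <- vapply(grid, obj, numeric(1))
  best <- NULL
  if (any(is.finite(vals))) {
    k <- which.min(vals)
    lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
    op <- stats::optimize(obj, c(lo, hi), tol = 1e-9)
    if (is.finite(op$objective)) {
      best <- .family_eval(rn, a, op$minimum)
      best$branch <- "torus"
    }
  }
  if (allow_catenoid) {
    fc <- .family_eval_catenoid(rn, a)
    if (!is.null(fc)) {
      score <- function(fe) fe$E_bend_unit - dp_unit * fe$V
      if (is.null(best) || score(fc) < score(best)) best <- fc
    }
  }
  if (is.null(best)) return(NULL)
  best$converged <- TRUE
  best
}

## ---- profile construction --------------------------------------------------

## Meridian profile of the cap+collar family (dimensionless), as a data frame
## with columns r, z, component.  n controls the total resolution.
.family_profile <- function(fe, n = 400) {
  cat_branch <- identical(fe$branch, "catenoid")
  ## arc lengths of the three segments
  L2 <- fe$R2 * (pi / 2 + fe$phi2)
  Lc <- if (cat_branch) {
    fe$rn * (sinh(fe$t1) + sinh(fe$t2))      # catenoid arclength = c sinh(t)
  } else fe$rho * (fe$phi1 + fe$phi2)
  L1 <- fe$R1 * (pi / 2 + fe$phi1)
  Ltot <- L1 + L2 + Lc
  n2 <- max(8, round(n * L2 / Ltot))
  nc <- max(8, round(n * Lc / Ltot))
  n1 <- max(8, n - n2 - nc)
  if (cat_branch) {
    z2 <- -(fe$rn * fe$t2 + fe$R2 * tanh(fe$t2))
    z1 <-   fe$rn * fe$t1 + fe$R1 * tanh(fe$t1)
    t2s <- seq(0, pi / 2 + fe$phi2, length.out = n2)
    seg2 <- cbind(r = fe$R2 * sin(t2s), z = z2 - fe$R2 * cos(t2s))
    tc <- seq(-fe$t2, fe$t1, length.out = nc)
    segc <- cbind(r = fe$rn * cosh(tc), z = fe$rn * tc)
    t1s <- seq(pi / 2 - fe$phi1, pi, length.out = n1)
    seg1 <- cbind(r = fe$R1 * sin(t1s), z = z1 - fe$R1 * cos(t1s))
  } else {
    rc <- fe$rn + fe$rho
    z2 <- -(fe$rho + fe$R2) * sin(fe$phi2)
    z1 <-  (fe$rho + fe$R1) * sin(fe$phi1)
    ## bottom cap: theta in [0, pi/2 + phi2], point = c2 + R2 (sin t, -cos t)
    t2s <- seq(0, pi / 2 + fe$phi2, length.out = n2)
    seg2 <- cbind(r = fe$R2 * sin(t2s), z = z2 - fe$R2 * cos(t2s))
    ## collar: f in [-phi2, phi1], point = (rc - rho cos f, rho sin f)
    fc <- seq(-fe$phi2, fe$phi1, length.out = nc)
    segc <- cbind(r = rc - fe$rho * cos(fc), z = fe$rho * sin(fc))
    ## top cap: theta in [pi/2 - phi1, pi], point = c1 + R1 (sin t, -cos t)
    t1s <- seq(pi / 2 - fe$phi1, pi, length.out = n1)
    seg1 <- cbind(r = fe$R1 * sin(t1s), z = z1 - fe$R1 * cos(t1s))
  }
  prof <- rbind(seg2[-n2, , drop = FALSE], segc[-nc, , drop = FALSE], seg1)
  data.frame(r = prof[, "r"], z = prof[, "z"], component = 1L)
}

## Meridian of a sphere of radius R centred at (0, z0).
.sphere_profile <- function(R, z0 = 0, n = 400, component = 1L) {
  t <- seq(0, pi, length.out = n)
  data.frame(r = R * sin(t), z = z0 - R * cos(t), component = as.integer(component))
}

.finish_profile <- function(profile, scale = 1) {
  profile$r <- profile$r * scale
  profile$z <- profile$z * scale
  s <- numeric(nrow(profile))
  for (cp in unique(profile$component)) {
    i <- which(profile$component == cp)
    ds <- sqrt(diff(profile$r[i])^2 + diff(profile$z[i])^2)
    s[i] <- cumsum(c(0, ds))
  }
  data.frame(s_um = s, r_um = profile$r, z_um = profile$z,
             component = profile$component)
}

## ---- user-facing constructors ---------------------------------------------

#' Build a constrained minimum-bending-energy two-lobed shape
#'
#' Constructs the minimum-energy member of the analytic shape family (two
#' spherical caps joined tangentially by a toroidal collar) under the
#' constraints of fixed total membrane area \code{4 A_p}, fixed neck waist
#' radius \code{w * R_eq} and fixed area split \code{a}.  The collar's
#' meridional (tube) radius is the free variable of the minimisation.
#'
#' At \code{w = 0} the family degenerates to two tangent spheres with the
#' prescribed area split; the neck energy is then defined by the limit
#' convention of a waist radius equal to the minimum bending radius
#' \code{R0} (see \code{\link{neck_bending_energy}}).
#'
#' @param params a \code{\link{shape_params}} object (or list with
#'   \code{w}, \code{a}, \code{A_p}).
#' @param phys a \code{\link{physical_params}} object.
#' @param floor_r0 logical; if \code{TRUE} the collar tube radius is bounded
#'   below by \code{R0} and the waist radius used for the collar is floored
#'   at \code{R0}.  This regularises the neck energy at small \code{w} (used
#'   by the large-vesicle landscape); with \code{FALSE} the minimisation is
#'   scale free.
#' @param include_osmotic logical; if \code{TRUE} the minimisation objective
#'   is \code{E_bend - delta_p V} instead of the bending energy alone.
#' @param n_profile number of meridian samples in the stored profile.
#' @return An object of class \code{membrane_shape} with elements
#'   \code{params}, \code{phys}, \code{profile} (columns \code{s_um},
#'   \code{r_um}, \code{z_um}, \code{component}), \code{S_total} (um^2),
#'   \code{V} (um^3), \code{E_bend} and \code{E_neck} (kBT), the collar
#'   geometry, and \code{converged}.
#' @export
build_shape <- function(params, phys = physical_params(), floor_r0 = TRUE,
                        include_osmotic = FALSE, n_profile = 400) {
  if (!inherits(params, "shape_params"))
    params <- shape_params(params$w, params$a, params$A_p)
  w <- params$w; a <- params$a; A_p <- params$A_p
  Req <- sqrt(A_p / pi)                # lengths scale, um
  S_total <- 4 * A_p
  kappa <- phys$kappa
  r0_unit <- phys$R0_um / Req

  if (w == 0) {
    ## two tangent spheres, closed form
    R1 <- sqrt(a); R2 <- sqrt(1 - a)
    V_unit <- 4 * pi / 3 * (a^1.5 + (1 - a)^1.5)
    prof <- rbind(.sphere_profile(R2, z0 = 0, n = n_profile %/% 2, component = 1L),
                  .sphere_profile(R1, z0 = R2 + R1 + 2 * R1 / n_profile,
                                  n = n_profile %/% 2, component = 2L))
    ## neck energy at w = 0: limit convention, waist radius = R0
    neck <- .minimise_family(r0_unit, a, rho_lo = max(r0_unit, 1e-4))
    out <- structure(list(
      params = params, phys = phys,
      profile = .finish_profile(prof, scale = Req),
      S_total = S_total, V = V_unit * Req^3,
      E_bend = 16 * pi * kappa,
      E_neck = if (is.null(neck)) NA_real_ else kappa * neck$E_neck_unit,
      R_lobes_um = c(R1, R2) * Req, rho_um = NA_real_,
      converged = TRUE, floor_r0 = floor_r0),
      class = "membrane_shape")
    return(out)
  }

  rn <- if (floor_r0) max(w, r0_unit) else w
  rho_lo <- if (floor_r0) max(r0_unit, 1e-4) else 1e-4
  dp_unit <- if (include_osmotic)
    phys$delta_p_Pa * pa_um3_in_kBT(phys$T_K) * Req^3 / kappa else 0
  fe <- .minimise_family(rn, a, rho_lo = rho_lo, dp_unit = dp_unit,
                         allow_catenoid = !floor_r0)
  if (is.null(fe)) {
    if (!feasible_wa(w, a))
      stop(sprintf("infeasible (w, a) = (%g, %g): requires w < sqrt(2 a)", w, a))
    warning(sprintf("shape minimisation did not converge at (w, a) = (%g, %g)", w, a))
    return(structure(list(params = params, phys = phys, profile = NULL,
                          S_total = S_total, V = NA_real_, E_bend = NA_real_,
                          E_neck = NA_real_, converged = FALSE,
                          floor_r0 = floor_r0),
                     class = "membrane_shape"))
  }
  prof <- .family_profile(fe, n = n_profile)
  structure(list(
    params = params, phys = phys,
    profile = .finish_profile(prof, scale = Req),
    S_total = fe$area * Req^2, V = fe$V * Req^3,
    E_bend = kappa * fe$E_bend_unit,
    E_neck = kappa * fe$E_neck_unit,
    R_lobes_um = c(fe$R1, fe$R2) * Req,
    rho_um = if (identical(fe$branch, "torus")) fe$rho * Req else NA_real_,
    phi = c(fe$phi1, fe$phi2), collar = fe$branch,
    converged = TRUE, floor_r0 = floor_r0),
    class = "membrane_shape")
}

#' @export
print.membrane_shape <- function(x, ...) {
  cat("Two-lobed membrane shape\n")
  cat(sprintf("  w = %.3f, a = %.3f, A_p = %g um^2\n",
              x$params$w, x$params$a, x$params$A_p))
  cat(sprintf("  S_total = %.4f um^2, V = %.4f um^3\n", x$S_total, x$V))
  cat(sprintf("  E_bend = %.2f kBT, E_neck = %.2f kBT, converged: %s\n",
              x$E_bend, x$E_neck, x$converged))
  invisible(x)
}

#' Spherical reference shape
#'
#' A single sphere as a \code{membrane_shape}, mainly used to validate the
#' bending-energy quadrature against the closed form 8 pi kappa.
#'
#' @param R_um sphere radius in micrometres.
#' @param phys a \code{\link{physical_params}} object.
#' @param n_profile meridian resolution.
#' @return A \code{membrane_shape}.
#' @export
sphere_shape <- function(R_um = 1, phys = physical_params(), n_profile = 400) {
  prof <- .finish_profile(.sphere_profile(R_um, n = n_profile))
  structure(list(
    params = list(w = NA_real_, a = NA_real_, A_p = pi * R_um^2),
    phys = phys, profile = prof,
    S_total = 4 * pi * R_um^2, V = 4 * pi / 3 * R_um^3,
    E_bend = 8 * pi * phys$kappa, E_neck = 0,
    converged = TRUE, floor_r0 = FALSE),
    class = "membrane_shape")
}

## ---- quadrature operations -------------------------------------------------

.check_profile <- function(profile) {
  if (is.null(profile) || nrow(profile) < 8)
    stop("invalid profile: need at least 8 meridian samples")
  if (any(!is.finite(profile$r_um)) || any(!is.finite(profile$z_um)))
    stop("invalid profile: non-finite coordinates")
  if (any(profile$r_um < -1e-9))
    stop("invalid profile: negative radial coordinates")
  for (cp in unique(profile$component)) {
    pr <- profile[profile$component == cp, ]
    span <- max(pr$r_um)
    if (pr$r_um[1] > 1e-6 * span || pr$r_um[nrow(pr)] > 1e-6 * span)
      stop("open profile: each meridian component must start and end on the axis")
  }
  invisible(TRUE)
}

#' Helfrich bending energy of a shape by meridian quadrature
#'
#' Integrates \code{(kappa / 2) (2H)^2} over the axisymmetric surface
#' defined by the shape's meridian profile, with zero spontaneous curvature
#' (the Gaussian term is a topological constant and omitted).  The meridional
#' curvature is obtained by finite differences of the tangent angle along
#' the arclength; the azimuthal curvature is \code{sin(psi)/r}, replaced by
#' the meridional value at the poles where both principal curvatures
#' coincide.
#'
#' @param shape a \code{membrane_shape} (or a list with a \code{profile}
#'   data frame holding \code{r_um}, \code{z_um} and \code{component}).
#' @param kappa bending modulus in kBT; defaults to the shape's.
#' @return Bending energy in kBT.
#' @export
bending_energy <- function(shape, kappa = NULL) {
  if (is.null(kappa)) kappa <- shape$phys$kappa
  profile <- shape$profile
  .check_profile(profile)
  total <- 0
  for (cp in unique(profile$component)) {
    pr <- profile[profile$component == cp, ]
    r <- pr$r_um; z <- pr$z_um
    n <- length(r)
    dr <- diff(r); dz <- diff(z)
    ds <- sqrt(dr^2 + dz^2)
    if (any(ds == 0)) {
      keep <- c(TRUE, ds > 0)
      r <- r[keep]; z <- z[keep]
      dr <- diff(r); dz <- diff(z); ds <- sqrt(dr^2 + dz^2)
      n <- length(r)
    }
    psi_mid <- atan2(dz, dr)
    psi_mid <- .unwrap(psi_mid)
    ## node values (one-sided at the poles)
    psi <- c(psi_mid[1],
             (psi_mid[-1] * ds[-(n - 1)] + psi_mid[-(n - 1)] * ds[-1]) /
               (ds[-1] + ds[-(n - 1)]),
             psi_mid[n - 1])
    s_mid <- cumsum(ds) - ds / 2
    cm <- c((psi_mid[2] - psi_mid[1]) / (s_mid[2] - s_mid[1]),
            diff(psi_mid) / diff(s_mid),
            (psi_mid[n - 1] - psi_mid[n - 2]) / (s_mid[n - 1] - s_mid[n - 2]))
    span <- max(r)
    cp_curv <- ifelse(r > 1e-6 * span, sin(psi) / pmax(r, 1e-300), cm)
    integrand <- (cm + cp_curv)^2 * r          # times 2 pi ds below
    seg <- (integrand[-n] + integrand[-1]) / 2 * ds
    total <- total + sum(seg) * 2 * pi
  }
  kappa / 2 * total
}

.unwrap <- function(x) {
  d <- diff(x)
  jumps <- cumsum(c(0, round(-d / (2 * pi)))) * 2 * pi
  x + jumps
}

#' Enclosed volume of a shape by solid-of-revolution quadrature
#'
#' Computes \code{pi * integral r^2 dz} along each closed meridian component
#' and sums the components (so it is additive over the two lobes in the
#' zero-neck limit).
#'
#' @param shape a \code{membrane_shape}.
#' @return Volume in cubic micrometres.
#' @export
enclosed_volume <- function(shape) {
  profile <- shape$profile
  .check_profile(profile)
  total <- 0
  for (cp in unique(profile$component)) {
    pr <- profile[profile$component == cp, ]
    r <- pr$r_um; z <- pr$z_um
    total <- total + sum(pi * (r[-length(r)]^2 + r[-1]^2) / 2 * diff(z))
  }
  abs(total)
}

#' Bending energy of the neck (collar) region
#'
#' Returns the bending energy of the toroidal collar of the constrained
#' minimum-energy shape, with curvature radii floored at the minimum bending
#' radius \code{R0}: the collar tube radius is bounded below by \code{R0}
#' and the waist radius entering the collar is \code{max(w R_eq, R0)}.
#' At \code{w = 0} this is by convention the limit value computed with a
#' waist radius equal to \code{R0}, never a division-by-zero fault.
#'
#' @param params a \code{\link{shape_params}} object.
#' @param phys a \code{\link{physical_params}} object.
#' @return Neck bending energy in kBT.
#' @export
neck_bending_energy <- function(params, phys = physical_params()) {
  shape <- build_shape(params, phys, floor_r0 = TRUE)
  shape$E_neck
}

#' Export a meridian profile as CSV
#'
#' @param shape a \code{membrane_shape}.
#' @param file path to write (columns \code{arclength_um, r_um, z_um,
#'   component}).
#' @return The file path, invisibly.
#' @export
write_shape_csv <- function(shape, file) {
  pr <- shape$profile
  out <- data.frame(arclength_um = pr$s_um, r_um = pr$r_um, z_um = pr$z_um,
                    component = pr$component)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Summarise a shape as JSON
#'
#' @param shape a \code{membrane_shape}.
#' @param file optional path; if missing the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
shape_json <- function(shape, file = NULL) {
  x <- list(w = shape$params$w, a = shape$params$a, A_p = shape$params$A_p,
            S_total_um2 = shape$S_total, V_um3 = shape$V,
            E_bend_kBT = shape$E_bend, E_neck_kBT = shape$E_neck,
            converged = shape$converged)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
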