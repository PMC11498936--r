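## High-accuracy shape mode: direct relaxation of a discretised meridian.
##
## The meridian is parameterised by its tangent angle psi at arclength nodes
## along two segments (bottom pole -> neck waist, waist -> top pole) with the
## two segment lengths as additional unknowns.  The bending energy is
## minimised under quadratic penalties enforcing the side-area split, the
## waist radius and closure on the axis.  This representation is independent
## of the analytic cap+collar family and serves to validate it.

.relax_geometry <- function(par, n_b, n_t, rn, a) {
  nn <- n_b + n_t - 1
  psi <- c(0, par[seq_len(nn - 2)], pi)
  L_b <- exp(par[nn - 1]); L_t <- exp(par[nn])
  h_b <- L_b / (n_b - 1); h_t <- L_t / (n_t - 1)
  ds <- c(rep(h_b, n_b - 1), rep(h_t, n_t - 1))
  s <- c(0, cumsum(ds))
  cp <- cos(psi); sp <- sin(psi)
  ## trapezoid integration of the tangent
  r <- c(0, cumsum((cp[-nn] + cp[-1]) / 2 * ds))
  z <- c(0, cumsum((sp[-nn] + sp[-1]) / 2 * ds))
  list(psi = psi, s = s, ds = ds, r = r, z = z, n = nn,
       i_waist = n_b, L_b = L_b, L_t = L_t)
}

.relax_objective <- function(par, n_b, n_t, rn, a, w_pen = 1e5) {
  g <- .relax_geometry(par, n_b, n_t, rn, a)
  nn <- g$n; psi <- g$psi; r <- g$r; s <- g$s
  ## curvatures
  cm <- numeric(nn)
  cm[2:(nn - 1)] <- (psi[3:nn] - psi[1:(nn - 2)]) / (s[3:nn] - s[1:(nn - 2)])
  cm[1] <- (psi[2] - psi[1]) / (s[2] - s[1])
  cm[nn] <- (psi[nn] - psi[nn - 1]) / (s[nn] - s[nn - 1])
  rmax <- max(r)
  cpol <- ifelse(r > 1e-4 * rmax, sin(psi) / pmax(r, 1e-12), cm)
  integ <- (cm + cpol)^2 * r
  wts <- c(g$ds / 2, 0) + c(0, g$ds / 2)
  E <- 0.5 * sum(integ * wts) * 2 * pi          # in units of kappa
  ## areas of the two sides (bottom = larger lobe)
  ring <- r * wts
  A_b <- 2 * pi * sum(ring[seq_len(g$i_waist)])
  A_t <- 2 * pi * sum(ring[g$i_waist:nn]) - 2 * pi * ring[g$i_waist] / 2
  A_t <- 2 * pi * (sum(ring) ) - A_b
  pen <- (A_b / (4 * pi * (1 - a)) - 1)^2 +
    (A_t / (4 * pi * a) - 1)^2 +
    ((r[g$i_waist] - rn) / max(rn, 0.05))^2 +
    (r[nn] / 0.05)^2 +
    sum(pmin(r, 0)^2) * 100
  E + w_pen * pen
}

#' Relax a discretised meridian to validate the analytic shape family
#'
#' Minimises the Helfrich bending energy of a tangent-angle-parameterised
#' meridian (default 81 nodes) under penalty constraints fixing the total
#' membrane area split across the neck and the neck waist radius, starting
#' from the analytic cap+collar solution.  Returns the relaxed bending
#' energy and constraint residuals.  Used as the package's high-accuracy
#' mode and as an independent check of \code{\link{build_shape}}.
#'
#' @param params a \code{\link{shape_params}} (requires \code{w > 0}).
#' @param phys a \code{\link{physical_params}}.
#' @param n_nodes total meridian nodes (split evenly across the waist).
#' @param maxit optimisation iterations.
#' @return List: \code{E_bend} (kBT), \code{E_bend_family} (analytic family
#'   value, kBT), \code{area_residual}, \code{waist_residual},
#'   \code{closure_residual}, \code{converged}.
#' @export
relax_shape <- function(params, phys = physical_params(), n_nodes = 81,
                        maxit = 400) {
  if (!inherits(params, "shape_params"))
    params <- shape_params(params$w, params$a, params$A_p)
  if (params$w <= 0) stop("relaxation requires w > 0")
  shape <- build_shape(params, phys, floor_r0 = FALSE, n_profile = 4 * n_nodes)
  Req <- sqrt(params$A_p / pi)
  prof <- shape$profile
  r <- prof$r_um / Req; z <- prof$z_um / Req
  ## split at the waist (minimum radius away from the poles)
  n <- length(r)
  core <- seq(round(n * 0.15), round(n * 0.85))
  i_w <- core[which.min(r[core])]
  n_b <- (n_nodes + 1) %/% 2; n_t <- n_nodes + 1 - n_b
  resample_psi <- function(idx, m) {
    rr <- r[idx]; zz <- z[idx]
    ds <- sqrt(diff(rr)^2 + diff(zz)^2)
    s <- c(0, cumsum(ds))
    psi_mid <- .unwrap(atan2(diff(zz), diff(rr)))
    s_mid <- s[-length(s)] + ds / 2
    stats::approx(s_mid, psi_mid, xout = seq(0, s[length(s)], length.out = m),
                  rule = 2)$y
  }
  psi_b <- resample_psi(1:i_w, n_b)
  psi_t <- resample_psi(i_w:n, n_t)
  L_b0 <- sum(sqrt(diff(r[1:i_w])^2 + diff(z[1:i_w])^2))
  L_t0 <- sum(sqrt(diff(r[i_w:n])^2 + diff(z[i_w:n])^2))
  psi0 <- c(psi_b, psi_t[-1])
  par0 <- c(psi0[2:(length(psi0) - 1)], log(L_b0), log(L_t0))
  rn <- params$w
  np <- length(par0)
  lower <- c(rep(-2, np - 2), par0[np - 1] - 2, par0[np] - 2)
  upper <- c(rep(2 * pi + 2, np - 2), par0[np - 1] + 2, par0[np] + 2)
  opt <- stats::optim(par0, .relax_objective, n_b = n_b, n_t = n_t,
                      rn = rn, a = params$a,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 1e9))
  g <- .relax_geometry(opt$par, n_b, n_t, rn, params$a)
  wts <- c(g$ds / 2, 0) + c(0, g$ds / 2)
  ring <- g$r * wts
  A_b <- 2 * pi * sum(ring[seq_len(g$i_waist)])
  A_t <- 2 * pi * sum(ring) - A_b
  E_unit <- .relax_objective(opt$par, n_b, n_t, rn, params$a, w_pen = 0)
  list(E_bend = phys$kappa * E_unit,
       E_bend_family = shape$E_bend,
       area_residual = abs(A_b + A_t - 4 * pi) / (4 * pi),
       split_residual = abs(A_t / (4 * pi) - params$a),
       waist_residual = abs(g$r[g$i_waist] - rn),
       closure_residual = abs(g$r[g$n]),
       converged = opt$convergence == 0)
}
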