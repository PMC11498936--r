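## Orbits on a free-energy landscape: deterministic gradient descent and
## overdamped Langevin (Monte-Carlo) dynamics, fusion-mode classification,
## and phase diagrams of explosive-fusion probability.
##
## The dynamics carry no physical time scale; tau is dimensionless.  The
## stochastic update is Euler-Maruyama for
##   dx = -M grad(F) dtau + sqrt(2 M E_fluct) dW,
## with mobility M = 1 and F in kBT, so E_fluct = 1 kBT corresponds to
## thermal fluctuations at room temperature.  The zero-noise limit is the
## deterministic gradient orbit, bitwise.

.reflect_interval <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  lo + y
}

## One reflection pass for the feasibility bound w < sqrt(2 a)
.reflect_feasibility <- function(w, a, wmax) {
  bound <- min(sqrt(2 * a) * (1 - 1e-6), wmax)
  if (w > bound) w <- max(2 * bound - w, 0)
  w
}

.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629L)
}

.simulate_orbit <- function(L, init, E_fluct, step, max_steps,
                            w_dev, a_abs, record = TRUE,
                            max_move = 0.01, dtau_min = 1e-16) {
  wlo <- min(L$w); whi <- max(L$w)
  alo <- min(L$a); ahi <- max(L$a)
  x <- c(init[1], init[2])
  .check_in_hull(L, x)
  ## thresholds outside the landscape domain are clipped to its edges: the
  ## grid cannot represent smaller lobes (or wider necks) than it covers
  a_abs <- max(a_abs, alo)
  w_dev <- min(w_dev, whi)
  g0 <- .interp_point(L, x[1], x[2], deriv = TRUE)
  Fx <- g0$F
  if (record) {
    states <- matrix(NA_real_, max_steps + 1, 2)
    Fs <- numeric(max_steps + 1); taus <- numeric(max_steps + 1)
    states[1, ] <- x; Fs[1] <- Fx; taus[1] <- 0
  }
  dtau <- step
  tau <- 0
  classification <- "undetermined"
  n <- 0L
  deterministic <- E_fluct == 0
  for (k in seq_len(max_steps)) {
    g <- .interp_point(L, x[1], x[2], deriv = TRUE)
    grad <- c(g$dw, g$da)
    gnorm <- max(abs(grad))
    if (deterministic && gnorm < 1e-10) break        # stationary point
    ## adapt the time step: cap the drift move, and in the deterministic
    ## case never allow F to increase; proposals that cross a
    ## classification threshold are always accepted
    repeat {
      drift <- -grad * dtau
      if (max(abs(drift)) > max_move && dtau > dtau_min) { dtau <- dtau / 2; next }
      xp <- x + drift
      if (xp[2] <= a_abs || xp[1] >= w_dev) break
      if (deterministic) {
        xt <- .apply_bounds(xp, wlo, whi, alo, ahi)
        Ft <- .interp_point(L, xt[1], xt[2])$F
        if (Ft > g$F + 1e-10 * (1 + abs(g$F)) && dtau > dtau_min) {
          dtau <- dtau / 2; next
        }
      }
      break
    }
    noise <- if (deterministic) c(0, 0) else sqrt(2 * E_fluct * dtau) * stats::rnorm(2)
    xp <- x + drift + noise
    tau <- tau + dtau
    n <- k
    ## classification on the proposed state, before boundary reflection;
    ## the absorption threshold is checked first so that ties are bridge
    if (xp[2] <= a_abs) {
      x <- c(.reflect_interval(xp[1], wlo, whi), max(xp[2], alo))
      classification <- "bridge"
    } else if (xp[1] >= w_dev) {
      x <- c(min(xp[1], whi), .reflect_interval(xp[2], alo, ahi))
      classification <- "explosive"
    } else {
      x <- .apply_bounds(xp, wlo, whi, alo, ahi)
    }
    Fx <- .interp_point(L, x[1], x[2])$F
    if (record) { states[k + 1, ] <- x; Fs[k + 1] <- Fx; taus[k + 1] <- tau }
    if (classification != "undetermined") break
    ## cautious step-size recovery
    if (dtau < step) dtau <- min(dtau * 1.5, step)
  }
  list(states = if (record) states[seq_len(n + 1), , drop = FALSE] else
         matrix(x, 1, 2),
       F_values = if (record) Fs[seq_len(n + 1)] else Fx,
       tau = if (record) taus[seq_len(n + 1)] else tau,
       classification = classification, n_steps = n)
}

.apply_bounds <- function(x, wlo, whi, alo, ahi) {
  w <- .reflect_interval(x[1], wlo, whi)
  a <- .reflect_interval(x[2], alo, ahi)
  w <- .reflect_feasibility(w, a, whi)
  c(w, a)
}

#' Deterministic gradient-descent orbit on a landscape
#'
#' Explicit descent \code{x_{k+1} = x_k - M grad(F) dtau} with mobility
#' \code{M = 1}, reflecting boundaries and an adaptive time step (halved
#' whenever a step would raise the interpolated free energy, so F is
#' non-increasing along the orbit).  The orbit terminates when it is
#' classified as explosive or bridge fusion, reaches a stationary point, or
#' exhausts \code{max_steps}.
#'
#' @param L a \code{\link{compute_landscape}} result.
#' @param init initial \code{c(w, a)}; default \code{c(0, 0.3)}, the state
#'   just after fusion-pore formation.
#' @param step initial dimensionless time step.
#' @param max_steps maximum number of steps.
#' @param w_dev neck-width threshold for explosive fusion.
#' @param a_abs area-fraction threshold for complete absorption of the
#'   smaller lobe (bridge fusion).
#' @return An object of class \code{fusion_orbit} with the visited states,
#'   interpolated free energies, dimensionless times and the classification.
#' @export
gradient_orbit <- function(L, init = c(0, 0.3), step = 1e-3, max_steps = 2e5,
                           w_dev = 0.2, a_abs = 0.02) {
  out <- .simulate_orbit(L, init, E_fluct = 0, step = step,
                         max_steps = max_steps, w_dev = w_dev, a_abs = a_abs)
  structure(c(out, list(E_fluct = 0, seed = NA_integer_, init = init,
                        w_dev = w_dev, a_abs = a_abs)),
            class = "fusion_orbit")
}

#' Fluctuation-driven (Langevin Monte-Carlo) orbit
#'
#' Overdamped Langevin dynamics
#' \code{x_{k+1} = x_k - M grad(F) dtau + sqrt(2 M E_fluct dtau) xi_k}
#' with independent standard-normal components \code{xi_k}, reflecting
#' boundaries and the same adaptive time step as
#' \code{\link{gradient_orbit}}.  With \code{E_fluct = 0} the orbit is
#' bitwise identical to the deterministic gradient orbit.  Fully
#' reproducible from \code{seed}.
#'
#' @inheritParams gradient_orbit
#' @param E_fluct fluctuation energy in kBT (1 kBT is thermal noise at room
#'   temperature).
#' @param seed integer random seed (required).
#' @param record keep the full state history (set \code{FALSE} for
#'   probability estimation loops).
#' @return A \code{fusion_orbit}.
#' @export
mc_orbit <- function(L, E_fluct, init = c(0, 0.3), step = 1e-3,
                     max_steps = 2e5, seed, w_dev = 0.2, a_abs = 0.02,
                     record = TRUE) {
  if (missing(seed) || !is.numeric(seed)) stop("'seed' is required for mc_orbit")
  if (E_fluct < 0) stop("'E_fluct' must be non-negative (kBT)")
  set.seed(as.integer(seed))
  out <- .simulate_orbit(L, init, E_fluct = E_fluct, step = step,
                         max_steps = max_steps, w_dev = w_dev, a_abs = a_abs,
                         record = record)
  structure(c(out, list(E_fluct = E_fluct, seed = as.integer(seed),
                        init = init, w_dev = w_dev, a_abs = a_abs)),
            class = "fusion_orbit")
}

#' @export
print.fusion_orbit <- function(x, ...) {
  cat("Fusion orbit\n")
  cat(sprintf("  init (w, a) = (%g, %g), E_fluct = %g kBT, steps = %d\n",
              x$init[1], x$init[2], x$E_fluct, x$n_steps))
  last <- x$states[nrow(x$states), ]
  cat(sprintf("  final (w, a) = (%.4f, %.4f); classification: %s\n",
              last[1], last[2], x$classification))
  invisible(x)
}

#' Classify an orbit as explosive or bridge fusion
#'
#' Explosive fusion: the neck width reaches \code{w_dev} strictly before the
#' smaller lobe is absorbed (\code{a} crosses \code{a_abs}).  Bridge fusion:
#' absorption happens first while the neck never widened to \code{w_dev}.
#' First-crossing ties are classified as bridge.  Orbits crossing neither
#' threshold are undetermined.
#'
#' @param orbit a \code{fusion_orbit}, or a two-column matrix of (w, a)
#'   states.
#' @param w_dev neck-width deviation threshold (default 0.2).
#' @param a_abs absorption threshold on the area fraction (default 0.02).
#' @param a_side \code{"below"} (default: absorption means a falls to
#'   \code{a_abs}) or \code{"above"} (absorption read as a rising across
#'   \code{a_abs}).
#' @return \code{"explosive"}, \code{"bridge"} or \code{"undetermined"}.
#' @export
classify_orbit <- function(orbit, w_dev = 0.2, a_abs = 0.02,
                           a_side = c("below", "above")) {
  a_side <- match.arg(a_side)
  states <- if (inherits(orbit, "fusion_orbit")) orbit$states else as.matrix(orbit)
  if (is.null(dim(states)) || nrow(states) < 1 || ncol(states) != 2)
    stop("orbit must contain at least one (w, a) state")
  iw <- which(states[, 1] >= w_dev)
  ia <- if (a_side == "below") which(states[, 2] <= a_abs) else
    which(states[, 2] >= a_abs)
  iw <- if (length(iw)) iw[1] else Inf
  ia <- if (length(ia)) ia[1] else Inf
  if (is.infinite(iw) && is.infinite(ia)) return("undetermined")
  if (iw < ia) "explosive" else "bridge"
}

.wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Explosive-fusion probability at one parameter set
#'
#' Builds (or reuses) the landscape for the given vesicle size and osmotic
#' pressure, runs \code{n_runs} Langevin orbits from the post-pore initial
#' condition with per-orbit seeds derived deterministically from
#' \code{seed}, and returns the explosive fraction with a 95\% Wilson
#' confidence interval.  Undetermined orbits stay in the denominator and are
#' reported separately.
#'
#' @param A_p projected area, um^2.
#' @param delta_p_Pa osmotic pressure difference, Pa.
#' @param E_fluct fluctuation energy, kBT.
#' @param n_runs number of Monte-Carlo orbits (>= 1).
#' @param seed master seed.
#' @param mode landscape mode (default \code{"large"}; \code{"small"} gives
#'   the small-vesicle regime).
#' @param landscape optional precomputed \code{fusion_landscape} to reuse.
#' @param phys physical parameters (its \code{delta_p_Pa} is overridden).
#' @param init,step,max_steps,w_dev,a_abs orbit controls, see
#'   \code{\link{mc_orbit}}.
#' @return A one-row data frame (a \code{PhaseDiagram} row).
#' @export
explosive_probability <- function(A_p, delta_p_Pa, E_fluct, n_runs, seed,
                                  mode = "large", landscape = NULL,
                                  phys = physical_params(),
                                  init = c(0, 0.3), step = 1e-3,
                                  max_steps = 2e5, w_dev = 0.2, a_abs = 0.02) {
  if (!is.numeric(n_runs) || n_runs < 1) stop("'n_runs' must be >= 1")
  phys$delta_p_Pa <- delta_p_Pa
  L <- if (is.null(landscape)) {
    compute_landscape(A_p = A_p, phys = phys, mode = mode)
  } else .with_delta_p(landscape, delta_p_Pa)
  cls <- character(n_runs)
  for (i in seq_len(n_runs)) {
    o <- mc_orbit(L, E_fluct = E_fluct, init = init, step = step,
                  max_steps = max_steps, seed = .derive_seed(seed, i),
                  w_dev = w_dev, a_abs = a_abs, record = FALSE)
    cls[i] <- o$classification
  }
  k <- sum(cls == "explosive")
  ci <- .wilson_ci(k, n_runs)
  data.frame(A_p_um2 = A_p, delta_p_Pa = delta_p_Pa, E_fluct_kBT = E_fluct,
             n_runs = as.integer(n_runs), n_explosive = as.integer(k),
             n_undetermined = as.integer(sum(cls == "undetermined")),
             P_explosive = k / n_runs, CI_low = ci[1], CI_high = ci[2],
             Gamma_kBT = neck_energy_scale(A_p, phys),
             seed = as.integer(seed))
}

#' Phase diagram of explosive-fusion probability
#'
#' Cartesian sweep of \code{\link{explosive_probability}} over vesicle
#' sizes, osmotic pressure differences and fluctuation energies.  The
#' landscape geometry is computed once per vesicle size and rescaled in
#' pressure (the free energy is linear in the osmotic pressure difference).
#' Fully reproducible from \code{seed}.
#'
#' @param A_p_um2 vector of projected areas, um^2.
#' @param delta_p_Pa vector of osmotic pressure differences, Pa.
#' @param E_fluct_kBT vector of fluctuation energies, kBT.
#' @param n_runs Monte-Carlo orbits per cell.
#' @param seed master seed; row seeds are derived deterministically so each
#'   cell equals the corresponding single \code{explosive_probability} call.
#' @param ... further arguments passed to \code{\link{explosive_probability}}.
#' @param phys physical parameters.
#' @param mode landscape mode.
#' @return A data frame with one row per parameter combination.
#' @export
phase_diagram <- function(A_p_um2, delta_p_Pa, E_fluct_kBT, n_runs = 200,
                          seed = 1, phys = physical_params(), mode = "large",
                          ...) {
  if (!length(A_p_um2) || !length(delta_p_Pa) || !length(E_fluct_kBT))
    stop("parameter lists must be non-empty")
  rows <- vector("list", 0)
  row_id <- 0L
  for (A in A_p_um2) {
    Lgeo <- compute_landscape(A_p = A, phys = phys, mode = mode)
    for (dp in delta_p_Pa) {
      for (E in E_fluct_kBT) {
        row_id <- row_id + 1L
        rows[[row_id]] <- explosive_probability(
          A_p = A, delta_p_Pa = dp, E_fluct = E, n_runs = n_runs,
          seed = .phase_seed(seed, A, dp, E), mode = mode,
          landscape = Lgeo, phys = phys, ...)
      }
    }
  }
  do.call(rbind, rows)
}

## Row seed derived from the cell's parameters (not its position), so a
## single-cell sweep equals the corresponding explosive_probability call
## with the same derived seed.
.phase_seed <- function(seed, A, dp, E) {
  h <- sum(as.integer(charToRaw(sprintf("%.6g|%.6g|%.6g", A, dp, E))) *
             seq_len(nchar(sprintf("%.6g|%.6g|%.6g", A, dp, E))))
  .derive_seed(seed, h)
}

#' Export an orbit as CSV
#'
#' @param orbit a \code{fusion_orbit}.
#' @param file output path (columns \code{tau, w, a, F_kBT}).
#' @return The path, invisibly.
#' @export
write_orbit_csv <- function(orbit, file) {
  out <- data.frame(tau = orbit$tau, w = orbit$states[, 1],
                    a = orbit$states[, 2], F_kBT = orbit$F_values)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
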