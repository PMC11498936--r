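## Measurement pipeline: fusion-event detection from track tables, fusion
## kinetics statistics, size-distribution comparison, size--duration
## correlation, FRAP half-time estimation and perimeter-region intensity
## profiling.

.track_schema <- c("frame", "time_s", "track_id", "x_um", "y_um", "area_um2")

.check_tracks <- function(tracks) {
  missing_cols <- setdiff(.track_schema, names(tracks))
  if (length(missing_cols))
    stop(sprintf("track table is missing required columns: %s",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(tracks) < 2) stop("track table needs at least 2 frames of data")
  invisible(TRUE)
}

#' Detect fusion events in a vesicle track table
#'
#' Operationalises the visual scoring rules on track data.  Homotypic
#' (explosive) fusion: two tracks end at the same frame and a child track
#' begins at the next frame with an area equal to the parents' sum within
#' \code{area_tol} and a centroid inside the parents' neighbourhood; the
#' fusion time runs from the child's appearance to the end of the rounding
#' transient, located by intersecting a line fit of the decaying area ramp
#' with the final plateau area (sub-frame resolution).  Heterotypic
#' (bridge) fusion: a track whose area declines monotonically (within
#' noise) over at least \code{min_shrink_frames} frames and then disappears
#' before the recording ends; shrink onset and the disappearance time are
#' obtained by intersecting a line fit of the declining segment with the
#' pre-shrink level and zero.
#'
#' Overlapping homotypic candidate assignments are resolved greedily by the
#' area-conservation score, ties by the earlier frame.
#'
#' @param tracks a track table (see \code{\link{simulate_tracks}} for the
#'   schema); only observational columns are used.
#' @param area_tol relative tolerance on child area = sum of parent areas.
#' @param min_shrink_frames minimum length of the terminal shrink run.
#' @param noise_rel assumed relative area noise (sets plateau and shrink
#'   detection margins).
#' @return Data frame of events: \code{type}, \code{track_ids},
#'   \code{t_start_s}, \code{t_end_s}, \code{duration_s}, \code{size_um2}
#'   (larger fusion partner for homotypic, pre-shrink area for
#'   heterotypic).
#' @export
detect_fusion_events <- function(tracks, area_tol = 0.15,
                                 min_shrink_frames = 3, noise_rel = 0.02) {
  .check_tracks(tracks)
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  byid <- split(tracks, tracks$track_id)
  fmax <- max(tracks$frame); fmin <- min(tracks$frame)
  first_f <- vapply(byid, function(d) d$frame[1], numeric(1))
  last_f  <- vapply(byid, function(d) d$frame[nrow(d)], numeric(1))
  dt <- stats::median(diff(sort(unique(tracks$time_s))))

  events <- list()
  used <- character()

  ## ---- homotypic: parent-pair -> child signatures -------------------------
  child_ids <- names(byid)[first_f > fmin]
  cand <- list()
  for (cid in child_ids) {
    ch <- byid[[cid]]
    f0 <- ch$frame[1]
    parents <- names(byid)[last_f == f0 - 1]
    parents <- setdiff(parents, cid)
    if (length(parents) < 2) next
    for (i in seq_along(parents)) for (j in seq_len(i - 1)) {
      p1 <- byid[[parents[i]]]; p2 <- byid[[parents[j]]]
      a1 <- p1$area_um2[nrow(p1)]; a2 <- p2$area_um2[nrow(p2)]
      score <- abs(ch$area_um2[1] - (a1 + a2)) / (a1 + a2)
      if (score > area_tol) next
      margin <- 2 + sqrt((a1 + a2) / pi)
      if (abs(ch$x_um[1] - mean(c(p1$x_um[nrow(p1)], p2$x_um[nrow(p2)]))) > margin ||
          abs(ch$y_um[1] - mean(c(p1$y_um[nrow(p1)], p2$y_um[nrow(p2)]))) > margin)
        next
      cand[[length(cand) + 1]] <- list(child = cid, p1 = parents[i],
                                       p2 = parents[j], score = score,
                                       frame = f0, size = max(a1, a2))
    }
  }
  if (length(cand)) {
    ord <- order(vapply(cand, `[[`, numeric(1), "score"),
                 vapply(cand, `[[`, numeric(1), "frame"))
    for (k in ord) {
      cc <- cand[[k]]
      if (any(c(cc$child, cc$p1, cc$p2) %in% used)) next
      used <- c(used, cc$child, cc$p1, cc$p2)
      ch <- byid[[cc$child]]
      t0 <- ch$time_s[1]
      t_end <- .plateau_crossing(ch$time_s, ch$area_um2, dt, noise_rel)
      events[[length(events) + 1]] <- data.frame(
        type = "homotypic",
        track_ids = paste(cc$p1, cc$p2, cc$child, sep = ";"),
        t_start_s = t0, t_end_s = t_end, duration_s = t_end - t0,
        size_um2 = cc$size)
    }
  }

  ## ---- heterotypic: shrink-to-disappearance signatures --------------------
  for (id in names(byid)) {
    if (id %in% used) next
    tr <- byid[[id]]
    if (tr$frame[nrow(tr)] >= fmax) next           # survives to the end
    res <- .shrink_event(tr, min_shrink_frames, noise_rel)
    if (is.null(res)) next
    events[[length(events) + 1]] <- data.frame(
      type = "heterotypic", track_ids = id,
      t_start_s = res$t_on, t_end_s = res$t_zero,
      duration_s = res$t_zero - res$t_on, size_um2 = res$size)
  }

  if (!length(events))
    return(data.frame(type = character(), track_ids = character(),
                      t_start_s = numeric(), t_end_s = numeric(),
                      duration_s = numeric(), size_um2 = numeric()))
  out <- do.call(rbind, events)
  out <- out[order(out$t_start_s), ]
  rownames(out) <- NULL
  out
}

## End of the rounding transient: intersect a line fit of the decaying ramp
## with the plateau level (median of the last frames).
.plateau_crossing <- function(time, area, dt, noise_rel) {
  n <- length(area)
  A_fin <- stats::median(area[max(1, n - 2):n])
  ramp <- which(area > A_fin * (1 + 2 * noise_rel))
  ramp <- ramp[ramp < n]
  if (!length(ramp)) return(time[1] + dt)
  ramp <- seq_len(max(ramp))                      # contiguous from appearance
  if (length(ramp) >= 2) {
    fit <- stats::lm(area[ramp] ~ time[ramp])
    slope <- stats::coef(fit)[2]
    if (is.finite(slope) && slope < 0) {
      t_cross <- (A_fin - stats::coef(fit)[1]) / slope
      return(min(max(t_cross, time[max(ramp)]), time[min(max(ramp) + 2, n)]))
    }
  }
  time[min(max(ramp) + 1, n)]
}

## Terminal shrink run of a disappearing track; NULL if no convincing run.
.shrink_event <- function(tr, min_shrink_frames, noise_rel) {
  a <- tr$area_um2; t <- tr$time_s
  n <- length(a)
  if (n < min_shrink_frames + 1) return(NULL)
  ## walk back from disappearance while the decline per frame is clearly
  ## above the noise level (relative to the local area)
  run <- 0L
  for (i in (n - 1):1) {
    if (a[i] - a[i + 1] > 2 * noise_rel * a[i]) run <- run + 1L else break
  }
  if (run < min_shrink_frames) return(NULL)
  idx <- (n - run):n
  if (a[idx[1]] - a[n] < 0.5 * a[idx[1]]) return(NULL)   # net decline < 50%
  ## two-pass onset refinement: a rough pre-shrink level separates flat
  ## frames from the declining ramp, the final level uses flat frames only
  ## and the line fit uses the full ramp
  pre_rough <- stats::median(a[seq_len(max(idx[1] - 3, 1))])
  is_flat <- a > pre_rough * (1 - 3 * noise_rel)
  flat_end <- if (any(is_flat[seq_len(idx[1])]))
    max(which(is_flat[seq_len(idx[1])])) else 1L
  pre <- stats::median(a[seq_len(flat_end)])
  idx <- seq(min(flat_end + 1, idx[1]), n)
  if (length(idx) < 2) return(NULL)
  fit <- stats::lm(a[idx] ~ t[idx])
  b0 <- stats::coef(fit)[1]; b1 <- stats::coef(fit)[2]
  if (!is.finite(b1) || b1 >= 0) return(NULL)
  t_on <- max((pre - b0) / b1, t[1])
  t_zero <- -b0 / b1
  list(t_on = unname(t_on), t_zero = unname(t_zero), size = unname(pre))
}

#' Fusion-kinetics summary statistics
#'
#' @param events a data frame of fusion events with a \code{duration_s}
#'   column (and optionally \code{size_um2}).
#' @param n_vesicles number of vesicles present at recording start
#'   (frequency denominator).
#' @param duration_s recording length in seconds.
#' @param size_classes boundaries of the size classes in um^2 (default
#'   \code{c(2, 25)}, i.e. classes <2, 2--25, >25).
#' @return A list of class \code{fusion_statistics}: \code{n},
#'   \code{mean_s}, \code{sd_s}, \code{sem_s}, \code{frequency_per_min}
#'   (fusions per minute per vesicle) and \code{size_class_counts}.
#' @export
fusion_statistics <- function(events, n_vesicles, duration_s,
                              size_classes = c(2, 25)) {
  if (!is.numeric(n_vesicles) || n_vesicles < 1) stop("'n_vesicles' must be >= 1")
  if (!is.numeric(duration_s) || duration_s <= 0) stop("'duration_s' must be positive")
  n <- nrow(events)
  if (is.null(n)) stop("'events' must be a data frame")
  mean_s <- if (n > 0) mean(events$duration_s) else NA_real_
  sd_s <- if (n > 1) stats::sd(events$duration_s) else NA_real_
  cls <- if (n > 0 && "size_um2" %in% names(events)) {
    table(cut(events$size_um2, c(0, size_classes, Inf),
              labels = c(sprintf("<%g", size_classes[1]),
                         sprintf("%g-%g", size_classes[1], size_classes[2]),
                         sprintf(">%g", size_classes[2]))))
  } else NULL
  structure(list(n = n, mean_s = mean_s, sd_s = sd_s,
                 sem_s = if (n > 1) sd_s / sqrt(n) else NA_real_,
                 frequency_per_min = n / (n_vesicles * duration_s / 60),
                 undefined_mean = n == 0,
                 size_class_counts = cls),
            class = "fusion_statistics")
}

#' @export
print.fusion_statistics <- function(x, ...) {
  cat("Fusion statistics\n")
  if (x$n > 0)
    cat(sprintf("  n = %d, mean = %.2f s (SEM %.3f s)\n", x$n, x$mean_s, x$sem_s))
  else cat("  n = 0 (mean undefined)\n")
  cat(sprintf("  frequency = %.4f fusions / min / vesicle\n", x$frequency_per_min))
  if (!is.null(x$size_class_counts)) {
    cat("  size classes (um^2): ")
    print(x$size_class_counts)
  }
  invisible(x)
}

#' Pearson correlation between vesicle size and fusion time
#'
#' Product-moment correlation computed from the definitional formula, with
#' a Fisher-z 95\% confidence interval.
#'
#' @param events data frame with \code{size_um2} and \code{duration_s}
#'   columns, or a numeric vector (then \code{y} must be given).
#' @param y optional second numeric vector.
#' @return List of class \code{size_time_correlation}: \code{r}, \code{n},
#'   \code{conf_low}, \code{conf_high}.
#' @export
size_time_correlation <- function(events, y = NULL) {
  if (is.data.frame(events)) {
    x <- events$size_um2; y <- events$duration_s
  } else x <- events
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in one of the variables")
  n <- length(x)
  xm <- x - mean(x); ym <- y - mean(y)
  r <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- 1.959963984540054 / sqrt(n - 3)
  structure(list(r = r, n = n,
                 conf_low = tanh(z - half), conf_high = tanh(z + half)),
            class = "size_time_correlation")
}

#' @export
print.size_time_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, 95%% CI %.3f to %.3f)\n",
              x$r, x$n, x$conf_low, x$conf_high))
  invisible(x)
}

#' Mann-Whitney U comparison of two size distributions
#'
#' U statistic for the first sample (number of (x, y) pairs with x > y,
#' counting ties as 1/2) with a two-sided p value.  For combined sample
#' sizes up to \code{exact_max} the null distribution is obtained by full
#' enumeration of all group assignments of the pooled observations (exact,
#' tie-safe); otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest combined sample size for the exact branch
#'   (default 12).
#' @return List of class \code{mann_whitney}: \code{U}, \code{p_value},
#'   \code{method}.
#' @export
compare_size_distributions <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  rk <- rank(pool)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    splits <- utils::combn(n1 + n2, n1)
    Uall <- apply(splits, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
    mu <- n1 * n2 / 2
    lo <- min(U, 2 * mu - U); hi <- max(U, 2 * mu - U)
    p <- (sum(Uall <= lo + 1e-9) + sum(Uall >= hi - 1e-9)) / length(Uall)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    ties <- table(pool)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tie_term))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  structure(list(U = U, p_value = min(p, 1), n1 = n1, n2 = n2,
                 method = method),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' FRAP curve correction and half-recovery time
#'
#' Correction follows the standard protocol: the background channel is
#' subtracted from the ROI and whole-cell channels, the ROI is divided by
#' the same-frame whole-cell intensity (normalised to its pre-bleach mean)
#' to compensate fluorescence loss during acquisition, and the result is
#' normalised to the mean pre-bleach ROI level.  Two half-time estimators
#' are reported: the model-free first crossing of 50\% recovery (linear
#' interpolation between frames; primary) and a mono-exponential fit
#' \code{I(t) = I_inf - (I_inf - I_0) exp(-t log(2) / t_half)}.
#'
#' @param curve data frame with \code{time_s}, \code{roi},
#'   \code{background}, \code{whole_cell}; bleach end at time 0.
#' @return List of class \code{frap_fit}: the corrected curve,
#'   \code{t_half_crossing}, \code{t_half_fit}, \code{plateau}, \code{I0},
#'   \code{reached_half}.
#' @export
fit_frap <- function(curve) {
  need <- c("time_s", "roi", "background", "whole_cell")
  missing_cols <- setdiff(need, names(curve))
  if (length(missing_cols))
    stop(sprintf("FRAP curve is missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  pre <- curve$time_s < 0
  post <- !pre
  if (sum(pre) < 3) stop("need at least 3 pre-bleach points")
  if (sum(post) < 5) stop("need at least 5 post-bleach points")
  roi_b <- curve$roi - curve$background
  wc_b <- curve$whole_cell - curve$background
  if (any(wc_b <= 0)) stop("whole-cell channel at or below background")
  rises <- diff(wc_b) > 0.1 * mean(wc_b)
  if (any(rises))
    warning("whole-cell channel is non-monotone; photobleach correction may be unreliable")
  loss <- wc_b / mean(wc_b[pre])
  corr <- roi_b / loss
  corr <- corr / mean(corr[pre])
  corrected <- data.frame(time_s = curve$time_s, intensity = corr)

  tp <- curve$time_s[post]; Ip <- corr[post]
  ## light 3-frame smoothing for the first-crossing detector (damps the
  ## early-triggering bias of a first passage through noise)
  Is <- as.numeric(stats::filter(Ip, rep(1 / 3, 3), sides = 2))
  Is[1] <- Ip[1]; Is[length(Is)] <- Ip[length(Ip)]
  I0 <- Is[1]
  plateau <- mean(utils::tail(Ip, 10))
  level <- I0 + 0.5 * (plateau - I0)
  ## no meaningful recovery: amplitude is a negligible fraction of the
  ## bleached depth
  reached <- (plateau - I0) > 0.05 * max(1 - I0, 1e-12) && any(Is >= level)
  t_cross <- NA_real_
  if (reached && plateau > I0) {
    k <- which(Is >= level)[1]
    if (k == 1) t_cross <- tp[1] else {
      t_cross <- tp[k - 1] + (level - Is[k - 1]) / (Is[k] - Is[k - 1]) *
        (tp[k] - tp[k - 1])
    }
  }
  t_fit <- NA_real_
  fit <- tryCatch(
    minpack.lm::nlsLM(Ip ~ Iinf - (Iinf - Izero) * exp(-tp * log(2) / th),
                      start = list(Iinf = plateau, Izero = I0,
                                   th = if (is.na(t_cross)) diff(range(tp)) / 4
                                        else max(t_cross, 1e-3)),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) t_fit <- stats::coef(fit)[["th"]]
  structure(list(corrected = corrected, t_half_crossing = unname(t_cross),
                 t_half_fit = t_fit, plateau = plateau, I0 = I0,
                 reached_half = reached),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP half-recovery\n")
  if (x$reached_half)
    cat(sprintf("  t1/2 (model-free crossing) = %.2f s\n", x$t_half_crossing))
  else cat("  recovery never reached 50% of plateau: t1/2 undefined\n")
  cat(sprintf("  t1/2 (mono-exponential fit) = %.2f s\n", x$t_half_fit))
  cat(sprintf("  plateau = %.3f, post-bleach floor = %.3f (pre-bleach = 1)\n",
              x$plateau, x$I0))
  invisible(x)
}

#' Perimeter-region intensity shares of a vesicle
#'
#' Partitions the vesicle perimeter into proximal (facing the fusion
#' partner), lateral and distal sectors by the angle between each boundary
#' point and the partner direction, and returns each sector's share of the
#' total perimeter intensity.
#'
#' @param outline closed polygon as a two-column matrix (x, y) in um.
#' @param direction length-2 vector pointing towards the fusion partner
#'   (normalised internally).
#' @param intensity intensity sample at each polygon vertex.
#' @param sector_deg sector boundaries in degrees from the partner
#'   direction: proximal up to the first, lateral up to the second, distal
#'   beyond (default \code{c(60, 120)}).
#' @return Named numeric vector \code{c(proximal, lateral, distal)} in
#'   percent, summing to 100.
#' @export
region_intensity_profile <- function(outline, direction, intensity,
                                     sector_deg = c(60, 120)) {
  outline <- as.matrix(outline)
  if (ncol(outline) != 2 || nrow(outline) < 3)
    stop("degenerate outline: need a closed polygon with >= 3 vertices")
  if (length(intensity) != nrow(outline))
    stop("'intensity' must have one value per outline vertex")
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("'direction' must be a non-zero vector")
  direction <- direction / nrm
  ## polygon area centroid
  x <- outline[, 1]; y <- outline[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A2 <- sum(cr)
  if (abs(A2) < 1e-12) stop("degenerate outline: zero area")
  cx <- sum((x + xn) * cr) / (3 * A2)
  cy <- sum((y + yn) * cr) / (3 * A2)
  vx <- x - cx; vy <- y - cy
  ang <- acos(pmin(pmax((vx * direction[1] + vy * direction[2]) /
                          sqrt(vx^2 + vy^2), -1), 1)) * 180 / pi
  ## arc-length weight of each vertex: half of each adjacent segment
  seg <- sqrt((xn - x)^2 + (yn - y)^2)
  segp <- c(seg[length(seg)], seg[-length(seg)])
  wgt <- (seg + segp) / 2
  contrib <- intensity * wgt
  tot <- sum(contrib)
  if (tot <= 0) stop("total perimeter intensity must be positive")
  shares <- c(
    proximal = sum(contrib[ang <= sector_deg[1]]),
    lateral  = sum(contrib[ang > sector_deg[1] & ang <= sector_deg[2]]),
    distal   = sum(contrib[ang > sector_deg[2]])) / tot * 100
  shares
}

#' Score detected events against embedded ground truth
#'
#' Greedy matching by event type and start-time proximity.
#'
#' @param detected result of \code{\link{detect_fusion_events}}.
#' @param truth ground-truth table (\code{attr(tracks, "truth")}).
#' @param time_tol_s maximum start-time mismatch for a match.
#' @return List: \code{sensitivity}, \code{false_discovery_rate},
#'   \code{n_matched}, and the matched pairs with duration errors.
#' @export
score_events <- function(detected, truth, time_tol_s = 20) {
  if (!nrow(truth))
    return(list(sensitivity = NA_real_,
                false_discovery_rate = if (nrow(detected)) 1 else 0,
                n_matched = 0L, matches = NULL))
  matched_t <- rep(FALSE, nrow(truth))
  matched_d <- rep(FALSE, nrow(detected))
  pairs <- list()
  if (nrow(detected)) for (i in seq_len(nrow(detected))) {
    j <- which(!matched_t & truth$type == detected$type[i] &
                 abs(truth$t_start_s - detected$t_start_s[i]) <= time_tol_s)
    if (length(j)) {
      j <- j[which.min(abs(truth$t_start_s[j] - detected$t_start_s[i]))]
      matched_t[j] <- TRUE; matched_d[i] <- TRUE
      pairs[[length(pairs) + 1]] <- data.frame(
        type = detected$type[i],
        duration_true = truth$duration_s[j],
        duration_detected = detected$duration_s[i],
        size_true = truth$size_um2[j],
        size_detected = detected$size_um2[i])
    }
  }
  list(sensitivity = mean(matched_t),
       false_discovery_rate = if (nrow(detected)) mean(!matched_d) else 0,
       n_matched = sum(matched_d),
       matches = if (length(pairs)) do.call(rbind, pairs) else NULL)
}
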