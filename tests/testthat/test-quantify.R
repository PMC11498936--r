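cfg <- fusion_generator_config(seed = 1)

## minimal hand-built noise-free track tables for the detector's
## constructional examples
make_merge_tracks <- function(dt = 5, nf = 41, k = 10, D = 30,
                              a1 = 6, a2 = 4) {
  times <- (seq_len(nf) - 1) * dt
  a_fin <- pi * ((a1 / pi)^1.5 + (a2 / pi)^1.5)^(2 / 3)
  tc <- times[(k + 1):nf] - times[k + 1]
  child_area <- a_fin + (a1 + a2 - a_fin) * pmax(0, 1 - tc / D)
  rbind(
    data.frame(frame = 1:k, time_s = times[1:k], track_id = 1L,
               x_um = 10, y_um = 10, area_um2 = a1, intensity = 100),
    data.frame(frame = 1:k, time_s = times[1:k], track_id = 2L,
               x_um = 12, y_um = 10, area_um2 = a2, intensity = 100),
    data.frame(frame = (k + 1):nf, time_s = times[(k + 1):nf], track_id = 3L,
               x_um = 11, y_um = 10, area_um2 = child_area, intensity = 100),
    data.frame(frame = 1:nf, time_s = times, track_id = 4L,
               x_um = 40, y_um = 40, area_um2 = 8, intensity = 100))
}

make_shrink_tracks <- function(dt = 5, nf = 81, t_on = 100, D = 150, A = 9) {
  times <- (seq_len(nf) - 1) * dt
  area <- A * pmax(0, 1 - pmax(times - t_on, 0) / D)
  alive <- which(area >= 0.05 * A)
  rbind(
    data.frame(frame = alive, time_s = times[alive], track_id = 1L,
               x_um = 10, y_um = 10, area_um2 = area[alive], intensity = 100),
    data.frame(frame = 1:nf, time_s = times, track_id = 2L,
               x_um = 40, y_um = 40, area_um2 = 5, intensity = 100))
}

test_that("a planted noise-free merge is detected with its exact duration", {
  ev <- detect_fusion_events(make_merge_tracks(D = 30))
  expect_equal(nrow(ev), 1)
  expect_identical(ev$type, "homotypic")
  expect_equal(ev$t_start_s, 50)             # child appearance
  expect_equal(ev$duration_s, 30, tolerance = 0.1)
  expect_equal(ev$size_um2, 6)               # larger partner
})

test_that("a planted shrink-to-disappearance is timed within a frame", {
  ev <- detect_fusion_events(make_shrink_tracks(t_on = 100, D = 150))
  expect_equal(nrow(ev), 1)
  expect_identical(ev$type, "heterotypic")
  expect_equal(ev$t_start_s, 100, tolerance = 5)
  expect_equal(ev$duration_s, 150, tolerance = 5)
  expect_equal(ev$size_um2, 9, tolerance = 0.01)
})

test_that("schema violations are reported with the offending columns", {
  bad <- make_merge_tracks()
  bad$area_um2 <- NULL
  expect_error(detect_fusion_events(bad), "area_um2")
  expect_error(detect_fusion_events(data.frame(frame = 1)), "missing")
})

test_that("fusion statistics compute exact frequencies and SEMs", {
  ev12 <- data.frame(duration_s = rep(30, 12), size_um2 = rep(5, 12))
  st <- fusion_statistics(ev12, n_vesicles = 30, duration_s = 400)
  expect_equal(st$frequency_per_min, 12 / (30 * 400 / 60), tolerance = 1e-12)
  st3 <- fusion_statistics(data.frame(duration_s = c(30, 32, 34)), 10, 400)
  expect_equal(st3$mean_s, 32)
  expect_equal(st3$sem_s, 2 / sqrt(3), tolerance = 1e-12)
  ## empty events: flagged, frequency zero
  st0 <- fusion_statistics(data.frame(duration_s = numeric()), 10, 400)
  expect_true(st0$undefined_mean)
  expect_equal(st0$frequency_per_min, 0)
  ## size-class breakdown at the standard thresholds
  evc <- data.frame(duration_s = 1:4, size_um2 = c(1, 5, 24, 30))
  stc <- fusion_statistics(evc, 10, 400)
  expect_equal(as.integer(stc$size_class_counts), c(1L, 2L, 1L))
  expect_error(fusion_statistics(ev12, 0, 400), "n_vesicles")
})

test_that("large synthetic samples recover the generator duration target", {
  ev <- simulate_fusion_events(cfg, n_homotypic = 1e4, seed = 6)
  st <- fusion_statistics(ev, n_vesicles = 1, duration_s = 400)
  expect_lt(abs(st$mean_s - 31.9), 2 * st$sem_s + 1e-9)
})

test_that("Pearson correlation equals the definitional formula", {
  r1 <- size_time_correlation(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r1$r, 1, tolerance = 1e-12)
  r2 <- size_time_correlation(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r2$r, 3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  ## against the reference implementation on random data
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20)
    rr <- size_time_correlation(x, y)
    expect_equal(rr$r, cor(x, y), tolerance = 1e-12)
    expect_true(abs(rr$r) <= 1)
    expect_true(rr$conf_low <= rr$r && rr$r <= rr$conf_high)
  }
  expect_error(size_time_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(size_time_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("synthetic homotypic events place the coupling target inside the CI", {
  hits <- vapply(1:50, function(s) {
    ev <- simulate_fusion_events(cfg, n_homotypic = 37, seed = 3000 + s)
    ct <- size_time_correlation(ev)
    ct$conf_low <= 0.60 && 0.60 <= ct$conf_high
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Mann-Whitney exact branch equals brute-force enumeration", {
  ## definitional examples
  m1 <- compare_size_distributions(c(1, 2), c(3, 4))
  expect_equal(m1$U, 0)
  expect_equal(m1$p_value, 1 / 3, tolerance = 1e-12)
  m2 <- compare_size_distributions(c(1, 3), c(2, 4))
  expect_equal(m2$U, 1)
  expect_equal(m2$p_value, 2 / 3, tolerance = 1e-12)

  ## independent oracle: count pairwise wins over all group assignments
  brute <- function(x, y) {
    pool <- c(x, y); n1 <- length(x)
    U_of <- function(xs, ys)
      sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    U_obs <- U_of(x, y)
    idx <- utils::combn(length(pool), n1)
    Uall <- apply(idx, 2, function(i) U_of(pool[i], pool[-i]))
    mu <- n1 * length(y) / 2
    lo <- min(U_obs, 2 * mu - U_obs); hi <- max(U_obs, 2 * mu - U_obs)
    list(U = U_obs,
         p = (sum(Uall <= lo + 1e-9) + sum(Uall >= hi - 1e-9)) / length(Uall))
  }
  set.seed(11)
  for (i in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:4, 1)
    x <- sample(1:6, n1, replace = TRUE)   # ties included
    y <- sample(1:6, n2, replace = TRUE)
    got <- compare_size_distributions(x, y)
    want <- brute(x, y)
    expect_equal(got$U, want$U, tolerance = 1e-12)
    expect_equal(got$p_value, min(want$p, 1), tolerance = 1e-12)
    if (!any(duplicated(c(x, y)))) {
      wt <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
      expect_equal(got$p_value, wt$p.value, tolerance = 1e-9)
    }
  }
})

test_that("Mann-Whitney large-sample branch handles identical samples", {
  x <- rep(1:20, 3)
  m <- compare_size_distributions(x, x)
  expect_equal(m$U, length(x)^2 / 2)
  expect_equal(m$p_value, 1)
  ## no-tie large samples against the reference implementation
  set.seed(2)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  got <- compare_size_distributions(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(compare_size_distributions(numeric(0), 1), "non-empty")
})

test_that("size distributions of fusing and total vesicles are comparable", {
  tot <- simulate_population(cfg, 265, "5min", seed = 21)
  fus <- simulate_population(cfg, 37, "fused_homotypic", seed = 22)
  m <- compare_size_distributions(fus, tot)
  expect_gt(m$p_value, 0.001)   # same-family populations: no strong difference
})

test_that("FRAP fitting recovers preset half-times within 5 percent", {
  for (cond in c("cell_surface", "apical")) {
    est <- vapply(1:50, function(s) {
      fit_frap(simulate_frap(cfg, cond, seed = s))$t_half_crossing
    }, numeric(1))
    expect_lt(abs(median(est) / cfg$frap$presets[cond] - 1), 0.05)
  }
})

test_that("degenerate FRAP inputs are flagged rather than fitted", {
  cv <- simulate_frap(cfg, "cell_surface", seed = 1)
  ## flat post-bleach curve: no recovery, undefined half-time
  flat <- data.frame(time_s = cv$time_s,
                     roi = ifelse(cv$time_s < 0, 1000, 250),
                     background = 50, whole_cell = 5000)
  ff <- fit_frap(flat)
  expect_false(ff$reached_half)
  expect_true(is.na(ff$t_half_crossing))
  ## insufficient sampling
  expect_error(fit_frap(cv[cv$time_s >= -1, ]), "pre-bleach")
  expect_error(fit_frap(cv[cv$time_s <= 2, ]), "post-bleach")
  expect_error(fit_frap(cv[, c("time_s", "roi")]), "missing columns")
  ## non-monotone whole-cell channel triggers a warning
  bad <- cv
  bad$whole_cell[50] <- bad$whole_cell[50] * 2
  expect_warning(fit_frap(bad), "non-monotone")
})

test_that("perimeter-region shares are exact on analytic intensity fields", {
  th <- seq(0, 2 * pi, length.out = 1441)[-1441]
  circ <- cbind(cos(th), sin(th))
  u <- region_intensity_profile(circ, c(1, 0), rep(1, length(th)))
  expect_equal(unname(u), rep(100 / 3, 3), tolerance = 0.5)
  expect_equal(sum(u), 100, tolerance = 1e-9)
  ## all intensity at the distal pole
  spot <- as.numeric(abs(th - pi) < 0.01)
  d <- region_intensity_profile(circ, c(1, 0), spot)
  expect_equal(unname(d), c(0, 0, 100), tolerance = 1e-9)
  ## wrapped Gaussian patch at the distal pole, sigma = 20 degrees
  sg <- 20 * pi / 180
  g <- exp(-((th - pi)^2) / (2 * sg^2))
  shares <- region_intensity_profile(circ, c(1, 0), g)
  distal_frac <- (pnorm(pi + pi / 3, pi, sg) - pnorm(pi - pi / 3, pi, sg)) /
    (pnorm(2 * pi, pi, sg) - pnorm(0, pi, sg))
  expect_lt(abs(shares["distal"] - 100 * distal_frac), 2)
  ## shares always sum to 100 on irregular outlines
  set.seed(9)
  for (i in 1:5) {
    rr <- 1 + 0.3 * sin(3 * th + runif(1, 0, 2 * pi))
    poly <- cbind(rr * cos(th), rr * sin(th))
    s <- region_intensity_profile(poly, c(runif(1, -1, 1), runif(1, -1, 1)),
                                  runif(length(th), 0.1, 1))
    expect_equal(sum(s), 100, tolerance = 1e-9)
  }
  expect_error(region_intensity_profile(circ[1:2, ], c(1, 0), 1:2), "degenerate")
  expect_error(region_intensity_profile(circ, c(0, 0), rep(1, length(th))),
               "non-zero")
})

test_that("the end-to-end pipeline recovers generator kinetics", {
  dur_h <- dur_t <- numeric(0)
  freq_ratio <- numeric(0)
  for (s in 1:12) {
    tr <- simulate_tracks(cfg, 30, "mixed", seed = 500 + s)
    truth <- attr(tr, "truth")
    det <- detect_fusion_events(tr)
    dur_h <- c(dur_h, det$duration_s[det$type == "homotypic"])
    dur_t <- c(dur_t, det$duration_s[det$type == "heterotypic"])
    if (nrow(truth) > 0)
      freq_ratio <- c(freq_ratio, nrow(det) / nrow(truth))
  }
  sem_h <- sd(dur_h) / sqrt(length(dur_h))
  sem_t <- sd(dur_t) / sqrt(length(dur_t))
  expect_lt(abs(mean(dur_h) - 31.9), max(2 * sem_h, 1))
  expect_lt(abs(mean(dur_t) - 154.8), max(2 * sem_t, 3))
  ## detected fusion frequency within 10% of the planted one
  expect_lt(abs(mean(freq_ratio) - 1), 0.1)
})
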