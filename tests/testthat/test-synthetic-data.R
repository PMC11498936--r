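cfg <- fusion_generator_config(seed = 1)

test_that("size populations are moment-matched log-normals", {
  s <- simulate_population(cfg, 1e5, "5min", seed = 1)
  expect_lt(abs(mean(s) / 5.7 - 1), 0.01)
  expect_lt(abs(sd(s) / 6.4 - 1), 0.03)
  s15 <- simulate_population(cfg, 1e5, "15min", seed = 1)
  expect_lt(abs(mean(s15) / 10.1 - 1), 0.01)
  expect_true(all(s > 0))
  ## degenerate SD: all values equal the mean
  cfg0 <- cfg; cfg0$population[["5min"]]["sd"] <- 0
  expect_equal(simulate_population(cfg0, 10, "5min"), rep(5.7, 10))
  ## determinism and seed sensitivity
  expect_identical(simulate_population(cfg, 100, seed = 7),
                   simulate_population(cfg, 100, seed = 7))
  expect_false(identical(simulate_population(cfg, 100, seed = 7),
                         simulate_population(cfg, 100, seed = 8)))
  expect_error(simulate_population(cfg, 10, "nonsense"), "time point")
})

test_that("fusion-event copula hits the target size-duration coupling", {
  ev <- simulate_fusion_events(cfg, n_homotypic = 1e4, seed = 2)
  expect_lt(abs(cor(ev$size_um2, ev$duration_s) - 0.60), 0.03)
  expect_lt(abs(mean(ev$duration_s) - 31.9), 0.05)
  eh <- simulate_fusion_events(cfg, n_heterotypic = 1e4, seed = 2)
  expect_lt(abs(cor(eh$size_um2, eh$duration_s)), 0.03)
  expect_lt(abs(mean(eh$duration_s) - 154.8), 0.3)
  expect_true(all(ev$duration_s > 0))
  ## near-perfect coupling: rank-preserving monotone map
  cfg99 <- cfg; cfg99$homotypic$r <- 0.999
  e99 <- simulate_fusion_events(cfg99, n_homotypic = 2000, seed = 3)
  expect_gt(cor(e99$size_um2, e99$duration_s, method = "spearman"), 0.99)
  cfg_bad <- cfg; cfg_bad$homotypic$r <- 1
  expect_error(simulate_fusion_events(cfg_bad, n_homotypic = 5), "\\|r\\| < 1")
  ## empty request
  e0 <- simulate_fusion_events(cfg)
  expect_equal(nrow(e0), 0)
})

test_that("the range-calibrated duration preset widens the spread", {
  cfg_r <- fusion_generator_config(seed = 1, duration_sd = "range")
  expect_equal(cfg_r$homotypic$sd_s, 7)
  expect_equal(cfg$homotypic$sd_s, 0.2 * sqrt(37))
  ev <- simulate_fusion_events(cfg_r, n_homotypic = 2000, seed = 4)
  expect_gt(sd(ev$duration_s), 5)
})

test_that("track tables carry the planted fusion signatures", {
  tr <- simulate_tracks(cfg, 30, "mixed", seed = 42)
  truth <- attr(tr, "truth")
  expect_true(all(c("frame", "time_s", "track_id", "x_um", "y_um",
                    "area_um2", "intensity", "zone", "parent_ids") %in% names(tr)))
  expect_true(all(tr$area_um2 > 0))
  ## time strictly increasing within each track
  expect_true(all(tapply(tr$time_s, tr$track_id, function(x) all(diff(x) > 0))))
  ## merged child area equals the parent sum within noise
  hom <- truth[truth$type == "homotypic", ]
  for (i in seq_len(nrow(hom))) {
    ids <- as.integer(strsplit(hom$track_ids[i], ";")[[1]])
    child <- tr[tr$track_id == hom$child_id[i], ]
    psum <- sum(vapply(ids, function(id) {
      d <- tr[tr$track_id == id, ]; d$area_um2[nrow(d)]
    }, numeric(1)))
    expect_lt(abs(child$area_um2[1] / psum - 1), 0.1)
  }
  ## determinism
  tr2 <- simulate_tracks(cfg, 30, "mixed", seed = 42)
  expect_identical(tr, tr2)
  ## no events planted in the quiescent scenario
  tn <- simulate_tracks(cfg, 20, "none", seed = 5)
  expect_equal(nrow(attr(tn, "truth")), 0)
  expect_equal(nrow(detect_fusion_events(tn)), 0)
  ## configuration errors
  cfg_hot <- cfg; cfg_hot$homotypic$rate_per_vesicle_min <- 5
  expect_error(simulate_tracks(cfg_hot, 10, "homotypic", seed = 1),
               "event rate too high")
})

test_that("planted events are recovered with high sensitivity and low FDR", {
  sens <- fdr <- numeric(50)
  for (s in 1:50) {
    tr <- simulate_tracks(cfg, 30, "mixed", seed = 1000 + s)
    sc <- score_events(detect_fusion_events(tr), attr(tr, "truth"))
    sens[s] <- sc$sensitivity
    fdr[s] <- sc$false_discovery_rate
  }
  expect_gte(mean(sens, na.rm = TRUE), 0.95)
  expect_lte(mean(fdr), 0.05)
})

test_that("FRAP curves are constructed so the correction is exactly invertible", {
  cfg0 <- cfg
  cfg0$frap$noise_sd <- 0
  cfg0$frap$lambda_acq <- 0
  cv <- simulate_frap(cfg0, "cell_surface", t_half_s = 15, seed = 1)
  ff <- fit_frap(cv)
  expect_lt(abs(ff$t_half_crossing - 15), cfg$frap$dt_s)
  expect_lt(abs(ff$t_half_fit - 15), 0.05)
  ## with acquisition photobleaching the whole-cell channel recovers it
  cfg1 <- cfg; cfg1$frap$noise_sd <- 0
  cv1 <- simulate_frap(cfg1, "cell_surface", t_half_s = 15, seed = 1)
  ff1 <- fit_frap(cv1)
  expect_lt(abs(ff1$t_half_fit - 15), 0.1)
  ## determinism and unknown conditions
  expect_identical(simulate_frap(cfg, "apical", seed = 3),
                   simulate_frap(cfg, "apical", seed = 3))
  expect_error(simulate_frap(cfg, "nonsense"), "unknown FRAP condition")
  tt <- attr(simulate_frap(cfg, "basal", seed = 1), "truth")
  expect_equal(tt$t_half_s, 18.9)
})

test_that("generator tables serialise to plain-text formats", {
  tr <- simulate_tracks(cfg, 10, "homotypic", seed = 2)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".json")
  f3 <- tempfile(fileext = ".csv")
  write_tracks_tsv(tr, f1)
  back <- read.delim(f1)
  expect_equal(nrow(back), nrow(tr))
  write_truth_json(tr, f2)
  js <- jsonlite::read_json(f2, simplifyVector = TRUE)
  expect_equal(nrow(js), nrow(attr(tr, "truth")))
  write_frap_csv(simulate_frap(cfg, "RV", seed = 1), f3)
  expect_named(read.csv(f3), c("time_s", "roi", "background", "whole_cell"))
  unlink(c(f1, f2, f3))
})
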