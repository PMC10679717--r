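test_that("degenerate retention models pin the coefficients", {
  ramp <- standard_ramp()
  frozen <- synth_score_series(20, ramp, retention_model(0), seed = 1)
  expect_true(all(frozen$ifp_cs == -1))
  expect_equal(ms_coefficient(frozen), 0)
  expect_equal(iff_coefficient(frozen), 0)
  expect_equal(nrow(frozen), 1600)

  blown <- synth_score_series(20, ramp, retention_model(1e6), seed = 1)
  expect_equal(max(blown$step), 1)
  expect_equal(ms_coefficient(blown), 1)
  expect_error(retention_model(-1), "non-negative")
  expect_error(synth_score_series(20, ramp, retention_model(0.1),
                                  stride = 0.3), "divide")
})

test_that("generators are bit-reproducible for a fixed seed", {
  ramp <- build_ramp(300, 360, 10, 2)
  m <- retention_model(0.05, lambda = 0.01)
  expect_identical(synth_score_series(15, ramp, m, seed = 5),
                   synth_score_series(15, ramp, m, seed = 5))
  p1 <- make_pose_panel(4)
  p2 <- make_pose_panel(4)
  expect_identical(p1$k0, p2$k0)
  expect_identical(run_pose_panel(p1, ramp, n_replicates = 2, seed = 3),
                   run_pose_panel(p2, ramp, n_replicates = 2, seed = 3))
})

test_that("mean termination step matches a high-replicate brute-force oracle", {
  ramp <- standard_ramp()
  model <- retention_model(0.05, alpha = 0.02, t_ref = 300)
  stride <- 0.1
  # package path, 200 seeds
  term_pkg <- vapply(1:200, function(s)
    max(synth_score_series(20, ramp, model, seed = s)$step), 0L)
  # oracle: vectorised first-passage sampling over the same per-frame
  # hazard schedule; termination = first step whose trailing 10% of frames
  # have no surviving native bit
  nf <- round(ramp$duration / stride)
  k <- model$k0 * exp(model$alpha * (ramp$temperature - model$t_ref))
  cum <- cumsum(rep(k * stride, times = nf))     # per-frame cumulative hazard
  n_frames <- length(cum)
  step_end <- cumsum(nf)
  win <- lapply(seq_len(nrow(ramp)), function(i)
    (step_end[i] - ceiling(0.1 * nf[i]) + 1):step_end[i])
  set.seed(123456)
  n_rep <- 20000L; n_bits <- 20L
  term_oracle <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    u <- -log(runif(n_bits))                     # unit-exponential lifetimes
    dies <- findInterval(u, cum) + 1L            # first frame each bit is dead
    alive <- n_bits - cumsum(tabulate(pmin(dies, n_frames + 1L),
                                      nbins = n_frames + 1L))[1:n_frames]
    sc <- -sqrt(alive / n_bits)                  # cosine vs all-native ref
    stop_at <- nrow(ramp)
    for (i in seq_len(nrow(ramp)))
      if (mean(sc[win[[i]]]) > -0.05) { stop_at <- i; break }
    term_oracle[r] <- stop_at
  }
  expect_lt(abs(mean(term_pkg) - mean(term_oracle)), 1)
})

test_that("expected MS never decreases when the loss rate grows", {
  ramp <- build_ramp(300, 450, 30, 2)     # coarse ramp keeps this cheap
  grid <- c(0.01, 0.05, 0.25)
  stats <- lapply(grid, function(k0) {
    ms <- vapply(1:200, function(s)
      ms_coefficient(synth_score_series(15, ramp, retention_model(k0),
                                        seed = 7000 + s)), 0)
    c(mean = mean(ms), se = sd(ms) / sqrt(length(ms)))
  })
  for (i in seq_len(length(grid) - 1)) {
    lo <- stats[[i]]; hi <- stats[[i + 1]]
    expect_gt(hi["mean"] - lo["mean"], -2 * sqrt(lo["se"]^2 + hi["se"]^2))
  }
})

test_that("the toy engine is deterministic and freezes at 0 K", {
  ts <- toy_system()
  cx <- ts$complex
  lay <- build_layout(cx, select_binding_site(cx, 6.0))
  ramp <- build_ramp(300, 320, 10, 1)
  eng <- toy_engine(ts)
  cfg <- engine_config("production", temperature = 300, duration = 1,
                       stride = 0.1, seed = 42)
  run1 <- eng$run(cfg, list(coords = cx$reference_coords))
  run2 <- eng$run(cfg, list(coords = cx$reference_coords))
  expect_identical(run1$frames, run2$frames)

  cold <- engine_config("production", temperature = 0, duration = 1,
                        stride = 0.1, seed = 42)
  frames <- eng$run(cold, list(coords = cx$reference_coords))$frames
  lig <- which(cx$atoms$is_ligand)
  drift <- max(vapply(frames, function(f) sqrt(sum(f[lig, ]^2)), 0))
  expect_lt(drift, 1e-6)   # stays at the well minimum
  ref_fp <- fingerprint(cx$reference_coords, cx, lay)
  for (f in frames[c(1, 5, 10)])
    expect_identical(as.integer(fingerprint(f, cx, lay)),
                     as.integer(ref_fp))
})

test_that("deeper binding wells yield lower mean MS (Kramers ordering)", {
  ramp <- build_ramp(300, 440, 20, 1)
  mean_ms <- function(depth, seeds) {
    ts <- toy_system(well_depth = depth)
    lay <- build_layout(ts$complex, select_binding_site(ts$complex, 6.0))
    mean(vapply(seeds, function(s)
      ms_coefficient(run_titration(toy_engine(ts), ts$complex, lay, ramp,
                                   seed = s)$scores), 0))
  }
  seeds <- 1:50
  deep <- mean_ms(4.0, seeds)
  shallow <- mean_ms(1.0, seeds)
  expect_lt(deep, shallow)
})

test_that("identical pose models are statistically indistinguishable", {
  ramp <- standard_ramp()
  panel <- make_pose_panel(2, k0_range = c(0.05, 0.0500001))
  co <- run_pose_panel(panel, ramp, n_replicates = 5, seed = 21)
  agg <- aggregate_replicates(co, value = "ms")
  diff <- abs(agg$trim_mean[1] - agg$trim_mean[2])
  expect_lt(diff, max(agg$trim_error))
})

test_that("the synthetic pipeline drives every public operation end to end", {
  # coordinate-level path: toy engine through the full protocol
  ts <- toy_system(well_depth = 2.0)
  cx <- ts$complex
  site <- select_binding_site(cx, 6.0)
  lay <- build_layout(cx, site)
  ramp <- build_ramp(300, 340, 20, 1)
  res <- run_titration(toy_engine(ts), cx, lay, ramp, seed = 2,
                       keep_frames = TRUE)
  expect_s3_class(titration_profile(res), "tbl_df")
  expect_gt(nrow(tidy(res)), 0)
  dres <- dry_run(toy_engine(ts), cx, ramp, seed = 2)
  expect_null(dres$scores)
  cfgs <- emit_preparation_configs(cx)
  expect_length(cfgs, 3)

  # trajectory + fingerprint export plumbing
  traj <- ttmd:::new_trajectory(res$frames,
                                times = seq_along(res$frames) * 0.1)
  fps <- fingerprint_frames(traj, cx, lay)
  expect_equal(ncol(fps), nrow(lay))
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_fingerprints(fps, csv); write_fingerprints(fps, jsn)
  expect_true(file.exists(csv) && file.exists(jsn))

  # score-level path into aggregation, ranking and reports
  panel <- make_pose_panel(3)
  co <- run_pose_panel(panel, ramp, n_replicates = 3, seed = 5)
  ranked <- rank_poses(aggregate_replicates(co, value = "ms"))
  expect_equal(nrow(ranked), 3)
  out <- withr::local_tempdir()
  files <- write_result_csv(res, out)
  expect_true(all(file.exists(file.path(out, c("timeline.csv",
                                               "profile.csv",
                                               "provenance.json")))))
})
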