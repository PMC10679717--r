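test_that("ramp arithmetic and preconditions", {
  std <- build_ramp(300, 450, 10, 10)
  expect_equal(nrow(std), 16)
  expect_equal(std$temperature, seq(300, 450, 10))
  expect_equal(sum(std$duration), 160)
  alt <- build_ramp(73, 223, 10, 10)
  expect_equal(nrow(alt), 16)
  expect_identical(standard_ramp(), std)
  expect_identical(alternative_ramp(), alt)
  expect_error(build_ramp(300, 455, 10, 10), "divisible")
  expect_error(build_ramp(300, 450, -5, 10), "positive")
  expect_error(build_ramp(450, 300, 10, 10), "exceed")
  pre <- protocol_preset(4)
  expect_equal(pre$metric, "iff")
  expect_equal(pre$ramp$temperature[1], 73)
})

test_that("the early-termination rule averages the trailing window strictly", {
  expect_false(should_terminate(rep(-0.5, 100)))
  expect_true(should_terminate(c(rep(-1, 90), rep(-0.01, 10))))
  # boundary equality continues the run
  expect_false(should_terminate(rep(-0.05, 100)))
  expect_true(should_terminate(rep(-0.049999, 100)))
  # window is the ceiling of fraction * n trailing frames
  x <- c(rep(-1, 95), rep(0, 5))          # last 10 frames average -0.5
  expect_false(should_terminate(x))
  expect_true(should_terminate(x, fraction = 0.05))
  expect_error(should_terminate(numeric(0)), "empty")
})

test_that("a contact-preserving engine completes the ramp with MS ~ 0", {
  ts <- toy_system()
  cx <- ts$complex
  lay <- build_layout(cx, select_binding_site(cx, 6.0))
  eng <- scripted_engine(function(step, frame) cx$reference_coords)
  ramp <- standard_ramp()
  res <- run_titration(eng, cx, lay, ramp, seed = 1)
  expect_false(res$terminated_early)
  expect_equal(res$steps_completed, 16)
  expect_true(all(res$scores$ifp_cs == -1))
  expect_lt(abs(ms_coefficient(res$scores)), 1e-9)
  expect_equal(iff_coefficient(res$scores), 0)
})

test_that("breaking all contacts at step 3 terminates early at T_3", {
  ts <- toy_system()
  cx <- ts$complex
  lay <- build_layout(cx, select_binding_site(cx, 6.0))
  lig <- cx$atoms$is_ligand
  eng <- scripted_engine(function(step, frame) {
    co <- cx$reference_coords
    if (step >= 3) co[lig, ] <- co[lig, ] + 60
    co
  })
  ramp <- standard_ramp()
  res <- run_titration(eng, cx, lay, ramp, seed = 1)
  expect_true(res$terminated_early)
  expect_equal(res$steps_completed, 3)
  expect_equal(res$last_temperature, ramp$temperature[3])
  expect_equal(max(res$scores$step), 3)
  # MS convention: last completed step mean is 0 at T = 320
  expect_equal(ms_coefficient(res$scores), 1 / 20)
})

test_that("step temperatures reach the engine exactly and in ramp order", {
  ts <- toy_system()
  cx <- ts$complex
  lay <- build_layout(cx, select_binding_site(cx, 6.0))
  seen <- new.env(); seen$temps <- numeric()
  eng <- new_engine(function(config, state) {
    seen$temps <- c(seen$temps, config$temperature)
    list(frames = list(cx$reference_coords),
         state = state)
  })
  ramp <- build_ramp(300, 350, 10, 1)
  run_titration(eng, cx, lay, ramp, seed = 1, stride = 1)
  expect_identical(seen$temps, ramp$temperature)
})

test_that("an unreachable threshold never terminates a run early", {
  set.seed(31)
  for (i in 1:5) {
    ramp <- build_ramp(300, 340, 10, 1)
    s <- synth_score_series(10, ramp, retention_model(0.8), seed = i,
                            threshold = 0)
    expect_equal(max(s$step), nrow(ramp))
  }
})

test_that("identical seeds reproduce the score series bit for bit", {
  ts <- toy_system(well_depth = 1.5)
  cx <- ts$complex
  lay <- build_layout(cx, select_binding_site(cx, 6.0))
  ramp <- build_ramp(300, 340, 20, 1)
  r1 <- run_titration(toy_engine(ts), cx, lay, ramp, seed = 11)
  r2 <- run_titration(toy_engine(ts), cx, lay, ramp, seed = 11)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$rmsd, r2$rmsd)
  r3 <- run_titration(toy_engine(ts), cx, lay, ramp, seed = 12)
  expect_false(identical(r1$scores$ifp_cs, r3$scores$ifp_cs) &&
                 identical(r1$rmsd$rmsd_ligand, r3$rmsd$rmsd_ligand))
})

test_that("a zero-interaction reference is refused", {
  ts <- toy_system()
  cx <- ts$complex
  cx$flags$hydrophobe[] <- FALSE   # strip all annotations
  lay <- build_layout(cx, select_binding_site(cx, 6.0))
  expect_error(
    run_titration(toy_engine(ts), cx, lay, build_ramp(300, 310, 10, 1)),
    "reference fingerprint")
})

test_that("preparation configs encode the two-stage equilibration protocol", {
  ts <- toy_system()
  cfgs <- emit_preparation_configs(ts$complex)
  expect_length(cfgs, 3)
  expect_equal(vapply(cfgs, function(x) x$stage, ""),
               c("minimize", "nvt_restrained", "npt_restrained"))
  expect_equal(cfgs[[1]]$steps, 500)
  expect_equal(cfgs[[2]]$restraint$force_constant, 5)
  expect_equal(cfgs[[2]]$duration, 0.5)
  expect_equal(cfgs[[3]]$pressure, 1)
  expect_equal(cfgs[[3]]$restraint$selection, "ligand+backbone")
  for (cfg in cfgs) {
    expect_equal(cfg$timestep, 2)
    expect_equal(cfg$cutoff, 9.0)
    expect_equal(cfg$solvation$padding, 15)
    expect_equal(cfg$solvation$salt_concentration, 0.154)
  }
})

test_that("receptor-only structures load for dry runs", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- guanine_fixture_atoms()
  write_pdb_fixture(atoms[!atoms$is_ligand, ], path)
  cx <- read_complex(path, ligand = NULL)
  expect_false(any(cx$atoms$is_ligand))
  static <- scripted_engine(function(step, frame) cx$reference_coords)
  res <- dry_run(static, cx, build_ramp(300, 320, 10, 1), seed = 1)
  expect_null(res$scores)
  expect_true(all(is.na(res$rmsd$rmsd_ligand)))
  expect_lt(max(res$rmsd$rmsd_backbone), 1e-9)
})

test_that("the dry run skips scoring, never terminates, and tracks plasticity", {
  ts <- toy_system()
  cx <- ts$complex
  ramp <- build_ramp(300, 390, 10, 1)
  static <- scripted_engine(function(step, frame) cx$reference_coords)
  res <- dry_run(static, cx, ramp, seed = 1)
  expect_null(res$scores)
  expect_false(res$terminated_early)
  expect_equal(res$steps_completed, nrow(ramp))
  expect_lt(max(res$rmsd$rmsd_backbone), 1e-9)
  expect_lt(max(res$rmsd$rmsd_site), 1e-9)

  # isotropic noise doubling each step: mean site RMSD grows with step index
  noisy <- local({
    level <- new.env(); level$s <- 0
    new_engine(function(config, state) {
      level$s <- level$s + 1
      set.seed(config$seed)
      frames <- lapply(1:10, function(f)
        cx$reference_coords +
          matrix(rnorm(nrow(cx$atoms) * 3, sd = 0.1 * 2^(level$s - 1)),
                 ncol = 3))
      list(frames = frames, state = state)
    })
  })
  res2 <- dry_run(noisy, cx, build_ramp(300, 350, 10, 1), seed = 2)
  mean_site <- tapply(res2$rmsd$rmsd_site, res2$rmsd$step, mean)
  expect_true(all(diff(mean_site) > 0))
})
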