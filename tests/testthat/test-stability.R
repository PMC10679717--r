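series_of <- function(scores, per_step, t0 = 300, dT = 10) {
  step <- rep(seq_len(length(scores) / per_step), each = per_step)
  score_series(scores, step, t0 + dT * (step - 1))
}

test_that("ifp_cs worked values, bounds and invariances", {
  expect_equal(ifp_cs(c(1, 1, 0), c(1, 1, 0)), -1)
  expect_equal(ifp_cs(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(ifp_cs(c(1, 1, 0), c(1, 0, 1)), -0.5)
  expect_equal(ifp_cs(c(0, 0), c(1, 1)), 0)    # all-zero convention
  expect_error(ifp_cs(c(1, 0), c(1, 0, 1)), "mismatch")
  set.seed(5)
  for (i in 1:50) {
    a <- rbinom(30, 1, 0.4); b <- rbinom(30, 1, 0.4)
    expect_equal(ifp_cs(a, b), ifp_cs(b, a))
    expect_true(ifp_cs(a, b) >= -1 - 1e-12 && ifp_cs(a, b) <= 0)
    k <- runif(1, 0.1, 9)
    expect_equal(ifp_cs(k * a, b), ifp_cs(a, b), tolerance = 1e-12)
  }
})

test_that("ifp_cs equals an independent cosine computation on random vectors", {
  set.seed(99)
  worst <- 0
  for (i in 1:10000) {
    n <- sample(4:40, 1)
    a <- rbinom(n, 1, runif(1, 0.1, 0.9))
    b <- rbinom(n, 1, runif(1, 0.1, 0.9))
    # plain-arithmetic oracle
    dot <- 0; na <- 0; nb <- 0
    for (k in seq_len(n)) {
      dot <- dot + a[k] * b[k]; na <- na + a[k]^2; nb <- nb + b[k]^2
    }
    want <- if (na == 0 || nb == 0) 0 else -dot / (sqrt(na) * sqrt(nb))
    worst <- max(worst, abs(ifp_cs(a, b) - want))
  }
  expect_lt(worst, 1e-12)
})

test_that("step means follow the titration profile construction", {
  s <- series_of(rep(-1, 10), per_step = 10)
  expect_equal(step_means(s)$mean_ifp_cs, -1)
  s2 <- series_of(c(-1, 0), per_step = 2)
  expect_equal(step_means(s2)$mean_ifp_cs, -0.5)
  s3 <- series_of(rep(-0.8, 160), per_step = 10)
  expect_equal(nrow(step_means(s3)), 16)
  expect_equal(step_means(s3)$temperature, seq(300, 450, 10))
})

test_that("MS coefficient follows the slope formula and its conventions", {
  # full standard ramp, last step fully native -> 0
  full <- series_of(rep(-1, 160), per_step = 10)
  expect_equal(ms_coefficient(full), 0)
  # termination after step 2 with last-step mean 0 -> 0.1
  two <- series_of(c(rep(-1, 10), rep(0, 10)), per_step = 10)
  expect_equal(ms_coefficient(two), 0.1)
  # analogous published values at steps 3 and 4
  expect_equal(ms_coefficient(series_of(c(rep(-1, 20), rep(0, 10)), 10)), 0.05)
  expect_equal(ms_coefficient(series_of(c(rep(-1, 30), rep(0, 10)), 10)),
               1 / 30)
  # first-step termination -> 1 by convention
  one <- series_of(rep(-0.01, 10), per_step = 10)
  expect_equal(ms_coefficient(one), 1)
  # clamped to [0, 1]
  set.seed(8)
  for (i in 1:25) {
    ns <- sample(1:16, 1)
    s <- series_of(-runif(ns * 10), per_step = 10)
    m <- ms_coefficient(s)
    expect_true(m >= 0 && m <= 1)
  }
})

test_that("IFF is the RMS fluctuation about the whole-run mean", {
  expect_equal(iff_coefficient(rep(-0.4, 50)), 0)
  expect_equal(iff_coefficient(c(-1, 0)), 0.5)
  expect_equal(iff_coefficient(c(-1, -0.5, 0)), sqrt(1 / 6),
               tolerance = 1e-12)
  # brute-force arithmetic oracle on random series; bounded by 0.5
  set.seed(21)
  for (i in 1:50) {
    x <- -runif(sample(5:200, 1))
    m <- sum(x) / length(x)
    acc <- 0
    for (v in x) acc <- acc + (v - m)^2
    expect_equal(iff_coefficient(x), sqrt(acc / length(x)),
                 tolerance = 1e-12)
    expect_lte(iff_coefficient(x), 0.5)
  }
})

test_that("trimmed aggregation handles ties, missing values and errors", {
  st <- trim_stats(c(0.00759, 0.00909, 0.01960, 0.01667, 0.00514))
  expect_lt(abs(st$trim_mean - 0.01112), 1e-5)
  expect_lt(abs(st$trim_error - 0.00554), 1.1e-5)
  st2 <- trim_stats(c(1, NA, 1, 1, 0.0333))
  expect_equal(st2$trim_mean, 1)
  expect_lt(abs(st2$trim_error - 0.41859), 1e-5)
  expect_equal(st2$n_used, 2)
  st3 <- trim_stats(rep(0.7, 5))
  expect_equal(st3$trim_mean, 0.7)
  expect_equal(st3$trim_error, 0)
  expect_error(trim_stats(c(1, NA, NA, NA, 2)), ">= 3")
})

test_that("pose ranking orders by trimmed mean with stable ties", {
  d <- tibble::tibble(pose_id = rep(c("a", "b", "c"), each = 3),
                      value = c(0.004, 0.004, 0.004,
                                0.001, 0.001, 0.001,
                                0.3, 0.3, 0.3))
  ranked <- rank_poses(aggregate_replicates(d))
  expect_equal(ranked$pose_id, c("b", "a", "c"))
  single <- rank_poses(aggregate_replicates(
    tibble::tibble(pose_id = "only", value = c(1, 2, 3))))
  expect_equal(nrow(single), 1)
})

test_that("published per-replicate tables aggregate to their printed summaries", {
  bench <- benchmark_replicates()
  vals <- as.matrix(bench[, c("md1", "md2", "md3", "md4", "md5")])
  stats <- apply(vals, 1, trim_stats)
  err_mean <- abs(vapply(stats, `[[`, 0, "trim_mean") - bench$trim_mean)
  err_sd <- abs(vapply(stats, `[[`, 0, "trim_error") - bench$trim_error)
  # agreement to the printed precision (inputs themselves are 5-decimal)
  expect_lt(max(err_mean), 1.1e-5)
  expect_lt(max(err_sd), 1.1e-5)
  # the well-resolved aptamer panel ranks native-like poses above wrong ones
  p2 <- bench[bench$protocol == 2 & bench$system == "5BJO", ]
  ranked <- rank_poses(aggregate_replicates(
    tidyr::pivot_longer(p2[, c("pose", "md1", "md2", "md3", "md4", "md5")],
                        -1, values_to = "value"),
    pose = "pose"))
  top <- ranked$pose_id[1:3]
  expect_true(all(c("crystal", "1") %in% top))
  expect_true(which(ranked$pose_id == "4") < which(ranked$pose_id == "2"))
  expect_true(which(ranked$pose_id == "4") < which(ranked$pose_id == "5"))
})
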