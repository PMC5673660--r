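# Resampling engine and the sampling experiments.

make_pool <- function(n = 40, n_cells = 5, seed = 99) {
  set.seed(seed)
  make_subject_beeps("pool", n,
    what = sample(context_levels("what"), n, replace = TRUE),
    who = sample(context_levels("who"), n, replace = TRUE),
    pa_items = sample(1:7, n, replace = TRUE)
  )
}

test_that("resample_spec validates its design", {
  spec <- resample_spec(sizes = c(10, 20), replicates = 5, seed = 3)
  expect_s3_class(spec, "resample_spec")
  expect_error(resample_spec(sizes = c(20, 10)), "increasing")
  expect_error(resample_spec(sizes = integer(0)), "increasing")
  expect_error(resample_spec(replicates = 0), "replicates")
})

test_that("auto replacement permutes at the pool size and contains beyond it", {
  pool <- make_pool(15)
  set.seed(1)
  perm <- draw_sample(pool, 15, "auto")
  expect_equal(
    as.data.frame(perm[order(perm$day, perm$beep), ]),
    as.data.frame(pool[order(pool$day, pool$beep), ])
  )
  set.seed(2)
  big <- draw_sample(pool, 150, "auto")
  expect_equal(nrow(big), 150)
  expect_true(all(big$what %in% pool$what))
  set.seed(7)
  a <- draw_sample(pool, 10)
  set.seed(7)
  b <- draw_sample(pool, 10)
  expect_identical(a, b)
  expect_error(draw_sample(pool, 0), ">= 1")
  expect_error(draw_sample(pool[0, ], 5), "empty")
})

test_that("run_experiment summarizes replicate distributions correctly", {
  pool <- make_pool(30)
  spec <- resample_spec(sizes = c(5, 10), replicates = 50, seed = 4)

  const <- run_experiment(pool, function(d) 7, spec)
  expect_equal(const$mean, c(7, 7))
  expect_equal(const$sd, c(0, 0))
  expect_equal(const$min, const$max)

  sizes <- run_experiment(pool, nrow, spec)
  expect_equal(sizes$mean, c(5, 10))

  # law of large numbers on the sample mean of pool PA values
  pool$pa <- compute_pa(pool)
  lln_spec <- resample_spec(sizes = 20, replicates = 400, seed = 5, replacement = "always")
  lln <- run_experiment(pool, function(d) mean(d$pa), lln_spec)
  mcse <- lln$sd / sqrt(lln$replicates)
  expect_lt(abs(lln$mean - mean(pool$pa)), 3 * mcse)
})

test_that("failed replicates are skipped with warning, many failures abort", {
  pool <- make_pool(20)
  spec <- resample_spec(sizes = 10, replicates = 50, seed = 8)
  flaky <- function(d) if (sum(d$cheerful) %% 17 == 0) stop("bad") else 1
  expect_warning(res <- run_experiment(pool, flaky, spec), "failed")
  expect_lt(res$replicates, 50)
  expect_error(
    suppressWarnings(run_experiment(pool, function(d) stop("no"), spec)),
    "10%"
  )
})

test_that("summaries obey sem = sd/sqrt(N) and min <= mean <= max", {
  pool <- make_pool(60)
  spec <- resample_spec(sizes = c(10, 25), replicates = 60, seed = 6)
  res <- experiment_unique_settings(pool, "WWW", spec)
  expect_equal(res$sem, res$sd / sqrt(res$size))
  expect_true(all(res$min <= res$mean & res$mean <= res$max))
})

test_that("unique-setting means stay below the ceiling and saturate onto it", {
  pool <- make_pool(50)
  pool_unique <- count_unique_settings(add_settings(pool, "WWW")$setting)
  spec <- resample_spec(
    sizes = c(5, 20, 50, 400), replicates = 150, seed = 9
  )
  res <- experiment_unique_settings(pool, "WWW", spec)
  expect_true(all(res$mean <= pmin(res$size, pool_unique) + 1e-9))
  expect_true(all(diff(res$mean) >= -3 * sqrt(sum((res$sd / sqrt(res$replicates))^2))))
  # under auto replacement, N at the pool size captures every setting;
  # far beyond it the mean sits at the ceiling
  expect_equal(res$mean[res$size == 50], pool_unique)
  expect_equal(res$mean[res$size == 400], pool_unique, tolerance = 0.01)

  one <- make_subject_beeps("s", 12)
  res1 <- experiment_unique_settings(one, "WWW", resample_spec(sizes = c(2, 6), replicates = 20, seed = 2))
  expect_equal(res1$mean, c(1, 1))
})

test_that("bootstrap unique-setting counts match the closed-form occupancy oracle", {
  pool <- make_pool(40, seed = 123)
  keys <- add_settings(pool, "W")$setting
  p <- as.vector(table(keys)) / length(keys)
  spec <- resample_spec(sizes = c(4, 12), replicates = 600, seed = 10, replacement = "always")
  res <- experiment_unique_settings(pool, "W", spec)
  for (i in seq_len(nrow(res))) {
    expected <- oracle_expected_unique(p, res$size[i])
    mcse <- res$sd[i] / sqrt(res$replicates[i])
    expect_lt(abs(res$mean[i] - expected), 3 * mcse)
    # replacement effect: strictly below the pool's occupied count
    expect_lt(res$mean[i], length(p))
  }
})

test_that("rqol spread stays bounded with mean near zero and reruns byte-identically", {
  pool <- make_pool(80, seed = 321)
  spec <- resample_spec(sizes = c(20, 60), replicates = 80, seed = 11)
  res <- experiment_rqol_spread(pool, "WWW", 0.5, spec)
  expect_setequal(
    unique(res$statistic),
    c("rqol_mean", "rqol_sd", "rqol_min", "rqol_max")
  )
  expect_true(all(abs(res$mean[res$statistic == "rqol_mean"]) < 0.25))
  expect_true(all(res$max[res$statistic == "rqol_max"] <= 3))
  expect_true(all(res$min[res$statistic == "rqol_min"] >= -3))
  rerun <- experiment_rqol_spread(pool, "WWW", 0.5, spec)
  expect_identical(res, rerun)
})

test_that("adding sizes to the grid does not perturb existing replicates", {
  pool <- make_pool(50, seed = 55)
  short <- experiment_unique_settings(pool, "WW", resample_spec(sizes = c(10, 30), replicates = 40, seed = 12))
  long <- experiment_unique_settings(pool, "WW", resample_spec(sizes = c(10, 20, 30), replicates = 40, seed = 12))
  expect_equal(
    as.data.frame(long[long$size %in% c(10, 30), ]),
    as.data.frame(short),
    ignore_attr = TRUE
  )
})

test_that("PA-rQoL correlations are computed per replicate, degenerate pools abort", {
  pool <- make_pool(100, seed = 77)
  spec <- resample_spec(sizes = c(20, 80), replicates = 60, seed = 13)
  res <- experiment_pa_rqol_correlation(pool, "WW", 0.5, spec)
  expect_true(all(res$min >= -1 & res$max <= 1))
  # replicate spread narrows with N
  expect_lt(
    res$max[res$size == 80] - res$min[res$size == 80],
    res$max[res$size == 20] - res$min[res$size == 20]
  )
  flat <- make_subject_beeps("s", 30,
    what = sample(context_levels("what"), 30, replace = TRUE)
  )
  expect_error(
    suppressWarnings(
      experiment_pa_rqol_correlation(flat, "W", 0.5, resample_spec(sizes = 10, replicates = 20, seed = 1))
    ),
    "10%"
  )
})

test_that("percentile subjects are selected by occupied-setting rank", {
  set.seed(41)
  low <- make_subject_beeps("low", 31,
    what = sample(context_levels("what")[1:2], 31, replace = TRUE)
  ) # at most 2 settings
  mid <- make_subject_beeps("mid", 40,
    what = sample(context_levels("what"), 40, replace = TRUE),
    who = sample(context_levels("who")[1:3], 40, replace = TRUE)
  )
  high <- make_subject_beeps("high", 55,
    what = sample(context_levels("what"), 55, replace = TRUE),
    who = sample(context_levels("who"), 55, replace = TRUE),
    where = sample(context_levels("where"), 55, replace = TRUE)
  )
  data <- dplyr::bind_rows(low, mid, high)
  spec <- resample_spec(sizes = c(20, 40, 60, 80, 100), replicates = 60, seed = 14)
  res <- experiment_subject_percentiles(data, c(5, 50, 95), "WWW", spec = spec)
  expect_setequal(unique(res$subject_id), c("low", "mid", "high"))
  expect_equal(unique(res$subject_id[res$percentile == 5]), "low")
  expect_equal(unique(res$subject_id[res$percentile == 95]), "high")

  us <- res[res$statistic == "unique_settings", ]
  low_occ <- unique(res$occupied_settings[res$subject_id == "low"])
  expect_true(all(us$mean[us$subject_id == "low"] <= low_occ))
  # low-variability subject's curve is nearly flat; high-variability rises
  low_rise <- diff(range(us$mean[us$subject_id == "low"]))
  high_rise <- diff(range(us$mean[us$subject_id == "high"]))
  expect_lt(low_rise, 1.5)
  expect_gt(high_rise, low_rise + 2)

  expect_error(
    experiment_subject_percentiles(low, c(5, 50, 95), "WWW", spec = spec),
    "fewer subjects"
  )
})
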