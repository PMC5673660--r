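# Monte Carlo resampling engine and the four sampling experiments.
#
# Each experiment draws `replicates` virtual-subject beep sets of size N from
# a pool of moments, evaluates a statistic inside each set (the resampled set
# IS the analysis unit: affect centering and setting frequencies are computed
# within it) and summarizes the replicate distribution per N. Replicate RNG
# streams are derived from the master seed together with the experiment name,
# the sample size and the replicate index, so runs are reproducible and adding
# sizes to the grid does not perturb existing replicates.

#' Resampling design
#'
#' @param sizes Strictly increasing sample sizes (numbers of beeps drawn per
#'   virtual subject). The default grid spans 20 to 10,000.
#' @param replicates Samples drawn per size (default 1000).
#' @param seed Master seed for the whole experiment.
#' @param replacement `"auto"` draws without replacement while `n` does not
#'   exceed the pool and with replacement beyond it; `"always"` is a pure
#'   bootstrap.
#' @return A `resample_spec` list.
#' @export
resample_spec <- function(sizes = c(
                            20, 40, 60, 80, 100, 250, 500, 750,
                            1000, 2000, 3000, 4000, 8000, 10000
                          ),
                          replicates = 1000L, seed = 1L,
                          replacement = c("auto", "always")) {
  replacement <- match.arg(replacement)
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || any(sizes < 1L) || is.unsorted(sizes, strictly = TRUE)) {
    stop("sizes must be strictly increasing integers >= 1", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  structure(
    list(
      sizes = sizes, replicates = replicates, seed = seed,
      replacement = replacement
    ),
    class = "resample_spec"
  )
}

# deterministic 31-bit substream seed from (master seed, experiment, N, rep)
.substream_seed <- function(seed, experiment, size, replicate) {
  h <- 5381
  for (code in utf8ToInt(paste(experiment, size, replicate, sep = ":"))) {
    h <- (h * 33 + code) %% 2147483647
  }
  h <- (h + (abs(as.numeric(seed)) %% 2147483647) * 48271) %% 2147483647
  as.integer(max(h, 1))
}

.draw_indices <- function(n_pool, n, replacement) {
  if (n < 1L) stop("sample size must be >= 1", call. = FALSE)
  replace <- replacement == "always" || n > n_pool
  sample.int(n_pool, n, replace = replace)
}

#' Draw one virtual-subject sample from a pool of moments
#'
#' Uses the current RNG state; set a seed beforehand for reproducibility.
#' Under `"auto"` replacement the draw is a subsample (a permutation when `n`
#' equals the pool size) and switches to with-replacement only when `n`
#' exceeds the available observations.
#'
#' @param pool Tibble of moments.
#' @param n Number of beeps to draw.
#' @param replacement `"auto"` or `"always"`, see [resample_spec()].
#' @return Tibble of `n` drawn rows.
#' @export
draw_sample <- function(pool, n, replacement = c("auto", "always")) {
  replacement <- match.arg(replacement)
  if (nrow(pool) == 0L) stop("pool is empty", call. = FALSE)
  pool[.draw_indices(nrow(pool), n, replacement), , drop = FALSE]
}

# shared engine: eval_fun(idx) returns a named numeric vector of statistics
# for one replicate, or signals an error (replicate skipped with a warning;
# more than 10% failures at any size aborts the experiment).
.run_mc <- function(n_pool, eval_fun, spec, experiment) {
  rows <- list()
  for (size in spec$sizes) {
    vals <- NULL
    failed <- 0L
    for (r in seq_len(spec$replicates)) {
      set.seed(.substream_seed(spec$seed, experiment, size, r))
      idx <- .draw_indices(n_pool, size, spec$replacement)
      v <- tryCatch(eval_fun(idx), error = function(e) NULL)
      if (is.null(v)) {
        failed <- failed + 1L
        next
      }
      if (is.null(vals)) {
        vals <- matrix(NA_real_, spec$replicates, length(v),
          dimnames = list(NULL, names(v))
        )
      }
      vals[r, ] <- v
    }
    if (failed > 0L) {
      warning(
        experiment, ": ", failed, " of ", spec$replicates,
        " replicates failed at N = ", size,
        call. = FALSE
      )
    }
    if (failed > 0.1 * spec$replicates || is.null(vals)) {
      stop(
        experiment, ": more than 10% of replicates failed at N = ", size,
        call. = FALSE
      )
    }
    keep <- stats::complete.cases(vals)
    for (stat in colnames(vals)) {
      x <- vals[keep, stat]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        experiment = experiment, statistic = stat, size = size,
        replicates = sum(keep),
        mean = mean(x), sd = sd(x), sem = sd(x) / sqrt(size),
        min = min(x), max = max(x)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Run a custom resampling experiment
#'
#' Draws `spec$replicates` samples at every size in `spec$sizes` and
#' summarizes `statistic` over the replicate distribution. The `sem` column
#' follows the convention `sd / sqrt(N)` with `N` the sample size.
#'
#' @param pool Tibble of moments.
#' @param statistic Function taking a tibble of drawn moments and returning a
#'   single number. A replicate where it signals an error is skipped with a
#'   warning; more than 10% failures at a size aborts.
#' @param spec A [resample_spec()].
#' @param experiment Label written into the summary rows.
#' @return Tidy summary tibble: one row per (statistic, size) with
#'   `replicates`, `mean`, `sd`, `sem`, `min`, `max`.
#' @export
run_experiment <- function(pool, statistic, spec = resample_spec(),
                           experiment = "custom") {
  if (nrow(pool) == 0L) stop("pool is empty", call. = FALSE)
  .run_mc(
    nrow(pool),
    function(idx) c(statistic = as.numeric(statistic(pool[idx, , drop = FALSE]))),
    spec, experiment
  )
}

.pool_codes <- function(pool, definition) {
  if (!"setting" %in% names(pool)) {
    pool <- add_settings(pool, definition)
  }
  f <- factor(pool$setting)
  list(codes = as.integer(f), nbins = nlevels(f), pool = pool)
}

#' Unique-setting saturation experiment
#'
#' Tracks the number of distinct behavior settings occupied by a virtual
#' subject as a function of sample size. The mean rises steeply at small N,
#' slows, and plateaus at the pool's occupied-setting count (saturation).
#'
#' @param pool Beep tibble (raw context or `setting` column present).
#' @param definition Setting granularity.
#' @param spec A [resample_spec()].
#' @return Tidy summary tibble, statistic `"unique_settings"`.
#' @export
experiment_unique_settings <- function(pool, definition = c("WWW", "WW", "W"),
                                       spec = resample_spec()) {
  definition <- match.arg(definition)
  pc <- .pool_codes(pool, definition)
  .run_mc(
    nrow(pc$pool),
    function(idx) {
      c(unique_settings = sum(tabulate(pc$codes[idx], nbins = pc$nbins) > 0L))
    },
    spec, paste0("unique_settings_", definition)
  )
}

#' rQoL spread experiment
#'
#' Scores every replicate as a virtual subject (centering and setting
#' frequencies computed within the replicate) and tracks the mean, standard
#' deviation, minimum and maximum of the rQoL scores per replicate.
#'
#' @param pool Beep tibble with affect (items or `pa`) and context.
#' @param definition Setting granularity.
#' @param cutoff Cumulative-proportion cut point, see [compute_rqol()].
#' @param spec A [resample_spec()].
#' @return Tidy summary tibble, statistics `"rqol_mean"`, `"rqol_sd"`,
#'   `"rqol_min"`, `"rqol_max"`.
#' @export
experiment_rqol_spread <- function(pool, definition = c("WWW", "WW", "W"),
                                   cutoff = 0.5, spec = resample_spec()) {
  definition <- match.arg(definition)
  pc <- .pool_codes(pool, definition)
  if (!"pa" %in% names(pc$pool)) pc$pool$pa <- compute_pa(pc$pool)
  pa <- pc$pool$pa
  .run_mc(
    nrow(pc$pool),
    function(idx) {
      r <- .rqol_codes(pa[idx], pc$codes[idx], pc$nbins, cutoff)
      c(
        rqol_mean = mean(r), rqol_sd = sd(r),
        rqol_min = min(r), rqol_max = max(r)
      )
    },
    spec, paste0("rqol_spread_", definition)
  )
}

#' PA-rQoL correlation experiment
#'
#' Per replicate, the Pearson correlation between PA and rQoL is computed
#' within the resampled virtual subject. Replicates with zero variance in
#' either series are skipped with a warning.
#'
#' @inheritParams experiment_rqol_spread
#' @return Tidy summary tibble, statistic `"pearson_r"`.
#' @export
experiment_pa_rqol_correlation <- function(pool, definition = c("WWW", "WW", "W"),
                                           cutoff = 0.5, spec = resample_spec()) {
  definition <- match.arg(definition)
  pc <- .pool_codes(pool, definition)
  if (!"pa" %in% names(pc$pool)) pc$pool$pa <- compute_pa(pc$pool)
  pa <- pc$pool$pa
  .run_mc(
    nrow(pc$pool),
    function(idx) {
      r <- .rqol_codes(pa[idx], pc$codes[idx], pc$nbins, cutoff)
      c(pearson_r = pearson_r(pa[idx], r))
    },
    spec, paste0("pa_rqol_correlation_", definition)
  )
}

#' Contextual-variability percentile subjects experiment
#'
#' Ranks included subjects by their number of occupied settings (contextual
#' variability), selects the subjects at the requested percentiles by the
#' nearest-rank method, and runs the unique-setting and rQoL-spread
#' experiments on each selected subject's own beeps as the pool. With real
#' protocol lengths these pools are small, so larger sizes resample with
#' replacement.
#'
#' @param data Beep tibble of several subjects (already validity-filtered, or
#'   raw; rows failing [validate_beeps()] are dropped).
#' @param percentiles Percentiles of the variability ranking (default 5, 50,
#'   95 -- low, average, high variability).
#' @param definition Setting granularity used for ranking and experiments.
#' @param cutoff Cut point for the rQoL spread runs.
#' @param spec A [resample_spec()]; the default grid uses the small sizes 20,
#'   40, 60, 80, 100 appropriate for single-subject pools.
#' @return Tidy summary tibble with `percentile`, `subject_id` and
#'   `occupied_settings` columns joined to the experiment summaries.
#' @export
experiment_subject_percentiles <- function(data, percentiles = c(5, 50, 95),
                                           definition = c("WWW", "WW", "W"),
                                           cutoff = 0.5,
                                           spec = resample_spec(sizes = c(20, 40, 60, 80, 100))) {
  definition <- match.arg(definition)
  data <- data[validate_beeps(data), , drop = FALSE]
  data <- add_settings(data, definition)
  occ <- dplyr::summarise(dplyr::group_by(data, .data$subject_id),
    occupied = dplyr::n_distinct(.data$setting), .groups = "drop"
  )
  occ <- occ[order(occ$occupied, occ$subject_id), ]
  n_subj <- nrow(occ)
  if (n_subj < length(unique(percentiles))) {
    stop("fewer subjects (", n_subj, ") than distinct percentiles", call. = FALSE)
  }
  ranks <- pmax(1L, ceiling(percentiles / 100 * n_subj)) # nearest rank
  out <- list()
  for (k in seq_along(percentiles)) {
    subj <- occ$subject_id[ranks[k]]
    pool <- data[data$subject_id == subj, , drop = FALSE]
    tag <- paste0("p", percentiles[k])
    su <- experiment_unique_settings(pool, definition, spec)
    sr <- experiment_rqol_spread(pool, definition, cutoff, spec)
    res <- dplyr::bind_rows(su, sr)
    res$percentile <- percentiles[k]
    res$subject_id <- subj
    res$occupied_settings <- occ$occupied[ranks[k]]
    res$experiment <- paste0(res$experiment, "_", tag)
    out[[k]] <- res
  }
  dplyr::bind_rows(out)
}
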