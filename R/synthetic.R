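# Synthetic ESM beep generator.
#
# Emulates the statistical profile of a 23-subject severe-mental-illness seed
# sample: ~48 valid beeps per subject (SD 9, truncated to the protocol range),
# overall PA mean 4.0 / SD 1.41 with between-subject SD 0.99, a skewed
# (Zipf-like) setting-frequency distribution with roughly half the pooled
# occurrence mass in a few frequent cells, pooled occupied WWW cells well
# below the 216 possible (~113), and per-subject occupied-setting counts
# spanning roughly 5 to 28. Optionally, affect is shifted with the cumulative
# occurrence proportion of the current setting (`reward_effect`), giving a
# positive-control dataset with known effect size.

# latent affect SDs are inflated relative to the observed targets because
# rounding items to the Likert grid and clipping at 1 and 7 shrink observed
# dispersion; factors fixed by one-off calibration against the targets.
.latent_between_infl <- 1.061
.latent_within_infl <- 1.046
.item_noise_sd <- 0.9

#' Configuration of the synthetic beep generator
#'
#' @param n_subjects Number of subjects (default 23).
#' @param beeps_mean,beeps_sd,beeps_range Valid beeps per subject: normal with
#'   this mean and SD, truncated to the range (default 48, 9, `c(20, 60)`).
#' @param pa_mean,pa_sd Target overall PA mean and SD (default 4.0, 1.41).
#' @param pa_between_sd Target SD of subject PA means (default 0.99).
#' @param context_concentration Zipf exponent of the within-subject setting
#'   distribution over the subject's support cells (default 0.6).
#' @param pool_concentration Zipf exponent of the pool-level cell popularity
#'   from which subject supports are drawn, so frequent cells are shared
#'   across subjects (default 1.0).
#' @param subject_variability_range Range of target per-subject occupied
#'   WWW-setting counts; targets are drawn log-uniformly inside it (default
#'   `c(5, 28)`).
#' @param reward_effect Latent PA shift per unit of `cp - 0.5` of the beep's
#'   WWW setting; 0 generates affect independent of context.
#' @param mqol_r Target order of magnitude of the correlation between the
#'   momentary-QoL item and PA (default 0.35; a convention, not a
#'   reproduction of any observed value).
#' @param missing_rate Proportion of all beeps rendered invalid (default 0.1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 23L,
                             beeps_mean = 48, beeps_sd = 9,
                             beeps_range = c(20, 60),
                             pa_mean = 4.0, pa_sd = 1.41, pa_between_sd = 0.99,
                             context_concentration = 0.6,
                             pool_concentration = 1.0,
                             subject_variability_range = c(5, 28),
                             reward_effect = 0, mqol_r = 0.35,
                             missing_rate = 0.1, seed = NULL) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), beeps_mean = beeps_mean,
    beeps_sd = beeps_sd, beeps_range = beeps_range, pa_mean = pa_mean,
    pa_sd = pa_sd, pa_between_sd = pa_between_sd,
    context_concentration = context_concentration,
    pool_concentration = pool_concentration,
    subject_variability_range = subject_variability_range,
    reward_effect = reward_effect, mqol_r = mqol_r,
    missing_rate = missing_rate, seed = seed
  )
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (cfg$beeps_sd < 0 || cfg$pa_sd < 0 || cfg$pa_between_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  svr <- cfg$subject_variability_range
  if (length(svr) != 2L || svr[1] < 1 || svr[2] < svr[1] || svr[2] > 216) {
    stop("subject_variability_range must lie within [1, 216]", call. = FALSE)
  }
  if (any(cfg$beeps_range < 1) || cfg$beeps_range[2] < cfg$beeps_range[1]) {
    stop("beeps_range must be an increasing positive range", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

.rtruncnorm1 <- function(mean, sd, range) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) {
      return(x)
    }
  }
}

# expected occupied cells after n draws from Zipf(a) over s cells
.expected_occupied <- function(s, a, n) {
  p <- (seq_len(s))^(-a)
  p <- p / sum(p)
  sum(1 - (1 - p)^n)
}

# smallest Zipf support giving expected occupancy >= target at n beeps
.support_for_target <- function(target, a, n, max_s = 216L) {
  for (s in seq(max(1L, ceiling(target)), max_s)) {
    if (.expected_occupied(s, a, n) >= target) {
      return(s)
    }
  }
  max_s
}

.clip_likert <- function(x) as.integer(pmin(7, pmax(1, round(x))))

# raw-category preimages of the collapsed vocabularies
.who_preimage <- function() split(names(.who_collapse), unname(.who_collapse))
.what_preimage <- function() split(names(.what_collapse), unname(.what_collapse))

.uncollapse <- function(values, preimage) {
  vapply(values, function(v) {
    opts <- preimage[[v]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic beep dataset
#'
#' Per subject, draws a Zipf-like context distribution over Who-What-Where
#' cells (support cells sampled from a shared pool-level popularity ranking,
#' support size solved from the occupancy identity so the expected occupied
#' count matches the subject's variability target), then draws beeps from it.
#' Latent affect is a subject mean plus within-subject noise, optionally
#' shifted by `reward_effect * (cp - 0.5)` of the beep's setting; the four PA
#' items add independent item noise and are rounded and clipped to the 1..7
#' Likert grid. The momentary-QoL item shares the latent affect so it
#' correlates moderately with PA. A `missing_rate` share of beeps is rendered
#' invalid by blanking answers.
#'
#' @param config A [synthetic_config()].
#' @return Beep tibble in canonical columns (see [read_beeps()]), with the
#'   generating configuration attached as attribute `"config"`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  space <- context_space(collapsed = TRUE) # canonical popularity order
  gw <- (seq_len(nrow(space)))^(-config$pool_concentration)
  a <- config$context_concentration
  svr <- config$subject_variability_range

  lat_between <- config$pa_between_sd * .latent_between_infl
  lat_within <- sqrt(max(config$pa_sd^2 - config$pa_between_sd^2, 0.04)) *
    .latent_within_infl

  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    n_valid <- as.integer(round(
      .rtruncnorm1(config$beeps_mean, max(config$beeps_sd, 1e-9), config$beeps_range)
    ))
    target <- exp(runif(1, log(svr[1]), log(svr[2])))
    support_size <- .support_for_target(target, a, n_valid)
    support <- sort(sample.int(nrow(space), support_size, prob = gw))
    w <- (seq_len(support_size))^(-a)
    cells <- support[sample.int(support_size, n_valid, replace = TRUE, prob = w / sum(w))]

    # cp of each beep's WWW setting within this subject's valid beeps
    f <- factor(cells)
    cp <- .cp_codes(as.integer(f), nlevels(f))

    mu <- config$pa_mean + rnorm(1, 0, lat_between)
    latent <- mu + config$reward_effect * (cp - 0.5) + rnorm(n_valid, 0, lat_within)
    items <- vapply(
      seq_len(4),
      function(k) .clip_likert(latent + rnorm(n_valid, 0, .item_noise_sd)),
      integer(n_valid)
    )
    # mqol shares the latent affect; loading and noise sized so the pooled
    # correlation with PA lands near the configured order of magnitude
    load <- config$mqol_r * 0.95
    mqol <- .clip_likert(
      config$pa_mean + load * (latent - config$pa_mean) +
        rnorm(n_valid, 0, 1.3)
    )

    n_invalid <- min(
      60L - n_valid,
      as.integer(round(n_valid * config$missing_rate / (1 - config$missing_rate)))
    )
    n_total <- n_valid + n_invalid
    slot <- sort(sample.int(60L, n_total))
    valid_pos <- sort(sample.int(n_total, n_valid))

    sub <- tibble::tibble(
      subject_id = subjects[i],
      day = (slot - 1L) %/% 10L + 1L,
      beep = (slot - 1L) %% 10L + 1L,
      cheerful = NA_integer_, satisfied = NA_integer_, relaxed = NA_integer_,
      enthusiastic = NA_integer_, mqol = NA_integer_,
      who = NA_character_, what = NA_character_, where = NA_character_,
      completed = FALSE
    )
    sub$cheerful[valid_pos] <- items[, 1]
    sub$satisfied[valid_pos] <- items[, 2]
    sub$relaxed[valid_pos] <- items[, 3]
    sub$enthusiastic[valid_pos] <- items[, 4]
    sub$mqol[valid_pos] <- mqol
    sub$who[valid_pos] <- .uncollapse(space$who[cells], .who_preimage())
    sub$what[valid_pos] <- .uncollapse(space$what[cells], .what_preimage())
    sub$where[valid_pos] <- space$where[cells]
    sub$completed[valid_pos] <- TRUE

    # invalid beeps carry partial answers: each field blanked independently,
    # at least one always missing
    inval <- setdiff(seq_len(n_total), valid_pos)
    if (length(inval)) {
      extra_cells <- support[sample.int(support_size, length(inval),
        replace = TRUE, prob = w / sum(w)
      )]
      part_items <- mu + rnorm(length(inval), 0, lat_within)
      fields <- c(pa_item_cols, "mqol", "who", "what", "where")
      for (j in seq_along(inval)) {
        r <- inval[j]
        sub$cheerful[r] <- .clip_likert(part_items[j] + rnorm(1, 0, .item_noise_sd))
        sub$satisfied[r] <- .clip_likert(part_items[j] + rnorm(1, 0, .item_noise_sd))
        sub$relaxed[r] <- .clip_likert(part_items[j] + rnorm(1, 0, .item_noise_sd))
        sub$enthusiastic[r] <- .clip_likert(part_items[j] + rnorm(1, 0, .item_noise_sd))
        sub$mqol[r] <- .clip_likert(part_items[j] + rnorm(1, 0, 1.2))
        sub$who[r] <- .uncollapse(space$who[extra_cells[j]], .who_preimage())
        sub$what[r] <- .uncollapse(space$what[extra_cells[j]], .what_preimage())
        sub$where[r] <- space$where[extra_cells[j]]
        drop <- fields[runif(length(fields)) < 0.3]
        if (!length(drop)) drop <- sample(fields, 1L)
        for (col in drop) sub[[col]][r] <- if (col %in% c("who", "what", "where")) NA_character_ else NA_integer_
      }
    }
    rows[[i]] <- sub
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "provenance") <- paste0(
    "synthetic (seed ",
    if (is.null(config$seed)) "none" else config$seed, ")"
  )
  attr(out, "config") <- config
  out
}

#' Generate a null dataset (affect independent of context)
#'
#' As [generate_dataset()] with `reward_effect` forced to 0, for mean-zero
#' checks of the reward function.
#'
#' @inheritParams generate_dataset
#' @export
generate_null_dataset <- function(config = synthetic_config()) {
  config$reward_effect <- 0
  generate_dataset(config)
}

#' Generate a positive-control dataset with a known reward effect
#'
#' As [generate_dataset()] with `reward_effect = effect`: frequent settings
#' elicit systematically higher latent affect, so grand-mean rQoL is positive
#' and the effect is recoverable by [estimate_reward_effect()].
#'
#' @inheritParams generate_dataset
#' @param effect Positive latent PA shift per unit of `cp - 0.5`.
#' @export
generate_reward_dataset <- function(config = synthetic_config(), effect) {
  stopifnot(is.numeric(effect), length(effect) == 1L, effect > 0)
  config$reward_effect <- effect
  generate_dataset(config)
}
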