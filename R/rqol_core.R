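# The reward function: rQoL = zPA x (cp - cutoff).
#
# zPA is positive affect centered on the person's own mean, so it measures
# momentary deviation from that person's usual mood. cp is the cumulative
# occurrence proportion of the moment's behavior setting within the person's
# own data (ascending-frequency cumulation), so frequent settings sit above
# the cutoff and rare settings below it. A positive product means reward
# efficiency: feeling better than usual in a frequent context, or worse than
# usual in a rare one.

#' Within-person centering of positive affect
#'
#' Subtracts the person's own mean PA from each moment. Positive values mark
#' better-than-usual mental states. Optionally also divides by the person's PA
#' standard deviation; the default is centering only, matching the definition
#' of the reward function.
#'
#' @param pa Numeric vector of PA scores of one analysis unit (a subject, or
#'   one resampled virtual subject).
#' @param standardize Also divide by the standard deviation (default `FALSE`).
#' @return Numeric vector of centered (optionally standardized) scores.
#' @export
#' @examples
#' center_pa(c(3, 5)) # -1, +1
center_pa <- function(pa, standardize = FALSE) {
  if (length(pa) == 0L) {
    stop("cannot center an empty PA series", call. = FALSE)
  }
  out <- pa - mean(pa)
  if (standardize) {
    s <- sd(pa)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize a constant PA series", call. = FALSE)
    }
    out <- out / s
  }
  out
}

# fast scorer on bare vectors; codes are integer setting codes in
# lexicographic level order (see .cp_codes)
.rqol_codes <- function(pa, codes, nbins, cutoff) {
  (pa - mean(pa)) * (.cp_codes(codes, nbins) - cutoff)
}

#' Score moments with the rQoL reward function
#'
#' For each analysis unit the PA mean and the setting frequency table are
#' computed from that unit's own moments, then every moment is scored as
#' `rqol = zpa * (cp - cutoff)`. With `unit = "subject"` each subject is an
#' analysis unit (the use for real diary data); with `unit = "pool"` all rows
#' form a single virtual subject (the use inside resampling experiments).
#'
#' @param data Beep tibble. Needs either a `setting` column (see
#'   [add_settings()]) or raw `who`/`what`/`where` columns, and either a `pa`
#'   column or the four affect items.
#' @param definition Setting granularity used when `setting` is absent.
#' @param cutoff Cumulative-proportion cut point separating low- from
#'   high-frequency settings, in (0, 1); default 0.5, the value found sensitive
#'   enough for meaningful detection.
#' @param unit `"subject"` or `"pool"`.
#' @param standardize Standardize instead of center PA (default `FALSE`).
#' @return Tibble with one row per moment: `subject_id`, `moment`, `pa`,
#'   `zpa`, `setting`, `cp`, `rqol`.
#' @export
compute_rqol <- function(data, definition = c("WWW", "WW", "W"), cutoff = 0.5,
                         unit = c("subject", "pool"), standardize = FALSE) {
  definition <- match.arg(definition)
  unit <- match.arg(unit)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must be a single number strictly between 0 and 1", call. = FALSE)
  }
  if (nrow(data) == 0L) {
    stop("no moments to score", call. = FALSE)
  }
  if (!"setting" %in% names(data)) {
    data <- add_settings(data, definition)
  }
  if (!"pa" %in% names(data)) {
    data$pa <- compute_pa(data)
  }
  group <- if (unit == "subject") data$subject_id else rep("pool", nrow(data))
  parts <- lapply(split(seq_len(nrow(data)), group), function(idx) {
    pa <- data$pa[idx]
    keys <- data$setting[idx]
    zpa <- center_pa(pa, standardize = standardize)
    cp <- setting_cp(keys)
    tibble::tibble(
      subject_id = data$subject_id[idx],
      moment = seq_along(idx),
      pa = pa, zpa = zpa, setting = keys, cp = cp,
      rqol = zpa * (cp - cutoff)
    )
  })
  out <- dplyr::bind_rows(parts)
  attr(out, "definition") <- definition
  attr(out, "cutoff") <- cutoff
  out
}

#' Pearson product-moment correlation
#'
#' Thin, validated wrapper around the standard product-moment correlation,
#' used to relate PA with rQoL and rQoL with the momentary-QoL item.
#'
#' @param x,y Numeric vectors of equal length, at least 3, each with nonzero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a zero-variance series", call. = FALSE)
  }
  cor(x, y)
}

#' Estimate the reward effect from scored moments
#'
#' Regression slope of centered PA on the within-person centered
#' cumulative-proportion weight `cp - cutoff`. Within-person centering of the
#' predictor removes between-subject differences in mean cp, so the slope
#' estimates the common within-person affect shift per unit of cp. Used for
#' parameter-recovery checks against the synthetic generator.
#'
#' @param scored Output of [compute_rqol()].
#' @return Slope estimate (numeric scalar).
#' @export
estimate_reward_effect <- function(scored) {
  cpc <- scored$cp - ave(scored$cp, scored$subject_id)
  if (sd(cpc) == 0) {
    stop("no within-person variation in cp; effect not identifiable", call. = FALSE)
  }
  unname(coef(lm(scored$zpa ~ cpc))[2])
}
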