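# Behavior-setting encoding and occurrence-frequency tables.
#
# A behavior setting is the categorical context of a beep. Three granularities
# are supported: W (activity only, 6 cells), WW (persons x activity, 36 cells)
# and WWW (persons x activity x location, 216 cells). Occurrence proportions
# are cumulated in ascending-frequency order, so rare settings receive low
# cumulative proportions and the most frequent setting always reaches 1.

setting_definitions <- c("W", "WW", "WWW")

#' Collapse raw context categories to the 6-level vocabularies
#'
#' Persons: "partner" joins "resident family" and "colleagues" joins
#' "acquaintances". Activities: "resting" joins "nothing" and
#' "household/groceries" joins "hygiene". Locations are unchanged.
#'
#' @param who,what,where Character vectors of raw categories (recycled to a
#'   common length).
#' @return Tibble with columns `who6`, `what6`, `where6`.
#' @export
#' @examples
#' collapse_context("partner", "hygiene", "home")
collapse_context <- function(who, what, where) {
  n <- max(length(who), length(what), length(where))
  who <- rep_len(who, n)
  what <- rep_len(what, n)
  where <- rep_len(where, n)
  bad <- !(who %in% who_levels_raw) | !(what %in% what_levels_raw) |
    !(where %in% where_levels)
  if (any(bad)) {
    stop("unknown raw context categor(ies), e.g. row ", which(bad)[1],
      ": (", who[which(bad)[1]], ", ", what[which(bad)[1]], ", ",
      where[which(bad)[1]], ")",
      call. = FALSE
    )
  }
  tibble::tibble(
    who6 = unname(.who_collapse[who]),
    what6 = unname(.what_collapse[what]),
    where6 = where
  )
}

#' Encode behavior-setting keys
#'
#' Builds a deterministic, injective key per context tuple under the chosen
#' granularity: `"W"` uses the activity only, `"WW"` persons and activity,
#' `"WWW"` persons, activity and location.
#'
#' @param who6,what6,where6 Collapsed categories (see [collapse_context()]).
#'   `who6` is ignored under `"W"`; `where6` under `"W"` and `"WW"`.
#' @param definition `"W"`, `"WW"` or `"WWW"`.
#' @return Character vector of setting keys.
#' @export
#' @examples
#' encode_setting("friends", "relaxation", "public place", "WWW")
encode_setting <- function(who6, what6, where6 = NULL,
                           definition = c("WWW", "WW", "W")) {
  definition <- match.arg(definition)
  if (!all(what6 %in% what_levels6)) {
    stop("unknown collapsed activity categor(ies)", call. = FALSE)
  }
  if (definition == "W") {
    return(what6)
  }
  if (!all(who6 %in% who_levels6)) {
    stop("unknown collapsed person categor(ies)", call. = FALSE)
  }
  if (definition == "WW") {
    return(paste(who6, what6, sep = " | "))
  }
  if (is.null(where6) || !all(where6 %in% where_levels)) {
    stop("unknown or missing collapsed location categor(ies)", call. = FALSE)
  }
  paste(who6, what6, where6, sep = " | ")
}

#' Add collapsed context and setting keys to a beep tibble
#'
#' @param data Beep tibble with raw `who`, `what`, `where` columns.
#' @param definition Setting granularity, see [encode_setting()].
#' @return `data` with `who6`, `what6`, `where6` and `setting` columns added.
#' @export
add_settings <- function(data, definition = c("WWW", "WW", "W")) {
  definition <- match.arg(definition)
  ctx <- collapse_context(data$who, data$what, data$where)
  data$who6 <- ctx$who6
  data$what6 <- ctx$what6
  data$where6 <- ctx$where6
  data$setting <- encode_setting(ctx$who6, ctx$what6, ctx$where6, definition)
  attr(data, "definition") <- definition
  data
}

# cumulative proportions from integer setting codes; codes must be assigned in
# lexicographic key order so tie-breaking matches frequency_table(). Returns
# the cp of each moment's setting. Tied frequencies all receive the cumulative
# value at the end of their tied block.
.cp_codes <- function(codes, nbins) {
  cnt <- tabulate(codes, nbins = nbins)
  occ <- which(cnt > 0L)
  ord <- occ[order(cnt[occ], occ)]
  prop <- cnt[ord] / length(codes)
  cum <- cumsum(prop)
  cum <- ave(cum, cnt[ord], FUN = max)
  cp <- rep(NA_real_, nbins)
  cp[ord] <- cum
  cp[codes]
}

#' Occurrence-frequency table of behavior settings
#'
#' Tallies setting keys, orders them by ascending proportion (ties broken by
#' lexicographic key order) and cumulates proportions along that order. Keys
#' tied on frequency all receive the cumulative value at the end of their tied
#' block, so an arbitrary rank order among ties cannot change any score. The
#' most frequent setting always has cumulative proportion 1; rare settings sit
#' low in the cumulative distribution.
#'
#' @param keys Character vector of setting keys for the analysis unit (one
#'   subject, or one resampled virtual subject).
#' @param definition Optional granularity label stored as an attribute.
#' @return Tibble with columns `setting`, `count`, `proportion`,
#'   `cum_proportion`, ordered by ascending frequency; attributes `n_total`
#'   and `definition`.
#' @export
#' @examples
#' frequency_table(c("a", "a", "a", "b"))
frequency_table <- function(keys, definition = NULL) {
  if (length(keys) == 0L) {
    stop("cannot tabulate an empty collection of settings", call. = FALSE)
  }
  f <- factor(keys) # levels sorted lexicographically
  codes <- as.integer(f)
  nbins <- nlevels(f)
  cnt <- tabulate(codes, nbins = nbins)
  ord <- order(cnt, seq_len(nbins))
  prop <- cnt[ord] / length(keys)
  cum <- cumsum(prop)
  cum <- ave(cum, cnt[ord], FUN = max)
  out <- tibble::tibble(
    setting = levels(f)[ord],
    count = cnt[ord],
    proportion = prop,
    cum_proportion = cum
  )
  attr(out, "n_total") <- length(keys)
  attr(out, "definition") <- definition
  out
}

#' Cumulative proportion of each moment's setting
#'
#' Convenience lookup: computes the frequency table of `keys` and returns the
#' cumulative proportion of the setting occupied at each moment.
#'
#' @param keys Character vector of setting keys.
#' @return Numeric vector aligned with `keys`, values in `(0, 1]`.
#' @export
setting_cp <- function(keys) {
  f <- factor(keys)
  .cp_codes(as.integer(f), nlevels(f))
}

#' Number of distinct behavior settings occupied
#'
#' @param keys Character vector of setting keys; `0` for empty input.
#' @return Integer count of occupied settings.
#' @export
count_unique_settings <- function(keys) {
  length(unique(keys))
}
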