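# Loading, validation and inclusion filtering of long-format beep records.
#
# A beep dataset is an ordinary tibble with one row per signaled questionnaire:
#   subject_id  chr   opaque subject identifier
#   day         int   study day, >= 1
#   beep        int   beep index within day, 1..10
#   cheerful, satisfied, relaxed, enthusiastic
#               int   positive-affect Likert items, 1..7
#   mqol        int   momentary quality of life item, 1..7
#   who, what, where
#               chr   raw context categories (8 / 8 / 6 options)
#   completed   lgl   whole questionnaire answered
# The (subject_id, day, beep) triple is unique. Invalid beeps keep their
# partial answers (flagged, not dropped) so compliance can still be reported.

pa_item_cols <- c("cheerful", "satisfied", "relaxed", "enthusiastic")

beep_canonical_cols <- c(
  "subject_id", "day", "beep", pa_item_cols, "mqol",
  "who", "what", "where", "completed"
)

#' Column-name mapping for beep CSV files
#'
#' @param ... Named overrides, e.g. `subject_id = "id"`, mapping canonical
#'   names to the column names used in the file.
#' @return Named character vector mapping canonical names to file columns.
#' @export
#' @examples
#' beep_dialect(subject_id = "participant", beep = "beep_no")
beep_dialect <- function(...) {
  dialect <- setNames(beep_canonical_cols, beep_canonical_cols)
  override <- c(...)
  if (length(override)) {
    bad <- setdiff(names(override), beep_canonical_cols)
    if (length(bad)) {
      stop("unknown canonical column(s) in dialect: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    dialect[names(override)] <- override
  }
  dialect
}

.parse_likert <- function(x) {
  v <- suppressWarnings(as.integer(x))
  v[!is.na(v) & (v < 1L | v > 7L)] <- NA_integer_
  v
}

.resolve_multiselect <- function(x, precedence, sep) {
  vapply(x, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) {
      return(NA_character_)
    }
    opts <- trimws(strsplit(cell, sep, fixed = TRUE)[[1]])
    hit <- precedence[precedence %in% opts]
    if (length(hit)) hit[[1]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read a beep dataset from delimited text
#'
#' Parses one row per beep. Likert cells that do not parse or fall outside
#' 1..7 become missing and force `completed = FALSE` (with a warning), as do
#' context cells outside their vocabulary. Multi-checked context cells
#' (options separated by `sep`) are reduced to a single category by a fixed
#' precedence order per domain.
#'
#' @param path CSV file path.
#' @param dialect Column mapping from [beep_dialect()].
#' @param sep Separator inside multi-select context cells.
#' @param provenance Free-text label stored as an attribute on the result.
#' @return Tibble of beep records in canonical columns.
#' @export
read_beeps <- function(path, dialect = beep_dialect(), sep = ";",
                       provenance = path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(raw) == 0L) {
    stop("empty beep file: ", path, call. = FALSE)
  }
  raw <- raw[, unname(dialect)]
  names(raw) <- names(dialect)

  out <- tibble::tibble(
    subject_id = as.character(raw$subject_id),
    day = suppressWarnings(as.integer(raw$day)),
    beep = suppressWarnings(as.integer(raw$beep))
  )
  if (anyNA(out$subject_id) || anyNA(out$day) || anyNA(out$beep) ||
    any(out$day < 1L) || any(out$beep < 1L | out$beep > 10L)) {
    stop("unparseable or out-of-range subject/day/beep key fields", call. = FALSE)
  }
  key <- paste(out$subject_id, out$day, out$beep, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (subject_id, day, beep) key(s), e.g. row ",
      which(duplicated(key))[1], call. = FALSE
    )
  }

  broken <- rep(FALSE, nrow(raw))
  for (col in c(pa_item_cols, "mqol")) {
    parsed <- .parse_likert(raw[[col]])
    broken <- broken | (is.na(parsed) & !is.na(raw[[col]]) & nzchar(trimws(raw[[col]])))
    out[[col]] <- parsed
  }
  ctx <- list(
    who = list(prec = who_precedence),
    what = list(prec = what_precedence),
    where = list(prec = where_precedence)
  )
  for (col in names(ctx)) {
    resolved <- .resolve_multiselect(raw[[col]], ctx[[col]]$prec, sep)
    broken <- broken | (is.na(resolved) & !is.na(raw[[col]]) & nzchar(trimws(raw[[col]])))
    out[[col]] <- resolved
  }
  completed <- tolower(trimws(raw$completed)) %in% c("true", "t", "1", "yes", "y")
  if (any(broken & completed)) {
    warning(sum(broken & completed), " beep(s) had out-of-range or unknown cells; ",
      "flagged as not completed",
      call. = FALSE
    )
  }
  out$completed <- completed & !broken
  attr(out, "provenance") <- provenance
  out
}

#' Write a beep dataset as CSV
#'
#' @param data Beep tibble in canonical columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beeps <- function(data, path) {
  readr::write_csv(data[, intersect(c(beep_canonical_cols, setdiff(names(data), beep_canonical_cols)), names(data))], path, progress = FALSE)
  invisible(path)
}

#' Beep validity
#'
#' A beep is valid when the whole questionnaire was completed: the completion
#' flag holds, all four positive-affect items and the momentary-QoL item are
#' present Likert values in 1..7, and all three context fields carry a known
#' category.
#'
#' @param data Beep tibble.
#' @return Logical vector, one element per row.
#' @export
validate_beeps <- function(data) {
  ok <- as.logical(data$completed)
  ok[is.na(ok)] <- FALSE
  for (col in c(pa_item_cols, "mqol")) {
    v <- data[[col]]
    ok <- ok & !is.na(v) & v >= 1 & v <= 7
  }
  ok <- ok & data$who %in% who_levels_raw
  ok <- ok & data$what %in% what_levels_raw
  ok <- ok & data$where %in% where_levels
  ok
}

#' Per-subject compliance report
#'
#' @param data Beep tibble.
#' @param min_valid Valid-beep inclusion threshold.
#' @return Tibble with per-subject beep counts, valid counts and inclusion.
#' @export
compliance_report <- function(data, min_valid = 20L) {
  data$.valid <- validate_beeps(data)
  out <- dplyr::summarise(dplyr::group_by(data, .data$subject_id),
    n_beeps = dplyr::n(),
    n_valid = sum(.data$.valid),
    .groups = "drop"
  )
  out$included <- out$n_valid >= min_valid
  out
}

#' Apply the validity and inclusion filter
#'
#' Keeps only valid beeps of subjects contributing at least `min_valid` valid
#' beeps (the conventional one-third of a 10-beeps-a-day, 6-day protocol).
#' Idempotent. The per-subject compliance table is attached as attribute
#' `"compliance"`.
#'
#' @param data Beep tibble.
#' @param min_valid Minimum number of valid beeps for a subject to be included
#'   (default 20).
#' @return Filtered beep tibble (possibly zero rows).
#' @export
filter_subjects <- function(data, min_valid = 20L) {
  stopifnot(min_valid >= 1L)
  report <- compliance_report(data, min_valid)
  keep_subjects <- report$subject_id[report$included]
  out <- data[validate_beeps(data) & data$subject_id %in% keep_subjects, , drop = FALSE]
  attr(out, "compliance") <- report
  attr(out, "provenance") <- attr(data, "provenance")
  out
}

#' Momentary positive affect
#'
#' PA at a beep is the arithmetic mean of the four mood items "cheerful",
#' "satisfied", "relaxed" and "enthusiastic", staying on the 1..7 scale.
#'
#' @param data Beep tibble whose rows are valid beeps.
#' @return Numeric vector of PA scores in `[1, 7]`.
#' @export
compute_pa <- function(data) {
  items <- as.matrix(data[, pa_item_cols])
  if (anyNA(items)) {
    stop("missing positive-affect item(s); compute PA on valid beeps only",
      call. = FALSE
    )
  }
  rowMeans(items)
}

#' Protocol arithmetic
#'
#' The sampling protocol emits a fixed number of beeps per day over a fixed
#' number of days; subjects are conventionally included when they answer at
#' least a third of them.
#'
#' @param beeps_per_day Signals per day (default 10).
#' @param days Sampling days (default 6).
#' @param max_beeps Protocol maximum used to derive the threshold.
#' @param fraction Included fraction (default 1/3).
#' @return Integer count.
#' @export
#' @examples
#' protocol_max_beeps()                  # 60
#' inclusion_threshold()                 # 20
protocol_max_beeps <- function(beeps_per_day = 10L, days = 6L) {
  as.integer(beeps_per_day) * as.integer(days)
}

#' @rdname protocol_max_beeps
#' @export
inclusion_threshold <- function(max_beeps = protocol_max_beeps(), fraction = 1 / 3) {
  as.integer(ceiling(max_beeps * fraction))
}
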