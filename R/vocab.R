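# Context vocabularies of the beep questionnaire and their collapsed forms.
#
# The raw checklists offer 8 person categories, 8 activity categories and 6
# location categories. For behavior-setting analysis each domain is collapsed
# to 6 levels: "partner" joins "resident family", "colleagues" joins
# "acquaintances", "resting" joins "nothing" and "household/groceries" joins
# "hygiene"; locations are kept as-is.

who_levels_raw <- c(
  "partner", "resident family", "family away", "friends",
  "colleagues", "acquaintances", "strangers/others", "nobody"
)

what_levels_raw <- c(
  "resting", "work/school", "household/groceries", "hygiene",
  "eating/drinking", "relaxation", "something else", "nothing"
)

where_levels <- c(
  "home", "someone else's home", "work/school",
  "public place", "on the go", "somewhere else"
)

who_levels6 <- c(
  "resident family", "family away", "friends",
  "acquaintances", "strangers/others", "nobody"
)

what_levels6 <- c(
  "resting/nothing", "work/school", "household/hygiene",
  "eating/drinking", "relaxation", "something else"
)

.who_collapse <- c(
  "partner"          = "resident family",
  "resident family"  = "resident family",
  "family away"      = "family away",
  "friends"          = "friends",
  "colleagues"       = "acquaintances",
  "acquaintances"    = "acquaintances",
  "strangers/others" = "strangers/others",
  "nobody"           = "nobody"
)

.what_collapse <- c(
  "resting"             = "resting/nothing",
  "nothing"             = "resting/nothing",
  "work/school"         = "work/school",
  "household/groceries" = "household/hygiene",
  "hygiene"             = "household/hygiene",
  "eating/drinking"     = "eating/drinking",
  "relaxation"          = "relaxation",
  "something else"      = "something else"
)

# Precedence used to reduce multi-checked context cells to one category per
# domain (social/active options outrank passive ones). A convention of this
# package, configurable in read_beeps().
who_precedence <- c(
  "partner", "resident family", "family away", "friends",
  "colleagues", "acquaintances", "strangers/others", "nobody"
)
what_precedence <- c(
  "work/school", "household/groceries", "hygiene", "eating/drinking",
  "relaxation", "resting", "something else", "nothing"
)
where_precedence <- c(
  "home", "someone else's home", "work/school",
  "public place", "on the go", "somewhere else"
)

#' Context vocabularies
#'
#' Raw and collapsed category sets for the three contextual domains of a beep:
#' persons present (Who), activity (What) and location (Where).
#'
#' @param domain One of `"who"`, `"what"`, `"where"`.
#' @param collapsed Return the 6-level collapsed vocabulary instead of the raw
#'   checklist options. Locations are identical in both forms.
#' @return Character vector of category labels.
#' @export
#' @examples
#' context_levels("who")
#' context_levels("what", collapsed = TRUE)
context_levels <- function(domain = c("who", "what", "where"), collapsed = FALSE) {
  domain <- match.arg(domain)
  switch(domain,
    who   = if (collapsed) who_levels6 else who_levels_raw,
    what  = if (collapsed) what_levels6 else what_levels_raw,
    where = where_levels
  )
}

#' Enumerate the raw and collapsed context spaces
#'
#' Builds the full cross of context categories as observed on the device. The
#' raw questionnaire crosses a 3-block time-of-day indicator with 8 person, 8
#' activity and 6 location options (1,152 cells); the collapsed space drops
#' time of day and uses the 6-level vocabularies (216 cells). Time of day is
#' never part of a behavior-setting key; the raw enumeration exists to document
#' why the full cross is unusable for per-subject frequency work.
#'
#' @param collapsed If `TRUE` (default) cross the collapsed 6x6x6 vocabularies;
#'   otherwise the raw 3x8x8x6 space including time of day.
#' @return A tibble with one row per cell (`who`, `what`, `where`, and
#'   `time_block` for the raw space).
#' @export
#' @examples
#' nrow(context_space())            # 216
#' nrow(context_space(FALSE))       # 1152
context_space <- function(collapsed = TRUE) {
  if (collapsed) {
    grid <- expand.grid(
      who = who_levels6, what = what_levels6, where = where_levels,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
  } else {
    grid <- expand.grid(
      time_block = c("morning", "afternoon", "evening"),
      who = who_levels_raw, what = what_levels_raw, where = where_levels,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
  }
  tibble::as_tibble(grid)
}
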