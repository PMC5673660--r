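# Loading, validity and inclusion filtering of beep records.

test_that("a well-formed CSV round-trips field by field", {
  data <- dplyr::bind_rows(
    beep_row(beep = 1L, who = "partner", what = "hygiene", where = "on the go"),
    beep_row(beep = 2L, cheerful = 7L, mqol = 1L),
    beep_row(beep = 3L, who = "nobody", what = "nothing", where = "home")
  )
  path <- write_beep_csv(data)
  loaded <- read_beeps(path)
  expect_equal(nrow(loaded), 3L)
  expect_equal(loaded, data, ignore_attr = TRUE)
})

test_that("out-of-range and unknown cells become missing and void completion", {
  data <- dplyr::bind_rows(
    beep_row(beep = 1L),
    beep_row(beep = 2L, cheerful = 8L), # outside the Likert scale
    beep_row(beep = 3L, who = "imaginary friends")
  )
  path <- write_beep_csv(data)
  expect_warning(loaded <- read_beeps(path), "not completed")
  expect_true(is.na(loaded$cheerful[2]))
  expect_false(loaded$completed[2])
  expect_true(is.na(loaded$who[3]))
  expect_false(loaded$completed[3])
  expect_true(loaded$completed[1])
})

test_that("structural errors are rejected at load", {
  dup <- dplyr::bind_rows(beep_row(beep = 1L), beep_row(beep = 1L))
  expect_error(read_beeps(write_beep_csv(dup)), "duplicated")

  nocol <- beep_row()[, -4] # drop an affect item column
  expect_error(read_beeps(write_beep_csv(nocol)), "missing mandatory")

  empty <- beep_row()[0, ]
  expect_error(read_beeps(write_beep_csv(empty)), "empty")
})

test_that("multi-checked context cells resolve by precedence", {
  data <- beep_row(who = "nobody;partner", what = "resting;work/school")
  loaded <- read_beeps(write_beep_csv(data))
  expect_equal(loaded$who, "partner") # partner outranks nobody
  expect_equal(loaded$what, "work/school") # activity outranks resting
})

test_that("a beep is valid only when the whole questionnaire is completed", {
  expect_true(validate_beeps(beep_row()))
  expect_false(validate_beeps(beep_row(enthusiastic = NA_integer_)))
  expect_false(validate_beeps(beep_row(where = NA_character_)))
  expect_false(validate_beeps(beep_row(mqol = NA_integer_)))
  expect_false(validate_beeps(beep_row(completed = FALSE)))
})

test_that("inclusion keeps subjects at or above the valid-beep threshold", {
  data <- dplyr::bind_rows(
    make_subject_beeps("S19", 19),
    make_subject_beeps("S20", 20),
    make_subject_beeps("S22", 22)
  )
  kept <- filter_subjects(data, min_valid = 20)
  expect_setequal(unique(kept$subject_id), c("S20", "S22"))
  report <- attr(kept, "compliance")
  expect_equal(report$n_valid[report$subject_id == "S19"], 19L)
  expect_false(report$included[report$subject_id == "S19"])

  # invalid beeps count for compliance but never survive filtering
  mixed <- dplyr::bind_rows(
    make_subject_beeps("S30", 25),
    beep_row(subject_id = "S30", day = 6L, beep = 9L, completed = FALSE)
  )
  kept2 <- filter_subjects(mixed)
  expect_equal(nrow(kept2), 25L)
  expect_equal(attr(kept2, "compliance")$n_beeps, 26L)
})

test_that("filtering is idempotent", {
  data <- dplyr::bind_rows(
    make_subject_beeps("A", 25), make_subject_beeps("B", 10)
  )
  once <- filter_subjects(data)
  twice <- filter_subjects(once)
  expect_equal(twice, once, ignore_attr = TRUE)
})

test_that("PA is the arithmetic mean of the four items, bounded by the scale", {
  expect_equal(compute_pa(beep_row()), 4)
  expect_equal(compute_pa(beep_row(
    cheerful = 1L, satisfied = 1L, relaxed = 1L, enthusiastic = 1L
  )), 1)
  expect_equal(compute_pa(beep_row(
    cheerful = 7L, satisfied = 6L, relaxed = 5L, enthusiastic = 2L
  )), 5)
  expect_error(compute_pa(beep_row(relaxed = NA_integer_)), "missing")

  set.seed(11)
  items <- matrix(sample(1:7, 400, replace = TRUE), ncol = 4)
  df <- beep_row()[rep(1, 100), ]
  df[, c("cheerful", "satisfied", "relaxed", "enthusiastic")] <- items
  pa <- compute_pa(df)
  expect_true(all(pa >= 1 & pa <= 7))
  expect_equal(pa, rowMeans(items))
})

test_that("protocol arithmetic gives the 60-beep maximum and 20-beep threshold", {
  expect_identical(protocol_max_beeps(10, 6), 60L)
  expect_identical(inclusion_threshold(60, 1 / 3), 20L)
  expect_identical(inclusion_threshold(protocol_max_beeps(), 1 / 3), 20L)
})
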