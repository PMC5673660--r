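# Fixture builders and independent oracles used across the suite.

# one fully answered beep row; override any field via ...
beep_row <- function(subject_id = "S01", day = 1L, beep = 1L,
                     cheerful = 4L, satisfied = 4L, relaxed = 4L,
                     enthusiastic = 4L, mqol = 4L,
                     who = "friends", what = "relaxation", where = "home",
                     completed = TRUE) {
  tibble::tibble(
    subject_id = subject_id, day = day, beep = beep,
    cheerful = cheerful, satisfied = satisfied, relaxed = relaxed,
    enthusiastic = enthusiastic, mqol = mqol,
    who = who, what = what, where = where, completed = completed
  )
}

# n fully answered beeps for one subject with cycling contexts
make_subject_beeps <- function(subject_id, n, who = "friends",
                               what = "relaxation", where = "home",
                               pa_items = 4L) {
  tibble::tibble(
    subject_id = subject_id,
    day = (seq_len(n) - 1L) %/% 10L + 1L,
    beep = (seq_len(n) - 1L) %% 10L + 1L,
    cheerful = rep_len(pa_items, n), satisfied = rep_len(pa_items, n),
    relaxed = rep_len(pa_items, n), enthusiastic = rep_len(pa_items, n),
    mqol = rep_len(pa_items, n),
    who = rep_len(who, n), what = rep_len(what, n), where = rep_len(where, n),
    completed = TRUE
  )
}

write_beep_csv <- function(data) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(data, path, progress = FALSE)
  path
}

# brute-force frequency-table oracle: tallies keys one by one, sorts by
# (count, key), cumulates, then walks tied blocks assigning the block-end
# cumulative value. Independent of the package's tabulate/ave implementation.
oracle_frequency_table <- function(keys) {
  uk <- sort(unique(keys))
  counts <- vapply(uk, function(k) sum(keys == k), integer(1))
  ord <- order(counts, uk)
  uk <- uk[ord]
  counts <- counts[ord]
  prop <- counts / length(keys)
  cum <- numeric(length(prop))
  running <- 0
  i <- 1
  while (i <= length(prop)) {
    j <- i
    while (j < length(prop) && counts[j + 1] == counts[i]) j <- j + 1
    block_end <- running + sum(prop[i:j])
    cum[i:j] <- block_end
    running <- block_end
    i <- j + 1
  }
  data.frame(
    setting = uk, count = counts, proportion = prop,
    cum_proportion = cum, stringsAsFactors = FALSE
  )
}

# closed-form occupancy oracle: expected number of distinct cells after n
# draws with replacement from probabilities p
oracle_expected_unique <- function(p, n) sum(1 - (1 - p)^n)

# random setting keys for property tests
random_keys <- function(n, n_cells = 8) {
  sample(sprintf("cell%02d", seq_len(n_cells)), n, replace = TRUE)
}
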