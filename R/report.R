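# High-level run commands behind the command-line interface. Each command is
# a pure function of (inputs, seed): rerunning with the same configuration
# reproduces its output files exactly. Every run writes a machine-readable
# provenance record next to its outputs.

.write_provenance <- function(path, info) {
  info$package_version <- as.character(utils::packageVersion("rqol"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

.as_beeps <- function(input) {
  if (is.character(input)) read_beeps(input) else input
}

#' Score a beep dataset and summarize per subject
#'
#' Applies the inclusion filter, scores every included subject with the rQoL
#' reward function, and writes the scored moments, a per-subject summary
#' (mean, SD, min, max rQoL) and a provenance record to `out_dir`. The
#' correlation between rQoL and the momentary-QoL item over all included
#' beeps is reported in the summary attributes and provenance.
#'
#' @param input Beep CSV path or beep tibble.
#' @param definition Setting granularity.
#' @param cutoff rQoL cut point in (0, 1).
#' @param out_dir Output directory (created if needed); `NULL` writes nothing.
#' @param min_valid Inclusion threshold of valid beeps per subject.
#' @return List with `scored`, `subject_summary`, `rqol_mqol_r` and
#'   `compliance`, invisibly when writing.
#' @export
cmd_score <- function(input, definition = c("WWW", "WW", "W"), cutoff = 0.5,
                      out_dir = NULL, min_valid = 20L) {
  definition <- match.arg(definition)
  data <- .as_beeps(input)
  kept <- filter_subjects(data, min_valid)
  compliance <- attr(kept, "compliance")
  if (nrow(kept) == 0L) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(compliance, file.path(out_dir, "compliance.csv"), progress = FALSE)
    }
    stop("no subjects pass the inclusion threshold of ", min_valid,
      " valid beeps",
      call. = FALSE
    )
  }
  scored <- compute_rqol(kept, definition, cutoff, unit = "subject")
  subject_summary <- dplyr::summarise(
    dplyr::group_by(scored, .data$subject_id),
    n = dplyr::n(),
    rqol_mean = mean(.data$rqol), rqol_sd = sd(.data$rqol),
    rqol_min = min(.data$rqol), rqol_max = max(.data$rqol),
    .groups = "drop"
  )
  rqol_mqol_r <- tryCatch(pearson_r(scored$rqol, kept$mqol),
    error = function(e) {
      warning("rQoL-mQoL correlation undefined: ", conditionMessage(e), call. = FALSE)
      NA_real_
    }
  )
  result <- list(
    scored = scored, subject_summary = subject_summary,
    rqol_mqol_r = rqol_mqol_r, compliance = compliance
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(scored, file.path(out_dir, "scored_moments.csv"), progress = FALSE)
    readr::write_csv(subject_summary, file.path(out_dir, "subject_summary.csv"), progress = FALSE)
    readr::write_csv(compliance, file.path(out_dir, "compliance.csv"), progress = FALSE)
    .write_provenance(file.path(out_dir, "provenance.json"), list(
      command = "score", definition = definition, cutoff = cutoff,
      min_valid = min_valid, rqol_mqol_r = rqol_mqol_r,
      input = attr(data, "provenance")
    ))
    return(invisible(result))
  }
  result
}

#' Run a named resampling experiment on a pooled beep dataset
#'
#' Pools the valid beeps of all included subjects as the sampling domain and
#' runs one of the four experiments: `"unique_settings"`, `"rqol_spread"`,
#' `"subject_percentiles"` or `"pa_rqol_correlation"`.
#'
#' @param input Beep CSV path or beep tibble.
#' @param experiment Experiment name (see above).
#' @param definition Setting granularity.
#' @param cutoff rQoL cut point.
#' @param spec A [resample_spec()].
#' @param out_dir Output directory; `NULL` writes nothing.
#' @param min_valid Inclusion threshold.
#' @return Tidy summary tibble, invisibly when writing.
#' @export
cmd_simulate <- function(input,
                         experiment = c(
                           "unique_settings", "rqol_spread",
                           "subject_percentiles", "pa_rqol_correlation"
                         ),
                         definition = c("WWW", "WW", "W"), cutoff = 0.5,
                         spec = resample_spec(), out_dir = NULL,
                         min_valid = 20L) {
  experiment <- match.arg(experiment)
  definition <- match.arg(definition)
  data <- .as_beeps(input)
  kept <- filter_subjects(data, min_valid)
  if (nrow(kept) == 0L) {
    stop("no subjects pass the inclusion threshold", call. = FALSE)
  }
  kept$pa <- compute_pa(kept)
  summary <- switch(experiment,
    unique_settings = experiment_unique_settings(kept, definition, spec),
    rqol_spread = experiment_rqol_spread(kept, definition, cutoff, spec),
    pa_rqol_correlation = experiment_pa_rqol_correlation(kept, definition, cutoff, spec),
    subject_percentiles = experiment_subject_percentiles(kept,
      definition = definition, cutoff = cutoff, spec = spec
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(summary, file.path(out_dir, paste0(experiment, "_summary.csv")), progress = FALSE)
    .write_provenance(file.path(out_dir, "provenance.json"), list(
      command = "simulate", experiment = experiment, definition = definition,
      cutoff = cutoff, sizes = spec$sizes, replicates = spec$replicates,
      seed = spec$seed, replacement = spec$replacement,
      input = attr(data, "provenance")
    ))
    return(invisible(summary))
  }
  summary
}

#' Generate a synthetic dataset and write it as CSV
#'
#' @param config A [synthetic_config()].
#' @param out Output CSV path; `NULL` returns the tibble without writing.
#' @return The generated beep tibble, invisibly when writing.
#' @export
cmd_synth <- function(config = synthetic_config(), out = NULL) {
  data <- generate_dataset(config)
  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    write_beeps(data, out)
    cfg <- unclass(config)
    .write_provenance(paste0(sub("\\.csv$", "", out), "_provenance.json"), list(
      command = "synth", config = cfg
    ))
    return(invisible(data))
  }
  data
}
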