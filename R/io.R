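# Plain-text file dialects. Beat files: one row per heartbeat with
# subject_id, beat_time_s, phase. Metadata files: one row per subject with
# the scalar clinical columns. All CSV, UTF-8, "." decimal separator.

#' Read a beat CSV into per-subject beat series
#'
#' Expected header: `subject_id, beat_time_s, phase`. Times must be strictly
#' increasing within a subject and phases contiguous in the order
#' rest, exercise, recovery; violations raise a parse error naming the first
#' offending line (1-based, counting the header).
#'
#' @param path CSV file path.
#' @return Named list of [beat_series()], one per subject.
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "beat_time_s", "phase")
  if (!all(need %in% names(df))) {
    stop(sprintf("parse error: missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  }
  df$.line <- seq_len(nrow(df)) + 1L
  out <- list()
  for (id in unique(df$subject_id)) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    bad_t <- which(diff(sub$beat_time_s) <= 0)
    if (length(bad_t)) {
      stop(sprintf("parse error: non-monotone beat time for subject '%s' at line %d",
                   id, sub$.line[bad_t[1L] + 1L]), call. = FALSE)
    }
    bad_p <- which(!sub$phase %in% c("rest", "exercise", "recovery"))
    if (length(bad_p)) {
      stop(sprintf("parse error: unknown phase '%s' at line %d",
                   sub$phase[bad_p[1L]], sub$.line[bad_p[1L]]), call. = FALSE)
    }
    out[[as.character(id)]] <- tryCatch(
      beat_series(sub$beat_time_s, sub$phase),
      error = function(e) stop(sprintf("parse error: subject '%s': %s",
                                       id, conditionMessage(e)), call. = FALSE))
  }
  out
}

#' Write a cohort's beat series to a beat CSV
#'
#' @param cohort An `hrr_cohort`, list of `subject_record`s, or named list of
#'   [beat_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(cohort, path) {
  rows <- lapply(seq_along(cohort), function(i) {
    el <- cohort[[i]]
    if (inherits(el, "subject_record")) {
      data.frame(subject_id = el$id, beat_time_s = el$beats$times,
                 phase = el$beats$phase, stringsAsFactors = FALSE)
    } else {
      id <- names(cohort)[i]
      data.frame(subject_id = id, beat_time_s = el$times, phase = el$phase,
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  df$beat_time_s <- sprintf("%.6f", df$beat_time_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cohort metadata to CSV
#'
#' One row per subject with the scalar clinical fields; missing values are
#' written as empty cells.
#'
#' @param cohort An `hrr_cohort` or list of `subject_record`s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(cohort, path) {
  rows <- lapply(cohort, function(s) {
    m <- s$meta
    scal <- m[vapply(m, function(v) is.atomic(v) && length(v) == 1L, TRUE)]
    data.frame(id = s$id, scal, stringsAsFactors = FALSE, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a metadata CSV
#'
#' @param path CSV path with at least `id` and `group` columns.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(df))) {
    stop("parse error: metadata needs 'id' and 'group' columns", call. = FALSE)
  }
  bad <- setdiff(unique(df$group), c("control", "nonobstructive", "obstructive"))
  if (length(bad)) {
    stop(sprintf("parse error: unknown group label '%s'", bad[1L]), call. = FALSE)
  }
  df
}

#' Write a generator configuration as JSON
#'
#' Echoes every parameter and the seed so a simulated data set is fully
#' reproducible from its sidecar config.
#'
#' @param config A [generator_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  out <- unclass(config)
  out$n_per_group <- as.list(out$n_per_group)      # keep names in JSON
  out$phase_durations <- as.list(out$phase_durations)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a generator configuration from JSON
#'
#' @param path JSON path written by [write_config()] (or hand-authored with
#'   the same fields; absent fields fall back to defaults).
#' @return A validated [generator_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- formals(generator_config)
  args <- list()
  if (!is.null(raw$n_per_group)) args$n_per_group <- unlist(raw$n_per_group)
  if (!is.null(raw$group_params)) {
    gp <- default_group_params()
    for (g in names(raw$group_params)) {
      gp[[g]][names(raw$group_params[[g]])] <- raw$group_params[[g]]
    }
    args$group_params <- gp
  }
  for (f in c("lf_freq", "hf_freq", "lf_amp_ms", "hf_amp_ms", "noise_sd_ms",
              "ectopy_rate", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$phase_durations)) {
    args$phase_durations <- unlist(raw$phase_durations)
  }
  do.call(generator_config, args)
}
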