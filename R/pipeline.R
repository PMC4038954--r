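#' Per-subject metrics table for a cohort
#'
#' Runs [compute_hrr_profile()] and [recovery_spectrum()] on every subject
#' and binds the results with the clinical metadata into one data frame (one
#' row per subject). Per-subject failures are isolated: the affected columns
#' are NA and the failure is recorded in the `failures` attribute.
#'
#' @param cohort An `hrr_cohort` (or plain list of `subject_record`s).
#' @param methods Spectral methods to compute band powers for.
#' @return Data frame with metadata, HRR metrics (`hr_at_60` ...,
#'   `hrr_abs_60` ..., `hrr_pct_peak_60` ..., `hrr_pct_reserve_60` ...) and,
#'   per method, `lf_<m>`, `hf_<m>`, `lf_nu_<m>`, `hf_nu_<m>`,
#'   `lf_hf_ratio_<m>`.
#' @export
cohort_metrics <- function(cohort, methods = c("welch", "ar", "lomb_scargle")) {
  failures <- list()
  rows <- lapply(cohort, function(subj) {
    meta <- subj$meta
    row <- data.frame(id = subj$id, group = subj$group,
                      stringsAsFactors = FALSE)
    for (nm in setdiff(names(meta), "group")) row[[nm]] <- meta[[nm]]
    hm <- tryCatch(suppressWarnings(compute_hrr_profile(subj)),
                   error = function(e) e)
    if (inherits(hm, "error")) {
      failures[[subj$id]] <<- conditionMessage(hm)
      row$hr_rest <- NA_real_; row$hr_peak <- NA_real_; row$delta_hr <- NA_real_
      for (tp in c("60", "120", "180")) {
        row[[paste0("hr_at_", tp)]] <- NA_real_
        row[[paste0("hrr_abs_", tp)]] <- NA_real_
        row[[paste0("hrr_pct_peak_", tp)]] <- NA_real_
        row[[paste0("hrr_pct_reserve_", tp)]] <- NA_real_
      }
    } else {
      row$hr_rest <- hm$hr_rest; row$hr_peak <- hm$hr_peak
      row$delta_hr <- hm$delta_hr
      for (tp in c("60", "120", "180")) {
        row[[paste0("hr_at_", tp)]] <- hm$hr_at[[tp]]
        row[[paste0("hrr_abs_", tp)]] <- hm$hrr_abs[[tp]]
        row[[paste0("hrr_pct_peak_", tp)]] <- hm$hrr_pct_peak[[tp]]
        row[[paste0("hrr_pct_reserve_", tp)]] <- hm$hrr_pct_reserve[[tp]]
      }
    }
    for (m in methods) {
      bp <- tryCatch(suppressWarnings(recovery_spectrum(subj, method = m)),
                     error = function(e) e)
      if (inherits(bp, "error")) {
        failures[[paste0(subj$id, ":", m)]] <<- conditionMessage(bp)
        row[[paste0("lf_", m)]] <- NA_real_
        row[[paste0("hf_", m)]] <- NA_real_
        row[[paste0("lf_nu_", m)]] <- NA_real_
        row[[paste0("hf_nu_", m)]] <- NA_real_
        row[[paste0("lf_hf_ratio_", m)]] <- NA_real_
      } else {
        row[[paste0("lf_", m)]] <- bp$lf
        row[[paste0("hf_", m)]] <- bp$hf
        row[[paste0("lf_nu_", m)]] <- bp$lf_nu
        row[[paste0("hf_nu_", m)]] <- bp$hf_nu
        row[[paste0("lf_hf_ratio_", m)]] <- bp$lf_hf_ratio
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

#' Run the full analysis pipeline
#'
#' Reads (or accepts) beat and metadata tables, applies the stated exclusion
#' rules (submaximal test: respiratory exchange ratio < 1.05; athletic
#' controls flagged in metadata), computes the per-subject metrics, the group
#' summary table, control-vs-patient and three-group comparisons, and the two
#' regression models. Deterministic given inputs.
#'
#' @param beats Path to a beat CSV (see [read_beats()]) or an `hrr_cohort`.
#' @param metadata Optional path to a metadata CSV (ignored when `beats` is a
#'   cohort, which carries its own metadata).
#' @param methods Spectral methods for band powers.
#' @param elimination_threshold Backward-elimination threshold.
#' @return List of class `hrr_results`: `metrics` (per-subject data frame),
#'   `summary` (group table), `comparisons`, `model1`, `model2`,
#'   `exclusions` (data frame of id + machine-readable reason).
#' @export
run_pipeline <- function(beats, metadata = NULL,
                         methods = c("welch", "ar", "lomb_scargle"),
                         elimination_threshold = 0.05) {
  cohort <- if (inherits(beats, "hrr_cohort") || (is.list(beats) &&
                all(vapply(beats, inherits, TRUE, "subject_record")))) {
    beats
  } else {
    series <- read_beats(beats)
    meta <- if (!is.null(metadata)) read_metadata(metadata) else NULL
    lapply(names(series), function(id) {
      m <- if (!is.null(meta) && id %in% meta$id) {
        as.list(meta[meta$id == id, , drop = FALSE])
      } else {
        list(group = "control")
      }
      structure(list(id = id, group = m$group, meta = m, beats = series[[id]]),
                class = "subject_record")
    })
  }
  if (!length(cohort)) stop("empty cohort", call. = FALSE)

  excl <- data.frame(id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  keep <- vapply(cohort, function(s) {
    rer <- s$meta$rer
    athletic <- isTRUE(s$meta$athletic)
    if (!is.null(rer) && is.finite(rer) && rer < 1.05) {
      excl <<- rbind(excl, data.frame(id = s$id, reason = "submaximal_test_rer_lt_1.05"))
      return(FALSE)
    }
    if (athletic) {
      excl <<- rbind(excl, data.frame(id = s$id, reason = "athletic_control"))
      return(FALSE)
    }
    TRUE
  }, TRUE)
  cohort <- cohort[keep]
  if (!length(cohort)) stop("empty cohort after exclusions", call. = FALSE)

  metrics <- cohort_metrics(cohort, methods = methods)
  metrics <- design_columns(metrics)
  summary_tab <- table1_summary(metrics)

  comparisons <- list()
  has_controls <- any(metrics$group == "control")
  has_patients <- any(metrics$group != "control")
  if (has_controls && has_patients) {
    for (v in c("hrr_abs_60", "hrr_abs_120", "hrr_abs_180")) {
      a <- metrics[[v]][metrics$group == "control"]
      b <- metrics[[v]][metrics$group != "control"]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) >= 2 && length(b) >= 2) {
        comparisons[[paste0(v, "_t")]] <- t_test_independent(a, b)
      }
    }
    m <- methods[1]
    v <- paste0("lf_hf_ratio_", m)
    if (v %in% names(metrics)) {
      a <- metrics[[v]][metrics$group == "control"]
      b <- metrics[[v]][metrics$group != "control"]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) >= 2 && length(b) >= 2) {
        comparisons[[paste0(v, "_rank")]] <- rank_tests(a, b)
      }
    }
  }
  if (length(unique(metrics$group)) == 3L) {
    for (v in c("hrr_abs_60", "hrr_abs_120", "hrr_abs_180")) {
      gs <- split(metrics[[v]], metrics$group)
      gs <- lapply(gs, function(x) x[is.finite(x)])
      if (all(vapply(gs, length, 1L) >= 2)) {
        comparisons[[paste0(v, "_anova")]] <- anova_bonferroni(gs)
      }
    }
  }

  model1 <- if (has_controls && has_patients) {
    tryCatch(run_model1(metrics, threshold = elimination_threshold),
             error = function(e) conditionMessage(e))
  } else NULL
  model2 <- if (has_patients && sum(metrics$group != "control") >= 10) {
    tryCatch(suppressMessages(run_model2(metrics,
                                         threshold = elimination_threshold)),
             error = function(e) conditionMessage(e))
  } else NULL

  structure(list(metrics = metrics, summary = summary_tab,
                 comparisons = comparisons, model1 = model1, model2 = model2,
                 exclusions = excl),
            class = "hrr_results")
}

#' @export
print.hrr_results <- function(x, ...) {
  cat(sprintf("<hrr_results> %d subjects analysed, %d excluded\n",
              nrow(x$metrics), nrow(x$exclusions)))
  cat("components: metrics, summary, comparisons, model1, model2, exclusions\n")
  invisible(x)
}
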