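# Cohort statistics layer: group summaries, two- and three-group
# comparisons, frequency tests, and the two multivariable models with
# backward elimination. Test machinery is delegated to base `stats` where a
# canonical implementation exists; Fisher's exact test is authored directly
# as the hypergeometric tail sum so its enumeration contract is explicit.

comparison_result <- function(name, estimates, statistic, df = NA_real_,
                              p, posthoc = NULL, flags = character(0)) {
  structure(list(name = name, estimates = estimates, statistic = statistic,
                 df = df, p = p, posthoc = posthoc, flags = flags),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, p = %.4g%s\n",
              x$name, x$statistic, x$p,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  if (!is.null(x$posthoc)) {
    print(x$posthoc)
  }
  invisible(x)
}

#' Decide summary and test style from a normality check
#'
#' Shapiro-Wilk at alpha = 0.05: normal data are summarised as mean and SD
#' and compared with t/ANOVA; non-normal data as median and IQR with
#' rank-based tests. Constant input is degenerate and treated as non-normal.
#'
#' @param x Numeric vector, `n >= 3`.
#' @param alpha Significance level of the Shapiro-Wilk test.
#' @return `"normal"` or `"non-normal"` (attribute `p` holds the Shapiro-Wilk
#'   p-value; attribute `degenerate` flags constant input).
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("insufficient data: need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(structure("non-normal", p = NA_real_, degenerate = TRUE))
  }
  p <- stats::shapiro.test(x)$p.value
  structure(if (p >= alpha) "normal" else "non-normal", p = p, degenerate = FALSE)
}

#' Independent two-sample t-test (pooled variance)
#'
#' @param a,b Numeric vectors, `n >= 2` each.
#' @return A `comparison_result` with the t statistic, df and two-sided p.
#' @export
t_test_independent <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group", call. = FALSE)
  est <- data.frame(group = c("a", "b"),
                    mean = c(mean(a), mean(b)),
                    sd = c(stats::sd(a), stats::sd(b)))
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    return(comparison_result("independent t-test", est,
                             statistic = if (mean(a) == mean(b)) 0 else NA_real_,
                             df = length(a) + length(b) - 2,
                             p = if (mean(a) == mean(b)) 1 else NA_real_,
                             flags = "degenerate-variance"))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  comparison_result("independent t-test", est,
                    statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p = tt$p.value)
}

#' One-way ANOVA with Bonferroni-adjusted pairwise post hoc tests
#'
#' Omnibus F across the groups, then all pairwise pooled-variance t-tests
#' with the Bonferroni multiplier (number of pairs), adjusted p capped at 1.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, n >= 2 each).
#' @return A `comparison_result`; `posthoc` is a data frame of pairwise
#'   raw and adjusted p-values.
#' @export
anova_bonferroni <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L)) stop("need n >= 2 per group", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  est <- data.frame(group = names(groups),
                    mean = vapply(groups, mean, 1),
                    sd = vapply(groups, stats::sd, 1))
  flags <- character(0)
  if (stats::sd(x - stats::ave(x, g)) == 0) {
    # no within-group variance
    flags <- "degenerate-variance"
  }
  fit <- stats::aov(x ~ g)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]
  if (all(vapply(groups, mean, 1) == mean(x)) && an[["Sum Sq"]][1] < 1e-12) {
    Fv <- 0; pv <- 1
  }
  pairs <- utils::combn(names(groups), 2)
  k <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(k), function(j) {
    r <- t_test_independent(groups[[pairs[1, j]]], groups[[pairs[2, j]]])
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               p_raw = r$p, p_adjusted = min(1, k * r$p))
  }))
  comparison_result("one-way ANOVA + Bonferroni", est, statistic = Fv,
                    df = an[["Df"]][1], p = pv, posthoc = posthoc,
                    flags = flags)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value computed by summing, over the hypergeometric support
#' fixed by the table margins, the probabilities of all tables no more
#' probable than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return A `comparison_result`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("validation error: empty table margin", call. = FALSE)
  }
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  comparison_result("Fisher exact", estimates = tab, statistic = tab[1, 1], p = p)
}

#' Rank-based group comparison
#'
#' Mann-Whitney U for two groups (exact enumeration when both groups have
#' n <= 20 and there are no ties; otherwise the tie-corrected normal
#' approximation with continuity correction) or Kruskal-Wallis for three.
#'
#' @param a,b Numeric vectors.
#' @param c Optional third group.
#' @return A `comparison_result` (two-group: statistic is the Mann-Whitney U
#'   of the first sample).
#' @export
rank_tests <- function(a, b, c = NULL) {
  groups <- if (is.null(c)) list(a = a, b = b) else list(a = a, b = b, c = c)
  est <- data.frame(group = names(groups),
                    median = vapply(groups, stats::median, 1),
                    iqr_lo = vapply(groups, function(x) unname(stats::quantile(x, 0.25)), 1),
                    iqr_hi = vapply(groups, function(x) unname(stats::quantile(x, 0.75)), 1))
  allx <- unlist(groups, use.names = FALSE)
  if (stats::sd(allx) == 0) {
    return(comparison_result("rank test", est, statistic = NA_real_, p = 1,
                             flags = "all-tied"))
  }
  if (is.null(c)) {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- length(a) <= 20 && length(b) <= 20 && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    comparison_result(sprintf("Mann-Whitney U (%s)",
                              if (exact) "exact" else "normal approximation"),
                      est, statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    kw <- stats::kruskal.test(groups)
    comparison_result("Kruskal-Wallis", est,
                      statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value)
  }
}

#' Linear regression with coefficient confidence intervals
#'
#' Ordinary least squares of `y` on the covariate matrix, with two-sided
#' p-values and 95% confidence intervals from the t distribution on
#' `n - p - 1` df. Rank-deficient designs are rejected, naming the collinear
#' columns.
#'
#' @param y Response vector.
#' @param X Covariate matrix or data frame (no intercept column; one is
#'   added).
#' @param conf_level Confidence level for the intervals.
#' @return A `regression_model`: list with `response`, `coefficients`
#'   (data frame: term, B, ci_lo, ci_hi, p), `n`, `r_squared`, `sigma` and
#'   the underlying `lm` fit.
#' @export
linear_regression <- function(y, X, conf_level = 0.95) {
  X <- as.data.frame(X)
  if (!nrow(X)) stop("empty design", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (length(y) <= ncol(X) + 1L) {
    stop("insufficient data: need n > p + 1", call. = FALSE)
  }
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop(sprintf("validation error: rank-deficient design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      B = sm$coefficients[, 1],
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      p = sm$coefficients[, 4],
                      row.names = NULL)
  structure(list(response = deparse(substitute(y)), coefficients = coefs,
                 n = length(y), r_squared = sm$r.squared, sigma = sm$sigma,
                 fit = fit, eliminated = character(0)),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf("<regression_model> n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  print(x$coefficients, digits = 4)
  if (length(x$eliminated)) {
    cat("eliminated (in order):", paste(x$eliminated, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Backward elimination for a linear model
#'
#' Iteratively refits the model, at each step removing the non-forced
#' covariate with the largest p-value at or above the threshold, until every
#' retained non-forced covariate is significant. The elimination order is
#' recorded. An intercept-only final model is allowed.
#'
#' @param data Data frame holding response and covariates.
#' @param response Response column name.
#' @param covariates Candidate covariate column names.
#' @param forced Covariates never eliminated.
#' @param threshold Retention threshold on the coefficient p-value.
#' @return A `regression_model` with the `eliminated` trace filled in, or an
#'   intercept-only summary when everything is eliminated.
#' @export
backward_eliminate <- function(data, response, covariates,
                               forced = character(0), threshold = 0.05) {
  stopifnot(all(c(response, covariates, forced) %in% names(data)))
  covariates <- union(covariates, forced)
  keep <- stats::complete.cases(data[, c(response, covariates), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  current <- covariates
  trace <- character(0)
  repeat {
    if (!length(current)) {
      y <- data[[response]]
      fit <- stats::lm(y ~ 1)
      sm <- summary(fit)
      out <- structure(list(response = response,
                            coefficients = data.frame(term = "(Intercept)",
                                                      B = stats::coef(fit)[[1]],
                                                      ci_lo = stats::confint(fit)[1],
                                                      ci_hi = stats::confint(fit)[2],
                                                      p = sm$coefficients[1, 4],
                                                      row.names = NULL),
                            n = length(y), r_squared = 0, sigma = sm$sigma,
                            fit = fit, eliminated = trace),
                       class = "regression_model")
      return(out)
    }
    model <- linear_regression(data[[response]],
                               data[, current, drop = FALSE])
    model$response <- response
    cf <- model$coefficients
    cand <- cf[cf$term %in% setdiff(current, forced), , drop = FALSE]
    if (!nrow(cand) || max(cand$p) < threshold) {
      model$eliminated <- trace
      model$retained <- current
      return(model)
    }
    worst <- cand$term[which.max(cand$p)]
    trace <- c(trace, worst)
    current <- setdiff(current, worst)
  }
}

# internal: add derived design columns (hc indicator, sex_male) to a cohort
# metrics data frame
design_columns <- function(df) {
  if (!"hc" %in% names(df) && "group" %in% names(df)) {
    df$hc <- as.integer(df$group != "control")
  }
  if (!"sex_male" %in% names(df) && "sex" %in% names(df)) {
    df$sex_male <- as.integer(df$sex == "M")
  }
  if (!"la_size" %in% names(df) && "la_diameter" %in% names(df)) {
    df$la_size <- df$la_diameter
  }
  df
}

#' Model 1: pooled predictors of recovery heart rate
#'
#' Backward elimination over \{HC diagnosis, sex, age, peak HR, BMI, peak
#' VO2\} for the heart rate at 1, 2 and 3 minutes of recovery, in the pooled
#' control + patient cohort. Subjects with a missing response or covariate
#' are excluded listwise per response.
#'
#' @param df Cohort metrics data frame (see [cohort_metrics()]); must contain
#'   `group`, `sex`, `age`, `hr_peak`, `bmi`, `peak_vo2` and the responses
#'   `hr_at_60`, `hr_at_120`, `hr_at_180`.
#' @param threshold Elimination threshold.
#' @return Named list of `regression_model`s, one per response.
#' @export
run_model1 <- function(df, threshold = 0.05) {
  df <- design_columns(df)
  if (length(unique(df$group)) < 2L || length(unique(df$hc)) < 2L) {
    stop("validation error: single-group cohort; the HC indicator is constant",
         call. = FALSE)
  }
  covs <- c("hc", "sex_male", "age", "hr_peak", "bmi", "peak_vo2")
  responses <- c("hr_at_60", "hr_at_120", "hr_at_180")
  stopifnot(all(c(covs, responses) %in% names(df)))
  out <- lapply(responses, function(rsp) {
    backward_eliminate(df, rsp, covs, threshold = threshold)
  })
  names(out) <- responses
  out
}

#' Model 2: disease-severity predictors in the patient group
#'
#' Stage 1 screens five clinical surrogates of disease severity (lateral
#' E/E', left atrial size, ejection fraction, maximal wall thickness, peak
#' LVOT gradient) one at a time against each recovery heart rate. Stage 2
#' fits the screen-passing surrogates together with the forced adjustment
#' covariates (by default peak HR and sex, the pooled-model predictors),
#' eliminating non-forced covariates backwards; forced covariates are never
#' removed.
#'
#' @param df Patient-only cohort metrics data frame (control rows, if
#'   present, are dropped with a message).
#' @param forced Covariates forced into stage 2.
#' @param threshold Significance threshold for both stages.
#' @return Named list per response: `stage1` (data frame of univariable B,
#'   CI, p per surrogate), `stage2` (a `regression_model`).
#' @export
run_model2 <- function(df, forced = c("hr_peak", "sex_male"),
                       threshold = 0.05) {
  df <- design_columns(df)
  if (any(df$group == "control")) {
    message("run_model2: dropping control rows (patient-only model)")
    df <- df[df$group != "control", , drop = FALSE]
  }
  surrogates <- c("e_eprime_lateral", "la_size", "ef", "mwt",
                  "lvot_gradient_peak")
  responses <- c("hr_at_60", "hr_at_120", "hr_at_180")
  stopifnot(all(c(surrogates, forced, responses) %in% names(df)))
  out <- lapply(responses, function(rsp) {
    stage1 <- do.call(rbind, lapply(surrogates, function(sv) {
      keep <- stats::complete.cases(df[, c(rsp, sv)])
      m <- linear_regression(df[[rsp]][keep], df[keep, sv, drop = FALSE])
      cf <- m$coefficients[m$coefficients$term == sv, ]
      data.frame(term = sv, B = cf$B, ci_lo = cf$ci_lo, ci_hi = cf$ci_hi,
                 p = cf$p, row.names = NULL)
    }))
    passed <- stage1$term[stage1$p < threshold]
    stage2 <- backward_eliminate(df, rsp, covariates = c(passed, forced),
                                 forced = forced, threshold = threshold)
    list(stage1 = stage1, screened_in = passed, stage2 = stage2)
  })
  names(out) <- responses
  out
}

#' Group summary table of cohort characteristics and recovery results
#'
#' Per-group summaries (control / all patients / nonobstructive /
#' obstructive) of the demographic, haemodynamic, recovery and spectral
#' columns: mean (SD) when the pooled normality gate passes, median \[IQR\]
#' otherwise, with a control-vs-patients test p-value per row (t-test or
#' Mann-Whitney as the gate dictates).
#'
#' @param df Cohort metrics data frame.
#' @param variables Columns to summarise (defaults to every numeric column
#'   except identifiers).
#' @return Data frame, one row per variable: per-group summary strings,
#'   summary style, and control-vs-HC p.
#' @export
table1_summary <- function(df,
                           variables = NULL) {
  stopifnot("group" %in% names(df))
  if (is.null(variables)) {
    variables <- setdiff(names(df)[vapply(df, is.numeric, TRUE)],
                         c("id", "risk_factor_count"))
  }
  grp_sets <- list(control = df$group == "control",
                   all_hc = df$group != "control",
                   nonobstructive = df$group == "nonobstructive",
                   obstructive = df$group == "obstructive")
  grp_sets <- grp_sets[vapply(grp_sets, any, TRUE)]
  rows <- lapply(variables, function(v) {
    x <- df[[v]]
    gate <- tryCatch(as.character(normality_gate(x[is.finite(x)])),
                     error = function(e) "non-normal")
    cells <- vapply(grp_sets, function(sel) {
      xi <- x[sel & is.finite(x)]
      if (!length(xi)) return(NA_character_)
      if (gate == "normal") {
        sprintf("%.1f ± %.1f", mean(xi), stats::sd(xi))
      } else {
        q <- stats::quantile(xi, c(0.25, 0.5, 0.75))
        sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3])
      }
    }, character(1))
    p <- NA_real_
    if (all(c("control", "all_hc") %in% names(grp_sets))) {
      a <- x[grp_sets$control & is.finite(x)]
      b <- x[grp_sets$all_hc & is.finite(x)]
      if (length(a) >= 2 && length(b) >= 2 && stats::sd(c(a, b)) > 0) {
        p <- if (gate == "normal") t_test_independent(a, b)$p
             else rank_tests(a, b)$p
      }
    }
    cbind(data.frame(variable = v, style = gate, stringsAsFactors = FALSE),
          as.data.frame(as.list(cells), stringsAsFactors = FALSE),
          data.frame(p_control_vs_hc = p))
  })
  do.call(rbind, rows)
}
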