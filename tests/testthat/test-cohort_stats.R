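test_that("normality_gate separates normal from heavy-tailed samples", {
  set.seed(101)
  normal_hits <- mean(replicate(50, {
    as.character(normality_gate(rnorm(100))) == "normal"
  }))
  expect_gte(normal_hits, 0.9)
  lognormal_hits <- mean(replicate(50, {
    as.character(normality_gate(rlnorm(100, sdlog = 1.2))) == "non-normal"
  }))
  expect_gte(lognormal_hits, 0.9)

  g <- normality_gate(rep(5, 10))
  expect_identical(as.character(g), "non-normal")
  expect_true(attr(g, "degenerate"))
  expect_error(normality_gate(c(1, 2)), "insufficient data")
})

test_that("pooled t-test matches the hand-computed example", {
  r <- t_test_independent(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.2247449, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.2878641, tolerance = 1e-6)

  same <- t_test_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  shifted <- t_test_independent(rnorm(10, 0, 0.01), rnorm(10, 100, 0.01))
  expect_lt(shifted$p, 1e-6)

  degen <- t_test_independent(c(2, 2), c(2, 2))
  expect_identical(degen$flags, "degenerate-variance")
})

test_that("anova_bonferroni: omnibus, pairwise adjustment, cap at 1", {
  gs <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- anova_bonferroni(gs)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_true(all(r$posthoc$p_adjusted == 1))

  set.seed(6)
  gs2 <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15, 8))
  r2 <- anova_bonferroni(gs2)
  expect_lt(r2$p, 1e-6)
  ph <- r2$posthoc
  expect_gt(ph$p_adjusted[ph$group1 == "a" & ph$group2 == "b"], 0.5)
  expect_lt(max(ph$p_adjusted[ph$group2 == "c" | ph$group1 == "c"]), 1e-6)
  expect_true(all(ph$p_adjusted <= 1))
  expect_true(all(ph$p_adjusted >= pmin(1, ph$p_raw)))
})

test_that("fisher_exact matches closed forms and stats::fisher.test", {
  expect_equal(fisher_exact(matrix(1, 2, 2))$p, 1)
  expect_equal(fisher_exact(matrix(c(0, 10, 10, 0), 2, 2))$p, 2 / choose(20, 10))

  sexes <- matrix(c(9, 9, 36, 5), 2, 2, byrow = TRUE)  # men/women, two groups
  r <- fisher_exact(sexes)
  expect_lt(r$p, 0.05)
  expect_equal(r$p, stats::fisher.test(sexes)$p.value, tolerance = 1e-9)

  set.seed(14)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "margin")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
})

test_that("rank tests: exact small-sample enumeration and approximation agree", {
  r <- rank_tests(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p, 0.1)

  tied <- rank_tests(rep(2, 5), rep(2, 5))
  expect_equal(tied$p, 1)
  expect_identical(tied$flags, "all-tied")

  set.seed(23)
  a <- rnorm(25); b <- rnorm(25, 0.4)
  approx_p <- rank_tests(a, b)$p       # n > 20 -> normal approximation
  exact_p <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)$p.value
  expect_lt(abs(approx_p - exact_p), 0.02)

  kw <- rank_tests(rnorm(10), rnorm(10), rnorm(10, 5))
  expect_lt(kw$p, 0.01)
  expect_identical(kw$name, "Kruskal-Wallis")
})

test_that("linear_regression: perfect fit, inference, rank checks", {
  x <- 1:20
  m <- linear_regression(3 + 2 * x, data.frame(x = x))
  cf <- m$coefficients
  expect_equal(cf$B[cf$term == "x"], 2, tolerance = 1e-10)
  expect_lt(m$sigma, 1e-8)

  expect_error(linear_regression(rnorm(20), data.frame(x = x, x2 = 2 * x)),
               "collinear.*x2")
  expect_error(linear_regression(rnorm(3), data.frame(x = 1:3, z = c(1, 5, 2))),
               "insufficient data")

  set.seed(41)
  X <- data.frame(g = rnorm(41, 40, 30))
  y <- 5 + 0.15 * X$g + rnorm(41, 0, 3)
  m2 <- linear_regression(y, X)
  cf2 <- m2$coefficients[m2$coefficients$term == "g", ]
  expect_true(cf2$ci_lo < cf2$B && cf2$B < cf2$ci_hi)
})

test_that("backward_eliminate: boundaries and noise rejection", {
  set.seed(55)
  n <- 59
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  df$y <- 2 * df$x1 + 1.5 * df$x2 + rnorm(n, 0, 0.5)

  m <- backward_eliminate(df, "y", c("x1", "x2"))
  expect_length(m$eliminated, 0L)
  expect_setequal(m$retained, c("x1", "x2"))

  df$noise <- rnorm(n)
  m1 <- backward_eliminate(df, "y", c("x1", "x2", "noise"), threshold = 1.0)
  expect_length(m1$eliminated, 0L)  # threshold 1 eliminates nothing

  first_out <- replicate(200, {
    d <- data.frame(x1 = rnorm(n), noise = rnorm(n))
    d$y <- 2 * d$x1 + rnorm(n, 0, 1)
    m <- backward_eliminate(d, "y", c("x1", "noise"))
    identical(m$eliminated, "noise") || !("noise" %in% (m$retained %||% character(0)))
  })
  expect_gte(mean(first_out), 0.9)
})

test_that("run_model1 recovers a planted pooled-model structure", {
  set.seed(66)
  make_df <- function() {
    n <- 59
    df <- data.frame(
      group = sample(c(rep("control", 18), rep("nonobstructive", 28),
                       rep("obstructive", 13))),
      sex = sample(c("M", "F"), n, replace = TRUE),
      age = rnorm(n, 45, 12), bmi = rnorm(n, 27, 5),
      hr_peak = rnorm(n, 160, 20), peak_vo2 = rnorm(n, 28, 7))
    hc <- as.integer(df$group != "control")
    df$hr_at_60 <- 20 + 0.8 * df$hr_peak + 8 * hc + rnorm(n, 0, 4)
    df$hr_at_120 <- df$hr_at_60 - 10 + rnorm(n, 0, 4)
    df$hr_at_180 <- df$hr_at_120 - 6 + rnorm(n, 0, 4)
    df
  }
  hits <- replicate(100, {
    m <- run_model1(make_df())[["hr_at_60"]]
    all(c("hr_peak", "hc") %in% m$retained)
  })
  expect_gte(mean(hits), 0.9)

  null_small <- replicate(100, {
    df <- make_df()
    df$hr_at_60 <- rnorm(nrow(df), 120, 10)
    m <- run_model1(df)[["hr_at_60"]]
    length(m$retained %||% character(0))
  })
  expect_lte(stats::median(null_small), 1)

  df1 <- make_df(); df1$group <- "nonobstructive"
  expect_error(run_model1(df1), "single-group")
})

test_that("run_model2 screens and retains a planted gradient effect", {
  set.seed(91)
  make_patients <- function(gradient_effect = 0.15) {
    n <- 41
    df <- data.frame(
      group = c(rep("nonobstructive", 28), rep("obstructive", 13)),
      sex = sample(rep(c("M", "F"), c(36, 5))),
      hr_peak = rnorm(n, 150, 20),
      e_eprime_lateral = rnorm(n, 9, 3), la_size = rnorm(n, 44, 6),
      ef = rnorm(n, 67, 8), mwt = rnorm(n, 18, 4),
      lvot_gradient_peak = c(rlnorm(28, log(6), 0.66),
                             rlnorm(13, log(78), 0.38)))
    df$hr_at_180 <- 60 + 0.3 * df$hr_peak +
      gradient_effect * df$lvot_gradient_peak + rnorm(n, 0, 3)
    df$hr_at_60 <- df$hr_at_180 + 15 + rnorm(n, 0, 3)
    df$hr_at_120 <- df$hr_at_180 + 7 + rnorm(n, 0, 3)
    df
  }
  planted <- replicate(100, {
    m <- suppressMessages(run_model2(make_patients()))[["hr_at_180"]]
    ok <- "lvot_gradient_peak" %in% m$screened_in &&
      "lvot_gradient_peak" %in% m$stage2$retained
    b <- m$stage2$coefficients
    c(ok, b$B[b$term == "lvot_gradient_peak"])
  })
  expect_gte(mean(planted[1, ]), 0.9)
  expect_equal(mean(planted[2, ], na.rm = TRUE), 0.15, tolerance = 0.2)

  nulls <- replicate(100, {
    m <- suppressMessages(run_model2(make_patients(0)))[["hr_at_180"]]
    !("lvot_gradient_peak" %in% m$screened_in)
  })
  expect_gte(mean(nulls), 0.9)

  # empty screen: stage 2 holds only the forced covariates
  df0 <- make_patients(0)
  df0$hr_at_180 <- 0.6 * df0$hr_peak + rnorm(41, 0, 2)
  m0 <- suppressMessages(run_model2(df0))[["hr_at_180"]]
  if (!length(m0$screened_in)) {
    expect_setequal(m0$stage2$retained, c("hr_peak", "sex_male"))
  }
})

test_that("table1_summary styles, identities and degenerate cohorts", {
  set.seed(19)
  n <- 60
  df <- data.frame(group = rep(c("control", "nonobstructive", "obstructive"),
                               each = 20),
                   hr_peak = rnorm(n, 160, 18), hr_rest = rnorm(n, 78, 12))
  df$delta_hr <- df$hr_peak - df$hr_rest
  tab <- table1_summary(df, variables = c("hr_peak", "hr_rest", "delta_hr"))
  expect_identical(tab$variable, c("hr_peak", "hr_rest", "delta_hr"))
  expect_true(all(c("control", "all_hc", "nonobstructive", "obstructive")
                  %in% names(tab)))
  # linearity: group mean of delta equals mean(peak) - mean(rest)
  for (g in unique(df$group)) {
    sel <- df$group == g
    expect_equal(mean(df$delta_hr[sel]),
                 mean(df$hr_peak[sel]) - mean(df$hr_rest[sel]))
  }
  ident <- data.frame(group = rep(c("control", "nonobstructive"), each = 5),
                      hr_peak = rep(150, 10))
  tabi <- table1_summary(ident, variables = "hr_peak")
  expect_true(is.na(tabi$p_control_vs_hc))
})
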