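#' Published group-level reference values
#'
#' Group means and SDs of the heart-rate variables from the study's baseline
#' table, used to parameterise the synthetic cohort generator and as inputs
#' to the arithmetic-identity checks (the cohort mean of per-subject
#' differences equals the difference of cohort means, so group-mean inputs
#' must reproduce the printed group-mean reductions).
#'
#' @return Data frame with one row per group (`control`, `all_hc`,
#'   `nonobstructive`, `obstructive`): `n`, and mean/SD pairs for resting HR,
#'   peak HR, and the mean HR at 1, 2 and 3 minutes of recovery (beats/min).
#' @export
table1_reference <- function() {
  data.frame(
    group = c("control", "all_hc", "nonobstructive", "obstructive"),
    n = c(18L, 41L, 28L, 13L),
    hr_rest_mean = c(80.5, 76.6, 74.6, 81.1),
    hr_rest_sd = c(14.7, 14.51, 15.8, 10.6),
    hr_peak_mean = c(176.8, 149.8, 148.3, 153.0),
    hr_peak_sd = c(18.1, 21.7, 24.4, 14.7),
    hr_1min_mean = c(141.4, 124.1, 121.9, 128.9),
    hr_1min_sd = c(24.19, 19.3, 21.5, 13.1),
    hr_2min_mean = c(123.2, 113.6, 110.5, 118.5),
    hr_2min_sd = c(25.7, 17.1, 18.9, 11.3),
    hr_3min_mean = c(114.7, 108.6, 104.9, 116.6),
    hr_3min_sd = c(24.1, 16.8, 16.6, 14.7),
    stringsAsFactors = FALSE
  )
}
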