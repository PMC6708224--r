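# Published reference values from the clinical MS fatigue cohort analysis
# (n = 212 severely fatigued patients, 7-day ActiGraph wear) that the
# package's defaults emulate. These are fixtures: regression anchors for the
# key-measure selection rule and generative parameters for the synthetic
# cohort. They are not recomputed by the package.

#' Measure metadata for the 15 physical-behavior measures
#'
#' Internal names, display labels, domain (physical activity vs sedentary
#' behavior) and category (amount/intensity, frequency/duration, day
#' pattern) for the fifteen measures the pipeline computes.
#'
#' @return a data.frame with columns `measure`, `label`, `domain`,
#'   `category`.
#' @export
pb_measure_info <- function() {
  data.frame(
    measure = c("pct_active", "pct_mvpa", "cpd", "cpm", "pct_sb",
                "mvpa_bl", "mvpa_nob", "tt_mvpa", "sb_bl", "sb_nob", "tt_sb",
                "d_mvpa1", "d_mvpa2", "d_sb1", "d_sb2"),
    label = c("%Active", "%MVPA", "CPD", "CPM", "%SB",
              "MVPA BL", "MVPA NoB", "tt MVPA", "SB BL", "SB NoB", "tt SB",
              "dMVPA1", "dMVPA2", "dSB1", "dSB2"),
    domain = c("PA", "PA", "PA", "PA", "SB",
               "PA", "PA", "PA", "SB", "SB", "SB",
               "PA", "PA", "SB", "SB"),
    category = c(rep("amount_intensity", 5),
                 rep("frequency_duration", 6),
                 rep("day_pattern", 4)),
    stringsAsFactors = FALSE
  )
}

#' Reference rotated pattern-loading matrix (15 measures x 5 components)
#'
#' The published oblimin pattern loadings of the reference cohort, with the
#' component eigenvalues and percentage of explained variance as attributes.
#' Used as the regression fixture for [select_key_measures()].
#'
#' @return a 15 x 5 numeric matrix with measure rownames and attributes
#'   `eigenvalues` and `pct_variance` (length-5 numeric vectors).
#' @export
pb_reference_loadings <- function() {
  m <- matrix(c(
     0.97,  0.02,  0.04, -0.10, -0.04,   # pct_active
     0.78,  0.07, -0.08,  0.36, -0.10,   # pct_mvpa
    -0.97, -0.02, -0.04,  0.10,  0.03,   # cpd
     0.88,  0.09,  0.04,  0.20, -0.09,   # cpm
     0.92,  0.07, -0.06,  0.18, -0.08,   # pct_sb
    -0.04,  0.08, -0.09,  0.64,  0.01,   # mvpa_bl
    -0.04, -0.10,  0.39,  0.48,  0.04,   # mvpa_nob
     0.42, -0.06,  0.04,  0.67, -0.07,   # tt_mvpa
    -0.63,  0.06, -0.64,  0.15, -0.03,   # sb_bl
    -0.16,  0.07,  0.94, -0.01, -0.05,   # sb_nob
    -0.83,  0.16,  0.18,  0.16, -0.12,   # tt_sb
    -0.07, -0.94,  0.02,  0.05, -0.02,   # d_mvpa1
    -0.03,  0.21,  0.07, -0.21,  0.79,   # d_mvpa2
    -0.02,  0.91,  0.05,  0.08,  0.04,   # d_sb1
     0.00,  0.07,  0.06, -0.21, -0.93    # d_sb2
  ), ncol = 5, byrow = TRUE)
  rownames(m) <- pb_measure_info()$measure
  colnames(m) <- paste0("PC", 1:5)
  attr(m, "eigenvalues") <- c(5.94, 1.98, 1.58, 1.36, 1.15)
  attr(m, "pct_variance") <- c(39.59, 13.21, 10.53, 9.07, 7.68)
  m
}

#' Reference subtype profiles of the clinical cohort
#'
#' Per-subtype sample sizes, key-measure means and SDs, and covariate
#' distributions of the three published physical-behavior subtypes. These
#' are the default generative parameters of [default_subtype_specs()].
#'
#' Units: `pct_sb` percent of wear time; `tt_mvpa` minutes per week in
#' prolonged (>= 10 min) MVPA bouts; `sb_nob` sedentary bouts per week;
#' `d_sb1`, `d_sb2` percentage-point day-part change scores.
#'
#' @return a list with elements `n` (named integer vector), `measures`
#'   (list per subtype of `mean`/`sd` named vectors), and `covariates`
#'   (list per subtype).
#' @export
pb_reference_profiles <- function() {
  key <- c("pct_sb", "tt_mvpa", "sb_nob", "d_sb1", "d_sb2")
  mk <- function(mean, sd) list(mean = setNames(mean, key),
                                sd = setNames(sd, key))
  list(
    n = c(afternoon_active = 46L, most_sedentary = 114L,
          most_active = 48L),
    measures = list(
      afternoon_active = mk(c(63.8,  94.1, 766.6, -8.8, 19.5),
                               c( 7.5,  67.5, 178.2,  8.3,  6.8)),
      most_sedentary      = mk(c(69.0,  89.6, 794.7,  2.1,  6.8),
                               c( 6.2,  62.5, 177.4,  7.3,  6.6)),
      most_active         = mk(c(54.2, 195.9, 706.1, -0.2, 12.9),
                               c( 6.0,  97.8, 135.6,  8.6,  7.3))
    ),
    covariates = list(
      afternoon_active = list(
        male_fraction = 0.304,
        ms_type = c(RR = 0.804, PP = 0.087, SP = 0.087, EU = 0.021),
        age = c(mean = 49.8, sd = 8.7), bmi = c(mean = 25.1, sd = 3.75),
        edss = c(median = 3, iqr = 1.9), cis20r = c(mean = 42.3, sd = 7.2),
        duration = c(median = 6.9, iqr = 10.3)),
      most_sedentary = list(
        male_fraction = 0.272,
        ms_type = c(RR = 0.681, PP = 0.115, SP = 0.124, EU = 0.080),
        age = c(mean = 46.0, sd = 10.7), bmi = c(mean = 25.6, sd = 5.2),
        edss = c(median = 3, iqr = 2), cis20r = c(mean = 44.2, sd = 7.4),
        duration = c(median = 6.7, iqr = 11.9)),
      most_active = list(
        male_fraction = 0.188,
        ms_type = c(RR = 0.833, PP = 0.063, SP = 0.042, EU = 0.063),
        age = c(mean = 44.4, sd = 10.6), bmi = c(mean = 24.1, sd = 3.4),
        edss = c(median = 2, iqr = 1.5), cis20r = c(mean = 44.0, sd = 6.6),
        duration = c(median = 4.9, iqr = 12.4))
    )
  )
}

#' The five canonical key measures
#'
#' @return character vector of internal measure names, one per component in
#'   descending component-variance order.
#' @export
pb_key_measures <- function() {
  c("pct_sb", "d_sb1", "sb_nob", "tt_mvpa", "d_sb2")
}
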