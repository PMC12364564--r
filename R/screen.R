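# Pairwise shape-performance regressions and the packaged reference tables.

#' Load the packaged spine reference tables
#'
#' Returns the two packaged per-species and per-spine tables used as
#' regression inputs and as fixtures: `table1` (one row per sampled
#' species: family, snout-vent length, spine count, largest spine volume,
#' highest structural curvature) and `table2` (one row per mechanically
#' tested spine: tip angle, length-normalised tip radius of curvature,
#' puncture range, lowest and average puncture force, and a broken flag
#' for the spine that fractured during testing). Missing force entries
#' (the spine that never punctured) are `NA`. File checksums are verified
#' on load.
#'
#' @return list with data frames `table1` and `table2`.
#' @export
load_spine_tables <- function() {
  f1 <- system.file("extdata", "spine_species_table1.csv",
                    package = "spinemorph", mustWork = TRUE)
  f2 <- system.file("extdata", "spine_performance_table2.csv",
                    package = "spinemorph", mustWork = TRUE)
  sums <- tools::md5sum(c(f1, f2))
  expect <- c("1a3ca4ba65fc4b2c2a51432239ee6efb",
              "b1c3401c23118769d4b879c68331eec4")
  if (!identical(unname(sums), expect)) {
    stopf("packaged reference tables failed checksum verification")
  }
  t1 <- utils::read.csv(f1, na.strings = "na", stringsAsFactors = FALSE)
  t2 <- utils::read.csv(f2, na.strings = "na", stringsAsFactors = FALSE)
  list(table1 = t1, table2 = t2)
}

#' Pairwise ordinary least squares
#'
#' Simple linear regression with intercept after listwise deletion of
#' incomplete pairs; the slope p-value is the two-sided t test with n - 2
#' degrees of freedom.
#'
#' @param y response vector.
#' @param x predictor vector, same length.
#' @return one-row data frame: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
ols <- function(y, x) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("fewer than 3 complete pairs")
  if (stats::var(x) < 1e-24) stopf("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  data.frame(slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             r_squared = sm$r.squared,
             p_value = sm$coefficients[2L, 4L],
             n = length(x))
}

#' Screen shape predictors against a puncture-performance response
#'
#' Runs one pairwise linear model per predictor against the chosen
#' performance response over a per-spine table (the packaged reference
#' table or a measured one). The cohort policy controls exclusions:
#' `"default"` drops spines flagged broken everywhere; never-puncturing
#' spines (range 0 with missing forces) remain in puncture-range models
#' and drop out of force models through their missing values.
#' `"include_broken"` keeps broken spines. A Benjamini-Hochberg adjusted
#' p-value column is added for transparency; the primary p-values are
#' unadjusted marginal values.
#'
#' @param tab data frame with one row per spine.
#' @param response one of `"average_force"`, `"puncture_range"`,
#'   `"lowest_force"` (or a column name present in `tab`).
#' @param predictors character vector of predictor column names.
#' @param cohort `"default"` or `"include_broken"`.
#' @return data frame with one row per predictor: `response`, `predictor`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `p_adjusted_bh`, `n`;
#'   attribute `cohort` records the spine ids used per model.
#' @export
shape_performance_screen <- function(tab,
                                     response = c("average_force",
                                                  "puncture_range",
                                                  "lowest_force"),
                                     predictors = c("tip_angle_deg",
                                                    "tip_roc_norm"),
                                     cohort = c("default",
                                                "include_broken")) {
  cohort <- match.arg(cohort)
  response <- response[1L]
  resp_col <- switch(response,
                     average_force = "average_force_n",
                     puncture_range = "puncture_range_deg",
                     lowest_force = "lowest_force_n",
                     response)
  if (!resp_col %in% names(tab)) {
    stopf("response column '%s' not found", resp_col)
  }
  missing_pred <- setdiff(predictors, names(tab))
  if (length(missing_pred)) {
    stopf("predictor(s) not found: %s", paste(missing_pred, collapse = ", "))
  }
  if (cohort == "default" && "broken" %in% names(tab)) {
    tab <- tab[!isTRUE_vec(tab$broken), , drop = FALSE]
  }
  used <- list()
  rows <- lapply(predictors, function(p) {
    ok <- stats::complete.cases(tab[[resp_col]], tab[[p]])
    used[[p]] <<- if ("spine_id" %in% names(tab)) tab$spine_id[ok] else which(ok)
    cbind(data.frame(response = response, predictor = p,
                     stringsAsFactors = FALSE),
          ols(tab[[resp_col]], tab[[p]]))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted_bh <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "cohort") <- used
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
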