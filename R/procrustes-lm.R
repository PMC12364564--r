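#' Permutation linear model on Procrustes shape data
#'
#' Tests the association between aligned shape and a covariate with a
#' linear model on the vectorised GPA-aligned coordinates, evaluated by
#' residual randomization: the effect and residual Procrustes sums of
#' squares come from the least-squares fit, F = (SS_eff / df_eff) /
#' (SS_res / df_res), and the p-value is the proportion of permutations
#' (residuals of the reduced, intercept-only model randomized across
#' specimens, observed case included) with F at least as large as
#' observed.
#'
#' @param g a [gpa()] result.
#' @param covariate numeric vector or factor, one value per specimen, no
#'   missing values.
#' @param n_permutations number of random permutations (the observed
#'   arrangement is added to the null set, so the smallest attainable
#'   p-value is `1 / (n_permutations + 1)`).
#' @param seed integer seed; p-values are bit-reproducible given the seed.
#' @return object of class `procrustes_lm`: `ss_effect`, `ss_residual`,
#'   `df_effect`, `df_residual`, `f_statistic`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
procrustes_lm <- function(g, covariate, n_permutations = 999L, seed = 1L) {
  stopifnot(inherits(g, "gpa"))
  n <- dim(g$aligned)[3L]
  if (length(covariate) != n) {
    stopf("covariate length (%d) does not match specimen count (%d)",
          length(covariate), n)
  }
  if (anyNA(covariate)) stopf("covariate contains missing values")
  X <- if (is.factor(covariate) || is.character(covariate)) {
    fac <- factor(covariate)
    if (nlevels(fac) < 2L) stopf("constant covariate")
    stats::model.matrix(~fac)[, -1L, drop = FALSE]
  } else {
    if (stats::var(covariate) < 1e-24) stopf("constant covariate")
    matrix(as.numeric(covariate), ncol = 1L)
  }
  Y <- t(apply(g$aligned, 3L, as.numeric))
  Yc <- scale(Y, scale = FALSE)            # residuals of the reduced model
  Xc <- scale(X, scale = FALSE)
  qx <- qr(Xc)
  df_eff <- qx$rank
  df_res <- n - df_eff - 1L
  if (df_res < 1L) stopf("too few specimens for the model")

  ss_for <- function(Ymat) {
    fitted <- qr.fitted(qx, Ymat)
    ss_eff <- sum(fitted^2)
    ss_tot <- sum(Ymat^2)
    c(ss_eff, ss_tot - ss_eff)
  }
  obs <- ss_for(Yc)
  f_obs <- (obs[1L] / df_eff) / (obs[2L] / df_res)

  f_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      Yp <- Yc[sample.int(n), , drop = FALSE]
      ssp <- ss_for(Yp)
      (ssp[1L] / df_eff) / (ssp[2L] / df_res)
    }, numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (n_permutations + 1)
  structure(list(ss_effect = obs[1L], ss_residual = obs[2L],
                 df_effect = df_eff, df_residual = df_res,
                 f_statistic = f_obs, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "procrustes_lm")
}

#' @export
print.procrustes_lm <- function(x, ...) {
  cat(sprintf(
    "Procrustes LM: SS_eff %.4g (df %d), SS_res %.4g (df %d), F = %.3f, p = %.4g (%d permutations)\n",
    x$ss_effect, x$df_effect, x$ss_residual, x$df_residual,
    x$f_statistic, x$p_value, x$n_permutations))
  invisible(x)
}
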