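# Foci-counting statistics and the dose-response calibration: Poisson
# summaries with background subtraction, per-dataset and pooled ordinary
# least-squares fits, normality/homogeneity checks on the slopes, the
# confidence band, forward prediction and inverse dose estimation.

#' Summarise scored foci counts
#'
#' Mean foci per cell and its Poisson standard error,
#' `sqrt(mean / cells)`, as used when foci are counted manually in a fixed
#' number of cell nuclei.
#'
#' @param total_foci total foci counted over all cells; alternatively a
#'   vector of per-cell counts (then `cells_scored` defaults to its
#'   length).
#' @param cells_scored number of cells scored (>= 1).
#' @return object of class `foci_measurement`: `cells`, `total`, `mean`,
#'   `se`.
#' @examples
#' summarize_counts(17, 100)   # 0.17 +- 0.041 foci/cell
#' @export
summarize_counts <- function(total_foci, cells_scored = NULL) {
  if (length(total_foci) > 1) {
    if (is.null(cells_scored)) cells_scored <- length(total_foci)
    total_foci <- sum(total_foci)
  }
  if (is.null(cells_scored) || cells_scored < 1)
    stop("cells_scored must be at least 1")
  if (total_foci < 0 || total_foci != round(total_foci))
    stop("total_foci must be a non-negative integer")
  m <- total_foci / cells_scored
  structure(list(cells = cells_scored, total = total_foci, mean = m,
                 se = sqrt(m / cells_scored)),
            class = "foci_measurement")
}

#' @export
print.foci_measurement <- function(x, ...) {
  cat(sprintf("%.3f +- %.3f foci/cell (%d foci in %d cells)\n",
              x$mean, x$se, x$total, x$cells))
  invisible(x)
}

#' Background-subtracted radiation-induced foci
#'
#' Net RIF/cell = exposed mean - background mean, with the two Poisson
#' standard errors combined in quadrature.  Negative net values are kept
#' (clipping them would bias low-dose fits); only reported dose point
#' estimates are clipped at zero.
#'
#' @param sample,background `foci_measurement` objects for the exposed
#'   aliquot and its matched unexposed aliquot.
#' @return list with `net` (RIF/cell) and `se`.
#' @export
net_rif <- function(sample, background) {
  stopifnot(inherits(sample, "foci_measurement"),
            inherits(background, "foci_measurement"))
  list(net = sample$mean - background$mean,
       se = sqrt(sample$se^2 + background$se^2))
}

new_calibration_fit <- function(fit, n) {
  cf <- stats::coef(fit)
  # summary.lm warns on zero-residual fits; exact lines are legitimate
  # inputs here (noise-free synthetic checks)
  sm <- suppressWarnings(summary(fit))
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 se_intercept = sm$coefficients[1, 2],
                 se_slope = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 sigma2 = sm$sigma^2,
                 cov = suppressWarnings(stats::vcov(fit)),
                 n = n, df = fit$df.residual),
            class = "calibration_fit")
}

#' Ordinary least-squares dose-response fit for one dataset
#'
#' Unweighted OLS of net RIF/cell on absorbed dose (mGy).  The counting
#' errors are deliberately not used as weights by default, matching how
#' such calibration lines are usually fitted; set `weights` for a
#' weighted sensitivity fit.
#'
#' @param dose_mGy absorbed doses, mGy.
#' @param net net RIF/cell values.
#' @param weights optional fit weights (e.g. `1/se^2`).
#' @return object of class `calibration_fit`: `intercept`, `slope`, their
#'   standard errors, `r_squared`, residual variance `sigma2`, parameter
#'   covariance `cov`, `n`, `df`.
#' @export
fit_dataset <- function(dose_mGy, net, weights = NULL) {
  if (length(dose_mGy) != length(net)) stop("dose and net lengths differ")
  if (length(unique(dose_mGy)) < 3)
    stop("need at least 3 samples with distinct doses")
  if (stats::var(dose_mGy) == 0) stop("zero dose variance")
  df <- data.frame(dose = dose_mGy, net = net)
  fit <- if (is.null(weights)) stats::lm(net ~ dose, data = df)
         else stats::lm(net ~ dose, data = df, weights = weights)
  new_calibration_fit(fit, length(net))
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("net RIF/cell = %.4f (+-%.4f) + %.4f (+-%.4f) * dose[mGy]\n",
              x$intercept, x$se_intercept, x$slope, x$se_slope))
  cat(sprintf("  n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  invisible(x)
}

#' Pooled dose-response fit
#'
#' OLS over all (dose, net RIF) points of a study.  Pooling is only
#' meaningful when the per-subject slopes are homogeneous; pass the
#' one-way ANOVA p-value obtained upstream, or `force = TRUE` to pool
#' regardless.
#'
#' @inheritParams fit_dataset
#' @param anova_p p-value of the one-way ANOVA comparing per-dataset
#'   slopes between subjects; pooling requires `anova_p > 0.05`.
#' @param force pool without (or despite) the ANOVA check.
#' @return a `calibration_fit` over all points.
#' @export
pooled_fit <- function(dose_mGy, net, weights = NULL, anova_p = NULL,
                       force = FALSE) {
  if (!force && !is.null(anova_p) && anova_p <= 0.05)
    stop(sprintf("slopes differ between subjects (ANOVA p = %.3g); use force = TRUE to pool anyway",
                 anova_p))
  fit_dataset(dose_mGy, net, weights)
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric sample, 3 <= n <= 50.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 50) stop("Shapiro-Wilk test requires 3 <= n <= 50")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' One-way ANOVA on grouped values
#'
#' Standard one-way analysis of variance, e.g. per-dataset calibration
#' slopes grouped by subject.
#'
#' @param values numeric vector.
#' @param groups grouping factor of the same length.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 1) || !any(sizes >= 2))
    stop("degenerate grouping: need every group non-empty and at least one group with 2+ values")
  # aov warns when the groups are an essentially perfect fit (e.g. the
  # degenerate noise-free designs used in recovery checks)
  a <- suppressWarnings(stats::anova(stats::aov(values ~ groups)))
  list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1],
       df_between = a$Df[1], df_within = a$Df[2])
}

#' Pointwise confidence band for the calibration line
#'
#' Confidence interval for the mean response at each dose from the
#' parameter covariance and the t quantile with `n - 2` degrees of
#' freedom; the band is narrowest at the mean design dose.
#'
#' @param fit a `calibration_fit`.
#' @param dose_mGy dose grid, mGy.
#' @param level confidence level in (0, 1).
#' @return data.frame with `dose_mGy`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, dose_mGy, level = 0.95) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  y <- fit$intercept + fit$slope * dose_mGy
  se <- sqrt(fit$cov[1, 1] + 2 * dose_mGy * fit$cov[1, 2] +
               dose_mGy^2 * fit$cov[2, 2])
  tq <- stats::qt(1 - (1 - level) / 2, fit$df)
  data.frame(dose_mGy = dose_mGy, fit = y, lower = y - tq * se,
             upper = y + tq * se)
}

#' Predict net RIF/cell at a dose
#'
#' @param fit a `calibration_fit` (or anything with `intercept` and
#'   `slope` elements, e.g. [reference_calibration()]).
#' @param dose_mGy absorbed dose, mGy (>= 0, vectorised).
#' @return predicted net RIF/cell, `intercept + slope * dose`.
#' @examples
#' predict_rif(reference_calibration(), 500)  # ~7.4 RIF/cell
#' @export
predict_rif <- function(fit, dose_mGy) {
  if (any(dose_mGy < 0)) stop("dose must be non-negative")
  fit$intercept + fit$slope * dose_mGy
}

#' Inverse dose estimation from an observed foci measurement
#'
#' Point estimate `(net - intercept) / slope` with a confidence interval
#' propagating the net-measurement standard error and the fit parameter
#' covariance, by the delta method (default) or as a Fieller interval.
#' Dose point estimates below zero are clipped to zero and flagged.
#'
#' @param fit a `calibration_fit`.
#' @param observed `foci_measurement` for the sample (or a list with
#'   elements `net` and `se` if background subtraction was already done,
#'   in which case leave `background` as `NULL`).
#' @param background matched unexposed `foci_measurement`, or `NULL`.
#' @param level confidence level.
#' @param method `"delta"` or `"fieller"`.
#' @return object of class `dose_estimate`: `dose`, `ci_low`, `ci_high`
#'   (mGy), `se`, `level`, `method`, `clipped`.
#' @export
estimate_dose <- function(fit, observed, background = NULL, level = 0.95,
                          method = c("delta", "fieller")) {
  stopifnot(inherits(fit, "calibration_fit"))
  method <- match.arg(method)
  if (fit$slope <= 0) stop("calibration slope must be positive")
  if (!is.null(background)) {
    nr <- net_rif(observed, background)
  } else if (inherits(observed, "foci_measurement")) {
    nr <- list(net = observed$mean, se = observed$se)
  } else nr <- observed
  a <- fit$intercept; b <- fit$slope
  vaa <- fit$cov[1, 1]; vab <- fit$cov[1, 2]; vbb <- fit$cov[2, 2]
  x <- (nr$net - a) / b
  tq <- if (is.finite(fit$df) && fit$df > 0)
    stats::qt(1 - (1 - level) / 2, fit$df) else stats::qnorm(1 - (1 - level) / 2)
  if (method == "delta") {
    # the parameter part can dip below zero for externally supplied,
    # internally inconsistent covariances; clamp rather than propagate NaN
    vx <- (nr$se^2 + pmax(vaa + 2 * x * vab + x^2 * vbb, 0)) / b^2
    se <- sqrt(vx)
    lo <- x - tq * se; hi <- x + tq * se
  } else {
    # Fieller: roots of (net - a - b x)^2 = t^2 (V0 + 2 x vab + x^2 vbb)
    nn <- nr$net - a
    A <- b^2 - tq^2 * vbb
    B <- -2 * (nn * b + tq^2 * vab)
    C <- nn^2 - tq^2 * (nr$se^2 + vaa)
    disc <- B^2 - 4 * A * C
    if (A <= 0 || disc < 0) {
      warning("Fieller interval unbounded; slope not significant at this level")
      lo <- 0; hi <- Inf
    } else {
      rts <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
      lo <- rts[1]; hi <- rts[2]
    }
    se <- NA_real_
  }
  clipped <- x < 0
  structure(list(dose = max(x, 0), ci_low = min(lo, max(x, 0)),
                 ci_high = max(hi, max(x, 0)), se = se, level = level,
                 method = method, clipped = clipped),
            class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf("estimated dose %.1f mGy (%d%% CI %.1f - %.1f, %s)%s\n",
              x$dose, round(100 * x$level), x$ci_low, x$ci_high, x$method,
              if (x$clipped) " [point estimate clipped at 0]" else ""))
  invisible(x)
}

#' Reference pooled calibration
#'
#' The pooled in-vitro calibration line for this assay configuration,
#' net RIF/cell = 0.0363 + 0.0147 * dose[mGy], with standard errors
#' 0.0182 (intercept) and 0.0006 (slope), R^2 = 0.92 over 55 samples.
#' The intercept/slope covariance is reconstructed from the OLS identity
#' `cov(a, b) = -mean(x) * se_b^2` at the design mean dose.
#'
#' @param mean_dose_mGy mean dose of the calibration design, used only to
#'   reconstruct the parameter covariance.  The published standard errors
#'   imply a mean calibration dose no larger than `se_a/se_b ~ 30` mGy
#'   (the design oversampled the low-dose end), so the default stays
#'   safely below that bound; values above it would make the
#'   reconstructed covariance inconsistent.
#' @return a `calibration_fit`.
#' @export
reference_calibration <- function(mean_dose_mGy = 25) {
  se_a <- 0.0182; se_b <- 0.0006
  cov <- matrix(c(se_a^2, -mean_dose_mGy * se_b^2,
                  -mean_dose_mGy * se_b^2, se_b^2), 2, 2,
                dimnames = list(c("(Intercept)", "dose"),
                                c("(Intercept)", "dose")))
  structure(list(intercept = 0.0363, slope = 0.0147,
                 se_intercept = se_a, se_slope = se_b,
                 r_squared = 0.92, sigma2 = NA_real_, cov = cov,
                 n = 55, df = 53),
            class = "calibration_fit")
}
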