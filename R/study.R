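# Study-level calibration: per-dataset fits, normality and homogeneity
# checks on the slopes, the pooling decision, and the pooled line.

# net RIF and SE per row of a sample table
add_net_columns <- function(samples) {
  m <- samples$total_foci / samples$cells_scored
  mb <- samples$bg_total_foci / samples$bg_cells_scored
  samples$net_rif <- m - mb
  samples$net_se <- sqrt(m / samples$cells_scored +
                           mb / samples$bg_cells_scored)
  samples
}

#' Run the full calibration on a sample table
#'
#' Computes background-subtracted net RIF/cell per sample, fits each
#' dataset (blood draw x nuclide) separately by OLS, tests the slopes for
#' normality (Shapiro-Wilk, overall and per subject) and for between-
#' subject homogeneity (one-way ANOVA), and pools all points into a single
#' calibration line when the ANOVA is non-significant (p > 0.05) or when
#' `force_pool = TRUE`.
#'
#' @param samples data.frame with columns `subject_id`, `dataset_id`,
#'   `nuclide`, `dose_mGy`, `cells_scored`, `total_foci`,
#'   `bg_cells_scored`, `bg_total_foci` (see [read_samples()]).
#' @param force_pool pool even if the ANOVA rejects homogeneity.
#' @param weighted use `1/se^2` weights in the fits (sensitivity option;
#'   the default, like the published calibrations this mirrors, is
#'   unweighted).
#' @return object of class `calibration_report`: `per_dataset`
#'   (data.frame of per-dataset fits), `slopes_mean`, `slopes_sd`,
#'   `shapiro_slopes`, `shapiro_by_subject`, `anova`, `pooled`
#'   (a `calibration_fit`, or `NULL` when pooling was not justified),
#'   `pooled_decision`, plus the echo of the options.
#' @export
calibrate_study <- function(samples, force_pool = FALSE, weighted = FALSE) {
  req <- c("subject_id", "dataset_id", "nuclide", "dose_mGy",
           "cells_scored", "total_foci", "bg_cells_scored", "bg_total_foci")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  samples <- add_net_columns(samples)

  ds <- split(samples, samples$dataset_id)
  per <- do.call(rbind, lapply(ds, function(d) {
    w <- if (weighted) 1 / pmax(d$net_se^2, 1e-12) else NULL
    f <- fit_dataset(d$dose_mGy, d$net_rif, weights = w)
    data.frame(dataset_id = d$dataset_id[1], subject_id = d$subject_id[1],
               nuclide = d$nuclide[1], n = f$n, slope = f$slope,
               intercept = f$intercept, se_slope = f$se_slope,
               se_intercept = f$se_intercept, r_squared = f$r_squared)
  }))
  rownames(per) <- NULL

  # constant slopes (noise-free designs) make the normality test
  # inapplicable; report NULL instead of failing
  sw_all <- if (nrow(per) >= 3)
    tryCatch(shapiro_wilk(per$slope), error = function(e) NULL) else NULL
  sw_subj <- lapply(split(per$slope, per$subject_id), function(s)
    if (length(s) >= 3)
      tryCatch(shapiro_wilk(s), error = function(e) NULL) else NULL)
  an <- if (length(unique(per$subject_id)) >= 2)
    anova_oneway(per$slope, per$subject_id) else NULL

  decision <- force_pool || (is.null(an) || an$p > 0.05)
  w_all <- if (weighted) 1 / pmax(samples$net_se^2, 1e-12) else NULL
  pooled <- if (decision)
    pooled_fit(samples$dose_mGy, samples$net_rif, weights = w_all,
               anova_p = if (is.null(an)) NULL else an$p,
               force = force_pool) else NULL

  structure(list(per_dataset = per,
                 slopes_mean = mean(per$slope),
                 slopes_sd = stats::sd(per$slope),
                 shapiro_slopes = sw_all,
                 shapiro_by_subject = sw_subj,
                 anova = an,
                 pooled = pooled,
                 pooled_decision = decision,
                 force_pool = force_pool,
                 weighted = weighted,
                 n_samples = nrow(samples)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report>  %d samples, %d datasets\n",
              x$n_samples, nrow(x$per_dataset)))
  cat(sprintf("  mean of slopes %.4f +- %.4f RIF/cell per mGy\n",
              x$slopes_mean, x$slopes_sd))
  if (!is.null(x$shapiro_slopes))
    cat(sprintf("  Shapiro-Wilk on slopes: W = %.3f, p = %.2f\n",
                x$shapiro_slopes$W, x$shapiro_slopes$p))
  if (!is.null(x$anova))
    cat(sprintf("  one-way ANOVA between subjects: F = %.2f, p = %.2f\n",
                x$anova$F, x$anova$p))
  if (!is.null(x$pooled)) {
    cat("  pooled fit:\n    ")
    print(x$pooled)
  } else cat("  not pooled (slopes heterogeneous)\n")
  invisible(x)
}
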