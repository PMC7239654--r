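#' Four-parameter logistic (variable-slope) response curve
#'
#' `response = Bottom + (Top - Bottom) / (1 + 10^(hill * (log_ec50 - log10(dose))))`.
#' With `hill > 0` the response rises from `Bottom` at low dose to `Top` at
#' high dose, crossing the midpoint at `dose = 10^log_ec50`.
#'
#' @param dose dose(s) in nM, strictly positive.
#' @param bottom,top asymptotic responses (arbitrary fluorescence units).
#' @param log_ec50 log10 of the half-maximal dose (log10 nM).
#' @param hill dimensionless slope factor.
#' @return Response values, same length as `dose`.
#' @export
fourpl <- function(dose, bottom, top, log_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log_ec50 - log10(dose))))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the variable-slope 4PL model, parameterized in
#' log10-EC50 for numerical stability. Standard errors come from the curvature
#' of the fit at the optimum (the estimated covariance of the nonlinear
#' least-squares estimator). Wells at dose 0 (untreated controls) are excluded
#' (log dose undefined); set `anchor_bottom = TRUE` to instead use their mean
#' response as a fixed `Bottom`.
#'
#' The fit is flagged non-converged — and no EC50 is reported — when the
#' optimizer fails, the fitted dynamic range is not positive, or the fitted
#' EC50 falls more than 10-fold outside the dosed range (the data then do not
#' bracket the midpoint and the estimate is extrapolation).
#'
#' @param data data.frame with columns `dose` (nM) and `response`, or a
#'   titration table with `dose_nM`/`response` as written by
#'   [simulate_dose_response()]; replicate wells are individual rows.
#' @param anchor_bottom if `TRUE`, fix `Bottom` at the mean zero-dose response.
#' @return A `fourpl_fit`: list with `bottom`, `top`, `log_ec50`, `hill`,
#'   their standard errors (`se_*`), `residual_df` (points minus free
#'   parameters), `rss`, `n_points`, `dose_range` and `converged`.
#' @examples
#' d <- simulate_dose_response(bottom = 100, top = 1000, ec50 = 0.05, hill = 1,
#'                             doses = 10 / 3^(0:7), noise_sd = 0,
#'                             n_replicates = 1, seed = 1)
#' fit <- fit_4pl(d)
#' ec50(fit)
#' @export
fit_4pl <- function(data, anchor_bottom = FALSE) {
  data <- as.data.frame(data)
  if (!"dose" %in% names(data) && "dose_nM" %in% names(data)) {
    data$dose <- data$dose_nM
  }
  if (!all(c("dose", "response") %in% names(data))) {
    abort("`data` needs columns dose (or dose_nM) and response")
  }
  if (any(data$dose < 0)) abort("doses must be non-negative")
  if (any(!is.finite(data$response))) abort("responses must be finite")
  zero <- data$dose == 0
  fixed_bottom <- if (anchor_bottom && any(zero)) mean(data$response[zero]) else NULL
  data <- data[!zero, , drop = FALSE]
  if (length(unique(data$dose)) < 4) {
    abort("need at least 4 distinct positive doses to fit 4 parameters")
  }

  n_par <- if (is.null(fixed_bottom)) 4L else 3L
  n <- nrow(data)
  res_df <- n - n_par
  failed <- function() {
    structure(list(bottom = NA_real_, top = NA_real_, log_ec50 = NA_real_,
                   hill = NA_real_, se_bottom = NA_real_, se_top = NA_real_,
                   se_log_ec50 = NA_real_, se_hill = NA_real_,
                   residual_df = res_df, rss = NA_real_, n_points = n,
                   dose_range = range(data$dose), converged = FALSE),
              class = "fourpl_fit")
  }
  if (diff(range(data$response)) == 0) return(failed())

  half <- (min(data$response) + max(data$response)) / 2
  start <- list(bottom = min(data$response), top = max(data$response),
                log_ec50 = log10(data$dose[which.min(abs(data$response - half))]),
                hill = 1)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  fit <- tryCatch({
    if (is.null(fixed_bottom)) {
      minpack.lm::nlsLM(
        response ~ fourpl(dose, bottom, top, log_ec50, hill),
        data = data, start = start, control = ctrl)
    } else {
      minpack.lm::nlsLM(
        response ~ fourpl(dose, fb, top, log_ec50, hill),
        data = cbind(data, fb = fixed_bottom),
        start = start[c("top", "log_ec50", "hill")], control = ctrl)
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(failed())

  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(est)), names(est)))
  bottom <- if (is.null(fixed_bottom)) est[["bottom"]] else fixed_bottom
  se_bottom <- if (is.null(fixed_bottom)) se[["bottom"]] else 0
  out <- structure(list(
    bottom = bottom, top = est[["top"]],
    log_ec50 = est[["log_ec50"]], hill = est[["hill"]],
    se_bottom = se_bottom, se_top = se[["top"]],
    se_log_ec50 = se[["log_ec50"]], se_hill = se[["hill"]],
    residual_df = res_df, rss = sum(stats::residuals(fit)^2), n_points = n,
    dose_range = range(data$dose), converged = TRUE),
    class = "fourpl_fit")

  ec <- 10^out$log_ec50
  in_range <- ec >= out$dose_range[1] / 10 && ec <= out$dose_range[2] * 10
  if (!is.finite(ec) || !in_range || out$top <= out$bottom) {
    out$converged <- FALSE
  }
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("fourpl_fit: not converged (", x$n_points, "points )\n")
    return(invisible(x))
  }
  cat(sprintf(
    "fourpl_fit: EC50 = %.4g nM (log10 %.3f +/- %.3f), hill = %.3f, range [%.4g, %.4g], n = %d\n",
    10^x$log_ec50, x$log_ec50, x$se_log_ec50, x$hill, x$bottom, x$top, x$n_points))
  invisible(x)
}

#' Half-maximal effective concentration from a 4PL fit
#'
#' Back-transforms the fitted log10-EC50 to nM; the standard error follows by
#' the delta method, `se = ln(10) * EC50 * se_log_ec50`.
#'
#' @param fit a converged `fourpl_fit`.
#' @return List with `value` (nM) and `se` (nM).
#' @export
ec50 <- function(fit) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!fit$converged) abort("fit did not converge: no EC50 reported")
  value <- 10^fit$log_ec50
  list(value = value, se = log(10) * value * fit$se_log_ec50)
}

#' Fold-change in potency between two fits
#'
#' Ratio of EC50s, `EC50(num) / EC50(den)`; values above 1 mean the numerator
#' ligand is less potent (needs more to reach half-maximal response).
#'
#' @param fit_num,fit_den converged `fourpl_fit` objects.
#' @return Dimensionless ratio.
#' @export
fold_change <- function(fit_num, fit_den) {
  ec50(fit_num)$value / ec50(fit_den)$value
}

#' Efficacy ratio between two fits
#'
#' Efficacy is operationalized as the fitted dynamic range `Top - Bottom`; the
#' ratio compares a variant's maximal attainable reporter induction to a
#' reference.
#'
#' @param fit_a,fit_ref converged `fourpl_fit` objects.
#' @return Dimensionless ratio.
#' @export
efficacy_ratio <- function(fit_a, fit_ref) {
  for (f in list(fit_a, fit_ref)) {
    stopifnot(inherits(f, "fourpl_fit"))
    if (!f$converged) abort("fit did not converge")
  }
  span_ref <- fit_ref$top - fit_ref$bottom
  if (span_ref == 0) abort("reference fit has zero dynamic range")
  (fit_a$top - fit_a$bottom) / span_ref
}

#' Two-tailed unpaired comparison of two EC50s
#'
#' Tests the difference of the EC50 point estimates using the curve-fit
#' standard errors (delta-method, nM scale):
#' `t = (EC50_a - EC50_b) / sqrt(se_a^2 + se_b^2)`, with Welch-Satterthwaite
#' degrees of freedom combining the two fits' residual degrees of freedom.
#'
#' @param fit_a,fit_b converged `fourpl_fit` objects with `residual_df >= 1`.
#' @return List with `t`, `df`, and two-tailed `p`.
#' @export
compare_ec50 <- function(fit_a, fit_b) {
  ea <- ec50(fit_a); eb <- ec50(fit_b)
  if (fit_a$residual_df < 1 || fit_b$residual_df < 1) {
    abort("both fits need residual_df >= 1")
  }
  v_a <- ea$se^2; v_b <- eb$se^2
  if (v_a + v_b == 0) abort("zero combined standard error")
  t <- (ea$value - eb$value) / sqrt(v_a + v_b)
  df <- (v_a + v_b)^2 / (v_a^2 / fit_a$residual_df + v_b^2 / fit_b$residual_df)
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Read a dose-response table
#'
#' TSV with columns `sample`, `dose_nM`, `replicate`, `response` (per-well
#' median reporter fluorescence).
#'
#' @param path input TSV path.
#' @param sample optional sample id to filter to.
#' @return Tibble of titration rows.
#' @export
read_dose_response <- function(path, sample = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  d <- as_tibble(read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE))
  need <- c("sample", "dose_nM", "replicate", "response")
  if (!all(need %in% names(d))) {
    abort(paste0("dose-response table needs columns: ", paste(need, collapse = ", ")))
  }
  if (!is.null(sample)) d <- d[d$sample == sample, ]
  d
}

#' Serialize a 4PL fit as JSON
#'
#' @param fit a `fourpl_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fourpl_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Reference EC50 measurements for RSPO3 variants
#'
#' Published EC50 estimates (nM, with standard errors) for wild-type and
#' mutant RSPO3 ligands titrated on WNT-reporter HAP1-7TGP cells, shipped with
#' the package as the reference input for fold-change-in-potency
#' calculations. `panel` identifies the titration series a value belongs to
#' (variants are comparable within a panel, where cell line and WNT dose are
#' shared).
#'
#' @return Tibble with columns `panel`, `sample`, `ec50_nM`, `se_nM`.
#' @export
rspo3_ec50_reference <- function() {
  path <- system.file("extdata", "rspo3_ec50_reference.tsv",
                      package = "gtscreen", mustWork = TRUE)
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE))
}
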