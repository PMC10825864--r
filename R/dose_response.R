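#' Normalize per-well intensities to untreated controls
#'
#' Within every (dye, time) stratum, each well's mean intensity is divided
#' by the mean intensity of that stratum's untreated (dose 0) wells, so the
#' control condition sits at 1 by construction and treated conditions read
#' as fractions of it. Per condition the replicate mean, standard
#' deviation, and a Welch t-test against the stratum's controls (two
#' significance levels: `*` p < 0.05, `**` p < 0.01) are reported.
#'
#' Passing an already-normalized table re-divides by its (unit) control
#' means, so normalization is idempotent.
#'
#' @param wells a data frame of well records with columns `dye`, `dose`,
#'   `time`, `replicate`, `mean_intensity` (and optionally `cell_model`,
#'   `snr`), or an existing `dose_response_table`.
#' @return a `dose_response_table` data frame with columns `dye`, `dose`,
#'   `time`, `n`, `mean_norm`, `sd_norm`, `p_value`, `stars`.
#' @export
normalize_to_control <- function(wells) {
  if (inherits(wells, "dose_response_table")) {
    out <- wells
    for (key in unique(paste(out$dye, out$time))) {
      sel <- paste(out$dye, out$time) == key
      ctrl <- out$mean_norm[sel & out$dose == 0]
      if (length(ctrl) == 0)
        stop(sprintf("no dose-0 control in stratum (dye=%s, time=%s)",
                     out$dye[sel][1], out$time[sel][1]))
      denom <- mean(ctrl)
      out$mean_norm[sel] <- out$mean_norm[sel] / denom
      out$sd_norm[sel] <- out$sd_norm[sel] / denom
    }
    return(out)
  }
  need <- c("dye", "dose", "time", "replicate", "mean_intensity")
  if (!is.data.frame(wells) || !all(need %in% names(wells)))
    stop("`wells` must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (any(wells$dose < 0) || any(wells$time < 0))
    stop("doses and times must be nonnegative")
  wells$.norm <- NA_real_
  for (dye in unique(wells$dye)) for (tm in unique(wells$time[wells$dye == dye])) {
    sel <- wells$dye == dye & wells$time == tm
    ctrl <- wells$mean_intensity[sel & wells$dose == 0]
    if (length(ctrl) == 0)
      stop(sprintf("no dose-0 control in stratum (dye=%s, time=%g)", dye, tm))
    wells$.norm[sel] <- wells$mean_intensity[sel] / mean(ctrl)
  }
  combos <- unique(wells[order(wells$dye, wells$time, wells$dose),
                         c("dye", "dose", "time")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- wells$dye == combos$dye[i] & wells$dose == combos$dose[i] &
      wells$time == combos$time[i]
    vals <- wells$.norm[sel]
    ctrl <- wells$.norm[wells$dye == combos$dye[i] &
                          wells$time == combos$time[i] & wells$dose == 0]
    if (combos$dose[i] == 0 || length(vals) < 2 || length(ctrl) < 2) {
      p <- NA_real_; st <- ""
    } else {
      cmp <- compare_to_control(vals, ctrl)
      p <- cmp$p_value; st <- cmp$stars
    }
    data.frame(dye = combos$dye[i], dose = combos$dose[i],
               time = combos$time[i], n = length(vals),
               mean_norm = mean(vals),
               sd_norm = if (length(vals) > 1) sd(vals) else NA_real_,
               p_value = p, stars = st)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dose_response_table", "data.frame")
  out
}

#' @export
print.dose_response_table <- function(x, digits = 3, ...) {
  cat("Dose-response table (normalized to untreated controls; * p<0.05, ** p<0.01)\n")
  y <- as.data.frame(x)
  y$mean_norm <- round(y$mean_norm, digits)
  y$sd_norm <- round(y$sd_norm, digits)
  y$p_value <- signif(y$p_value, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

significance_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Welch comparison of a treated condition against its control
#'
#' Two-sided Welch t-test of replicate values; stars follow the two-level
#' convention `*` p < 0.05, `**` p < 0.01. No multiple-testing correction
#' is applied — stars annotate conditions individually, and the table
#' metadata says so.
#'
#' @param treated,control numeric replicate vectors (length >= 2 each).
#' @return a list with `p_value` and `stars`.
#' @export
compare_to_control <- function(treated, control) {
  if (length(treated) < 2 || length(control) < 2)
    stop("at least 2 replicates per group are required (variance undefined)")
  if (sd(treated) == 0 && sd(control) == 0) {
    p <- if (isTRUE(all.equal(mean(treated), mean(control)))) 1 else 0
  } else {
    p <- t.test(treated, control, var.equal = FALSE)$p.value
  }
  list(p_value = p, stars = significance_stars(p))
}

#' Detect the onset concentration of an increasing response
#'
#' Fits a hinge model — flat baseline, then a linear rise in
#' log-concentration — by least squares, trying every tested concentration
#' (except the last two, which cannot support a slope estimate) as the
#' breakpoint and keeping the one with the smallest residual sum of
#' squares. The onset is declared detected only when the fitted rise slope
#' exceeds twice its standard error; a flat series therefore reports no
#' onset. This replaces onset-by-inspection with a reproducible rule.
#'
#' @param concentrations strictly increasing positive concentrations
#'   (>= 4 values; any unit).
#' @param intensities matched response values.
#' @return a list with `onset_concentration` (`NA` when undetected),
#'   `detected`, `index` (breakpoint position), `slope` and `slope_se`
#'   (per decade of concentration).
#' @export
detect_onset <- function(concentrations, intensities) {
  n <- length(concentrations)
  if (n < 4) stop("at least 4 concentration points are required")
  if (length(intensities) != n) stop("series lengths differ")
  if (any(diff(concentrations) <= 0))
    stop("`concentrations` must be strictly increasing")
  if (any(concentrations <= 0))
    stop("concentrations must be positive (log scale)")
  lg <- log10(concentrations)
  best <- NULL
  for (k in seq_len(n - 2)) {
    h <- pmax(0, lg - lg[k])
    fit <- lm(intensities ~ h)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(k = k, fit = fit, rss = rss)
  }
  sm <- summary(best$fit)$coefficients
  slope <- sm["h", "Estimate"]
  se <- sm["h", "Std. Error"]
  detected <- is.finite(se) && slope > 2 * se
  list(onset_concentration = if (detected) concentrations[best$k] else NA_real_,
       detected = detected, index = best$k, slope = slope, slope_se = se)
}

#' Fit a decreasing Hill curve to normalized dose-response data
#'
#' Model: `y = 1 - emax * dose^h / (dose^h + ec50^h)`, the saturating loss
#' of proximity signal as cluster disruption approaches its maximum.
#' Fitted by Levenberg-Marquardt least squares with data-driven starting
#' values.
#'
#' @param dose doses (>= 0; zeros allowed, they pin the baseline).
#' @param response normalized mean intensities.
#' @return a `hill_fit` object; `coef()` gives `emax`, `ec50`, `hill`,
#'   `predict()` evaluates the curve.
#' @export
fit_hill_decay <- function(dose, response) {
  stopifnot(length(dose) == length(response), length(dose) >= 4,
            all(dose >= 0))
  emax0 <- max(min(1 - min(response), 0.99), 0.05)
  pos <- dose > 0
  half <- 1 - emax0 / 2
  ec50_0 <- tryCatch(
    exp(stats::approx(response[pos], log(dose[pos]), xout = half,
                      ties = mean, rule = 2)$y),
    error = function(e) stats::median(dose[pos]))
  df <- data.frame(dose = dose, response = response)
  fit <- minpack.lm::nlsLM(
    response ~ 1 - emax * ifelse(dose > 0, dose^hill / (dose^hill + ec50^hill), 0),
    data = df,
    start = list(emax = emax0, ec50 = ec50_0, hill = 1),
    lower = c(emax = 0, ec50 = 1e-6, hill = 0.2),
    upper = c(emax = 1.5, ec50 = 1e6, hill = 5),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  structure(list(fit = fit, data = df), class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) coef(object$fit)

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose else
    if (is.data.frame(newdata)) newdata$dose else newdata
  p <- coef(object$fit)
  1 - p["emax"] * ifelse(d > 0, d^p["hill"] / (d^p["hill"] + p["ec50"]^p["hill"]), 0)
}

#' @export
print.hill_fit <- function(x, ...) {
  p <- coef(x$fit)
  cat(sprintf("<hill_fit> y = 1 - %.3f * d^%.2f / (d^%.2f + %.3g^%.2f)  [ec50 = %.3g]\n",
              p["emax"], p["hill"], p["hill"], p["ec50"], p["hill"], p["ec50"]))
  invisible(x)
}
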