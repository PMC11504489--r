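#' Plate table of raw assay signals
#'
#' Long-format records of a 96-well style assay: one row per well, with a
#' treatment label, concentration, replicate index and raw signal
#' (absorbance). One treatment label is designated the untreated control.
#'
#' @param records data frame with columns `treatment`, `concentration`
#'   (mM), `replicate`, `signal`.
#' @param control treatment label of the untreated control.
#' @return An object of class `plate_table`.
#' @export
plate_table <- function(records, control = "control") {
  stopifnot(is.data.frame(records))
  need <- c("treatment", "concentration", "replicate", "signal")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!control %in% records$treatment)
    stop("control label '", control, "' not present", call. = FALSE)
  structure(list(records = records, control = control),
            class = "plate_table")
}

#' Per-condition percent of control
#'
#' Normalizes each (treatment, concentration) condition to the untreated
#' control: condition mean divided by the control mean, times 100. The
#' SEM is the replicate-scatter SEM of the condition, propagated through
#' the same scale factor (the control mean is treated as the fixed
#' normalizer, as in routine plate summaries).
#'
#' @param plate a [plate_table()].
#' @return Data frame with `treatment`, `concentration`, `n`,
#'   `percent_of_control`, `sem`.
#' @examples
#' rec <- data.frame(treatment = rep(c("control", "drug"), each = 3),
#'                   concentration = rep(c(0, 5), each = 3),
#'                   replicate = rep(1:3, 2),
#'                   signal = c(99, 100, 101, 49, 50, 51))
#' percent_of_control(plate_table(rec))
#' @export
percent_of_control <- function(plate) {
  stopifnot(inherits(plate, "plate_table"))
  rec <- plate$records
  ctrl <- rec$signal[rec$treatment == plate$control]
  cm <- mean(ctrl)
  if (!is.finite(cm) || cm <= 0)
    stop("control mean must be positive", call. = FALSE)
  agg <- stats::aggregate(
    signal ~ treatment + concentration, data = rec,
    FUN = function(x) c(n = length(x), mean = mean(x),
                        sem = stats::sd(x) / sqrt(length(x)))
  )
  out <- data.frame(
    treatment = agg$treatment,
    concentration = agg$concentration,
    n = agg$signal[, "n"],
    percent_of_control = agg$signal[, "mean"] / cm * 100,
    sem = agg$signal[, "sem"] / cm * 100,
    stringsAsFactors = FALSE
  )
  out[order(out$treatment, out$concentration), , drop = FALSE]
}

#' Fit a four-parameter logistic and read off the IC50
#'
#' Fits the monotone-decreasing 4PL
#' `y = lower + (upper - lower) / (1 + (x / x_mid)^hill)` (hill > 0) to a
#' percent-of-control dose-response and reports the IC50 as the
#' concentration at which the fitted curve crosses 50% of control. Two
#' reporting modes: `"fitted"` (default) reads the crossing from the
#' continuous curve; `"snapped"` reports the tested concentration nearest
#' to that crossing. A crossing outside the tested range (or a curve that
#' never reaches 50%) is flagged as extrapolated and, in snapped mode,
#' returns NA.
#'
#' @param dose_response data frame with columns `concentration` (mM, > 0)
#'   and `percent_of_control`.
#' @param mode `"fitted"` or `"snapped"`.
#' @return Object of class `dose_response_fit`: `ic50` (mM), `hill`,
#'   `upper`, `lower`, `stderr` (named, for the 4PL parameters),
#'   `extrapolated`, `mode`, `rss`.
#' @examples
#' conc <- c(0.5, 1, 2.5, 5, 10, 20)
#' y <- 100 / (1 + (conc / 5)^1.5)
#' fit_ic50(data.frame(concentration = conc, percent_of_control = y))
#' @export
fit_ic50 <- function(dose_response, mode = c("fitted", "snapped")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(dose_response))
  if (!all(c("concentration", "percent_of_control") %in%
           names(dose_response)))
    stop("need columns 'concentration' and 'percent_of_control'",
         call. = FALSE)
  x <- dose_response$concentration
  y <- dose_response$percent_of_control
  if (any(x <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(unique(x)) < 4L)
    stop("need >= 4 distinct concentrations", call. = FALSE)

  start <- c(lower = max(min(y), 1e-3), upper = max(y),
             x_mid = exp(mean(log(range(x)))), hill = 1)
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = c(lower = 0, upper = 1e-6, x_mid = 1e-9, hill = 1e-3),
    fn = function(p) {
      p[["lower"]] + (p[["upper"]] - p[["lower"]]) /
        (1 + (x / p[["x_mid"]])^p[["hill"]]) - y
    },
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- stats::coef(fit)
  dof <- length(x) - length(p)
  se <- stats::setNames(rep(NA_real_, length(p)), names(p))
  h <- try(chol2inv(chol(fit$hessian)), silent = TRUE)
  if (!inherits(h, "try-error") && dof > 0)
    se <- stats::setNames(sqrt(pmax(diag(h), 0) * fit$deviance / dof),
                          names(p))

  # concentration where the fitted curve crosses 50% of control
  lo <- p[["lower"]]; up <- p[["upper"]]
  ic50 <- NA_real_
  extrapolated <- TRUE
  if (up > 50 && lo < 50) {
    ratio <- (up - lo) / (50 - lo) - 1
    ic50 <- p[["x_mid"]] * ratio^(1 / p[["hill"]])
    extrapolated <- ic50 < min(x) || ic50 > max(x)
  }
  if (mode == "snapped")
    ic50 <- if (is.finite(ic50) && !extrapolated)
      x[which.min(abs(x - ic50))] else NA_real_

  structure(list(
    ic50 = ic50, hill = p[["hill"]], upper = up, lower = lo,
    x_mid = p[["x_mid"]], stderr = se,
    extrapolated = extrapolated, mode = mode,
    rss = fit$deviance
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (is.finite(x$ic50))
    cat(sprintf("IC50 = %.4g mM (%s%s), hill = %.3g, asymptotes %.3g-%.3g%%\n",
                x$ic50, x$mode,
                if (x$extrapolated) ", extrapolated" else "",
                x$hill, x$lower, x$upper))
  else
    cat("IC50 not reached within the tested range (flagged)\n")
  invisible(x)
}

#' Relative enzyme activity from kinetic traces
#'
#' Normalizes hexokinase activity in the presence of an inhibitor to the
#' uninhibited activity: both kinetic traces (absorbance vs time over the
#' same window) are reduced to their linear slopes and the ratio
#' inhibited/uninhibited is returned, so activity is 1.0 with no
#' inhibitor and 0 for complete inhibition.
#'
#' @param trace_with,trace_without data frames with columns `time` and
#'   `absorbance` over the same kinetic window.
#' @return Relative activity (dimensionless, ~\[0, 1\]).
#' @examples
#' t <- 0:10
#' normalize_activity(data.frame(time = t, absorbance = 0.02 * t),
#'                    data.frame(time = t, absorbance = 0.04 * t))
#' @export
normalize_activity <- function(trace_with, trace_without) {
  slope <- function(tr) {
    stopifnot(is.data.frame(tr),
              all(c("time", "absorbance") %in% names(tr)))
    stats::lm.fit(cbind(1, tr$time), tr$absorbance)$coefficients[[2]]
  }
  s1 <- slope(trace_with)
  s0 <- slope(trace_without)
  # a numerically flat trace counts as non-positive
  eps <- .Machine$double.eps^0.5 *
    max(mean(abs(trace_without$absorbance)), .Machine$double.eps)
  if (!is.finite(s0) || s0 <= eps)
    stop("uninhibited trace must have a positive slope", call. = FALSE)
  s1 / s0
}
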