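# Mono-exponential TCSPC lifetime fitting and ROI averaging.
#
# Model: I(t) = A * exp(-t / tau) + b, fit by weighted least squares with
# Poisson weights 1 / max(counts, 1) over a window starting at the peak bin
# (tail fitting; no instrument-response deconvolution). For fixed tau the
# model is linear in (A, b), so tau is profiled by 1-D minimization of the
# weighted RSS with the (A, b) pair solved analytically at each step -
# this cannot diverge and is exact for noise-free model data.

#' Fit a mono-exponential decay
#'
#' @param hist an `fq_decay` (see [make_decay()]) or a list/data.frame with
#'   `time_ns` and `counts`.
#' @param fit_start "peak" (default: window starts at the maximum-count
#'   bin) or a 1-based bin index.
#' @param min_counts minimum peak counts required to attempt a fit.
#' @param min_bins minimum number of bins in the fit window.
#' @return `fq_lifetime_fit` list: `tau_ns`, `amplitude`, `baseline`,
#'   `chi2_reduced`, `window` (bin index range), `converged`.
#' @export
fit_monoexp <- function(hist, fit_start = "peak", min_counts = 20,
                        min_bins = 10L) {
  t_all <- hist$time_ns
  c_all <- hist$counts
  if (length(t_all) != length(c_all) || any(!is.finite(c_all)) ||
      any(c_all < 0))
    stop_fq("invalid decay histogram")
  start <- if (identical(fit_start, "peak")) which.max(c_all)
           else as.integer(fit_start)
  if (start < 1L || start > length(c_all)) stop_fq("fit_start out of range")
  idx <- start:length(c_all)
  if (length(idx) < min_bins) {
    # a peak at the histogram tail usually means a rising (non-decaying)
    # signal; report that, not the window size
    sl_all <- tryCatch(
      stats::coef(stats::lm(log(pmax(c_all, 0.5)) ~ t_all))[2],
      error = function(e) NA_real_)
    if (identical(fit_start, "peak") && (!is.finite(sl_all) || sl_all >= 0))
      stop_fq("no decaying structure in the histogram (slope >= 0); fit did not converge")
    stop_fq("fit window has %d bins; need >= %d", length(idx), min_bins)
  }
  t <- t_all[idx]; cts <- c_all[idx]
  if (max(cts) < min_counts)
    stop_fq("low signal: peak counts %.1f below minimum %s", max(cts),
            format(min_counts))

  # initial tau from the log-linear slope over the top decade
  top <- cts >= max(cts) / 10 & cts > 0
  if (sum(top) >= 3) {
    sl <- stats::coef(stats::lm(log(cts[top]) ~ t[top]))[2]
  } else sl <- NA_real_
  if (!is.finite(sl) || sl >= 0) {
    # flat or rising: check for any decaying structure at all
    sl_all <- tryCatch(
      stats::coef(stats::lm(log(pmax(cts, 0.5)) ~ t))[2],
      error = function(e) NA_real_)
    if (!is.finite(sl_all) || sl_all >= 0)
      stop_fq("no decaying structure in the histogram (slope >= 0); fit did not converge")
    sl <- sl_all
  }
  tau0 <- -1 / sl

  wts <- 1 / pmax(cts, 1)
  rss_for <- function(tau) {
    e <- exp(-t / tau)
    # weighted LS for counts ~ A * e + b
    sw <- sum(wts); swe <- sum(wts * e); swee <- sum(wts * e * e)
    swc <- sum(wts * cts); swec <- sum(wts * e * cts)
    det <- swee * sw - swe^2
    if (det <= 0) return(list(rss = Inf, A = NA, b = NA))
    A <- (swec * sw - swe * swc) / det
    b <- (swee * swc - swe * swec) / det
    r <- cts - (A * e + b)
    list(rss = sum(wts * r^2), A = A, b = b)
  }
  lo <- max(tau0 / 10, (t[2] - t[1]) / 10)
  hi <- tau0 * 10
  opt <- stats::optimize(function(x) rss_for(x)$rss, c(lo, hi),
                         tol = .Machine$double.eps^0.5)
  tau_hat <- opt$minimum
  fit <- rss_for(tau_hat)
  converged <- is.finite(fit$rss) &&
    tau_hat > lo * 1.0001 && tau_hat < hi * 0.9999
  structure(list(tau_ns = tau_hat, amplitude = fit$A, baseline = fit$b,
                 chi2_reduced = fit$rss / max(length(idx) - 3L, 1L),
                 window = c(start, length(c_all)), converged = converged),
            class = "fq_lifetime_fit")
}

#' ROI scheme for lifetime averaging
#'
#' @param rois_per_cell ROIs drawn per cell (default 3).
#' @param cells_per_condition cells per condition (default 6).
#' @param min_rois minimum ROI count for a condition average; defaults to
#'   `rois_per_cell * cells_per_condition` (18).
#' @param min_counts minimum counts per ROI decay.
#' @export
roi_scheme <- function(rois_per_cell = 3L, cells_per_condition = 6L,
                       min_rois = rois_per_cell * cells_per_condition,
                       min_counts = 20) {
  structure(list(rois_per_cell = rois_per_cell,
                 cells_per_condition = cells_per_condition,
                 min_rois = min_rois, min_counts = min_counts),
            class = "fq_roi_scheme")
}

#' Average lifetimes over ROIs
#'
#' Unweighted mean and SEM of ROI-level lifetimes. Errors (rather than
#' silently excluding) when any fit did not converge or fewer ROIs than the
#' scheme minimum are supplied.
#'
#' @param fits list of `fq_lifetime_fit` objects.
#' @param scheme a [roi_scheme()].
#' @return list: `mean_tau_ns`, `sem_ns`, `n`.
#' @export
roi_lifetimes <- function(fits, scheme = roi_scheme()) {
  if (!is.list(fits) || length(fits) == 0) stop_fq("no fits supplied")
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (any(!conv))
    stop_fq("%d of %d ROI fits did not converge; refusing silent exclusion",
            sum(!conv), length(fits))
  if (length(fits) < scheme$min_rois)
    stop_fq("only %d ROIs supplied; scheme requires >= %d (short by %d)",
            length(fits), scheme$min_rois, scheme$min_rois - length(fits))
  taus <- vapply(fits, function(f) f$tau_ns, 1)
  s <- summarize_values(taus)
  list(mean_tau_ns = s$mean, sem_ns = s$sem, n = s$n)
}

#' Compare lifetime conditions
#'
#' One-way ANOVA with Tukey-Kramer post hoc tests across per-condition ROI
#' lifetime sets (delegates to [anova_tukey()]).
#'
#' @param tau_sets named list of numeric vectors of ROI lifetimes (ns).
#' @param alpha significance level.
#' @return see [anova_tukey()].
#' @export
compare_conditions <- function(tau_sets, alpha = 0.05) {
  anova_tukey(tau_sets, alpha = alpha, check_normality = FALSE)
}
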