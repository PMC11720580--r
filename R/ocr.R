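# Mito-stress-test metrics from oxygen consumption rate (OCR) traces.
#
# The standard four-phase protocol: baseline, oligomycin (blocks ATP
# synthase), FCCP (uncouples, maximal respiration), rotenone/antimycin A
# (shuts down the electron transport chain, leaving non-mitochondrial
# respiration). Conventions follow the vendor protocol: basal uses the
# LAST pre-injection measurement, ATP-linked the MINIMUM post-oligomycin,
# maximal the MAXIMUM post-FCCP, non-mitochondrial the MEAN of the final
# phase.

#' Construct an OCR trace
#'
#' @param time_min strictly increasing measurement times, minutes.
#' @param ocr OCR values, pmol O2/min.
#' @param boundaries 3 ordered interior indices: the last measurement index
#'   of phases 1-3 (injections of oligomycin, FCCP, rotenone/antimycin A
#'   happen immediately after these points).
#' @param well,group labels.
#' @return `fq_ocr_trace` list with a `phase` vector (1-4).
#' @export
ocr_trace <- function(time_min, ocr, boundaries, well = "A1", group = "ctrl") {
  n <- length(time_min)
  if (length(ocr) != n) stop_fq("time and OCR lengths differ")
  if (any(diff(time_min) <= 0)) stop_fq("times must be strictly increasing")
  if (any(!is.finite(ocr))) stop_fq("non-finite OCR values")
  b <- as.integer(boundaries)
  if (length(b) != 3L || any(diff(b) <= 0) || b[1] < 1L || b[3] >= n)
    stop_fq("need 3 ordered interior injection boundaries (got: %s)",
            paste(boundaries, collapse = ", "))
  phase <- findInterval(seq_len(n), b + 1L) + 1L
  structure(list(time_min = time_min, ocr = ocr, boundaries = b,
                 phase = phase, well = well, group = group),
            class = "fq_ocr_trace")
}

#' Mito stress test metrics from one OCR trace
#'
#' * non-mitochondrial = mean of phase-4 values
#' * basal = last phase-1 value - non-mito
#' * ATP-linked = last phase-1 value - min of phase-2 values
#'   (oligomycin-sensitive OCR; note this is an OCR difference in
#'   pmol O2/min, not a vendor-derived ATP production rate)
#' * maximal = max of phase-3 values - non-mito
#' * spare = maximal - basal
#'
#' A negative computed basal respiration is flagged (`basal_negative`), not
#' clipped.
#'
#' @param trace an [ocr_trace()].
#' @return list: `non_mito`, `basal`, `atp_linked`, `maximal`, `spare`,
#'   `basal_negative`, `well`, `group`.
#' @export
stress_metrics <- function(trace) {
  if (!inherits(trace, "fq_ocr_trace"))
    stop_fq("`trace` must be an fq_ocr_trace (see ocr_trace())")
  ph <- split(trace$ocr, trace$phase)
  if (length(ph) != 4L || any(vapply(ph, length, 1L) < 1L))
    stop_fq("every phase needs >= 1 measurement")
  non_mito <- mean(ph[[4]])
  last_basal <- ph[[1]][length(ph[[1]])]
  basal <- last_basal - non_mito
  atp_linked <- last_basal - min(ph[[2]])
  maximal <- max(ph[[3]]) - non_mito
  if (basal < 0)
    warning(sprintf("negative basal respiration (%.3g); check the trace",
                    basal))
  list(non_mito = non_mito, basal = basal, atp_linked = atp_linked,
       maximal = maximal, spare = maximal - basal,
       basal_negative = basal < 0,
       well = trace$well, group = trace$group)
}

#' Compare a stress-test metric across conditions
#'
#' Aggregates per-well metric values by group and runs one-way ANOVA with
#' Tukey-Kramer post hoc tests. Wells are the independent unit; in strict
#' mode each group must carry at least `min_n` wells (the standard design
#' uses n = 6).
#'
#' @param metrics list of [stress_metrics()] results (one per well).
#' @param which metric name, e.g. "maximal", "basal", "atp_linked".
#' @param strict enforce the minimum group size.
#' @param min_n minimum wells per group in strict mode.
#' @param alpha significance level.
#' @return list: `groups` (named value lists) plus the [anova_tukey()]
#'   fields.
#' @export
group_compare <- function(metrics, which = "maximal", strict = FALSE,
                          min_n = 6L, alpha = 0.05) {
  if (!is.list(metrics) || length(metrics) == 0) stop_fq("no metrics supplied")
  vals <- vapply(metrics, function(m) m[[which]], 1)
  grp <- vapply(metrics, function(m) m$group, "")
  groups <- split(vals, grp)
  if (strict) {
    short <- names(groups)[vapply(groups, length, 1L) < min_n]
    if (length(short) > 0)
      stop_fq("strict mode: group(s) %s have fewer than %d wells",
              paste(short, collapse = ", "), min_n)
  }
  res <- anova_tukey(groups, alpha = alpha, check_normality = FALSE)
  c(list(groups = groups), res)
}
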