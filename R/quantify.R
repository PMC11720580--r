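# Per-cell fluorescence quantification, treatment/control ratios,
# wound-closure and BrdU fractions, and the group statistics used to
# compare conditions (one-way ANOVA with Tukey-Kramer post hoc tests,
# mean +/- SEM summaries).

#' Measure labeled cells on an intensity image
#'
#' One record per label: mean intensity over exactly the labeled pixels
#' (of the background-corrected image in the standard pipeline), area and
#' centroid.
#'
#' @param img intensity matrix.
#' @param labels aligned integer label matrix.
#' @return data.frame: `label`, `mean_intensity`, `area_px`, `cx`, `cy`
#'   (0-based centroid).
#' @export
measure_cells <- function(img, labels) {
  check_image(img)
  if (!is.matrix(labels) || !all(dim(labels) == dim(img)))
    stop_fq("`labels` must be a matrix aligned to `img`")
  labs <- sort(unique(labels[labels > 0]))
  if (length(labs) == 0) {
    warning("empty label set: no cells to measure")
    return(data.frame(label = integer(0), mean_intensity = numeric(0),
                      area_px = numeric(0), cx = numeric(0), cy = numeric(0)))
  }
  ridx <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cidx <- matrix(rep(seq_len(ncol(img)), each = nrow(img)),
                 nrow(img), ncol(img))
  sel <- labels > 0
  f <- factor(labels[sel], levels = labs)
  data.frame(
    label = labs,
    mean_intensity = as.numeric(tapply(img[sel], f, mean)),
    area_px = as.numeric(tabulate(f)),
    cx = as.numeric(tapply(cidx[sel], f, mean)) - 1,
    cy = as.numeric(tapply(ridx[sel], f, mean)) - 1
  )
}

#' Treated / control ratio with propagated SEM
#'
#' Ratio of group means (not mean of per-cell ratios: cells are unpaired
#' across wells). The SEM is first-order error propagation from the two
#' group SEMs:
#' `sem = ratio * sqrt((sem_t / mean_t)^2 + (sem_c / mean_c)^2)`.
#'
#' @param treated,control numeric vectors of per-cell (or per-image) values.
#' @return list: `ratio`, `sem`, `n_treated`, `n_control`, `mean_treated`,
#'   `mean_control`. `sem` is NA when either group has n < 2.
#' @export
pbm_ratio <- function(treated, control) {
  if (length(treated) == 0 || length(control) == 0)
    stop_fq("both groups must be non-empty")
  mt <- mean(treated); mc <- mean(control)
  if (mc <= 0) stop_fq("control mean must be > 0 (got %.3g)", mc)
  ratio <- mt / mc
  sem <- NA_real_
  if (length(treated) >= 2 && length(control) >= 2) {
    st <- stats::sd(treated) / sqrt(length(treated))
    sc <- stats::sd(control) / sqrt(length(control))
    sem <- abs(ratio) * sqrt((st / mt)^2 + (sc / mc)^2)
  }
  list(ratio = ratio, sem = sem,
       n_treated = length(treated), n_control = length(control),
       mean_treated = mt, mean_control = mc)
}

#' Wound closure fraction
#'
#' `(area_t0 - area_t) / area_t0`: 0 = unchanged, 1 = fully closed;
#' negative values (wound growth) are passed through.
#'
#' @param area_t0 cell-free area at t = 0, px^2 (> 0).
#' @param area_t cell-free area at the later time point, px^2 (>= 0).
#' @return closure fraction, capped above at 1.
#' @export
wound_closure <- function(area_t0, area_t) {
  check_scalar(area_t0, "area_t0")
  if (area_t < 0) stop_fq("area_t must be >= 0")
  min(1, (area_t0 - area_t) / area_t0)
}

#' Cell-free scratch area from a phase-contrast-like texture image
#'
#' Cell-covered regions are textured while the scratch is smooth, so the
#' cell-free region is recovered as the largest connected component of the
#' low-local-variance mask (variance over a sliding window, Otsu threshold
#' on log-variance).
#'
#' @param img intensity matrix.
#' @param window sliding-window size, px; rule of thumb is about twice the
#'   cell diameter.
#' @param min_fraction error out when the candidate region is smaller than
#'   this fraction of the frame (no scratch present).
#' @param min_contrast minimum ratio between the median local variance of
#'   the textured (cell) and smooth (scratch) classes; below it the image is
#'   declared confluent (no scratch) and an error is raised.
#' @return list: `area_px`, `mask` (logical scratch mask).
#' @export
wound_area <- function(img, window = 25L, min_fraction = 0.01,
                       min_contrast = 5) {
  check_image(img)
  mu <- window_mean(img, window)
  mu2 <- window_mean(img^2, window)
  v <- pmax(mu2 - mu^2, 0)
  thr <- otsu_threshold(log1p(v))
  low <- log1p(v) <= thr
  if (!any(low) || all(low))
    stop_fq("no candidate cell-free region found (uniform texture)")
  contrast <- stats::median(v[!low]) / max(stats::median(v[low]), 1e-12)
  if (contrast < min_contrast)
    stop_fq("no scratch detected: texture contrast %.2f below %.1f (image looks confluent)",
            contrast, min_contrast)
  lab <- label_components(low, 8L)
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  if (areas[big] < min_fraction * length(img))
    stop_fq("no candidate cell-free region found (largest smooth region is %.2f%% of the frame)",
            100 * areas[big] / length(img))
  # the variance window straddles the scratch boundary, shrinking the
  # low-variance core by ~window/2 on each side; dilate it back
  mask <- dilate_cheb(lab == big, (window - 1L) %/% 2L)
  list(area_px = sum(mask), mask = mask)
}

#' BrdU-positive fraction
#'
#' @param n_positive count of BrdU-positive nuclei (0 <= n_positive <=
#'   n_total).
#' @param n_total count of DAPI-positive nuclei (> 0).
#' @return fraction in [0, 1].
#' @export
brdu_fraction <- function(n_positive, n_total) {
  if (n_total <= 0) stop_fq("n_total must be > 0")
  if (n_positive < 0 || n_positive > n_total)
    stop_fq("need 0 <= n_positive <= n_total")
  n_positive / n_total
}

#' Count nuclei co-localized across two channels
#'
#' A nucleus (object in the DAPI label mask) is positive when its centroid
#' falls inside any object of the marker-channel label mask - robust to
#' small channel misregistration.
#'
#' @param nuclei_labels label mask of the nuclear (DAPI) channel.
#' @param marker_labels label mask of the marker (e.g. BrdU) channel.
#' @return list: `n_total`, `n_positive`, `fraction`.
#' @export
count_colocalized <- function(nuclei_labels, marker_labels) {
  if (!all(dim(nuclei_labels) == dim(marker_labels)))
    stop_fq("channel masks must have identical shape")
  cells <- measure_cells(matrix(0, nrow(nuclei_labels), ncol(nuclei_labels)),
                         nuclei_labels)
  if (nrow(cells) == 0) stop_fq("no nuclei in the DAPI channel")
  hit <- marker_labels[cbind(pmin(pmax(round(cells$cy) + 1L, 1L), nrow(marker_labels)),
                             pmin(pmax(round(cells$cx) + 1L, 1L), ncol(marker_labels)))]
  n_pos <- sum(hit > 0)
  list(n_total = nrow(cells), n_positive = n_pos,
       fraction = brdu_fraction(n_pos, nrow(cells)))
}

#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Standard one-way decomposition (between / within sums of squares) with
#' the studentized-range (Tukey-Kramer for unequal n) adjustment for all
#' pairwise comparisons. Normality is pre-checked per group with
#' Shapiro-Wilk as a logged warning only - the analysis always proceeds
#' parametrically.
#'
#' @param groups named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @param alpha significance level for flagging.
#' @param check_normality run the Shapiro-Wilk pre-check (warning only).
#' @return list: `F`, `p`, `df_between`, `df_within`, `exact_separation`
#'   (TRUE when within-group variance is 0 with unequal means; `F` is then
#'   `Inf`), and `tukey` data.frame (`group1`, `group2`, `diff`, `p_adj`,
#'   `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05, check_normality = TRUE) {
  if (!is.list(groups) || length(groups) < 2)
    stop_fq("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop_fq("each group needs >= 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  if (check_normality) {
    for (nm in names(groups)) {
      g <- groups[[nm]]
      if (length(g) >= 3 && length(g) <= 5000 && stats::sd(g) > 0) {
        pw <- stats::shapiro.test(g)$p.value
        if (pw < 0.05)
          warning(sprintf("normality pre-check: group '%s' fails Shapiro-Wilk (p = %.3g); proceeding parametrically",
                          nm, pw))
      }
    }
  }
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  all_v <- unlist(groups, use.names = FALSE)
  grand <- mean(all_v)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df_b <- k - 1L
  df_w <- length(all_v) - k
  exact_sep <- ss_within == 0 && ss_between > 0
  mse <- ss_within / df_w
  F_stat <- if (exact_sep) Inf else if (ss_between == 0) 0 else
    (ss_between / df_b) / mse
  p <- if (exact_sep) 0 else stats::pf(F_stat, df_b, df_w, lower.tail = FALSE)
  pairs <- utils::combn(seq_len(k), 2)
  tk <- data.frame(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    p_adj = NA_real_
  )
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (exact_sep) {
      tk$p_adj[i] <- if (means[a] != means[b]) 0 else 1
    } else {
      se <- sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
      q <- abs(means[a] - means[b]) / se
      tk$p_adj[i] <- stats::ptukey(q, k, df_w, lower.tail = FALSE)
    }
  }
  tk$significant <- tk$p_adj < alpha
  list(F = F_stat, p = p, df_between = df_b, df_within = df_w,
       exact_separation = exact_sep, tukey = tk)
}
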