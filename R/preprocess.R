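# Noise suppression and background-illumination correction.
#
# The pipeline mirrors common practice for widefield fluorescence frames:
# a small-kernel filter suppresses high-frequency (shot) noise, a
# large-kernel Gaussian estimated from cell-free pixels approximates the
# inhomogeneous illumination field, and dividing by the unit-mean field
# flattens the background while preserving the global intensity scale
# (vignetting is multiplicative, so division - not subtraction - is the
# default; subtraction is available for comparison).

#' Despeckle an image
#'
#' Small-kernel noise suppression. The default is Gaussian smoothing;
#' a 3x3 median filter is available as the classic "despeckle" alternative.
#'
#' @param img numeric intensity matrix (finite, non-negative).
#' @param sigma_small Gaussian kernel scale, pixels. Below 0.25 px the
#'   filter degenerates to the identity.
#' @param method "gaussian" (default) or "median" (3x3).
#' @return filtered image, same shape, non-negative.
#' @export
despeckle <- function(img, sigma_small = 1, method = c("gaussian", "median")) {
  method <- match.arg(method)
  check_image(img)
  if (method == "gaussian") {
    check_scalar(sigma_small, "sigma_small")
    return(gaussian_blur(img, sigma_small))
  }
  median_filter3(img)
}

# 3x3 median with reflective borders
median_filter3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  stack <- array(0, c(h, w, 9L))
  n <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    n <- n + 1L
    stack[, , n] <- img[reflect_index(seq_len(h) + dy, h),
                        reflect_index(seq_len(w) + dx, w)]
  }
  # median of 9 = 5th order statistic; apply is fine at these sizes
  matrix(apply(stack, c(1, 2), stats::median), h, w)
}

#' Estimate the background illumination field
#'
#' Approximates the smooth inhomogeneous illumination with a large-kernel
#' Gaussian computed over background (cell-free) support only:
#'
#' * `mask_excluded` (default): foreground pixels are excluded and in-filled
#'   by normalized convolution (blur of `img * weight` divided by blur of
#'   `weight`, weight = 1 on background). If no `exclusion_mask` is given, a
#'   coarse candidate-foreground pre-threshold (median + 3 * MAD of the
#'   despeckled image) is used.
#' * `sampled_rois`: a quadratic polynomial surface is fit to user-supplied
#'   cell-free rectangles and evaluated everywhere.
#'
#' @param img intensity matrix.
#' @param sigma_large Gaussian scale, pixels; should be much larger than a
#'   cell radius (a warning fires below `3 * cell_scale`).
#' @param mode "mask_excluded" or "sampled_rois".
#' @param exclusion_mask optional matrix, > 0 marks foreground to exclude.
#' @param rois for `sampled_rois`: list of `c(x0, y0, x1, y1)` rectangles
#'   (0-based, inclusive pixel coordinates).
#' @param cell_scale expected cell diameter, px (for the kernel-size warning).
#' @return strictly positive background field, same shape as `img`.
#' @export
estimate_background <- function(img, sigma_large = 52,
                                mode = c("mask_excluded", "sampled_rois"),
                                exclusion_mask = NULL, rois = NULL,
                                cell_scale = 13) {
  mode <- match.arg(mode)
  check_image(img)
  check_scalar(sigma_large, "sigma_large")
  if (sigma_large < 3 * cell_scale)
    warning(sprintf(
      "sigma_large = %.1f px is < 3x the expected cell scale (%.1f px); the background estimate may absorb cells",
      sigma_large, cell_scale))
  h <- nrow(img); w <- ncol(img)
  if (mode == "sampled_rois") {
    if (is.null(rois) || length(rois) == 0)
      stop_fq("sampled_rois mode requires a non-empty `rois` list")
    sel <- matrix(FALSE, h, w)
    for (r in rois) {
      cols <- (max(0, r[1]):min(w - 1, r[3])) + 1L
      rows <- (max(0, r[2]):min(h - 1, r[4])) + 1L
      sel[rows, cols] <- TRUE
    }
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    dat <- data.frame(z = img[sel], x = xs[sel] / w, y = ys[sel] / h)
    fit <- stats::lm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), data = dat)
    field <- matrix(stats::predict(fit, data.frame(x = as.vector(xs) / w,
                                                   y = as.vector(ys) / h)),
                    h, w)
  } else {
    if (is.null(exclusion_mask)) {
      sm <- despeckle(img, 1)
      thr <- stats::median(sm) + 3 * stats::mad(sm)
      exclusion_mask <- sm > thr
    }
    fg <- exclusion_mask > 0
    if (mean(fg) > 0.9)
      stop_fq("exclusion mask covers %.0f%% of pixels; insufficient background support",
              100 * mean(fg))
    # detrend-then-smooth: a quadratic surface fit over background pixels
    # captures the global illumination trend without the border bias a
    # plain blur would introduce; the large-kernel blur (normalized
    # convolution over background support only) then absorbs the smooth
    # residual structure
    wgt <- 1 - fg
    xs <- matrix(seq_len(w), h, w, byrow = TRUE) / w
    ys <- matrix(seq_len(h), h, w) / h
    dat <- data.frame(z = img[!fg], x = xs[!fg], y = ys[!fg])
    fit <- stats::lm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), data = dat)
    trend <- matrix(stats::predict(fit, data.frame(x = as.vector(xs),
                                                   y = as.vector(ys))),
                    h, w)
    resid <- img - trend
    k <- gaussian_kernel(sigma_large)
    num <- convolve_sep(resid * wgt, k)
    den <- convolve_sep(wgt + 0, k)
    field <- trend + num / pmax(den, 1e-9)
  }
  if (any(field <= 0)) {
    if (mean(field <= 0) > 0.05)
      stop_fq("estimated background field is non-positive over %.0f%% of pixels",
              100 * mean(field <= 0))
    field <- pmax(field, min(field[field > 0]))
  }
  field
}

#' Correct background illumination
#'
#' Default: divide by the unit-mean field, `img / (field / mean(field))`,
#' which flattens multiplicative vignetting while preserving the global
#' intensity scale. `method = "subtract"` removes `field - mean(field)`
#' instead (clamped at zero).
#'
#' @param img intensity matrix.
#' @param field strictly positive background field, same shape.
#' @param method "divide" (default) or "subtract".
#' @return corrected non-negative image.
#' @export
correct_background <- function(img, field, method = c("divide", "subtract")) {
  method <- match.arg(method)
  check_image(img)
  if (!is.matrix(field) || !all(dim(field) == dim(img)))
    stop_fq("`field` shape %s does not match image %s",
            paste(dim(field), collapse = "x"), paste(dim(img), collapse = "x"))
  if (any(!is.finite(field)) || any(field <= 0))
    stop_fq("`field` must be strictly positive and finite")
  out <- if (method == "divide") img / (field / mean(field))
         else img - (field - mean(field))
  pmax(out, 0)
}
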