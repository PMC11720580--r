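# Bradley mean adaptive thresholding, object labeling, seed-guided cell
# selection, and the detection-success-rate parameter tuner.
#
# Conventions: pixel coordinates are 0-based with x = column, y = row
# (row 1 / y = 0 at the top); label masks are integer matrices with 0 =
# background and labels 1..K assigned in raster-scan (row-major) order of
# each component's first pixel.

#' Segmentation parameters
#'
#' @param w odd neighborhood (window) size in pixels, >= 3.
#' @param s sensitivity in (0, 1): a pixel is foreground iff its value
#'   strictly exceeds `(1 - s)` times its local w x w mean. Larger s =
#'   more permissive. Other conventions map onto this one as
#'   `s = 1 - t` for a "threshold fraction" t, or `s = p / 100` for a
#'   "percentage below mean" p.
#' @param connectivity 4 or 8 (default) for component labeling.
#' @param min_area,max_area component area filter bounds, px^2.
#' @return `fq_segment_params` list.
#' @export
segment_params <- function(w = 25L, s = 0.1, connectivity = 8L,
                           min_area = 30, max_area = 5000) {
  w <- as.integer(w)
  if (w < 3L || w %% 2L == 0L) stop_fq("`w` must be odd and >= 3")
  if (!(s > 0 && s < 1)) stop_fq("`s` must be in (0, 1)")
  if (!connectivity %in% c(4L, 8L)) stop_fq("connectivity must be 4 or 8")
  if (min_area < 0 || min_area >= max_area)
    stop_fq("need 0 <= min_area < max_area")
  structure(list(w = w, s = s, connectivity = as.integer(connectivity),
                 min_area = min_area, max_area = max_area),
            class = "fq_segment_params")
}

#' Summed-area table (integral image)
#'
#' `S[i, j]` is the sum of `img` over rows <= i and columns <= j, so any
#' rectangle sum is retrievable in four lookups.
#'
#' @param img numeric matrix with finite entries.
#' @return matrix of cumulative sums, same shape.
#' @export
integral_image <- function(img) {
  if (!is.matrix(img) || any(!is.finite(img)))
    stop_fq("`img` must be a finite numeric matrix")
  t(apply(apply(img, 2, cumsum), 1, cumsum))
}

# local w x w window mean with the window clipped at the borders
# (mean over the in-bounds part; no padding bias)
window_mean <- function(img, w) {
  h <- nrow(img); wd <- ncol(img)
  k <- (w - 1L) %/% 2L
  P <- matrix(0, h + 1L, wd + 1L)
  P[-1, -1] <- integral_image(img)
  r0 <- pmax(seq_len(h) - k, 1L); r1 <- pmin(seq_len(h) + k, h)
  c0 <- pmax(seq_len(wd) - k, 1L); c1 <- pmin(seq_len(wd) + k, wd)
  sums <- P[r1 + 1L, c1 + 1L, drop = FALSE] - P[r0, c1 + 1L, drop = FALSE] -
          P[r1 + 1L, c0, drop = FALSE] + P[r0, c0, drop = FALSE]
  counts <- outer(r1 - r0 + 1L, c1 - c0 + 1L)
  sums / counts
}

#' Bradley mean adaptive threshold
#'
#' A pixel is foreground iff its intensity strictly exceeds `(1 - s)` times
#' the mean of the w x w window centered on it, with windows clipped (not
#' padded) at image borders. Computed via the integral image, bit-exact
#' against the naive per-pixel rule.
#'
#' @param img intensity matrix.
#' @param params [segment_params()] (only `w` and `s` are used).
#' @return logical matrix, TRUE = foreground.
#' @export
bradley_threshold <- function(img, params = segment_params()) {
  check_image(img)
  stopifnot(inherits(params, "fq_segment_params"))
  if (params$w >= min(dim(img)))
    stop_fq("window w = %d must be smaller than the smallest image dimension (%d)",
            params$w, min(dim(img)))
  img > window_mean(img, params$w) * (1 - params$s)
}

#' Label connected components
#'
#' Maximal connected foreground regions get labels 1..K in raster-scan
#' (row-major) order of each component's first pixel.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return integer label matrix, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stop_fq("`mask` must be a matrix")
  if (!connectivity %in% c(4L, 8L)) stop_fq("connectivity must be 4 or 8")
  fg <- mask > 0
  if (!any(fg)) return(matrix(0L, nrow(fg), ncol(fg)))
  label_components_cpp(fg, as.integer(connectivity))
}

#' Filter labeled components by area
#'
#' Components with pixel count outside `[min_area, max_area]` are removed;
#' survivors are compactly relabeled 1..K preserving their original order.
#'
#' @param labels integer label matrix.
#' @param min_area,max_area inclusive area bounds, px^2.
#' @return filtered label matrix.
#' @export
filter_by_area <- function(labels, min_area = 0, max_area = Inf) {
  if (!is.matrix(labels)) stop_fq("`labels` must be a matrix")
  if (min_area > max_area) stop_fq("min_area > max_area")
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0 & labels %in% keep
  out[pos] <- match(labels[pos], keep)
  out
}

#' Select labeled objects by seed points
#'
#' A seed is DETECTED iff it falls on a labeled pixel; the selected mask
#' keeps only components containing at least one seed. Multiple seeds in
#' one component select a single object and raise a merge warning.
#'
#' @param labels integer label matrix (post-filter).
#' @param seeds data.frame with 0-based columns `x` (column), `y` (row) and
#'   optionally `label`.
#' @return list: `labels` (selected objects, compactly relabeled in original
#'   label order), `detected` / `missed` (row subsets of `seeds`),
#'   `success_rate`, `merges` (count of extra seeds landing in an already
#'   selected component).
#' @export
select_by_seeds <- function(labels, seeds) {
  if (!is.matrix(labels)) stop_fq("`labels` must be a matrix")
  if (is.null(seeds) || nrow(seeds) == 0)
    stop_fq("empty seed set: the workflow is seed-driven")
  h <- nrow(labels); w <- ncol(labels)
  if (any(seeds$x < 0 | seeds$x >= w | seeds$y < 0 | seeds$y >= h))
    stop_fq("seed points outside image bounds")
  hit <- labels[cbind(seeds$y + 1L, seeds$x + 1L)]
  detected <- hit > 0
  sel <- sort(unique(hit[detected]))
  merges <- sum(detected) - length(sel)
  if (merges > 0)
    warning(sprintf("%d seed(s) merged: multiple seeds fall in one component",
                    merges))
  out <- matrix(0L, h, w)
  pos <- labels %in% sel
  out[pos] <- match(labels[pos], sel)
  list(labels = out,
       detected = seeds[detected, , drop = FALSE],
       missed = seeds[!detected, , drop = FALSE],
       success_rate = mean(detected),
       merges = merges)
}

#' Tune Bradley threshold parameters against seed detection
#'
#' Runs threshold -> label -> area filter -> seed matching for every (w, s)
#' on the grid and reports the seed detection success-rate surface and its
#' argmax. Ties are broken toward larger w, then smaller s (smoother, less
#' noise-sensitive segmentation).
#'
#' @param img intensity matrix (background-corrected).
#' @param seeds seed data.frame (0-based x, y).
#' @param w_grid,s_grid candidate neighborhood sizes / sensitivities.
#' @param min_area,max_area area filter applied before seed matching.
#' @param connectivity 4 or 8.
#' @return `fq_tune_report` list: `grid` (data.frame w, s, success_rate),
#'   `best_w`, `best_s`, `best_rate`, `detected`, `missed`.
#' @export
tune_parameters <- function(img, seeds, w_grid = c(15L, 25L, 35L),
                            s_grid = c(0.05, 0.1, 0.2),
                            min_area = 30, max_area = 5000,
                            connectivity = 8L) {
  check_image(img)
  if (length(w_grid) == 0 || length(s_grid) == 0) stop_fq("empty tuning grid")
  if (is.null(seeds) || nrow(seeds) == 0) stop_fq("empty seed set")
  grid <- expand.grid(w = as.integer(w_grid), s = s_grid)
  grid$success_rate <- NA_real_
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rate <- 0
    res <- NULL
    tryCatch({
      p <- segment_params(w = grid$w[i], s = grid$s[i],
                          connectivity = connectivity,
                          min_area = min_area, max_area = max_area)
      mask <- bradley_threshold(img, p)
      lab <- filter_by_area(label_components(mask, connectivity),
                            min_area, max_area)
      res <- suppressWarnings(select_by_seeds(lab, seeds))
      rate <- res$success_rate
    }, error = function(e) {
      message(sprintf("tune: (w=%d, s=%.3f) failed: %s",
                      grid$w[i], grid$s[i], conditionMessage(e)))
    })
    grid$success_rate[i] <- rate
    results[[i]] <- res
  }
  # argmax with tie-break: larger w, then smaller s
  ord <- order(-grid$success_rate, -grid$w, grid$s)
  best <- ord[1]
  structure(list(grid = grid,
                 best_w = grid$w[best], best_s = grid$s[best],
                 best_rate = grid$success_rate[best],
                 detected = if (!is.null(results[[best]])) results[[best]]$detected,
                 missed = if (!is.null(results[[best]])) results[[best]]$missed),
            class = "fq_tune_report")
}
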