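#' @keywords internal
#' @useDynLib fluoquant, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Internal validation helpers -------------------------------------------------

stop_fq <- function(fmt, ..., class = "fluoquant_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_image <- function(img, arg = "img", allow_negative = FALSE) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_fq("`%s` must be a numeric matrix", arg)
  if (any(!is.finite(img)))
    stop_fq("`%s` contains non-finite pixels", arg)
  if (!allow_negative && any(img < 0))
    stop_fq("`%s` contains negative intensities", arg)
  invisible(img)
}

check_scalar <- function(x, arg, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_fq("`%s` must be a finite numeric scalar", arg)
  if (positive && x <= 0)
    stop_fq("`%s` must be > 0", arg)
  invisible(x)
}

# Gaussian kernels and separable convolution ----------------------------------

#' Discrete normalized 1-D Gaussian kernel
#'
#' Samples exp(-x^2 / (2 sigma^2)) on integer offsets out to `radius`
#' (default 3 sigma, minimum 1) and normalizes to unit sum.
#'
#' @param sigma kernel scale in pixels (> 0).
#' @param radius half-width in pixels; default `max(1, ceiling(3 * sigma))`.
#' @return numeric vector of odd length `2 * radius + 1` summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius = NULL) {
  check_scalar(sigma, "sigma")
  if (is.null(radius)) radius <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Index vector that reflects out-of-range indices back into 1..n
# (reflection about the edge pixel: ... 3 2 | 1 2 3 ... n | n-1 n-2 ...)
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  m <- (idx - 1L) %% period
  m <- ifelse(m >= n, period - m, m)
  as.integer(m + 1L)
}

# Separable 2-D convolution with reflective borders.  Shift-and-add over the
# kernel taps: O(len(k) * npix) but fully vectorized, plenty fast at the
# image sizes this package targets.
convolve_sep <- function(img, kernel_y, kernel_x = kernel_y) {
  h <- nrow(img); w <- ncol(img)
  ry <- (length(kernel_y) - 1L) %/% 2L
  rx <- (length(kernel_x) - 1L) %/% 2L
  out <- matrix(0, h, w)
  for (j in seq_along(kernel_y)) {
    rows <- reflect_index(seq_len(h) + (j - 1L - ry), h)
    out <- out + kernel_y[j] * img[rows, , drop = FALSE]
  }
  img2 <- out
  out <- matrix(0, h, w)
  for (j in seq_along(kernel_x)) {
    cols <- reflect_index(seq_len(w) + (j - 1L - rx), w)
    out <- out + kernel_x[j] * img2[, cols, drop = FALSE]
  }
  out
}

#' Gaussian blur with reflective border handling
#'
#' @param img numeric matrix of intensities.
#' @param sigma Gaussian scale in pixels. Values below 0.25 px (kernel
#'   support under half a pixel) return the input unchanged.
#' @return blurred matrix, same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  check_image(img, allow_negative = TRUE)
  check_scalar(sigma, "sigma", positive = FALSE)
  if (sigma < 0) stop_fq("`sigma` must be >= 0")
  if (sigma < 0.25) return(img)
  k <- gaussian_kernel(sigma)
  convolve_sep(img, k)
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

# Cheap stable checksum of a character scalar (FNV-1a 32-bit), used to stamp
# output CSVs with a config fingerprint without a digest dependency.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)  # xor touches low byte only
    # 32-bit modular multiply by 16777619 = 0x1000193, split to stay exact
    # in doubles: h*0x1000193 = h*0x193 + (h mod 2^8)*2^24 (mod 2^32)
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# mean + SEM -------------------------------------------------------------

#' Mean and standard error of the mean
#'
#' @param values numeric vector, length >= 2.
#' @return list with `mean`, `sem` (sample SD / sqrt(n)) and `n`.
#' @export
summarize_values <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_fq("`values` must be finite numeric")
  n <- length(values)
  if (n < 2L) stop_fq("SEM undefined for n < 2 (got n = %d)", n)
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}
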