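# Synthetic scene / decay / trace generators with full ground truth.
#
# Every generator takes an explicit integer seed and restores the caller's
# RNG state on exit, so runs are exactly reproducible and never perturb the
# session RNG.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

apply_noise <- function(clean, noise, noise_param, rendered = NULL) {
  img <- switch(noise,
    none = clean,
    poisson = matrix(stats::rpois(length(clean), lambda = clean),
                     nrow(clean), ncol(clean)),
    gaussian = clean + matrix(stats::rnorm(length(clean), sd = noise_param),
                              nrow(clean), ncol(clean)),
    stop_fq("unknown noise model '%s'", noise))
  pmax(img, 0)
}

#' Parameters for a synthetic cell scene
#'
#' Defaults describe the kind of field the segmentation pipeline targets:
#' roughly 20 bright, roughly elliptical cells per frame on a smooth
#' inhomogeneous background with shot noise.
#'
#' @param width,height frame size in pixels.
#' @param n_cells number of cells to plant (>= 0).
#' @param radius_range min/max cell semi-minor radius, pixels.
#' @param peak_range min/max cell peak intensity, arbitrary units (a.u.).
#' @param ecc_range min/max eccentricity (major/minor axis ratio, >= 1).
#' @param base background base level, a.u.
#' @param gradient_amplitude peak-to-peak planar gradient amplitude, a.u.
#'   (the default, half the base, gives a strongly vignetted field).
#' @param smooth_scale correlation length (px) of the smooth low-frequency
#'   background component. The default (two thirds of the frame) models
#'   vignetting-like variation: structure much finer than the correction
#'   kernel would not be an "illumination" field and could not be corrected
#'   by any method of this family.
#' @param smooth_amplitude peak amplitude (a.u.) of the smooth component;
#'   default `gradient_amplitude / 8` (a mild perturbation on top of the
#'   dominant planar vignetting); 0 gives a pure base + gradient
#'   background.
#' @param noise one of "none", "poisson" (shot noise; the default for a
#'   photon-counting camera model) or "gaussian".
#' @param noise_param standard deviation for gaussian noise; ignored
#'   otherwise.
#' @param min_spacing minimum center-to-center distance, pixels; the default
#'   guarantees non-overlapping ground-truth masks.
#' @param seed integer RNG seed.
#' @return a `fq_scene_params` list.
#' @export
scene_params <- function(width = 192L, height = 192L, n_cells = 20L,
                         radius_range = c(5, 8), peak_range = c(400, 800),
                         ecc_range = c(1, 1.6), base = 100,
                         gradient_amplitude = 50, smooth_scale = 128,
                         smooth_amplitude = gradient_amplitude / 8,
                         noise = c("poisson", "none", "gaussian"),
                         noise_param = 5,
                         min_spacing = NULL, seed = 1L) {
  noise <- match.arg(noise)
  if (n_cells < 0) stop_fq("n_cells must be >= 0")
  if (any(radius_range <= 0)) stop_fq("radii must be > 0")
  if (any(ecc_range < 1)) stop_fq("eccentricity must be >= 1")
  if (base < 0 || gradient_amplitude < 0) stop_fq("intensities must be >= 0")
  if (gradient_amplitude >= 2 * base && base > 0)
    stop_fq("gradient amplitude would drive the background negative")
  max_semi_major <- max(radius_range) * max(ecc_range)
  if (is.null(min_spacing)) min_spacing <- ceiling(2 * max_semi_major) + 2
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_cells = as.integer(n_cells), radius_range = radius_range,
    peak_range = peak_range, ecc_range = ecc_range, base = base,
    gradient_amplitude = gradient_amplitude, smooth_scale = smooth_scale,
    smooth_amplitude = smooth_amplitude,
    noise = noise, noise_param = noise_param,
    min_spacing = min_spacing, seed = as.integer(seed)
  ), class = "fq_scene_params")
}

# smooth positive background field: base + planar gradient + filtered noise
make_background <- function(h, w, base, amplitude, smooth_scale,
                            smooth_amplitude) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  theta <- stats::runif(1, 0, 2 * pi)
  u <- (cos(theta) * (xs - (w + 1) / 2) + sin(theta) * (ys - (h + 1) / 2))
  span <- max(u) - min(u)
  grad <- if (span > 0) amplitude * (u - min(u)) / span - amplitude / 2 else 0
  smooth <- matrix(stats::rnorm(h * w), h, w)
  smooth <- gaussian_blur(smooth, smooth_scale / 3)
  if (stats::sd(smooth) > 0 && smooth_amplitude > 0)
    smooth <- smooth / max(abs(smooth)) * smooth_amplitude
  else smooth <- 0 * smooth
  pmax(base + grad + smooth, base * 0.01 + 1e-6)
}

#' Generate a synthetic fluorescence cell scene with ground truth
#'
#' Cells are anisotropic Gaussian intensity profiles truncated at 2.5 sigma;
#' the truncation ellipse is the ground-truth mask, so every object has an
#' unambiguous true mean intensity (mean of the noise-free cell signal over
#' its mask, background excluded). Placement is rejection sampling under the
#' minimum-spacing constraint; spacing at its default makes masks disjoint,
#' so the truth mask has exactly `n_cells` connected components.
#'
#' @param params a [scene_params()] list.
#' @param max_tries placement retry budget per scene.
#' @return `fq_scene` list: `image`, `truth_mask` (0 = background,
#'   k = cell k), `background` (the noise-free background field), `objects`
#'   (data.frame label, cx, cy, area_px, true_mean; x/y are 0-based pixel
#'   coordinates), `seeds` (data.frame x, y, label; one interior point per
#'   cell) and `params`.
#' @export
make_cell_scene <- function(params = scene_params(), max_tries = 5000L) {
  stopifnot(inherits(params, "fq_scene_params"))
  with_seed(params$seed, {
    h <- params$height; w <- params$width
    background <- make_background(h, w, params$base,
                                  params$gradient_amplitude,
                                  params$smooth_scale,
                                  params$smooth_amplitude)
    signal <- matrix(0, h, w)
    mask <- matrix(0L, h, w)
    n <- params$n_cells
    objects <- data.frame(label = integer(0), cx = numeric(0),
                          cy = numeric(0), area_px = numeric(0),
                          true_mean = numeric(0))
    seeds <- data.frame(x = integer(0), y = integer(0), label = integer(0))
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    k <- 0L
    while (k < n) {
      if (tries >= max_tries)
        stop_fq(paste0("could not place %d cells at min spacing %.1f px in a ",
                       "%dx%d frame after %d tries"),
                n, params$min_spacing, w, h, max_tries)
      tries <- tries + 1L
      r <- stats::runif(1, params$radius_range[1], params$radius_range[2])
      ecc <- stats::runif(1, params$ecc_range[1], params$ecc_range[2])
      sigma_b <- r / 2.5
      sigma_a <- ecc * sigma_b
      margin <- ceiling(2.5 * sigma_a) + 1
      if (2 * margin + 2 >= min(h, w))
        stop_fq("cells too large for the frame")
      cx <- stats::runif(1, margin + 1, w - margin)
      cy <- stats::runif(1, margin + 1, h - margin)
      if (nrow(centers) > 0 &&
          min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)) <
            params$min_spacing) next
      k <- k + 1L
      centers <- rbind(centers, c(cx, cy))
      peak <- stats::runif(1, params$peak_range[1], params$peak_range[2])
      phi <- stats::runif(1, 0, pi)
      ext <- ceiling(2.5 * sigma_a) + 1L
      cols <- max(1L, floor(cx - ext)):min(w, ceiling(cx + ext))
      rows <- max(1L, floor(cy - ext)):min(h, ceiling(cy + ext))
      dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
      dy <- matrix(rows - cy, length(rows), length(cols))
      xr <- cos(phi) * dx + sin(phi) * dy
      yr <- -sin(phi) * dx + cos(phi) * dy
      q <- (xr / sigma_a)^2 + (yr / sigma_b)^2
      inside <- q <= 2.5^2
      prof <- peak * exp(-q / 2)
      sig_patch <- signal[rows, cols]
      sig_patch[inside] <- sig_patch[inside] + prof[inside]
      signal[rows, cols] <- sig_patch
      m_patch <- mask[rows, cols]
      m_patch[inside] <- k
      mask[rows, cols] <- m_patch
      objects <- rbind(objects, data.frame(
        label = k, cx = cx - 1, cy = cy - 1, area_px = sum(inside),
        true_mean = mean(prof[inside])))
      seeds <- rbind(seeds, data.frame(
        x = round(cx) - 1L, y = round(cy) - 1L, label = k))
    }
    clean <- background + signal
    image <- apply_noise(clean, params$noise, params$noise_param)
    structure(list(image = image, truth_mask = mask,
                   background = background, clean = clean,
                   objects = objects, seeds = seeds, params = params),
              class = "fq_scene")
  })
}

#' Parameters for a synthetic mitochondrial-network scene
#'
#' Networks are rendered as star-shaped polyline graphs (1 arm = a single
#' tubule, >= 3 arms = a branched network with one junction) drawn with a
#' fixed tube width; the generating graph is kept as ground truth,
#' independent of any re-skeletonization.
#'
#' @param width,height frame size, pixels.
#' @param n_networks number of disjoint networks.
#' @param branch_choices candidate arm counts per network; 2 is excluded
#'   because a degree-2 node is not a junction and the rendered structure
#'   would read as a single branch.
#' @param branch_length_range min/max arm length, pixels.
#' @param tube_width rendered tube width, pixels.
#' @param intensity tube intensity, a.u.; background is `base`.
#' @param base background level, a.u.
#' @param noise,noise_param noise model as in [scene_params()].
#' @param seed integer RNG seed.
#' @export
mito_scene_params <- function(width = 192L, height = 192L, n_networks = 5L,
                              branch_choices = c(1L, 3L, 4L, 5L),
                              branch_length_range = c(12, 20),
                              tube_width = 3, intensity = 500, base = 10,
                              noise = c("none", "poisson", "gaussian"),
                              noise_param = 2, seed = 1L) {
  noise <- match.arg(noise)
  if (any(branch_length_range <= 0)) stop_fq("branch lengths must be > 0")
  if (any(branch_choices == 2L))
    stop_fq("2-arm stars are ambiguous (degree-2 center is not a junction)")
  if (tube_width <= 0) stop_fq("tube width must be > 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_networks = as.integer(n_networks),
                 branch_choices = as.integer(branch_choices),
                 branch_length_range = branch_length_range,
                 tube_width = tube_width, intensity = intensity, base = base,
                 noise = noise, noise_param = noise_param,
                 seed = as.integer(seed)),
            class = "fq_mito_params")
}

# distance from grid pixels to a segment, vectorized over a bounding patch
paint_segment <- function(canvas, x0, y0, x1, y1, halfwidth, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  ext <- ceiling(halfwidth) + 1L
  cols <- max(1L, floor(min(x0, x1) - ext)):min(w, ceiling(max(x0, x1) + ext))
  rows <- max(1L, floor(min(y0, y1) - ext)):min(h, ceiling(max(y0, y1) + ext))
  px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  py <- matrix(rows, length(rows), length(cols))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
  d2 <- (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
  patch <- canvas[rows, cols]
  patch[d2 <= halfwidth^2] <- value
  canvas[rows, cols] <- patch
  canvas
}

#' Generate a synthetic mitochondrial network scene
#'
#' @param params a [mito_scene_params()] list.
#' @param max_tries placement retry budget.
#' @return `fq_scene` list with `image`, `truth_mask` (label = network id),
#'   `networks` (data.frame label, branches, junctions, total_length_px) and
#'   `params`.
#' @export
make_mito_scene <- function(params = mito_scene_params(), max_tries = 5000L) {
  stopifnot(inherits(params, "fq_mito_params"))
  with_seed(params$seed, {
    h <- params$height; w <- params$width
    lmax <- params$branch_length_range[2]
    margin <- lmax + params$tube_width + 2
    if (2 * margin >= min(h, w)) stop_fq("branches too long for the frame")
    spacing <- 2 * lmax + params$tube_width + 4
    mask <- matrix(0L, h, w)
    networks <- data.frame(label = integer(0), branches = integer(0),
                           junctions = integer(0), total_length_px = numeric(0))
    centers <- matrix(numeric(0), 0, 2)
    k <- 0L; tries <- 0L
    while (k < params$n_networks) {
      if (tries >= max_tries)
        stop_fq("could not place %d networks at spacing %.1f px after %d tries",
                params$n_networks, spacing, max_tries)
      tries <- tries + 1L
      cx <- stats::runif(1, margin, w - margin)
      cy <- stats::runif(1, margin, h - margin)
      if (nrow(centers) > 0 &&
          min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)) < spacing)
        next
      k <- k + 1L
      centers <- rbind(centers, c(cx, cy))
      n_arm <- params$branch_choices[sample.int(length(params$branch_choices), 1L)]
      total_len <- 0
      if (n_arm == 1L) {
        len <- stats::runif(1, params$branch_length_range[1],
                            params$branch_length_range[2])
        if (len <= 0) stop_fq("degenerate zero-length branch")
        ang <- stats::runif(1, 0, pi)
        mask <- paint_segment(mask, cx - cos(ang) * len / 2,
                              cy - sin(ang) * len / 2,
                              cx + cos(ang) * len / 2,
                              cy + sin(ang) * len / 2,
                              params$tube_width / 2, k)
        total_len <- len
        nj <- 0L; nb <- 1L
      } else {
        base_ang <- stats::runif(1, 0, 2 * pi)
        jitter <- stats::runif(n_arm, -pi / (3 * n_arm), pi / (3 * n_arm))
        angs <- base_ang + 2 * pi * seq_len(n_arm) / n_arm + jitter
        for (a in angs) {
          len <- stats::runif(1, params$branch_length_range[1],
                              params$branch_length_range[2])
          mask <- paint_segment(mask, cx, cy, cx + cos(a) * len,
                                cy + sin(a) * len, params$tube_width / 2, k)
          total_len <- total_len + len
        }
        nj <- 1L; nb <- n_arm
      }
      networks <- rbind(networks, data.frame(
        label = k, branches = nb, junctions = nj,
        total_length_px = total_len))
    }
    clean <- params$base + (mask > 0) * params$intensity
    image <- apply_noise(clean, params$noise, params$noise_param)
    structure(list(image = image, truth_mask = mask, clean = clean,
                   networks = networks, params = params),
              class = "fq_scene")
  })
}

#' Generate a synthetic TCSPC decay histogram
#'
#' Expected counts in the bin centered at t are
#' `amplitude * exp(-t / tau) + baseline`; in `"poisson"` mode each bin is
#' an independent Poisson draw with that mean.
#'
#' @param tau lifetime, ns (> 0).
#' @param amplitude peak amplitude, counts per bin.
#' @param baseline constant offset, counts per bin.
#' @param n_bins number of time bins.
#' @param bin_width bin width, ns (> 0).
#' @param mode "expected" (noise-free) or "poisson".
#' @param seed integer RNG seed (poisson mode).
#' @return `fq_decay` list: `time_ns` (bin centers), `counts`, `bin_width`.
#' @export
make_decay <- function(tau, amplitude = 1000, baseline = 0, n_bins = 256L,
                       bin_width = 0.05, mode = c("expected", "poisson"),
                       seed = 1L) {
  mode <- match.arg(mode)
  check_scalar(tau, "tau"); check_scalar(bin_width, "bin_width")
  if (amplitude < 0 || baseline < 0) stop_fq("amplitude/baseline must be >= 0")
  t <- (seq_len(n_bins) - 0.5) * bin_width
  mu <- amplitude * exp(-t / tau) + baseline
  counts <- if (mode == "expected") mu else
    with_seed(seed, stats::rpois(n_bins, mu))
  structure(list(time_ns = t, counts = counts, bin_width = bin_width,
                 mode = mode),
            class = "fq_decay")
}

#' Generate a synthetic mito-stress-test OCR trace
#'
#' Four phases (baseline, post-oligomycin, post-FCCP,
#' post-rotenone/antimycin-A) at the given plateau rates, with additive
#' Gaussian noise.
#'
#' @param phase_levels 4 non-negative plateau rates, pmol O2/min.
#' @param n_per_phase measurements per phase.
#' @param noise_sd Gaussian noise SD.
#' @param interval_min minutes between measurements.
#' @param well,group labels carried through to results tables.
#' @param seed integer RNG seed.
#' @return an [ocr_trace()] object with 3 recorded injection boundaries.
#' @export
make_stress_trace <- function(phase_levels, n_per_phase = 3L, noise_sd = 0,
                              interval_min = 6, well = "A1", group = "ctrl",
                              seed = 1L) {
  if (length(phase_levels) != 4L) stop_fq("exactly 4 phase levels required")
  if (any(phase_levels < 0)) stop_fq("negative OCR levels rejected")
  n <- 4L * n_per_phase
  vals <- rep(phase_levels, each = n_per_phase)
  if (noise_sd > 0)
    vals <- with_seed(seed, vals + stats::rnorm(n, sd = noise_sd))
  ocr_trace(time_min = seq_len(n) * interval_min, ocr = vals,
            boundaries = n_per_phase * c(1L, 2L, 3L),
            well = well, group = group)
}

#' Write a synthetic scene to disk
#'
#' Image and label mask as 16-bit TIFF (image intensities scaled to the
#' 16-bit range; scale factor stored alongside), truth records and seeds as
#' CSV.
#'
#' @param scene an `fq_scene`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  stopifnot(inherits(scene, "fq_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(prefix, ...))
  scale <- if (max(scene$image) > 0) 65535 / max(scene$image) else 1
  write_image(round(scene$image * scale), p("_image.tif"), bits = 16)
  write_image(scene$truth_mask, p("_mask.tif"), bits = 16)
  utils::write.csv(data.frame(key = "intensity_scale", value = scale),
                   p("_scale.csv"), row.names = FALSE)
  paths <- c(image = p("_image.tif"), mask = p("_mask.tif"),
             scale = p("_scale.csv"))
  if (!is.null(scene$objects)) {
    utils::write.csv(scene$objects, p("_truth.csv"), row.names = FALSE)
    utils::write.csv(scene$seeds, p("_seeds.csv"), row.names = FALSE)
    paths <- c(paths, truth = p("_truth.csv"), seeds = p("_seeds.csv"))
  }
  if (!is.null(scene$networks)) {
    utils::write.csv(scene$networks, p("_networks.csv"), row.names = FALSE)
    paths <- c(paths, networks = p("_networks.csv"))
  }
  invisible(paths)
}
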