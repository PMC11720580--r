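test_that("empty scene is pure background and determinism holds", {
  p <- scene_params(n_cells = 0, noise = "none", seed = 7)
  sc <- make_cell_scene(p)
  expect_true(all(sc$truth_mask == 0))
  expect_identical(sc$image, sc$background)
  sc2 <- make_cell_scene(p)
  expect_identical(sc$image, sc2$image)
})

test_that("default scene has exactly n_cells components (igraph oracle)", {
  skip_if_not_installed("igraph")
  for (s in c(1, 5, 9)) {
    sc <- make_cell_scene(scene_params(seed = s))
    expect_identical(igraph_n_components(sc$truth_mask, 8L), 20L)
    expect_setequal(unique(sc$truth_mask[sc$truth_mask > 0]), 1:20)
  }
})

test_that("additive construction: single cell on flat base", {
  p <- scene_params(n_cells = 1, radius_range = c(6, 6),
                    peak_range = c(1000, 1000), ecc_range = c(1, 1),
                    base = 100, gradient_amplitude = 0, smooth_amplitude = 0,
                    noise = "none", seed = 3)
  sc <- make_cell_scene(p)
  ctr <- c(round(sc$objects$cy) + 1, round(sc$objects$cx) + 1)
  # nearest-center pixel value = base + peak * exp(-d^2 / (2 sigma^2)),
  # evaluated analytically at the sub-pixel offset d (sigma = r / 2.5)
  d2 <- (ctr[2] - 1 - sc$objects$cx)^2 + (ctr[1] - 1 - sc$objects$cy)^2
  expect_equal(sc$image[ctr[1], ctr[2]],
               100 + 1000 * exp(-d2 / (2 * (6 / 2.5)^2)), tolerance = 1e-10)
  expect_lte(max(sc$image), 1100 + 1e-9)
  # noise-free image minus background is zero outside mask support
  resid <- sc$image - sc$background
  expect_true(all(resid[sc$truth_mask == 0] == 0))
})

test_that("seeds lie inside their objects and truths are consistent", {
  sc <- make_cell_scene(scene_params(seed = 12, noise = "none"))
  hit <- sc$truth_mask[cbind(sc$seeds$y + 1, sc$seeds$x + 1)]
  expect_identical(hit, sc$seeds$label)
  m <- measure_cells(sc$image - sc$background, sc$truth_mask)
  expect_equal(m$area_px, sc$objects$area_px)
  expect_equal(m$mean_intensity, sc$objects$true_mean, tolerance = 1e-12)
})

test_that("infeasible placement errors out with the constraint named", {
  p <- scene_params(n_cells = 50, width = 64L, height = 64L, seed = 1)
  expect_error(make_cell_scene(p, max_tries = 200), "min spacing")
})

test_that("mito scene ground truth is by construction", {
  p1 <- mito_scene_params(n_networks = 3, branch_choices = 1L, seed = 2)
  ms1 <- make_mito_scene(p1)
  expect_true(all(ms1$networks$branches == 1L))
  expect_true(all(ms1$networks$junctions == 0L))
  p4 <- mito_scene_params(n_networks = 3, branch_choices = 4L, seed = 2)
  ms4 <- make_mito_scene(p4)
  expect_true(all(ms4$networks$branches == 4L))
  expect_true(all(ms4$networks$junctions == 1L))
  # determinism
  expect_identical(make_mito_scene(p4)$image, ms4$image)
  # 2-arm stars rejected as ambiguous
  expect_error(mito_scene_params(branch_choices = c(1L, 2L)), "2-arm")
})

test_that("expected-mode decay follows the exponential exactly", {
  d <- make_decay(tau = 2, amplitude = 500, baseline = 0, n_bins = 64,
                  bin_width = 0.1, mode = "expected")
  ratios <- d$counts[-length(d$counts)] / d$counts[-1]
  expect_equal(ratios, rep(exp(0.1 / 2), 63), tolerance = 1e-12)
  # paper-scale lifetime: log-counts linear with slope -1/tau
  d2 <- make_decay(tau = 3.263, amplitude = 1000, baseline = 0,
                   n_bins = 128, bin_width = 0.05, mode = "expected")
  fit <- lm(log(d2$counts) ~ d2$time_ns)
  expect_equal(unname(coef(fit)[2]), -1 / 3.263, tolerance = 1e-10)
})

test_that("poisson decay totals and per-bin means behave as Poisson", {
  tau <- 2.5; bw <- 0.05; nb <- 128
  tt <- (seq_len(nb) - 0.5) * bw
  A <- 1e5 / sum(exp(-tt / tau))
  d <- make_decay(tau, A, 0, nb, bw, mode = "poisson", seed = 11)
  expect_lt(abs(sum(d$counts) - 1e5), 4 * sqrt(1e5))
  expect_identical(d$counts,
                   make_decay(tau, A, 0, nb, bw, "poisson", seed = 11)$counts)
  # generator statistics: 200-seed mean within 3 SE of the expected curve
  mu <- A * exp(-tt / tau)
  acc <- matrix(0, 200, nb)
  for (s in 1:200)
    acc[s, ] <- make_decay(tau, A, 0, nb, bw, "poisson", seed = s)$counts
  se <- sqrt(mu / 200)
  expect_true(all(abs(colMeans(acc) - mu) <= 3 * se))
})

test_that("stress trace generator honors its contracts", {
  tr <- make_stress_trace(c(100, 40, 150, 20), n_per_phase = 3, noise_sd = 0)
  expect_length(tr$ocr, 12)
  expect_identical(tr$boundaries, c(3L, 6L, 9L))
  expect_true(all(tr$ocr[tr$phase == 1] == 100))
  expect_true(all(tr$ocr[tr$phase == 4] == 20))
  t1 <- make_stress_trace(c(100, 40, 150, 20), 3, noise_sd = 2, seed = 5)
  expect_identical(t1$ocr,
                   make_stress_trace(c(100, 40, 150, 20), 3, 2, seed = 5)$ocr)
  expect_error(make_stress_trace(c(100, -1, 150, 20)), "negative")
  expect_error(make_stress_trace(c(100, 40, 150)), "4 phase")
})

test_that("scene export writes readable rasters and tables", {
  dir <- withr::local_tempdir()
  sc <- make_cell_scene(scene_params(seed = 3))
  paths <- write_scene(sc, dir)
  img <- read_image(paths[["image"]])
  expect_identical(dim(img), dim(sc$image))
  mask <- read_image(paths[["mask"]])
  expect_identical(mask, sc$truth_mask + 0.0)
  truth <- read.csv(paths[["truth"]])
  expect_identical(nrow(truth), 20L)
  seeds <- read.csv(paths[["seeds"]])
  expect_named(seeds, c("x", "y", "label"))
})
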