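test_that("integral image matches its definition", {
  m <- matrix(c(1, 3, 2, 4), 2, 2, byrow = TRUE)  # [[1,2],[3,4]] row-major
  S <- integral_image(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(S[2, 2], 10)
  ones <- matrix(1, 5, 5)
  expect_equal(integral_image(ones), outer(1:5, 1:5))
  # every 3x3 window sum equals naive summation exactly
  set.seed(3)
  img <- matrix(runif(256, 0, 10), 16, 16)
  P <- matrix(0, 17, 17); P[-1, -1] <- integral_image(img)
  for (i in 2:15) for (j in 2:15) {
    ws <- P[i + 2, j + 2] - P[i - 1, j + 2] - P[i + 2, j - 1] + P[i - 1, j - 1]
    expect_equal(ws, sum(img[(i - 1):(i + 1), (j - 1):(j + 1)]),
                 tolerance = 1e-12)
  }
})

test_that("bradley_threshold: uniform images and param validation", {
  u <- matrix(3, 20, 20)
  expect_true(all(bradley_threshold(u, segment_params(w = 5, s = 0.2))))
  expect_error(segment_params(w = 4), "odd")
  expect_error(segment_params(s = 0), "0, 1")
  expect_error(segment_params(s = 1), "0, 1")
  expect_error(bradley_threshold(u, segment_params(w = 21)), "smaller")
})

test_that("bradley_threshold equals the brute-force rule (bright square)", {
  img <- matrix(10, 40, 40); img[18:23, 18:23] <- 200
  p <- segment_params(w = 15, s = 0.2)
  mask <- bradley_threshold(img, p)
  expect_identical(mask, naive_bradley(img, 15, 0.2))
  expect_true(all(mask[19:22, 19:22]))  # square interior foreground
  # NB: far-field background is also "foreground" under the strict-> rule
  # (uniform value > (1-s) * local mean), consistent with the uniform-image
  # case; the area filter is what discards it. The ring around the square,
  # whose windows straddle the bright pixels, is genuinely suppressed:
  ring <- matrix(FALSE, 40, 40)
  ring[14:27, 14:27] <- TRUE; ring[17:24, 17:24] <- FALSE
  expect_true(all(!mask[ring]))
})

test_that("foreground grows monotonically in s (exact set inclusion)", {
  set.seed(9)
  img <- matrix(runif(1024, 0, 100), 32, 32)
  prev <- bradley_threshold(img, segment_params(w = 9, s = 0.02))
  for (s in c(0.05, 0.1, 0.3, 0.6)) {
    cur <- bradley_threshold(img, segment_params(w = 9, s = s))
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("label_components: connectivity semantics and raster order", {
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
  expect_equal(max(label_components(m, 8L)), 1)
  expect_equal(max(label_components(m, 4L)), 2)
  expect_equal(max(label_components(matrix(0, 5, 5))), 0)
  # raster-scan order of first pixel: labels ordered by row-major first pixel
  m2 <- matrix(0, 6, 8)
  m2[5, 2] <- 1          # component with later first pixel
  m2[2, 6] <- 1          # earlier in raster order (row 2)
  lab <- label_components(m2, 8L)
  expect_equal(lab[2, 6], 1L)
  expect_equal(lab[5, 2], 2L)
})

test_that("label_components agrees with igraph on random masks", {
  skip_if_not_installed("igraph")
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(runif(30 * 30) < 0.35, 30, 30)
    for (conn in c(4L, 8L))
      expect_equal(max(label_components(m, conn)),
                   igraph_n_components(m, conn))
  }
})

test_that("filter_by_area keeps, relabels, empties", {
  m <- matrix(0, 10, 12)
  m[2:3, 2:3] <- 1   # 4 px
  m[6, 6] <- 1       # 1 px speckle
  m[8:9, 9:11] <- 1  # 6 px
  lab <- label_components(m, 8L)
  f <- filter_by_area(lab, 2, 100)
  expect_equal(sort(unique(f[f > 0])), c(1L, 2L))
  expect_equal(sum(f == 1), 4)    # original order preserved
  expect_equal(sum(f == 2), 6)
  expect_identical(filter_by_area(lab, 0, Inf), lab)
  expect_true(all(filter_by_area(lab, 1000, Inf) == 0))
})

test_that("speckle rejection: exactly the planted cells survive", {
  sc <- make_cell_scene(scene_params(seed = 6, noise = "none"))
  m <- sc$truth_mask > 0
  set.seed(1)
  # plant 30 one-pixel speckles on background
  bg <- which(!m)
  m[bg[sample(length(bg), 30)]] <- TRUE
  lab <- label_components(m, 8L)
  min_true_area <- min(sc$objects$area_px)
  f <- filter_by_area(lab, ceiling(min_true_area / 2), Inf)
  expect_equal(max(f), 20)
})

test_that("select_by_seeds detects, misses, merges", {
  m <- matrix(0, 10, 10); m[3:5, 3:5] <- 1; m[8:9, 8:9] <- 1
  lab <- label_components(m, 8L)
  seeds <- data.frame(x = c(3, 0, 8), y = c(3, 0, 8), label = 1:3)
  r <- select_by_seeds(lab, seeds)
  expect_equal(nrow(r$detected), 2)
  expect_equal(r$missed$label, 2L)
  expect_equal(r$success_rate, 2 / 3)
  expect_equal(max(r$labels), 2)
  # merge: two seeds in one component
  seeds2 <- data.frame(x = c(3, 4), y = c(3, 4))
  expect_warning(r2 <- select_by_seeds(lab, seeds2), "merged")
  expect_equal(max(r2$labels), 1)
  expect_equal(r2$merges, 1L)
  expect_error(select_by_seeds(lab, seeds[0, ]), "seed")
  expect_error(select_by_seeds(lab, data.frame(x = 99, y = 1)), "bounds")
})

test_that("tuner finds a perfect grid point on a synthetic scene", {
  sc <- make_cell_scene(scene_params(seed = 11))
  corr <- correct_background(
    despeckle(sc$image, 1),
    estimate_background(sc$image, 52, cell_scale = 13))
  rep <- tune_parameters(corr, sc$seeds)
  expect_equal(rep$best_rate, 1.0)
  expect_equal(nrow(rep$missed), 0)
})

test_that("degenerate sensitivity floods and is rejected by the area filter", {
  sc <- make_cell_scene(scene_params(seed = 2))
  rep <- tune_parameters(sc$image, sc$seeds, w_grid = 25L, s_grid = 0.999,
                         min_area = 30, max_area = 5000)
  expect_equal(rep$grid$success_rate, 0)
})

test_that("tuner tie-break prefers larger w then smaller s", {
  # uniform image: every pixel foreground, giant component always rejected
  # by the area filter, so all grid points tie at rate 0
  u <- matrix(10, 50, 50)
  seeds <- data.frame(x = 25, y = 25)
  rep <- tune_parameters(u, seeds, w_grid = c(9L, 15L), s_grid = c(0.1, 0.3),
                         min_area = 5, max_area = 100)
  expect_true(all(rep$grid$success_rate == 0))
  expect_equal(rep$best_w, 15L)
  expect_equal(rep$best_s, 0.1)
})
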