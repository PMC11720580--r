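test_that("measure_cells measures exactly the labeled pixels", {
  img <- matrix(0, 10, 10)
  lab <- matrix(0L, 10, 10)
  img[2:4, 2:4] <- 37; lab[2:4, 2:4] <- 1L
  img[7:8, 7:9] <- c(1, 2, 3, 4, 5, 6); lab[7:8, 7:9] <- 2L
  m <- measure_cells(img, lab)
  expect_equal(m$mean_intensity, c(37, 3.5))
  expect_equal(m$area_px, c(9, 6))
  expect_equal(m$cx[1], 2)  # 0-based centroid of cols 2:4 (1-based)
  expect_warning(m0 <- measure_cells(img, matrix(0L, 10, 10)), "empty")
  expect_equal(nrow(m0), 0)
})

test_that("noise-free synthetic means match truth within 2%", {
  sc <- make_cell_scene(scene_params(seed = 2, noise = "none"))
  m <- measure_cells(sc$image - sc$background, sc$truth_mask)
  expect_equal(nrow(m), 20)  # ~20 cells per frame by design
  expect_lt(max(abs(m$mean_intensity - sc$objects$true_mean) /
                sc$objects$true_mean), 0.02)
})

test_that("pbm_ratio: identities, scaling, error propagation", {
  x <- c(1.1, 1.3, 0.9)
  expect_equal(pbm_ratio(x, x)$ratio, 1.0)
  expect_equal(pbm_ratio(2 * x, x)$ratio, 2.0)
  # scale invariance (to floating-point rounding)
  r1 <- pbm_ratio(c(1.2, 1.4), c(1.0, 1.1))
  r2 <- pbm_ratio(5 * c(1.2, 1.4), 5 * c(1.0, 1.1))
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-14)
  expect_error(pbm_ratio(x, numeric(0)), "non-empty")
  expect_error(pbm_ratio(x, c(-2, 0)), "control mean")
  expect_equal(pbm_ratio(c(1.2, 1.4), c(1.0, 1.0))$ratio, 1.3)
  # propagated SEM against a bootstrap oracle (1e4 resamples). At n = 2 the
  # plug-in bootstrap SD is sqrt((n-1)/n) = 0.71x the sample-SD SEM by
  # construction, so the comparison is made at a realistic group size.
  set.seed(77)
  tr <- rnorm(20, 1.3, 0.12); ct <- rnorm(20, 1.0, 0.10)
  r <- pbm_ratio(tr, ct)
  boot <- replicate(1e4,
                    mean(sample(tr, 20, TRUE)) / mean(sample(ct, 20, TRUE)))
  expect_lt(abs(r$sem - sd(boot)) / sd(boot), 0.15)
})

test_that("wound_closure arithmetic", {
  expect_equal(wound_closure(500, 500), 0)
  expect_equal(wound_closure(500, 0), 1)
  expect_equal(wound_closure(1000, 400), 0.6)
  expect_equal(wound_closure(500, 600), -0.2)
  expect_error(wound_closure(0, 10), "area_t0")
  expect_error(wound_closure(10, -1), ">= 0")
})

test_that("wound_area recovers a planted scratch band within 10%", {
  set.seed(5)
  h <- 150; w <- 200
  img <- matrix(100 + rnorm(h * w, 0, 25)^2, h, w)  # textured monolayer
  band <- 80:130
  img[, band] <- 100 + rnorm(h * length(band), 0, 3)
  wa <- wound_area(img, window = 15)
  expect_lt(abs(wa$area_px - h * length(band)) / (h * length(band)), 0.10)
  # half-retextured band reads as ~50% closure
  img2 <- matrix(100 + rnorm(h * w, 0, 25)^2, h, w)
  img2[, 80:105] <- 100 + rnorm(h * 26, 0, 3)
  cl <- wound_closure(wa$area_px, wound_area(img2, window = 15)$area_px)
  expect_lt(abs(cl - 0.5), 0.10)
  # confluent texture: no scratch -> error
  img3 <- matrix(100 + rnorm(h * w, 0, 25)^2, h, w)
  expect_error(wound_area(img3, window = 15), "confluent|cell-free")
})

test_that("brdu_fraction and centroid co-localization", {
  expect_equal(brdu_fraction(0, 100), 0)
  expect_equal(brdu_fraction(25, 100), 0.25)
  expect_error(brdu_fraction(5, 0), "n_total")
  expect_error(brdu_fraction(11, 10), "<=")

  # two-channel synthetic scene, 30% of nuclei positive
  sc <- make_cell_scene(scene_params(seed = 21))
  pos <- sc$objects$label[1:6]
  sig <- sc$clean - sc$background
  brdu_clean <- 50 + sig * (sc$truth_mask %in% pos)
  set.seed(8)
  brdu_img <- matrix(rpois(length(brdu_clean), brdu_clean), nrow(brdu_clean))
  seg <- function(img) {
    sm <- despeckle(img, 1)
    corr <- correct_background(
      sm, estimate_background(sm, 52, cell_scale = 13))
    filter_by_area(
      label_components(
        bradley_threshold(corr, segment_params(w = 25, s = 0.1)), 8L),
      30, 5000)
  }
  r <- count_colocalized(seg(sc$image), seg(brdu_img))
  expect_lt(abs(r$fraction - 0.3), 0.05)
})

test_that("anova_tukey: F identities and the hand-expanded oracle", {
  # equal means, nonzero within-variance -> F = 0 exactly
  g <- list(a = c(1, 2, 3), b = c(2, 2, 2) + c(-1, 0, 1), c = c(0, 2, 4))
  r0 <- anova_tukey(g, check_normality = FALSE)
  expect_identical(r0$F, 0)
  # hand-expanded sums of squares: SSB = 42, SSW = 6, F = 21
  g2 <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  r <- anova_tukey(g2, check_normality = FALSE)
  expect_equal(r$F, 21, tolerance = 1e-10)
  expect_equal(r$df_between, 2L)
  expect_equal(r$df_within, 6L)
  # Tukey p monotone in mean separation
  tk <- r$tukey
  p_ab <- tk$p_adj[tk$group1 == "a" & tk$group2 == "b"]
  p_ac <- tk$p_adj[tk$group1 == "a" & tk$group2 == "c"]
  expect_gt(p_ab, p_ac)
  # exact separation: zero within-variance, unequal means
  rs <- anova_tukey(list(a = c(1, 1), b = c(2, 2)), check_normality = FALSE)
  expect_true(rs$exact_separation)
  expect_identical(rs$F, Inf)
  expect_error(anova_tukey(list(a = 1:3)), ">= 2 groups")
  expect_error(anova_tukey(list(a = 1, b = 1:2)), ">= 2 values")
})

test_that("anova_tukey matches aov/TukeyHSD on 100 random tables", {
  set.seed(123)
  for (i in 1:100) {
    k <- sample(3:5, 1)
    ns <- sample(4:9, k, replace = TRUE)
    vals <- lapply(ns, function(n) rnorm(n, mean = runif(1, 0, 3)))
    names(vals) <- paste0("g", seq_len(k))
    mine <- anova_tukey(vals, check_normality = FALSE)
    df <- data.frame(y = unlist(vals),
                     g = factor(rep(names(vals), times = ns)))
    fit <- aov(y ~ g, data = df)
    F_ref <- summary(fit)[[1]]$`F value`[1]
    expect_equal(mine$F, F_ref, tolerance = 1e-8)
    ref <- TukeyHSD(fit)$g
    key <- paste(mine$tukey$group2, mine$tukey$group1, sep = "-")
    expect_equal(mine$tukey$p_adj, unname(ref[key, "p adj"]),
                 tolerance = 1e-4)
  }
})

test_that("summarize_values: arithmetic and degenerate input", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_equal(summarize_values(c(4, 4, 4, 4))$sem, 0)
  expect_error(summarize_values(5), "n < 2")
})
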