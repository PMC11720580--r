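test_that("TIFF round trips preserve values bit-exactly", {
  dir <- withr::local_tempdir()
  p16 <- file.path(dir, "a.tif")
  m <- matrix(sample(0:65535, 300), 15, 20)
  write_image(m, p16, bits = 16)
  expect_identical(read_image(p16), m + 0.0)
  # constant 16-bit image reads back unscaled
  pc <- file.path(dir, "c.tif")
  write_image(matrix(1234, 7, 9), pc, bits = 16)
  expect_identical(read_image(pc), matrix(1234.0, 7, 9))
  # float32
  pf <- file.path(dir, "f.tif")
  mf <- matrix(rnorm(200), 10, 20)
  write_image(mf, pf, bits = "float32")
  expect_lt(max(abs(read_image(pf) - mf)), 1e-6)
  # 8-bit
  p8 <- file.path(dir, "b.tif")
  m8 <- matrix(sample(0:255, 96, TRUE), 8, 12)
  write_image(m8, p8, bits = 8)
  expect_identical(read_image(p8), m8 + 0.0)
  # out-of-range data refused
  expect_error(write_image(matrix(70000, 2, 2), p16, bits = 16), "rescale")
})

test_that("multi-page and multi-channel files require explicit selection", {
  dir <- withr::local_tempdir()
  p2 <- file.path(dir, "two.tif")
  m1 <- matrix(1:12, 3, 4); m2 <- matrix(13:24, 3, 4)
  write_image(list(m1, m2), p2, bits = 16)
  expect_error(read_image(p2), "pages")
  expect_identical(read_image(p2, page = 1), m1 + 0.0)
  expect_identical(read_image(p2, page = 2), m2 + 0.0)
  expect_error(read_image(p2, page = 3), "range")
  prgb <- file.path(dir, "rgb.tif")
  a <- array(sample(0:255, 60, TRUE), c(4, 5, 3))
  write_image(a, prgb, bits = 8)
  expect_error(read_image(prgb), "channel")
  expect_identical(read_image(prgb, channel = 3), a[, , 3] + 0.0)
  expect_error(read_image(file.path(dir, "nope.tif")), "not found")
})

test_that("config round-trip is idempotent and unknown keys are rejected", {
  dir <- withr::local_tempdir()
  cfg <- default_config()
  cfg$segment$s <- 0.07
  p <- file.path(dir, "run.yaml")
  write_config(cfg, p)
  cfg2 <- read_config(p)
  expect_equal(cfg2, cfg)
  p2 <- file.path(dir, "again.yaml")
  write_config(cfg2, p2)
  expect_equal(read_config(p2), cfg2)
  writeLines("segment:\n  nonsense: 4\n", p)
  expect_error(read_config(p), "unknown configuration key 'segment.nonsense'")
})

test_that("write_table stamps a version/config header", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.csv")
  write_table(data.frame(a = 1:2, b = c("x", "y")), p)
  lines <- readLines(p)
  expect_match(lines[1], "^# fluoquant .+ config=[0-9a-f]{8}$")
  back <- read.csv(p, comment.char = "#")
  expect_equal(back$a, 1:2)
})

test_that("run_pipeline measures every planted cell deterministically", {
  sc <- make_cell_scene(scene_params(seed = 13))
  res <- run_pipeline(sc$image, sc$seeds, tune = TRUE)
  expect_equal(nrow(res$measurements), 20)
  expect_equal(res$selection$success_rate, 1.0)
  # determinism: byte-identical measurement CSVs on rerun
  dir <- withr::local_tempdir()
  res2 <- run_pipeline(sc$image, sc$seeds, tune = TRUE)
  f1 <- file.path(dir, "m1.csv"); f2 <- file.path(dir, "m2.csv")
  write_table(res$measurements, f1)
  write_table(res2$measurements, f2)
  expect_identical(readLines(f1), readLines(f2))
  # missing seeds abort with the seed-driven contract named
  expect_error(run_pipeline(sc$image, NULL), "seed-driven")
  expect_error(run_pipeline(sc$image, file.path(dir, "no.csv")),
               "seed-driven")
})

test_that("run_pipeline works from files and writes intermediates", {
  dir <- withr::local_tempdir()
  sc <- make_cell_scene(scene_params(seed = 3, noise = "none"))
  paths <- write_scene(sc, dir)
  cfg <- default_config()
  res <- run_pipeline(paths[["image"]], paths[["seeds"]], cfg, tune = FALSE,
                      save_intermediates = file.path(dir, "inter"))
  expect_gt(nrow(res$measurements), 0)
  for (f in c("despeckled.tif", "background.tif", "corrected.tif",
              "labels.tif", "selected.tif"))
    expect_true(file.exists(file.path(dir, "inter", f)))
})

test_that("CLI subcommands run end-to-end and report status codes", {
  dir <- withr::local_tempdir()
  # synth -> segment -> quantify chain
  expect_equal(suppressMessages(
    fluoquant_cli(c("synth", "--out", dir, "--seed", "5"))), 0L)
  img <- file.path(dir, "cells_5_image.tif")
  seeds <- file.path(dir, "cells_5_seeds.csv")
  expect_true(file.exists(img) && file.exists(seeds))
  out <- file.path(dir, "meas.csv")
  expect_equal(suppressMessages(fluoquant_cli(
    c("quantify", "--image", img, "--seeds", seeds, "--out", out))), 0L)
  meas <- read.csv(out, comment.char = "#")
  expect_equal(nrow(meas), 20)
  # stats subcommand
  vals <- file.path(dir, "vals.csv")
  write.csv(data.frame(group = rep(c("a", "b"), each = 5),
                       value = c(rnorm(5, 1), rnorm(5, 3))),
            vals, row.names = FALSE)
  expect_equal(suppressMessages(fluoquant_cli(
    c("stats", "--values", vals, "--out", file.path(dir, "st.csv")))), 0L)
  # ocr subcommand
  tr <- make_stress_trace(c(100, 40, 150, 20), 3, 1, well = "w1",
                          group = "g", seed = 2)
  tcsv <- file.path(dir, "traces.csv")
  write.csv(data.frame(well = tr$well, group = tr$group,
                       time_min = tr$time_min, ocr_pmol_min = tr$ocr,
                       phase = tr$phase), tcsv, row.names = FALSE)
  expect_equal(suppressMessages(fluoquant_cli(
    c("ocr", "--traces", tcsv, "--out", file.path(dir, "sm.csv")))), 0L)
  sm <- read.csv(file.path(dir, "sm.csv"), comment.char = "#")
  expect_equal(sm$non_mito, 20, tolerance = 3)
  # unknown subcommand -> input error code
  expect_equal(suppressMessages(fluoquant_cli("frobnicate")), 2L)
  # stage failure -> code 3
  expect_equal(suppressMessages(fluoquant_cli(
    c("quantify", "--image", img, "--seeds", file.path(dir, "no.csv")))), 3L)
})

test_that("CLI flim subcommand fits long-format decays", {
  dir <- withr::local_tempdir()
  rows <- do.call(rbind, lapply(1:3, function(i) {
    d <- make_decay(2.5, 3000, 5, n_bins = 128, mode = "poisson", seed = i)
    data.frame(roi_id = paste0("r", i), time_ns = d$time_ns,
               counts = d$counts)
  }))
  dcsv <- file.path(dir, "decays.csv")
  write.csv(rows, dcsv, row.names = FALSE)
  out <- file.path(dir, "taus.csv")
  expect_equal(suppressMessages(fluoquant_cli(
    c("flim", "--decays", dcsv, "--out", out))), 0L)
  res <- read.csv(out, comment.char = "#")
  expect_equal(nrow(res), 3)
  expect_true(all(abs(res$tau_ns - 2.5) / 2.5 < 0.05))
})
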