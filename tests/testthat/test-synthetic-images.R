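test_that("degenerate spec yields a constant image at the background level", {
  g <- gen_sheet_image(image_spec(width_px = 32, height_px = 32,
                                  clustered_fraction = 0, mean_signal = 0,
                                  background_level = 7, noise_model = "none"))
  expect_true(all(g$image$pixels == 7))
  g2 <- gen_sheet_image(image_spec(width_px = 32, height_px = 32,
                                   clustered_fraction = 0, mean_signal = 12,
                                   background_level = 7,
                                   noise_model = "none"))
  expect_equal(unname(diff(range(g2$image$pixels))), 0)
  expect_equal(g2$image$pixels[1, 1], 19)
})

test_that("a single generated cluster peaks at its reported centre", {
  # scan seeds for a realization with exactly one cluster
  found <- FALSE
  for (s in 1:50) {
    spec <- image_spec(width_px = 64, height_px = 64, pixel_size_nm = 40,
                       cluster_density_per_um2 = 0.15,
                       cluster_radius_nm = 80, clustered_fraction = 0.9,
                       noise_model = "none", seed = s)
    g <- gen_sheet_image(spec)
    if (g$n_clusters == 1) { found <- TRUE; break }
  }
  expect_true(found)
  peak <- which(g$image$pixels == max(g$image$pixels), arr.ind = TRUE)[1, ]
  expect_lte(abs(peak["col"] - 1 - g$centers[1, "x"]), 1)
  expect_lte(abs(peak["row"] - 1 - g$centers[1, "y"]), 1)
})

test_that("cluster counts are Poisson with the requested density", {
  # field of 25 um^2 at density 4 um^-2 -> lambda = 100 per image
  counts <- vapply(1:100, function(s) {
    gen_sheet_image(image_spec(width_px = 125, height_px = 125,
                               pixel_size_nm = 40,
                               cluster_density_per_um2 = 4,
                               cluster_radius_nm = 40,
                               noise_model = "none", seed = s))$n_clusters
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 100))
})

test_that("total signal is conserved (background + injected signal)", {
  spec <- image_spec(width_px = 48, height_px = 48, mean_signal = 30,
                     background_level = 5, clustered_fraction = 0.7,
                     cluster_radius_nm = 60, psf_sigma_nm = 50,
                     noise_model = "none", seed = 4)
  g <- gen_sheet_image(spec)
  npx <- 48 * 48
  expect_equal(sum(g$image$pixels), npx * (5 + 30), tolerance = 1e-10)
})

test_that("generation is deterministic in the seed and rejects bad specs", {
  s <- image_spec(seed = 11, noise_model = "poisson")
  expect_identical(gen_sheet_image(s)$image$pixels,
                   gen_sheet_image(s)$image$pixels)
  s2 <- image_spec(seed = 12, noise_model = "poisson")
  expect_false(identical(gen_sheet_image(s)$image$pixels,
                         gen_sheet_image(s2)$image$pixels))
  expect_error(gen_sheet_image(image_spec(width_px = 16, height_px = 16,
                                          pixel_size_nm = 1000,
                                          cluster_density_per_um2 = 10)),
               "exceeds pixel count")
  expect_error(image_spec(clustered_fraction = 1.4), "clustered_fraction")
  expect_error(image_spec(pixel_size_nm = -1), "positive")
})

test_that("noise models keep the image non-negative", {
  g <- gen_sheet_image(image_spec(background_level = 1, mean_signal = 2,
                                  noise_model = "gaussian", noise_sd = 10,
                                  seed = 3))
  expect_true(all(g$image$pixels >= 0))
  p <- gen_sheet_image(image_spec(noise_model = "poisson", gain = 2,
                                  seed = 3))
  expect_true(all(p$image$pixels >= 0))
})

test_that("TIFF round trip preserves the raster up to 16-bit quantization", {
  g <- gen_sheet_image(image_spec(width_px = 32, height_px = 24, seed = 8))
  path <- tempfile(fileext = ".tif")
  write_sheet_image(g, path)
  back <- read_sheet_image(path)
  expect_equal(dim(back$pixels), dim(g$image$pixels))
  expect_equal(back$pixel_size_nm, g$image$pixel_size_nm)
  expect_lt(max(abs(back$pixels - g$image$pixels)) / max(g$image$pixels),
            1 / 65000)
  unlink(c(path, paste0(path, ".json")))
})
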