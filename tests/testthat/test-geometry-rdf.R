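test_that("minimum-image distance wraps correctly", {
  expect_equal(minimum_image_distance(c(1, 2, 3), c(1, 2, 3), c(10, 10, 10)), 0)
  expect_equal(minimum_image_distance(c(0, 0, 0), c(9.9, 0, 0), c(10, 10, 10)),
               0.1, tolerance = 1e-12)
  expect_equal(minimum_image_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_error(minimum_image_distance(c(0, 0, 0), c(1, 1, 1), c(-1, 2, 2)),
               "positive")
})

test_that("minimum-image distances equal brute-force image enumeration", {
  set.seed(17)
  box <- c(3.2, 4.1, 2.7)
  for (k in 1:50) {
    a <- runif(3) * box; b <- runif(3) * box
    expect_equal(minimum_image_distance(a, b, box),
                 brute_min_image(a, b, box), tolerance = 1e-12)
  }
})

test_that("window selection handles fractions, times and indices", {
  tr <- gen_ideal_gas_frames(5, c(3, 3, 3), 10, seed = 1)
  expect_equal(select_window(tr, "last:0.2"), 9:10)
  expect_equal(select_window(tr, "all"), 1:10)
  expect_equal(select_window(tr, 3:5), 3:5)
  tr$times_ps <- seq(0, 90, by = 10)
  expect_equal(select_window(tr, "last_ps:25"), 8:10)
  expect_error(select_window(tr, "last:1.5"), "fraction")
  expect_error(select_window(tr, 0:2), "out of range")
})

test_that("two fixed atoms produce a single occupied RDF bin", {
  atoms <- data.frame(atom_id = 1:2, atom_name = c("CA", "CG"),
                      residue_name = c("CA", "ASP"),
                      residue_number = 1:2, chain_id = "A",
                      stringsAsFactors = FALSE)
  coords <- rbind(c(5, 5, 5), c(5.32, 5, 5))
  tr <- trajectory(atoms, coords, box = c(10, 10, 10))
  rdf <- compute_rdf(tr, "calcium", "carboxylate_carbon",
                     bin_width_nm = 0.02, r_max_nm = 1.0)
  occupied <- which(rdf$g_r > 0)
  expect_length(occupied, 1L)
  expect_lt(abs(rdf$r_centers_nm[occupied] - 0.32), 0.02)
})

test_that("ideal gas RDF is flat and integrates to the neighbour count", {
  tr <- gen_ideal_gas_frames(300, c(4, 4, 4), 30, seed = 6)
  rdf <- compute_rdf(tr, "gas", "gas", bin_width_nm = 0.1, r_max_nm = 1.6)
  # flat beyond the first bin, judged against the per-bin standard error
  dev <- abs(rdf$g_r[-1] - 1) / rdf$g_se[-1]
  expect_lt(max(dev), 4)
  expect_lt(abs(mean(rdf$g_r[-1]) - 1), 0.01)
  # neighbour-count closure: sum over shells vs direct distance count
  rho <- (300 - 1) / 64
  shell <- 4 / 3 * pi * diff(seq(0, 1.6, by = 0.1)^3)
  predicted <- sum(rho * rdf$g_r * shell)
  direct <- mean(vapply(seq_len(30), function(f) {
    d <- min_image_dist_matrix(frame_coords(tr, 1:300, f),
                               frame_coords(tr, 1:300, f), c(4, 4, 4))
    (sum(d < 1.6) - 300) / 300   # exclude self-distances
  }, numeric(1)))
  expect_equal(predicted, direct, tolerance = 1e-6)
})

test_that("r_max beyond half the box edge is rejected", {
  tr <- gen_ideal_gas_frames(10, c(3, 3, 3), 2, seed = 1)
  expect_error(compute_rdf(tr, "gas", "gas", 0.05, 2.0), "half the smallest")
})

synthetic_rdf <- function(r, g) {
  structure(list(r_centers_nm = r, g_r = g,
                 g_se = rep(0.01, length(r)), bin_width_nm = diff(r[1:2]),
                 n_frames = 1L, n_a = 1L, n_b = 1L,
                 role_a = "calcium", role_b = "carboxylate_carbon"),
            class = "rdf_result")
}

test_that("first-shell threshold finds the minimum after the first peak", {
  r <- seq(0.01, 1, by = 0.01)
  g <- 1 + 3 * exp(-(r - 0.32)^2 / 0.002) - 0.9 * exp(-(r - 0.45)^2 / 0.002)
  thr <- first_shell_threshold(synthetic_rdf(r, g))
  expect_lt(abs(thr - 0.45), 0.02)
  expect_false(attr(thr, "fallback"))
})

test_that("a bimodal first shell is not split at the intermediate dip", {
  r <- seq(0.01, 1, by = 0.01)
  g <- 1 +
    4.0 * exp(-(r - 0.32)^2 / 0.0008) +
    3.5 * exp(-(r - 0.38)^2 / 0.0008) -
    0.95 * exp(-(r - 0.50)^2 / 0.002)
  # the dip between 0.32 and 0.38 stays above 1; the true shell boundary
  # is the deep minimum near 0.50
  thr <- first_shell_threshold(synthetic_rdf(r, g))
  expect_gt(thr, 0.45)
  expect_lt(abs(thr - 0.50), 0.03)
})

test_that("a featureless RDF falls back to the default threshold table", {
  tr <- gen_ideal_gas_frames(200, c(4, 4, 4), 10, seed = 3)
  rdf <- compute_rdf(tr, "gas", "gas", bin_width_nm = 0.1, r_max_nm = 1.5)
  rdf$role_b <- "carboxylate_carbon"
  expect_warning(thr <- first_shell_threshold(rdf), "fall")
  expect_equal(as.numeric(thr), 0.4)
  expect_true(attr(thr, "fallback"))
  expect_equal(unname(default_threshold_table()["carboxylate_carbon"]), 0.4)
})
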