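test_that("constructed fixtures give exact contact counts with conservation", {
  b <- gen_bridged_frames(bridged_frame_spec(
    n_ions = 3L, n_sites = 12L, contact_distribution = c("2" = 1),
    n_frames = 10L, seed = 4))
  for (f in 1:10) {
    cc <- contact_counts(b$trajectory, f)
    expect_true(all(cc$per_ion == 2L))
    expect_equal(sum(cc$per_ion), sum(cc$per_site))
    expect_equal(cc$n_pairs, 6L)
  }
})

test_that("an empty partner group yields all-zero counts", {
  tr <- gen_ideal_gas_frames(5, c(4, 4, 4), 1, seed = 1)
  cc <- contact_counts(tr, 1, ion_role = "gas", site_role = "calcium")
  expect_length(cc$per_site, 0L)
  expect_equal(cc$n_pairs, 0L)
})

test_that("contact counts match the brute-force oracle on random frames", {
  b <- gen_bridged_frames(bridged_frame_spec(
    n_ions = 3L, n_sites = 15L,
    contact_distribution = c("0" = 0.2, "1" = 0.3, "2" = 0.3, "4" = 0.2),
    n_frames = 6L, seed = 9))
  for (f in 1:6) {
    got <- contact_counts(b$trajectory, f)
    want <- oracle_contact_counts(b$trajectory, f, "calcium",
                                  "carboxylate_carbon", 0.4)
    expect_equal(unname(got$per_ion), want$per_ion)
    expect_equal(unname(got$per_site), want$per_site)
  }
})

test_that("generated contact counts are reproduced by distance recomputation", {
  b <- gen_bridged_frames(bridged_frame_spec(
    n_ions = 4L, n_sites = 20L,
    contact_distribution = c("1" = 0.4, "2" = 0.3, "3" = 0.3),
    n_frames = 25L, seed = 12))
  for (f in 1:25) {
    cc <- contact_counts(b$trajectory, f)
    expect_equal(unname(cc$per_ion), b$drawn_counts[, f])
  }
})

test_that("the stoichiometry spectrum tallies exact fixtures", {
  # 2 ions with exactly 1 contact, 1 ion with exactly 3, every frame
  atoms <- data.frame(
    atom_id = 1:8,
    atom_name = c(rep("CA", 3), rep("CG", 5)),
    residue_name = c(rep("CA", 3), rep("ASP", 5)),
    residue_number = 1:8, chain_id = "A", stringsAsFactors = FALSE)
  ion_pos <- rbind(c(1, 1, 1), c(4, 4, 4), c(7, 7, 7))
  sites <- rbind(c(1.2, 1, 1),                      # ion 1: one contact
                 c(4.2, 4, 4),                      # ion 2: one contact
                 c(7.2, 7, 7), c(7, 7.2, 7), c(7, 7, 7.2))  # ion 3: three
  coords <- array(rbind(ion_pos, sites), c(8, 3, 4))
  tr <- trajectory(atoms, coords, box = c(10, 10, 10))
  sp <- stoichiometry_spectrum(tr, "all")
  expect_equal(unname(sp$ion_with_i_sites[c("1", "3")]), c(2, 1))
  expect_equal(sum(sp$ion_with_i_sites), 3)
  expect_equal(unname(sp$site_with_i_ions["1"]), 5)
  expect_equal(sp$mean_zero_contact_ions, 0)
})

test_that("a zero-contact fixture yields an empty spectrum", {
  b <- gen_bridged_frames(bridged_frame_spec(
    n_ions = 3L, n_sites = 10L, contact_distribution = c("0" = 1),
    n_frames = 8L, seed = 5))
  sp <- stoichiometry_spectrum(b$trajectory, "all")
  expect_true(all(sp$ion_with_i_sites == 0))
  expect_equal(sp$mean_zero_contact_ions, 3)
  expect_equal(bridging_frame_fraction(b$trajectory, "all"), 0)
})

test_that("spectrum recovery matches the binomial ground truth", {
  b <- gen_bridged_frames(bridged_frame_spec(
    n_ions = 3L, n_sites = 15L,
    contact_distribution = c("1" = 0.5, "3" = 0.5),
    n_frames = 400L, seed = 21))
  sp <- stoichiometry_spectrum(b$trajectory, "all")
  # measured spectrum equals realized ground truth exactly (placement is
  # exact); realized vs nominal within 3 binomial SE
  expect_equal(unname(sp$ion_with_i_sites),
               unname(b$ground_truth$ion_with_i_sites))
  se <- sqrt(0.5 * 0.5 / (3 * 400))
  expect_lt(abs(sp$ion_with_i_sites[["1"]] / 3 - 0.5), 3 * se)
})

test_that("bridging frame fraction follows Bernoulli expectations", {
  b2 <- gen_bridged_frames(bridged_frame_spec(
    n_ions = 3L, n_sites = 12L, contact_distribution = c("2" = 1),
    n_frames = 10L, seed = 2))
  expect_equal(bridging_frame_fraction(b2$trajectory, "all"), 1)
  expect_equal(bridging_frame_fraction(b2$trajectory, "all", min_sites = 3L), 0)
  p <- 0.7; k <- 3
  b3 <- gen_bridged_frames(bridged_frame_spec(
    n_ions = 3L, n_sites = 12L,
    contact_distribution = c("0" = 1 - p, "1" = p),
    n_frames = 600L, seed = 8))
  frac <- bridging_frame_fraction(b3$trajectory, "all")
  se <- sqrt(p^k * (1 - p^k) / 600)
  expect_lt(abs(frac - p^k), 3 * se)
})

test_that("infeasible placement fails loudly, naming the frame", {
  # contact radius + margin nearly half the box: ion spacing impossible
  expect_error(
    gen_bridged_frames(bridged_frame_spec(
      n_ions = 8L, n_sites = 8L, contact_distribution = c("1" = 1),
      contact_radius_nm = 1.1, placement_margin_nm = 0.05,
      box_nm = c(2.4, 2.4, 2.4), n_frames = 1L, seed = 1),
      max_retries = 20L),
    "frame 1")
})
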