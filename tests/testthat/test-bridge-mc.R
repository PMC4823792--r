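test_that("zero-energy proposals are always accepted; no ions, no bonds", {
  flat <- toy_params(ion_count = 10L, bind_energy_kT = 0,
                     second_bind_energy_kT = 0, bridge_energy_kT = 0,
                     charge_penalty_kT = 0, n_sweeps = 1500L,
                     sample_every = 10L)
  r <- run_mc(flat)
  expect_equal(unname(r$acceptance["bind"]), 1)
  gas <- run_mc(toy_params(ion_count = 0L, n_sweeps = 1000L,
                           sample_every = 10L))
  expect_equal(max(gas$observables$n_bound), 0)
  expect_equal(unname(gas$acceptance["particle"]), 1)
  expect_true(all(gas$observables$mean_cluster == 1))
})

test_that("running energy matches the recomputed energy", {
  r <- run_mc(toy_params(ion_count = 40L, n_sweeps = 3000L,
                         sample_every = 100L, seed = 3L))
  expect_lt(r$energy_bookkeeping_error_kT, 1e-9)
})

test_that("traces are bit-reproducible under a fixed seed", {
  p <- toy_params(ion_count = 25L, n_sweeps = 800L, sample_every = 10L,
                  seed = 7L)
  r1 <- run_mc(p); r2 <- run_mc(p)
  expect_identical(r1$observables, r2$observables)
  expect_identical(r1$state, r2$state)
  p$seed <- 8L
  expect_false(identical(run_mc(p)$observables, r1$observables))
})

test_that("the sampler reproduces Boltzmann weights on an enumerable system", {
  # two particles with one site each, one ion, frozen positions: states are
  # {unbound, bound to one site (x2), bridging both}. Energies by hand:
  b <- -1; g <- -0.8; cc <- 0.3
  E <- c(unbound = 6 * cc, one = b + 2 * cc, both = 2 * b + g)
  w <- c(exp(-E["unbound"]), 2 * exp(-E["one"]), exp(-E["both"]))
  p_exact <- unname(w / sum(w))
  mk <- function(seed, sweeps = 1L, sample = 0L)
    toy_params(n_particles = 2L, sites_per_particle = 1L, ion_count = 1L,
               box_nm = c(3, 3), contact_radius_nm = 1.4,
               bind_energy_kT = b, second_bind_energy_kT = 0,
               bridge_energy_kT = g, charge_penalty_kT = cc,
               max_sites_per_ion = 2L,
               move_sizes = c(particle = 0, ion = 0),
               n_sweeps = sweeps, sample_every = sample, seed = seed)
  # find an initial placement where the ion can reach both sites
  seed <- NA
  for (s in 1:60) {
    st <- run_mc(mk(s))$state
    d <- sqrt(colSums((t(st$particle_xy) - c(st$ion_xy))^2))
    dwrap <- sqrt(colSums((pmin(abs(t(st$particle_xy) - c(st$ion_xy)),
                                3 - abs(t(st$particle_xy) -
                                          c(st$ion_xy))))^2))
    if (all(dwrap < 1.35)) { seed <- s; break }
  }
  expect_false(is.na(seed))
  r <- run_mc(mk(seed, sweeps = 60000L, sample = 5L))
  counts <- table(factor(r$observables$n_bound, levels = 0:2))
  p_obs <- as.numeric(counts / sum(counts))
  expect_lt(abs(p_obs[1] - p_exact[1]), 0.015)
  expect_lt(abs(p_obs[2] - p_exact[2]), 0.03)
  expect_lt(abs(p_obs[3] - p_exact[3]), 0.03)
})

test_that("cluster partition matches an igraph components oracle", {
  expect_cluster_equal <- function(sb, np, S) {
    state <- list(particle_xy = matrix(0, np, 2), site_bond = sb,
                  box_nm = c(10, 10))
    got <- cluster_partition(state, S)$membership
    # oracle: igraph over particles, edges between particles sharing an ion
    g <- igraph::make_empty_graph(np, directed = FALSE)
    sbv <- as.vector(cbind(sb))
    part <- ((rep(seq_len(np * S), ncol(cbind(sb))) - 1L) %/% S) + 1L
    for (u in unique(sbv[!is.na(sbv)])) {
      ps <- unique(part[!is.na(sbv) & sbv == u])
      if (length(ps) > 1L)
        for (k in 2:length(ps))
          g <- igraph::add_edges(g, c(ps[1], ps[k]))
    }
    want <- igraph::components(g)$membership
    expect_equal(outer(got, got, `==`), outer(want, want, `==`))
  }
  # no ions bound: all singletons
  expect_cluster_equal(matrix(NA_integer_, 6, 2), 3L, 2L)
  # one ion bridging particles 1 and 2
  sb <- matrix(NA_integer_, 6, 2); sb[1, 1] <- 5L; sb[3, 1] <- 5L
  expect_cluster_equal(sb, 3L, 2L)
  set.seed(44)
  for (rep in 1:8) {
    np <- 8L; S <- 3L
    sb <- matrix(NA_integer_, np * S, 2)
    fill <- sample(length(sb), 20)
    sb[fill] <- sample(1:6, 20, replace = TRUE)
    expect_cluster_equal(sb, np, S)
  }
})

test_that("direct-contact linking joins close particle pairs", {
  state <- list(particle_xy = rbind(c(1, 1), c(1.4, 1), c(5, 5)),
                site_bond = matrix(NA_integer_, 9, 2), box_nm = c(10, 10))
  cp <- cluster_partition(state, 3L, direct_contact_nm = 0.6)
  expect_equal(cp$membership[1], cp$membership[2])
  expect_false(cp$membership[1] == cp$membership[3])
  expect_equal(unname(as.integer(cp$sizes)), c(2L, 1L))
})

test_that("structural ablations isolate the mechanism", {
  # forbidding cross-particle ions removes clustering entirely
  nobridge <- run_mc(mc_reference_params(ion_count = 120L,
                                         allow_bridging = FALSE,
                                         n_sweeps = 6000L,
                                         sample_every = 50L))
  expect_true(all(nobridge$observables$mean_cluster == 1))
  expect_gt(mean(tail(nobridge$observables$n_bound, 20)), 0)
  # disabling binding leaves a particle gas at any load
  nobind <- run_mc(mc_reference_params(ion_count = 120L,
                                       bind_energy_kT = 30,
                                       second_bind_energy_kT = 30,
                                       n_sweeps = 3000L,
                                       sample_every = 50L))
  expect_true(all(nobind$observables$mean_cluster == 1))
  expect_equal(max(nobind$observables$n_bound), 0)
})

test_that("parameter validation rejects impossible configurations", {
  expect_error(toy_params(box_nm = c(1, 2, 3, 4)), "2 or 3")
  expect_error(toy_params(contact_radius_nm = 20), "half min box")
  expect_error(toy_params(max_sites_per_ion = 0L), "1..10")
  expect_error(toy_params(bind_energy_kT = Inf), "finite")
  expect_error(biphasic_scan(toy_params(), c(2, 30)), "at least 3")
})
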