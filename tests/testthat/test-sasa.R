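test_that("an isolated atom has the analytic extended-sphere area", {
  tr <- atoms_traj(matrix(c(1, 1, 1), 1), elements = "O")
  s <- shrake_rupley_sasa(tr, radii_table = c(O = 0.15),
                          probe_radius_nm = 0.14)
  expect_equal(s$total_nm2, 4 * pi * 0.29^2, tolerance = 1e-12)
})

test_that("an atom enclosed by a much larger sphere has zero area", {
  tr <- atoms_traj(rbind(c(0, 0, 0), c(0.05, 0, 0)),
                   elements = c("C", "X"))
  s <- shrake_rupley_sasa(tr, radii_table = c(C = 0.1, X = 1.0),
                          probe_radius_nm = 0.14)
  expect_equal(unname(s$per_atom_nm2[1]), 0)
})

test_that("two-sphere areas match the Monte-Carlo surface oracle", {
  r1 <- 0.15; r2 <- 0.18; probe <- 0.14
  for (d in c(0.20, 0.30, 0.45)) {
    tr <- atoms_traj(rbind(c(1, 1, 1), c(1 + d, 1, 1)),
                     elements = c("A", "B"))
    s <- shrake_rupley_sasa(tr, radii_table = c(A = r1, B = r2),
                            probe_radius_nm = probe,
                            n_sphere_points = 960L)
    want <- oracle_two_sphere_sasa(c(1, 1, 1), r1, c(1 + d, 1, 1), r2, probe)
    expect_lt(abs(s$total_nm2 - want) / want, 0.02)
  }
})

test_that("SASA is invariant under rigid rotation and periodic wrapping", {
  set.seed(14)
  xyz <- matrix(rnorm(30, sd = 0.2), 10, 3)
  tr <- atoms_traj(xyz, elements = rep("C", 10))
  s0 <- shrake_rupley_sasa(tr)$total_nm2
  theta <- 0.83
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  rot <- atoms_traj(xyz %*% t(R) + 5, elements = rep("C", 10))
  expect_lt(abs(shrake_rupley_sasa(rot)$total_nm2 - s0) / s0, 0.005)
  # periodic wrap: shift by half a box and wrap back in
  box <- c(3, 3, 3)
  trp <- atoms_traj(xyz + 1.5, elements = rep("C", 10), box = box)
  wrapped <- atoms_traj((xyz + 1.5 + 1.7) %% box, elements = rep("C", 10),
                        box = box)
  expect_equal(shrake_rupley_sasa(wrapped)$total_nm2,
               shrake_rupley_sasa(trp)$total_nm2, tolerance = 1e-9)
})

test_that("aggregation lowers total SASA relative to dispersion", {
  n <- 20
  set.seed(3)
  clustered <- matrix(rnorm(n * 3, sd = 0.12), n, 3) + 2
  dispersed <- expand.grid(x = 1:5, y = 1:4)[seq_len(n), ]
  dispersed <- cbind(dispersed$x, dispersed$y, 2)
  tr_c <- atoms_traj(clustered, elements = rep("C", n))
  tr_d <- atoms_traj(dispersed, elements = rep("C", n))
  expect_gt(shrake_rupley_sasa(tr_d)$total_nm2,
            shrake_rupley_sasa(tr_c)$total_nm2)
})

test_that("ions are excluded by default and radii gaps are reported", {
  atoms <- data.frame(atom_id = 1:2, atom_name = c("CG", "CA"),
                      residue_name = c("ASP", "CA"), residue_number = 1:2,
                      chain_id = "A", stringsAsFactors = FALSE)
  tr <- trajectory(atoms, rbind(c(1, 1, 1), c(1.2, 1, 1)))
  s <- shrake_rupley_sasa(tr)
  expect_length(s$per_atom_nm2, 1L)   # the calcium is not counted
  expect_gt(shrake_rupley_sasa(tr, include_ions = TRUE)$total_nm2,
            s$total_nm2)
  bad <- atoms_traj(matrix(0, 1, 3), elements = "Zz")
  expect_error(shrake_rupley_sasa(bad), "Zz")
})

test_that("window statistics follow the frame and run conventions", {
  mk <- function(v) structure(list(times_ps = seq_along(v) * 10,
                                   total_sasa_nm2 = v,
                                   probe_radius_nm = 0.14),
                              class = "sasa_trace")
  const <- mk(rep(7, 50))
  ws <- window_stats(const, "last:0.2")
  expect_equal(ws$mean_nm2, 7)
  expect_equal(ws$sem_nm2, 0)
  expect_equal(ws$n, 10L)
  # across runs: mean (a+b)/2, sem |a-b|/2
  two <- window_stats(list(mk(rep(4, 20)), mk(rep(10, 20))), "last:0.2")
  expect_equal(two$mean_nm2, 7)
  expect_equal(two$sem_nm2, 3)
  expect_equal(two$unit, "runs")
})

test_that("sasa trace and velocity work end to end on a small fixture", {
  set.seed(6)
  coords <- array(rnorm(6 * 3 * 4, sd = 0.3), c(6, 3, 4)) + 2
  tr <- atoms_traj(coords[, , 1], elements = rep("C", 6))
  tr$coords <- coords
  tr$times_ps <- c(0, 100, 200, 300)
  trace <- sasa_trace(tr, n_sphere_points = 240L)
  expect_length(trace$total_sasa_nm2, 4L)
  expect_true(all(trace$total_sasa_nm2 > 0))
  v <- sasa_velocity(trace)
  expect_true(is.finite(v))
  expect_error(sasa_velocity(trace, 0, 50), "fewer than 2")
})
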