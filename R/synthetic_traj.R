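#' Ideal-gas trajectory generator
#'
#' Draws every coordinate i.i.d. uniform in the box, independently per
#' frame: the calibration fixture for radial distribution functions, whose
#' g(r) must be 1 at all distances.
#'
#' @param n_particles number of particles (>= 2).
#' @param box_nm length-3 orthorhombic box (nm).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return a \code{\link{trajectory}} whose atoms all carry role "gas".
#' @export
gen_ideal_gas_frames <- function(n_particles, box_nm, n_frames, seed = 1L) {
  if (n_particles < 2L) stop_usage("need at least 2 particles")
  if (length(box_nm) != 3L || any(box_nm <= 0))
    stop_usage("box_nm must be 3 positive edges")
  if (n_frames < 1L) stop_usage("need at least 1 frame")
  coords <- with_seed(seed, {
    array(runif(n_particles * 3L * n_frames) *
            rep(box_nm, each = n_particles),
          c(n_particles, 3L, n_frames))
  })
  atoms <- data.frame(atom_id = seq_len(n_particles), atom_name = "GAS",
                      residue_name = "GAS", residue_number = 1L,
                      chain_id = "A", element = "X", role = "gas",
                      stringsAsFactors = FALSE)
  trajectory(atoms, coords, box = box_nm)
}

#' Specification for the ion-carboxylate contact fixture
#'
#' Parameters of \code{\link{gen_bridged_frames}}: frames containing ions
#' and carboxylate sites in which each ion's contact count is drawn from a
#' known distribution — the parameter-recovery ground truth for contact
#' stoichiometry analysis.
#'
#' @param n_ions number of ions per frame.
#' @param n_sites number of carboxylate sites per frame.
#' @param contact_distribution named numeric vector: probability of an ion
#'   having i contacts, names in "0".."10"; must sum to 1.
#' @param contact_radius_nm contact threshold used for placement (nm).
#' @param placement_margin_nm non-contact sites are kept beyond
#'   \code{contact_radius_nm + placement_margin_nm} of every ion.
#' @param box_nm length-3 box (nm); \code{contact_radius + margin} must be
#'   below half the smallest edge.
#' @param n_frames frames to generate.
#' @param seed integer seed.
#' @return object of class \code{bridged_frame_spec}.
#' @export
bridged_frame_spec <- function(n_ions = 3L, n_sites = 30L,
                               contact_distribution = c("1" = 0.5, "3" = 0.5),
                               contact_radius_nm = 0.4,
                               placement_margin_nm = 0.1,
                               box_nm = c(5, 5, 5), n_frames = 100L,
                               seed = 1L) {
  p <- contact_distribution
  if (is.null(names(p)) || anyNA(suppressWarnings(as.integer(names(p)))))
    stop_usage("contact_distribution must be named by integer contact counts")
  ks <- as.integer(names(p))
  if (any(ks < 0L | ks > 10L)) stop_usage("contact counts must be in 0..10")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_usage("contact probabilities must be non-negative and sum to 1")
  if (length(box_nm) != 3L || any(box_nm <= 0))
    stop_usage("box_nm must be 3 positive edges")
  if (contact_radius_nm <= 0 || placement_margin_nm < 0)
    stop_usage("radius must be > 0 and margin >= 0")
  if (contact_radius_nm + placement_margin_nm >= min(box_nm) / 2)
    stop_usage("contact_radius + margin must be < half the smallest box edge")
  if (n_ions * max(ks) > n_sites)
    stop_usage("worst-case contact draw needs more sites than available")
  structure(list(n_ions = as.integer(n_ions), n_sites = as.integer(n_sites),
                 contact_distribution = p,
                 contact_radius_nm = contact_radius_nm,
                 placement_margin_nm = placement_margin_nm,
                 box_nm = box_nm, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "bridged_frame_spec")
}

#' Generate trajectory frames with known ion-site contact ground truth
#'
#' For every frame and ion a contact count i is drawn from the spec's
#' distribution; exactly i sites are then placed within the contact radius
#' of that ion and all remaining sites beyond radius + margin of every ion
#' (minimum-image distances). Ions are spaced at least
#' \code{2 * (radius + margin)} apart so contact shells never overlap.
#'
#' @param spec a \code{\link{bridged_frame_spec}}.
#' @param max_retries placement retries per frame before giving up.
#' @return list: \code{trajectory} (roles "calcium" / "carboxylate_carbon"),
#'   \code{drawn_counts} (n_ions x n_frames matrix of ground-truth contact
#'   counts) and \code{ground_truth}, the realized
#'   \code{stoichiometry_spectrum}-style tallies (mean occurrences per
#'   frame of ions with i contacts, i = 1..10, plus the zero-contact mean).
#' @export
gen_bridged_frames <- function(spec, max_retries = 1000L) {
  stopifnot(inherits(spec, "bridged_frame_spec"))
  R <- spec$contact_radius_nm; M <- spec$placement_margin_nm
  box <- spec$box_nm
  ni <- spec$n_ions; ns <- spec$n_sites; nf <- spec$n_frames
  ks <- as.integer(names(spec$contact_distribution))
  with_seed(spec$seed, {
    coords <- array(NA_real_, c(ni + ns, 3L, nf))
    drawn <- matrix(NA_integer_, ni, nf)
    for (f in seq_len(nf)) {
      counts <- ks[sample.int(length(ks), ni, replace = TRUE,
                              prob = spec$contact_distribution)]
      # 1. ions mutually separated by > 2 (R + M)
      ions <- NULL
      for (try in seq_len(max_retries)) {
        cand <- matrix(runif(ni * 3L) * rep(box, each = ni), ni, 3L)
        if (ni < 2L) { ions <- cand; break }
        d <- min_image_dist_matrix(cand, cand, box)
        if (min(d[upper.tri(d)]) > 2 * (R + M)) { ions <- cand; break }
      }
      if (is.null(ions))
        stop_data("infeasible ion placement in frame ", f,
                  " after ", max_retries, " retries")
      # 2. contact sites uniform in each ion's contact ball
      sites <- matrix(NA_real_, ns, 3L)
      s_at <- 0L
      for (u in seq_len(ni)) {
        k <- counts[u]
        if (k == 0L) next
        got <- 0L
        while (got < k) {
          v <- runif(3L, -R, R)
          if (sum(v^2) < R^2 && sqrt(sum(v^2)) > 1e-6) {
            p <- (ions[u, ] + v) %% box
            sites[s_at + got + 1L, ] <- p
            got <- got + 1L
          }
        }
        s_at <- s_at + k
      }
      # 3. remaining sites beyond R + M of every ion
      n_far <- ns - sum(counts)
      placed <- 0L; tries <- 0L
      while (placed < n_far) {
        tries <- tries + 1L
        if (tries > max_retries * max(n_far, 1L))
          stop_data("infeasible far-site placement in frame ", f)
        p <- runif(3L) * box
        dd <- min_image_dist_matrix(matrix(p, 1L), ions, box)
        if (all(dd > R + M)) {
          placed <- placed + 1L
          sites[s_at + placed, ] <- p
        }
      }
      coords[, , f] <- rbind(ions, sites)
      drawn[, f] <- counts
    }
    atoms <- data.frame(
      atom_id = seq_len(ni + ns),
      atom_name = c(rep("CA", ni), rep("CG", ns)),
      residue_name = c(rep("CA", ni), rep("ASP", ns)),
      residue_number = seq_len(ni + ns),
      chain_id = "A",
      element = c(rep("Ca", ni), rep("C", ns)),
      role = c(rep("calcium", ni), rep("carboxylate_carbon", ns)),
      stringsAsFactors = FALSE)
    gt <- setNames(numeric(10L), 1:10)
    for (i in 1:10) gt[i] <- sum(drawn == i) / nf
    list(trajectory = trajectory(atoms, coords, box = box),
         drawn_counts = drawn,
         ground_truth = list(ion_with_i_sites = gt,
                             mean_zero_contact_ions = sum(drawn == 0L) / nf,
                             n_frames_analysed = nf))
  })
}
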