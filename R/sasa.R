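#' Bundled van der Waals radii (nm)
#'
#' Bondi-style van der Waals radii for the elements occurring in
#' protein/ion systems, in nanometres. Used as the default radii table for
#' \code{\link{shrake_rupley_sasa}}; any entry can be overridden.
#'
#' @param override named numeric vector of radii (nm) replacing or adding
#'   entries.
#' @return named numeric vector, element symbol to radius (nm).
#' @export
vdw_radii <- function(override = NULL) {
  r <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180,
         Ca = 0.231, Na = 0.227, Cl = 0.175, K = 0.275, Mg = 0.173,
         Sr = 0.249, Ba = 0.268, X = 0.170)
  if (!is.null(override)) r[names(override)] <- override
  r
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-section spiral lattice: points at heights \code{z_k} uniformly
#' spaced in \[-1, 1\] and azimuths advancing by the golden angle. Fully
#' deterministic, so all SASA values reproduce exactly.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n = 960L) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area of one frame
#'
#' Classic point-counting SASA: each atom's solvent-extended sphere
#' (van der Waals radius + probe radius) is sampled with a deterministic
#' spherical lattice; a test point is accessible when it lies outside every
#' neighbouring atom's extended sphere. Per-atom area is the accessible
#' point fraction times the extended-sphere area. Periodic images of
#' neighbours are included when the trajectory has a box.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param frame frame index.
#' @param radii_table named radii vector (nm) as from \code{\link{vdw_radii}}.
#' @param probe_radius_nm solvent probe radius; 0.14 nm is the standard
#'   water probe.
#' @param n_sphere_points lattice size (>= 32; default 960).
#' @param atoms indices of atoms whose area is computed and which occlude
#'   (default: all atoms whose element is not an ion when
#'   \code{include_ions = FALSE}).
#' @param include_ions include monatomic ions as occluders/areas.
#' @return list: \code{per_atom_nm2} (named by atom_id), \code{total_nm2},
#'   \code{probe_radius_nm}, \code{n_sphere_points}.
#' @export
shrake_rupley_sasa <- function(traj, frame = 1L, radii_table = vdw_radii(),
                               probe_radius_nm = 0.14,
                               n_sphere_points = 960L, atoms = NULL,
                               include_ions = FALSE) {
  if (n_sphere_points < 32L) stop_usage("n_sphere_points must be >= 32")
  if (probe_radius_nm < 0) stop_usage("probe radius must be >= 0")
  if (is.null(atoms)) {
    atoms <- seq_len(n_atoms(traj))
    if (!include_ions)
      atoms <- atoms[!traj$atoms$role %in% c("calcium", "sodium", "chloride")]
  }
  el <- traj$atoms$element[atoms]
  missing <- setdiff(unique(el), names(radii_table))
  if (length(missing))
    stop_data("no van der Waals radius for element(s): ",
              paste(missing, collapse = ", "),
              " (atoms ", paste(traj$atoms$atom_id[atoms][el %in% missing][
                seq_len(min(5, sum(el %in% missing)))], collapse = ", "), ")")
  rr <- unname(radii_table[el]) + probe_radius_nm
  xyz <- frame_coords(traj, atoms, frame)
  box <- frame_box(traj, frame)
  pts <- sphere_points(n_sphere_points)
  n <- length(atoms)
  # neighbour displacements via minimum image
  dmat <- min_image_dist_matrix(xyz, xyz, box)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] < rr[i] + rr & seq_len(n) != i)
    p <- pts * rr[i]                      # points relative to atom i centre
    if (length(nb)) {
      acc <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        d <- xyz[j, ] - xyz[i, ]
        if (!is.null(box)) d <- d - box * round(d / box)
        acc <- acc & ((p[, 1L] - d[1L])^2 + (p[, 2L] - d[2L])^2 +
                        (p[, 3L] - d[3L])^2 > rr[j]^2)
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    per_atom[i] <- frac * 4 * pi * rr[i]^2
  }
  list(per_atom_nm2 = setNames(per_atom, traj$atoms$atom_id[atoms]),
       total_nm2 = sum(per_atom), probe_radius_nm = probe_radius_nm,
       n_sphere_points = n_sphere_points)
}

#' Per-frame total SASA trace of a trajectory
#'
#' @inheritParams shrake_rupley_sasa
#' @param frames frame indices (default all).
#' @return object of class \code{sasa_trace}: \code{times_ps},
#'   \code{total_sasa_nm2}, \code{probe_radius_nm}.
#' @export
sasa_trace <- function(traj, radii_table = vdw_radii(),
                       probe_radius_nm = 0.14, n_sphere_points = 960L,
                       frames = seq_len(n_frames(traj)),
                       include_ions = FALSE) {
  tot <- vapply(frames, function(f)
    shrake_rupley_sasa(traj, f, radii_table, probe_radius_nm,
                       n_sphere_points, include_ions = include_ions)$total_nm2,
    numeric(1))
  structure(list(times_ps = traj$times_ps[frames], total_sasa_nm2 = tot,
                 probe_radius_nm = probe_radius_nm),
            class = "sasa_trace")
}

#' Windowed mean and standard error of SASA traces
#'
#' For a single trace: mean and s.e.m. across the frames of the window
#' (e.g. the last fifth of a run). For a list of traces (multi-copy runs):
#' per-run window means are computed first, then mean and s.e.m. across
#' runs, so n is the number of independent simulations.
#'
#' @param trace a \code{sasa_trace} or a list of them.
#' @param window \code{"last:<fraction>"} or \code{"last_ps:<ps>"}
#'   (see \code{\link{select_window}}); default last 20%.
#' @return list: \code{mean_nm2}, \code{sem_nm2}, \code{n} (frames or runs),
#'   \code{unit} ("frames" or "runs"), \code{window}.
#' @export
window_stats <- function(trace, window = "last:0.2") {
  window_idx <- function(tr) {
    nf <- length(tr$total_sasa_nm2)
    fake <- structure(list(coords = array(0, c(1, 3, nf)),
                           times_ps = tr$times_ps), class = "trajectory")
    select_window(fake, window)
  }
  if (inherits(trace, "sasa_trace")) {
    idx <- window_idx(trace)
    v <- trace$total_sasa_nm2[idx]
    list(mean_nm2 = mean(v),
         sem_nm2 = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0,
         n = length(v), unit = "frames", window = window)
  } else {
    means <- vapply(trace, function(tr) mean(tr$total_sasa_nm2[window_idx(tr)]),
                    numeric(1))
    list(mean_nm2 = mean(means),
         sem_nm2 = if (length(means) > 1L) sd(means) / sqrt(length(means)) else 0,
         n = length(means), unit = "runs", window = window)
  }
}

#' Reaction velocity of a SASA trace
#'
#' Slope of total SASA against time over a stated interval, i.e. the
#' oligomerization reaction velocity (nm^2 per ns).
#'
#' @param trace a \code{sasa_trace}.
#' @param from_ps,to_ps interval bounds (default whole trace).
#' @return slope in nm^2/ns.
#' @export
sasa_velocity <- function(trace, from_ps = min(trace$times_ps),
                          to_ps = max(trace$times_ps)) {
  sel <- trace$times_ps >= from_ps & trace$times_ps <= to_ps
  if (sum(sel) < 2L) stop_usage("velocity interval holds fewer than 2 frames")
  unname(coef(lm(trace$total_sasa_nm2[sel] ~ I(trace$times_ps[sel] / 1000)))[2])
}
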