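#' Per-ion and per-site contact counts in one frame
#'
#' Counts, for every ion atom, the number of site atoms within the distance
#' threshold (minimum-image convention), and the transpose per site. The
#' bookkeeping is exactly symmetric: the two count vectors sum to the same
#' number of contact pairs.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param frame frame index.
#' @param ion_role,site_role atom roles (see \code{\link{atom_role}}).
#' @param threshold_nm contact distance threshold, nm (default 0.4, the
#'   standard cation-carboxylate cutoff).
#' @return list with \code{per_ion}, \code{per_site} (integer vectors named
#'   by atom_id) and \code{n_pairs}.
#' @export
contact_counts <- function(traj, frame = 1L, ion_role = "calcium",
                           site_role = "carboxylate_carbon",
                           threshold_nm = 0.4) {
  if (threshold_nm <= 0) stop_usage("threshold_nm must be positive")
  ii <- which(traj$atoms$role == ion_role)
  is <- which(traj$atoms$role == site_role)
  per_ion <- setNames(integer(length(ii)), traj$atoms$atom_id[ii])
  per_site <- setNames(integer(length(is)), traj$atoms$atom_id[is])
  if (length(ii) && length(is)) {
    d <- min_image_dist_matrix(frame_coords(traj, ii, frame),
                               frame_coords(traj, is, frame),
                               frame_box(traj, frame))
    hit <- d < threshold_nm
    per_ion[] <- as.integer(rowSums(hit))
    per_site[] <- as.integer(colSums(hit))
  }
  list(per_ion = per_ion, per_site = per_site, n_pairs = sum(per_ion))
}

#' Ion-carboxylate interaction stoichiometry spectrum
#'
#' For each frame of the analysis window, tallies ions engaging exactly
#' \emph{i} sites (\emph{i} = 1..10) and sites engaged by exactly \emph{i}
#' ions (\emph{i} = 1..3), then normalizes the tallies by the number of
#' analysed frames, giving mean occurrences per frame. Zero-contact ions
#' and sites are excluded from the spectra and reported separately.
#'
#' @inheritParams contact_counts
#' @param window window specification (see \code{\link{select_window}}).
#' @param max_i_ion,max_i_site largest multiplicities tabulated.
#' @return object of class \code{stoichiometry_spectrum}:
#'   \code{ion_with_i_sites} (named numeric, i = 1..max_i_ion),
#'   \code{site_with_i_ions} (i = 1..max_i_site),
#'   \code{mean_zero_contact_ions}, \code{mean_zero_contact_sites},
#'   \code{n_frames_analysed}, \code{window}.
#' @export
stoichiometry_spectrum <- function(traj, window = "last:0.2",
                                   ion_role = "calcium",
                                   site_role = "carboxylate_carbon",
                                   threshold_nm = 0.4,
                                   max_i_ion = 10L, max_i_site = 3L) {
  frames <- select_window(traj, window)
  ion_tab <- setNames(numeric(max_i_ion), seq_len(max_i_ion))
  site_tab <- setNames(numeric(max_i_site), seq_len(max_i_site))
  zero_ions <- 0; zero_sites <- 0
  for (f in frames) {
    cc <- contact_counts(traj, f, ion_role, site_role, threshold_nm)
    for (i in seq_len(max_i_ion))
      ion_tab[i] <- ion_tab[i] + sum(cc$per_ion == i)
    for (i in seq_len(max_i_site))
      site_tab[i] <- site_tab[i] + sum(cc$per_site == i)
    zero_ions <- zero_ions + sum(cc$per_ion == 0)
    zero_sites <- zero_sites + sum(cc$per_site == 0)
  }
  nf <- length(frames)
  structure(list(ion_with_i_sites = ion_tab / nf,
                 site_with_i_ions = site_tab / nf,
                 mean_zero_contact_ions = zero_ions / nf,
                 mean_zero_contact_sites = zero_sites / nf,
                 n_frames_analysed = nf,
                 window = window,
                 threshold_nm = threshold_nm),
            class = "stoichiometry_spectrum")
}

#' @export
print.stoichiometry_spectrum <- function(x, ...) {
  cat("<stoichiometry_spectrum> over", x$n_frames_analysed, "frames (window",
      paste(x$window, collapse = ","), ") at", x$threshold_nm, "nm\n")
  nz <- x$ion_with_i_sites[x$ion_with_i_sites > 0]
  cat("  ion with i sites: ",
      if (length(nz)) paste0("i=", names(nz), ": ", signif(nz, 4),
                             collapse = ", ") else "(none)", "\n")
  nz <- x$site_with_i_ions[x$site_with_i_ions > 0]
  cat("  site with i ions: ",
      if (length(nz)) paste0("i=", names(nz), ": ", signif(nz, 4),
                             collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Fraction of frames in which every ion is engaged in salt bridges
#'
#' Computes the share of window frames where each ion of the given role has
#' at least \code{min_sites} site contacts. With \code{min_sites = 1} this
#' is the all-ions-bound fraction (every ion in an ion-carboxylate pair);
#' \code{min_sites = 2} asks for every ion to bridge two or more
#' carboxylates.
#'
#' @inheritParams stoichiometry_spectrum
#' @param min_sites minimum contacts per ion (>= 1).
#' @return fraction in \[0, 1\].
#' @export
bridging_frame_fraction <- function(traj, window = "last:0.2",
                                    ion_role = "calcium",
                                    site_role = "carboxylate_carbon",
                                    threshold_nm = 0.4, min_sites = 1L) {
  if (min_sites < 1L) stop_usage("min_sites must be >= 1")
  frames <- select_window(traj, window)
  ok <- vapply(frames, function(f) {
    cc <- contact_counts(traj, f, ion_role, site_role, threshold_nm)
    length(cc$per_ion) > 0L && all(cc$per_ion >= min_sites)
  }, logical(1))
  mean(ok)
}
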