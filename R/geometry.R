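#' Minimum-image distance in an orthorhombic periodic box
#'
#' Euclidean distance after wrapping each Cartesian difference into
#' \code{[-L/2, L/2]} for the corresponding box edge \code{L}.
#'
#' @param a_nm,b_nm numeric length-3 coordinates (nm), or matrices with 3
#'   columns (paired row-wise).
#' @param box_nm length-3 orthorhombic box edges (nm); \code{NULL} for
#'   plain Euclidean distance.
#' @return numeric distance(s) in nm.
#' @export
minimum_image_distance <- function(a_nm, b_nm, box_nm = NULL) {
  a <- rbind(a_nm); b <- rbind(b_nm)
  if (!is.null(box_nm)) {
    if (length(box_nm) != 3L || any(box_nm <= 0))
      stop_usage("box_nm must be 3 positive edge lengths")
  }
  d <- a - b
  if (!is.null(box_nm))
    d <- d - rep(box_nm, each = nrow(d)) * round(d / rep(box_nm, each = nrow(d)))
  out <- sqrt(rowSums(d^2))
  if (length(out) == 1L) out[[1L]] else out
}

#' Minimum-image distance matrix between two coordinate sets
#'
#' @param a,b numeric matrices (n x 3, m x 3), nm.
#' @param box_nm length-3 box or NULL for non-periodic.
#' @return n x m distance matrix, nm.
#' @keywords internal
min_image_dist_matrix <- function(a, b, box_nm = NULL) {
  if (is.null(box_nm)) box_nm <- c(0, 0, 0)  # 0 = non-periodic axis
  .min_image_dist_cpp(rbind(a), rbind(b), as.numeric(box_nm))
}

frame_coords <- function(traj, idx, f) {
  matrix(traj$coords[idx, , f], ncol = 3L)
}

frame_box <- function(traj, f) {
  if (is.null(traj$box)) NULL else traj$box[f, ]
}

require_box <- function(traj, what) {
  if (is.null(traj$box))
    stop_data("trajectory has no periodic box; required for ", what)
  invisible(TRUE)
}

role_indices <- function(traj, role) {
  idx <- which(traj$atoms$role == role)
  if (!length(idx)) stop_data("no atoms with role '", role, "' in trajectory")
  idx
}

#' Resolve a window specification to frame indices
#'
#' Windows follow the `last:<fraction>` / `last_ps:<ps>` mini-language, or
#' may be given directly as integer frame indices. The default
#' \code{"last:0.2"} analyses the final fifth of a run, the usual
#' late-trajectory averaging window.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param window \code{"last:<fraction>"}, \code{"last_ps:<ps>"},
#'   \code{"all"}, or an integer vector of frame indices.
#' @return integer frame indices (non-empty).
#' @export
select_window <- function(traj, window = "last:0.2") {
  nf <- n_frames(traj)
  if (is.numeric(window)) {
    idx <- as.integer(window)
    if (!length(idx) || any(idx < 1L | idx > nf))
      stop_usage("window frame indices out of range 1..", nf)
    return(idx)
  }
  if (identical(window, "all")) return(seq_len(nf))
  if (grepl("^last:", window)) {
    frac <- as.numeric(sub("^last:", "", window))
    if (is.na(frac) || frac <= 0 || frac > 1)
      stop_usage("bad window fraction in '", window, "'")
    k <- max(1L, ceiling(frac * nf))
    return(seq.int(nf - k + 1L, nf))
  }
  if (grepl("^last_ps:", window)) {
    ps <- as.numeric(sub("^last_ps:", "", window))
    if (is.na(ps) || ps <= 0) stop_usage("bad window '", window, "'")
    t_end <- traj$times_ps[nf]
    idx <- which(traj$times_ps > t_end - ps)
    if (!length(idx)) stop_data("window '", window, "' longer than trace")
    return(idx)
  }
  stop_usage("unrecognised window spec '", window, "'")
}
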