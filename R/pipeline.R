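#' Run the membrane-sheet imaging pipeline end to end
#'
#' Chains the imaging operations in acquisition-analysis order over a set
#' of images grouped by condition: background-corrected mean, rel. SD,
#' normalization to the control condition, cluster counting, averaged
#' autocorrelation radius per condition and clustered fraction. Writes
#' per-sheet and per-condition CSV tables, a provenance JSON, and
#' (optionally) a rel. SD summary plot.
#'
#' @param images named list of \code{\link{sheet_image}} objects; names are
#'   sheet ids. Alternatively a data.frame with columns \code{path},
#'   \code{condition} (TIFFs read via \code{\link{read_sheet_image}}).
#' @param conditions character vector, one condition label per image (not
#'   needed when \code{images} is a data.frame).
#' @param control label of the baseline condition (no divalent cations).
#' @param noise_level prominence tolerance for cluster counting; one value
#'   applied to all recordings.
#' @param out_dir output directory (created).
#' @param roi_spec a \code{\link{roi}} applied to every image (default:
#'   full frame minus nothing), or a list of ROIs named by sheet id.
#' @param background scalar background intensity subtracted before rel. SD
#'   (synthetic fixtures know it; for real data pass a measured off-sheet
#'   mean).
#' @param max_shift_px autocorrelation shift range (default: half ROI
#'   width).
#' @param k_sigma punctate-segmentation threshold (SD units).
#' @param plot write a PNG of normalized rel. SD by condition.
#' @param seed recorded in the provenance (the pipeline itself is
#'   deterministic).
#' @return invisibly, list with \code{per_sheet}, \code{per_condition}
#'   data.frames and the output paths.
#' @export
run_image_pipeline <- function(images, conditions = NULL, control,
                               noise_level, out_dir, roi_spec = NULL,
                               background = 0, max_shift_px = NULL,
                               k_sigma = 2, plot = FALSE, seed = NA) {
  if (is.data.frame(images)) {
    conditions <- images$condition
    paths <- images$path
    images <- lapply(paths, read_sheet_image)
    names(images) <- make.unique(basename(paths))
  }
  if (is.null(conditions) || length(conditions) != length(images))
    stop_usage("one condition label per image is required")
  if (!control %in% conditions)
    stop_data("control condition '", control, "' not present")
  if (missing(noise_level)) stop_usage("noise_level must be supplied")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(images)
  if (is.null(ids)) ids <- paste0("sheet", seq_along(images))

  per <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    r <- if (is.null(roi_spec)) roi(0, 0, ncol(img$pixels), nrow(img$pixels))
    else if (inherits(roi_spec, "roi")) roi_spec else roi_spec[[ids[i]]]
    ms <- if (is.null(max_shift_px)) max(4L, r$width %/% 2L) else max_shift_px
    det <- detect_clusters(img, r, noise_level)
    ac <- autocorr_curve(img, r, ms)
    rad <- tryCatch(as.numeric(radius_from_autocorr(ac)),
                    error = function(e) NA_real_)
    data.frame(sheet = ids[i], condition = conditions[i],
               mean_intensity_bgcorr = mean(roi_pixels(img, r)) - background,
               rel_sd = relative_sd(img, r, background),
               cluster_density_per_um2 = det$density_per_um2,
               cluster_radius_nm = rad,
               clustered_fraction = clustered_fraction(img, r, k_sigma),
               stringsAsFactors = FALSE)
  })
  per_sheet <- do.call(rbind, per)
  ctrl_mean <- mean(per_sheet$rel_sd[per_sheet$condition == control])
  per_sheet$rel_sd_normalized <- per_sheet$rel_sd / ctrl_mean

  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sem = if (sum(!is.na(v)) > 1L)
                         sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))) else 0)
  conds <- unique(per_sheet$condition)
  per_condition <- do.call(rbind, lapply(conds, function(cc) {
    s <- per_sheet[per_sheet$condition == cc, ]
    data.frame(condition = cc, n_sheets = nrow(s),
               t(c(rel_sd = agg(s$rel_sd),
                   rel_sd_normalized = agg(s$rel_sd_normalized),
                   cluster_density = agg(s$cluster_density_per_um2),
                   cluster_radius = agg(s$cluster_radius_nm),
                   clustered_fraction = agg(s$clustered_fraction))),
               stringsAsFactors = FALSE)
  }))

  f_sheet <- file.path(out_dir, "per_sheet.csv")
  f_cond <- file.path(out_dir, "per_condition.csv")
  write.csv(per_sheet, f_sheet, row.names = FALSE)
  write.csv(per_condition, f_cond, row.names = FALSE)
  prov <- list(pipeline = "image", package_version =
                 as.character(utils::packageVersion("ionbridge")),
               control = control, noise_level = noise_level,
               background = background, k_sigma = k_sigma, seed = seed,
               n_images = length(images), conditions = unique(conditions))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (plot) {
    grDevices::png(file.path(out_dir, "rel_sd.png"), 600, 400)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::barplot(per_condition$rel_sd_normalized.mean,
                      names.arg = per_condition$condition,
                      ylab = "rel. SD (normalized to control)")
  }
  invisible(list(per_sheet = per_sheet, per_condition = per_condition,
                 files = c(f_sheet, f_cond,
                           file.path(out_dir, "provenance.json"))))
}

#' Run the trajectory pipeline end to end
#'
#' Reads a trajectory, computes the cation-carboxylate RDF and its
#' first-shell threshold (falling back to the default table when
#' featureless), the contact stoichiometry spectra and the all-ions-bound
#' bridging fraction over the analysis window, and the SASA trace with
#' window statistics. Writes CSV/JSON outputs plus a provenance record.
#'
#' @param traj a \code{\link{trajectory}} or a file path readable by
#'   \code{\link{read_frames}}.
#' @param out_dir output directory.
#' @param ion_role,site_role analysis roles.
#' @param threshold_nm contact threshold; \code{NULL} derives it from the
#'   RDF via \code{\link{first_shell_threshold}}.
#' @param window analysis window (see \code{\link{select_window}}).
#' @param rdf_bin_width_nm,rdf_r_max_nm RDF histogram parameters (r_max is
#'   clipped to half the smallest box edge).
#' @param sasa compute the SASA outputs (slowest step; on by default).
#' @param n_sphere_points SASA lattice size.
#' @return invisibly, list with the computed objects and output paths.
#' @export
run_traj_pipeline <- function(traj, out_dir, ion_role = "calcium",
                              site_role = "carboxylate_carbon",
                              threshold_nm = 0.4, window = "last:0.2",
                              rdf_bin_width_nm = 0.01, rdf_r_max_nm = 1.0,
                              sasa = TRUE, n_sphere_points = 960L) {
  if (is.character(traj)) traj <- read_frames(traj)
  if (!any(traj$atoms$role == ion_role))
    stop_data("role selection empty: no atoms with role '", ion_role, "'")
  if (!any(traj$atoms$role == site_role))
    stop_data("role selection empty: no atoms with role '", site_role, "'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  r_max <- min(rdf_r_max_nm, min(traj$box) / 2)
  rdf <- compute_rdf(traj, ion_role, site_role, rdf_bin_width_nm, r_max)
  thr_fallback <- FALSE
  thr_from_rdf <- withCallingHandlers(
    first_shell_threshold(rdf),
    warning = function(w) {
      thr_fallback <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.null(threshold_nm)) threshold_nm <- as.numeric(thr_from_rdf)
  spec <- stoichiometry_spectrum(traj, window, ion_role, site_role,
                                 threshold_nm)
  bff <- bridging_frame_fraction(traj, window, ion_role, site_role,
                                 threshold_nm, min_sites = 1L)
  bff2 <- bridging_frame_fraction(traj, window, ion_role, site_role,
                                  threshold_nm, min_sites = 2L)

  write.csv(data.frame(r_nm = rdf$r_centers_nm, g_r = rdf$g_r,
                       g_se = rdf$g_se),
            file.path(out_dir, "rdf.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(threshold_used_nm = threshold_nm,
         threshold_from_rdf_nm = as.numeric(thr_from_rdf),
         rdf_fallback = thr_fallback),
    file.path(out_dir, "threshold_report.json"), auto_unbox = TRUE,
    digits = NA)
  write.csv(data.frame(
    kind = c(rep("ion_with_i_sites", length(spec$ion_with_i_sites)),
             rep("site_with_i_ions", length(spec$site_with_i_ions))),
    i = c(as.integer(names(spec$ion_with_i_sites)),
          as.integer(names(spec$site_with_i_ions))),
    mean_per_frame = c(unname(spec$ion_with_i_sites),
                       unname(spec$site_with_i_ions))),
    file.path(out_dir, "stoichiometry.csv"), row.names = FALSE)
  out <- list(rdf = rdf, threshold_nm = threshold_nm, spectrum = spec,
              bridging_fraction_min1 = bff, bridging_fraction_min2 = bff2)
  if (sasa) {
    tr <- sasa_trace(traj, n_sphere_points = n_sphere_points)
    ws <- window_stats(tr, window)
    write.csv(data.frame(time_ps = tr$times_ps,
                         total_sasa_nm2 = tr$total_sasa_nm2),
              file.path(out_dir, "sasa_trace.csv"), row.names = FALSE)
    jsonlite::write_json(ws, file.path(out_dir, "sasa_window.json"),
                         auto_unbox = TRUE, digits = NA)
    out$sasa <- list(trace = tr, window = ws)
  }
  prov <- list(pipeline = "traj", package_version =
                 as.character(utils::packageVersion("ionbridge")),
               ion_role = ion_role, site_role = site_role,
               threshold_nm = threshold_nm, window = window,
               n_frames = n_frames(traj), n_atoms = n_atoms(traj),
               bridging_fraction_all_ions_min1 = bff,
               bridging_fraction_all_ions_min2 = bff2)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
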