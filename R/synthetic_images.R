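#' Specification for a synthetic membrane-sheet image
#'
#' Collects the parameters of the membrane-sheet image generator. The
#' generator emulates an immunostained membrane sheet: a diffuse signal
#' floor plus bright microdomains (clusters), on a constant camera
#' background, optionally degraded by noise.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_nm physical pixel size (nm per pixel).
#' @param cluster_density_per_um2 expected cluster count per square
#'   micrometre; realized counts are Poisson.
#' @param cluster_radius_nm cluster radius; maps to the Gaussian profile
#'   sigma (one sigma = one radius, see Details).
#' @param psf_sigma_nm optical blur sigma. Folded analytically into the
#'   cluster profile (a Gaussian convolved with a Gaussian PSF stays
#'   Gaussian); the diffuse and background components are blur-invariant.
#' @param clustered_fraction share of the total above-background signal
#'   placed into clusters, in \[0, 1\].
#' @param mean_signal mean above-background signal per pixel (intensity
#'   units). Total injected signal is \code{mean_signal * width * height}.
#' @param background_level constant camera background added everywhere.
#' @param noise_model one of \code{"none"}, \code{"gaussian"},
#'   \code{"poisson"}.
#' @param noise_sd Gaussian noise sigma (used when
#'   \code{noise_model = "gaussian"}).
#' @param gain photon gain for Poisson noise: counts are drawn as
#'   \code{rpois(pixel * gain) / gain}.
#' @param seed integer seed; generation is fully reproducible.
#'
#' @details Cluster profiles are isotropic 2-D Gaussians truncated at three
#' sigma and renormalized, so the injected signal is conserved exactly.
#' Clusters wrap periodically at the image edge (torus geometry) for the
#' same reason. \code{cluster_radius_nm} is interpreted as the Gaussian
#' sigma of the profile; this convention is configurable downstream via
#' \code{\link{autocorr_radius_to_sigma}}.
#'
#' @return an object of class \code{image_spec}.
#' @export
image_spec <- function(width_px = 128L, height_px = 128L, pixel_size_nm = 40,
                       cluster_density_per_um2 = 4, cluster_radius_nm = 60,
                       psf_sigma_nm = 0, clustered_fraction = 0.5,
                       mean_signal = 50, background_level = 10,
                       noise_model = c("none", "gaussian", "poisson"),
                       noise_sd = 5, gain = 1, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (width_px < 1 || height_px < 1)
    stop_usage("image dimensions must be positive")
  if (pixel_size_nm <= 0 || cluster_radius_nm <= 0)
    stop_usage("lengths must be positive")
  if (psf_sigma_nm < 0) stop_usage("psf_sigma_nm must be >= 0")
  if (clustered_fraction < 0 || clustered_fraction > 1)
    stop_usage("clustered_fraction must lie in [0, 1]")
  if (cluster_density_per_um2 < 0) stop_usage("cluster density must be >= 0")
  if (mean_signal < 0 || background_level < 0)
    stop_usage("intensities must be >= 0")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_nm = pixel_size_nm,
                 cluster_density_per_um2 = cluster_density_per_um2,
                 cluster_radius_nm = cluster_radius_nm,
                 psf_sigma_nm = psf_sigma_nm,
                 clustered_fraction = clustered_fraction,
                 mean_signal = mean_signal,
                 background_level = background_level,
                 noise_model = noise_model, noise_sd = noise_sd,
                 gain = gain, seed = as.integer(seed)),
            class = "image_spec")
}

#' Generate a synthetic membrane-sheet image with known ground truth
#'
#' Draws a Poisson number of cluster centres uniformly over the field,
#' injects truncated-Gaussian clusters carrying the requested share of the
#' total signal, adds the diffuse remainder and the background, then applies
#' the noise model. The expected clustered signal share equals
#' \code{spec$clustered_fraction} before noise.
#'
#' @param spec an \code{\link{image_spec}}.
#' @return a list with components \code{image} (a \code{\link{sheet_image}}),
#'   \code{centers} (matrix of cluster centres, 0-based pixel coordinates,
#'   columns x, y), \code{radii_nm} (per-cluster profile sigma, nm),
#'   \code{n_clusters}, \code{realized_clustered_fraction} (0 when no
#'   cluster was drawn) and \code{spec}.
#' @export
gen_sheet_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  W <- spec$width_px; H <- spec$height_px
  npx <- as.double(W) * H
  area_um2 <- npx * (spec$pixel_size_nm / 1000)^2
  lambda <- spec$cluster_density_per_um2 * area_um2
  if (lambda > npx)
    stop_data("expected cluster count (", round(lambda), ") exceeds pixel count")

  with_seed(spec$seed, {
    n_clusters <- rpois(1L, lambda)
    centers <- cbind(x = runif(n_clusters, 0, W), y = runif(n_clusters, 0, H))
    total_signal <- spec$mean_signal * npx
    clustered_signal <- if (n_clusters > 0) spec$clustered_fraction * total_signal else 0
    diffuse_signal <- total_signal - clustered_signal

    img <- matrix(spec$background_level + diffuse_signal / npx, nrow = H, ncol = W)
    sigma_px <- sqrt(spec$cluster_radius_nm^2 + spec$psf_sigma_nm^2) /
      spec$pixel_size_nm
    if (n_clusters > 0) {
      amp <- clustered_signal / n_clusters
      half <- ceiling(3 * sigma_px)
      off <- seq(-half, half)
      for (k in seq_len(n_clusters)) {
        cx <- centers[k, 1L]; cy <- centers[k, 2L]
        # separable truncated kernel on pixel centres nearest the centre
        gx <- exp(-((round(cx) + off + 0.5 - 0.5 - cx)^2) / (2 * sigma_px^2))
        gy <- exp(-((round(cy) + off + 0.5 - 0.5 - cy)^2) / (2 * sigma_px^2))
        ker <- outer(gy, gx)
        ker <- ker * (amp / sum(ker))
        rows <- ((round(cy) + off) %% H) + 1L   # periodic wrap conserves signal
        cols <- ((round(cx) + off) %% W) + 1L
        img[rows, cols] <- img[rows, cols] + ker
      }
    }

    img <- switch(spec$noise_model,
      none = img,
      gaussian = pmax(img + rnorm(npx, 0, spec$noise_sd), 0),
      poisson = matrix(rpois(npx, pmax(img, 0) * spec$gain) / spec$gain,
                       nrow = H, ncol = W))

    list(image = sheet_image(img, spec$pixel_size_nm, "synthetic"),
         centers = centers,
         radii_nm = rep(sqrt(spec$cluster_radius_nm^2 + spec$psf_sigma_nm^2),
                        n_clusters),
         n_clusters = n_clusters,
         realized_clustered_fraction =
           if (n_clusters > 0) spec$clustered_fraction else 0,
         spec = spec)
  })
}

#' Write a generated image as 16-bit TIFF with a JSON ground-truth sidecar
#'
#' @param gen result of \code{\link{gen_sheet_image}}.
#' @param path output TIFF path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @param max_intensity intensity mapped to the top of the 16-bit range.
#'   Defaults to the image maximum.
#' @return invisibly, the two paths written.
#' @export
write_sheet_image <- function(gen, path, max_intensity = NULL) {
  img <- gen$image
  m <- img$pixels
  if (is.null(max_intensity)) max_intensity <- max(m, 1)
  tiff::writeTIFF(pmin(m / max_intensity, 1), path, bits.per.sample = 16L)
  side <- list(
    pixel_size_nm = img$pixel_size_nm,
    max_intensity = max_intensity,
    n_clusters = gen$n_clusters,
    centers = gen$centers,
    radii_nm = gen$radii_nm,
    realized_clustered_fraction = gen$realized_clustered_fraction,
    spec = unclass(gen$spec))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, paste0(path, ".json")))
}

#' Read a 16-bit grayscale TIFF as a sheet image
#'
#' @param path TIFF path.
#' @param pixel_size_nm pixel size; if missing, taken from the JSON sidecar
#'   written by \code{\link{write_sheet_image}} when present.
#' @param scale multiply stored \[0,1\] samples back to intensity units
#'   (defaults to the sidecar's \code{max_intensity}, else 65535).
#' @param channel_label free-text channel tag.
#' @return a \code{\link{sheet_image}}.
#' @export
read_sheet_image <- function(path, pixel_size_nm = NULL, scale = NULL,
                             channel_label = basename(path)) {
  if (!file.exists(path)) stop_data("no such image file: ", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  sidecar <- paste0(path, ".json")
  if ((is.null(pixel_size_nm) || is.null(scale)) && file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size_nm)) pixel_size_nm <- side$pixel_size_nm
    if (is.null(scale)) scale <- side$max_intensity
  }
  if (is.null(scale)) scale <- 65535
  if (is.null(pixel_size_nm))
    stop_data("pixel_size_nm not given and no sidecar found for ", path)
  sheet_image(m * scale, pixel_size_nm, channel_label)
}
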