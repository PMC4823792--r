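#' Sheet image container
#'
#' A 2-D non-negative intensity raster with its physical pixel size.
#' Pixel coordinates are 0-based with origin at the top-left; x indexes
#' columns, y indexes rows.
#'
#' @param pixels numeric matrix (rows = y, columns = x), non-negative.
#' @param pixel_size_nm physical pixel size, nm per pixel.
#' @param channel_label free-text channel tag.
#' @return object of class \code{sheet_image}.
#' @export
sheet_image <- function(pixels, pixel_size_nm, channel_label = "") {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop_data("pixels must be a finite numeric matrix")
  if (any(pixels < 0)) stop_data("pixel intensities must be non-negative")
  if (pixel_size_nm <= 0) stop_usage("pixel_size_nm must be positive")
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 channel_label = channel_label), class = "sheet_image")
}

#' @export
print.sheet_image <- function(x, ...) {
  cat("<sheet_image> ", ncol(x$pixels), " x ", nrow(x$pixels), " px @ ",
      x$pixel_size_nm, " nm/px",
      if (nzchar(x$channel_label)) paste0(" [", x$channel_label, "]"), "\n",
      sep = "")
  invisible(x)
}

#' Rectangular region of interest
#'
#' @param x0,y0 0-based pixel origin (top-left corner of the ROI).
#' @param width,height extent in pixels.
#' @return object of class \code{roi}.
#' @export
roi <- function(x0, y0, width, height) {
  if (width < 1 || height < 1) stop_usage("ROI must be at least 1 x 1")
  if (x0 < 0 || y0 < 0) stop_usage("ROI origin must be non-negative")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

roi_pixels <- function(image, r) {
  m <- image$pixels
  if (r$x0 + r$width > ncol(m) || r$y0 + r$height > nrow(m))
    stop_usage("ROI exceeds image bounds")
  m[(r$y0 + 1L):(r$y0 + r$height), (r$x0 + 1L):(r$x0 + r$width), drop = FALSE]
}

roi_area_um2 <- function(r, pixel_size_nm) {
  as.double(r$width) * r$height * (pixel_size_nm / 1000)^2
}

#' Background-corrected mean intensity
#'
#' Mean ROI intensity minus mean background-ROI intensity. A negative
#' result is returned as-is with attribute \code{negative = TRUE} (it
#' signals a background region brighter than the sheet, worth inspecting,
#' not clamping).
#'
#' @param image a \code{\link{sheet_image}}.
#' @param roi sheet \code{\link{roi}}.
#' @param background_roi background \code{\link{roi}} placed off the sheet.
#' @return background-corrected mean intensity.
#' @export
background_corrected_mean <- function(image, roi, background_roi) {
  v <- mean(roi_pixels(image, roi)) - mean(roi_pixels(image, background_roi))
  if (v < 0) attr(v, "negative") <- TRUE
  v
}

#' Relative standard deviation (coefficient of variation) of a ROI
#'
#' Population standard deviation of the background-corrected ROI pixels
#' divided by their mean: the segmentation-free heterogeneity readout.
#' Zero for a perfectly uniform intensity distribution; grows as signal
#' accumulates in clusters.
#'
#' @param image a \code{\link{sheet_image}}.
#' @param roi a \code{\link{roi}}.
#' @param background scalar background intensity subtracted before the
#'   statistic (default 0: image already corrected).
#' @return dimensionless rel. SD (>= 0).
#' @export
relative_sd <- function(image, roi, background = 0) {
  v <- as.vector(roi_pixels(image, roi)) - background
  m <- mean(v)
  if (m <= 0)
    stop_data("background-corrected mean is not positive; rel. SD undefined")
  sqrt(mean((v - m)^2)) / m
}

#' Normalize a set of measurements to a control condition
#'
#' Divides each value by the mean of the control set (baseline condition).
#'
#' @param values numeric vector.
#' @param control_values numeric vector of control measurements.
#' @return normalized values.
#' @export
normalize_to_control <- function(values, control_values) {
  if (!length(control_values)) stop_usage("empty control set")
  m <- mean(control_values)
  if (m <= 0) stop_data("control mean must be positive")
  values / m
}

#' Detect clusters as prominent local maxima
#'
#' Counts local intensity maxima with prominence exceeding
#' \code{noise_level}, following find-maxima semantics: a maximum is
#' accepted if it cannot be reached from any strictly higher pixel without
#' descending by more than \code{noise_level}, i.e. the connected region of
#' pixels above (value - noise_level) around the maximum contains no higher
#' pixel. Of several equal maxima connected within tolerance, one is
#' counted. Plateau maxima report their centroid. A constant ROI yields no
#' maxima.
#'
#' @param image a \code{\link{sheet_image}}.
#' @param roi a \code{\link{roi}}.
#' @param noise_level prominence tolerance (intensity units, >= 0). Must be
#'   chosen per dataset and held fixed across recordings; no default.
#' @return list: \code{maxima} (data.frame x, y in 0-based image
#'   coordinates, value), \code{count}, \code{density_per_um2}.
#' @export
detect_clusters <- function(image, roi, noise_level) {
  if (missing(noise_level)) stop_usage("noise_level must be supplied")
  if (noise_level < 0) stop_usage("noise_level must be >= 0")
  m <- roi_pixels(image, roi)
  H <- nrow(m); W <- ncol(m)
  nbrs <- neighbour_lookup(H, W)
  cand <- find_plateau_maxima(m, nbrs)
  if (!nrow(cand$reps)) {
    return(list(maxima = data.frame(x = numeric(0), y = numeric(0),
                                    value = numeric(0)),
                count = 0L, density_per_um2 = 0))
  }
  ord <- order(-cand$reps$value, cand$reps$idx)
  processed <- logical(H * W)
  out_x <- out_y <- out_v <- numeric(0)
  v <- as.vector(m)
  for (k in ord) {
    start <- cand$reps$idx[k]; v0 <- cand$reps$value[k]
    if (processed[start]) next
    lo <- v0 - noise_level
    # flood the connected region strictly above v0 - noise_level
    seen <- logical(H * W)
    stack <- integer(H * W); stack[1L] <- start; top <- 1L
    seen[start] <- TRUE
    higher <- FALSE
    while (top > 0L && !higher) {
      cur <- stack[top]; top <- top - 1L
      for (nb in nbrs[[cur]]) {
        if (seen[nb]) next
        if (v[nb] > v0) { higher <- TRUE; break }
        if (v[nb] > lo) {
          seen[nb] <- TRUE
          top <- top + 1L; stack[top] <- nb
        }
      }
    }
    if (!higher) {
      members <- which(cand$plateau_id == cand$plateau_id[start])
      my <- ((members - 1L) %% H) + 1L
      mx <- ((members - 1L) %/% H) + 1L
      out_x <- c(out_x, mean(mx) - 1 + roi$x0)
      out_y <- c(out_y, mean(my) - 1 + roi$y0)
      out_v <- c(out_v, v0)
      processed <- processed | seen
    }
  }
  maxima <- data.frame(x = out_x, y = out_y, value = out_v)
  list(maxima = maxima, count = nrow(maxima),
       density_per_um2 = nrow(maxima) / roi_area_um2(roi, image$pixel_size_nm))
}

# 8-neighbour index lists for an H x W matrix stored column-major
neighbour_lookup <- function(H, W) {
  lapply(seq_len(H * W), function(i) {
    y <- ((i - 1L) %% H) + 1L; x <- ((i - 1L) %/% H) + 1L
    ys <- max(y - 1L, 1L):min(y + 1L, H)
    xs <- max(x - 1L, 1L):min(x + 1L, W)
    nb <- as.vector(outer(ys, (xs - 1L) * H, `+`))
    nb[nb != i]
  })
}

# connected equal-value plateaus that are local maxima; returns one
# representative pixel per plateau (member nearest the plateau centroid)
# plus the plateau label vector
find_plateau_maxima <- function(m, nbrs = neighbour_lookup(nrow(m), ncol(m))) {
  H <- nrow(m); W <- ncol(m)
  v <- as.vector(m)
  lab <- integer(H * W)
  nextlab <- 0L
  rep_idx <- integer(0); rep_val <- numeric(0)
  stack <- integer(H * W)
  for (i0 in seq_len(H * W)) {
    if (lab[i0] != 0L) next
    v0 <- v[i0]
    nextlab <- nextlab + 1L
    lab[i0] <- nextlab
    stack[1L] <- i0; top <- 1L
    cells <- integer(H * W); ncells <- 0L
    has_higher <- FALSE; has_lower <- FALSE
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      ncells <- ncells + 1L; cells[ncells] <- cur
      for (nb in nbrs[[cur]]) {
        if (v[nb] > v0) has_higher <- TRUE
        else if (v[nb] < v0) has_lower <- TRUE
        else if (lab[nb] == 0L) {
          lab[nb] <- nextlab
          top <- top + 1L; stack[top] <- nb
        }
      }
    }
    if (!has_higher && has_lower) {
      cells <- cells[seq_len(ncells)]
      cy <- ((cells - 1L) %% H) + 1L
      cx <- ((cells - 1L) %/% H) + 1L
      i <- which.min((cy - mean(cy))^2 + (cx - mean(cx))^2)
      rep_idx <- c(rep_idx, cells[i])
      rep_val <- c(rep_val, v0)
    }
  }
  list(reps = data.frame(idx = rep_idx, value = rep_val),
       plateau_id = lab)
}

#' Pixel-shift autocorrelation curve of a ROI
#'
#' For each shift, the Pearson correlation between the ROI and the ROI
#' translated rightward by that many pixels, computed on the overlapping
#' columns only (no wraparound). A zero-variance overlap yields NA for
#' that shift. Optionally averages the four axis directions.
#'
#' @param image a \code{\link{sheet_image}}.
#' @param roi a \code{\link{roi}}.
#' @param max_shift_px largest shift; must be < ROI width.
#' @param isotropic average rightward, leftward, downward and upward
#'   shifts (off by default; rightward-only is the reference behaviour).
#' @return object of class \code{autocorr_curve}: \code{shifts_px},
#'   \code{pcc}, \code{pixel_size_nm}.
#' @export
autocorr_curve <- function(image, roi, max_shift_px, isotropic = FALSE) {
  m <- roi_pixels(image, roi)
  if (max_shift_px >= ncol(m)) stop_usage("max_shift_px must be < ROI width")
  if (isotropic && max_shift_px >= nrow(m))
    stop_usage("max_shift_px must be < ROI height for isotropic curves")
  shift_pcc <- function(mat, d) {
    if (d == 0L) return(1)
    a <- mat[, seq_len(ncol(mat) - d), drop = FALSE]
    b <- mat[, seq_len(ncol(mat) - d) + d, drop = FALSE]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(as.vector(a), as.vector(b))
  }
  shifts <- 0:max_shift_px
  pcc <- vapply(shifts, function(d) {
    if (!isotropic) shift_pcc(m, d)
    else mean(c(shift_pcc(m, d), shift_pcc(m[, rev(seq_len(ncol(m)))], d),
                shift_pcc(t(m), d), shift_pcc(t(m)[, rev(seq_len(nrow(m)))], d)),
              na.rm = TRUE)
  }, numeric(1))
  structure(list(shifts_px = shifts, pcc = pcc,
                 pixel_size_nm = image$pixel_size_nm),
            class = "autocorr_curve")
}

#' Average several autocorrelation curves pointwise
#'
#' @param curves list of \code{autocorr_curve} objects on identical shift
#'   grids (e.g. all ROIs of one condition and day). Missing values are
#'   excluded pointwise.
#' @return an \code{autocorr_curve}.
#' @export
average_curves <- function(curves) {
  if (!length(curves)) stop_usage("empty curve list")
  s0 <- curves[[1L]]$shifts_px
  for (cv in curves)
    if (!identical(cv$shifts_px, s0)) stop_usage("shift grids differ")
  pcc <- rowMeans(vapply(curves, `[[`, numeric(length(s0)), "pcc"),
                  na.rm = TRUE)
  structure(list(shifts_px = s0, pcc = pcc,
                 pixel_size_nm = curves[[1L]]$pixel_size_nm),
            class = "autocorr_curve")
}

#' Average object radius from an autocorrelation curve
#'
#' Fits the PCC-versus-shift curve (shift 0 included) with a least-squares
#' polynomial and locates the 50% decay point: the shift at which the
#' fitted curve first crosses midway between its value at shift 0 and the
#' baseline, taken as the fitted value at the largest shift. The radius is
#' that shift times the pixel size.
#'
#' @param curve an \code{autocorr_curve}.
#' @param poly_order polynomial order (default 4).
#' @return radius in nm, with attributes \code{shift_px} (the half-decay
#'   shift) and \code{baseline}.
#' @export
radius_from_autocorr <- function(curve, poly_order = 4L) {
  ok <- !is.na(curve$pcc)
  x <- curve$shifts_px[ok]; y <- curve$pcc[ok]
  if (length(x) < poly_order + 2L)
    stop_usage("need at least poly_order + 2 points")
  fit <- lm(y ~ poly(x, poly_order, raw = TRUE))
  fx <- function(s) predict(fit, newdata = data.frame(x = s))
  p0 <- fx(0)
  baseline <- fx(max(x))
  if (p0 - baseline < 1e-8)
    stop_data("autocorrelation curve does not decay to the 50% level")
  half <- (p0 + baseline) / 2
  grid <- seq(0, max(x), length.out = 2048L)
  vals <- fx(grid)
  below <- which(vals < half)
  below <- below[below > 1L]
  if (!length(below))
    stop_data("autocorrelation curve does not decay to the 50% level")
  i <- below[1L]
  root <- uniroot(function(s) fx(s) - half, c(grid[i - 1L], grid[i]))$root
  structure(root * curve$pixel_size_nm, shift_px = root, baseline = baseline)
}

#' Convert an autocorrelation half-decay radius to a Gaussian profile sigma
#'
#' For an image of isotropic Gaussian objects with profile sigma, the
#' spatial autocorrelation is Gaussian with variance doubled, so the 50%
#' decay shift is \code{2 * sigma * sqrt(log(2))}. This converter recovers
#' sigma from the raw half-decay radius reported by
#' \code{\link{radius_from_autocorr}}.
#'
#' @param radius_nm half-decay radius (nm).
#' @return Gaussian sigma (nm).
#' @export
autocorr_radius_to_sigma <- function(radius_nm) {
  as.numeric(radius_nm) / (2 * sqrt(log(2)))
}

#' Fraction of signal residing in punctate areas
#'
#' Segments punctate pixels as those above \code{mean + k_sigma * SD} of
#' the (background-corrected) ROI and returns the share of total ROI signal
#' they carry.
#'
#' @param image a background-corrected \code{\link{sheet_image}}.
#' @param roi a \code{\link{roi}}.
#' @param k_sigma segmentation threshold in SD units (default 2).
#' @return fraction in \[0, 1\].
#' @export
clustered_fraction <- function(image, roi, k_sigma = 2) {
  v <- as.vector(roi_pixels(image, roi))
  tot <- sum(v)
  if (tot <= 0) stop_data("total ROI signal must be positive")
  thr <- mean(v) + k_sigma * sqrt(mean((v - mean(v))^2))
  sum(v[v > thr]) / tot
}
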