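# Image quantification: averaged line profiles, FWHM resolution, face-on
# ring diameters and channel offsets, cytoplasmic signal fractions,
# constriction-rate fits and cumulative abscission scoring. Pixel indexing
# is 0-based with positions reported at pixel centres; physical outputs are
# in nm or um, never pixels.

#' Averaged line profile through an image
#'
#' Samples the image along a line of the given physical length, averaging
#' the intensity across \code{width_px} parallel lines (arithmetic mean, as
#' in the common image tools); off-grid positions use bilinear
#' interpolation.
#'
#' @param image Numeric matrix (row = x, column = y).
#' @param anchor Profile centre, 0-based pixel coordinates \code{c(x, y)}.
#' @param direction Length-2 vector along the profile (any norm).
#' @param length_nm Profile length, nm.
#' @param width_px Averaging width, pixels.
#' @param pixel_nm Pixel size, nm.
#' @return A \code{cdv_line_profile}: \code{position_nm} (centred on the
#'   anchor), \code{intensity}, \code{width_px}, \code{length_nm}.
#' @export
line_profile <- function(image, anchor, direction, length_nm,
                         width_px = 1, pixel_nm = 17) {
  stopifnot(is.matrix(image), length(anchor) == 2, length(direction) == 2)
  u <- direction / sqrt(sum(direction^2))
  v <- c(-u[2], u[1])
  # odd number of samples spaced exactly one pixel apart, centred on the
  # anchor, so axis-aligned profiles read pixel values directly
  half_n <- floor(length_nm / (2 * pixel_nm))
  n_s <- 2L * half_n + 1L
  if (n_s < 5) stop("profile too short for the pixel size")
  s <- (-half_n):half_n
  offs <- seq_len(width_px) - (width_px + 1) / 2
  xs <- outer(s, rep(1, width_px)) * u[1] + outer(rep(1, n_s), offs) * v[1] +
    anchor[1]
  ys <- outer(s, rep(1, width_px)) * u[2] + outer(rep(1, n_s), offs) * v[2] +
    anchor[2]
  if (min(xs) < 0 || min(ys) < 0 ||
      max(xs) > nrow(image) - 1 || max(ys) > ncol(image) - 1)
    stop("profile rectangle exceeds the image bounds")
  vals <- matrix(bilinear_sample(image, xs, ys), n_s, width_px)
  structure(list(position_nm = s * pixel_nm,
                 intensity = rowMeans(vals),
                 width_px = width_px, length_nm = length_nm,
                 pixel_nm = pixel_nm),
            class = "cdv_line_profile")
}

# bilinear interpolation at 0-based pixel-centre coordinates
bilinear_sample <- function(image, x, y) {
  x0 <- pmin(pmax(floor(as.vector(x)), 0), nrow(image) - 2)
  y0 <- pmin(pmax(floor(as.vector(y)), 0), ncol(image) - 2)
  fx <- as.vector(x) - x0; fy <- as.vector(y) - y0
  i <- x0 + 1; j <- y0 + 1
  image[cbind(i, j)] * (1 - fx) * (1 - fy) +
    image[cbind(i + 1, j)] * fx * (1 - fy) +
    image[cbind(i, j + 1)] * (1 - fx) * fy +
    image[cbind(i + 1, j + 1)] * fx * fy
}

#' Full width at half maximum of a line profile
#'
#' The background defaults to the profile minimum (optionally the median of
#' the outer 10% of samples); the two half-maximum crossings around the
#' unique global maximum are located by monotone cubic interpolation.
#' Invariant under intensity scaling and offset.
#'
#' @param profile A \code{cdv_line_profile}, or a list with
#'   \code{position_nm} and \code{intensity}.
#' @param background "min" or "edges".
#' @return Width in nm.
#' @examples
#' p <- list(position_nm = seq(-100, 100, by = 2),
#'           intensity = dnorm(seq(-100, 100, by = 2), sd = 10))
#' fwhm(p)  # ~23.55 = 2.3548 * 10
#' @export
fwhm <- function(profile, background = c("min", "edges")) {
  background <- match.arg(background)
  x <- profile$position_nm
  y <- profile$intensity
  stopifnot(length(x) == length(y), length(x) >= 5)
  bg <- switch(background,
               min = min(y),
               edges = stats::median(y[c(seq_len(max(2, length(y) %/% 10)),
                                         seq(length(y) -
                                               max(2, length(y) %/% 10) + 1,
                                             length(y)))]))
  imax <- which.max(y)
  if (imax == 1 || imax == length(y))
    stop("profile has no interior maximum (monotonic or flat)")
  half <- bg + (y[imax] - bg) / 2
  sf <- stats::splinefun(x, y - half, method = "natural")
  left_idx <- max(which(y[1:imax] <= half))
  right_idx <- imax - 1 + min(which(y[imax:length(y)] <= half))
  if (!is.finite(left_idx) || left_idx < 1 ||
      !length(which(y[imax:length(y)] <= half)))
    stop("no half-maximum crossings on both sides of the peak")
  xl <- stats::uniroot(sf, c(x[left_idx], x[left_idx + 1]))$root
  xr <- stats::uniroot(sf, c(x[right_idx - 1], x[right_idx]))$root
  xr - xl
}

#' Face-on ring diameter and two-channel offsets
#'
#' The ring centre is refined as the intensity centroid; the azimuthally
#' averaged radial intensity profile is computed on pixel-width annular
#' bins and the peak located with parabolic (sub-pixel) interpolation.
#'
#' @param image Numeric matrix.
#' @param pixel_nm Pixel size, nm.
#' @param center Optional centre hint, 0-based pixel coordinates; default
#'   is the intensity centroid.
#' @return Ring diameter, nm.
#' @export
ring_diameter <- function(image, pixel_nm = 17, center = NULL) {
  if (max(image) <= 0 || stats::sd(image) == 0)
    stop("blank image: no radial peak above background")
  n <- nrow(image); m <- ncol(image)
  xs <- matrix(rep(seq_len(n) - 1, m), n)
  ys <- t(matrix(rep(seq_len(m) - 1, n), m))
  if (is.null(center)) {
    w <- pmax(image, 0)
    center <- c(sum(xs * w), sum(ys * w)) / sum(w)
  }
  rr <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  bin <- floor(rr) + 1L
  nb <- max(bin)
  tot <- tabulate(bin, nb)
  means <- as.numeric(rowsum(as.vector(image), as.vector(bin))) / tot
  pk <- which.max(means)
  if (pk <= 1 || pk >= nb || means[pk] <= mean(image))
    stop("no radial peak above background")
  # parabolic refinement around the peak bin (bin centres at r = bin - 0.5)
  y1 <- means[pk - 1]; y2 <- means[pk]; y3 <- means[pk + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  r_px <- (pk - 0.5) + delta
  2 * r_px * pixel_nm
}

#' @rdname ring_diameter
#' @param set A \code{cdv_image_set} with two or more channels.
#' @return \code{channel_offset}: named vector of pairwise diameter
#'   differences (nm), second channel minus first, etc.
#' @export
channel_offset <- function(set, pixel_nm = set$truth$pixel_nm) {
  ds <- vapply(set$channels, ring_diameter, numeric(1), pixel_nm = pixel_nm)
  if (length(ds) < 2) stop("need at least two channels")
  combs <- utils::combn(names(ds), 2)
  out <- apply(combs, 2, function(p) ds[p[2]] - ds[p[1]])
  names(out) <- apply(combs, 2, paste, collapse = "-")
  attr(out, "diameters_nm") <- ds
  out
}

#' Cytoplasmic signal fraction of a cell image
#'
#' The cytoplasm region is the cell mask minus the ring mask dilated by
#' \code{dilate_px}; the background (mean intensity outside the cell) is
#' subtracted before computing region means and the cytoplasmic share of
#' the total cell signal.
#'
#' @param image Numeric matrix.
#' @param cell_mask,ring_mask Logical matrices; the ring mask must lie
#'   inside the cell mask.
#' @param dilate_px Ring dilation radius, pixels.
#' @return List: \code{cytoplasm_mean}, \code{ring_mean},
#'   \code{cytoplasmic_share} (cytoplasm total / cell total, background
#'   subtracted), \code{background}.
#' @export
cytoplasmic_fraction <- function(image, cell_mask, ring_mask,
                                 dilate_px = 2) {
  stopifnot(any(cell_mask), any(ring_mask))
  if (any(ring_mask & !cell_mask))
    stop("ring mask extends outside the cell mask")
  ring_d <- dilate_mask(ring_mask, dilate_px)
  cyto <- cell_mask & !ring_d
  if (!any(cyto))
    stop("empty cytoplasm region after ring dilation")
  cell_all <- cell_mask | ring_d
  bg <- if (any(!cell_all)) mean(image[!cell_all]) else 0
  cyto_mean <- mean(image[cyto]) - bg
  ring_mean <- mean(image[ring_d]) - bg
  # ring signal in excess of the local cytoplasmic level; the cytoplasmic
  # share is the complement, so uniform cytoplasm under the ring zone is
  # booked as cytoplasm, not ring
  ring_excess <- sum(image[ring_d] - bg - cyto_mean)
  cell_tot <- sum(image[cell_all] - bg)
  share <- 1 - max(0, ring_excess) / max(cell_tot, 1e-300)
  list(cytoplasm_mean = cyto_mean, ring_mean = ring_mean,
       cytoplasmic_share = min(1, max(0, share)),
       background = bg)
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  out <- mask
  n <- nrow(mask); m <- ncol(mask)
  for (dx in -radius:radius) for (dy in -radius:radius) {
    if (dx * dx + dy * dy > radius * radius) next
    xs <- pmin(pmax(seq_len(n) + dx, 1), n)
    ys <- pmin(pmax(seq_len(m) + dy, 1), m)
    out <- out | mask[xs, ys]
  }
  out
}

#' Constriction rate from a diameter-vs-time series
#'
#' The fit window opens at the first frame whose diameter falls below 95%
#' of the initial diameter and closes at the last frame above 0.2 um; the
#' rate is the magnitude of the least-squares slope within the window. A
#' series whose diameter rises by more than 3 SD of the residuals is
#' flagged non-monotonic (but still fitted).
#'
#' @param time_min Frame times, minutes.
#' @param diameter_um Measured diameters, micrometres.
#' @return A \code{cdv_rate_estimate}: \code{rate} (um/min),
#'   \code{window} (frame indices), \code{n_frames},
#'   \code{nonmonotonic} flag.
#' @examples
#' t <- seq(0, 5, by = 0.25)
#' constriction_rate(t, 1 - 0.11 * t)$rate  # 0.11
#' @export
constriction_rate <- function(time_min, diameter_um) {
  stopifnot(length(time_min) == length(diameter_um))
  if (length(time_min) < 3) stop("need at least 3 frames")
  d0 <- diameter_um[1]
  start <- which(diameter_um < 0.95 * d0)
  end <- which(diameter_um > 0.2)
  if (!length(start) || !length(end))
    stop("no frames inside the fit window")
  w <- seq(min(start), max(end))
  w <- w[w >= min(start)]
  if (length(w) < 3) stop("fewer than 3 frames inside the fit window")
  fit <- stats::lm(diameter_um[w] ~ time_min[w])
  res_sd <- stats::sd(stats::residuals(fit))
  rises <- diff(diameter_um[w])
  nonmono <- any(rises > 3 * max(res_sd, 1e-12))
  structure(list(rate = abs(unname(stats::coef(fit)[2])),
                 window = range(w), n_frames = length(w),
                 nonmonotonic = nonmono),
            class = "cdv_rate_estimate")
}

#' @rdname constriction_rate
#' @param series_list List of series, each a list with \code{time_min} and
#'   \code{diameter_um} (e.g. from \code{\link{render_timelapse}}).
#' @return \code{constriction_rate_multi}: list with \code{mean_rate},
#'   \code{sd_rate} (across cells), \code{n_cells}, \code{rates}.
#' @export
constriction_rate_multi <- function(series_list) {
  rates <- vapply(series_list, function(s)
    constriction_rate(s$time_min, s$diameter_um)$rate, numeric(1))
  list(mean_rate = mean(rates), sd_rate = stats::sd(rates),
       n_cells = length(rates), rates = rates)
}

#' Cumulative abscission curve
#'
#' Given per-cell separation times (minutes after the end of constriction;
#' cells never observed to separate encoded as \code{NA} or \code{Inf} and
#' counted as not separated), returns the fraction separated within the
#' scoring window and the full cumulative curve.
#'
#' @param separation_min Separation times, minutes (>= 0).
#' @param window_min Scoring window, minutes.
#' @return List: \code{fraction_within} (in percent), \code{window_min},
#'   \code{curve} (data frame time_min, cumulative_percent), \code{n}.
#' @export
abscission_curve <- function(separation_min, window_min = 20) {
  if (!length(separation_min)) stop("empty input")
  times <- separation_min
  times[is.na(times)] <- Inf
  if (any(times < 0)) stop("separation times must be >= 0")
  n <- length(times)
  grid <- sort(unique(c(0, times[is.finite(times)], window_min)))
  curve <- data.frame(
    time_min = grid,
    cumulative_percent = vapply(grid, function(tt)
      100 * sum(times <= tt) / n, numeric(1)))
  list(fraction_within = 100 * sum(times <= window_min) / n,
       window_min = window_min, curve = curve, n = n)
}
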