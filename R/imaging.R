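# Synthetic fluorescence-microscopy generator with embedded ground truth.
#
# Emulates the study's readouts: STED-like face-on rings and side-view
# bands (17-nm pixels, ~30-nm Gaussian PSF), constriction time-lapses with
# linear diameter decrease, and cell images with a division ring plus a
# cytoplasmic pool. Images carry arbitrary intensity units ("photons");
# the noiseless total intensity of each channel equals the configured
# photon budget exactly (rendering normalises the discretised signal to
# the budget), so quantification tests are closed-loop against the truth.

#' Ground truth for synthetic microscopy images
#'
#' @param pixel_nm Pixel size, nm (STED default 17).
#' @param psf_fwhm_nm Gaussian PSF full width at half maximum, nm
#'   (default 30, the STED working resolution).
#' @param size_px Image side length, pixels.
#' @param photon_budget Expected total intensity per channel.
#' @param poisson Apply Poisson shot noise?
#' @param read_sd Gaussian read-noise SD (intensity units; 0 = off).
#' @param seed Integer seed; generators are deterministic given
#'   (truth, seed).
#' @param geometry Named list of geometric parameters (see the individual
#'   generators).
#' @return Object of class \code{cdv_ground_truth}.
#' @export
ground_truth <- function(pixel_nm = 17, psf_fwhm_nm = 30, size_px = 128,
                         photon_budget = 2e5, poisson = FALSE, read_sd = 0,
                         seed = 1L, geometry = list()) {
  stopifnot(pixel_nm > 0, psf_fwhm_nm > 0, size_px >= 8, photon_budget > 0)
  structure(list(pixel_nm = pixel_nm, psf_fwhm_nm = psf_fwhm_nm,
                 size_px = as.integer(size_px),
                 photon_budget = photon_budget, poisson = poisson,
                 read_sd = read_sd, seed = as.integer(seed),
                 geometry = geometry),
            class = "cdv_ground_truth")
}

psf_sigma_px <- function(truth) truth$psf_fwhm_nm / 2.354820045 / truth$pixel_nm

# discrete 1-D Gaussian kernel, sum-normalised
gauss_kernel <- function(sigma, half = ceiling(5 * sigma)) {
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with zero padding (kernel sums to 1, so total
# intensity is conserved up to edge truncation; callers re-normalise)
convolve_sep <- function(img, kernel) {
  half <- (length(kernel) - 1) / 2
  n <- nrow(img); m <- ncol(img)
  pad <- function(v) c(rep(0, half), v, rep(0, half))
  conv1 <- function(v) {
    out <- stats::filter(pad(v), kernel, sides = 2)
    as.numeric(out)[(half + 1):(half + length(v))]
  }
  img <- apply(img, 2, conv1)
  t(apply(t(img), 2, conv1))
}

apply_noise <- function(img, truth, which_seed = truth$seed) {
  if (!truth$poisson && truth$read_sd <= 0) return(img)
  with_local_seed(which_seed, {
    if (truth$poisson) img[] <- stats::rpois(length(img), pmax(img, 0))
    if (truth$read_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), sd = truth$read_sd),
                          nrow(img))
    pmax(img, 0)
  })
}

new_image_set <- function(channels, truth) {
  dims <- vapply(channels, dim, integer(2))
  stopifnot(all(dims == dims[, 1]))
  structure(list(channels = channels, truth = truth),
            class = "cdv_image_set")
}

#' @export
print.cdv_image_set <- function(x, ...) {
  cat(sprintf("<cdv_image_set> %d channel(s) of %dx%d px (%g nm/px)\n",
              length(x$channels), nrow(x$channels[[1]]),
              ncol(x$channels[[1]]), x$truth$pixel_nm))
  invisible(x)
}

# rasterise a circle of total mass `budget` (centre cx,cy in px units,
# radius in px) on an o-times oversampled grid, blur, block-sum back
render_annulus <- function(size_px, cx, cy, radius_px, sigma_px, budget,
                           oversample = 4L) {
  o <- oversample
  n <- size_px * o
  img <- matrix(0, n, n)
  m_pts <- max(4096L, ceiling(2 * pi * radius_px * o * 4))
  th <- (seq_len(m_pts) - 0.5) / m_pts * 2 * pi
  # pixel centre convention: pixel (i,j) covers [(i-1),i] x [(j-1),j] px
  xs <- (cx + radius_px * cos(th)) * o
  ys <- (cy + radius_px * sin(th)) * o
  ix <- floor(xs) + 1L; iy <- floor(ys) + 1L
  ok <- ix >= 1 & ix <= n & iy >= 1 & iy <= n
  if (!all(ok)) stop("ring extends beyond the field of view")
  idx <- cbind(ix, iy)
  w <- budget / m_pts
  for (k in seq_len(m_pts)) img[idx[k, 1], idx[k, 2]] <-
    img[idx[k, 1], idx[k, 2]] + w
  img <- convolve_sep(img, gauss_kernel(sigma_px * o))
  # block-sum downsample
  img <- rowsum(img, rep(seq_len(size_px), each = o))
  img <- t(rowsum(t(img), rep(seq_len(size_px), each = o)))
  img * (budget / sum(img))
}

#' Render synthetic STED-like ring and band images
#'
#' Face-on geometry (\code{geometry$ring_diameters_nm}, one per channel):
#' each channel is a thin annulus of the stated diameter convolved with
#' the Gaussian PSF. Side-view geometry (\code{geometry$bands}, a data
#' frame with \code{channel}, \code{position_nm} along x relative to the
#' image centre, \code{width_nm}): each band is a smoothed stripe spanning
#' the central half of y. A single point emitter
#' (\code{geometry$point_emitter = TRUE}) renders the PSF itself, for
#' resolution estimation.
#'
#' @param truth A \code{\link{ground_truth}}; noise is applied per channel
#'   with seeds derived from \code{truth$seed}.
#' @return A \code{cdv_image_set} (channels in acquisition order).
#' @examples
#' tr <- ground_truth(geometry = list(point_emitter = TRUE))
#' img <- render_rings(tr)$channels[[1]]
#' which(img == max(img), arr.ind = TRUE)  # centre pixel
#' @export
render_rings <- function(truth) {
  stopifnot(inherits(truth, "cdv_ground_truth"))
  g <- truth$geometry
  s_px <- psf_sigma_px(truth)
  n <- truth$size_px
  ctr <- (n + 1) / 2          # image centre in pixel-centre coordinates
  channels <- list()
  if (isTRUE(g$point_emitter)) {
    x <- matrix(rep(seq_len(n), n), n) - ctr
    y <- t(x)
    img <- exp(-(x^2 + y^2) / (2 * s_px^2))
    channels$emitter <- img * (truth$photon_budget / sum(img))
  }
  if (!is.null(g$ring_diameters_nm)) {
    for (ch in names(g$ring_diameters_nm)) {
      r_px <- g$ring_diameters_nm[[ch]] / 2 / truth$pixel_nm
      channels[[ch]] <- render_annulus(n, ctr - 0.5, ctr - 0.5, r_px, s_px,
                                       truth$photon_budget)
    }
  }
  if (!is.null(g$bands)) {
    for (ch in unique(g$bands$channel)) {
      bb <- g$bands[g$bands$channel == ch, , drop = FALSE]
      xs <- (seq_len(n) - ctr) * truth$pixel_nm   # nm along x
      s_nm <- truth$psf_fwhm_nm / 2.354820045
      prof <- rep(0, n)
      for (b in seq_len(nrow(bb)))
        prof <- prof +
          (stats::pnorm(xs, bb$position_nm[b] - bb$width_nm[b] / 2, s_nm) -
           stats::pnorm(xs, bb$position_nm[b] + bb$width_nm[b] / 2, s_nm))
      ymask <- rep(0, n)
      yq <- abs(seq_len(n) - ctr) <= n / 4
      ymask[yq] <- 1
      img <- outer(prof, ymask)
      if (sum(img) <= 0) stop("band geometry renders no signal in the field")
      channels[[as.character(ch)]] <- img * (truth$photon_budget / sum(img))
    }
  }
  if (!length(channels))
    stop("ground truth geometry defines no renderable content")
  channels <- lapply(seq_along(channels), function(i)
    apply_noise(channels[[i]], truth, truth$seed * 131L + i))
  names(channels) <- names(truth$geometry$ring_diameters_nm) %||%
    names(channels)
  new_image_set(channels, truth)
}

#' Render a constriction time-lapse
#'
#' The ground-truth ring diameter decreases linearly from
#' \code{geometry$start_diameter_um} at \code{geometry$rate_um_min}
#' (micrometres per minute), floored at zero; the measured series adds
#' seeded Gaussian measurement noise of SD \code{geometry$noise_sd_um}.
#'
#' @param truth A \code{\link{ground_truth}} whose geometry lists
#'   \code{start_diameter_um}, \code{rate_um_min}, \code{noise_sd_um}.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval_s Frame interval, seconds.
#' @param render_frames Also render a ring-image stack (slower)?
#' @return List: \code{time_min}, \code{diameter_true_um},
#'   \code{diameter_um} (noisy), and optionally \code{frames}
#'   (a \code{cdv_image_set} per frame).
#' @export
render_timelapse <- function(truth, n_frames = 30, frame_interval_s = 15,
                             render_frames = FALSE) {
  stopifnot(n_frames >= 2)
  g <- truth$geometry
  rate <- g$rate_um_min %||% 0.11
  if (rate < 0) stop("constriction rate must be >= 0")
  d0 <- g$start_diameter_um %||% 1.0
  noise_sd <- g$noise_sd_um %||% 0
  t_min <- (seq_len(n_frames) - 1) * frame_interval_s / 60
  d_true <- pmax(d0 - rate * t_min, 0)
  d_meas <- d_true + with_local_seed(truth$seed,
                                     stats::rnorm(n_frames, sd = noise_sd))
  out <- list(time_min = t_min, diameter_true_um = d_true,
              diameter_um = d_meas, truth = truth)
  if (render_frames) {
    out$frames <- lapply(seq_len(n_frames), function(k) {
      if (d_true[k] <= 0) {
        new_image_set(list(ring = matrix(0, truth$size_px, truth$size_px)),
                      truth)
      } else {
        tr_k <- truth
        tr_k$seed <- truth$seed + k
        tr_k$geometry <- list(ring_diameters_nm = list(
          ring = d_true[k] * 1000))
        render_rings(tr_k)
      }
    })
  }
  out
}

#' Render a cell with a division ring and a cytoplasmic pool
#'
#' A disk-shaped cell of diameter \code{geometry$cell_diameter_nm} carries
#' fraction \code{geometry$ring_fraction} of the photon budget in a thin
#' ring of diameter \code{geometry$ring_diameter_nm}; the remainder is
#' spread uniformly over the cell disk. Ground-truth cell and ring masks
#' are attached for closed-loop quantification.
#'
#' @param truth A \code{\link{ground_truth}}.
#' @return A \code{cdv_image_set} with one channel \code{cell} and truth
#'   masks \code{cell_mask}, \code{ring_mask} (logical matrices).
#' @export
render_cell <- function(truth) {
  g <- truth$geometry
  f <- g$ring_fraction %||% 0.5
  stopifnot(f >= 0, f <= 1)
  cell_d_px <- (g$cell_diameter_nm %||% 1600) / truth$pixel_nm
  ring_d_px <- (g$ring_diameter_nm %||% 1000) / truth$pixel_nm
  if (ring_d_px > cell_d_px) stop("ring lies outside the cell mask")
  n <- truth$size_px
  ctr <- (n + 1) / 2
  s_px <- psf_sigma_px(truth)
  x <- matrix(rep(seq_len(n), n), n) - ctr
  y <- t(x)
  rr <- sqrt(x^2 + y^2)
  cell_mask <- rr <= cell_d_px / 2
  ring_mask <- abs(rr - ring_d_px / 2) <= max(1.5, s_px)
  cyto <- matrix(0, n, n)
  cyto[cell_mask] <- 1
  cyto <- convolve_sep(cyto, gauss_kernel(s_px))
  cyto <- cyto * ((1 - f) * truth$photon_budget / sum(cyto))
  ring <- render_annulus(n, ctr - 0.5, ctr - 0.5, ring_d_px / 2, s_px,
                         max(f, 1e-12) * truth$photon_budget)
  if (f <= 0) ring[] <- 0
  img <- apply_noise(cyto + ring, truth)
  out <- new_image_set(list(cell = img), truth)
  out$cell_mask <- cell_mask
  out$ring_mask <- ring_mask
  out
}

#' Write an image set as multi-channel TIFF plus a JSON truth sidecar
#'
#' @param set A \code{cdv_image_set}.
#' @param path Output TIFF path; the sidecar is written alongside with
#'   extension \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_image_set <- function(set, path) {
  imgs <- lapply(set$channels, function(ch) ch / max(ch, 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- sub("\\.tiff?$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(set$truth[setdiff(names(set$truth), "")],
                       sidecar, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
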