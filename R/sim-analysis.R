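# Trajectory reduction: axial filament-density profiles, spatial-separation
# scores, and membrane constriction traces.

#' Axial filament density profile
#'
#' Histogram of bead axial (z) coordinates of one species, pooled over the
#' analysis window (by default the final 20% of snapshots, taken as the
#' post-disassembly steady state), on uniform bins spanning the periodic
#' tube length. "Normalized" follows the convention of comparable peak
#' heights: each profile is scaled to unit maximum; unit-integral
#' normalisation is available by flag.
#'
#' @param traj A \code{cdv_trajectory}.
#' @param species Species label.
#' @param n_bins Number of axial bins.
#' @param window Fraction (0,1] of trailing snapshots to pool.
#' @param normalize "peak" (max = 1) or "integral" (sums to 1 over bins x
#'   bin width).
#' @return A \code{cdv_density_profile}: \code{bin_centers} (sigma),
#'   \code{density}, \code{species}, \code{bin_width}, \code{n_snapshots}.
#' @export
axial_density <- function(traj, species, n_bins = 32, window = 0.2,
                          normalize = c("peak", "integral")) {
  normalize <- match.arg(normalize)
  L <- traj$config$tube_length
  snaps <- traj$snapshots
  n_take <- max(1L, ceiling(length(snaps) * window))
  snaps <- snaps[seq(length(snaps) - n_take + 1L, length(snaps))]
  z <- unlist(lapply(snaps, function(s) {
    b <- s$beads[[species]]
    if (is.null(b)) numeric(0) else b[, 3] %% L
  }))
  if (!length(z))
    stop("species ", species, " absent from the entire analysis window")
  breaks <- seq(0, L, length.out = n_bins + 1)
  counts <- graphics::hist(z, breaks = breaks, plot = FALSE)$counts
  bw <- L / n_bins
  dens <- counts / (length(snaps))          # mean beads per bin
  dens <- switch(normalize,
                 peak = dens / max(dens),
                 integral = dens / (sum(dens) * bw))
  stopifnot(all(dens >= 0))
  if (normalize == "peak") stopifnot(abs(max(dens) - 1) < 1e-12)
  else stopifnot(abs(sum(dens) * bw - 1) < 1e-9)
  structure(list(bin_centers = breaks[-1] - bw / 2, density = dens,
                 species = species, bin_width = bw,
                 n_snapshots = length(snaps), normalize = normalize),
            class = "cdv_density_profile")
}

#' Aggregate density profiles across replicates
#'
#' @param profiles List of \code{cdv_density_profile} objects on identical
#'   bins (one per replicate).
#' @return List with \code{bin_centers}, \code{mean}, \code{sd} (per bin,
#'   across replicates) and \code{n_replicates}.
#' @export
aggregate_density <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  bc <- profiles[[1]]$bin_centers
  for (p in profiles)
    if (!isTRUE(all.equal(p$bin_centers, bc)))
      stop("profiles have mismatched bins")
  m <- do.call(rbind, lapply(profiles, `[[`, "density"))
  mu <- colMeans(m)
  # population SD: the dispersion of the replicate band around the mean
  s <- sqrt(colMeans(sweep(m, 2, mu)^2))
  list(bin_centers = bc, mean = mu, sd = s, n_replicates = nrow(m))
}

#' Overlap between two axial density profiles
#'
#' Profiles are rescaled to unit integral and the overlap
#' \eqn{\int \min(p_a, p_b)} is returned: 1 for identical profiles, 0 for
#' disjoint supports.
#'
#' @param a,b \code{cdv_density_profile} objects on identical bins.
#' @return Overlap in \[0, 1\].
#' @export
separation_score <- function(a, b) {
  if (!isTRUE(all.equal(a$bin_centers, b$bin_centers)))
    stop("profiles have mismatched bins")
  pa <- a$density / sum(a$density)
  pb <- b$density / sum(b$density)
  sum(pmin(pa, pb))
}

#' Membrane constriction trace
#'
#' For every snapshot the tube radius profile r(z) is computed as the mean
#' radial distance of membrane particles in uniform axial bins; the trace
#' records the minimum radius and the necks: local radius minima below
#' \code{threshold} times the nominal tube radius, with distinct necks
#' separated by at least one tube radius along z (periodic). An axial bin
#' left empty (membrane rupture) flags the trace and truncates it at that
#' snapshot.
#'
#' @param traj A \code{cdv_trajectory}.
#' @param n_bins Number of axial bins (default: one per 2 sigma).
#' @param threshold Neck detection threshold as a fraction of the nominal
#'   radius.
#' @param min_sep Minimum axial separation between distinct necks, sigma
#'   (default: one tube radius; reduced geometries pack neck structures
#'   closer and may need a finer resolution scale).
#' @return List with \code{trace} (data frame: time, min_radius,
#'   neck_count), \code{neck_positions} (list of numeric vectors, sigma),
#'   \code{ruptured} flag, and \code{radius_profiles} (matrix snapshots x
#'   bins).
#' @export
constriction_trace <- function(traj, n_bins = NULL, threshold = 0.9,
                               min_sep = NULL) {
  L <- traj$config$tube_length
  R0 <- traj$config$tube_radius
  if (is.null(min_sep)) min_sep <- R0
  if (is.null(n_bins)) n_bins <- max(8L, round(L / 2))
  breaks <- seq(0, L, length.out = n_bins + 1)
  bw <- L / n_bins
  rows <- list()
  necks <- list()
  profs <- list()
  ruptured <- FALSE
  for (k in seq_along(traj$snapshots)) {
    s <- traj$snapshots[[k]]
    z <- s$membrane[, 3] %% L
    r <- sqrt(s$membrane[, 1]^2 + s$membrane[, 2]^2)
    bin <- pmin(n_bins, pmax(1L, findInterval(z, breaks,
                                              rightmost.closed = TRUE)))
    cnt <- tabulate(bin, n_bins)
    if (any(cnt == 0)) { ruptured <- TRUE; break }
    rz <- as.numeric(tapply(r, factor(bin, levels = seq_len(n_bins)), mean))
    profs[[k]] <- rz
    nk <- find_necks(rz, breaks[-1] - bw / 2, L, threshold * R0, min_sep)
    rows[[k]] <- data.frame(time = s$time, min_radius = min(rz),
                            neck_count = length(nk))
    necks[[k]] <- nk
  }
  list(trace = do.call(rbind, rows), neck_positions = necks,
       ruptured = ruptured,
       radius_profiles = do.call(rbind, profs))
}

# local minima of a periodic radius profile below `cut`, merged so that
# distinct necks are at least `min_sep` apart along z
find_necks <- function(rz, centers, L, cut, min_sep) {
  n <- length(rz)
  lm <- which(rz < cut &
              rz <= rz[c(n, 1:(n - 1))] &
              rz <= rz[c(2:n, 1)])
  if (!length(lm)) return(numeric(0))
  # sort candidate minima by depth, greedily keep those far enough apart
  lm <- lm[order(rz[lm])]
  kept <- numeric(0)
  for (i in lm) {
    zi <- centers[i]
    if (!length(kept)) { kept <- zi; next }
    dz <- abs(zi - kept)
    dz <- pmin(dz, L - dz)
    if (all(dz >= min_sep)) kept <- c(kept, zi)
  }
  sort(kept)
}
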