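#' Scaled-down replica of the two-protocol division simulation
#'
#' Runs the pre-division arrangement both without disassembly (Vps4-minus:
#' empty schedule, all three species persist) and with CdvB removed part
#' way through the run (Vps4-plus), for every seed in \code{seeds}, then
#' aggregates the per-replicate axial density profiles (mean and SD per
#' bin), CdvB1/CdvB2 separation scores, neck counts and constriction
#' traces.
#'
#' @param seeds Integer vector of replicate seeds (at least 2).
#' @param config Base \code{\link{simulation_config}} (desk scale by
#'   default). The Vps4-plus branch removes CdvB at
#'   \code{cut_fraction * n_steps}.
#' @param cut_fraction Fraction of the run after which CdvB is removed in
#'   the Vps4-plus branch.
#' @param n_bins Bins for density profiles.
#' @param keep_trajectories Keep the full trajectories in the result
#'   (memory-heavy)?
#' @return A \code{cdv_fig5_report}: per-branch profiles (replicates,
#'   mean, SD), separation scores, neck counts, minimum radii, failures.
#' @export
run_fig5_replica <- function(seeds, config = NULL, cut_fraction = 0.3,
                             n_bins = 24, keep_trajectories = FALSE) {
  stopifnot(length(seeds) >= 2)
  if (is.null(config)) config <- simulation_config()
  cut_step <- as.integer(round(config$n_steps * cut_fraction))
  branches <- list(
    vps4_minus = NULL,
    vps4_plus = data.frame(step = cut_step, species = "CdvB",
                           stringsAsFactors = FALSE))
  out <- list(config = config, seeds = seeds, cut_step = cut_step)
  for (br in names(branches)) {
    profs <- list(); traces <- list(); fails <- c(); trajs <- list()
    for (si in seq_along(seeds)) {
      cfg <- config
      cfg$seed <- as.integer(seeds[si])
      cfg$schedule <- branches[[br]]
      res <- tryCatch({
        traj <- run_protocol(cfg)
        sp_present <- if (br == "vps4_plus") c("CdvB1", "CdvB2")
                      else c("CdvB", "CdvB1", "CdvB2")
        prof <- lapply(stats::setNames(sp_present, sp_present),
                       function(sp) axial_density(traj, sp, n_bins))
        tr <- constriction_trace(traj)
        list(prof = prof, trace = tr,
             traj = if (keep_trajectories) traj else NULL)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails <- c(fails, stats::setNames(conditionMessage(res),
                                          seeds[si]))
      } else {
        profs[[length(profs) + 1]] <- res$prof
        traces[[length(traces) + 1]] <- res$trace
        if (keep_trajectories) trajs[[length(trajs) + 1]] <- res$traj
      }
    }
    agg <- lapply(stats::setNames(names(profs[[1]]), names(profs[[1]])),
                  function(sp)
                    aggregate_density(lapply(profs, `[[`, sp)))
    sep <- vapply(profs, function(p)
      if (all(c("CdvB1", "CdvB2") %in% names(p)))
        separation_score(p$CdvB1, p$CdvB2) else NA_real_, numeric(1))
    lastrow <- function(tr) tr$trace[nrow(tr$trace), ]
    out[[br]] <- list(
      profiles = profs, aggregated = agg, separation = sep,
      neck_count = vapply(traces, function(tr) lastrow(tr)$neck_count,
                          numeric(1)),
      min_radius = vapply(traces, function(tr) lastrow(tr)$min_radius,
                          numeric(1)),
      min_radius_t = do.call(rbind, lapply(traces, function(tr)
        tr$trace$min_radius)),
      times = traces[[1]]$trace$time,
      failures = fails,
      trajectories = if (keep_trajectories) trajs else NULL)
  }
  class(out) <- "cdv_fig5_report"
  out
}

#' @export
print.cdv_fig5_report <- function(x, ...) {
  cat(sprintf("<cdv_fig5_report> %d seeds, CdvB removed at step %d (Vps4+)\n",
              length(x$seeds), x$cut_step))
  for (br in c("vps4_minus", "vps4_plus")) {
    b <- x[[br]]
    cat(sprintf("  %s: min radius %.2f +/- %.2f sigma, necks %s\n",
                br, mean(b$min_radius), stats::sd(b$min_radius),
                paste(b$neck_count, collapse = ",")))
  }
  invisible(x)
}

#' Machine-readable summary of a replica report
#'
#' @param report A \code{cdv_fig5_report}.
#' @param path Optional CSV output path.
#' @return Data frame (one row per seed and branch).
#' @export
summarize_fig5_report <- function(report, path = NULL) {
  rows <- list()
  for (br in c("vps4_minus", "vps4_plus")) {
    b <- report[[br]]
    rows[[br]] <- data.frame(
      branch = br, seed = report$seeds[seq_along(b$min_radius)],
      min_radius = b$min_radius, neck_count = b$neck_count,
      separation = b$separation)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
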