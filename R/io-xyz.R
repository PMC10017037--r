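# Extended-XYZ trajectory export/import. One frame per snapshot; membrane
# particles use type MEM, filament beads their species label; directors are
# written as extra per-atom columns. A YAML comment header embeds the
# config hash and seed so outputs are traceable to their configuration.

#' Write a trajectory as extended XYZ
#'
#' @param traj A \code{cdv_trajectory}.
#' @param path Output file path (plain text).
#' @return \code{path}, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hash <- config_hash(traj$config)
  for (s in traj$snapshots) {
    types <- c(rep("MEM", nrow(s$membrane)),
               rep(names(s$beads), vapply(s$beads, nrow, integer(1))))
    pos <- rbind(s$membrane, do.call(rbind, unname(s$beads)))
    dirs <- rbind(s$directors,
                  matrix(0, nrow(pos) - nrow(s$directors), 3))
    writeLines(as.character(nrow(pos)), con)
    writeLines(sprintf(
      paste0("Lattice=\"50 0 0 0 50 0 0 0 %g\" ",
             "Properties=species:S:1:pos:R:3:dir:R:3 ",
             "Time=%g ConfigHash=%s Seed=%d"),
      traj$config$tube_length, s$time, hash, traj$config$seed), con)
    writeLines(sprintf("%s %.6f %.6f %.6f %.4f %.4f %.4f",
                       types, pos[, 1], pos[, 2], pos[, 3],
                       dirs[, 1], dirs[, 2], dirs[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory written by \code{write_trajectory_xyz}
#'
#' @param path File path.
#' @return List of frames, each with \code{time}, \code{types},
#'   \code{positions}, \code{directors}.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    header <- lines[i + 1]
    tm <- as.numeric(sub(".*Time=([0-9.eE+-]+).*", "\\1", header))
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(body, " +")
    types <- vapply(parts, `[[`, "", 1)
    num <- t(vapply(parts, function(p) as.numeric(p[2:7]), numeric(6)))
    frames[[length(frames) + 1]] <- list(
      time = tm, types = types,
      positions = num[, 1:3, drop = FALSE],
      directors = num[, 4:6, drop = FALSE])
    i <- i + 2L + n
  }
  frames
}

#' Write per-species density profiles as long-format CSV
#'
#' One row per (replicate, species, bin): columns replicate, species,
#' bin_center, density.
#'
#' @param profiles Nested list: per replicate, a named list of
#'   \code{cdv_density_profile} objects.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- list()
  for (rep_i in seq_along(profiles)) {
    for (sp in names(profiles[[rep_i]])) {
      p <- profiles[[rep_i]][[sp]]
      rows[[length(rows) + 1]] <- data.frame(
        replicate = rep_i, species = sp,
        bin_center = p$bin_centers, density = p$density)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
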