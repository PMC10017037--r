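# shared configuration for the end-to-end division-replica checks: a
# reduced desk-scale geometry (radius 6 sigma, ~1100 membrane particles)
# so a 10-seed two-protocol panel fits in the test run; species keep the
# full-scale preferred-radius ratios and published stiffness ratios

replica_test_config <- function(seed = 1L, inverted = FALSE,
                                n_steps = 16000L, cut_step = 4000L,
                                vps4_plus = TRUE) {
  tube <- 6
  species <- fig5_species(tube)
  arrangement <- fig5_arrangement(tube, ring_gap = 1.0, inverted = inverted)
  simulation_config(
    tube_radius = tube, tube_length = 4 * tube,
    membrane_spacing = 0.90,
    species = species, arrangement = arrangement,
    n_steps = n_steps, snap_every = max(1000L, n_steps %/% 8),
    seed = as.integer(seed),
    schedule = if (vps4_plus)
      data.frame(step = as.integer(cut_step), species = "CdvB") else NULL)
}

# the two-protocol panel is expensive; run it once per test session and
# share the reductions between the constriction and arrangement checks
replica_panel_cache <- new.env(parent = emptyenv())

replica_panel <- function(seeds = 1:10) {
  key <- paste0("panel_", paste(seeds, collapse = "_"))
  if (!is.null(replica_panel_cache[[key]])) return(replica_panel_cache[[key]])
  res <- list(min_plus = numeric(0), min_minus = numeric(0),
              necks_out = integer(0), necks_in = integer(0),
              b1 = list(), b2 = list(), radius_final = list())
  for (seed in seeds) {
    trp <- run_protocol(replica_test_config(seed = seed))
    ctp <- constriction_trace(trp, min_sep = 3)
    res$min_plus <- c(res$min_plus,
                      ctp$trace$min_radius[nrow(ctp$trace)])
    res$necks_out <- c(res$necks_out,
                       ctp$trace$neck_count[nrow(ctp$trace)])
    res$b1[[length(res$b1) + 1]] <- axial_density(trp, "CdvB1", 24)
    res$b2[[length(res$b2) + 1]] <- axial_density(trp, "CdvB2", 24)
    res$radius_final[[length(res$radius_final) + 1]] <-
      ctp$radius_profiles[nrow(ctp$radius_profiles), ]
    trm <- run_protocol(replica_test_config(seed = seed,
                                            vps4_plus = FALSE))
    ctm <- constriction_trace(trm, min_sep = 3)
    res$min_minus <- c(res$min_minus,
                       ctm$trace$min_radius[nrow(ctm$trace)])
    tri <- run_protocol(replica_test_config(seed = seed, inverted = TRUE))
    cti <- constriction_trace(tri, min_sep = 3)
    res$necks_in <- c(res$necks_in,
                      cti$trace$neck_count[nrow(cti$trace)])
  }
  replica_panel_cache[[key]] <- res
  res
}
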