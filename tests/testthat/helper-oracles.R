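# Shared fixtures and independent oracles for the test suite.

ovcar3_geom <- function() cell_line("OVCAR-3")$geometry

# hand-built population (bypasses the generator)
make_pop <- function(centers, cell_radius, nucleus_radius, spheroid_radius,
                     geometry = ovcar3_geom()) {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  structure(list(spheroid_radius = spheroid_radius,
                 target_compaction = NA, achieved_compaction = NA,
                 compaction_se = NA,
                 cells = data.frame(id = seq_len(n),
                                    x = centers[, 1], y = centers[, 2],
                                    z = centers[, 3],
                                    cell_radius = rep_len(cell_radius, n),
                                    nucleus_radius = rep_len(nucleus_radius,
                                                             n)),
                 seed = 0L, geometry = geometry),
            class = "cell_population")
}

# analytic volume of the intersection of two equal spheres (radius r,
# center distance d)
sphere_intersection_volume <- function(r, d) {
  if (d >= 2 * r) return(0)
  pi / 12 * (4 * r + d) * (2 * r - d)^2
}

# brute-force pure-R tracer: all-pairs ray/sphere intersection, energies via
# the package's R-side interpolators (code path independent of the C++ core)
r_trace_oracle <- function(events, pop, table = range_table()) {
  cr <- list()
  cells <- pop$cells
  for (i in seq_len(nrow(events))) {
    o <- as.numeric(events[i, c("x", "y", "z")])
    d <- as.numeric(events[i, c("dx", "dy", "dz")])
    E0 <- events$energy[i]
    smax <- csda_range(E0, table)
    oc <- sweep(as.matrix(cells[, c("x", "y", "z")]), 2, o)  # c - o
    b <- (oc %*% d)[, 1]                                     # = -d.(o - c)
    c2 <- rowSums(oc^2) - cells$nucleus_radius^2
    disc <- b^2 - c2
    hit <- which(disc > 0)
    for (j in hit) {
      t1 <- b[j] - sqrt(disc[j]); t2 <- b[j] + sqrt(disc[j])
      tin <- max(t1, 0); tout <- min(t2, smax)
      if (tout <= tin + 1e-12) next
      Ei <- residual_energy(E0, tin, table)
      if (Ei <= 0) next
      cr[[length(cr) + 1L]] <- data.frame(
        track = i, cell = cells$id[j], tin = tin,
        Ei = Ei, Ef = residual_energy(E0, tout, table),
        chord = tout - tin)
    }
  }
  if (!length(cr)) return(data.frame(track = integer(), cell = integer(),
                                     tin = numeric(), Ei = numeric(),
                                     Ef = numeric(), chord = numeric()))
  out <- do.call(rbind, cr)
  out[order(out$track, out$tin, out$cell), ]
}

# one irradiation configuration of the isolated reference cell; returns the
# population-mean nucleus specific energy
single_cell_zn <- function(pop, icrd, decays, seed) {
  r <- simulate_config(pop, icrd, activity_model(
    mean_decays_to_activity(decays, "At-211"), "uniform"), "At-211", seed)
  mean(r$tally$cells$Zn)
}
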