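# Config-driven experiment drivers: the reference irradiation, parametric
# sweeps, and the pipeline closures consumed by the activity-for-TCP search.

ICRD_KINDS <- c("membrane", "cytoplasm", "homogeneous", "nucleus")

#' Reference experiment configuration
#'
#' The default irradiated system and irradiation: 95 um spheroid at 75%
#' compaction, OVCAR-3 cell geometry with HSG reference photon coefficients,
#' At-211, uniform intratumoral activity of 1.12 mBq per cell (42 decays),
#' membrane distribution, no daughter diffusion.
#'
#' @param seed master seed.
#' @param configs irradiation configurations per point.
#' @return An `experiment_config` list; fields can be overridden before use.
#' @export
reference_config <- function(seed = 1L, configs = 3L) {
  structure(list(radius = 95, compaction = 0.75,
                 geometry = cell_line("OVCAR-3")$geometry,
                 photon_ref = photon_reference("furusawa"),
                 nuclide = "At-211",
                 icrd = "membrane",
                 ita = activity_model(1.12, "uniform"),
                 diffusion = diffusion_params(enabled = FALSE),
                 configs = configs, seed = seed),
            class = "experiment_config")
}

#' Run one irradiation configuration
#'
#' Draws per-cell decay counts, places and emits decays, traces them and
#' tallies dose; optionally computes per-cell survival under a Charlton
#' model.
#'
#' @param pop a `cell_population`.
#' @param icrd intracellular distribution kind.
#' @param ita an [activity_model()].
#' @param nuclide a `radionuclide` or its name.
#' @param seed configuration seed.
#' @param diffusion optional [diffusion_params()].
#' @param params optional [charlton_params()] for survival.
#' @param table a [range_table()].
#' @return List with `tally`, `trace`, `counts` and (with `params`)
#'   `survival`.
#' @export
simulate_config <- function(pop, icrd, ita, nuclide, seed,
                            diffusion = NULL, params = NULL,
                            table = .default_range_table()) {
  set.seed(seed)
  counts <- counts_per_cell(ita, nrow(pop$cells), nuclide)
  if (sum(counts) == 0) {
    n <- nrow(pop$cells)
    return(list(tally = list(cells = data.frame(id = pop$cells$id,
                                                z_self = 0, z_cross = 0,
                                                Zn = 0, Cn = 0),
                             spheroid_energy = 0, dose = 0),
                trace = NULL, counts = counts,
                survival = if (!is.null(params))
                  data.frame(cell = seq_len(n), n_lethal = 0, S = 1)))
  }
  dif <- if (!is.null(diffusion) && diffusion$enabled) diffusion
  ev <- make_decay_events(pop, icrd, counts, nuclide, dif)
  tr <- trace_alphas(ev, pop, table)
  out <- list(tally = tally_dose(tr, pop), trace = tr, counts = counts)
  if (!is.null(params))
    out$survival <- survival_charlton(tr$crossings, params,
                                      nrow(pop$cells),
                                      .nanotarget_scale(pop))
  out
}

# nanotarget-density normalization relative to the line's nominal nucleus
.nanotarget_scale <- function(pop)
  (pop$geometry$max_nucleus_radius / pop$cells$nucleus_radius)^3

#' Run the reference irradiation over intracellular distributions
#'
#' For each requested distribution and replicate configuration: population
#' mean nucleus specific energy `Zn`, mean cross-fire fraction `Cn`, spheroid
#' dose `D`, and (when a survival model is supplied) mean survival, TCP and
#' RBE.
#'
#' @param config an [reference_config()]-style `experiment_config`.
#' @param icrds distributions to run (default all four).
#' @param pop optional pre-generated population (otherwise generated from
#'   the config).
#' @param params optional [charlton_params()].
#' @return Long-format data.frame, one row per (icrd, replicate).
#' @export
run_reference <- function(config = reference_config(),
                          icrds = ICRD_KINDS, pop = NULL, params = NULL) {
  if (is.null(pop))
    pop <- generate_spheroid(config$radius, config$compaction,
                             config$geometry, config$seed)
  rows <- list()
  for (icrd in icrds) {
    for (rep in seq_len(config$configs)) {
      s <- config$seed + 7919L * match(icrd, ICRD_KINDS) + rep
      res <- simulate_config(pop, icrd, config$ita, config$nuclide, s,
                             config$diffusion, params)
      row <- data.frame(icrd = icrd, replicate = rep, seed = s,
                        n_cells = nrow(pop$cells),
                        mean_Zn = mean(res$tally$cells$Zn),
                        mean_Cn = mean(res$tally$cells$Cn),
                        dose = res$tally$dose)
      if (!is.null(params)) {
        row$mean_S <- mean(res$survival$S)
        row$tcp <- as.numeric(tcp(res$survival$S))
        row$rbe <- if (row$mean_S > 0 && row$mean_S < 1 && row$dose > 0)
          rbe(row$mean_S, row$dose, config$photon_ref) else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Run a parametric sweep
#'
#' Each grid row overrides fields of the base configuration (recognized
#' columns: `radius`, `compaction`, `cell_line`, `nuclide`, `icrd`, `apc`,
#' `ita_kind`, `sigma`, `diffusion`). Point seeds are derived
#' deterministically from the master seed and the row index, every output row
#' carries its seed, and a failing point is recorded (column `error`) while
#' the sweep continues.
#'
#' @param config base `experiment_config`.
#' @param grid data.frame of parameter points.
#' @param params optional [charlton_params()] for biological endpoints.
#' @return Long-format data.frame, one row per (point, replicate), with the
#'   realized parameter values.
#' @export
run_sweep <- function(config = reference_config(), grid, params = NULL) {
  stopifnot(nrow(grid) >= 1)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + 104729L * i
    if (!is.null(g$radius)) cfg$radius <- g$radius
    if (!is.null(g$compaction)) cfg$compaction <- g$compaction
    if (!is.null(g$cell_line)) cfg$geometry <- cell_line(g$cell_line)$geometry
    if (!is.null(g$nuclide)) cfg$nuclide <- as.character(g$nuclide)
    if (!is.null(g$apc) || !is.null(g$ita_kind) || !is.null(g$sigma))
      cfg$ita <- activity_model(
        if (!is.null(g$apc)) g$apc else cfg$ita$mean_apc,
        if (!is.null(g$ita_kind)) as.character(g$ita_kind) else cfg$ita$kind,
        if (!is.null(g$sigma)) g$sigma else cfg$ita$sigma)
    if (!is.null(g$diffusion))
      cfg$diffusion <- diffusion_params(enabled = isTRUE(g$diffusion))
    icrds <- if (!is.null(g$icrd)) as.character(g$icrd) else cfg$icrd
    res <- tryCatch({
      out <- run_reference(cfg, icrds = icrds, params = params)
      out$point <- i
      out$error <- NA_character_
      cbind(out, g[rep(1, nrow(out)), , drop = FALSE], row.names = NULL)
    }, error = function(e) {
      cbind(data.frame(icrd = icrds[1], replicate = NA, seed = cfg$seed,
                       n_cells = NA, mean_Zn = NA, mean_Cn = NA, dose = NA,
                       point = i, error = conditionMessage(e)),
            g, row.names = NULL)
    })
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Pipeline closure for the activity-for-TCP search
#'
#' Builds the `function(apc, seed)` closure consumed by
#' [find_activity_for_tcp()]: one irradiation configuration of `pop` at the
#' given activity, returning per-cell survivals and the spheroid dose.
#'
#' @param pop a `cell_population`.
#' @param icrd intracellular distribution kind.
#' @param params a calibrated [charlton_params()].
#' @param nuclide a `radionuclide` or its name.
#' @param ita_kind,sigma intratumoral activity model.
#' @param table a [range_table()].
#' @return A closure `function(apc, seed) -> list(S, dose)`.
#' @export
tcp_pipeline <- function(pop, icrd, params, nuclide = "At-211",
                         ita_kind = "uniform", sigma = 2,
                         table = .default_range_table()) {
  force(pop); force(icrd); force(params)
  function(apc, seed) {
    res <- simulate_config(pop, icrd, activity_model(apc, ita_kind, sigma),
                           nuclide, seed, params = params, table = table)
    list(S = res$survival$S, dose = res$tally$dose)
  }
}

#' Deterministic fixture populations
#'
#' Tiny hand-built populations for tests and cross-implementation
#' comparison: a single isolated cell at the origin, a pair of touching
#' cells, or a small cubic grid.
#'
#' @param kind `"single"`, `"pair"` or `"grid"`.
#' @param geometry a [cell_line_geometry()].
#' @param spheroid_radius enclosing radius (um); default fits the fixture.
#' @return A `cell_population`.
#' @export
fixture_population <- function(kind = c("single", "pair", "grid"),
                               geometry = cell_line("OVCAR-3")$geometry,
                               spheroid_radius = NULL) {
  kind <- match.arg(kind)
  rc <- geometry$max_cell_radius
  rn <- geometry$max_nucleus_radius
  centers <- switch(kind,
                    single = matrix(0, 1, 3),
                    pair = rbind(c(-rc, 0, 0), c(rc, 0, 0)),
                    grid = as.matrix(expand.grid(x = c(-rc, rc),
                                                 y = c(-rc, rc),
                                                 z = c(-rc, rc))) * 1.05)
  R <- if (is.null(spheroid_radius))
    max(sqrt(rowSums(centers^2))) + rc + 1 else spheroid_radius
  n <- nrow(centers)
  cells <- data.frame(id = seq_len(n), x = centers[, 1], y = centers[, 2],
                      z = centers[, 3], cell_radius = rc,
                      nucleus_radius = rn)
  structure(list(spheroid_radius = R, target_compaction = NA,
                 achieved_compaction = NA, compaction_se = NA,
                 cells = cells, seed = 0L, geometry = geometry),
            class = "cell_population")
}
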