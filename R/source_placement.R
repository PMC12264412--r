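# Decay-count assignment per cell (uniform or lognormal intratumoral
# activity) and uniform decay-position sampling per intracellular
# radionuclide distribution (ICRD).

#' Activity model (intratumoral activity distribution)
#'
#' @param mean_apc mean activity per cell (mBq), non-negative.
#' @param kind `"uniform"` (every cell carries the same activity) or
#'   `"lognormal"` (cell activities follow a lognormal law whose arithmetic
#'   mean equals `mean_apc`).
#' @param sigma lognormal shape factor (default 2, matching alpha-camera
#'   uptake measurements); ignored for the uniform kind.
#' @return An `activity_model` object.
#' @export
activity_model <- function(mean_apc, kind = c("uniform", "lognormal"),
                           sigma = 2.0) {
  kind <- match.arg(kind)
  stopifnot(mean_apc >= 0, kind != "lognormal" || sigma > 0)
  structure(list(mean_apc = mean_apc, kind = kind, sigma = sigma),
            class = "activity_model")
}

# stochastic rounding: expectation-preserving integer conversion
.stochastic_round <- function(x) {
  f <- floor(x)
  as.integer(f + rbinom(length(x), 1L, x - f))
}

#' Decay counts per cell
#'
#' Converts the activity model into integer decay counts: uniform activity
#' gives every cell the rounded mean decay number; lognormal activity draws a
#' continuous activity per cell with mean-preserving parameterization
#' (`meanlog = log(mean) - sigma^2/2`) and converts it to integers by
#' stochastic rounding, so the expected total matches the uniform case.
#'
#' @param model an [activity_model()].
#' @param n_cells number of cells (>= 1).
#' @param nuclide a `radionuclide` or its name (sets the activity-to-decay
#'   conversion through its half-life).
#' @return Integer vector of length `n_cells`.
#' @export
#' @examples
#' counts_per_cell(activity_model(1.12, "uniform"), 3, "At-211")  # 42 42 42
counts_per_cell <- function(model, n_cells, nuclide) {
  stopifnot(inherits(model, "activity_model"), n_cells >= 1)
  if (model$kind == "uniform") {
    m <- activity_to_mean_decays(model$mean_apc, nuclide)
    return(rep.int(as.integer(round(m)), n_cells))
  }
  if (model$mean_apc == 0) return(integer(n_cells))
  a <- rlnorm(n_cells,
              meanlog = log(model$mean_apc) - model$sigma^2 / 2,
              sdlog = model$sigma)
  .stochastic_round(activity_to_mean_decays(a, nuclide))
}

#' Sample decay positions per intracellular distribution
#'
#' Positions are uniform on/in the requested compartment of each cell:
#' `membrane` on the cell sphere surface, `cytoplasm` in the shell between
#' nucleus and cell radius, `nucleus` in the nucleus ball, `homogeneous` in
#' the whole cell ball.
#'
#' @param pop a `cell_population`.
#' @param icrd one of `"membrane"`, `"cytoplasm"`, `"homogeneous"`,
#'   `"nucleus"`.
#' @param counts integer decay count per cell (same order/length as
#'   `pop$cells`).
#' @return data.frame `cell, x, y, z, compartment` with one row per decay.
#' @export
place_decays <- function(pop, icrd = c("membrane", "cytoplasm",
                                       "homogeneous", "nucleus"), counts) {
  icrd <- match.arg(icrd)
  stopifnot(inherits(pop, "cell_population"),
            length(counts) == nrow(pop$cells))
  idx <- rep.int(seq_len(nrow(pop$cells)), counts)
  n <- length(idx)
  rn <- pop$cells$nucleus_radius[idx]
  rc <- pop$cells$cell_radius[idx]
  if (icrd == "cytoplasm" && any(pop$cells$nucleus_radius >=
                                 pop$cells$cell_radius - 1e-12))
    stop("cytoplasm distribution requested but the cytoplasm shell has zero ",
         "thickness (nucleus radius equals cell radius)", call. = FALSE)
  ctr <- as.matrix(pop$cells[idx, c("x", "y", "z")])
  draw <- function(m, rn, rc) {
    u <- runif(m)
    r <- switch(icrd,
                membrane = rc,
                nucleus = rn * u^(1 / 3),
                homogeneous = rc * u^(1 / 3),
                cytoplasm = (rn^3 + u * (rc^3 - rn^3))^(1 / 3))
    .runif_sphere(m) * r
  }
  pos <- draw(n, rn, rc) + ctr
  # nuclei are impenetrable organelles: positions of cytoplasm-overlapping
  # cells falling inside a *foreign* nucleus are redrawn (own-nucleus
  # positions are legitimate and, nuclei being disjoint, unambiguous)
  if (icrd != "nucleus" && nrow(pop$cells) > 1) {
    nuc_c <- as.matrix(pop$cells[, c("x", "y", "z")])
    nuc_r <- pop$cells$nucleus_radius
    bad_of <- function(p) {
      inside_any <- cpp_in_union(p, nuc_c, nuc_r)
      own <- rowSums((p - ctr)^2) <= rn^2
      inside_any & !own
    }
    bad <- bad_of(pos)
    tries <- 0L
    while (any(bad) && tries < 50L) {
      pos[bad, ] <- draw(sum(bad), rn[bad], rc[bad]) + ctr[bad, , drop = FALSE]
      bad <- bad_of(pos)
      tries <- tries + 1L
    }
  }
  data.frame(cell = pop$cells$id[idx],
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             compartment = rep(icrd, n))
}

#' Build complete decay events (position + emission)
#'
#' Convenience wrapper: [place_decays()] then [sample_emission()], optionally
#' followed by [apply_daughter_diffusion()].
#'
#' @inheritParams place_decays
#' @param nuclide a `radionuclide` or its name.
#' @param diffusion optional [diffusion_params()].
#' @return data.frame `cell, x, y, z, compartment, energy, dx, dy, dz,
#'   from_daughter`.
#' @export
make_decay_events <- function(pop, icrd, counts, nuclide, diffusion = NULL) {
  ev <- place_decays(pop, icrd, counts)
  ev <- cbind(ev, sample_emission(nuclide, nrow(ev)))
  if (!is.null(diffusion))
    ev <- apply_daughter_diffusion(ev, nuclide, diffusion, pop)
  ev
}

#' Export decay events as CSV
#'
#' Columns `cell_id,x,y,z,compartment,energy,dx,dy,dz` for replay and
#' cross-implementation comparison.
#'
#' @param events decay-event data.frame.
#' @param path file path.
#' @export
write_decay_events <- function(events, path) {
  out <- data.frame(cell_id = events$cell, x = events$x, y = events$y,
                    z = events$z, compartment = events$compartment,
                    energy = events$energy, dx = events$dx, dy = events$dy,
                    dz = events$dz)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
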