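# Alpha-emitter decay data, activity <-> cumulated-decay conversion,
# isotropic emission sampling, and daughter diffusion displacement.

#' Load alpha-emitter decay data
#'
#' Reads a structured-text (YAML) nuclide file. The packaged file ships
#' At-211 (default emitter), Po-210 (low-energy) and Po-213 (high-energy);
#' user files in the same schema are accepted.
#'
#' @param path YAML file; defaults to the packaged data.
#' @return Named list of `radionuclide` objects.
#' @export
load_nuclides <- function(path = system.file("extdata", "nuclides.yaml",
                                             package = "alphasphere")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw$nuclides, function(nd) {
    lines <- do.call(rbind, lapply(nd$lines, as.data.frame))
    stopifnot(all(lines$energy_MeV > 0), all(lines$intensity > 0),
              nd$daughter$branch >= 0, nd$daughter$branch <= 1)
    lines$intensity <- lines$intensity / sum(lines$intensity)
    structure(list(name = nd$name,
                   half_life = nd$half_life_s,
                   lines = lines,
                   daughter_branch = nd$daughter$branch,
                   daughter_half_life = nd$daughter$half_life_s,
                   daughter_diffusible = isTRUE(nd$daughter$diffusible)),
              class = "radionuclide")
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Look up a packaged radionuclide by name
#'
#' @param name nuclide name, e.g. `"At-211"`; an explicit failure is raised
#'   for unknown names. A `radionuclide` object passes through unchanged.
#' @return A `radionuclide` object.
#' @export
#' @examples
#' nuclide("At-211")$half_life / 3600
nuclide <- function(name) {
  if (inherits(name, "radionuclide")) return(name)
  if (is.null(.pkg_env$nuclides)) .pkg_env$nuclides <- load_nuclides()
  if (!name %in% names(.pkg_env$nuclides))
    stop("unknown radionuclide: ", name, call. = FALSE)
  .pkg_env$nuclides[[name]]
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> %s | t1/2 %.4g s | %d alpha line(s)\n",
              x$name, x$half_life, nrow(x$lines)))
  invisible(x)
}

#' Convert activity per cell to mean cumulated decays (and back)
#'
#' Under instantaneous uptake and complete decay of the initial activity, the
#' cumulated number of decays is N = A0 * t_half / ln 2.
#'
#' @param apc activity per cell (mBq), non-negative.
#' @param nuclide a `radionuclide` or its name.
#' @return Mean number of decays (not rounded).
#' @export
#' @examples
#' round(activity_to_mean_decays(1.12, "At-211"))  # 42
activity_to_mean_decays <- function(apc, nuclide) {
  stopifnot(all(apc >= 0))
  nd <- nuclide(nuclide)
  apc * 1e-3 * nd$half_life / log(2)
}

#' @rdname activity_to_mean_decays
#' @param decays mean cumulated decay count.
#' @export
mean_decays_to_activity <- function(decays, nuclide) {
  stopifnot(all(decays >= 0))
  nd <- nuclide(nuclide)
  decays * log(2) / nd$half_life * 1e3
}

# isotropic unit vectors, n x 3
.runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(dx = s * cos(phi), dy = s * sin(phi), dz = z)
}

#' Sample alpha emissions
#'
#' Draws emission energies from the nuclide's alpha lines (intensities
#' normalized to 1) and isotropic unit directions.
#'
#' @param nuclide a `radionuclide` or its name.
#' @param n number of emissions.
#' @return A data.frame with `energy` (MeV), `dx`, `dy`, `dz` (unit vector)
#'   and `from_daughter` (logical).
#' @export
sample_emission <- function(nuclide, n = 1L) {
  nd <- nuclide(nuclide)
  stopifnot(nrow(nd$lines) >= 1)
  idx <- sample.int(nrow(nd$lines), n, replace = TRUE,
                    prob = nd$lines$intensity)
  data.frame(energy = nd$lines$energy_MeV[idx],
             .runif_sphere(n),
             from_daughter = as.logical(nd$lines$from_daughter[idx]))
}

#' Daughter diffusion parameters
#'
#' @param diffusion_coefficient diffusion coefficient D (um^2/s); the default
#'   1000 um^2/s corresponds to the 1e-5 cm^2/s scale of small solutes in
#'   water and is a configuration value, not a measured constant.
#' @param enabled logical; disabled parameters make
#'   [apply_daughter_diffusion()] the identity.
#' @param mode `"3d"` (independent Gaussian displacement per axis, mean
#'   squared displacement 6 D t) or `"1d"` (single Gaussian displacement
#'   along an isotropic direction, MSD 2 D t).
#' @return A `diffusion_params` object.
#' @export
diffusion_params <- function(diffusion_coefficient = 1000, enabled = TRUE,
                             mode = c("3d", "1d")) {
  stopifnot(diffusion_coefficient >= 0)
  structure(list(D = diffusion_coefficient, enabled = enabled,
                 mode = match.arg(mode)),
            class = "diffusion_params")
}

# fold a radius into [lo, hi] by reflection
.reflect_radius <- function(r, lo, hi) {
  w <- hi - lo
  r <- abs(r - lo) %% (2 * w)
  lo + ifelse(r > w, 2 * w - r, r)
}

# rescale offset rows to a new radius
.set_radius <- function(off, r_new) {
  r <- sqrt(rowSums(off^2))
  bad <- r < 1e-12
  if (any(bad)) {
    off[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE)
    r[bad] <- 1
  }
  off * (r_new / r)
}

#' Displace daughter decays by thermal diffusion
#'
#' For the fraction of decays routed through a short-lived diffusible
#' daughter, draws a decay time from the exponential law of the daughter
#' half-life and a Gaussian thermal displacement, then constrains the final
#' position: intracellular sources (cytoplasm, nucleus, homogeneous) stay in
#' their original compartment of their own cell; membrane sources move in the
#' extracellular space without entering any cell. Constraints are enforced by
#' redrawing the displacement up to `max_retries` times, then by radial
#' reflection (membrane sources fall back to their original position).
#'
#' @param events decay-event data.frame from [place_decays()] /
#'   [make_decay_events()]; rows with `from_daughter = TRUE` are displaced.
#' @param nuclide a `radionuclide` or its name.
#' @param params a [diffusion_params()].
#' @param pop the `cell_population` providing the compartment geometry.
#' @param max_retries bounded rejection retries before reflection.
#' @return The events with updated positions.
#' @export
apply_daughter_diffusion <- function(events, nuclide, params, pop,
                                     max_retries = 100L) {
  nd <- nuclide(nuclide)
  if (!params$enabled || !nd$daughter_diffusible || nd$daughter_branch == 0)
    return(events)
  sel <- which(events$from_daughter)
  if (length(sel) == 0) return(events)

  n <- length(sel)
  t <- rexp(n, rate = log(2) / nd$daughter_half_life)
  sd1 <- sqrt(2 * params$D * t)
  draw <- function(keep) {
    m <- sum(keep)
    if (params$mode == "3d") {
      matrix(rnorm(3 * m, sd = rep(sd1[keep], 3)), ncol = 3)
    } else {
      .runif_sphere(m) * rnorm(m, sd = sd1[keep])
    }
  }

  cells <- pop$cells[match(events$cell[sel], pop$cells$id), ]
  ctr <- as.matrix(cells[, c("x", "y", "z")])
  rn <- cells$nucleus_radius
  rc <- cells$cell_radius
  comp <- as.character(events$compartment[sel])
  pos0 <- as.matrix(events[sel, c("x", "y", "z")])
  allc <- as.matrix(pop$cells[, c("x", "y", "z")])
  allr <- pop$cells$cell_radius

  ok_fun <- function(p) {
    off <- p - ctr
    r <- sqrt(rowSums(off^2))
    valid <- rep(TRUE, length(r))
    ic <- comp != "membrane"
    valid[comp == "nucleus"] <- r[comp == "nucleus"] <= rn[comp == "nucleus"]
    valid[comp == "homogeneous"] <-
      r[comp == "homogeneous"] <= rc[comp == "homogeneous"]
    valid[comp == "cytoplasm"] <- r[comp == "cytoplasm"] >=
      rn[comp == "cytoplasm"] & r[comp == "cytoplasm"] <= rc[comp ==
      "cytoplasm"]
    memb <- comp == "membrane"
    if (any(memb))  # strictly inside a cell sphere is a violation
      valid[memb] <- !.strictly_in_union(p[memb, , drop = FALSE], allc, allr)
    valid
  }

  pos <- pos0 + draw(rep(TRUE, n))
  ok <- ok_fun(pos)
  tries <- 0L
  while (any(!ok) && tries < max_retries) {
    pos[!ok, ] <- pos0[!ok, , drop = FALSE] + draw(!ok)
    ok <- ok_fun(pos)
    tries <- tries + 1L
  }
  if (any(!ok)) {         # reflection fallback
    bad <- which(!ok)
    for (i in bad) {
      off <- pos[i, ] - ctr[i, ]
      r <- sqrt(sum(off^2))
      newr <- switch(comp[i],
                     nucleus = .reflect_radius(r, 0, rn[i]),
                     homogeneous = .reflect_radius(r, 0, rc[i]),
                     cytoplasm = .reflect_radius(r, rn[i], rc[i]),
                     membrane = NA_real_)
      if (is.na(newr)) {
        pos[i, ] <- pos0[i, ]      # membrane: keep original surface point
      } else {
        pos[i, ] <- ctr[i, ] + .set_radius(matrix(off, 1), newr)
      }
    }
  }
  events[sel, c("x", "y", "z")] <- pos
  events
}

.strictly_in_union <- function(pts, centers, radii) {
  # shrink radii by a hair so membrane surface points do not self-flag
  cpp_in_union(pts, centers, radii - 1e-9)
}
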