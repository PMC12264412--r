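test_that("activity converts to cumulated decays by complete decay of the
          initial activity", {
  expect_equal(round(activity_to_mean_decays(1.12, "At-211")), 42)
  expect_equal(round(activity_to_mean_decays(0.40, "At-211")), 15)
  expect_equal(activity_to_mean_decays(0, "At-211"), 0)
  a <- c(0.027, 0.387, 1.12, 3)
  expect_equal(mean_decays_to_activity(
    activity_to_mean_decays(a, "At-211"), "At-211"), a, tolerance = 1e-12)
  expect_error(nuclide("Xx-999"), "unknown radionuclide")
})

test_that("packaged nuclide data match their evaluated decay properties", {
  at <- nuclide("At-211")
  expect_equal(at$half_life / 3600, 7.214, tolerance = 1e-6)
  expect_equal(sum(at$lines$intensity), 1)
  expect_equal(at$daughter_branch, 0.582)
  expect_equal(at$daughter_half_life, 0.516)
  expect_equal(nuclide("Po-210")$lines$energy_MeV, 5.304)
})

test_that("emission sampling reproduces line intensities and isotropy", {
  set.seed(42)
  n <- 1e5
  em <- sample_emission("At-211", n)
  at <- nuclide("At-211")
  e_mean <- sum(at$lines$energy_MeV * at$lines$intensity)
  se <- stats::sd(em$energy) / sqrt(n)
  expect_lt(abs(mean(em$energy) - e_mean), 3 * se)

  cnt <- table(em$energy)
  expect_gt(stats::chisq.test(cnt, p = at$lines$intensity[
    order(at$lines$energy_MeV)])$p.value, 0.001)

  # single-line emitter is deterministic in energy
  expect_true(all(sample_emission("Po-210", 1000)$energy == 5.304))

  # direction: unit norm, cos(theta) uniform on [-1, 1]
  expect_equal(rowSums(em[, c("dx", "dy", "dz")]^2), rep(1, n),
               tolerance = 1e-9)
  expect_lt(abs(mean(em$dz)), 3 / sqrt(3 * n))  # sd of U(-1,1) = 1/sqrt(3)
  expect_gt(suppressWarnings(stats::ks.test(em$dz, "punif", -1, 1))$p.value, 0.001)
  # daughter routing fraction matches the branch
  expect_lt(abs(mean(em$from_daughter) - at$daughter_branch),
            3 * sqrt(0.582 * 0.418 / n))
})

test_that("daughter diffusion is the identity when disabled, for D = 0 and
          for branchless nuclides", {
  pop <- make_pop(c(0, 0, 0), 6.9, 5.5, 10)
  set.seed(1)
  ev <- make_decay_events(pop, "cytoplasm", 200L, "At-211")
  off <- apply_daughter_diffusion(ev, "At-211",
                                  diffusion_params(enabled = FALSE), pop)
  expect_identical(off, ev)
  d0 <- apply_daughter_diffusion(ev, "At-211", diffusion_params(0), pop)
  expect_equal(d0[, c("x", "y", "z")], ev[, c("x", "y", "z")])
  po <- apply_daughter_diffusion(ev, "Po-210", diffusion_params(1000), pop)
  expect_identical(po, ev)
  # parent-line rows are never displaced
  moved <- apply_daughter_diffusion(ev, "At-211", diffusion_params(1000), pop)
  keep <- !ev$from_daughter
  expect_equal(moved[keep, c("x", "y", "z")], ev[keep, c("x", "y", "z")])
})

test_that("free diffusion reproduces the Brownian mean squared displacement
          with an exponential decay time", {
  # an absurdly large nucleus makes the compartment constraint inactive
  pop <- make_pop(c(0, 0, 0), 2e6, 1e6, 3e6)
  n <- 20000L
  ev <- data.frame(cell = 1L, x = 0, y = 0, z = 0, compartment = "nucleus",
                   energy = 7.45, dx = 1, dy = 0, dz = 0,
                   from_daughter = TRUE)[rep(1, n), ]
  at <- nuclide("At-211")
  D <- 500
  for (mode in c("3d", "1d")) {
    set.seed(7)
    out <- apply_daughter_diffusion(ev, at, diffusion_params(D, mode = mode),
                                    pop)
    sq <- out$x^2 + out$y^2 + out$z^2
    expected <- (if (mode == "3d") 6 else 2) * D * at$daughter_half_life /
      log(2)
    expect_lt(abs(mean(sq) - expected), 4 * stats::sd(sq) / sqrt(n))
  }
})

test_that("constrained diffusion never leaves the stated region", {
  set.seed(3)
  centers <- rbind(c(-7, 0, 0), c(7, 0, 0))
  pop <- make_pop(centers, 6.9, 5.5, 16)
  par <- diffusion_params(1000)
  for (comp in c("nucleus", "cytoplasm", "homogeneous", "membrane")) {
    ev <- make_decay_events(pop, comp, c(300L, 300L), "At-211")
    out <- apply_daughter_diffusion(ev, "At-211", par, pop)
    ctr <- centers[out$cell, ]
    r <- sqrt(rowSums((as.matrix(out[, c("x", "y", "z")]) - ctr)^2))
    if (comp == "nucleus") expect_true(all(r <= 5.5 + 1e-9))
    if (comp == "homogeneous") expect_true(all(r <= 6.9 + 1e-9))
    if (comp == "cytoplasm")
      expect_true(all(r >= 5.5 - 1e-9 & r <= 6.9 + 1e-9))
    if (comp == "membrane") {
      # never strictly inside any cell sphere
      d1 <- sqrt(rowSums((as.matrix(out[, c("x", "y", "z")]) -
                            matrix(centers[1, ], nrow(out), 3,
                                   byrow = TRUE))^2))
      d2 <- sqrt(rowSums((as.matrix(out[, c("x", "y", "z")]) -
                            matrix(centers[2, ], nrow(out), 3,
                                   byrow = TRUE))^2))
      expect_true(all(d1 >= 6.9 - 1e-6 & d2 >= 6.9 - 1e-6))
    }
  }
})
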