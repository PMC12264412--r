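test_that("range table reproduces the evaluated anchor and is strictly
          monotone", {
  tab <- range_table()
  expect_equal(csda_range(10), 113, tolerance = 0.02)
  expect_equal(csda_range(0), 0)
  e <- seq(0.05, 11.9, length.out = 200)
  expect_true(all(diff(csda_range(e)) > 0))
  expect_error(csda_range(15), "above the range-table span")
})

test_that("residual energy inverts the range and satisfies the semigroup
          property", {
  set.seed(10)
  E <- runif(50, 0.5, 9)
  expect_equal(residual_energy(E, 0), E, tolerance = 1e-9)
  expect_equal(residual_energy(E, csda_range(E)), rep(0, 50),
               tolerance = 1e-9)
  s1 <- runif(50, 0, 30); s2 <- runif(50, 0, 30)
  lhs <- residual_energy(E, s1 + s2)
  rhs <- residual_energy(residual_energy(E, s1), s2)
  expect_equal(lhs, rhs, tolerance = 2e-3)
  # residual energy decreases with path length
  expect_true(all(residual_energy(E, 5) <= residual_energy(E, 2)))
})

test_that("a decay at the nucleus center deposits the closed-form
          energy over one nucleus radius", {
  pop <- make_pop(c(0, 0, 0), 6.9, 5.5, 10)
  set.seed(12)
  dirs <- sample_emission("Po-210", 500)
  ev <- data.frame(cell = 1L, x = 0, y = 0, z = 0, compartment = "nucleus",
                   dirs)
  tr <- trace_alphas(ev, pop)
  expect_equal(nrow(tr$crossings), 500)
  expect_equal(tr$crossings$chord, rep(5.5, 500), tolerance = 1e-9)
  expect_equal(tr$crossings$Ei, rep(5.304, 500))
  expect_equal(tr$crossings$Ef,
               rep(residual_energy(5.304, 5.5), 500), tolerance = 1e-6)
  expect_true(all(tr$crossings$self))
})

test_that("tracks too short to reach any nucleus leave all energy outside
          nuclei", {
  pop <- make_pop(c(0, 0, 0), 6.9, 5.5, 40)
  # 1 MeV alpha (~6 um range) emitted 20 um from the nucleus
  ev <- data.frame(cell = 0L, x = 20, y = 0, z = 0,
                   compartment = "membrane", energy = 1,
                   dx = 1, dy = 0, dz = 0, from_daughter = FALSE)
  tr <- trace_alphas(ev, pop)
  expect_equal(nrow(tr$crossings), 0)
  expect_equal(tr$tracks$e_nuclear, 0)
  expect_equal(tr$tracks$e_extranuclear + tr$tracks$e_escaped, 1,
               tolerance = 1e-9)
})

test_that("grid-accelerated tracer is identical to brute force and matches
          the pure-R all-pairs oracle", {
  pop <- fixture_population("grid")
  set.seed(20)
  counts <- rep(60L, nrow(pop$cells))
  ev <- make_decay_events(pop, "homogeneous", counts, "At-211")
  g <- trace_alphas(ev, pop, method = "grid")
  b <- trace_alphas(ev, pop, method = "brute")
  expect_identical(g$crossings, b$crossings)
  expect_identical(g$tracks, b$tracks)

  oracle <- r_trace_oracle(ev, pop)
  expect_equal(nrow(g$crossings), nrow(oracle))
  expect_equal(g$crossings$cell, oracle$cell)
  expect_equal(g$crossings$track, oracle$track)
  expect_equal(g$crossings$Ei, oracle$Ei, tolerance = 1e-6)
  expect_equal(g$crossings$Ef, oracle$Ef, tolerance = 1e-6)
  expect_equal(g$crossings$chord, oracle$chord, tolerance = 1e-9)
})

test_that("energy is conserved exactly for every track", {
  pop <- fixture_population("pair")
  set.seed(21)
  ev <- make_decay_events(pop, "membrane", c(500L, 500L), "At-211")
  tr <- trace_alphas(ev, pop)
  dep <- rowsum(tr$crossings$Ei - tr$crossings$Ef, tr$crossings$track)
  nuc <- numeric(nrow(ev))
  nuc[as.integer(rownames(dep))] <- dep[, 1]
  total <- nuc + tr$tracks$e_extranuclear + tr$tracks$e_escaped
  expect_equal(total, ev$energy, tolerance = 1e-9)
  expect_equal(tr$tracks$e_nuclear, nuc, tolerance = 1e-12)
  expect_true(all(tr$tracks$e_extranuclear >= 0))
  expect_true(all(tr$crossings$Ei >= tr$crossings$Ef))
  expect_true(all(tr$crossings$Ef >= 0))
})

test_that("tally converts nucleus deposits to specific energy (1 MeV in a
          5.5 um nucleus is 0.230 Gy) and flags cross-fire", {
  pop <- make_pop(c(0, 0, 0), 6.9, 5.5, 10)
  fake <- list(crossings = data.frame(track = 1, cell = 1, Ei = 3, Ef = 2,
                                      chord = 2, self = TRUE),
               tracks = data.frame(e_nuclear = 1, e_extranuclear = 0,
                                   e_escaped = 0))
  ta <- tally_dose(fake, pop)
  expect_equal(ta$cells$Zn, 0.22989, tolerance = 1e-4)  # 1.602e-13 J / mass
  expect_equal(ta$cells$Cn, 0)

  # isolated cell: all ICRDs give pure self-dose
  set.seed(22)
  for (icrd in c("membrane", "nucleus")) {
    ev <- make_decay_events(pop, icrd, 200L, "At-211")
    ta <- tally_dose(trace_alphas(ev, pop), pop)
    expect_equal(ta$cells$Cn, 0)
    expect_equal(ta$cells$z_cross, 0)
  }
})

test_that("mono-cellular nucleus-source self-dose matches the analytic
          mean-chord expectation", {
  pop <- make_pop(c(0, 0, 0), 6.9, 5.5, 10)
  set.seed(23)
  n <- 20000L
  ev <- make_decay_events(pop, "nucleus", n, "Po-210")
  tr <- trace_alphas(ev, pop)
  dep <- tr$crossings$Ei - tr$crossings$Ef
  # independent oracle: sample interior chords analytically and slow down
  # through the package range table
  r <- 5.5 * runif(n)^(1 / 3)
  u <- runif(n, -1, 1)
  b <- -r * u
  chord <- -b + sqrt(b^2 - (r^2 - 5.5^2))
  dep_oracle <- 5.304 - residual_energy(5.304, chord)
  se <- sqrt(stats::sd(dep)^2 + stats::sd(dep_oracle)^2) / sqrt(n)
  expect_lt(abs(mean(dep) - mean(dep_oracle)), 3 * se)
})

test_that("tracing rejects malformed events", {
  pop <- make_pop(c(0, 0, 0), 6.9, 5.5, 10)
  ev <- data.frame(cell = 1L, x = 0, y = 0, z = 0, compartment = "nucleus",
                   energy = 6, dx = 2, dy = 0, dz = 0, from_daughter = FALSE)
  expect_error(trace_alphas(ev, pop), "unit vectors")
  ev$dx <- 1
  ev$x <- 100   # far outside the bounding sphere
  expect_error(trace_alphas(ev, pop), "bounding sphere")
  ev$x <- 0
  ev$energy <- 14
  expect_error(trace_alphas(ev, pop), "above the range-table span")
})
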