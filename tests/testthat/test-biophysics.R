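test_that("linear-quadratic photon survival and RBE invert each other", {
  furu <- photon_reference("furusawa")
  expect_equal(photon_survival(0, furu), 1)
  expect_equal(photon_survival(4.072, furu), 0.100, tolerance = 1e-3)
  expect_equal(rbe(0.1, 2.036, furu), 2.0, tolerance = 1e-3)

  # self-consistency: pure-alpha survival with the reference alpha gives
  # RBE = 1 when beta = 0
  ref0 <- reference_photon_params(0.313, 0, "beta0")
  D <- 2.5
  expect_equal(rbe(exp(-0.313 * D), D, ref0), 1, tolerance = 1e-12)

  # mutual inverses: rbe(photon_survival(R * D), D) = R
  set.seed(30)
  for (k in 1:10) {
    R <- runif(1, 0.5, 4); D <- runif(1, 0.5, 6)
    expect_equal(rbe(photon_survival(R * D, furu), D, furu), R,
                 tolerance = 1e-9)
  }
  expect_error(rbe(1, 2, furu), "undefined")
})

test_that("an RBE of 3.3 under the 140 kV reference maps to about 4.0 under
          the LINAC reference at 10% survival", {
  furu <- photon_reference("furusawa")
  aoki <- photon_reference("aoki-nakano")
  D <- 1.3  # any alpha dose: the ratio is dose-independent
  mapped <- 3.3 * rbe(0.1, D, aoki) / rbe(0.1, D, furu)
  expect_equal(mapped, 4.061, tolerance = 1e-3)  # quadratic-root oracle
})

test_that("lethal-function survival follows the cumulative-table contract", {
  none <- data.frame(track = numeric(), cell = numeric(), Ei = numeric(),
                     Ef = numeric(), chord = numeric(), self = logical())
  tab <- lethal_function_table(c(0, 10), c(0, 5))   # F_L = 0.5 * E
  expect_equal(survival_lethal_events(none, tab, 3)$S, rep(1, 3))

  one <- data.frame(track = 1, cell = 1, Ei = 6, Ef = 4.5, chord = 3,
                    self = TRUE)
  out <- survival_lethal_events(one, tab, 1)
  expect_equal(out$S, exp(-0.5 * 1.5))

  two <- rbind(one, data.frame(track = 2, cell = 1, Ei = 3, Ef = 1,
                               chord = 3, self = FALSE))
  expect_equal(survival_lethal_events(two, tab, 1)$S,
               exp(-0.5 * 1.5) * exp(-0.5 * 2))
  # global events add to local ones in the exponent
  tab2 <- lethal_function_table(c(0, 10), c(0, 5), F_G = c(0, 2))
  expect_equal(survival_lethal_events(one, tab2, 1)$S,
               exp(-(0.5 + 0.2) * 1.5))
  one$Ei <- 12
  expect_error(survival_lethal_events(one, tab, 1), "table span")
  expect_error(lethal_function_table(c(0, 10), c(0, -1)))
})

test_that("Charlton survival is exp(-chord/lambda) per crossing and its
          Poisson mean matches the closed form", {
  flat <- charlton_params(scale = 4, slope0_ratio = 1, plateau_ratio = 1)
  expect_equal(lambda_let(c(0, 50, 150, 300), flat), rep(4, 4))
  one <- data.frame(track = 1, cell = 1, Ei = 6, Ef = 5.8, chord = 3,
                    self = TRUE)
  expect_equal(survival_charlton(one, flat, 1)$S, exp(-3 / 4))
  expect_equal(survival_charlton(one[0, ], flat, 1)$S, 1)

  # Poisson(m) crossings of fixed chord T: E[S] = exp(-m (1 - e^(-T/lambda)))
  set.seed(31)
  n <- 30000L; m <- 2; T <- 3
  k <- stats::rpois(n, m)
  cr <- data.frame(track = 1, cell = rep(seq_len(n), k), Ei = 6, Ef = 5.8,
                   chord = T, self = TRUE)
  S <- survival_charlton(cr, flat, n)$S
  closed <- exp(-m * (1 - exp(-T / 4)))
  expect_lt(abs(mean(S) - closed), 3 * stats::sd(S) / sqrt(n))

  # volume normalization scales the event count
  expect_equal(survival_charlton(one, flat, 1, volume_scale = 2)$S,
               exp(-2 * 3 / 4))
})

test_that("lambda(LET) is piecewise linear with a plateau and the induced
          cumulative table reproduces the finite-difference survival", {
  p <- charlton_params(scale = 2, slope0_ratio = 3, plateau_ratio = 0.8)
  expect_equal(lambda_let(0, p), 6)
  expect_equal(lambda_let(100, p), 2)
  expect_equal(lambda_let(150, p), 1.8)   # linear bridge midpoint
  expect_equal(lambda_let(c(200, 500), p), c(1.6, 1.6))
  expect_true(all(diff(lambda_let(seq(0, 300, 5), p)) <= 0))

  tab <- lethal_table_from_charlton(p)
  expect_equal(tab$F_L[1], 0)
  expect_true(all(diff(tab$F_L) >= 0))
  pop <- make_pop(c(0, 0, 0), 6.9, 5.5, 10)
  set.seed(32)
  ev <- make_decay_events(pop, "nucleus", 400L, "At-211")
  cr <- trace_alphas(ev, pop)$crossings
  s_fd <- survival_charlton(cr, p, 1)$S
  s_tab <- survival_lethal_events(cr, tab, 1)$S
  expect_equal(log(s_tab), log(s_fd), tolerance = 0.05)
})

test_that("adding a crossing never increases survival", {
  p <- charlton_params(scale = 5)
  set.seed(33)
  cr <- data.frame(track = 1:20, cell = 1,
                   Ei = runif(20, 2, 8), chord = runif(20, 0.5, 8),
                   self = TRUE)
  cr$Ef <- pmax(cr$Ei - runif(20, 0.05, 1), 0)
  s_prev <- 1
  for (k in seq_len(20)) {
    s_k <- survival_charlton(cr[seq_len(k), ], p, 1)$S
    expect_lte(s_k, s_prev)
    s_prev <- s_k
  }
})

test_that("TCP is the product of kill probabilities, computed in log space", {
  expect_equal(as.numeric(tcp(c(0.5, 1, 0.2))), 0)
  expect_equal(as.numeric(tcp(rep(0, 100))), 1)
  est <- tcp(rep(0.1, 3069))
  expect_equal(attr(est, "log_per_config"), 3069 * log(0.9))
  expect_equal(as.numeric(est), 0)  # ~1e-141 underflows to 0 as expected
  multi <- tcp(list(rep(0.01, 10), rep(0.02, 10)))
  expect_equal(as.numeric(multi),
               mean(c(0.99^10, 0.98^10)), tolerance = 1e-12)
  expect_false(is.na(attr(multi, "se")))
})

test_that("activity bisection recovers thresholds of constructed survival
          models", {
  # degenerate model: a cell dies iff it carries at least one decay
  n <- 50
  pipe_count <- function(apc, seed) {
    cnt <- counts_per_cell(activity_model(apc, "uniform"), n, "At-211")
    list(S = as.numeric(cnt == 0), dose = apc)
  }
  thr <- mean_decays_to_activity(0.5, "At-211")  # rounding threshold
  out <- find_activity_for_tcp(pipe_count, bracket = c(0.001, 0.05),
                               tol = 1e-4, configs = 5, seed = 1)
  expect_lt(abs(out$activity - thr), 2e-4)
  expect_equal(out$tcp, 1)

  # closed-form S(APC): TCP = (1 - exp(-k A))^n = 0.9 inverts analytically
  k <- 8
  pipe_exp <- function(apc, seed) list(S = rep(exp(-k * apc), n), dose = apc)
  a_star <- -log(1 - 0.9^(1 / n)) / k
  out2 <- find_activity_for_tcp(pipe_exp, bracket = c(0.05, 2), tol = 1e-4,
                                configs = 3, seed = 1)
  expect_equal(out2$activity, a_star, tolerance = 2e-3)

  expect_error(find_activity_for_tcp(pipe_exp, bracket = c(0.0001, 0.001),
                                     configs = 2, seed = 1),
               "does not straddle")
})

test_that("calibration recovers a known lambda scale from generated
          endpoint data", {
  pop <- generate_spheroid(40, 0.4, ovcar3_geom(), seed = 6)
  true <- charlton_params(scale = 25)
  vs <- (pop$geometry$max_nucleus_radius / pop$cells$nucleus_radius)^3
  # measure the TCP this scale produces at a fixed activity...
  seeds <- 900 + 1:8
  S <- lapply(seeds, function(s) {
    res <- simulate_config(pop, "membrane", activity_model(0.5, "uniform"),
                           "At-211", s, params = true)
    res$survival$S
  })
  target <- as.numeric(tcp(S))
  expect_gt(target, 0.05); expect_lt(target, 0.999)
  # ...then re-fitting the scale against that TCP recovers it
  cal <- calibrate_charlton(pop, "membrane", "At-211", apc = 0.5,
                            target = target, configs = 8, seed = 900,
                            volume_scale = vs)
  expect_equal(cal$scale, 25, tolerance = 0.02)
})
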