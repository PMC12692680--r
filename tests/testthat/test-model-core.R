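ec_sscm <- strain_params("ecoli", mu_max = 1.02, K_S = 79.8,
                         Y_XS = 0.067, k_d = 4.8e-3)

test_that("strain and lysis parameter validation enforces the model's domain", {
  expect_error(strain_params("x", mu_max = -1, K_S = 1, Y_XS = 1, k_d = 0),
               "mu_max")
  expect_error(strain_params("x", 1, K_S = 0, Y_XS = 1, k_d = 0), "K_S")
  expect_error(strain_params("x", 1, 1, Y_XS = 1, k_d = 0,
                             is_product_producer = TRUE), "Y_XP")
  expect_error(strain_params("x", 1, 1, 1, 0, is_product_inhibited = TRUE),
               "K_P")
  expect_error(strain_params("x", 1, 1, 1, 0,
                             is_product_producer = TRUE, Y_XP = 1,
                             is_product_inhibited = TRUE, K_P = 1),
               "cannot be both")
  expect_error(lysis_params(-0.1), "k_s")
  expect_error(lysis_params(0.1, theta = -1), "theta")
})

test_that("scenario validation pins the time origin and strain bookkeeping", {
  lys <- lysis_params(0.1, 1)
  expect_error(
    culture_scenario(ec_sscm, lys, S0 = 1, inoculum = 0.01,
                     inoculation_time = 5, horizon = 10),
    "t = 0")
  expect_error(
    culture_scenario(list(ec_sscm, ec_sscm), lys, S0 = 1, inoculum = 0.01,
                     horizon = 10),
    "distinct")
  expect_error(
    culture_scenario(ec_sscm, lys, S0 = 1, inoculum = 0.01,
                     inoculation_time = 0, horizon = -1),
    "horizon")
})

test_that("Monod rate: half saturation, zero substrate, and a worked value", {
  expect_equal(specific_growth_rate(S = 79.8, P = 0, params = ec_sscm),
               1.02 / 2)
  expect_identical(specific_growth_rate(S = 0, P = 0, params = ec_sscm), 0)
  # hand arithmetic: 1.02 * 20 / (79.8 + 20)
  expect_equal(specific_growth_rate(S = 20, P = 0, params = ec_sscm),
               1.02 * 20 / 99.8, tolerance = 1e-12)
  expect_error(specific_growth_rate(S = -1, P = 0, params = ec_sscm), ">= 0")
  expect_error(specific_growth_rate(S = 1, P = -1, params = ec_sscm), ">= 0")
})

test_that("product inhibition enters as an extra denominator term", {
  inh <- strain_params("ecoli", 1.5, K_S = 4, Y_XS = 0.1, k_d = 0,
                       is_product_inhibited = TRUE, K_P = 0.7)
  # S = K_S and P = K_S * K_P collapse the denominator to 3 K_S
  expect_equal(specific_growth_rate(S = 4, P = 4 * 0.7, params = inh),
               1.5 / 3, tolerance = 1e-12)
  # P = 0 (or a huge K_P) recovers the plain Monod rate
  expect_equal(specific_growth_rate(S = 11, P = 0, params = inh),
               1.5 * 11 / 15)
  inh_weak <- strain_params("ecoli", 1.5, 4, 0.1, 0,
                            is_product_inhibited = TRUE, K_P = 1e300)
  expect_equal(specific_growth_rate(S = 11, P = 5, params = inh_weak),
               1.5 * 11 / 15, tolerance = 1e-15)
})

test_that("Monod rate is monotone in S and anti-monotone in P", {
  set.seed(7)
  for (rep in 1:20) {
    sp <- strain_params("x", mu_max = 10^runif(1, -2, 2),
                        K_S = 10^runif(1, -2, 4), Y_XS = 1, k_d = 0,
                        is_product_inhibited = TRUE, K_P = 10^runif(1, -2, 2))
    S <- sort(10^runif(6, -3, 4))
    P <- sort(10^runif(6, -3, 3))
    mu_S <- specific_growth_rate(S, P = 1, params = sp)
    expect_true(all(diff(mu_S) >= 0))
    mu_P <- vapply(P, function(p)
      specific_growth_rate(S = 5, P = p, params = sp), 0)
    expect_true(all(diff(mu_P) <= 0))
  }
})

test_that("lysis rate reads the dead pool a lag ago and is zero pre-history", {
  lys <- lysis_params(k_s = 0.211, theta = 2)
  # constant history of 2 g/L: hand value 0.211 * 2 = 0.422
  expect_equal(lysis_rate(function(t) 2, t = 10, lysis = lys), 0.422)
  # tabulated history starting at t = 0: zero before the start
  hist_tab <- data.frame(time = 0:10, Xd = rep(2, 11))
  expect_equal(lysis_rate(hist_tab, t = 1, lysis = lys), 0)
  expect_equal(lysis_rate(hist_tab, t = 5, lysis = lys), 0.422)
  expect_equal(lysis_rate(hist_tab, t = 3, lysis = lysis_params(0, 2)), 0)
})

test_that("state derivatives match hand-evaluated mass balances", {
  sc <- culture_scenario(ec_sscm, lysis_params(0.211, 2), S0 = 79.8,
                         inoculum = 1, horizon = 48)
  st <- culture_state(
    time = 0,
    clusters = list(ecoli = data.frame(generation = 1L, birth_time = 0,
                                       concentration = 1)),
    dead_biomass = 0, substrate = 79.8, product = 0,
    division_clock = c(ecoli = 0))
  d <- state_derivatives(st, sc)
  # mu = mu_max / 2 at S = K_S; dX = (0.51 - 0.0048) * 1
  expect_equal(d$clusters$ecoli, 0.51 - 4.8e-3, tolerance = 1e-12)
  expect_equal(d$substrate, -0.51 / 0.067, tolerance = 1e-10)
  expect_equal(d$dead_biomass, 4.8e-3)
  expect_equal(d$division_clock[["ecoli"]], 0.51)
})

test_that("all-zero concentrations give all-zero derivatives", {
  sc <- culture_scenario(ec_sscm, lysis_params(0.211, 2), S0 = 1,
                         inoculum = 0.01, horizon = 48)
  st <- culture_state(
    time = 5,
    clusters = list(ecoli = data.frame(generation = 1:2,
                                       birth_time = c(0, 1),
                                       concentration = c(0, 0))),
    dead_biomass = 0, substrate = 0, product = 0)
  d <- state_derivatives(st, sc)
  expect_equal(d$clusters$ecoli, c(0, 0))
  expect_equal(d$substrate, 0)
  expect_equal(d$dead_biomass, 0)
  expect_equal(d$product, 0)
})

test_that("with unit yield and no producer, death and lysis conserve mass", {
  s1 <- strain_params("a", 0.8, 5, Y_XS = 1, k_d = 0.05)
  sc <- culture_scenario(s1, lysis_params(0.3, 0), S0 = 10, inoculum = 0.2,
                         horizon = 48)
  st <- culture_state(
    time = 3,
    clusters = list(a = data.frame(generation = 1:3, birth_time = c(0, 1, 2),
                                   concentration = c(0.1, 0.2, 0.3))),
    dead_biomass = 0.4, substrate = 4, product = 0)
  d <- state_derivatives(st, sc)
  expect_equal(sum(d$clusters$a) + d$dead_biomass + d$substrate, 0,
               tolerance = 1e-14)
})

test_that("state derivatives agree with an independent term-by-term oracle", {
  set.seed(42)
  producer <- strain_params("lacidophilus", 4.38, 883, 0.092, 3.68e-7,
                            is_product_producer = TRUE, Y_XP = 0.8)
  inhibited <- strain_params("ecoli", 1.88, 70.8, 0.078, 2.32e-5,
                             is_product_inhibited = TRUE, K_P = 0.5)
  sc <- culture_scenario(list(inhibited, producer), lysis_params(0.1, 1.5),
                         S0 = 20, inoculum = 0.01, horizon = 48,
                         product_dynamics = TRUE)
  for (rep in 1:25) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    st <- culture_state(
      time = runif(1, 2, 40),
      clusters = list(
        ecoli = data.frame(generation = seq_len(n1),
                           birth_time = sort(runif(n1, 0, 2)),
                           concentration = runif(n1, 0, 3)),
        lacidophilus = data.frame(generation = seq_len(n2),
                                  birth_time = sort(runif(n2, 0, 2)),
                                  concentration = runif(n2, 0, 3))),
      dead_biomass = runif(1, 0, 1), substrate = runif(1, 0, 25),
      product = runif(1, 0, 2),
      division_clock = c(ecoli = runif(1, 0, 0.6),
                         lacidophilus = runif(1, 0, 0.6)))
    hist_fun <- local({
      a <- runif(1, 0, 0.5)
      function(t) a * pmax(t, 0)
    })
    got <- state_derivatives(st, sc, dead_history = hist_fun)
    want <- oracle_derivatives(st, sc, dead_history = hist_fun)
    expect_equal(got$clusters$ecoli, want$clusters$ecoli, tolerance = 1e-12)
    expect_equal(got$clusters$lacidophilus, want$clusters$lacidophilus,
                 tolerance = 1e-12)
    expect_equal(got$dead_biomass, want$dead_biomass, tolerance = 1e-12)
    expect_equal(got$substrate, want$substrate, tolerance = 1e-12)
    expect_equal(got$product, want$product, tolerance = 1e-12)
    expect_equal(unname(got$division_clock), unname(want$division_clock),
                 tolerance = 1e-12)
  }
})
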