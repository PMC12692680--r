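test_that("division trigger fires exactly at one mass doubling", {
  expect_false(should_divide(0))
  expect_true(should_divide(log(2)))
  expect_false(should_divide(log(2) - 1e-9))
  expect_error(should_divide(-0.1), ">= 0")
})

test_that("division halves every cluster and conserves the strain total", {
  one <- data.frame(generation = 1L, birth_time = 0, concentration = 0.4)
  out <- apply_division(one, t = 1.5)
  expect_equal(out$concentration, c(0.2, 0.2))
  expect_equal(out$generation, 1:2)
  expect_equal(out$birth_time[2], 1.5)

  two <- data.frame(generation = 1:2, birth_time = c(0, 1),
                    concentration = c(0.4, 0.2))
  out2 <- apply_division(two, t = 2)
  expect_equal(out2$concentration, c(0.2, 0.1, 0.3))
  expect_equal(sum(out2$concentration), sum(two$concentration))

  set.seed(1)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    cl <- data.frame(generation = seq_len(n), birth_time = sort(runif(n)),
                     concentration = runif(n))
    res <- apply_division(cl, t = 2)
    expect_equal(sum(res$concentration), sum(cl$concentration))
    expect_equal(res$concentration[seq_len(n)], cl$concentration / 2)
  }
  expect_error(apply_division(one[0, ], 1), "non-empty")
})

test_that("inoculate adds a fresh generation-1 cluster and rejects rerun", {
  st <- culture_state(
    time = 20,
    clusters = list(lacidophilus = data.frame(
      generation = 1:3, birth_time = c(0, 5, 9),
      concentration = c(0.1, 0.1, 0.2))),
    dead_biomass = 0.01, substrate = 0.5, product = 0,
    division_clock = c(lacidophilus = 0.2))
  ec <- strain_params("ecoli", 1.02, 79.8, 0.067, 4.8e-3)
  st2 <- inoculate(st, ec, concentration = 0.01, t = 20)
  expect_equal(nrow(st2$clusters$ecoli), 1L)
  expect_equal(st2$clusters$ecoli$concentration, 0.01)
  expect_equal(st2$division_clock[["ecoli"]], 0)
  expect_equal(nrow(st2$clusters$lacidophilus), 3L)
  expect_error(inoculate(st2, ec, 0.01, 21), "re-inoculated")
  # zero-concentration inoculation is allowed (inert strain)
  st3 <- inoculate(st, strain_params("x", 1, 1, 1, 0), 0, 20)
  expect_equal(st3$clusters$x$concentration, 0)
})

test_that("a culture with zero inoculum stays flat with no events", {
  sc <- culture_scenario(strain_params("b", 1, 1, 1, 0),
                         lysis_params(0.1, 1), S0 = 5, inoculum = 0,
                         horizon = 10)
  tr <- simulate_culture(sc, output_grid = 0:10)
  expect_equal(nrow(tr$events), 0L)
  expect_equal(tr$samples$S, rep(5, 11))
  expect_equal(tr$samples$b_total, rep(0, 11))
})

test_that("saturating substrate with no death gives exponential growth and
           divisions at multiples of ln2 / mu", {
  mu <- 0.9
  sc <- culture_scenario(strain_params("ec", mu, K_S = 1e-4, Y_XS = 0.5,
                                       k_d = 0),
                         lysis_params(0, 0), S0 = 1e5, inoculum = 0.01,
                         horizon = 3)
  tr <- simulate_culture(sc, output_grid = seq(0, 3, 0.25))
  expect_equal(tr$samples$ec_total, 0.01 * exp(mu * tr$samples$time),
               tolerance = 1e-3)
  div_t <- tr$events$time[tr$events$event == "division"]
  expect_equal(div_t, seq_along(div_t) * log(2) / mu, tolerance = 1e-3)
})

test_that("after cumulative growth of 4 ln2 the strain holds five generations", {
  mu <- 1.2
  horizon <- 4 * log(2) / mu * 1.02   # just past the fourth division
  sc <- culture_scenario(strain_params("ec", mu, K_S = 1e-4, Y_XS = 0.5,
                                       k_d = 0),
                         lysis_params(0, 0), S0 = 1e5, inoculum = 0.01,
                         horizon = horizon)
  tr <- simulate_culture(sc, output_grid = c(0, horizon))
  expect_equal(sum(tr$events$event == "division"), 4L)
  expect_equal(sum(grepl("^ec_G", names(tr$samples))), 5L)
  # cluster count = divisions + 1 at all times, read off the event log
  expect_equal(max(tr$events$generation, na.rm = TRUE), 5L)
})

test_that("division events halve clusters exactly and keep totals continuous", {
  sc <- scenario_presets("ecoli_mrs", S0 = 20, horizon = 30)
  tr <- simulate_culture(sc, output_grid = seq(0, 30, 0.5))
  expect_gt(length(tr$division_detail), 2L)
  for (d in tr$division_detail) {
    n_old <- length(d$before)
    expect_equal(d$after[seq_len(n_old)] / d$before, rep(0.5, n_old))
    expect_equal(d$after[n_old + 1L], sum(d$before) / 2)
    rel_jump <- abs(sum(d$after) - sum(d$before)) / sum(d$before)
    expect_lt(rel_jump, 1e-10)
  }
})

test_that("staggered inoculation starts the second strain mid-run", {
  la <- strain_params("la", 0.5, K_S = 2, Y_XS = 0.5, k_d = 0)
  ec <- strain_params("ec", 0.9, K_S = 5, Y_XS = 0.5, k_d = 0)
  sc <- culture_scenario(list(la, ec), lysis_params(0, 0), S0 = 10,
                         inoculum = c(0.05, 0.02),
                         inoculation_time = c(0, 6), horizon = 12,
                         product_dynamics = FALSE)
  tr <- simulate_culture(sc, output_grid = 0:12)
  ino <- tr$events[tr$events$event == "inoculation", ]
  expect_equal(ino$strain, "ec")
  expect_equal(ino$time, 6)
  expect_equal(tr$samples$ec_total[tr$samples$time < 6], rep(0, 6))
  expect_equal(tr$samples$ec_total[tr$samples$time == 6], 0.02)
  expect_gt(tail(tr$samples$ec_total, 1), 0.02)
})

test_that("substrate is monotone non-increasing when lysis cannot return mass", {
  sc <- culture_scenario(strain_params("a", 1.0, 5, 0.5, 0.05),
                         lysis_params(0, 0), S0 = 10, inoculum = 0.1,
                         horizon = 24)
  tr <- simulate_culture(sc, output_grid = seq(0, 24, 0.25))
  expect_true(all(diff(tr$samples$S) <= 1e-10))
  expect_true(all(tr$samples$S >= -1e-12))
})

test_that("unit yields without a producer conserve total mass over 48 h", {
  for (nm in c("ecoli_sscm", "lacidophilus_mrs")) {
    sc <- scenario_presets(nm)
    for (i in seq_along(sc$strains)) sc$strains[[i]]$Y_XS <- 1
    tr <- simulate_culture(sc, output_grid = 0:48)
    tot <- tr$samples$S + tr$samples$Xd +
      rowSums(as.matrix(tr$samples[grep("_total$", names(tr$samples))]))
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-3)
  }
})

test_that("a vanishing lysis lag reproduces the plain ODE limit", {
  s1 <- strain_params("a", 1.0, 5, 1, 0.05)
  base <- culture_scenario(s1, lysis_params(0.2, 0), S0 = 10,
                           inoculum = 0.1, horizon = 24)
  tiny <- culture_scenario(s1, lysis_params(0.2, 1e-9), S0 = 10,
                           inoculum = 0.1, horizon = 24)
  ta <- simulate_culture(base, output_grid = 0:24)
  tb <- simulate_culture(tiny, output_grid = 0:24)
  expect_equal(tb$samples$a_total, ta$samples$a_total, tolerance = 1e-8)
  expect_equal(tb$samples$S, ta$samples$S, tolerance = 1e-8)
})

test_that("adaptive integration matches a fine fixed-step Euler oracle", {
  # one preset here keeps the unit suite quick; all four run in the
  # acceptance suite
  sc <- scenario_presets("ecoli_sscm")
  grid <- seq(0, 48, 1)
  tr <- simulate_culture(sc, output_grid = grid)
  eu <- euler_simulate(sc, h = 1e-3, sample_times = grid)
  for (col in c("ecoli_total", "Xd", "S"))
    expect_lt(component_rel_err(tr$samples[[col]], eu[[col]]), 0.005)
})

test_that("trajectory export uses the documented column naming", {
  sc <- scenario_presets("ecoli_mrs", S0 = 20, horizon = 10)
  tr <- simulate_culture(sc, output_grid = 0:10)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectory(tr, f1, f2)
  hdr <- names(utils::read.csv(f1, check.names = FALSE))
  expect_equal(hdr[1], "time")
  expect_true(all(c("ecoli_G1", "ecoli_total", "Xd", "S", "P") %in% hdr))
  ev <- utils::read.csv(f2)
  expect_equal(names(ev), c("time", "event", "strain", "generation"))
  unlink(c(f1, f2))
})

test_that("co-culture lactic acid accumulates and suppresses the inhibited strain", {
  producer <- strain_params("la", 2.0, K_S = 5, Y_XS = 0.3, k_d = 1e-4,
                            is_product_producer = TRUE, Y_XP = 0.5)
  inhibited <- strain_params("ec", 1.5, K_S = 5, Y_XS = 0.3, k_d = 1e-4,
                             is_product_inhibited = TRUE, K_P = 0.05)
  mk <- function(prod_on)
    culture_scenario(list(inhibited, producer), lysis_params(0.05, 1),
                     S0 = 20, inoculum = 0.01, horizon = 24,
                     product_dynamics = prod_on)
  with_p <- simulate_culture(mk(TRUE), output_grid = 0:24)
  without_p <- simulate_culture(mk(FALSE), output_grid = 0:24)
  expect_gt(tail(with_p$samples$P, 1), 0)
  expect_equal(tail(without_p$samples$P, 1), 0)
  expect_lt(tail(with_p$samples$ec_total, 1),
            tail(without_p$samples$ec_total, 1))
})
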