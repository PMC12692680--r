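#' Observed time series of a batch culture
#'
#' Viable (living-cell) biomass per strain, as measured e.g. by fluorescence
#' flow cytometry, optionally with a reducing-sugar substrate series.
#'
#' @param times Sampling times, h; strictly increasing.
#' @param biomass Data frame or matrix of viable biomass, g/L, one named
#'   column per observed strain.
#' @param substrate Optional substrate series, g/L.
#' @param weights Optional positive per-point weights for the objective.
#' @return An object of class `observation_series`.
#' @export
observation_series <- function(times, biomass, substrate = NULL,
                               weights = NULL) {
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop("'times' must be finite")
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  biomass <- as.data.frame(biomass)
  if (!ncol(biomass) || is.null(names(biomass)) || any(!nzchar(names(biomass))))
    stop("'biomass' needs one named column per observed strain")
  if (nrow(biomass) != length(times))
    stop("'biomass' must have one row per time point")
  if (any(as.matrix(biomass) < 0, na.rm = TRUE))
    stop("negative biomass observations are not allowed")
  if (!is.null(substrate)) {
    substrate <- as.numeric(substrate)
    if (length(substrate) != length(times))
      stop("'substrate' must have one value per time point")
    if (any(substrate < 0, na.rm = TRUE))
      stop("negative substrate observations are not allowed")
  }
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(times) || any(weights <= 0))
      stop("'weights' must be positive, one per time point")
  }
  structure(list(times = times, biomass = biomass, substrate = substrate,
                 weights = weights),
            class = "observation_series")
}

#' @export
print.observation_series <- function(x, ...) {
  cat(sprintf("<observation_series> %d points over [%g, %g] h; strains: %s%s\n",
              length(x$times), min(x$times), max(x$times),
              paste(names(x$biomass), collapse = ", "),
              if (is.null(x$substrate)) "" else "; with substrate"))
  invisible(x)
}

#' Root-mean-square calibration objective on viable biomass
#'
#' The regression objective `F_OB`: the root of the mean (over time points)
#' of the squared residuals between the modelled total viable biomass of
#' each observed strain and the observations, in g/L,
#' `F_OB = sqrt( (1/N) * sum_i sum_strains (X_model(t_i) - X_obs(t_i))^2 )`.
#' Substrate measurements do not enter the objective. If per-point weights
#' are present the mean is weight-weighted. A failed simulation yields a
#' large finite penalty (`1e6`) rather than an error.
#'
#' @param params Named numeric vector of parameter overrides applied to the
#'   scenario before simulation; names use the form `"<strain_id>:<field>"`
#'   (fields of [strain_params()]) or `"lysis:<field>"` (fields of
#'   [lysis_params()]). May be empty to evaluate the scenario as is.
#' @param obs An [observation_series()]; its biomass column names must match
#'   strain ids of the scenario.
#' @param scenario A [culture_scenario()] covering the observation span.
#' @return The objective value, g/L.
#' @export
culture_objective <- function(params, obs, scenario) {
  stopifnot(inherits(obs, "observation_series"),
            inherits(scenario, "culture_scenario"))
  scn <- apply_params(scenario, params)
  traj <- tryCatch(
    simulate_culture(scn, output_grid = obs$times),
    error = function(e) e)
  if (inherits(traj, "error")) return(1e6)
  res2 <- 0
  for (id in names(obs$biomass)) {
    model <- viable_total(traj, id)
    res2 <- res2 + (model - obs$biomass[[id]])^2
  }
  w <- if (is.null(obs$weights)) rep(1, length(obs$times)) else obs$weights
  sqrt(sum(w * res2) / sum(w))
}

#' Apply named parameter overrides to a scenario
#'
#' @param scenario A [culture_scenario()].
#' @param params Named numeric vector; names `"<strain_id>:<field>"` or
#'   `"lysis:<field>"`.
#' @return The modified scenario (re-validated).
#' @export
apply_params <- function(scenario, params) {
  if (!length(params)) return(scenario)
  if (is.null(names(params)) || any(!nzchar(names(params))))
    stop("'params' must be a named vector")
  ids <- scenario_strain_ids(scenario)
  for (nm in names(params)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("parameter name '%s' is not of the form 'target:field'", nm))
    if (parts[1L] == "lysis") {
      if (!parts[2L] %in% c("k_s", "theta"))
        stop(sprintf("unknown lysis field '%s'", parts[2L]))
      scenario$lysis[[parts[2L]]] <- unname(params[[nm]])
    } else {
      i <- match(parts[1L], ids)
      if (is.na(i)) stop(sprintf("unknown strain id '%s'", parts[1L]))
      if (!parts[2L] %in% c("mu_max", "K_S", "Y_XS", "k_d", "Y_XP", "K_P"))
        stop(sprintf("unknown strain field '%s'", parts[2L]))
      scenario$strains[[i]][[parts[2L]]] <- unname(params[[nm]])
    }
  }
  scenario
}

#' Optimizer settings for [fit_culture()]
#'
#' Defaults follow a real-coded genetic algorithm: tournament selection of
#' size 3, blend (BLX-alpha) crossover with alpha 0.5, Gaussian mutation
#' with standard deviation 10% of each parameter's (log-scale) range,
#' elitism of one, population 40 and 60 generations. Differential evolution
#' (`method = "de"`, rand/1/bin) is available as a drop-in alternative.
#' The search runs in log10 parameter space, so initial populations are
#' log-uniform over the bounds. An optional deterministic two-stage local
#' polish (bounded L-BFGS-B followed by a Nelder-Mead simplex descent, both
#' from the best individual) sharpens the returned optimum; the simplex
#' stage follows the long curved valleys that jointly-compensating kinetic
#' parameters produce, where finite-difference gradients stall.
#'
#' @param method `"ga"` or `"de"`.
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param p_crossover Crossover probability (GA).
#' @param p_mutation Per-gene mutation probability (GA).
#' @param blx_alpha Blend crossover expansion factor (GA).
#' @param tournament_size Tournament size for parent selection (GA).
#' @param mutation_sigma_frac Mutation s.d. as a fraction of the log-range.
#' @param elitism Number of elites copied unchanged each generation.
#' @param de_F,de_CR Differential-evolution scale factor and crossover rate.
#' @param polish Run a bounded local refinement from the best individual?
#' @param polish_maxit Iteration cap for the polish stage.
#' @param profile_restarts Also run a one-parameter profile sweep after the
#'   polish: the simplex is re-launched from three interior values of each
#'   identifiable free parameter in turn, and the best endpoints are
#'   descended to convergence. This is the escape hatch for compensated
#'   local optima (often flagged by a parameter pinned against a search
#'   bound, which the fit warns about); it roughly doubles the cost of a
#'   fit and is off by default.
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(method = c("ga", "de"), pop_size = 40,
                         generations = 60, p_crossover = 0.9,
                         p_mutation = 0.15, blx_alpha = 0.5,
                         tournament_size = 3, mutation_sigma_frac = 0.1,
                         elitism = 1, de_F = 0.7, de_CR = 0.9,
                         polish = TRUE, polish_maxit = 60,
                         profile_restarts = FALSE) {
  method <- match.arg(method)
  stopifnot(pop_size >= 4, generations >= 1, elitism >= 0,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1)
  structure(list(method = method, pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 blx_alpha = blx_alpha,
                 tournament_size = as.integer(tournament_size),
                 mutation_sigma_frac = mutation_sigma_frac,
                 elitism = as.integer(elitism), de_F = de_F, de_CR = de_CR,
                 polish = isTRUE(polish),
                 polish_maxit = as.integer(polish_maxit),
                 profile_restarts = isTRUE(profile_restarts)),
            class = "fit_settings")
}

#' Specification of a calibration problem
#'
#' Declares which model parameters are free (with finite positive box
#' bounds), which scenario they are estimated in, and how the stochastic
#' optimizer is configured. Every model parameter not listed as free keeps
#' its scenario value (i.e. is fixed).
#'
#' @param scenario A [culture_scenario()] template.
#' @param free Named list of length-2 numeric bounds `c(lower, upper)`,
#'   named like the overrides of [apply_params()], e.g.
#'   `list("ecoli:mu_max" = c(0.01, 100))`. Bounds must be finite, positive
#'   and ordered (the search is performed on a log scale).
#' @param settings A [fit_settings()] list.
#' @param seed Integer seed driving the optimizer's random draws.
#' @param init_seed Integer seed for the initial population draw; defaults
#'   to `seed`. Keeping it separate lets the ten-run uncertainty protocol
#'   vary one source of randomness at a time.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(scenario, free, settings = fit_settings(),
                     seed = 1L, init_seed = seed) {
  stopifnot(inherits(scenario, "culture_scenario"))
  if (!is.list(free) || !length(free) || is.null(names(free)))
    stop("'free' must be a non-empty named list of c(lower, upper) bounds")
  for (nm in names(free)) {
    b <- free[[nm]]
    if (!is.numeric(b) || length(b) != 2L || any(!is.finite(b)) ||
        b[1L] <= 0 || b[1L] >= b[2L])
      stop(sprintf("bounds for '%s' must be finite, positive and lower < upper",
                   nm))
  }
  # verify every name is addressable
  apply_params(scenario, setNames(vapply(free, `[[`, 0, 1L), names(free)))
  if (!inherits(settings, "fit_settings")) stop("'settings' must be fit_settings()")
  structure(list(scenario = scenario, free = free, settings = settings,
                 seed = as.integer(seed), init_seed = as.integer(init_seed)),
            class = "fit_spec")
}

draw_population <- function(n, lo_log, hi_log, seed) {
  d <- length(lo_log)
  set.seed(seed)
  matrix(stats::runif(n * d, rep(lo_log, each = n), rep(hi_log, each = n)),
         nrow = n, ncol = d)
}

#' Fit model parameters to observations
#'
#' Population-based stochastic global minimization of the viable-biomass
#' objective [culture_objective()] over box bounds, on a log10 parameter
#' scale, by a real-coded genetic algorithm (default) or differential
#' evolution, followed by an optional bounded local polish. The result is
#' deterministic given the spec and its seeds.
#'
#' A warning is emitted when a fitted substrate affinity constant exceeds
#' ten times the largest substrate level the data can have seen: in that
#' regime `mu_max` and `K_S` are only jointly identifiable through their
#' ratio.
#'
#' @param obs An [observation_series()].
#' @param spec A [fit_spec()].
#' @param objective Objective function `f(params, obs, scenario) -> value`;
#'   defaults to [culture_objective()]. Replaceable mainly for testing the
#'   optimizer and protocol machinery on analytic objectives.
#' @return An object of class `fit_result`: best parameters (natural scale),
#'   re-evaluated objective value, best-per-generation trace, evaluation
#'   count and the seeds used.
#' @export
fit_culture <- function(obs, spec, objective = culture_objective) {
  stopifnot(inherits(spec, "fit_spec"))
  st <- spec$settings
  pn <- names(spec$free)
  lo <- vapply(spec$free, `[[`, 0, 1L)
  hi <- vapply(spec$free, `[[`, 0, 2L)
  lo_log <- log10(lo); hi_log <- log10(hi)
  d <- length(pn)
  n_eval <- 0L
  fn <- function(z) {
    # z in log10 space, clamped to bounds
    z <- pmin(pmax(z, lo_log), hi_log)
    p <- setNames(10^z, pn)
    n_eval <<- n_eval + 1L
    v <- objective(p, obs, spec$scenario)
    if (!is.finite(v)) 1e6 else v
  }

  pop <- draw_population(st$pop_size, lo_log, hi_log, spec$init_seed)
  fit_vals <- apply(pop, 1L, fn)
  trace <- numeric(st$generations + 1L)
  trace[1L] <- min(fit_vals)

  set.seed(spec$seed)
  sigma <- st$mutation_sigma_frac * (hi_log - lo_log)
  for (g in seq_len(st$generations)) {
    if (st$method == "ga") {
      ord <- order(fit_vals)
      elite_idx <- ord[seq_len(min(st$elitism, st$pop_size))]
      newpop <- matrix(NA_real_, st$pop_size, d)
      ne <- length(elite_idx)
      if (ne) newpop[seq_len(ne), ] <- pop[elite_idx, , drop = FALSE]
      for (i in seq.int(ne + 1L, st$pop_size)) {
        tournament <- function() {
          cand <- sample.int(st$pop_size, st$tournament_size, replace = TRUE)
          cand[which.min(fit_vals[cand])]
        }
        p1 <- pop[tournament(), ]
        if (stats::runif(1) < st$p_crossover) {
          p2 <- pop[tournament(), ]
          rng <- abs(p1 - p2)
          child <- stats::runif(d, pmin(p1, p2) - st$blx_alpha * rng,
                                pmax(p1, p2) + st$blx_alpha * rng)
        } else child <- p1
        mut <- stats::runif(d) < st$p_mutation
        if (any(mut))
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, sigma[mut])
        newpop[i, ] <- pmin(pmax(child, lo_log), hi_log)
      }
      new_vals <- c(fit_vals[elite_idx],
                    apply(newpop[seq.int(ne + 1L, st$pop_size), , drop = FALSE],
                          1L, fn))
      pop <- newpop; fit_vals <- new_vals
    } else {  # differential evolution, rand/1/bin
      for (i in seq_len(st$pop_size)) {
        idx <- sample.int(st$pop_size, 3L)
        mutant <- pop[idx[1L], ] + st$de_F * (pop[idx[2L], ] - pop[idx[3L], ])
        cross <- stats::runif(d) < st$de_CR
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        trial <- pmin(pmax(trial, lo_log), hi_log)
        v <- fn(trial)
        if (v <= fit_vals[i]) { pop[i, ] <- trial; fit_vals[i] <- v }
      }
    }
    trace[g + 1L] <- min(fit_vals)
  }

  best_i <- which.min(fit_vals)
  best_z <- pop[best_i, ]
  best_v <- fit_vals[best_i]

  if (st$polish) {
    # stage 1: bounded quasi-Newton from the best individual
    pol <- tryCatch(
      stats::optim(best_z, fn, method = "L-BFGS-B",
                   lower = lo_log, upper = hi_log,
                   control = list(maxit = st$polish_maxit, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value <= best_v) {
      best_z <- pmin(pmax(pol$par, lo_log), hi_log)
      best_v <- pol$value
    }
    # stage 2: iterated simplex descent. Finite-difference gradients stall
    # in the long curved valleys these kinetic objectives form (jointly
    # compensating parameters); Nelder-Mead follows them, and restarting it
    # with a fresh (re-inflated) simplex resumes descent whenever the
    # previous simplex collapsed partway along the valley.
    if (d >= 2L) {
      for (round in 1:4) {
        pol2 <- tryCatch(
          stats::optim(best_z, fn, method = "Nelder-Mead",
                       control = list(maxit = 25L * st$polish_maxit,
                                      reltol = 1e-12)),
          error = function(e) NULL)
        if (is.null(pol2) || !is.finite(pol2$value)) break
        gain <- best_v - pol2$value
        if (pol2$value <= best_v) {
          best_z <- pmin(pmax(pol2$par, lo_log), hi_log)
          best_v <- pol2$value
        }
        if (gain <= 1e-6 * max(best_v, 1e-12)) break
      }
    }

    # stage 3 (opt-in): one-parameter profile restarts. Compensated local
    # optima are common here (e.g. the death/lysis pair against the Monod
    # pair): the polished point describes the data almost as well as the
    # true optimum with one parameter far off, often against a bound.
    # Re-launching the simplex from interior values of one parameter at a
    # time — a cheap profile sweep — and finishing the best endpoints lets
    # the descent cross into the neighbouring basin.
    rng_log <- hi_log - lo_log
    pin_of <- function(z) which(z <= lo_log + 0.01 * rng_log |
                                  z >= hi_log - 0.01 * rng_log)
    if (st$profile_restarts && d >= 2L) {
      base_z <- best_z
      ends <- list()
      for (j in seq_len(d)) {
        # skip parameters the objective is flat in (unidentifiable)
        probes <- vapply(c(0.25, 0.75), function(fr) {
          zp <- base_z
          zp[j] <- lo_log[j] + fr * rng_log[j]
          fn(zp)
        }, 0)
        if (max(abs(probes - best_v)) < 0.02 * max(best_v, 1e-12)) next
        for (fr in c(0.25, 0.5, 0.75)) {
          z0 <- base_z
          z0[j] <- lo_log[j] + fr * rng_log[j]
          r <- tryCatch(
            stats::optim(z0, fn, method = "Nelder-Mead",
                         control = list(maxit = 300, reltol = 1e-9)),
            error = function(e) NULL)
          if (!is.null(r) && is.finite(r$value))
            ends[[length(ends) + 1L]] <- r
        }
      }
      if (length(ends)) {
        # crawls converge at very different speeds and a quickly converged
        # value does not mean a better basin: finish the descent from up
        # to four endpoints (iterated simplex), picked greedily by value
        # but required to be mutually distinct in log-parameter space so
        # that different basins all get finished
        ord <- order(vapply(ends, `[[`, 0, "value"))
        take <- integer(0)
        for (k in ord) {
          if (length(take) >= 4L) break
          zk <- ends[[k]]$par
          distinct <- all(vapply(take, function(m)
            max(abs(zk - ends[[m]]$par)) > 0.3, TRUE))
          if (distinct) take <- c(take, k)
        }
        for (k in take) {
          z_k <- ends[[k]]$par
          v_k <- ends[[k]]$value
          for (round in 1:3) {
            r <- tryCatch(
              stats::optim(z_k, fn, method = "Nelder-Mead",
                           control = list(maxit = 25L * st$polish_maxit,
                                          reltol = 1e-12)),
              error = function(e) NULL)
            if (is.null(r) || !is.finite(r$value)) break
            gain <- v_k - r$value
            if (r$value <= v_k) { z_k <- r$par; v_k <- r$value }
            if (gain <= 1e-6 * max(v_k, 1e-12)) break
          }
          if (v_k < best_v) {
            best_z <- pmin(pmax(z_k, lo_log), hi_log)
            best_v <- v_k
          }
        }
      }
    }
    pinned <- pin_of(best_z)
    if (length(pinned) && !st$profile_restarts)
      warning(sprintf(
        paste0("parameter(s) %s sit on a search bound, which often marks a ",
               "compensated local optimum; consider ",
               "fit_settings(profile_restarts = TRUE)"),
        paste(pn[pinned], collapse = ", ")), call. = FALSE)
  }

  best <- setNames(10^best_z, pn)
  value <- objective(best, obs, spec$scenario)

  # identifiability guard: data never probed substrate levels near K_S
  s_seen <- max(c(spec$scenario$S0, obs$substrate), na.rm = TRUE)
  ks_names <- grep(":K_S$", pn, value = TRUE)
  for (nm in ks_names) {
    if (s_seen < 0.1 * best[[nm]])
      warning(sprintf(
        paste0("observed substrate range (max %.3g g/L) never exceeds 10%% of ",
               "the fitted %s (%.3g g/L): mu_max and K_S are only jointly ",
               "identifiable through their ratio"), s_seen, nm, best[[nm]]),
        call. = FALSE)
  }

  structure(list(best_parameters = best, objective_value = value,
                 trace = data.frame(generation = 0:st$generations,
                                    best = trace),
                 n_evaluations = n_eval, seed = spec$seed,
                 init_seed = spec$init_seed, settings = st,
                 free = spec$free),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> F_OB = %.6g g/L after %d evaluations (%s%s)\n",
              x$objective_value, x$n_evaluations, x$settings$method,
              if (x$settings$polish) " + polish" else ""))
  print(data.frame(parameter = names(x$best_parameters),
                   value = unname(x$best_parameters),
                   lower = vapply(x$free, `[[`, 0, 1L),
                   upper = vapply(x$free, `[[`, 0, 2L),
                   row.names = NULL))
  invisible(x)
}

#' Ten-run uncertainty protocol for stochastic fits
#'
#' Standard deviations for evolutionary-algorithm estimates are obtained by
#' repetition: exactly ten fits are run, five starting from the same initial
#' population but with five different operator seeds (`arm = "vary_seed"`),
#' and five starting from five different initial populations with the same
#' operator seed (`arm = "vary_init"`). The per-parameter mean and sample
#' standard deviation (N - 1 denominator) over the ten best-fit values are
#' reported.
#'
#' @param obs An [observation_series()].
#' @param spec A [fit_spec()]; its `seed` / `init_seed` are the base values
#'   the ten runs are derived from.
#' @param objective Objective passed through to [fit_culture()].
#' @return An object of class `uncertainty_protocol`: the ten `fit_result`s
#'   with their arm labels and a summary data frame
#'   (`parameter`, `mean`, `sd`).
#' @export
uncertainty_protocol <- function(obs, spec, objective = culture_objective) {
  stopifnot(inherits(spec, "fit_spec"))
  arms <- c(rep("vary_seed", 5L), rep("vary_init", 5L))
  run_seeds <- c(spec$seed + 1:5, rep(spec$seed, 5L))
  init_seeds <- c(rep(spec$init_seed, 5L), spec$init_seed + 100L + 1:5)
  runs <- vector("list", 10L)
  for (r in 1:10) {
    sp <- spec
    sp$seed <- as.integer(run_seeds[r])
    sp$init_seed <- as.integer(init_seeds[r])
    runs[[r]] <- fit_culture(obs, sp, objective = objective)
  }
  mat <- do.call(rbind, lapply(runs, `[[`, "best_parameters"))
  structure(list(runs = runs, arm = arms, summary = protocol_summary(mat)),
            class = "uncertainty_protocol")
}

#' Per-parameter mean and sample standard deviation of repeated fits
#'
#' @param values Numeric matrix, one row per run, one named column per
#'   parameter.
#' @return Data frame with columns `parameter`, `mean`, `sd` (sample
#'   standard deviation, N - 1 denominator).
#' @export
protocol_summary <- function(values) {
  values <- as.matrix(values)
  data.frame(parameter = colnames(values),
             mean = colMeans(values),
             sd = apply(values, 2L, stats::sd),
             row.names = NULL)
}

#' @export
print.uncertainty_protocol <- function(x, ...) {
  cat(sprintf("<uncertainty_protocol> %d runs (%d vary_seed / %d vary_init)\n",
              length(x$runs), sum(x$arm == "vary_seed"),
              sum(x$arm == "vary_init")))
  print(x$summary)
  invisible(x)
}

#' Export a fit result as a flat summary table
#'
#' @param result A `fit_result`.
#' @param path Optional CSV path; when given, the table is also written.
#' @return Data frame with columns `parameter`, `value`, `lower`, `upper`,
#'   `objective`, `seed`, `init_seed`.
#' @export
fit_result_table <- function(result, path = NULL) {
  stopifnot(inherits(result, "fit_result"))
  tab <- data.frame(parameter = names(result$best_parameters),
                    value = unname(result$best_parameters),
                    lower = vapply(result$free, `[[`, 0, 1L),
                    upper = vapply(result$free, `[[`, 0, 2L),
                    objective = result$objective_value,
                    seed = result$seed, init_seed = result$init_seed,
                    row.names = NULL)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
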