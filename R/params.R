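#' Kinetic parameters of one bacterial strain
#'
#' Bundles the Monod growth constants and first-order death constant of a
#' single strain, plus its (optional) role in the lactic-acid coupling used
#' for co-cultures: a strain can either produce lactic acid or have its
#' growth inhibited by it, not both.
#'
#' @param strain_id Character label, e.g. `"ecoli"` or `"lacidophilus"`.
#'   Used to name trajectory columns and to address parameters in fits.
#' @param mu_max Maximum specific growth rate, 1/h. Must be positive.
#' @param K_S Substrate affinity (half-saturation) constant, g/L. Positive.
#' @param Y_XS Biomass-on-substrate yield, g biomass per g substrate. Positive.
#' @param k_d First-order death rate constant, 1/h. Non-negative.
#' @param is_product_producer Logical; does this strain produce lactic acid?
#' @param Y_XP Biomass-on-product yield, g biomass per g lactic acid.
#'   Required (positive) iff the strain is a producer.
#' @param is_product_inhibited Logical; is this strain's growth inhibited by
#'   lactic acid through an extra `P / K_P` term in the Monod denominator?
#' @param K_P Dimensionless product inhibition constant. Required (positive)
#'   iff the strain is inhibited.
#'
#' @return An object of class `strain_params`.
#' @examples
#' ec <- strain_params("ecoli", mu_max = 1.02, K_S = 79.8,
#'                     Y_XS = 0.067, k_d = 4.8e-3)
#' @export
strain_params <- function(strain_id, mu_max, K_S, Y_XS, k_d,
                          is_product_producer = FALSE, Y_XP = NULL,
                          is_product_inhibited = FALSE, K_P = NULL) {
  if (!is.character(strain_id) || length(strain_id) != 1L || !nzchar(strain_id))
    stop("'strain_id' must be a non-empty character scalar")
  chk_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a finite numeric scalar", nm))
    x
  }
  mu_max <- chk_num(mu_max, "mu_max")
  K_S <- chk_num(K_S, "K_S")
  Y_XS <- chk_num(Y_XS, "Y_XS")
  k_d <- chk_num(k_d, "k_d")
  if (mu_max <= 0) stop("'mu_max' must be > 0")
  if (K_S <= 0) stop("'K_S' must be > 0")
  if (Y_XS <= 0) stop("'Y_XS' must be > 0")
  if (k_d < 0) stop("'k_d' must be >= 0")
  if (isTRUE(is_product_producer) && isTRUE(is_product_inhibited))
    stop("a strain cannot be both lactic-acid producer and product-inhibited")
  if (isTRUE(is_product_producer)) {
    if (is.null(Y_XP)) stop("'Y_XP' is required for a product-producing strain")
    Y_XP <- chk_num(Y_XP, "Y_XP")
    if (Y_XP <= 0) stop("'Y_XP' must be > 0")
  } else Y_XP <- NULL
  if (isTRUE(is_product_inhibited)) {
    if (is.null(K_P)) stop("'K_P' is required for a product-inhibited strain")
    K_P <- chk_num(K_P, "K_P")
    if (K_P <= 0) stop("'K_P' must be > 0")
  } else K_P <- NULL
  structure(
    list(strain_id = strain_id, mu_max = mu_max, K_S = K_S, Y_XS = Y_XS,
         k_d = k_d,
         is_product_producer = isTRUE(is_product_producer), Y_XP = Y_XP,
         is_product_inhibited = isTRUE(is_product_inhibited), K_P = K_P),
    class = "strain_params")
}

#' @export
print.strain_params <- function(x, ...) {
  cat(sprintf("<strain_params> %s\n", x$strain_id))
  cat(sprintf("  mu_max = %g 1/h, K_S = %g g/L, Y_XS = %g g/g, k_d = %g 1/h\n",
              x$mu_max, x$K_S, x$Y_XS, x$k_d))
  if (x$is_product_producer)
    cat(sprintf("  lactic-acid producer, Y_XP = %g g/g\n", x$Y_XP))
  if (x$is_product_inhibited)
    cat(sprintf("  product-inhibited, K_P = %g\n", x$K_P))
  invisible(x)
}

#' Lysis (dead-biomass recycling) parameters
#'
#' Dead cells of either strain accumulate in a single shared pool and are
#' converted back into substrate by a delayed first-order process with rate
#' `k_s * X_d(t - theta)`.
#'
#' @param k_s Lysis rate constant, 1/h. Non-negative.
#' @param theta Lysis lag time, h. Non-negative. Values at or below
#'   `1e-6` h are treated as zero delay (plain ODE limit).
#'
#' @return An object of class `lysis_params`.
#' @examples
#' lysis_params(k_s = 0.211, theta = 2)
#' @export
lysis_params <- function(k_s, theta = 0) {
  if (!is.numeric(k_s) || length(k_s) != 1L || !is.finite(k_s) || k_s < 0)
    stop("'k_s' must be a finite numeric scalar >= 0")
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta < 0)
    stop("'theta' must be a finite numeric scalar >= 0")
  structure(list(k_s = k_s, theta = theta), class = "lysis_params")
}

#' Batch cultivation scenario
#'
#' Describes one batch experiment: the strains present (one or two), the
#' shared lysis parameters, the initial substrate load, per-strain inoculum
#' concentrations and inoculation times, and the simulation horizon.
#' Time is measured in hours from the first inoculation, which must occur
#' at t = 0.
#'
#' @param strains A single `strain_params` or a list of one or two of them
#'   with distinct `strain_id`s.
#' @param lysis A `lysis_params` object.
#' @param S0 Initial substrate concentration, g/L (non-negative).
#' @param inoculum Numeric vector of inoculum concentrations, g/L, one per
#'   strain (recycled if scalar). Zero is allowed and gives an inert strain.
#' @param inoculation_time Numeric vector of inoculation times, h, one per
#'   strain. The earliest must be 0 (`Sync-co`: both 0; `Lag-Sync`: second
#'   strain offset, e.g. 20 h). All must be below `horizon`.
#' @param horizon Simulation end time, h (> 0).
#' @param medium Free-text medium label, e.g. `"SSCM"` or `"MRS"`.
#' @param product_dynamics Logical; activate the lactic-acid state (production
#'   by the producer strain and inhibition of the inhibited strain)?
#'   Defaults to `TRUE` for two-strain scenarios, `FALSE` for mono-cultures.
#'
#' @return An object of class `culture_scenario`.
#' @examples
#' sc <- culture_scenario(
#'   strains = strain_params("ecoli", 1.02, 79.8, 0.067, 4.8e-3),
#'   lysis = lysis_params(0.211, 2), S0 = 1, inoculum = 0.01, horizon = 48)
#' @export
culture_scenario <- function(strains, lysis, S0, inoculum,
                             inoculation_time = 0, horizon,
                             medium = "", product_dynamics = NULL) {
  if (inherits(strains, "strain_params")) strains <- list(strains)
  if (!is.list(strains) || !length(strains) ||
      !all(vapply(strains, inherits, TRUE, "strain_params")))
    stop("'strains' must be one or a list of 'strain_params' objects")
  if (length(strains) > 2L) stop("at most two strains are supported")
  ids <- vapply(strains, `[[`, "", "strain_id")
  if (anyDuplicated(ids)) stop("strain ids must be distinct")
  if (!inherits(lysis, "lysis_params")) stop("'lysis' must be a 'lysis_params'")
  if (!is.numeric(S0) || length(S0) != 1L || !is.finite(S0) || S0 < 0)
    stop("'S0' must be a finite numeric scalar >= 0")
  ns <- length(strains)
  inoculum <- rep_len(as.numeric(inoculum), ns)
  inoculation_time <- rep_len(as.numeric(inoculation_time), ns)
  if (any(!is.finite(inoculum)) || any(inoculum < 0))
    stop("'inoculum' concentrations must be finite and >= 0")
  if (any(!is.finite(inoculation_time)) || any(inoculation_time < 0))
    stop("'inoculation_time' must be finite and >= 0")
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0)
    stop("'horizon' must be a finite numeric scalar > 0")
  if (min(inoculation_time) != 0)
    stop("the first inoculation defines t = 0: min(inoculation_time) must be 0")
  if (any(inoculation_time >= horizon))
    stop("all inoculation times must be earlier than 'horizon'")
  if (is.null(product_dynamics)) product_dynamics <- ns >= 2L
  product_dynamics <- isTRUE(product_dynamics)
  if (product_dynamics) {
    has_prod <- any(vapply(strains, `[[`, TRUE, "is_product_producer"))
    if (!has_prod)
      warning("product_dynamics = TRUE but no strain is a lactic-acid producer")
  }
  names(inoculum) <- names(inoculation_time) <- ids
  structure(
    list(strains = strains, lysis = lysis, S0 = S0, inoculum = inoculum,
         inoculation_time = inoculation_time, horizon = horizon,
         medium = medium, product_dynamics = product_dynamics),
    class = "culture_scenario")
}

#' @export
print.culture_scenario <- function(x, ...) {
  ids <- vapply(x$strains, `[[`, "", "strain_id")
  cat(sprintf("<culture_scenario> %s on '%s'\n",
              paste(ids, collapse = " + "), x$medium))
  cat(sprintf("  S0 = %g g/L, horizon = %g h, lysis k_s = %g 1/h, theta = %g h\n",
              x$S0, x$horizon, x$lysis$k_s, x$lysis$theta))
  for (id in ids)
    cat(sprintf("  %s: inoculum %g g/L at t = %g h\n",
                id, x$inoculum[[id]], x$inoculation_time[[id]]))
  cat(sprintf("  lactic-acid dynamics: %s\n",
              if (x$product_dynamics) "on" else "off"))
  invisible(x)
}

scenario_strain_ids <- function(scenario)
  vapply(scenario$strains, `[[`, "", "strain_id")

scenario_strain <- function(scenario, id) {
  i <- match(id, scenario_strain_ids(scenario))
  if (is.na(i)) stop(sprintf("unknown strain id '%s'", id))
  scenario$strains[[i]]
}

#' Full dynamical state of a culture
#'
#' A snapshot of the segregated model state: the generation clusters of each
#' active strain, the shared dead-biomass pool, substrate, lactic acid, and
#' each strain's division clock (cumulative gross specific growth since its
#' last division, dimensionless; a division fires when it reaches `log(2)`).
#'
#' @param time Time, h.
#' @param clusters Named list (by strain id); each element a data frame with
#'   columns `generation` (consecutive integers from 1), `birth_time` (h,
#'   non-decreasing) and `concentration` (g/L, non-negative).
#' @param dead_biomass Shared dead-cell pool, g/L.
#' @param substrate Substrate concentration, g/L.
#' @param product Lactic-acid concentration, g/L.
#' @param division_clock Named numeric vector (by strain id), dimensionless.
#'
#' @return An object of class `culture_state`.
#' @export
culture_state <- function(time, clusters, dead_biomass = 0, substrate = 0,
                          product = 0, division_clock = NULL) {
  if (!is.list(clusters) || is.null(names(clusters)) ||
      any(!nzchar(names(clusters))))
    stop("'clusters' must be a named list of data frames (one per strain)")
  for (id in names(clusters)) {
    cl <- clusters[[id]]
    if (!is.data.frame(cl) ||
        !all(c("generation", "birth_time", "concentration") %in% names(cl)))
      stop(sprintf(
        "clusters[['%s']] needs columns generation, birth_time, concentration",
        id))
    if (nrow(cl)) {
      if (!identical(as.integer(cl$generation), seq_len(nrow(cl))))
        stop(sprintf("generation indices of '%s' must run 1, 2, ... in order", id))
      if (is.unsorted(cl$birth_time))
        stop(sprintf("birth times of '%s' must be non-decreasing", id))
      if (any(cl$concentration < 0))
        stop("cluster concentrations must be >= 0")
    }
  }
  if (dead_biomass < 0 || substrate < 0 || product < 0)
    stop("pool concentrations must be >= 0")
  if (is.null(division_clock))
    division_clock <- setNames(numeric(length(clusters)), names(clusters))
  if (!all(names(clusters) %in% names(division_clock)))
    stop("'division_clock' must be named by strain id")
  if (any(division_clock < 0)) stop("division clocks must be >= 0")
  structure(
    list(time = time, clusters = clusters, dead_biomass = dead_biomass,
         substrate = substrate, product = product,
         division_clock = division_clock[names(clusters)]),
    class = "culture_state")
}
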