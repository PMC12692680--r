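#' Gross specific growth rate of a strain
#'
#' Monod kinetics on a single limiting substrate,
#' `mu = mu_max * S / (K_S + S)`, extended for a product-inhibited strain by
#' a lactic-acid term in the denominator,
#' `mu = mu_max * S / (K_S + S + P / K_P)`. The rate is gross (division
#' clock input); death is accounted separately.
#'
#' @param S Substrate concentration, g/L (vectorised, non-negative).
#' @param P Lactic-acid concentration, g/L (non-negative; ignored unless the
#'   strain is product-inhibited).
#' @param params A [strain_params()] object.
#' @return Specific growth rate(s), 1/h. Zero when `S = 0`.
#' @examples
#' ec <- strain_params("ecoli", 1.02, 79.8, 0.067, 4.8e-3)
#' specific_growth_rate(S = 20, P = 0, params = ec)   # ~0.2044 1/h
#' @export
specific_growth_rate <- function(S, P = 0, params) {
  stopifnot(inherits(params, "strain_params"))
  if (any(!is.finite(S)) || any(S < 0)) stop("'S' must be finite and >= 0")
  if (any(!is.finite(P)) || any(P < 0)) stop("'P' must be finite and >= 0")
  denom <- params$K_S + S
  if (params$is_product_inhibited) denom <- denom + P / params$K_P
  params$mu_max * S / denom
}

#' Substrate appearance rate from delayed lysis of dead biomass
#'
#' Dead cells are converted into substrate at rate `k_s * X_d(t - theta)`:
#' first order in the dead-biomass concentration a lag time `theta` ago.
#' The history is zero before the culture starts, so the rate is zero
#' whenever `t - theta` precedes the start of the recorded history.
#'
#' @param dead_history Either a function of time returning the dead-biomass
#'   concentration (g/L), or a two-column matrix / data frame of
#'   `(time, X_d)` samples (linearly interpolated; zero before the first
#'   sample time).
#' @param t Evaluation time, h.
#' @param lysis A [lysis_params()] object.
#' @return Substrate appearance rate, g/(L h).
#' @examples
#' lys <- lysis_params(k_s = 0.211, theta = 2)
#' lysis_rate(function(t) 2, t = 10, lysis = lys)  # 0.422
#' @export
lysis_rate <- function(dead_history, t, lysis) {
  stopifnot(inherits(lysis, "lysis_params"))
  hfun <- as_history_fun(dead_history)
  lysis$k_s * pmax(hfun(t - lysis$theta), 0)
}

as_history_fun <- function(dead_history) {
  if (is.function(dead_history)) return(dead_history)
  if (is.data.frame(dead_history)) dead_history <- as.matrix(dead_history)
  if (is.matrix(dead_history) && ncol(dead_history) >= 2L) {
    tt <- dead_history[, 1L]; xx <- dead_history[, 2L]
    if (length(tt) == 1L)
      return(function(t) ifelse(t < tt, 0, xx))
    f <- stats::approxfun(tt, xx, rule = 2L)
    t0 <- tt[1L]
    return(function(t) ifelse(t < t0, 0, f(t)))
  }
  stop("'dead_history' must be a function or a (time, X_d) table")
}

#' Time derivatives of a full culture state
#'
#' Evaluates the instantaneous mass balances of the segregated model on a
#' [culture_state()]: per-cluster viable growth minus death, accumulation of
#' the shared dead pool net of delayed lysis, substrate consumption by all
#' clusters plus lysis return, lactic-acid accumulation by producer clusters
#' (when the scenario's product dynamics are on), and advancement of each
#' strain's division clock at its gross specific growth rate.
#'
#' @param state A [culture_state()].
#' @param scenario A [culture_scenario()]; strains present in `state` must
#'   be declared in the scenario.
#' @param dead_history History of the dead pool for the delay term (see
#'   [lysis_rate()]). Defaults to the current value (zero-delay evaluation).
#' @return A list mirroring the state: `clusters` (named list of numeric
#'   derivative vectors, g/(L h)), `dead_biomass`, `substrate`, `product`
#'   (g/(L h)) and `division_clock` (1/h).
#' @export
state_derivatives <- function(state, scenario, dead_history = NULL) {
  stopifnot(inherits(state, "culture_state"),
            inherits(scenario, "culture_scenario"))
  ids <- names(state$clusters)
  known <- scenario_strain_ids(scenario)
  if (!all(ids %in% known))
    stop("state contains strains not declared in the scenario: ",
         paste(setdiff(ids, known), collapse = ", "))
  if (is.null(dead_history)) {
    xd_now <- state$dead_biomass
    dead_history <- function(t) xd_now
  }
  S <- max(state$substrate, 0)
  P <- max(state$product, 0)
  Xd <- state$dead_biomass

  d_clusters <- vector("list", length(ids)); names(d_clusters) <- ids
  d_clock <- setNames(numeric(length(ids)), ids)
  consumption <- 0; death_in <- 0; dP <- 0
  for (id in ids) {
    sp <- scenario_strain(scenario, id)
    X <- state$clusters[[id]]$concentration
    mu <- specific_growth_rate(S, if (scenario$product_dynamics) P else 0, sp)
    d_clusters[[id]] <- (mu - sp$k_d) * X
    d_clock[[id]] <- mu
    sumX <- sum(X)
    consumption <- consumption + mu / sp$Y_XS * sumX
    death_in <- death_in + sp$k_d * sumX
    if (scenario$product_dynamics && sp$is_product_producer)
      dP <- dP + mu / sp$Y_XP * sumX
  }
  raw <- lysis_rate(dead_history, state$time, scenario$lysis)
  # cap the drain so the dead pool cannot be driven negative by the delayed term
  drain <- min(raw, scenario$lysis$k_s * max(Xd, 0))
  list(clusters = d_clusters,
       dead_biomass = death_in - drain,
       substrate = -consumption + drain,
       product = dP,
       division_clock = d_clock)
}
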