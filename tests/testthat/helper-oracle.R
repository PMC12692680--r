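# Independent reference implementations used as oracles. They share nothing
# with the package internals beyond the model definition itself.

# Term-by-term derivative oracle: recomputes every mass balance directly
# from a culture_state, one term at a time.
oracle_derivatives <- function(state, scenario, dead_history = NULL) {
  ids <- names(state$clusters)
  S <- max(state$substrate, 0)
  P <- max(state$product, 0)
  d_cl <- list(); d_clock <- c()
  dXd <- 0; dS <- 0; dP <- 0
  for (id in ids) {
    sp <- NULL
    for (s in scenario$strains) if (s$strain_id == id) sp <- s
    denom <- sp$K_S + S
    if (scenario$product_dynamics && sp$is_product_inhibited)
      denom <- denom + P / sp$K_P
    mu <- sp$mu_max * S / denom
    X <- state$clusters[[id]]$concentration
    d_cl[[id]] <- mu * X - sp$k_d * X
    d_clock[id] <- mu
    for (x in X) {
      dXd <- dXd + sp$k_d * x
      dS <- dS - mu / sp$Y_XS * x
      if (scenario$product_dynamics && sp$is_product_producer)
        dP <- dP + mu / sp$Y_XP * x
    }
  }
  xd_lagged <- if (is.null(dead_history)) state$dead_biomass else {
    f <- if (is.function(dead_history)) dead_history else NULL
    f(state$time - scenario$lysis$theta)
  }
  v_lys <- scenario$lysis$k_s * min(max(xd_lagged, 0), max(state$dead_biomass, 0))
  list(clusters = d_cl, dead_biomass = dXd - v_lys,
       substrate = dS + v_lys, product = dP, division_clock = d_clock)
}

# Fixed-step explicit Euler integration of the full hybrid system, with the
# delay term read from the step-indexed dead-pool history and division
# events applied at step boundaries (clock remainder carried over).
euler_simulate <- function(scenario, h = 1e-3, sample_times) {
  ids <- vapply(scenario$strains, `[[`, "", "strain_id")
  ns <- length(ids)
  inoc_t <- scenario$inoculation_time
  theta <- scenario$lysis$theta
  ks <- scenario$lysis$k_s
  lag_steps <- round(theta / h)
  prod_on <- scenario$product_dynamics
  ln2 <- log(2)

  nstep <- round(scenario$horizon / h)
  active <- inoc_t <= 0
  conc <- vector("list", ns)
  for (i in seq_len(ns)) if (active[i]) conc[[i]] <- scenario$inoculum[[i]]
  clocks <- numeric(ns)
  Xd <- 0; S <- scenario$S0; P <- 0
  xd_hist <- numeric(nstep + 1L)

  sample_steps <- round(sample_times / h)
  out <- matrix(NA_real_, length(sample_times), ns + 3L,
                dimnames = list(NULL, c(paste0(ids, "_total"), "Xd", "S", "P")))
  record <- function(step) {
    hit <- which(sample_steps == step)
    if (length(hit)) {
      tot <- vapply(seq_len(ns), function(i)
        if (is.null(conc[[i]])) 0 else sum(conc[[i]]), 0)
      out[hit, ] <<- rep(c(tot, Xd, S, P), each = length(hit))
    }
  }
  record(0L)

  for (step in seq_len(nstep)) {
    S_eff <- max(S, 0); P_eff <- max(P, 0)
    cons <- 0; death <- 0; dP <- 0
    mu_s <- numeric(ns)
    for (i in which(active)) {
      sp <- scenario$strains[[i]]
      den <- sp$K_S + S_eff
      if (prod_on && sp$is_product_inhibited) den <- den + P_eff / sp$K_P
      mu <- sp$mu_max * S_eff / den
      mu_s[i] <- mu
      sX <- sum(conc[[i]])
      cons <- cons + mu / sp$Y_XS * sX
      death <- death + sp$k_d * sX
      if (prod_on && sp$is_product_producer) dP <- dP + mu / sp$Y_XP * sX
      conc[[i]] <- conc[[i]] + h * (mu - sp$k_d) * conc[[i]]
    }
    xdel <- if (step - 1L - lag_steps >= 0L) xd_hist[step - lag_steps] else 0
    if (lag_steps == 0L) xdel <- max(Xd, 0)
    drain <- ks * min(xdel, max(Xd, 0))
    Xd <- Xd + h * (death - drain)
    S <- S + h * (-cons + drain)
    P <- P + h * dP
    xd_hist[step + 1L] <- max(Xd, 0)
    # inoculations due at the end of this step
    t_next <- step * h
    for (i in which(!active)) {
      if (abs(inoc_t[[i]] - t_next) < h / 2) {
        active[i] <- TRUE
        conc[[i]] <- scenario$inoculum[[i]]
        clocks[i] <- 0
      }
    }
    # synchronized divisions (clock remainder carried)
    for (i in which(active)) {
      clocks[i] <- clocks[i] + h * mu_s[i] * (sum(conc[[i]]) > 0)
      if (clocks[i] >= ln2) {
        halves <- conc[[i]] / 2
        conc[[i]] <- c(halves, sum(halves))
        clocks[i] <- clocks[i] - ln2
      }
    }
    record(step)
  }
  data.frame(time = sample_times, out, check.names = FALSE)
}

# scaled sup-norm discrepancy between two trajectories of one component
component_rel_err <- function(a, b) {
  scale <- max(abs(b))
  if (scale == 0) return(max(abs(a - b)))
  max(abs(a - b)) / scale
}
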