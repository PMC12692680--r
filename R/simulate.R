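LN2 <- log(2)
# delays at or below this (h) are integrated as plain ODEs
THETA_ZERO_TOL <- 1e-6

#' Division trigger test
#'
#' A strain's cells are assumed to divide once their per-cell mass has
#' doubled, i.e. once the division clock (cumulative gross specific growth
#' since the last division) reaches `log(2)`.
#'
#' @param division_clock Non-negative dimensionless clock value(s).
#' @return Logical; `TRUE` where `division_clock >= log(2)`.
#' @export
should_divide <- function(division_clock) {
  if (any(division_clock < 0)) stop("'division_clock' must be >= 0")
  division_clock >= LN2
}

#' Apply one synchronized division event to a strain's clusters
#'
#' Every existing cluster's concentration is halved (each cell splits in
#' two, one half of the biomass staying on its mother timeline) and the
#' removed halves together found a new cluster: the next generation, born at
#' the event time. Total viable biomass is conserved exactly.
#'
#' @param clusters Data frame with columns `generation`, `birth_time`,
#'   `concentration` (as in [culture_state()]); at least one row.
#' @param t Event time, h.
#' @return The updated cluster data frame with one extra row.
#' @examples
#' cl <- data.frame(generation = 1:2, birth_time = c(0, 1),
#'                  concentration = c(0.4, 0.2))
#' apply_division(cl, t = 2)  # halves become 0.2, 0.1; new cluster 0.3
#' @export
apply_division <- function(clusters, t) {
  if (!is.data.frame(clusters) || nrow(clusters) == 0L)
    stop("'clusters' must be a non-empty data frame")
  halves <- clusters$concentration / 2
  rbind(
    data.frame(generation = clusters$generation,
               birth_time = clusters$birth_time,
               concentration = halves),
    data.frame(generation = max(clusters$generation) + 1L,
               birth_time = t,
               concentration = sum(halves)))
}

#' Add a strain to a running culture
#'
#' Inserts a strain as a single generation-1 cluster at the given
#' concentration, with its division clock at zero. Used for staggered
#' (Lag-Sync) inoculation.
#'
#' @param state A [culture_state()].
#' @param strain A [strain_params()] object not already present in `state`.
#' @param concentration Inoculum concentration, g/L (zero gives an inert,
#'   but tracked, strain).
#' @param t Inoculation time, h (becomes the new state time).
#' @return The updated `culture_state`.
#' @export
inoculate <- function(state, strain, concentration, t) {
  stopifnot(inherits(state, "culture_state"), inherits(strain, "strain_params"))
  id <- strain$strain_id
  if (id %in% names(state$clusters))
    stop(sprintf("strain '%s' is already active and cannot be re-inoculated", id))
  if (concentration < 0) stop("'concentration' must be >= 0")
  state$clusters[[id]] <- data.frame(
    generation = 1L, birth_time = t, concentration = concentration)
  state$division_clock[[id]] <- 0
  state$time <- t
  culture_state(state$time, state$clusters, state$dead_biomass,
                state$substrate, state$product, state$division_clock)
}

#' Simulate a batch culture scenario
#'
#' Integrates the segregated growth model as a hybrid system: smooth Monod
#' growth / death / delayed-lysis / product dynamics between events, with
#' discrete events for synchronized per-strain divisions (located by root
#' finding on the division clock), staggered inoculations, and substrate
#' exhaustion. The lysis delay is handled by the method of steps: the
#' integration proceeds in segments no longer than `theta`, against a dense
#' interpolated history of the dead pool (zero before culture start), with
#' the internal step capped at `theta / 4`.
#'
#' @param scenario A [culture_scenario()].
#' @param output_grid Sample times, h (strictly increasing, within
#'   `[0, horizon]`). Default: every 0.1 h from 0 to the horizon.
#' @param rtol,atol Relative / absolute tolerances of the adaptive
#'   (LSODAR) integrator.
#' @return An object of class `culture_trajectory`: a list with
#'   \describe{
#'     \item{samples}{data frame with columns `time`, one `<strain>_G<k>`
#'       column per generation cluster (`NA` before the cluster is born),
#'       one `<strain>_total` column per strain, `Xd`, `S`, `P`.}
#'     \item{events}{data frame `time`, `event`
#'       (`division` / `inoculation` / `substrate_exhausted`), `strain`,
#'       `generation`.}
#'     \item{division_detail}{list of per-division records with the cluster
#'       concentrations immediately before and after the event.}
#'     \item{scenario}{the input scenario.}
#'   }
#' @examples
#' sc <- culture_scenario(
#'   strains = strain_params("ecoli", 1.02, 79.8, 0.067, 0),
#'   lysis = lysis_params(0, 0), S0 = 500, inoculum = 0.01, horizon = 4)
#' tr <- simulate_culture(sc, output_grid = seq(0, 4, 0.5))
#' tr$events
#' @export
simulate_culture <- function(scenario, output_grid = NULL,
                             rtol = 1e-7, atol = 1e-9) {
  stopifnot(inherits(scenario, "culture_scenario"))
  horizon <- scenario$horizon
  if (is.null(output_grid)) output_grid <- seq(0, horizon, by = 0.1)
  output_grid <- sort(unique(as.numeric(output_grid)))
  if (any(output_grid < 0) || any(output_grid > horizon + 1e-9))
    stop("'output_grid' must lie within [0, horizon]")

  ids <- scenario_strain_ids(scenario)
  ns <- length(ids)
  inoc_t <- scenario$inoculation_time
  theta <- scenario$lysis$theta
  ks <- scenario$lysis$k_s
  use_delay <- theta > THETA_ZERO_TOL && ks > 0
  prod_on <- scenario$product_dynamics
  eps_S <- 1e-9 * max(scenario$S0, 1)

  # mutable bookkeeping ------------------------------------------------
  active <- inoc_t <= 0
  conc <- gen <- born <- vector("list", ns)
  for (i in seq_len(ns)) if (active[i]) {
    conc[[i]] <- scenario$inoculum[[i]]; gen[[i]] <- 1L; born[[i]] <- 0
  }
  clocks <- numeric(ns)
  Xd <- 0; S <- scenario$S0; P <- 0
  hist_t <- 0; hist_xd <- 0
  depleted <- FALSE
  events <- list(); div_detail <- list()
  seg_records <- list()
  t_now <- 0

  log_event <- function(time, event, strain, generation) {
    events[[length(events) + 1L]] <<- data.frame(
      time = time, event = event, strain = strain, generation = generation,
      stringsAsFactors = FALSE)
  }

  while (t_now < horizon - 1e-10) {
    act <- which(active)
    pend <- inoc_t[!active & inoc_t > t_now + 1e-12]
    seg_end <- min(horizon,
                   if (length(pend)) min(pend) else Inf,
                   if (use_delay) t_now + theta else Inf)

    # state vector layout for this segment
    nclus <- if (length(act)) lengths(conc[act]) else integer(0)
    idx_clus <- vector("list", length(act))
    off <- 0L
    for (j in seq_along(act)) {
      idx_clus[[j]] <- off + seq_len(nclus[j]); off <- off + nclus[j]
    }
    i_xd <- off + 1L; i_s <- off + 2L; i_p <- off + 3L
    i_clk <- off + 3L + seq_along(act)
    y <- c(unlist(conc[act], use.names = FALSE), Xd, S, P, clocks[act])
    if (any(!is.finite(y)))
      stop(sprintf("non-finite state at t = %.6g h", t_now))

    sp_act <- scenario$strains[act]
    na_ <- length(act)

    # parameter block for the compiled right-hand side (see src/seg_deriv.c)
    pvec <- numeric(8 + 2 * 10)
    pvec[1] <- na_
    pvec[2] <- as.numeric(prod_on)
    pvec[3] <- ks
    pvec[4] <- theta
    pvec[5] <- as.numeric(use_delay)
    pvec[6] <- eps_S
    pvec[7] <- as.numeric(depleted)
    for (j in seq_len(na_)) {
      sp <- sp_act[[j]]
      base <- 8 + (j - 1L) * 10L
      pvec[base + 1L] <- nclus[j]
      pvec[base + 2L] <- sp$mu_max
      pvec[base + 3L] <- sp$K_S
      pvec[base + 4L] <- 1 / sp$Y_XS
      pvec[base + 5L] <- sp$k_d
      pvec[base + 6L] <- as.numeric(sp$is_product_inhibited)
      pvec[base + 7L] <- if (is.null(sp$K_P)) 1 else sp$K_P
      pvec[base + 8L] <- as.numeric(sp$is_product_producer)
      pvec[base + 9L] <- if (is.null(sp$Y_XP)) 0 else 1 / sp$Y_XP
      # a strain with no viable mass has no cells to divide: clock frozen
      pvec[base + 10L] <- as.numeric(sum(conc[[act[j]]]) > 0)
    }

    # delayed dead pool as a forcing: the history table shifted by theta,
    # with a leading zero node (history is 0 before the culture starts)
    ftab <- cbind(c(hist_t[1L] + theta - 1, hist_t + theta),
                  c(0, hist_xd))

    dt_hist <- if (use_delay) theta / 4 else max((seg_end - t_now) / 8, 1e-6)
    times <- sort(unique(c(t_now,
                           output_grid[output_grid > t_now + 1e-12 &
                                       output_grid < seg_end - 1e-12],
                           seq(t_now, seg_end, by = dt_hist),
                           seg_end)))
    times <- times[c(TRUE, diff(times) > 1e-10)]
    # lsodar warns when a root stops it early; that is the intended behaviour
    out <- withCallingHandlers(
      deSolve::lsodar(y, times, func = "seg_deriv", parms = pvec,
                      dllname = "segrowth", initfunc = "seg_init",
                      rootfunc = "seg_root", nroot = na_ + 1L,
                      forcings = ftab, initforc = "seg_initforc",
                      fcontrol = list(method = "linear", rule = 2),
                      rtol = rtol, atol = atol,
                      maxsteps = if (use_delay) 2000 else 5000,
                      hmax = if (use_delay) theta / 4 else NULL),
      warning = function(w) {
        if (grepl("Returning early|root|maxsteps|excessive", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    troot <- attr(out, "troot")
    t_end <- out[nrow(out), 1L]
    ymat <- out[, -1L, drop = FALSE]
    if (any(!is.finite(ymat)))
      stop(sprintf("integration failed: non-finite state after t = %.6g h", t_now))
    if (t_end <= t_now + 1e-12)
      stop(sprintf("integration stalled at t = %.6g h (last good time)", t_now))
    if (is.null(troot) && t_end < seg_end - 1e-9)
      stop(sprintf(
        "integration gave up before t = %.6g h (last good time %.6g h)",
        seg_end, t_end))

    # record dense output of this segment; the start row repeats the previous
    # segment's end time but carries post-event values, so later records
    # overwrite earlier ones during assembly
    seg_records[[length(seg_records) + 1L]] <- list(
      times = out[, 1L],
      clusters = lapply(seq_along(act), function(j)
        ymat[, idx_clus[[j]], drop = FALSE]),
      strain = ids[act],
      gens = gen[act],
      xd = ymat[, i_xd], s = ymat[, i_s], p = ymat[, i_p])
    if (nrow(out) > 1L) {
      hist_t <- c(hist_t, out[2:nrow(out), 1L])
      hist_xd <- c(hist_xd, pmax(ymat[2:nrow(out), i_xd], 0))
    }

    # pull end state back into bookkeeping
    yend <- unname(ymat[nrow(ymat), ])
    for (j in seq_along(act)) conc[[act[j]]] <- pmax(yend[idx_clus[[j]]], 0)
    Xd <- max(yend[i_xd], 0); S <- max(yend[i_s], 0); P <- max(yend[i_p], 0)
    clocks[act] <- yend[i_clk]
    t_now <- t_end

    if (!is.null(troot) && length(troot)) {
      # which condition fired? divisions take precedence over depletion
      fired <- which(clocks[act] >= LN2 - 1e-8)
      if (length(fired)) {
        for (j in fired) {
          i <- act[j]
          before <- conc[[i]]
          halves <- before / 2
          conc[[i]] <- c(halves, sum(halves))
          new_gen <- max(gen[[i]]) + 1L
          gen[[i]] <- c(gen[[i]], new_gen)
          born[[i]] <- c(born[[i]], t_now)
          clocks[i] <- 0
          log_event(t_now, "division", ids[i], new_gen)
          div_detail[[length(div_detail) + 1L]] <- list(
            time = t_now, strain = ids[i],
            before = before, after = conc[[i]])
        }
      } else if (!depleted && S <= eps_S * 1.01) {
        depleted <- TRUE
        S <- max(S, 0)
        log_event(t_now, "substrate_exhausted", NA_character_, NA_integer_)
      }
    }
    if (depleted && S > 10 * eps_S) depleted <- FALSE

    # pending inoculations reached?
    for (i in which(!active)) {
      if (abs(inoc_t[[i]] - t_now) <= 1e-9) {
        active[i] <- TRUE
        conc[[i]] <- scenario$inoculum[[i]]
        gen[[i]] <- 1L; born[[i]] <- t_now; clocks[i] <- 0
        log_event(t_now, "inoculation", ids[i], 1L)
      }
    }
  }

  assemble_trajectory(scenario, output_grid, seg_records, ids, gen, born,
                      events, div_detail)
}

assemble_trajectory <- function(scenario, output_grid, seg_records, ids,
                                gen, born, events, div_detail) {
  # final generation labels per strain (strains never inoculated have none)
  gen_final <- setNames(gen, ids)
  all_times <- unlist(lapply(seg_records, `[[`, "times"), use.names = FALSE)
  # for duplicated times (event instants) keep the later (post-event) record
  cols <- list(time = output_grid)
  n <- length(output_grid)
  col_names <- character(0)
  mats <- list()
  for (id in ids) {
    gmax <- if (is.null(gen_final[[id]])) 0L else max(gen_final[[id]])
    if (gmax > 0L)
      mats[[id]] <- matrix(NA_real_, n, gmax,
                           dimnames = list(NULL, paste0(id, "_G", seq_len(gmax))))
  }
  xd <- s <- p <- rep(NA_real_, n)
  for (rec in seg_records) {
    pos <- match(round(output_grid, 9), round(rec$times, 9))
    hit <- which(!is.na(pos))
    if (!length(hit)) next
    rows <- pos[hit]
    for (j in seq_along(rec$strain)) {
      id <- rec$strain[j]
      gens <- rec$gens[[j]]
      mats[[id]][hit, gens] <- rec$clusters[[j]][rows, , drop = FALSE]
    }
    xd[hit] <- rec$xd[rows]; s[hit] <- rec$s[rows]; p[hit] <- rec$p[rows]
  }
  samples <- data.frame(time = output_grid)
  for (id in ids) {
    if (!is.null(mats[[id]])) {
      samples <- cbind(samples, as.data.frame(mats[[id]]))
      samples[[paste0(id, "_total")]] <- rowSums(mats[[id]], na.rm = TRUE)
    } else {
      samples[[paste0(id, "_total")]] <- 0
    }
  }
  samples$Xd <- xd; samples$S <- s; samples$P <- p

  events_df <- if (length(events)) {
    df <- do.call(rbind, events)
    rownames(df) <- NULL
    df$time <- unname(df$time)
    df
  } else
    data.frame(time = numeric(0), event = character(0),
               strain = character(0), generation = integer(0),
               stringsAsFactors = FALSE)
  structure(list(samples = samples, events = events_df,
                 division_detail = div_detail, scenario = scenario),
            class = "culture_trajectory")
}

#' @export
print.culture_trajectory <- function(x, ...) {
  ids <- scenario_strain_ids(x$scenario)
  cat(sprintf("<culture_trajectory> %s, %d samples over [%g, %g] h\n",
              paste(ids, collapse = " + "), nrow(x$samples),
              min(x$samples$time), max(x$samples$time)))
  ndiv <- sum(x$events$event == "division")
  cat(sprintf("  events: %d division(s), %d inoculation(s), %d depletion(s)\n",
              ndiv, sum(x$events$event == "inoculation"),
              sum(x$events$event == "substrate_exhausted")))
  invisible(x)
}

#' @export
as.data.frame.culture_trajectory <- function(x, ...) x$samples

#' Total viable biomass of one strain along a trajectory
#'
#' @param trajectory A [simulate_culture()] result.
#' @param strain_id Strain label.
#' @return Numeric vector aligned with `trajectory$samples$time`.
#' @export
viable_total <- function(trajectory, strain_id) {
  col <- paste0(strain_id, "_total")
  if (!col %in% names(trajectory$samples))
    stop(sprintf("no strain '%s' in this trajectory", strain_id))
  trajectory$samples[[col]]
}

#' Write a trajectory and its event log to CSV files
#'
#' The samples table has one row per sample time and columns `time`,
#' `<strain>_G<k>` per generation cluster, `<strain>_total` per strain,
#' `Xd`, `S`, `P` (all concentrations in g/L, time in h).
#'
#' @param trajectory A `culture_trajectory`.
#' @param path Output CSV path for the samples table.
#' @param events_path Optional CSV path for the event log.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, events_path = NULL) {
  stopifnot(inherits(trajectory, "culture_trajectory"))
  utils::write.csv(trajectory$samples, path, row.names = FALSE)
  if (!is.null(events_path))
    utils::write.csv(trajectory$events, events_path, row.names = FALSE)
  invisible(path)
}
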