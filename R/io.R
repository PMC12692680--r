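#' Write an observation series to a delimited file
#'
#' Comma-separated, `"."` decimal; header `time_h`, one viable-biomass
#' column per strain (named by strain id), then `S` if a substrate series
#' is present and `weight` if weights are present. A leading block of `#`
#' comment lines records machine-parsable provenance (truth parameters and
#' noise settings) when the series carries it.
#'
#' @param series An [observation_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(series, path) {
  stopifnot(inherits(series, "observation_series"))
  con <- file(path, "w")
  on.exit(close(con))
  prov <- attr(series, "provenance")
  if (!is.null(prov)) {
    flat <- yaml::as.yaml(prov)
    writeLines(paste0("# ", strsplit(flat, "\n")[[1L]]), con)
  }
  df <- data.frame(time_h = series$times, check.names = FALSE)
  for (nm in names(series$biomass)) df[[nm]] <- series$biomass[[nm]]
  if (!is.null(series$substrate)) df$S <- series$substrate
  if (!is.null(series$weights)) df$weight <- series$weights
  # %.17g round-trips doubles exactly through text
  fmt <- as.data.frame(lapply(df, function(x) sprintf("%.17g", x)),
                       check.names = FALSE)
  names(fmt) <- names(df)
  writeLines(paste(names(fmt), collapse = ","), con)
  utils::write.table(fmt, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an observation series from a delimited file
#'
#' Expects the format of [write_observations()]: a `time_h` column followed
#' by one viable-biomass column per strain and optional `S` / `weight`
#' columns; `#` lines are treated as comments. Malformed content is
#' reported with the offending line number.
#'
#' @param path Input file path.
#' @return An [observation_series()].
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(body_idx)) stop(sprintf("'%s': no data found", path))
  header_line <- body_idx[1L]
  df <- tryCatch(
    utils::read.csv(text = paste(lines[body_idx], collapse = "\n"),
                    check.names = FALSE),
    error = function(e) stop(sprintf("'%s': cannot parse: %s", path,
                                     conditionMessage(e))))
  if (!"time_h" %in% names(df))
    stop(sprintf("'%s': missing required header column 'time_h'", path))
  # map data-frame rows back to file lines for error reporting
  row_line <- body_idx[-1L]
  bad <- which(!vapply(df, is.numeric, TRUE))
  if (length(bad)) {
    col <- names(df)[bad[1L]]
    nonnum <- suppressWarnings(which(is.na(as.numeric(df[[col]]))))[1L]
    stop(sprintf("'%s': non-numeric value in column '%s' at line %d",
                 path, col, row_line[nonnum]))
  }
  tt <- df$time_h
  if (anyNA(tt)) stop(sprintf("'%s': missing time at line %d",
                              path, row_line[which(is.na(tt))[1L]]))
  nd <- which(diff(tt) <= 0)
  if (length(nd))
    stop(sprintf("'%s': non-monotone time at line %d", path,
                 row_line[nd[1L] + 1L]))
  strain_cols <- setdiff(names(df), c("time_h", "S", "weight"))
  if (!length(strain_cols))
    stop(sprintf("'%s': no viable-biomass columns after 'time_h'", path))
  for (col in c(strain_cols, intersect("S", names(df)))) {
    neg <- which(df[[col]] < 0)
    if (length(neg))
      stop(sprintf("'%s': negative value in column '%s' at line %d",
                   path, col, row_line[neg[1L]]))
  }
  observation_series(
    times = tt,
    biomass = df[strain_cols],
    substrate = if ("S" %in% names(df)) df$S else NULL,
    weights = if ("weight" %in% names(df)) df$weight else NULL)
}

RUN_CONFIG_KEYS <- list(
  top = c("schema_version", "seed", "scenario", "noise", "fit", "output",
          "verbose"),
  scenario = c("preset", "strains", "lysis", "S0", "inoculum",
               "inoculation_time", "horizon", "medium", "product_dynamics",
               "K_P", "Y_XP", "theta"),
  noise = c("kind", "cv", "seed", "sampling_interval", "detection_floor"),
  fit = c("free", "settings", "seed", "init_seed"),
  output = c("dir", "prefix"))

#' Read and validate a run configuration file
#'
#' A single YAML file with a `schema_version` field drives every
#' command-line run. Top-level blocks: `scenario` (either `preset` plus
#' optional overrides, or an explicit `strains`/`lysis` description),
#' `noise`, `fit` (free-parameter bounds and optimizer settings), `output`
#' and `seed`. Unknown keys at any validated level are rejected.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config '%s' does not exist", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  if (is.null(cfg$schema_version))
    stop("config is missing 'schema_version'")
  if (!identical(as.integer(cfg$schema_version), 1L))
    stop("unsupported schema_version (only 1 is known)")
  chk <- function(block, keys, where) {
    unknown <- setdiff(names(block), keys)
    if (length(unknown))
      stop(sprintf("unknown config key%s %s in %s",
                   if (length(unknown) > 1L) "s" else "",
                   paste(sQuote(unknown), collapse = ", "), where))
  }
  chk(cfg, RUN_CONFIG_KEYS$top, "top level")
  if (!is.null(cfg$scenario)) chk(cfg$scenario, RUN_CONFIG_KEYS$scenario,
                                  "'scenario'")
  if (!is.null(cfg$noise)) chk(cfg$noise, RUN_CONFIG_KEYS$noise, "'noise'")
  if (!is.null(cfg$fit)) chk(cfg$fit, RUN_CONFIG_KEYS$fit, "'fit'")
  if (!is.null(cfg$output)) chk(cfg$output, RUN_CONFIG_KEYS$output,
                                "'output'")
  structure(cfg, class = c("run_config", "list"))
}

#' Build a scenario from a config block
#'
#' @param block The `scenario` element of a [read_run_config()] result:
#'   either a `preset` name with optional overrides (`S0`, `inoculum`,
#'   `horizon`, `theta`, `K_P`, `Y_XP`), or an explicit description with
#'   `strains` (list of [strain_params()] fields), `lysis` (`k_s`, `theta`)
#'   and the [culture_scenario()] fields.
#' @return A [culture_scenario()].
#' @export
scenario_from_config <- function(block) {
  if (is.null(block)) stop("config has no 'scenario' block")
  if (!is.null(block$preset)) {
    return(scenario_presets(block$preset, S0 = block$S0,
                            inoculum = block$inoculum,
                            horizon = block$horizon, theta = block$theta,
                            K_P = block$K_P, Y_XP = block$Y_XP))
  }
  if (is.null(block$strains) || is.null(block$lysis))
    stop("explicit scenario config needs 'strains' and 'lysis'")
  strains <- lapply(block$strains, function(s) do.call(strain_params, s))
  lysis <- do.call(lysis_params, block$lysis)
  culture_scenario(
    strains = strains, lysis = lysis, S0 = block$S0,
    inoculum = unlist(block$inoculum),
    inoculation_time = if (is.null(block$inoculation_time)) 0 else
      unlist(block$inoculation_time),
    horizon = block$horizon,
    medium = if (is.null(block$medium)) "" else block$medium,
    product_dynamics = block$product_dynamics)
}

noise_from_config <- function(block) {
  if (is.null(block)) return(noise_model("none"))
  do.call(noise_model, block)
}

fit_spec_from_config <- function(block, scenario, default_seed = 1L) {
  if (is.null(block) || is.null(block$free))
    stop("config has no 'fit.free' block")
  free <- lapply(block$free, function(b) as.numeric(unlist(b)))
  settings <- if (is.null(block$settings)) fit_settings() else
    do.call(fit_settings, block$settings)
  seed <- if (is.null(block$seed)) default_seed else block$seed
  init_seed <- if (is.null(block$init_seed)) seed else block$init_seed
  fit_spec(scenario, free, settings = settings, seed = seed,
           init_seed = init_seed)
}
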