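#' Read and write model parameters as flat YAML/JSON
#'
#' A parameter file is a flat mapping using the field names of
#' [deb_params()] (`Rmax`, `delta`, `Q`, `P`, `M`, `T`, `mu_c`, `mu_j`,
#' `mu_a`, `sigma`, `H`, `s_b`, `s_j`, `s_m`, `s_r`, `s_rI`, `s_rT`,
#' `chi`); omitted fields take their defaults. The packaged file
#' `system.file("extdata", "defaults.yaml", package = "debevo")` spells out
#' the default parameterization.
#'
#' @param path File path; `.json` is parsed as JSON, anything else as YAML.
#' @return [read_params()]: a `deb_params` object.
#' @examples
#' p <- read_params(system.file("extdata", "defaults.yaml",
#'                              package = "debevo"))
#' @export
read_params <- function(path) {
  raw <- read_mapping(path)
  unknown <- setdiff(names(raw), names(formals(deb_params)))
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(deb_params, raw)
}

#' @rdname read_params
#' @param p A [deb_params()] object to write.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "deb_params"))
  write_mapping(unclass(p), path)
  invisible(path)
}

read_mapping <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else {
    out <- yaml::read_yaml(path)
    if (is.null(out)) list() else out
  }
}

write_mapping <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path, precision = 15)
}

config_blocks <- c("model", "numerics", "ebt", "seed", "output_dir",
                   "log_level", "equilibrium", "simulate", "css",
                   "isocline", "sweep_css", "regress")

#' Load a full run configuration
#'
#' Reads a YAML or JSON run configuration with optional blocks `model`
#' (fields of [deb_params()]), `numerics` ([numerics_config()]), `ebt`
#' ([ebt_options()]), scalar entries `seed`, `output_dir`, `log_level`, and
#' free-form per-command blocks (`equilibrium`, `simulate`, `css`,
#' `isocline`, `sweep_css`, `regress`). Unknown keys, at the top level or
#' inside the validated blocks, are all reported in one error. An empty file
#' yields the full default configuration.
#'
#' @param path Configuration file path.
#' @param echo_path If non-`NULL`, the fully resolved configuration is
#'   written there (YAML), so a run's inputs are reproducible from its
#'   outputs.
#' @return A list of class `deb_config` with elements `params`, `numerics`,
#'   `ebt`, `seed`, `output_dir`, `log_level` and any command blocks.
#' @export
load_config <- function(path, echo_path = NULL) {
  raw <- read_mapping(path)
  if (!is.list(raw)) stop("config must be a mapping: ", path)
  bad <- character(0)
  bad <- c(bad, setdiff(names(raw), config_blocks))
  bad <- c(bad, paste0("model.",
                       setdiff(names(raw$model), names(formals(deb_params)))))
  bad <- c(bad, paste0("numerics.",
                       setdiff(names(raw$numerics),
                               names(formals(numerics_config)))))
  bad <- c(bad, paste0("ebt.",
                       setdiff(names(raw$ebt), names(formals(ebt_options)))))
  bad <- bad[!grepl("\\.$", bad)]
  if (length(bad))
    stop("invalid configuration key(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  for (tr in c("Q", "P"))
    if (!is.null(raw$model[[tr]]) &&
        (raw$model[[tr]] < 0 || raw$model[[tr]] > 3))
      stop("invalid configuration key(s) in ", path, ": model.", tr,
           " outside the guard range [0, 3]")
  cfg <- list(
    params = do.call(deb_params, as.list(raw$model)),
    numerics = do.call(numerics_config, as.list(raw$numerics)),
    ebt = do.call(ebt_options, as.list(raw$ebt)),
    seed = raw$seed, output_dir = raw$output_dir,
    log_level = if (is.null(raw$log_level)) "info" else raw$log_level)
  for (blk in c("equilibrium", "simulate", "css", "isocline",
                "sweep_css", "regress"))
    cfg[[blk]] <- raw[[blk]]
  class(cfg) <- "deb_config"
  if (!is.null(echo_path)) save_config(cfg, echo_path)
  cfg
}

#' @rdname load_config
#' @param cfg A `deb_config` object.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "deb_config"))
  out <- list(model = unclass(cfg$params),
              numerics = unclass(cfg$numerics),
              ebt = unclass(cfg$ebt))
  for (nm in c("seed", "output_dir", "log_level", "equilibrium", "simulate",
               "css", "isocline", "sweep_css", "regress"))
    if (!is.null(cfg[[nm]])) out[[nm]] <- cfg[[nm]]
  write_mapping(out, path)
  invisible(path)
}

#' Write a result table as CSV with full float precision
#'
#' Deterministic column order (as given), header included, numeric columns
#' rendered with 17 significant digits so that re-reading reproduces the
#' doubles bit-for-bit. Overwrites silently.
#'
#' @param rows A data frame (may have zero rows).
#' @param path Output path.
#' @param schema Optional character vector; if given, the column names must
#'   match it exactly (order included).
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path, schema = NULL) {
  rows <- as.data.frame(rows)
  if (!is.null(schema) && !identical(names(rows), schema))
    stop("column names do not match the declared schema; expected: ",
         paste(schema, collapse = ", "))
  out <- rows
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a life-history trajectory to CSV
#'
#' Columns: `age`, `size`, `survivorship`, `cum_fecundity`,
#' `cum_ingestion`.
#'
#' @param lh A [life_history()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_trajectory <- function(lh, path) {
  stopifnot(inherits(lh, "deb_life_history"))
  write_table(as.data.frame(lh), path,
              schema = c("age", "size", "survivorship", "cum_fecundity",
                         "cum_ingestion"))
}
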