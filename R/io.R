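# File formats and configuration: plain CSV point tables with JSON sidecars.

#' Read a point-referenced value table from CSV
#'
#' Expects a header with columns `x`, `y` plus any named value columns.
#' Coordinates must be numeric and finite; offending rows are reported by
#' number. Missing values (empty fields or NA) in value columns are allowed
#' and counted.
#'
#' @param path CSV file path.
#' @param value_cols optional character vector of required value columns.
#' @return Data frame with attribute `n_missing` (named count of NAs per
#'   value column).
#' @export
read_point_table <- function(path, value_cols = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty input: ", path, " has 0 data rows")
  for (cc in c("x", "y", value_cols))
    if (!cc %in% names(d)) stop("missing required column '", cc, "' in ", path)
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric or missing coordinate '", cc, "' at row",
           if (length(bad) > 1) "s " else " ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path)
    d[[cc]] <- v
  }
  vcols <- setdiff(names(d), c("x", "y"))
  nmiss <- vapply(vcols, function(cc) sum(is.na(d[[cc]])), integer(1))
  attr(d, "n_missing") <- nmiss
  d
}

#' Write a grid map to CSV with a JSON sidecar
#'
#' The CSV holds one row per cell (cell_x, cell_y, mean, sd; masked cells as
#' explicit NA). The sidecar `<path>.json` records the grid specification,
#' the mapped quantity, and any metadata supplied (model, seed, package
#' version), so the map can be reproduced and re-read exactly.
#'
#' @param map a [grid_map()].
#' @param path output CSV path.
#' @param metadata named list merged into the sidecar.
#' @return `path`, invisibly. `read_grid_map(path)` reverses the operation.
#' @export
write_grid_map <- function(map, path, metadata = list()) {
  stopifnot(inherits(map, "grid_map"))
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, na = "NA")
  side <- c(list(grid = list(origin = map$grid$origin,
                             cell_size = map$grid$cell_size,
                             nx = map$grid$nx, ny = map$grid$ny),
                 quantity = map$quantity,
                 package_version = as.character(utils::packageVersion("krigsdm"))),
            metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_grid_map
#' @export
read_grid_map <- function(path) {
  d <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- prediction_grid(unlist(side$grid$origin), side$grid$cell_size,
                       side$grid$nx, side$grid$ny)
  grid_map(g, d$mean, d$sd, quantity = side$quantity)
}

#' Write a deterministic on-disk fixture data set
#'
#' Wraps [generate_dataset()] and writes plain-CSV files: `species.csv`
#' (x, y, y01 plus covariate columns, NA under misalignment where abiotic
#' values are unobserved at species locations), one `abiotic_<name>.csv` per
#' covariate, and a `manifest.json`. "tiny" uses N = 200, M = 40 for fast
#' tests; "paper" uses the full study conditions N = 1000, M = 100.
#'
#' @param kind "aligned" or "misaligned".
#' @param size "tiny" or "paper".
#' @param seed integer seed (same seed, same bytes).
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
make_fixture <- function(kind = c("misaligned", "aligned"),
                         size = c("tiny", "paper"), seed = 1L,
                         dir = tempfile("fixture")) {
  kind <- match.arg(kind); size <- match.arg(size)
  dims <- if (size == "tiny") c(200L, 40L) else c(1000L, 100L)
  cfg <- simulation_config(n_species_locations = dims[1],
                           n_abiotic_locations = dims[2],
                           misalignment = (kind == "misaligned"), seed = seed)
  ds <- generate_dataset(cfg, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- data.frame(x = ds$species$points$x, y = ds$species$points$y,
                   y01 = ds$species$y)
  if (is.null(ds$species$covariates)) {
    sp$x1 <- NA_real_; sp$x2 <- NA_real_
  } else {
    sp$x1 <- ds$species$covariates$x1; sp$x2 <- ds$species$covariates$x2
  }
  utils::write.csv(sp, file.path(dir, "species.csv"), row.names = FALSE)
  for (nm in names(ds$abiotic))
    write_field_csv(ds$abiotic[[nm]], file.path(dir, paste0("abiotic_", nm, ".csv")))
  jsonlite::write_json(
    list(kind = kind, size = size, seed = seed,
         n_species = dims[1], n_abiotic = dims[2],
         package_version = as.character(utils::packageVersion("krigsdm"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# ---- run configuration (YAML/JSON) ----------------------------------------

run_config_keys <- c("species", "abiotic", "regions", "spec", "priors",
                     "inference", "simulation", "grid", "seed")

#' Read and validate a run configuration file
#'
#' YAML (or JSON) mapping with any of the keys: `species` (path), `abiotic`
#' (name: path mapping), `regions` (path), `spec` (linear, splines,
#' spline_bins, spatial, intercept), `priors`, `inference`, `simulation`,
#' `grid` (origin, cell_size, nx, ny), `seed`. Unknown keys are rejected
#' before any computation.
#'
#' @param path config file path.
#' @return Validated list of class `run_config` with constructed
#'   `sdm_spec` / `prior_config` / `inference_config` / `prediction_grid` /
#'   `simulation_config` objects where given.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), run_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- raw
  pr <- do.call(prior_config, raw$priors %||% list())
  if (!is.null(raw$spec))
    out$spec <- do.call(sdm_spec,
                        c(raw$spec, list(priors = pr)))
  out$priors <- pr
  if (!is.null(raw$inference))
    out$inference <- do.call(inference_config, raw$inference)
  if (!is.null(raw$simulation))
    out$simulation <- do.call(simulation_config, raw$simulation)
  if (!is.null(raw$grid))
    out$grid <- prediction_grid(unlist(raw$grid$origin %||% c(0, 0)),
                                raw$grid$cell_size, raw$grid$nx, raw$grid$ny)
  structure(out, class = "run_config")
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration file path and its MD5 checksum, the master
#' seed, package and R versions, and a timestamp — enough to rerun the
#' command that produced a set of outputs.
#'
#' @param path output JSON path.
#' @param config_path configuration file used (NULL if none).
#' @param seed master seed of the run.
#' @param extra named list of additional fields (e.g. the subcommand).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config_path, seed, extra = list()) {
  m <- c(list(config = config_path,
              config_md5 = if (!is.null(config_path) && file.exists(config_path))
                unname(tools::md5sum(config_path)) else NULL,
              seed = seed,
              package_version = as.character(utils::packageVersion("krigsdm")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a fitted model as CSV tables plus a JSON summary
#'
#' Writes `<prefix>_coefficients.csv`, `<prefix>_hyper.csv`, one spline table
#' per smooth term, and `<prefix>_summary.json` (kind, diagnostics,
#' identifiability constraints applied to splines, stage-1 hyperparameter
#' tables).
#'
#' @param fit an `sdm_fit`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "sdm_fit"))
  utils::write.csv(fit$coefficients, paste0(prefix, "_coefficients.csv"),
                   row.names = FALSE)
  hyp <- rbind(fit$spatial_hyper, fit$spline_hyper)
  if (!is.null(hyp))
    utils::write.csv(hyp, paste0(prefix, "_hyper.csv"), row.names = FALSE)
  for (nm in names(fit$splines %||% list()))
    utils::write.csv(fit$splines[[nm]],
                     paste0(prefix, "_spline_", nm, ".csv"), row.names = FALSE)
  stage1 <- lapply(fit$stage1 %||% list(), function(s) s$hyper)
  jsonlite::write_json(
    list(kind = fit$kind,
         diagnostics = fit$diagnostics[c("converged", "elapsed_seconds")],
         spline_constraint = if (length(fit$spec$splines))
           "sum-to-zero across bins; unpenalized linear trend kept as an explicit coefficient"
         else NULL,
         stage1_hyper = stage1),
    paste0(prefix, "_summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(prefix)
}
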