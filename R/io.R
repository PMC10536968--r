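#' Energy/CV series files
#'
#' The package's delimited-text dialect for per-frame series: a comment
#' header (lines prefixed `#`, the last of which names the columns,
#' tab-separated) followed by tab-separated numeric rows in full
#' round-trip precision (17 significant digits).  Canonical columns are
#' `time_ps`, per-term potential energies (`V_<term id>`), per-region
#' boost energies (`dV_<region>`, `dV_total`) and CV columns; any column
#' set is accepted, so output of external engines can be ingested via
#' the `mapping` argument.
#'
#' @name energy_series
NULL

#' @rdname energy_series
#' @param df data.frame of numeric per-frame values; column names become
#'   the header.
#' @param path file path.
#' @param comments optional extra header comment lines (without `#`).
#' @export
write_energy_series <- function(df, path, comments = character()) {
  df <- as.data.frame(df)
  if (!nrow(df)) stop("refusing to write an empty series")
  if (anyDuplicated(names(df))) stop("column names must be unique")
  hdr <- c("# selgamd energy series v1",
           paste0("# ", comments),
           paste0("# ", paste(names(df), collapse = "\t")))
  hdr <- hdr[nzchar(sub("^# ?", "", hdr)) | grepl("series", hdr)]
  rows <- do.call(paste, c(lapply(df, function(col)
    sprintf("%.17g", as.numeric(col))), list(sep = "\t")))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname energy_series
#' @param mapping optional named character vector renaming file columns
#'   to canonical names, as `c(canonical = "file_column")`.
#' @param required character vector of column names that must be present
#'   after mapping.
#' @return `read_energy_series()`: data.frame of numeric columns.
#' @export
read_energy_series <- function(path, mapping = NULL, required = "time_ps") {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  if (!length(hdr)) stop("not an energy-series file (no '#' header): ", path)
  cols <- strsplit(sub("^#\\s*", "", hdr[length(hdr)]), "\t")[[1]]
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t")
  nbad <- which(lengths(parts) != length(cols))
  if (length(nbad))
    stop("row ", nbad[1], " has ", lengths(parts)[nbad[1]],
         " field(s), expected ", length(cols))
  df <- as.data.frame(lapply(seq_along(cols), function(j)
    vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[j]))
      v
    }, 0)), col.names = cols, check.names = FALSE)
  for (j in seq_along(df)) {
    raw <- vapply(parts, `[`, "", j)
    bad <- which(is.na(df[[j]]) & !raw %in% c("NA", "NaN", "nan"))
    if (length(bad))
      stop("non-numeric cell in column '", cols[j], "', row ", bad[1])
  }
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df)) stop("mapped column '", src, "' not in file")
      names(df)[names(df) == src] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df
}

#' Trajectory as an energy-series data.frame
#'
#' @param traj a `trajectory`.
#' @return data.frame with `time_ps`, `V_*` term columns, `dV_*` boost
#'   columns and CV columns.
#' @export
trajectory_series <- function(traj) {
  df <- data.frame(time_ps = traj$times, check.names = FALSE)
  te <- traj$term_energies
  colnames(te) <- paste0("V_", colnames(te))
  df <- cbind(df, as.data.frame(te, check.names = FALSE))
  df <- cbind(df, as.data.frame(traj$boost, check.names = FALSE))
  if (!is.null(traj$cv) && ncol(traj$cv))
    df <- cbind(df, as.data.frame(traj$cv, check.names = FALSE))
  df
}

#' Run configurations
#'
#' A run configuration is a YAML document with sections `system`,
#' `groups`, `regions`, `gamd`, `leus`, `cv`, `engine` and `output`,
#' mirroring the in-memory objects; it round-trips to an identical
#' in-memory form.  Region members use term ids or the compact
#' group-index notation (`"1-1"`, `"1-2"`).
#'
#' @param config a run-config list (see [build_run()] for the sections
#'   actually consumed).
#' @param path file path.
#' @name run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

#' @rdname run_config
#' @return `read_run_config()`: the configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(cfg$system) || is.null(cfg$system$type))
    stop("schema violation in ", path, ": section 'system' with field 'type' is required")
  cfg
}

#' Materialise a run configuration
#'
#' Builds the system, integrator config and (when defined) region set
#' from a configuration list.
#'
#' @param config list from [read_run_config()].
#' @return list with `system`, `cfg` (integrator), `regions` (or NULL),
#'   `catalogue`, `config` (the input).
#' @export
build_run <- function(config) {
  sysc <- config$system
  system <- switch(sysc$type,
    double_well = make_double_well(sysc$barrier %||% 20,
                                   period = sysc$period %||% 360,
                                   mass = sysc$mass %||% 1e-4),
    harmonic_well = make_harmonic_well(sysc$k_spring %||% 0.01,
                                       x0 = sysc$x0 %||% 0,
                                       mass = sysc$mass %||% 1e-4),
    solute_solvent = make_solute_solvent(sysc$n_solute %||% 4,
                                         sysc$n_solvent %||% 20,
                                         seed = sysc$seed %||% 1),
    stop("schema violation: unknown system type '", sysc$type, "'"))
  eng <- config$engine %||% list()
  cfg <- integrator_config(
    timestep = eng$timestep %||% 0.002,
    temperature = eng$temperature %||% 300,
    friction = eng$friction %||% 2,
    n_steps = eng$n_steps %||% 1000,
    output_stride = eng$output_stride %||% 10,
    seed = config$seed %||% eng$seed %||% 1)
  regions <- NULL
  catalogue <- NULL
  if (inherits(system, "bead_system")) {
    dual <- any(vapply(config$regions %||% list(),
                       function(r) isTRUE(r$dual_boost), TRUE))
    catalogue <- build_catalogue(system, dual_boost = dual)
    if (!is.null(config$regions)) {
      specs <- lapply(config$regions, function(r)
        acceleration_region(r$name, unlist(r$terms),
                            accelerate = r$accelerate %||% TRUE,
                            dual_boost = r$dual_boost %||% FALSE,
                            sigma0 = r$sigma0 %||%
                              (config$gamd$sigma0 %||% 10)))
      regions <- validate_regions(specs, catalogue)
    }
  }
  list(system = system, cfg = cfg, regions = regions,
       catalogue = catalogue, config = config)
}

#' Serialize a system definition
#'
#' @param system a `potential_surface` or `bead_system` built by the
#'   package constructors.
#' @param ... construction metadata (`type` plus constructor arguments)
#'   when the system was built directly.
#' @return a list suitable for the `system` section of a run config.
#' @export
system_config <- function(system, ...) {
  meta <- list(...)
  if (length(meta)) return(meta)
  if (inherits(system, "potential_surface")) {
    if (system$harm_k != 0)
      list(type = "harmonic_well", k_spring = system$harm_k,
           x0 = system$harm_x0, mass = system$mass)
    else list(type = "double_well",
              barrier = 2 * system$cos_amp[1], period = system$period,
              mass = system$mass)
  } else stop("pass construction metadata for bead systems")
}
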