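#' Load and validate a run configuration
#'
#' The configuration is one human-readable YAML file with sections
#' `lattice`, `potentials`, `protocol`, `dynamics` and `output`. All
#' physical quantities carry fixed units (nm, fs, K, kJ/mol-based); no
#' unit inference is performed. Unknown keys are rejected. Missing keys
#' are filled with the model defaults (spacing 9.17 nm, the default
#' pristine/damaged potentials, 5% horizontal strain, 350 fs time step,
#' 300 K, friction 0.1/ps) and every filled default is reported via
#' `message()`.
#'
#' @param path path to a YAML configuration file.
#' @param quiet suppress the filled-default messages.
#' @return an object of class `cg_config`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  .validate_config(raw, quiet = quiet)
}

#' @rdname load_config
#' @param config a configuration list (possibly partial).
#' @export
as_cg_config <- function(config, quiet = TRUE) .validate_config(config, quiet)

.config_defaults <- function() list(
  lattice = list(n_cols = 100L, n_rows = 100L, spacing = 9.17,
                 species = "P", mass = 1e6, boundary = "clamped",
                 notch = list(center_col = 50L, width_blocks = 0L, depth_rows = 0L)),
  potentials = list(
    PP = list(k = 1.77e5, r0 = 9.17, rc = 9.65),
    DD = list(k = 1.10e5, r0 = 9.35, rc = 9.82),
    PD = NULL),  # NULL = use DD (mixing rule)
  protocol = list(axis = "horizontal", magnitude = 0.05, hold_steps = 10000L),
  dynamics = list(time_step = 350, temperature = 300, friction = 0.1,
                  random_seed = 1L, snapshot_every = 0L, series_every = 100L),
  output = list(directory = "cgfrac_out")
)

.validate_config <- function(raw, quiet = FALSE) {
  defaults <- .config_defaults()
  if (!is.list(raw)) stop("configuration must be a key-value mapping", call. = FALSE)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- defaults
  filled <- character(0)
  for (sec in names(defaults)) {
    user <- raw[[sec]]
    if (is.null(user)) {
      filled <- c(filled, sec)
      next
    }
    bad <- setdiff(names(user), names(defaults[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (key in names(defaults[[sec]])) {
      if (key %in% names(user)) {
        val <- user[[key]]
        if (sec == "potentials" && key == "PD" && is.null(val)) next
        if (key == "notch" || (sec == "potentials" && key %in% c("PP", "DD", "PD"))) {
          sub_def <- defaults[[sec]][[key]]
          if (sec == "potentials" && is.null(sub_def)) sub_def <- defaults$potentials$DD
          bad2 <- setdiff(names(val), names(sub_def))
          if (length(bad2))
            stop("unknown key(s) in ", sec, "$", key, ": ",
                 paste(bad2, collapse = ", "), call. = FALSE)
          merged <- sub_def
          merged[names(val)] <- val
          val <- merged
        }
        cfg[[sec]][[key]] <- val
      } else {
        filled <- c(filled, paste0(sec, "$", key))
      }
    }
  }
  # cross-field validation (delegates to the constructors)
  pots <- config_potentials(cfg)
  if (cfg$protocol$magnitude < 0)
    stop("configuration error at protocol$magnitude: strain must be >= 0",
         call. = FALSE)
  strain_protocol(cfg$protocol$axis, cfg$protocol$magnitude,
                  cfg$protocol$hold_steps)
  do.call(dynamics_config, c(cfg$dynamics, list(n_steps = cfg$protocol$hold_steps)))
  if (cfg$lattice$spacing <= 0)
    stop("configuration error at lattice$spacing: must be positive", call. = FALSE)
  if (cfg$lattice$n_cols < 1 || cfg$lattice$n_rows < 1)
    stop("configuration error at lattice size: must be >= 1", call. = FALSE)
  if (!cfg$lattice$boundary %in% c("clamped", "periodic_x"))
    stop("configuration error at lattice$boundary: must be 'clamped' or 'periodic_x'",
         call. = FALSE)
  if (!quiet && length(filled))
    message("config defaults filled: ", paste(filled, collapse = ", "))
  structure(cfg, class = "cg_config")
}

#' Serialize a configuration back to YAML
#'
#' A round trip `load_config(write_config(cfg, path))` yields an
#' identical configuration.
#'
#' @param config a `cg_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cg_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' `config_system()` builds the (possibly notched) lattice,
#' `config_potentials()` the [potential_table()], `config_protocol()` the
#' [strain_protocol()], and `config_dynamics()` the [dynamics_config()].
#'
#' @param config a `cg_config` (see [load_config()]).
#' @return the corresponding model object.
#' @export
config_system <- function(config) {
  stopifnot(inherits(config, "cg_config"))
  lat <- config$lattice
  sys <- build_hexagonal_lattice(lat$n_cols, lat$n_rows, lat$spacing,
                                 lat$species, lat$mass, lat$boundary)
  if (!is.null(lat$notch) && lat$notch$width_blocks > 0 && lat$notch$depth_rows > 0)
    sys <- insert_notch(sys, lat$notch$center_col, lat$notch$width_blocks,
                        lat$notch$depth_rows)
  sys
}

#' @rdname config_system
#' @export
config_potentials <- function(config) {
  p <- config$potentials
  pp <- pair_potential(p$PP$k, p$PP$r0, p$PP$rc)
  dd <- pair_potential(p$DD$k, p$DD$r0, p$DD$rc)
  pd <- if (is.null(p$PD)) dd else pair_potential(p$PD$k, p$PD$r0, p$PD$rc)
  potential_table(pp = pp, dd = dd, pd = pd)
}

#' @rdname config_system
#' @export
config_protocol <- function(config) {
  stopifnot(inherits(config, "cg_config"))
  strain_protocol(config$protocol$axis, config$protocol$magnitude,
                  config$protocol$hold_steps)
}

#' @rdname config_system
#' @export
config_dynamics <- function(config) {
  stopifnot(inherits(config, "cg_config"))
  do.call(dynamics_config,
          c(config$dynamics, list(n_steps = config$protocol$hold_steps)))
}
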