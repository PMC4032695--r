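#' Configuration
#'
#' A single INI-style plain-text file with sections [gabor], [abm], [flow],
#' [fuzzy], [snn], [pipeline]. Every option has a documented default;
#' [biomotion_config()] returns the full default tree and merges overrides.
#'
#' @name config
NULL

#' Default configuration
#'
#' @param overrides nested named list merged over the defaults (section ->
#'   option).
#' @return nested named list of all options.
#' @export
biomotion_config <- function(overrides = list()) {
  cfg <- list(
    gabor = list(n_orientations = 8L, n_scales = 2L, base_size = 17L,
                 omega0 = pi / 2, scale_step = sqrt(2), gamma = 0.5),
    abm = list(n_elements = 6L, saturation = 6, bound_location = 2L,
               bound_orientation = 1L, inhibition_radius = NA),
    flow = list(rho = 0.05, xi = 0.03, n_levels = 4L, n_outer = 5L,
                n_inner = 3L, n_jacobi = 50L, presmooth_sigma = 0.8,
                eps = 1e-3),
    fuzzy = list(tau = 0.1, beta = 2, beta_prime = 2, N = 3L, margin = 0.05,
                 enable_left_right = FALSE),
    snn = list(P1 = 0.1, P2 = 0.1, prototype_mode = "retained"),
    pipeline = list(n_snippets = 5L, min_frames = 3L, mirror_augment = FALSE,
                    roi_quantile = 0.9, roi_dilate = 4L, use_abm = TRUE,
                    gate_enabled = TRUE, decision = "gate_then_snn")
  )
  for (sec in names(overrides)) {
    if (!sec %in% names(cfg)) stop("unknown config section [", sec, "]",
                                   call. = FALSE)
    for (opt in names(overrides[[sec]])) {
      if (!opt %in% names(cfg[[sec]]))
        stop("unknown option '", opt, "' in section [", sec, "]",
             call. = FALSE)
      cfg[[sec]][[opt]] <- overrides[[sec]][[opt]]
    }
  }
  cfg
}

#' Read / write the INI configuration file
#'
#' @param path file path.
#' @param config nested list as returned by [biomotion_config()].
#' @return `read_config` returns the full configuration (defaults overlaid
#'   with the file's values); `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  config_from_lines(readLines(path, warn = FALSE))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(config_to_lines(config), path)
  invisible(path)
}

# INI-format serialization shared by write_config and the model container.
config_to_lines <- function(config) {
  out <- character(0)
  for (sec in names(config)) {
    out <- c(out, sprintf("[%s]", sec))
    for (opt in names(config[[sec]])) {
      v <- config[[sec]][[opt]]
      sv <- if (is.logical(v) && !is.na(v)) tolower(as.character(v))
      else if (is.numeric(v)) sprintf("%.17g", v)
      else as.character(v)
      out <- c(out, sprintf("%s = %s", opt, sv))
    }
    out <- c(out, "")
  }
  out
}

config_from_lines <- function(lines) {
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nzchar(lines)]
  over <- list()
  sec <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L || is.null(sec))
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parsed <- if (val %in% c("true", "TRUE")) TRUE
    else if (val %in% c("false", "FALSE")) FALSE
    else if (val %in% c("NA", "na")) NA
    else if (grepl("^-?[0-9.eE+-]+$", val)) as.numeric(val)
    else val
    over[[sec]][[key]] <- parsed
  }
  biomotion_config(over)
}
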