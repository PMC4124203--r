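#' Default run configuration
#'
#' The flat key-value configuration understood by [sq_load_config()] and
#' the `sqsim` command line. Defaults are the standard study conditions.
#'
#' @return Named list of defaults.
#' @export
sq_default_config <- function() {
  list(side = 20, rho = 0.3, tstar = 1.0, lambda = 1.5,
       moves = 3000, max_disp = 0.5, retry_cap = 1e6, realizations = 100,
       u1 = 1.0, u2 = 1.0, pattern = NULL, dr = 0.05, rmax = NULL)
}

#' Load and validate a run configuration
#'
#' Reads a flat YAML key-value file (all keys optional; missing keys take
#' the defaults of [sq_default_config()]), applies overrides on top, and
#' validates everything at once, reporting every violation in a single
#' error. Unknown keys are rejected.
#'
#' The optional `pattern` key is a list of `(label, width, factor)` triples
#' (widths as fractions summing to 1); when present it overrides `u1`/`u2`.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file (e.g. CLI flags).
#' @return An object of class \code{sq_run_config}: the validated flat
#'   list plus assembled `box`, `pattern_obj`, `potential` and `sim`
#'   components.
#' @export
sq_load_config <- function(path = NULL, overrides = list()) {
  cfg <- sq_default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    if (is.null(file_cfg)) file_cfg <- list()
    cfg <- merge_config(cfg, file_cfg, "config file")
  }
  cfg <- merge_config(cfg, overrides, "overrides")
  validate_config(cfg)
  build_run_config(cfg)
}

merge_config <- function(cfg, new, what) {
  if (length(new) == 0) return(cfg)
  if (is.null(names(new)) || any(names(new) == ""))
    stop("all entries in ", what, " must be named")
  unknown <- setdiff(names(new), names(cfg))
  if (length(unknown) > 0)
    stop("unknown key(s) in ", what, ": ", paste(unknown, collapse = ", "))
  modifyList(cfg, new)
}

validate_config <- function(cfg) {
  bad <- character(0)
  num1 <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)
  chk <- function(ok, msg) if (!ok) bad <<- c(bad, msg)
  chk(num1(cfg$side) && cfg$side > 0, "side must be a positive number")
  chk(num1(cfg$rho) && cfg$rho > 0 && cfg$rho < 0.547,
      "rho must be in (0, 0.547) (RSA jamming bound for disks)")
  chk(num1(cfg$tstar) && cfg$tstar > 0, "tstar must be positive")
  chk(num1(cfg$lambda) && cfg$lambda > 1, "lambda must exceed 1")
  chk(num1(cfg$side) && num1(cfg$lambda) && cfg$side > 2 * cfg$lambda,
      "side must exceed 2*lambda (minimum-image validity)")
  chk(num1(cfg$moves) && cfg$moves >= 0 && cfg$moves == round(cfg$moves),
      "moves must be a non-negative integer")
  chk(num1(cfg$max_disp) && cfg$max_disp > 0,
      "max_disp must be positive")
  chk(num1(cfg$retry_cap) && cfg$retry_cap >= 1,
      "retry_cap must be at least 1")
  chk(num1(cfg$realizations) && cfg$realizations >= 1 &&
        cfg$realizations == round(cfg$realizations),
      "realizations must be a positive integer")
  chk(num1(cfg$u1) && cfg$u1 > 0, "u1 must be positive")
  chk(num1(cfg$u2) && cfg$u2 > 0, "u2 must be positive")
  chk(num1(cfg$dr) && cfg$dr > 0, "dr must be positive")
  chk(is.null(cfg$rmax) || (num1(cfg$rmax) && cfg$rmax > 0),
      "rmax must be positive when given")
  if (!is.null(cfg$pattern)) {
    ok <- is.list(cfg$pattern) && length(cfg$pattern) >= 1 &&
      all(vapply(cfg$pattern, function(tr)
        is.list(tr) && all(c("label", "width", "factor") %in% names(tr)),
        logical(1)))
    chk(ok, "pattern must be a list of (label, width, factor) triples")
  }
  if (length(bad) > 0)
    stop("invalid configuration:\n  - ", paste(bad, collapse = "\n  - "))
  invisible(TRUE)
}

build_run_config <- function(cfg) {
  pat <- if (is.null(cfg$pattern)) stripe_pattern(cfg$u1, cfg$u2)
  else sq_pattern(widths = vapply(cfg$pattern, `[[`, numeric(1), "width"),
                  labels = vapply(cfg$pattern, `[[`, character(1), "label"),
                  factors = vapply(cfg$pattern, `[[`, numeric(1), "factor"))
  structure(c(cfg, list(
    box = sq_box(cfg$side),
    pattern_obj = pat,
    potential = sq_potential(lambda = cfg$lambda, tstar = cfg$tstar),
    sim = sq_sim_params(rho = cfg$rho, moves = cfg$moves,
                        max_disp = cfg$max_disp, retry_cap = cfg$retry_cap,
                        realizations = cfg$realizations))),
    class = "sq_run_config")
}

#' Write the flat part of a configuration back to YAML
#'
#' The echo re-loaded through [sq_load_config()] reproduces an identical
#' configuration, making output directories self-describing.
#'
#' @param config An \code{sq_run_config}.
#' @param path Output YAML path.
#' @export
sq_write_config <- function(config, path) {
  flat <- config[names(sq_default_config())]
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Run an ensemble from a configuration
#'
#' @param config An \code{sq_run_config}.
#' @param seed Master seed.
#' @return An \code{sq_ensemble}.
#' @export
sq_run <- function(config, seed = 1) {
  stopifnot(inherits(config, "sq_run_config"))
  run_ensemble(box = config$box, pattern = config$pattern_obj,
               potential = config$potential, sim = config$sim, seed = seed)
}

#' Export / import ensembles as CSV tables
#'
#' The table has one row per particle with columns `realization`,
#' `particle_index`, `x`, `y`, `region`, `final_energy`; box side and seed
#' travel in `# key: value` comment lines at the top.
#'
#' @param ensemble An \code{sq_ensemble}.
#' @param path CSV path.
#' @export
write_configurations <- function(ensemble, path) {
  clist <- as_config_list(ensemble)
  rows <- do.call(rbind, lapply(seq_along(clist), function(k) {
    cf <- clist[[k]]
    data.frame(realization = k, particle_index = seq_along(cf$x),
               x = cf$x, y = cf$y,
               region = if (is.null(cf$region)) NA_character_ else cf$region,
               final_energy = if (is.null(cf$energy)) NA_real_ else cf$energy)
  }))
  box <- attr(ensemble, "box")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box)) writeLines(sprintf("# side: %.17g", box$side), con)
  if (!is.null(attr(ensemble, "seed")))
    writeLines(sprintf("# seed: %d", attr(ensemble, "seed")), con)
  write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_configurations
#' @param path CSV path written by [write_configurations()] (or any table
#'   with at least `realization`, `x`, `y` columns).
#' @param box An [sq_box]; recovered from the `# side:` header when omitted.
#' @return An \code{sq_ensemble}.
#' @export
read_configurations <- function(path, box = NULL) {
  hdr <- readLines(path, n = 10)
  if (is.null(box)) {
    m <- grep("^# side:", hdr, value = TRUE)
    if (length(m) == 1) box <- sq_box(as.numeric(sub("^# side:", "", m)))
    else stop("no '# side:' header; supply box explicitly")
  }
  tab <- read.csv(path, comment.char = "#")
  configs <- lapply(split(tab, tab$realization), function(df)
    data.frame(x = df$x, y = df$y,
               region = if ("region" %in% names(df)) df$region else NULL,
               energy = if ("final_energy" %in% names(df)) df$final_energy
                        else NULL))
  names(configs) <- NULL
  structure(configs, box = box, class = "sq_ensemble")
}
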