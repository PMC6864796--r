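#' Load a run configuration file
#'
#' YAML file with optional sections `alignment`, `detector`, `profile`
#' (with sub-sections `lokomat` / `lyra`), `stimulation` and `simulator`.
#' Keys inside each section must name arguments of the corresponding
#' constructor ([alignment_config()], [detector_config()],
#' [gait_phase_anchors()], [simulate_gait()]); unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param path YAML file path, or `NULL` for an empty configuration.
#' @return A named list of class `run_config` with the (possibly empty)
#'   sections.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("alignment", "detector", "profile", "stimulation", "simulator")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    abort(paste0("unknown config section(s): ", paste(extra, collapse = ", ")))
  }
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      abort(paste0("unknown key(s) in [", where, "]: ", paste(extra, collapse = ", ")))
    }
    x
  }
  cfg$alignment <- check_keys(
    cfg$alignment %||% list(), names(formals(alignment_config)), "alignment"
  )
  det_keys <- setdiff(names(formals(detector_config)), c("profile", "alignment", "..."))
  cfg$detector <- check_keys(cfg$detector %||% list(), det_keys, "detector")
  for (p in names(cfg$profile %||% list())) {
    if (!p %in% c("lokomat", "lyra")) abort(paste0("unknown profile: ", p))
    check_keys(cfg$profile[[p]], det_keys, paste0("profile.", p))
  }
  cfg$stimulation <- check_keys(
    cfg$stimulation %||% list(),
    c("fc", "ho", "to", "chart", "current", "frequency", "pulse_width"),
    "stimulation"
  )
  sim_keys <- setdiff(names(formals(simulate_gait)), "seed")
  cfg$simulator <- check_keys(cfg$simulator %||% list(), sim_keys, "simulator")
  structure(cfg, class = "run_config")
}

#' Build a detector configuration from a run configuration
#'
#' Merges, in increasing precedence: package defaults, the `[detector]`
#' section, the `[profile.<profile>]` section, then `...` overrides.
#'
#' @param run A `run_config` from [load_run_config()].
#' @param profile Device profile name.
#' @param ... Final overrides (e.g. from command-line flags).
#' @return A [detector_config()].
#' @export
detector_config_from <- function(run = load_run_config(),
                                 profile = c("lokomat", "lyra"), ...) {
  profile <- match.arg(profile)
  args <- c(run$detector %||% list(), (run$profile %||% list())[[profile]] %||% list())
  dots <- list(...)
  args[names(dots)] <- dots
  if (length(run$alignment %||% list()) > 0) {
    args$alignment <- do.call(alignment_config, run$alignment)
  }
  args$a_heeloff_thresh <- unlist(args$a_heeloff_thresh) %||% NULL
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(detector_config, c(list(profile = profile), args))
}
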