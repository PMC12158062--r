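# Run configuration: defaults resolve to the reference setup (six 300-s
# segments, Table-6-style hyperparameters, 300-s windows); every field is
# overridable from a JSON file and/or --set key=value flags with
# precedence CLI > file > defaults.

#' Default run configuration
#'
#' @param seed master seed; every per-session and training seed derives
#'   from it.
#' @return nested list of class `run_config` with `generator`, `training`,
#'   `evaluation`, `seed` and `log_level` entries.
#' @export
run_config <- function(seed = 1L) {
  structure(
    list(
      generator = list(
        n_sessions = 17L, segment_duration_s = 300L,
        hr_rest = 65, hr_slope = 9, noise_sd = 2, ar = 0.9, tau_s = 30
      ),
      training = unclass(dqn_config(seed = as.integer(seed))),
      evaluation = list(clamp_keytel = TRUE, fill = "locf",
                        met_offset = 0),
      seed = as.integer(seed),
      log_level = "info"
    ),
    class = "run_config"
  )
}

# recursive merge: values in `over` replace same-named values in `base`
merge_config <- function(base, over) {
  for (k in names(over)) {
    if (is.list(base[[k]]) && is.list(over[[k]])) {
      base[[k]] <- merge_config(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Load a run configuration
#'
#' @param path optional JSON config file; fields present there override the
#'   defaults.
#' @param overrides character vector of `key=value` strings with dot paths
#'   (e.g. `"training.epochs=10"`, `"generator.noise_sd=0"`); they override
#'   both defaults and file.
#' @param seed optional master seed override.
#' @return a `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = character(0),
                            seed = NULL) {
  cfg <- unclass(run_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    cfg <- merge_config(cfg, jsonlite::read_json(path,
                                                 simplifyVector = TRUE))
  }
  for (ov in overrides) {
    kv <- regmatches(ov, regexpr("=", ov), invert = TRUE)[[1]]
    if (length(kv) != 2) stop("bad --set override (need key=value): ", ov,
                              call. = FALSE)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    value <- utils::type.convert(kv[2], as.is = TRUE)
    cfg[[keys]] <- value
  }
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    cfg$training$seed <- as.integer(seed)
  }
  structure(cfg, class = "run_config")
}

training_config <- function(cfg) {
  do.call(dqn_config, cfg$training)
}

#' Short stable hash of a configuration
#'
#' Polynomial rolling hash of the canonical JSON serialization; embedded
#' in every output artifact so a run is reconstructable from its output
#' directory alone.
#'
#' @param x any jsonlite-serializable object.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     null = "null"))
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

log_msg <- function(cfg, level, ...) {
  threshold <- .log_levels[[cfg$log_level %||% "info"]]
  if (.log_levels[[level]] >= threshold) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  logfile <- attr(cfg, "logfile")
  if (!is.null(logfile)) {
    cat(sprintf("%s [%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                toupper(level), paste0(...)),
        file = logfile, append = TRUE)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
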