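# Run configuration.
#
# Every tunable threshold in the pipeline lives in one nested config:
# band definitions are fixed (consensus targets), everything else —
# sampling interval, gap threshold, grid step, epoch length, MET
# cutpoints, guideline minutes, flag thresholds, review-period length,
# standard-time offset — is configurable.  Config files are JSON (or YAML);
# unknown keys are rejected so typos fail loudly.

#' Default run configuration
#'
#' @return nested list of defaults; see the fields for units.
#' @export
default_config <- function() {
  list(
    time = list(std_offset_min = 0),
    period = list(days = 14),
    cgm = list(sampling_interval_min = 5),
    sync = list(gap_threshold_min = 15, grid_step_min = 1),
    activity = list(epoch_minutes = 15,
                    met_cutpoints = c(1.5, 3),
                    guideline_minutes = 60),
    flags = list(drop_threshold = 50, hypo_threshold = 70,
                 min_cgm_wear = 70, min_tracker_wear = 50,
                 min_guideline_pct = 50, tir_drop_pp = 5,
                 activity_drop_pct = 25))
}

# Recursive merge of a user config into the defaults; unknown keys are an
# error, naming the full key path.
.merge_config <- function(base, user, path = character()) {
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base))
      stop("unknown config key: ", here)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key ", here, " must be a table")
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]], c(path, nm))
    } else {
      base[[nm]] <- unlist(user[[nm]])
    }
  }
  base
}

#' Read a run configuration file
#'
#' JSON (`.json`) or YAML (`.yaml`/`.yml`); keys given in the file override
#' the defaults, unknown keys are rejected.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return validated nested config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("cannot read config file: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, " (use .json or .yaml)"))
  cfg <- .merge_config(cfg, user)
  stopifnot(cfg$period$days > 0, cfg$cgm$sampling_interval_min > 0,
            cfg$sync$gap_threshold_min > 0, cfg$sync$grid_step_min > 0,
            cfg$activity$epoch_minutes > 0,
            cfg$activity$guideline_minutes > 0,
            cfg$flags$drop_threshold > 0, cfg$flags$hypo_threshold > 0)
  cfg
}

#' Fingerprint a configuration
#'
#' 32-bit FNV-1a hash of the canonical JSON serialization; logged by the
#' CLI so a run's effective config is auditable.
#'
#' @param config nested config list.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  txt <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                       digits = NA))
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  # FNV prime 16777619 = 2^24 + 2^8 + 2^7 + 2^4 + 2^1 + 2^0; the multiply
  # is done shift-wise so every intermediate stays exactly representable
  shifts <- c(0, 1, 4, 7, 8, 24)
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- sum((h %% 2^(32 - shifts)) * 2^shifts) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
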