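#' Run configuration
#'
#' All tunables of the tracking and counting pipeline live in one flat named
#' list with documented defaults. [load_config()] merges a YAML override file
#' onto the defaults and rejects unknown keys or out-of-range values.
#'
#' @name config
NULL

#' Default pipeline configuration
#'
#' @return named list of defaults:
#' \describe{
#'   \item{min_confidence}{detections below this score are dropped at ingest
#'     (0.3).}
#'   \item{max_cosine}{cosine-distance acceptance threshold of the cascade
#'     (0.2).}
#'   \item{chi2_gate}{Mahalanobis gate, chi-square 0.95 quantile at 4 dof
#'     (9.4877).}
#'   \item{iou_max_cost}{cost cap of the IOU fallback stage, i.e. matches need
#'     IOU >= 0.3 (0.7).}
#'   \item{n_init}{consecutive hits before a tentative track is confirmed (3).}
#'   \item{max_age}{frames a confirmed track survives unmatched, 1 s at 30 fps
#'     (30).}
#'   \item{gallery_size}{embedding gallery budget per track (100).}
#'   \item{rematch_threshold}{cosine threshold of the appearance re-matching
#'     stage, stricter than the cascade (0.15).}
#'   \item{enable_rematch}{toggle for the appearance re-matching stage (TRUE).}
#'   \item{enable_postprocess}{toggle for offline segment merging (TRUE).}
#'   \item{w_pos, w_vel}{Kalman noise weights per unit box height (1/20,
#'     1/160).}
#'   \item{stability_min_length}{segments shorter than this are unstable (5).}
#'   \item{stability_v_partial}{appearance-similarity variance above which a
#'     segment is only partially stable (0.01).}
#'   \item{stability_v_max}{variance above which a segment is unstable (0.05).}
#'   \item{vote_s_min}{cosine similarity counted as a vote in the M x N pair
#'     matrix (0.8).}
#'   \item{merge_max_gap}{largest temporal gap (missing frames) bridged by a
#'     merge, 1.5 s at 30 fps (45).}
#'   \item{merge_p_max}{position tolerance in mean-diagonal units (1.0).}
#'   \item{merge_r_max}{largest allowed width/height ratio between merged
#'     segments (1.5).}
#'   \item{iou_match_threshold}{minimum overlap for a CLEAR-MOT match (0.5).}
#'   \item{motp_mode}{"overlap" (mean IOU of matches, in percent) or
#'     "distance" (mean normalized center distance of matches, in percent).}
#'   \item{seed}{seed recorded for synthetic runs (1).}
#' }
#' @export
default_config <- function() {
  list(
    min_confidence = 0.3,
    max_cosine = 0.2,
    chi2_gate = 9.4877,
    iou_max_cost = 0.7,
    n_init = 3L,
    max_age = 30L,
    gallery_size = 100L,
    rematch_threshold = 0.15,
    enable_rematch = TRUE,
    enable_postprocess = TRUE,
    w_pos = 1 / 20,
    w_vel = 1 / 160,
    stability_min_length = 5L,
    stability_v_partial = 0.01,
    stability_v_max = 0.05,
    vote_s_min = 0.8,
    merge_max_gap = 45L,
    merge_p_max = 1.0,
    merge_r_max = 1.5,
    iou_match_threshold = 0.5,
    motp_mode = "overlap",
    seed = 1L
  )
}

validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  num_pos <- c(
    "max_cosine", "chi2_gate", "iou_max_cost", "rematch_threshold",
    "w_pos", "w_vel", "stability_v_partial", "stability_v_max",
    "vote_s_min", "merge_p_max", "merge_r_max"
  )
  for (key in num_pos) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("configuration key '", key, "' must be a positive number")
    }
  }
  for (key in c(
    "n_init", "max_age", "gallery_size",
    "stability_min_length", "merge_max_gap"
  )) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop("configuration key '", key, "' must be a positive integer")
    }
    config[[key]] <- as.integer(v)
  }
  if (!is.numeric(config$min_confidence) || config$min_confidence < 0 ||
    config$min_confidence > 1) {
    stop("configuration key 'min_confidence' must be in [0, 1]")
  }
  if (!is.numeric(config$iou_match_threshold) ||
    config$iou_match_threshold <= 0 || config$iou_match_threshold > 1) {
    stop("configuration key 'iou_match_threshold' must be in (0, 1]")
  }
  if (config$stability_v_partial > config$stability_v_max) {
    stop("'stability_v_partial' must not exceed 'stability_v_max'")
  }
  if (!config$motp_mode %in% c("overlap", "distance")) {
    stop("configuration key 'motp_mode' must be 'overlap' or 'distance'")
  }
  for (key in c("enable_rematch", "enable_postprocess")) {
    if (!is.logical(config[[key]]) || length(config[[key]]) != 1L ||
      is.na(config[[key]])) {
      stop("configuration key '", key, "' must be TRUE or FALSE")
    }
  }
  config
}

#' Load a configuration file
#'
#' Reads a YAML file of key-value overrides, merges it onto
#' [default_config()], validates and returns the resolved configuration.
#' Unknown keys are an error; missing keys take their defaults; a missing or
#' `NULL` path returns the validated defaults.
#'
#' @param path path to a YAML file, or `NULL`.
#' @param verbose if `TRUE`, log the fully resolved configuration to stderr.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL, verbose = FALSE) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("configuration file not found: ", path)
    }
    overrides <- yaml::read_yaml(path)
    if (length(overrides) > 0L) {
      if (is.null(names(overrides)) || any(names(overrides) == "")) {
        stop("configuration file must be a mapping of key: value pairs")
      }
      config[names(overrides)] <- overrides
    }
  }
  config <- validate_config(config)
  if (verbose) {
    message(
      "resolved configuration:\n",
      paste0("  ", names(config), " = ",
        vapply(config, function(x) paste(format(x), collapse = ","),
          character(1)
        ),
        collapse = "\n"
      )
    )
  }
  config
}
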