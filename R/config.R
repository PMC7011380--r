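# Hierarchical run configuration shared by the command-line entry point.

#' Default run configuration
#'
#' Every tunable default of the pipeline, keyed hierarchically. Unknown keys
#' are rejected by [resolve_config()]; every run of [run_subcommand()]
#' writes its resolved configuration alongside its outputs.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    glove = list(window = 5L, distance_weighting = "inverse", dim = 100L,
                 iterations = 1000L, learning_rate = 0.05, x_max = 100,
                 alpha = 0.75, combine = "sum"),
    sampler = list(m = 256L, composition = "balanced"),
    network = list(variant = "full", head = "classification",
                   recurrent_units = 30L,
                   conv_filters = c(10L, 20L, 40L, 80L, 100L),
                   conv_kernels = c(5L, 5L, 3L, 3L, 3L),
                   dropout_rate = 0.3, learning_rate = 0.01, epochs = 100L,
                   validation_fraction = 0.1, patience = 10L,
                   freeze_embedding = FALSE),
    eval = list(threshold = 0.5),
    cfd = list(strict = TRUE, position_origin = "pam_distal"),
    simulate = list(n_sgrnas = 29L, sites_per_sgrna = 500L,
                    imbalance_ratio = 250, noise_sd = 0.05,
                    mismatch_min = 1L, mismatch_max = 5L)
  )
}

merge_config <- function(base, overrides, prefix = "") {
  unknown <- character(0)
  for (key in names(overrides)) {
    full <- if (nzchar(prefix)) paste(prefix, key, sep = ".") else key
    if (!key %in% names(base)) {
      unknown <- c(unknown, full)
    } else if (is.list(base[[key]]) && is.list(overrides[[key]])) {
      res <- merge_config(base[[key]], overrides[[key]], full)
      base[[key]] <- res$config
      unknown <- c(unknown, res$unknown)
    } else {
      value <- overrides[[key]]
      if (is.numeric(base[[key]]) && is.character(value)) {
        value <- suppressWarnings(as.numeric(unlist(strsplit(value, ","))))
      }
      if (is.logical(base[[key]]) && is.character(value)) {
        value <- as.logical(value)
      }
      base[[key]] <- value
    }
  }
  list(config = base, unknown = unknown)
}

#' Resolve a run configuration
#'
#' Deep-merges overrides (from a YAML file and/or a named list, the list
#' winning) into [default_config()]. Validation failures list every
#' offending key at once.
#'
#' @param overrides Named (possibly nested) list of overrides; flat
#'   dot-separated names such as `"network.epochs"` are also accepted.
#' @param file Optional YAML file of overrides.
#' @return The resolved configuration list.
#' @export
resolve_config <- function(overrides = list(), file = NULL) {
  cfg <- default_config()
  unknown <- character(0)
  nest <- function(flat) {
    out <- list()
    for (nm in names(flat)) {
      path <- strsplit(nm, ".", fixed = TRUE)[[1]]
      node <- flat[[nm]]
      for (p in rev(path)) node <- stats::setNames(list(node), p)
      out <- utils::modifyList(out, node)
    }
    out
  }
  for (src in list(if (!is.null(file)) yaml::read_yaml(file), overrides)) {
    if (is.null(src) || !length(src)) next
    if (any(grepl(".", names(src), fixed = TRUE))) src <- nest(src)
    res <- merge_config(cfg, src)
    cfg <- res$config
    unknown <- c(unknown, res$unknown)
  }
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg
}

log_line <- function(cfg, stage, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf("[%s] %-10s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}

write_run_snapshot <- function(cfg, out_dir, subcommand) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  snapshot <- c(list(subcommand = subcommand,
                     package_version =
                       as.character(utils::packageVersion("crisprot"))),
                cfg)
  yaml::write_yaml(snapshot, file.path(out_dir, "run-config.yaml"))
}
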