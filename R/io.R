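## Text-format round-tripping: trace CSV + JSON metadata sidecars, feature
## tables, run manifests. All floating-point text output uses 6 significant
## digits for reproducible diffs.

.FMT_DIGITS <- 6

.fmt <- function(x) signif(x, .FMT_DIGITS)

#' Write a set of voltage traces
#'
#' Each trace becomes `<stem>_<k>.csv` (columns `t_ms,v_mV`) with a JSON
#' sidecar `<stem>_<k>.json` holding the stimulus metadata.
#'
#' @param traces List of [voltage_trace()] objects.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; default `"trace"`.
#' @return Invisibly, the CSV paths.
#' @export
write_traces <- function(traces, dir, stem = "trace") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(traces))
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    csv <- file.path(dir, sprintf("%s_%03d.csv", stem, k))
    write.csv(data.frame(t_ms = .fmt(tr$t_ms), v_mV = .fmt(tr$v_mV)),
              csv, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(tr$meta, sub("\\.csv$", ".json", csv),
                         auto_unbox = TRUE, digits = NA)
    paths[k] <- csv
  }
  invisible(paths)
}

#' Read a set of voltage traces
#'
#' @param dir Directory holding `*.csv` traces with `*.json` sidecars.
#' @return List of [voltage_trace()] objects.
#' @export
read_traces <- function(dir) {
  csvs <- sort(list.files(dir, "\\.csv$", full.names = TRUE))
  if (!length(csvs)) stop("no trace CSVs found in ", dir)
  lapply(csvs, function(csv) {
    side <- sub("\\.csv$", ".json", csv)
    if (!file.exists(side))
      stop("missing metadata sidecar for ", basename(csv))
    d <- read.csv(csv)
    if (!all(c("t_ms", "v_mV") %in% names(d)))
      stop("trace CSV must have columns t_ms,v_mV")
    dt <- diff(d$t_ms)
    if (any(abs(dt - dt[1]) > 1e-6 * dt[1] + 1e-9))
      stop("non-uniform time base in ", basename(csv))
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    voltage_trace(d$t_ms, d$v_mV, as.list(meta))
  })
}

#' Write a feature table as TSV
#'
#' Long format: cell, species, protocol, amplitude, feature, value.
#'
#' @param df Feature data frame.
#' @param path Output TSV path.
#' @export
write_feature_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmt)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_feature_table <- function(path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)

#' Write a run manifest
#'
#' Records command, configuration hash, seeds, inputs/outputs and the
#' package version for reproducibility.
#'
#' @param dir Output directory.
#' @param command Command label.
#' @param config Configuration list (hashed into the manifest).
#' @param seed Seed(s) used.
#' @param inputs,outputs Character vectors of paths.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, command, config = list(), seed = NA,
                           inputs = character(0), outputs = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    command = command,
    config_hash = unname(tools::md5sum(
      local({ f <- tempfile(); writeLines(cfg_json, f); f }))),
    seed = seed, inputs = inputs, outputs = outputs,
    tool_version = as.character(utils::packageVersion("ca1pyr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}
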