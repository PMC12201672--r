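# Delimited-text readers and writers.  All files are tab-separated with a
# mandatory header comment declaring the time unit, so unit mismatches
# (seconds vs milliseconds) fail loudly instead of silently rescaling.

.write_tsv <- function(df, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# engramsim %s", kind), "# time_unit: ms"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, kind, required) {
  head <- readLines(path, n = 5)
  unit <- grep("^# time_unit:", head, value = TRUE)
  if (length(unit) == 0)
    stop(path, ": missing mandatory '# time_unit:' header")
  if (trimws(sub("^# time_unit:", "", unit[1])) != "ms")
    stop(path, ": time unit is not ms (got '",
         trimws(sub("^# time_unit:", "", unit[1])), "')")
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) stop(path, ": parse error: ", conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!complete.cases(df[required]))
  if (length(bad))
    stop(path, ": malformed row(s) at data line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  df
}

#' Write / read a spike raster
#'
#' Tab-separated columns `neuron_id`, `group`, `time_ms` (and `epoch` when
#' present), with a header comment declaring the time unit.  Round-trips
#' byte-identically for canonical files.
#'
#' @param raster spike raster data frame.
#' @param path file path.
#' @return The path (write) or the raster (read).
#' @export
write_raster <- function(raster, path) {
  stopifnot(all(c("neuron_id", "time_ms") %in% names(raster)))
  .write_tsv(raster, path, "spike raster")
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  df <- .read_tsv(path, "spike raster", c("neuron_id", "time_ms"))
  df$neuron_id <- as.integer(df$neuron_id)
  df
}

#' Write / read a synaptic edge list
#'
#' Tab-separated columns `pre_id`, `post_id`, `pre_group`, `post_group`,
#' `A`, `M`, `w`, `snapshot_time_ms`.
#'
#' @param network an `engram_network`.
#' @param w edge weights to record (defaults to the initial weights).
#' @param time_ms snapshot time recorded in the file.
#' @param path file path.
#' @return The path (write) or the edge data frame (read).
#' @export
write_edges <- function(network, path, w = network$edges$w0, time_ms = 0) {
  e <- network$edges
  g <- network$neurons$group
  df <- data.frame(pre_id = e$pre, post_id = e$post,
                   pre_group = g[e$pre], post_group = g[e$post],
                   A = 1L, M = e$M, w = w, snapshot_time_ms = time_ms)
  .write_tsv(df, path, "synaptic edge list")
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  .read_tsv(path, "synaptic edge list",
            c("pre_id", "post_id", "A", "M", "w"))
}

#' Write / read a sleep-bout annotation table
#'
#' Tab-separated columns `state`, `start`, `end` (ms).  Reading validates
#' ordering and non-overlap and reports offending line numbers.
#'
#' @param bouts bout table data frame.
#' @param path file path.
#' @return The path (write) or the validated bout table (read).
#' @export
write_bouts <- function(bouts, path) {
  validate_bouts(bouts)
  .write_tsv(bouts, path, "sleep bout table")
}

#' @rdname write_bouts
#' @export
read_bouts <- function(path) {
  validate_bouts(.read_tsv(path, "sleep bout table",
                           c("state", "start", "end")))
}

#' Read a simulation configuration file
#'
#' YAML configuration with a fixed key vocabulary mirroring the arguments
#' of [run_two_memory_experiment()] plus `dt` and `noise.p_per_ms`.
#' Unknown keys are an error listing the valid ones.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  valid <- c("seed", "order", "n_cycles", "tests", "dur_minus", "dur_plus",
             "test_duration", "bout_length", "gap", "drive_on",
             "drive_suppress", "test_gks", "test_drive", "bias",
             "suppress_drive", "scale", "violet_drive", "fc_threshold",
             "dt", "noise_p")
  unknown <- setdiff(names(cfg), valid)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(valid, collapse = ", "))
  cfg
}
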