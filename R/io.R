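# TSV / JSON I/O contracts: tab-separated, UTF-8, '.' decimal, header row;
# times in seconds, event onsets block-relative.

#' Write and read behavior tables as TSV
#'
#' @param behavior data.frame from [simulate_behavior()].
#' @param path output file.
#' @return `read_behavior_tsv` returns the data.frame.
#' @export
write_behavior_tsv <- function(behavior, path) {
  utils::write.table(behavior, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write and read a pupil recording as a pair of TSV files
#'
#' Samples go to `<stem>_samples.tsv` (`t_s`, `pupil`) and events to
#' `<stem>_events.tsv` (`onset_s`, `type`, `trial`).
#'
#' @param rec a `pupil_recording`.
#' @param stem path stem (no extension).
#' @param rate sampling rate when reading back.
#' @param subject,block_id identifiers when reading back.
#' @return `read_recording_tsv` returns a `pupil_recording`.
#' @export
write_recording_tsv <- function(rec, stem) {
  n <- length(rec$samples)
  samples <- data.frame(t_s = (seq_len(n) - 1) / rec$rate, pupil = rec$samples)
  utils::write.table(samples, paste0(stem, "_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(rec$events, paste0(stem, "_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(stem)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(stem, rate = NULL, subject = NA,
                               block_id = NA) {
  samples <- utils::read.delim(paste0(stem, "_samples.tsv"), sep = "\t")
  events <- utils::read.delim(paste0(stem, "_events.tsv"), sep = "\t",
                              stringsAsFactors = FALSE)
  if (is.null(rate)) {
    dt <- diff(samples$t_s)
    if (max(abs(dt - dt[1])) > 1e-6)
      stop_param("irregular sample spacing; supply 'rate'")
    rate <- 1 / dt[1]
  }
  .make_recording(samples$pupil, round(rate, 6), events, block_id, subject)
}

#' Write a configuration to JSON
#'
#' @param config a `"run_config"` list.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
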