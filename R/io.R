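## Plain-text serialization of cohorts and result tables.

#' Write a cohort to a directory of CSV files
#'
#' Serializes the per-cell metadata (manifest), one trace matrix per
#' stimulus and the trigger logs as plain CSV, so cohorts can be archived
#' or exchanged without binary formats.
#'
#' @param cohort an [RGCCohort-class]
#' @param dir output directory (created if needed).
#' @return the directory, invisibly
#' @export
writeCohortCSV <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cd <- as.data.frame(cellData(cohort)[
    , setdiff(colnames(cellData(cohort)), "gt_rf")])
  utils::write.csv(cd, file.path(dir, "manifest.csv"), row.names = FALSE)
  meta <- data.frame(key = "sample_rate_hz", value = cohort@sampleRate)
  for (nm in names(cohort@traces)) {
    utils::write.csv(cohort@traces[[nm]],
                     file.path(dir, sprintf("traces_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(data.frame(trigger_s = cohort@triggers[[nm]]),
                     file.path(dir, sprintf("triggers_%s.csv", nm)),
                     row.names = FALSE)
  }
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a CSV directory
#'
#' Inverse of [writeCohortCSV()]. Ground-truth receptive-field parameters
#' are not round-tripped (they are simulation internals, not data).
#'
#' @param dir directory written by [writeCohortCSV()].
#' @return an [RGCCohort-class]
#' @export
readCohortCSV <- function(dir) {
  cd <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  fs <- meta$value[meta$key == "sample_rate_hz"]
  traceFiles <- list.files(dir, pattern = "^traces_.*\\.csv$")
  traces <- list(); triggers <- list()
  for (f in traceFiles) {
    nm <- sub("^traces_(.*)\\.csv$", "\\1", f)
    traces[[nm]] <- unname(as.matrix(utils::read.csv(file.path(dir, f))))
    dimnames(traces[[nm]]) <- NULL
    triggers[[nm]] <- utils::read.csv(
      file.path(dir, sprintf("triggers_%s.csv", nm)))$trigger_s
  }
  new("RGCCohort", traces = traces, triggers = triggers,
      sampleRate = fs, cellData = S4Vectors::DataFrame(cd),
      stimuli = list())
}
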