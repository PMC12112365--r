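beat_units <- c(
  EDV = "mL", ESV = "mL", SV = "mL", Pes = "mmHg", EDP = "mmHg",
  SBP = "mmHg", DBP = "mmHg", PP = "mmHg", dP_dt_max = "mmHg/s",
  SW = "mmHg.mL", PE = "mmHg.mL", PVA = "mmHg.mL", beat_index = "count",
  degenerate = "flag")

#' Write / read a per-beat metrics table as CSV
#'
#' Comma-separated, '.' decimal, UTF-8; header row carries
#' `"name (unit)"` columns.  A round trip restores values to full double
#' precision.
#'
#' @param beats a `beat_metrics` data frame (non-empty).
#' @param path file path.
#' @return `read_beat_table()` returns a `beat_metrics` data frame.
#' @export
write_beat_table <- function(beats, path) {
  if (!inherits(beats, "data.frame") || nrow(beats) == 0L)
    abort_invalid_input("`beats` must be a non-empty beat table")
  hdr <- paste(sprintf("%s (%s)", names(beats),
                       beat_units[names(beats)]), collapse = ",")
  con <- tryCatch(file(path, "w", encoding = "UTF-8"), error = function(e)
    abort_io("cannot open '%s' for writing", path))
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    format(as.data.frame(beats), digits = 17, scientific = FALSE,
           trim = TRUE),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beat_table
#' @export
read_beat_table <- function(path) {
  if (!file.exists(path)) abort_io("beat table '%s' not found", path)
  x <- utils::read.csv(path, check.names = FALSE)
  names(x) <- sub(" \\(.*\\)$", "", names(x))
  x$degenerate <- as.logical(x$degenerate)
  structure(x, class = c("beat_metrics", "data.frame"))
}

fit_to_list <- function(f) {
  f[c(setdiff(names(f), character(0)))]
}

result_to_list <- function(res) {
  list(
    condition = res$condition,
    steady_state_ok = res$steady_state_ok,
    steady_state_beat = as.list(res$steady_state_beat[1, ]),
    fits = lapply(res$fits[c("espvr", "prsw", "dpdt_edv", "pva_edv")],
                  unclass),
    Vo_used = res$fits$Vo_used,
    energetics = list(
      eMVO2 = res$energetics$eMVO2, ME = res$energetics$ME,
      MyoEff_SW = res$energetics$MyoEff_SW,
      MyoEff_PVA = res$energetics$MyoEff_PVA),
    constants = unclass(res$energetics$constants)
  )
}

#' Write a JSON experiment report
#'
#' One block per condition (keyed by level label and heart rate), each
#' holding the condition metadata, the steady-state beat, the four
#' contractility fits, the energetics panel and the constants used, plus
#' the package version.
#'
#' @param results list of `experiment_result` (e.g. from [run_phase1()]),
#'   or a single result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "experiment_result")) results <- list(results)
  if (length(results) == 0L)
    abort_invalid_input("empty result list")
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- vapply(results, function(r)
      sprintf("%s_%g", r$condition$level, r$condition$HR), character(1))
  out <- list(
    software = list(package = "cardiosim",
                    version = as.character(utils::packageVersion("cardiosim"))),
    conditions = lapply(results, result_to_list)
  )
  tryCatch(
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null"),
    error = function(e) abort_io("cannot write report '%s': %s", path,
                                 conditionMessage(e)))
  invisible(path)
}
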