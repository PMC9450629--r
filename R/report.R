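fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "cochleaR")
  if (p == "") abort_cochlear(paste("missing packaged fixture", file),
                              "cochleaR_io_error")
  p
}

read_fixture_tables <- function() {
  readings <- read.csv(fixture_path("table3_readings.csv"),
                       comment.char = "#", stringsAsFactors = FALSE)
  totals <- read.csv(fixture_path("table2_totals.csv"),
                     comment.char = "#", stringsAsFactors = FALSE)
  list(readings = readings, totals = totals)
}

#' Load a packaged reference case
#'
#' The package ships the per-ruler readings and per-case totals of the six
#' reference cadaver temporal bones as plain-CSV fixtures. Readings run from
#' the vestibule (R1) towards the apex; rows the source table marks "DNM"
#' (no further measurement recorded) are omitted.
#'
#' @param case_id one of `"case1"` .. `"case6"`.
#' @return An object of class `case_fixture`: list with `case_id`, `readings`
#'   (named numeric vector, mm) and `expected_total` (mm).
#' @examples
#' fx <- load_fixture("case5")
#' sum(fx$readings) == fx$expected_total
#' @export
load_fixture <- function(case_id) {
  tabs <- read_fixture_tables()
  if (!is.character(case_id) || length(case_id) != 1L ||
      !case_id %in% tabs$totals$case_id)
    abort_cochlear(sprintf("unknown case id '%s' (expected case1..case6)",
                           as.character(case_id)[1]),
                   "cochleaR_not_found")
  r <- tabs$readings[tabs$readings$case_id == case_id, ]
  readings <- r$length_mm
  names(readings) <- r$label
  structure(list(case_id = case_id, readings = readings,
                 expected_total = tabs$totals$total_mm[
                   tabs$totals$case_id == case_id]),
            class = "case_fixture")
}

#' @export
print.case_fixture <- function(x, ...) {
  cat(sprintf("<case_fixture> %s: %d rulers, expected total %.2f mm\n",
              x$case_id, length(x$readings), x$expected_total))
  invisible(x)
}

#' Segment table of a packaged case fixture
#'
#' Wraps a fixture's recorded readings in a `segment_table` (geometry columns
#' are `NA`: the source is a table of lengths, not of coordinates), so that
#' [sum_segments()] and the report renderers apply.
#'
#' @param fixture a [load_fixture()] result.
#' @return A [segment_table()].
#' @export
fixture_segment_table <- function(fixture) {
  stopifnot(inherits(fixture, "case_fixture"))
  segment_table(data.frame(label = names(fixture$readings),
                           nominal_length = unname(fixture$readings)),
                remainder_arc = NA_real_,
                terminated_with_remainder = length(fixture$readings) < 14L)
}

#' Verify all packaged case fixtures
#'
#' Re-sums every case's readings with [sum_segments()] and compares against
#' the packaged expected total; also checks the mandatory six-ruler 2.0 mm
#' prefix. Failures are reported, not raised.
#'
#' @return Data frame with one row per case: `case_id`, `n_readings`,
#'   `total`, `expected_total`, `deficit` and `pass`.
#' @export
verify_fixtures <- function() {
  ids <- paste0("case", 1:6)
  out <- lapply(ids, function(id) {
    fx <- load_fixture(id)
    tot <- sum_segments(fixture_segment_table(fx))
    data.frame(case_id = id, n_readings = length(fx$readings),
               total = tot, expected_total = fx$expected_total,
               deficit = fx$expected_total - tot,
               pass = isTRUE(all.equal(tot, fx$expected_total)) &&
                 length(fx$readings) >= 6L &&
                 all(fx$readings[1:6] == 2.0))
  })
  do.call(rbind, out)
}

#' Render a measurement report
#'
#' Writes the placed-segment CSV (see [write_segments_csv()]) and a
#' plain-text report: one row per ruler label with its length, then the
#' totals row, mirroring the reference table layout. Single-case reports
#' omit trailing unplaced rows.
#'
#' @param table a `segment_table`.
#' @param meta named list of provenance fields (volume file, seeds, scheme,
#'   software version, ...) echoed into the report header.
#' @param csv_path,txt_path output file paths (`NULL` skips that file).
#' @param bias optional result of [chord_bias()] to append (phantom runs with
#'   known ground truth).
#' @return Invisibly, an object of class `measurement_report` holding the
#'   rendered lines, the table and the provenance.
#' @export
render_report <- function(table, meta = list(), csv_path = NULL,
                          txt_path = NULL, bias = NULL) {
  stopifnot(inherits(table, "segment_table"))
  lines <- c("Cochlear spiral canal measurement report",
             strrep("=", 40))
  for (nm in names(meta))
    lines <- c(lines, sprintf("%s: %s", nm, paste(format(meta[[nm]]), collapse = " ")))
  lines <- c(lines, "")
  for (i in seq_len(nrow(table)))
    lines <- c(lines, sprintf("%-5s %8.2f", table$label[i],
                              table$nominal_length[i]))
  lines <- c(lines, sprintf("%-5s %8.2f", "total", attr(table, "total")))
  if (isTRUE(attr(table, "terminated_with_remainder")) &&
      is.finite(attr(table, "remainder_arc")))
    lines <- c(lines, sprintf("unmeasured remainder arc: %.3f mm",
                              attr(table, "remainder_arc")))
  if (!is.null(bias))
    lines <- c(lines,
               sprintf("true arc length: %.3f mm", bias$spanned_arc + bias$remainder_arc),
               sprintf("relative underestimate: %.2f%%",
                       100 * bias$relative_underestimate))
  if (!is.null(txt_path)) {
    ok <- tryCatch({ writeLines(lines, txt_path); TRUE },
                   error = function(e) FALSE)
    if (!ok) abort_cochlear(paste("cannot write", txt_path), "cochleaR_io_error")
  }
  if (!is.null(csv_path)) write_segments_csv(table, csv_path)
  invisible(structure(list(lines = lines, table = table, meta = meta,
                           bias = bias),
                      class = "measurement_report"))
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}

#' Multi-case report over the packaged fixtures
#'
#' Renders the six reference cases side by side: rows R1 up to the longest
#' case, `"DNM"` printed literally for ruler positions a case did not
#' measure, totals row last.
#'
#' @param case_ids cases to include (default all six).
#' @param txt_path optional output path for the plain-text table.
#' @return Invisibly, a character matrix (rulers x cases, plus totals row)
#'   with `"DNM"` in unmeasured cells.
#' @export
render_fixture_report <- function(case_ids = paste0("case", 1:6),
                                  txt_path = NULL) {
  fxs <- lapply(case_ids, load_fixture)
  nmax <- max(vapply(fxs, function(f) length(f$readings), integer(1)))
  labels <- paste0("R", seq_len(nmax))
  m <- matrix("DNM", nrow = nmax, ncol = length(fxs),
              dimnames = list(labels, case_ids))
  for (j in seq_along(fxs)) {
    r <- fxs[[j]]$readings
    m[seq_along(r), j] <- sprintf("%.2f", r)
  }
  totals <- sprintf("%.2f", vapply(fxs, function(f) f$expected_total, numeric(1)))
  out <- rbind(m, total = totals)
  if (!is.null(txt_path)) {
    hdr <- paste(c(sprintf("%-6s", ""), sprintf("%8s", case_ids)), collapse = "")
    body <- vapply(seq_len(nrow(out)), function(i)
      paste(c(sprintf("%-6s", rownames(out)[i]), sprintf("%8s", out[i, ])),
            collapse = ""), character(1))
    ok <- tryCatch({ writeLines(c(hdr, body), txt_path); TRUE },
                   error = function(e) FALSE)
    if (!ok) abort_cochlear(paste("cannot write", txt_path), "cochleaR_io_error")
  }
  invisible(out)
}
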