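#' Write / read a centerline as CSV
#'
#' Plain tabular centerline interchange: columns `index` (0-based),
#' `x_mm`, `y_mm`, `z_mm`, `cum_arc_mm`; dot-decimal, full double precision,
#' so a write/read round trip is exact.
#'
#' @param curve a [centerline_curve()].
#' @param path output CSV path.
#' @return `write_centerline_csv()` returns `path` invisibly;
#'   `read_centerline_csv()` returns the [centerline_curve()].
#' @export
write_centerline_csv <- function(curve, path) {
  stopifnot(inherits(curve, "centerline_curve"))
  n <- nrow(curve$points)
  lines <- c("index,x_mm,y_mm,z_mm,cum_arc_mm",
             sprintf("%d,%.17g,%.17g,%.17g,%.17g", seq_len(n) - 1L,
                     curve$points[, 1], curve$points[, 2], curve$points[, 3],
                     curve$cum_arc))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) abort_cochlear(paste("cannot write", path), "cochleaR_io_error")
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    abort_cochlear("centerline CSV must have x_mm,y_mm,z_mm columns",
                   "cochleaR_io_error")
  centerline_curve(as.matrix(df[, need]))
}

#' Write / read a placed-segment table as CSV
#'
#' Columns `label`, `length_mm`, `x0,y0,z0`, `x1,y1,z1`, `start_arc_mm`,
#' `end_arc_mm`, followed by a trailing metadata block of comment lines
#' (`# total_mm=...`, `# remainder_arc_mm=...`,
#' `# terminated_with_remainder=...`). Lengths and labels round-trip
#' bit-exactly.
#'
#' @param table a [segment_table()].
#' @param path CSV path.
#' @return `write_segments_csv()` returns `path` invisibly;
#'   `read_segments_csv()` reconstructs the [segment_table()].
#' @export
write_segments_csv <- function(table, path) {
  stopifnot(inherits(table, "segment_table"))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- "label,length_mm,x0,y0,z0,x1,y1,z1,start_arc_mm,end_arc_mm"
  if (nrow(table))
    lines <- c(lines, sprintf("%s,%s,%s,%s,%s,%s,%s,%s,%s,%s",
                              table$label, fmt(table$nominal_length),
                              fmt(table$x0), fmt(table$y0), fmt(table$z0),
                              fmt(table$x1), fmt(table$y1), fmt(table$z1),
                              fmt(table$start_arc), fmt(table$end_arc)))
  lines <- c(lines,
             sprintf("# total_mm=%s", fmt(attr(table, "total"))),
             sprintf("# remainder_arc_mm=%s", fmt(attr(table, "remainder_arc"))),
             sprintf("# terminated_with_remainder=%s",
                     tolower(as.character(attr(table, "terminated_with_remainder")))))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) abort_cochlear(paste("cannot write", path), "cochleaR_io_error")
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
read_segments_csv <- function(path) {
  raw <- readLines(path)
  meta_lines <- grep("^#", raw, value = TRUE)
  df <- read.csv(text = raw[!grepl("^#", raw)], stringsAsFactors = FALSE)
  meta <- function(key, default = NA) {
    hit <- grep(paste0("^# ", key, "="), meta_lines, value = TRUE)
    if (!NROW(hit)) return(default)
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  seg <- data.frame(label = as.character(df$label),
                    nominal_length = as.numeric(df$length_mm),
                    x0 = as.numeric(df$x0), y0 = as.numeric(df$y0),
                    z0 = as.numeric(df$z0), x1 = as.numeric(df$x1),
                    y1 = as.numeric(df$y1), z1 = as.numeric(df$z1),
                    start_arc = as.numeric(df$start_arc_mm),
                    end_arc = as.numeric(df$end_arc_mm))
  segment_table(seg,
                remainder_arc = as.numeric(meta("remainder_arc_mm", NA)),
                terminated_with_remainder =
                  identical(meta("terminated_with_remainder", "false"), "true"))
}

#' Write a phantom ground-truth JSON sidecar
#'
#' Records the full [phantom_spec()] plus the quadrature true arc length next
#' to an exported volume, so downstream measurements can be scored against
#' ground truth without regenerating the phantom.
#'
#' @param spec a [phantom_spec()].
#' @param path output JSON path.
#' @param true_arc precomputed truth (defaults to [true_arc_length()]).
#' @return `path`, invisibly.
#' @export
write_phantom_truth <- function(spec, path, true_arc = true_arc_length(spec)) {
  stopifnot(inherits(spec, "phantom_spec"))
  jsonlite::write_json(c(unclass(spec), list(true_arc_length_mm = true_arc)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ruler scheme from JSON
#'
#' Accepts `{"fixed_prefix": [...], "allowed_set": [...],
#' "deviation_tol_mm": ..., "max_segments": ...}`; missing keys fall back to
#' the defaults of [ruler_scheme()].
#'
#' @param path JSON path.
#' @return A [ruler_scheme()].
#' @export
read_scheme_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- ruler_scheme()
  ruler_scheme(
    fixed_prefix = if (is.null(j$fixed_prefix)) defaults$fixed_prefix else j$fixed_prefix,
    allowed_set = if (is.null(j$allowed_set)) defaults$allowed_set else j$allowed_set,
    deviation_tol = if (is.null(j$deviation_tol_mm)) defaults$deviation_tol else j$deviation_tol_mm,
    max_segments = if (is.null(j$max_segments)) defaults$max_segments else j$max_segments)
}

# ---- MetaImage (.mha / .mhd) volume I/O -------------------------------------
# The environment ships no medical-image reader for R, so the package carries
# a minimal implementation of the (plain "Key = Value" header + raw block)
# MetaImage format: enough for uncompressed 3D scalar volumes.

met_types <- data.frame(
  met = c("MET_UCHAR", "MET_SHORT", "MET_USHORT", "MET_INT", "MET_FLOAT",
          "MET_DOUBLE"),
  what = c("integer", "integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

#' Write / read a volume in MetaImage format
#'
#' Uncompressed MetaImage: `.mha` holds header and raw voxel block in one
#' file; `.mhd` writes the header plus a sibling `.raw`. Geometry maps
#' `ElementSpacing` to voxel spacing and `Offset` to the world position of
#' voxel (0,0,0). Data are written `MET_DOUBLE`, little-endian; masks are
#' written `MET_UCHAR`.
#'
#' @param vol a [canal_volume()] or [canal_mask()].
#' @param path output path ending in `.mha` or `.mhd`.
#' @return `write_metaimage()` returns `path` invisibly; `read_metaimage()`
#'   returns a [canal_volume()] (use [segment_canal()] to re-binarize masks).
#' @export
write_metaimage <- function(vol, path) {
  if (!inherits(vol, "canal_volume") && !inherits(vol, "canal_mask"))
    abort_cochlear("`vol` must be a canal_volume or canal_mask",
                   "cochleaR_invalid_argument")
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("mha", "mhd"))
    abort_cochlear("path must end in .mha or .mhd", "cochleaR_invalid_argument")
  is_mask <- inherits(vol, "canal_mask")
  d <- dim(vol$data)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(sprintf("%.17g", vol$origin), collapse = " ")),
           paste("ElementSpacing =", paste(sprintf("%.17g", vol$spacing), collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementType =", if (is_mask) "MET_UCHAR" else "MET_DOUBLE"))
  payload <- if (is_mask) as.integer(vol$data) else as.double(vol$data)
  if (ext == "mha") {
    hdr <- c(hdr, "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(payload, con, size = if (is_mask) 1L else 8L, endian = "little")
  } else {
    raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    hdr <- c(hdr, paste("ElementDataFile =", raw_name))
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    writeBin(payload, con, size = if (is_mask) 1L else 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_metaimage
#' @export
read_metaimage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("mha", "mhd"))
    abort_cochlear("path must end in .mha or .mhd", "cochleaR_invalid_argument")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      abort_cochlear("truncated MetaImage header", "cochleaR_io_error")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (is.null(hdr$Offset)) c(0, 0, 0) else
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  ti <- match(hdr$ElementType, met_types$met)
  if (is.na(ti))
    abort_cochlear(paste("unsupported ElementType", hdr$ElementType),
                   "cochleaR_io_error")
  n <- prod(d)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_con <- file(file.path(dirname(path), hdr$ElementDataFile), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  v <- readBin(raw_con, met_types$what[ti], n = n, size = met_types$size[ti],
               signed = met_types$signed[ti] || met_types$size[ti] > 2,
               endian = if (identical(hdr$BinaryDataByteOrderMSB, "True"))
                 "big" else "little")
  if (length(v) != n)
    abort_cochlear("MetaImage raw block shorter than DimSize promises",
                   "cochleaR_io_error")
  canal_volume(array(as.numeric(v), d), spacing, origin)
}
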