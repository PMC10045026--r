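# Plain-text interchange: two-column CSV for waveforms/series, CSV for
# contours, XYZ/PLY point clouds, ASCII PGM image stacks with a JSON
# sidecar, and minimal legacy-ASCII VTK for field snapshots (no VTK
# library exists for this R environment, so the small subset used here is
# written and read directly).

#' Read / write a sampled waveform as two-column CSV
#'
#' Files have a header `t,value` and one row per sample over one period.
#'
#' @param waveform a [sampled_waveform()].
#' @param path file path.
#' @param period,unit metadata for reading (the CSV stores only samples).
#' @return `read_waveform_csv` returns a [sampled_waveform()];
#'   `write_waveform_csv` returns `path` invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  stop_if_not(inherits(waveform, "sampled_waveform"), "need a sampled_waveform")
  utils::write.csv(data.frame(t = waveform$times, value = waveform$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, period = NULL, unit = "m/s") {
  df <- utils::read.csv(path)
  stop_if_not(all(c("t", "value") %in% names(df)), "CSV must have t,value")
  if (is.null(period)) {
    dt <- diff(df$t)
    period <- df$t[nrow(df)] + stats::median(dt)
  }
  sampled_waveform(df$t, df$value, period, unit = unit)
}

#' Write traced contours as CSV
#'
#' Columns `slice,contour,row,col`, one row per boundary pixel, in tracing
#' order.
#'
#' @param contours_by_slice per-slice contour lists (see
#'   [trace_boundary()]).
#' @param path file path.
#' @export
write_contours_csv <- function(contours_by_slice, path) {
  rows <- list()
  for (s in seq_along(contours_by_slice)) {
    cl <- contours_by_slice[[s]]
    for (i in seq_along(cl)) {
      px <- if (is.matrix(cl[[i]])) cl[[i]] else cl[[i]]$pixels
      rows[[length(rows) + 1L]] <-
        data.frame(slice = s, contour = i, row = px[, 1L], col = px[, 2L])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice = integer(0), contour = integer(0),
               row = integer(0), col = integer(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- list()
  for (s in sort(unique(df$slice))) {
    ds <- df[df$slice == s, ]
    out[[s]] <- lapply(sort(unique(ds$contour)), function(i) {
      dc <- ds[ds$contour == i, ]
      list(pixels = cbind(dc$row, dc$col), closed = TRUE)
    })
  }
  out
}

#' Write a point cloud as XYZ or ASCII PLY
#'
#' @param cloud a `point_cloud` from [stack_to_cloud()].
#' @param path file path.
#' @param format `"xyz"` (whitespace-separated x y z per line) or `"ply"`
#'   (ASCII PLY 1.0 with vertex elements).
#' @export
write_point_cloud <- function(cloud, path, format = c("xyz", "ply")) {
  format <- match.arg(format)
  stop_if_not(inherits(cloud, "point_cloud"), "need a point_cloud")
  p <- cloud$points
  if (format == "xyz") {
    utils::write.table(p, path, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(p)),
                 "property float x", "property float y", "property float z",
                 "end_header"), con)
    utils::write.table(p, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write / read an image stack as ASCII PGM slices plus JSON metadata
#'
#' Each slice becomes `slice_###.pgm` (portable graymap, plain `P2`
#' variant) under `dir`, and `metadata.json` records pixel spacing, slice
#' thickness and bit depth.
#'
#' @param stack an [image_stack()].
#' @param dir target directory (created if needed).
#' @return the directory (write) or an [image_stack()] (read).
#' @export
write_image_stack <- function(stack, dir) {
  stop_if_not(inherits(stack, "image_stack"), "need an image_stack")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(stack$intensities)
  for (s in seq_len(d[3]))
    write_pgm(stack$intensities[, , s], file.path(dir,
              sprintf("slice_%03d.pgm", s)), stack$bit_depth)
  jsonlite::write_json(list(pixel_spacing = stack$pixel_spacing,
                            slice_thickness = stack$slice_thickness,
                            bit_depth = stack$bit_depth,
                            n_slices = d[3]),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.pgm$",
                           full.names = TRUE))
  stop_if_not(length(files) >= 1, "no slice_###.pgm files found")
  slices <- lapply(files, read_pgm)
  arr <- array(0, c(nrow(slices[[1]]), ncol(slices[[1]]), length(slices)))
  for (s in seq_along(slices)) arr[, , s] <- slices[[s]]
  image_stack(arr, meta$pixel_spacing, meta$slice_thickness, meta$bit_depth)
}

#' Plain (P2) PGM write / read for one grayscale slice
#'
#' @param img integer matrix.
#' @param path file path.
#' @param bit_depth bits per pixel (sets the PGM maxval).
#' @export
write_pgm <- function(img, path, bit_depth = 8L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", 2^bit_depth - 1)), con)
  # one image row per line, row-major as PGM requires
  writeLines(apply(img, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  stop_if_not(lines[1] == "P2", "only plain (P2) PGM is supported")
  hdr <- scan(text = paste(lines[2:3], collapse = " "), quiet = TRUE)
  nc <- hdr[1]; nr <- hdr[2]
  vals <- scan(text = paste(lines[-(1:3)], collapse = " "), quiet = TRUE)
  stop_if_not(length(vals) == nr * nc, "pixel count mismatch")
  matrix(vals, nr, nc, byrow = TRUE)
}

#' Write / read a field snapshot as legacy ASCII VTK
#'
#' Unstructured-grid legacy VTK (version 2.0) with the sample locations as
#' vertex cells and point-data arrays `velocity` (VECTORS) and, when
#' present, `pressure` and `k` (SCALARS). This covers the minimal subset
#' needed to exchange snapshot series with VTK-based tools.
#'
#' @param snapshot a [field_snapshot()].
#' @param path file path (conventionally `fields_<step>.vtk`).
#' @export
write_vtk_snapshot <- function(snapshot, path) {
  stop_if_not(inherits(snapshot, "field_snapshot"), "need a field_snapshot")
  n <- nrow(snapshot$locations)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0",
               sprintf("aortaflow snapshot t=%.12g", snapshot$time),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(snapshot$locations, con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", n, 2L * n), con)
  utils::write.table(cbind(1L, seq_len(n) - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", n), con)
  writeLines(as.character(rep(1L, n)), con)
  writeLines(c(sprintf("POINT_DATA %d", n), "VECTORS velocity double"), con)
  utils::write.table(snapshot$velocity, con, row.names = FALSE,
                     col.names = FALSE)
  for (nm in c("pressure", "k")) {
    if (!is.null(snapshot[[nm]])) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(snapshot[[nm]], digits = 17, trim = TRUE,
                        scientific = NA), con)
    }
  }
  invisible(path)
}

#' @rdname write_vtk_snapshot
#' @export
read_vtk_snapshot <- function(path) {
  lines <- readLines(path)
  time <- 0
  tl <- grep("t=", lines[1:4], value = TRUE)
  if (length(tl)) time <- as.numeric(sub(".*t=", "", tl[1]))
  ip <- grep("^POINTS", lines)
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  num_block <- function(start, count, ncol) {
    vals <- scan(text = paste(lines[start:(start + count - 1)],
                              collapse = "\n"), quiet = TRUE)
    matrix(vals, ncol = ncol, byrow = TRUE)
  }
  locations <- num_block(ip + 1L, n, 3L)
  iv <- grep("^VECTORS velocity", lines)
  velocity <- num_block(iv + 1L, n, 3L)
  pressure <- k <- NULL
  for (nm in c("pressure", "k")) {
    is_ <- grep(sprintf("^SCALARS %s ", nm), lines)
    if (length(is_)) {
      vals <- scan(text = paste(lines[(is_ + 2L):(is_ + 1L + n)],
                                collapse = "\n"), quiet = TRUE)
      if (nm == "pressure") pressure <- vals else k <- vals
    }
  }
  field_snapshot(time, locations, velocity, pressure = pressure, k = k)
}
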