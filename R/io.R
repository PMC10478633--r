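#' Read a detector image
#'
#' Reads a 2D intensity array from TIFF (`.tif`/`.tiff`, integer values
#' preserved) or delimited text (`.csv`, `.tsv`, `.txt`; plain numeric
#' matrix, no header). Coordinates throughout the package are 1-based
#' (row, col), row-major as printed.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = {
      m <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(m)) != 2L) stop("expected a single-channel 2D TIFF")
      m
    },
    csv = as.matrix(read.csv(path, header = FALSE)),
    tsv = ,
    txt = as.matrix(utils::read.table(path, header = FALSE)),
    stop("unsupported image format: .", ext,
         " (supported: tif/tiff, csv, tsv, txt)"))
  storage.mode(img) <- "double"
  dimnames(img) <- NULL
  img
}

#' Write a detector image
#'
#' Counterpart of [read_image()]: TIFF (32-bit float) or delimited text.
#' @param image Numeric matrix.
#' @param path Destination; format chosen by extension.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 32L,
                           reduce = TRUE),
    csv = write.table(image, path, sep = ",", row.names = FALSE,
                      col.names = FALSE),
    tsv = ,
    txt = write.table(image, path, sep = "\t", row.names = FALSE,
                      col.names = FALSE),
    stop("unsupported image format: .", ext))
  invisible(path)
}

peak_columns <- c("seed_row", "seed_col", "centroid_row", "centroid_col",
                  "n_pixels", "total_intensity", "snr")

#' Write a peak list as CSV
#'
#' Fixed column order (`frame`, then the peak statistics), comma separator,
#' `.` decimal mark, header row — bit-stable for a fixed input. An empty
#' list yields a header-only file.
#'
#' @param peaks A `peak_list` from [find_peaks()], or a list of them (one
#'   per frame).
#' @param path Destination CSV path.
#' @param frame Frame index (or indices, when `peaks` is a list) recorded
#'   in the `frame` column.
#' @export
write_peaks <- function(peaks, path, frame = 1L) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  if (length(frame) == 1L) frame <- seq_along(peaks) - 1L + frame
  tabs <- lapply(seq_along(peaks), function(i) {
    p <- as.data.frame(peaks[[i]])[, peak_columns, drop = FALSE]
    if (nrow(p) > 0L) cbind(frame = frame[i], p) else
      cbind(data.frame(frame = integer()), p)
  })
  out <- do.call(rbind, tabs)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a peak CSV written by [write_peaks()]
#' @param path CSV path.
#' @return Data frame with a `frame` column plus the peak statistics.
#' @export
read_peaks <- function(path) {
  read.csv(path, header = TRUE)
}

#' Write a bad-pixel mask
#'
#' The 8-bit codes go to a CSV matrix of integers (exact round trip,
#' including code 255); a JSON summary (per-class counts, bits, threshold,
#' window) is written alongside when `summary_path` is given.
#'
#' @param mask A `bad_pixel_mask` from [make_mask()] (or any integer
#'   matrix with values in 0..255).
#' @param path Destination CSV path.
#' @param summary_path Optional JSON summary path.
#' @export
write_mask <- function(mask, path, summary_path = NULL) {
  codes <- unclass(mask)
  if (any(codes < 0L | codes > 255L)) stop("mask codes must be in 0..255")
  write.table(codes, path, sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(summary_path)) {
    cnt <- attr(mask, "counts")
    jsonlite::write_json(
      list(shape = dim(codes), n_flagged = sum(codes > 0L),
           counts = as.list(cnt %||% integer()),
           bits = as.list(attr(mask, "bits") %||% integer()),
           threshold = attr(mask, "threshold"),
           win = attr(mask, "win")),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a bad-pixel mask CSV
#' @param path CSV path written by [write_mask()].
#' @return Integer matrix of codes.
#' @export
read_mask <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE))
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Order-preserving (optionally parallel) map over frames
#'
#' Applies `f` to each element of `xs`. For `workers > 1` on Unix the
#' elements are processed on forked workers; results are gathered in input
#' order and are identical to the serial run for any worker count. An error
#' in `f` is reported with the index of the failing element.
#'
#' @param f Function of one element.
#' @param xs List (or vector) of inputs, e.g. frames.
#' @param workers Number of workers (default 1 = serial).
#' @return List of results, in input order.
#' @export
parallel_map <- function(f, xs, workers = 1L) {
  wrap <- function(i) {
    tryCatch(list(ok = TRUE, value = f(xs[[i]])),
             error = function(e) list(ok = FALSE,
                                      msg = conditionMessage(e)))
  }
  idx <- seq_along(xs)
  res <- if (workers > 1L && .Platform$OS.type != "windows") {
    parallel::mclapply(idx, wrap, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(idx, wrap)
  }
  for (i in idx) {
    r <- res[[i]]
    if (!is.list(r) || is.null(r$ok)) {
      stop("parallel_map: element ", i, " failed: worker error")
    }
    if (!r$ok) stop("parallel_map: element ", i, " failed: ", r$msg)
  }
  lapply(res, `[[`, "value")
}
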