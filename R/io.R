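#' Read a multi-page TIFF movie
#'
#' Pages become frames; 8/16-bit integer data are preserved exactly as
#' integers-in-float. The frame rate is not stored in plain TIFF, so it
#' must be supplied (from a config or sidecar).
#'
#' @param path multi-page TIFF file
#' @param rate frame rate in Hz (required)
#' @return a `movie`
#' @export
read_movie <- function(path, rate) {
  if (missing(rate) || is.null(rate))
    stop_validation("frame rate missing: supply `rate` (Hz)")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    stop_validation("movie must have at least 2 pages (got ",
                    length(pages), ")")
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1)
    stop_validation("inconsistent page shapes in ", path)
  H <- dims[[1]][1]; W <- dims[[1]][2]
  frames <- array(0, dim = c(length(pages), H, W))
  for (t in seq_along(pages)) frames[t, , ] <- as.numeric(pages[[t]])
  movie(frames, rate)
}

#' Write a movie as a multi-page 16-bit TIFF
#'
#' Intensities are rounded to integers and must fit 16 bits; they round
#' trip exactly through [read_movie()].
#'
#' @param mov a `movie`
#' @param path output path
#' @export
write_movie <- function(mov, path) {
  d <- dim(mov$frames)
  vals <- round(mov$frames)
  if (min(vals) < 0 || max(vals) > 65535)
    stop_validation("intensities must be within 0..65535 for 16-bit TIFF")
  pages <- lapply(seq_len(d[1]), function(t) mov$frames[t, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Trace tables: first row time stamps, one trace per subsequent row
#'
#' The on-disk layout mirrors published per-larva trace tables: a CSV whose
#' first row holds the time stamps in seconds and each following row one
#' fluorescence trace. Time stamps must be uniform; the frame rate is
#' inferred as `1 / dt`.
#'
#' @param path CSV file
#' @return list of `trace` objects
#' @export
read_trace_table <- function(path) {
  tab <- as.matrix(read.csv(path, header = FALSE))
  if (!nrow(tab) || !ncol(tab)) stop_validation("empty trace table: ", path)
  if (nrow(tab) < 2)
    stop_validation("trace table needs a time row plus at least one trace")
  ts <- as.numeric(tab[1, ])
  dt <- diff(ts)
  if (length(dt) < 1) stop_validation("need at least 2 time stamps")
  rel <- abs(dt - dt[1]) / dt[1]
  bad <- which(rel > 1e-6)
  if (length(bad))
    stop_validation("non-uniform time stamps: gap ", bad[1] + 1, " (",
                    ts[bad[1] + 1], " s -> ", ts[bad[1] + 2], " s)")
  rate <- 1 / dt[1]
  lapply(seq_len(nrow(tab) - 1), function(i)
    trace(as.numeric(tab[i + 1, ]), rate))
}

#' @rdname read_trace_table
#' @param traces list of equal-length `trace` objects at one rate
#' @export
write_trace_table <- function(traces, path) {
  lens <- vapply(traces, function(tr) length(tr$values), integer(1))
  rates <- vapply(traces, function(tr) tr$rate, numeric(1))
  if (length(unique(lens)) != 1) stop_validation("traces differ in length")
  if (length(unique(rates)) != 1) stop_validation("traces differ in rate")
  ts <- (seq_len(lens[1]) - 1) / rates[1]
  m <- rbind(ts, do.call(rbind, lapply(traces, function(tr) tr$values)))
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a kymograph as a CSV matrix
#'
#' @param kym a `kymograph_grid`
#' @param path CSV path (positions as rows, frames as columns)
#' @export
write_kymograph_csv <- function(kym, path) {
  write.table(kym$grid, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph_csv
#' @param rate frame rate in Hz for the reconstructed object
#' @export
read_kymograph_csv <- function(path, rate) {
  kymograph_grid(as.matrix(read.csv(path, header = FALSE)), rate)
}
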