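#' Fluorescence movies and traces
#'
#' A movie is a T x H x W array of non-negative intensities with a frame
#' rate; a trace is a length-T fluorescence series with a rate. Frames are
#' 1-based (R convention); the time of frame k is `(k - 1) / rate` seconds.
#'
#' @param frames numeric array with dim `c(T, H, W)`, T >= 2
#' @param rate frame rate in Hz (> 0)
#' @return a `movie`
#' @export
movie <- function(frames, rate) {
  if (length(dim(frames)) != 3) stop_validation("frames must be a T x H x W array")
  if (dim(frames)[1] < 2) stop_validation("a movie needs at least 2 frames")
  if (!all(is.finite(frames))) stop_validation("intensities must be finite")
  if (!is.numeric(rate) || rate <= 0) stop_validation("rate must be > 0")
  structure(list(frames = frames, rate = rate), class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames)
  cat("<movie> ", d[1], " frames of ", d[2], " x ", d[3], " px at ",
      x$rate, " Hz (", format(d[1] / x$rate, digits = 4), " s)\n", sep = "")
  invisible(x)
}

#' @param values numeric vector of fluorescence values (arbitrary units)
#' @rdname movie
#' @return a `trace`
#' @export
trace <- function(values, rate) {
  if (!all(is.finite(values))) stop_validation("trace values must be finite")
  if (!is.numeric(rate) || rate <= 0) stop_validation("rate must be > 0")
  structure(list(values = as.numeric(values), rate = rate), class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat("<", class(x)[1], "> ", length(x$values), " frames at ", x$rate,
      " Hz; range [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.trace <- function(x, ...) {
  t_s <- (seq_along(x$values) - 1) / x$rate
  plot(t_s, x$values, type = "l", xlab = "time (s)",
       ylab = if (inherits(x, "dff_trace")) expression(Delta * F / F[0])
              else "F (a.u.)", ...)
}

trace_values <- function(x) if (inherits(x, "trace")) x$values else as.numeric(x)

#' Extract a mean-intensity trace from a movie ROI
#'
#' @param mov a `movie`
#' @param roi logical H x W matrix (the region of interest); at least one
#'   `TRUE` pixel
#' @return a `trace` of per-frame mean intensity over the ROI
#' @export
extract_trace <- function(mov, roi) {
  d <- dim(mov$frames)
  roi <- as.matrix(roi)
  if (!identical(dim(roi), d[2:3]))
    stop_validation("ROI shape must match the movie frames")
  idx <- which(roi)
  if (!length(idx)) stop_validation("ROI mask is empty")
  flat <- matrix(mov$frames, nrow = d[1])
  vals <- rowMeans(flat[, idx, drop = FALSE])
  trace(vals, mov$rate)
}

#' Rigid (integer-translation) motion correction
#'
#' Registers every frame to the first by exhaustive search over integer
#' shifts with `|dy|, |dx| <= max_shift`, maximising the Pearson
#' correlation of the overlapping region. Pixels shifted in from outside
#' the frame are filled with that frame's median intensity. This replaces
#' heavier registration plugins for the rigid-drift case.
#'
#' @param mov a `movie`
#' @param max_shift maximum shift in pixels (>= 0); `0` is the identity
#' @return list with `movie` (corrected) and `shifts` (T x 2 matrix of the
#'   applied `(dy, dx)` per frame; a planted drift of `+d` per frame is
#'   recovered as `-d`)
#' @export
motion_correct <- function(mov, max_shift) {
  if (!is.numeric(max_shift) || max_shift < 0)
    stop_validation("max_shift must be >= 0")
  max_shift <- as.integer(round(max_shift))
  d <- dim(mov$frames)
  ref <- mov$frames[1, , ]
  out <- mov$frames
  shifts <- matrix(0L, nrow = d[1], ncol = 2,
                   dimnames = list(NULL, c("dy", "dx")))
  if (max_shift > 0 && d[1] > 1) {
    rng <- -max_shift:max_shift
    for (t in 2:d[1]) {
      fr <- mov$frames[t, , ]
      best <- c(0L, 0L); best_score <- -Inf
      for (dy in rng) for (dx in rng) {
        sc <- overlap_correlation(ref, fr, dy, dx)
        if (is.finite(sc) &&
            (sc > best_score + 1e-12 ||
             (abs(sc - best_score) <= 1e-12 &&
              sum(abs(c(dy, dx))) < sum(abs(best))))) {
          best_score <- sc; best <- c(dy, dx)
        }
      }
      shifts[t, ] <- best
      out[t, , ] <- translate_frame(fr, best[1], best[2])
    }
  }
  list(movie = movie(out, mov$rate), shifts = shifts)
}

# Correlation between ref and frame translated by (dy, dx), on the overlap.
overlap_correlation <- function(ref, fr, dy, dx) {
  H <- nrow(ref); W <- ncol(ref)
  ys <- max(1, 1 + dy):min(H, H + dy)   # rows of the translated frame
  xs <- max(1, 1 + dx):min(W, W + dx)
  a <- ref[ys, xs, drop = FALSE]
  b <- fr[ys - dy, xs - dx, drop = FALSE]
  if (length(a) < 3) return(-Inf)
  if (sd(a) == 0 || sd(b) == 0) return(if (all(a == b)) 1 else 0)
  cor(as.vector(a), as.vector(b))
}

translate_frame <- function(fr, dy, dx) {
  H <- nrow(fr); W <- ncol(fr)
  out <- matrix(median(fr), H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs] <- fr[ys - dy, xs - dx]
  out
}

#' Baseline fluorescence from the minimum-variance window
#'
#' F0 is taken from the quietest epoch of the recording: among all
#' contiguous windows of `window` frames, the one with the smallest sample
#' standard deviation of fluorescence is selected (earliest window wins
#' ties) and F0 is its mean.
#'
#' @param tr a `trace` (or numeric vector of fluorescence)
#' @param window window length in frames (default 10; 2 <= window <= T)
#' @return list with `f0` (baseline, must be > 0) and `window_start`
#'   (1-based frame index of the selected window)
#' @export
compute_f0 <- function(tr, window = 10) {
  x <- trace_values(tr)
  n <- length(x)
  if (window < 2) stop_validation("window must be >= 2 frames")
  if (n < window) stop_validation("trace shorter than the baseline window")
  n_win <- n - window + 1
  sds <- vapply(seq_len(n_win),
                function(i) sd(x[i:(i + window - 1)]), numeric(1))
  i0 <- which.min(sds)  # which.min returns the earliest minimum
  f0 <- mean(x[i0:(i0 + window - 1)])
  if (f0 <= 0)
    stop_validation("baseline F0 must be positive (got ", format(f0), ")")
  list(f0 = f0, window_start = i0)
}

#' Delta F / F0 transform
#'
#' @param tr a `trace` of raw fluorescence
#' @param f0 baseline fluorescence; when `NULL` it is estimated with
#'   [compute_f0()] using `window`
#' @param window baseline window length forwarded to [compute_f0()]
#' @return a `dff_trace` with values `(F - F0) / F0`, carrying `f0` and the
#'   selected `f0_window_start`
#' @export
dff <- function(tr, f0 = NULL, window = 10) {
  x <- trace_values(tr)
  rate <- if (inherits(tr, "trace")) tr$rate else
    stop_validation("dff needs a trace (for its frame rate)")
  ws <- NA_integer_
  if (is.null(f0)) {
    b <- compute_f0(tr, window = window)
    f0 <- b$f0; ws <- b$window_start
  }
  if (!is.numeric(f0) || f0 <= 0) stop_validation("f0 must be > 0")
  structure(list(values = (x - f0) / f0, f0 = f0, f0_window_start = ws,
                 rate = rate),
            class = c("dff_trace", "trace"))
}

#' Invert a Delta F / F0 transform back to raw fluorescence
#'
#' @param dtr a `dff_trace`
#' @return a `trace` with values `F0 * (1 + dff)`
#' @export
dff_inverse <- function(dtr) {
  if (!inherits(dtr, "dff_trace")) stop_validation("not a dff_trace")
  trace(dtr$f0 * (1 + dtr$values), dtr$rate)
}

#' Normalise a trace to the unit interval
#'
#' @param tr a `trace` (non-constant)
#' @return a `trace` rescaled to `[0, 1]`, attaining both bounds
#' @export
normalize01 <- function(tr) {
  x <- trace_values(tr)
  rg <- range(x)
  if (diff(rg) == 0) stop_validation("cannot normalise a constant trace")
  out <- (x - rg[1]) / diff(rg)
  if (inherits(tr, "trace")) trace(out, tr$rate) else out
}

#' Pearson correlation of two traces
#'
#' @param a,b traces (or numeric vectors) of equal length >= 3
#' @return Pearson r in `[-1, 1]`; `NA` when either series is constant
#'   (the undefined marker, distinct from a true 0 correlation)
#' @export
pearson <- function(a, b) {
  x <- trace_values(a); y <- trace_values(b)
  if (length(x) != length(y)) stop_validation("traces differ in length")
  if (length(x) < 3) stop_validation("need at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Pixel-wise Pearson correlation map
#'
#' Correlates a reference trace (typically from a manually drawn ROI over
#' the prototroch) with the time series of every pixel, producing a single
#' image of Pearson coefficients. Pixels with zero temporal variance carry
#' `NA`, the undefined marker, so static background is distinguishable
#' from truly uncorrelated signal.
#'
#' @param mov a `movie` with T frames
#' @param ref a `trace` (or numeric vector) of length T
#' @return a `correlation_map`: list with `r` (H x W matrix in `[-1, 1]`
#'   or `NA`) and `rate`
#' @export
correlation_map <- function(mov, ref) {
  y <- trace_values(ref)
  d <- dim(mov$frames)
  if (length(y) != d[1])
    stop_validation("reference length must equal the movie frame count")
  if (sd(y) == 0) stop_validation("reference trace is constant")
  X <- matrix(mov$frames, nrow = d[1])       # T x (H*W)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sx <- sqrt(colSums(Xc^2))
  r <- as.vector(crossprod(Xc, yc)) / (sx * sqrt(sum(yc^2)))
  r[sx == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  structure(list(r = matrix(r, d[2], d[3]), rate = mov$rate),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("<correlation_map> ", nrow(x$r), " x ", ncol(x$r), " px; defined r in [",
      format(min(x$r, na.rm = TRUE), digits = 3), ", ",
      format(max(x$r, na.rm = TRUE), digits = 3), "]; ",
      sum(is.na(x$r)), " undefined px\n", sep = "")
  invisible(x)
}

#' @export
plot.correlation_map <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(255)
  image(t(x$r[nrow(x$r):1, ]), zlim = c(-1, 1), col = pal, axes = FALSE, ...)
}

#' Write a correlation map to CSV and float TIFF
#'
#' Undefined pixels are written as empty cells in the CSV and as `NaN` in
#' the TIFF.
#'
#' @param cmap a `correlation_map`
#' @param csv_path,tiff_path output paths (either may be `NULL` to skip)
#' @export
write_correlation_map <- function(cmap, csv_path = NULL, tiff_path = NULL) {
  if (!is.null(csv_path))
    write.table(cmap$r, csv_path, sep = ",", row.names = FALSE,
                col.names = FALSE, na = "")
  if (!is.null(tiff_path)) {
    m <- cmap$r
    m[is.na(m)] <- NaN
    tiff::writeTIFF(m, tiff_path, bits.per.sample = 32L)
  }
  invisible(cmap)
}

#' Dominant cycle length by Fourier analysis
#'
#' Mean-subtracts the series, computes the discrete Fourier transform, and
#' takes the positive-frequency bin with maximal power; the cycle length is
#' the reciprocal of that frequency. No detrending or windowing is applied
#' beyond mean subtraction, and bin resolution is `rate / T` unless
#' zero-padding is requested.
#'
#' @param tr a non-constant `trace` with at least 8 frames
#' @param pad zero-padding factor (1 = none; 2 doubles the spectral grid)
#' @return a `cycle_estimate`: list with `period` (s), `frequency` (Hz) and
#'   `spectrum` (data.frame of frequency and power)
#' @export
cycle_length <- function(tr, pad = 1) {
  x <- trace_values(tr)
  rate <- if (inherits(tr, "trace")) tr$rate else
    stop_validation("cycle_length needs a trace (for its frame rate)")
  n <- length(x)
  if (n < 8) stop_validation("need at least 8 frames for a spectrum")
  if (sd(x) == 0) stop_validation("constant trace has no cycle")
  if (pad < 1) stop_validation("pad must be >= 1")
  x <- x - mean(x)
  nfft <- as.integer(round(n * pad))
  if (nfft > n) x <- c(x, numeric(nfft - n))
  sp <- fft(x)
  k <- seq_len(floor(nfft / 2))          # positive-frequency bins
  freq <- k * rate / nfft
  power <- Mod(sp[k + 1])^2
  peak <- which.max(power)               # earliest bin wins ties
  structure(list(period = 1 / freq[peak], frequency = freq[peak],
                 spectrum = data.frame(frequency = freq, power = power)),
            class = "cycle_estimate")
}

#' @export
print.cycle_estimate <- function(x, ...) {
  cat("<cycle_estimate> period ", format(x$period, digits = 5), " s (",
      format(x$frequency, digits = 5), " Hz)\n", sep = "")
  invisible(x)
}

#' Cohort summary of cycle lengths
#'
#' Runs [cycle_length()] on every analysable trace of a cohort and
#' summarises the distribution of periods: the median, the fraction inside
#' an inclusive period band (default 50-100 s, the band used to summarise
#' pacemaker rhythms across larvae), and a binned histogram.
#'
#' @param traces list of `trace` objects
#' @param band length-2 numeric, inclusive period band in seconds
#' @param bin_width histogram bin width in seconds
#' @return list with `median_period`, `fraction_in_band`, `histogram`
#'   (data.frame `bin_lo`, `bin_hi`, `count`), `periods` and `n`
#' @export
cycle_length_summary <- function(traces, band = c(50, 100), bin_width = 10) {
  if (!length(traces)) stop_validation("no traces supplied")
  periods <- vapply(traces, function(tr) {
    if (sd(trace_values(tr)) == 0) NA_real_ else cycle_length(tr)$period
  }, numeric(1))
  periods <- periods[!is.na(periods)]
  if (!length(periods)) stop_validation("all traces are constant")
  brk <- seq(0, ceiling(max(periods) / bin_width) * bin_width, by = bin_width)
  h <- hist(periods, breaks = brk, plot = FALSE)
  list(median_period = median(periods),
       fraction_in_band = mean(periods >= band[1] & periods <= band[2]),
       histogram = data.frame(bin_lo = head(brk, -1), bin_hi = brk[-1],
                              count = h$counts),
       periods = periods, n = length(periods))
}

#' Time derivative of a trace
#'
#' Central differences scaled by the frame rate (units: a.u./s), one-sided
#' at the endpoints, length preserved. Used for the calcium derivative
#' d\[Ca2+\]/dt whose sign tracks ciliary arrest.
#'
#' @param tr a `trace` with at least 3 frames
#' @return a `trace` of derivatives
#' @export
derivative <- function(tr) {
  x <- trace_values(tr)
  rate <- if (inherits(tr, "trace")) tr$rate else
    stop_validation("derivative needs a trace (for its frame rate)")
  n <- length(x)
  if (n < 3) stop_validation("need at least 3 frames")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2 * rate
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  trace(d, rate)
}
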