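#' Kymographs of ciliary activity
#'
#' A kymograph is a position x time intensity grid sampled along a line
#' drawn across beating cilia; arrested cilia produce static (low temporal
#' variance) stripes, beating cilia an oscillating texture.
#'
#' @param grid numeric P x T matrix (position along the line x frame)
#' @param rate frame rate in Hz
#' @param line optional polyline (n x 2 matrix of x, y pixel coordinates)
#'   the grid was sampled along
#' @return a `kymograph_grid`
#' @export
kymograph_grid <- function(grid, rate, line = NULL) {
  grid <- as.matrix(grid)
  if (ncol(grid) < 2) stop_validation("kymograph needs at least 2 frames")
  if (!is.numeric(rate) || rate <= 0) stop_validation("rate must be > 0")
  structure(list(grid = grid, rate = rate, line = line),
            class = "kymograph_grid")
}

#' @export
print.kymograph_grid <- function(x, ...) {
  cat("<kymograph> ", nrow(x$grid), " positions x ", ncol(x$grid),
      " frames at ", x$rate, " Hz\n", sep = "")
  invisible(x)
}

#' @export
plot.kymograph_grid <- function(x, ...) {
  image(t(x$grid), col = grDevices::gray.colors(255), axes = FALSE,
        xlab = "time", ylab = "position", ...)
}

#' Sample a kymograph from a movie along a polyline
#'
#' Intensities are sampled by bilinear interpolation at unit arc-length
#' steps along the line and averaged across `width` perpendicular offsets
#' (centred on the line); one column per frame.
#'
#' @param mov a `movie`
#' @param line n x 2 matrix of `(x, y)` pixel coordinates (1-based, x =
#'   column, y = row); must lie within the frame, including offsets
#' @param width averaging width in pixels (>= 1)
#' @return a `kymograph_grid`
#' @export
kymograph <- function(mov, line, width = 1) {
  line <- as.matrix(line)
  if (ncol(line) != 2 || nrow(line) < 2)
    stop_validation("line must be an n x 2 matrix of (x, y) with n >= 2")
  if (width < 1) stop_validation("width must be >= 1")
  d <- dim(mov$frames)
  seglen <- sqrt(rowSums(diff(line)^2))
  L <- sum(seglen)
  if (L <= 0) stop_validation("line has zero length")
  s_all <- c(0, cumsum(seglen))
  s_smp <- seq(0, L, by = 1)
  xy <- cbind(approx(s_all, line[, 1], xout = s_smp)$y,
              approx(s_all, line[, 2], xout = s_smp)$y)
  # unit tangent per sample (central differences), normal = rotate 90 deg
  P <- nrow(xy)
  nxt <- pmin(seq_len(P) + 1, P)
  prv <- pmax(seq_len(P) - 1, 1)
  tang <- xy[nxt, , drop = FALSE] - xy[prv, , drop = FALSE]
  tang <- tang / pmax(sqrt(rowSums(tang^2)), .Machine$double.eps)
  nrm <- cbind(-tang[, 2], tang[, 1])
  offs <- seq_len(width) - (width + 1) / 2
  grid <- matrix(0, P, d[1])
  pts_x <- outer(xy[, 1], rep(1, width)) + outer(nrm[, 1], offs)
  pts_y <- outer(xy[, 2], rep(1, width)) + outer(nrm[, 2], offs)
  if (any(pts_x < 1 | pts_x > d[3] | pts_y < 1 | pts_y > d[2]))
    stop_validation("sampling line (with width offsets) falls outside the frame")
  for (t in seq_len(d[1])) {
    fr <- mov$frames[t, , ]
    vals <- bilinear(fr, pts_y, pts_x)
    grid[, t] <- rowMeans(matrix(vals, P, width))
  }
  kymograph_grid(grid, mov$rate, line)
}

# Bilinear interpolation of matrix m (rows = y, cols = x) at real positions.
bilinear <- function(m, y, x) {
  y0 <- pmin(floor(y), nrow(m) - 1); x0 <- pmin(floor(x), ncol(m) - 1)
  fy <- y - y0; fx <- x - x0
  m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    m[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    m[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    m[cbind(y0 + 1, x0 + 1)] * fy * fx
}

#' Arrest intervals
#'
#' Half-open frame intervals `[start, end)` (1-based) classified as ciliary
#' arrests, sorted and non-overlapping.
#'
#' @param intervals data.frame with integer columns `start`, `end`
#' @param rate frame rate in Hz
#' @param n_frames recording length in frames (intervals must fit)
#' @return an `arrest_intervals` object
#' @export
arrest_intervals <- function(intervals, rate, n_frames = NULL) {
  if (is.null(intervals) || !nrow(intervals)) {
    intervals <- data.frame(start = integer(), end = integer())
  }
  intervals <- intervals[order(intervals$start), c("start", "end"),
                         drop = FALSE]
  rownames(intervals) <- NULL
  if (any(intervals$end <= intervals$start))
    stop_validation("intervals must satisfy end > start")
  if (nrow(intervals) > 1 &&
      any(intervals$start[-1] < intervals$end[-nrow(intervals)]))
    stop_validation("intervals must not overlap")
  if (!is.null(n_frames) && nrow(intervals) &&
      (min(intervals$start) < 1 || max(intervals$end) > n_frames + 1))
    stop_validation("intervals must lie within the recording")
  structure(list(intervals = intervals, rate = rate, n_frames = n_frames),
            class = "arrest_intervals")
}

#' @export
print.arrest_intervals <- function(x, ...) {
  tot <- sum(x$intervals$end - x$intervals$start)
  cat("<arrest_intervals> ", nrow(x$intervals), " intervals, ",
      tot, " arrested frames at ", x$rate, " Hz\n", sep = "")
  invisible(x)
}

#' Logical arrest indicator per frame
#'
#' @param x an `arrest_intervals`
#' @param n_frames recording length (defaults to the stored value)
#' @return logical vector, `TRUE` on arrested frames
#' @export
arrest_indicator <- function(x, n_frames = x$n_frames) {
  if (is.null(n_frames)) stop_validation("n_frames unknown")
  ind <- logical(n_frames)
  for (i in seq_len(nrow(x$intervals)))
    ind[x$intervals$start[i]:(x$intervals$end[i] - 1)] <- TRUE
  ind
}

#' Read/write arrest intervals as CSV (`start_frame,end_frame`)
#'
#' @param x an `arrest_intervals`
#' @param path CSV path
#' @export
write_intervals_csv <- function(x, path) {
  write.csv(data.frame(start_frame = x$intervals$start,
                       end_frame = x$intervals$end),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @param rate,n_frames metadata for the reconstructed object
#' @export
read_intervals_csv <- function(path, rate, n_frames = NULL) {
  tab <- read.csv(path)
  arrest_intervals(data.frame(start = tab$start_frame, end = tab$end_frame),
                   rate, n_frames)
}

#' Detect ciliary arrest intervals in a kymograph
#'
#' Arrested cilia leave a static stripe: the temporal variance of the
#' position-averaged kymograph signal collapses. The detector computes a
#' centred sliding standard deviation of that signal, takes the upper
#' quartile of the sliding std as the beating-epoch reference, and marks
#' frames whose sliding std falls below `threshold` times the reference;
#' runs of at least `min_duration` frames become half-open intervals. The
#' statistic is invariant to affine rescaling of the kymograph intensities.
#'
#' @param kym a `kymograph_grid`
#' @param std_window sliding-window length in frames (>= 2)
#' @param threshold fraction of the beating-epoch (upper-quartile) sliding
#'   std below which a frame counts as arrested
#' @param min_duration minimum run length in frames; the default is 0.2 s
#'   worth of frames (shorter gaps are within a normal inter-beat interval)
#' @return an `arrest_intervals`
#' @export
detect_arrests <- function(kym, std_window, threshold = 0.25,
                           min_duration = max(1L, round(0.2 * kym$rate))) {
  if (std_window < 2) stop_validation("std_window must be >= 2")
  n <- ncol(kym$grid)
  if (std_window > n) stop_validation("std_window exceeds the recording")
  signal <- colMeans(kym$grid)
  s_sd <- sliding_sd(signal, std_window)
  ref <- quantile(s_sd, 0.75, names = FALSE)
  cand <- s_sd < threshold * ref
  runs <- rle(cand)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_duration
  st <- starts[keep]; en <- ends[keep] + 1L
  # A frame scores low only when its whole window lies inside the arrest,
  # so raw runs are short by the window half-widths; undo that known bias.
  half_lo <- floor((std_window - 1) / 2)
  half_hi <- ceiling((std_window - 1) / 2)
  st <- pmax(1L, st - half_lo)
  en <- pmin(n + 1L, en + half_hi)
  # dilation may bridge neighbouring runs; merge overlaps
  if (length(st) > 1) {
    m_st <- st[1]; m_en <- en[1]; out_st <- integer(); out_en <- integer()
    for (i in 2:length(st)) {
      if (st[i] <= m_en) m_en <- max(m_en, en[i])
      else { out_st <- c(out_st, m_st); out_en <- c(out_en, m_en)
             m_st <- st[i]; m_en <- en[i] }
    }
    st <- c(out_st, m_st); en <- c(out_en, m_en)
  }
  arrest_intervals(data.frame(start = st, end = en), kym$rate, n_frames = n)
}

# Centred sliding sd with partial windows at the edges.
sliding_sd <- function(x, window) {
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    sd(x[max(1, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
}

#' Ciliary beat frequency from a kymograph
#'
#' For every position, the power spectrum of the longest beating segment
#' (arrest frames excluded) is computed and its peak taken; the reported
#' beat frequency is the median of the per-position peaks.
#'
#' @param kym a `kymograph_grid` sampled above twice the expected beat
#'   frequency
#' @param arrests optional `arrest_intervals` whose frames are excluded
#' @param min_segment minimum beating-segment length in frames
#' @return a `beat_estimate`: list with `frequency` (Hz), `per_position`
#'   (data.frame of per-position peak frequencies), `reliable` (`FALSE`
#'   when the median peak sits in the top spectral bin, i.e. at Nyquist)
#' @export
beat_frequency <- function(kym, arrests = NULL, min_segment = 16) {
  n <- ncol(kym$grid)
  beating <- rep(TRUE, n)
  if (!is.null(arrests)) beating <- !arrest_indicator(arrests, n)
  runs <- rle(beating)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- runs$values & runs$lengths >= min_segment
  if (!any(ok)) stop_validation("no beating segment of at least ",
                                min_segment, " frames")
  # longest beating segment
  k <- which(ok)[which.max(runs$lengths[ok])]
  seg <- starts[k]:ends[k]
  m <- length(seg)
  kk <- seq_len(floor(m / 2))
  freqs <- kk * kym$rate / m
  per_pos <- vapply(seq_len(nrow(kym$grid)), function(p) {
    x <- kym$grid[p, seg]
    if (sd(x) == 0) return(NA_real_)
    pow <- Mod(fft(x - mean(x))[kk + 1])^2
    freqs[which.max(pow)]
  }, numeric(1))
  med <- median(per_pos, na.rm = TRUE)
  structure(list(frequency = med,
                 per_position = data.frame(position = seq_along(per_pos),
                                           frequency = per_pos),
                 rate = kym$rate,
                 reliable = is.finite(med) && med < freqs[length(freqs)]),
            class = "beat_estimate")
}

#' @export
print.beat_estimate <- function(x, ...) {
  cat("<beat_estimate> ", format(x$frequency, digits = 5), " Hz",
      if (!x$reliable) " (unreliable: at Nyquist)", "\n", sep = "")
  invisible(x)
}

#' Arrest rate in closures per minute
#'
#' @param intervals an `arrest_intervals`
#' @param duration recording duration in seconds (> 0)
#' @return arrests per minute
#' @export
arrest_rate <- function(intervals, duration) {
  if (duration <= 0) stop_validation("duration must be > 0")
  nrow(intervals$intervals) * 60 / duration
}

#' Resumption delay between two ciliary bands
#'
#' Cilia resume beating band by band; this measures the mean signed delay
#' of band `b`'s resumptions relative to band `a`'s. With
#' `method = "events"` each resumption event (interval end) in `a` is
#' matched to the nearest resumption in `b` within `max_lag` seconds and
#' the mean of `t_b - t_a` over matched pairs is returned (positive: `b`
#' resumes after `a`). With `method = "xcorr"` the delay is the lag
#' maximising the cross-correlation of the two binary arrest indicators.
#'
#' @param a,b `arrest_intervals` at the same frame rate, both non-empty
#' @param max_lag maximum match distance in seconds
#' @param method `"events"` (default) or `"xcorr"`
#' @return list with `mean_delay` (s), `sd_delay`, `n_pairs`, `method`
#' @export
band_delay <- function(a, b, max_lag, method = c("events", "xcorr")) {
  method <- match.arg(method)
  if (!nrow(a$intervals) || !nrow(b$intervals))
    stop_validation("both interval lists must be non-empty")
  if (a$rate != b$rate) stop_validation("frame rates differ")
  rate <- a$rate
  if (method == "events") {
    ta <- (a$intervals$end - 1) / rate
    tb <- (b$intervals$end - 1) / rate
    deltas <- vapply(ta, function(t0) {
      dd <- tb - t0
      dd <- dd[abs(dd) <= max_lag]
      if (!length(dd)) NA_real_ else dd[which.min(abs(dd))]
    }, numeric(1))
    deltas <- deltas[!is.na(deltas)]
    if (!length(deltas))
      stop_validation("no resumption pairs matched within max_lag")
    list(mean_delay = mean(deltas),
         sd_delay = if (length(deltas) > 1) sd(deltas) else 0,
         n_pairs = length(deltas), method = method)
  } else {
    n <- max(a$intervals$end, b$intervals$end) - 1 + as.integer(max_lag * rate)
    ia <- as.numeric(arrest_indicator(a, n))
    ib <- as.numeric(arrest_indicator(b, n))
    lags <- -as.integer(max_lag * rate):as.integer(max_lag * rate)
    sc <- vapply(lags, function(l) {
      if (l >= 0) sum(ia[seq_len(n - l)] * ib[seq_len(n - l) + l])
      else sum(ia[seq_len(n + l) - l] * ib[seq_len(n + l)])
    }, numeric(1))
    best <- lags[which.max(sc)]
    list(mean_delay = best / rate, sd_delay = NA_real_,
         n_pairs = nrow(a$intervals), method = method)
  }
}

#' Association between ciliary arrest and the calcium derivative
#'
#' Tests the derivative law — cilia are arrested while calcium rises and
#' beat while it falls — by classifying every frame by arrest state and by
#' the sign of d\[Ca2+\]/dt. Frames whose absolute derivative falls below a
#' dead-band (a fraction of the derivative's interquartile range) are
#' excluded from both denominators so numerical noise near zero slope does
#' not count as a sign.
#'
#' @param ca a `dff_trace` (or `trace`) of calcium signal
#' @param arrests an `arrest_intervals` at the same rate and length
#' @param dead_band_frac dead-band as a fraction of the derivative IQR
#'   (default 0.05)
#' @return list with `p_arrest_rising` (fraction of arrest frames with
#'   rising calcium), `p_beating_falling` (fraction of beating frames with
#'   non-rising calcium), and the frame counts used
#' @export
arrest_vs_dcadt <- function(ca, arrests, dead_band_frac = 0.05) {
  x <- trace_values(ca)
  n <- length(x)
  if (!is.null(arrests$n_frames) && arrests$n_frames != n)
    stop_validation("trace and arrest intervals differ in length")
  if (inherits(ca, "trace") && !is.null(arrests$rate) &&
      ca$rate != arrests$rate)
    stop_validation("trace and arrest intervals differ in rate")
  d <- derivative(if (inherits(ca, "trace")) ca else trace(x, arrests$rate))
  dv <- d$values
  eps <- dead_band_frac * IQR(dv)
  eligible <- abs(dv) > eps
  arr <- arrest_indicator(arrests, n)
  n_arr <- sum(eligible & arr)
  n_beat <- sum(eligible & !arr)
  if (n_arr + n_beat == 0)
    stop_validation("no frames outside the derivative dead-band")
  list(p_arrest_rising = if (n_arr) sum(dv > 0 & eligible & arr) / n_arr
                         else NA_real_,
       p_beating_falling = if (n_beat) sum(dv <= 0 & eligible & !arr) / n_beat
                           else NA_real_,
       n_arrest_frames = n_arr, n_beating_frames = n_beat,
       dead_band = eps)
}
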