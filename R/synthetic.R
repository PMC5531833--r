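#' Generate two-phase pacemaker calcium traces
#'
#' Emulates the stop-and-go rhythm that alternates whole-body ciliary
#' arrest and beating: a square-wave drive `s(t)` is 1 during the arrest
#' half of each cycle; "sync" cells follow the drive (active with the
#' arrest phase, like the cholinergic pacemaker neurons and the ciliary
#' band), "anti" cells follow its complement (active in anti-phase, like
#' the serotonergic neurons). A first-order calcium-indicator kernel
#' `dc/dt = s(t) - c/tau` (forward Euler at the frame rate) turns the
#' drive into calcium, and fluorescence is `F(t) = 100 (1 + c(t))` plus
#' Gaussian shot-noise.
#'
#' @param n_sync,n_anti number of in-phase / anti-phase cells
#' @param period rhythm period in seconds (default 71, a typical pacemaker
#'   cycle length)
#' @param duty fraction of the cycle spent in the arrest phase, in (0, 1)
#' @param rate frame rate in Hz
#' @param tau indicator decay time constant in seconds (default 1.5, a
#'   slow genetically encoded indicator regime)
#' @param noise_sd Gaussian noise sd in fluorescence units
#' @param duration recording length in seconds (default 6 periods)
#' @param smooth_edges when `TRUE` the square drive gets sigmoidal edges
#'   (10% of the period), for testing robustness to waveform shape
#' @param seed RNG seed; output is bit-reproducible given all parameters
#' @return list with `traces` (list of `trace`, sync cells first) and
#'   `truth` (a `pacemaker_truth`: period, duty, per-cell `phase_class`,
#'   ground-truth `arrest_intervals`, `indicator_tau`, `drive`, `seed`)
#' @export
gen_pacemaker_traces <- function(n_sync, n_anti, period = 71, duty = 0.5,
                                 rate = 1.5, tau = 1.5, noise_sd = 0,
                                 duration = 6 * period,
                                 smooth_edges = FALSE, seed = 1) {
  if (period <= 0 || rate <= 0 || tau <= 0 || duration <= 0)
    stop_validation("period, rate, tau and duration must be positive")
  if (duty <= 0 || duty >= 1) stop_validation("duty must be in (0, 1)")
  if (rate * period < 8)
    stop_validation("under-resolved cycle: rate * period must be >= 8")
  n_frames <- as.integer(round(duration * rate))
  t_s <- (seq_len(n_frames) - 1) / rate
  phase <- (t_s %% period) / period
  if (smooth_edges) {
    # sigmoidal edges: s = logistic(signed circular distance to the nearest
    # arrest-window edge), edge width 2% of the period
    circ <- function(a, b) pmin(abs(a - b), 1 - abs(a - b))
    d_edge <- pmin(circ(phase, 0), circ(phase, duty))
    signed <- ifelse(phase < duty, d_edge, -d_edge)
    s <- 1 / (1 + exp(-signed / 0.02))
  } else {
    s <- as.numeric(phase < duty)
  }
  drive_to_f <- function(sv) {
    c_t <- numeric(n_frames)
    dt <- 1 / rate
    for (k in seq_len(n_frames - 1))
      c_t[k + 1] <- c_t[k] + dt * (sv[k] - c_t[k] / tau)
    100 * (1 + c_t)
  }
  f_sync <- drive_to_f(s)
  f_anti <- drive_to_f(1 - s)
  n_cells <- n_sync + n_anti
  traces <- with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      base <- if (i <= n_sync) f_sync else f_anti
      trace(base + rnorm(n_frames, 0, noise_sd), rate)
    })
  })
  arr <- s >= 0.5
  runs <- rle(arr)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  truth <- structure(
    list(period = period, duty = duty,
         phase_class = rep(c("sync", "anti"), c(n_sync, n_anti)),
         arrest_intervals = arrest_intervals(
           data.frame(start = starts[runs$values],
                      end = ends[runs$values] + 1L),
           rate, n_frames = n_frames),
         indicator_tau = tau, drive = s, rate = rate, seed = seed),
    class = "pacemaker_truth")
  list(traces = traces, truth = truth)
}

#' Render traces into a synthetic calcium-imaging movie
#'
#' Each cell is a disk whose intensity follows its trace; the rest of the
#' frame is flat background. Per-pixel Gaussian noise and an optional
#' rigid integer drift (accumulating per frame) complete the scene.
#' Ground-truth ROI masks are returned pre-drift.
#'
#' @param traces list of equal-length `trace` objects, one per cell
#' @param scene list with `centers` (n x 2 matrix of x, y pixel centres),
#'   `radii` (per-cell disk radius, px), `frame_size` `c(H, W)`,
#'   `background` level, `noise_sd`, and `drift` `c(dy, dx)` added per
#'   frame (before rounding to integer pixels)
#' @param seed RNG seed
#' @return list with `movie`, `masks` (list of logical H x W ground-truth
#'   masks) and `scene`
#' @export
gen_movie <- function(traces, scene, seed = 1) {
  n_cells <- length(traces)
  lens <- vapply(traces, function(tr) length(tr$values), integer(1))
  if (length(unique(lens)) != 1) stop_validation("traces differ in length")
  n_frames <- lens[1]
  rate <- traces[[1]]$rate
  H <- scene$frame_size[1]; W <- scene$frame_size[2]
  centers <- as.matrix(scene$centers)
  radii <- scene$radii
  if (nrow(centers) != n_cells || length(radii) != n_cells)
    stop_validation("scene must describe one centre and radius per trace")
  if (any(radii <= 0)) stop_validation("radii must be > 0")
  if (n_cells > 1) {
    for (i in seq_len(n_cells - 1)) for (j in (i + 1):n_cells) {
      if (sqrt(sum((centers[i, ] - centers[j, ])^2)) < radii[i] + radii[j])
        stop_validation("cells ", i, " and ", j,
                        " overlap: ground truth would be ambiguous")
    }
  }
  xg <- matrix(rep(seq_len(W), each = H), H, W)
  yg <- matrix(rep(seq_len(H), W), H, W)
  masks <- lapply(seq_len(n_cells), function(i) {
    (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <= radii[i]^2
  })
  if (any(vapply(masks, sum, integer(1)) == 0))
    stop_validation("a cell has no pixels inside the frame")
  drift <- if (is.null(scene$drift)) c(0, 0) else scene$drift
  bg <- if (is.null(scene$background)) 0 else scene$background
  nsd <- if (is.null(scene$noise_sd)) 0 else scene$noise_sd
  frames <- array(0, dim = c(n_frames, H, W))
  with_seed(seed, {
    for (t in seq_len(n_frames)) {
      img <- matrix(bg, H, W)
      for (i in seq_len(n_cells)) img[masks[[i]]] <- traces[[i]]$values[t]
      dy <- as.integer(round((t - 1) * drift[1]))
      dx <- as.integer(round((t - 1) * drift[2]))
      if (dy != 0 || dx != 0) {
        shifted <- matrix(bg, H, W)
        ys <- max(1, 1 + dy):min(H, H + dy)
        xs <- max(1, 1 + dx):min(W, W + dx)
        shifted[ys, xs] <- img[ys - dy, xs - dx]
        img <- shifted
      }
      if (nsd > 0) img <- img + matrix(rnorm(H * W, 0, nsd), H, W)
      frames[t, , ] <- img
    }
  })
  list(movie = movie(frames, rate), masks = masks, scene = scene)
}

#' Generate a synthetic kymograph with planted arrests
#'
#' Beating frames carry a travelling metachronal wave,
#' `A sin(2 pi f t + g p) + B` for position `p` and frame `t`; arrest
#' frames are flat at `B`. Gaussian noise is added on top. The planted
#' arrest intervals are returned as ground truth.
#'
#' @param beat_hz ciliary beat frequency (must be below Nyquist,
#'   `rate / 2`)
#' @param phase_gradient metachronal phase advance per position (rad/px)
#' @param arrests an `arrest_intervals` (or data.frame `start`, `end`) of
#'   planted arrest frames
#' @param rate frame rate in Hz
#' @param n_frames recording length in frames
#' @param positions number of positions along the sampling line
#' @param amplitude,baseline wave amplitude A and offset B
#' @param noise_sd Gaussian noise sd
#' @param seed RNG seed
#' @return list with `kymograph` (a `kymograph_grid`) and `arrests`
#'   (ground-truth `arrest_intervals`)
#' @export
gen_kymograph <- function(beat_hz, phase_gradient = 0.2, arrests = NULL,
                          rate = 60, n_frames = 600, positions = 20,
                          amplitude = 50, baseline = 100, noise_sd = 0,
                          seed = 1) {
  if (beat_hz >= rate / 2)
    stop_validation("beat_hz must be below Nyquist (rate / 2): ground truth ",
                    "would be aliased")
  if (is.data.frame(arrests)) arrests <- arrest_intervals(arrests, rate,
                                                          n_frames)
  if (is.null(arrests)) arrests <- arrest_intervals(NULL, rate, n_frames)
  arr <- arrest_indicator(arrests, n_frames)
  t_s <- (seq_len(n_frames) - 1) / rate
  p <- seq_len(positions)
  grid <- baseline +
    outer(p, t_s, function(pp, tt)
      amplitude * sin(2 * pi * beat_hz * tt + phase_gradient * pp))
  grid[, arr] <- baseline
  if (noise_sd > 0)
    grid <- grid + with_seed(seed, matrix(rnorm(length(grid), 0, noise_sd),
                                          positions, n_frames))
  list(kymograph = kymograph_grid(grid, rate), arrests = arrests)
}

#' Generate a connectome with planted modules
#'
#' Directed network whose nodes are split into blocks: within-block edges
#' are dense and heavy, between-block edges sparse and light, so the
#' planted labels are the modularity ground truth.
#'
#' @param module_sizes integer vector of block sizes (each >= 2)
#' @param w_in inclusive integer weight range for within-block edges
#' @param p_in probability of each ordered within-block pair being connected
#' @param p_out probability for between-block pairs (in `[0, 1)`)
#' @param w_out inclusive integer weight range for between-block edges
#' @param seed RNG seed
#' @return list with `network` (a `ciliomotor_network`), `partition`
#'   (named integer vector of planted 0-based labels), and `degenerate`
#'   (`TRUE` when `p_out >= p_in`, i.e. the planted structure is not
#'   meaningful)
#' @export
gen_planted_connectome <- function(module_sizes, w_in = c(5, 10), p_in = 0.9,
                                   p_out = 0.05, w_out = c(1, 2), seed = 1) {
  if (any(module_sizes < 2)) stop_validation("module sizes must be >= 2")
  if (p_out < 0 || p_out >= 1) stop_validation("p_out must be in [0, 1)")
  labels <- rep(seq_along(module_sizes), module_sizes) - 1L
  ids <- sprintf("m%d_n%d", labels,
                 unlist(lapply(module_sizes, seq_len)))
  n <- length(ids)
  edges <- with_seed(seed, {
    pre <- character(); post <- character(); w <- integer()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      same <- labels[i] == labels[j]
      p <- if (same) p_in else p_out
      if (runif(1) < p) {
        rng <- if (same) w_in else w_out
        pre <- c(pre, ids[i]); post <- c(post, ids[j])
        w <- c(w, sample(rng[1]:rng[2], 1))
      }
    }
    data.frame(pre = pre, post = post, weight = w)
  })
  ann <- data.frame(id = ids, cell_class = "neuron",
                    group = paste0("block", labels), side = "unpaired",
                    transmitter = "unknown")
  list(network = load_edge_table(edges, ann),
       partition = setNames(labels, ids),
       degenerate = p_out >= p_in)
}

#' Planted cycle-length distribution for a 96-larva cohort
#'
#' A fixed set of 96 pacemaker periods (seconds) emulating the reported
#' cohort statistics for the cholinergic pacemaker neuron: the median
#' period is 71 s and 41 of 96 periods (43%) fall in the inclusive
#' 50-100 s band, with short-cycle and long-cycle tails on either side.
#' Deterministic: the same vector is returned on every call.
#'
#' @return numeric vector of 96 periods in seconds
#' @export
mc_cohort_periods <- function() {
  c(seq(20, 47),              # 28 fast larvae, below the band
    seq(50, 68), 71, 71,      # 21 in the lower band, median pinned at 71
    seq(76, 95),              # 20 in the upper band
    seq(105, 365, by = 10))   # 27 slow larvae, above the band
}

#' Generate a synthetic cohort of pacemaker traces
#'
#' One noisy calcium trace per larva, with periods planted from
#' [mc_cohort_periods()] (or any supplied vector). Each recording spans a
#' whole number of cycles (at least `min_cycles`, and at least
#' `min_duration` seconds), so the planted period sits on a spectral bin.
#'
#' @param periods planted periods in seconds (default [mc_cohort_periods()])
#' @param rate frame rate in Hz
#' @param noise_sd fluorescence noise sd (signal swing is about 140 units)
#' @param min_cycles,min_duration minimum cycles and seconds per recording
#' @param seed RNG seed (per-larva seeds are derived from it)
#' @return list of `trace` objects, one per planted period
#' @export
gen_mc_cohort <- function(periods = mc_cohort_periods(), rate = 1,
                          noise_sd = 5, min_cycles = 3, min_duration = 600,
                          seed = 1) {
  lapply(seq_along(periods), function(i) {
    p <- periods[i]
    n_cyc <- max(min_cycles, ceiling(min_duration / p))
    gen_pacemaker_traces(n_sync = 1, n_anti = 0, period = p, duty = 0.5,
                         rate = rate, tau = 1.5, noise_sd = noise_sd,
                         duration = n_cyc * p,
                         seed = seed + i)$traces[[1]]
  })
}
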