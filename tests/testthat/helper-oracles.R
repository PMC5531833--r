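# Independent oracles used to validate package computations. These are
# deliberately separate implementations (enumeration, brute force, closed
# form); they never call the code paths they check.

# --- modularity -------------------------------------------------------------

# Resolution-scaled Newman modularity on a symmetric adjacency matrix.
oracle_modularity <- function(A, memb, gamma) {
  S <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(A[idx, idx]) / S - gamma * (sum(k[idx]) / S)^2
  }
  q
}

# All set partitions of n elements (restricted-growth strings).
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1))
    for (c in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, c)
  out
}

oracle_best_modularity <- function(A, gamma) {
  max(vapply(all_partitions(nrow(A)),
             function(p) oracle_modularity(A, p, gamma), numeric(1)))
}

# Build a ciliomotor_network from a symmetric weight matrix (upper triangle
# becomes directed edges; symmetrisation inside detect_modules restores A).
net_from_symmetric <- function(A, ids = paste0("v", seq_len(nrow(A)))) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  load_edge_table(data.frame(pre = ids[idx[, 1]], post = ids[idx[, 2]],
                             weight = A[idx]),
                  data.frame(id = ids, cell_class = "neuron",
                             group = "g", side = "unpaired",
                             transmitter = "unknown"))
}

random_symmetric_graph <- function(n, p_edge = 0.5, wmax = 5) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p_edge) A[i, j] <- A[j, i] <- sample(seq_len(wmax), 1)
  A
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# --- traces -----------------------------------------------------------------

# Brute-force minimum-std window scan.
brute_f0 <- function(x, window) {
  best_sd <- Inf; best_i <- NA
  for (i in seq_len(length(x) - window + 1)) {
    s <- sd(x[i:(i + window - 1)])
    if (s < best_sd - 1e-15) { best_sd <- s; best_i <- i }
  }
  list(f0 = mean(x[best_i:(best_i + window - 1)]), window_start = best_i)
}

# Direct O(n^2) DFT peak (no fft call).
brute_dft_peak <- function(x, rate) {
  x <- x - mean(x)
  n <- length(x)
  ks <- seq_len(floor(n / 2))
  pow <- vapply(ks, function(k) {
    ang <- -2 * pi * k * (seq_len(n) - 1) / n
    Re(sum(x * cos(ang)))^2 + Re(sum(x * sin(ang)))^2
  }, numeric(1))
  list(frequency = ks[which.max(pow)] * rate / n, power = pow)
}

# --- ciliary ----------------------------------------------------------------

jaccard_frames <- function(a, b, n) {
  ia <- arrest_indicator(a, n); ib <- arrest_indicator(b, n)
  sum(ia & ib) / sum(ia | ib)
}

# --- stats ------------------------------------------------------------------

# Exact two-sided signed-rank p by direct enumeration of all 2^n sign
# assignments (feasible for n <= 14).
enum_wilcoxon_p <- function(values, center = 0) {
  d <- values - center
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- 2^n
  w_all <- numeric(total)
  for (m in 0:(total - 1)) {
    signs <- bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0
    w_all[m + 1] <- sum(r[signs])
  }
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
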