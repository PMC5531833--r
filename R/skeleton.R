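#' Neuron skeletons and smoothed cable length
#'
#' A skeleton is an ordered set of 3-D points (micrometres) with a parent
#' index per point forming a rooted tree, as produced by skeleton tracing
#' tools and stored in SWC files.
#'
#' @param points numeric matrix with 3 columns (x, y, z in um)
#' @param parent integer vector, one entry per point; `NA` marks the root
#'   (exactly one), other entries index the parent point
#' @return a `skeleton` object
#' @export
skeleton <- function(points, parent) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop_validation("points must have 3 columns")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop_validation("coordinates must be finite")
  n <- nrow(points)
  parent <- as.integer(parent)
  if (length(parent) != n) stop_validation("one parent entry per point")
  roots <- which(is.na(parent))
  if (length(roots) != 1) stop_validation("skeleton must have exactly one root")
  ok <- is.na(parent) | (parent >= 1 & parent <= n)
  if (!all(ok)) stop_validation("parent indices out of range")
  # acyclicity: walking up from every node must reach the root
  for (i in seq_len(n)) {
    j <- i; steps <- 0
    while (!is.na(parent[j])) {
      j <- parent[j]; steps <- steps + 1
      if (steps > n) stop_validation("parent indices contain a cycle")
    }
  }
  structure(list(points = points, parent = parent, root = roots),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat("<skeleton> ", nrow(x$points), " points, raw cable ",
      format(cable_length(x, smoothing_sigma = 0), digits = 5), " um\n",
      sep = "")
  invisible(x)
}

#' Read a skeleton from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`); coordinates are
#' interpreted in micrometres, the radius column is ignored, parent `-1`
#' marks the root.
#'
#' @param path SWC file path
#' @return a `skeleton`
#' @export
read_swc <- function(path) {
  tab <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius",
                                  "parent"))
  idx <- match(tab$parent, tab$id)
  idx[tab$parent < 0] <- NA
  skeleton(as.matrix(tab[c("x", "y", "z")]), idx)
}

#' Smoothed neurite cable length
#'
#' Total cable length of a skeleton after Gaussian smoothing, the standard
#' way to de-jitter manually traced neurites before measuring them. The
#' tree is decomposed into unbranched segments between critical points
#' (root, branch points, leaves); each segment is resampled at 0.5 um arc
#' steps, its interior points are convolved with a Gaussian kernel of the
#' given sigma along arc length (kernel renormalised near the ends), and
#' its endpoints are pinned so branch points stay put and smoothing cannot
#' shrink the tree topologically. The returned length is the summed
#' Euclidean length of the smoothed segments.
#'
#' @param skel a `skeleton`
#' @param smoothing_sigma Gaussian sigma in micrometres (default 6);
#'   `0` returns the raw polyline length exactly
#' @return cable length in micrometres
#' @export
cable_length <- function(skel, smoothing_sigma = 6) {
  if (!inherits(skel, "skeleton")) stop_validation("not a skeleton")
  if (!is.numeric(smoothing_sigma) || smoothing_sigma < 0)
    stop_validation("smoothing_sigma must be >= 0")
  n <- nrow(skel$points)
  if (n < 2) return(0)
  segs <- tree_segments(skel)
  total <- 0
  for (seg in segs) {
    pts <- skel$points[seg, , drop = FALSE]
    if (smoothing_sigma > 0) pts <- smooth_polyline(pts, smoothing_sigma)
    total <- total + polyline_length(pts)
  }
  total
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

# Decompose the tree into maximal unbranched paths between critical points
# (root, branch points, leaves). Each segment is an index vector ordered
# from the upstream critical point to the downstream one.
tree_segments <- function(skel) {
  parent <- skel$parent
  n <- length(parent)
  nchild <- tabulate(parent[!is.na(parent)], nbins = n)
  is_critical <- is.na(parent) | nchild != 1
  segs <- list()
  # walk up from every critical non-root node to the previous critical node
  crit_nonroot <- which(!is.na(parent) & is_critical)
  for (e in crit_nonroot) {
    path <- e
    j <- parent[e]
    while (!is_critical[j]) { path <- c(path, j); j <- parent[j] }
    path <- rev(c(path, j))
    segs[[length(segs) + 1]] <- path
  }
  segs
}

# Resample a polyline at `step` um arc-length spacing (endpoints kept),
# Gaussian-smooth along arc length with end-renormalised kernel, pin the
# endpoints. Returns the smoothed point matrix.
smooth_polyline <- function(pts, sigma, step = 0.5) {
  if (nrow(pts) < 3) return(pts)
  seglen <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seglen))
  L <- s[length(s)]
  if (L <= 0) return(pts[c(1, nrow(pts)), , drop = FALSE])
  # drop duplicated arc positions (zero-length steps) for interpolation
  keep <- !duplicated(s)
  s_u <- s[keep]; pts_u <- pts[keep, , drop = FALSE]
  s_new <- unique(c(seq(0, L, by = step), L))
  res <- vapply(1:3, function(k)
    approx(s_u, pts_u[, k], xout = s_new)$y, numeric(length(s_new)))
  res <- matrix(res, ncol = 3)
  m <- nrow(res)
  if (m < 3) return(res)
  sm <- res
  half <- 4 * sigma
  for (i in 2:(m - 1)) {
    lo <- s_new[i] - half; hi <- s_new[i] + half
    sel <- which(s_new >= lo & s_new <= hi)
    w <- exp(-(s_new[sel] - s_new[i])^2 / (2 * sigma^2))
    w <- w / sum(w)
    sm[i, ] <- colSums(res[sel, , drop = FALSE] * w)
  }
  sm[1, ] <- res[1, ]; sm[m, ] <- res[m, ]
  sm
}
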