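#' Build a ciliomotor network from a synapse edge table
#'
#' Assembles a directed, synapse-count-weighted graph of neurons and
#' multiciliated cells. Edge weights are synapse counts; duplicate
#' `(pre, post)` rows are summed, mirroring connector exports in which each
#' synapse arrives as its own row.
#'
#' @param rows data.frame with columns `pre`, `post`, `weight` (positive
#'   integer synapse counts). May be empty.
#' @param node_annotations optional data.frame with columns `id`,
#'   `cell_class` (`"neuron"`, `"multiciliated"` or `"unknown"`), `group`
#'   (anatomical unit, e.g. `"prototroch"`), `side` (`"left"`, `"right"`,
#'   `"unpaired"`) and `transmitter` (`"cholinergic"`, `"serotonergic"`,
#'   `"catecholaminergic_peptidergic"`, `"unknown"`). Annotated ids absent
#'   from the edge table are kept as isolated nodes; unannotated endpoints
#'   get `"unknown"` defaults.
#'
#' @return A `ciliomotor_network`: list with `nodes` (one row per cell) and
#'   `edges` (one row per ordered `(pre, post)` pair) data.frames.
#' @export
#' @examples
#' net <- load_edge_table(data.frame(pre = "MC", post = "proto_1", weight = 5))
#' net
load_edge_table <- function(rows, node_annotations = NULL) {
  if (is.null(rows)) rows <- data.frame(pre = character(), post = character(),
                                        weight = integer())
  req <- c("pre", "post", "weight")
  if (!all(req %in% names(rows)))
    stop_validation("edge table must have columns pre, post, weight")
  rows$pre <- as.character(rows$pre)
  rows$post <- as.character(rows$post)
  w <- rows$weight
  bad <- which(!is.finite(w) | w <= 0 | w != round(w))
  if (length(bad))
    stop_validation("edge weight must be a positive integer; offending row ",
                    bad[1], " (weight = ", w[bad[1]], ")")
  self <- which(rows$pre == rows$post)
  if (length(self))
    stop_validation("self-edge not allowed; offending row ", self[1],
                    " (", rows$pre[self[1]], ")")
  if (nrow(rows)) {
    agg <- aggregate(weight ~ pre + post, data = rows, FUN = sum)
  } else {
    agg <- rows
  }
  ids <- unique(c(agg$pre, agg$post))
  ann <- node_annotations
  if (!is.null(ann)) {
    if (!"id" %in% names(ann)) stop_validation("annotations need an id column")
    ann$id <- as.character(ann$id)
    if (anyDuplicated(ann$id))
      stop_validation("duplicated id in node annotations: ",
                      ann$id[duplicated(ann$id)][1])
    ids <- unique(c(ids, ann$id))
  }
  nodes <- data.frame(id = ids,
                      cell_class = rep("unknown", length(ids)),
                      group = rep("unknown", length(ids)),
                      side = rep("unpaired", length(ids)),
                      transmitter = rep("unknown", length(ids)),
                      stringsAsFactors = FALSE)
  if (!is.null(ann)) {
    for (f in c("cell_class", "group", "side", "transmitter")) {
      if (f %in% names(ann)) {
        m <- match(ann$id, nodes$id)
        nodes[[f]][m] <- as.character(ann[[f]])
      }
    }
  }
  new_ciliomotor_network(nodes, agg)
}

new_ciliomotor_network <- function(nodes, edges) {
  edges <- edges[order(edges$pre, edges$post), , drop = FALSE]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "ciliomotor_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  if (anyDuplicated(nodes$id))
    stop_validation("node ids must be unique")
  if (any(!nzchar(nodes$id)))
    stop_validation("node ids must be non-empty")
  ok_class <- c("neuron", "multiciliated", "unknown")
  if (!all(nodes$cell_class %in% ok_class))
    stop_validation("cell_class must be one of ", paste(ok_class, collapse = ", "))
  mc_tr <- nodes$transmitter[nodes$cell_class == "multiciliated"]
  if (any(mc_tr != "unknown"))
    stop_validation("multiciliated cells must have transmitter = unknown")
  if (nrow(edges)) {
    if (!all(c(edges$pre, edges$post) %in% nodes$id))
      stop_validation("edge endpoints must exist in the node table")
    if (anyDuplicated(edges[c("pre", "post")]))
      stop_validation("at most one edge per ordered (pre, post) pair")
  }
  invisible(net)
}

#' @export
print.ciliomotor_network <- function(x, ...) {
  n_mc <- sum(x$nodes$cell_class == "multiciliated")
  cat("<ciliomotor_network> ", nrow(x$nodes), " cells (",
      n_mc, " multiciliated), ", nrow(x$edges), " edges, ",
      sum(x$edges$weight), " synapses\n", sep = "")
  invisible(x)
}

#' Apply the ciliomotor inclusion rule
#'
#' A neuron counts as ciliomotor when it forms at least `threshold` synapses
#' combined (summed across all multiciliated targets) onto multiciliated
#' cells; the default of five matches the convention used for whole-body
#' connectome reconstructions of this circuit.
#'
#' @param net a `ciliomotor_network`
#' @param threshold minimum combined synapse count (inclusive), default 5
#' @return character vector of neuron ids, in node-table order
#' @export
select_ciliomotor <- function(net, threshold = 5) {
  validate_network(net)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1)
    stop_validation("threshold must be a single number >= 1")
  mc <- net$nodes$id[net$nodes$cell_class == "multiciliated"]
  if (!length(mc)) return(character())
  e <- net$edges[net$edges$post %in% mc, , drop = FALSE]
  tot <- tapply(e$weight, e$pre, sum)
  keep <- names(tot)[tot >= threshold]
  keep <- setdiff(keep, mc)  # only non-ciliated cells can be ciliomotor
  net$nodes$id[net$nodes$id %in% keep]
}

#' Group-wise synaptic connectivity matrix
#'
#' Entry `(i, j)` is the total number of synapses from any cell in row group
#' `i` onto any cell in column group `j`, the matrix form used to display
#' neuron-to-ciliary-band connectivity.
#'
#' @param net a `ciliomotor_network`
#' @param row_groups,col_groups (optionally named) lists of node-id vectors.
#'   Ids may not repeat within one axis (that would double-count synapses).
#' @return integer matrix with one row/column per group
#' @export
connectivity_matrix <- function(net, row_groups, col_groups) {
  validate_network(net)
  check_groups <- function(groups, axis) {
    ids <- unlist(groups, use.names = FALSE)
    if (anyDuplicated(ids))
      stop_validation("overlapping ids within ", axis, " groups: ",
                      ids[duplicated(ids)][1])
    missing <- setdiff(ids, net$nodes$id)
    if (length(missing))
      stop_validation("unknown node id in ", axis, " groups: ", missing[1])
  }
  check_groups(row_groups, "row")
  check_groups(col_groups, "column")
  gname <- function(groups, prefix)
    if (!is.null(names(groups)) && all(nzchar(names(groups)))) names(groups)
    else paste0(prefix, seq_along(groups))
  m <- matrix(0L, nrow = length(row_groups), ncol = length(col_groups),
              dimnames = list(gname(row_groups, "row"),
                              gname(col_groups, "col")))
  e <- net$edges
  for (i in seq_along(row_groups)) {
    ei <- e[e$pre %in% row_groups[[i]], , drop = FALSE]
    if (!nrow(ei)) next
    for (j in seq_along(col_groups)) {
      m[i, j] <- as.integer(sum(ei$weight[ei$post %in% col_groups[[j]]]))
    }
  }
  m
}

#' Detect network modules by weighted modularity maximisation
#'
#' Partitions the network into communities by greedy multi-level (Louvain)
#' maximisation of resolution-scaled Newman modularity on the symmetrised
#' weighted graph (reciprocal synapse counts summed). The optimisation is
#' randomised: the first restart is the classic all-singletons start, every
#' further restart begins from a random partition before the greedy sweeps,
#' which lets the search escape the merge-only traps of the plain
#' singleton start on small graphs. The best of `n_restarts` runs is
#' returned, so results are deterministic given `(seed, n_restarts)`.
#'
#' @param net a non-empty `ciliomotor_network`
#' @param resolution resolution parameter gamma of the modularity objective
#'   (> 0); 1.4 is the value used for the three-module partition of the
#'   ciliomotor circuit
#' @param seed integer seed for the randomised restarts
#' @param n_restarts number of independent randomised runs (best kept)
#' @return a `partition`: list with `assignment` (named integer vector of
#'   0-based contiguous module ids), `n_modules`, `modularity_score`,
#'   `resolution`, `seed`, `n_restarts`
#' @export
detect_modules <- function(net, resolution = 1.4, seed = 1, n_restarts = 20) {
  validate_network(net)
  if (!nrow(net$nodes)) stop_validation("network has no nodes")
  if (!is.numeric(resolution) || resolution <= 0)
    stop_validation("resolution must be > 0")
  ids <- net$nodes$id
  A <- symmetric_adjacency(net)
  if (sum(A) == 0) {
    assignment <- setNames(seq_along(ids) - 1L, ids)
    return(new_partition(assignment, NaN, resolution, seed, n_restarts))
  }
  best <- NULL; best_q <- -Inf
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      memb <- louvain_partition(A, resolution, random_init = r > 1)
      q <- modularity_q(A, memb, resolution)
      if (q > best_q + 1e-12) { best_q <- q; best <- memb }
    }
  })
  relab <- match(best, unique(best)) - 1L   # contiguous 0-based labels
  assignment <- setNames(relab, ids)
  new_partition(assignment, best_q, resolution, seed, n_restarts)
}

# Symmetrised weighted adjacency matrix (w_ij + w_ji), zero diagonal,
# rows/columns in node-table order.
symmetric_adjacency <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- net$edges
  if (nrow(e)) {
    i <- match(e$pre, ids); j <- match(e$post, ids)
    for (k in seq_along(i)) {
      A[i[k], j[k]] <- A[i[k], j[k]] + e$weight[k]
      A[j[k], i[k]] <- A[j[k], i[k]] + e$weight[k]
    }
  }
  A
}

#' Resolution-scaled Newman modularity of a partition
#'
#' `Q = sum_c [ w_c / (2m) - gamma * (K_c / (2m))^2 ]` on the symmetrised
#' weighted graph, where `w_c` is twice the internal weight of community
#' `c`, `K_c` the summed degree and `m` the total edge weight.
#'
#' @param net a `ciliomotor_network`
#' @param assignment named vector of module labels (names = node ids), as
#'   in a `partition`'s `assignment`
#' @param resolution resolution parameter gamma
#' @return the modularity score
#' @export
modularity_score <- function(net, assignment, resolution = 1.4) {
  A <- symmetric_adjacency(net)
  modularity_q(A, assignment[rownames(A)], resolution)
}

modularity_q <- function(A, memb, gamma) {
  S <- sum(A)
  if (S == 0) return(NaN)
  k <- rowSums(A)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(A[idx, idx]) / S - gamma * (sum(k[idx]) / S)^2
  }
  q
}

# One randomised multi-level (Louvain) run on symmetric adjacency A.
# Returns an integer membership vector over the rows of A.
louvain_partition <- function(A, gamma, random_init = TRUE) {
  n0 <- nrow(A)
  node_comm <- seq_len(n0)
  A_l <- A
  level <- 1
  repeat {
    n <- nrow(A_l)
    init <- if (level == 1 && random_init) {
      sample.int(sample.int(n, 1), n, replace = TRUE)
    } else {
      seq_len(n)
    }
    memb <- greedy_sweeps(A_l, init, gamma)
    memb <- match(memb, unique(memb))
    node_comm <- memb[node_comm]
    if (max(memb) == n || max(memb) == 1) break
    # aggregate: communities become nodes (memb is contiguous 1..k, and
    # rowsum orders its groups 1..k, so row/column order is consistent)
    A_l <- as.matrix(rowsum(t(rowsum(A_l, memb)), memb))
    level <- level + 1
  }
  match(node_comm, unique(node_comm))
}

# Greedy single-node moves (to any existing community or a new one),
# swept in random order until no move improves Q.
greedy_sweeps <- function(A, memb, gamma) {
  S <- sum(A)
  k <- rowSums(A)
  n <- nrow(A)
  memb <- match(memb, unique(memb))
  K <- as.vector(rowsum(k, memb))          # community degree sums
  names(K) <- NULL
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      ci <- memb[i]
      w_i <- rowsum(A[i, ], memb)          # weight from i to each community
      comms <- as.integer(rownames(w_i))
      w_i <- as.vector(w_i)
      w_ic <- w_i[match(ci, comms)] - A[i, i]
      K_ci <- K[ci] - k[i]
      # candidate communities: all existing plus an empty one
      cand <- c(comms, max(memb) + 1L)
      w_cand <- c(w_i, 0); w_cand[match(ci, cand)] <- w_ic
      K_cand <- c(K[comms], 0); K_cand[match(ci, cand)] <- K_ci
      gain <- 2 * (w_cand - w_ic) / S -
        2 * gamma * k[i] * (K_cand - K_ci) / S^2
      gain[match(ci, cand)] <- 0
      j <- which.max(gain)
      if (gain[j] > 1e-12) {
        d <- cand[j]
        K[ci] <- K[ci] - k[i]
        if (d > length(K)) K <- c(K, 0)
        K[d] <- K[d] + k[i]
        memb[i] <- d
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  memb
}

new_partition <- function(assignment, score, resolution, seed, n_restarts) {
  structure(list(assignment = assignment,
                 n_modules = length(unique(assignment)),
                 modularity_score = score, resolution = resolution,
                 seed = seed, n_restarts = n_restarts),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", x$n_modules, " modules over ", length(x$assignment),
      " nodes; modularity = ", format(x$modularity_score, digits = 4),
      " at resolution ", x$resolution, "\n", sep = "")
  invisible(x)
}

#' Convert a ciliomotor network to an igraph graph
#'
#' @param net a `ciliomotor_network`
#' @param directed keep directionality (`TRUE`) or symmetrise by summing
#'   reciprocal weights (`FALSE`, the convention used for modularity)
#' @return an igraph graph with a `weight` edge attribute and node metadata
#' @export
as_igraph <- function(net, directed = TRUE) {
  validate_network(net)
  e <- net$edges
  if (!directed && nrow(e)) {
    a <- pmin(e$pre, e$post); b <- pmax(e$pre, e$post)
    key <- paste(a, b, sep = "\r")
    w <- tapply(e$weight, key, sum)
    pairs <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    e <- data.frame(pre = pairs[, 1], post = pairs[, 2],
                    weight = as.numeric(w), stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(e[c("pre", "post", "weight")],
                                directed = directed, vertices = net$nodes)
}

#' Export a network to GraphML
#'
#' @param net a `ciliomotor_network`
#' @param path output file path
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net, directed = TRUE), path,
                      format = "graphml")
  invisible(path)
}

#' Write / read a weighted edge list as CSV
#'
#' @param net a `ciliomotor_network`
#' @param path CSV path (`pre,post,weight` header)
#' @export
write_edge_csv <- function(net, path) {
  write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_csv
#' @param node_annotations optional annotation table forwarded to
#'   [load_edge_table()]
#' @export
read_edge_csv <- function(path, node_annotations = NULL) {
  load_edge_table(read.csv(path, stringsAsFactors = FALSE), node_annotations)
}

#' Export a module partition as CSV (`id,module`)
#'
#' @param partition a `partition` from [detect_modules()]
#' @param path CSV path
#' @export
write_partition_csv <- function(partition, path) {
  write.csv(data.frame(id = names(partition$assignment),
                       module = as.integer(partition$assignment)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
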