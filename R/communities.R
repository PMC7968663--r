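#' Newman-Girvan modularity of a partition
#'
#' `Q = sum over communities c of [ e_c / m - resolution * (d_c / 2m)^2 ]`,
#' computed on the undirected, unweighted view: `e_c` counts intra-community
#' edges, `d_c` is the total degree of the community's nodes and `m` the
#' total number of edges. `Q = 0` means the within-community edge count is
#' what a degree-preserving random null would give; values near 1 indicate
#' strong community structure. The resolution parameter scales the null
#' term: values above 1 favour smaller communities.
#'
#' @param net A `dtn_network`.
#' @param assignment Integer or character community label per node (in node
#'   order), or a `dtn_partition`.
#' @param resolution Resolution parameter (default 1, plain modularity).
#' @return A single numeric value.
#' @export
modularity_score <- function(net, assignment, resolution = 1) {
  if (inherits(assignment, "dtn_partition")) {
    assignment <- assignment$assignment$community
  }
  if (length(assignment) != n_nodes(net)) {
    abort("`assignment` must label every node exactly once")
  }
  if (anyNA(assignment)) abort("`assignment` must label every node exactly once")
  lab <- as.integer(factor(assignment))
  ue <- undirected_edges(net)
  m <- nrow(ue)
  if (m == 0) return(0)
  deg <- tabulate(c(ue$from, ue$to), nbins = n_nodes(net))
  intra <- tabulate(lab[ue$from][lab[ue$from] == lab[ue$to]], nbins = max(lab))
  d_c <- tapply(deg, lab, sum)
  d_c_full <- numeric(max(lab))
  d_c_full[as.integer(names(d_c))] <- d_c
  sum(intra / m - resolution * (d_c_full / (2 * m))^2)
}

# Simple undirected edge list: self-loops dropped, parallel edges collapsed.
undirected_edges <- function(net) {
  e <- net$edges[net$edges$from != net$edges$to, ]
  a <- pmin(e$from, e$to)
  b <- pmax(e$from, e$to)
  keep <- !duplicated(paste(a, b))
  tibble(from = a[keep], to = b[keep])
}

#' Multilevel (Louvain) community detection
#'
#' The two-phase multilevel heuristic: every node starts in its own
#' community; in the local phase, nodes are visited in a seeded random
#' permutation and each is moved to the neighbouring community giving the
#' highest positive modularity gain (ties broken by smallest community
#' label), repeating passes until no move improves Q; in the aggregation
#' phase each community becomes a single node (intra-community weight as a
#' self-loop) and the local phase is rerun, until modularity cannot be
#' increased further. Computed on the undirected, unweighted view.
#' Isolated nodes form singleton communities.
#'
#' @param net A `dtn_network` with at least one edge.
#' @param resolution Resolution parameter multiplying the null-model term.
#' @param seed Integer seed controlling the node visit order; the same
#'   (network, resolution, seed) always returns the same partition.
#' @param n_restarts Run the algorithm this many times with seeds
#'   `seed, seed + 1, ...` and keep the highest-Q partition.
#' @return A `dtn_partition`: list with `assignment` (tibble `id`, `role`,
#'   `community`), `Q`, `resolution`, `seed`, `n_communities`, and
#'   `q_trace` (modularity after each level, non-decreasing).
#' @export
cluster_multilevel <- function(net, resolution = 1, seed = 1L,
                               n_restarts = 1L) {
  if (n_edges(net) == 0) abort("community detection needs at least one edge")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    p <- louvain_once(net, resolution, seed + r - 1L)
    if (is.null(best) || p$Q > best$Q) best <- p
  }
  best
}

louvain_once <- function(net, resolution, seed) {
  with_seed(seed, louvain_once_impl(net, resolution, seed))
}

louvain_once_impl <- function(net, resolution, seed) {
  ue <- undirected_edges(net)
  n0 <- n_nodes(net)
  # current aggregated graph: weighted edge list incl. self-loops
  ef <- ue$from
  et <- ue$to
  ew <- rep(1, nrow(ue))
  node_map <- seq_len(n0) # original node -> current super-node
  m <- sum(ew)
  q_trace <- numeric(0)
  n_cur <- n0
  repeat {
    res <- louvain_local_phase(n_cur, ef, et, ew, m, resolution)
    comm <- res$comm
    q_trace <- c(q_trace, res$Q)
    # compact labels
    lab <- as.integer(factor(comm))
    n_new <- max(lab)
    if (n_new == n_cur || !res$moved) break
    node_map <- lab[node_map]
    # aggregate edges between communities (self-loops keep intra weight)
    af <- pmin(lab[ef], lab[et])
    at <- pmax(lab[ef], lab[et])
    key <- af * (n_new + 1) + at
    agg <- rowsum(ew, key)
    kk <- as.numeric(rownames(agg))
    ef <- as.integer(kk %/% (n_new + 1))
    et <- as.integer(kk %% (n_new + 1))
    ew <- agg[, 1]
    n_cur <- n_new
  }
  final <- node_map
  lab <- as.integer(factor(final))
  q <- modularity_score(net, lab, resolution)
  structure(
    list(
      assignment = tibble(id = net$nodes$id, role = net$nodes$role,
                          community = lab),
      Q = q,
      resolution = resolution,
      seed = seed,
      n_communities = max(lab),
      q_trace = q_trace
    ),
    class = "dtn_partition"
  )
}

# One local-move phase on a weighted graph given as an edge list
# (undirected; self-loops carry intra-community weight). Returns the
# community assignment, whether any node moved, and the phase's final Q.
louvain_local_phase <- function(n, ef, et, ew, m, resolution) {
  # adjacency with weights, excluding self-loops from neighbour moves
  nl <- ef != et
  adj_from <- c(ef[nl], et[nl])
  adj_to <- c(et[nl], ef[nl])
  adj_w <- c(ew[nl], ew[nl])
  ord <- order(adj_from, method = "radix")
  adj_from <- adj_from[ord]
  adj_to <- adj_to[ord]
  adj_w <- adj_w[ord]
  ptr <- c(0, cumsum(tabulate(adj_from, nbins = n)))
  # weighted degree: self-loop counts twice (both ends)
  k <- numeric(n)
  kt <- rowsum(c(adj_w, 2 * ew[!nl]), c(adj_from, ef[!nl]))
  k[as.integer(rownames(kt))] <- kt[, 1]
  self_w <- numeric(n)
  st <- rowsum(ew[!nl], ef[!nl])
  if (nrow(st) > 0) self_w[as.integer(rownames(st))] <- st[, 1]

  comm <- seq_len(n)
  sigma_tot <- k # total degree per community
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      if (ptr[v + 1] == ptr[v]) next
      idx <- (ptr[v] + 1):ptr[v + 1]
      nb <- adj_to[idx]
      w <- adj_w[idx]
      cv <- comm[v]
      # weight from v to each neighbouring community
      wc <- rowsum(w, comm[nb])
      cand <- as.integer(rownames(wc))
      wvc <- wc[, 1]
      w_own <- if (cv %in% cand) wvc[match(cv, cand)] else 0
      # remove v from its community
      sigma_tot[cv] <- sigma_tot[cv] - k[v]
      # gain of joining community c: (w_vc - res * k_v * sigma_c / 2m) / m
      gain <- (wvc - resolution * k[v] * sigma_tot[cand] / (2 * m)) / m
      gain_stay <- (w_own - resolution * k[v] * sigma_tot[cv] / (2 * m)) / m
      best <- which(gain - gain_stay > 1e-12)
      if (length(best) > 0) {
        b <- best[order(-gain[best], cand[best])][1]
        new_c <- cand[b]
        if (new_c != cv) {
          comm[v] <- new_c
          moved <- TRUE
          moved_any <- TRUE
        }
      }
      sigma_tot[comm[v]] <- sigma_tot[comm[v]] + k[v]
    }
    if (!moved) break
  }
  # Q of the aggregated assignment on the current weighted graph
  intra <- sum(ew[comm[ef] == comm[et]])
  d_c <- rowsum(k, comm)
  q <- intra / m - resolution * sum((d_c[, 1] / (2 * m))^2)
  list(comm = comm, moved = moved_any, Q = q)
}

#' @export
print.dtn_partition <- function(x, ...) {
  cat(sprintf(
    "# Multilevel partition: %d communities, Q = %.4f (resolution %g, seed %d)\n",
    x$n_communities, x$Q, x$resolution, x$seed
  ))
  invisible(x)
}

#' Tidy a partition into a node-community tibble
#' @param x A `dtn_partition`.
#' @param ... Unused.
#' @return Tibble `id`, `role`, `community`.
#' @method tidy dtn_partition
#' @export
tidy.dtn_partition <- function(x, ...) x$assignment

#' One-row summary of a partition
#' @param x A `dtn_partition`.
#' @param ... Unused.
#' @return Tibble `n_communities`, `Q`, `resolution`, `seed`, `largest`.
#' @method glance dtn_partition
#' @export
glance.dtn_partition <- function(x, ...) {
  s <- community_size_stats(x)
  tibble(n_communities = x$n_communities, Q = x$Q,
         resolution = x$resolution, seed = x$seed, largest = s$largest)
}

#' Community size statistics
#'
#' @param partition A `dtn_partition` (or a vector of labels).
#' @return A list of class `dtn_size_stats`: `sizes` (descending),
#'   `largest`, `frac_over_100` (fraction of communities with more than 100
#'   nodes), `frac_size_2` (fraction with exactly 2 nodes).
#' @export
community_size_stats <- function(partition) {
  lab <- if (inherits(partition, "dtn_partition")) {
    partition$assignment$community
  } else {
    partition
  }
  sizes <- sort(as.integer(table(lab)), decreasing = TRUE)
  structure(
    list(
      sizes = sizes,
      largest = sizes[1],
      frac_over_100 = mean(sizes > 100),
      frac_size_2 = mean(sizes == 2)
    ),
    class = "dtn_size_stats"
  )
}

#' @export
print.dtn_size_stats <- function(x, ...) {
  cat(sprintf(
    "# Community sizes: largest=%d, %.1f%% over 100 nodes, %.1f%% of size 2\n",
    x$largest, 100 * x$frac_over_100, 100 * x$frac_size_2
  ))
  invisible(x)
}
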