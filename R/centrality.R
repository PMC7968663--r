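#' Degree centrality
#'
#' Degree of each node divided by `n - 1`, the maximum possible degree in a
#' network of `n` vertices.
#'
#' @param net A `dtn_network`.
#' @param direction `"in"` (drugs affecting a target), `"out"` (targets a
#'   drug affects) or `"total"` (undirected-neighbor count).
#' @return A `dtn_centrality` tibble: `id`, `role`, `value`, sorted by
#'   decreasing value (ties by id). The `metric`, `normalization` and
#'   `parameters` attributes record the convention used.
#' @export
degree_centrality <- function(net, direction = c("in", "out", "total")) {
  direction <- match.arg(direction)
  if (n_nodes(net) < 2) abort("degree centrality needs at least 2 nodes")
  deg <- switch(direction,
    "in" = lengths(net$in_adj),
    "out" = lengths(net$out_adj),
    total = lengths(lapply(seq_len(n_nodes(net)), undirected_adj_one,
                           net = net))
  )
  new_centrality(net, deg / (n_nodes(net) - 1),
                 metric = paste0("degree_", direction),
                 normalization = "k/(n-1)",
                 parameters = list(direction = direction))
}

new_centrality <- function(net, value, metric, normalization, parameters) {
  out <- tibble(id = net$nodes$id, role = net$nodes$role,
                value = as.numeric(value))
  out <- out[canonical_order(-out$value, out$id), ]
  structure(
    out,
    class = c("dtn_centrality", class(tibble())),
    metric = metric, normalization = normalization, parameters = parameters
  )
}

#' @export
print.dtn_centrality <- function(x, ...) {
  cat(sprintf("# %s centrality (%s)\n", attr(x, "metric"),
              attr(x, "normalization")))
  NextMethod()
}

# Adjacency list for a traversal sense. directed_out follows edges
# drug -> target; directed_in walks them backwards; undirected merges both.
sense_adj <- function(net, sense) {
  switch(sense,
    directed_out = net$out_adj,
    directed_in = net$in_adj,
    undirected = undirected_adj(net)
  )
}

bfs_distances <- function(adj, n, src) {
  d <- rep(NA_integer_, n)
  d[src] <- 0L
  frontier <- src
  lvl <- 0L
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(d[nxt])]
    lvl <- lvl + 1L
    d[nxt] <- lvl
    frontier <- nxt
  }
  d
}

#' All-pairs shortest-path distances
#'
#' Breadth-first search from every node, in the requested traversal sense.
#' Unreachable pairs are `NA`. The result is a dense integer matrix, so
#' this is intended for networks up to a few thousand nodes.
#'
#' @param net A `dtn_network`.
#' @param sense `"directed_out"` (along drug-to-target edges),
#'   `"directed_in"` (against them) or `"undirected"`.
#' @return An `n x n` integer matrix `D` with `D[s, v]` the length of the
#'   shortest path from `s` to `v` in the chosen sense; dimnames are node
#'   ids; class `dtn_distances`.
#' @export
all_pairs_distances <- function(net,
                                sense = c("undirected", "directed_out",
                                          "directed_in")) {
  sense <- match.arg(sense)
  n <- n_nodes(net)
  adj <- sense_adj(net, sense)
  D <- matrix(NA_integer_, n, n, dimnames = list(net$nodes$id, net$nodes$id))
  for (s in seq_len(n)) D[s, ] <- bfs_distances(adj, n, s)
  structure(D, sense = sense, class = c("dtn_distances", "matrix", "array"))
}

#' Closeness centrality
#'
#' The reciprocal of the mean shortest-path distance from the reachable
#' set, damped for disconnected graphs: with `R(v)` the nodes that reach
#' `v` in the chosen sense (excluding `v`), the score is
#' `(|R(v)| / sum d) * (|R(v)| / (n - 1))` — the Wasserman-Faust
#' component-scaled convention, which keeps scores of nodes in small
#' components proportionally small instead of rewarding isolation. Nodes
#' nothing reaches score 0.
#'
#' The default sense `"directed_in"` measures how quickly a node is reached
#' along drug-to-target edges, which is the convention under which heavily
#' drugged receptors top the ranking in real drug-target landscapes.
#'
#' @param net A `dtn_network`.
#' @param sense Traversal sense, as [all_pairs_distances()].
#' @return A `dtn_centrality` tibble.
#' @export
closeness_centrality <- function(net,
                                 sense = c("directed_in", "directed_out",
                                           "undirected")) {
  sense <- match.arg(sense)
  n <- n_nodes(net)
  if (n < 2) abort("closeness centrality needs at least 2 nodes")
  # walking the in-adjacency from v enumerates exactly the nodes that can
  # reach v along drug->target edges, at their incoming-path distance, so
  # the sense's own adjacency is the right traversal for BFS from v
  adj <- sense_adj(net, sense)
  value <- numeric(n)
  for (v in seq_len(n)) {
    d <- bfs_distances(adj, n, v)
    d <- d[-v]
    reach <- which(!is.na(d) & d > 0)
    if (length(reach) == 0) next
    r <- length(reach)
    value[v] <- (r / sum(d[reach])) * (r / (n - 1))
  }
  new_centrality(net, value, metric = "closeness",
                 normalization = "Wasserman-Faust component-scaled",
                 parameters = list(sense = sense))
}

# Single-source Brandes pass: BFS with shortest-path counting, then
# level-by-level backward dependency accumulation. esrc/edst are the edge
# arrays of the traversal sense.
brandes_source <- function(esrc, edst, n, s) {
  d <- rep(NA_integer_, n)
  sigma <- numeric(n)
  d[s] <- 0L
  sigma[s] <- 1
  lvl <- 0L
  frontier <- s
  repeat {
    on_frontier <- esrc %in% frontier
    dst <- edst[on_frontier]
    src <- esrc[on_frontier]
    lvl <- lvl + 1L
    newn <- unique(dst[is.na(d[dst])])
    if (length(newn) == 0) break
    d[newn] <- lvl
    at_level <- d[dst] == lvl & !is.na(d[dst])
    add <- rowsum(sigma[src[at_level]], dst[at_level])
    idx <- as.integer(rownames(add))
    sigma[idx] <- sigma[idx] + add[, 1]
    frontier <- newn
  }
  delta <- numeric(n)
  edge_lvl_src <- d[esrc]
  edge_lvl_dst <- d[edst]
  shortest <- !is.na(edge_lvl_src) & !is.na(edge_lvl_dst) &
    edge_lvl_dst == edge_lvl_src + 1L
  for (l in seq(lvl - 1L, 0L)) {
    sel <- shortest & edge_lvl_src == l
    if (!any(sel)) next
    w <- edst[sel]
    v <- esrc[sel]
    contrib <- rowsum((1 + delta[w]) / sigma[w], v)
    idx <- as.integer(rownames(contrib))
    delta[idx] <- delta[idx] + sigma[idx] * contrib[, 1]
  }
  delta[s] <- 0
  delta
}

#' Betweenness centrality
#'
#' `C(v) = sum over s != t != v of sigma(s, t | v) / sigma(s, t)`, the
#' fraction of all-pairs shortest paths passing through `v` as an interior
#' vertex, computed exactly with Brandes' shortest-path-counting
#' accumulation. Scores are normalized by `(n - 1)(n - 2)` ordered source-
#' target pairs in the directed senses; in the undirected sense each
#' unordered pair is counted from both endpoints, so the same divisor
#' yields the conventional `2 / ((n - 1)(n - 2))` normalization.
#'
#' The default sense is `"directed_out"`: on a near-bipartite drug-target
#' graph only dual-role compounds can be interior vertices of directed
#' paths, which is why the top of the directed betweenness ranking is
#' populated exclusively by dual-role nodes.
#'
#' @param net A `dtn_network`.
#' @param sense Traversal sense, as [all_pairs_distances()].
#' @return A `dtn_centrality` tibble.
#' @export
betweenness_centrality <- function(net,
                                   sense = c("directed_out", "undirected",
                                             "directed_in")) {
  sense <- match.arg(sense)
  n <- n_nodes(net)
  if (n < 3) abort("betweenness centrality needs at least 3 nodes")
  if (sense == "undirected") {
    e <- net$edges[net$edges$from != net$edges$to, ]
    ekey <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    e <- e[!duplicated(ekey), ]
    esrc <- c(e$from, e$to)
    edst <- c(e$to, e$from)
  } else if (sense == "directed_out") {
    esrc <- net$edges$from
    edst <- net$edges$to
  } else {
    esrc <- net$edges$to
    edst <- net$edges$from
  }
  raw <- numeric(n)
  for (s in seq_len(n)) {
    if (!s %in% esrc) next
    raw <- raw + brandes_source(esrc, edst, n, s)
  }
  value <- raw / ((n - 1) * (n - 2))
  new_centrality(net, value, metric = "betweenness",
                 normalization = "sum over ordered pairs / ((n-1)(n-2))",
                 parameters = list(sense = sense))
}

#' Eigenvector centrality by power iteration
#'
#' Computes the leading eigenvector of the undirected adjacency matrix `B`
#' of one weakly connected component by power iteration: starting from the
#' uniform positive vector, repeat `x <- B x / ||B x||` until the maximum
#' componentwise change drops below `tol`. For a connected non-bipartite
#' component Perron-Frobenius guarantees convergence to the unique
#' non-negative leading eigenvector; on an exactly bipartite component the
#' two leading eigenvalues have equal magnitude and plain power iteration
#' can oscillate, so the iteration adds a small diagonal shift (which
#' leaves the eigenvectors unchanged). Nodes outside the chosen component
#' score 0; the reported vector has unit Euclidean norm.
#'
#' @param net A `dtn_network`.
#' @param component Component index to run on (1 = giant); `NULL` uses the
#'   whole network only if it is connected.
#' @param tol Convergence tolerance on the max-norm change.
#' @param max_iter Maximum iterations; exceeding it is an error carrying
#'   the last iterate in its condition data.
#' @return A `dtn_centrality` tibble; attribute `lambda` is the leading
#'   eigenvalue estimate of `B`.
#' @export
eigenvector_centrality <- function(net, component = 1L, tol = 1e-10,
                                   max_iter = 1e6) {
  comp <- weak_components(net)
  if (is.null(component)) {
    if (length(comp$sizes) > 1) {
      abort("network is disconnected; pick a `component` to run on")
    }
    component <- 1L
  }
  keep <- which(comp$component_of == component)
  if (length(keep) < 2) abort("component has no edges")
  sub <- induced_subnetwork(net, keep)
  e <- sub$edges[sub$edges$from != sub$edges$to, ]
  ekey <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  e <- e[!duplicated(ekey), ]
  m <- length(keep)
  B <- Matrix::sparseMatrix(i = c(e$from, e$to), j = c(e$to, e$from),
                            x = 1, dims = c(m, m))
  shift <- 1 # diagonal shift: same eigenvectors, breaks the +/- lambda tie
  # of exactly bipartite components and speeds separation of the leading pair
  x <- rep(1 / sqrt(m), m)
  lambda <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    y <- as.numeric(B %*% x) + shift * x
    ny <- sqrt(sum(y^2))
    if (ny == 0) abort("adjacency annihilated the iterate; no edges?")
    y <- y / ny
    if (max(abs(y - x)) < tol) {
      x <- y
      lambda <- ny - shift
      converged <- TRUE
      break
    }
    x <- y
  }
  if (!converged) {
    abort(sprintf("power iteration did not converge in %d iterations",
                  max_iter), last_state = x)
  }
  value <- numeric(n_nodes(net))
  value[keep] <- x
  out <- new_centrality(net, value, metric = "eigenvector",
                        normalization = "unit Euclidean norm on component",
                        parameters = list(component = component, tol = tol,
                                          iterations = it))
  attr(out, "lambda") <- lambda
  out
}

#' Top-k ranking of a centrality table
#'
#' Deterministic descending ranking: values non-increasing, ties broken
#' lexicographically by node id (C locale).
#'
#' @param scores A `dtn_centrality` tibble (already sorted this way).
#' @param k Number of nodes to keep; larger than the table triggers a
#'   warning and truncation.
#' @return A tibble `rank`, `id`, `role`, `value`.
#' @export
top_nodes <- function(scores, k = 10L) {
  stopifnot(k >= 1)
  if (k > nrow(scores)) {
    warn(sprintf("k = %d exceeds the %d scored nodes; truncating",
                 k, nrow(scores)))
    k <- nrow(scores)
  }
  out <- as_tibble(scores)[seq_len(k), ]
  tibble(rank = seq_len(k), id = out$id, role = out$role, value = out$value)
}
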