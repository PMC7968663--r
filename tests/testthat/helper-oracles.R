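# Independent oracles used to validate the package's algorithms on small
# instances. Everything here is deliberately naive (enumeration, dense
# matrices) and shares no code with the implementation under test.

# Build a network from integer edge vectors; ids are zero-padded so that
# lexicographic and numeric order coincide.
toy_net <- function(from, to, merge = TRUE) {
  tab <- interaction_table(tibble::tibble(
    drug_id = sprintf("n%03d", from),
    target_id = sprintf("n%03d", to)
  ))
  build_network(tab, merge_dual_roles = merge)
}

# Random sparse directed edge list on n nodes (no self-loops, dedup).
random_edges <- function(n, p = 0.25) {
  g <- expand.grid(from = seq_len(n), to = seq_len(n))
  g <- g[g$from != g$to, ]
  keep <- stats::runif(nrow(g)) < p
  g[keep, , drop = FALSE]
}

# Dense adjacency matrix of a dtn_network in a traversal sense.
dense_adjacency <- function(net, sense = c("undirected", "directed_out",
                                           "directed_in")) {
  sense <- match.arg(sense)
  n <- nrow(net$nodes)
  A <- matrix(0, n, n)
  e <- net$edges
  if (sense %in% c("undirected", "directed_out")) A[cbind(e$from, e$to)] <- 1
  if (sense %in% c("undirected", "directed_in")) A[cbind(e$to, e$from)] <- 1
  diag(A) <- 0
  A
}

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix.
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# Enumerate every simple path between two nodes by DFS; returns a list of
# integer vectors. Exponential; for oracle use on <= 10 nodes only.
all_simple_paths_dfs <- function(adj, s, t) {
  paths <- list()
  walk <- function(v, seen, trail) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- trail
      return(invisible())
    }
    for (u in adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        walk(u, seen, c(trail, u))
        seen[u] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, length(adj))
  seen[s] <- TRUE
  walk(s, seen, s)
  paths
}

# Betweenness by explicit shortest-path enumeration, normalized over
# ordered pairs by (n-1)(n-2). `A` is the adjacency matrix of the sense.
brute_betweenness <- function(A) {
  n <- nrow(A)
  adj <- apply(A > 0, 1, which, simplify = FALSE)
  raw <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- all_simple_paths_dfs(adj, s, t)
      if (length(paths) == 0) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        raw[v] <- raw[v] + through / sigma
      }
    }
  }
  raw / ((n - 1) * (n - 2))
}

# Highest modularity over all set partitions of <= 9 nodes, enumerated via
# restricted growth strings.
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(i, labels, m) {
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (c in seq_len(m + 1)) {
      labels[i] <- c
      rec(i + 1, labels, max(m, c))
    }
  }
  rec(1, integer(n), 0L)
  out
}

best_modularity_exhaustive <- function(net, resolution = 1) {
  parts <- all_set_partitions(nrow(net$nodes))
  qs <- vapply(parts, function(p) modularity_score(net, p, resolution),
               numeric(1))
  list(Q = max(qs), assignment = parts[[which.max(qs)]])
}

# Exact minimum set cover: smallest drug subset covering all targets,
# by exhaustive subset search over <= 12 drugs.
exact_min_cover_size <- function(net) {
  drugs <- which(net$nodes$is_drug)
  targets <- which(lengths(net$in_adj) > 0)
  stopifnot(length(drugs) <= 12)
  covers <- lapply(drugs, function(d) intersect(net$out_adj[[d]], targets))
  for (k in seq_along(drugs)) {
    sets <- utils::combn(seq_along(drugs), k, simplify = FALSE)
    for (s in sets) {
      if (setequal(unique(unlist(covers[s])), targets)) return(k)
    }
  }
  length(drugs)
}

# Exact upper-tail hypergeometric P(X >= k) by direct combinatorial sums.
hyper_tail_exact <- function(k, term_size, background_size, query_size) {
  xs <- k:min(term_size, query_size)
  sum(choose(term_size, xs) *
        choose(background_size - term_size, query_size - xs)) /
    choose(background_size, query_size)
}

# Benjamini-Hochberg step-up recomputed from first principles.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
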