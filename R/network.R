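#' Build a directed drug-target network from an interaction table
#'
#' Nodes are the distinct entities of the table; each edge points from a
#' drug to one of its targets. When `merge_dual_roles` is `TRUE` (the
#' default), a drug and a target whose canonicalized names match (trimmed,
#' case-folded) become a single node carrying both roles — this is what
#' makes real drug-target networks non-bipartite: compounds such as nitric
#' oxide or copper are listed both as drugs and as targets of other drugs.
#'
#' @param table A `dtn_interactions` table (or coercible data frame).
#' @param merge_dual_roles Merge same-named drug and target entries into one
#'   dual-role node. When `FALSE` drug and target namespaces are kept
#'   disjoint even if names coincide.
#' @return An object of class `dtn_network`: a list with
#'   \describe{
#'     \item{nodes}{tibble with `id` (canonical key), `name` (display),
#'       `is_drug`, `is_target`, `role`.}
#'     \item{edges}{tibble of integer node indices `from`, `to`.}
#'     \item{out_adj, in_adj}{adjacency lists (successors/predecessors) as
#'       integer vectors per node.}
#'   }
#' @examples
#' net <- build_network(interaction_table(
#'   data.frame(drug_id = c("D1", "D1"), target_id = c("T1", "T2"))
#' ))
#' net
#' @export
build_network <- function(table, merge_dual_roles = TRUE) {
  if (!inherits(table, "dtn_interactions")) table <- interaction_table(table)
  dk <- canonical_key(table$drug_name)
  tk <- canonical_key(table$target_name)
  if (!merge_dual_roles) {
    dk <- paste0("drug:", canonical_key(table$drug_id))
    tk <- paste0("target:", canonical_key(table$target_id))
  }
  ids <- sort(unique(c(dk, tk)), method = "radix")
  from <- match(dk, ids)
  to <- match(tk, ids)
  # first-seen display name per node
  name_of <- setNames(rep(NA_character_, length(ids)), ids)
  nm <- c(table$drug_name, table$target_name)
  ky <- c(dk, tk)
  first <- !duplicated(ky)
  name_of[ky[first]] <- nm[first]
  ekey <- paste(from, to)
  keep <- !duplicated(ekey)
  from <- from[keep]
  to <- to[keep]
  nodes <- tibble(
    id = ids,
    name = unname(name_of),
    is_drug = seq_along(ids) %in% from,
    is_target = seq_along(ids) %in% to
  )
  nodes$role <- dplyr::case_when(
    nodes$is_drug & nodes$is_target ~ "both",
    nodes$is_drug ~ "drug",
    TRUE ~ "target"
  )
  new_dtn_network(nodes, from, to)
}

new_dtn_network <- function(nodes, from, to) {
  n <- nrow(nodes)
  out_adj <- unname(split(to, factor(from, levels = seq_len(n))))
  in_adj <- unname(split(from, factor(to, levels = seq_len(n))))
  structure(
    list(
      nodes = nodes,
      edges = tibble(from = as.integer(from), to = as.integer(to)),
      out_adj = lapply(out_adj, as.integer),
      in_adj = lapply(in_adj, as.integer)
    ),
    class = "dtn_network"
  )
}

#' @export
print.dtn_network <- function(x, ...) {
  cat(sprintf(
    paste0("# Drug-target network: %d nodes (%d drug, %d target, ",
           "%d dual-role), %d directed edges\n"),
    nrow(x$nodes), sum(x$nodes$role == "drug"),
    sum(x$nodes$role == "target"), sum(x$nodes$role == "both"),
    nrow(x$edges)
  ))
  invisible(x)
}

n_nodes <- function(net) nrow(net$nodes)
n_edges <- function(net) nrow(net$edges)

# Undirected adjacency list (successors and predecessors merged, dedup).
undirected_adj <- function(net) {
  map2(net$out_adj, net$in_adj, function(a, b) unique(c(a, b)))
}

#' Tidy a drug-target network into node or edge tibbles
#'
#' @param x A `dtn_network`.
#' @param what `"nodes"` for one row per node (id, display name, role),
#'   `"edges"` for one row per directed edge with endpoint ids.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dtn_network
#' @export
tidy.dtn_network <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  if (what == "nodes") return(x$nodes)
  tibble(
    drug = x$nodes$id[x$edges$from],
    target = x$nodes$id[x$edges$to]
  )
}

#' One-row summary of a drug-target network
#'
#' @param x A `dtn_network`.
#' @param ... Unused.
#' @return A one-row tibble with node/edge counts, role tallies, the number
#'   of weak components and the giant-component share of nodes.
#' @method glance dtn_network
#' @export
glance.dtn_network <- function(x, ...) {
  comp <- weak_components(x)
  tibble(
    n_nodes = n_nodes(x),
    n_edges = n_edges(x),
    n_drugs = sum(x$nodes$is_drug),
    n_targets = sum(x$nodes$is_target),
    n_dual_role = sum(x$nodes$role == "both"),
    n_components = length(comp$sizes),
    giant_frac = comp$sizes[comp$giant_index] / n_nodes(x),
    mean_degree = mean_degree(x)
  )
}

#' Test bipartiteness of a drug-target network
#'
#' Two checks are reported. The role-based check asks whether any node is
#' simultaneously a drug and a target — the operative criterion for
#' drug-target landscapes, where dual-role compounds destroy the two-set
#' partition. The graph-theoretic check attempts a 2-coloring of the
#' undirected view via BFS and, when it fails, returns an odd closed walk
#' (derived from a conflicting edge within one BFS tree) as a witness.
#'
#' @param net A `dtn_network`.
#' @return A list of class `dtn_bipartite_report`: `role_disjoint`,
#'   `dual_role_nodes` (sorted ids), `two_colorable`, `witness_odd_cycle`
#'   (node ids, `NULL` when 2-colorable).
#' @export
check_bipartite <- function(net) {
  dual <- sort(net$nodes$id[net$nodes$role == "both"], method = "radix")
  n <- n_nodes(net)
  adj <- undirected_adj(net)
  color <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  witness <- NULL
  for (s in seq_len(n)) {
    if (!is.na(color[s])) next
    color[s] <- 0L
    frontier <- s
    while (length(frontier) > 0 && is.null(witness)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (u == v) { # self-loop: odd cycle of length 1
            witness <- c(net$nodes$id[v], net$nodes$id[v])
            break
          }
          if (is.na(color[u])) {
            color[u] <- 1L - color[v]
            parent[u] <- v
            nxt <- c(nxt, u)
          } else if (color[u] == color[v]) {
            witness <- odd_cycle_witness(v, u, parent, net$nodes$id)
            break
          }
        }
        if (!is.null(witness)) break
      }
      frontier <- nxt
    }
    if (!is.null(witness)) break
  }
  structure(
    list(
      role_disjoint = length(dual) == 0,
      dual_role_nodes = dual,
      two_colorable = is.null(witness),
      witness_odd_cycle = witness
    ),
    class = "dtn_bipartite_report"
  )
}

# Close the cycle through the BFS-tree paths of the conflicting edge (v,u).
odd_cycle_witness <- function(v, u, parent, ids) {
  path_to_root <- function(x) {
    p <- x
    while (!is.na(parent[x])) {
      x <- parent[x]
      p <- c(p, x)
    }
    p
  }
  pv <- path_to_root(v)
  pu <- path_to_root(u)
  common <- intersect(pv, pu)[1] # lowest common ancestor on BFS paths
  cyc <- c(rev(pv[seq_len(match(common, pv))]),
           pu[seq_len(match(common, pu) - 1)])
  ids[c(cyc, cyc[1])]
}

#' @export
print.dtn_bipartite_report <- function(x, ...) {
  cat(sprintf("# Bipartiteness: role_disjoint=%s two_colorable=%s\n",
              x$role_disjoint, x$two_colorable))
  if (length(x$dual_role_nodes) > 0) {
    cat(sprintf("# %d dual-role node(s): %s\n", length(x$dual_role_nodes),
                paste(head(x$dual_role_nodes, 15), collapse = ", ")))
  }
  invisible(x)
}

#' Weakly connected components
#'
#' Components of the undirected view, found by breadth-first search.
#' Component indices are deterministic: components are numbered by
#' decreasing size with ties broken by their smallest (C-locale) member id,
#' so repeated runs and platforms agree.
#'
#' @param net A `dtn_network`.
#' @return A list of class `dtn_components`: `membership` (tibble `id`,
#'   `role`, `component`), `component_of` (integer vector per node),
#'   `sizes` (descending), `giant_index` (index into `sizes`, always the
#'   largest), and `size_histogram` (tibble `size`, `n_components`).
#' @export
weak_components <- function(net) {
  n <- n_nodes(net)
  adj <- undirected_adj(net)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    comp[s] <- k
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.na(comp[nxt])]
      comp[nxt] <- k
      frontier <- nxt
    }
  }
  raw_sizes <- tabulate(comp, nbins = k)
  min_id <- vapply(split(net$nodes$id, comp), min, character(1))
  ord <- canonical_order(-raw_sizes, min_id)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  comp <- relabel[comp]
  sizes <- raw_sizes[ord]
  hist <- count(tibble(size = sizes), .data$size, name = "n_components")
  structure(
    list(
      membership = tibble(id = net$nodes$id, role = net$nodes$role,
                          component = comp),
      component_of = comp,
      sizes = sizes,
      giant_index = 1L,
      size_histogram = hist
    ),
    class = "dtn_components"
  )
}

#' @export
print.dtn_components <- function(x, ...) {
  cat(sprintf("# %d weakly connected components; giant component: %d nodes (%.1f%%)\n",
              length(x$sizes), x$sizes[x$giant_index],
              100 * x$sizes[x$giant_index] / sum(x$sizes)))
  invisible(x)
}

#' Tidy component membership
#' @param x A `dtn_components` object.
#' @param ... Unused.
#' @return Tibble with `id`, `role`, `component`.
#' @method tidy dtn_components
#' @export
tidy.dtn_components <- function(x, ...) x$membership

#' Extract one weakly connected component as a network
#'
#' @param net A `dtn_network`.
#' @param decomposition Result of [weak_components()] for `net`; computed
#'   when missing.
#' @param index Component index (1 = giant component).
#' @return The induced `dtn_network` on that component, roles preserved.
#' @export
extract_component <- function(net, index = 1L, decomposition = NULL) {
  decomposition <- decomposition %||% weak_components(net)
  if (index < 1 || index > length(decomposition$sizes)) {
    abort(sprintf("component index %d out of range (1..%d)",
                  index, length(decomposition$sizes)))
  }
  keep <- which(decomposition$component_of == index)
  induced_subnetwork(net, keep)
}

induced_subnetwork <- function(net, keep) {
  remap <- rep(NA_integer_, n_nodes(net))
  remap[keep] <- seq_along(keep)
  e <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ]
  new_dtn_network(net$nodes[keep, ], remap[e$from], remap[e$to])
}
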