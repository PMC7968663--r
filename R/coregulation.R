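#' Drug-drug coregulation projection
#'
#' Two drugs are coregulated when they share at least one target, i.e. both
#' are in-neighbours of a common node. The projection is the weighted
#' undirected graph on drug-role nodes where the edge weight counts the
#' distinct shared targets: for every target, all unordered pairs of its
#' in-neighbour drugs gain one unit of weight. No self-edges.
#'
#' @param net A `dtn_network`.
#' @return A list of class `dtn_coregulation`: `edges` (tibble `drug_a`,
#'   `drug_b`, `shared_targets`, with `drug_a < drug_b` in C-locale order),
#'   and `partner_count` (tibble `id`, `n_partners` over all drug-role
#'   nodes, including zeros).
#' @export
drug_projection <- function(net) {
  drugs <- net$nodes$id
  acc_a <- vector("list", n_nodes(net))
  acc_b <- vector("list", n_nodes(net))
  for (t in seq_len(n_nodes(net))) {
    ins <- net$in_adj[[t]]
    ins <- ins[ins != t]
    if (length(ins) < 2) next
    cmb <- combn_pairs(sort(ins))
    acc_a[[t]] <- cmb$a
    acc_b[[t]] <- cmb$b
  }
  pair_from <- unlist(acc_a, use.names = FALSE)
  pair_to <- unlist(acc_b, use.names = FALSE)
  if (is.null(pair_from)) pair_from <- pair_to <- integer(0)
  if (length(pair_from) == 0) {
    edges <- tibble(drug_a = character(), drug_b = character(),
                    shared_targets = integer())
  } else {
    n <- n_nodes(net)
    key <- (pair_from - 1) * n + pair_to # unique per ordered (a < b) pair
    cnt <- rowsum(rep(1L, length(key)), key)
    kk <- as.numeric(rownames(cnt))
    a <- as.integer((kk - 1) %/% n + 1)
    b <- as.integer(kk - (a - 1) * n)
    edges <- tibble(drug_a = drugs[a], drug_b = drugs[b],
                    shared_targets = as.integer(cnt[, 1]))
    ord <- canonical_order(edges$drug_a, edges$drug_b)
    edges <- edges[ord, ]
  }
  drug_ids <- net$nodes$id[net$nodes$is_drug]
  pc <- table(factor(c(edges$drug_a, edges$drug_b), levels = sort(drug_ids, method = "radix")))
  structure(
    list(
      edges = edges,
      partner_count = tibble(id = names(pc), n_partners = as.integer(pc))
    ),
    class = "dtn_coregulation"
  )
}

combn_pairs <- function(x) {
  n <- length(x)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) seq(k + 1, n)))
  list(a = x[i], b = x[j])
}

#' @export
print.dtn_coregulation <- function(x, ...) {
  cat(sprintf(
    "# Coregulation projection: %d drug pairs over %d drugs\n",
    nrow(x$edges), nrow(x$partner_count)
  ))
  invisible(x)
}

#' Tidy the coregulation projection into its weighted edge list
#' @param x A `dtn_coregulation`.
#' @param ... Unused.
#' @return Tibble `drug_a`, `drug_b`, `shared_targets`.
#' @method tidy dtn_coregulation
#' @export
tidy.dtn_coregulation <- function(x, ...) x$edges

#' Rank drugs by number of coregulation partners
#'
#' @param projection A `dtn_coregulation` from [drug_projection()].
#' @param k Number of drugs to keep.
#' @return A tibble `rank`, `id`, `n_partners`, descending with
#'   lexicographic tie-break.
#' @export
top_coregulated <- function(projection, k = 10L) {
  stopifnot(k >= 1)
  pc <- projection$partner_count
  pc <- pc[canonical_order(-pc$n_partners, pc$id), ]
  k <- min(k, nrow(pc))
  tibble(rank = seq_len(k), id = pc$id[seq_len(k)],
         n_partners = pc$n_partners[seq_len(k)])
}

#' Check target coverage of a drug subset
#'
#' A drug subset covers the network when every target (node with at least
#' one drug in-neighbour) keeps at least one in-neighbour inside the
#' subset. This is the verifier for [dominating_set_reduction()].
#'
#' @param net A `dtn_network`.
#' @param drug_subset Character vector of node ids acting as the retained
#'   drug set.
#' @return A list: `covered` (logical) and `uncovered_targets` (ids).
#' @export
coverage <- function(net, drug_subset) {
  sub_idx <- match(drug_subset, net$nodes$id)
  if (anyNA(sub_idx)) {
    abort(sprintf("unknown node ids in drug_subset: %s",
                  paste(head(drug_subset[is.na(sub_idx)], 5), collapse = ", ")))
  }
  in_sub <- logical(n_nodes(net))
  in_sub[sub_idx] <- TRUE
  targets <- which(lengths(net$in_adj) > 0)
  ok <- vapply(targets, function(t) any(in_sub[net$in_adj[[t]]]), logical(1))
  list(covered = all(ok),
       uncovered_targets = net$nodes$id[targets[!ok]])
}

#' Randomized minimal covering-drug-set reduction
#'
#' Starting from all drug-role nodes of a weakly connected component, the
#' procedure repeatedly draws one retained drug uniformly at random; if the
#' component's targets all keep at least one in-neighbour after its
#' removal, the drug is discarded, otherwise it is kept (the failed draw
#' still consumes an iteration). After the given number of random draws an
#' optional deterministic sweep attempts removal of every retained drug
#' once, in seeded random order, which makes the result provably minimal:
#' removing any single retained drug would leave some target uncovered.
#'
#' @param net A `dtn_network`; should be a single weakly connected
#'   component (apply [extract_component()] first), and every target must
#'   have at least one drug in-neighbour.
#' @param iterations Number of random exclusion draws.
#' @param seed Integer seed; the same seed reproduces the same retained
#'   set.
#' @param minimality_sweep Run the final deterministic sweep (default
#'   `TRUE`). Disable for a strict replication of the purely random
#'   procedure.
#' @return A list of class `dtn_dominating_set`: `retained`, `removed`
#'   (character ids), `iterations`, `seed`, `coverage_check` (logical),
#'   `minimal` (logical, `NA` when the sweep was skipped).
#' @export
dominating_set_reduction <- function(net, iterations = 100000L, seed = 1L,
                                     minimality_sweep = TRUE) {
  comp <- weak_components(net)
  if (length(comp$sizes) > 1) {
    warn("network has several weak components; the reduction treats them jointly")
  }
  drugs <- which(net$nodes$is_drug)
  targets <- which(lengths(net$in_adj) > 0)
  if (length(targets) == 0) abort("network has no targets to cover")
  with_seed(seed, {
    # cover_count[t] = number of retained drugs pointing at t
    cover <- lengths(net$in_adj)
    retained <- rep(FALSE, n_nodes(net))
    retained[drugs] <- TRUE
    ret_idx <- drugs # retained drug indices; swap-removed for O(1) draws
    n_ret <- length(drugs)
    for (i in seq_len(iterations)) {
      j <- sample.int(n_ret, 1L)
      d <- ret_idx[j]
      tg <- net$out_adj[[d]]
      if (length(tg) == 0 || all(cover[tg] >= 2L)) {
        retained[d] <- FALSE
        cover[tg] <- cover[tg] - 1L
        ret_idx[j] <- ret_idx[n_ret]
        n_ret <- n_ret - 1L
        if (n_ret == 0L) break
      }
    }
    minimal <- NA
    if (minimality_sweep) {
      for (d in sample(which(retained))) {
        tg <- net$out_adj[[d]]
        if (length(tg) == 0 || all(cover[tg] >= 2L)) {
          retained[d] <- FALSE
          cover[tg] <- cover[tg] - 1L
        }
      }
      minimal <- TRUE
    }
    ret_ids <- sort(net$nodes$id[retained], method = "radix")
    rem_ids <- sort(net$nodes$id[setdiff(drugs, which(retained))],
                    method = "radix")
    cov <- coverage(net, ret_ids)
    structure(
      list(
        retained = ret_ids,
        removed = rem_ids,
        iterations = as.integer(iterations),
        seed = as.integer(seed),
        coverage_check = cov$covered,
        minimal = minimal
      ),
      class = "dtn_dominating_set"
    )
  })
}

#' @export
print.dtn_dominating_set <- function(x, ...) {
  cat(sprintf(
    paste0("# Covering drug set: %d retained / %d total drugs ",
           "(%d iterations, seed %d); coverage %s, minimal %s\n"),
    length(x$retained), length(x$retained) + length(x$removed),
    x$iterations, x$seed, x$coverage_check, x$minimal
  ))
  invisible(x)
}

#' One-row summary of a covering-set reduction
#' @param x A `dtn_dominating_set`.
#' @param ... Unused.
#' @return Tibble with retained/removed counts and the checks.
#' @method glance dtn_dominating_set
#' @export
glance.dtn_dominating_set <- function(x, ...) {
  tibble(
    n_retained = length(x$retained),
    n_removed = length(x$removed),
    iterations = x$iterations,
    seed = x$seed,
    coverage_check = x$coverage_check,
    minimal = x$minimal
  )
}
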