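#' Node degrees of the directed network
#'
#' In a drug-target network the in-degree of a target counts the drugs that
#' affect it and the out-degree of a drug counts the targets it affects;
#' `k_total` is their sum, the degree of the undirected multiview.
#'
#' @param net A `dtn_network`.
#' @return A tibble with `id`, `role`, `k_in`, `k_out`, `k_total`.
#' @export
node_degrees <- function(net) {
  tibble(
    id = net$nodes$id,
    role = net$nodes$role,
    k_in = lengths(net$in_adj),
    k_out = lengths(net$out_adj),
    k_total = lengths(net$in_adj) + lengths(net$out_adj)
  )
}

#' Mean number of neighbors per node
#'
#' Undirected-neighbor convention: `2|E| / |V|`, counting each directed
#' edge as one adjacency for both endpoints.
#'
#' @param net A `dtn_network`.
#' @return A single numeric value.
#' @export
mean_degree <- function(net) {
  if (n_nodes(net) == 0) abort("mean degree of an empty network is undefined")
  2 * n_edges(net) / n_nodes(net)
}

#' Empirical degree distribution
#'
#' `P(k)` is the fraction of degree-`k` nodes among the nodes with degree
#' at least 1; zero-degree nodes are excluded (their logarithm is undefined
#' for the power-law fit) and their count is recorded in the `n_zero`
#' attribute. Optionally the distribution can be restricted to one role's
#' nodes (drugs for out-degrees, targets for in-degrees).
#'
#' @param deg A degree tibble from [node_degrees()] (or any tibble with the
#'   same columns).
#' @param which Which degree: `"in"`, `"out"` or `"total"`.
#' @param role_restrict `NULL` (all nodes, the default normalization) or a
#'   role filter: nodes with `is_drug` semantics (`"drug"`) or
#'   `is_target` semantics (`"target"`); dual-role nodes count for both.
#' @return A tibble of class `dtn_degree_distribution` with sorted distinct
#'   `k`, `p`, and attributes `which`, `n_zero`, `n_nodes_used`.
#' @export
degree_distribution <- function(deg, which = c("total", "in", "out"),
                                role_restrict = NULL) {
  which <- match.arg(which)
  k <- switch(which, "in" = deg$k_in, "out" = deg$k_out, total = deg$k_total)
  if (!is.null(role_restrict)) {
    role_restrict <- match.arg(role_restrict, c("drug", "target"))
    keep <- if (role_restrict == "drug") deg$role %in% c("drug", "both")
            else deg$role %in% c("target", "both")
    k <- k[keep]
  }
  n_zero <- sum(k == 0)
  k <- k[k > 0]
  if (length(k) == 0) abort("all degrees are zero; distribution undefined")
  tab <- table(k)
  new_degree_distribution(
    k = as.integer(names(tab)),
    p = as.numeric(tab) / length(k),
    which = which, n_zero = n_zero, n_nodes_used = length(k)
  )
}

#' Assemble a degree distribution from support and probabilities
#'
#' Mostly useful for fitting a known analytic law; [degree_distribution()]
#' is the empirical constructor.
#'
#' @param k Sorted distinct positive degrees.
#' @param p Probability mass at each `k`; must sum to 1.
#' @param which Label: `"in"`, `"out"` or `"total"`.
#' @return A `dtn_degree_distribution` tibble.
#' @export
new_degree_distribution <- function(k, p, which = "total", n_zero = 0L,
                                    n_nodes_used = NA_integer_) {
  stopifnot(length(k) == length(p), all(k >= 1), all(p > 0), all(p <= 1),
            !is.unsorted(k), abs(sum(p) - 1) < 1e-8)
  structure(
    tibble(k = as.integer(k), p = as.numeric(p)),
    class = c("dtn_degree_distribution", class(tibble())),
    which = which, n_zero = n_zero, n_nodes_used = n_nodes_used
  )
}

#' Fit a power law P(k) = A k^-gamma to a degree distribution
#'
#' Two estimators are available. `"loglog_ls"` (default) is ordinary least
#' squares of `log P(k)` on `log k` over the support at or above `k_min`,
#' the classical straight-line fit on the log-log degree plot;
#' `gamma` is the negative slope and `A` is chosen so the fitted line
#' passes through the regression value at `k_min`. `"mle"` is the discrete
#' power-law maximum likelihood estimator (Clauset-style), which maximizes
#' `-gamma * sum(log k) - n * log zeta(gamma, k_min)` using a Hurwitz-zeta
#' normalization; it needs the raw degree sample, so it is only available
#' when `samples` is supplied (or when the distribution carries its sample
#' via [degree_distribution()] counts and `n_nodes_used`).
#'
#' @param dist A `dtn_degree_distribution`.
#' @param method `"loglog_ls"` or `"mle"`.
#' @param k_min Smallest degree used in the fit (>= 1).
#' @param samples Optional integer vector of raw degrees for `"mle"`; when
#'   missing, the sample is reconstituted from the distribution's
#'   probabilities and `n_nodes_used`.
#' @return An object of class `dtn_powerlaw_fit` with fields `gamma`, `A`,
#'   `method`, `k_min`, `r_squared` (`loglog_ls` only, else `NA`),
#'   `n_support`.
#' @export
fit_power_law <- function(dist, method = c("loglog_ls", "mle"), k_min = 1L,
                          samples = NULL) {
  method <- match.arg(method)
  stopifnot(k_min >= 1)
  sup <- dist[dist$k >= k_min, ]
  if (nrow(sup) < 3) {
    abort("need at least 3 distinct degrees >= k_min to fit a power law")
  }
  if (method == "loglog_ls") {
    fit <- lm(log(p) ~ log(k), data = sup)
    gamma <- -unname(coef(fit)[2])
    # A such that A * k_min^-gamma equals the fitted value at k_min
    a_log <- unname(coef(fit)[1])
    A <- exp(a_log)
    # exact laws trigger the perfect-fit warning; R^2 = 1 is the answer
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    if (is.null(samples)) {
      n_used <- attr(dist, "n_nodes_used")
      if (is.na(n_used)) {
        abort("mle needs raw degree `samples` (or an empirical distribution)")
      }
      samples <- rep(dist$k, round(dist$p * n_used))
    }
    samples <- samples[samples >= k_min]
    s_log <- mean(log(samples))
    nll <- function(g) g * s_log + log(hurwitz_zeta(g, k_min))
    opt <- optimize(nll, c(1 + 1e-6, 20))
    gamma <- opt$minimum
    A <- 1 / hurwitz_zeta(gamma, k_min)
    r2 <- NA_real_
  }
  structure(
    list(gamma = gamma, A = A, method = method, k_min = as.integer(k_min),
         r_squared = r2, n_support = nrow(sup),
         which = attr(dist, "which") %||% "total"),
    class = "dtn_powerlaw_fit"
  )
}

# Hurwitz zeta for s > 1: finite sum plus Euler-Maclaurin tail correction.
hurwitz_zeta <- function(s, a, n_terms = 2000L) {
  k <- seq(0, n_terms - 1)
  b <- a + n_terms
  sum((a + k)^(-s)) + b^(1 - s) / (s - 1) + 0.5 * b^(-s) +
    s * b^(-s - 1) / 12 - s * (s + 1) * (s + 2) * b^(-s - 3) / 720
}

#' @export
print.dtn_powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "# Power-law fit (%s degrees, %s): gamma=%.4f A=%.4g k_min=%d%s\n",
    x$which, x$method, x$gamma, x$A, x$k_min,
    if (is.na(x$r_squared)) "" else sprintf(" R2=%.4f", x$r_squared)
  ))
  invisible(x)
}

#' @method tidy dtn_powerlaw_fit
#' @export
tidy.dtn_powerlaw_fit <- function(x, ...) {
  tibble(
    term = c("gamma", "A"),
    estimate = c(x$gamma, x$A)
  )
}

#' @method glance dtn_powerlaw_fit
#' @export
glance.dtn_powerlaw_fit <- function(x, ...) {
  tibble(gamma = x$gamma, A = x$A, method = x$method, k_min = x$k_min,
         r_squared = x$r_squared, n_support = x$n_support, which = x$which)
}

#' Clustering-coefficient profile
#'
#' For each node of the undirected view, `C_i = 2 E_i / (k_i (k_i - 1))`,
#' where `E_i` is the number of edges among the `k_i` distinct neighbors of
#' node `i` (self-loops ignored); `C_i = 0` when `k_i < 2`. A strictly
#' bipartite drug-target graph has no triangles, so every `C_i` is zero —
#' non-zero clustering only enters through dual-role merges.
#'
#' @param net A `dtn_network`.
#' @return A list of class `dtn_clustering`: `per_node` tibble (`id`,
#'   `role`, `k`, `e_among_neighbors`, `c`), `mean_c`, and `c_of_k` (mean
#'   `C` over nodes of each exact total degree `k`).
#' @export
clustering_profile <- function(net) {
  n <- n_nodes(net)
  adj <- lapply(seq_len(n), function(v) {
    a <- undirected_adj_one(net, v)
    a[a != v]
  })
  deg <- lengths(adj)
  e_i <- integer(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) < 2) next
    # count edges among neighbors once per unordered pair
    cnt <- 0L
    nbset <- nb
    for (u in nb) {
      cnt <- cnt + sum(adj[[u]] %in% nbset & adj[[u]] > u)
    }
    e_i[v] <- cnt
  }
  c_i <- ifelse(deg < 2, 0, 2 * e_i / (deg * (deg - 1)))
  per_node <- tibble(id = net$nodes$id, role = net$nodes$role, k = deg,
                     e_among_neighbors = e_i, c = c_i)
  c_of_k <- per_node |>
    filter(.data$k > 0) |>
    group_by(.data$k) |>
    summarise(mean_c = mean(.data$c), n_nodes = n(), .groups = "drop")
  structure(
    list(per_node = per_node, mean_c = mean(c_i), c_of_k = c_of_k),
    class = "dtn_clustering"
  )
}

undirected_adj_one <- function(net, v) {
  unique(c(net$out_adj[[v]], net$in_adj[[v]]))
}

#' @export
print.dtn_clustering <- function(x, ...) {
  cat(sprintf("# Clustering profile: mean C = %.4f over %d nodes\n",
              x$mean_c, nrow(x$per_node)))
  invisible(x)
}

#' @method tidy dtn_clustering
#' @export
tidy.dtn_clustering <- function(x, ...) x$per_node
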