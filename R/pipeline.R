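#' Configuration for a full landscape run
#'
#' Exactly one input source must be given: a DrugBank-style XML path, a
#' native TSV edge table path, or synthetic-generator parameters. Every
#' stochastic stage (generator, community detection, covering-set
#' reduction) takes its seed from here, so a configuration determines the
#' whole report.
#'
#' @param xml,edge_table,synthetic Input source: path to a DrugBank-style
#'   XML, path to a native edge TSV, or a [synthetic_params()] list.
#' @param out_dir Output directory for per-stage TSV/JSON artifacts;
#'   `NULL` skips persistence.
#' @param filter [filter_spec()] applied when reading XML.
#' @param merge_dual_roles Merge same-named drugs and targets into
#'   dual-role nodes.
#' @param seed_louvain,seed_reduction Seeds for the stochastic stages.
#' @param resolution Louvain resolution.
#' @param reduction_iterations Random-exclusion draws of the covering-set
#'   reduction.
#' @param minimality_sweep Run the deterministic minimality sweep after
#'   the random draws.
#' @param closeness_sense,betweenness_sense Direction conventions for the
#'   path-based centralities.
#' @param fit_method Power-law fitting method for the degree
#'   distributions.
#' @param top_k Length of the per-metric rankings kept in the report.
#' @param annotations Optional `dtn_annotation` for an enrichment stage on
#'   the giant component's targets.
#' @param run_betweenness,run_distances Stage toggles: exact betweenness
#'   and the dense distance matrix are the two expensive stages on large
#'   networks.
#' @return A list of class `dtn_config`.
#' @export
landscape_config <- function(xml = NULL, edge_table = NULL, synthetic = NULL,
                             out_dir = NULL,
                             filter = filter_spec(),
                             merge_dual_roles = TRUE,
                             seed_louvain = 1L, seed_reduction = 1L,
                             resolution = 1,
                             reduction_iterations = 100000L,
                             minimality_sweep = TRUE,
                             closeness_sense = "directed_in",
                             betweenness_sense = "directed_out",
                             fit_method = "loglog_ls",
                             top_k = 10L,
                             annotations = NULL,
                             run_betweenness = TRUE,
                             run_distances = FALSE) {
  sources <- !c(is.null(xml), is.null(edge_table), is.null(synthetic))
  if (sum(sources) != 1) {
    abort("exactly one of `xml`, `edge_table`, `synthetic` must be given")
  }
  structure(
    list(xml = xml, edge_table = edge_table, synthetic = synthetic,
         out_dir = out_dir, filter = filter,
         merge_dual_roles = merge_dual_roles,
         seed_louvain = as.integer(seed_louvain),
         seed_reduction = as.integer(seed_reduction),
         resolution = resolution,
         reduction_iterations = as.integer(reduction_iterations),
         minimality_sweep = minimality_sweep,
         closeness_sense = closeness_sense,
         betweenness_sense = betweenness_sense,
         fit_method = fit_method, top_k = as.integer(top_k),
         annotations = annotations,
         run_betweenness = run_betweenness,
         run_distances = run_distances),
    class = "dtn_config"
  )
}

#' Run the full drug-target landscape analysis
#'
#' Executes the stages in order: ingestion, network construction,
#' bipartiteness and components, degree/power-law/clustering topology,
#' centralities with top-k rankings, multilevel communities, coregulation
#' projection, covering-set reduction on the giant component, and (when
#' annotations are supplied) enrichment of the giant component's targets.
#' When `config$out_dir` is set, each stage's table is persisted as TSV
#' and a `manifest.json` summarises the run; every number in the returned
#' report is recomputable from those artifacts.
#'
#' @param config A [landscape_config()].
#' @return A list of class `dtn_report`; see the elements' own classes for
#'   details.
#' @export
run_landscape <- function(config) {
  stopifnot(inherits(config, "dtn_config"))
  table <- if (!is.null(config$xml)) {
    parse_drugbank_xml(config$xml, config$filter)
  } else if (!is.null(config$edge_table)) {
    read_edge_table(config$edge_table)
  } else {
    generate_interactions(config$synthetic)
  }
  net <- build_network(table, merge_dual_roles = config$merge_dual_roles)
  bip <- check_bipartite(net)
  comp <- weak_components(net)
  giant <- extract_component(net, 1L, comp)

  deg <- node_degrees(net)
  dist_in <- degree_distribution(deg, "in", role_restrict = "target")
  dist_out <- degree_distribution(deg, "out", role_restrict = "drug")
  fit_in <- fit_power_law(dist_in, method = config$fit_method)
  fit_out <- fit_power_law(dist_out, method = config$fit_method)
  clust <- clustering_profile(net)

  cent <- list(
    degree_in = degree_centrality(net, "in"),
    degree_out = degree_centrality(net, "out"),
    closeness = closeness_centrality(net, config$closeness_sense)
  )
  if (config$run_betweenness) {
    cent$betweenness <- betweenness_centrality(net, config$betweenness_sense)
  }
  cent$eigenvector <- eigenvector_centrality(net, component = 1L)
  rankings <- lapply(cent, top_nodes, k = config$top_k)

  part <- cluster_multilevel(net, resolution = config$resolution,
                             seed = config$seed_louvain)
  sizes <- community_size_stats(part)

  proj <- drug_projection(net)
  reduction <- dominating_set_reduction(
    giant, iterations = config$reduction_iterations,
    seed = config$seed_reduction,
    minimality_sweep = config$minimality_sweep
  )

  enr <- NULL
  if (!is.null(config$annotations)) {
    giant_targets <- giant$nodes$id[giant$nodes$is_target]
    query <- intersect(giant_targets, config$annotations$background)
    if (length(query) > 0) enr <- enrich(query, config$annotations)
  }

  distances <- if (config$run_distances) all_pairs_distances(net) else NULL

  report <- structure(
    list(
      counts = glance.dtn_network(net),
      interactions = table,
      network = net,
      bipartiteness = bip,
      components = comp,
      degree_fits = list(k_in = fit_in, k_out = fit_out),
      clustering = clust,
      centralities = cent,
      rankings = rankings,
      partition = part,
      community_sizes = sizes,
      coregulation = proj,
      reduction = reduction,
      enrichment = enr,
      distances = distances,
      config = config
    ),
    class = "dtn_report"
  )
  if (!is.null(config$out_dir)) persist_report(report, config$out_dir)
  report
}

persist_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_tsv(as_tibble(df), file.path(out_dir, name))
  }
  write_edge_table(report$interactions, file.path(out_dir, "edges.tsv"))
  w(report$components$membership, "components.tsv")
  w(node_degrees(report$network), "degrees.tsv")
  for (m in names(report$centralities)) {
    w(report$centralities[[m]], paste0("centrality_", m, ".tsv"))
  }
  w(report$partition$assignment, "communities.tsv")
  w(report$coregulation$edges, "coregulation.tsv")
  if (!is.null(report$enrichment)) w(report$enrichment, "enrichment.tsv")
  manifest <- list(
    counts = as.list(report$counts),
    bipartite = list(
      role_disjoint = report$bipartiteness$role_disjoint,
      two_colorable = report$bipartiteness$two_colorable,
      dual_role_nodes = report$bipartiteness$dual_role_nodes
    ),
    component_sizes = report$components$sizes,
    degree_fits = lapply(report$degree_fits, function(f) {
      list(gamma = f$gamma, A = f$A, method = f$method, k_min = f$k_min,
           r_squared = f$r_squared)
    }),
    mean_clustering = report$clustering$mean_c,
    partition = list(Q = report$partition$Q,
                     n_communities = report$partition$n_communities,
                     resolution = report$partition$resolution,
                     seed = report$partition$seed),
    community_sizes = report$community_sizes[c("largest", "frac_over_100",
                                               "frac_size_2")],
    reduction = list(n_retained = length(report$reduction$retained),
                     iterations = report$reduction$iterations,
                     seed = report$reduction$seed,
                     coverage = report$reduction$coverage_check,
                     minimal = report$reduction$minimal),
    seeds = list(louvain = report$config$seed_louvain,
                 reduction = report$config$seed_reduction)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.dtn_report <- function(x, ...) {
  cat("# Drug-target landscape report\n")
  print(x$network)
  print(x$bipartiteness)
  print(x$components)
  cat(sprintf("# gamma_in = %.3f, gamma_out = %.3f (%s); mean C = %.4f\n",
              x$degree_fits$k_in$gamma, x$degree_fits$k_out$gamma,
              x$degree_fits$k_in$method, x$clustering$mean_c))
  print(x$partition)
  print(x$reduction)
  invisible(x)
}

#' One-row summary of a landscape report
#' @param x A `dtn_report`.
#' @param ... Unused.
#' @return A one-row tibble of the headline quantities.
#' @method glance dtn_report
#' @export
glance.dtn_report <- function(x, ...) {
  dplyr::bind_cols(
    x$counts,
    tibble(
      gamma_in = x$degree_fits$k_in$gamma,
      gamma_out = x$degree_fits$k_out$gamma,
      mean_clustering = x$clustering$mean_c,
      modularity = x$partition$Q,
      n_communities = x$partition$n_communities,
      n_retained_drugs = length(x$reduction$retained)
    )
  )
}
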