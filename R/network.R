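# Rule-based selection of treatment-responsive genes and extraction of
# their JAK/STAT-anchored interaction subnetwork from a user-supplied edge
# table (SIF/TSV). The package ships no interaction database; any curated
# edge table can be used.

jak_rule_anchors <- function() c("JAK1", "JAK2")

#' Default network anchor genes
#'
#' The JAK/STAT core always included in the network: STAT1, STAT2, JAK1,
#' JAK2, TYK2.
#'
#' @return Character vector.
#' @export
default_anchors <- function() c("STAT1", "STAT2", "JAK1", "JAK2", "TYK2")

#' Select genes for the interaction network
#'
#' Takes the per-gene PD effects for one arm/week (canonically the 4 mg
#' arm at week 12 versus placebo) and selects the union of: (1) the
#' `n_top` genes with the smallest q-values; (2) genes with an adjusted
#' `q < alpha` that share a transcription-regulation or phosphorylation
#' edge with JAK1 or JAK2 (either direction by default); (3) the anchors.
#' Provenance is recorded per gene.
#'
#' @param pd One arm/week slice of [pd_effects()] output.
#' @param edges Interaction tibble (source, target, mechanism, directed).
#' @param anchors Anchor genes (default [default_anchors()]).
#' @param n_top Size of the top-significance list (default 50).
#' @param alpha Adjusted-p threshold for rule (2) (default 0.05).
#' @param directed_rule If `TRUE`, rule (2) only qualifies edges whose
#'   source is JAK1/JAK2; default treats qualification as undirected.
#' @return Tibble gene, top_n, jak_interactor, anchor, provenance.
#' @export
select_network_genes <- function(pd, edges, anchors = default_anchors(),
                                 n_top = 50, alpha = 0.05,
                                 directed_rule = FALSE) {
  if (nrow(pd) == 0) stop_jak("pd effects table is empty")
  check_columns(pd, c("feature_id", "q"), "pd effects")
  if (dplyr::n_distinct(pd$arm) > 1 || dplyr::n_distinct(pd$week) > 1) {
    stop_jak("pd must be restricted to a single arm and week")
  }
  edges <- normalize_edges(edges)
  ranked <- dplyr::arrange(pd, .data$q, .data$p)
  top <- utils::head(ranked$feature_id[!is.na(ranked$q)], n_top)
  qual <- edges$mechanism %in% c("transcription_regulation", "phosphorylation")
  jak_partner <- unique(c(
    edges$target[qual & edges$source %in% jak_rule_anchors()],
    if (!directed_rule) edges$source[qual & edges$target %in% jak_rule_anchors()]
  ))
  sig <- pd$feature_id[!is.na(pd$q) & pd$q < alpha]
  interactors <- intersect(sig, jak_partner)
  genes <- unique(c(top, interactors, anchors))
  tibble::tibble(
    gene = genes,
    top_n = genes %in% top,
    jak_interactor = genes %in% interactors,
    anchor = genes %in% anchors
  ) |>
    dplyr::mutate(provenance = purrr::pmap_chr(
      list(.data$top_n, .data$jak_interactor, .data$anchor),
      function(t, j, a) paste(c(if (t) "top50", if (j) "jak_interactor",
                                if (a) "anchor"), collapse = ";")
    )) |>
    dplyr::arrange(.data$gene)
}

#' Build the anchor-connected interaction subnetwork
#'
#' Induces the subgraph of the edge table on the selected genes, then
#' removes every connected component (undirected sense) that contains no
#' anchor; nodes left without a path to an anchor are dropped. Node
#' categories (kinase / ligand_receptor / transcription_factor / other)
#' come from an optional annotation table.
#'
#' @param selected Selection tibble from [select_network_genes()] (or a
#'   character vector of genes).
#' @param edges Interaction tibble.
#' @param anchors Anchor genes.
#' @param annotations Optional tibble gene, category.
#' @return Object of class `gene_network` with `nodes`, `edges` and an
#'   igraph `graph`; `no_edges` flags an empty edge table.
#' @export
build_connected_subnetwork <- function(selected, edges,
                                       anchors = default_anchors(),
                                       annotations = NULL) {
  sel_tbl <- if (is.character(selected)) {
    tibble::tibble(gene = unique(selected),
                   provenance = ifelse(selected %in% anchors, "anchor", "selected"))
  } else selected
  check_columns(sel_tbl, c("gene", "provenance"), "selection")
  keep <- unique(c(sel_tbl$gene, anchors))
  edges <- normalize_edges(edges)
  no_edges <- nrow(edges) == 0
  if (!no_edges) {
    universe <- unique(c(edges$source, edges$target))
    if (!any(anchors %in% universe)) {
      stop_jak("no anchor gene present in the edge table")
    }
  }
  sub <- edges |>
    dplyr::filter(.data$source %in% keep, .data$target %in% keep) |>
    dplyr::arrange(.data$source, .data$target, .data$mechanism)
  g <- igraph::graph_from_data_frame(
    sub[c("source", "target", "mechanism", "directed")],
    directed = TRUE, vertices = sort(keep)
  )
  comp <- igraph::components(g, mode = "weak")
  anchor_comps <- unique(comp$membership[names(comp$membership) %in% anchors])
  retain <- names(comp$membership)[comp$membership %in% anchor_comps]
  # isolated non-anchor nodes sit in their own anchor-free component and
  # drop out here; isolated anchors stay
  drop_isolated <- setdiff(retain, c(unique(c(sub$source, sub$target)), anchors))
  retain <- setdiff(retain, drop_isolated)
  g <- igraph::induced_subgraph(g, retain)
  if (no_edges) {
    rlang::inform("edge table is empty: network reduced to anchors only")
    retain <- intersect(sort(keep), anchors)
    g <- igraph::graph_from_data_frame(sub[0, 1:2], directed = TRUE,
                                       vertices = retain)
  }
  nodes <- tibble::tibble(gene = sort(retain)) |>
    dplyr::left_join(sel_tbl[c("gene", "provenance")], by = "gene") |>
    dplyr::mutate(provenance = ifelse(
      is.na(.data$provenance) & .data$gene %in% anchors, "anchor",
      .data$provenance))
  cat_tbl <- if (is.null(annotations)) {
    tibble::tibble(gene = character(), category = character())
  } else {
    check_columns(annotations, c("gene", "category"), "annotations")
    annotations
  }
  nodes <- nodes |>
    dplyr::left_join(cat_tbl, by = "gene") |>
    dplyr::mutate(category = ifelse(
      is.na(.data$category) |
        !.data$category %in% c("kinase", "ligand_receptor",
                               "transcription_factor"),
      "other", .data$category))
  out_edges <- sub |>
    dplyr::filter(.data$source %in% nodes$gene, .data$target %in% nodes$gene)
  structure(list(nodes = nodes, edges = out_edges, graph = g,
                 anchors = anchors, no_edges = no_edges),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene network: %d node(s), %d edge(s)%s\n", nrow(x$nodes),
              nrow(x$edges), if (x$no_edges) " [no edges supplied]" else ""))
  invisible(x)
}

#' @method tidy gene_network
#' @export
tidy.gene_network <- function(x, ...) x$nodes

#' @method glance gene_network
#' @export
glance.gene_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_anchors_present = sum(x$nodes$gene %in% x$anchors),
                 no_edges = x$no_edges)
}

#' Export a gene network as GraphML plus node/edge TSVs
#'
#' @param network A `gene_network`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the three files.
#' @return Paths of the written files, invisibly.
#' @export
write_network <- function(network, dir, name = "network") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- network$graph
  idx <- match(igraph::V(g)$name, network$nodes$gene)
  igraph::V(g)$category <- network$nodes$category[idx]
  igraph::V(g)$provenance <- network$nodes$provenance[idx]
  paths <- file.path(dir, paste0(name, c(".graphml", "_nodes.tsv",
                                         "_edges.tsv")))
  igraph::write_graph(g, paths[1], format = "graphml")
  readr::write_tsv(network$nodes, paths[2], progress = FALSE)
  readr::write_tsv(network$edges, paths[3], progress = FALSE)
  invisible(paths)
}
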