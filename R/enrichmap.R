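#' @name enrichment-map
#' @title Hypergeometric over-representation and the enrichment map
#'
#' @description Annotation gene sets (e.g. GO Biological Process) within a
#' size band are tested for over-representation in a query gene list by the
#' hypergeometric tail, corrected by Benjamini-Hochberg FDR. Surviving sets
#' become nodes of an enrichment map; two nodes are linked when their
#' membership similarity — the average of the Jaccard coefficient
#' `|A∩B|/|A∪B|` and the overlap coefficient `|A∩B|/min(|A|,|B|)` — meets a
#' cutoff. The graph is emitted as an igraph object, exportable to GraphML
#' and a TSV edge list.
NULL

#' Membership similarity of two gene sets
#' @param a,b character vectors.
#' @return `(Jaccard + overlap) / 2`, in `[0, 1]`.
#' @examples
#' set_similarity(paste0("g", 1:4), paste0("g", 3:6))  # 0.41667
#' @export
set_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  i <- length(intersect(a, b))
  if (i == 0L) return(0)
  jac <- i / length(union(a, b))
  ovl <- i / min(length(a), length(b))
  (jac + ovl) / 2
}

#' Hypergeometric over-representation p-value
#'
#' Probability of observing at least `k` query genes in a set of size `K`
#' drawn against a universe of size `N` with query size `n`.
#'
#' @param k overlap count.
#' @param n query size.
#' @param K annotation-set size (within the universe).
#' @param N universe size.
#' @return upper-tail hypergeometric probability, inclusive of `k`.
#' @export
hypergeom_test <- function(k, n, K, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build a functional enrichment map
#'
#' @param query_genes character vector of genes of interest (must be a
#'   subset of `universe`).
#' @param annotation_sets named list of gene sets (e.g. from
#'   [read_gene_sets()]).
#' @param universe character vector of all testable genes.
#' @param fdr Benjamini-Hochberg FDR threshold for node inclusion
#'   (default 0.1).
#' @param size_band annotation sets annotating fewer than `size_band[1]` or
#'   more than `size_band[2]` universe genes are discarded before testing
#'   (default `c(25, 750)`).
#' @param sim_cutoff minimum similarity for an edge (default 0.375, the
#'   EnrichmentMap-style default for the combined coefficient).
#' @return object of class `enrichment_map`: list with `nodes` (data.frame
#'   `set, size, overlap, p, q`), `edges` (data.frame
#'   `from, to, similarity`), and `graph` (igraph, possibly with 0 nodes).
#' @export
build_enrichment_map <- function(query_genes, annotation_sets, universe,
                                 fdr = 0.1, size_band = c(25, 750),
                                 sim_cutoff = 0.375) {
  query_genes <- unique(query_genes)
  offenders <- setdiff(query_genes, universe)
  if (length(offenders))
    stopf("query genes outside the universe: %s",
          paste(head(offenders, 10L), collapse = ", "))
  sets <- lapply(annotation_sets, intersect, universe)
  sizes <- lengths(sets)
  keep <- sizes >= size_band[1] & sizes <= size_band[2]
  sets <- sets[keep]; sizes <- sizes[keep]
  if (length(sets) == 0L)
    return(empty_enrichment_map())
  ov <- vapply(sets, function(s) length(intersect(s, query_genes)),
               integer(1))
  p <- hypergeom_test(ov, length(query_genes), sizes, length(universe))
  q <- stats::p.adjust(p, method = "BH")
  nodes <- data.frame(set = names(sets), size = as.integer(sizes),
                      overlap = as.integer(ov), p = p, q = q,
                      stringsAsFactors = FALSE)
  nodes <- nodes[nodes$q < fdr & nodes$overlap > 0, , drop = FALSE]
  nodes <- nodes[order(nodes$set), , drop = FALSE]   # order-independent
  rownames(nodes) <- NULL
  edges <- data.frame(from = character(0), to = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(nodes) > 1L) {
    cmb <- utils::combn(nodes$set, 2L)
    sim <- apply(cmb, 2L, function(pr)
      set_similarity(sets[[pr[1]]], sets[[pr[2]]]))
    sel <- sim >= sim_cutoff
    edges <- data.frame(from = cmb[1, sel], to = cmb[2, sel],
                        similarity = sim[sel], stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "enrichment_map")
}

empty_enrichment_map <- function() {
  nodes <- data.frame(set = character(0), size = integer(0),
                      overlap = integer(0), p = numeric(0), q = numeric(0))
  edges <- data.frame(from = character(0), to = character(0),
                      similarity = numeric(0))
  structure(list(nodes = nodes, edges = edges,
                 graph = igraph::make_empty_graph(directed = FALSE)),
            class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat(sprintf("enrichment map: %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write an enrichment map to GraphML and a TSV edge list
#' @param em an [build_enrichment_map()] result.
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @return invisibly, `em`.
#' @export
write_enrichment_map <- function(em, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(em$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.table(em$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(em)
}

#' Select genes for the enrichment map the way the burden pipeline does
#'
#' Genes carrying damaging de novo variants, restricted to constrained genes
#' (pLI at or above a cutoff) plus an explicit allow-list of known disease
#' genes.
#'
#' @param variants variant data.frame.
#' @param pli named pLI vector.
#' @param rule a [variant_class_rule()].
#' @param pli_threshold constraint cutoff (default 0.5).
#' @param allow_list genes kept regardless of pLI.
#' @return character vector of selected genes.
#' @export
select_map_genes <- function(variants, pli, rule = variant_class_rule(),
                             pli_threshold = 0.5, allow_list = character(0)) {
  labels <- classify_variant(variants$consequence, variants$cadd_phred, rule)
  hit <- unique(variants$gene[labels %in% c("LGD", "D-mis")])
  constrained <- names(pli)[pli >= pli_threshold]
  intersect(hit, union(constrained, allow_list))
}
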