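# Unrooted minimum-spanning haplotype networks.

#' Build the minimum spanning network over a locus's haplotypes
#'
#' Pairwise Hamming distances (differing sites, one mutation per differing
#' site) among distinct haplotypes; edges are added in ascending weight
#' and, within each weight class, every edge joining two components (as
#' the components stood before that class) is kept - ties are not broken.
#' This is the epsilon = 0 minimum spanning network: the union of all
#' minimum spanning trees.
#'
#' @param haps a `haplotype_table` from [collapse_haplotypes()].
#' @return An object of class `haplo_network`: list with `graph` (an
#'   igraph object; node attributes `count` and one `n_<region>` per
#'   region, edge attribute `mutations`), `nodes`, `edges` data frames.
#' @export
#' @examples
#' p <- seq_panel(list(L = locus_spec("L", 3, 1, 1e-9, 1)),
#'                list(L = data.frame(individual = c("a", "b", "c"),
#'                                    population = "X", region = "NWP",
#'                                    allele = 1L,
#'                                    seq = c("AAA", "AAT", "ATT"))))
#' net <- build_msn(collapse_haplotypes(p, "L"))
build_msn <- function(haps) {
  stopifnot(inherits(haps, "haplotype_table"))
  hseq <- haps$haplotypes$seq
  H <- length(hseq)
  enc <- encode_alignment(hseq)
  dm <- pair_diff_matrix(enc$alleles)
  edges <- data.frame(from = integer(0), to = integer(0), mutations = integer(0))
  if (H > 1L) {
    cand <- which(upper.tri(dm), arr.ind = TRUE)
    w <- dm[upper.tri(dm)]
    parent <- seq_len(H)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    kept <- list()
    for (wt in sort(unique(w))) {
      in_class <- which(w == wt)
      comp_before <- vapply(seq_len(H), find, 0L)
      joins <- in_class[comp_before[cand[in_class, 1L]] !=
                          comp_before[cand[in_class, 2L]]]
      for (e in joins) {
        kept[[length(kept) + 1L]] <- c(cand[e, 1L], cand[e, 2L], wt)
        r1 <- find(cand[e, 1L]); r2 <- find(cand[e, 2L])
        if (r1 != r2) parent[r2] <- r1
      }
      if (length(unique(vapply(seq_len(H), find, 0L))) == 1L) break
    }
    m <- do.call(rbind, kept)
    if (!is.null(m))
      edges <- data.frame(from = m[, 1L], to = m[, 2L], mutations = m[, 3L])
  }
  nodes <- data.frame(name = haps$haplotypes$id, count = haps$haplotypes$count,
                      stringsAsFactors = FALSE)
  for (rg in colnames(haps$region_counts))
    nodes[[paste0("n_", rg)]] <- as.integer(haps$region_counts[, rg])
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes$name[edges$from], to = nodes$name[edges$to],
               mutations = edges$mutations),
    directed = FALSE, vertices = nodes)
  structure(list(graph = g, nodes = nodes,
                 edges = data.frame(from = nodes$name[edges$from],
                                    to = nodes$name[edges$to],
                                    mutations = edges$mutations,
                                    stringsAsFactors = FALSE),
                 locus = haps$locus),
            class = "haplo_network")
}

#' @exportS3Method base::print
print.haplo_network <- function(x, ...) {
  cat("<haplo_network>", x$locus, "-", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Export a haplotype network as GraphML plus a TSV edge list
#'
#' Node attributes carry total and per-region counts; the edge attribute
#' `mutations` is the Hamming distance. Node order is the deterministic
#' haplotype order of [collapse_haplotypes()].
#'
#' @param net a [build_msn()] result.
#' @param graphml_path output GraphML path.
#' @param edgelist_path optional TSV edge-list path.
#' @param dot_path optional Graphviz DOT path for quick rendering.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, graphml_path, edgelist_path = NULL,
                           dot_path = NULL) {
  igraph::write_graph(net$graph, graphml_path, format = "graphml")
  out <- graphml_path
  if (!is.null(edgelist_path)) {
    write_stats_table(net$edges, edgelist_path)
    out <- c(out, edgelist_path)
  }
  if (!is.null(dot_path)) {
    igraph::write_graph(net$graph, dot_path, format = "dot")
    out <- c(out, dot_path)
  }
  invisible(out)
}
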