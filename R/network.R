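## Correlation-based genus co-occurrence networks. With the field design's
## four replicates per treatment these are illustrative rather than
## inferential; thresholds and the correlation method are configurable.

#' Genus co-occurrence network
#'
#' Builds an undirected network over genera: an edge joins two genera when
#' the absolute correlation of their abundances across samples reaches
#' \code{rMin} and the correlation-test p-value is at most \code{pMax}.
#' Zero-variance genera are excluded. Modularity uses igraph's
#' deterministic greedy agglomeration (\code{cluster_fast_greedy}) on
#' absolute edge weights, so metrics are reproducible without seeds.
#'
#' @param object a \linkS4class{NemaExperiment} or genus-by-sample matrix;
#'   at least four samples.
#' @param rMin minimum absolute correlation for an edge.
#' @param pMax maximum correlation-test p-value for an edge.
#' @param method correlation method, \code{"spearman"} (default) or
#'   \code{"pearson"}.
#' @return list with \code{graph} (igraph object over connected genera),
#'   \code{edges} (data.frame \code{source}, \code{target}, \code{r},
#'   \code{p}, \code{sign}) and \code{metrics} (list: \code{nodes},
#'   \code{edges}, \code{average_degree} = 2E/V, \code{modularity},
#'   \code{positive_edges}, \code{negative_edges}).
#' @export
cooccurrenceNetwork <- function(object, rMin = 0.6, pMax = 0.05,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  a <- if (is(object, "NemaExperiment")) abundance(object) else
    as.matrix(object)
  if (ncol(a) < 4L)
    stop("at least four samples are required, got ", ncol(a))
  keep <- apply(a, 1L, stats::var) > 0
  a <- a[keep, , drop = FALSE]
  g <- nrow(a)
  edges <- list()
  if (g >= 2L) {
    for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
      ct <- suppressWarnings(
        stats::cor.test(a[i, ], a[j, ], method = method, exact = FALSE))
      r <- unname(ct$estimate)
      if (is.finite(r) && abs(r) >= rMin && ct$p.value <= pMax)
        edges[[length(edges) + 1L]] <-
          data.frame(source = rownames(a)[i], target = rownames(a)[j],
                     r = r, p = ct$p.value,
                     sign = if (r > 0) "positive" else "negative",
                     stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(), r = numeric(),
               p = numeric(), sign = character(), stringsAsFactors = FALSE)
  gr <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                      directed = FALSE)
  nV <- igraph::vcount(gr); nE <- nrow(edges)
  mod <- if (nE > 0L) {
    comm <- igraph::cluster_fast_greedy(gr, weights = abs(edges$r))
    igraph::modularity(comm)
  } else NA_real_
  list(graph = gr, edges = edges,
       metrics = list(nodes = nV, edges = nE,
                      average_degree = if (nV > 0L) 2 * nE / nV else 0,
                      modularity = mod,
                      positive_edges = sum(edges$sign == "positive"),
                      negative_edges = sum(edges$sign == "negative")))
}

#' Co-occurrence networks per treatment
#'
#' @param object a \linkS4class{NemaExperiment}.
#' @param ... passed to \code{\link{cooccurrenceNetwork}}.
#' @return named list of networks, one per treatment.
#' @export
networksByTreatment <- function(object, ...) {
  tr <- treatments(object)
  lev <- unique(tr)
  stats::setNames(lapply(lev, function(t)
    cooccurrenceNetwork(object[, tr == t], ...)), lev)
}

#' Export a co-occurrence network
#'
#' @param network result of \code{\link{cooccurrenceNetwork}}.
#' @param path output path; \code{.graphml} selects GraphML, anything
#'   else an edge-list TSV (source, target, r, p, sign).
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(network, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    gr <- network$graph
    if (nrow(network$edges)) {
      igraph::E(gr)$r <- network$edges$r
      igraph::E(gr)$p <- network$edges$p
      igraph::E(gr)$sign <- network$edges$sign
    }
    igraph::write_graph(gr, path, format = "graphml")
  } else {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
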