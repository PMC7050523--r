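#' Gene-by-condition logFC matrix
#'
#' Builds the heatmap-ready matrix of signed log2 fold changes: rows are
#' the union of genes significant in at least one condition, columns the
#' conditions; each cell holds the logFC of that gene's
#' maximum-|logFC| significant row in that condition, or 0 when the gene
#' is not significant there. Rows are ordered by the number of conditions
#' the gene is called in (descending), ties broken by gene id, so the
#' layout is reproducible without clustering.
#'
#' @param records_by_condition named list of [compareCondition()]
#'   data.frames; names are condition labels and must be unique.
#' @return numeric matrix (possibly 0-row when nothing is significant).
#' @export
buildMatrix <- function(records_by_condition) {
  conds <- names(records_by_condition)
  if (is.null(conds) || anyDuplicated(conds))
    stop("conditions must be uniquely labelled")
  cell <- function(df) {
    sig <- df[df$significant, , drop = FALSE]
    if (!nrow(sig)) return(numeric(0))
    vapply(split(sig, sig$gene_id),
           function(g) g$logFC[which.max(abs(g$logFC))], numeric(1))
  }
  cells <- lapply(records_by_condition, cell)
  genes <- sort(unique(unlist(lapply(cells, names))))
  m <- matrix(0, nrow = length(genes), ncol = length(conds),
              dimnames = list(genes, conds))
  for (j in seq_along(conds)) {
    v <- cells[[j]]
    m[names(v), j] <- v
  }
  if (nrow(m) == 0L) return(m)
  ord <- order(-rowSums(m != 0), rownames(m))
  m[ord, , drop = FALSE]
}

#' Bipartite gene-condition network
#'
#' One node per called gene and per condition; one undirected edge per
#' (gene, condition) pair with at least one effect call, annotated with
#' the call of the strongest supporting row and its |logFC|. Genes shared
#' between conditions appear as high-degree nodes, exposing the
#' similarity structure of the responses.
#'
#' @param calls_by_condition named list of [classifyEffects()]
#'   data.frames; names are condition labels.
#' @param include_unclassified include genes whose only call is
#'   `unclassified`; default FALSE.
#' @return an `igraph` graph with vertex attributes `name` and `kind`
#'   (`gene`/`condition`, plus logical `type` for bipartite layouts) and
#'   edge attributes `call` and `max_abs_logFC`.
#' @export
buildNetwork <- function(calls_by_condition, include_unclassified = FALSE) {
  conds <- names(calls_by_condition)
  if (is.null(conds) || anyDuplicated(conds))
    stop("conditions must be uniquely labelled")
  edges <- list()
  for (cond in conds) {
    calls <- calls_by_condition[[cond]]
    if (!nrow(calls)) next
    if (!include_unclassified)
      calls <- calls[calls$call != "unclassified", , drop = FALSE]
    for (gene in unique(calls$gene_id)) {
      g <- calls[calls$gene_id == gene, , drop = FALSE]
      top <- which.max(abs(g$logFC))
      edges[[length(edges) + 1L]] <- data.frame(
        from = gene, to = cond, call = g$call[top],
        max_abs_logFC = abs(g$logFC[top]))
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               call = character(0), max_abs_logFC = numeric(0))
  genes <- sort(unique(edges$from))
  vertices <- data.frame(
    name = c(genes, conds),
    kind = c(rep("gene", length(genes)), rep("condition", length(conds))))
  vertices$type <- vertices$kind == "condition"
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' Export a condition network
#'
#' Writes the network as GraphML and as a flat edge-list TSV
#' (`gene`, `condition`, `call`, `max_abs_logFC`).
#'
#' @param network graph from [buildNetwork()].
#' @param graphml_path,edges_path output paths; either may be NULL to
#'   skip that format.
#' @return Invisibly, the written paths.
#' @export
exportNetwork <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(network, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    el <- igraph::as_data_frame(network, what = "edges")
    names(el)[1:2] <- c("gene", "condition")
    el <- el[order(el$condition, el$gene), , drop = FALSE]
    write.table(el, edges_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(graphml = graphml_path, edges = edges_path))
}

#' Write the gene-by-condition matrix as TSV
#'
#' @param m matrix from [buildMatrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMatrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
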