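#' Classify significant signals into biological effect calls
#'
#' Translates significant (gene, region, channel) comparison rows into
#' per-gene effect calls, using the orientation of the transposon's
#' outward promoter relative to each gene:
#' \itemize{
#'   \item significant change in the gene body (combined channel):
#'     enrichment means insertions disrupting the gene were selected
#'     (\code{inactivation_advantage}); depletion means loss of the gene
#'     carries a cost (\code{inactivation_cost});
#'   \item enrichment in the upstream window restricted to the
#'     toward-gene channel (forward for plus-strand genes, reverse for
#'     minus-strand) and not mirrored in the opposite channel: the
#'     outward promoter drives the gene up
#'     (\code{increased_expression_advantage});
#'   \item enrichment in the downstream window in the antisense channel
#'     (reverse for plus-strand genes): promoter-driven interfering
#'     antisense transcript knocks the gene down
#'     (\code{decreased_expression_advantage});
#'   \item significant rows matching no rule are reported as
#'     \code{unclassified} with their supporting rows attached.
#' }
#' "Not mirrored" means the opposite upstream channel is either
#' non-significant or has less than half the signal channel's logFC. A
#' gene may carry several calls in one condition; every call is backed by
#' at least one significant row.
#'
#' @param records comparison data.frame from [compareCondition()].
#' @param genes `GRanges` with `gene_id` (for strands).
#' @param condition condition label stored in the output.
#' @return data.frame with one row per supporting record: `gene_id`,
#'   `condition`, `call`, `region`, `channel`, `logFC`, `q_value`.
#'   Zero significant rows give a zero-row data.frame.
#' @export
classifyEffects <- function(records, genes, condition = "condition") {
  unknown <- setdiff(unique(records$gene_id), genes$gene_id)
  if (length(unknown))
    stop("record references unknown gene: ", paste(unknown, collapse = ", "))
  strands <- as.character(strand(genes))
  names(strands) <- genes$gene_id
  empty <- data.frame(gene_id = character(0), condition = character(0),
                      call = character(0), region = character(0),
                      channel = character(0), logFC = numeric(0),
                      q_value = numeric(0))
  sig <- records[records$significant, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  out <- list()
  emit <- function(gene, call, rows) {
    out[[length(out) + 1L]] <<- data.frame(
      gene_id = gene, condition = condition, call = call,
      region = rows$region, channel = rows$channel,
      logFC = rows$logFC, q_value = rows$q_value)
  }
  for (gene in unique(sig$gene_id)) {
    rows <- sig[sig$gene_id == gene, , drop = FALSE]
    used <- rep(FALSE, nrow(rows))
    st <- strands[[gene]]
    toward <- toward_channel(st)
    anti <- antisense_channel(st)

    body <- rows$region == "gene" & rows$channel == "combined"
    if (any(body)) {
      dir <- rows$direction[body][1L]
      emit(gene,
           if (dir == "enriched") "inactivation_advantage"
           else "inactivation_cost",
           rows[rows$region == "gene", , drop = FALSE])
      used[rows$region == "gene"] <- TRUE
    }

    up <- rows$region == "upstream" & rows$channel == toward &
      rows$direction == "enriched"
    if (any(up)) {
      sig_lfc <- max(rows$logFC[up])
      opp <- records$gene_id == gene & records$region == "upstream" &
        records$channel == setdiff(c("forward", "reverse"), toward)
      mirrored <- any(records$significant[opp] &
                        records$logFC[opp] >= 0.5 * sig_lfc)
      if (!mirrored) {
        emit(gene, "increased_expression_advantage",
             rows[up, , drop = FALSE])
        used[rows$region == "upstream"] <- TRUE
      }
    }

    down <- rows$region == "downstream" & rows$channel == anti &
      rows$direction == "enriched"
    if (any(down)) {
      emit(gene, "decreased_expression_advantage", rows[down, , drop = FALSE])
      used[rows$region == "downstream"] <- TRUE
    }

    if (any(!used))
      emit(gene, "unclassified", rows[!used, , drop = FALSE])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distinct genes called in a set of effect calls
#'
#' @param calls output of [classifyEffects()].
#' @param include_unclassified count genes whose only call is
#'   `unclassified`; default FALSE.
#' @return character vector of gene ids.
#' @export
calledGenes <- function(calls, include_unclassified = FALSE) {
  if (!nrow(calls)) return(character(0))
  keep <- if (include_unclassified) calls else
    calls[calls$call != "unclassified", , drop = FALSE]
  sort(unique(keep$gene_id))
}

#' Target gain from promoter induction
#'
#' Compares the target sets recovered with and without induction of the
#' transposon's outward promoter for the same condition and reports the
#' percentage gain, \code{100 * (|induced| - |uninduced|) / |uninduced|}.
#'
#' @param targets_induced,targets_uninduced character vectors of gene ids
#'   called under identical settings.
#' @return list with `n_induced`, `n_uninduced`, `pct_gain` (NA with
#'   `undefined = TRUE` when the uninduced set is empty), `gained` and
#'   `lost` gene sets.
#' @examples
#' inductionGain(paste0("g", 1:121), paste0("g", 1:100))$pct_gain  # 21
#' @export
inductionGain <- function(targets_induced, targets_uninduced) {
  ind <- unique(targets_induced); unind <- unique(targets_uninduced)
  undefined <- length(unind) == 0L
  list(n_induced = length(ind),
       n_uninduced = length(unind),
       pct_gain = if (undefined) NA_real_ else
         100 * (length(ind) - length(unind)) / length(unind),
       undefined = undefined,
       gained = sort(setdiff(ind, unind)),
       lost = sort(setdiff(unind, ind)))
}
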