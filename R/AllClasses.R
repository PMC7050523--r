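#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Strand-split per-base insertion profile for one replicon
#'
#' An \code{InsertionProfile} records, for every base of a replicon, the
#' number of sequencing reads whose transposon--genome junction falls at that
#' base, split by transposon orientation. The \emph{forward} channel holds
#' reads from insertions whose outward-facing promoter transcribes in the
#' increasing-coordinate direction; the \emph{reverse} channel holds the
#' opposite orientation. Read mapping orientation is used as the proxy for
#' promoter orientation, so "a forward read" and "a forward insertion" are
#' interchangeable throughout the package.
#'
#' @slot replicon_id single character, name of the replicon.
#' @slot reads_fwd integer vector, one entry per base, forward-channel reads.
#' @slot reads_rev integer vector, same length, reverse-channel reads.
#'
#' @seealso [readPlot()], [writePlot()], [samToProfile()]
#' @export
setClass("InsertionProfile",
  representation(
    replicon_id = "character",
    reads_fwd = "integer",
    reads_rev = "integer"
  )
)

setValidity("InsertionProfile", function(object) {
  msg <- character()
  if (length(object@replicon_id) != 1L || is.na(object@replicon_id))
    msg <- c(msg, "replicon_id must be a single non-NA string")
  if (length(object@reads_fwd) != length(object@reads_rev))
    msg <- c(msg, "reads_fwd and reads_rev must have equal length")
  if (anyNA(object@reads_fwd) || anyNA(object@reads_rev))
    msg <- c(msg, "read counts must not contain NA")
  else if (any(object@reads_fwd < 0L) || any(object@reads_rev < 0L))
    msg <- c(msg, "read counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an InsertionProfile
#'
#' @param replicon_id replicon name.
#' @param reads_fwd,reads_rev non-negative integer vectors of equal length,
#'   one entry per base.
#' @return An [InsertionProfile-class] object.
#' @examples
#' InsertionProfile("chr", c(0L, 3L, 0L), c(0L, 1L, 0L))
#' @export
InsertionProfile <- function(replicon_id, reads_fwd, reads_rev) {
  new("InsertionProfile",
      replicon_id = as.character(replicon_id),
      reads_fwd = as.integer(reads_fwd),
      reads_rev = as.integer(reads_rev))
}

#' @describeIn InsertionProfile-class replicon length in bp.
#' @param x,object an \code{InsertionProfile}.
#' @export
setMethod("length", "InsertionProfile", function(x) length(x@reads_fwd))

#' Accessors for InsertionProfile
#'
#' @param x an [InsertionProfile-class].
#' @return `readsFwd`/`readsRev` return the per-base integer count vectors;
#'   `repliconId` the replicon name; `totalReads` the library size
#'   (sum of both channels).
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
readsFwd <- function(x) x@reads_fwd

#' @rdname profile-accessors
#' @export
readsRev <- function(x) x@reads_rev

#' @rdname profile-accessors
#' @export
repliconId <- function(x) x@replicon_id

#' @rdname profile-accessors
#' @export
totalReads <- function(x) sum(x@reads_fwd) + sum(x@reads_rev)

setMethod("show", "InsertionProfile", function(object) {
  n_sites <- sum(object@reads_fwd + object@reads_rev > 0L)
  cat("InsertionProfile for", object@replicon_id,
      "-", length(object), "bp\n")
  cat("  unique insertion sites:", n_sites, "\n")
  cat("  total reads:", totalReads(object),
      sprintf("(fwd %d / rev %d)\n",
              sum(object@reads_fwd), sum(object@reads_rev)))
})

#' Per-region, per-channel insertion counts across samples
#'
#' A \code{RegionCountTable} is a [SummarizedExperiment] whose rows are
#' (gene, region, channel) triples -- region one of \code{gene},
#' \code{upstream}, \code{downstream} (flanking windows of at most 198 bp,
#' strand-flipped for minus-strand genes) and channel one of \code{forward},
#' \code{reverse}, \code{combined} -- and whose columns are samples. Two
#' assays are carried: \code{reads} (junction read counts, the quantity that
#' is statistically modelled) and \code{sites} (unique insertion sites,
#' reported only). Column data holds each sample's \code{library_size}
#' (total mapped reads in its profile).
#'
#' @seealso [regionCountTable()], [countRegions()], [compareCondition()]
#' @export
setClass("RegionCountTable", contains = "SummarizedExperiment")

setValidity("RegionCountTable", function(object) {
  msg <- character()
  need <- c("gene_id", "region", "channel")
  if (!all(need %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must contain gene_id, region, channel")
  if (!all(c("reads", "sites") %in% names(SummarizedExperiment::assays(object))))
    msg <- c(msg, "assays 'reads' and 'sites' are required")
  if (!"library_size" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain library_size")
  if (!length(msg)) {
    rd <- rowData(object)
    if (!all(rd$region %in% c("gene", "upstream", "downstream")))
      msg <- c(msg, "region must be gene/upstream/downstream")
    if (!all(rd$channel %in% c("forward", "reverse", "combined")))
      msg <- c(msg, "channel must be forward/reverse/combined")
    if (any(assay(object, "reads") < 0) || any(assay(object, "sites") < 0))
      msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname RegionCountTable-class
#' @param x a \code{RegionCountTable}.
#' @return `readCounts`/`siteCounts` return the count matrices,
#'   `librarySizes` the named vector of per-sample library sizes.
#' @export
readCounts <- function(x) assay(x, "reads")

#' @rdname RegionCountTable-class
#' @export
siteCounts <- function(x) assay(x, "sites")

#' @rdname RegionCountTable-class
#' @export
librarySizes <- function(x) {
  ls <- colData(x)$library_size
  names(ls) <- colnames(x)
  ls
}

#' Two-component mixture fit to the insertion-index distribution
#'
#' Parameters of the exponential (essential) + gamma (non-essential)
#' mixture fitted by EM to per-gene insertion indices. The exponential
#' component captures genes with (near-)zero insertion density; the gamma
#' component the permissive bulk.
#'
#' @slot weight_essential mixing weight of the exponential component.
#' @slot rate_essential exponential rate (1 / mean index of essential genes).
#' @slot shape,rate gamma shape and rate of the non-essential component.
#' @slot converged,n_iter EM convergence flag and iteration count.
#' @slot loglik final mixture log-likelihood.
#' @slot unimodal TRUE when the fitted essential weight is negligible
#'   (<= 0.02), i.e. the index distribution shows no essential mode.
#'
#' @seealso [fitBimodal()], [classifyEssentiality()]
#' @export
setClass("MixtureFit",
  representation(
    weight_essential = "numeric",
    rate_essential = "numeric",
    shape = "numeric",
    rate = "numeric",
    converged = "logical",
    n_iter = "integer",
    loglik = "numeric",
    unimodal = "logical"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (object@weight_essential < 0 || object@weight_essential > 1)
    msg <- c(msg, "weight_essential must lie in [0, 1]")
  if (any(c(object@rate_essential, object@shape, object@rate) <= 0))
    msg <- c(msg, "component parameters must be strictly positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MixtureFit", function(object) {
  cat("Insertion-index mixture fit (exponential + gamma)\n")
  cat(sprintf("  essential weight: %.4f (exp rate %.4g, mean %.4g)\n",
              object@weight_essential, object@rate_essential,
              1 / object@rate_essential))
  cat(sprintf("  non-essential gamma: shape %.3f, rate %.3f (mean %.4g)\n",
              object@shape, object@rate, object@shape / object@rate))
  cat(sprintf("  %s after %d EM iterations, loglik %.3f%s\n",
              if (object@converged) "converged" else "NOT converged",
              object@n_iter, object@loglik,
              if (object@unimodal) " [unimodal warning]" else ""))
})
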