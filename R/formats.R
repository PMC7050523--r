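NULL

#' Read a strand-split insertion plot file
#'
#' Parses the plain-text insert-site plot dialect used by transposon
#' insertion-site sequencing pipelines: one line per genome base, two
#' whitespace-separated non-negative integers -- forward-channel then
#' reverse-channel junction read counts. Line \eqn{i} populates base
#' \eqn{i} of the profile. Files ending in \code{.gz} are read through a
#' gzip connection transparently.
#'
#' @param path path to the plot file (optionally gzip-compressed).
#' @param replicon_id replicon name to attach to the profile.
#' @return An [InsertionProfile-class]; an empty file yields a profile of
#'   length 0.
#' @examples
#' f <- tempfile(fileext = ".plot")
#' writeLines(c("0 0", "3 1", "0 0"), f)
#' p <- readPlot(f, "chr")
#' readsFwd(p)  # 0 3 0
#' @export
readPlot <- function(path, replicon_id = sub("\\.(plot|txt)(\\.gz)?$", "",
                                             basename(path))) {
  if (!file.exists(path)) stop("plot file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines))
    return(InsertionProfile(replicon_id, integer(0), integer(0)))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop("malformed plot line ", which(nf != 2L)[1L],
         ": expected exactly two fields")
  flat <- unlist(fields, use.names = FALSE)
  bad <- !grepl("^[0-9]+$", flat)
  if (any(bad))
    stop("malformed plot line ", ceiling(which(bad)[1L] / 2),
         ": counts must be non-negative integers")
  counts <- as.integer(flat)
  InsertionProfile(replicon_id,
                   counts[seq(1L, length(counts), by = 2L)],
                   counts[seq(2L, length(counts), by = 2L)])
}

#' Write an insertion profile as a plot file
#'
#' Loss-free inverse of [readPlot()]: one line per base,
#' \code{"fwd rev"}, newline-terminated. A \code{.gz} extension writes
#' through a gzip connection.
#'
#' @param profile an [InsertionProfile-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePlot <- function(profile, path) {
  stopifnot(is(profile, "InsertionProfile"))
  validObject(profile)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(profile) > 0L)
    writeLines(paste(profile@reads_fwd, profile@reads_rev), con, sep = "\n")
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Imports a GFF3 file and returns the gene features as a
#' \code{GRanges} with a \code{gene_id} metadata column (taken from the
#' \code{ID}, \code{locus_tag}, or \code{Name} attribute, in that order of
#' preference) and a \code{name} column. When the file contains no
#' \code{gene} features, \code{CDS} features are used as a fallback.
#'
#' @param path GFF3 file.
#' @return A `GRanges`, sorted by start coordinate, with metadata columns
#'   `gene_id` (unique) and `name`. Zero gene features give an empty
#'   `GRanges` with a warning.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) == "gene"
  if (!any(keep)) keep <- as.character(gr$type) == "CDS"
  genes <- gr[keep]
  if (!length(genes)) {
    warning("no gene or CDS features found in ", path)
    out <- GRanges()
    mcols(out)$gene_id <- character(0)
    mcols(out)$name <- character(0)
    return(out)
  }
  pick <- function(a, b) ifelse(is.na(a) | a == "", b, a)
  id <- rep(NA_character_, length(genes))
  for (col in c("ID", "locus_tag", "Name"))
    if (col %in% colnames(mcols(genes)))
      id <- pick(id, as.character(mcols(genes)[[col]]))
  if (anyNA(id)) stop("gene feature without ID/locus_tag/Name attribute")
  if (anyDuplicated(id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  nm <- if ("Name" %in% colnames(mcols(genes)))
    pick(as.character(genes$Name), id) else id
  sl <- GenomeInfoDb::seqlengths(genes)
  if (all(is.na(sl))) {
    # rtracklayer does not surface the ##sequence-region pragma; scan it
    prag <- grep("^##sequence-region", readLines(path, n = 200L),
                 value = TRUE)
    for (line in prag) {
      parts <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
      if (length(parts) >= 4L && parts[2L] %in% names(sl))
        sl[parts[2L]] <- as.integer(parts[4L])
    }
  }
  known <- !is.na(sl[as.character(seqnames(genes))])
  if (any(known & end(genes) > sl[as.character(seqnames(genes))]))
    stop("gene feature exceeds declared sequence-region length")
  suppressWarnings(GenomeInfoDb::seqlengths(genes) <- sl)
  out <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
                 strand = strand(genes), seqinfo = GenomeInfoDb::seqinfo(genes))
  mcols(out)$gene_id <- id
  mcols(out)$name <- nm
  out[order(start(out))]
}

#' Write gene annotation as GFF3
#'
#' @param genes `GRanges` with `gene_id` (and optionally `name`) metadata.
#' @param path output GFF3 path.
#' @param seqlength declared replicon length for the `##sequence-region`
#'   pragma; taken from `seqlengths(genes)` when NULL.
#' @return Invisibly, `path`.
#' @export
writeAnnotation <- function(genes, path, seqlength = NULL) {
  g <- genes
  mcols(g) <- NULL
  g$type <- "gene"
  g$ID <- genes$gene_id
  g$Name <- if (!is.null(genes$name)) genes$name else genes$gene_id
  if (!is.null(seqlength))
    GenomeInfoDb::seqlengths(g) <- seqlength
  g$source <- "tnxpress"
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

#' Build an insertion profile from SAM alignments
#'
#' Extracts transposon--genome junctions from single-end alignments. For a
#' forward-mapped read the junction is the leftmost aligned reference base
#' and increments the forward channel; for a reverse-mapped read it is the
#' rightmost aligned base and increments the reverse channel (the read's 5'
#' end marks the transposon junction in both cases). Unmapped, secondary,
#' supplementary, other-replicon, and low-mapping-quality records are
#' skipped and tallied.
#'
#' @param path SAM (or BAM) file.
#' @param replicon_id reference name to count on.
#' @param length replicon length in bp.
#' @param min_mapq minimum mapping quality; default 10.
#' @return An [InsertionProfile-class] with attribute `"skipped"`: a named
#'   vector of skip counts (`unmapped`, `secondary`, `supplementary`,
#'   `other_replicon`, `low_mapq`).
#' @export
samToProfile <- function(path, replicon_id, length, min_mapq = 10L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "mapq", "cigar", "strand")))[[1L]]
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- !unmapped & bitwAnd(flag, 256L) != 0L
  supplementary <- !unmapped & !secondary & bitwAnd(flag, 2048L) != 0L
  usable <- !(unmapped | secondary | supplementary)
  other <- usable & (is.na(res$rname) | as.character(res$rname) != replicon_id)
  usable <- usable & !other
  low <- usable & (is.na(res$mapq) | res$mapq < min_mapq)
  usable <- usable & !low
  fwd <- integer(length)
  rev <- integer(length)
  if (any(usable)) {
    pos <- res$pos[usable]
    width <- GenomicAlignments::cigarWidthAlongReferenceSpace(
      res$cigar[usable])
    minus <- as.character(res$strand[usable]) == "-"
    junction <- ifelse(minus, pos + width - 1L, pos)
    if (any(junction < 1L | junction > length))
      stop("alignment junction outside [1, ", length, "] at record ",
           which(usable)[which(junction < 1L | junction > length)[1L]])
    fwd <- tabulate(junction[!minus], nbins = length)
    rev <- tabulate(junction[minus], nbins = length)
  }
  out <- InsertionProfile(replicon_id, fwd, rev)
  attr(out, "skipped") <- c(
    unmapped = sum(unmapped), secondary = sum(secondary),
    supplementary = sum(supplementary), other_replicon = sum(other),
    low_mapq = sum(low))
  out
}
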