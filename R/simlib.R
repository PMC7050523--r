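#' Configuration for a synthetic insertion library
#'
#' Captures the properties of the simulated screen: a single circular-free
#' replicon tiled with non-overlapping genes, a fraction of which are
#' essential (their interiors host no insertions), and a saturating pool of
#' unique insertion sites at the given per-base density. Site read counts
#' follow a shifted negative binomial (at least one read per existing site,
#' mean exactly \code{mean_reads_per_site}); the NB is parameterized by mean
#' \eqn{\mu} and dispersion \eqn{\phi} with variance \eqn{\mu + \phi\mu^2},
#' so \eqn{\phi = 0} is Poisson.
#'
#' Defaults mirror a saturating screen scaled to desk size: a 60 kb
#' replicon, 300 genes, 10\% essential, one insertion site every 6 bp, and
#' 10 reads per site.
#'
#' @param genome_length replicon length in bp.
#' @param n_genes number of non-overlapping genes to place.
#' @param essential_fraction fraction of genes that are essential.
#' @param site_density expected unique insertion sites per permissive bp.
#' @param mean_reads_per_site mean reads at an existing site (>= 1).
#' @param read_dispersion NB dispersion \eqn{\phi \ge 0}.
#' @param seed integer seed; fixed seed gives byte-identical libraries.
#' @return A `SimConfig` list.
#' @export
simConfig <- function(genome_length = 60000L, n_genes = 300L,
                      essential_fraction = 0.1, site_density = 1 / 6,
                      mean_reads_per_site = 10, read_dispersion = 0.1,
                      seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              essential_fraction = essential_fraction,
              site_density = site_density,
              mean_reads_per_site = mean_reads_per_site,
              read_dispersion = read_dispersion,
              seed = as.integer(seed))
  stopifnot(cfg$genome_length > 0, cfg$n_genes > 0,
            cfg$essential_fraction >= 0, cfg$essential_fraction <= 1,
            cfg$site_density > 0, cfg$site_density <= 1,
            cfg$mean_reads_per_site >= 1, cfg$read_dispersion >= 0)
  class(cfg) <- "SimConfig"
  cfg
}

# shifted NB: 1 + NB(mu - 1, phi); mean exactly mu, support >= 1
rreads_site <- function(n, mu, phi) {
  if (mu <= 1) return(rep(1L, n))
  1L + if (phi == 0) stats::rpois(n, mu - 1) else
    stats::rnbinom(n, size = 1 / phi, mu = mu - 1)
}

# unconstrained NB draw used for re-drawing abundances under selection
rreads_open <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else
    stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a saturating transposon insertion library
#'
#' Places \code{n_genes} non-overlapping genes on the replicon (one gene
#' per equal-width slot, length and offset drawn within the slot), marks a
#' random subset essential, then scatters unique insertion sites over all
#' permissive bases (everything except essential-gene interiors) with the
#' configured density. Each site is assigned a fair-coin orientation and a
#' shifted-NB read count. The site set is fixed at library creation: it is
#' the one biological pool later split across growth conditions by
#' [applyCondition()], which only re-draws abundances.
#'
#' @param config a [simConfig()].
#' @param effects optional data.frame describing condition-specific
#'   selection: columns `condition`, `gene_id`, `effect_kind` (one of
#'   `knockout_fitness`, `upstream_promoter`, `downstream_antisense`) and
#'   `multiplier` (> 0, scales the expected reads of the affected
#'   positions/channel in that condition).
#' @return A list with elements `profile` (the control
#'   [InsertionProfile-class]), `genes` (a `GRanges` with `gene_id`,
#'   `name`, `essential`), and `truth` (a `SimTruth` list carrying the
#'   essential flags, the effect table, and the generative parameters).
#' @examples
#' sim <- simulateLibrary(simConfig(genome_length = 6000, n_genes = 30))
#' sum(readsFwd(sim$profile) + readsRev(sim$profile) > 0)  # unique sites
#' @export
simulateLibrary <- function(config, effects = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  L <- config$genome_length
  n <- config$n_genes
  slot <- L %/% n
  min_len <- 100L
  max_len <- as.integer(floor(0.7 * slot))
  if (max_len < min_len)
    stop("genes cannot be placed without overlap: need genome_length/n_genes",
         " >= ", ceiling(min_len / 0.7), " bp per gene")
  set.seed(config$seed)
  lens <- sample(min_len:max_len, n, replace = TRUE)
  margin <- slot - lens
  offs <- floor(stats::runif(n) * (margin + 1))
  starts <- (seq_len(n) - 1L) * slot + as.integer(offs) + 1L
  ends <- starts + lens - 1L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("gene%04d", seq_len(n))
  n_ess <- round(config$essential_fraction * n)
  essential <- rep(FALSE, n)
  essential[sample(n, n_ess)] <- TRUE

  permissive <- rep(TRUE, L)
  for (i in which(essential)) permissive[starts[i]:ends[i]] <- FALSE
  is_site <- permissive & (stats::runif(L) < min(1, config$site_density))
  site_pos <- which(is_site)
  fwd_site <- stats::runif(length(site_pos)) < 0.5
  counts <- rreads_site(length(site_pos), config$mean_reads_per_site,
                        config$read_dispersion)
  fwd <- integer(L); rev <- integer(L)
  fwd[site_pos[fwd_site]] <- counts[fwd_site]
  rev[site_pos[!fwd_site]] <- counts[!fwd_site]

  genes <- GRanges("sim", IRanges(starts, ends), strand = strands)
  GenomeInfoDb::seqlengths(genes) <- L
  mcols(genes)$gene_id <- ids
  mcols(genes)$name <- ids
  mcols(genes)$essential <- essential

  if (is.null(effects)) {
    effects <- data.frame(condition = character(0), gene_id = character(0),
                          effect_kind = character(0), multiplier = numeric(0))
  } else {
    effects <- as.data.frame(effects)
    stopifnot(all(c("condition", "gene_id", "effect_kind", "multiplier") %in%
                    names(effects)))
    if (!all(effects$gene_id %in% ids))
      stop("effect references unknown gene_id")
    if (!all(effects$effect_kind %in%
             c("knockout_fitness", "upstream_promoter", "downstream_antisense")))
      stop("unknown effect_kind in effects table")
    if (any(effects$multiplier < 0)) stop("multiplier must be >= 0")
  }
  truth <- list(
    genes = data.frame(gene_id = ids, essential = essential),
    effects = effects,
    site_pos = site_pos,
    site_fwd = fwd_site,
    mean_reads_per_site = config$mean_reads_per_site,
    read_dispersion = config$read_dispersion,
    window = 198L)
  class(truth) <- "SimTruth"
  list(profile = InsertionProfile("sim", fwd, rev), genes = genes,
       truth = truth)
}

# 1-based inclusive flanking windows, strand-aware and clamped at the ends
flank_windows <- function(start, end, strand, window, L) {
  left <- c(max(1L, start - window), start - 1L)     # may be empty
  right <- c(end + 1L, min(L, end + window))
  if (strand == "-") list(upstream = right, downstream = left)
  else list(upstream = left, downstream = right)
}

# channel whose outward promoter points into the gene from upstream
toward_channel <- function(strand) ifelse(strand == "+", "forward", "reverse")
# channel transcribing antisense to the gene from the downstream window
antisense_channel <- function(strand) ifelse(strand == "+", "reverse", "forward")

#' Draw a condition profile from the simulated library
#'
#' Re-draws read abundances for every site of the library under a named
#' growth condition, emulating selection: `knockout_fitness` scales the
#' expected reads of all sites inside the gene (both channels);
#' `upstream_promoter` scales only toward-gene-oriented sites in the
#' gene's upstream 198 bp window; `downstream_antisense` scales only
#' antisense-oriented sites in the downstream window. Untouched sites are
#' re-drawn with unchanged mean, so calling with the always-available
#' condition \code{"control"} (no effects) and different seeds yields
#' control replicates.
#'
#' @param sim the list returned by [simulateLibrary()].
#' @param condition condition name; must be `"control"` or appear in the
#'   truth's effect table.
#' @param seed seed for this draw.
#' @return An [InsertionProfile-class] for the condition.
#' @export
applyCondition <- function(sim, condition, seed) {
  truth <- sim$truth
  genes <- sim$genes
  known <- unique(c("control", truth$effects$condition))
  if (!condition %in% known)
    stop("unknown condition '", condition, "'; known: ",
         paste(known, collapse = ", "))
  L <- length(sim$profile)
  mult_f <- rep(1, L)
  mult_r <- rep(1, L)
  eff <- truth$effects[truth$effects$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(eff))) {
    g <- genes[genes$gene_id == eff$gene_id[i]]
    s <- start(g); e <- end(g); st <- as.character(strand(g))
    m <- eff$multiplier[i]
    kind <- eff$effect_kind[i]
    if (kind == "knockout_fitness") {
      mult_f[s:e] <- mult_f[s:e] * m
      mult_r[s:e] <- mult_r[s:e] * m
    } else {
      w <- flank_windows(s, e, st, truth$window, L)
      rng <- if (kind == "upstream_promoter") w$upstream else w$downstream
      ch <- if (kind == "upstream_promoter") toward_channel(st) else
        antisense_channel(st)
      if (rng[1] <= rng[2]) {
        idx <- rng[1]:rng[2]
        if (ch == "forward") mult_f[idx] <- mult_f[idx] * m
        else mult_r[idx] <- mult_r[idx] * m
      }
    }
  }
  set.seed(seed)
  pos <- truth$site_pos
  fwd_site <- truth$site_fwd
  mu0 <- truth$mean_reads_per_site
  phi <- truth$read_dispersion
  fwd <- integer(L); rev <- integer(L)
  mult_site <- ifelse(fwd_site, mult_f[pos], mult_r[pos])
  touched <- mult_site != 1
  counts <- integer(length(pos))
  counts[!touched] <- rreads_site(sum(!touched), mu0, phi)
  counts[touched] <- rreads_open(sum(touched), mu0 * mult_site[touched], phi)
  fwd[pos[fwd_site]] <- counts[fwd_site]
  rev[pos[!fwd_site]] <- counts[!fwd_site]
  InsertionProfile(repliconId(sim$profile), fwd, rev)
}

#' Write a simulated library to disk
#'
#' Emits the control plot file, the GFF3 annotation, and a ground-truth
#' TSV (`gene_id`, `essential`, and one row per condition effect).
#'
#' @param sim result of [simulateLibrary()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plot = file.path(dir, "control.plot"),
             gff = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.tsv"))
  writePlot(sim$profile, paths[["plot"]])
  writeAnnotation(sim$genes, paths[["gff"]],
                  seqlength = length(sim$profile))
  tr <- merge(sim$truth$genes,
              sim$truth$effects[, c("gene_id", "condition", "effect_kind",
                                    "multiplier")],
              by = "gene_id", all.x = TRUE)
  tr <- tr[order(tr$gene_id, tr$condition), ]
  write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
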