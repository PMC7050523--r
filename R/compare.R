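range_sum <- function(cs, from, to) {
  # cs = c(0, cumsum(v)); inclusive 1-based [from, to]; empty range -> 0
  if (to < from) return(0L)
  cs[to + 1L] - cs[from]
}

#' Count insertions per gene region and channel for one sample
#'
#' Tallies junction reads and unique insertion sites over three regions
#' per gene -- the gene body and flanking windows of at most
#' \code{window} bp (198 by default) upstream and downstream, clamped at
#' the replicon ends and strand-flipped for minus-strand genes -- in three
#' channels: forward, reverse, and combined (their sum). Channels are
#' reference-oriented; translation to gene-relative toward/antisense
#' orientation happens at classification time.
#'
#' @param profile an [InsertionProfile-class].
#' @param genes `GRanges` with `gene_id`.
#' @param window flanking window width in bp; must be positive.
#' @return data.frame with one row per (gene, region, channel):
#'   `gene_id`, `region`, `channel`, `read_count`, `unique_sites`;
#'   the sample's library size is attached as attribute
#'   `"library_size"`.
#' @export
countRegions <- function(profile, genes, window = 198L) {
  if (window <= 0) stop("window must be a positive number of bp")
  L <- length(profile)
  if (length(genes) && (min(start(genes)) < 1L || max(end(genes)) > L))
    stop("gene outside profile bounds")
  f <- readsFwd(profile); r <- readsRev(profile)
  cs_f <- c(0L, cumsum(f)); cs_r <- c(0L, cumsum(r))
  ss_f <- c(0L, cumsum(f > 0L)); ss_r <- c(0L, cumsum(r > 0L))
  ss_c <- c(0L, cumsum((f + r) > 0L))
  n <- length(genes)
  regions <- c("gene", "upstream", "downstream")
  channels <- c("forward", "reverse", "combined")
  out <- data.frame(
    gene_id = rep(genes$gene_id, each = 9L),
    region = rep(rep(regions, each = 3L), n),
    channel = rep(channels, 3L * n),
    read_count = 0L, unique_sites = 0L)
  row <- 0L
  for (i in seq_len(n)) {
    s <- start(genes)[i]; e <- end(genes)[i]
    w <- flank_windows(s, e, as.character(strand(genes))[i], window, L)
    for (rg in list(c(s, e), w$upstream, w$downstream)) {
      vals <- c(range_sum(cs_f, rg[1], rg[2]), range_sum(cs_r, rg[1], rg[2]))
      sites <- c(range_sum(ss_f, rg[1], rg[2]), range_sum(ss_r, rg[1], rg[2]),
                 range_sum(ss_c, rg[1], rg[2]))
      out$read_count[row + 1:3] <- c(vals, sum(vals))
      out$unique_sites[row + 1:3] <- sites
      row <- row + 3L
    }
  }
  attr(out, "library_size") <- totalReads(profile)
  out
}

#' Assemble a RegionCountTable across samples
#'
#' Runs [countRegions()] on each sample profile and binds the results
#' into a [RegionCountTable-class] (a `SummarizedExperiment` with `reads`
#' and `sites` assays and per-sample `library_size`).
#'
#' @param profiles named list of [InsertionProfile-class] objects; names
#'   are sample ids.
#' @param genes `GRanges` with `gene_id`.
#' @param window flanking window width in bp.
#' @return A [RegionCountTable-class].
#' @export
regionCountTable <- function(profiles, genes, window = 198L) {
  stopifnot(length(profiles) >= 1L)
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    stop("profiles must be a uniquely named list of samples")
  per <- lapply(profiles, countRegions, genes = genes, window = window)
  key <- per[[1L]][, c("gene_id", "region", "channel")]
  reads <- vapply(per, `[[`, integer(nrow(key)), "read_count")
  sites <- vapply(per, `[[`, integer(nrow(key)), "unique_sites")
  libs <- vapply(per, attr, numeric(1), "library_size")
  se <- SummarizedExperiment(
    assays = list(reads = reads, sites = sites),
    rowData = DataFrame(key),
    colData = DataFrame(library_size = libs, row.names = names(profiles)))
  rownames(se) <- paste(key$gene_id, key$region, key$channel, sep = ":")
  new("RegionCountTable", se)
}

#' Log2 counts-per-million with a prior count
#'
#' \code{log2((count + prior) / (library_size + 2 * prior) * 1e6)}; the
#' prior keeps zero counts finite.
#'
#' @param read_count non-negative count(s).
#' @param library_size total mapped reads in the sample (> 0).
#' @param prior prior count; default 0.5.
#' @return numeric, same length as `read_count`.
#' @export
logCPM <- function(read_count, library_size, prior = 0.5) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  log2((read_count + prior) / (library_size + 2 * prior) * 1e6)
}

#' Negative-binomial conditional exact test
#'
#' Two-sided exact test for a difference between two NB counts,
#' conditioning on their total \eqn{t = a + b}. Group totals of
#' \eqn{n_A} and \eqn{n_B} library-size-equalized replicates are modelled
#' as NB with mean \eqn{n\mu} and dispersion \eqn{\phi/n}; conditional on
#' \eqn{t} the split then follows a beta-binomial with parameters
#' \eqn{n_A/\phi} and \eqn{n_B/\phi} (a binomial with success probability
#' \eqn{n_A/(n_A+n_B)} in the Poisson limit \eqn{\phi = 0}). The p-value
#' sums the probabilities of every split as or less probable than the
#' observed one; splits within relative tolerance \code{tie_tol} of the
#' observed probability count as ties.
#'
#' @param count_a,count_b equalized group-summed counts.
#' @param phi per-replicate NB dispersion, >= 0.
#' @param n_a,n_b number of replicates summed into each group.
#' @param tie_tol relative tolerance for probability ties; default 1e-8.
#' @return p-value in (0, 1]; both counts zero give exactly 1.
#' @examples
#' nbExactTest(10, 0, phi = 0)   # 2 * (1/2)^10 = 0.001953125
#' nbExactTest(5, 5, phi = 0)    # modal split -> 1
#' @export
nbExactTest <- function(count_a, count_b, phi, n_a = 1L, n_b = 1L,
                        tie_tol = 1e-8) {
  if (phi < 0) stop("dispersion phi must be non-negative")
  a <- as.integer(round(count_a)); b <- as.integer(round(count_b))
  if (a < 0 || b < 0) stop("counts must be non-negative")
  t <- a + b
  if (t == 0L) return(1)
  x <- 0:t
  if (phi == 0) {
    # Poisson limit: iid Poisson given the total is binomial
    lp <- stats::dbinom(x, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    sa <- n_a / phi; sb <- n_b / phi
    lp <- lchoose(x + sa - 1, x) + lchoose(t - x + sb - 1, t - x) -
      lchoose(t + sa + sb - 1, t)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[a + 1L] * (1 + tie_tol)]))
}

#' Estimate a common NB dispersion by conditional maximum likelihood
#'
#' Maximizes, over the dispersion \eqn{\phi}, the likelihood of the
#' observed replicate splits conditional on each row's within-group
#' total: for a group of \eqn{n} equalized replicates the split of the
#' row total among replicates follows a symmetric Dirichlet-multinomial
#' with per-replicate size \eqn{1/\phi}, which is free of the row mean,
#' so rows of any abundance -- including genuinely differential ones --
#' pool cleanly and treatment effects cannot inflate the estimate. The
#' log-likelihood is summed over rows and both groups and optimized
#' numerically; a boundary optimum returns 0 (Poisson).
#'
#' When neither group has replicates (one sample each), replicate
#' variability is unavailable and the estimator falls back to
#' conditioning on the between-group split, which is only valid when
#' most rows are non-differential; a message notes this.
#'
#' @param counts_a,counts_b matrices (rows x replicates) of library-size
#'   equalized counts for the control and condition group (vectors are
#'   treated as single-replicate groups).
#' @param upper search upper bound for \eqn{\phi}; default 10.
#' @param default_phi returned (with a warning) when fewer than 2 rows
#'   with nonzero totals are available; default 0.1.
#' @return estimated common dispersion \eqn{\phi \ge 0}.
#' @export
estimateDispersion <- function(counts_a, counts_b, upper = 10,
                               default_phi = 0.1) {
  a <- round(as.matrix(counts_a)); b <- round(as.matrix(counts_b))
  if (nrow(a) != nrow(b)) stop("groups must share rows")
  usable <- (rowSums(a) + rowSums(b)) > 0
  if (sum(usable) < 2L) {
    warning("fewer than 2 rows with nonzero totals; ",
            "falling back to default dispersion ", default_phi)
    return(default_phi)
  }
  a <- a[usable, , drop = FALSE]; b <- b[usable, , drop = FALSE]
  groups <- Filter(function(m) ncol(m) >= 2L, list(a, b))
  if (length(groups)) {
    # within-group conditioning on each row's replicate total
    cll <- function(phi) {
      s <- 1 / phi
      sum(vapply(groups, function(m) {
        t <- rowSums(m)
        sum(lchoose(m + s - 1, m)) -
          sum(lchoose(t + ncol(m) * s - 1, t))
      }, numeric(1)))
    }
    ll0 <- sum(vapply(groups, function(m) {
      t <- rowSums(m)
      sum(lfactorial(t)) - sum(lfactorial(m)) - sum(t) * log(ncol(m))
    }, numeric(1)))
  } else {
    message("no replicated group; estimating dispersion from the ",
            "between-group split (assumes mostly non-differential rows)")
    as <- rowSums(a); bs <- rowSums(b)
    t <- as + bs
    cll <- function(phi) {
      s <- 1 / phi
      sum(lchoose(as + s - 1, as) + lchoose(bs + s - 1, bs) -
            lchoose(t + 2 * s - 1, t))
    }
    ll0 <- sum(stats::dbinom(as, t, 0.5, log = TRUE))
  }
  opt <- stats::optimize(cll, c(1e-6, upper), maximum = TRUE)
  if (opt$objective <= ll0 || opt$maximum <= 2e-6) 0 else opt$maximum
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Input p-values must lie in
#' (0, 1]; the output q-values are component-wise at least as large and
#' capped at 1.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bhAdjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Compare a condition against the control
#'
#' The comparative core of the screen: for every (gene, region, channel)
#' row, replicate counts are equalized to the geometric-mean library
#' size, summed within group, and tested with the NB conditional exact
#' test at a common dispersion estimated from within-group replicate
#' variability of the combined-channel rows (overridable). \code{logFC} is the log2 ratio of the
#' prior-augmented equalized group sums (condition over control);
#' \code{logCPM} is the mean over all used samples of per-sample
#' [logCPM()]. BH adjustment is applied jointly across all rows of the
#' comparison, and a row is flagged significant when
#' \code{q <= q_cut & |logFC| >= lfc_cut & logCPM > lcpm_cut}
#' (defaults 0.05 / 1 / 8).
#'
#' @param table a [RegionCountTable-class] containing all samples.
#' @param controls,conditions column names of the control and condition
#'   replicates.
#' @param q_cut,lfc_cut,lcpm_cut significance cutoffs.
#' @param prior prior count for logFC/logCPM; default 0.5.
#' @param phi common dispersion override; estimated when NULL.
#' @return data.frame with one row per (gene, region, channel):
#'   `gene_id`, `region`, `channel`, `ctrl_reads`, `cond_reads` (equalized
#'   group sums), `logFC`, `logCPM`, `p_value`, `q_value`, `significant`,
#'   `direction` (enriched/depleted). The dispersion used is attached as
#'   attribute `"phi"`.
#' @export
compareCondition <- function(table, controls, conditions,
                             q_cut = 0.05, lfc_cut = 1, lcpm_cut = 8,
                             prior = 0.5, phi = NULL) {
  stopifnot(is(table, "RegionCountTable"))
  miss <- setdiff(c(controls, conditions), colnames(table))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  libs <- librarySizes(table)[c(controls, conditions)]
  if (any(libs <= 0)) stop("zero library size in ",
                           paste(names(libs)[libs <= 0], collapse = ", "))
  reads <- readCounts(table)
  geo <- exp(mean(log(libs)))
  eq <- sweep(reads[, c(controls, conditions), drop = FALSE], 2,
              geo / libs, `*`)
  ctrl <- round(rowSums(eq[, controls, drop = FALSE]))
  cond <- round(rowSums(eq[, conditions, drop = FALSE]))
  n_a <- length(controls); n_b <- length(conditions)
  rd <- as.data.frame(rowData(table))
  if (is.null(phi)) {
    comb <- rd$channel == "combined"
    phi <- estimateDispersion(eq[comb, controls, drop = FALSE],
                              eq[comb, conditions, drop = FALSE])
  }
  p <- vapply(seq_along(ctrl), function(i)
    nbExactTest(ctrl[i], cond[i], phi = phi, n_a = n_a, n_b = n_b),
    numeric(1))
  lfc <- log2((cond + prior) / (ctrl + prior))
  lcpm_mat <- vapply(c(controls, conditions), function(s)
    logCPM(reads[, s], libs[s], prior), numeric(nrow(reads)))
  lcpm <- rowMeans(lcpm_mat)
  q <- bhAdjust(p)
  out <- data.frame(
    gene_id = rd$gene_id, region = rd$region, channel = rd$channel,
    ctrl_reads = as.integer(ctrl), cond_reads = as.integer(cond),
    logFC = lfc, logCPM = lcpm, p_value = p, q_value = q,
    significant = q <= q_cut & abs(lfc) >= lfc_cut & lcpm > lcpm_cut,
    direction = ifelse(lfc >= 0, "enriched", "depleted"),
    row.names = NULL)
  attr(out, "phi") <- phi
  out
}
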