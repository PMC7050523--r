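#' Per-gene insertion index
#'
#' The insertion index of a gene is the number of unique insertion sites
#' inside the gene (bases with at least one read in either channel)
#' divided by the gene length, in sites/bp. Essential genes cluster near
#' zero; permissive genes around the library's site density, making the
#' distribution across genes bimodal.
#'
#' @param profile an [InsertionProfile-class].
#' @param genes a `GRanges` with a `gene_id` column (see
#'   [readAnnotation()]), fully inside the profile.
#' @return Named numeric vector of insertion indices, one per gene.
#' @export
insertionIndex <- function(profile, genes) {
  L <- length(profile)
  if (length(genes) && (min(start(genes)) < 1L || max(end(genes)) > L))
    stop("gene outside profile bounds")
  occupied <- (readsFwd(profile) + readsRev(profile)) > 0L
  cs <- c(0L, cumsum(occupied))
  sites <- cs[end(genes) + 1L] - cs[start(genes)]
  idx <- sites / GenomicRanges::width(genes)
  names(idx) <- genes$gene_id
  idx
}

# weighted gamma MLE: solve log(k) - digamma(k) = s for the shape
gamma_shape_mle <- function(s) {
  if (!is.finite(s) || s <= 0) return(1e6)
  # Minka-style initialization, then Newton on log k
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    k_new <- k - f / fp
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * (1 + k)) { k <- k_new; break }
    k <- k_new
  }
  min(max(k, 1e-3), 1e6)
}

em_once <- function(x, lo, max_iter, tol, rate_e_floor) {
  n <- length(x)
  w <- min(max(mean(lo), 0.01), 0.9)
  rate_e <- max(1 / mean(x[lo]), rate_e_floor)
  xg <- x[!lo]
  m <- mean(xg); v <- stats::var(xg)
  shape <- if (is.finite(v) && v > 0) max(m^2 / v, 0.5) else 1
  rate <- shape / m
  ll_old <- -Inf; ll <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    le <- log(w) + stats::dexp(x, rate_e, log = TRUE)
    lg <- log1p(-w) + stats::dgamma(x, shape = shape, rate = rate, log = TRUE)
    mx <- pmax(le, lg)
    lse <- mx + log(exp(le - mx) + exp(lg - mx))
    ll <- sum(lse)
    r <- exp(le - lse)
    w <- min(max(mean(r), 1e-8), 1 - 1e-8)
    rate_e <- max(sum(r) / sum(r * x), rate_e_floor)
    sw <- sum(1 - r)
    mw <- sum((1 - r) * x) / sw
    mlog <- sum((1 - r) * log(x)) / sw
    shape <- gamma_shape_mle(log(mw) - mlog)
    rate <- shape / mw
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(w = w, rate_e = rate_e, shape = shape, rate = rate, ll = ll,
       converged = converged, n_iter = it)
}

#' Fit the bimodal insertion-index mixture
#'
#' Fits, by EM, a two-component mixture to per-gene insertion indices: an
#' exponential component for the essential mode at (near-)zero and a gamma
#' component for the permissive bulk. Zero indices are floored at
#' \code{zero_floor} before fitting so densities stay finite; true zeros
#' remain unambiguous because they sit far below any permissive index. For
#' identifiability the essential component's mean is constrained to at
#' most a fifth of the overall mean index, which forces genuinely unimodal
#' data to a negligible essential weight (reported via the
#' \code{unimodal} flag) instead of letting the exponential absorb the
#' gamma's left flank.
#'
#' EM is run from a small fixed grid of split-point initializations and
#' the highest-likelihood fit is kept, so the result is deterministic
#' given the data.
#'
#' @param indices numeric vector of insertion indices (>= 50 values, at
#'   least one positive).
#' @param zero_floor floor applied to zero indices; default 1e-6.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A [MixtureFit-class].
#' @examples
#' set.seed(7)
#' ii <- c(rexp(50, 1 / 0.002), rgamma(200, 5, scale = 0.03))
#' fitBimodal(ii)
#' @export
fitBimodal <- function(indices, zero_floor = 1e-6, max_iter = 500L,
                       tol = 1e-9) {
  if (length(indices) < 50L)
    stop("need at least 50 insertion indices to fit the mixture")
  if (anyNA(indices) || any(indices < 0))
    stop("insertion indices must be non-negative and non-missing")
  if (all(indices == 0)) stop("all insertion indices are zero")
  x <- pmax(indices, zero_floor)
  if (length(unique(x)) == 1L)
    stop("degenerate input: all insertion indices identical")
  rate_e_floor <- 5 / mean(x)
  xs <- sort(unique(x))
  cuts <- stats::quantile(x, c(0.05, 0.1, 0.2, 0.35), names = FALSE)
  best <- NULL
  for (cut in unique(cuts)) {
    lo <- x <= cut
    if (!any(lo) || all(lo)) {
      lo <- x <= xs[max(2L, ceiling(length(xs) * 0.05))]
      if (all(lo)) next
    }
    fit <- em_once(x, lo, max_iter, tol, rate_e_floor)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  if (is.null(best)) stop("mixture fit failed: no usable initialization")
  if (!best$converged)
    stop("EM did not converge within ", max_iter, " iterations ",
         sprintf("(loglik %.4f, weight %.4f)", best$ll, best$w))
  new("MixtureFit",
      weight_essential = best$w, rate_essential = best$rate_e,
      shape = best$shape, rate = best$rate,
      converged = best$converged, n_iter = best$n_iter,
      loglik = best$ll, unimodal = best$w <= 0.02)
}

#' Classify genes as essential / ambiguous / non-essential
#'
#' Scores each gene by the log-odds of the non-essential versus the
#' essential mixture component at its insertion index,
#' \eqn{\log[(1-w)\,g(x)] - \log[w\,e(x)]}, and thresholds it: below
#' \code{-log_odds_cut} is essential, above \code{+log_odds_cut}
#' non-essential, in between ambiguous. Genes shorter than
#' \code{min_gene_length} are still classified but flagged (their indices
#' are noisy and are best excluded from fitting).
#'
#' @param indices named numeric vector of insertion indices (names are
#'   gene ids).
#' @param fit a converged [MixtureFit-class] from [fitBimodal()].
#' @param log_odds_cut symmetric threshold on the log-odds; default 2
#'   (about e^2 : 1 odds).
#' @param gene_lengths optional named vector of gene lengths (bp) used for
#'   the short-gene flag.
#' @param min_gene_length genes shorter than this are flagged; default 100.
#' @param zero_floor floor applied to zero indices, matching
#'   [fitBimodal()].
#' @return data.frame with columns `gene_id`, `insertion_index`,
#'   `log_odds`, `class` (factor essential/ambiguous/non_essential) and
#'   `short_gene`.
#' @export
classifyEssentiality <- function(indices, fit, log_odds_cut = 2,
                                 gene_lengths = NULL,
                                 min_gene_length = 100L,
                                 zero_floor = 1e-6) {
  stopifnot(is(fit, "MixtureFit"))
  if (!fit@converged) stop("mixture fit did not converge")
  x <- pmax(indices, zero_floor)
  lg <- log1p(-fit@weight_essential) +
    stats::dgamma(x, shape = fit@shape, rate = fit@rate, log = TRUE)
  le <- log(fit@weight_essential) +
    stats::dexp(x, fit@rate_essential, log = TRUE)
  lo <- lg - le
  cls <- ifelse(lo < -log_odds_cut, "essential",
                ifelse(lo > log_odds_cut, "non_essential", "ambiguous"))
  short <- if (is.null(gene_lengths)) rep(FALSE, length(x)) else
    unname(gene_lengths[names(indices)] < min_gene_length)
  data.frame(
    gene_id = if (is.null(names(indices))) as.character(seq_along(indices))
              else names(indices),
    insertion_index = unname(indices),
    log_odds = unname(lo),
    class = factor(cls, levels = c("essential", "ambiguous", "non_essential")),
    short_gene = short,
    row.names = NULL)
}

#' Essentiality calling for one profile
#'
#' Convenience wrapper: computes insertion indices, fits the mixture on
#' genes of at least \code{min_gene_length} bp, and classifies every gene
#' (short genes included).
#'
#' @inheritParams insertionIndex
#' @inheritParams classifyEssentiality
#' @return The [classifyEssentiality()] data.frame with additional columns
#'   `length` and `unique_sites`; the [MixtureFit-class] is attached as
#'   attribute `"fit"`.
#' @export
callEssentiality <- function(profile, genes, log_odds_cut = 2,
                             min_gene_length = 100L) {
  ii <- insertionIndex(profile, genes)
  lens <- GenomicRanges::width(genes)
  names(lens) <- genes$gene_id
  fit <- fitBimodal(ii[lens >= min_gene_length])
  out <- classifyEssentiality(ii, fit, log_odds_cut = log_odds_cut,
                              gene_lengths = lens,
                              min_gene_length = min_gene_length)
  out$length <- unname(lens[out$gene_id])
  out$unique_sites <- as.integer(round(out$insertion_index * out$length))
  attr(out, "fit") <- fit
  out[, c("gene_id", "length", "unique_sites", "insertion_index",
          "log_odds", "class", "short_gene")]
}
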