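# Shared fixtures (built once per test run) and independent oracles.

fx_cache <- new.env(parent = emptyenv())

# Standard designed effects: ten genes per effect kind, spaced apart so the
# 198 bp windows of affected genes never touch each other.
fx_effects <- function() {
  ko <- sprintf("gene%04d", seq(20, 290, by = 30))
  up <- sprintf("gene%04d", seq(25, 295, by = 30))
  dn <- sprintf("gene%04d", seq(10, 280, by = 30))
  data.frame(
    condition = "drug",
    gene_id = c(ko, up, dn),
    effect_kind = rep(c("knockout_fitness", "upstream_promoter",
                        "downstream_antisense"), each = 10),
    multiplier = 8)
}

fx_sim <- function() {
  if (is.null(fx_cache$sim))
    fx_cache$sim <- simulateLibrary(simConfig(seed = 42),
                                    effects = fx_effects())
  fx_cache$sim
}

fx_profiles <- function() {
  if (is.null(fx_cache$profiles)) {
    sim <- fx_sim()
    fx_cache$profiles <- list(
      c1 = applyCondition(sim, "control", 101),
      c2 = applyCondition(sim, "control", 102),
      d1 = applyCondition(sim, "drug", 201),
      d2 = applyCondition(sim, "drug", 202),
      n1 = applyCondition(sim, "control", 301),
      n2 = applyCondition(sim, "control", 302))
  }
  fx_cache$profiles
}

fx_rct <- function() {
  if (is.null(fx_cache$rct))
    fx_cache$rct <- regionCountTable(fx_profiles(), fx_sim()$genes)
  fx_cache$rct
}

fx_records <- function() {
  if (is.null(fx_cache$records))
    fx_cache$records <- compareCondition(fx_rct(), c("c1", "c2"),
                                         c("d1", "d2"))
  fx_cache$records
}

fx_null_records <- function() {
  if (is.null(fx_cache$null_records))
    fx_cache$null_records <- compareCondition(fx_rct(), c("c1", "c2"),
                                              c("n1", "n2"))
  fx_cache$null_records
}

# Independent enumeration oracle for the conditional exact test: joint NB
# (or Poisson) products normalized by their explicit sum.
oracle_exact_p <- function(a, b, phi, tol = 1e-8) {
  t <- a + b
  if (t == 0) return(1)
  x <- 0:t
  pr <- if (phi == 0) dpois(x, t / 2) * dpois(t - x, t / 2) else
    dnbinom(x, size = 1 / phi, mu = t / 2) *
      dnbinom(t - x, size = 1 / phi, mu = t / 2)
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[a + 1] * (1 + tol)]))
}

# Hand-written BH step-up, independent of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Reverse-complement the whole experiment: base i -> L + 1 - i, channels swap
mirror_profile <- function(profile) {
  InsertionProfile(repliconId(profile),
                   rev(readsRev(profile)), rev(readsFwd(profile)))
}

mirror_genes <- function(genes, L) {
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(L + 1L - BiocGenerics::end(genes),
                     L + 1L - BiocGenerics::start(genes)),
    strand = ifelse(as.character(BiocGenerics::strand(genes)) == "+",
                    "-", "+"))
  S4Vectors::mcols(out) <- S4Vectors::mcols(genes)
  out
}

# Minimal comparison record for classification unit tests
make_record <- function(gene_id, region, channel, logFC, q = 1e-3,
                        significant = TRUE) {
  data.frame(gene_id = gene_id, region = region, channel = channel,
             ctrl_reads = 100L, cond_reads = 100L, logFC = logFC,
             logCPM = 12, p_value = q, q_value = q,
             significant = significant,
             direction = ifelse(logFC >= 0, "enriched", "depleted"))
}
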