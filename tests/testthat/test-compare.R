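make_gene <- function(start, end, strand) {
  g <- GenomicRanges::GRanges("chr", IRanges::IRanges(start, end),
                              strand = strand)
  g$gene_id <- "g1"
  g
}

test_that("region windows respect strand and clamp at replicon ends", {
  fwd <- integer(1000); fwd[50] <- 3L
  p <- InsertionProfile("chr", fwd, integer(1000))
  plus <- countRegions(p, make_gene(101, 400, "+"))
  get <- function(df, region, channel)
    df$read_count[df$region == region & df$channel == channel]
  expect_equal(get(plus, "upstream", "forward"), 3L)
  expect_equal(get(plus, "upstream", "combined"), 3L)
  expect_true(all(get(plus, "gene", c("forward")) == 0L))
  expect_equal(sum(plus$read_count[plus$region == "downstream"]), 0L)
  # same site, minus-strand gene: the window left of the gene is downstream
  minus <- countRegions(p, make_gene(101, 400, "-"))
  expect_equal(get(minus, "downstream", "forward"), 3L)
  expect_equal(sum(minus$read_count[minus$region == "upstream"]), 0L)
  # gene close to the origin: upstream window clamps to the start
  fwd2 <- integer(1000); fwd2[1:1000] <- 1L
  p2 <- InsertionProfile("chr", fwd2, integer(1000))
  clamp <- countRegions(p2, make_gene(21, 220, "+"))
  expect_equal(get(clamp, "upstream", "forward"), 20L)
  expect_equal(get(clamp, "downstream", "forward"), 198L)
  expect_error(countRegions(p, make_gene(101, 400, "+"), window = 0),
               "window")
})

test_that("combined channel equals forward plus reverse everywhere", {
  rct <- fx_rct()
  rd <- as.data.frame(SummarizedExperiment::rowData(rct))
  reads <- readCounts(rct)
  comb <- reads[rd$channel == "combined", ]
  expect_equal(comb, reads[rd$channel == "forward", ] +
                 reads[rd$channel == "reverse", ],
               ignore_attr = TRUE)
  expect_equal(unname(librarySizes(rct)["c1"]),
               totalReads(fx_profiles()$c1))
})

test_that("logCPM matches its closed form", {
  expect_equal(logCPM(256, 1e6, prior = 0), 8)
  expect_equal(logCPM(0, 1e6, prior = 0.5), log2(0.5 / (1e6 + 1) * 1e6),
               tolerance = 1e-12)
  expect_lt(abs(logCPM(0, 1e6, prior = 0.5) - (-1)), 1e-4)
  # scale invariance at large counts
  expect_lt(abs(logCPM(1e6, 1e8, prior = 0.5) -
                  logCPM(2e6, 2e8, prior = 0.5)), 1e-6)
  expect_error(logCPM(5, 0), "positive")
})

test_that("exact test closed forms and enumeration oracle agree", {
  expect_equal(nbExactTest(0, 0, phi = 0.3), 1)
  expect_equal(nbExactTest(10, 0, phi = 0), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(nbExactTest(10, 0, phi = 0), binom.test(10, 10)$p.value,
               tolerance = 1e-12)
  expect_equal(nbExactTest(5, 5, phi = 0), 1)
  expect_error(nbExactTest(3, 3, phi = -1), "non-negative")
  for (phi in c(0, 0.2, 1)) {
    for (t in c(7, 30, 121)) {
      for (a in unique(c(0, 3, t %/% 2, t))) {
        expect_equal(nbExactTest(a, t - a, phi = phi),
                     oracle_exact_p(a, t - a, phi),
                     tolerance = 1e-10,
                     label = sprintf("p(a=%d, t=%d, phi=%g)", a, t, phi))
      }
    }
  }
})

test_that("dispersion is recovered from simulated counts", {
  set.seed(13)
  A <- matrix(rnbinom(4000, size = 1 / 0.2, mu = 60), ncol = 2)
  B <- matrix(rnbinom(4000, size = 1 / 0.2, mu = 60), ncol = 2)
  expect_lt(abs(estimateDispersion(A, B) - 0.2), 0.05)
  set.seed(14)
  P <- matrix(rpois(4000, 80), ncol = 2)
  Q <- matrix(rpois(4000, 80), ncol = 2)
  expect_lte(estimateDispersion(P, Q), 0.01)
  # genuinely differential rows must not inflate the estimate
  set.seed(16)
  mu_b <- rep(c(60, 480), times = c(1800, 200))
  A2 <- matrix(rnbinom(4000, size = 1 / 0.2, mu = 60), ncol = 2)
  B2 <- cbind(rnbinom(2000, size = 1 / 0.2, mu = mu_b),
              rnbinom(2000, size = 1 / 0.2, mu = mu_b))
  expect_lt(abs(estimateDispersion(A2, B2) - 0.2), 0.05)
  # single-sample groups fall back to the between-group split
  set.seed(17)
  expect_message(
    phi1 <- estimateDispersion(rnbinom(2000, size = 1 / 0.2, mu = 60),
                               rnbinom(2000, size = 1 / 0.2, mu = 60)),
    "between-group")
  expect_lt(abs(phi1 - 0.2), 0.05)
  expect_warning(phi <- suppressMessages(estimateDispersion(5, 7)),
                 "default")
  expect_equal(phi, 0.1)
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.03, 5)), rep(0.03, 5))
  expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(4)
  p <- runif(500)
  q <- bhAdjust(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(q >= p))
  perm <- sample(500)
  expect_equal(bhAdjust(p[perm]), q[perm], tolerance = 1e-12)
})

test_that("swapping control and condition negates logFC and keeps p", {
  fwd <- compareCondition(fx_rct(), c("c1", "c2"), c("d1", "d2"))
  bwd <- compareCondition(fx_rct(), c("d1", "d2"), c("c1", "c2"),
                          phi = attr(fwd, "phi"))
  expect_equal(bwd$logFC, -fwd$logFC)
  expect_equal(bwd$p_value, fwd$p_value)
  expect_equal(bwd$q_value, fwd$q_value)
})

test_that("designed knockout genes are detected as enriched gene rows", {
  rec <- fx_records()
  eff <- fx_effects()
  ko <- eff$gene_id[eff$effect_kind == "knockout_fitness"]
  hit <- rec$significant & rec$direction == "enriched" &
    rec$region == "gene" & rec$channel == "combined" &
    rec$gene_id %in% ko
  expect_gte(sum(hit), 9)
})

test_that("a null comparison stays quiet", {
  rec <- fx_null_records()
  expect_lte(mean(rec$significant), 0.05)
  expect_error(compareCondition(fx_rct(), c("c1", "nope"), "d1"), "unknown")
})

test_that("compareCondition is deterministic", {
  a <- compareCondition(fx_rct(), c("c1", "c2"), c("d1", "d2"))
  b <- compareCondition(fx_rct(), c("c1", "c2"), c("d1", "d2"))
  expect_identical(a, b)
})
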