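test_that("a fixed seed reproduces the library exactly", {
  eff <- fx_effects()
  a <- simulateLibrary(simConfig(seed = 42), effects = eff)
  b <- simulateLibrary(simConfig(seed = 42), effects = eff)
  expect_identical(readsFwd(a$profile), readsFwd(b$profile))
  expect_identical(readsRev(a$profile), readsRev(b$profile))
  expect_identical(a$truth$site_pos, b$truth$site_pos)
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
  pa <- applyCondition(a, "drug", 7)
  pb <- applyCondition(b, "drug", 7)
  expect_identical(readsFwd(pa), readsFwd(pb))
})

test_that("essential genes have zero interior insertions by construction", {
  sim <- fx_sim()
  ess <- sim$genes[sim$genes$essential]
  expect_equal(sum(sim$truth$genes$essential), 30L)
  ii <- insertionIndex(sim$profile, ess)
  expect_true(all(ii == 0))
  # and in every condition draw, since the site pool is fixed
  ii_drug <- insertionIndex(fx_profiles()$d1, ess)
  expect_true(all(ii_drug == 0))
})

test_that("unique-site count matches the binomial expectation", {
  sim <- fx_sim()
  permissive <- length(sim$profile) -
    sum(BiocGenerics::width(sim$genes)[sim$genes$essential])
  n_sites <- length(sim$truth$site_pos)
  expectation <- permissive / 6
  sigma <- sqrt(permissive * (1 / 6) * (5 / 6))
  expect_lt(abs(n_sites - expectation), 3 * sigma)
  occupied <- sum(readsFwd(sim$profile) + readsRev(sim$profile) > 0)
  expect_equal(occupied, n_sites)
})

test_that("degenerate limit: density 1, Poisson, mean 1 gives one read per base", {
  sim <- simulateLibrary(simConfig(genome_length = 3000, n_genes = 10,
                                   essential_fraction = 0.2,
                                   site_density = 1, mean_reads_per_site = 1,
                                   read_dispersion = 0, seed = 3))
  tot <- readsFwd(sim$profile) + readsRev(sim$profile)
  ess <- sim$genes[sim$genes$essential]
  interior <- unlist(lapply(seq_along(ess), function(i)
    BiocGenerics::start(ess)[i]:BiocGenerics::end(ess)[i]))
  expect_true(all(tot[interior] == 0))
  expect_true(all(tot[-interior] == 1))
})

test_that("a lethal knockout zeroes all interior reads in the condition", {
  eff <- data.frame(condition = "kill", gene_id = "gene0003",
                    effect_kind = "knockout_fitness", multiplier = 0)
  sim <- simulateLibrary(simConfig(genome_length = 6000, n_genes = 30,
                                   seed = 5), effects = eff)
  p <- applyCondition(sim, "kill", 9)
  g <- sim$genes[sim$genes$gene_id == "gene0003"]
  idx <- BiocGenerics::start(g):BiocGenerics::end(g)
  expect_true(all((readsFwd(p) + readsRev(p))[idx] == 0))
  expect_error(applyCondition(sim, "nonexistent", 1), "unknown condition")
})

test_that("flanking effects scale only the designed window and channel", {
  # plus-strand gene with an 8x upstream-promoter effect: over replicate
  # draws the forward-channel upstream mean is ~8x control, reverse unchanged
  cfg <- simConfig(genome_length = 6000, n_genes = 12, essential_fraction = 0,
                   seed = 21)
  sim <- simulateLibrary(cfg)
  st <- as.character(BiocGenerics::strand(sim$genes))
  gene <- sim$genes$gene_id[st == "+"][2]
  sim <- simulateLibrary(cfg, effects = data.frame(
    condition = "ind", gene_id = gene,
    effect_kind = "upstream_promoter", multiplier = 8))
  g <- sim$genes[sim$genes$gene_id == gene]
  win <- (BiocGenerics::start(g) - 198):(BiocGenerics::start(g) - 1)
  ctrl_f <- sum(readsFwd(sim$profile)[win])
  ctrl_r <- sum(readsRev(sim$profile)[win])
  reps <- vapply(1:200, function(s) {
    p <- applyCondition(sim, "ind", s)
    c(sum(readsFwd(p)[win]), sum(readsRev(p)[win]))
  }, numeric(2))
  expect_gt(mean(reps[1, ]) / ctrl_f, 7 * 0.9)
  expect_lt(mean(reps[1, ]) / ctrl_f, 9 * 1.1)
  expect_lt(abs(mean(reps[2, ]) / ctrl_r - 1), 0.25)
})

test_that("gene placement fails cleanly when the genome is too small", {
  expect_error(simulateLibrary(simConfig(genome_length = 1000, n_genes = 50)),
               "cannot be placed")
})

test_that("writeSimulation emits loadable plot, annotation, and truth", {
  dir <- withr::local_tempdir()
  sim <- simulateLibrary(simConfig(genome_length = 6000, n_genes = 30,
                                   seed = 8), effects = data.frame(
    condition = "c1", gene_id = "gene0002",
    effect_kind = "knockout_fitness", multiplier = 4))
  paths <- writeSimulation(sim, dir)
  p <- readPlot(paths[["plot"]])
  expect_equal(readsFwd(p), readsFwd(sim$profile))
  g <- readAnnotation(paths[["gff"]])
  expect_equal(g$gene_id, sim$genes$gene_id)
  tr <- read.delim(paths[["truth"]])
  expect_equal(nrow(tr), 30L)
  expect_equal(tr$multiplier[tr$gene_id == "gene0002"], 4)
})
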