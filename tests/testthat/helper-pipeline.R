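pipeline_inputs <- function(dir) {
  eff <- data.frame(condition = "drug",
                    gene_id = c("gene0010", "gene0020", "gene0030"),
                    effect_kind = c("knockout_fitness", "upstream_promoter",
                                    "downstream_antisense"),
                    multiplier = 8)
  sim <- simulateLibrary(simConfig(genome_length = 12000, n_genes = 60,
                                   seed = 77), effects = eff)
  paths <- list(gff = file.path(dir, "genes.gff3"))
  writeAnnotation(sim$genes, paths$gff, seqlength = length(sim$profile))
  for (nm in c("c1", "c2")) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".plot"))
    writePlot(applyCondition(sim, "control", 500 + match(nm, c("c1", "c2"))),
              paths[[nm]])
  }
  for (nm in c("d1", "d2")) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".plot"))
    writePlot(applyCondition(sim, "drug", 600 + match(nm, c("d1", "d2"))),
              paths[[nm]])
  }
  growth <- rbind(
    data.frame(strain = "wt", plate = "P1",
               concentration = rep(c(0, 0.015, 0.125), each = 5),
               time_h = rep(0:4, 3),
               od = 0.1 + rep(c(0.5, 0.3, 0.2), each = 5) * rep(0:4, 3)),
    data.frame(strain = "mut", plate = "P1",
               concentration = rep(c(0, 0.015, 0.125), each = 5),
               time_h = rep(0:4, 3),
               od = 0.1 + rep(c(0.5, 0.4, 0.35), each = 5) * rep(0:4, 3)))
  paths$growth <- file.path(dir, "growth.tsv")
  write.table(growth, paths$growth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

pipeline_config <- function(paths, outdir) {
  runConfig(gff = paths$gff,
            controls = c(ctrlA = paths$c1, ctrlB = paths$c2),
            conditions = list(drug = c(paths$d1, paths$d2)),
            outdir = outdir, growth = paths$growth, parent = "wt",
            seed = 99)
}
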