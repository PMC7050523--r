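# FNV-1a hash of the serialized config; stamps outputs for provenance
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); h is kept as a double mod 2^32
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

write_stamped_tsv <- function(df, path, stamp) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(stamp, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' @param gff GFF3 annotation path.
#' @param controls named character vector of control plot files.
#' @param conditions named list; each element a character vector of plot
#'   files for one condition.
#' @param outdir output directory.
#' @param growth optional growth-curve TSV (see [readGrowthCurves()]).
#' @param parent parent strain for growth summaries.
#' @param window flanking window in bp (default 198).
#' @param q_cut,lfc_cut,lcpm_cut significance cutoffs (defaults 0.05, 1, 8).
#' @param prior prior count (default 0.5).
#' @param phi optional common dispersion override.
#' @param log_odds_cut essentiality log-odds threshold (default 2).
#' @param seed seed recorded in output headers (the comparison pipeline
#'   itself is deterministic).
#' @return a `RunConfig` list.
#' @export
runConfig <- function(gff, controls, conditions, outdir,
                      growth = NULL, parent = NULL,
                      window = 198L, q_cut = 0.05, lfc_cut = 1,
                      lcpm_cut = 8, prior = 0.5, phi = NULL,
                      log_odds_cut = 2, seed = 1L) {
  cfg <- list(gff = gff, controls = controls, conditions = conditions,
              outdir = outdir, growth = growth, parent = parent,
              window = as.integer(window), q_cut = q_cut,
              lfc_cut = lfc_cut, lcpm_cut = lcpm_cut, prior = prior,
              phi = phi, log_odds_cut = log_odds_cut,
              seed = as.integer(seed))
  stopifnot(cfg$window > 0, cfg$q_cut > 0, cfg$lfc_cut > 0,
            cfg$prior > 0, length(cfg$controls) >= 1,
            length(cfg$conditions) >= 1)
  if (is.null(names(cfg$conditions)) || anyDuplicated(names(cfg$conditions)))
    stop("conditions must be uniquely named")
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [runConfig()]'s arguments; missing optional fields
#' take the defaults. Round-trips losslessly through [yaml::write_yaml].
#'
#' @param path YAML file.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(runConfig)))]
  if (!is.null(args$controls)) args$controls <- unlist(args$controls)
  do.call(runConfig, args)
}

#' Run the full analysis pipeline
#'
#' Wires the stages in dependency order: read annotation and plot files,
#' call essentiality on the first control sample, build the region count
#' table, compare every condition against the controls, classify effects,
#' and aggregate into the gene-by-condition matrix and bipartite network;
#' growth-curve scoring runs when curves are supplied. All inputs are
#' validated before any stage runs, outputs are staged in a temporary
#' directory and only moved into \code{outdir} on success, and every TSV
#' carries a header comment with the package version, a config hash, and
#' the seed, so a fixed configuration reproduces outputs byte for byte.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return Invisibly, a named vector of output paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  inputs <- c(config$gff, unlist(config$controls),
              unlist(config$conditions), config$growth)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))

  hashed <- unclass(config)
  hashed$outdir <- NULL  # the destination does not alter the analysis
  stamp <- sprintf("# tnxpress %s; config %s; seed %d",
                   as.character(utils::packageVersion("tnxpress")),
                   config_hash(hashed), config$seed)
  stage <- tempfile("tnxpress_run_")
  dir.create(stage)
  out <- character(0)
  put <- function(df, name) {
    p <- file.path(stage, name)
    write_stamped_tsv(df, p, stamp)
    out[[name]] <<- p
  }

  genes <- readAnnotation(config$gff)
  ctrl_names <- if (is.null(names(config$controls)))
    paste0("control_", seq_along(config$controls)) else names(config$controls)
  profiles <- stats::setNames(
    lapply(config$controls, readPlot), ctrl_names)
  cond_samples <- list()
  for (cond in names(config$conditions)) {
    files <- config$conditions[[cond]]
    nm <- paste0(cond, "_", seq_along(files))
    for (k in seq_along(files)) profiles[[nm[k]]] <- readPlot(files[k])
    cond_samples[[cond]] <- nm
  }

  ess <- callEssentiality(profiles[[1L]], genes,
                          log_odds_cut = config$log_odds_cut)
  put(ess, "essentiality.tsv")

  rct <- regionCountTable(profiles, genes, window = config$window)
  records <- list()
  calls <- list()
  for (cond in names(config$conditions)) {
    rec <- compareCondition(rct, controls = ctrl_names,
                            conditions = cond_samples[[cond]],
                            q_cut = config$q_cut, lfc_cut = config$lfc_cut,
                            lcpm_cut = config$lcpm_cut,
                            prior = config$prior, phi = config$phi)
    records[[cond]] <- rec
    put(rec, paste0("compare_", cond, ".tsv"))
    cl <- classifyEffects(rec, genes, condition = cond)
    calls[[cond]] <- cl
    put(cl, paste0("effects_", cond, ".tsv"))
  }

  m <- buildMatrix(records)
  put(data.frame(gene_id = rownames(m), m, check.names = FALSE),
      "matrix.tsv")
  net <- buildNetwork(calls)
  gml <- file.path(stage, "network.graphml")
  edg <- file.path(stage, "network_edges.tsv")
  exportNetwork(net, gml, edg)
  out[["network.graphml"]] <- gml
  out[["network_edges.tsv"]] <- edg

  if (!is.null(config$growth)) {
    curves <- readGrowthCurves(config$growth)
    fr <- fitnessRatios(curves)
    fr$ratio_shifted <- shiftRatios(fr$ratio)
    put(fr, "fitness_ratios.tsv")
    if (!is.null(config$parent))
      put(compareToParent(fr, config$parent), "parent_comparison.tsv")
  }

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  final <- character(0)
  for (name in names(out)) {
    dest <- file.path(config$outdir, name)
    file.copy(out[[name]], dest, overwrite = TRUE)
    final[[name]] <- dest
  }
  unlink(stage, recursive = TRUE)
  invisible(final)
}
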