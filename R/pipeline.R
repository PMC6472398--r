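## End-to-end runs driven by one structured configuration: detection
## (profiles -> per-gene offsets -> offset table), synthetic validation
## (simulate -> detect -> aggregate -> compare), and pause analysis.
## Every run writes a machine-readable manifest next to its outputs and
## derives stage seeds from one master seed.

#' Read a run configuration
#'
#' YAML file with any of: `profiles`, `genes` (input TSV paths), `out_dir`,
#' `size_min`, `size_max`, `anchor`, `thresholds` (named list for
#' [selectionThresholds()]), `bootstrap`, `seed`, and the simulation block
#' (`n_genes`, `length_min`, `length_max`, `lam`, `mode_size`,
#' `mode_frame`, `scheme`), and the pause block (`fasta`, `motifs`,
#' `n_perm`).  Missing fields fall back to package defaults.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

runDefaults <- function(config) {
  config$size_min <- config$size_min %||% 20L
  config$size_max <- config$size_max %||% 35L
  config$anchor <- config$anchor %||% "five_prime"
  config$bootstrap <- config$bootstrap %||% 1000L
  config$seed <- config$seed %||% 1L
  config$thresholds <- if (is.null(config$thresholds)) selectionThresholds()
                       else do.call(selectionThresholds, config$thresholds)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeManifest <- function(outDir, stage, config, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("riboAsite")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[!vapply(config, is.function, logical(1)) &
                    !vapply(config, inherits, logical(1),
                            "SelectionThresholds")],
    outputs = outputs)
  path <- file.path(outDir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run offset detection end to end
#'
#' Reads a gene table and a profile table, runs [detectOffsets()] and
#' [aggregateOffsets()], and writes the per-gene results TSV, the wide
#' offset table with its diagnostics TSV, and a JSON manifest.
#'
#' @param config list (or path to a YAML file) with at least `profiles`,
#'   `genes` and `out_dir`.
#' @return invisibly, a list with the `offsets` [OffsetTable-class] and
#'   the per-gene `results` data.frame.
#' @export
runDetect <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- runDefaults(config)
  for (p in c(config$profiles, config$genes))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- readGeneTable(config$genes)
  profiles <- readProfileTable(config$profiles, genes,
                               anchor = config$anchor)
  sizeRange <- config$size_min:config$size_max
  results <- detectOffsets(profiles, config$thresholds, sizeRange)
  offsets <- aggregateOffsets(results, config$thresholds, sizeRange,
                              B = config$bootstrap,
                              seed = deriveSeed(config$seed, "bootstrap"))
  resPath <- file.path(config$out_dir, "gene_offsets.tsv")
  utils::write.table(results, resPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  offPath <- file.path(config$out_dir, "offset_table.tsv")
  diagPath <- file.path(config$out_dir, "offset_diagnostics.tsv")
  writeOffsetTable(offsets, offPath, diagnosticsPath = diagPath)
  writeManifest(config$out_dir, "detect", config,
                list(gene_offsets = resPath, offset_table = offPath,
                     diagnostics = diagPath))
  invisible(list(offsets = offsets, results = results))
}

#' Run the synthetic validation pipeline
#'
#' Simulates an artificial Ribo-Seq dataset with a known ground-truth
#' offset scheme, detects and aggregates offsets, and compares the
#' recovered table with the truth.  Writes the simulated profile table,
#' the truth and recovered offset tables, the per-combination match report
#' and a manifest.
#'
#' @param config list (or YAML path) with `out_dir` and optionally the
#'   simulation block (see [readRunConfig()]).
#' @return invisibly, the [compareOffsetTables()] result.
#' @export
runValidateSynthetic <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- runDefaults(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateRiboseq(
    nGenes = config$n_genes %||% 300L,
    lengthRange = c(config$length_min %||% 150L, config$length_max %||% 500L),
    lam = config$lam %||% 8,
    modeSF = c(config$mode_size %||% 28L, config$mode_frame %||% 0L),
    scheme = config$scheme %||% "const15",
    seed = deriveSeed(config$seed, "simulate"))
  sizeRange <- config$size_min:config$size_max
  results <- detectOffsets(sim$profiles, config$thresholds, sizeRange)
  recovered <- aggregateOffsets(results, config$thresholds, sizeRange,
                                B = config$bootstrap,
                                seed = deriveSeed(config$seed, "bootstrap"))
  cmp <- compareOffsetTables(sim$truth, recovered)
  profPath <- file.path(config$out_dir, "sim_profiles.tsv")
  writeProfileTable(sim$profiles, profPath)
  genePath <- file.path(config$out_dir, "sim_genes.tsv")
  writeGeneTable(sim$genes, genePath)
  truthPath <- file.path(config$out_dir, "truth_offsets.tsv")
  writeOffsetTable(sim$truth, truthPath)
  recPath <- file.path(config$out_dir, "recovered_offsets.tsv")
  writeOffsetTable(recovered, recPath)
  repPath <- file.path(config$out_dir, "recovery_report.tsv")
  utils::write.table(cmp$report, repPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeManifest(config$out_dir, "validate", config,
                list(profiles = profPath, genes = genePath,
                     truth = truthPath, recovered = recPath,
                     report = repPath,
                     fraction_all = cmp$fraction_all,
                     fraction_covered = cmp$fraction_covered))
  invisible(cmp)
}

#' Run the pause-motif analysis
#'
#' Builds A-site profiles from a profile table and an offset table,
#' normalizes them, and writes the PPX/XPP pause-score tables with
#' permutation p-values.
#'
#' @param config list (or YAML path) with `profiles`, `genes` (gene table
#'   with CDS sequences), `offsets` (wide offset table TSV), `out_dir`,
#'   and optionally `motifs` (default c("PPX", "XPP")) and `n_perm`.
#' @return invisibly, a named list of pause-score data.frames.
#' @export
runPause <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- runDefaults(config)
  if (!is.null(config$n_perm) && config$n_perm < 1)
    stop("n_perm must be a positive integer")
  for (p in c(config$profiles, config$genes, config$offsets))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- readGeneTable(config$genes)
  profiles <- readProfileTable(config$profiles, genes)
  offsets <- readOffsetTable(config$offsets)
  asites <- buildAsiteProfile(profiles, offsets,
                              dropFlagged = config$drop_flagged %||%
                                list(c(27L, 1L), c(27L, 2L)))
  dens <- normalizedDensity(asites)
  motifs <- config$motifs %||% c("PPX", "XPP")
  outputs <- list()
  tables <- list()
  for (m in motifs) {
    tab <- pauseScoreTable(genes, dens, pattern = m,
                           nPerm = config$n_perm %||% 10000L,
                           seed = deriveSeed(config$seed, m))
    p <- file.path(config$out_dir, paste0("pause_", tolower(m), ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[m]] <- p
    tables[[m]] <- tab
  }
  writeManifest(config$out_dir, "pause", config, outputs)
  invisible(tables)
}
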