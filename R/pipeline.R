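#' Pipeline configuration
#'
#' Bundles every tunable threshold of the census pipeline with its
#' default: the fold-acceptance Z threshold (6, the score's standard
#' deviations above the shuffle-null mean), the minimum hydrophobic
#' fraction over the checklist positions (2/3), the Sgb length cutoff
#' (260 residues), the minimum C-terminal extension of a sensor chimera
#' (100), the N-terminal extension threshold for the signal-peptide flag
#' (25), the normal flavohemoglobin length range (380-420), the number of
#' shuffle replicates for the null (200), the number of bootstrap
#' replicates (1000), and the master seed.
#'
#' @param zThreshold Fold-acceptance Z threshold.
#' @param hydroThreshold Minimum hydrophobic checklist fraction.
#' @param sgbMaxLength Sgb length cutoff (residues).
#' @param chimeraMinExt Sensor-chimera C-terminal extension minimum.
#' @param extMin N-terminal extension threshold for the signal flag.
#' @param normalRange Normal FHb length range.
#' @param nShuffles Shuffle replicates per Z-score.
#' @param bootstrapReps Bootstrap replicates.
#' @param seed Master seed.
#' @return A list with class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(zThreshold = 6, hydroThreshold = 2/3,
                           sgbMaxLength = 260L, chimeraMinExt = 100L,
                           extMin = 25L, normalRange = c(380L, 420L),
                           nShuffles = 200L, bootstrapReps = 1000L,
                           seed = 1L) {
  stopifnot(zThreshold > 0, hydroThreshold > 0, sgbMaxLength > 0,
            chimeraMinExt > 0, extMin > 0, all(normalRange > 0),
            nShuffles >= 30, bootstrapReps >= 1)
  structure(list(zThreshold = zThreshold,
                 hydroThreshold = hydroThreshold,
                 sgbMaxLength = as.integer(sgbMaxLength),
                 chimeraMinExt = as.integer(chimeraMinExt),
                 extMin = as.integer(extMin),
                 normalRange = as.integer(normalRange),
                 nShuffles = as.integer(nShuffles),
                 bootstrapReps = as.integer(bootstrapReps),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full census pipeline
#'
#' Executes detect (fold validation) -> classify (architecture) -> trim
#' (globin-domain FASTA) -> census on a proteome FASTA with a taxonomy
#' sidecar, and — when alignment ensembles are supplied — overlap scoring
#' of each ensemble followed by a Poisson-corrected NJ tree with
#' bootstrap supports for the winning alignment.  Every stage is a pure
#' function of (inputs, config, seed); a manifest records the
#' configuration, the seed, and MD5 digests of all inputs and outputs.
#'
#' @param fasta Path to the proteome FASTA.
#' @param taxonomyTsv Path to the per-protein taxonomy sidecar (`id`,
#'   `genome`, `taxon`, `phylum`).
#' @param outDir Output directory (created if needed).
#' @param config A [pipelineConfig()].
#' @param genomesTsv Optional genome roster TSV (`genome`, `taxon`,
#'   `phylum`) so that globin-free genomes enter the census.
#' @param msaFiles Optional named character vector of aligned-FASTA paths
#'   forming one ensemble of alternative alignments of the same
#'   sequences.
#' @param templates Named list of packaged templates.
#' @return Invisibly, a list with the per-stage results (`detections`,
#'   `calls`, `census`, `summary`, and when alignments were supplied,
#'   `msaScores` and `bootstrap`).
#' @export
runPipeline <- function(fasta, taxonomyTsv, outDir,
                        config = pipelineConfig(), genomesTsv = NULL,
                        msaFiles = NULL, templates = globinTemplates()) {
  for (f in c(fasta, taxonomyTsv, genomesTsv, msaFiles))
    if (!file.exists(f))
      stop("input file does not exist: ", f)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  proteins <- asProteinVector(fasta)
  taxonomy <- utils::read.delim(taxonomyTsv, stringsAsFactors = FALSE)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))

  detections <- stage("detect",
    detectGlobins(proteins, familyTemplates(templates),
                  zThreshold = config$zThreshold,
                  hydroThreshold = config$hydroThreshold,
                  nShuffles = config$nShuffles, seed = config$seed))
  utils::write.table(detections, file.path(outDir, "detections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- stage("classify",
    classifyProteins(proteins, detections, templates,
                     sgbMaxLength = config$sgbMaxLength,
                     chimeraMinExt = config$chimeraMinExt,
                     extMin = config$extMin,
                     normalRange = config$normalRange))
  utils::write.table(calls, file.path(outDir, "architecture.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage("trim", {
    acc <- detections[detections$accepted & !is.na(detections$start), ]
    trimmed <- substr(proteins[acc$id], acc$start, acc$end)
    names(trimmed) <- acc$id
    writeFastaAA(trimmed, file.path(outDir, "trimmed_domains.fasta"))
  })

  genomes <- if (!is.null(genomesTsv))
    utils::read.delim(genomesTsv, stringsAsFactors = FALSE) else NULL
  census <- stage("census", censusFromCalls(calls, taxonomy, genomes))
  writeCensus(census, file.path(outDir, "census.tsv"))
  summary <- summarizeCensus(census, groupBy = "phylum")
  utils::write.table(summary, file.path(outDir, "census_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  msaScores <- NULL
  boot <- NULL
  if (!is.null(msaFiles) && length(msaFiles) >= 2L) {
    ensemble <- lapply(msaFiles, readMsa)
    if (is.null(names(ensemble)))
      names(ensemble) <- basename(msaFiles)
    msaScores <- stage("msa-score", selectBest(ensemble))
    utils::write.table(
      data.frame(alignment = names(msaScores$means),
                 mean_overlap = unname(msaScores$means)),
      file.path(outDir, "msa_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    boot <- stage("nj",
      bootstrapSupports(ensemble[[msaScores$winner]],
                        nReps = config$bootstrapReps,
                        seed = config$seed))
    newickWrite(boot$tree, file.path(outDir, "nj_tree.nwk"))
  }

  writeManifest(outDir, config,
                inputs = c(fasta = fasta, taxonomy = taxonomyTsv,
                           if (!is.null(genomesTsv))
                             c(genomes = genomesTsv),
                           msaFiles))
  invisible(list(detections = detections, calls = calls, census = census,
                 summary = summary, msaScores = msaScores,
                 bootstrap = boot))
}

writeManifest <- function(outDir, config, inputs) {
  outputs <- setdiff(list.files(outDir, full.names = TRUE),
                     file.path(outDir, "manifest.tsv"))
  digest <- function(paths) unname(tools::md5sum(paths))
  man <- rbind(
    data.frame(key = paste0("config.", names(config)),
               value = vapply(config, function(v)
                 paste(v, collapse = ","), ""),
               stringsAsFactors = FALSE),
    data.frame(key = paste0("input.", basename(inputs)),
               value = digest(inputs), stringsAsFactors = FALSE),
    data.frame(key = paste0("output.", basename(outputs)),
               value = digest(outputs), stringsAsFactors = FALSE))
  utils::write.table(man, file.path(outDir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}
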