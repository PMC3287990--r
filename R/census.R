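#' Load a globin census table
#'
#' A census table has one row per genome: a species identifier, taxonomy
#' rank columns (`phylum`, and optionally `subphylum` and `class`), one
#' non-negative count column per architecture label, and an optional
#' `genome_complete` flag.
#'
#' @param file Path to a tab-separated census table with a header row.
#' @return A validated `data.frame` (zero rows, with a warning, for an
#'   empty file).
#' @export
loadCensus <- function(file) {
  rows <- utils::read.delim(file, stringsAsFactors = FALSE, sep = "\t")
  if (nrow(rows) == 0L) {
    warning("census table is empty")
    return(rows)
  }
  validateCensus(rows)
}

validateCensus <- function(rows) {
  required <- c("species", "phylum")
  missing <- setdiff(required, names(rows))
  if (length(missing))
    stop("census table lacks required column(s): ",
         paste(missing, collapse = ", "))
  counts <- intersect(names(rows), architectureLabels())
  if (length(counts) == 0L)
    stop("census table carries no architecture count columns")
  unknown <- setdiff(names(rows),
                     c(required, "subphylum", "class", "genome_complete",
                       architectureLabels()))
  if (length(unknown))
    stop("unknown column(s) in census table: ",
         paste(unknown, collapse = ", "))
  for (cc in counts) {
    if (any(is.na(rows[[cc]])) || any(rows[[cc]] < 0))
      stop("negative or missing count in column ", cc)
  }
  rows
}

censusCountColumns <- function(rows) {
  intersect(names(rows), setdiff(architectureLabels(), "NonGlobin"))
}

#' Summarize a census by taxon
#'
#' Groups genomes by a taxonomy rank and reports, per group, the total
#' number of genomes, the number with at least one globin (any label
#' count > 0), their ratio, and per-label genome totals.  Rounded
#' percentages are presentation only; the raw ratio is always retained.
#'
#' @param rows Census `data.frame` (see [loadCensus()]).
#' @param groupBy Rank column to group by (`"phylum"`, `"subphylum"`,
#'   ...) or `"overall"` for a single summary row.
#' @return A `data.frame` with columns `taxon`, `genomes_total`,
#'   `genomes_with_globins`, `ratio`, `percent` and one total column per
#'   label.  Groups with zero genomes keep an `NA` ratio rather than
#'   being dropped.
#' @export
summarizeCensus <- function(rows, groupBy = "phylum") {
  if (nrow(rows) == 0L)
    stop("cannot summarize an empty census")
  counts <- censusCountColumns(rows)
  grp <- if (identical(groupBy, "overall"))
    factor(rep("overall", nrow(rows))) else factor(rows[[groupBy]])
  hasGlobin <- rowSums(rows[, counts, drop = FALSE]) > 0
  out <- lapply(levels(grp), function(g) {
    sel <- grp == g
    tot <- sum(sel)
    with <- sum(hasGlobin[sel])
    labelTotals <- colSums(rows[sel, counts, drop = FALSE])
    df <- data.frame(taxon = g, genomes_total = tot,
                     genomes_with_globins = with,
                     ratio = if (tot > 0) with / tot else NA_real_,
                     stringsAsFactors = FALSE)
    df$percent <- round(100 * df$ratio)
    cbind(df, as.data.frame(as.list(labelTotals)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-taxon report of genomes carrying incomplete flavohemoglobins
#'
#' @param rows Census `data.frame`.
#' @param groupBy Rank column to group by (default `"subphylum"`).
#' @return `data.frame` with `taxon`, `genomes_total` and
#'   `genomes_with_incomplete_fhb` (genomes with at least one
#'   `FHb_incomplete`).
#' @export
incompleteFhbReport <- function(rows, groupBy = "subphylum") {
  if (!"FHb_incomplete" %in% names(rows))
    rows$FHb_incomplete <- 0L
  grp <- factor(rows[[groupBy]])
  out <- data.frame(
    taxon = levels(grp),
    genomes_total = as.integer(table(grp)),
    genomes_with_incomplete_fhb = as.integer(
      tapply(rows$FHb_incomplete > 0, grp, sum)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a census table from architecture calls
#'
#' Aggregates per-protein architecture calls into one row per genome,
#' counting proteins per label.  Genomes listed in the roster but
#' carrying no classified proteins appear with zero counts.
#'
#' @param calls Architecture call `data.frame` from [classifyProteins()].
#' @param proteinMeta `data.frame` mapping `id` to `genome` plus taxonomy
#'   columns (`taxon`/`subphylum`, `phylum`).
#' @param genomes Optional roster `data.frame` with `genome` and taxonomy
#'   columns, to include globin-free genomes.
#' @return A census `data.frame` as accepted by [summarizeCensus()].
#' @export
censusFromCalls <- function(calls, proteinMeta, genomes = NULL) {
  merged <- merge(calls, proteinMeta, by = "id", all.x = TRUE)
  if (is.null(genomes)) {
    genomes <- unique(proteinMeta[, setdiff(names(proteinMeta), "id"),
                                  drop = FALSE])
  }
  subCol <- intersect(c("subphylum", "taxon"), names(genomes))[1L]
  labels <- setdiff(architectureLabels(), "NonGlobin")
  rows <- lapply(seq_len(nrow(genomes)), function(g) {
    sel <- merged$genome == genomes$genome[g]
    cnt <- vapply(labels, function(lab)
      sum(merged$label[sel] == lab, na.rm = TRUE), 0L)
    df <- data.frame(species = genomes$genome[g],
                     phylum = genomes$phylum[g],
                     subphylum = genomes[[subCol]][g],
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(as.list(cnt)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged census fixture configuration
#'
#' Per-stratum genome totals and globin content emulating a published
#' fungal census at its printed totals: 165 genomes, 136 with globins,
#' 117 Ascomycota (with 21 of 29 Saccharomycotina genomes carrying
#' incomplete flavohemoglobins), 33 Basidiomycota, and two genomes with
#' T1 globins.  Species names are synthetic placeholders.
#'
#' @return A `data.frame` with one row per stratum: `phylum`,
#'   `subphylum`, `n_genomes`, `n_with_globins`, `n_incomplete_fhb`,
#'   `n_t1`, `typical_label` (the label planted in with-globin genomes).
#' @export
defaultCensusConfig <- function() {
  data.frame(
    phylum = c("Ascomycota", "Ascomycota", "Ascomycota",
               "Basidiomycota", "Basidiomycota", "Basidiomycota",
               "Microsporidia", "Glomeromycota",
               "Fungi_incertae_sedis", "Blastocladiomycota",
               "Chytridiomycota"),
    subphylum = c("Saccharomycotina", "Pezizomycotina",
                  "Taphrinomycotina", "Agaricomycotina",
                  "Pucciniomycotina", "Ustilaginomycotina",
                  "Microsporidia", "Glomeromycota", "Mucoromycotina",
                  "Blastocladiomycota", "Chytridiomycota"),
    n_genomes = c(29L, 80L, 8L, 20L, 6L, 7L, 7L, 1L, 3L, 2L, 2L),
    n_with_globins = c(29L, 75L, 5L, 14L, 1L, 5L, 0L, 0L, 3L, 2L, 2L),
    n_incomplete_fhb = c(21L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    n_t1 = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L),
    typical_label = c("FHb", "FHb", "FHb", "FHb", "Sgb", "FHb",
                      "FHb", "FHb", "Fgb", "Sgb", "Sgb"),
    stringsAsFactors = FALSE)
}

#' Build the packaged census fixture
#'
#' Expands a stratum configuration into one census row per genome.
#' Within each stratum, the first `n_with_globins` genomes receive the
#' stratum's typical label, the first `n_incomplete_fhb` of those
#' additionally carry an incomplete flavohemoglobin, and the first
#' `n_t1` carry a T1 globin (as a chimera in the Blastocladiomycota-like
#' stratum, mirroring a T globin domain embedded in a large chimeric
#' protein, and as a single-domain T1 otherwise).
#'
#' @param config Stratum `data.frame` (default [defaultCensusConfig()]).
#' @return A census `data.frame` as accepted by [summarizeCensus()].
#' @export
buildCensusFixture <- function(config = defaultCensusConfig()) {
  if (any(config$n_with_globins > config$n_genomes))
    stop("with-globin count exceeds stratum genome total")
  if (nrow(config) == 0L || sum(config$n_genomes) == 0L) {
    out <- data.frame(species = character(), phylum = character(),
                      subphylum = character(),
                      genome_complete = logical(),
                      stringsAsFactors = FALSE)
    for (lab in setdiff(architectureLabels(), "NonGlobin"))
      out[[lab]] <- integer()
    return(out)
  }
  labels <- setdiff(architectureLabels(), "NonGlobin")
  rows <- list()
  for (s in seq_len(nrow(config))) {
    n <- config$n_genomes[s]
    if (n == 0L) next
    for (g in seq_len(n)) {
      cnt <- stats::setNames(integer(length(labels)), labels)
      if (g <= config$n_with_globins[s])
        cnt[[config$typical_label[s]]] <- 1L
      if (g <= config$n_incomplete_fhb[s])
        cnt[["FHb_incomplete"]] <- 1L
      if (g <= config$n_t1[s]) {
        if (config$subphylum[s] == "Blastocladiomycota")
          cnt[["T1Chimera"]] <- 1L
        else cnt[["T1"]] <- 1L
      }
      df <- data.frame(
        species = sprintf("%s_sp%02d", config$subphylum[s], g),
        phylum = config$phylum[s], subphylum = config$subphylum[s],
        genome_complete = g %% 2L == 0L,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- cbind(df, as.data.frame(as.list(cnt)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a census table
#'
#' @param rows Census `data.frame`.
#' @param file Output path (tab-separated, header row).
#' @return `file`, invisibly.
#' @export
writeCensus <- function(rows, file) {
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
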