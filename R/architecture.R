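#' ArchitectureCall: a protein's domain architecture classification
#'
#' Produced by [classifyArchitecture()].  The label is one of `FHb`,
#' `FHb_incomplete`, `Fgb`, `Sgb`, `SensorChimera`, `T1`, `T1Chimera`,
#' `NonGlobin`.
#'
#' @slot label Architecture class label.
#' @slot hits Ordered `data.frame` of domain hits (`kind`, `start`, `end`,
#'   `score`).
#' @slot nTermExt Residues before the first (non-signal) domain hit.
#' @slot cTermExt Residues after the last domain hit.
#' @slot signalPeptide `TRUE` when the N-terminal extension exceeds the
#'   threshold and a signal peptide is detected in it.
#' @slot normalLength `TRUE` for FHbs within the normal length range
#'   (380-420 residues by default).
#' @slot length Protein length in residues.
#' @aliases ArchitectureCall
#' @export
setClass("ArchitectureCall",
         representation(label = "character",
                        hits = "data.frame",
                        nTermExt = "integer",
                        cTermExt = "integer",
                        signalPeptide = "logical",
                        normalLength = "logical",
                        length = "integer"))

setValidity("ArchitectureCall", function(object) {
  msg <- character()
  if (!object@label %in% architectureLabels())
    msg <- c(msg, "unknown architecture label")
  if (object@nTermExt < 0L || object@cTermExt < 0L)
    msg <- c(msg, "extensions must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ArchitectureCall", function(object) {
  cat("ArchitectureCall: ", object@label,
      " (", object@length, " aa, N-ext ", object@nTermExt,
      ", C-ext ", object@cTermExt, ")\n", sep = "")
  if (nrow(object@hits))
    cat("  hits: ", paste0(object@hits$kind, ":", object@hits$start, "-",
                           object@hits$end, collapse = ", "), "\n", sep = "")
})

#' @describeIn classifyArchitecture Label accessor.
#' @param x An `ArchitectureCall`.
#' @export
callLabel <- function(x) x@label

## Per-kind local-alignment score thresholds for the reductase moieties,
## calibrated so that random 400-aa sequences exceed them in well under 5%
## of cases (random local scores top out near 52; true hits at 40%
## identity score >110).
.DOMAIN_SCORE_THRESHOLDS <- c(CQX2 = 60, CQX3 = 60)

#' Scan a protein for non-globin domains
#'
#' Finds FAD-binding (`CQX2`) and NAD(P)-binding (`CQX3`) reductase
#' moieties by local alignment against the packaged templates, leucine-rich
#' repeat regions by the 11-residue motif `LxxLxLxxN/CxL` (three or more
#' tandem matches merged into one hit), and a signal peptide by
#' [detectSignalPeptide()].  An externally supplied globin hit (from the
#' fold detector) can be included so that overlaps are resolved jointly;
#' overlapping hits are resolved greedily by score.
#'
#' @param protein Amino-acid string.
#' @param templates Named list of [DomainTemplate-class] objects containing
#'   at least `CQX2` and `CQX3`.
#' @param globinHit Optional list with `kind`, `start`, `end`, `score`
#'   describing an accepted globin domain.
#' @param thresholds Named numeric vector of per-kind score thresholds.
#' @return Ordered `data.frame` of hits (`kind`, `start`, `end`, `score`).
#' @export
scanDomains <- function(protein, templates = globinTemplates(),
                        globinHit = NULL,
                        thresholds = .DOMAIN_SCORE_THRESHOLDS) {
  checkProteinSequence(protein, "protein")
  sc <- alignmentScoring()
  hits <- list()
  for (kind in c("CQX2", "CQX3")) {
    tpl <- templates[[kind]]
    if (is.null(tpl)) next
    pa <- Biostrings::pairwiseAlignment(
      protein, templateSequence(tpl), substitutionMatrix = sc$matrix,
      gapOpening = sc$gapOpening, gapExtension = sc$gapExtension,
      type = "local")
    if (Biostrings::score(pa) >= thresholds[[kind]]) {
      rng <- Biostrings::pattern(pa)
      hits[[length(hits) + 1L]] <- data.frame(
        kind = kind, start = Biostrings::start(rng),
        end = Biostrings::end(rng), score = Biostrings::score(pa),
        stringsAsFactors = FALSE)
    }
  }
  lrr <- scanLrr(protein)
  if (!is.null(lrr)) hits[[length(hits) + 1L]] <- lrr
  sig <- detectSignalPeptide(protein)
  if (sig$detected)
    hits[[length(hits) + 1L]] <- data.frame(
      kind = "SIG", start = sig$span[1L], end = sig$span[2L],
      score = 0, stringsAsFactors = FALSE)
  if (!is.null(globinHit))
    hits[[length(hits) + 1L]] <- data.frame(
      kind = globinHit$kind, start = globinHit$start, end = globinHit$end,
      score = globinHit$score, stringsAsFactors = FALSE)
  if (length(hits) == 0L)
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  all <- do.call(rbind, hits)
  ## greedy overlap resolution by score
  all <- all[order(-all$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(all))
  for (i in seq_len(nrow(all))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (keep[j] && all$start[i] <= all$end[j] &&
          all$end[i] >= all$start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  all <- all[keep, , drop = FALSE]
  all[order(all$start), , drop = FALSE]
}

## Leucine-rich-repeat scan: >= 3 tandem matches of the 11-mer motif,
## merged into a single hit covering the repeats.
scanLrr <- function(protein, minRepeats = 3L) {
  m <- gregexpr("L..L.L..[NC].L", protein)[[1]]
  if (m[1L] == -1L) return(NULL)
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  ## group matches separated by at most a few residues (tandem repeats)
  grp <- cumsum(c(1L, as.integer(starts[-1L] - ends[-length(ends)] > 6L)))
  best <- NULL
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) >= minRepeats) {
      hit <- data.frame(kind = "LRR", start = starts[idx[1L]],
                        end = ends[idx[length(idx)]],
                        score = 10 * length(idx), stringsAsFactors = FALSE)
      if (is.null(best) || hit$score > best$score) best <- hit
    }
  }
  best
}

#' Heuristic signal-peptide detection
#'
#' Looks within the first 20 residues for a basic n-region (at least one
#' K or R among the first 5 residues) followed by a hydrophobic stretch of
#' at least 8 residues.
#'
#' @param sequence Amino-acid string.
#' @param hydrophobicSet Residues counted as hydrophobic.
#' @return List with `detected` (logical) and `span` (integer start/end of
#'   the putative signal region, `c(NA, NA)` when not detected).
#' @examples
#' detectSignalPeptide(paste0("MKK", strrep("L", 10), strrep("G", 50)))
#' @export
detectSignalPeptide <- function(sequence,
                                hydrophobicSet = hydrophobicResidues()) {
  v <- seqToChars(sequence)
  if (length(v) < 20L)
    return(list(detected = FALSE, span = c(NA_integer_, NA_integer_)))
  nregion <- any(v[1:5] %in% c("K", "R"))
  head20 <- v[1:20]
  hydro <- head20 %in% hydrophobicSet
  r <- rle(hydro)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  long <- which(r$values & r$lengths >= 8L)
  if (nregion && length(long)) {
    list(detected = TRUE, span = c(1L, runEnd[long[1L]]))
  } else {
    list(detected = FALSE, span = c(NA_integer_, NA_integer_))
  }
}

#' Measure N- and C-terminal extensions
#'
#' @param hits Non-empty ordered hit `data.frame` (see [scanDomains()]).
#' @param length Protein length.
#' @return Integer vector `c(nTermExt, cTermExt)`: residues before the
#'   first hit and after the last hit.
#' @export
measureExtensions <- function(hits, length) {
  if (is.null(hits) || nrow(hits) == 0L)
    stop("cannot measure extensions without hits")
  c(nTermExt = as.integer(min(hits$start)) - 1L,
    cTermExt = as.integer(length) - as.integer(max(hits$end)))
}

#' Classify a protein's globin architecture
#'
#' Applies the architecture rule table, in order: an F-family globin with
#' both reductase moieties is a flavohemoglobin (`FHb`); with `CQX2` but
#' not `CQX3` (the diagnostic absence) an incomplete flavohemoglobin
#' (`FHb_incomplete`); alone, a single-domain F globin (`Fgb`).  An
#' S-family globin with a C-terminal extension of at least
#' `chimeraMinExt` residues is a `SensorChimera`, otherwise an `Sgb`
#' (single-domain sensor globins are generally shorter than
#' `sgbMaxLength`).  A T-family globin alone is a `T1`; with any other
#' (non-signal) hit, a `T1Chimera`.  Without an accepted globin the
#' protein is a `NonGlobin`.  FHbs within `normalRange` are flagged
#' normal-length; an N-terminal extension exceeding `extMin` residues that
#' contains a detected signal peptide sets the signal-peptide flag.
#'
#' @param hits Ordered hit `data.frame` from [scanDomains()] (at most one
#'   globin hit; more is an error).
#' @param family Globin family of the accepted fold (`"F"`, `"S"`, `"T"`
#'   or `"none"`).
#' @param length Protein length in residues.
#' @param signal Logical: signal peptide detected at the N-terminus
#'   (see [detectSignalPeptide()]).
#' @param sgbMaxLength Sgb length cutoff (default 260, strict).
#' @param chimeraMinExt Minimum C-terminal extension for a sensor chimera
#'   (default 100).
#' @param extMin N-terminal extension threshold for the signal-peptide
#'   flag (default 25).
#' @param normalRange Normal FHb length range (default `c(380, 420)`).
#' @return An [ArchitectureCall-class].
#' @export
classifyArchitecture <- function(hits, family, length, signal = FALSE,
                                 sgbMaxLength = 260L, chimeraMinExt = 100L,
                                 extMin = 25L, normalRange = c(380L, 420L)) {
  globKinds <- c("GLB3", "GLB2", "SGB")
  nGlob <- sum(hits$kind %in% globKinds)
  if (nGlob > 1L)
    stop("more than one globin hit: multi-globin proteins are reported, ",
         "not classified")
  domHits <- hits[hits$kind != "SIG", , drop = FALSE]
  kinds <- domHits$kind
  ext <- if (nrow(domHits)) measureExtensions(domHits, length) else
    c(nTermExt = 0L, cTermExt = 0L)
  label <- if (!family %in% globinFamilies() || nGlob == 0L) {
    "NonGlobin"
  } else if (family == "F") {
    if (all(c("CQX2", "CQX3") %in% kinds)) "FHb"
    else if ("CQX2" %in% kinds) "FHb_incomplete"
    else "Fgb"
  } else if (family == "S") {
    if (ext[["cTermExt"]] >= chimeraMinExt) "SensorChimera" else "Sgb"
  } else {
    if (any(!kinds %in% globKinds)) "T1Chimera" else "T1"
  }
  normalLength <- label == "FHb" &&
    length >= normalRange[1L] && length <= normalRange[2L]
  signalPeptide <- isTRUE(signal) && ext[["nTermExt"]] > extMin
  new("ArchitectureCall", label = label, hits = hits,
      nTermExt = ext[["nTermExt"]], cTermExt = ext[["cTermExt"]],
      signalPeptide = signalPeptide, normalLength = normalLength,
      length = as.integer(length))
}

#' Classify all proteins of a detection run
#'
#' Joins fold-detector output with the domain scan and the rule table, one
#' protein at a time.
#'
#' @param proteins Proteins as for [detectGlobins()].
#' @param detections Detection `data.frame` from [detectGlobins()].
#' @param templates Named list of packaged templates.
#' @param ... Passed to [classifyArchitecture()].
#' @return A `data.frame` with one row per protein: `id`, `label`,
#'   `n_term_ext`, `c_term_ext`, `signal_peptide`, `normal_length`,
#'   `length`, `hits` (encoded `kind:start-end`).
#' @export
classifyProteins <- function(proteins, detections,
                             templates = globinTemplates(), ...) {
  seqs <- asProteinVector(proteins)
  rows <- lapply(seq_along(seqs), function(i) {
    id <- names(seqs)[i]
    det <- detections[detections$id == id, , drop = FALSE]
    fam <- if (nrow(det) && det$accepted[1L]) det$family[1L] else "none"
    globinHit <- NULL
    if (fam != "none" && !is.na(det$start[1L]))
      globinHit <- list(kind = det$template[1L], start = det$start[1L],
                        end = det$end[1L], score = det$z[1L] * 100)
    hits <- scanDomains(seqs[[i]], templates, globinHit = globinHit)
    sig <- detectSignalPeptide(seqs[[i]])
    call <- classifyArchitecture(hits, fam, nchar(seqs[[i]]),
                                 signal = sig$detected, ...)
    data.frame(id = id, label = callLabel(call),
               n_term_ext = call@nTermExt, c_term_ext = call@cTermExt,
               signal_peptide = call@signalPeptide,
               normal_length = call@normalLength,
               length = call@length,
               hits = paste0(hits$kind, ":", hits$start, "-", hits$end,
                             collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
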