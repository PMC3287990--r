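#' FoldAssessment: result of testing a query against the Mb-fold criteria
#'
#' Produced by [assessFold()] / [assignFamily()].  A query is accepted as a
#' globin when its alignment Z-score against a globin template exceeds the
#' threshold (default 6, the number of standard deviations above the mean
#' score obtained by chance), the residue anchored to the proximal F8
#' position is His, and the checklist positions are predominantly
#' hydrophobic.
#'
#' @slot rawScore Alignment score of query vs template.
#' @slot z Standardized score against the shuffle null.
#' @slot hydrophobicFraction Fraction of the family checklist's
#'   hydrophobicity positions that are mapped onto the query and carry a
#'   hydrophobic residue.
#' @slot f8Residue Query residue at the mapped F8 position (`NA` if
#'   unmapped).
#' @slot family Family of the template (`"F"`, `"S"`, `"T"`) or `"none"`.
#' @slot template Name of the template used.
#' @slot accepted Logical acceptance flag.
#' @slot positionMap Named integer vector mapping template coordinate
#'   labels to 1-based query indices (`NA` = unaligned).
#' @aliases FoldAssessment
#' @export
setClass("FoldAssessment",
         representation(rawScore = "numeric",
                        z = "numeric",
                        hydrophobicFraction = "numeric",
                        f8Residue = "character",
                        family = "character",
                        template = "character",
                        accepted = "logical",
                        positionMap = "integer"))

setValidity("FoldAssessment", function(object) {
  msg <- character()
  hf <- object@hydrophobicFraction
  if (length(hf) == 1L && !is.na(hf) && (hf < 0 || hf > 1))
    msg <- c(msg, "hydrophobicFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FoldAssessment", function(object) {
  cat("FoldAssessment vs ", object@template,
      " (family ", object@family, ")\n",
      "  raw score ", format(object@rawScore, digits = 5),
      ", z ", format(object@z, digits = 4),
      ", hydrophobic fraction ", format(object@hydrophobicFraction,
                                        digits = 3),
      ", F8 ", object@f8Residue, "\n",
      "  accepted: ", object@accepted, "\n", sep = "")
})

#' @describeIn assessFold Acceptance flag accessor.
#' @export
isAccepted <- function(x) x@accepted

#' @describeIn assessFold Z-score accessor.
#' @export
foldZ <- function(x) x@z

#' @describeIn assessFold Position-map accessor.
#' @export
positionMap <- function(x) x@positionMap

#' Anchor a query sequence to an annotated template
#'
#' Aligns the query to the template with a deterministic pairwise alignment
#' (BLOSUM62, affine gaps open 11 / extend 1, end gaps free so that domains
#' embedded in chimeric proteins anchor correctly) and transfers the
#' template's helix-coordinate labels onto the query.  Labels falling in
#' query gap columns, or outside the aligned region, map to `NA`
#' ("unaligned").
#'
#' @param query Amino-acid string (standard alphabet, `X` allowed).
#' @param template A [DomainTemplate-class].
#' @return A list with `map` (named integer vector, label -> 1-based query
#'   index or `NA`) and `score` (alignment raw score).
#' @examples
#' tpl <- globinTemplates()[["GLB3"]]
#' a <- anchorToTemplate(templateSequence(tpl), tpl)
#' identical(a$map, templateAnnotations(tpl))
#' @export
anchorToTemplate <- function(query, template) {
  checkProteinSequence(query, "query")
  sc <- alignmentScoring()
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = templateSequence(template),
    substitutionMatrix = sc$matrix, gapOpening = sc$gapOpening,
    gapExtension = sc$gapExtension, type = "overlap")
  qs <- seqToChars(Biostrings::alignedPattern(pa))
  ts <- seqToChars(Biostrings::alignedSubject(pa))
  qoff <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  toff <- Biostrings::start(Biostrings::subject(pa)) - 1L
  tmap <- rep(NA_integer_, nchar(templateSequence(template)))
  qi <- 0L; ti <- 0L
  for (k in seq_along(qs)) {
    qgap <- qs[k] == "-"
    tgap <- ts[k] == "-"
    if (!qgap) qi <- qi + 1L
    if (!tgap) ti <- ti + 1L
    if (!qgap && !tgap) tmap[toff + ti] <- qoff + qi
  }
  ann <- templateAnnotations(template)
  map <- tmap[ann]
  names(map) <- names(ann)
  list(map = map, score = Biostrings::score(pa))
}

#' Shuffle-null Z-score for a query/template alignment
#'
#' Standardizes the query-template alignment score against a null
#' distribution of scores obtained by aligning composition-preserving
#' (Fisher-Yates) shuffles of the query to the same template:
#' `z = (S - mean(null)) / sd(null)`.
#'
#' @param query Amino-acid string.
#' @param template A [DomainTemplate-class].
#' @param nShuffles Number of shuffled replicates (>= 30; default 200).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return The Z-score (single numeric).
#' @examples
#' tpl <- globinTemplates()[["GLB3"]]
#' foldZscore(templateSequence(tpl), tpl, nShuffles = 50, seed = 1) > 6
#' @export
foldZscore <- function(query, template, nShuffles = 200L, seed = NULL) {
  checkProteinSequence(query, "query")
  if (nShuffles < 30L)
    stop("nShuffles must be at least 30")
  sc <- alignmentScoring()
  tseq <- templateSequence(template)
  S <- Biostrings::pairwiseAlignment(
    query, tseq, substitutionMatrix = sc$matrix, gapOpening = sc$gapOpening,
    gapExtension = sc$gapExtension, type = "overlap", scoreOnly = TRUE)
  v <- seqToChars(query)
  withSeed(seed, {
    shuf <- vapply(seq_len(nShuffles),
                   function(i) paste(sample(v), collapse = ""), "")
    null <- Biostrings::pairwiseAlignment(
      shuf, tseq, substitutionMatrix = sc$matrix,
      gapOpening = sc$gapOpening, gapExtension = sc$gapExtension,
      type = "overlap", scoreOnly = TRUE)
    s <- stats::sd(null)
    if (!is.finite(s) || s == 0)
      stop("degenerate query: null score distribution has zero variance")
    (S - mean(null)) / s
  })
}

#' Score the myoglobin-fold checklist through a position map
#'
#' Counts, over the hydrophobicity positions of the family checklist
#' (33 intra-helical + CD1 + FG4 for the 3/3 fold; A- and E-helix labels
#' dropped for the 2/2 fold), the fraction that are mapped onto the query
#' and carry a hydrophobic residue; unmapped positions count as failures.
#' The residue at F8 is read through the map separately.
#'
#' @param query Amino-acid string.
#' @param map Named integer position map from [anchorToTemplate()].
#' @param family Checklist variant, `"F"`, `"S"` or `"T"`.
#' @param hydrophobicSet Residues counted as hydrophobic.
#' @return List with `hydrophobicFraction` and `f8Residue` (`NA_character_`
#'   when F8 is unaligned).
#' @export
mbfoldCheck <- function(query, map, family = "F",
                        hydrophobicSet = hydrophobicResidues()) {
  chk <- mbFoldChecklist(family)
  v <- seqToChars(query)
  pos <- map[chk$hydrophobicity]
  ok <- !is.na(pos) & v[ifelse(is.na(pos), 1L, pos)] %in% hydrophobicSet
  f8 <- map[["F8"]]
  list(hydrophobicFraction = mean(ok),
       f8Residue = if (is.na(f8)) NA_character_ else v[f8])
}

#' Assess a query against one globin template
#'
#' Combines [anchorToTemplate()], [foldZscore()] and [mbfoldCheck()] into a
#' single [FoldAssessment-class].  Acceptance is conjunctive: the Z-score
#' must exceed `zThreshold`, the mapped F8 residue must be His, and the
#' hydrophobic fraction must reach `hydroThreshold`.
#'
#' @inheritParams foldZscore
#' @param zThreshold Z-score acceptance threshold (default 6).
#' @param hydroThreshold Minimum hydrophobic fraction (default 2/3).
#' @return A [FoldAssessment-class].
#' @export
assessFold <- function(query, template, zThreshold = 6,
                       hydroThreshold = 2/3, nShuffles = 200L, seed = NULL) {
  anc <- anchorToTemplate(query, template)
  fam <- templateFamily(template)
  chk <- mbfoldCheck(query, anc$map,
                     family = if (fam %in% globinFamilies()) fam else "F")
  z <- foldZscore(query, template, nShuffles = nShuffles, seed = seed)
  accepted <- isTRUE(z > zThreshold) &&
    isTRUE(chk$f8Residue == "H") &&
    isTRUE(chk$hydrophobicFraction >= hydroThreshold)
  new("FoldAssessment", rawScore = anc$score, z = z,
      hydrophobicFraction = chk$hydrophobicFraction,
      f8Residue = if (is.na(chk$f8Residue)) NA_character_ else chk$f8Residue,
      family = fam, template = templateName(template),
      accepted = accepted, positionMap = anc$map)
}

#' Assign a query to a globin family
#'
#' Assesses the query against one template per family and returns the
#' family of the template with the highest Z-score among accepted
#' assessments, or `"none"` if no template is accepted.
#'
#' @inheritParams assessFold
#' @param templates Named list of globin [DomainTemplate-class] objects
#'   (at least one per family; default the packaged family templates).
#' @return List with `family` (`"F"`, `"S"`, `"T"` or `"none"`),
#'   `bestTemplate` (name or `NA`), and `assessment` (the winning
#'   [FoldAssessment-class], or the highest-z one if none accepted).
#' @export
assignFamily <- function(query, templates = familyTemplates(),
                         zThreshold = 6, hydroThreshold = 2/3,
                         nShuffles = 200L, seed = NULL) {
  if (length(templates) == 0L)
    stop("empty template set")
  withSeed(seed, {
    assessments <- lapply(templates, function(tpl)
      assessFold(query, tpl, zThreshold = zThreshold,
                 hydroThreshold = hydroThreshold,
                 nShuffles = nShuffles, seed = NULL))
    zs <- vapply(assessments, foldZ, 0)
    acc <- vapply(assessments, isAccepted, NA)
    if (any(acc)) {
      best <- which(acc)[which.max(zs[acc])]
      list(family = assessments[[best]]@family,
           bestTemplate = assessments[[best]]@template,
           assessment = assessments[[best]])
    } else {
      best <- which.max(zs)
      list(family = "none", bestTemplate = NA_character_,
           assessment = assessments[[best]])
    }
  })
}

#' Trim a query to its globin domain
#'
#' Applies the fixed trimming rule: the globin domain is taken to start 11
#' residues before the mapped B10 position and to end 15 residues after the
#' mapped H8 position, clamped to the sequence.
#'
#' @param query Amino-acid string.
#' @param map Named integer position map with `B10` and `H8` entries.
#' @return Integer vector `c(start, end)` (1-based, inclusive).
#' @examples
#' trimDomain(strrep("A", 200), c(B10 = 40L, H8 = 160L))  # 29 175
#' @export
trimDomain <- function(query, map) {
  b10 <- map[["B10"]]
  h8 <- map[["H8"]]
  if (is.null(b10) || is.null(h8) || is.na(b10) || is.na(h8))
    stop("cannot trim: B10 or H8 is unaligned")
  len <- nchar(query)
  c(start = max(1L, b10 - 11L), end = min(len, h8 + 15L))
}

#' Detect globins in a set of proteins
#'
#' Runs [assignFamily()] over every sequence and reports one row per
#' protein: family call, Z-score, hydrophobic fraction, F8 residue, and the
#' trimmed globin-domain span (NA when the protein is rejected or B10/H8
#' cannot be anchored).
#'
#' @param proteins A named character vector, [Biostrings::AAStringSet], or
#'   path to a FASTA file.
#' @inheritParams assignFamily
#' @return A `data.frame` with columns `id`, `family`, `template`, `z`,
#'   `hydrophobic_fraction`, `f8`, `accepted`, `start`, `end`.
#' @export
detectGlobins <- function(proteins, templates = familyTemplates(),
                          zThreshold = 6, hydroThreshold = 2/3,
                          nShuffles = 200L, seed = NULL) {
  seqs <- asProteinVector(proteins)
  withSeed(seed, {
    rows <- lapply(seq_along(seqs), function(i) {
      af <- assignFamily(seqs[[i]], templates, zThreshold = zThreshold,
                         hydroThreshold = hydroThreshold,
                         nShuffles = nShuffles, seed = NULL)
      a <- af$assessment
      span <- c(start = NA_integer_, end = NA_integer_)
      if (af$family != "none") {
        m <- positionMap(a)
        if (!is.na(m[["B10"]]) && !is.na(m[["H8"]]))
          span <- trimDomain(seqs[[i]], m)
      }
      data.frame(id = names(seqs)[i], family = af$family,
                 template = a@template, z = foldZ(a),
                 hydrophobic_fraction = a@hydrophobicFraction,
                 f8 = a@f8Residue, accepted = af$family != "none",
                 start = span[["start"]], end = span[["end"]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

## Coerce FASTA path / AAStringSet / character vector to a named
## character vector of protein sequences.
asProteinVector <- function(proteins) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins) && !grepl("^[A-Z]+$", proteins))
    proteins <- readFastaAA(proteins)
  if (methods::is(proteins, "XStringSet")) {
    out <- as.character(proteins)
  } else if (is.character(proteins)) {
    out <- proteins
  } else stop("cannot interpret 'proteins'")
  if (is.null(names(out)))
    names(out) <- paste0("seq", seq_along(out))
  ## FASTA headers may carry descriptions; keep the first token as id
  names(out) <- vapply(strsplit(names(out), "\\s+"), `[`, "", 1L)
  out
}
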