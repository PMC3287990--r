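#' Amino-acid alphabet and hydrophobic set
#'
#' `aminoAcids()` returns the 20 standard one-letter amino-acid codes.
#' `hydrophobicResidues()` returns the residue set used when scoring the
#' myoglobin-fold checklist positions for hydrophobicity.
#'
#' @return A character vector of one-letter residue codes.
#' @export
aminoAcids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' @rdname aminoAcids
#' @export
hydrophobicResidues <- function() {
  c("A", "V", "L", "I", "M", "F", "W", "Y", "C")
}

## Run expr with a locally seeded RNG, restoring any prior state afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has.seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has.seed)
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(as.integer(seed))
    on.exit({
      if (has.seed)
        assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

## Validate a protein sequence: standard alphabet plus X, non-empty.
checkProteinSequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a single non-empty character string")
  bad <- setdiff(unique(strsplit(x, "")[[1]]), c(aminoAcids(), "X"))
  if (length(bad))
    stop(what, " contains non-amino-acid characters: ",
         paste(bad, collapse = ", "))
  invisible(x)
}

seqToChars <- function(x) strsplit(as.character(x), "")[[1]]

#' Read and write protein FASTA
#'
#' Thin wrappers around [Biostrings::readAAStringSet()] and
#' [Biostrings::writeXStringSet()]; output is wrapped at 60 columns.
#'
#' @param file Path to a FASTA file.
#' @param x A named character vector or [Biostrings::AAStringSet].
#' @return `readFastaAA` returns an [Biostrings::AAStringSet];
#'   `writeFastaAA` returns `file` invisibly.
#' @export
readFastaAA <- function(file) {
  Biostrings::readAAStringSet(file)
}

#' @rdname readFastaAA
#' @export
writeFastaAA <- function(x, file) {
  if (!methods::is(x, "AAStringSet"))
    x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, file, width = 60L)
  invisible(file)
}

## Substitution scoring shared by all alignment-based operations:
## BLOSUM62 with affine gaps, open 11 / extend 1.
alignmentScoring <- function() {
  mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
  list(matrix = mat, gapOpening = 11, gapExtension = 1)
}

globinFamilies <- function() c("F", "S", "T")

architectureLabels <- function() {
  c("FHb", "FHb_incomplete", "Fgb", "Sgb", "SensorChimera",
    "T1", "T1Chimera", "NonGlobin")
}
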