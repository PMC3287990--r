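#' Read and validate a multiple sequence alignment
#'
#' Alignments are handled as named character vectors of equal-width gapped
#' rows.  On read, residues are upper-cased and `.` gap characters are
#' normalized to `-`.
#'
#' @param file Path to an aligned FASTA or Clustal file.
#' @param format `"fasta"` or `"clustal"`.
#' @return A named character vector of aligned rows.
#' @export
readMsa <- function(file, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(file, format = format)
  msa <- as.character(methods::as(aln, "AAStringSet"))
  names(msa) <- vapply(strsplit(names(msa), "\\s+"), `[`, "", 1L)
  validateMsa(normalizeMsa(msa))
}

#' @rdname readMsa
#' @param msa A named character vector of aligned rows.
#' @export
writeMsa <- function(msa, file) {
  writeFastaAA(validateMsa(msa), file)
}

normalizeMsa <- function(msa) {
  msa <- toupper(msa)
  gsub(".", "-", msa, fixed = TRUE)
}

validateMsa <- function(msa) {
  if (length(msa) == 0L)
    stop("empty alignment")
  w <- nchar(msa)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: rows differ in width")
  if (is.null(names(msa)) || anyDuplicated(names(msa)))
    stop("alignment rows must carry unique names")
  msa
}

## Per-row residue indices: matrix [seq, column] of the 1-based ungapped
## residue index at each column, NA at gaps.
residueIndexMatrix <- function(msa) {
  mat <- do.call(rbind, strsplit(unname(msa), ""))
  res <- mat != "-"
  idx <- matrix(NA_integer_, nrow(mat), ncol(mat),
                dimnames = list(names(msa), NULL))
  for (i in seq_len(nrow(mat)))
    idx[i, res[i, ]] <- seq_len(sum(res[i, ]))
  idx
}

#' Enumerate aligned residue pairs
#'
#' The substrate of the overlap score: the set of tuples
#' `(seq s, residue i, seq t, residue j)`, `s < t` in name order, for
#' residues of two sequences sharing an alignment column.
#'
#' @param msa Named character vector of aligned rows.
#' @return Character vector of canonical pair keys
#'   (`"s:i|t:j"`).
#' @export
residuePairs <- function(msa) {
  msa <- validateMsa(normalizeMsa(msa))
  msa <- msa[order(names(msa))]
  idx <- residueIndexMatrix(msa)
  n <- nrow(idx)
  keys <- list()
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      both <- !is.na(idx[s, ]) & !is.na(idx[t, ])
      if (!any(both)) next
      keys[[length(keys) + 1L]] <-
        paste0(rownames(idx)[s], ":", idx[s, both], "|",
               rownames(idx)[t], ":", idx[t, both])
    }
  }
  unlist(keys, use.names = FALSE)
}

#' Overlap fraction between two alignments of the same sequences
#'
#' The size of the intersection of the two aligned-residue-pair sets,
#' normalized by the mean of the two set sizes — a symmetric, bounded
#' overlap score in the style of multiple-alignment consistency scoring.
#'
#' @param A,B Alignments (named character vectors) of the same sequences.
#' @return A fraction in `[0, 1]`.
#' @export
pairwiseOverlap <- function(A, B) {
  if (!setequal(names(A), names(B)))
    stop("alignments cover different sequence sets")
  lenA <- nchar(gsub("-", "", A))[order(names(A))]
  lenB <- nchar(gsub("-", "", B))[order(names(B))]
  if (!identical(lenA, lenB))
    stop("alignments disagree on per-sequence residue counts")
  pa <- residuePairs(A)
  pb <- residuePairs(B)
  denom <- (length(pa) + length(pb)) / 2
  if (denom == 0) return(1)
  length(intersect(pa, pb)) / denom
}

#' Select the best alignment from an ensemble by mean overlap
#'
#' Scores every pair of alignments with [pairwiseOverlap()] and selects
#' the alignment maximizing the mean overlap against all others; ties are
#' broken deterministically by input order.
#'
#' @param ensemble Named (or unnamed) list of >= 2 alignments of the same
#'   sequences.
#' @return A list with `winner` (index into the ensemble), `winnerName`,
#'   `scores` (symmetric overlap matrix with unit diagonal) and `means`
#'   (per-alignment mean overlap against the others).
#' @export
selectBest <- function(ensemble) {
  k <- length(ensemble)
  if (k < 2L)
    stop("need at least two alignments")
  if (is.null(names(ensemble)))
    names(ensemble) <- paste0("aln", seq_len(k))
  scores <- diag(1, k)
  dimnames(scores) <- list(names(ensemble), names(ensemble))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      scores[i, j] <- scores[j, i] <-
        pairwiseOverlap(ensemble[[i]], ensemble[[j]])
    }
  }
  means <- (rowSums(scores) - 1) / (k - 1)
  winner <- which.max(means)   # first maximum wins
  list(winner = unname(winner), winnerName = names(ensemble)[winner],
       scores = scores, means = means)
}

#' Check conservation of the F8 His column
#'
#' For each sequence, reports whether the residue at its mapped F8
#' position is His and whether that residue falls in the alignment column
#' shared by the majority of sequences — the manual F8-conservation check
#' applied to candidate alignments.
#'
#' @param msa Named character vector of aligned rows.
#' @param maps Named list (per sequence) of position maps carrying an
#'   `F8` entry in ungapped sequence coordinates.
#' @return Named logical vector, one entry per sequence.
#' @export
checkF8Column <- function(msa, maps) {
  msa <- validateMsa(normalizeMsa(msa))
  missing <- setdiff(names(msa), names(maps))
  if (length(missing))
    stop("no position map for: ", paste(missing, collapse = ", "))
  idx <- residueIndexMatrix(msa)
  f8col <- vapply(names(msa), function(id) {
    f8 <- maps[[id]][["F8"]]
    if (is.null(f8) || is.na(f8))
      stop("unmapped F8 for sequence ", id)
    col <- which(idx[id, ] == f8)
    if (length(col)) col else NA_integer_
  }, 0L)
  f8res <- vapply(names(msa), function(id)
    substr(msa[[id]], f8col[[id]], f8col[[id]]), "")
  common <- as.integer(names(which.max(table(f8col))))
  ok <- f8res == "H" & f8col == common
  names(ok) <- names(msa)
  ok
}
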