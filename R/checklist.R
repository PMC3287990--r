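#' The myoglobin-fold position checklist
#'
#' The 3/3 alpha-helical myoglobin fold is operationalized as a pattern of
#' predominantly hydrophobic residues at 36 conserved, solvent-inaccessible
#' positions: 33 intra-helical positions on helices A through H, the two
#' inter-helical corner positions CD1 and FG4, and the invariant proximal
#' histidine at F8.  Positions are named by helix letter and index within
#' the helix.  For the truncated 2/2 fold (T family), helices A and E are
#' vestigial and their labels are dropped.
#'
#' @param family One of `"F"`, `"S"` (full 3/3 checklist) or `"T"`
#'   (2/2 checklist without A- and E-helix labels).
#' @return A list with elements `intraHelical` (character vector of
#'   intra-helical labels), `interHelical` (`CD1`, `FG4`), `invariant`
#'   (`F8`), `hydrophobicity` (the labels scored for hydrophobicity, i.e.
#'   intra- plus inter-helical) and `all` (every label including `F8`).
#' @examples
#' length(mbFoldChecklist()$all)          # 36
#' length(mbFoldChecklist()$intraHelical) # 33
#' @export
mbFoldChecklist <- function(family = c("F", "S", "T")) {
  family <- match.arg(family)
  intra <- c("A8", "A11", "A12", "A15",
             "B6", "B9", "B10", "B13", "B14",
             "C4",
             "E4", "E7", "E8", "E11", "E12", "E15", "E18", "E19",
             "F1", "F4",
             "G5", "G8", "G11", "G12", "G13", "G15", "G16",
             "H7", "H8", "H11", "H12", "H15", "H19")
  if (family == "T")
    intra <- intra[!grepl("^[AE]", intra)]
  inter <- c("CD1", "FG4")
  list(intraHelical = intra,
       interHelical = inter,
       invariant = "F8",
       hydrophobicity = c(intra, inter),
       all = c(intra, inter, "F8"))
}

## Canonical ordering of helix-coordinate labels along the fold
## (A < B < C < CD < E < F < FG < G < H, then index within helix).
orderHelixLabels <- function(labels) {
  helix <- sub("[0-9]+$", "", labels)
  idx <- as.integer(sub("^[A-Z]+", "", labels))
  rank <- match(helix, c("A", "B", "C", "CD", "E", "F", "FG", "G", "H"))
  labels[order(rank, idx)]
}
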