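#' @import methods
NULL

#' DomainTemplate: an annotated reference domain sequence
#'
#' A `DomainTemplate` carries a reference amino-acid sequence for one domain
#' type, and — for globin templates — a map from helix-coordinate labels
#' (`A8` ... `H19`, `CD1`, `FG4`, `F8`) to 1-based positions in that
#' sequence.  Globin queries are anchored to a template by pairwise
#' alignment, which transfers the labels onto the query so that the
#' myoglobin-fold checklist can be scored and the domain trimmed.
#'
#' @slot name Template label, e.g. `"GLB3"`, `"GLB2"`, `"SGB"`, `"CQX2"`.
#' @slot sequence The reference sequence (single character string).
#' @slot annotations Named integer vector mapping coordinate labels to
#'   1-based positions; empty for non-globin templates.
#' @slot familyTag Globin family `"F"`, `"S"`, `"T"`, or `"none"`.
#'
#' @section Validity:
#' Annotation indices must lie within the sequence, be strictly increasing
#' in helix order, and the residue at `F8` (when annotated) must be His.
#'
#' @aliases DomainTemplate
#' @export
setClass("DomainTemplate",
         representation(name = "character",
                        sequence = "character",
                        annotations = "integer",
                        familyTag = "character"))

setValidity("DomainTemplate", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
    msg <- c(msg, "'sequence' must be a single non-empty string")
  if (!object@familyTag %in% c(globinFamilies(), "none"))
    msg <- c(msg, "'familyTag' must be one of F, S, T, none")
  ann <- object@annotations
  if (length(ann)) {
    if (is.null(names(ann)) || any(!nzchar(names(ann))))
      msg <- c(msg, "annotations must be named")
    if (any(ann < 1L) || any(ann > nchar(object@sequence)))
      msg <- c(msg, "annotation indices must lie within the sequence")
    isHelix <- grepl("^(A|B|C|CD|E|F|FG|G|H)[0-9]+$", names(ann))
    if (all(isHelix)) {
      ord <- orderHelixLabels(names(ann))
      if (any(diff(ann[ord]) <= 0L))
        msg <- c(msg,
                 "annotation indices must increase strictly in helix order")
    }
    if ("F8" %in% names(ann) &&
        substr(object@sequence, ann[["F8"]], ann[["F8"]]) != "H")
      msg <- c(msg, "residue at F8 must be His")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DomainTemplate
#'
#' @param name Template label.
#' @param sequence Amino-acid string.
#' @param annotations Named integer vector of coordinate labels (optional).
#' @param familyTag `"F"`, `"S"`, `"T"` or `"none"`.
#' @return A [DomainTemplate-class] object.
#' @examples
#' tpl <- globinTemplates()[["GLB3"]]
#' templateName(tpl)
#' templateAnnotations(tpl)[["F8"]]
#' @export
domainTemplate <- function(name, sequence, annotations = integer(),
                           familyTag = "none") {
  checkProteinSequence(sequence, paste0("template '", name, "' sequence"))
  ann <- as.integer(annotations)
  names(ann) <- names(annotations)
  new("DomainTemplate", name = name, sequence = sequence,
      annotations = ann, familyTag = familyTag)
}

#' @describeIn domainTemplate Template label accessor.
#' @param x A `DomainTemplate`.
#' @export
templateName <- function(x) x@name

#' @describeIn domainTemplate Sequence accessor (character string).
#' @export
templateSequence <- function(x) x@sequence

#' @describeIn domainTemplate Annotation map accessor.
#' @export
templateAnnotations <- function(x) x@annotations

#' @describeIn domainTemplate Globin family tag accessor.
#' @export
templateFamily <- function(x) x@familyTag

setMethod("show", "DomainTemplate", function(object) {
  cat("DomainTemplate '", object@name, "' (family ", object@familyTag,
      "), ", nchar(object@sequence), " aa, ",
      length(object@annotations), " annotated positions\n", sep = "")
})

## ---------------------------------------------------------------------------
## Packaged reference templates.  These are synthetic sequences designed so
## that every checklist position carries a hydrophobic residue and F8 is His;
## they are not derived from any database entry.  Lengths are chosen so that
## GLB3 + CQX2 + CQX3 = 396 aa, the length of a canonical three-domain
## flavohemoglobin.

.GLB3_SEQ <- "GPMFNETEKWYMIFRKLSGPMVSFVMQGWVREIIHWSCPVRCLEGCQWIQQRFLRIFLMKWYKALVPEFVSAICCNPYFVLIIAHVERDAFWMSNCCSQMDPMICEYWIADPTWYAYHEKGDQTNCTHFWAGNMMHHIRFVAVEYDRFPR"

.SGB_SEQ <- "DFESGISSRIQSLWPSWFFDRTYKSVRRLIGSCYNRCHVTKACNCYIWKNKPMKFPNLATLICDWYQYCSMYFTMKPMSSYHMFHKMSYYKDATDKCPNLSCIFMALAMPLYTTTKFFRIYKCNTCPGTMYDKIIQELCVKCNIHLRKRI"

.GLB2_SEQ <- "ECKLFAHRNNMYQAMSGWAFYFCNCKILSGDVINENERMCMEKHIINCIGTHRMDRAWLKNVSLHCLALMQWVMMLCFHRVEMAIRGLEFDSCYQFIYPCVKTYPKRISAPGNYSF"

.CQX2_SEQ <- "LELGRMIHACSHIYCKPYLTRPTQNNIGSRIGCNVESLMENAFQWVEIDNPWKVGCFKCPQQKRAEICCIPSVWKNHGKCISPPCMRPNGTPVRAW"

.CQX3_SEQ <- "TDVFSYFRLRATKLINLMVNTNRMSTTDVTLVRFLDRLVGQDTFFWLIWVKGADMPKNASLRFNTQACTMQMMKHRCKPHQLCDFHQWGQPNKPEPPTFTDYFRPCTAQSTNEFYQYCYGSMSLFDGDNIKDENMATKDTDSCRLACTIH"

## Five tandem copies of the 11-residue leucine-rich repeat consensus
## LxxLxLxxN/CxL.  The motif-defining residues (positions 1, 4, 6, 9, 11
## of each repeat) are annotated so that, like the globin checklist, they
## are conserved when synthetic homologs are generated: LRR proteins keep
## exactly these residues.
.LRR_SEQ <- paste(rep("LTALELSHNQL", 5L), collapse = "")

.LRR_ANN <- local({
  motif <- c(1L, 4L, 6L, 9L, 11L)
  pos <- as.integer(outer(motif, 11L * (0:4), `+`))
  names(pos) <- paste0("R", rep(1:5, each = length(motif)), "P",
                       rep(motif, 5L))
  pos
})

## Signal-peptide template: basic n-region followed by a hydrophobic core.
.SIG_SEQ <- "MKRLLSLVLLVLAVVAFA"

.GLB3_ANN <- c(A8 = 10L, A11 = 13L, A12 = 14L, A15 = 17L,
               B6 = 26L, B9 = 29L, B10 = 30L, B13 = 33L, B14 = 34L,
               C4 = 42L, CD1 = 46L,
               E4 = 58L, E7 = 61L, E8 = 62L, E11 = 65L, E12 = 66L,
               E15 = 69L, E18 = 72L, E19 = 73L,
               F1 = 78L, F4 = 81L, F8 = 85L, FG4 = 90L,
               G5 = 97L, G8 = 100L, G11 = 103L, G12 = 104L, G13 = 105L,
               G15 = 107L, G16 = 108L,
               H7 = 130L, H8 = 131L, H11 = 134L, H12 = 135L,
               H15 = 138L, H19 = 142L)

.GLB2_ANN <- c(B6 = 11L, B9 = 14L, B10 = 15L, B13 = 18L, B14 = 19L,
               C4 = 28L, CD1 = 32L,
               F1 = 45L, F4 = 48L, F8 = 52L, FG4 = 58L,
               G5 = 66L, G8 = 69L, G11 = 72L, G12 = 73L, G13 = 74L,
               G15 = 76L, G16 = 77L,
               H7 = 96L, H8 = 97L, H11 = 100L, H12 = 101L,
               H15 = 104L, H19 = 108L)

#' Packaged domain templates
#'
#' Returns the named list of packaged [DomainTemplate-class] objects used
#' throughout the pipeline: `GLB3` (3/3 globin, F family, 150 aa), `SGB`
#' (3/3 sensor globin, S family, 150 aa), `GLB2` (2/2 truncated globin,
#' T family, 116 aa), `CQX2` (FAD-binding reductase moiety, 96 aa), `CQX3`
#' (NAD(P)-binding reductase moiety, 150 aa), `LRR` (tandem leucine-rich
#' repeats) and `SIG` (signal peptide).  All are synthetic reference
#' sequences built for self-contained testing; the globin templates carry
#' the full helix-coordinate annotation with His at F8.
#'
#' @return Named list of `DomainTemplate` objects.
#' @examples
#' names(globinTemplates())
#' @export
globinTemplates <- function() {
  list(GLB3 = domainTemplate("GLB3", .GLB3_SEQ, .GLB3_ANN, "F"),
       SGB  = domainTemplate("SGB",  .SGB_SEQ,  .GLB3_ANN, "S"),
       GLB2 = domainTemplate("GLB2", .GLB2_SEQ, .GLB2_ANN, "T"),
       CQX2 = domainTemplate("CQX2", .CQX2_SEQ, familyTag = "none"),
       CQX3 = domainTemplate("CQX3", .CQX3_SEQ, familyTag = "none"),
       LRR  = domainTemplate("LRR",  .LRR_SEQ,  .LRR_ANN,
                             familyTag = "none"),
       SIG  = domainTemplate("SIG",  .SIG_SEQ,  familyTag = "none"))
}

## The globin-family subset of the packaged templates (one per family).
familyTemplates <- function(templates = globinTemplates()) {
  templates[vapply(templates, templateFamily, "") %in% globinFamilies()]
}
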