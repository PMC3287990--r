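#' PoissonDistances: corrected pairwise distances with pairwise deletion
#'
#' Produced by [poissonDistances()].  For each sequence pair, alignment
#' columns where either row carries a gap or missing data (`X`) are
#' excluded for that pair only (pairwise deletion); the observed
#' proportion of differences `p` over the remaining usable sites is then
#' corrected for superimposed substitutions by the Poisson formula
#' `d = -ln(1 - p)`.
#'
#' @slot taxa Sequence identifiers.
#' @slot d Symmetric matrix of corrected distances (``Inf`` where
#'   saturated).
#' @slot p Symmetric matrix of observed difference proportions.
#' @slot usable Symmetric matrix of per-pair usable site counts.
#' @aliases PoissonDistances
#' @export
setClass("PoissonDistances",
         representation(taxa = "character",
                        d = "matrix",
                        p = "matrix",
                        usable = "matrix"))

setValidity("PoissonDistances", function(object) {
  msg <- character()
  if (!isSymmetric(unname(object@d)))
    msg <- c(msg, "distance matrix must be symmetric")
  if (any(diag(object@d) != 0))
    msg <- c(msg, "distance matrix must have zero diagonal")
  if (any(object@d[is.finite(object@d)] < 0))
    msg <- c(msg, "distances must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PoissonDistances", function(object) {
  cat("PoissonDistances over ", length(object@taxa), " taxa; ",
      sum(!is.finite(object@d[upper.tri(object@d)])),
      " saturated pair(s)\n", sep = "")
})

#' @describeIn poissonDistances Distance-matrix accessor.
#' @param x A `PoissonDistances` object.
#' @export
distMatrix <- function(x) x@d

#' p-distance of two aligned rows under pairwise deletion
#'
#' @param a,b Aligned (gapped) amino-acid strings of equal length.
#' @return List with `p` (proportion of differences) and `usableSites`
#'   (columns where neither row has a gap or `X`).
#' @examples
#' pDistance("AC-A", "AG-A")  # p = 1/3 over 3 usable sites
#' @export
pDistance <- function(a, b) {
  va <- seqToChars(a)
  vb <- seqToChars(b)
  if (length(va) != length(vb))
    stop("aligned rows differ in length")
  use <- !(va %in% c("-", "X")) & !(vb %in% c("-", "X"))
  n <- sum(use)
  if (n == 0L)
    stop("no usable sites for this pair")
  list(p = sum(va[use] != vb[use]) / n, usableSites = n)
}

#' Poisson correction for superimposed substitutions
#'
#' @param p Observed proportion of differences, `0 <= p < 1`.
#' @return Corrected distance `d = -ln(1 - p)`.
#' @examples
#' poissonCorrect(0.5)           # ln 2
#' poissonCorrect(1 - exp(-1))   # 1
#' @export
poissonCorrect <- function(p) {
  if (any(p < 0))
    stop("p must be non-negative")
  if (any(p >= 1))
    stop("saturated: p >= 1 has no finite Poisson-corrected distance")
  -log(1 - p)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' @param msa Named character vector of aligned rows.
#' @return A [PoissonDistances-class]; saturated pairs (`p >= 1`) carry
#'   `Inf` in the distance slot.
#' @export
poissonDistances <- function(msa) {
  msa <- validateMsa(normalizeMsa(msa))
  n <- length(msa)
  taxa <- names(msa)
  p <- matrix(0, n, n, dimnames = list(taxa, taxa))
  usable <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  chars <- strsplit(unname(msa), "")
  for (i in seq_len(n)) {
    usable[i, i] <- sum(!chars[[i]] %in% c("-", "X"))
    for (j in seq_len(i - 1L)) {
      pd <- pDistance(msa[[i]], msa[[j]])
      p[i, j] <- p[j, i] <- pd$p
      usable[i, j] <- usable[j, i] <- pd$usableSites
    }
  }
  d <- ifelse(p >= 1, Inf, -log(1 - p))
  diag(d) <- 0
  new("PoissonDistances", taxa = taxa, d = d, p = p, usable = usable)
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration via the Q-criterion.  Deterministic:
#' ties in Q are broken by the lowest taxon-index pair (clusters ordered
#' by creation, original taxa first).  Negative branch lengths are clamped
#' to zero by default.
#'
#' @param D A [PoissonDistances-class] or a symmetric numeric matrix with
#'   dimnames.
#' @param clampNegative Clamp negative branch lengths to 0
#'   (default `TRUE`).
#' @return An unrooted `ape::phylo` tree.
#' @export
njTree <- function(D, clampNegative = TRUE) {
  d <- if (methods::is(D, "PoissonDistances")) distMatrix(D) else D
  n <- nrow(d)
  if (n < 3L)
    stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(d)))
    stop("distance matrix contains saturated (non-finite) entries")
  taxa <- rownames(d)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  bl <- function(v) {
    v <- if (clampNegative) max(v, 0) else v
    sprintf("%.17g", v)
  }
  sub <- taxa           # Newick fragment per active cluster
  act <- d
  while (nrow(act) > 3L) {
    m <- nrow(act)
    r <- rowSums(act)
    q <- (m - 2) * act - outer(r, r, `+`)
    diag(q) <- Inf
    ## lowest-index pair among ties, scanning i < j
    best <- c(NA_integer_, NA_integer_)
    bestQ <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (q[i, j] < bestQ) {
          bestQ <- q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    vi <- act[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- act[i, j] - vi
    newSub <- paste0("(", sub[i], ":", bl(vi), ",", sub[j], ":", bl(vj),
                     ")")
    newD <- (act[i, ] + act[j, ] - act[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    act2 <- rbind(cbind(act[keep, keep, drop = FALSE], newD[keep]),
                  c(newD[keep], 0))
    sub <- c(sub[keep], newSub)
    act <- act2
  }
  v1 <- (act[1, 2] + act[1, 3] - act[2, 3]) / 2
  v2 <- (act[1, 2] + act[2, 3] - act[1, 3]) / 2
  v3 <- (act[1, 3] + act[2, 3] - act[1, 2]) / 2
  txt <- paste0("(", sub[1L], ":", bl(v1), ",", sub[2L], ":", bl(v2),
                ",", sub[3L], ":", bl(v3), ");")
  ape::read.tree(text = txt)
}

## Canonical keys for the non-trivial bipartitions of an unrooted tree:
## each internal edge splits the leaves in two; the key is the sorted
## leaf-name list of the side containing the alphabetically first leaf.
bipartitionKeys <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(clade) {
    side <- tips[clade]
    if (length(side) <= 1L || length(side) >= n - 1L)
      return(NA_character_)
    if (!min(tips) %in% side)
      side <- setdiff(tips, side)
    paste(sort(side), collapse = ",")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-corrected NJ tree for each replicate, and reports for every
#' non-trivial bipartition of the original tree the fraction of
#' replicates containing it.  By the usual rendering convention, node
#' labels are written only for supports above `suppressBelow` (default
#' 0.5, i.e. only values >50% are shown).
#'
#' @param msa Named character vector of aligned rows.
#' @param nReps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param clampNegative Passed to [njTree()].
#' @param suppressBelow Supports at or below this fraction are left blank
#'   in the labeled tree.
#' @return List with `tree` (the original NJ tree with percent supports
#'   as node labels), `supports` (named numeric vector of fractions per
#'   bipartition key) and `nReps`.
#' @export
bootstrapSupports <- function(msa, nReps = 1000L, seed = 1L,
                              clampNegative = TRUE, suppressBelow = 0.5) {
  msa <- validateMsa(normalizeMsa(msa))
  if (nReps < 1L)
    stop("nReps must be at least 1")
  width <- nchar(msa[[1L]])
  if (width < 2L)
    stop("alignment must have at least 2 columns")
  chars <- do.call(rbind, strsplit(unname(msa), ""))
  rownames(chars) <- names(msa)
  tree <- njTree(poissonDistances(msa), clampNegative = clampNegative)
  keys <- bipartitionKeys(tree)
  counts <- stats::setNames(numeric(length(keys)), keys)
  withSeed(seed, {
    for (b in seq_len(nReps)) {
      cols <- sample.int(width, width, replace = TRUE)
      rep.msa <- apply(chars[, cols, drop = FALSE], 1L, paste,
                       collapse = "")
      rep.tree <- njTree(poissonDistances(rep.msa),
                         clampNegative = clampNegative)
      hit <- keys %in% bipartitionKeys(rep.tree)
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- counts / nReps
  labeled <- labelTreeWithSupports(tree, supports,
                                   suppressBelow = suppressBelow)
  list(tree = labeled, supports = supports, nReps = nReps)
}

## Attach percent supports as internal-node labels; values at or below
## the suppression threshold are left blank.
labelTreeWithSupports <- function(tree, supports, suppressBelow = 0.5) {
  tips <- tree$tip.label
  n <- length(tips)
  pp <- ape::prop.part(tree)
  labs <- vapply(seq_along(pp), function(k) {
    side <- tips[pp[[k]]]
    if (length(side) <= 1L || length(side) >= n - 1L) return("")
    if (!min(tips) %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = ",")
    s <- supports[[key]]
    if (is.null(s) || is.na(s) || s <= suppressBelow) ""
    else sprintf("%d", round(100 * s))
  }, "")
  tree$node.label <- labs
  tree
}

#' Fraction of t1's bipartitions shared with t2
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return `|shared non-trivial bipartitions| / |non-trivial bipartitions
#'   of t1|`; when `t1` has none (a star tree), 1 if `t2` also has none,
#'   else 0.
#' @export
sharedBipartitionFraction <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  k1 <- bipartitionKeys(t1)
  k2 <- bipartitionKeys(t2)
  if (length(k1) == 0L)
    return(as.numeric(length(k2) == 0L))
  length(intersect(k1, k2)) / length(k1)
}

#' Newick round trip
#'
#' Serializes and parses trees in Newick format, preserving topology,
#' branch lengths and internal-node support labels.
#'
#' @param tree An `ape::phylo` tree.
#' @param file Optional path; when `NULL` the Newick text is returned.
#' @return `newickWrite` returns the Newick string (invisibly when
#'   writing to a file); `newickRead` returns an `ape::phylo`.
#' @export
newickWrite <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname newickWrite
#' @param text Newick text (used when `file` is `NULL`).
#' @export
newickRead <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  src <- if (is.null(text)) paste(readLines(file), collapse = "") else text
  if (length(gregexpr("(", src, fixed = TRUE)[[1L]]) !=
      length(gregexpr(")", src, fixed = TRUE)[[1L]]) ||
      !grepl(";\\s*$", src))
    stop("malformed Newick: unbalanced parentheses or missing terminator")
  tree <- tryCatch(ape::read.tree(text = src),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    stop("malformed Newick input")
  tree
}

#' Export a distance matrix in square PHYLIP format
#'
#' @param D A [PoissonDistances-class] or numeric matrix.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writePhylipDist <- function(D, file) {
  d <- if (methods::is(D, "PoissonDistances")) distMatrix(D) else D
  taxa <- rownames(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste0(formatC(taxa[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")),
               ""))
  writeLines(lines, file)
  invisible(file)
}
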