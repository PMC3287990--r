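test_that("p-distances apply pairwise deletion per pair", {
  expect_equal(pDistance("ACDE", "ACDE"), list(p = 0, usableSites = 4L))
  ## hand count: usable 3, one mismatch
  expect_equal(pDistance("AC-A", "AG-A"), list(p = 1/3, usableSites = 3L))
  ## X is treated as missing data
  expect_equal(pDistance("ACXE", "ACDE")$usableSites, 3L)
  ## a site gapped in one pair still counts for another pair of the same
  ## alignment
  msa <- c(a = "ACDE", b = "AC-E", c = "AGDE")
  pd <- poissonDistances(msa)
  expect_equal(pd@usable["a", "b"], 3L)
  expect_equal(pd@usable["a", "c"], 4L)
  expect_equal(pd@p["a", "c"], 1/4)
  ## symmetry and conserved mismatch count under row swap
  expect_equal(pDistance("ACDE", "AGKE"), pDistance("AGKE", "ACDE"))
  expect_error(pDistance("ACD", "AC"), "differ in length")
  expect_error(pDistance("--", "AC"), "no usable sites")
})

test_that("Poisson correction follows its closed form and is monotone", {
  expect_equal(poissonCorrect(0), 0)
  expect_equal(poissonCorrect(1 - exp(-1)), 1.0)
  expect_equal(poissonCorrect(0.5), log(2))
  ## strictly increasing and >= p on [0, 1)
  p <- seq(0, 0.95, by = 0.05)
  d <- poissonCorrect(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
  expect_error(poissonCorrect(1), "saturated")
  expect_error(poissonCorrect(-0.1), "non-negative")
})

test_that("NJ recovers additive trees exactly and matches the ape oracle", {
  ## 3 taxa: closed-form three-point branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- njTree(D3)
  bl <- setNames(t3$edge.length,
                 t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[c("x", "y", "z")], c(x = 1, y = 2, z = 3))
  ## additive 4-taxon matrix: exact topology and path lengths
  D <- additive4()
  tr <- njTree(D)
  co <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(co, D, tolerance = 1e-12)
  ## independent oracle: ape::nj finds the same topology
  expect_equal(ape::dist.topo(ape::unroot(tr),
                              ape::unroot(ape::nj(as.dist(D)))), 0,
               ignore_attr = TRUE)
  ## two identical rows are joined first, at zero length
  D5 <- D
  D5 <- cbind(rbind(D5, e = D5["a", ]), e = c(D5["a", ], 0))
  tr5 <- njTree(D5)
  co5 <- ape::cophenetic.phylo(tr5)
  expect_equal(co5["a", "e"], 0)
  expect_error(njTree(D[1:2, 1:2]), "at least 3")
  Dsat <- D; Dsat["a", "b"] <- Dsat["b", "a"] <- Inf
  expect_error(njTree(Dsat), "saturated")
})

test_that("NJ agrees with the ape oracle on random distance matrices", {
  for (s in 1:5) {
    D <- withr::with_seed(s, {
      n <- 7
      M <- matrix(stats::runif(n * n, 0.1, 2), n, n)
      M <- (M + t(M)) / 2
      diag(M) <- 0
      dimnames(M) <- list(letters[1:n], letters[1:n])
      M
    })
    mine <- njTree(D, clampNegative = FALSE)
    theirs <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs)),
                 0, ignore_attr = TRUE)
  }
})

test_that("distance matrices from alignments flag saturation", {
  msa <- c(a = "AAAA", b = "CCCC", c = "AACC")
  pd <- poissonDistances(msa)
  expect_true(is.infinite(distMatrix(pd)["a", "b"]))
  expect_error(njTree(pd), "saturated")
})

test_that("bootstrap supports the planted split and respects seeds and labels", {
  tc <- twoCladeAlignment(nPerClade = 4, seed = 11)
  b1 <- bootstrapSupports(tc$msa, nReps = 50, seed = 4)
  b2 <- bootstrapSupports(tc$msa, nReps = 50, seed = 4)
  expect_identical(b1$supports, b2$supports)
  key <- paste(sort(tc$split), collapse = ",")
  expect_gte(b1$supports[[key]], 0.9)
  ## relabeling taxa permutes but does not change supports
  msa2 <- tc$msa
  names(msa2) <- paste0("x", rev(seq_along(msa2)))
  b3 <- bootstrapSupports(msa2, nReps = 50, seed = 4)
  expect_setequal(unname(b3$supports), unname(b1$supports))
  ## rendering convention: only supports above 50% get a label
  labs <- b1$tree$node.label
  shown <- labs[labs != ""]
  expect_true(all(as.numeric(shown) > 50))
  expect_error(bootstrapSupports(c(a = "A", b = "C", c = "A")),
               "at least 2 columns")
})

test_that("bipartition sharing is 1 for identical trees and 0 against a star", {
  D <- additive4()
  tr <- njTree(D)
  expect_equal(sharedBipartitionFraction(tr, tr), 1.0)
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(sharedBipartitionFraction(star, tr), 0.0)
  expect_equal(sharedBipartitionFraction(tr, star), 0.0)
  expect_equal(sharedBipartitionFraction(star, star), 1.0)
  other <- ape::read.tree(text = "((a:1,c:1):1,b:1,d:1);")
  expect_equal(sharedBipartitionFraction(tr, other), 0.0)
  expect_error(sharedBipartitionFraction(
    tr, ape::read.tree(text = "(a:1,b:1,e:1);")), "different leaf sets")
})

test_that("Newick IO round-trips topology, lengths and supports", {
  tc <- twoCladeAlignment(nPerClade = 3, seed = 2)
  b <- bootstrapSupports(tc$msa, nReps = 30, seed = 1)
  txt <- newickWrite(b$tree)
  back <- newickRead(text = txt)
  expect_setequal(back$tip.label, b$tree$tip.label)
  expect_equal(sharedBipartitionFraction(back, b$tree), 1.0)
  expect_equal(sort(back$edge.length), sort(b$tree$edge.length),
               tolerance = 1e-6)
  expect_identical(sort(back$node.label), sort(b$tree$node.label))
  f <- withr::local_tempfile(fileext = ".nwk")
  newickWrite(b$tree, f)
  expect_equal(sharedBipartitionFraction(newickRead(file = f), b$tree),
               1.0)
  expect_error(newickRead(text = "((a:1,b:1;"), "malformed")
  ## PHYLIP distance export carries the right header
  pd <- poissonDistances(tc$msa)
  f2 <- withr::local_tempfile(fileext = ".dist")
  writePhylipDist(pd, f2)
  lines <- readLines(f2)
  expect_equal(as.integer(trimws(lines[1])), length(tc$msa))
  expect_length(lines, length(tc$msa) + 1L)
})
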