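test_that("packaged templates satisfy their invariants", {
  expect_setequal(names(tpls),
                  c("GLB3", "SGB", "GLB2", "CQX2", "CQX3", "LRR", "SIG"))
  for (nm in c("GLB3", "SGB")) {
    ann <- templateAnnotations(tpls[[nm]])
    expect_setequal(names(ann), mbFoldChecklist("F")$all)
    expect_equal(substr(templateSequence(tpls[[nm]]),
                        ann[["F8"]], ann[["F8"]]), "H")
  }
  ann2 <- templateAnnotations(tpls$GLB2)
  expect_setequal(names(ann2), mbFoldChecklist("T")$all)
  expect_false(any(grepl("^[AE][0-9]", names(ann2))))
  ## three-domain flavohemoglobin totals the canonical 396 residues
  expect_equal(nchar(templateSequence(tpls$GLB3)) +
                 nchar(templateSequence(tpls$CQX2)) +
                 nchar(templateSequence(tpls$CQX3)), 396L)
  expect_equal(nchar(templateSequence(tpls$GLB2)), 116L)
  ## invalid templates are refused
  expect_error(domainTemplate("bad", "AC9DE"), "non-amino-acid")
  seqv <- strsplit(templateSequence(tpls$GLB3), "")[[1]]
  seqv[templateAnnotations(tpls$GLB3)[["F8"]]] <- "A"
  expect_error(domainTemplate("bad", paste(seqv, collapse = ""),
                              templateAnnotations(tpls$GLB3), "F"),
               "F8 must be His")
})

test_that("mutateTemplate hits its target identity and conserves the checklist", {
  tpl <- tpls$GLB3
  ## identity case: no substitutions, no indels, identity map
  m <- mutateTemplate(tpl, mutationModel(1.0, indelRate = 0), seed = 1)
  expect_identical(m$sequence, templateSequence(tpl))
  expect_identical(m$annotations, templateAnnotations(tpl))
  expect_identical(m$templateMap, seq_len(nchar(templateSequence(tpl))))
  ## measured identity near the 0.6 target over 100 draws
  v0 <- strsplit(templateSequence(tpl), "")[[1]]
  idents <- withr::with_seed(7, vapply(1:100, function(i) {
    mi <- mutateTemplate(tpl, mutationModel(0.6, indelRate = 0))
    mean(strsplit(mi$sequence, "")[[1]] == v0)
  }, 0))
  expect_lt(abs(mean(idents) - 0.6), 0.05)
  ## F8 stays His under conservation, any seed
  for (s in c(2, 11, 99)) {
    mi <- mutateTemplate(tpl, mutationModel(0.4, indelRate = 2), seed = s)
    f8 <- mi$annotations[["F8"]]
    expect_equal(substr(mi$sequence, f8, f8), "H")
    ## every conserved label keeps its residue
    ann0 <- templateAnnotations(tpl)
    for (lab in names(ann0)) {
      expect_equal(substr(mi$sequence, mi$annotations[[lab]],
                          mi$annotations[[lab]]),
                   substr(templateSequence(tpl), ann0[[lab]], ann0[[lab]]))
    }
  }
})

test_that("mutated identity decreases with divergence and maps stay consistent", {
  tpl <- tpls$GLB3
  v0 <- strsplit(templateSequence(tpl), "")[[1]]
  meanIdent <- function(target) {
    withr::with_seed(3, mean(vapply(1:30, function(i) {
      mi <- mutateTemplate(tpl, mutationModel(target, indelRate = 0))
      mean(strsplit(mi$sequence, "")[[1]] == v0)
    }, 0)))
  }
  ids <- vapply(c(0.9, 0.7, 0.5), meanIdent, 0)
  expect_true(all(diff(ids) < 0))
  ## templateMap is an injective, order-preserving edit script
  mi <- mutateTemplate(tpl, mutationModel(0.5, indelRate = 3), seed = 5)
  mp <- mi$templateMap[!is.na(mi$templateMap)]
  expect_true(all(diff(mp) > 0))
  expect_lte(max(mp), nchar(mi$sequence))
})

test_that("buildProtein realizes grammars with consistent ground truth", {
  ## canonical FHb grammar: three domains, true class FHb
  bp <- buildProtein(classArchitectures()$FHb,
                     mutationModel(0.8, indelRate = 0), seed = 2)
  expect_equal(bp$truth$trueClass, "FHb")
  expect_equal(bp$truth$spans$kind, c("GLB3", "CQX2", "CQX3"))
  expect_equal(nchar(bp$sequence), 396L)
  ## spans tile the protein without gaps
  expect_equal(bp$truth$spans$start[-1], head(bp$truth$spans$end, -1) + 1L)
  expect_equal(bp$truth$spans$start[1], 1L)
  expect_equal(tail(bp$truth$spans$end, 1), nchar(bp$sequence))
  ## dropping CQX3 yields the incomplete flavohemoglobin
  bp2 <- buildProtein(architectureSpec(c("GLB3", "CQX2")),
                      mutationModel(0.8), seed = 2)
  expect_equal(bp2$truth$trueClass, "FHb_incomplete")
  ## a bare 2/2 globin is a single-domain T1 of 116 residues
  bp3 <- buildProtein(architectureSpec("GLB2"),
                      mutationModel(1.0, indelRate = 0), seed = 2)
  expect_equal(bp3$truth$trueClass, "T1")
  expect_equal(nchar(bp3$sequence), 116L)
  ## globin coordinate map points at the planted F8
  f8 <- bp$truth$globinMap[["F8"]]
  expect_equal(substr(bp$sequence, f8, f8), "H")
  expect_error(buildProtein(architectureSpec("NOPE")), "unknown template")
  expect_error(architectureSpec(c("GLB3", "GLB2")), "one globin")
})

test_that("buildProteome is deterministic and matches presence probabilities", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  buildProteome(nGenomes = 5, seed = 42, dir = d1)
  buildProteome(nGenomes = 5, seed = 42, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_error(buildProteome(nGenomes = 0), "at least 1")
  ## all-ones profile puts every class in every genome
  prof <- defaultTaxonProfile()[1, ]
  prof[setdiff(architectureLabels(), "NonGlobin")] <- 1
  pr <- buildProteome(prof, nGenomes = 4, seed = 1)
  tab <- table(pr$truth$genome)
  expect_true(all(tab == length(setdiff(architectureLabels(),
                                        "NonGlobin"))))
  ## binomial presence check: p = 0.6 over 200 genomes
  prof2 <- prof
  prof2[setdiff(architectureLabels(), "NonGlobin")] <- 0
  prof2$Sgb <- 0.6
  pr2 <- buildProteome(prof2, nGenomes = 200, seed = 1)
  frac <- nrow(pr2$truth) / 200
  expect_lt(abs(frac - 0.6), 0.07)
})

test_that("true MSAs reproduce domain sequences and share the template frame", {
  pr <- buildProteome(nGenomes = 8, seed = 9)
  for (fam in names(pr$msas)) {
    msa <- pr$msas[[fam]]
    expect_length(unique(nchar(msa)), 1L)
    for (id in names(msa)) {
      tr <- pr$truthDetails[[id]]
      sp <- tr$spans[tr$spans$kind == tr$globinKind, ]
      expect_identical(gsub("-", "", msa[[id]]),
                       substr(pr$proteins[[id]], sp$start, sp$end))
    }
  }
})
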