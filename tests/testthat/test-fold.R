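test_that("the checklist has 36 positions, 33 intra-helical, F8 separate", {
  chk <- mbFoldChecklist("F")
  expect_length(chk$all, 36L)
  expect_length(chk$intraHelical, 33L)
  expect_identical(chk$interHelical, c("CD1", "FG4"))
  expect_identical(chk$invariant, "F8")
  expect_false("F8" %in% chk$hydrophobicity)
  ## 2/2 checklist drops the vestigial A and E helices, keeps the rest
  chkT <- mbFoldChecklist("T")
  expect_false(any(grepl("^[AE][0-9]", chkT$all)))
  expect_true(all(chkT$all %in% chk$all))
})

test_that("anchoring transfers labels exactly under identity, shift and deletion", {
  tpl <- tpls$GLB3
  ann <- templateAnnotations(tpl)
  ## identity
  a <- anchorToTemplate(templateSequence(tpl), tpl)
  expect_identical(a$map, ann)
  ## +3 N-terminal extension shifts every label by 3
  a3 <- anchorToTemplate(paste0("MKT", templateSequence(tpl)), tpl)
  expect_identical(a3$map, ann + 3L)
  ## deleting the E7-E8 segment (positions 61-62) unaligns exactly those
  ## labels and shifts downstream labels by -2 (verified by hand against
  ## the optimal alignment)
  s <- templateSequence(tpl)
  q <- paste0(substr(s, 1, 60), substr(s, 63, nchar(s)))
  ad <- anchorToTemplate(q, tpl)$map
  expect_identical(names(ad)[is.na(ad)], c("E7", "E8"))
  expect_identical(ad[ann < 61], ann[ann < 61])
  sel <- !is.na(ad) & ann > 62
  expect_identical(ad[sel], ann[sel] - 2L)
  expect_error(anchorToTemplate("", tpl), "non-empty")
  expect_error(anchorToTemplate("ACB1", tpl), "non-amino-acid")
})

test_that("shuffle-null Z-scores separate self-matches from noise", {
  tpl <- tpls$GLB3
  s <- templateSequence(tpl)
  ## a self-match clears the acceptance threshold comfortably
  z <- foldZscore(s, tpl, nShuffles = 200, seed = 1)
  expect_gt(z, 6)
  ## deterministic for a fixed seed
  expect_identical(z, foldZscore(s, tpl, nShuffles = 200, seed = 1))
  ## stable across seeds: the decision never flips and the spread is
  ## small relative to the score
  zs <- vapply(1:4, function(sd) foldZscore(s, tpl, nShuffles = 500,
                                            seed = sd), 0)
  expect_true(all(zs > 6))
  expect_lt(stats::sd(zs) / mean(zs), 0.10)
  ## degenerate query has no defined score
  expect_error(foldZscore(strrep("A", 100), tpl, seed = 1), "degenerate")
  expect_error(foldZscore(s, tpl, nShuffles = 10), "at least 30")
})

test_that("checklist scoring counts hydrophobicity and reads F8 through the map", {
  tpl <- tpls$GLB3
  ann <- templateAnnotations(tpl)
  ## by construction the template itself scores a perfect checklist
  chk <- mbfoldCheck(templateSequence(tpl), ann, family = "F")
  expect_equal(chk$hydrophobicFraction, 1.0)
  expect_equal(chk$f8Residue, "H")
  ## a conserved synthetic homolog keeps the perfect score
  m <- mutateTemplate(tpl, mutationModel(0.6, indelRate = 1), seed = 4)
  chk2 <- mbfoldCheck(m$sequence, m$annotations, family = "F")
  expect_equal(chk2$hydrophobicFraction, 1.0)
  expect_equal(chk2$f8Residue, "H")
  ## unmapped positions count as failures
  mp <- ann
  mp[c("A8", "A11")] <- NA_integer_
  chk3 <- mbfoldCheck(templateSequence(tpl), mp, family = "F")
  expect_equal(chk3$hydrophobicFraction, 33 / 35)
})

test_that("acceptance is conjunctive: F8 and z each veto independently", {
  tpl <- tpls$GLB3
  m <- mutateTemplate(tpl, mutationModel(0.7, indelRate = 0), seed = 8)
  a <- assessFold(m$sequence, tpl, nShuffles = 60, seed = 1)
  expect_true(isAccepted(a))
  ## flip F8 to Ala: rejected regardless of everything else
  v <- strsplit(m$sequence, "")[[1]]
  v[m$annotations[["F8"]]] <- "A"
  a2 <- assessFold(paste(v, collapse = ""), tpl, nShuffles = 60, seed = 1)
  expect_false(isAccepted(a2))
  expect_equal(a2@f8Residue, "A")
  ## raise the z threshold above the observed z: rejected
  a3 <- assessFold(m$sequence, tpl, zThreshold = foldZ(a) + 100,
                   nShuffles = 60, seed = 1)
  expect_false(isAccepted(a3))
})

test_that("family assignment takes the accepted-argmax and matches a brute-force oracle", {
  fams <- familyTemplates(tpls)
  ## queries generated from each family template recover their family
  for (nm in names(fams)) {
    m <- mutateTemplate(fams[[nm]], mutationModel(0.6), seed = 21)
    af <- assignFamily(m$sequence, fams, nShuffles = 60, seed = 2)
    expect_equal(af$family, templateFamily(fams[[nm]]), label = nm)
    ## oracle: evaluate every template independently, take the argmax z
    ## among accepted
    oracle <- lapply(names(fams), function(k)
      assessFold(m$sequence, fams[[k]], nShuffles = 60, seed = 2))
    accepted <- vapply(oracle, isAccepted, NA)
    zs <- vapply(oracle, foldZ, 0)
    expect_true(any(accepted))
    expect_equal(af$bestTemplate,
                 vapply(oracle, function(o) o@template, "")[
                   which(accepted)[which.max(zs[accepted])]])
  }
  ## poly-alternating junk is assigned to no family
  af0 <- assignFamily(strrep("AG", 60), fams, nShuffles = 60, seed = 3)
  expect_equal(af0$family, "none")
  expect_error(assignFamily("ACDE", list()), "empty template set")
})

test_that("the trimming rule applies fixed offsets 11 and 15 with clamping", {
  q <- strrep("A", 200)
  expect_equal(trimDomain(q, c(B10 = 40L, H8 = 160L)),
               c(start = 29L, end = 175L))
  ## clamped at both ends
  expect_equal(trimDomain(q, c(B10 = 5L, H8 = 160L))[["start"]], 1L)
  expect_equal(trimDomain(strrep("A", 170),
                          c(B10 = 40L, H8 = 160L))[["end"]], 170L)
  ## the span always contains both anchors
  for (b10 in c(12L, 40L, 80L)) {
    sp <- trimDomain(q, c(B10 = b10, H8 = 160L))
    expect_lte(sp[["start"]], b10)
    expect_gte(sp[["end"]], 160L)
  }
  expect_error(trimDomain(q, c(B10 = NA_integer_, H8 = 160L)),
               "unaligned")
  expect_error(trimDomain(q, c(B10 = 40L, H8 = NA_integer_)),
               "unaligned")
})

test_that("detectGlobins reports spans and is deterministic per seed", {
  bp <- buildProtein(classArchitectures()$FHb, mutationModel(0.7),
                     seed = 6)
  seqs <- c(fhb = bp$sequence, junk = strrep("GS", 100))
  d1 <- detectGlobins(seqs, nShuffles = 60, seed = 11)
  d2 <- detectGlobins(seqs, nShuffles = 60, seed = 11)
  expect_identical(d1, d2)
  expect_equal(d1$family, c("F", "none"))
  expect_true(is.na(d1$start[2]))
  ## the trimmed span contains the true B10 and H8 anchors
  expect_lte(d1$start[1], bp$truth$globinMap[["B10"]])
  expect_gte(d1$end[1], bp$truth$globinMap[["H8"]])
})
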