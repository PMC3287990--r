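#' MutationModel: divergence model for synthetic homologs
#'
#' Controls how a template sequence is mutated when a synthetic homolog is
#' generated: point substitutions down to a target identity, short indels
#' at a given rate, and optional conservation of the myoglobin-fold
#' checklist positions.
#'
#' @slot targetIdentity Fraction of template residues left unchanged by
#'   substitution, in (0, 1].
#' @slot indelRate Expected indels per 100 residues (>= 0); indel lengths
#'   are 1-3 and indels never fall within 5 residues of an annotated
#'   coordinate label, which keeps label remapping well-defined.
#' @slot conserveChecklist When `TRUE`, residues at all annotated
#'   checklist positions (including F8) are exempt from substitution.
#' @slot seed Default seed used when an operation is called without one
#'   (`NA` = use the current RNG stream).
#' @aliases MutationModel
#' @export
setClass("MutationModel",
         representation(targetIdentity = "numeric",
                        indelRate = "numeric",
                        conserveChecklist = "logical",
                        seed = "integer"))

setValidity("MutationModel", function(object) {
  msg <- character()
  ti <- object@targetIdentity
  if (length(ti) != 1L || is.na(ti) || ti <= 0 || ti > 1)
    msg <- c(msg, "targetIdentity must lie in (0, 1]")
  if (object@indelRate < 0)
    msg <- c(msg, "indelRate must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a MutationModel
#'
#' @param targetIdentity Target identity in (0, 1] (default 0.6).
#' @param indelRate Expected indels per 100 residues (default 1).
#' @param conserveChecklist Exempt annotated positions from substitution
#'   (default `TRUE`).
#' @param seed Optional default seed.
#' @return A [MutationModel-class].
#' @export
mutationModel <- function(targetIdentity = 0.6, indelRate = 1,
                          conserveChecklist = TRUE, seed = NA_integer_) {
  new("MutationModel", targetIdentity = targetIdentity,
      indelRate = indelRate, conserveChecklist = conserveChecklist,
      seed = as.integer(seed))
}

setMethod("show", "MutationModel", function(object) {
  cat("MutationModel: target identity ", object@targetIdentity,
      ", indel rate ", object@indelRate, "/100 aa, conserve checklist: ",
      object@conserveChecklist, "\n", sep = "")
})

#' Mutate a template into a synthetic homolog
#'
#' Substitutes `round((1 - targetIdentity) * length)` positions (drawn
#' uniformly among non-exempt positions, replacements drawn uniformly from
#' the 19 non-identical residues) and applies indels of length 1-3 at the
#' model's rate, never within 5 residues of an annotated label.  The
#' annotation map is carried through the applied edit script.
#'
#' @param template A [DomainTemplate-class].
#' @param model A [MutationModel-class].
#' @param seed Optional seed (overrides the model's default).
#' @return A list with `sequence` (mutated string), `annotations` (remapped
#'   named integer vector) and `templateMap` (integer vector over template
#'   positions giving the corresponding mutant position, `NA` for deleted
#'   positions) — the edit script used to build aligner-free true MSAs.
#' @export
mutateTemplate <- function(template, model, seed = NULL) {
  if (is.null(seed) && !is.na(model@seed)) seed <- model@seed
  tseq <- seqToChars(templateSequence(template))
  ann <- templateAnnotations(template)
  L <- length(tseq)
  aa <- aminoAcids()
  withSeed(seed, {
    v <- tseq
    exempt <- if (model@conserveChecklist) unname(ann) else integer()
    free <- setdiff(seq_len(L), exempt)
    nSub <- round((1 - model@targetIdentity) * L)
    nSub <- min(nSub, length(free))
    if (nSub > 0L) {
      pos <- sample(free, nSub)
      for (p in pos) v[p] <- sample(setdiff(aa, v[p]), 1L)
    }
    ## indels: forbidden within 5 residues of any annotated label
    forbidden <- unique(unlist(lapply(unname(ann), function(p)
      seq(max(1L, p - 5L), min(L, p + 5L)))))
    nIndel <- if (model@indelRate > 0)
      stats::rpois(1L, model@indelRate * L / 100) else 0L
    templateMap <- seq_len(L)   # template position -> current position
    for (k in seq_len(nIndel)) {
      len <- sample(1:3, 1L)
      del <- stats::runif(1L) < 0.5
      if (del) {
        ## candidate template-coordinate windows clear of labels
        cand <- setdiff(seq_len(L - len + 1L),
                        unique(unlist(lapply(forbidden, function(p)
                          seq(max(1L, p - len + 1L), p)))))
        cand <- cand[!is.na(templateMap[cand])]
        cand <- cand[vapply(cand, function(p)
          all(!is.na(templateMap[p:(p + len - 1L)])), NA)]
        if (length(cand) == 0L) next
        p <- cand[sample.int(length(cand), 1L)]
        at <- templateMap[p]
        v <- v[-(at:(at + len - 1L))]
        templateMap[p:(p + len - 1L)] <- NA_integer_
        shift <- !is.na(templateMap) & templateMap > at
        templateMap[shift] <- templateMap[shift] - len
      } else {
        ## insertion before template position p (p = L + 1 appends)
        cand <- setdiff(seq_len(L + 1L), forbidden)
        if (length(cand) == 0L) next
        p <- cand[sample.int(length(cand), 1L)]
        mapped <- templateMap[!is.na(templateMap[seq_len(min(p - 1L, L))])]
        at <- if (p == 1L || length(mapped) == 0L) 0L else
          max(templateMap[seq_len(p - 1L)], na.rm = TRUE)
        ins <- sample(aa, len, TRUE)
        v <- append(v, ins, after = at)
        shift <- !is.na(templateMap) & templateMap > at
        templateMap[shift] <- templateMap[shift] + len
      }
    }
    newAnn <- templateMap[ann]
    names(newAnn) <- names(ann)
    list(sequence = paste(v, collapse = ""),
         annotations = newAnn,
         templateMap = templateMap)
  })
}

#' Architecture specifications for synthetic proteins
#'
#' An architecture spec is an ordered domain grammar: an optional signal
#' peptide, an optional unannotated N-terminal extension, a list of domain
#' template names (at most one globin), and an optional C-terminal
#' extension.
#'
#' @param domains Character vector of template names, in order.
#' @param signal Prepend the signal-peptide template (default `FALSE`).
#' @param nTermExt Length of a random N-terminal extension (default 0).
#' @param cTermExt Length of a random C-terminal extension (default 0).
#' @return A list with class `"ArchitectureSpec"`.
#' @export
architectureSpec <- function(domains, signal = FALSE, nTermExt = 0L,
                             cTermExt = 0L) {
  glob <- sum(domains %in% c("GLB3", "GLB2", "SGB"))
  if (glob > 1L)
    stop("at most one globin template per architecture spec")
  structure(list(domains = domains, signal = signal,
                 nTermExt = as.integer(nTermExt),
                 cTermExt = as.integer(cTermExt)),
            class = "ArchitectureSpec")
}

#' Canonical architecture specs for each globin class
#'
#' The grammars realized for each architecture label: a normal
#' three-domain flavohemoglobin (globin + FAD-binding + NAD(P)-binding,
#' 396 aa before indels), the incomplete flavohemoglobin with an unknown
#' N-terminal domain and no `CQX3`, a single-domain F globin, a
#' single-domain sensor globin, a sensor chimera with a 120-residue
#' C-terminal extension, a single-domain 116-residue truncated T1 globin,
#' and a T1 chimera carrying an N-terminal extension and a leucine-rich
#' repeat region.
#'
#' @return Named list of `ArchitectureSpec` objects.
#' @export
classArchitectures <- function() {
  list(FHb = architectureSpec(c("GLB3", "CQX2", "CQX3")),
       FHb_incomplete = architectureSpec(c("GLB3", "CQX2"), nTermExt = 60L),
       Fgb = architectureSpec("GLB3"),
       Sgb = architectureSpec("SGB", cTermExt = 40L),
       SensorChimera = architectureSpec("SGB", cTermExt = 120L),
       T1 = architectureSpec("GLB2"),
       T1Chimera = architectureSpec(c("LRR", "GLB2"), nTermExt = 100L))
}

#' Build one synthetic protein from an architecture spec
#'
#' Concatenates mutated copies of the named templates (signal peptides are
#' kept unmutated so that the heuristic they are built for still holds;
#' extensions are random background sequence), and returns the protein
#' together with its ground truth: realized domain spans, the coordinate
#' map for globin labels, and the true class derived from the grammar by
#' the same rule table as [classifyArchitecture()].
#'
#' @param spec An [architectureSpec()].
#' @param model A [MutationModel-class].
#' @param id Protein identifier.
#' @param templates Named list of packaged templates.
#' @param seed Optional seed.
#' @return A list with `sequence`, and `truth` — a list holding `id`,
#'   `trueClass`, `spans` (`data.frame` kind/start/end), `globinMap`
#'   (named integer map for globin labels, protein coordinates),
#'   `globinTemplateMap` (edit script of the globin segment) and
#'   `globinKind`.
#' @export
buildProtein <- function(spec, model = mutationModel(), id = "protein1",
                         templates = globinTemplates(), seed = NULL) {
  aa <- aminoAcids()
  withSeed(seed, {
    segs <- character()
    spans <- list()
    globinMap <- NULL
    globinTemplateMap <- NULL
    globinKind <- NA_character_
    offset <- 0L
    addSeg <- function(kind, s) {
      segs <<- c(segs, s)
      spans[[length(spans) + 1L]] <<- data.frame(
        kind = kind, start = offset + 1L, end = offset + nchar(s),
        stringsAsFactors = FALSE)
      offset <<- offset + nchar(s)
    }
    if (spec$signal)
      addSeg("SIG", templateSequence(templates[["SIG"]]))
    if (spec$nTermExt > 0L)
      addSeg("EXT", paste(sample(aa, spec$nTermExt, TRUE), collapse = ""))
    for (dn in spec$domains) {
      tpl <- templates[[dn]]
      if (is.null(tpl))
        stop("unknown template name: ", dn)
      mut <- mutateTemplate(tpl, model, seed = NULL)
      if (dn %in% c("GLB3", "GLB2", "SGB")) {
        globinKind <- dn
        globinMap <- mut$annotations + offset
        globinTemplateMap <- mut$templateMap
      }
      addSeg(dn, mut$sequence)
    }
    if (spec$cTermExt > 0L)
      addSeg("EXT", paste(sample(aa, spec$cTermExt, TRUE), collapse = ""))
    spans <- do.call(rbind, spans)
    sequence <- paste(segs, collapse = "")
    trueClass <- trueClassFromGrammar(spans, globinKind, nchar(sequence),
                                      signal = spec$signal,
                                      templates = templates)
    list(sequence = sequence,
         truth = list(id = id, trueClass = trueClass, spans = spans,
                      globinMap = globinMap,
                      globinTemplateMap = globinTemplateMap,
                      globinKind = globinKind))
  })
}

## True class from the realized grammar, through the same rule table as
## the classifier (so classifier recovery is well-defined).
trueClassFromGrammar <- function(spans, globinKind, length, signal = FALSE,
                                 templates = globinTemplates()) {
  fam <- if (is.na(globinKind)) "none" else
    templateFamily(templates[[globinKind]])
  hits <- spans[!spans$kind %in% c("EXT"), , drop = FALSE]
  hits$score <- 1
  callLabel(classifyArchitecture(hits, fam, length, signal = signal))
}

#' Default per-taxon presence profile for synthetic proteomes
#'
#' A small emulation of the fungal phyla: an Ascomycota-like taxon rich in
#' flavohemoglobins and sensor globins, a Saccharomycotina-like taxon
#' carrying incomplete FHbs, a Basidiomycota-like taxon with sparser
#' globin content, and a chytrid-like taxon carrying T1 globins.
#'
#' @return A `data.frame` with columns `taxon`, `phylum` and one presence
#'   probability column per architecture class.
#' @export
defaultTaxonProfile <- function() {
  data.frame(
    taxon = c("Pezizomycotina_like", "Saccharomycotina_like",
              "Basidiomycota_like", "Chytrid_like"),
    phylum = c("Ascomycota", "Ascomycota", "Basidiomycota",
               "Chytridiomycota"),
    FHb = c(0.9, 0.6, 0.5, 0),
    FHb_incomplete = c(0, 0.7, 0, 0),
    Fgb = c(0.1, 0, 0, 0),
    Sgb = c(0.7, 0.2, 0.4, 0.8),
    SensorChimera = c(0.2, 0, 0.1, 0),
    T1 = c(0, 0, 0, 0.5),
    T1Chimera = c(0, 0, 0, 0.3),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-genome proteome with ground truth
#'
#' Assigns genomes to the profile's taxa in rotation; for each genome and
#' each architecture class, a protein is planted with the class's presence
#' probability.  Target identities are drawn uniformly from
#' `identityRange`.  True multiple alignments of the globin domains are
#' derived per family from the template-coordinate edit scripts — no
#' aligner is run.
#'
#' @param taxonProfile Profile `data.frame` (see [defaultTaxonProfile()]).
#' @param nGenomes Number of genomes (>= 1).
#' @param seed Integer seed; for a fixed seed all outputs are
#'   byte-identical across runs.
#' @param identityRange Range of target identities (default `c(0.4, 0.8)`).
#' @param indelRate Indels per 100 residues (default 1).
#' @param dir Optional output directory; when given, writes
#'   `proteome.fasta` (60-column wrap), `ground_truth.tsv`,
#'   `taxonomy.tsv` (per-protein sidecar), `genomes.tsv` (full genome
#'   roster) and `true_msa_<family>.fasta`.
#' @param templates Named list of packaged templates.
#' @return Invisibly, a list with `proteins` (named character vector),
#'   `truth` (`data.frame`), `truthDetails` (list of per-protein truth
#'   records), `genomes` (`data.frame`) and `msas` (named list of aligned
#'   named character vectors, per family).
#' @export
buildProteome <- function(taxonProfile = defaultTaxonProfile(),
                          nGenomes = 20L, seed = 1L,
                          identityRange = c(0.4, 0.8), indelRate = 1,
                          dir = NULL, templates = globinTemplates()) {
  if (nGenomes < 1L)
    stop("nGenomes must be at least 1")
  labels <- setdiff(architectureLabels(), "NonGlobin")
  specs <- classArchitectures()
  withSeed(seed, {
    proteins <- character()
    truthDetails <- list()
    genomes <- data.frame(genome = sprintf("g%03d", seq_len(nGenomes)),
                          taxon = taxonProfile$taxon[
                            (seq_len(nGenomes) - 1L) %%
                              nrow(taxonProfile) + 1L],
                          stringsAsFactors = FALSE)
    genomes$phylum <- taxonProfile$phylum[match(genomes$taxon,
                                                taxonProfile$taxon)]
    for (g in seq_len(nGenomes)) {
      prof <- taxonProfile[match(genomes$taxon[g], taxonProfile$taxon), ]
      for (lab in labels) {
        p <- prof[[lab]]
        if (is.null(p) || stats::runif(1L) >= p) next
        ident <- stats::runif(1L, identityRange[1L], identityRange[2L])
        model <- mutationModel(targetIdentity = ident,
                               indelRate = indelRate)
        pid <- paste0(genomes$genome[g], "_", lab)
        bp <- buildProtein(specs[[lab]], model, id = pid,
                           templates = templates, seed = NULL)
        bp$truth$genome <- genomes$genome[g]
        bp$truth$taxon <- genomes$taxon[g]
        bp$truth$phylum <- genomes$phylum[g]
        proteins[[pid]] <- bp$sequence
        truthDetails[[pid]] <- bp$truth
      }
    }
    truth <- do.call(rbind, lapply(truthDetails, function(tr)
      data.frame(id = tr$id, true_class = tr$trueClass,
                 genome = tr$genome, taxon = tr$taxon, phylum = tr$phylum,
                 spans = paste0(tr$spans$kind, ":", tr$spans$start, "-",
                                tr$spans$end, collapse = ";"),
                 globin_map = if (is.null(tr$globinMap)) "" else
                   paste0(names(tr$globinMap), "=", tr$globinMap,
                          collapse = ","),
                 stringsAsFactors = FALSE)))
    rownames(truth) <- NULL
    msas <- buildTrueMsas(proteins, truthDetails, templates)
    out <- list(proteins = proteins, truth = truth,
                truthDetails = truthDetails, genomes = genomes,
                msas = msas)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      writeFastaAA(proteins, file.path(dir, "proteome.fasta"))
      utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sidecar <- truth[, c("id", "genome", "taxon", "phylum")]
      utils::write.table(sidecar, file.path(dir, "taxonomy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(genomes, file.path(dir, "genomes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (fam in names(msas))
        writeFastaAA(msas[[fam]],
                     file.path(dir, paste0("true_msa_", fam, ".fasta")))
    }
    invisible(out)
  })
}

## Aligner-free true alignments of the globin domains, one per family,
## from the template-coordinate edit scripts.
buildTrueMsas <- function(proteins, truthDetails, templates) {
  byFam <- split(truthDetails, vapply(truthDetails, function(tr)
    if (is.na(tr$globinKind)) "none" else
      templateFamily(templates[[tr$globinKind]]), ""))
  byFam$none <- NULL
  lapply(byFam, function(trs) {
    ## domain-local maps and sequences
    rows <- lapply(trs, function(tr) {
      span <- tr$spans[tr$spans$kind == tr$globinKind, ]
      dom <- substr(proteins[[tr$id]], span$start, span$end)
      list(id = tr$id, seq = seqToChars(dom), map = tr$globinTemplateMap)
    })
    L <- length(rows[[1L]]$map)
    ## anchor each unmapped (inserted) residue to the last mapped
    ## template position before it
    insBlocks <- lapply(rows, function(r) {
      inv <- rep(NA_integer_, length(r$seq))
      mappedT <- which(!is.na(r$map))
      inv[r$map[mappedT]] <- mappedT
      anchor <- integer(0)
      blocks <- vector("list", L + 1L)
      lastT <- 0L
      for (q in seq_along(r$seq)) {
        if (!is.na(inv[q])) lastT <- inv[q]
        else blocks[[lastT + 1L]] <- c(blocks[[lastT + 1L]], q)
      }
      blocks
    })
    widths <- vapply(seq_len(L + 1L), function(a)
      max(vapply(insBlocks, function(b) length(b[[a]]), 0L)), 0L)
    aligned <- vapply(seq_along(rows), function(s) {
      r <- rows[[s]]
      b <- insBlocks[[s]]
      out <- character()
      for (a in 0:L) {
        ins <- b[[a + 1L]]
        pad <- widths[a + 1L] - length(ins)
        out <- c(out, r$seq[ins], rep("-", pad))
        if (a < L) {
          t <- a + 1L
          out <- c(out, if (is.na(r$map[t])) "-" else r$seq[r$map[t]])
        }
      }
      paste(out, collapse = "")
    }, "")
    names(aligned) <- vapply(rows, `[[`, "", "id")
    aligned
  })
}

#' Build a two-clade synthetic alignment with a known generating tree
#'
#' Two clade ancestors are derived from the F-globin template at the
#' between-clade identity; clade members are then derived from their
#' ancestor at the within-clade identity.  No indels are introduced, so
#' the raw sequences are already aligned.  Used to exercise the
#' neighbor-joining and bootstrap machinery against planted structure.
#'
#' @param nPerClade Sequences per clade (default 4).
#' @param withinIdentity Member-to-ancestor identity (default 0.95).
#' @param betweenIdentity Ancestor-to-template identity (default 0.4).
#' @param seed Integer seed.
#' @return List with `msa` (aligned named character vector) and `split`
#'   (character vector of the taxa in clade A).
#' @export
twoCladeAlignment <- function(nPerClade = 4L, withinIdentity = 0.95,
                              betweenIdentity = 0.4, seed = 1L) {
  tpl <- globinTemplates()[["GLB3"]]
  withSeed(seed, {
    anc <- lapply(1:2, function(i)
      mutateTemplate(tpl, mutationModel(betweenIdentity, indelRate = 0,
                                        conserveChecklist = FALSE),
                     seed = NULL)$sequence)
    mkClade <- function(ancSeq, prefix) {
      ancTpl <- domainTemplate(prefix, ancSeq)
      out <- vapply(seq_len(nPerClade), function(i)
        mutateTemplate(ancTpl,
                       mutationModel(withinIdentity, indelRate = 0,
                                     conserveChecklist = FALSE),
                       seed = NULL)$sequence, "")
      names(out) <- paste0(prefix, seq_len(nPerClade))
      out
    }
    msa <- c(mkClade(anc[[1L]], "cladeA_"), mkClade(anc[[2L]], "cladeB_"))
    list(msa = msa, split = names(msa)[seq_len(nPerClade)])
  })
}
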