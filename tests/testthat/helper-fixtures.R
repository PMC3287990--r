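## Shared helpers for the test suite.  All fixtures are built in code.

tpls <- globinTemplates()

## A tiny toy alignment trio used by the MSA tests.
toyMsa <- function() {
  c(s1 = "ACDE", s2 = "ACDE", s3 = "AC-E")
}

## Independent brute-force enumeration of aligned residue pairs:
## walks columns one at a time, tracking per-row residue counters by hand.
bruteForcePairs <- function(msa) {
  msa <- msa[order(names(msa))]
  rows <- strsplit(unname(msa), "")
  ids <- names(msa)
  counters <- integer(length(rows))
  out <- character()
  for (col in seq_along(rows[[1L]])) {
    here <- integer(0)
    for (s in seq_along(rows)) {
      if (rows[[s]][col] != "-") {
        counters[s] <- counters[s] + 1L
        here <- c(here, s)
      }
    }
    if (length(here) >= 2L) {
      for (a in seq_along(here)) {
        for (b in seq_along(here)) {
          if (a < b) {
            s <- here[a]; t <- here[b]
            out <- c(out, paste0(ids[s], ":", counters[s], "|",
                                 ids[t], ":", counters[t]))
          }
        }
      }
    }
  }
  out
}

## An additive distance matrix from the 4-taxon tree ((a:2,b:3):1,c:4,d:5)
## built by summing path lengths by hand.
additive4 <- function() {
  taxa <- c("a", "b", "c", "d")
  D <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  D["a", "b"] <- 2 + 3
  D["a", "c"] <- 2 + 1 + 4
  D["a", "d"] <- 2 + 1 + 5
  D["b", "c"] <- 3 + 1 + 4
  D["b", "d"] <- 3 + 1 + 5
  D["c", "d"] <- 4 + 5
  D + t(D)
}
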