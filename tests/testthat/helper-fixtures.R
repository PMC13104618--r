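# Shared fixtures and independent oracles, all built in code.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

# The six packaged reference profiles instantiated with seeded synthetic
# sequences (fixed seed shared across the suite).
fixture_refs <- function(seed = 101L) synthetic_references(seed)

# Independent oracle: top-down memoized recursion over the affine-gap
# state machine, written without the DP matrices of the implementation.
# Gap of length L costs open + L * extend; end gaps penalized.
brute_force_score <- function(a, b, submat, open = 10, extend = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  rec <- function(i, j, state) {
    # best score of aligning a[i..], b[j..] given the previous column state
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > length(av) && j > length(bv)) return(0)
    cand <- -Inf
    if (i <= length(av) && j <= length(bv))
      cand <- max(cand, submat[av[i], bv[j]] + rec(i + 1L, j + 1L, "m"))
    if (i <= length(av)) {
      gap <- if (state == "ga") extend else open + extend
      cand <- max(cand, -gap + rec(i + 1L, j, "ga"))
    }
    if (j <= length(bv)) {
      gap <- if (state == "gb") extend else open + extend
      cand <- max(cand, -gap + rec(i, j + 1L, "gb"))
    }
    memo[[key]] <- cand
    cand
  }
  rec(1L, 1L, "m")
}

# Column-scanning identity recount, independent of the aligner's counter.
recount_identities <- function(aln) {
  av <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  sum(av == bv & av != "-" & av != "X")
}

# A small fixed GenBank snippet exercising the parser paths: verbatim
# translation, derived translation (+ and - strand), multi-record.
write_fixture_genbank <- function(path) {
  lines <- c(
    "LOCUS       pTEST1 90 bp    DNA     circular BCT",
    "DEFINITION  fixture record one.",
    "FEATURES             Location/Qualifiers",
    "     source          1..90",
    "     CDS             3..14",
    '                     /gene="traN"',
    '                     /product="conjugal transfer protein"',
    '                     /translation="MKT"',
    "     CDS             21..32",
    '                     /product="TraN"',
    "     CDS             complement(41..52)",
    '                     /gene="trhN"',
    "ORIGIN",
    paste0("        1 ccatgaaaac ctaacccccc atgaaaacct aaccccccgg ",
           "ttaggttttc atcccccccc"),
    "       61 cccccccccc cccccccccc cccccccccc",
    "//",
    "LOCUS       pTEST2 40 bp    DNA     linear BCT",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..12",
    '                     /gene="traM"',
    '                     /translation="MTA"',
    "     CDS             13..24",
    '                     /product="putative TraN"',
    '                     /translation="MNE"',
    "ORIGIN",
    "        1 atgactgcgt aaatgaacga ataacccccc cccccccccc",
    "//")
  writeLines(lines, path)
  path
}

# Small typing fixture: typed records with plasmid metadata.
fixture_metadata_tsv <- function(path) {
  writeLines(c(
    "# synthetic metadata fixture",
    paste("plasmid_id", "host_genus", "host_family", "replicons",
          "mob_type", "ptu", "carbapenemases", sep = "\t"),
    paste("p1", "Klebsiella", "Enterobacteriaceae", "IncHI1A;IncHI1B",
          "MOBH", "PTU-HI1", "blaNDM-1", sep = "\t"),
    paste("p2", "Escherichia", "Enterobacteriaceae", "IncA/C2", "MOBH",
          "PTU-C", "", sep = "\t")), path)
  path
}
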