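# Synthetic plasmid corpora with known ground truth: seeded reference
# proteins, a substitution/indel mutator with a replayable event log, and
# a corpus builder that emits GenBank-style records plus metadata.

#' Generate a seeded synthetic reference protein
#'
#' Draws a pseudorandom amino-acid sequence of exactly `length` residues
#' and plants the anchor letters at the tip-domain boundaries, yielding a
#' `ReferenceProfile` whose [verify_reference()] report passes by
#' construction. Deterministic under `seed`.
#'
#' @param name Profile name.
#' @param length Protein length (aa).
#' @param tip_start,tip_end 1-based tip-domain boundaries.
#' @param anchor_start,anchor_end Anchor residues planted at the
#'   boundaries.
#' @param seed Integer seed.
#' @param family Family letter (`M`, `L`, `V`, `S`, `other`).
#' @param protein_id,source_plasmid Identifier strings recorded on the
#'   profile (marked synthetic by default).
#' @return A `ReferenceProfile` with sequence.
#' @examples
#' r <- make_reference("TraN_Malpha_like", 912, 230, 360, "C", "D", seed = 7)
#' verify_reference(r)
#' @export
make_reference <- function(name, length, tip_start, tip_end, anchor_start,
                           anchor_end, seed, family = "M",
                           protein_id = paste0("SYN_", name),
                           source_plasmid = "synthetic") {
  if (tip_start < 1L || tip_end > length || tip_start >= tip_end)
    stop("anchor positions out of range for length ", length, call. = FALSE)
  chars <- with_substream(seed, paste0("ref/", name),
                          sample(AA20, length, replace = TRUE))
  chars[tip_start] <- anchor_start
  chars[tip_end] <- anchor_end
  new_reference_profile(name = name, protein_id = protein_id,
                        source_plasmid = source_plasmid, family = family,
                        length = length, tip_start = tip_start,
                        tip_end = tip_end, anchor_start = anchor_start,
                        anchor_end = anchor_end,
                        sequence = paste(chars, collapse = ""))
}

#' Seeded synthetic stand-ins for the built-in reference profiles
#'
#' Builds one synthetic sequence per packaged reference profile
#' ([reference_profiles()]), honouring each profile's deposited length,
#' tip span and anchor residues. These stand-ins let the whole pipeline
#' run and be tested without fetching the deposited accessions; they are
#' labelled synthetic in their `protein_id`.
#'
#' @param seed Integer seed.
#' @param profiles Profile list to instantiate (default: packaged table).
#' @return Named list of `ReferenceProfile`s with sequences.
#' @export
synthetic_references <- function(seed = 101L,
                                 profiles = reference_profiles()) {
  refs <- lapply(profiles, function(p)
    make_reference(p$name, p$length, p$tip_start, p$tip_end,
                   p$anchor_start, p$anchor_end, seed = seed,
                   family = p$family,
                   protein_id = paste0("SYN_", p$protein_id),
                   source_plasmid = p$source_plasmid))
  names(refs) <- vapply(refs, function(r) r$name, character(1L))
  refs
}

#' Mutate a protein sequence with a replayable event log
#'
#' Applies per-site substitutions (to a uniformly chosen different
#' residue) and insertions/deletions (geometric lengths with mean
#' `indel_length`, equal insertion and deletion probability) in a single
#' left-to-right pass. Every event is logged in parent coordinates;
#' [apply_mutation_log()] replays the log to reproduce the child exactly.
#' Deterministic under `seed`.
#'
#' @param seq Parent amino-acid sequence.
#' @param substitution_rate Per-site substitution probability in `[0,1]`.
#' @param indel_rate Per-site probability of starting an indel.
#' @param indel_length Mean indel length (geometric).
#' @param seed Integer seed.
#' @return List with `sequence` (child) and `log` (data frame `event`,
#'   `pos`, `ref`, `alt`).
#' @export
mutate_sequence <- function(seq, substitution_rate = 0, indel_rate = 0,
                            indel_length = 3, seed = 1L) {
  check_protein(seq)
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, indel_length >= 1)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  empty_log <- data.frame(event = character(0L), pos = integer(0L),
                          ref = character(0L), alt = character(0L),
                          stringsAsFactors = FALSE)
  with_substream(seed, "mutate", {
    if (indel_rate == 0) {
      # vectorized substitution-only path
      hit <- which(stats::runif(n) < substitution_rate)
      out <- chars
      if (length(hit)) {
        alt <- vapply(chars[hit], function(c0)
          sample(setdiff(AA20, c0), 1L), character(1L))
        out[hit] <- alt
        log <- data.frame(event = "sub", pos = hit, ref = chars[hit],
                          alt = alt, stringsAsFactors = FALSE)
      } else log <- empty_log
      list(sequence = paste(out, collapse = ""), log = log)
    } else {
      out <- character(0L)
      logs <- list()
      i <- 1L
      while (i <= n) {
        u <- stats::runif(1L)
        if (u < indel_rate / 2) {                     # deletion at i
          L <- min(stats::rgeom(1L, 1 / indel_length) + 1L, n - i + 1L)
          logs[[length(logs) + 1L]] <- data.frame(
            event = "del", pos = i,
            ref = paste(chars[i:(i + L - 1L)], collapse = ""), alt = "",
            stringsAsFactors = FALSE)
          i <- i + L
          next
        }
        if (u < indel_rate) {                         # insertion before i
          L <- stats::rgeom(1L, 1 / indel_length) + 1L
          ins <- paste(sample(AA20, L, replace = TRUE), collapse = "")
          logs[[length(logs) + 1L]] <- data.frame(
            event = "ins", pos = i, ref = "", alt = ins,
            stringsAsFactors = FALSE)
          out <- c(out, strsplit(ins, "", fixed = TRUE)[[1L]])
        }
        if (stats::runif(1L) < substitution_rate) {
          alt <- sample(setdiff(AA20, chars[i]), 1L)
          logs[[length(logs) + 1L]] <- data.frame(
            event = "sub", pos = i, ref = chars[i], alt = alt,
            stringsAsFactors = FALSE)
          out <- c(out, alt)
        } else out <- c(out, chars[i])
        i <- i + 1L
      }
      log <- if (length(logs)) do.call(rbind, logs) else empty_log
      list(sequence = paste(out, collapse = ""), log = log)
    }
  })
}

#' Replay a mutation log against the parent sequence
#'
#' @param seq Parent sequence passed to [mutate_sequence()].
#' @param log Event log returned by it.
#' @return The child sequence.
#' @export
apply_mutation_log <- function(seq, log) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- character(0L)
  cursor <- 1L
  for (k in seq_len(nrow(log))) {
    pos <- log$pos[k]
    if (pos > cursor) {
      out <- c(out, chars[cursor:(pos - 1L)])
      cursor <- pos
    }
    ev <- log$event[k]
    if (ev == "sub") {
      stopifnot(chars[cursor] == log$ref[k])
      out <- c(out, log$alt[k])
      cursor <- cursor + 1L
    } else if (ev == "del") {
      cursor <- cursor + nchar(log$ref[k])
    } else if (ev == "ins") {
      out <- c(out, strsplit(log$alt[k], "", fixed = TRUE)[[1L]])
    } else stop("unknown event: ", ev, call. = FALSE)
  }
  if (cursor <= length(chars)) out <- c(out, chars[cursor:length(chars)])
  paste(out, collapse = "")
}

# Project a parent-coordinate position through a mutation log onto the
# child; deletions covering the position shift it to the next surviving
# residue.
#' @noRd
project_position <- function(log, pos) {
  shift <- 0L
  for (k in seq_len(nrow(log))) {
    p <- log$pos[k]
    if (log$event[k] == "ins" && p <= pos) shift <- shift + nchar(log$alt[k])
    if (log$event[k] == "del") {
      L <- nchar(log$ref[k])
      if (p + L - 1L < pos) shift <- shift - L
      else if (p <= pos) shift <- shift - (pos - p)  # pos inside deletion
    }
  }
  pos + shift
}

#' Largest-remainder integer quotas
#'
#' Turns a weight vector into category counts summing exactly to `n`,
#' assigning floors first and distributing the remainder by largest
#' fractional part (ties by category order).
#'
#' @param weights Non-negative weights (normalized internally).
#' @param n Total count.
#' @return Integer vector of counts, same names as `weights`.
#' @export
quota_counts <- function(weights, n) {
  w <- weights / sum(weights)
  x <- w * n
  base <- floor(x + 1e-9)
  need <- n - sum(base)
  if (need > 0) {
    rem <- x - base
    give <- order(-rem, seq_along(rem))[seq_len(need)]
    base[give] <- base[give] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Corpus simulation settings
#'
#' Defines a synthetic MPF_F plasmid corpus. The defaults reproduce the
#' structure of the surveyed corpus: 1,517 plasmids of which 121 carry no
#' TraN annotation, 1,358 a single copy and 38 carry 2–3 copies (36
#' double, 2 triple — 1,436 proteins in total); protein size classes
#' split 898 short / 216 medium / 160 long / 162 outside the bins;
#' carbapenemase carriage 72/184 among medium-class and 24/155 among
#' long-class plasmids, with host-taxon mixes matching the reported
#' family compositions. In `"quota"` mode category counts are hit
#' exactly via largest-remainder allocation (the printed survey
#' percentages are exact ratios, so this mode regression-locks them);
#' `"random"` mode draws every category independently.
#'
#' @param n_plasmids Number of plasmids.
#' @param copy_number Named weights (or quota counts) over copies
#'   `"0","1","2","3"`.
#' @param class_mix Named weights over protein classes
#'   (`S`, `Malpha`, `Mbeta`, `Lalpha`, `Lbeta`, `Lgamma`, `V`,
#'   `other`); applies to proteins, all copies of one plasmid sharing a
#'   class.
#' @param substitution_rate,indel_rate,indel_length Divergence of each
#'   protein from its class seed reference (see [mutate_sequence()]).
#' @param trait_rates Per-family list with elements `carbapenemase`
#'   (probability) and `hosts` (data frame `genus`, `family`, `w`).
#' @param mode `"quota"` or `"random"`.
#' @param seed Master seed; all draws flow from it through labelled
#'   substreams, so sub-generators are order-independent.
#' @return A `CorpusSpec` list.
#' @export
corpus_spec <- function(n_plasmids = 1517L,
                        copy_number = c("0" = 121, "1" = 1358,
                                        "2" = 36, "3" = 2),
                        class_mix = c(S = 898, Malpha = 54, Mbeta = 162,
                                      Lalpha = 64, Lbeta = 48, Lgamma = 48,
                                      V = 0, other = 162),
                        substitution_rate = 0.1, indel_rate = 0,
                        indel_length = 3,
                        trait_rates = default_trait_rates(),
                        mode = c("quota", "random"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_plasmids >= 1L, all(copy_number >= 0), sum(copy_number) > 0,
            all(class_mix >= 0), sum(class_mix) > 0,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  stopifnot(all(names(copy_number) %in% c("0", "1", "2", "3")))
  known <- c("S", "Malpha", "Mbeta", "Lalpha", "Lbeta", "Lgamma", "V",
             "other")
  if (!all(names(class_mix) %in% known))
    stop("unknown class in class_mix: ",
         paste(setdiff(names(class_mix), known), collapse = ", "),
         call. = FALSE)
  structure(list(n_plasmids = as.integer(n_plasmids),
                 copy_number = copy_number, class_mix = class_mix,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate, indel_length = indel_length,
                 trait_rates = trait_rates, mode = mode,
                 seed = as.integer(seed)),
            class = "CorpusSpec")
}

#' @noRd
default_trait_rates <- function() {
  ent <- "Enterobacteriaceae"
  list(
    M = list(carbapenemase = 72 / 184, hosts = data.frame(
      genus = c("Escherichia", "Klebsiella", "Citrobacter", "Salmonella",
                "Aeromonas", "Vibrio", "Proteus", "Shewanella"),
      family = c(ent, ent, ent, ent, "Aeromonadaceae", "Vibrionaceae",
                 "Morganellaceae", "Shewanellaceae"),
      w = c(40, 46, 18, 18, 20, 16, 14, 12), stringsAsFactors = FALSE)),
    L = list(carbapenemase = 24 / 155, hosts = data.frame(
      genus = c("Salmonella", "Escherichia", "Klebsiella", "Enterobacter",
                "Acinetobacter"),
      family = c(ent, ent, ent, ent, "Moraxellaceae"),
      w = c(60, 40, 40, 14, 1), stringsAsFactors = FALSE)),
    S = list(carbapenemase = 0.05, hosts = data.frame(
      genus = c("Escherichia", "Klebsiella", "Salmonella"),
      family = ent, w = c(5, 3, 2), stringsAsFactors = FALSE)),
    V = list(carbapenemase = 0, hosts = data.frame(
      genus = "Acinetobacter", family = "Moraxellaceae", w = 1,
      stringsAsFactors = FALSE)),
    other = list(carbapenemase = 0, hosts = data.frame(
      genus = "Xanthomonas", family = "Xanthomonadaceae", w = 1,
      stringsAsFactors = FALSE)),
    none = list(carbapenemase = 0, hosts = data.frame(
      genus = c("Escherichia", "Klebsiella"), family = ent, w = c(3, 1),
      stringsAsFactors = FALSE)))
}

#' @noRd
class_info <- function() {
  data.frame(
    class = c("S", "Malpha", "Mbeta", "Lalpha", "Lbeta", "Lgamma", "V",
              "other"),
    family = c("S", "M", "M", "L", "L", "L", "V", "other"),
    ref = c("TraN_S_synthetic", "TraN_Malpha", "TraN_Mbeta", "TraN_Lalpha",
            "TraN_Lbeta", "TraN_Lgamma", "TraN_V", "TraN_other_synthetic"),
    stringsAsFactors = FALSE)
}

#' Build a synthetic plasmid corpus with ground truth
#'
#' Realizes a [corpus_spec()]: draws per-plasmid TraN copy numbers, makes
#' each TraN protein a mutated descendant of its class's seed reference,
#' back-translates it with the bacterial code into a CDS annotated
#' `product="TraN"` (IncH-like long-class genes are annotated
#' `gene="trhN"` instead, as deposited IncH records are), adds decoy CDS
#' (`traM`, `repA`, and a `"putative TraN"` product that must not match
#' exact extraction), and draws host taxa and carbapenemase carriage per
#' family. Short and outside-bin classes descend from additional
#' synthetic seed references (605 aa and 1,882 aa).
#'
#' @param spec A `CorpusSpec`.
#' @return List with `records` (a `tran_corpus` of `PlasmidRecord`s),
#'   `metadata` (data frame), `truth` (data frame: per-record generating
#'   reference, true class/family, true tip span, mutation counts),
#'   `references` (all seed `ReferenceProfile`s) and `spec`. Byte-stable
#'   under a fixed spec and seed.
#' @export
build_corpus <- function(spec) {
  stopifnot(inherits(spec, "CorpusSpec"))
  seed <- spec$seed
  refs <- synthetic_references(seed)
  refs$TraN_S_synthetic <- make_reference(
    "TraN_S_synthetic", 605L, 150L, 280L, "C", "G", seed = seed,
    family = "S")
  refs$TraN_other_synthetic <- make_reference(
    "TraN_other_synthetic", 1882L, 400L, 700L, "A", "W", seed = seed,
    family = "other")
  ci <- class_info()
  active <- names(spec$class_mix)[spec$class_mix > 0]
  miss <- setdiff(ci$ref[match(active, ci$class)], names(refs))
  if (length(miss))
    stop("class requested without a seed reference: ",
         paste(miss, collapse = ", "), call. = FALSE)

  n <- spec$n_plasmids
  ids <- sprintf("p%04d", seq_len(n))

  # per-plasmid copy numbers
  cats <- as.integer(names(spec$copy_number))
  copies <- if (spec$mode == "quota") {
    counts <- quota_counts(spec$copy_number, n)
    rep(cats, counts)
  } else {
    with_substream(seed, "copies",
                   sample(cats, n, replace = TRUE,
                          prob = spec$copy_number / sum(spec$copy_number)))
  }
  copies <- with_substream(seed, "copies/permute",
                           copies[sample.int(length(copies))])

  # per-plasmid class, exact over proteins in quota mode
  total_prot <- sum(copies)
  classes <- rep(NA_character_, n)
  carrier <- which(copies > 0)
  if (spec$mode == "quota") {
    quota <- quota_counts(spec$class_mix, total_prot)
    remaining <- quota
    ord <- carrier[order(-copies[carrier])]  # multi-copy first
    for (p in ord) {
      pick <- which.max(remaining - ifelse(remaining >= copies[p], 0, Inf))
      if (remaining[pick] < copies[p]) pick <- which.max(remaining)
      classes[p] <- names(remaining)[pick]
      remaining[pick] <- remaining[pick] - copies[p]
    }
  } else {
    classes[carrier] <- with_substream(
      seed, "classes",
      sample(names(spec$class_mix), length(carrier), replace = TRUE,
             prob = spec$class_mix / sum(spec$class_mix)))
  }

  records <- vector("list", n)
  truth_rows <- vector("list", n)
  for (p in seq_len(n)) {
    built <- build_plasmid(ids[p], copies[p], classes[p], refs, ci, spec)
    records[[p]] <- built$record
    truth_rows[[p]] <- built$truth
  }
  truth <- do.call(rbind, truth_rows)

  metadata <- draw_metadata(ids, classes, ci, spec)
  records <- attach_metadata(structure(records, class = "tran_corpus"),
                             metadata)

  list(records = records, metadata = metadata, truth = truth,
       references = refs, spec = spec)
}

#' @noRd
build_plasmid <- function(id, k, class, refs, ci, spec) {
  feats <- list()
  parts <- character(0L)
  pos <- 1L
  spacer <- "acgtacgtac"
  add_cds <- function(aa, gene, product, strand = "+",
                      with_translation = TRUE) {
    nt <- back_translate(aa)
    genome_nt <- if (strand == "-") revcomp_chr(nt) else nt
    start <- pos + nchar(spacer)
    end <- start + nchar(genome_nt) - 1L
    parts <<- c(parts, spacer, genome_nt)
    pos <<- end + 1L
    feats[[length(feats) + 1L]] <<- data.frame(
      index = length(feats) + 1L, gene = gene, product = product,
      start = start, end = end, strand = strand,
      translation = if (with_translation) aa else NA_character_,
      stringsAsFactors = FALSE)
    length(feats)
  }
  truth <- NULL
  if (k > 0L) {
    info <- ci[ci$class == class, ]
    ref <- refs[[info$ref]]
    rows <- vector("list", k)
    for (j in seq_len(k)) {
      mut <- mutate_sequence(ref$sequence, spec$substitution_rate,
                             spec$indel_rate, spec$indel_length,
                             seed = substream_seed(spec$seed,
                                                   paste0(id, "/", j)))
      if (info$family == "L")
        idx <- add_cds(mut$sequence, "trhN", "conjugal transfer protein")
      else
        idx <- add_cds(mut$sequence, NA_character_, "TraN")
      rows[[j]] <- data.frame(
        record_id = paste0(id, "|", idx), plasmid_id = id,
        class = info$ref, subclade = info$ref, family = info$family,
        seed_ref = info$ref,
        n_sub = sum(mut$log$event == "sub"),
        n_indel = sum(mut$log$event != "sub"),
        tip_start = project_position(mut$log, ref$tip_start),
        tip_end = project_position(mut$log, ref$tip_end),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
  }
  # decoys: never extracted under the exact default name set
  add_cds("MKTAYIAKQRQISFVKSHFSRQLEERL", "traM", "TraM", strand = "-")
  add_cds("MSDLIVKANELHQALAGLSQE", "repA",
          "replication initiation protein")
  add_cds("MNTELLKQAVRG", NA_character_, "putative TraN")
  parts <- c(parts, spacer)
  sequence <- toupper(paste(parts, collapse = ""))
  features <- do.call(rbind, feats)
  rec <- new_plasmid_record(id, nchar(sequence), sequence, features)
  list(record = rec, truth = truth)
}

#' @noRd
revcomp_chr <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' @noRd
draw_metadata <- function(ids, classes, ci, spec) {
  fam <- ifelse(is.na(classes), "none",
                ci$family[match(classes, ci$class)])
  n <- length(ids)
  host_genus <- character(n)
  host_family <- character(n)
  carb <- vector("list", n)
  for (f in unique(fam)) {
    sel <- which(fam == f)
    tr <- spec$trait_rates[[f]] %||% spec$trait_rates$none
    nf <- length(sel)
    hosts <- tr$hosts
    hi <- if (spec$mode == "quota") {
      counts <- quota_counts(stats::setNames(hosts$w, hosts$genus), nf)
      idx <- rep(seq_len(nrow(hosts)), counts)
      with_substream(spec$seed, paste0("hosts/", f),
                     idx[sample.int(length(idx))])
    } else {
      with_substream(spec$seed, paste0("hosts/", f),
                     sample(seq_len(nrow(hosts)), nf, replace = TRUE,
                            prob = hosts$w))
    }
    host_genus[sel] <- hosts$genus[hi]
    host_family[sel] <- hosts$family[hi]
    pos <- if (spec$mode == "quota") {
      kf <- quota_counts(c(yes = tr$carbapenemase,
                           no = 1 - tr$carbapenemase), nf)[["yes"]]
      with_substream(spec$seed, paste0("carb/", f),
                     sample.int(nf, kf))
    } else {
      which(with_substream(spec$seed, paste0("carb/", f),
                           stats::runif(nf)) < tr$carbapenemase)
    }
    for (i in seq_len(nf))
      carb[[sel[i]]] <- if (i %in% pos) "blaNDM-1" else character(0L)
  }
  repl <- c(S = "IncFII", M = "IncA/C2", L = "IncHI1A;IncHI1B(R27)",
            V = "", other = "", none = "IncFII")
  mob <- c(S = "MOBF", M = "MOBH", L = "MOBH", V = "MOBF", other = "",
           none = "")
  ptu <- c(S = "PTU-FE", M = "PTU-C", L = "PTU-HI1", V = "PTU-Pse1",
           other = "", none = "")
  data.frame(
    plasmid_id = ids, host_genus = host_genus, host_family = host_family,
    replicons = I(lapply(repl[fam], function(x)
      if (nzchar(x)) strsplit(x, ";", fixed = TRUE)[[1L]]
      else character(0L))),
    mob_type = ifelse(nzchar(mob[fam]), mob[fam], NA_character_),
    ptu = ifelse(nzchar(ptu[fam]), ptu[fam], NA_character_),
    carbapenemases = I(carb), stringsAsFactors = FALSE)
}

# Lazily built reverse-codon table: lexicographically first codon per
# residue under the bacterial code; X back-translates to NNN.
codon_env <- new.env(parent = emptyenv())

#' @noRd
rev_codon_table <- function() {
  if (is.null(codon_env$tab)) {
    gc <- Biostrings::getGeneticCode("11")
    codons <- sort(names(gc))
    tab <- vapply(AA20, function(a) codons[gc[codons] == a][1L],
                  character(1L))
    tab[["X"]] <- "NNN"
    codon_env$tab <- tab
  }
  codon_env$tab
}

#' Back-translate a protein into a CDS
#'
#' Uses the lexicographically first codon per residue under the bacterial
#' genetic code and appends a TAA stop, so translating the CDS with
#' code table 11 reproduces the protein exactly. Codon usage realism is
#' deliberately out of scope.
#'
#' @param aa Amino-acid sequence.
#' @return Nucleotide sequence (uppercase), length `3 * (nchar(aa) + 1)`.
#' @export
back_translate <- function(aa) {
  tab <- rev_codon_table()
  chars <- strsplit(aa, "", fixed = TRUE)[[1L]]
  paste0(paste(tab[chars], collapse = ""), "TAA")
}

#' Write a synthetic corpus to disk
#'
#' Emits the GenBank flat file, the metadata TSV (list columns joined
#' with `";"`), the seed reference FASTA and profile TSV, and the ground
#' truth as JSON.
#'
#' @param corpus Result of [build_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genbank(corpus$records, file.path(dir, "corpus.gbk"))
  md <- corpus$metadata
  md$replicons <- vapply(md$replicons, paste, character(1L),
                         collapse = ";")
  md$carbapenemases <- vapply(md$carbapenemases, paste, character(1L),
                              collapse = ";")
  utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  seqs <- Biostrings::AAStringSet(vapply(corpus$references,
                                         function(r) r$sequence,
                                         character(1L)))
  Biostrings::writeXStringSet(seqs, file.path(dir, "references.faa"))
  prof <- do.call(rbind, lapply(corpus$references, function(r)
    data.frame(name = r$name, protein_id = r$protein_id,
               source_plasmid = r$source_plasmid, family = r$family,
               length = r$length, tip_start = r$tip_start,
               tip_end = r$tip_end, anchor_start = r$anchor_start,
               anchor_end = r$anchor_end, stringsAsFactors = FALSE)))
  utils::write.table(prof, file.path(dir, "references.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(corpus$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
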