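#' Built-in TraN reference profiles
#'
#' Loads the reference profile table describing one representative per
#' TraN subclade: TraN_Malpha (plasmid RA1), TraN_Mbeta (pNDM-US),
#' TraN_Lalpha (R27), TraN_Lbeta (pHNAH67), TraN_Lgamma (pNDM-MAR) and
#' TraN_V (pABAY10001), with the deposited protein accession, length and
#' the receptor-binding tip-domain span with its anchor residues (e.g.
#' 230C-360D: the tip runs from Cys230 to Asp360).
#'
#' Profile rows ship without sequences (the deposited proteins are not
#' redistributed). Attach sequences from a FASTA named by profile name or
#' accession via `sequences`, or generate seeded synthetic stand-ins with
#' [synthetic_references()].
#'
#' @param path Profile TSV; defaults to the packaged table. Columns:
#'   `name`, `protein_id`, `source_plasmid`, `family`, `length`,
#'   `tip_start`, `tip_end`, `anchor_start`, `anchor_end`.
#' @param sequences Optional named character vector or `AAStringSet` (or
#'   FASTA path) supplying reference sequences.
#' @return A list of `ReferenceProfile` objects.
#' @export
reference_profiles <- function(path = NULL, sequences = NULL) {
  path <- path %||% system.file("extdata", "tran_references.tsv",
                                package = "trantyper", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- Biostrings::readAAStringSet(sequences)
  if (!is.null(sequences)) sequences <- as.character(sequences)
  refs <- lapply(seq_len(nrow(df)), function(i) {
    seq <- NULL
    if (!is.null(sequences)) {
      hit <- intersect(c(df$name[i], df$protein_id[i]), names(sequences))
      if (length(hit)) seq <- unname(sequences[[hit[1L]]])
    }
    new_reference_profile(
      name = df$name[i], protein_id = df$protein_id[i],
      source_plasmid = df$source_plasmid[i], family = df$family[i],
      length = df$length[i], tip_start = df$tip_start[i],
      tip_end = df$tip_end[i], anchor_start = df$anchor_start[i],
      anchor_end = df$anchor_end[i], sequence = seq)
  })
  names(refs) <- df$name
  refs
}

#' @noRd
new_reference_profile <- function(name, protein_id, source_plasmid, family,
                                  length, tip_start, tip_end, anchor_start,
                                  anchor_end, sequence = NULL) {
  stopifnot(tip_start >= 1L, tip_start < tip_end, tip_end <= length)
  ref <- structure(list(
    name = name, protein_id = protein_id, source_plasmid = source_plasmid,
    family = family, length = as.integer(length),
    tip_start = as.integer(tip_start), tip_end = as.integer(tip_end),
    anchor_start = anchor_start, anchor_end = anchor_end,
    sequence = sequence), class = "ReferenceProfile")
  if (!is.null(sequence)) {
    check_protein(sequence, paste0("reference ", name))
    if (nchar(sequence) != ref$length)
      warning("reference ", name, ": sequence length ", nchar(sequence),
              " differs from profile length ", ref$length, call. = FALSE)
  }
  ref
}

#' @export
print.ReferenceProfile <- function(x, ...) {
  cat("<ReferenceProfile>", x$name, paste0("(", x$protein_id, ","),
      x$source_plasmid, ")", x$length, "aa, tip",
      paste0(x$tip_start, x$anchor_start, "-", x$tip_end, x$anchor_end),
      if (is.null(x$sequence)) "[no sequence]" else "", "\n")
  invisible(x)
}

#' Assign the TraN size class from protein length
#'
#' The survey typology bins TraN proteins by length: short (TraN_S,
#' 550–660 aa, IncF plasmids), medium (TraN_M, 880–950 aa, IncA/C), long
#' (TraN_L, 1,050–1,070 aa, IncH); everything else is `"other"`. All bins
#' are inclusive. The V-shaped Acinetobacter class (TraN_V, 891 aa) falls
#' inside the M bin, so it can only be confirmed by similarity to the
#' TraN_V reference — a length of exactly 891 is therefore flagged
#' `"possible V"` in the `notes` attribute, never called V from length
#' alone.
#'
#' @param length Integer vector of protein lengths (aa), all positive.
#' @return Character vector over `{"S","M","L","other"}` with a `notes`
#'   attribute (character, `"possible V"` where length == 891).
#' @export
assign_size_class <- function(length) {
  if (any(is.na(length)) || any(length <= 0))
    stop("protein length must be positive", call. = FALSE)
  cls <- rep("other", base::length(length))
  cls[length >= 550 & length <= 660] <- "S"
  cls[length >= 880 & length <= 950] <- "M"
  cls[length >= 1050 & length <= 1070] <- "L"
  notes <- ifelse(length == 891L, "possible V", "")
  attr(cls, "notes") <- notes
  cls
}

#' Type one TraN protein against the reference profiles
#'
#' Computes percent similarity of the query to every reference (exact
#' global alignment, [percent_similarity()] under the parameter set's
#' metric) and assigns family and subclade from the highest-identity
#' reference at or above `threshold` (default 30%, the inclusion rule
#' used for the family trees). Ties are broken by reference order. A
#' query below threshold falls back to family `"S"` when its length is in
#' the short bin (TraN_S subtyping requires user-supplied profiles),
#' otherwise `"unassigned"`.
#'
#' @param record One extracted record: a one-row data frame from
#'   [extract_tran()], or a list with `record_id` and `sequence`.
#' @param refs Reference profiles with sequences (see
#'   [synthetic_references()] or [reference_profiles()]).
#' @param threshold Family-membership percent-similarity threshold.
#' @param params Alignment parameters.
#' @return A `TypingResult`: `record_id`, `length`, `size_class`,
#'   `family` (`M`/`L`/`V`/`S`/`unassigned`), `subclade`,
#'   `nearest_reference`, `identity_to_nearest`, `notes`.
#' @export
assign_family <- function(record, refs, threshold = 30,
                          params = align_params()) {
  rec <- as_tran_record(record)
  if (!length(refs)) stop("empty reference set", call. = FALSE)
  has_seq <- vapply(refs, function(r) !is.null(r$sequence), logical(1L))
  if (!all(has_seq))
    stop("references without sequences: ",
         paste(vapply(refs[!has_seq], function(r) r$name, character(1L)),
               collapse = ", "), call. = FALSE)
  ident <- vapply(refs, function(r)
    percent_similarity(align_global(rec$sequence, r$sequence, params),
                       metric = params$metric), numeric(1L))
  size_class <- assign_size_class(rec$length)
  notes <- attr(size_class, "notes")
  notes <- if (nzchar(notes)) notes else character(0L)
  best <- which.max(ident)  # first max = reference-order tie-break
  res <- list(record_id = rec$record_id, length = rec$length,
              size_class = as.character(size_class),
              family = "unassigned", subclade = NA_character_,
              nearest_reference = NA_character_,
              identity_to_nearest = unname(ident[best]),
              notes = notes)
  if (ident[best] >= threshold) {
    res$family <- refs[[best]]$family
    res$subclade <- refs[[best]]$name
    res$nearest_reference <- refs[[best]]$name
    if (res$family == "V") res$size_class <- "V"
  } else if (res$size_class == "S") {
    res$family <- "S"
    res$notes <- c(res$notes, "short-bin length; no reference at threshold")
  } else {
    res$notes <- c(res$notes, "below threshold")
  }
  structure(res, class = "TypingResult")
}

#' @noRd
as_tran_record <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  if (is.null(record$length)) record$length <- nchar(record$sequence)
  check_protein(record$sequence, "query")
  record
}

#' @export
print.TypingResult <- function(x, ...) {
  cat("<TypingResult>", x$record_id, "-", x$length, "aa, size", x$size_class,
      "family", x$family,
      if (!is.na(x$subclade))
        paste0("(", x$subclade, ", ",
               round_half_up(x$identity_to_nearest, 1), "% id)") else "",
      "\n")
  invisible(x)
}

#' Type every extracted TraN protein of a corpus
#'
#' @param tran Extraction table from [extract_tran_corpus()].
#' @param refs Reference profiles with sequences. `NULL` skips
#'   similarity-based family assignment and types by size class only
#'   (family `S` for short-bin lengths, otherwise `unassigned`) — useful
#'   for length-distribution surveys of large corpora.
#' @param map_tips Also project the matched reference's tip span onto
#'   each assigned query ([map_tip()]).
#' @inheritParams assign_family
#' @return A typing data frame: one row per record with `record_id`,
#'   `plasmid_id`, `length`, `size_class`, `family`, `subclade`,
#'   `nearest_reference`, `identity`, `tip_start`, `tip_end`, `notes`.
#' @export
type_corpus <- function(tran, refs = NULL, threshold = 30,
                        params = align_params(), map_tips = FALSE) {
  stopifnot(is.data.frame(tran))
  n <- nrow(tran)
  size_class <- assign_size_class(tran$length)
  size_notes <- attr(size_class, "notes")
  out <- data.frame(
    record_id = tran$record_id, plasmid_id = tran$plasmid_id,
    length = tran$length, size_class = as.character(size_class),
    family = ifelse(size_class == "S", "S", "unassigned"),
    subclade = NA_character_, nearest_reference = NA_character_,
    identity = NA_real_, tip_start = NA_integer_, tip_end = NA_integer_,
    notes = size_notes, stringsAsFactors = FALSE)
  if (is.null(refs)) return(out)
  for (i in seq_len(n)) {
    tr <- assign_family(tran[i, ], refs, threshold = threshold,
                        params = params)
    out$size_class[i] <- tr$size_class
    out$family[i] <- tr$family
    out$subclade[i] <- tr$subclade
    out$nearest_reference[i] <- tr$nearest_reference
    out$identity[i] <- tr$identity_to_nearest
    out$notes[i] <- paste(tr$notes, collapse = "; ")
    if (map_tips && !is.na(tr$subclade)) {
      tip <- tryCatch(map_tip(tran[i, ], refs[[tr$subclade]],
                              params = params, threshold = threshold),
                      error = function(e) NULL)
      if (!is.null(tip) && !is.na(tip$start)) {
        out$tip_start[i] <- tip$start
        out$tip_end[i] <- tip$end
      }
    }
  }
  out
}

#' Project a reference tip domain onto a query protein
#'
#' Globally aligns the query to the reference and projects the
#' reference's tip-domain boundaries through the alignment onto query
#' coordinates. A boundary residue aligned to a gap projects to the
#' nearest query residue inside the tip span; if no reference tip
#' position aligns to any query residue the tip is reported absent with a
#' note. Projection is refused when query–reference identity is below
#' `threshold`, where coordinates would be meaningless.
#'
#' @param record Query record (see [assign_family()]).
#' @param ref A `ReferenceProfile` with sequence.
#' @param params Alignment parameters.
#' @param threshold Minimum percent similarity required to project.
#' @return A `TipDomain`: `record_id`, `start`, `end` (1-based inclusive
#'   on the query), `sequence`, `notes`.
#' @export
map_tip <- function(record, ref, params = align_params(), threshold = 30) {
  rec <- as_tran_record(record)
  if (is.null(ref$sequence))
    stop("reference ", ref$name, " has no sequence", call. = FALSE)
  aln <- align_global(rec$sequence, ref$sequence, params)
  ident <- percent_similarity(aln, metric = params$metric)
  if (ident < threshold)
    stop("identity to ", ref$name, " (", round_half_up(ident, 1),
         "%) below threshold ", threshold,
         "%; refusing tip projection", call. = FALSE)
  qa <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  ra <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  qpos <- cumsum(qa != "-")
  rpos <- cumsum(ra != "-")
  # query residue aligned to each reference position (NA at gaps)
  ref_to_query <- rep(NA_integer_, nchar(ref$sequence))
  hit <- which(ra != "-" & qa != "-")
  ref_to_query[rpos[hit]] <- qpos[hit]
  span <- ref$tip_start:ref$tip_end
  aligned <- span[!is.na(ref_to_query[span])]
  if (!length(aligned)) {
    return(structure(list(record_id = rec$record_id, start = NA_integer_,
                          end = NA_integer_, sequence = NA_character_,
                          notes = "tip unalignable"), class = "TipDomain"))
  }
  q_start <- ref_to_query[aligned[1L]]
  q_end <- ref_to_query[aligned[length(aligned)]]
  structure(list(record_id = rec$record_id, start = q_start, end = q_end,
                 sequence = substr(rec$sequence, q_start, q_end),
                 notes = if (length(aligned) < length(span))
                   "tip boundary adjusted across gaps" else ""),
            class = "TipDomain")
}

#' @export
print.TipDomain <- function(x, ...) {
  cat("<TipDomain>", x$record_id, "residues", x$start, "-", x$end, "\n")
  invisible(x)
}

#' Verify a reference profile against its stated length and anchors
#'
#' Checks that the profile's sequence has the tabulated length and that
#' the residues at the tip boundaries equal the recorded anchor letters.
#' All checks are always evaluated; failures are carried in the report,
#' not raised.
#'
#' @param ref A `ReferenceProfile` with sequence.
#' @return Data frame with columns `check`, `expected`, `observed`,
#'   `pass`.
#' @export
verify_reference <- function(ref) {
  if (is.null(ref$sequence))
    stop("reference ", ref$name, " has no sequence", call. = FALSE)
  n <- nchar(ref$sequence)
  res_at <- function(i) if (i >= 1L && i <= n)
    substr(ref$sequence, i, i) else NA_character_
  obs_start <- res_at(ref$tip_start)
  obs_end <- res_at(ref$tip_end)
  data.frame(
    check = c("length", "anchor_start", "anchor_end"),
    expected = c(as.character(ref$length), ref$anchor_start, ref$anchor_end),
    observed = c(as.character(n), obs_start, obs_end),
    pass = c(n == ref$length,
             identical(obs_start, ref$anchor_start),
             identical(obs_end, ref$anchor_end)),
    stringsAsFactors = FALSE)
}

#' Write a typing table as TSV
#'
#' @param typing Data frame from [type_corpus()].
#' @param path Output path.
#' @export
write_typing_tsv <- function(typing, path) {
  out <- typing
  out$identity <- round_half_up(out$identity, 1L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
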