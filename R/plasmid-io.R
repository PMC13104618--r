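#' Read plasmid records from a GenBank flat file
#'
#' Parses a (possibly multi-record) GenBank flat file and returns one
#' `PlasmidRecord` per entry. Only CDS features are retained; their
#' `gene`, `product` and `translation` qualifiers are preserved verbatim.
#' CDS features that lack a `/translation` qualifier but fall inside the
#' record's ORIGIN sequence are translated with the bacterial genetic code
#' (NCBI table 11), the trailing stop codon stripped; codons containing
#' ambiguous nucleotides translate to `X`.
#'
#' @param path Path to a GenBank flat file with at least one record.
#' @return A list of `PlasmidRecord` objects (class `tran_corpus`). Each
#'   record holds `plasmid_id`, `length`, a feature table
#'   (`index`, `gene`, `product`, `start`, `end`, `strand`, `translation`)
#'   and empty metadata slots (`host_genus`, `host_family`, `replicons`,
#'   `mob_type`, `ptu`, `carbapenemases`) to be filled by
#'   [attach_metadata()].
#' @seealso [extract_tran()], [read_metadata()], [write_genbank()]
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus_at <- grep("^LOCUS ", lines)
  if (!length(locus_at))
    stop("no GenBank records found in ", path, call. = FALSE)
  term_at <- grep("^//\\s*$", lines)
  if (length(term_at) < length(locus_at)) {
    stop("truncated GenBank file ", path, ": record starting at line ",
         locus_at[length(term_at) + 1L], " has no '//' terminator",
         call. = FALSE)
  }
  records <- vector("list", length(locus_at))
  for (k in seq_along(locus_at)) {
    from <- locus_at[k]
    to <- term_at[term_at > from][1L]
    records[[k]] <- parse_genbank_record(lines[from:to], from, path)
  }
  ids <- vapply(records, function(r) r$plasmid_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate plasmid ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(records, class = "tran_corpus")
}

#' @noRd
parse_genbank_record <- function(rl, offset, path) {
  locus <- strsplit(trimws(rl[1L]), "\\s+")[[1L]]
  if (length(locus) < 2L)
    stop("malformed LOCUS line at ", path, ":", offset, call. = FALSE)
  plasmid_id <- locus[2L]
  len <- suppressWarnings(as.integer(locus[3L]))

  feat_from <- grep("^FEATURES", rl)
  origin_from <- grep("^ORIGIN", rl)

  sequence <- ""
  if (length(origin_from)) {
    seq_lines <- rl[(origin_from[1L] + 1L):(length(rl) - 1L)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  if (is.na(len)) len <- nchar(sequence)

  features <- empty_feature_table()
  if (length(feat_from)) {
    to <- if (length(origin_from)) origin_from[1L] - 1L else length(rl) - 1L
    if (to > feat_from[1L]) {
      ft_lines <- rl[(feat_from[1L] + 1L):to]
      features <- parse_feature_table(ft_lines, plasmid_id, sequence,
                                      offset + feat_from[1L], path)
    }
  }
  bad <- which(!(features$start >= 1L & features$start <= features$end &
                   (features$end <= len | len == 0L)))
  if (length(bad))
    stop("record ", plasmid_id, ": feature span ", features$start[bad[1L]],
         "..", features$end[bad[1L]], " outside record length ", len,
         call. = FALSE)

  new_plasmid_record(plasmid_id, len, sequence, features)
}

#' @noRd
new_plasmid_record <- function(plasmid_id, length, sequence, features) {
  structure(list(
    plasmid_id = plasmid_id, length = length, sequence = sequence,
    features = features,
    host_genus = NA_character_, host_family = NA_character_,
    replicons = character(0L), mob_type = NA_character_,
    ptu = NA_character_, carbapenemases = character(0L)
  ), class = "PlasmidRecord")
}

empty_feature_table <- function() {
  data.frame(index = integer(0L), gene = character(0L),
             product = character(0L), start = integer(0L), end = integer(0L),
             strand = character(0L), translation = character(0L),
             stringsAsFactors = FALSE)
}

#' @noRd
parse_feature_table <- function(ft, plasmid_id, sequence, offset, path) {
  key_at <- grep("^ {5}\\S", ft)
  keys <- sub("^ {5}(\\S+).*", "\\1", ft[key_at])
  out <- list()
  for (i in seq_along(key_at)) {
    if (keys[i] != "CDS") next
    from <- key_at[i]
    to <- if (i < length(key_at)) key_at[i + 1L] - 1L else length(ft)
    block <- ft[from:to]
    loc_txt <- sub("^ {5}\\S+\\s+", "", block[1L])
    j <- 2L
    while (j <= length(block) && !grepl("^\\s+/", block[j])) {
      loc_txt <- paste0(loc_txt, trimws(block[j]))
      j <- j + 1L
    }
    quals <- parse_qualifiers(block[seq.int(j, length.out = max(0L, length(block) - j + 1L))])
    loc <- parse_location(loc_txt, plasmid_id, offset + from - 1L, path)
    translation <- quals[["translation"]]
    if (is.null(translation) && nzchar(sequence)) {
      translation <- translate_span(sequence, loc$spans, loc$strand)
    }
    out[[length(out) + 1L]] <- data.frame(
      index = length(out) + 1L,
      gene = quals[["gene"]] %||% NA_character_,
      product = quals[["product"]] %||% NA_character_,
      start = loc$spans[1L, 1L], end = loc$spans[nrow(loc$spans), 2L],
      strand = loc$strand,
      translation = translation %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_feature_table())
  do.call(rbind, out)
}

#' @noRd
parse_qualifiers <- function(qlines) {
  if (!length(qlines)) return(list())
  qlines <- trimws(qlines)
  starts <- grep("^/", qlines)
  quals <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(qlines)
    txt <- paste(qlines[from:to], collapse = "")
    m <- regmatches(txt, regexec("^/([A-Za-z_]+)=?\"?([^\"]*)\"?$", txt))[[1L]]
    if (length(m) == 3L) quals[[m[2L]]] <- m[3L]
  }
  quals
}

#' @noRd
parse_location <- function(txt, plasmid_id, line, path) {
  strand <- "+"
  t <- gsub("[<>]", "", gsub("\\s", "", txt))
  if (grepl("^complement\\(", t)) {
    strand <- "-"
    t <- sub("^complement\\((.*)\\)$", "\\1", t)
  }
  if (grepl("^join\\(", t)) t <- sub("^join\\((.*)\\)$", "\\1", t)
  parts <- strsplit(t, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
  ok <- vapply(m, length, integer(1L)) == 3L
  if (!all(ok))
    stop("record ", plasmid_id, ": unparseable CDS location '", txt,
         "' near ", path, ":", line, call. = FALSE)
  spans <- t(vapply(m, function(x) as.integer(x[2:3]), integer(2L)))
  list(spans = spans, strand = strand)
}

# Translate a (possibly multi-span) CDS with the bacterial code; trailing
# stop stripped, internal ambiguity becomes X.
#' @noRd
translate_span <- function(sequence, spans, strand) {
  nt <- paste(substring(sequence, spans[, 1L], spans[, 2L]), collapse = "")
  dna <- Biostrings::DNAString(nt)
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  aa <- as.character(suppressWarnings(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X")))
  sub("\\*$", "", aa)
}

#' Extract TraN candidate proteins from a plasmid record
#'
#' Scans the CDS features of a plasmid for the annotation strings used to
#' label the mating-pair-stabilization protein TraN (and its IncH synonym
#' TrhN). A feature matches when its `gene` or `product` qualifier,
#' compared as a whole token after stripping flanking whitespace, equals
#' one of `name_set` (case-sensitive). `substring = TRUE` relaxes this to
#' a fixed substring match.
#'
#' @param plasmid A `PlasmidRecord`.
#' @param name_set Annotation tokens accepted as TraN.
#' @param substring Match qualifiers by substring instead of whole-token
#'   equality. Off by default.
#' @return A data frame with one row per extracted protein: `record_id`
#'   (`plasmid_id|feature_index`), `plasmid_id`, `feature_index`,
#'   `matched_qualifier` (`"product:<token>"` or `"gene:<token>"`),
#'   `sequence` and `length` (aa). Matched features with no obtainable
#'   translation are skipped with a warning.
#' @examples
#' corp <- build_corpus(corpus_spec(n_plasmids = 2, seed = 1))
#' extract_tran(corp$records[[1]])
#' @export
extract_tran <- function(plasmid,
                         name_set = c("traN", "TraN", "trhN", "TrhN"),
                         substring = FALSE) {
  stopifnot(inherits(plasmid, "PlasmidRecord"))
  ft <- plasmid$features
  out <- empty_tran_table()
  if (!nrow(ft)) return(out)
  match_one <- function(q) {
    if (is.na(q)) return(FALSE)
    q <- trimws(q)
    if (substring) any(vapply(name_set, grepl, logical(1L), x = q,
                              fixed = TRUE))
    else q %in% name_set
  }
  rows <- list()
  for (i in seq_len(nrow(ft))) {
    mq <- NULL
    if (match_one(ft$product[i])) mq <- paste0("product:", trimws(ft$product[i]))
    else if (match_one(ft$gene[i])) mq <- paste0("gene:", trimws(ft$gene[i]))
    if (is.null(mq)) next
    tr <- ft$translation[i]
    if (is.na(tr) || !nzchar(tr)) {
      warning("plasmid ", plasmid$plasmid_id, " feature ", ft$index[i],
              ": matched TraN annotation but no translation; skipped",
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = paste0(plasmid$plasmid_id, "|", ft$index[i]),
      plasmid_id = plasmid$plasmid_id, feature_index = ft$index[i],
      matched_qualifier = mq, sequence = tr, length = nchar(tr),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_tran_table <- function() {
  data.frame(record_id = character(0L), plasmid_id = character(0L),
             feature_index = integer(0L), matched_qualifier = character(0L),
             sequence = character(0L), length = integer(0L),
             stringsAsFactors = FALSE)
}

#' Extract TraN candidates from every plasmid of a corpus
#'
#' @param corpus A list of `PlasmidRecord`s (e.g. from [read_genbank()]).
#' @inheritParams extract_tran
#' @return A single data frame of all extracted records (see
#'   [extract_tran()]), in corpus and feature order.
#' @export
extract_tran_corpus <- function(corpus,
                                name_set = c("traN", "TraN", "trhN", "TrhN"),
                                substring = FALSE) {
  tabs <- lapply(corpus, extract_tran, name_set = name_set,
                 substring = substring)
  out <- do.call(rbind, c(tabs, list(empty_tran_table())))
  rownames(out) <- NULL
  out
}

#' Read a plasmid metadata table
#'
#' Reads the tab-delimited metadata produced by external replicon / AMR /
#' plasmid-taxonomy callers (PlasmidFinder, AMRFinderPlus, COPLA or
#' equivalents). Lines starting with `#` are ignored. The list-valued
#' columns `replicons` and `carbapenemases` are split on `";"`; empty
#' cells become empty lists. Missing columns are tolerated.
#'
#' @param path Path to a UTF-8 TSV with a header row containing at least
#'   `plasmid_id`.
#' @return A data frame keyed by `plasmid_id` with columns among
#'   `host_genus`, `host_family`, `replicons` (list), `mob_type`, `ptu`,
#'   `carbapenemases` (list). Duplicate `plasmid_id` rows are an error.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (!"plasmid_id" %in% names(df))
    stop("metadata has no 'plasmid_id' column: ", path, call. = FALSE)
  dup <- unique(df$plasmid_id[duplicated(df$plasmid_id)])
  if (length(dup))
    stop("duplicate plasmid_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  split_col <- function(x) {
    lapply(x, function(cell) {
      if (is.na(cell) || !nzchar(cell)) character(0L)
      else trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
    })
  }
  for (col in c("replicons", "carbapenemases"))
    if (col %in% names(df)) df[[col]] <- split_col(df[[col]])
  for (col in c("host_genus", "host_family", "mob_type", "ptu"))
    if (col %in% names(df)) df[[col]][!nzchar(df[[col]])] <- NA_character_
  df
}

#' Attach metadata rows to the matching plasmid records
#'
#' @param corpus List of `PlasmidRecord`s.
#' @param metadata Data frame from [read_metadata()].
#' @return The corpus with metadata fields filled in. Metadata rows whose
#'   `plasmid_id` is absent from the corpus trigger a warning.
#' @export
attach_metadata <- function(corpus, metadata) {
  ids <- vapply(corpus, function(r) r$plasmid_id, character(1L))
  missing <- setdiff(metadata$plasmid_id, ids)
  if (length(missing))
    warning("metadata rows with no matching plasmid: ",
            paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(ids, metadata$plasmid_id)
  for (k in seq_along(corpus)) {
    i <- idx[k]
    if (is.na(i)) next
    for (col in c("host_genus", "host_family", "mob_type", "ptu"))
      if (col %in% names(metadata)) corpus[[k]][[col]] <- metadata[[col]][i]
    for (col in c("replicons", "carbapenemases"))
      if (col %in% names(metadata)) corpus[[k]][[col]] <- metadata[[col]][[i]]
  }
  corpus
}

#' Write extracted TraN proteins to FASTA
#'
#' Headers follow `plasmid_id|feature_index|matched_qualifier`.
#'
#' @param tran Data frame from [extract_tran_corpus()].
#' @param path Output FASTA path.
#' @export
write_tran_fasta <- function(tran, path) {
  seqs <- Biostrings::AAStringSet(tran$sequence)
  names(seqs) <- paste(tran$plasmid_id, tran$feature_index,
                       tran$matched_qualifier, sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a protein FASTA into the extracted-record table layout
#'
#' The inverse of [write_tran_fasta()] for round-tripping; headers that do
#' not carry the `plasmid_id|feature_index|qualifier` structure are kept
#' whole as `record_id`.
#'
#' @param path FASTA path.
#' @return Data frame in the [extract_tran()] layout.
#' @export
read_tran_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  plasmid <- vapply(parts, function(p) p[1L], character(1L))
  fidx <- vapply(parts, function(p)
    if (length(p) >= 2L && grepl("^\\d+$", p[2L])) as.integer(p[2L])
    else NA_integer_, integer(1L))
  mq <- vapply(parts, function(p)
    if (length(p) >= 3L) paste(p[-(1:2)], collapse = "|")
    else NA_character_, character(1L))
  data.frame(record_id = ids, plasmid_id = plasmid, feature_index = fidx,
             matched_qualifier = mq, sequence = as.character(seqs),
             length = Biostrings::width(seqs), stringsAsFactors = FALSE)
}

#' Write plasmid records as a GenBank flat file
#'
#' Emits a minimal, re-readable GenBank rendering of the corpus: LOCUS,
#' FEATURES with CDS `gene`/`product`/`translation` qualifiers and ORIGIN.
#'
#' @param corpus List of `PlasmidRecord`s (or a single record).
#' @param path Output path.
#' @export
write_genbank <- function(corpus, path) {
  if (inherits(corpus, "PlasmidRecord")) corpus <- list(corpus)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in corpus) {
    writeLines(sprintf("LOCUS       %s %d bp    DNA     circular BCT",
                       rec$plasmid_id, rec$length), con)
    writeLines(sprintf("DEFINITION  %s, synthetic plasmid record.",
                       rec$plasmid_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", rec$length), con)
    ft <- rec$features
    for (i in seq_len(nrow(ft))) {
      loc <- sprintf("%d..%d", ft$start[i], ft$end[i])
      if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      pad <- strrep(" ", 21L)
      if (!is.na(ft$gene[i]))
        writeLines(sprintf('%s/gene="%s"', pad, ft$gene[i]), con)
      if (!is.na(ft$product[i]))
        writeLines(sprintf('%s/product="%s"', pad, ft$product[i]), con)
      if (!is.na(ft$translation[i])) {
        tr <- ft$translation[i]
        first_w <- 44L
        head_txt <- substr(tr, 1L, first_w)
        rest <- if (nchar(tr) > first_w)
          substring(tr, seq(first_w + 1L, nchar(tr), by = 58L),
                    pmin(seq(first_w + 58L, nchar(tr) + 57L, by = 58L),
                         nchar(tr)))
        else character(0L)
        writeLines(sprintf('%s/translation="%s%s', pad, head_txt,
                           if (!length(rest)) '"' else ""), con)
        if (length(rest)) {
          rest[length(rest)] <- paste0(rest[length(rest)], '"')
          writeLines(paste0(pad, rest), con)
        }
      }
    }
    writeLines("ORIGIN", con)
    s <- rec$sequence
    if (nzchar(s)) {
      starts <- seq(1L, nchar(s), by = 60L)
      for (st in starts) {
        chunk <- substr(s, st, min(st + 59L, nchar(s)))
        blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                            pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                                 nchar(chunk)))
        writeLines(sprintf("%9d %s", st, paste(tolower(blocks),
                                               collapse = " ")), con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' @export
print.PlasmidRecord <- function(x, ...) {
  cat("<PlasmidRecord>", x$plasmid_id, "-", x$length, "bp,",
      nrow(x$features), "CDS\n")
  if (!is.na(x$host_genus))
    cat("  host:", x$host_genus, paste0("(", x$host_family, ")"), "\n")
  if (length(x$replicons))
    cat("  replicons:", paste(x$replicons, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.tran_corpus <- function(x, ...) {
  cat("<tran_corpus>", length(x), "plasmid records\n")
  invisible(x)
}
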