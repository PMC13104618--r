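#' Alignment parameter set
#'
#' Bundles the substitution matrix and affine gap penalties used by every
#' alignment in the pipeline. Defaults are BLOSUM62 with gap open 10 and
#' gap extend 1; end gaps are always penalized (true global alignment), so
#' a 600 aa protein cannot align "for free" inside a 1,800 aa one. A gap
#' of length L costs `gap_open + L * gap_extend`.
#'
#' The similarity `metric` controls the denominator of
#' [percent_similarity()]: `"columns"` (identities over all alignment
#' columns, gaps included — the default, which penalizes length
#' differences) or `"shorter"` (identities over the shorter input).
#'
#' @param matrix Substitution matrix name (a matrix shipped with
#'   \pkg{Biostrings}, e.g. `"BLOSUM62"`, `"BLOSUM45"`) or a numeric
#'   matrix with amino-acid dimnames. `X` scores as the matrix's X column
#'   but never counts as an identity.
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Per-column gap extension penalty (positive).
#' @param metric Similarity denominator, `"columns"` or `"shorter"`.
#' @return An object of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1,
                         metric = c("columns", "shorter")) {
  metric <- match.arg(metric)
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  miss <- setdiff(AA_ALPHABET, rownames(matrix))
  if (length(miss))
    stop("substitution matrix lacks rows for: ", paste(miss, collapse = ","),
         call. = FALSE)
  submat <- matrix[AA_ALPHABET, AA_ALPHABET]
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(submat = submat, gap_open = gap_open,
                 gap_extend = gap_extend, metric = metric),
            class = "align_params")
}

#' Exact global pairwise protein alignment
#'
#' Needleman–Wunsch dynamic programming with affine gap costs and
#' penalized end gaps. The traceback is deterministic: at score ties a
#' diagonal step beats a gap in `b`, which beats a gap in `a`.
#'
#' @param a,b Amino-acid strings (20 standard residues plus `X`).
#' @param params An [align_params()] object.
#' @return An `AlignmentResult`: `aligned_a`, `aligned_b` (equal-length
#'   gapped strings), `score`, `identities` (matching non-X residue
#'   pairs) and `columns` (alignment length).
#' @examples
#' aln <- align_global("MKTA", "MKT")
#' percent_similarity(aln)
#' @export
align_global <- function(a, b, params = align_params()) {
  check_protein(a, "sequence a")
  check_protein(b, "sequence b")
  stopifnot(inherits(params, "align_params"))
  res <- nw_align_cpp(a, b, params$submat, colnames(params$submat),
                      params$gap_open, params$gap_extend)
  res$len_a <- nchar(a)
  res$len_b <- nchar(b)
  structure(res, class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat("<AlignmentResult> score", x$score, "- identities", x$identities,
      "/", x$columns, "columns\n")
  invisible(x)
}

#' Percent similarity of an alignment
#'
#' `100 * identities / columns` under the default `"columns"` metric
#' (gap columns count in the denominator), or
#' `100 * identities / min(input lengths)` under `"shorter"`. Values are
#' kept at full precision; round only for display.
#'
#' @param aln An `AlignmentResult` from [align_global()].
#' @param metric Overrides the metric recorded in the alignment call.
#' @return Percent in `[0, 100]`.
#' @export
percent_similarity <- function(aln, metric = c("columns", "shorter")) {
  stopifnot(inherits(aln, "AlignmentResult"))
  metric <- match.arg(metric)
  if (aln$columns == 0L) stop("alignment has zero columns", call. = FALSE)
  denom <- switch(metric, columns = aln$columns,
                  shorter = min(aln$len_a, aln$len_b))
  100 * aln$identities / denom
}

#' Pairwise percent-similarity matrix over a protein set
#'
#' Aligns every unordered pair once with [align_global()] and assembles a
#' symmetric percent-similarity matrix; the diagonal is fixed at 100
#' without self-alignment.
#'
#' @param records Extracted-protein data frame (columns `record_id`,
#'   `sequence`), or a named character vector of sequences.
#' @param params An [align_params()] object; its `metric` is used.
#' @return An object of class `SimilarityMatrix` with fields `ids` and
#'   `values` (square, symmetric, diagonal 100).
#' @export
similarity_matrix <- function(records, params = align_params()) {
  if (is.data.frame(records)) {
    ids <- records$record_id
    seqs <- records$sequence
  } else {
    ids <- names(records)
    seqs <- unname(records)
  }
  if (length(seqs) < 2L) stop("need at least 2 records", call. = FALSE)
  if (is.null(ids) || anyDuplicated(ids))
    stop("records must carry unique ids", call. = FALSE)
  n <- length(seqs)
  vals <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- percent_similarity(align_global(seqs[i], seqs[j], params),
                              metric = params$metric)
      vals[i, j] <- s
      vals[j, i] <- s
    }
  }
  new_similarity_matrix(ids, vals)
}

new_similarity_matrix <- function(ids, values) {
  stopifnot(nrow(values) == length(ids), ncol(values) == length(ids))
  structure(list(ids = ids, values = values), class = "SimilarityMatrix")
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat("<SimilarityMatrix>", length(x$ids), "x", length(x$ids),
      "percent similarity; off-diagonal range",
      if (length(x$ids) > 1L)
        paste(round(range(x$values[upper.tri(x$values)]), 1), collapse = "-")
      else "NA", "\n")
  invisible(x)
}

#' Write a similarity or distance matrix in square PHYLIP format
#'
#' @param x A `SimilarityMatrix` or `DistanceMatrix`.
#' @param path Output path.
#' @export
write_phylip <- function(x, path) {
  vals <- x$values
  ids <- x$ids
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(ids)), con)
  for (i in seq_along(ids)) {
    writeLines(paste(c(formatC(ids[i], width = -10L),
                       formatC(vals[i, ], format = "f", digits = 6L)),
                     collapse = "  "), con)
  }
  invisible(path)
}

#' Write pairwise similarities as long-format TSV
#'
#' One row per unordered pair: `id_a`, `id_b`, `similarity` (one decimal).
#'
#' @param x A `SimilarityMatrix`.
#' @param path Output path.
#' @export
write_similarity_tsv <- function(x, path) {
  n <- length(x$ids)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  df <- data.frame(id_a = x$ids[idx[, 1L]], id_b = x$ids[idx[, 2L]],
                   similarity = round_half_up(x$values[idx], 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
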