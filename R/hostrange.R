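#' Load the curated host-range evidence table
#'
#' The package ships a provenance-tagged table mapping each TraN class to
#' its experimentally determined recipient receptor (OmpA for TraN_L;
#' OmpW/OmpK36/OmpA/OmpF for the four TraN_S isotypes; unknown for
#' TraN_M and TraN_V) and to qualitative conjugation-efficiency tiers
#' (`high`, `reduced`, `very_low`, `untested`) per recipient species.
#' Every row cites the figure or section supporting it; `note` rows carry
#' class-level annotations (receptor dependency, fold magnitudes, tip
#' behavior).
#'
#' @param path Alternative table path (same TSV layout); defaults to the
#'   packaged table.
#' @return Data frame with columns `tran_class`, `family`, `receptor`,
#'   `recipient`, `tier`, `evidence`.
#' @export
host_range_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hostrange_evidence.tsv",
                                package = "trantyper", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("tran_class", "family", "receptor", "recipient", "tier",
            "evidence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("host-range table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(df$evidence)))
    stop("host-range table rows without evidence", call. = FALSE)
  df
}

#' Predict receptor dependency and recipient host range
#'
#' Looks up the curated entry for a typed TraN protein: the subclade row
#' set if present, falling back to family-level entries (`TraN_S` for
#' short proteins without isotype profiles). Untyped queries
#' (`family == "unassigned"`) yield an empty prediction with a note —
#' nothing is extrapolated beyond the curated evidence.
#'
#' @param typing A `TypingResult` from [assign_family()], one row of a
#'   [type_corpus()] table, or a class name such as `"TraN_Lalpha"`.
#' @param table Evidence table (defaults to [host_range_table()]).
#' @return A `HostRangePrediction`: `tran_class`, `receptor`, `tiers`
#'   (named character vector recipient -> tier), `evidence` (data frame
#'   of recipient/tier/evidence rows), `notes`.
#' @export
predict_host_range <- function(typing, table = host_range_table()) {
  cls <- NULL
  if (is.character(typing) && length(typing) == 1L) {
    cls <- typing
  } else {
    ty <- if (is.data.frame(typing)) as.list(typing) else typing
    # empty strings (e.g. from TSV round-trips) mean "no subclade"
    for (fld in c("subclade", "family"))
      if (!is.null(ty[[fld]]) && !is.na(ty[[fld]]) && !nzchar(ty[[fld]]))
        ty[[fld]] <- NA_character_
    if (identical(ty$family, "unassigned") || is.na(ty$family %||% NA) ||
        (is.na(ty$subclade %||% NA) && !identical(ty$family, "S"))) {
      return(structure(list(tran_class = NA_character_,
                            receptor = "unknown",
                            tiers = stats::setNames(character(0L),
                                                    character(0L)),
                            evidence = table[0L, ],
                            notes = "no curated entry for unassigned query"),
                       class = "HostRangePrediction"))
    }
    cls <- if (!is.na(ty$subclade %||% NA)) ty$subclade
    else paste0("TraN_", ty$family)
  }
  rows <- table[table$tran_class == cls, , drop = FALSE]
  if (!nrow(rows)) {
    # family-level fallback
    fam <- sub("^TraN_([MLSV]).*$", "\\1", cls)
    rows <- table[table$tran_class == paste0("TraN_", fam), , drop = FALSE]
  }
  if (!nrow(rows)) {
    return(structure(list(tran_class = cls, receptor = "unknown",
                          tiers = stats::setNames(character(0L),
                                                  character(0L)),
                          evidence = table[0L, ],
                          notes = "no curated entry"),
                     class = "HostRangePrediction"))
  }
  tier_rows <- rows[rows$tier %in% c("high", "reduced", "very_low",
                                     "untested") & rows$recipient != "-", ,
                    drop = FALSE]
  structure(list(
    tran_class = rows$tran_class[1L],
    receptor = rows$receptor[1L],
    tiers = stats::setNames(tier_rows$tier, tier_rows$recipient),
    evidence = rows[, c("recipient", "tier", "evidence")],
    notes = paste(rows$evidence[rows$tier == "note"], collapse = " | ")),
    class = "HostRangePrediction")
}

#' @export
print.HostRangePrediction <- function(x, ...) {
  cat("<HostRangePrediction>", x$tran_class %||% "(unassigned)",
      "- receptor:", x$receptor, "\n")
  if (length(x$tiers)) {
    for (tier in c("high", "reduced", "very_low", "untested")) {
      r <- names(x$tiers)[x$tiers == tier]
      if (length(r)) cat(" ", tier, ":", paste(r, collapse = ", "), "\n")
    }
  } else cat("  (no tier entries)\n")
  invisible(x)
}

#' List the curated evidence for one TraN class
#'
#' @param tran_class Class name present in the table (e.g.
#'   `"TraN_Lgamma"`).
#' @param table Evidence table.
#' @return Data frame of `(recipient, tier, evidence)` rows.
#' @export
list_evidence <- function(tran_class, table = host_range_table()) {
  rows <- table[table$tran_class == tran_class, , drop = FALSE]
  if (!nrow(rows))
    stop("unknown TraN class '", tran_class, "'; valid classes: ",
         paste(unique(table$tran_class), collapse = ", "), call. = FALSE)
  rows[, c("recipient", "tier", "evidence")]
}

#' Predict host range for every row of a typing table
#'
#' @param typing Typing table from [type_corpus()].
#' @param table Evidence table.
#' @return Data frame with `record_id`, `tran_class`, `receptor` and one
#'   `tier:<recipient>` summary string column.
#' @export
predict_corpus <- function(typing, table = host_range_table()) {
  rows <- lapply(seq_len(nrow(typing)), function(i) {
    p <- predict_host_range(typing[i, ], table)
    data.frame(record_id = typing$record_id[i],
               tran_class = p$tran_class %||% NA_character_,
               receptor = p$receptor,
               tiers = if (length(p$tiers))
                 paste(paste0(names(p$tiers), "=", p$tiers),
                       collapse = ";") else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
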