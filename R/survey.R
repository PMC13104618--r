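#' Per-plasmid TraN copy-number summary
#'
#' Tallies plasmids by how many TraN proteins were extracted from them,
#' in the literal categories `0`, `1`, `2-3` and `>3` (2–3 copies is the
#' multi-copy pattern actually observed in surveyed MPF_F corpora; more
#' than three gets its own bucket rather than being merged silently).
#' Percentages are over all plasmids, rounded half-up to one decimal.
#'
#' @param corpus List of `PlasmidRecord`s (the full corpus, including
#'   plasmids with no TraN).
#' @param tran Extraction table from [extract_tran_corpus()] run on that
#'   corpus.
#' @return Data frame with columns `category`, `count`, `percent`.
#' @export
copy_number_summary <- function(corpus, tran) {
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  ids <- vapply(corpus, function(r) r$plasmid_id, character(1L))
  copies <- table(factor(tran$plasmid_id, levels = ids))
  cat_of <- cut(as.integer(copies), breaks = c(-0.5, 0.5, 1.5, 3.5, Inf),
                labels = c("0", "1", "2-3", ">3"))
  counts <- table(cat_of)
  data.frame(category = names(counts), count = as.integer(counts),
             percent = round_half_up(100 * as.integer(counts) /
                                       length(corpus), 1L),
             stringsAsFactors = FALSE)
}

#' Size-class proportions of extracted TraN proteins
#'
#' Counts and percentages per size class over all extracted proteins
#' (one decimal, half-up). The `other` class is always reported, never
#' dropped.
#'
#' @param typing Typing table from [type_corpus()] (only `size_class` is
#'   used).
#' @return Data frame with columns `size_class`, `count`, `percent`.
#' @export
class_proportions <- function(typing) {
  if (!nrow(typing)) stop("no typing results", call. = FALSE)
  lv <- c("S", "M", "L", "V", "other")
  counts <- table(factor(typing$size_class, levels = lv))
  data.frame(size_class = lv, count = as.integer(counts),
             percent = round_half_up(100 * as.integer(counts) /
                                       nrow(typing), 1L),
             stringsAsFactors = FALSE)
}

#' Trait and host-taxon association report per TraN group
#'
#' For each TraN family and subclade, counts the associated plasmids
#' (`n`), those with a non-empty value in the `trait` metadata column
#' (`k`) and the percentage `100*k/n` (one decimal, half-up). A plasmid
#' carrying TraN of several groups counts once in each. A host-family
#' composition table per group is reported alongside.
#'
#' @param typing Typing table from [type_corpus()].
#' @param metadata Metadata data frame keyed by `plasmid_id` (see
#'   [read_metadata()]), with the `trait` column and optionally
#'   `host_family`.
#' @param trait Metadata column to test, e.g. `"carbapenemases"`.
#' @return List with elements `trait` (group, trait, n, k, percent) and
#'   `hosts` (group, host_family, count, percent).
#' @export
association_report <- function(typing, metadata, trait = "carbapenemases") {
  if (!trait %in% names(metadata))
    stop("trait column '", trait, "' absent from metadata", call. = FALSE)
  m <- metadata[match(typing$plasmid_id, metadata$plasmid_id), ,
                drop = FALSE]
  has_trait <- vapply(m[[trait]], function(x)
    length(x) > 0L && any(nzchar(x) & !is.na(x)), logical(1L))
  groups <- list()
  for (col in c("family", "subclade")) {
    for (g in stats::na.omit(unique(typing[[col]]))) {
      sel <- !is.na(typing[[col]]) & typing[[col]] == g
      # plasmid-level: count each plasmid once per group
      sel_pl <- sel & !duplicated(paste(typing$plasmid_id, typing[[col]]))
      n <- sum(sel_pl)
      k <- sum(has_trait[sel_pl])
      groups[[length(groups) + 1L]] <- data.frame(
        group = g, trait = trait, n = n, k = k,
        percent = round_half_up(100 * k / n, 1L), stringsAsFactors = FALSE)
    }
  }
  trait_tab <- do.call(rbind, groups)
  hosts <- NULL
  if ("host_family" %in% names(m)) {
    rows <- list()
    for (g in stats::na.omit(unique(typing$family))) {
      sel <- !is.na(typing$family) & typing$family == g &
        !duplicated(paste(typing$plasmid_id, typing$family))
      tab <- table(m$host_family[sel], useNA = "ifany")
      if (!length(tab)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, host_family = names(tab), count = as.integer(tab),
        percent = round_half_up(100 * as.integer(tab) / sum(sel), 1L),
        stringsAsFactors = FALSE)
    }
    hosts <- do.call(rbind, rows)
  }
  list(trait = trait_tab, hosts = hosts)
}

#' Log10 conjugation frequency
#'
#' Conjugation frequency is the ratio of transconjugant CFU/mL to
#' recipient CFU/mL, log10-transformed. A transconjugant count of zero is
#' reported as below the limit of detection (`NA` with the
#' `below_detection` attribute set), never as `-Inf`.
#'
#' @param transconjugant_cfu_per_ml Numeric vector, `>= 0`.
#' @param recipient_cfu_per_ml Numeric vector, strictly positive.
#' @return Numeric vector of log10 frequencies with a logical attribute
#'   `below_detection`.
#' @examples
#' conjugation_frequency(1e2, 1e8)  # -6
#' conjugation_frequency(0, 1e8)    # below detection
#' @export
conjugation_frequency <- function(transconjugant_cfu_per_ml,
                                  recipient_cfu_per_ml) {
  t <- transconjugant_cfu_per_ml
  r <- recipient_cfu_per_ml
  if (any(is.na(r)) || any(r <= 0))
    stop("recipient CFU/mL must be positive", call. = FALSE)
  if (any(t < 0)) stop("transconjugant CFU/mL must be >= 0", call. = FALSE)
  below <- t == 0
  out <- ifelse(below, NA_real_, log10(t / r))
  attr(out, "below_detection") <- below
  out
}

#' Fold difference between two log10 conjugation frequencies
#'
#' `10^(a - b)`: e.g. a log-frequency difference of ~-1.9 corresponds to
#' the ~80-fold reductions seen between efficient and restricted
#' recipients.
#'
#' @param a_log,b_log Log10 frequencies.
#' @return Linear fold difference.
#' @export
fold_difference <- function(a_log, b_log) 10^(a_log - b_log)

#' Full corpus survey report
#'
#' Bundles the copy-number, size-class and association tables with corpus
#' totals, labelling each table's denominator (plasmids vs extracted
#' proteins) explicitly.
#'
#' @param corpus List of `PlasmidRecord`s.
#' @param tran Extraction table.
#' @param typing Typing table.
#' @param metadata Metadata data frame (optional; associations are
#'   omitted without it).
#' @param trait Trait column for [association_report()].
#' @return A `SurveyReport` list.
#' @export
survey_report <- function(corpus, tran, typing, metadata = NULL,
                          trait = "carbapenemases") {
  rep <- list(
    totals = list(plasmids = length(corpus), extracted = nrow(tran),
                  denominators = c(copy_number = "plasmids",
                                   class_proportions = "extracted proteins",
                                   associations = "plasmids per group")),
    copy_number = copy_number_summary(corpus, tran),
    class_proportions = class_proportions(typing))
  if (!is.null(metadata) && trait %in% names(metadata))
    rep$associations <- association_report(typing, metadata, trait)
  structure(rep, class = "SurveyReport")
}

#' @export
print.SurveyReport <- function(x, ...) {
  cat("<SurveyReport>", x$totals$plasmids, "plasmids,",
      x$totals$extracted, "TraN proteins extracted\n")
  cat("copy number (% of plasmids):\n")
  print(x$copy_number)
  cat("size classes (% of extracted proteins):\n")
  print(x$class_proportions)
  invisible(x)
}

#' Write a survey report as JSON
#'
#' @param report A `SurveyReport`.
#' @param path Output path.
#' @export
write_survey_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
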