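test_that("copy-number summary tallies every plasmid and matches a direct loop", {
  spec <- corpus_spec(n_plasmids = 40,
                      copy_number = c("0" = 4, "1" = 30, "2" = 4, "3" = 2),
                      class_mix = c(S = 30, Malpha = 6, Lalpha = 6),
                      substitution_rate = 0.05, seed = 9)
  corp <- build_corpus(spec)
  tran <- extract_tran_corpus(corp$records)
  tab <- copy_number_summary(corp$records, tran)
  expect_equal(tab$category, c("0", "1", "2-3", ">3"))
  expect_equal(sum(tab$count), length(corp$records))
  # independent tally loop
  by_hand <- vapply(corp$records, function(p) nrow(extract_tran(p)),
                    integer(1L))
  expect_equal(tab$count,
               c(sum(by_hand == 0), sum(by_hand == 1),
                 sum(by_hand %in% 2:3), sum(by_hand > 3)))
  # 4 + 2 plasmids fall in the literal 2-3 category
  expect_equal(tab$percent, c(10, 75, 15, 0))
  expect_error(copy_number_summary(list(), tran), "empty")
})

test_that("an all-single corpus lands 100% in category 1", {
  spec <- corpus_spec(n_plasmids = 6, copy_number = c("1" = 1),
                      class_mix = c(S = 1), substitution_rate = 0, seed = 2)
  corp <- build_corpus(spec)
  tab <- copy_number_summary(corp$records,
                             extract_tran_corpus(corp$records))
  expect_equal(tab$percent[tab$category == "1"], 100)
})

test_that("class proportions cover every bin and sum to ~100", {
  ty <- data.frame(record_id = paste0("r", 1:8),
                   size_class = c("S", "S", "S", "M", "M", "L", "other",
                                  "V"))
  tab <- class_proportions(ty)
  expect_setequal(tab$size_class, c("S", "M", "L", "V", "other"))
  expect_equal(tab$count[tab$size_class == "S"], 3L)
  expect_equal(tab$percent[tab$size_class == "S"], 37.5)
  expect_lt(abs(sum(tab$percent) - 100), 0.2)
  # single record: 100 in its class
  tab1 <- class_proportions(ty[4L, , drop = FALSE])
  expect_equal(tab1$percent[tab1$size_class == "M"], 100)
})

test_that("percentages use half-up rounding to one decimal", {
  # 38/1517 = 2.5049... -> 2.5 ; 121/1517 = 7.976 -> 8.0 ; 0.25 -> 0.3
  expect_equal(trantyper:::round_half_up(100 * 38 / 1517, 1), 2.5)
  expect_equal(trantyper:::round_half_up(100 * 121 / 1517, 1), 8.0)
  expect_equal(trantyper:::round_half_up(0.25, 1), 0.3)
  expect_equal(trantyper:::round_half_up(-0.25, 1), -0.3)
  expect_equal(trantyper:::round_half_up(100 * 898 / 1436, 1), 62.5)
})

test_that("association report computes trait and host composition per group", {
  ty <- data.frame(
    record_id = paste0("r", 1:6), plasmid_id = paste0("p", 1:6),
    length = c(912, 912, 932, 1058, 1058, 605),
    size_class = c("M", "M", "M", "L", "L", "S"),
    family = c("M", "M", "M", "L", "L", "S"),
    subclade = c("TraN_Malpha", "TraN_Malpha", "TraN_Mbeta",
                 "TraN_Lalpha", "TraN_Lalpha", NA),
    stringsAsFactors = FALSE)
  md <- data.frame(plasmid_id = paste0("p", 1:6),
                   host_family = c(rep("Enterobacteriaceae", 4),
                                   "Vibrionaceae", "Enterobacteriaceae"),
                   stringsAsFactors = FALSE)
  md$carbapenemases <- list("blaNDM-1", character(0), "blaKPC-2",
                            character(0), character(0), character(0))
  rep <- association_report(ty, md)
  m_row <- rep$trait[rep$trait$group == "M", ]
  expect_equal(c(m_row$n, m_row$k), c(3L, 2L))
  expect_equal(m_row$percent, 66.7)
  l_row <- rep$trait[rep$trait$group == "L", ]
  expect_equal(c(l_row$n, l_row$k), c(2L, 0L))
  expect_equal(l_row$percent, 0)
  hostm <- rep$hosts[rep$hosts$group == "M", ]
  expect_equal(hostm$count[hostm$host_family == "Enterobacteriaceae"], 3L)
  expect_error(association_report(ty, md, trait = "nope"), "absent")
})

test_that("association report is invariant to input row order", {
  spec <- corpus_spec(n_plasmids = 20, copy_number = c("1" = 1),
                      class_mix = c(Malpha = 10, Lalpha = 10),
                      substitution_rate = 0.1, seed = 4)
  corp <- build_corpus(spec)
  tran <- extract_tran_corpus(corp$records)
  ty <- type_corpus(tran)
  set.seed(1)
  perm <- sample(nrow(ty))
  r1 <- association_report(ty, corp$metadata)
  r2 <- association_report(ty[perm, ], corp$metadata)
  key <- function(x) x[order(x$group), c("group", "n", "k", "percent")]
  expect_equal(key(r1$trait), key(r2$trait), ignore_attr = TRUE)
})

test_that("conjugation frequency is log10 with a below-detection sentinel", {
  expect_equal(as.numeric(conjugation_frequency(1e2, 1e8)), -6)
  expect_equal(as.numeric(conjugation_frequency(5e5, 5e5)), 0)
  f <- conjugation_frequency(c(0, 1e3), c(1e8, 1e8))
  expect_true(is.na(f[1L]))
  expect_false(is.infinite(f[1L]))
  expect_equal(attr(f, "below_detection"), c(TRUE, FALSE))
  expect_equal(as.numeric(f[2L]), -5)
  expect_error(conjugation_frequency(10, 0), "positive")
})

test_that("fold difference inverts the log transform", {
  expect_equal(fold_difference(-3, -5), 100)
  # ~80-fold lower efficiency is a log-difference of log10(80)
  expect_equal(fold_difference(-4, -4 + log10(80)), 1 / 80)
  a <- -6.2; b <- -3.7
  expect_equal(log10(fold_difference(a, b)), a - b)
})

test_that("survey report bundles tables with explicit denominators", {
  spec <- corpus_spec(n_plasmids = 10, copy_number = c("0" = 1, "1" = 9),
                      class_mix = c(S = 5, Malpha = 4), seed = 6)
  corp <- build_corpus(spec)
  tran <- extract_tran_corpus(corp$records)
  ty <- type_corpus(tran)
  rep <- survey_report(corp$records, tran, ty, corp$metadata)
  expect_equal(rep$totals$plasmids, 10L)
  expect_equal(rep$totals$extracted, nrow(tran))
  expect_equal(sum(rep$copy_number$count), 10L)
  expect_equal(sum(rep$class_proportions$count), nrow(tran))
  out <- withr::local_tempfile(fileext = ".json")
  write_survey_json(rep, out)
  parsed <- jsonlite::read_json(out)
  expect_equal(parsed$totals$plasmids, 10L)
})
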