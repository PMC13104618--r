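test_that("synthetic references honor length, anchors and determinism", {
  r <- make_reference("TraN_Malpha_like", 912, 230, 360, "C", "D",
                      seed = 7)
  expect_equal(nchar(r$sequence), 912L)
  expect_equal(substr(r$sequence, 230, 230), "C")
  expect_equal(substr(r$sequence, 360, 360), "D")
  expect_true(all(verify_reference(r)$pass))
  r2 <- make_reference("TraN_Malpha_like", 912, 230, 360, "C", "D",
                       seed = 7)
  expect_identical(r2$sequence, r$sequence)
  r3 <- make_reference("TraN_Malpha_like", 912, 230, 360, "C", "D",
                       seed = 8)
  expect_false(identical(r3$sequence, r$sequence))
  expect_error(make_reference("x", 100, 50, 120, "C", "D", seed = 1),
               "out of range")
  # the packaged profile set instantiates and self-verifies
  refs <- synthetic_references(5)
  for (ref in refs) expect_true(all(verify_reference(ref)$pass))
})

test_that("zero-rate mutation is the identity with an empty log", {
  s <- random_protein(200, seed = 3)
  m <- mutate_sequence(s, 0, 0, seed = 1)
  expect_identical(m$sequence, s)
  expect_equal(nrow(m$log), 0L)
})

test_that("substitution counts follow the binomial expectation", {
  s <- random_protein(1000, seed = 4)
  m <- mutate_sequence(s, 0.3, seed = 10)
  ident <- 100 * mean(strsplit(s, "")[[1L]] ==
                        strsplit(m$sequence, "")[[1L]])
  # 3 sigma of Binomial(1000, 0.7) around 70%
  expect_lt(abs(ident - 70), 3 * sqrt(0.3 * 0.7 / 1000) * 100)
  expect_equal(nrow(m$log), 1000L - sum(strsplit(s, "")[[1L]] ==
                                          strsplit(m$sequence, "")[[1L]]))
})

test_that("replaying the mutation log reproduces the child exactly", {
  s <- random_protein(400, seed = 5)
  for (k in 1:6) {
    m <- mutate_sequence(s, 0.15, indel_rate = 0.02, indel_length = 3,
                         seed = 100 + k)
    expect_identical(apply_mutation_log(s, m$log), m$sequence)
  }
  # substitution-only path too
  m0 <- mutate_sequence(s, 0.25, seed = 11)
  expect_identical(apply_mutation_log(s, m0$log), m0$sequence)
  expect_identical(mutate_sequence(s, 0.25, seed = 11)$sequence,
                   m0$sequence)
})

test_that("largest-remainder quotas hit exact counts", {
  expect_equal(unname(quota_counts(c(121, 1358, 36, 2), 1517)),
               c(121L, 1358L, 36L, 2L))
  q <- quota_counts(c(a = 1, b = 1, c = 1), 10)
  expect_equal(sum(q), 10L)
  expect_equal(unname(q), c(4L, 3L, 3L))
  expect_equal(sum(quota_counts(c(0.663, 0.337), 184)), 184L)
})

test_that("back-translation round-trips through the bacterial code", {
  refs <- synthetic_references(3)
  for (ref in refs[c("TraN_Malpha", "TraN_V")]) {
    nt <- back_translate(ref$sequence)
    expect_equal(nchar(nt), 3L * (nchar(ref$sequence) + 1L))
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt),
      genetic.code = Biostrings::getGeneticCode("11")))
    expect_equal(sub("\\*$", "", aa), ref$sequence)
  }
})

test_that("corpus generation is deterministic and writes byte-identical files", {
  spec <- corpus_spec(n_plasmids = 8, copy_number = c("0" = 1, "1" = 7),
                      class_mix = c(S = 3, Mbeta = 2, Lgamma = 2),
                      substitution_rate = 0.1, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_corpus(build_corpus(spec), d1)
  write_corpus(build_corpus(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("quota mode reproduces requested category counts exactly", {
  spec <- corpus_spec(n_plasmids = 60,
                      copy_number = c("0" = 6, "1" = 48, "2" = 4, "3" = 2),
                      class_mix = c(S = 30, Malpha = 10, Lalpha = 20),
                      substitution_rate = 0.05, seed = 15)
  corp <- build_corpus(spec)
  tran <- extract_tran_corpus(corp$records)
  counts <- table(factor(tran$plasmid_id,
                         levels = sprintf("p%04d", 1:60)))
  expect_equal(sum(counts == 0), 6L)
  expect_equal(sum(counts == 1), 48L)
  expect_equal(sum(counts == 2), 4L)
  expect_equal(sum(counts == 3), 2L)
  # class quotas apply to proteins (62 here: 48 + 4*2 + 2*3), allocated
  # by largest remainder from the class weights
  expect_equal(unname(table(corp$truth$class)[c("TraN_S_synthetic",
                                                "TraN_Malpha",
                                                "TraN_Lalpha")]),
               unname(quota_counts(c(30, 10, 20), nrow(corp$truth))),
               ignore_attr = TRUE)
})

test_that("random mode matches expectations within binomial 3 sigma", {
  spec <- corpus_spec(n_plasmids = 400,
                      copy_number = c("0" = 0.1, "1" = 0.9),
                      class_mix = c(S = 0.5, Malpha = 0.5),
                      substitution_rate = 0, mode = "random", seed = 23)
  corp <- build_corpus(spec)
  tran <- extract_tran_corpus(corp$records)
  n0 <- 400 - length(unique(tran$plasmid_id))
  expect_lt(abs(n0 - 40), 3 * sqrt(400 * 0.1 * 0.9))
  ns <- sum(corp$truth$class == "TraN_S_synthetic")
  expect_lt(abs(ns - nrow(tran) / 2), 3 * sqrt(nrow(tran) * 0.25))
})

test_that("requesting a class without a seed reference fails", {
  expect_error(corpus_spec(class_mix = c(Z = 1)), "unknown class")
})

test_that("planted tip coordinates survive indels via the mutation log", {
  refs <- synthetic_references(2)
  ref <- refs$TraN_Lalpha
  for (k in 1:5) {
    m <- mutate_sequence(ref$sequence, 0.05, indel_rate = 0.01,
                         indel_length = 3, seed = 300 + k)
    ts <- trantyper:::project_position(m$log, ref$tip_start)
    te <- trantyper:::project_position(m$log, ref$tip_end)
    expect_true(ts >= 1 && te <= nchar(m$sequence) && ts < te)
  }
})

test_that("end-to-end family recovery is perfect at rate 0.2 and degrades with rate", {
  recovery_at <- function(rate, seed) {
    spec <- corpus_spec(n_plasmids = 10, copy_number = c("1" = 1),
                        class_mix = c(Malpha = 3, Mbeta = 2, Lalpha = 2,
                                      Lbeta = 1, Lgamma = 1, V = 1),
                        substitution_rate = rate, seed = seed)
    corp <- build_corpus(spec)
    tran <- extract_tran_corpus(corp$records)
    refs <- corp$references[names(reference_profiles())]
    ty <- type_corpus(tran, refs)
    m <- merge(ty, corp$truth[, c("record_id", "family")],
               by = "record_id")
    mean(m$family.x == m$family.y)
  }
  expect_equal(recovery_at(0.10, 31), 1)
  expect_equal(recovery_at(0.20, 32), 1)
  r_extreme <- recovery_at(0.95, 33)
  expect_lt(r_extreme, 1)
})
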