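test_that("corpus construction enforces the documented invariants", {
  expect_s3_class(tiny_corpus(), "tcm_corpus")
  mk <- function(engraving = list("a"), tongue = list("t"),
                 elements = list("e")) {
    new_corpus("c1", engraving, tongue, list("m"), list("p"), elements)
  }
  expect_error(mk(engraving = list(character(0))),
               "at least one engraving symptom")
  expect_error(mk(elements = list(character(0))),
               "at least one syndrome element")
  expect_error(mk(tongue = list(c("t", "t"))), "duplicate tokens")
  expect_error(
    new_corpus(c("c1", "c1"), list("a", "b"), list("t", "t"), list("m", "m"),
               list("p", "p"), list("e", "e")),
    "duplicate case_id")
  expect_error(validate_corpus(tibble::tibble(case_id = "c1")),
               "missing column")
})

test_that("vocabularies are sorted, dense, 1-based and case-order invariant", {
  corpus <- tiny_corpus()
  vocab <- build_vocabulary(corpus)
  expect_s3_class(vocab, "tcm_vocabulary")
  expect_named(vocab, c(symptom_fields(), "elements"))
  for (fld in names(vocab)) {
    v <- vocab[[fld]]
    expect_identical(unname(v), seq_along(v))     # dense, starts at 1
    expect_identical(names(v), sort(names(v), method = "radix"))
  }
  expect_identical(unname(vocab$elements[c("cold", "damp", "heat")]), 1:3)
  shuffled <- corpus[c(3, 5, 1, 4, 2), ]
  expect_identical(build_vocabulary(shuffled), vocab)
})

test_that("tokens_to_id_matrix pads with 0, maps unknowns to 0 and truncates", {
  fv <- c(a = 1L, b = 2L, c = 3L)
  m <- tokens_to_id_matrix(list(c("a", "c"), "b", c("c", "zzz", "a")), fv)
  expect_identical(m, matrix(c(1L, 2L, 3L, 3L, 0L, 0L, 0L, 0L, 1L), 3, 3))
  m2 <- tokens_to_id_matrix(list(c("a", "b", "c")), fv, max_len = 2)
  expect_identical(ncol(m2), 2L)
  expect_identical(m2[1, ], c(1L, 2L))
})

test_that("build_samples 'all' emits the exact cross product with correct labels", {
  corpus <- tiny_corpus()
  vocab <- build_vocabulary(corpus)
  s <- build_samples(corpus, vocab)
  expect_s3_class(s, "tcm_samples")
  expect_identical(n_samples(s), nrow(corpus) * length(vocab$elements))
  expect_identical(sum(s$label), length(unlist(corpus$syndrome_elements)))
  # every sample's label matches membership in the case's true set
  el_names <- names(vocab$elements)
  for (r in seq_len(n_samples(s))) {
    truth <- corpus$syndrome_elements[[s$case_index[r]]]
    expect_identical(s$label[r],
                     as.integer(el_names[s$element_id[r]] %in% truth))
  }
  expect_identical(s$case_id, corpus$case_id[s$case_index])
  expect_null(s$extra)
})

test_that("build_samples 'sampled' keeps all positives and is seed-deterministic", {
  gen <- small_gen(n_cases = 30)
  vocab <- build_vocabulary(gen$corpus)
  s1 <- build_samples(gen$corpus, vocab, negative_policy = "sampled",
                      n_negatives = 2L, seed = 11)
  s2 <- build_samples(gen$corpus, vocab, negative_policy = "sampled",
                      n_negatives = 2L, seed = 11)
  expect_identical(s1, s2)
  s3 <- build_samples(gen$corpus, vocab, negative_policy = "sampled",
                      n_negatives = 2L, seed = 12)
  expect_false(identical(s1$element_id, s3$element_id))
  # all positives retained, negatives counted and truly negative
  n_pos_truth <- length(unlist(gen$corpus$syndrome_elements))
  expect_identical(sum(s1$label), n_pos_truth)
  el_names <- names(vocab$elements)
  for (i in seq_len(nrow(gen$corpus))) {
    rows <- which(s1$case_index == i)
    truth <- gen$corpus$syndrome_elements[[i]]
    expect_setequal(el_names[s1$element_id[rows][s1$label[rows] == 1]], truth)
    negs <- el_names[s1$element_id[rows][s1$label[rows] == 0]]
    expect_length(negs, min(length(el_names) - length(truth),
                            2L * length(truth)))
    expect_false(any(negs %in% truth))
    expect_false(anyDuplicated(negs) > 0)
  }
  expect_error(build_samples(gen$corpus, vocab, negative_policy = "sampled"),
               "requires a seed")
})

test_that("unknown elements error while unknown symptoms map to padding id 0", {
  corpus <- tiny_corpus()
  vocab <- build_vocabulary(corpus[1:2, ])   # 'cold' is absent from cases 1-2
  expect_error(build_samples(corpus, vocab), "absent from vocabulary")
  # drop only a symptom: same elements, one unseen engraving token
  vocab_full <- build_vocabulary(corpus)
  vocab_full$engraving_symptoms <-
    vocab_full$engraving_symptoms[names(vocab_full$engraving_symptoms) != "ache"]
  vocab_full$engraving_symptoms[] <- seq_along(vocab_full$engraving_symptoms)
  s <- build_samples(corpus, vocab_full)
  rows4 <- which(s$case_index == 4)
  expect_true(all(s$field_ids$engraving_symptoms[rows4, 3] == 0L))
})

test_that("engraving symptoms are truncated to seven per case", {
  corpus <- new_corpus("c1", list(paste0("s", 1:9)), list("t"), list("m"),
                       list("p"), list("e"))
  corpus2 <- new_corpus("c2", list("s1"), list("t"), list("m"), list("p"),
                        list("e"))
  both <- rbind(corpus, corpus2)
  vocab <- build_vocabulary(both)
  s <- build_samples(both, vocab)
  expect_identical(ncol(s$field_ids$engraving_symptoms), 7L)
  expect_true(all(s$field_ids$engraving_symptoms[s$case_index == 1, ] > 0))
})

test_that("samples_subset and attach_features behave consistently", {
  corpus <- tiny_corpus()
  vocab <- build_vocabulary(corpus)
  s <- build_samples(corpus, vocab)
  feat <- matrix(seq_len(2 * n_samples(s)), ncol = 2)
  s <- attach_features(s, feat)
  sub <- samples_subset(s, c(3, 1, 7))
  expect_identical(sub$label, s$label[c(3, 1, 7)])
  expect_identical(sub$extra, feat[c(3, 1, 7), ])
  expect_identical(sub$field_ids$tongue, s$field_ids$tongue[c(3, 1, 7), , drop = FALSE])
  expect_error(attach_features(s, feat[1:4, ]), "rows but there are")
})

test_that("split_cases is seeded, disjoint and exhaustive", {
  gen <- small_gen(n_cases = 60)
  sp1 <- split_cases(gen$corpus, 0.25, seed = 5)
  sp2 <- split_cases(gen$corpus, 0.25, seed = 5)
  expect_identical(sp1$test$case_id, sp2$test$case_id)
  expect_identical(nrow(sp1$test), 15L)
  expect_length(intersect(sp1$train$case_id, sp1$test$case_id), 0)
  expect_setequal(c(sp1$train$case_id, sp1$test$case_id), gen$corpus$case_id)
  sp3 <- split_cases(gen$corpus, 0.25, seed = 6)
  expect_false(identical(sp1$test$case_id, sp3$test$case_id))
  expect_error(split_cases(gen$corpus, 0, seed = 1), "strictly between")
  expect_error(split_cases(gen$corpus, 1, seed = 1), "strictly between")
})

test_that("JSONL round trip preserves the corpus, including UTF-8 tokens", {
  corpus <- tiny_corpus()
  corpus$tongue[[1]] <- c("红舵", "red")   # non-ASCII token
  corpus <- validate_corpus(corpus)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_cases(corpus, path)
  back <- read_cases(path)
  for (fld in c(symptom_fields(), "syndrome_elements")) {
    expect_identical(back[[fld]], corpus[[fld]])
  }
  expect_identical(back$case_id, corpus$case_id)
})

test_that("read_cases flags malformed and incomplete records with line numbers", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  good <- paste0('{"case_id":"c1","engraving_symptoms":["a"],"tongue":["t"],',
                 '"moss":["m"],"pulse":["p"],"syndrome_elements":["e"]}')
  writeLines(c(good, "{not json"), path)
  expect_error(read_cases(path), "line 2")
  writeLines(c(good, '{"case_id":"c2","tongue":["t"]}'), path)
  expect_error(read_cases(path), "line 2.*missing field")
  writeLines(character(0), path)
  expect_warning(empty <- read_cases(path), "no records")
  expect_identical(nrow(empty), 0L)
})

test_that("write_vocabulary emits one readable TSV per field", {
  vocab <- build_vocabulary(tiny_corpus())
  dir <- withr::local_tempdir()
  write_vocabulary(vocab, dir)
  files <- list.files(dir)
  expect_setequal(files, paste0(c(symptom_fields(), "elements"), ".tsv"))
  tab <- utils::read.delim(file.path(dir, "elements.tsv"))
  expect_identical(tab$token, names(vocab$elements))
  expect_identical(tab$id, unname(vocab$elements))
})
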