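# Synthetic medical-case corpora with planted symptom -> syndrome-element
# associations, emulating the structure of real laboratory case collections:
# ~62 elements, a few hundred distinct engraving symptoms, short tongue /
# moss / pulse fields, and co-occurrence signal strong enough for both the
# statistical features and a trained model to recover.

#' Configuration for the synthetic corpus generator
#'
#' @param n_cases Number of cases to generate.
#' @param n_elements Size of the syndrome-element vocabulary (default 62).
#' @param vocab_sizes Named integer vector of field vocabulary sizes
#'   (defaults: engraving 500, tongue 20, moss 20, pulse 25).
#' @param elements_per_case Integer range (length 2) of true elements per
#'   case, sampled uniformly.
#' @param tokens_per_case Named list of length-2 integer ranges per field
#'   (defaults: engraving 3-7, tongue/moss/pulse 1-2).
#' @param affinity_strength Probability that a non-noise token is drawn from
#'   a chosen element's characteristic set rather than uniformly (default
#'   0.8). The effective characteristic mass per token is
#'   `(1 - noise_rate) * affinity_strength`.
#' @param noise_rate Probability a token is drawn uniformly from the field
#'   vocabulary regardless of the case's elements (default 0.1).
#' @param char_set_sizes Named integer vector: characteristic tokens per
#'   element per field (defaults: engraving 6, tongue 2, moss 2, pulse 2).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cases = 5000L,
                             n_elements = 62L,
                             vocab_sizes = c(engraving_symptoms = 500L,
                                             tongue = 20L, moss = 20L,
                                             pulse = 25L),
                             elements_per_case = c(1L, 4L),
                             tokens_per_case = list(
                               engraving_symptoms = c(3L, 7L),
                               tongue = c(1L, 2L), moss = c(1L, 2L),
                               pulse = c(1L, 2L)),
                             affinity_strength = 0.8,
                             noise_rate = 0.1,
                             char_set_sizes = c(engraving_symptoms = 6L,
                                                tongue = 2L, moss = 2L,
                                                pulse = 2L),
                             seed = 7L) {
  cfg <- list(n_cases = as.integer(n_cases), n_elements = as.integer(n_elements),
              vocab_sizes = vocab_sizes, elements_per_case = as.integer(elements_per_case),
              tokens_per_case = tokens_per_case,
              affinity_strength = affinity_strength, noise_rate = noise_rate,
              char_set_sizes = char_set_sizes, seed = as.integer(seed))
  if (cfg$n_cases < 1) stop("n_cases must be positive")
  if (cfg$n_elements < 1) stop("n_elements must be positive")
  if (any(vocab_sizes < 1)) stop("vocabulary sizes must be positive")
  if (affinity_strength < 0 || affinity_strength > 1) stop("affinity_strength must be in [0,1]")
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0,1]")
  rng_ok <- function(r) length(r) == 2 && r[1] >= 1 && r[1] <= r[2]
  if (!rng_ok(cfg$elements_per_case)) stop("invalid elements_per_case range")
  for (fld in symptom_fields()) {
    r <- tokens_per_case[[fld]]
    if (is.null(r) || !rng_ok(r)) stop("invalid tokens_per_case range for ", fld)
    if (r[2] > vocab_sizes[[fld]]) {
      stop("tokens_per_case upper bound for ", fld,
           " exceeds its vocabulary size (cannot draw distinct tokens)")
    }
  }
  if (cfg$elements_per_case[2] > cfg$n_elements) {
    stop("elements_per_case upper bound exceeds n_elements")
  }
  structure(cfg, class = "generator_config")
}

# Short synthetic token names per field, e.g. sym007, tng03, el12.
field_token_names <- function(field, n) {
  prefix <- c(engraving_symptoms = "sym", tongue = "tng",
              moss = "mss", pulse = "pls")[[field]]
  sprintf("%s%03d", prefix, seq_len(n))
}

#' Generate a synthetic case corpus with planted associations
#'
#' Each case draws its true element set uniformly (size uniform over the
#' configured range, elements without replacement), then fills each symptom
#' field token by token: with probability `noise_rate` the token is uniform
#' over the field vocabulary; otherwise, with probability
#' `affinity_strength`, it is drawn from the characteristic token set of one
#' of the case's elements (element chosen uniformly), and with the remaining
#' probability uniformly. Duplicate tokens within a field are rejected and
#' redrawn, so corpus invariants hold by construction.
#'
#' Characteristic sets are carved from a seeded permutation of each field
#' vocabulary in consecutive blocks, so they are disjoint across elements
#' whenever the vocabulary is large enough and wrap around (overlap) when it
#' is not.
#'
#' @param config A [generator_config()].
#' @return A list with `corpus` (a corpus tibble) and `truth` (class
#'   `planted_truth`): per-element characteristic token sets per field plus
#'   the generating config.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)

  vocabs <- lapply(symptom_fields(), function(fld) {
    field_token_names(fld, config$vocab_sizes[[fld]])
  })
  names(vocabs) <- symptom_fields()
  elements <- sprintf("el%02d", seq_len(config$n_elements))

  # Characteristic sets: consecutive blocks of a permuted vocabulary,
  # wrapping around when n_elements * block exceeds the vocabulary.
  char_sets <- list()
  for (fld in symptom_fields()) {
    v <- config$vocab_sizes[[fld]]
    s <- max(1L, min(as.integer(config$char_set_sizes[[fld]]), v))
    perm <- sample(vocabs[[fld]])
    sets <- vector("list", config$n_elements)
    for (e in seq_len(config$n_elements)) {
      pos <- ((e - 1L) * s + seq_len(s) - 1L) %% v + 1L
      sets[[e]] <- perm[pos]
    }
    names(sets) <- elements
    char_sets[[fld]] <- sets
  }

  n <- config$n_cases
  epc <- config$elements_per_case
  n_els <- sample.int(epc[2] - epc[1] + 1L, n, replace = TRUE) + epc[1] - 1L
  case_elements <- lapply(n_els, function(k) sample(elements, k))

  draw_field <- function(fld, els) {
    r <- config$tokens_per_case[[fld]]
    k <- sample.int(r[2] - r[1] + 1L, 1L) + r[1] - 1L
    pool <- vocabs[[fld]]
    sets <- char_sets[[fld]]
    out <- character(0)
    tries <- 0L
    while (length(out) < k && tries < 100L * k) {
      tries <- tries + 1L
      u <- stats::runif(1)
      tok <- if (u < config$noise_rate) {
        pool[sample.int(length(pool), 1L)]
      } else if (stats::runif(1) < config$affinity_strength) {
        cs <- sets[[els[sample.int(length(els), 1L)]]]
        cs[sample.int(length(cs), 1L)]
      } else {
        pool[sample.int(length(pool), 1L)]
      }
      if (!tok %in% out) out <- c(out, tok)
    }
    out
  }

  fields <- list()
  for (fld in symptom_fields()) {
    fields[[fld]] <- lapply(case_elements, function(els) draw_field(fld, els))
  }

  corpus <- new_corpus(
    case_id = sprintf("case%06d", seq_len(n)),
    engraving_symptoms = fields$engraving_symptoms,
    tongue = fields$tongue, moss = fields$moss, pulse = fields$pulse,
    syndrome_elements = case_elements
  )
  truth <- structure(list(char_sets = char_sets, elements = elements,
                          config = config),
                     class = "planted_truth")
  list(corpus = corpus, truth = truth)
}

#' Save planted truth alongside a corpus
#'
#' @param truth A `planted_truth` object.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  out <- list(elements = truth$elements, char_sets = truth$char_sets,
              config = unclass(truth$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Published per-entry statistic values for one worked sample case
#'
#' The reference worked example: a single case with five engraving symptoms,
#' one tongue token, two moss tokens and one pulse token, all sharing one
#' syndrome element, together with the published per-entry values of the
#' four co-occurrence statistics. Used as input to the aggregation rules
#' (sum / average / padding) and as a consistency check on the lift
#' definition.
#'
#' @return A list with one element per statistic (`F1`, `F2`, `L`, `TFIDF`),
#'   each a named list of per-field numeric vectors.
#' @export
table3_fixture <- function() {
  entry <- function(engraving, tongue, moss, pulse) {
    list(engraving_symptoms = engraving, tongue = tongue, moss = moss,
         pulse = pulse)
  }
  list(
    F1 = entry(c(0.0821, 0.0698, 0.0850, 0.0855, 0.0575), 0.0653,
               c(0.0840, 0.1049), 0.0985),
    F2 = entry(c(0.3343, 0.2703, 0.3099, 0.3379, 0.2497), 0.2805,
               c(0.3415, 0.4384), 0.3960),
    L = entry(c(1.0938, 0.8844, 1.0139, 1.1056, 0.8170), 0.9178,
              c(1.1172, 1.4345), 1.2958),
    TFIDF = entry(c(0.1823, 0.1550, 0.1888, 0.1900, 0.1277), 0.0910,
                  c(0.0943, 0.1179), 0.1366)
  )
}

#' Published aggregated statistic values for the worked sample case
#'
#' The sum / average / padding rows that the aggregation rules should
#' reproduce from [table3_fixture()].
#'
#' @return A list per statistic with `sum`, `average` and `padding`.
#' @export
table4_fixture <- function() {
  list(
    F1 = list(sum = 0.7327, average = 0.0814,
              padding = c(0.0821, 0.0698, 0.0850, 0.0855, 0.0575, -1, -1,
                          0.0653, 0.0945, 0.0985)),
    F2 = list(sum = 2.9585, average = 0.3287,
              padding = c(0.3343, 0.2703, 0.3099, 0.3379, 0.2497, -1, -1,
                          0.2805, 0.3899, 0.3960)),
    L = list(sum = 9.6800, average = 1.0756,
             padding = c(1.0938, 0.8844, 1.0139, 1.1056, 0.8170, -1, -1,
                         0.9178, 1.2759, 1.2958)),
    TFIDF = list(sum = 1.2835, average = 0.1426,
                 padding = c(0.1823, 0.1550, 0.1888, 0.1900, 0.1277, -1, -1,
                             0.0910, 0.1061, 0.1366))
  )
}

#' Published benchmark AUC values
#'
#' Mean test AUC of the published large-corpus benchmark runs, used for
#' relative-improvement arithmetic.
#'
#' @return Named numeric vector (`mlp`, `textcnn`, `mmoe`, `mmoe_match_mimic`).
#' @export
benchmark_auc_fixture <- function() {
  c(mlp = 0.90844, textcnn = 0.90991, mmoe = 0.90780,
    mmoe_match_mimic = 0.91132)
}
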