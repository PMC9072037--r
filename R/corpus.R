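# Core domain types: the case corpus, vocabularies and labeled samples.
#
# A corpus is a tibble with one row per medical case and list-columns holding
# the token lists of the four symptom fields plus the ground-truth syndrome
# elements. All downstream code (statistics, sampling, the network) works on
# this representation.

#' Symptom field names of a medical case
#'
#' The four examination fields recorded for every case, in canonical order:
#' engraving (chief presenting) symptoms, tongue body, tongue coating (moss)
#' and pulse quality.
#'
#' @return Character vector of field names.
#' @export
symptom_fields <- function() {
  c("engraving_symptoms", "tongue", "moss", "pulse")
}

# Maximum number of engraving symptoms retained per case.
MAX_ENGRAVING <- 7L

#' Construct a medical-case corpus
#'
#' Assembles per-case token lists into a validated corpus tibble. Each
#' argument other than `case_id` is a list with one character vector per case.
#'
#' @param case_id Character vector of unique case identifiers.
#' @param engraving_symptoms,tongue,moss,pulse Lists of token character
#'   vectors, one element per case. Tokens are whole phrases; no sub-word
#'   splitting is performed.
#' @param syndrome_elements List of character vectors: the true syndrome
#'   elements of each case (non-empty).
#' @return A tibble of class `tcm_corpus` with one row per case.
#' @export
#' @examples
#' new_corpus(
#'   case_id = "c1",
#'   engraving_symptoms = list(c("nausea", "vomiting")),
#'   tongue = list("plump tongue"), moss = list("yellow coating"),
#'   pulse = list("thready pulse"), syndrome_elements = list("wetness")
#' )
new_corpus <- function(case_id, engraving_symptoms, tongue, moss, pulse,
                       syndrome_elements) {
  corpus <- tibble::tibble(
    case_id = as.character(case_id),
    engraving_symptoms = engraving_symptoms,
    tongue = tongue,
    moss = moss,
    pulse = pulse,
    syndrome_elements = syndrome_elements
  )
  class(corpus) <- c("tcm_corpus", class(corpus))
  validate_corpus(corpus)
}

#' Validate corpus invariants
#'
#' Checks that engraving symptoms and syndrome elements are non-empty for
#' every case, that no field contains duplicate tokens within a case, and
#' that case identifiers are unique.
#'
#' @param corpus A corpus tibble.
#' @return The corpus, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_corpus <- function(corpus) {
  needed <- c("case_id", symptom_fields(), "syndrome_elements")
  missing <- setdiff(needed, names(corpus))
  if (length(missing) > 0) {
    stop("corpus is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(corpus$case_id)) {
    stop("duplicate case_id in corpus")
  }
  if (any(lengths(corpus$engraving_symptoms) == 0)) {
    stop("every case must have at least one engraving symptom")
  }
  if (any(lengths(corpus$syndrome_elements) == 0)) {
    stop("every case must have at least one syndrome element")
  }
  for (fld in c(symptom_fields(), "syndrome_elements")) {
    dup <- vapply(corpus[[fld]], anyDuplicated, integer(1)) > 0
    if (any(dup)) {
      stop("duplicate tokens within field '", fld, "' for case(s): ",
           paste(utils::head(corpus$case_id[dup], 3), collapse = ", "))
    }
  }
  corpus
}

#' Build per-field vocabularies from a corpus
#'
#' Assigns dense positive integer ids to every token observed in each of the
#' four symptom fields and to every syndrome element. Tokens are sorted
#' lexicographically (C locale) before id assignment, so the vocabulary is
#' invariant to case order. Id 0 is reserved for padding and unknown tokens.
#'
#' @param corpus A corpus tibble (at least one case).
#' @return An object of class `tcm_vocabulary`: a list with one named integer
#'   vector per symptom field plus `elements`.
#' @export
build_vocabulary <- function(corpus) {
  validate_corpus(corpus)
  if (nrow(corpus) == 0) stop("cannot build a vocabulary from an empty corpus")
  index_field <- function(token_lists) {
    tokens <- sort(unique(unlist(token_lists, use.names = FALSE)), method = "radix")
    stats::setNames(seq_along(tokens), tokens)
  }
  vocab <- lapply(corpus[symptom_fields()], index_field)
  vocab$elements <- index_field(corpus$syndrome_elements)
  structure(vocab, class = "tcm_vocabulary")
}

#' @export
print.tcm_vocabulary <- function(x, ...) {
  cat("<tcm_vocabulary>\n")
  for (fld in names(x)) cat(sprintf("  %-20s %d tokens\n", fld, length(x[[fld]])))
  invisible(x)
}

# Map a list of token vectors to a 0-padded integer id matrix (n x max_len).
# Unknown tokens map to the reserved padding id 0.
tokens_to_id_matrix <- function(token_lists, field_vocab, max_len = NULL) {
  ids <- lapply(token_lists, function(tok) {
    v <- unname(field_vocab[tok])
    v[is.na(v)] <- 0L
    as.integer(v)
  })
  if (!is.null(max_len)) ids <- lapply(ids, utils::head, n = max_len)
  width <- max(1L, max(lengths(ids)))
  m <- matrix(0L, nrow = length(ids), ncol = width)
  for (i in seq_along(ids)) {
    if (length(ids[[i]]) > 0) m[i, seq_along(ids[[i]])] <- ids[[i]]
  }
  m
}

#' Build labeled (case, candidate element) samples
#'
#' Expands cases into binary-labeled samples by pairing each case with
#' candidate syndrome elements. A sample is positive exactly when the
#' candidate belongs to the case's true element set. Under the default
#' policy `"all"` the full cross product of cases and the element vocabulary
#' is emitted; under `"sampled"` every positive is kept and `n_negatives`
#' negatives per positive are drawn without replacement from the case's
#' non-true elements.
#'
#' @param corpus A corpus tibble.
#' @param vocab A `tcm_vocabulary`; must cover every element token in the
#'   corpus (unknown symptom tokens map to id 0, unknown elements are an
#'   error because the label would be ill-defined).
#' @param negative_policy `"all"` (default) or `"sampled"`.
#' @param n_negatives Negatives per positive under `"sampled"`.
#' @param seed Integer seed for negative sampling (required for `"sampled"`).
#' @return An object of class `tcm_samples`: a list with `field_ids` (one
#'   0-padded integer id matrix per symptom field; engraving truncated to 7
#'   tokens), `element_id`, `label`, `case_id`, `case_index` and `extra`
#'   (optional feature matrix, `NULL` until attached).
#' @export
build_samples <- function(corpus, vocab, negative_policy = c("all", "sampled"),
                          n_negatives = 5L, seed = NULL) {
  negative_policy <- match.arg(negative_policy)
  validate_corpus(corpus)
  n_elem <- length(vocab$elements)
  true_ids <- lapply(corpus$syndrome_elements, function(els) {
    ids <- unname(vocab$elements[els])
    if (anyNA(ids)) {
      stop("syndrome element(s) absent from vocabulary: ",
           paste(els[is.na(ids)], collapse = ", "))
    }
    as.integer(ids)
  })

  if (negative_policy == "all") {
    case_index <- rep(seq_len(nrow(corpus)), each = n_elem)
    element_id <- rep.int(seq_len(n_elem), nrow(corpus))
    is_true <- logical(length(element_id))
    offs <- (case_index - 1L) * n_elem
    pos_flat <- unlist(lapply(seq_along(true_ids),
                              function(i) (i - 1L) * n_elem + true_ids[[i]]))
    is_true[pos_flat] <- TRUE
    label <- as.integer(is_true)
  } else {
    if (is.null(seed)) stop("negative_policy 'sampled' requires a seed")
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    pieces_case <- vector("list", nrow(corpus))
    pieces_elem <- vector("list", nrow(corpus))
    pieces_lab <- vector("list", nrow(corpus))
    all_ids <- seq_len(n_elem)
    for (i in seq_len(nrow(corpus))) {
      pos <- true_ids[[i]]
      negpool <- all_ids[-pos]
      k <- min(length(negpool), n_negatives * length(pos))
      neg <- sample(negpool, k)
      pieces_elem[[i]] <- c(pos, neg)
      pieces_lab[[i]] <- c(rep.int(1L, length(pos)), rep.int(0L, length(neg)))
      pieces_case[[i]] <- rep.int(i, length(pos) + length(neg))
    }
    case_index <- unlist(pieces_case)
    element_id <- unlist(pieces_elem)
    label <- unlist(pieces_lab)
  }

  field_ids <- list()
  for (fld in symptom_fields()) {
    cap <- if (fld == "engraving_symptoms") MAX_ENGRAVING else NULL
    per_case <- tokens_to_id_matrix(corpus[[fld]], vocab[[fld]], max_len = cap)
    field_ids[[fld]] <- per_case[case_index, , drop = FALSE]
  }

  structure(
    list(field_ids = field_ids, element_id = element_id, label = label,
         case_id = corpus$case_id[case_index], case_index = case_index,
         n_elements = n_elem, extra = NULL),
    class = "tcm_samples"
  )
}

#' Number of samples in a sample set
#' @param samples A `tcm_samples` object.
#' @return Integer count.
#' @export
n_samples <- function(samples) length(samples$label)

#' @export
print.tcm_samples <- function(x, ...) {
  cat(sprintf("<tcm_samples> %d samples (%d positive), %d candidate elements\n",
              n_samples(x), sum(x$label), x$n_elements))
  if (!is.null(x$extra)) cat(sprintf("  %d extra feature(s) attached\n", ncol(x$extra)))
  invisible(x)
}

# Row subset of a sample set, used for shuffling and batching.
samples_subset <- function(samples, idx) {
  out <- samples
  out$field_ids <- lapply(samples$field_ids, function(m) m[idx, , drop = FALSE])
  out$element_id <- samples$element_id[idx]
  out$label <- samples$label[idx]
  out$case_id <- samples$case_id[idx]
  out$case_index <- samples$case_index[idx]
  if (!is.null(samples$extra)) out$extra <- samples$extra[idx, , drop = FALSE]
  out
}

#' Attach an extra feature matrix to a sample set
#'
#' Appends real-valued per-sample features (e.g. aggregated co-occurrence
#' statistics) that are concatenated to the embedding vector at the network
#' input.
#'
#' @param samples A `tcm_samples` object.
#' @param features Numeric matrix with one row per sample.
#' @return The sample set with `extra` set.
#' @export
attach_features <- function(samples, features) {
  features <- as.matrix(features)
  if (nrow(features) != n_samples(samples)) {
    stop("feature matrix has ", nrow(features), " rows but there are ",
         n_samples(samples), " samples")
  }
  samples$extra <- features
  samples
}

#' Split a corpus into training and test cases
#'
#' Random, seeded, disjoint and exhaustive split at the case level so that
#' no case contributes samples to both sides.
#'
#' @param corpus A corpus tibble.
#' @param test_fraction Fraction of cases assigned to the test set, in (0,1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both corpus tibbles.
#' @export
split_cases <- function(corpus, test_fraction, seed) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n <- nrow(corpus)
  n_test <- round(n * test_fraction)
  test_idx <- sort(sample.int(n, n_test))
  list(train = corpus[setdiff(seq_len(n), test_idx), ],
       test = corpus[test_idx, ])
}

#' Read a case corpus from a JSONL file
#'
#' One JSON object per line with keys `case_id`, `engraving_symptoms`,
#' `tongue`, `moss`, `pulse`, `syndrome_elements`. Token lists are arrays of
#' UTF-8 strings.
#'
#' @param path File path.
#' @return A corpus tibble. An empty file yields an empty corpus with a
#'   warning; a malformed record is an error naming the line.
#' @export
read_cases <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("no records in ", path, "; returning an empty corpus")
    return(new_corpus(character(), list(), list(), list(), list(), list()))
  }
  needed <- c("case_id", symptom_fields(), "syndrome_elements")
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed record at line ", i, " of ", path, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (!all(needed %in% names(rec))) {
      stop("record at line ", i, " of ", path, " is missing field(s): ",
           paste(setdiff(needed, names(rec)), collapse = ", "), call. = FALSE)
    }
    recs[[i]] <- rec
  }
  grab <- function(key) lapply(recs, function(r) as.character(unlist(r[[key]])))
  new_corpus(
    case_id = vapply(recs, function(r) as.character(r$case_id), character(1)),
    engraving_symptoms = grab("engraving_symptoms"),
    tongue = grab("tongue"), moss = grab("moss"), pulse = grab("pulse"),
    syndrome_elements = grab("syndrome_elements")
  )
}

#' Write a case corpus to a JSONL file
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cases <- function(corpus, path) {
  validate_corpus(corpus)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(case_id = corpus$case_id[[i]])
    for (fld in c(symptom_fields(), "syndrome_elements")) {
      rec[[fld]] <- corpus[[fld]][[i]]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = FALSE), con)
  }
  invisible(path)
}

#' Serialize a vocabulary as per-field TSV tables
#'
#' Writes one two-column (token, id) TSV per field into `dir`.
#'
#' @param vocab A `tcm_vocabulary`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_vocabulary <- function(vocab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fld in names(vocab)) {
    df <- data.frame(token = names(vocab[[fld]]), id = unname(vocab[[fld]]))
    utils::write.table(df, file.path(dir, paste0(fld, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

# Run code under a private RNG state: seeds R's RNG and returns a restorer.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
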