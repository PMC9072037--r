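# Hand-designed co-occurrence statistics between symptom tokens and syndrome
# elements: bidirectional association-rule confidence (F1, F2), lift (L) and
# a TF-IDF score, computed per field on the TRAINING split only, plus the
# per-case sum / average / padding aggregations that turn per-entry values
# into fixed-width sample features.

#' Compute co-occurrence count tables on a training corpus
#'
#' For each symptom field, counts case-level co-occurrence between every
#' symptom token and every syndrome element: a case contributes at most 1 to
#' any (token, element) cell regardless of token multiplicity. Also records
#' the marginal counts backing the derived statistics.
#'
#' @param train_corpus The training-split corpus (never the test split:
#'   the statistics leak labels if computed on evaluation cases).
#' @param vocab A `tcm_vocabulary` built on (at least) the training corpus.
#' @return An object of class `cooccurrence_stats`: per field, a sparse
#'   co-occurrence matrix `N` (tokens x elements), token marginals `T_zz`,
#'   the token co-occurrence mass `S_zz` (= rowSums of N) and the distinct
#'   observed token count `Y_zz`; globally, element marginals `T_zs`, the
#'   total case count `T_total` and `H_zs`, the number of distinct other
#'   elements each element co-occurs with in at least one case.
#' @export
compute_stats <- function(train_corpus, vocab) {
  validate_corpus(train_corpus)
  n <- nrow(train_corpus)
  if (n == 0) stop("cannot compute statistics on an empty corpus")

  incidence <- function(token_lists, field_vocab) {
    ids <- lapply(token_lists, function(tok) {
      v <- unname(field_vocab[tok])
      sort(unique(v[!is.na(v)]))
    })
    j <- unlist(ids, use.names = FALSE)
    i <- rep.int(seq_along(ids), lengths(ids))
    Matrix::sparseMatrix(i = i, j = j, x = 1,
                         dims = c(length(ids), length(field_vocab)))
  }

  B <- incidence(train_corpus$syndrome_elements, vocab$elements)
  T_zs <- Matrix::colSums(B)
  co_elem <- Matrix::crossprod(B)            # element x element case counts
  H_zs <- Matrix::rowSums(co_elem > 0) - as.integer(Matrix::diag(co_elem) > 0)

  fields <- list()
  for (fld in symptom_fields()) {
    A <- incidence(train_corpus[[fld]], vocab[[fld]])
    N <- Matrix::crossprod(A, B)             # token x element case counts
    T_zz <- Matrix::colSums(A)
    fields[[fld]] <- list(N = N, T_zz = T_zz, S_zz = Matrix::rowSums(N),
                          Y_zz = sum(T_zz > 0))
  }

  structure(list(fields = fields, T_zs = T_zs, H_zs = H_zs, T_total = n,
                 vocab = vocab),
            class = "cooccurrence_stats")
}

#' @export
print.cooccurrence_stats <- function(x, ...) {
  cat(sprintf("<cooccurrence_stats> %d training cases, %d elements\n",
              x$T_total, length(x$T_zs)))
  for (fld in names(x$fields)) {
    cat(sprintf("  %-20s %d observed tokens\n", fld, x$fields[[fld]]$Y_zz))
  }
  invisible(x)
}

# Resolve token/element names or ids to integer ids for a field.
resolve_ids <- function(keys, field_vocab, what) {
  if (is.character(keys)) {
    ids <- unname(field_vocab[keys])
    if (anyNA(ids)) stop("unknown ", what, ": ",
                         paste(keys[is.na(ids)], collapse = ", "))
    as.integer(ids)
  } else as.integer(keys)
}

stat_lookup <- function(stats, field, zz, zs) {
  f <- stats$fields[[field]]
  if (is.null(f)) stop("unknown field: ", field)
  zz <- resolve_ids(zz, stats$vocab[[field]], "symptom token")
  zs <- resolve_ids(zs, stats$vocab$elements, "element token")
  k <- max(length(zz), length(zs))
  zz <- rep_len(zz, k); zs <- rep_len(zs, k)
  list(N = f$N[cbind(zz, zs)], T_zz = f$T_zz[zz], T_zs = stats$T_zs[zs],
       S_zz = f$S_zz[zz], Y_zz = f$Y_zz, H_zs = stats$H_zs[zs])
}

# Division that returns 0 (with one warning) where the denominator is zero;
# rare tokens/elements are expected and must not abort feature building.
safe_ratio <- function(num, den, what) {
  bad <- den == 0
  if (any(bad)) {
    warning("zero ", what, " for ", sum(bad),
            " entr(ies); returning 0 for those")
    den[bad] <- 1
    num[bad] <- 0
  }
  num / den
}

#' Confidence of a symptom for an element (symptom-conditioned)
#'
#' F1 = N(zz, zs) / T(zz): the fraction of cases containing symptom token
#' `zz` that also carry element `zs`.
#'
#' @param stats A `cooccurrence_stats`.
#' @param field Symptom field name.
#' @param zz Symptom token(s) (names or ids); recycled against `zs`.
#' @param zs Element token(s) (names or ids).
#' @return Numeric vector in \[0, 1\]; 0 with a warning when T(zz) = 0.
#' @export
confidence_f1 <- function(stats, field, zz, zs) {
  l <- stat_lookup(stats, field, zz, zs)
  safe_ratio(l$N, l$T_zz, "symptom count T_zz")
}

#' Confidence of an element for a symptom (element-conditioned)
#'
#' F2 = N(zz, zs) / T(zs): the fraction of cases carrying element `zs` that
#' also contain symptom token `zz`.
#'
#' @inheritParams confidence_f1
#' @return Numeric vector in \[0, 1\]; 0 with a warning when T(zs) = 0.
#' @export
confidence_f2 <- function(stats, field, zz, zs) {
  l <- stat_lookup(stats, field, zz, zs)
  safe_ratio(l$N, l$T_zs, "element count T_zs")
}

#' Promotion degree (lift) of a symptom-element pair
#'
#' L = F2 / (T(zs) / T_total) * scale: element-conditioned confidence
#' relative to the element's marginal corpus frequency. Equals `scale` under
#' independence. The default scale of 1 reproduces the published worked
#' example, where every per-entry value satisfies L = F2 / element frequency
#' exactly; the scale is kept as a knob for rescaled variants.
#'
#' @inheritParams confidence_f1
#' @param scale Multiplicative scale, default 1.
#' @return Numeric vector, non-negative.
#' @export
lift <- function(stats, field, zz, zs, scale = 1) {
  l <- stat_lookup(stats, field, zz, zs)
  f2 <- safe_ratio(l$N, l$T_zs, "element count T_zs")
  safe_ratio(f2, l$T_zs / stats$T_total, "element frequency") * scale
}

#' TF-IDF score of a symptom-element pair
#'
#' TF = N(zz, zs) / S(zz) where S(zz) is the token's total co-occurrence
#' mass across all elements; IDF = log(Y_zz / (H_zs + 1)) where Y_zz is the
#' number of distinct observed tokens in the field and H_zs the number of
#' distinct other elements `zs` co-occurs with. TF-IDF = TF * IDF.
#'
#' @inheritParams confidence_f1
#' @param log_base Base of the IDF logarithm; natural log by default.
#' @return Numeric vector; 0 with a warning when S(zz) = 0.
#' @export
tfidf <- function(stats, field, zz, zs, log_base = exp(1)) {
  l <- stat_lookup(stats, field, zz, zs)
  tf <- safe_ratio(l$N, l$S_zz, "co-occurrence mass S_zz")
  idf <- log(l$Y_zz / (l$H_zs + 1), base = log_base)
  tf * idf
}

#' Aggregate per-entry statistic values for one case
#'
#' Turns the per-token values of one statistic over a case's four fields
#' into the three fixed-size summaries used as sample features:
#' \describe{
#'   \item{sum}{total over every entry of every field;}
#'   \item{average}{sum divided by the number of entries;}
#'   \item{padding}{a length-10 vector: the first 7 engraving values
#'     (-1-filled when fewer, truncated when more) followed by the tongue,
#'     moss and pulse field means.}
#' }
#'
#' @param values Named list with numeric vectors `engraving_symptoms`,
#'   `tongue`, `moss`, `pulse` (the per-entry statistic values of one case;
#'   tongue/moss/pulse may be empty).
#' @param max_engraving Padding width of the engraving block (default 7).
#' @param fill Fill value for short engraving lists (default -1).
#' @return A list with `sum`, `average` and `padding` (length
#'   `max_engraving + 3`).
#' @export
aggregate_case_features <- function(values, max_engraving = MAX_ENGRAVING,
                                    fill = -1) {
  flds <- symptom_fields()
  values <- values[flds]
  if (any(vapply(values, is.null, logical(1)))) {
    stop("values must contain all four symptom fields")
  }
  all_vals <- unlist(values, use.names = FALSE)
  if (length(all_vals) == 0) stop("no entries to aggregate")
  eng <- values$engraving_symptoms
  if (length(eng) == 0) stop("engraving entry list must be non-empty")
  eng_block <- rep(fill, max_engraving)
  keep <- min(length(eng), max_engraving)
  eng_block[seq_len(keep)] <- eng[seq_len(keep)]
  short_mean <- function(v) if (length(v) == 0) fill else mean(v)
  list(sum = sum(all_vals),
       average = sum(all_vals) / length(all_vals),
       padding = c(eng_block, short_mean(values$tongue),
                   short_mean(values$moss), short_mean(values$pulse)))
}

# Per-entry values of one statistic for one case against one element.
case_entry_values <- function(stats, corpus_row, element, statistic,
                              lift_scale = 1, log_base = exp(1)) {
  fn <- switch(statistic,
               F1 = confidence_f1,
               F2 = confidence_f2,
               L = function(s, f, zz, zs) lift(s, f, zz, zs, scale = lift_scale),
               TFIDF = function(s, f, zz, zs) tfidf(s, f, zz, zs, log_base = log_base),
               stop("unknown statistic: ", statistic))
  out <- list()
  for (fld in symptom_fields()) {
    tok <- corpus_row[[fld]][[1]]
    tok <- tok[tok %in% names(stats$vocab[[fld]])]
    out[[fld]] <- if (length(tok) == 0) numeric(0) else fn(stats, fld, tok, element)
  }
  out
}

#' Build aggregated statistic features for a sample set
#'
#' For every (case, candidate element) sample, computes the chosen
#' statistics over the case's fields against the candidate element and
#' aggregates them. Feature columns are laid out as `[sum, average]` per
#' statistic, followed by the length-10 padding block per statistic when
#' `include_padding` is `TRUE`, in the order of `statistics`.
#'
#' @param samples A `tcm_samples` object built from `corpus`.
#' @param corpus The corpus the samples were built from.
#' @param stats A `cooccurrence_stats` computed on the training split.
#' @param statistics Which statistics to include, subset of
#'   `c("F1","F2","L","TFIDF")`.
#' @param include_padding Include the padding blocks (default `FALSE`).
#' @param lift_scale,log_base Passed through to [lift()] and [tfidf()].
#' @return The sample set with the feature matrix attached.
#' @export
featurize_samples <- function(samples, corpus, stats,
                              statistics = c("F1", "F2", "L", "TFIDF"),
                              include_padding = FALSE,
                              lift_scale = 1, log_base = exp(1)) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  n <- n_samples(samples)
  width <- length(statistics) * (2L + if (include_padding) 10L else 0L)
  # Precompute, per statistic, the full per-case x element value structure
  # via vectorized lookups: loop over cases once, not over samples.
  feat <- matrix(0, nrow = n, ncol = width)
  el_names <- names(stats$vocab$elements)
  suppressWarnings({
    by_case <- split(seq_len(n), samples$case_index)
    for (ci_chr in names(by_case)) {
      ci <- as.integer(ci_chr)
      rows <- by_case[[ci_chr]]
      row <- corpus[ci, ]
      for (r in rows) {
        el <- el_names[samples$element_id[r]]
        col <- 0L
        vals_sum_avg <- numeric(0)
        pad_vals <- numeric(0)
        for (st in statistics) {
          vals <- case_entry_values(stats, row, el, st,
                                    lift_scale = lift_scale, log_base = log_base)
          agg <- aggregate_case_features(vals)
          vals_sum_avg <- c(vals_sum_avg, agg$sum, agg$average)
          if (include_padding) pad_vals <- c(pad_vals, agg$padding)
        }
        feat[r, ] <- c(vals_sum_avg, pad_vals)
      }
    }
  })
  attach_features(samples, feat)
}

#' Export per-field statistic tables
#'
#' Writes one long-format TSV per field with columns field, symptom token,
#' element token, the raw counts and all derived statistics, for every
#' (token, element) pair with a positive co-occurrence count.
#'
#' @param stats A `cooccurrence_stats`.
#' @param dir Output directory.
#' @param lift_scale,log_base Passed to [lift()] and [tfidf()].
#' @return The directory, invisibly.
#' @export
write_stats <- function(stats, dir, lift_scale = 1, log_base = exp(1)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  el_names <- names(stats$vocab$elements)
  for (fld in names(stats$fields)) {
    f <- stats$fields[[fld]]
    nz <- Matrix::which(f$N > 0, arr.ind = TRUE)
    zz <- nz[, 1]; zs <- nz[, 2]
    suppressWarnings(df <- data.frame(
      field = fld,
      symptom_token = names(stats$vocab[[fld]])[zz],
      element_token = el_names[zs],
      N = f$N[nz], T_zz = f$T_zz[zz], T_zs = stats$T_zs[zs],
      F1 = confidence_f1(stats, fld, zz, zs),
      F2 = confidence_f2(stats, fld, zz, zs),
      L = lift(stats, fld, zz, zs, scale = lift_scale),
      TFIDF = tfidf(stats, fld, zz, zs, log_base = log_base)
    ))
    utils::write.table(df, file.path(dir, paste0("stats_", fld, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(dir)
}
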