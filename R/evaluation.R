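# Ranking metrics: pairwise AUC, relative improvement over a baseline
# (RelaImpr), and the per-case top-10 metrics Hits@10, MeanRank and MRR.

#' Pairwise ranking AUC
#'
#' Fraction of (positive, negative) pairs in which the positive receives the
#' higher score, with ties credited 0.5. Computed by the rank-sum identity,
#' which is exactly equivalent to brute-force pair counting.
#'
#' @param labels 0/1 vector (both classes must be present).
#' @param scores Numeric score vector of equal length.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs both positive and negative samples")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Relative AUC improvement over a baseline
#'
#' `RelaImpr = ((AUC_new - 0.5) / (AUC_base - 0.5) - 1) * 100`, measuring
#' improvement above the 0.5 random-ranking floor, as a signed percentage.
#'
#' @param auc_new AUC of the evaluated model.
#' @param auc_base AUC of the baseline (must differ from 0.5).
#' @return Signed percentage.
#' @export
rela_impr <- function(auc_new, auc_base) {
  if (any(abs(auc_base - 0.5) < .Machine$double.eps^0.5)) {
    stop("RelaImpr is undefined for a baseline AUC of exactly 0.5")
  }
  ((auc_new - 0.5) / (auc_base - 0.5) - 1) * 100
}

#' Hits@k for one case
#'
#' Fraction of the case's true elements found in the top `k` of the ranked
#' candidate list.
#'
#' @param true_elements Non-empty vector of true element identifiers.
#' @param ranked_elements Candidate identifiers in rank order (best first).
#' @param k Cut-off (default 10).
#' @return Value in \[0, 1\].
#' @export
hits_at_k <- function(true_elements, ranked_elements, k = 10L) {
  if (length(true_elements) == 0) stop("true element set is empty")
  top <- utils::head(ranked_elements, k)
  sum(true_elements %in% top) / length(true_elements)
}

#' Rank-penalty score (MeanRank contribution) for one case
#'
#' With `y` the number of true elements found in the top 10, `s` the number
#' of true elements and `i` the deepest (largest) rank position of any true
#' element within the top 10, the per-case score is `y / s` when `i < 5`,
#' `(y + i - 3) / s` when `5 <= i <= 10`, and `(11 - s) / s` when no true
#' element reaches the top 10. Smaller is better. The choice of the deepest
#' hit for `i` penalizes hits that sit lower in the list; the whole rule is
#' isolated here so an alternative reading can be substituted in one place.
#'
#' @inheritParams hits_at_k
#' @return Non-negative score.
#' @export
rank_penalty <- function(true_elements, ranked_elements, k = 10L) {
  if (length(true_elements) == 0) stop("true element set is empty")
  s <- length(true_elements)
  top <- utils::head(ranked_elements, k)
  hit_pos <- which(top %in% true_elements)
  y <- length(hit_pos)
  if (y == 0) return((k + 1 - s) / s)
  i <- max(hit_pos)
  if (i < 5) y / s else (y + i - 3) / s
}

#' Evaluate scored samples
#'
#' Pools all samples for the AUC and computes the per-case ranking metrics
#' by ordering each case's candidate elements by score (ties broken by
#' element id for determinism). Cases are identified by `case_index`.
#'
#' @param samples A `tcm_samples` object covering at least two cases, with
#'   every candidate element scored per case.
#' @param scores Numeric score vector aligned with the samples.
#' @return A `metrics_report` for a single run.
#' @export
evaluate_scores <- function(samples, scores) {
  stopifnot(n_samples(samples) == length(scores))
  auc <- auc_score(samples$label, scores)
  by_case <- split(seq_len(n_samples(samples)), samples$case_index)
  if (length(by_case) < 2) stop("evaluation needs at least two cases")
  hits <- numeric(0); penalties <- numeric(0)
  skipped <- 0L
  for (rows in by_case) {
    el <- samples$element_id[rows]
    if (length(el) == 0) { skipped <- skipped + 1L; next }
    sc <- scores[rows]
    ord <- order(-sc, el)
    ranked <- el[ord]
    truth <- el[samples$label[rows] == 1]
    if (length(truth) == 0) { skipped <- skipped + 1L; next }
    hits <- c(hits, hits_at_k(truth, ranked))
    penalties <- c(penalties, rank_penalty(truth, ranked))
  }
  if (skipped > 0) {
    warning(skipped, " case(s) without candidates or labels skipped")
  }
  mean_rank <- mean(penalties)
  metrics_report(list(list(auc = auc, hits_at_10 = mean(hits),
                           mean_rank = mean_rank, mrr = 1 / mean_rank)))
}

#' Evaluate a trained network on test samples
#'
#' @param params Fitted `model_params`.
#' @param config The [model_config()] used in training.
#' @param test_samples Full-cross-product `tcm_samples` for the test cases.
#' @return A single-run `metrics_report`.
#' @export
evaluate <- function(params, config, test_samples) {
  evaluate_scores(test_samples, score_samples(params, test_samples, config))
}

#' Aggregate per-run metrics into a report
#'
#' MeanRank and MRR are averaged independently across runs (so the mean MRR
#' is not constrained to be the reciprocal of the mean MeanRank, although
#' within each run it is).
#'
#' @param run_list List of single-run metric lists or `metrics_report`s,
#'   each with `auc`, `hits_at_10`, `mean_rank`, `mrr`.
#' @param baseline_auc Optional baseline AUC for a RelaImpr column.
#' @return An object of class `metrics_report` with the mean metrics as
#'   top-level fields and the per-run values in `$runs`.
#' @export
metrics_report <- function(run_list, baseline_auc = NULL) {
  pick <- function(f) vapply(run_list, function(r) r[[f]], numeric(1))
  runs <- data.frame(run = seq_along(run_list), auc = pick("auc"),
                     hits_at_10 = pick("hits_at_10"),
                     mean_rank = pick("mean_rank"), mrr = pick("mrr"))
  rep <- list(auc = mean(runs$auc), hits_at_10 = mean(runs$hits_at_10),
              mean_rank = mean(runs$mean_rank), mrr = mean(runs$mrr),
              n_runs = nrow(runs), runs = runs)
  if (!is.null(baseline_auc)) rep$rela_impr <- rela_impr(rep$auc, baseline_auc)
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", x$n_runs, "run(s)\n")
  cat(sprintf("  AUC       %.4f\n  Hits@10   %.4f\n  MeanRank  %.4f\n  MRR       %.4f\n",
              x$auc, x$hits_at_10, x$mean_rank, x$mrr))
  if (!is.null(x$rela_impr)) cat(sprintf("  RelaImpr  %+.3f%%\n", x$rela_impr))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(mean = report[c("auc", "hits_at_10", "mean_rank", "mrr")],
              n_runs = report$n_runs, runs = report$runs)
  if (!is.null(report$rela_impr)) out$mean$rela_impr <- report$rela_impr
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
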