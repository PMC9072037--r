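# Shared fixtures: tiny handcrafted corpora, small generated corpora, and
# independent brute-force oracles for the statistics and the AUC.

# Five handcrafted cases with known counts; tokens chosen so every field has
# a couple of shared and a couple of unique tokens.
tiny_corpus <- function() {
  new_corpus(
    case_id = paste0("c", 1:5),
    engraving_symptoms = list(
      c("nausea", "vomiting"), c("nausea", "fever"), c("cough"),
      c("fever", "cough", "ache"), c("nausea")
    ),
    tongue = list("red", "red", "pale", "red", "pale"),
    moss = list("thin", c("thin", "yellow"), "yellow", "thin", "yellow"),
    pulse = list("rapid", "thready", "rapid", c("rapid", "thready"), "deep"),
    syndrome_elements = list(
      c("heat", "damp"), "heat", "cold", c("cold", "damp"), "damp"
    )
  )
}

small_gen <- function(n_cases = 80, n_elements = 8, seed = 3, ...) {
  generate_corpus(generator_config(
    n_cases = n_cases, n_elements = n_elements,
    vocab_sizes = c(engraving_symptoms = 40, tongue = 8, moss = 8, pulse = 10),
    seed = seed, ...
  ))
}

# A config small enough for hand checks and finite differences.
tiny_model <- function(...) {
  defaults <- list(embedding_dim = 3, n_experts = 2,
                   expert_layer_sizes = c(4, 3), tower_layer_sizes = 3,
                   match_tower_sizes = c(4, 3))
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# Naive double-loop co-occurrence counter: the independent oracle for
# compute_stats and every derived statistic.
brute_stats <- function(corpus, field, zz_token, zs_token) {
  n <- nrow(corpus)
  N <- 0; T_zz <- 0; T_zs <- 0; S_zz <- 0
  elements <- sort(unique(unlist(corpus$syndrome_elements)))
  for (i in seq_len(n)) {
    has_zz <- zz_token %in% corpus[[field]][[i]]
    has_zs <- zs_token %in% corpus$syndrome_elements[[i]]
    if (has_zz) T_zz <- T_zz + 1
    if (has_zs) T_zs <- T_zs + 1
    if (has_zz && has_zs) N <- N + 1
    if (has_zz) S_zz <- S_zz + sum(elements %in% corpus$syndrome_elements[[i]])
  }
  tokens <- unique(unlist(corpus[[field]]))
  Y_zz <- length(tokens)
  others <- setdiff(elements, zs_token)
  H_zs <- sum(vapply(others, function(e) {
    any(vapply(seq_len(n), function(i) {
      els <- corpus$syndrome_elements[[i]]
      zs_token %in% els && e %in% els
    }, logical(1)))
  }, logical(1)))
  list(N = N, T_zz = T_zz, T_zs = T_zs, T_total = n, S_zz = S_zz,
       Y_zz = Y_zz, H_zs = H_zs)
}

# All-pairs AUC oracle with 0.5 tie credit.
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Keep preactivations off relu's kink before finite-difference checks
# (two-sided differences straddle the non-differentiable point when
# zero-initialized biases leave preactivations exactly at 0).
jitter_params <- function(params, seed = 99) {
  restore <- tcmrank:::local_rng(seed)
  on.exit(restore())
  lapply(params, function(x) x + stats::runif(length(x), 0.01, 0.05))
}

loss_only <- function(params, batch, config) {
  out <- network_forward(params, batch, config)
  total_loss(batch$label, out$yk, out$ym, params[["mimic.a_u"]],
             params[["mimic.a_v"]], out$p_u, out$p_v, config)$total
}
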