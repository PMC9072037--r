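# Batch used throughout: the tiny corpus' full cross product (15 samples,
# both labels present).
model_batch <- function() {
  corpus <- tiny_corpus()
  vocab <- build_vocabulary(corpus)
  list(vocab = vocab, batch = build_samples(corpus, vocab))
}

# Worst relative finite-difference error over a few entries of every
# parameter array.
fd_max_err <- function(params, batch, config, n_entries = 2, eps = 1e-5) {
  gb <- network_grad(params, batch, config)
  worst <- 0
  restore <- tcmrank:::local_rng(5)
  on.exit(restore())
  for (nm in names(params)) {
    k <- length(params[[nm]])
    for (j in sample.int(k, min(n_entries, k))) {
      p1 <- params; p1[[nm]][j] <- p1[[nm]][j] + eps
      p2 <- params; p2[[nm]][j] <- p2[[nm]][j] - eps
      num <- (loss_only(p1, batch, config) -
                loss_only(p2, batch, config)) / (2 * eps)
      ana <- if (is.null(gb$grads[[nm]])) 0 else gb$grads[[nm]][j]
      worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1e-3))
    }
  }
  worst
}

test_that("model_config validates and resolves the match head by fusion mode", {
  expect_error(model_config(fusion = "sideways"), "arg")
  expect_error(model_config(lambda1 = -1))
  expect_identical(tcmrank:::match_head_for(model_config(fusion = "auxiliary_loss")),
                   "concat")
  expect_identical(tcmrank:::match_head_for(model_config(fusion = "match_as_feature")),
                   "concat")
  expect_identical(tcmrank:::match_head_for(model_config(fusion = "mimic")),
                   "cosine")
  expect_identical(tcmrank:::match_head_for(model_config(fusion = "full")),
                   "cosine")
  expect_identical(tcmrank:::match_head_for(
    model_config(fusion = "full", match_head = "concat")), "concat")
})

test_that("init_params produces the declared shapes with bounded truncated-normal draws", {
  mb <- model_batch()
  cfg <- tiny_model(fusion = "full", n_tasks = 2)
  restore <- tcmrank:::local_rng(1); on.exit(restore())
  p <- init_params(cfg, mb$vocab)
  d <- cfg$embedding_dim
  expect_identical(dim(p[["emb.tongue"]]), c(length(mb$vocab$tongue), d))
  expect_identical(dim(p[["emb.elements"]]), c(length(mb$vocab$elements), d))
  D <- 5L * d   # full fusion adds the match-score column
  expect_identical(dim(p[["expert1.W1"]]), c(D + 1L, 4L))
  expect_identical(dim(p[["expert2.W2"]]), c(4L, 3L))
  expect_identical(dim(p[["gate2.W"]]), c(D + 1L, cfg$n_experts))
  expect_identical(dim(p[["tower1.W1"]]), c(3L, 3L))
  expect_identical(dim(p[["tower2.Wout"]]), c(3L, 1L))
  # cosine towers: symptom side 4d + a_u, element side d + a_v, with the
  # augmentation vectors in the towers' output space
  a_dim <- utils::tail(cfg$match_tower_sizes, 1)
  expect_length(p[["mimic.a_u"]], a_dim)
  expect_length(p[["mimic.a_v"]], a_dim)
  expect_identical(nrow(p[["matchu.W1"]]), 4L * d + a_dim)
  expect_identical(nrow(p[["matchv.W1"]]), d + a_dim)
  # truncated at two standard deviations, biases zero
  ws <- unlist(p[grep("\\.W|emb\\.|a_[uv]|wcos", names(p))])
  expect_true(all(abs(ws) <= 2 * cfg$init_sd + 1e-12))
  expect_true(all(p[["expert1.b1"]] == 0))
  # concat head allocates a single match MLP instead
  pc <- init_params(tiny_model(fusion = "auxiliary_loss"), mb$vocab)
  expect_identical(nrow(pc[["match.W1"]]), 5L * cfg$embedding_dim)
  expect_null(pc[["mimic.a_u"]])
})

test_that("pool_field mean-pools real tokens and ignores padding", {
  table <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE)
  ids <- matrix(c(1L, 3L,
                  2L, 0L,
                  0L, 0L), nrow = 3, byrow = TRUE)
  P <- tcmrank:::pool_field(table, ids)
  expect_equal(P[1, ], c((1 + 5) / 2, (2 + 6) / 2))
  expect_equal(P[2, ], c(3, 4))
  expect_equal(P[3, ], c(0, 0))   # all-padding row pools to zero
})

test_that("embed_fields concatenates the four field means and the element row", {
  mb <- model_batch()
  cfg <- tiny_model()
  restore <- tcmrank:::local_rng(2); on.exit(restore())
  p <- init_params(cfg, mb$vocab)
  emb <- embed_fields(p, mb$batch)
  n <- n_samples(mb$batch)
  d <- cfg$embedding_dim
  expect_identical(dim(emb$E), c(n, 5L * d))
  expect_equal(emb$E, cbind(emb$Esym, emb$Zel))
  # spot-check sample 1 (case 1, engraving nausea+vomiting) by hand
  tab <- p[["emb.engraving_symptoms"]]
  ids <- mb$batch$field_ids$engraving_symptoms[1, ]
  ids <- ids[ids > 0]
  expect_equal(emb$Esym[1, 1:d], colMeans(tab[ids, , drop = FALSE]))
  expect_equal(emb$Zel[1, ], p[["emb.elements"]][mb$batch$element_id[1], ])
})

test_that("a single-expert MMOE reduces to an independently coded plain MLP", {
  mb <- model_batch()
  cfg <- tiny_model(n_experts = 1)
  restore <- tcmrank:::local_rng(3); on.exit(restore())
  p <- init_params(cfg, mb$vocab)
  out <- network_forward(p, mb$batch, cfg)
  # plain feed-forward reimplementation, no gates, no experts machinery
  relu <- function(x) pmax(x, 0)
  X <- embed_fields(p, mb$batch)$E
  h <- relu(sweep(X %*% p[["expert1.W1"]], 2, p[["expert1.b1"]], `+`))
  h <- relu(sweep(h %*% p[["expert1.W2"]], 2, p[["expert1.b2"]], `+`))
  t1 <- relu(sweep(h %*% p[["tower1.W1"]], 2, p[["tower1.b1"]], `+`))
  yref <- 1 / (1 + exp(-(drop(t1 %*% p[["tower1.Wout"]]) + p[["tower1.bout"]])))
  expect_equal(out$yk[, 1], yref, tolerance = 1e-12)
})

test_that("row_softmax and l2_normalize satisfy their defining properties", {
  Z <- matrix(rnorm(12, sd = 3), 3, 4)
  S <- tcmrank:::row_softmax(Z)
  expect_equal(rowSums(S), rep(1, 3))
  expect_true(all(S > 0))
  expect_equal(tcmrank:::row_softmax(Z + 100), S)   # shift invariance
  M <- matrix(rnorm(8), 2, 4)
  nm <- tcmrank:::l2_normalize(M)
  expect_equal(sqrt(rowSums(nm$P^2)), rep(1, 2))
  expect_warning(z <- tcmrank:::l2_normalize(rbind(M, 0)), "zero vector")
  expect_equal(z$P[3, ], rep(0, 4))
})

test_that("gradients match finite differences in every fusion mode without stop-gradients", {
  mb <- model_batch()
  configs <- list(
    none = tiny_model(fusion = "none", init_sd = 0.4),
    aux = tiny_model(fusion = "auxiliary_loss", lambda1 = 0.7, init_sd = 0.4),
    feature = tiny_model(fusion = "match_as_feature", lambda1 = 0.5,
                         detach_match_feature = FALSE, init_sd = 0.4),
    full = tiny_model(fusion = "full", lambda1 = 0.8, lambda_u = 0,
                      lambda_v = 0, detach_match_feature = FALSE,
                      init_sd = 0.4)
  )
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    restore <- tcmrank:::local_rng(7)
    p <- jitter_params(init_params(cfg, mb$vocab))
    restore()
    expect_lt(fd_max_err(p, mb$batch, cfg), 1e-4, label = nm)
  }
})

test_that("gradients match finite differences with statistical features attached", {
  mb <- model_batch()
  cfg <- tiny_model(fusion = "none", n_stat_features = 3L, init_sd = 0.4)
  restore <- tcmrank:::local_rng(8)
  p <- jitter_params(init_params(cfg, mb$vocab))
  feat <- matrix(rnorm(3 * n_samples(mb$batch)), ncol = 3)
  restore()
  batch <- attach_features(mb$batch, feat)
  expect_lt(fd_max_err(p, batch, cfg), 1e-4)
})

test_that("mimic gradients equal the closed form with the tower path blocked", {
  mb <- model_batch()
  cfg <- tiny_model(fusion = "mimic", lambda1 = 0, lambda_u = 0.3,
                    lambda_v = 0.7, init_sd = 0.3)
  restore <- tcmrank:::local_rng(9); on.exit(restore())
  p <- init_params(cfg, mb$vocab)
  # small init can leave individual tower outputs at zero; the zero-norm
  # warning is expected and irrelevant to the closed form
  gb <- suppressWarnings(network_grad(p, mb$batch, cfg))
  pos <- which(mb$batch$label == 1)
  gu <- 0.3 * 2 * (p[["mimic.a_u"]] - colMeans(gb$out$p_v[pos, , drop = FALSE]))
  gv <- 0.7 * 2 * (p[["mimic.a_v"]] - colMeans(gb$out$p_u[pos, , drop = FALSE]))
  expect_equal(unname(gb$grads[["mimic.a_u"]]), unname(gu), tolerance = 1e-12)
  expect_equal(unname(gb$grads[["mimic.a_v"]]), unname(gv), tolerance = 1e-12)
  # the loss actually contains the mimic terms
  expect_gt(gb$losses$u, 0)
  expect_gt(gb$losses$v, 0)
  expect_equal(gb$losses$total,
               gb$losses$main + 0.3 * gb$losses$u + 0.7 * gb$losses$v)
})

test_that("total_loss matches a hand-computed cross-entropy and collapses at zero lambdas", {
  cfg <- tiny_model(fusion = "none")
  labels <- c(1, 0, 1)
  yk <- matrix(c(0.9, 0.2, 0.6))
  ref <- -mean(c(log(0.9), log(0.8), log(0.6)))
  l <- total_loss(labels, yk, config = cfg)
  expect_equal(l$total, ref)
  expect_equal(l$main, ref)
  expect_identical(l$match, 0)
  expect_error(total_loss(numeric(0), yk[0, , drop = FALSE], config = cfg),
               "empty batch")
})

test_that("detached match-score fusion blocks the main loss from the match network", {
  mb <- model_batch()
  cfg <- tiny_model(fusion = "match_as_feature", lambda1 = 0,
                    detach_match_feature = TRUE, init_sd = 0.3)
  restore <- tcmrank:::local_rng(10); on.exit(restore())
  p <- init_params(cfg, mb$vocab)
  gb <- network_grad(p, mb$batch, cfg)
  # with lambda1 = 0 and detachment, the match MLP receives no gradient
  match_grads <- gb$grads[grep("^match\\.", names(gb$grads))]
  expect_true(all(vapply(match_grads, function(g) all(g == 0), logical(1))))
  # un-detached, the fused column feeds gradient back into the match MLP
  cfg2 <- cfg; cfg2$detach_match_feature <- FALSE
  gb2 <- network_grad(p, mb$batch, cfg2)
  expect_gt(max(abs(unlist(gb2$grads[grep("^match\\.", names(gb2$grads))]))), 0)
})

test_that("score_samples is invariant to the chunk size", {
  mb <- model_batch()
  cfg <- tiny_model(fusion = "full")
  restore <- tcmrank:::local_rng(11); on.exit(restore())
  p <- init_params(cfg, mb$vocab)
  suppressWarnings({   # zero-norm rows under the small random init
    s1 <- score_samples(p, mb$batch, cfg, chunk_size = 4L)
    s2 <- score_samples(p, mb$batch, cfg, chunk_size = 1000L)
  })
  expect_equal(s1, s2)
})

test_that("shape guards reject inconsistent inputs", {
  mb <- model_batch()
  cfg <- tiny_model(fusion = "none", n_stat_features = 2L)
  restore <- tcmrank:::local_rng(12); on.exit(restore())
  p <- init_params(cfg, mb$vocab)
  expect_error(network_forward(p, mb$batch, cfg),
               "none are attached")
  cfgm <- tiny_model(fusion = "mimic")
  pm <- init_params(cfgm, mb$vocab)
  pm[["mimic.a_u"]] <- numeric(2)   # wrong width
  emb <- embed_fields(pm, mb$batch)
  expect_error(mimic_augment(emb$Esym, emb$Zel, pm), "tower expects")
  pm[["mimic.a_u"]] <- NULL
  expect_error(mimic_augment(emb$Esym, emb$Zel, pm), "missing")
})
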