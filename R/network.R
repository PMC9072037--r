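# The ranking network: field-averaged embeddings feeding (a) a multi-gate
# mixture-of-experts main network and (b) a two-tower matching auxiliary
# network, coupled through an auxiliary loss, optional match-score feature
# fusion, and a mimic interaction mechanism (learned augmentation vectors
# trained to imitate the opposite tower's embedding on positive pairs).
#
# Forward and backward passes are written directly in matrix form; gradients
# are validated against finite differences in the test suite.

#' Network configuration
#'
#' @param embedding_dim Embedding width per field (default 64).
#' @param n_experts Number of expert networks (default 8).
#' @param expert_layer_sizes Hidden sizes of each expert's feed-forward
#'   network (default `c(256, 128)`).
#' @param n_tasks Number of prediction tasks / towers (default 1; all tasks
#'   share the binary relevance label here).
#' @param tower_layer_sizes Hidden sizes of each task tower (default 64).
#' @param match_tower_sizes Hidden sizes of the match network's layers
#'   (default `c(256, 128, 64)`).
#' @param match_head `"concat"` (one MLP on the concatenated symptom and
#'   element embeddings) or `"cosine"` (two towers with L2-normalized
#'   outputs compared by inner product). `NULL` (default) picks concat for
#'   fusion modes `auxiliary_loss` / `match_as_feature` and cosine for
#'   `mimic` / `full`.
#' @param fusion How the match network couples to the main network:
#'   `"none"` (main network only), `"auxiliary_loss"` (match loss added to
#'   the objective), `"match_as_feature"` (match score appended to the main
#'   input, plus the auxiliary loss), `"mimic"` (cosine head with
#'   augmentation-vector mimic losses), or `"full"` (all three mechanisms).
#' @param lambda1 Weight of the match auxiliary loss (default 1).
#' @param lambda_u,lambda_v Weights of the mimic losses (default 0.5 each).
#' @param detach_match_feature If `TRUE` (default) the match score entering
#'   feature fusion is treated as a constant by the main loss, so the match
#'   network is trained only by its own loss.
#' @param n_stat_features Width of the optional statistical feature vector
#'   appended to the main input (0 when none attached).
#' @param init_sd Standard deviation of the truncated-normal initializer
#'   (default 0.05; truncated at two standard deviations).
#' @return An object of class `model_config`.
#' @export
model_config <- function(embedding_dim = 64L,
                         n_experts = 8L,
                         expert_layer_sizes = c(256L, 128L),
                         n_tasks = 1L,
                         tower_layer_sizes = 64L,
                         match_tower_sizes = c(256L, 128L, 64L),
                         match_head = NULL,
                         fusion = c("none", "auxiliary_loss",
                                    "match_as_feature", "mimic", "full"),
                         lambda1 = 1.0, lambda_u = 0.5, lambda_v = 0.5,
                         detach_match_feature = TRUE,
                         n_stat_features = 0L,
                         init_sd = 0.05) {
  fusion <- match.arg(fusion)
  if (!is.null(match_head)) match_head <- match.arg(match_head, c("concat", "cosine"))
  stopifnot(embedding_dim >= 1, n_experts >= 1, n_tasks >= 1,
            all(expert_layer_sizes >= 1), all(match_tower_sizes >= 1),
            lambda1 >= 0, lambda_u >= 0, lambda_v >= 0, init_sd > 0,
            n_stat_features >= 0)
  structure(list(
    embedding_dim = as.integer(embedding_dim),
    n_experts = as.integer(n_experts),
    expert_layer_sizes = as.integer(expert_layer_sizes),
    n_tasks = as.integer(n_tasks),
    tower_layer_sizes = as.integer(tower_layer_sizes),
    match_tower_sizes = as.integer(match_tower_sizes),
    match_head = match_head, fusion = fusion,
    lambda1 = lambda1, lambda_u = lambda_u, lambda_v = lambda_v,
    detach_match_feature = isTRUE(detach_match_feature),
    n_stat_features = as.integer(n_stat_features),
    init_sd = init_sd
  ), class = "model_config")
}

# Effective match head for a fusion mode.
match_head_for <- function(config) {
  if (!is.null(config$match_head)) return(config$match_head)
  switch(config$fusion,
         none = "concat",
         auxiliary_loss = "concat", match_as_feature = "concat",
         mimic = "cosine", full = "cosine")
}

has_match_net <- function(config) config$fusion != "none"
has_feature_fusion <- function(config) config$fusion %in% c("match_as_feature", "full")
has_mimic <- function(config) config$fusion %in% c("mimic", "full")

# Width of the main-network input vector.
main_input_width <- function(config) {
  5L * config$embedding_dim +
    (if (has_feature_fusion(config)) 1L else 0L) +
    config$n_stat_features
}

# Truncated normal draws: resample outside +/- 2 sd.
trunc_normal <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

tn_mat <- function(nr, nc, sd) matrix(trunc_normal(nr * nc, sd), nr, nc)

#' Initialize network parameters
#'
#' All weights and embedding tables are drawn from a truncated normal
#' distribution; biases start at zero. Embedding tables are shared between
#' the main and match networks.
#'
#' @param config A [model_config()].
#' @param vocab A `tcm_vocabulary` giving the table sizes.
#' @return A flat named list of parameter arrays (class `model_params`).
#' @export
init_params <- function(config, vocab) {
  d <- config$embedding_dim
  sd <- config$init_sd
  p <- list()
  for (fld in symptom_fields()) {
    p[[paste0("emb.", fld)]] <- tn_mat(length(vocab[[fld]]), d, sd)
  }
  p[["emb.elements"]] <- tn_mat(length(vocab$elements), d, sd)

  D <- main_input_width(config)
  sizes <- c(D, config$expert_layer_sizes)
  for (i in seq_len(config$n_experts)) {
    for (l in seq_along(config$expert_layer_sizes)) {
      p[[sprintf("expert%d.W%d", i, l)]] <- tn_mat(sizes[l], sizes[l + 1], sd)
      p[[sprintf("expert%d.b%d", i, l)]] <- numeric(sizes[l + 1])
    }
  }
  h_out <- utils::tail(config$expert_layer_sizes, 1)
  for (k in seq_len(config$n_tasks)) {
    p[[sprintf("gate%d.W", k)]] <- tn_mat(D, config$n_experts, sd)
    tsizes <- c(h_out, config$tower_layer_sizes)
    for (l in seq_along(config$tower_layer_sizes)) {
      p[[sprintf("tower%d.W%d", k, l)]] <- tn_mat(tsizes[l], tsizes[l + 1], sd)
      p[[sprintf("tower%d.b%d", k, l)]] <- numeric(tsizes[l + 1])
    }
    p[[sprintf("tower%d.Wout", k)]] <- tn_mat(utils::tail(tsizes, 1), 1, sd)
    p[[sprintf("tower%d.bout", k)]] <- 0
  }

  if (has_match_net(config)) {
    msz <- config$match_tower_sizes
    if (match_head_for(config) == "concat") {
      csizes <- c(5L * d, msz)
      for (l in seq_along(msz)) {
        p[[sprintf("match.W%d", l)]] <- tn_mat(csizes[l], csizes[l + 1], sd)
        p[[sprintf("match.b%d", l)]] <- numeric(csizes[l + 1])
      }
      p[["match.Wout"]] <- tn_mat(utils::tail(csizes, 1), 1, sd)
      p[["match.bout"]] <- 0
    } else {
      # The augmentation vectors must live in the towers' output space so
      # the mimic loss (squared distance to the opposite tower's unit
      # embedding) is well defined.
      au_dim <- av_dim <- utils::tail(msz, 1)
      usizes <- c(4L * d + au_dim, msz)
      vsizes <- c(d + av_dim, msz)
      for (l in seq_along(msz)) {
        p[[sprintf("matchu.W%d", l)]] <- tn_mat(usizes[l], usizes[l + 1], sd)
        p[[sprintf("matchu.b%d", l)]] <- numeric(usizes[l + 1])
        p[[sprintf("matchv.W%d", l)]] <- tn_mat(vsizes[l], vsizes[l + 1], sd)
        p[[sprintf("matchv.b%d", l)]] <- numeric(vsizes[l + 1])
      }
      p[["match.wcos"]] <- trunc_normal(1, sd)
      p[["match.bcos"]] <- 0
      p[["mimic.a_u"]] <- trunc_normal(au_dim, sd)
      p[["mimic.a_v"]] <- trunc_normal(av_dim, sd)
    }
  }
  structure(p, class = "model_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically safe mean binary cross-entropy.
bce <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- embedding layer --------------------------------------------------------

# Mean-pool token embeddings of one field; padding id 0 is excluded.
pool_field <- function(table, ids) {
  n <- nrow(ids)
  d <- ncol(table)
  S <- matrix(0, n, d)
  for (l in seq_len(ncol(ids))) {
    sel <- ids[, l] > 0L
    if (any(sel)) S[sel, ] <- S[sel, ] + table[ids[sel, l], , drop = FALSE]
  }
  cnt <- rowSums(ids > 0L)
  S / pmax(cnt, 1L)
}

# Scatter pooled-gradient back into the embedding table (n x d -> V x d).
pool_field_backward <- function(dZ, table_dim, ids) {
  cnt <- pmax(rowSums(ids > 0L), 1L)
  g <- matrix(0, table_dim[1], table_dim[2])
  for (l in seq_len(ncol(ids))) {
    sel <- ids[, l] > 0L
    if (!any(sel)) next
    contrib <- dZ[sel, , drop = FALSE] / cnt[sel]
    agg <- rowsum(contrib, group = ids[sel, l])
    rows <- as.integer(rownames(agg))
    g[rows, ] <- g[rows, ] + agg
  }
  g
}

#' Embed a batch of samples
#'
#' Looks up and mean-pools token embeddings per field (padding/unknown id 0
#' excluded from the mean; a field of only padding ids yields a zero
#' vector), then concatenates the four symptom-field vectors and the
#' candidate-element vector.
#'
#' @param params A `model_params` list.
#' @param batch A `tcm_samples` object (or subset).
#' @return A list with `E` (n x 5d input matrix), `Esym` (n x 4d symptom
#'   block) and `Zel` (n x d element block).
#' @export
embed_fields <- function(params, batch) {
  blocks <- lapply(symptom_fields(), function(fld) {
    pool_field(params[[paste0("emb.", fld)]], batch$field_ids[[fld]])
  })
  Esym <- do.call(cbind, blocks)
  Zel <- params[["emb.elements"]][batch$element_id, , drop = FALSE]
  list(E = cbind(Esym, Zel), Esym = Esym, Zel = Zel)
}

# ---- generic relu MLP -------------------------------------------------------

mlp_forward <- function(X, params, prefix, n_layers) {
  A <- vector("list", n_layers + 1)
  Z <- vector("list", n_layers)
  A[[1]] <- X
  for (l in seq_len(n_layers)) {
    Z[[l]] <- sweep(A[[l]] %*% params[[sprintf("%s.W%d", prefix, l)]], 2,
                    params[[sprintf("%s.b%d", prefix, l)]], `+`)
    A[[l + 1]] <- pmax(Z[[l]], 0)
  }
  list(out = A[[n_layers + 1]], A = A, Z = Z)
}

mlp_backward <- function(dOut, cache, params, prefix, n_layers, grads) {
  dA <- dOut
  for (l in rev(seq_len(n_layers))) {
    dZ <- dA * (cache$Z[[l]] > 0)
    grads[[sprintf("%s.W%d", prefix, l)]] <- crossprod(cache$A[[l]], dZ)
    grads[[sprintf("%s.b%d", prefix, l)]] <- colSums(dZ)
    dA <- dZ %*% t(params[[sprintf("%s.W%d", prefix, l)]])
  }
  list(grads = grads, dX = dA)
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# L2-normalize rows; rows with (near-)zero norm are left unnormalized.
l2_normalize <- function(M, warn = TRUE) {
  r <- sqrt(rowSums(M^2))
  zero <- r < 1e-12
  if (any(zero) && warn) {
    warning(sum(zero), " zero vector(s) reached the L2 normalization layer; ",
            "left unnormalized")
  }
  r[zero] <- 1
  list(P = M / r, r = r, zero = zero)
}

l2_normalize_backward <- function(dP, P, r) {
  (dP - P * rowSums(dP * P)) / r
}

# ---- MMOE main network ------------------------------------------------------

#' Forward pass of the mixture-of-experts main network
#'
#' Each expert is a feed-forward relu network on the shared input; per task,
#' a softmax gate over the experts mixes their outputs, and a task tower
#' maps the mixture to a probability through a sigmoid.
#'
#' @param X Input matrix (n x input width).
#' @param params A `model_params` list.
#' @param config A [model_config()].
#' @return A list with `y` (n x n_tasks probability matrix), `gates` (list
#'   of per-task gate matrices) and a cache for the backward pass.
#' @export
mmoe_forward <- function(X, params, config) {
  nE <- config$n_experts
  nL <- length(config$expert_layer_sizes)
  experts <- lapply(seq_len(nE), function(i) {
    mlp_forward(X, params, sprintf("expert%d", i), nL)
  })
  nT <- config$n_tasks
  nTL <- length(config$tower_layer_sizes)
  y <- matrix(0, nrow(X), nT)
  gates <- vector("list", nT)
  towers <- vector("list", nT)
  fks <- vector("list", nT)
  for (k in seq_len(nT)) {
    G <- row_softmax(X %*% params[[sprintf("gate%d.W", k)]])
    fk <- matrix(0, nrow(X), utils::tail(config$expert_layer_sizes, 1))
    for (i in seq_len(nE)) fk <- fk + G[, i] * experts[[i]]$out
    tw <- mlp_forward(fk, params, sprintf("tower%d", k), nTL)
    logit <- drop(tw$out %*% params[[sprintf("tower%d.Wout", k)]]) +
      params[[sprintf("tower%d.bout", k)]]
    y[, k] <- sigmoid(logit)
    gates[[k]] <- G; towers[[k]] <- tw; fks[[k]] <- fk
  }
  if (!all(is.finite(y))) stop("non-finite activations in the main network")
  list(y = y, gates = gates,
       cache = list(X = X, experts = experts, towers = towers, fks = fks))
}

# Backward through MMOE given dlogit per task (n x n_tasks). Accumulates
# parameter grads into `grads`; returns dX as well.
mmoe_backward <- function(dlogit, out, params, config, grads) {
  cache <- out$cache
  X <- cache$X
  nE <- config$n_experts
  nL <- length(config$expert_layer_sizes)
  nTL <- length(config$tower_layer_sizes)
  dX <- matrix(0, nrow(X), ncol(X))
  dExpertOut <- vector("list", nE)
  for (i in seq_len(nE)) {
    dExpertOut[[i]] <- matrix(0, nrow(X), utils::tail(config$expert_layer_sizes, 1))
  }
  for (k in seq_len(config$n_tasks)) {
    tw <- cache$towers[[k]]
    dl <- dlogit[, k]
    grads[[sprintf("tower%d.Wout", k)]] <- crossprod(tw$out, dl)
    grads[[sprintf("tower%d.bout", k)]] <- sum(dl)
    dtow <- dl %*% t(params[[sprintf("tower%d.Wout", k)]])
    bk <- mlp_backward(dtow, tw, params, sprintf("tower%d", k), nTL, grads)
    grads <- bk$grads
    dfk <- bk$dX
    G <- out$gates[[k]]
    dG <- matrix(0, nrow(X), nE)
    for (i in seq_len(nE)) {
      dExpertOut[[i]] <- dExpertOut[[i]] + G[, i] * dfk
      dG[, i] <- rowSums(dfk * cache$experts[[i]]$out)
    }
    dZg <- G * (dG - rowSums(dG * G))
    grads[[sprintf("gate%d.W", k)]] <- crossprod(X, dZg)
    dX <- dX + dZg %*% t(params[[sprintf("gate%d.W", k)]])
  }
  for (i in seq_len(nE)) {
    bk <- mlp_backward(dExpertOut[[i]], cache$experts[[i]], params,
                       sprintf("expert%d", i), nL, grads)
    grads <- bk$grads
    dX <- dX + bk$dX
  }
  list(grads = grads, dX = dX)
}

# ---- match network ----------------------------------------------------------

#' Build the mimic-augmented tower inputs
#'
#' Concatenates the learned augmentation vectors onto the two sides'
#' embeddings: `c_u = [symptom-field embeddings, a_u]` and
#' `c_v = [element embedding, a_v]`. The augmentation vectors are global
#' (one per side), so every sample in a batch receives the same vectors.
#'
#' @param Esym n x 4d symptom-side embedding block.
#' @param Zel n x d element embedding block.
#' @param params A `model_params` list holding `mimic.a_u` and `mimic.a_v`.
#' @return A list with matrices `c_u` and `c_v`.
#' @export
mimic_augment <- function(Esym, Zel, params) {
  a_u <- params[["mimic.a_u"]]; a_v <- params[["mimic.a_v"]]
  if (is.null(a_u) || is.null(a_v)) stop("mimic augmentation vectors missing")
  W1u <- params[["matchu.W1"]]; W1v <- params[["matchv.W1"]]
  if (!is.null(W1u) && ncol(Esym) + length(a_u) != nrow(W1u)) {
    stop("augmented symptom input is ", ncol(Esym) + length(a_u),
         " wide but the tower expects ", nrow(W1u))
  }
  if (!is.null(W1v) && ncol(Zel) + length(a_v) != nrow(W1v)) {
    stop("augmented element input is ", ncol(Zel) + length(a_v),
         " wide but the tower expects ", nrow(W1v))
  }
  n <- nrow(Esym)
  list(c_u = cbind(Esym, matrix(a_u, n, length(a_u), byrow = TRUE)),
       c_v = cbind(Zel, matrix(a_v, n, length(a_v), byrow = TRUE)))
}

#' Forward pass of the two-tower match network
#'
#' In `concat` mode a single relu MLP scores the concatenated symptom and
#' element embeddings. In `cosine` mode each side passes its own tower
#' (mimic-augmented inputs) ending in L2 normalization; the match
#' probability is a sigmoid of a scaled inner product of the two unit
#' vectors.
#'
#' @param Esym,Zel Embedding blocks from [embed_fields()].
#' @param params A `model_params` list.
#' @param config A [model_config()].
#' @return A list with `ym` (match probabilities), `p_u`, `p_v` (unit
#'   vectors, cosine mode only) and a cache.
#' @export
match_forward <- function(Esym, Zel, params, config) {
  nL <- length(config$match_tower_sizes)
  if (match_head_for(config) == "concat") {
    X <- cbind(Esym, Zel)
    mc <- mlp_forward(X, params, "match", nL)
    logit <- drop(mc$out %*% params[["match.Wout"]]) + params[["match.bout"]]
    ym <- sigmoid(logit)
    list(ym = ym, p_u = NULL, p_v = NULL,
         cache = list(head = "concat", mlp = mc, X = X))
  } else {
    cc <- mimic_augment(Esym, Zel, params)
    mu <- mlp_forward(cc$c_u, params, "matchu", nL)
    mv <- mlp_forward(cc$c_v, params, "matchv", nL)
    nu <- l2_normalize(mu$out)
    nv <- l2_normalize(mv$out)
    dots <- rowSums(nu$P * nv$P)
    logit <- params[["match.wcos"]] * dots + params[["match.bcos"]]
    ym <- sigmoid(logit)
    list(ym = ym, p_u = nu$P, p_v = nv$P,
         cache = list(head = "cosine", mu = mu, mv = mv, nu = nu, nv = nv,
                      dots = dots))
  }
}

# Backward through the match network given dlogit_m (length n). Returns
# grads plus dEsym, dZel (embedding-side gradients).
match_backward <- function(dlogit, mout, params, config, grads) {
  nL <- length(config$match_tower_sizes)
  cache <- mout$cache
  if (cache$head == "concat") {
    grads[["match.Wout"]] <- crossprod(cache$mlp$out, dlogit)
    grads[["match.bout"]] <- sum(dlogit)
    dH <- dlogit %*% t(params[["match.Wout"]])
    bk <- mlp_backward(dH, cache$mlp, params, "match", nL, grads)
    d <- ncol(cache$X) / 5L
    list(grads = bk$grads,
         dEsym = bk$dX[, seq_len(4L * d), drop = FALSE],
         dZel = bk$dX[, 4L * d + seq_len(d), drop = FALSE])
  } else {
    w <- params[["match.wcos"]]
    grads[["match.wcos"]] <- sum(dlogit * cache$dots)
    grads[["match.bcos"]] <- sum(dlogit)
    ddots <- dlogit * w
    dPu <- ddots * cache$nv$P
    dPv <- ddots * cache$nu$P
    dMu <- l2_normalize_backward(dPu, cache$nu$P, cache$nu$r)
    dMv <- l2_normalize_backward(dPv, cache$nv$P, cache$nv$r)
    bku <- mlp_backward(dMu, cache$mu, params, "matchu", nL, grads)
    bkv <- mlp_backward(dMv, cache$mv, params, "matchv", nL, bku$grads)
    grads <- bkv$grads
    len_u <- length(params[["mimic.a_u"]])
    len_v <- length(params[["mimic.a_v"]])
    d_sym <- ncol(bku$dX) - len_u
    d_el <- ncol(bkv$dX) - len_v
    grads[["mimic.a_u"]] <- add_or_init(grads[["mimic.a_u"]],
                                        colSums(bku$dX[, d_sym + seq_len(len_u), drop = FALSE]))
    grads[["mimic.a_v"]] <- add_or_init(grads[["mimic.a_v"]],
                                        colSums(bkv$dX[, d_el + seq_len(len_v), drop = FALSE]))
    list(grads = grads,
         dEsym = bku$dX[, seq_len(d_sym), drop = FALSE],
         dZel = bkv$dX[, seq_len(d_el), drop = FALSE])
  }
}

add_or_init <- function(acc, x) if (is.null(acc)) x else acc + x

#' Fuse the match score into the main-network input
#'
#' Appends the match probability (and, when present, a statistical feature
#' vector) to the embedding vector.
#'
#' @param E n x 5d embedding matrix.
#' @param ym Match probability vector (or `NULL`).
#' @param extra Optional n x k statistical feature matrix.
#' @return The widened input matrix.
#' @export
fuse_match_feature <- function(E, ym = NULL, extra = NULL) {
  X <- E
  if (!is.null(ym)) X <- cbind(X, ym)
  if (!is.null(extra)) X <- cbind(X, extra)
  X
}

# ---- losses -----------------------------------------------------------------

#' Combined training objective
#'
#' `Loss = loss_main + lambda1 * loss_match + lambda_u * loss_u +
#' lambda_v * loss_v`, where the main and match losses are mean binary
#' cross-entropies against the same labels and the mimic losses are mean
#' squared distances, over positive samples only, between each side's
#' augmentation vector and the opposite tower's (gradient-blocked) unit
#' embedding. With all lambdas zero the objective is exactly the main
#' cross-entropy.
#'
#' @param labels 0/1 vector.
#' @param yk Main-task probability matrix (n x n_tasks).
#' @param ym Match probabilities, or `NULL` when no match network runs.
#' @param a_u,a_v Augmentation vectors, or `NULL`.
#' @param p_u,p_v Tower unit-embedding matrices, or `NULL`.
#' @param config A [model_config()].
#' @return A list with `total`, `main`, `match`, `u`, `v`.
#' @export
total_loss <- function(labels, yk, ym = NULL, a_u = NULL, a_v = NULL,
                       p_u = NULL, p_v = NULL, config) {
  if (length(labels) == 0) stop("empty batch")
  loss_main <- mean(vapply(seq_len(ncol(yk)), function(k) bce(labels, yk[, k]),
                           numeric(1)))
  loss_match <- if (!is.null(ym) && config$lambda1 > 0) bce(labels, ym) else 0
  loss_u <- 0; loss_v <- 0
  pos <- which(labels == 1)
  if (has_mimic(config) && !is.null(p_u) && length(pos) > 0) {
    if (config$lambda_u > 0) {
      loss_u <- mean(rowSums((matrix(a_u, length(pos), length(a_u), byrow = TRUE) -
                                p_v[pos, , drop = FALSE])^2))
    }
    if (config$lambda_v > 0) {
      loss_v <- mean(rowSums((matrix(a_v, length(pos), length(a_v), byrow = TRUE) -
                                p_u[pos, , drop = FALSE])^2))
    }
  }
  total <- loss_main + config$lambda1 * loss_match +
    config$lambda_u * loss_u + config$lambda_v * loss_v
  list(total = total, main = loss_main, match = loss_match,
       u = loss_u, v = loss_v)
}

# ---- full forward / backward ------------------------------------------------

#' Full network forward pass over a batch
#'
#' @param params A `model_params` list.
#' @param batch A `tcm_samples` object (or subset).
#' @param config A [model_config()].
#' @return A list with `yk`, `ym`, `p_u`, `p_v` and caches for the backward
#'   pass.
#' @export
network_forward <- function(params, batch, config) {
  emb <- embed_fields(params, batch)
  if (config$n_stat_features > 0 && is.null(batch$extra)) {
    stop("config declares ", config$n_stat_features,
         " statistical feature(s) but none are attached to the samples")
  }
  mout <- if (has_match_net(config)) {
    match_forward(emb$Esym, emb$Zel, params, config)
  } else NULL
  X <- fuse_match_feature(
    emb$E,
    ym = if (has_feature_fusion(config)) mout$ym else NULL,
    extra = if (config$n_stat_features > 0) batch$extra else NULL
  )
  main <- mmoe_forward(X, params, config)
  list(yk = main$y, ym = mout$ym, p_u = mout$p_u, p_v = mout$p_v,
       emb = emb, mout = mout, main = main)
}

#' Loss and gradients for one batch
#'
#' Runs the forward pass, evaluates [total_loss()] and backpropagates it
#' through every component: task towers, gates, experts, the match towers
#' (including the mimic augmentation vectors) and the shared embedding
#' tables. The match score entering feature fusion is gradient-detached
#' when `detach_match_feature` is set; the mimic losses propagate only into
#' the augmentation vectors, never through the opposing tower.
#'
#' @param params A `model_params` list.
#' @param batch A `tcm_samples` batch with labels.
#' @param config A [model_config()].
#' @return A list with `losses` (from [total_loss()]), `grads` (named like
#'   `params`) and the forward `out`.
#' @export
network_grad <- function(params, batch, config) {
  out <- network_forward(params, batch, config)
  y <- batch$label
  n <- length(y)
  losses <- total_loss(y, out$yk, out$ym, params[["mimic.a_u"]],
                       params[["mimic.a_v"]], out$p_u, out$p_v, config)
  grads <- list()

  # Main cross-entropy -> task logits.
  dlogit_main <- (out$yk - y) / (n * config$n_tasks)
  mb <- mmoe_backward(dlogit_main, out$main, params, config, grads)
  grads <- mb$grads
  dX <- mb$dX

  d <- config$embedding_dim
  dE <- dX[, seq_len(5L * d), drop = FALSE]
  dEsym <- dE[, seq_len(4L * d), drop = FALSE]
  dZel <- dE[, 4L * d + seq_len(d), drop = FALSE]

  if (has_match_net(config)) {
    dlogit_m <- if (config$lambda1 > 0) {
      config$lambda1 * (out$ym - y) / n
    } else rep(0, n)
    if (has_feature_fusion(config) && !config$detach_match_feature) {
      # Gradient of the main loss through the fused match-score column.
      dym <- dX[, 5L * d + 1L]
      dlogit_m <- dlogit_m + dym * out$ym * (1 - out$ym)
    }
    mbk <- match_backward(dlogit_m, out$mout, params, config, grads)
    grads <- mbk$grads
    dEsym <- dEsym + mbk$dEsym
    dZel <- dZel + mbk$dZel
    # Mimic losses: gradient flows only into the augmentation vectors.
    pos <- which(y == 1)
    if (has_mimic(config) && length(pos) > 0) {
      if (config$lambda_u > 0) {
        a_u <- params[["mimic.a_u"]]
        g <- 2 * (a_u - colMeans(out$p_v[pos, , drop = FALSE]))
        grads[["mimic.a_u"]] <- add_or_init(grads[["mimic.a_u"]],
                                            config$lambda_u * g)
      }
      if (config$lambda_v > 0) {
        a_v <- params[["mimic.a_v"]]
        g <- 2 * (a_v - colMeans(out$p_u[pos, , drop = FALSE]))
        grads[["mimic.a_v"]] <- add_or_init(grads[["mimic.a_v"]],
                                            config$lambda_v * g)
      }
    }
  }

  # Embedding tables: scatter the pooled gradients.
  for (fi in seq_along(symptom_fields())) {
    fld <- symptom_fields()[fi]
    block <- dEsym[, (fi - 1L) * d + seq_len(d), drop = FALSE]
    grads[[paste0("emb.", fld)]] <-
      pool_field_backward(block, dim(params[[paste0("emb.", fld)]]),
                          batch$field_ids[[fld]])
  }
  gel <- rowsum(dZel, group = batch$element_id)
  Gel <- matrix(0, nrow(params[["emb.elements"]]), d)
  Gel[as.integer(rownames(gel)), ] <- gel
  grads[["emb.elements"]] <- Gel

  list(losses = losses, grads = grads, out = out)
}

#' Score samples with a trained network
#'
#' Runs the forward pass in chunks and returns the main-task probability
#' (first task) for every sample.
#'
#' @param params A `model_params` list.
#' @param samples A `tcm_samples` object.
#' @param config A [model_config()].
#' @param chunk_size Samples per forward chunk (memory control).
#' @return Numeric probability vector.
#' @export
score_samples <- function(params, samples, config, chunk_size = 20000L) {
  n <- n_samples(samples)
  scores <- numeric(n)
  start <- 1L
  while (start <= n) {
    idx <- start:min(n, start + chunk_size - 1L)
    out <- network_forward(params, samples_subset(samples, idx), config)
    scores[idx] <- out$yk[, 1]
    start <- start + chunk_size
  }
  scores
}
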