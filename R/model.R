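# Bidirectional transformer encoder over protein-token sentences, written in
# base R matrix ops: learnable token + position embeddings, post-norm
# multi-head attention blocks with position-wise FFNs, a masked-token output
# projection and a [CLS] two-class head. Forward and backward passes are both
# explicit so the whole model trains with the in-package Adam optimizer.

#' Model configuration
#'
#' @param vocab_size Total token count V (specials + cluster tokens).
#' @param d_model Embedding width (full-scale default 512).
#' @param n_layers Number of transformer blocks (full-scale default 8).
#' @param n_heads Attention heads (full-scale default 8); must divide
#'   `d_model`.
#' @param max_len Sentence length (default 300).
#' @param ffn_dim Feed-forward inner width (default `4 * d_model`, the
#'   original-transformer convention).
#' @param dropout Dropout probability applied to each sublayer output during
#'   training (default 0.1); inference never drops.
#' @return A `model_config` list.
#' @export
model_config <- function(vocab_size, d_model = 512L, n_layers = 8L,
                         n_heads = 8L, max_len = 300L,
                         ffn_dim = 4L * d_model, dropout = 0.1) {
  stopifnot(vocab_size >= N_SPECIAL, d_model >= 1L, n_layers >= 1L,
            n_heads >= 1L, max_len >= 2L, ffn_dim >= 1L,
            dropout >= 0, dropout < 1)
  if (d_model %% n_heads != 0L)
    stop("d_model (", d_model, ") must be divisible by n_heads (", n_heads, ")")
  structure(list(vocab_size = as.integer(vocab_size),
                 d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 max_len = as.integer(max_len),
                 ffn_dim = as.integer(ffn_dim),
                 dropout = dropout),
            class = "model_config")
}

#' Desk-scale configuration preset
#'
#' A small encoder (d_model 64, 2 layers, 4 heads) that trains in minutes on
#' one CPU; the architecture is identical to the full-scale preset
#' ([model_config()] defaults), only the dimensions differ.
#'
#' @inheritParams model_config
#' @param ... Overrides passed through to [model_config()].
#' @export
desk_config <- function(vocab_size, d_model = 64L, n_layers = 2L,
                        n_heads = 4L, max_len = 300L, dropout = 0.1, ...) {
  model_config(vocab_size, d_model = d_model, n_layers = n_layers,
               n_heads = n_heads, max_len = max_len, dropout = dropout, ...)
}

rmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Initialize model parameters
#'
#' Weights are drawn N(0, 0.02); layer-norm gains start at 1, all biases at 0.
#'
#' @param config A `model_config`.
#' @param seed Optional integer seed for reproducible initialization.
#' @return A `model_params` list holding the config and all learnable tensors.
#' @export
init_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$d_model; V <- config$vocab_size; f <- config$ffn_dim
  layers <- lapply(seq_len(config$n_layers), function(i) list(
    Wq = rmat(d, d), bq = numeric(d),
    Wk = rmat(d, d), bk = numeric(d),
    Wv = rmat(d, d), bv = numeric(d),
    Wo = rmat(d, d), bo = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    W1 = rmat(d, f), b1 = numeric(f),
    W2 = rmat(f, d), b2 = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d)))
  structure(list(
    config = config,
    tok_emb = rmat(V, d),
    pos_emb = rmat(config$max_len, d),
    layers = layers,
    mlm_W = rmat(d, V),
    cls_W = rmat(d, 2L),
    cls_b = numeric(2L)), class = "model_params")
}

# ---- parameter-tree utilities (Adam and gradient accumulation) -------------

TREE_LEAVES <- c("tok_emb", "pos_emb", "mlm_W", "cls_W", "cls_b")

param_tree <- function(params) params[c(TREE_LEAVES, "layers")]

tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(a, function(x) tree_map(f, x))
           else Map(function(x, y) tree_map(f, x, y), a, b)
    return(out)
  }
  if (is.null(b)) f(a) else f(a, b)
}

tree_zeros <- function(params) tree_map(function(x) x * 0, param_tree(params))

tree_add <- function(a, b) tree_map(`+`, a, b)

tree_scale <- function(a, s) tree_map(function(x) x * s, a)

set_tree <- function(params, tree) {
  for (nm in TREE_LEAVES) params[[nm]] <- tree[[nm]]
  params$layers <- tree$layers
  params
}

# ---- numerics ---------------------------------------------------------------

row_softmax <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / s
  list(y = sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+"), xhat = xhat, s = s)
}

layernorm_bwd <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2L, g, "*")
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dx <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) /
    cache$s
  list(dx = dx, dg = dg, db = db)
}

drop_mask <- function(dim1, dim2, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(dim1 * dim2, 1L, 1 - p) / (1 - p), dim1, dim2)
}

#' Embed a sentence (token + position lookup)
#'
#' `X[i, ] = W_Et[token_ids[i], ] + W_Ep[i, ]`: both tables are look-ups, and
#' the two embeddings are combined by matrix addition.
#'
#' @param sentence A `token_sentence` or a plain 0-based integer id vector.
#' @param params A `model_params`.
#' @return The embedding matrix X (`length x d_model`).
#' @export
embed_sentence <- function(sentence, params) {
  ids0 <- if (inherits(sentence, "token_sentence")) sentence$token_ids
          else as.integer(sentence)
  V <- params$config$vocab_size
  bad <- which(ids0 < 0L | ids0 >= V)
  if (length(bad))
    stop("token id out of vocabulary (>= ", V, ") at position(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  n <- length(ids0)
  if (n > params$config$max_len)
    stop("sentence longer than max_len")
  params$tok_emb[ids0 + 1L, , drop = FALSE] +
    params$pos_emb[seq_len(n), , drop = FALSE]
}

# Forward through the transformer stack over the non-PAD prefix of a sentence.
# Working on the attention_length prefix is exactly equivalent to computing
# over the padded matrix with [PAD] attention-masked out: padded keys receive
# zero attention weight and padded rows feed nothing downstream.
encoder_forward <- function(params, ids0, train = FALSE, keep_cache = FALSE) {
  cfg <- params$config
  X <- embed_sentence(ids0, params)
  n <- nrow(X); d <- cfg$d_model; nh <- cfg$n_heads; dk <- d %/% nh
  scl <- 1 / sqrt(dk)
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    ly <- params$layers[[l]]
    Q <- sweep(X %*% ly$Wq, 2L, ly$bq, "+")
    K <- sweep(X %*% ly$Wk, 2L, ly$bk, "+")
    Vv <- sweep(X %*% ly$Wv, 2L, ly$bv, "+")
    H <- matrix(0, n, d)
    A_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) * scl
      A <- row_softmax(S)
      A_heads[[h]] <- A
      H[, cols] <- A %*% Vv[, cols, drop = FALSE]
    }
    O <- sweep(H %*% ly$Wo, 2L, ly$bo, "+")
    m1 <- if (train) drop_mask(n, d, cfg$dropout) else NULL
    if (!is.null(m1)) O <- O * m1
    R1 <- X + O
    ln1 <- layernorm_fwd(R1, ly$ln1_g, ly$ln1_b)
    X1 <- ln1$y
    pre <- sweep(X1 %*% ly$W1, 2L, ly$b1, "+")
    Fh <- pre * (pre > 0)
    F2 <- sweep(Fh %*% ly$W2, 2L, ly$b2, "+")
    m2 <- if (train) drop_mask(n, d, cfg$dropout) else NULL
    if (!is.null(m2)) F2 <- F2 * m2
    R2 <- X1 + F2
    ln2 <- layernorm_fwd(R2, ly$ln2_g, ly$ln2_b)
    if (anyNA(ln2$y) || any(!is.finite(ln2$y)))
      stop("non-finite values in encoder layer ", l,
           " (training instability)")
    caches[[l]] <- list(X = X, Q = Q, K = K, V = Vv, A = A_heads, H = H,
                        m1 = m1, ln1 = ln1, X1 = X1, pre = pre, Fh = Fh,
                        m2 = m2, ln2 = ln2)
    X <- ln2$y
  }
  list(Y = X, caches = if (keep_cache) caches else NULL, ids0 = ids0)
}

# Backward through the stack; dY has the shape of Y. Returns the gradient tree.
encoder_backward <- function(params, fwd, dY) {
  cfg <- params$config
  nh <- cfg$n_heads; d <- cfg$d_model; dk <- d %/% nh
  scl <- 1 / sqrt(dk)
  grads <- tree_zeros(params)
  dX <- dY
  for (l in rev(seq_len(cfg$n_layers))) {
    ly <- params$layers[[l]]
    ca <- fwd$caches[[l]]
    g <- grads$layers[[l]]
    bw2 <- layernorm_bwd(dX, ca$ln2, ly$ln2_g)
    g$ln2_g <- g$ln2_g + bw2$dg; g$ln2_b <- g$ln2_b + bw2$db
    dR2 <- bw2$dx
    dF2 <- if (is.null(ca$m2)) dR2 else dR2 * ca$m2
    g$W2 <- g$W2 + t(ca$Fh) %*% dF2
    g$b2 <- g$b2 + colSums(dF2)
    dFh <- dF2 %*% t(ly$W2)
    dpre <- dFh * (ca$pre > 0)
    g$W1 <- g$W1 + t(ca$X1) %*% dpre
    g$b1 <- g$b1 + colSums(dpre)
    dX1 <- dR2 + dpre %*% t(ly$W1)
    bw1 <- layernorm_bwd(dX1, ca$ln1, ly$ln1_g)
    g$ln1_g <- g$ln1_g + bw1$dg; g$ln1_b <- g$ln1_b + bw1$db
    dR1 <- bw1$dx
    dO <- if (is.null(ca$m1)) dR1 else dR1 * ca$m1
    g$Wo <- g$Wo + t(ca$H) %*% dO
    g$bo <- g$bo + colSums(dO)
    dH <- dO %*% t(ly$Wo)
    n <- nrow(dH)
    dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- ca$A[[h]]
      dHj <- dH[, cols, drop = FALSE]
      dA <- dHj %*% t(ca$V[, cols, drop = FALSE])
      dV[, cols] <- t(A) %*% dHj
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dS %*% ca$K[, cols, drop = FALSE]) * scl
      dK[, cols] <- (t(dS) %*% ca$Q[, cols, drop = FALSE]) * scl
    }
    g$Wq <- g$Wq + t(ca$X) %*% dQ; g$bq <- g$bq + colSums(dQ)
    g$Wk <- g$Wk + t(ca$X) %*% dK; g$bk <- g$bk + colSums(dK)
    g$Wv <- g$Wv + t(ca$X) %*% dV; g$bv <- g$bv + colSums(dV)
    grads$layers[[l]] <- g
    dX <- dR1 + dQ %*% t(ly$Wq) + dK %*% t(ly$Wk) + dV %*% t(ly$Wv)
  }
  # embeddings: dX is the gradient of the embedding matrix X
  ids1 <- fwd$ids0 + 1L
  agg <- rowsum(dX, group = ids1)
  rows <- as.integer(rownames(agg))
  grads$tok_emb[rows, ] <- grads$tok_emb[rows, , drop = FALSE] + agg
  npos <- nrow(dX)
  grads$pos_emb[seq_len(npos), ] <-
    grads$pos_emb[seq_len(npos), , drop = FALSE] + dX
  grads
}

#' Encode a sentence to its latent matrix Y
#'
#' Runs the embedding and the full transformer stack in evaluation mode
#' (dropout off, `[PAD]` excluded from attention). Y has the same shape as the
#' embedding X.
#'
#' @param sentence A `token_sentence`, or a 0-based id vector treated as the
#'   non-PAD prefix.
#' @param params A `model_params`.
#' @return Latent matrix Y: `max_len x d_model` for a `token_sentence` (rows
#'   past the attention length are zero, as padding carries no information),
#'   otherwise `length(ids) x d_model`.
#' @export
encode_latent <- function(sentence, params) {
  if (inherits(sentence, "token_sentence")) {
    n <- sentence$attention_length
    ids0 <- sentence$token_ids[seq_len(n)]
    Y <- encoder_forward(params, ids0)$Y
    out <- matrix(0, length(sentence$token_ids), params$config$d_model)
    out[seq_len(n), ] <- Y
    out
  } else {
    encoder_forward(params, as.integer(sentence))$Y
  }
}

#' Masked-token probabilities
#'
#' Feeds selected rows of the latent matrix through the output projection and
#' a softmax over the vocabulary.
#'
#' @param Y Latent matrix from [encode_latent()].
#' @param positions 1-based row indices (content positions).
#' @param params A `model_params`.
#' @return `length(positions) x V` matrix of probabilities; each row sums
#'   to 1.
#' @export
mlm_logits <- function(Y, positions, params) {
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > nrow(Y)))
    stop("position out of range")
  L <- Y[positions, , drop = FALSE] %*% params$mlm_W
  t(apply(L, 1L, softmax_vec))
}

#' Lifestyle class probabilities from the [CLS] latent row
#'
#' `softmax(Y_0 W_p + b_p)`; index 1 is temperate, index 2 virulent (the
#' repo-wide class convention: temperate is the positive class).
#'
#' @param Y Latent matrix (row 1 is the `[CLS]` position).
#' @param params A `model_params`.
#' @return Named numeric vector `c(temperate=, virulent=)` summing to 1.
#' @export
cls_logits <- function(Y, params) {
  z <- drop(Y[1L, , drop = FALSE] %*% params$cls_W) + params$cls_b
  p <- softmax_vec(z)
  stats::setNames(p, c("temperate", "virulent"))
}

# ---- per-example losses with gradients -------------------------------------

# ids0: masked sentence prefix (0-based); target_pos: 1-based positions in the
# prefix; target_ids0: original 0-based token ids at those positions.
mlm_example_grad <- function(params, ids0, target_pos, target_ids0,
                             train = TRUE) {
  fwd <- encoder_forward(params, ids0, train = train, keep_cache = TRUE)
  Y <- fwd$Y
  m <- length(target_pos)
  L <- Y[target_pos, , drop = FALSE] %*% params$mlm_W
  P <- t(apply(L, 1L, softmax_vec))
  picked <- P[cbind(seq_len(m), target_ids0 + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dL <- P
  dL[cbind(seq_len(m), target_ids0 + 1L)] <-
    dL[cbind(seq_len(m), target_ids0 + 1L)] - 1
  dL <- dL / m
  dY <- matrix(0, nrow(Y), ncol(Y))
  dY[target_pos, ] <- dL %*% t(params$mlm_W)
  grads <- encoder_backward(params, fwd, dY)
  grads$mlm_W <- grads$mlm_W + t(Y[target_pos, , drop = FALSE]) %*% dL
  list(loss = loss, grads = grads,
       correct = sum(max.col(P) == target_ids0 + 1L), n = m)
}

# label01: 0 = temperate, 1 = virulent
cls_example_grad <- function(params, ids0, label01, train = TRUE) {
  fwd <- encoder_forward(params, ids0, train = train, keep_cache = TRUE)
  Y <- fwd$Y
  z <- drop(Y[1L, , drop = FALSE] %*% params$cls_W) + params$cls_b
  p <- softmax_vec(z)
  loss <- -log(max(p[label01 + 1L], 1e-12))
  dz <- p
  dz[label01 + 1L] <- dz[label01 + 1L] - 1
  dY <- matrix(0, nrow(Y), ncol(Y))
  dY[1L, ] <- params$cls_W %*% dz
  grads <- encoder_backward(params, fwd, dY)
  grads$cls_W <- grads$cls_W + Y[1L, ] %o% dz
  grads$cls_b <- grads$cls_b + dz
  list(loss = loss, grads = grads, p_temperate = p[[1L]])
}

# evaluation-mode losses (no gradient, no dropout)
mlm_example_loss <- function(params, ids0, target_pos, target_ids0) {
  Y <- encoder_forward(params, ids0)$Y
  P <- mlm_logits(Y, target_pos, params)
  picked <- P[cbind(seq_along(target_pos), target_ids0 + 1L)]
  list(loss = -mean(log(pmax(picked, 1e-12))),
       correct = sum(max.col(P) == target_ids0 + 1L),
       n = length(target_pos))
}

#' Temperate probability for encoded sentences
#'
#' @param params A `model_params`.
#' @param sentences List of `token_sentence` (or 0-based id vectors).
#' @return Numeric vector of temperate probabilities.
#' @export
predict_sentences <- function(params, sentences) {
  vapply(sentences, function(s) {
    ids0 <- if (inherits(s, "token_sentence"))
      s$token_ids[seq_len(s$attention_length)] else as.integer(s)
    Y <- encoder_forward(params, ids0)$Y
    cls_logits(Y, params)[["temperate"]]
  }, numeric(1L))
}

#' Save model parameters
#'
#' One-file checkpoint holding the config block and all named tensors;
#' loading reproduces the forward pass bitwise.
#'
#' @param params A `model_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  saveRDS(list(format = "lysotype-checkpoint-v1",
               config = unclass(params$config),
               tensors = param_tree(params)),
          path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return A `model_params`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "lysotype-checkpoint-v1"))
    stop("not a lysotype checkpoint: ", path)
  cfg <- do.call(model_config, ck$config)
  params <- structure(c(list(config = cfg), ck$tensors),
                      class = "model_params")
  params
}
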