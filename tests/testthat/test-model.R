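# Micro configs keep every check fast; the architecture is identical to the
# full-scale preset.
micro_cfg <- function(V = 7L, d = 4L, layers = 1L, heads = 2L, max_len = 12L,
                      dropout = 0)
  model_config(V, d_model = d, n_layers = layers, n_heads = heads,
               max_len = max_len, ffn_dim = 2L * d, dropout = dropout)

test_that("embedding is a lookup: token table plus position table", {
  cfg <- micro_cfg()
  params <- init_model(cfg, seed = 1)

  # zero tables -> zero embedding
  p0 <- params
  p0$tok_emb[] <- 0; p0$pos_emb[] <- 0
  expect_true(all(embed_sentence(c(2L, 5L, 3L), p0) == 0))

  # zero position table: equal tokens give equal rows
  p1 <- params; p1$pos_emb[] <- 0
  X <- embed_sentence(c(5L, 6L, 5L), p1)
  expect_equal(X[1, ], X[3, ])

  # hand-set tables reproduce row-by-row sums
  p2 <- params
  p2$tok_emb <- matrix(seq_len(7 * 4), 7, 4)
  p2$pos_emb <- matrix(100 * seq_len(12 * 4), 12, 4)
  ids <- c(2L, 6L, 3L)
  X <- embed_sentence(ids, p2)
  for (i in seq_along(ids))
    expect_equal(X[i, ], p2$tok_emb[ids[i] + 1, ] + p2$pos_emb[i, ])

  # out-of-vocabulary ids are named by position
  expect_error(embed_sentence(c(2L, 99L, 3L), params), "position")
})

test_that("encoder output matches input shape and is permutation-equivariant without positions", {
  cfg <- micro_cfg(V = 12L, d = 8L, heads = 2L, max_len = 10L)
  params <- init_model(cfg, seed = 2)
  ids <- c(2L, 5L, 6L, 7L, 8L, 9L, 3L)
  Y <- lysotype:::encoder_forward(params, ids)$Y
  expect_equal(dim(Y), c(length(ids), cfg$d_model))

  # with position embeddings zeroed, permuting tokens permutes rows of Y
  p0 <- params; p0$pos_emb[] <- 0
  perm <- c(1L, 4L, 2L, 5L, 3L, 6L, 7L)
  Y1 <- lysotype:::encoder_forward(p0, ids)$Y
  Y2 <- lysotype:::encoder_forward(p0, ids[perm])$Y
  expect_equal(Y2, Y1[perm, ], tolerance = 1e-12)

  # encode_latent on a full sentence: [PAD] positions carry nothing, so
  # changing a padded token cannot touch content rows
  s <- encode_sentence(c(5L, 6L, 7L), max_len = 10L)
  Ya <- encode_latent(s, params)
  s2 <- s; s2$token_ids[9L] <- 11L   # padded slot
  expect_equal(encode_latent(s2, params)[1:5, ], Ya[1:5, ])
})

test_that("masked-token and classification heads are exact softmaxes", {
  cfg <- micro_cfg(V = 5L, d = 2L, heads = 1L)  # specials-only vocabulary
  params <- init_model(cfg, seed = 3)
  Y <- matrix(c(0.3, -1.2, 0.7, 0.1, -0.5, 2.0), 3, 2, byrow = TRUE)

  # rows sum to one for any weights
  P <- mlm_logits(Y, 1:3, params)
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-6)

  # zero projection -> uniform over V
  pz <- params; pz$mlm_W[] <- 0
  expect_true(all(abs(mlm_logits(Y, 1:2, pz) - 0.2) < 1e-12))

  # hand-computed softmax on a set 2x5 case
  ph <- params
  ph$mlm_W <- matrix(c(1, 0, -1, 0.5, 0, 0, 2, 1, -0.5, 0.25), 2, 5,
                     byrow = TRUE)
  z <- Y[1, ] %*% ph$mlm_W
  expect_equal(drop(mlm_logits(Y, 1L, ph)), drop(exp(z) / sum(exp(z))))

  # classification head closed forms
  pc <- params; pc$cls_W[] <- 0; pc$cls_b[] <- 0
  expect_equal(unname(cls_logits(Y, pc)), c(0.5, 0.5))
  pc$cls_b <- c(log(3), 0)
  expect_equal(unname(cls_logits(Y, pc)), c(0.75, 0.25))
  ph2 <- params
  ph2$cls_W <- matrix(c(0.2, -0.4, 1.0, 0.3), 2, 2)
  ph2$cls_b <- c(0.1, -0.2)
  z <- drop(Y[1, ] %*% ph2$cls_W) + ph2$cls_b
  expect_equal(unname(cls_logits(Y, ph2)), exp(z - max(z)) / sum(exp(z - max(z))))
  expect_equal(sum(cls_logits(Y, ph2)), 1, tolerance = 1e-6)
})

test_that("analytic gradients of both losses match finite differences", {
  cfg <- micro_cfg(V = 7L, d = 4L, layers = 1L, heads = 2L)
  params <- init_model(cfg, seed = 5)
  ids <- c(2L, 5L, 6L, 5L, 3L)

  an <- lysotype:::mlm_example_grad(params, ids, c(2L, 4L), c(5L, 6L),
                                    train = FALSE)
  num <- numeric_grad(params, function(p)
    lysotype:::mlm_example_grad(p, ids, c(2L, 4L), c(5L, 6L),
                                train = FALSE)$loss)
  expect_lt(max(abs(flat_grads(an$grads) - num)) / max(abs(num)), 1e-4)

  an2 <- lysotype:::cls_example_grad(params, ids, 1L, train = FALSE)
  num2 <- numeric_grad(params, function(p)
    lysotype:::cls_example_grad(p, ids, 1L, train = FALSE)$loss)
  expect_lt(max(abs(flat_grads(an2$grads) - num2)) / max(abs(num2)), 1e-4)
})

test_that("forward pass is deterministic in evaluation mode and checkpoints round-trip bitwise", {
  cfg <- micro_cfg(V = 20L, d = 8L, layers = 2L, heads = 2L, dropout = 0.3)
  params <- init_model(cfg, seed = 7)
  s <- encode_sentence(c(5L, 9L, 12L), max_len = 12L)
  p1 <- predict_sentences(params, list(s))
  p2 <- predict_sentences(params, list(s))
  expect_identical(p1, p2)   # dropout is off at inference

  path <- file.path(withr::local_tempdir(), "model.ckpt")
  save_checkpoint(params, path)
  loaded <- load_checkpoint(path)
  expect_identical(lysotype:::param_tree(loaded),
                   lysotype:::param_tree(params))
  expect_identical(predict_sentences(loaded, list(s)), p1)
  not_ckpt <- file.path(withr::local_tempdir(), "x.rds")
  saveRDS(list(a = 1), not_ckpt)
  expect_error(load_checkpoint(not_ckpt), "checkpoint")
})
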