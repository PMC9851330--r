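# Adam optimizer and the shared mini-batch training loop. Parameters live in a
# nested list ("tree"); optimizer state is kept as flat vectors aligned with
# unlist() order, which is stable for a fixed config.

adam_init <- function(params) {
  flat <- unlist(param_tree(params), use.names = FALSE)
  list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  skeleton <- param_tree(params)
  p <- unlist(skeleton, use.names = FALSE)
  g <- unlist(grads, use.names = FALSE)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  params <- set_tree(params, utils::relist(p, skeleton))
  list(params = params, state = state)
}

# Generic epoch loop: `examples` is a list; grad_fn(params, example) returns
# list(loss, grads). Gradients are averaged within each mini-batch.
train_epochs <- function(params, examples, grad_fn, epochs, batch_size = 8L,
                         lr = 1e-3, state = NULL, verbose = FALSE) {
  if (is.null(state)) state <- adam_init(params)
  losses <- numeric(epochs)
  n <- length(examples)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      acc <- NULL
      for (i in idx) {
        res <- grad_fn(params, examples[[i]])
        if (!is.finite(res$loss)) stop("non-finite training loss")
        ep_loss <- ep_loss + res$loss
        acc <- if (is.null(acc)) res$grads else tree_add(acc, res$grads)
      }
      acc <- tree_scale(acc, 1 / length(idx))
      upd <- adam_step(params, acc, state, lr = lr)
      params <- upd$params
      state <- upd$state
    }
    losses[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d  loss %.4f", ep, losses[ep]))
  }
  list(params = params, state = state, losses = losses)
}

# Deterministic fold assignment for n units.
make_folds <- function(n, folds) {
  stopifnot(folds >= 1L, n >= folds)
  sample(rep_len(seq_len(folds), n))
}
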