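# Independent oracles: a loop-based MCL iteration, the Mann-Whitney AUC
# identity, and a finite-difference gradient.

# Hand-iterated MCL, written deliberately without matrix products or any code
# shared with the package: explicit loops over entries, attractor-row cluster
# readout.
mcl_oracle <- function(nodes, edges, inflation, max_iter = 200, tol = 1e-6) {
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- edges$from[r]; j <- edges$to[r]
    W[i, j] <- max(W[i, j], edges$weight[r])
    W[j, i] <- W[i, j]
  }
  for (j in seq_len(n)) {
    mx <- 0
    for (i in seq_len(n)) if (i != j && W[i, j] > mx) mx <- W[i, j]
    W[j, j] <- if (mx > 0) mx else 1
  }
  M <- W
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(n)) s <- s + M[i, j]
    for (i in seq_len(n)) M[i, j] <- M[i, j] / s
  }
  for (it in seq_len(max_iter)) {
    E <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + M[i, k] * M[k, j]
      E[i, j] <- acc
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      v <- E[i, j]^inflation
      E[i, j] <- if (v < 1e-8) 0 else v
    }
    for (j in seq_len(n)) {
      s <- 0
      for (i in seq_len(n)) s <- s + E[i, j]
      if (s > 0) for (i in seq_len(n)) E[i, j] <- E[i, j] / s
    }
    d <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      d <- max(d, abs(E[i, j] - M[i, j]))
    M <- E
    if (d < tol) break
  }
  # attractor rows and their supports, merged when they overlap
  clusters <- list()
  for (i in seq_len(n)) {
    if (M[i, i] > 1e-5) {
      supp <- nodes[M[i, ] > 1e-5]
      placed <- FALSE
      for (c in seq_along(clusters)) {
        if (length(intersect(clusters[[c]], supp))) {
          clusters[[c]] <- union(clusters[[c]], supp)
          placed <- TRUE
          break
        }
      }
      if (!placed) clusters[[length(clusters) + 1L]] <- supp
    }
  }
  covered <- unique(unlist(clusters))
  for (x in setdiff(nodes, covered))
    clusters[[length(clusters) + 1L]] <- x
  sort(vapply(clusters, function(m) paste(sort(m), collapse = ","),
              character(1L)))
}

# AUC via the rank-based Mann-Whitney identity (average ranks handle ties)
mw_auc <- function(scores, labels) {
  pos <- labels == "temperate"
  r <- rank(scores)
  np <- sum(pos); nn <- sum(!pos)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

# central finite-difference gradient of scalar f over all model parameters
numeric_grad <- function(params, f, eps = 1e-5) {
  sk <- lysotype:::param_tree(params)
  flat <- unlist(sk, use.names = FALSE)
  g <- numeric(length(flat))
  for (i in seq_along(flat)) {
    fp <- flat; fp[i] <- fp[i] + eps
    fm <- flat; fm[i] <- fm[i] - eps
    g[i] <- (f(lysotype:::set_tree(params, utils::relist(fp, sk))) -
               f(lysotype:::set_tree(params, utils::relist(fm, sk)))) /
      (2 * eps)
  }
  g
}

flat_grads <- function(grads) unlist(grads, use.names = FALSE)
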