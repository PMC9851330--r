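# Shared fixtures, built in code and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

# default synthetic universe + vocabulary + gene tokens, computed once
test_universe <- function() {
  if (is.null(.fixture_env$u)) {
    u <- generate_universe(synth_spec(seed = 11))
    vocab <- universe_vocabulary(u)
    .fixture_env$u <- list(u = u, vocab = vocab,
                           tokens = universe_tokens(u, vocab))
  }
  .fixture_env$u
}

# 12-column alignment rows with defaults for the columns tests ignore
aln_rows <- function(q, s, evalue, bitscore = 100) {
  n <- length(q)
  data.frame(qseqid = q, sseqid = s, pident = rep(95, n),
             length = rep(100, n), mismatch = rep(0, n),
             gapopen = rep(0, n), qstart = rep(1, n), qend = rep(100, n),
             sstart = rep(1, n), send = rep(100, n), evalue = evalue,
             bitscore = rep_len(bitscore, n), stringsAsFactors = FALSE)
}

# small weighted undirected graph from an edge list data.frame(from,to,weight)
make_graph <- function(edges, nodes = NULL) {
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = if (is.null(nodes)) NULL
               else data.frame(name = nodes, stringsAsFactors = FALSE))
}

cluster_signature <- function(clusters) {
  sort(vapply(clusters, function(cl)
    paste(sort(unlist(cl$members)), collapse = ","), character(1L)))
}
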