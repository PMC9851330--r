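# Protein-cluster token vocabulary: similarity graph -> Markov clustering ->
# singleton removal -> contiguous token ids.

# Special-token convention, fixed repo-wide. Ids are 0-based as stored in
# sentences; add 1 when indexing R matrices.
SPECIAL_TOKENS <- c("[PAD]" = 0L, "[UNK]" = 1L, "[CLS]" = 2L,
                    "[SEP]" = 3L, "[MASK]" = 4L)
N_SPECIAL <- 5L

#' Build a weighted protein-similarity graph from pairwise alignments
#'
#' Nodes are proteins, edges connect aligned pairs. The alignment e-value is
#' converted to a similarity weight `-log10(max(evalue, 1e-200))`; when a pair
#' is reported in both search directions the stronger (maximum) weight is
#' kept. Self-alignments are dropped. Pairs with e-value above the cutoff are
#' not connected.
#'
#' @param edges Alignment table or file (see [read_alignments()]).
#' @param evalue_cutoff Retain alignments with evalue <= cutoff (default 1e-5,
#'   the conventional protein-search significance threshold).
#' @return An [igraph::graph] with vertex `name` and edge `weight` attributes;
#'   vertices sorted lexicographically so downstream clustering is
#'   reproducible. An empty table gives an empty graph.
#' @export
build_similarity_graph <- function(edges, evalue_cutoff = 1e-5) {
  stopifnot(evalue_cutoff > 0)
  aln <- read_alignments(edges)
  aln <- aln[aln$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(aln) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  # nodes: every protein in a retained alignment (self-alignments keep the
  # node but contribute no edge)
  nodes <- sort(unique(c(aln$qseqid, aln$sseqid)))
  aln <- aln[aln$qseqid != aln$sseqid, , drop = FALSE]
  if (nrow(aln) == 0L) {
    g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    return(g)
  }
  w <- -log10(pmax(aln$evalue, 1e-200))
  # canonical unordered pair, keep max weight across directions/duplicates
  a <- pmin(aln$qseqid, aln$sseqid)
  b <- pmax(aln$qseqid, aln$sseqid)
  key <- paste(a, b, sep = "\r")
  wmax <- tapply(w, key, max)
  pairs <- do.call(rbind, strsplit(names(wmax), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1L], to = pairs[, 2L],
               weight = as.numeric(wmax), stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  g
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Standard MCL: the weighted adjacency matrix gets self-loops, is column
#' normalized, then expansion (matrix squaring) and inflation (elementwise
#' power followed by column renormalization) alternate until the matrix stops
#' changing. Clusters are read off the converged matrix as connected attractor
#' sets. Isolated vertices become singleton clusters.
#'
#' @param graph An [igraph::graph] with non-negative `weight` edge attribute
#'   (as from [build_similarity_graph()]).
#' @param inflation Inflation exponent, > 1 (default 2).
#' @param self_loop_weight Either the string `"max"` (per node, the maximum
#'   incident edge weight; isolated nodes get 1) or a single non-negative
#'   number used for every node.
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance on the max absolute entry change
#'   (default 1e-6).
#' @param prune Entries below this are zeroed after each inflation for
#'   sparsity (default 1e-8).
#' @return A list of clusters, each `list(cluster_id, members,
#'   representative_id)` with members sorted and the representative the
#'   lexicographically smallest member. Clusters are ordered by descending
#'   size then representative. Attribute `converged` is FALSE (with a warning)
#'   if `max_iter` was hit.
#' @export
markov_cluster <- function(graph, inflation = 2, self_loop_weight = "max",
                           max_iter = 100L, tol = 1e-6, prune = 1e-8) {
  stopifnot(inflation > 1)
  n <- igraph::vcount(graph)
  if (n == 0L) {
    out <- list()
    attr(out, "converged") <- TRUE
    return(out)
  }
  nodes <- sort(igraph::V(graph)$name)
  A <- as.matrix(igraph::as_adjacency_matrix(
    graph, attr = if (igraph::ecount(graph) > 0) "weight" else NULL,
    sparse = FALSE))
  A <- A[nodes, nodes, drop = FALSE]
  if (any(A < 0)) stop("edge weights must be non-negative")
  loops <- if (identical(self_loop_weight, "max")) {
    m <- apply(A, 2L, max)
    ifelse(m > 0, m, 1)
  } else {
    stopifnot(is.numeric(self_loop_weight), self_loop_weight >= 0)
    rep(max(self_loop_weight, .Machine$double.eps), n)
  }
  diag(A) <- loops
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1                   # fully pruned column: leave as zeros
    M2 <- sweep(M2, 2L, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; returning current interpretation")
  # clusters = connected components of the non-zero structure of the limit
  S <- (M + t(M)) > 1e-5
  diag(S) <- TRUE
  gs <- igraph::graph_from_adjacency_matrix(S, mode = "undirected")
  comp <- igraph::components(gs)$membership
  cl <- split(nodes, comp)
  cl <- lapply(cl, sort)
  reps <- vapply(cl, `[[`, character(1L), 1L)
  ord <- order(-lengths(cl), reps)
  out <- lapply(seq_along(ord), function(i) {
    m <- cl[[ord[i]]]
    list(cluster_id = i, members = m, representative_id = m[[1L]])
  })
  attr(out, "converged") <- converged
  out
}

#' Build the protein-cluster token vocabulary
#'
#' Singleton clusters are removed; surviving clusters are sorted by descending
#' size, ties broken by lexicographically smallest member, and assigned token
#' ids 5, 6, ... after the five special tokens
#' `[PAD]=0, [UNK]=1, [CLS]=2, [SEP]=3, [MASK]=4`.
#'
#' @param clusters List of clusters as returned by [markov_cluster()] (a
#'   partition of the protein set).
#' @return An object of class `pc_vocab`: list with `special` (named integer
#'   vector), `clusters` (data.frame: token_id, cluster_id, size,
#'   representative_id, members as a list column), `size` (total token count
#'   V). Warns if no cluster has >= 2 members.
#' @export
build_vocabulary <- function(clusters) {
  members <- lapply(clusters, function(cl) sort(unlist(cl$members)))
  all_m <- unlist(members)
  if (anyDuplicated(all_m))
    stop("clusters do not form a partition: duplicated member(s)")
  keep <- lengths(members) >= 2L
  members <- members[keep]
  if (length(members) == 0L) {
    warning("all clusters are singletons; vocabulary has only special tokens")
    cl_df <- data.frame(token_id = integer(), cluster_id = integer(),
                        size = integer(), representative_id = character(),
                        stringsAsFactors = FALSE)
    cl_df$members <- list()
  } else {
    reps <- vapply(members, `[[`, character(1L), 1L)
    ord <- order(-lengths(members), reps)
    members <- members[ord]
    reps <- reps[ord]
    cl_df <- data.frame(
      token_id = N_SPECIAL + seq_along(members) - 1L,
      cluster_id = seq_along(members),
      size = lengths(members),
      representative_id = reps,
      stringsAsFactors = FALSE)
    cl_df$members <- members
  }
  rownames(cl_df) <- NULL
  structure(list(special = SPECIAL_TOKENS, clusters = cl_df,
                 size = N_SPECIAL + nrow(cl_df)),
            class = "pc_vocab")
}

#' @export
print.pc_vocab <- function(x, ...) {
  cat("Protein-cluster token vocabulary\n")
  cat("  special tokens :", paste(names(x$special), collapse = " "), "\n")
  cat("  cluster tokens :", nrow(x$clusters), "\n")
  cat("  total size V   :", x$size, "\n")
  invisible(x)
}

#' Map protein ids to the token id of their cluster
#'
#' @param vocab A `pc_vocab`.
#' @return Named integer vector: member protein id -> token id.
#' @export
vocab_member_tokens <- function(vocab) {
  stopifnot(inherits(vocab, "pc_vocab"))
  if (nrow(vocab$clusters) == 0L) return(stats::setNames(integer(), character()))
  tok <- rep(vocab$clusters$token_id, lengths(vocab$clusters$members))
  stats::setNames(tok, unlist(vocab$clusters$members))
}

#' Write a vocabulary to disk
#'
#' Emits `<prefix>.vocab.tsv` (token_id, cluster_id, size, representative_id,
#' comma-joined members), `<prefix>.vocab.json` (special-token ids and build
#' parameters) and `<prefix>.reps.faa` (representative protein FASTA) when
#' `proteins` is given.
#'
#' @param vocab A `pc_vocab`.
#' @param prefix Output path prefix.
#' @param proteins Optional named character vector / `AAStringSet` of protein
#'   sequences from which representative sequences are written.
#' @param params Optional named list of build parameters recorded in the JSON
#'   sidecar.
#' @return `prefix`, invisibly.
#' @export
write_vocabulary <- function(vocab, prefix, proteins = NULL, params = list()) {
  stopifnot(inherits(vocab, "pc_vocab"))
  tsv <- data.frame(
    token_id = vocab$clusters$token_id,
    cluster_id = vocab$clusters$cluster_id,
    size = vocab$clusters$size,
    representative_id = vocab$clusters$representative_id,
    members = vapply(vocab$clusters$members, paste, character(1L),
                     collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(tsv, paste0(prefix, ".vocab.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(special_tokens = as.list(vocab$special), size = vocab$size,
         params = params),
    paste0(prefix, ".vocab.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(proteins)) {
    pr <- stats::setNames(as.character(proteins), names(proteins))
    reps <- vocab$clusters$representative_id
    missing <- setdiff(reps, names(pr))
    if (length(missing))
      stop("representative sequence(s) missing: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(pr[reps]), paste0(prefix, ".reps.faa"))
  }
  invisible(prefix)
}

#' Read a vocabulary written by [write_vocabulary()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `pc_vocab`.
#' @export
read_vocabulary <- function(prefix) {
  tsv_path <- paste0(prefix, ".vocab.tsv")
  js_path <- paste0(prefix, ".vocab.json")
  if (!file.exists(tsv_path) || !file.exists(js_path))
    stop("vocabulary files not found at prefix: ", prefix)
  js <- jsonlite::read_json(js_path, simplifyVector = TRUE)
  tsv <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                           colClasses = c("integer", "integer", "integer",
                                          "character", "character"))
  members <- strsplit(tsv$members, ",", fixed = TRUE)
  cl_df <- tsv[c("token_id", "cluster_id", "size", "representative_id")]
  cl_df$members <- members
  rownames(cl_df) <- NULL
  special <- unlist(js$special_tokens)
  storage.mode(special) <- "integer"
  structure(list(special = special, clusters = cl_df,
                 size = as.integer(js$size)),
            class = "pc_vocab")
}
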