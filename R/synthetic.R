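# Seeded synthetic universe: protein clusters with mutated members, genomes as
# ordered gene mosaics with a planted lifestyle signal (marker clusters
# enriched in temperate genomes), and alignment tables synthesized from the
# ground truth so the whole pipeline runs without an external aligner.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# one fixed codon per amino acid (no codon-usage modeling)
CODON_TABLE <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                 G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
                 M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                 S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

#' Synthetic-universe specification
#'
#' Defaults define the package's reference study conditions: 20 protein
#' clusters of 5 members, 5 marker clusters whose sampling probability is
#' multiplied by 12 in temperate genomes, 60 genomes per lifestyle of 12-20
#' genes, 5% per-residue member divergence, 120-residue proteins. Under these
#' defaults the Bayes accuracy of the planted lifestyle signal is ~0.99 (a
#' likelihood-ratio test on the marker-gene count), so near-perfect held-out
#' classification is attainable in principle.
#'
#' @param n_clusters Number of protein clusters.
#' @param proteins_per_cluster Members per cluster.
#' @param n_genomes_per_class Genomes per lifestyle class.
#' @param genes_per_genome Integer range `c(lo, hi)` of genes per genome.
#' @param n_markers Number of temperate-marker clusters (the first
#'   `n_markers` clusters).
#' @param marker_enrichment Probability multiplier for marker clusters in
#'   temperate genomes (1 = no planted signal).
#' @param mutation_rate Per-residue substitution probability within a cluster.
#' @param protein_length Residues per ancestor protein.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_clusters = 20L, proteins_per_cluster = 5L,
                       n_genomes_per_class = 60L,
                       genes_per_genome = c(12L, 20L), n_markers = 5L,
                       marker_enrichment = 12, mutation_rate = 0.05,
                       protein_length = 120L, seed = 1L) {
  stopifnot(n_clusters >= 1L, proteins_per_cluster >= 1L,
            n_genomes_per_class >= 1L, length(genes_per_genome) == 2L,
            genes_per_genome[1L] >= 1L,
            genes_per_genome[2L] >= genes_per_genome[1L],
            marker_enrichment > 0, mutation_rate >= 0, mutation_rate <= 1,
            protein_length >= 3L)
  if (n_markers > n_clusters)
    stop("n_markers (", n_markers, ") exceeds n_clusters (", n_clusters, ")")
  structure(list(n_clusters = as.integer(n_clusters),
                 proteins_per_cluster = as.integer(proteins_per_cluster),
                 n_genomes_per_class = as.integer(n_genomes_per_class),
                 genes_per_genome = as.integer(genes_per_genome),
                 n_markers = as.integer(n_markers),
                 marker_enrichment = marker_enrichment,
                 mutation_rate = mutation_rate,
                 protein_length = as.integer(protein_length),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

mutate_protein <- function(aa, rate) {
  v <- strsplit(aa, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(v)) < rate
  if (any(hit))
    v[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  paste(v, collapse = "")
}

back_translate <- function(aa) {
  paste0(paste(CODON_TABLE[strsplit(aa, "", fixed = TRUE)[[1L]]],
               collapse = ""), "TAA")
}

rand_evalue_rows <- function(q, s, plen, lo = 30, hi = 120) {
  k <- stats::runif(length(q), lo, hi)
  data.frame(qseqid = q, sseqid = s, pident = round(stats::runif(length(q),
                                                                 80, 100), 1),
             length = plen, mismatch = 0L, gapopen = 0L, qstart = 1L,
             qend = plen, sstart = 1L, send = plen,
             evalue = 10^(-k), bitscore = round(2 * plen + k),
             stringsAsFactors = FALSE)
}

#' Generate the synthetic universe
#'
#' Builds, deterministically from the spec seed: ancestor proteins per
#' cluster and point-mutated members; genomes per lifestyle class as
#' concatenations of back-translated genes drawn from a per-class cluster
#' distribution (marker clusters up-weighted by `marker_enrichment` in
#' temperate genomes); an all-against-all alignment table with low e-values
#' for within-cluster pairs only (plus self hits); a query-vs-representative
#' hits table for every genome gene; lifestyle labels; and the ground-truth
#' cluster map.
#'
#' @param spec A `synth_spec`.
#' @return A `synth_universe` list: `proteins` (cluster members, named),
#'   `genomes` (named DNA), `calls` (`protein_calls` with a ground-truth
#'   `cluster` column), `labels` (genome_id, lifestyle), `alignments`,
#'   `hits` (12-column tables), `truth_clusters` (list cluster -> member ids),
#'   `spec`.
#' @export
generate_universe <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  nc <- spec$n_clusters
  pc <- spec$proteins_per_cluster
  plen <- spec$protein_length
  cl_names <- sprintf("PC%03d", seq_len(nc))

  ancestors <- vapply(seq_len(nc), function(i)
    paste(sample(AA_ALPHABET, plen, replace = TRUE), collapse = ""),
    character(1L))
  members <- list()
  proteins <- character()
  for (i in seq_len(nc)) {
    ids <- sprintf("%s_m%02d", cl_names[i], seq_len(pc))
    seqs <- vapply(seq_len(pc), function(j)
      mutate_protein(ancestors[i], spec$mutation_rate), character(1L))
    members[[cl_names[i]]] <- ids
    proteins[ids] <- seqs
  }

  # per-class cluster sampling distribution with the planted marker signal
  w_vir <- rep(1, nc)
  w_tmp <- rep(1, nc)
  if (spec$n_markers > 0L)
    w_tmp[seq_len(spec$n_markers)] <- spec$marker_enrichment
  p_vir <- w_vir / sum(w_vir)
  p_tmp <- w_tmp / sum(w_tmp)

  genomes <- character()
  calls_rows <- list()
  labels <- list()
  for (cls in c("temperate", "virulent")) {
    pr <- if (cls == "temperate") p_tmp else p_vir
    tag <- if (cls == "temperate") "T" else "V"
    for (g in seq_len(spec$n_genomes_per_class)) {
      gid <- sprintf("%s%03d", tag, g)
      ngenes <- sample(spec$genes_per_genome[1L]:spec$genes_per_genome[2L], 1L)
      cl_idx <- sample.int(nc, ngenes, replace = TRUE, prob = pr)
      mem_idx <- sample.int(pc, ngenes, replace = TRUE)
      gene_prot <- vapply(seq_len(ngenes), function(k)
        members[[cl_idx[k]]][mem_idx[k]], character(1L))
      gene_dna <- vapply(proteins[gene_prot], back_translate, character(1L))
      glen <- nchar(gene_dna)
      ends <- cumsum(glen)
      starts <- ends - glen
      genomes[gid] <- paste(gene_dna, collapse = "")
      calls_rows[[gid]] <- data.frame(
        contig_id = gid, ordinal = seq_len(ngenes) - 1L,
        start = starts, end = ends, strand = "+",
        protein_id = sprintf("%s_%d", gid, seq_len(ngenes)),
        aa_sequence = unname(proteins[gene_prot]),
        cluster = cl_names[cl_idx],
        member_id = gene_prot,
        stringsAsFactors = FALSE)
      labels[[gid]] <- data.frame(genome_id = gid, lifestyle = cls,
                                  stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls_rows)
  rownames(calls) <- NULL
  class(calls) <- c("protein_calls", "data.frame")
  labels <- do.call(rbind, unname(labels))

  # all-vs-all: both directions of every within-cluster pair, plus self hits
  aln_rows <- list()
  for (i in seq_len(nc)) {
    ids <- members[[i]]
    if (length(ids) >= 2L) {
      pairs <- t(utils::combn(ids, 2L))
      aln_rows[[length(aln_rows) + 1L]] <-
        rand_evalue_rows(pairs[, 1L], pairs[, 2L], plen)
      aln_rows[[length(aln_rows) + 1L]] <-
        rand_evalue_rows(pairs[, 2L], pairs[, 1L], plen)
    }
    aln_rows[[length(aln_rows) + 1L]] <-
      rand_evalue_rows(ids, ids, plen, lo = 150, hi = 200)
  }
  alignments <- do.call(rbind, aln_rows)
  rownames(alignments) <- NULL

  # query proteins vs cluster representatives (lexicographically smallest
  # member, matching the vocabulary's representative rule)
  reps <- vapply(members, function(m) sort(m)[[1L]], character(1L))
  hits <- rand_evalue_rows(calls$protein_id, unname(reps[calls$cluster]), plen)

  structure(list(proteins = proteins, genomes = genomes, calls = calls,
                 labels = labels, alignments = alignments, hits = hits,
                 truth_clusters = members, spec = spec),
            class = "synth_universe")
}

#' Write a universe to standard files
#'
#' FASTA for proteins and genomes, TSV for labels / alignments / hits — the
#' same formats the pipeline CLIs consume.
#'
#' @param universe A `synth_universe`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "synth_universe"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(universe$proteins),
    file.path(dir, "cluster_proteins.faa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(universe$genomes),
    file.path(dir, "genomes.fna"))
  calls <- universe$calls
  gene_fasta <- stats::setNames(
    calls$aa_sequence,
    sprintf("%s # %d # %d # +", calls$protein_id, calls$start + 1L,
            calls$end))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(gene_fasta),
                              file.path(dir, "genome_proteins.faa"))
  utils::write.table(universe$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_alignments(universe$alignments, file.path(dir, "all_vs_all.tsv"))
  write_alignments(universe$hits, file.path(dir, "hits.tsv"))
  jsonlite::write_json(universe$truth_clusters,
                       file.path(dir, "truth_clusters.json"))
  invisible(dir)
}

#' Build the token vocabulary of a universe from its alignment table
#'
#' Runs the real pipeline (similarity graph, Markov clustering, singleton
#' removal) on the synthesized all-vs-all table.
#'
#' @param universe A `synth_universe`.
#' @param ... Passed to [markov_cluster()].
#' @return A `pc_vocab`.
#' @export
universe_vocabulary <- function(universe, ...) {
  g <- build_similarity_graph(universe$alignments)
  build_vocabulary(markov_cluster(g, ...))
}

#' Per-genome gene tokens for a universe
#'
#' Assigns vocabulary tokens to every genome gene via the hits table and
#' returns the calls annotated with `token_id`.
#'
#' @param universe A `synth_universe`.
#' @param vocab A `pc_vocab` (e.g. from [universe_vocabulary()]).
#' @return The universe `calls` data.frame with a `token_id` column.
#' @export
universe_tokens <- function(universe, vocab) {
  assign_tokens(universe$calls, vocab, universe$hits)
}

#' Token sentences for fragments of universe genomes
#'
#' A fragment's sentence holds the tokens of the genes fully contained in
#' `[start, end)`, in gene order.
#'
#' @param tokens Output of [universe_tokens()].
#' @param manifest Fragment manifest (source_id, start, end), e.g. from
#'   [build_finetune_corpus()].
#' @param max_len Sentence length (default 300).
#' @return List of `token_sentence`, one per manifest row.
#' @export
fragment_sentences <- function(tokens, manifest, max_len = 300L) {
  by_g <- split(tokens[c("start", "end", "ordinal", "token_id")],
                tokens$contig_id)
  lapply(seq_len(nrow(manifest)), function(i) {
    g <- by_g[[manifest$source_id[i]]]
    if (is.null(g)) stop("unknown source: ", manifest$source_id[i])
    inside <- g$start >= manifest$start[i] & g$end <= manifest$end[i]
    encode_sentence(g$token_id[order(g$ordinal)][inside[order(g$ordinal)]],
                    max_len = max_len)
  })
}
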