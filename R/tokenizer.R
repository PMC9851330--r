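# Contig -> protein-token sentence: gene calls -> best-alignment token
# assignment -> [CLS]/tokens/[SEP]/[PAD] encoding at fixed length.

#' Read protein calls from a prodigal-style FASTA
#'
#' Headers follow the prodigal convention
#' `<contig>_<geneIndex> # <start> # <end> # <strand> [# ...]` with 1-based
#' inclusive DNA coordinates; these are converted to 0-based half-open.
#' A plain `<contig>_<geneIndex>` header (no coordinates) is accepted, with
#' coordinates reported as NA.
#'
#' @param x Path to a protein FASTA or an `AAStringSet`/named character vector.
#' @return A data.frame of class `protein_calls`: contig_id, ordinal (0-based
#'   gene order), start, end (0-based half-open), strand, protein_id,
#'   aa_sequence; sorted by contig then start.
#' @export
read_protein_calls <- function(x) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    s <- Biostrings::readAAStringSet(x)
    stats::setNames(as.character(s), names(s))
  } else {
    stats::setNames(as.character(x), names(x))
  }
  if (length(seqs) == 0L)
    return(empty_calls())
  parts <- strsplit(names(seqs), "\\s*#\\s*")
  pid <- vapply(parts, `[[`, character(1L), 1L)
  pid <- sub("\\s.*$", "", pid)
  has_coord <- lengths(parts) >= 4L
  start1 <- ifelse(has_coord,
                   suppressWarnings(as.numeric(vapply(parts, function(p)
                     if (length(p) >= 2L) p[[2L]] else NA_character_,
                     character(1L)))), NA_real_)
  end1 <- ifelse(has_coord,
                 suppressWarnings(as.numeric(vapply(parts, function(p)
                   if (length(p) >= 3L) p[[3L]] else NA_character_,
                   character(1L)))), NA_real_)
  strand <- ifelse(has_coord,
                   vapply(parts, function(p)
                     if (length(p) >= 4L) p[[4L]] else NA_character_,
                     character(1L)), NA_character_)
  strand <- ifelse(strand %in% c("1", "+"), "+",
                   ifelse(strand %in% c("-1", "-"), "-", strand))
  m <- regmatches(pid, regexec("^(.*)_([0-9]+)$", pid))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop("protein header(s) not in <contig>_<geneIndex> form: ",
         paste(utils::head(pid[!ok], 3L), collapse = ", "))
  contig <- vapply(m, `[[`, character(1L), 2L)
  gidx <- as.integer(vapply(m, `[[`, character(1L), 3L))
  df <- data.frame(contig_id = contig, ordinal = gidx,
                   start = start1 - 1, end = end1, strand = strand,
                   protein_id = pid, aa_sequence = unname(seqs),
                   stringsAsFactors = FALSE)
  key <- if (all(is.finite(df$start))) df$start else df$ordinal
  df <- df[order(df$contig_id, key), , drop = FALSE]
  df$ordinal <- stats::ave(seq_len(nrow(df)), df$contig_id,
                           FUN = seq_along) - 1L
  rownames(df) <- NULL
  class(df) <- c("protein_calls", "data.frame")
  df
}

empty_calls <- function() {
  df <- data.frame(contig_id = character(), ordinal = integer(),
                   start = numeric(), end = numeric(), strand = character(),
                   protein_id = character(), aa_sequence = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("protein_calls", "data.frame")
  df
}

#' Call genes on contigs
#'
#' Gene calling is pluggable: the `"precomputed"` backend reads an existing
#' protein FASTA / calls table (the hermetic path used throughout the test
#' suite and by the synthetic universe); the `"prodigal"` backend shells out to
#' prodigal in metagenomic mode when it is on PATH.
#'
#' @param contigs Contig FASTA path or named DNA character vector /
#'   `DNAStringSet`.
#' @param backend `"precomputed"` or `"prodigal"`.
#' @param proteins For `"precomputed"`: protein FASTA path / `AAStringSet` /
#'   `protein_calls` data.frame.
#' @return A `protein_calls` data.frame restricted to the supplied contigs;
#'   contigs with no genes simply contribute no rows.
#' @export
call_genes <- function(contigs, backend = c("precomputed", "prodigal"),
                       proteins = NULL) {
  backend <- match.arg(backend)
  ids <- contig_ids(contigs)
  if (backend == "precomputed") {
    if (is.null(proteins))
      stop("precomputed backend requires `proteins`")
    calls <- if (inherits(proteins, "protein_calls")) proteins
             else read_protein_calls(proteins)
    out <- calls[calls$contig_id %in% ids, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("protein_calls", "data.frame")
    return(out)
  }
  if (Sys.which("prodigal") == "")
    stop("prodigal not found on PATH")
  fa <- if (is.character(contigs) && length(contigs) == 1L &&
            file.exists(contigs)) contigs else {
    tmp <- tempfile(fileext = ".fna")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(as.character(contigs)), tmp)
    tmp
  }
  faa <- tempfile(fileext = ".faa")
  status <- system2("prodigal", c("-i", fa, "-a", faa, "-p", "meta",
                                  "-o", "/dev/null", "-q"))
  if (status != 0L)
    stop("prodigal failed (exit ", status, ") on input covering contig(s): ",
         paste(utils::head(ids, 3L), collapse = ", "))
  out <- read_protein_calls(faa)
  out$aa_sequence <- sub("\\*$", "", out$aa_sequence)
  out[out$contig_id %in% ids, , drop = FALSE]
}

contig_ids <- function(contigs) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    sub("\\s.*$", "", names(Biostrings::readDNAStringSet(contigs)))
  } else {
    sub("\\s.*$", "", names(contigs))
  }
}

#' Assign a vocabulary token to each called protein
#'
#' Each protein takes the token of its best alignment against the cluster
#' representatives: lowest e-value, ties broken by highest bit score, then
#' smallest token id. Proteins with no hit receive `[UNK]`.
#'
#' @param calls A `protein_calls` data.frame.
#' @param vocab A `pc_vocab`.
#' @param hits 12-column alignment table/file of query proteins vs. cluster
#'   representatives (`sseqid` must be a representative in `vocab`).
#' @return `calls` with an integer `token_id` column appended (gene order
#'   preserved).
#' @export
assign_tokens <- function(calls, vocab, hits) {
  stopifnot(inherits(vocab, "pc_vocab"))
  hits <- read_alignments(hits)
  rep2tok <- stats::setNames(vocab$clusters$token_id,
                             vocab$clusters$representative_id)
  if (nrow(hits)) {
    unknown <- setdiff(unique(hits$sseqid), names(rep2tok))
    if (length(unknown))
      stop("hit(s) reference unknown representative(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  hits <- hits[hits$qseqid %in% calls$protein_id, , drop = FALSE]
  token <- rep(SPECIAL_TOKENS[["[UNK]"]], nrow(calls))
  if (nrow(hits)) {
    hits$token_id <- rep2tok[hits$sseqid]
    ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$token_id)
    hits <- hits[ord, , drop = FALSE]
    best <- hits[!duplicated(hits$qseqid), c("qseqid", "token_id")]
    idx <- match(calls$protein_id, best$qseqid)
    hit_found <- !is.na(idx)
    token[hit_found] <- best$token_id[idx[hit_found]]
  }
  calls$token_id <- as.integer(token)
  calls
}

#' Encode a token list as a fixed-length sentence
#'
#' Produces `[CLS] t1 ... tk [SEP] [PAD]...` of length exactly `max_len`
#' (default 300). Contigs with more than `max_len - 2` tokens keep only the
#' first `max_len - 2`.
#'
#' @param tokens Integer vector of content token ids (possibly empty).
#' @param max_len Sentence length (default 300).
#' @return A `token_sentence`: list with `token_ids` (integer, length
#'   `max_len`), `position_ids` (0-based), `attention_length` (count of
#'   non-PAD entries).
#' @export
encode_sentence <- function(tokens, max_len = 300L) {
  stopifnot(max_len >= 2L)
  tokens <- as.integer(tokens)
  k <- min(length(tokens), max_len - 2L)
  content <- tokens[seq_len(k)]
  ids <- c(SPECIAL_TOKENS[["[CLS]"]], content, SPECIAL_TOKENS[["[SEP]"]],
           rep(SPECIAL_TOKENS[["[PAD]"]], max_len - 2L - k))
  structure(list(token_ids = as.integer(unname(ids)),
                 position_ids = seq_len(max_len) - 1L,
                 attention_length = k + 2L),
            class = "token_sentence")
}

#' Strip specials and padding from a sentence
#'
#' @param sentence A `token_sentence`.
#' @return Integer vector of content token ids.
#' @export
decode_sentence <- function(sentence) {
  stopifnot(inherits(sentence, "token_sentence"))
  n <- sentence$attention_length
  if (n <= 2L) return(integer())
  sentence$token_ids[2L:(n - 1L)]
}

#' Tokenize contigs end to end
#'
#' Gene calls (precomputed or prodigal) are token-assigned against the
#' vocabulary and encoded per contig in gene order. Deterministic: the same
#' inputs give byte-identical sentences.
#'
#' @inheritParams call_genes
#' @inheritParams assign_tokens
#' @param max_len Sentence length (default 300).
#' @return Named list of `token_sentence`, one per input contig (contigs
#'   without genes get the degenerate `[CLS][SEP]` sentence).
#' @export
tokenize_contigs <- function(contigs, vocab, hits,
                             backend = c("precomputed", "prodigal"),
                             proteins = NULL, max_len = 300L) {
  ids <- contig_ids(contigs)
  calls <- call_genes(contigs, backend = backend, proteins = proteins)
  calls <- assign_tokens(calls, vocab, hits)
  by_contig <- split(calls$token_id[order(calls$contig_id, calls$ordinal)],
                     calls$contig_id[order(calls$contig_id, calls$ordinal)])
  out <- lapply(ids, function(cid) {
    toks <- by_contig[[cid]]
    encode_sentence(if (is.null(toks)) integer() else toks, max_len = max_len)
  })
  stats::setNames(out, ids)
}

#' Write sentences as TSV (contig_id, space-separated token ids)
#'
#' @param sentences Named list of `token_sentence`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sentences <- function(sentences, path) {
  df <- data.frame(
    contig_id = names(sentences),
    tokens = vapply(sentences, function(s)
      paste(s$token_ids, collapse = " "), character(1L)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
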