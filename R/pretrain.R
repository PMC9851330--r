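# Masked-token self-supervised task: fragment corpus construction over whole
# genomes, random masking, and the pretraining loop with cross-validated model
# selection by validation loss.

as_genome_set <- function(genomes) {
  seqs <- if (is.character(genomes) && length(genomes) == 1L &&
              file.exists(genomes)) {
    s <- Biostrings::readDNAStringSet(genomes)
    stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
  } else {
    stats::setNames(as.character(genomes), names(genomes))
  }
  if (length(seqs) == 0L) stop("no genome sequences supplied")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("genomes must be named")
  seqs
}

# Integer-uniform start on [0, space-1]; space >= 1.
runif_start <- function(n, space) {
  pmin(floor(stats::runif(n) * space), space - 1)
}

#' Build the masked-LM fragment corpus
#'
#' Each genome contributes its full sequence (optionally) plus
#' `n_per_length` uniformly placed substrings per sampling length; genomes
#' shorter than a length contribute the whole sequence for that draw. With the
#' defaults every genome yields 4 x 10 + 1 = 41 fragments.
#'
#' @param genomes FASTA path or named DNA character vector / `DNAStringSet`.
#' @param lengths Fragment lengths in bp (default 5, 10, 15, 20 kbp).
#' @param n_per_length Substrings sampled per genome per length (default 10).
#' @param include_full Also keep each full genome (default TRUE).
#' @param seed Integer seed; sampling is reproducible (same seed, identical
#'   coordinates).
#' @return A data.frame manifest: source_id, start, end (0-based half-open),
#'   length_class (`"5000"`, ..., or `"full"`). Sequences are not copied; use
#'   [extract_fragments()] to materialize them.
#' @export
build_mlm_corpus <- function(genomes, lengths = c(5000L, 10000L, 15000L,
                                                  20000L),
                             n_per_length = 10L, include_full = TRUE, seed) {
  if (missing(seed)) stop("seed must be supplied")
  seqs <- as_genome_set(genomes)
  set.seed(as.integer(seed))
  glen <- nchar(seqs)
  ids <- names(seqs)
  G <- length(ids)
  out <- list()
  if (include_full)
    out[[length(out) + 1L]] <- data.frame(
      source_id = ids, start = 0, end = unname(glen), length_class = "full",
      stringsAsFactors = FALSE)
  for (L in lengths) {
    src <- rep(ids, each = n_per_length)
    len_rep <- rep(unname(glen), each = n_per_length)
    space <- pmax(len_rep - L, 0) + 1
    st <- runif_start(G * n_per_length, space)
    en <- pmin(st + L, len_rep)
    st[len_rep <= L] <- 0
    out[[length(out) + 1L]] <- data.frame(
      source_id = src, start = st, end = en,
      length_class = as.character(L), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Materialize fragment sequences from a manifest
#'
#' @param genomes As in [build_mlm_corpus()].
#' @param manifest Manifest data.frame with source_id, start, end.
#' @return Character vector of fragment sequences (exact substrings).
#' @export
extract_fragments <- function(genomes, manifest) {
  seqs <- as_genome_set(genomes)
  missing_src <- setdiff(unique(manifest$source_id), names(seqs))
  if (length(missing_src))
    stop("manifest references unknown source(s): ",
         paste(utils::head(missing_src, 3L), collapse = ", "))
  unname(substring(seqs[manifest$source_id], manifest$start + 1L,
                   manifest$end))
}

#' Randomly mask content tokens of a sentence
#'
#' Each content token is independently masked with probability `rate`; if none
#' is selected one content position is forced, so every example has at least
#' one target. `[CLS]`, `[SEP]` and `[PAD]` are never masked. Masked positions
#' are always replaced by `[MASK]`.
#'
#' @param sentence A `token_sentence` with at least one content token.
#' @param rate Per-token masking probability (default 0.05).
#' @return A `masked_example`: list(input (masked `token_sentence`),
#'   target_positions (1-based indices into the sentence), target_ids
#'   (original 0-based token ids)), or NULL with a warning for a sentence with
#'   no content tokens.
#' @export
mask_sentence <- function(sentence, rate = 0.05) {
  stopifnot(inherits(sentence, "token_sentence"), rate >= 0, rate <= 1)
  k <- sentence$attention_length - 2L
  if (k < 1L) {
    warning("sentence has no content tokens; skipping")
    return(NULL)
  }
  content_pos <- 2L:(k + 1L)
  sel <- stats::runif(k) < rate
  if (!any(sel)) sel[sample.int(k, 1L)] <- TRUE
  pos <- content_pos[sel]
  targets <- sentence$token_ids[pos]
  masked <- sentence
  masked$token_ids[pos] <- SPECIAL_TOKENS[["[MASK]"]]
  structure(list(input = masked, target_positions = pos,
                 target_ids = targets),
            class = "masked_example")
}

normalize_sentences <- function(sentences, max_len) {
  lapply(sentences, function(s) {
    if (inherits(s, "token_sentence")) s
    else encode_sentence(as.integer(s), max_len = max_len)
  })
}

# content prefix of an encoded sentence (what the encoder consumes)
sentence_prefix <- function(sentence) {
  sentence$token_ids[seq_len(sentence$attention_length)]
}

#' Pretrain the encoder on the masked-token task
#'
#' Sentences are split into `folds` train/validation splits; one model is
#' trained per split (masks redrawn every epoch) and the parameters with the
#' lowest validation masked-token loss are returned. `folds = 1` trains on
#' everything and reports the final training loss instead.
#'
#' @param sentences List of `token_sentence` or content-token id vectors.
#' @param config A `model_config` (its `vocab_size` must match the tokenizer
#'   vocabulary).
#' @param folds Cross-validation splits (default 10).
#' @param lr Adam learning rate (default 0.001).
#' @param epochs Passes over the training split (default 20).
#' @param batch_size Mini-batch size (default 8).
#' @param mask_rate Masking probability (default 0.05).
#' @param seed Integer seed controlling splits, initialization, masking and
#'   shuffling.
#' @param verbose Print per-epoch losses.
#' @return List: `params` (best `model_params`), `fold_stats` (data.frame:
#'   fold, val_loss, val_accuracy), `best_fold`.
#' @export
pretrain_mlm <- function(sentences, config, folds = 10L, lr = 1e-3,
                         epochs = 20L, batch_size = 8L, mask_rate = 0.05,
                         seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  sentences <- normalize_sentences(sentences, config$max_len)
  keep <- vapply(sentences, function(s) s$attention_length > 2L, logical(1L))
  sentences <- sentences[keep]
  if (length(sentences) == 0L) stop("no sentences with content tokens")
  grad_fn <- function(params, ex) {
    m <- mask_sentence(ex, rate = mask_rate)
    pre <- sentence_prefix(m$input)
    mlm_example_grad(params, pre, m$target_positions, m$target_ids,
                     train = params$config$dropout > 0)
  }
  eval_split <- function(params, split, eval_seed) {
    set.seed(eval_seed)
    tot <- 0; ntok <- 0L; ncorr <- 0L
    for (ex in split) {
      m <- mask_sentence(ex, rate = mask_rate)
      r <- mlm_example_loss(params, sentence_prefix(m$input),
                            m$target_positions, m$target_ids)
      tot <- tot + r$loss * r$n; ntok <- ntok + r$n; ncorr <- ncorr + r$correct
    }
    list(loss = tot / ntok, accuracy = ncorr / ntok)
  }
  seed <- as.integer(seed)
  if (folds == 1L) {
    set.seed(seed)
    params <- init_model(config, seed = seed)
    set.seed(seed + 1L)
    fit <- train_epochs(params, sentences, grad_fn, epochs = epochs,
                        batch_size = batch_size, lr = lr, verbose = verbose)
    tr <- eval_split(fit$params, sentences, seed + 2L)
    return(list(params = fit$params,
                fold_stats = data.frame(fold = 1L, val_loss = tr$loss,
                                        val_accuracy = tr$accuracy),
                best_fold = 1L, train_losses = fit$losses))
  }
  set.seed(seed)
  fold_of <- make_folds(length(sentences), folds)
  best <- NULL
  stats_df <- data.frame(fold = integer(), val_loss = numeric(),
                         val_accuracy = numeric())
  for (f in seq_len(folds)) {
    params <- init_model(config, seed = seed + f)
    set.seed(seed + 1000L + f)
    fit <- train_epochs(params, sentences[fold_of != f], grad_fn,
                        epochs = epochs, batch_size = batch_size, lr = lr,
                        verbose = verbose)
    ev <- eval_split(fit$params, sentences[fold_of == f], seed + 2000L + f)
    stats_df <- rbind(stats_df,
                      data.frame(fold = f, val_loss = ev$loss,
                                 val_accuracy = ev$accuracy))
    if (is.null(best) || ev$loss < best$loss)
      best <- list(params = fit$params, loss = ev$loss, fold = f)
    if (verbose)
      message(sprintf("fold %d  val loss %.4f  val acc %.3f",
                      f, ev$loss, ev$accuracy))
  }
  list(params = best$params, fold_stats = stats_df, best_fold = best$fold)
}
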