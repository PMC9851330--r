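# Lifestyle fine-tuning: length-augmented labeled fragment corpus, a
# length-binned short-fragment benchmark with k-mer-sketch deduplication,
# genome-level cross-validated fine-tuning selected by validation AUCROC, and
# end-to-end prediction.

#' Default augmentation length grid (bp)
#'
#' Eight lengths spanning 100 bp to 20 kbp: the four short-fragment benchmark
#' bin boundaries plus the four pretraining sampling lengths.
#' @export
DEFAULT_LENGTH_GRID <- c(100L, 400L, 800L, 1200L, 1800L, 5000L, 10000L,
                         20000L)

read_labels <- function(labels) {
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    labels <- utils::read.table(labels, sep = "\t", header = FALSE,
                                col.names = c("genome_id", "lifestyle"),
                                colClasses = "character")
  }
  labels <- as.data.frame(labels)
  names(labels)[1:2] <- c("genome_id", "lifestyle")
  bad <- setdiff(unique(labels$lifestyle), c("temperate", "virulent"))
  if (length(bad))
    stop("label(s) outside {temperate, virulent}: ",
         paste(bad, collapse = ", "))
  labels
}

# Sample n fragments of length L from the genomes of one class, uniformly over
# (genome, start) pairs: a genome is drawn with probability proportional to
# its number of admissible starts, then the start uniformly. Genomes shorter
# than L contribute their whole sequence.
sample_class_fragments <- function(ids, glen, L, n) {
  space <- pmax(glen - L, 0) + 1
  gi <- sample.int(length(ids), n, replace = TRUE, prob = space)
  st <- runif_start(n, space[gi])
  en <- pmin(st + L, glen[gi])
  st[glen[gi] <= L] <- 0
  data.frame(source_id = ids[gi], start = st, end = en,
             stringsAsFactors = FALSE)
}

#' Build the length-augmented fine-tuning corpus
#'
#' For every length in the grid and each lifestyle class, exactly
#' `n_per_class_per_length` fragments are sampled, giving an exactly
#' class-balanced corpus of `2 * length(grid) * n_per_class_per_length`
#' fragments (160,000 with the defaults).
#'
#' @param genomes FASTA path or named DNA character vector / `DNAStringSet`.
#' @param labels TSV path or data.frame: genome_id, lifestyle in
#'   {temperate, virulent}.
#' @param length_grid Fragment lengths in bp (default [DEFAULT_LENGTH_GRID]).
#' @param n_per_class_per_length Fragments per class per length
#'   (default 10000).
#' @param seed Integer seed.
#' @return Manifest data.frame: source_id, start, end, length_class, label.
#' @export
build_finetune_corpus <- function(genomes, labels,
                                  length_grid = DEFAULT_LENGTH_GRID,
                                  n_per_class_per_length = 10000L, seed) {
  if (missing(seed)) stop("seed must be supplied")
  seqs <- as_genome_set(genomes)
  labels <- read_labels(labels)
  labels <- labels[labels$genome_id %in% names(seqs), , drop = FALSE]
  set.seed(as.integer(seed))
  out <- list()
  for (L in length_grid) {
    for (cls in c("temperate", "virulent")) {
      ids <- labels$genome_id[labels$lifestyle == cls]
      if (length(ids) == 0L) stop("no genomes labeled ", cls)
      fr <- sample_class_fragments(ids, nchar(seqs[ids]), L,
                                   n_per_class_per_length)
      fr$length_class <- as.character(L)
      fr$label <- cls
      out[[length(out) + 1L]] <- fr
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- k-mer sketch near-duplicate removal ------------------------------------

KMER_BASE <- c(A = 0, C = 1, G = 2, T = 3)

encode_kmers <- function(seq, k) {
  v <- KMER_BASE[strsplit(toupper(seq), "", fixed = TRUE)[[1L]]]
  v[is.na(v)] <- 0
  n <- length(v)
  if (n < k) return(sum(v * 4^(seq_len(n) - 1)))
  idx <- embed(v, k)                    # rows = reversed windows
  unique(drop(idx %*% 4^(0:(k - 1))))
}

# Bottom-s sketch of hashed k-mer codes (one 64-bit-ish multiplicative hash).
kmer_sketch <- function(seq, k = 12L, sketch_size = 32L) {
  codes <- encode_kmers(seq, k)
  h <- (codes * 2654435761) %% 4294967291
  sort(h)[seq_len(min(sketch_size, length(h)))]
}

sketch_similarity <- function(a, b) {
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Remove near-duplicate sequences by k-mer sketch containment
#'
#' Each sequence is reduced to a bottom-k sketch of hashed k-mers; candidate
#' pairs are found by locality-sensitive banding over the sketch and a
#' candidate is removed when its sketch containment with an earlier-kept
#' sequence exceeds the threshold (first-seen wins).
#'
#' @param seqs Character vector of DNA sequences.
#' @param threshold Similarity above which the later sequence is removed
#'   (default 0.8).
#' @param k K-mer size (default 12).
#' @param sketch_size Sketch size (default 32).
#' @param band_rows Sketch values per LSH band (default 4).
#' @return Logical keep vector, same length as `seqs`.
#' @export
dedup_keep <- function(seqs, threshold = 0.8, k = 12L, sketch_size = 32L,
                       band_rows = 4L) {
  n <- length(seqs)
  if (n == 0L) return(logical())
  sketches <- lapply(seqs, kmer_sketch, k = k, sketch_size = sketch_size)
  keys <- lapply(sketches, function(s) {
    s <- rep_len(s, sketch_size)
    nb <- sketch_size %/% band_rows
    vapply(seq_len(nb), function(b)
      paste(b, paste(s[((b - 1L) * band_rows + 1L):(b * band_rows)],
                     collapse = ","), sep = ":"), character(1L))
  })
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(n)
  for (i in seq_len(n)) {
    cand <- unique(unlist(lapply(keys[[i]], function(kk)
      if (!is.null(buckets[[kk]])) buckets[[kk]] else integer())))
    dup <- FALSE
    for (j in cand) {
      if (sketch_similarity(sketches[[i]], sketches[[j]]) > threshold) {
        dup <- TRUE
        break
      }
    }
    keep[i] <- !dup
    if (!dup) {
      for (kk in keys[[i]])
        buckets[[kk]] <- c(buckets[[kk]], i)
    }
  }
  keep
}

#' Build the short-fragment length-bin benchmark
#'
#' For each length bin, `n_per_bin` fragments are sampled (half per class,
#' fragment length uniform within the bin), then near-duplicates above the
#' similarity threshold are removed (first-seen kept) when `dedup = TRUE`.
#'
#' @inheritParams build_finetune_corpus
#' @param bins List of `c(lo, hi)` length ranges in bp (defaults: 100-400,
#'   400-800, 800-1200, 1200-1800).
#' @param n_per_bin Fragments per bin before dedup (default 80000).
#' @param dedup_threshold Sketch-similarity removal threshold (default 0.8).
#' @param dedup Run deduplication (default TRUE; requires extracting
#'   sequences).
#' @return Named list, one manifest per bin with columns as in
#'   [build_finetune_corpus()] plus `kept` (post-dedup survivor flag; all TRUE
#'   when `dedup = FALSE`). Attribute `summary` holds per-bin pre/post counts.
#' @export
build_length_bin_benchmark <- function(genomes, labels,
                                       bins = list(c(100L, 400L),
                                                   c(400L, 800L),
                                                   c(800L, 1200L),
                                                   c(1200L, 1800L)),
                                       n_per_bin = 80000L,
                                       dedup_threshold = 0.8,
                                       dedup = TRUE, seed) {
  if (missing(seed)) stop("seed must be supplied")
  seqs <- as_genome_set(genomes)
  labels <- read_labels(labels)
  labels <- labels[labels$genome_id %in% names(seqs), , drop = FALSE]
  per_class <- n_per_bin %/% 2L
  set.seed(as.integer(seed))
  out <- list()
  summ <- data.frame(bin = character(), pre_dedup = integer(),
                     post_dedup = integer(), stringsAsFactors = FALSE)
  for (b in bins) {
    lo <- b[[1L]]; hi <- b[[2L]]
    bin_name <- paste0(lo, "-", hi)
    rows <- list()
    for (cls in c("temperate", "virulent")) {
      ids <- labels$genome_id[labels$lifestyle == cls]
      if (length(ids) == 0L) stop("no genomes labeled ", cls)
      glen <- nchar(seqs[ids])
      Ls <- lo + runif_start(per_class, hi - lo + 1)
      cnt <- table(Ls)
      fr <- do.call(rbind, lapply(names(cnt), function(L)
        sample_class_fragments(ids, glen, as.numeric(L), cnt[[L]])))
      fr$length_class <- bin_name
      fr$label <- cls
      rows[[cls]] <- fr
    }
    m <- do.call(rbind, rows)
    rownames(m) <- NULL
    if (dedup) {
      frags <- extract_fragments(seqs, m)
      m$kept <- dedup_keep(frags, threshold = dedup_threshold)
    } else {
      m$kept <- TRUE
    }
    out[[bin_name]] <- m
    summ <- rbind(summ, data.frame(bin = bin_name, pre_dedup = nrow(m),
                                   post_dedup = sum(m$kept),
                                   stringsAsFactors = FALSE))
  }
  attr(out, "summary") <- summ
  out
}

# ---- fine-tuning -----------------------------------------------------------

label_to_int <- function(label) {
  bad <- setdiff(unique(label), c("temperate", "virulent"))
  if (length(bad)) stop("label(s) outside {temperate, virulent}")
  ifelse(label == "temperate", 0L, 1L)
}

#' Fine-tune (or train from scratch) the lifestyle classifier
#'
#' Optimizes the two-class cross-entropy on the `[CLS]` head with Adam.
#' Cross-validation folds are assigned at the genome level so fragments of one
#' genome never straddle a train/validation split; the fold with the best
#' validation AUCROC supplies the returned parameters. Passing a
#' `model_config` instead of pretrained parameters trains from scratch (the
#' no-self-supervision ablation arm).
#'
#' @param init A pretrained `model_params`, or a `model_config` for
#'   from-scratch training.
#' @param sentences List of `token_sentence` / content-token id vectors.
#' @param labels Character vector in {temperate, virulent}, one per sentence.
#' @param genome_ids Source genome of each sentence (drives the fold split);
#'   defaults to one pseudo-genome per sentence.
#' @param folds Cross-validation splits (default 10); `folds = 1` trains on
#'   everything.
#' @param lr Adam learning rate (default 0.001).
#' @param epochs Training epochs per fold (default 10).
#' @param batch_size Mini-batch size (default 8).
#' @param seed Integer seed.
#' @param verbose Print fold metrics.
#' @return List: `params` (best fold), `fold_stats` (fold, val_auc, val_acc),
#'   `best_fold`.
#' @export
finetune_classifier <- function(init, sentences, labels,
                                genome_ids = NULL, folds = 10L, lr = 1e-3,
                                epochs = 10L, batch_size = 8L, seed = 1L,
                                verbose = FALSE) {
  from_scratch <- inherits(init, "model_config")
  config <- if (from_scratch) init else init$config
  sentences <- normalize_sentences(sentences, config$max_len)
  stopifnot(length(labels) == length(sentences))
  y <- label_to_int(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(genome_ids)) genome_ids <- as.character(seq_along(sentences))
  seed <- as.integer(seed)
  examples <- Map(function(s, lab) list(s = s, y = lab), sentences, y)
  grad_fn <- function(params, ex)
    cls_example_grad(params, sentence_prefix(ex$s), ex$y,
                     train = params$config$dropout > 0)
  new_params <- function(f) {
    if (from_scratch) init_model(config, seed = seed + f)
    else init
  }
  if (folds == 1L) {
    set.seed(seed)
    params <- new_params(0L)
    set.seed(seed + 1L)
    fit <- train_epochs(params, examples, grad_fn, epochs = epochs,
                        batch_size = batch_size, lr = lr)
    p <- predict_sentences(fit$params, sentences)
    auc <- roc_auc(p, labels)$auc
    acc <- mean((p >= 0.5) == (y == 0L))
    return(list(params = fit$params,
                fold_stats = data.frame(fold = 1L, val_auc = auc,
                                        val_acc = acc),
                best_fold = 1L, train_losses = fit$losses))
  }
  set.seed(seed)
  genomes <- sort(unique(genome_ids))
  gfold <- stats::setNames(make_folds(length(genomes), folds), genomes)
  fold_of <- gfold[genome_ids]
  best <- NULL
  stats_df <- data.frame(fold = integer(), val_auc = numeric(),
                         val_acc = numeric())
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    if (length(unique(y[tr])) < 2L)
      stop("training fold ", f, " contains a single class")
    params <- new_params(f)
    set.seed(seed + 1000L + f)
    fit <- train_epochs(params, examples[tr], grad_fn, epochs = epochs,
                        batch_size = batch_size, lr = lr)
    p_val <- predict_sentences(fit$params, sentences[!tr])
    y_val <- y[!tr]
    auc <- if (length(unique(y_val)) == 2L)
      roc_auc(p_val, ifelse(y_val == 0L, "temperate", "virulent"))$auc
    else NA_real_
    acc <- mean((p_val >= 0.5) == (y_val == 0L))
    stats_df <- rbind(stats_df, data.frame(fold = f, val_auc = auc,
                                           val_acc = acc))
    if (is.null(best) || (!is.na(auc) && auc > best$auc))
      best <- list(params = fit$params, auc = if (is.na(auc)) -Inf else auc,
                   fold = f)
    if (verbose)
      message(sprintf("fold %d  val AUC %.3f  val acc %.3f", f, auc, acc))
  }
  list(params = best$params, fold_stats = stats_df, best_fold = best$fold)
}

#' Predict lifestyle for contigs
#'
#' Tokenizes contigs (precomputed proteins or prodigal) and scores them with a
#' trained model. Contigs with zero called genes are reported as
#' "unclassified" with NaN probabilities. The hard call is temperate when the
#' temperate probability is `>= cutoff`.
#'
#' @inheritParams tokenize_contigs
#' @param params Trained `model_params`.
#' @param cutoff Decision threshold on the temperate probability
#'   (default 0.5).
#' @return Data.frame: contig_id, length_bp, n_genes, p_temperate, p_virulent,
#'   call.
#' @export
predict_lifestyle <- function(contigs, params, vocab, hits,
                              backend = c("precomputed", "prodigal"),
                              proteins = NULL, cutoff = 0.5) {
  seqs <- if (is.character(contigs) && length(contigs) == 1L &&
              file.exists(contigs)) {
    s <- Biostrings::readDNAStringSet(contigs)
    stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
  } else stats::setNames(as.character(contigs), names(contigs))
  sentences <- tokenize_contigs(seqs, vocab, hits, backend = backend,
                                proteins = proteins,
                                max_len = params$config$max_len)
  n_genes <- vapply(sentences, function(s) s$attention_length - 2L,
                    integer(1L))
  p <- rep(NaN, length(sentences))
  has_genes <- n_genes > 0L
  if (any(has_genes))
    p[has_genes] <- predict_sentences(params, sentences[has_genes])
  data.frame(
    contig_id = names(sentences),
    length_bp = unname(nchar(seqs[names(sentences)])),
    n_genes = unname(n_genes),
    p_temperate = unname(p),
    p_virulent = unname(1 - p),
    call = ifelse(!has_genes, "unclassified",
                  ifelse(p >= cutoff, "temperate", "virulent")),
    stringsAsFactors = FALSE)
}
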