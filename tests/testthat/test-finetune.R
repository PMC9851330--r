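test_that("fine-tuning corpus is exactly class-balanced at every length", {
  fx <- test_universe()
  u <- fx$u
  m <- build_finetune_corpus(u$genomes, u$labels,
                             length_grid = c(100L, 1200L),
                             n_per_class_per_length = 25L, seed = 5)
  expect_equal(nrow(m), 2 * 2 * 25)
  expect_true(all(table(m$label, m$length_class) == 25))
  expect_true(all(m$end - m$start <= as.integer(m$length_class) |
                    m$length_class == "full"))
  # labels inherited from the source genome
  lab <- setNames(u$labels$lifestyle, u$labels$genome_id)
  expect_equal(m$label, unname(lab[m$source_id]))

  # tiny grid example
  m1 <- build_finetune_corpus(u$genomes, u$labels, length_grid = 100L,
                              n_per_class_per_length = 5L, seed = 5)
  expect_equal(nrow(m1), 10)
  expect_equal(as.integer(table(m1$label)), c(5L, 5L))

  # short-genome rule shared with the pretraining builder
  short <- c(s1 = strrep("ACGT", 12))  # 48 bp
  lab2 <- data.frame(genome_id = c("s1", names(u$genomes)[61]),
                     lifestyle = c("temperate", "virulent"))
  genomes2 <- c(short, u$genomes[61])
  m2 <- build_finetune_corpus(genomes2, lab2, length_grid = 100L,
                              n_per_class_per_length = 3L, seed = 5)
  tmp <- m2[m2$label == "temperate", ]
  expect_true(all(tmp$start == 0 & tmp$end == 48))

  # a class with no genomes is an error
  expect_error(build_finetune_corpus(
    u$genomes[1:3], u$labels[1:3, ], length_grid = 100L,
    n_per_class_per_length = 2L, seed = 1), "virulent")
})

test_that("length-bin benchmark samples within bins and deduplicates near-identical fragments", {
  fx <- test_universe()
  u <- fx$u
  bb <- build_length_bin_benchmark(u$genomes, u$labels,
                                   bins = list(c(100L, 400L), c(400L, 800L)),
                                   n_per_bin = 40L, dedup = FALSE, seed = 9)
  sm <- attr(bb, "summary")
  expect_equal(sm$pre_dedup, c(40L, 40L))
  for (b in seq_along(bb)) {
    m <- bb[[b]]
    expect_equal(as.integer(table(m$label)), c(20L, 20L))
    lo <- c(100, 400)[b]; hi <- c(400, 800)[b]
    full_len <- m$end - m$start
    src_len <- nchar(u$genomes[m$source_id])
    expect_true(all(full_len <= hi))
    expect_true(all(full_len >= pmin(lo, src_len)))
  }

  # byte-identical fragments: later copy removed; random fragments survive
  set.seed(1)
  rand <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
    character(1))
  expect_true(all(dedup_keep(rand)))
  keep <- dedup_keep(c(rand[1], rand[2], rand[1]))
  expect_equal(keep, c(TRUE, TRUE, FALSE))
  # near-duplicate with a single substitution is also caught
  mut <- rand[1]
  substr(mut, 250, 250) <- "A"
  expect_equal(dedup_keep(c(rand[1], mut)), c(TRUE, FALSE))

  bb2 <- build_length_bin_benchmark(u$genomes, u$labels,
                                    bins = list(c(400L, 800L)),
                                    n_per_bin = 30L, dedup = TRUE, seed = 9)
  sm2 <- attr(bb2, "summary")
  expect_equal(sm2$post_dedup, sum(bb2[[1]]$kept))
  expect_lte(sm2$post_dedup, sm2$pre_dedup)
})

test_that("prediction output follows the probability, cutoff and degenerate-input contracts", {
  fx <- test_universe()
  u <- fx$u
  vocab <- fx$vocab
  cfg <- desk_config(vocab$size, d_model = 16L, n_heads = 2L, max_len = 32L)
  params <- init_model(cfg, seed = 1)

  contigs <- c(u$genomes[1:3],
               geneless = paste(rep("N", 200), collapse = ""))
  pred <- predict_lifestyle(contigs, params, vocab, u$hits,
                            proteins = u$calls)
  expect_equal(nrow(pred), length(contigs))
  expect_equal(pred$contig_id, names(contigs))
  ok <- pred$call != "unclassified"
  expect_equal(pred$p_temperate[ok] + pred$p_virulent[ok], rep(1, sum(ok)),
               tolerance = 1e-6)
  expect_equal(pred$call[!ok], "unclassified")
  expect_true(is.nan(pred$p_temperate[!ok]))
  expect_equal(pred$n_genes[!ok], 0L)

  # boundary convention: p exactly at the cutoff is called temperate
  pred2 <- predict_lifestyle(contigs[1], params, vocab, u$hits,
                             proteins = u$calls,
                             cutoff = pred$p_temperate[1])
  expect_equal(pred2$call, "temperate")
})

test_that("genome-level folds never split a genome and single-class folds error", {
  fx <- test_universe()
  sen <- list(c(5L, 6L), c(6L, 7L), c(5L, 8L), c(9L, 10L))
  labs <- c("temperate", "temperate", "virulent", "virulent")
  expect_error(
    finetune_classifier(desk_config(fx$vocab$size, d_model = 8L,
                                    n_heads = 2L, max_len = 8L),
                        sen, rep("temperate", 4), folds = 2L, epochs = 1L),
    "both classes")
  # two genomes, one per class: any 2-fold genome split leaves one class out
  expect_error(
    finetune_classifier(desk_config(fx$vocab$size, d_model = 8L,
                                    n_heads = 2L, max_len = 8L),
                        sen, labs, genome_ids = c("a", "a", "b", "b"),
                        folds = 2L, epochs = 1L),
    "single class")
})

test_that("seeded training and prediction are exactly reproducible", {
  fx <- test_universe()
  u <- fx$u
  mani <- build_finetune_corpus(u$genomes, u$labels, length_grid = 2000L,
                                n_per_class_per_length = 10L, seed = 3)
  sen <- fragment_sentences(fx$tokens, mani, max_len = 24L)
  cfg <- desk_config(fx$vocab$size, d_model = 8L, n_heads = 2L,
                     max_len = 24L, dropout = 0.1)
  run <- function() {
    ft <- finetune_classifier(cfg, sen, mani$label, folds = 1L, epochs = 2L,
                              seed = 11)
    predict_sentences(ft$params, sen)
  }
  expect_identical(run(), run())
})
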