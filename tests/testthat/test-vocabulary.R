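test_that("similarity graph applies the -log10 weight, direction max, self-edge and cutoff rules", {
  # two directions of one pair: max of the transformed weights is kept
  g <- build_similarity_graph(aln_rows(c("A", "B"), c("B", "A"),
                                       c(1e-50, 1e-40)))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 50)

  # self-alignment: node kept, edge dropped
  g <- build_similarity_graph(aln_rows("A", "A", 0))
  expect_equal(igraph::vcount(g), 1)
  expect_equal(igraph::ecount(g), 0)
  expect_equal(igraph::V(g)$name, "A")

  # two disjoint triangles survive intact
  tri <- aln_rows(c("A", "B", "C", "D", "E", "F"),
                  c("B", "C", "A", "E", "F", "D"), 1e-10)
  g <- build_similarity_graph(tri)
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 6)
  expect_true(all(igraph::E(g)$weight == 10))

  # e-value cutoff drops weak pairs; empty result is an empty graph
  g <- build_similarity_graph(aln_rows("A", "B", 1e-3), evalue_cutoff = 1e-5)
  expect_equal(igraph::vcount(g), 0)
  expect_equal(igraph::ecount(build_similarity_graph(
    aln_rows(character(), character(), numeric()))), 0)

  # malformed rows are reported with their position
  bad <- aln_rows("A", "B", 1e-10)
  bad$evalue <- -1
  expect_error(read_alignments(bad), "line")
})

test_that("markov clustering separates components and matches the hand-iterated oracle", {
  # disjoint equal-weight triangles can never merge
  tri <- data.frame(from = c("A", "B", "C", "D", "E", "F"),
                    to = c("B", "C", "A", "E", "F", "D"), weight = 10)
  cl <- markov_cluster(make_graph(tri))
  expect_equal(cluster_signature(cl), c("A,B,C", "D,E,F"))
  expect_true(attr(cl, "converged"))

  # empty graph -> empty cluster list
  expect_equal(length(markov_cluster(igraph::make_empty_graph(0, directed = FALSE))), 0)

  # oracle equivalence on small graphs across inflations
  barbell <- data.frame(
    from = c("A", "B", "C", "E", "F", "G", "C", "D"),
    to = c("B", "C", "A", "F", "G", "E", "D", "E"),
    weight = c(10, 10, 10, 10, 10, 10, 1, 1))
  path8 <- data.frame(from = LETTERS[1:7], to = LETTERS[2:8],
                      weight = c(5, 5, 5, 1, 5, 5, 5))
  star <- data.frame(from = rep("H", 5), to = LETTERS[1:5], weight = 3)
  for (edges in list(barbell, path8, star)) {
    nodes <- sort(unique(c(edges$from, edges$to)))
    for (infl in c(1.5, 2.0, 4.0)) {
      got <- cluster_signature(markov_cluster(make_graph(edges), inflation = infl))
      expect_equal(got, mcl_oracle(nodes, edges, infl),
                   info = sprintf("inflation %.1f", infl))
    }
  }
})

test_that("markov clustering yields a partition, handles isolated nodes, and ignores weight scale", {
  edges <- data.frame(from = c("A", "B", "C", "D"),
                      to = c("B", "C", "D", "A"), weight = c(8, 2, 8, 2))
  g <- make_graph(edges, nodes = c(LETTERS[1:4], "Z"))  # Z isolated
  cl <- markov_cluster(g)
  all_members <- unlist(lapply(cl, `[[`, "members"))
  expect_setequal(all_members, c(LETTERS[1:4], "Z"))
  expect_equal(anyDuplicated(all_members), 0L)
  expect_true("Z" %in% cluster_signature(cl))  # singleton survives clustering

  scaled <- edges; scaled$weight <- scaled$weight * 1000
  expect_equal(cluster_signature(markov_cluster(g)),
               cluster_signature(markov_cluster(make_graph(scaled,
                                                           nodes = c(LETTERS[1:4], "Z")))))
})

test_that("vocabulary drops singletons, orders deterministically, and round-trips", {
  cl <- function(...) lapply(list(...), function(m)
    list(cluster_id = 0L, members = m, representative_id = m[[1L]]))

  v <- build_vocabulary(cl(c("A", "B"), "C"))
  expect_equal(v$size, 6)
  expect_equal(v$clusters$token_id, 5L)

  # size tie broken by smallest member
  v <- build_vocabulary(cl(c("C", "D"), c("A", "B"), "E"))
  expect_equal(v$clusters$representative_id, c("A", "C"))
  expect_equal(v$clusters$token_id, c(5L, 6L))

  # all-singleton input: specials only, with a warning
  expect_warning(v0 <- build_vocabulary(cl("A", "B")), "singleton")
  expect_equal(v0$size, 5)

  # order independence
  a <- build_vocabulary(cl(c("A", "B"), c("C", "D", "E"), "F"))
  b <- build_vocabulary(cl("F", c("C", "D", "E"), c("A", "B")))
  expect_identical(a, b)

  # duplicated members violate the partition precondition
  expect_error(build_vocabulary(cl(c("A", "B"), c("B", "C"))), "partition")

  # disk round-trip (TSV + JSON sidecar), including representative FASTA
  prots <- c(A = "MKL", B = "MKI", C = "MNP", D = "MNQ", E = "MNR", F = "WYV")
  prefix <- file.path(withr::local_tempdir(), "vv")
  write_vocabulary(a, prefix, proteins = prots,
                   params = list(inflation = 2, evalue_cutoff = 1e-5))
  expect_identical(read_vocabulary(prefix), a)
  reps <- Biostrings::readAAStringSet(paste0(prefix, ".reps.faa"))
  expect_setequal(names(reps), a$clusters$representative_id)

  # member -> token lookup is lossless
  mt <- vocab_member_tokens(a)
  expect_equal(unname(mt[c("C", "D", "E")]), rep(5L, 3))
  expect_equal(unname(mt[c("A", "B")]), rep(6L, 2))
})

test_that("vocabulary built from synthetic alignments recovers the planted partition", {
  fx <- test_universe()
  got <- sort(vapply(fx$vocab$clusters$members, paste, character(1L),
                     collapse = ","))
  want <- sort(unname(vapply(fx$u$truth_clusters, function(m)
    paste(sort(m), collapse = ","), character(1L))))
  expect_equal(got, want)
  expect_equal(fx$vocab$size, 5 + fx$u$spec$n_clusters)
})
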