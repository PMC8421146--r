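test_that("encode_site one-hot rows follow the A,T,C,G channel order", {
  m <- encode_site(paste0("A", strrep("C", 22)))
  expect_equal(unname(m[1, ]), c(1, 0, 0, 0))
  g <- encode_site(paste0("G", strrep("C", 22)))
  expect_equal(unname(g[1, ]), c(0, 0, 0, 1))
  t_ <- encode_site(paste0("T", strrep("C", 22)))
  expect_equal(unname(t_[1, ]), c(0, 1, 0, 0))
  expect_equal(unname(rowSums(m)), rep(1, 23))
  expect_error(encode_site("ACGT"), "23 nt")
  expect_error(encode_site(strrep("N", 23)), "non-ACGT")
  set.seed(91)
  for (i in 1:25) {
    s <- rand_dna(23)
    expect_identical(decode_site(encode_site(s)), s)
  }
})

test_that("build_training_set: negative constraint, conservation, determinism", {
  guide <- guide_target("GACCTGAGTCCGGGTCAGGA", "NNN")
  pos <- c(paste0(guide$protospacer, "AGG"), paste0(guide$protospacer, "TGG"))
  d1 <- build_training_set(pos, guide, negatives_per_positive = 3, seed = 7L)
  expect_identical(sum(d1$labels == 1L), 2L)
  expect_identical(sum(d1$labels == 0L), 6L)
  expect_setequal(d1$sequences[d1$labels == 1L], pos)
  negs <- d1$sequences[d1$labels == 0L]
  mm <- vapply(negs, function(s)
    count_mismatches(substr(s, 1, 20), guide$protospacer), integer(1))
  expect_true(all(mm >= 11L))
  d2 <- build_training_set(pos, guide, negatives_per_positive = 3, seed = 7L)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$labels, d2$labels)
  d3 <- build_training_set(pos, guide, negatives_per_positive = 3, seed = 8L)
  expect_false(identical(d1$sequences, d3$sequences))
  expect_error(build_training_set(pos, guide, negatives_per_positive = 0),
               "> 0")
  expect_error(build_training_set(character(), guide), "no positive")
})

test_that("training contracts: history length, epoch 0, single-class error", {
  bench <- cnn_benchmark()
  small <- list(x = bench$train$x[1:64, , , drop = FALSE],
                labels = bench$train$labels[1:64])
  m2 <- cnn_train(cnn_config(epochs = 2L, seed = 5L), small)
  expect_identical(nrow(m2$history), 2L)
  expect_identical(m2$history$epoch, 1:2)
  m0 <- cnn_train(cnn_config(epochs = 0L, seed = 5L), small)
  expect_identical(nrow(m0$history), 0L)
  onecls <- list(x = small$x[small$labels == 1, , , drop = FALSE],
                 labels = small$labels[small$labels == 1])
  expect_error(cnn_train(cnn_config(epochs = 1L), onecls), "both labels")
  # seeded training is bit-reproducible
  m2b <- cnn_train(cnn_config(epochs = 2L, seed = 5L), small)
  expect_identical(m2$weights, m2b$weights)
  expect_identical(m2$history, m2b$history)
})

test_that("separable task: training accuracy and held-out AUROC >= 0.95", {
  bench <- cnn_benchmark()
  hist <- bench$model$history
  expect_identical(nrow(hist), 30L)
  expect_gte(hist$accuracy[30], 0.95)
  scores <- cnn_predict(bench$model, bench$test$x)
  expect_gte(rank_auc(scores, bench$test$labels), 0.95)
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("predict_rank: ordering, ties, order-invariance, empty input", {
  bench <- cnn_benchmark()
  set.seed(101)
  cand <- data.table::data.table(
    chrom = sample(paste0("chr", 1:5), 200, replace = TRUE),
    start = sample.int(1e6, 200), strand = "+",
    sequence_23 = vapply(1:200, function(i) rand_dna(23), character(1)),
    mismatch_count = 7L, pam = "AGG")
  cand[, end := start + 23L]
  r1 <- predict_rank(bench$model, cand)
  expect_identical(r1$rank, 1:200)
  expect_true(all(diff(r1$score) <= 0))
  r2 <- predict_rank(bench$model, cand[sample(.N)])
  expect_identical(r1$sequence_23, r2$sequence_23)
  expect_identical(r1$score, r2$score)
  single <- predict_rank(bench$model, cand[1])
  expect_identical(single$rank, 1L)
  empty <- predict_rank(bench$model, cand[0])
  expect_identical(nrow(empty), 0L)
})

test_that("recall_at_rank: boundaries, monotonicity, flags", {
  ranked <- data.table::data.table(
    chrom = "chr1", start = 1:100, strand = "+", rank = 1:100)
  best <- data.table::data.table(chrom = "chr1", start = 1:10, strand = "+")
  rb <- recall_at_rank(ranked, best)
  expect_identical(rb$curve$recovered[10], 10L)
  worst <- data.table::data.table(chrom = "chr1", start = 96:100, strand = "+")
  rw <- recall_at_rank(ranked, worst)
  expect_true(all(rw$curve$recovered[1:95] == 0L))
  expect_identical(rw$curve$recovered[100], 5L)
  # monotone, bounded by min(k, |truth|)
  expect_true(all(diff(rb$curve$recovered) >= 0))
  expect_true(all(rb$curve$recovered <= pmin(rb$curve$rank, rb$n_truth)))
  # absent truth flagged
  gone <- data.table::data.table(chrom = "chrZ", start = 1L, strand = "+")
  expect_warning(rg <- recall_at_rank(ranked, gone), "absent")
  expect_identical(rg$missing_truths, 1L)
  expect_identical(rg$curve$recovered[100], 0L)
})

test_that("random ranking recovers truths at ~ k|truth|/n (Monte-Carlo)", {
  set.seed(111)
  n <- 400L; n_truth <- 40L; k <- 100L
  sims <- replicate(300, {
    ord <- sample(n)
    sum(ord[1:k] <= n_truth)
  })
  expect_equal(mean(sims), k * n_truth / n, tolerance = 0.1)
})

test_that("planted truths among decoys land in the top ranks", {
  bench <- cnn_benchmark()
  guide <- bench$guide
  set.seed(121)
  mutate_k <- function(k) {
    s <- strsplit(guide$protospacer, "")[[1]]
    for (i in sample(20L, k)) s[i] <- sample(setdiff(c("A","C","G","T"), s[i]), 1)
    paste(c(s, sample(c("A","C","G","T"), 3, replace = TRUE)), collapse = "")
  }
  truth_seqs <- vapply(sample(1:3, 20, replace = TRUE), mutate_k, character(1))
  decoy_seqs <- vapply(sample(9:14, 1980, replace = TRUE), mutate_k, character(1))
  cand <- data.table::data.table(
    chrom = "chr1", start = seq_len(2000) * 100L, strand = "+",
    sequence_23 = c(truth_seqs, decoy_seqs), mismatch_count = 7L, pam = "NNN")
  cand[, end := start + 23L]
  ranked <- predict_rank(bench$model, cand)
  truth <- cand[1:20, .(chrom, start, strand)]
  rr <- recall_at_rank(ranked, truth)
  expect_gte(rr$curve$recovered[200], 16L)  # >= 80% in the top 10%
})

test_that("model serialises to JSON and round-trips predictions", {
  bench <- cnn_benchmark()
  path <- withr::local_tempfile(fileext = ".json")
  write_cnn_model(bench$model, path)
  back <- read_cnn_model(path)
  s1 <- cnn_predict(bench$model, bench$test$x[1:20, , , drop = FALSE])
  s2 <- cnn_predict(back, bench$test$x[1:20, , , drop = FALSE])
  expect_equal(s1, s2, tolerance = 1e-12)
})
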