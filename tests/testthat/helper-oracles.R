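# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the candidate oracle works on integer vectors with
# explicit shifts (no Biostrings matching), the clustering oracle builds the
# match graph and walks components, the signed-rank oracle enumerates all
# 2^n sign assignments.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# naive-but-vectorised sliding-window candidate scan over one or more
# contigs given as a named character vector; 0-based half-open output
oracle_scan <- function(chromseqs, protospacer, max_mm, pam_pattern) {
  out <- list()
  proto <- utf8ToInt(protospacer)
  proto_rc <- utf8ToInt(oracle_revcomp(protospacer))
  for (chrom in names(chromseqs)) {
    s <- chromseqs[[chrom]]
    L <- nchar(s)
    if (L < 23L) next
    x <- utf8ToInt(s)
    W <- L - 22L                       # number of 23-nt windows (1-based start)
    # plus strand: protospacer at window offsets 1..20, PAM at 21..23
    mm_p <- integer(W)
    for (j in 1:20) mm_p <- mm_p + (x[j:(j + W - 1L)] != proto[j])
    # minus strand: genome positions (i+3)..(i+22) against revcomp(proto)
    mm_m <- integer(W)
    for (j in 1:20) mm_m <- mm_m + (x[(j + 3L):(j + 3L + W - 1L)] != proto_rc[j])
    for (i in seq_len(W)) {
      win <- substr(s, i, i + 22L)
      if (mm_p[i] <= max_mm) {
        pam <- substr(win, 21L, 23L)
        if (pam_matches(pam, pam_pattern))
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = i - 1L, strand = "+", sequence_23 = win,
            mismatch_count = mm_p[i], pam = pam)
      }
      if (mm_m[i] <= max_mm) {
        rc <- oracle_revcomp(win)
        pam <- substr(rc, 21L, 23L)
        if (pam_matches(pam, pam_pattern))
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = i - 1L, strand = "-", sequence_23 = rc,
            mismatch_count = mm_m[i], pam = pam)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), sequence_23 = character(),
                      mismatch_count = integer(), pam = character()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

# connected components of the |pi - pj| <= window relation, per reference
oracle_cluster <- function(refs, pos, window) {
  out <- list()
  for (ch in unique(refs)) {
    p <- pos[refs == ch]
    n <- length(p)
    adj <- abs(outer(p, p, "-")) <= window
    seen <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (seen[i]) next
      comp <- i
      repeat {
        nb <- which(apply(adj[comp, , drop = FALSE], 2, any) & !seen)
        nb <- setdiff(nb, comp)
        if (!length(nb)) break
        comp <- c(comp, nb); seen[nb] <- TRUE
      }
      seen[comp] <- TRUE
      out[[length(out) + 1L]] <- list(chrom = ch, positions = sort(p[comp]))
    }
  }
  out
}

# exact two-sided signed-rank p-value by enumerating all sign assignments,
# replicating the inclusive-tail doubling convention for the two-sided test
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dist <- as.vector(signs %*% r)
  m <- n * (n + 1) / 2
  p <- if (w > m / 2) 2 * mean(dist >= w) else 2 * mean(dist <= w)
  min(p, 1)
}

# exact binomial 99% acceptance band for an observed count at n draws of
# probability p
binom99 <- function(n, p) c(lo = qbinom(0.005, n, p), hi = qbinom(0.995, n, p))

# default planted off-target layout reused by several tests
default_planted <- function(k = 4) {
  all <- data.frame(
    mismatch_count = c(2L, 3L, 4L, 5L, 6L, 7L, 2L, 3L, 4L, 5L),
    pam = c("AGG", "TGG", "AGA", "CGT", "GGG", "TGA", "CGG", "AGT", "TGC", "GGA"),
    chrom = rep(c("chr2", "chr3"), each = 5L),
    position = rep(c(15000L, 35000L, 55000L, 75000L, 92000L), 2L))
  all[seq_len(k), , drop = FALSE]
}

# memoised separable CNN benchmark shared by the unit and acceptance tests:
# positives are near-target sites (<= 3 mismatches), negatives >= 11
.cnn_cache <- new.env(parent = emptyenv())
cnn_benchmark <- function() {
  if (!is.null(.cnn_cache$bench)) return(.cnn_cache$bench)
  guide <- guide_target("GACCTGAGTCCGGGTCAGGA", "NNN")
  set.seed(4242)
  mutate_k <- function(proto, k) {
    s <- strsplit(proto, "")[[1]]
    for (i in sample(20L, k)) s[i] <- sample(setdiff(c("A","C","G","T"), s[i]), 1)
    paste(c(s, sample(c("A","C","G","T"), 3, replace = TRUE)), collapse = "")
  }
  pos <- vapply(sample(0:3, 1000, replace = TRUE),
                function(k) mutate_k(guide$protospacer, k), character(1))
  data <- build_training_set(pos, guide, negatives_per_positive = 1,
                             seed = 99L)
  n <- length(data$labels)
  set.seed(77)
  test_idx <- sample(n, round(0.2 * n))
  train <- list(x = data$x[-test_idx, , , drop = FALSE],
                labels = data$labels[-test_idx])
  test <- list(x = data$x[test_idx, , , drop = FALSE],
               labels = data$labels[test_idx])
  model <- cnn_train(cnn_config(epochs = 30L, seed = 11L), train)
  .cnn_cache$bench <- list(guide = guide, data = data, train = train,
                           test = test, model = model)
  .cnn_cache$bench
}
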