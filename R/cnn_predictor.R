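# Channel order follows the model's stated input convention: A, T, C, G
CNN_CHANNELS <- c("A", "T", "C", "G")

#' One-hot encode a 23-nt site
#'
#' @param sequence_23 a 23-character ACGT string (20-nt protospacer + 3-nt
#'   PAM in guide orientation).
#' @return 23 x 4 binary matrix, channel columns ordered A, T, C, G; every
#'   row is one-hot.
#' @export
encode_site <- function(sequence_23) {
  s <- .check_dna(sequence_23)
  if (nchar(s) != 23L) stop("sequence must be 23 nt", call. = FALSE)
  ch <- strsplit(s, "")[[1]]
  m <- matrix(0, 23L, 4L, dimnames = list(NULL, CNN_CHANNELS))
  m[cbind(1:23, match(ch, CNN_CHANNELS))] <- 1
  m
}

#' Decode a one-hot matrix back to its sequence
#' @param m 23 x 4 one-hot matrix from \code{\link{encode_site}}.
#' @return 23-nt string.
#' @export
decode_site <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 23L, ncol(m) == 4L)
  paste(CNN_CHANNELS[max.col(m)], collapse = "")
}

#' Build a labelled training set from called off-targets
#'
#' Positives are the observed off-target 23-mers (label 1). Negatives are
#' random 23-mers rejection-sampled until their protospacer portion carries
#' more than 10 mismatches (>= 11) against the on-target protospacer
#' (label 0). The combined set is shuffled under the seed.
#'
#' @param positives off-target table with \code{sequence_23}, or character
#'   vector of 23-mers.
#' @param guide a \code{\link{guide_target}}.
#' @param negatives_per_positive negatives generated per positive (> 0).
#' @param seed RNG seed.
#' @return list(sequences, labels, x = n x 23 x 4 array).
#' @export
build_training_set <- function(positives, guide, negatives_per_positive = 1,
                               seed = 1L) {
  stopifnot(inherits(guide, "guide_target"))
  pos <- if (is.character(positives)) positives else positives$sequence_23
  if (length(pos) == 0L) stop("no positive examples", call. = FALSE)
  if (negatives_per_positive <= 0)
    stop("negatives_per_positive must be > 0", call. = FALSE)
  n_neg <- ceiling(length(pos) * negatives_per_positive)
  proto <- strsplit(guide$protospacer, "")[[1]]
  with_seed(seed, {
    negs <- character(n_neg)
    got <- 0L
    while (got < n_neg) {
      cand <- .random_dna(23L)
      mm <- sum(strsplit(substr(cand, 1L, 20L), "")[[1]] != proto)
      if (mm >= 11L) { got <- got + 1L; negs[got] <- cand }
    }
    seqs <- c(pos, negs)
    labels <- c(rep(1L, length(pos)), rep(0L, n_neg))
    ord <- sample(length(seqs))
    seqs <- seqs[ord]; labels <- labels[ord]
    x <- array(0, dim = c(length(seqs), 23L, 4L))
    for (i in seq_along(seqs)) x[i, , ] <- encode_site(seqs[i])
    list(sequences = seqs, labels = labels, x = x)
  })
}

#' CNN hyperparameter configuration
#'
#' Topology is fixed -- convolution, batch normalisation, global max
#' pooling, dense(100), dense(23) with dropout, single sigmoid output --
#' with conventional defaults for the free hyperparameters.
#'
#' @param conv_filters number of convolution filters.
#' @param kernel_size convolution width in positions.
#' @param dropout_rate dropout probability on the 23-unit dense layer.
#' @param epochs training cycles (default 30).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @export
cnn_config <- function(conv_filters = 32L, kernel_size = 5L,
                       dropout_rate = 0.3, epochs = 30L,
                       learning_rate = 1e-3, batch_size = 32L, seed = 1L) {
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)), class = "cnn_config")
}

# im2col for a batch: x is n x 23 x 4, returns (n * n_win) x (k*4) matrix,
# rows ordered window-position-fastest within each sample
.im2col <- function(x, k) {
  n <- dim(x)[1]; n_win <- 23L - k + 1L
  out <- matrix(0, n * n_win, k * 4L)
  col <- 0L
  for (dk in seq_len(k)) for (ch in 1:4) {
    col <- col + 1L
    # value at window p comes from position p + dk - 1
    out[, col] <- as.vector(t(x[, dk:(dk + n_win - 1L), ch, drop = FALSE][, , 1]))
  }
  out
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.cnn_init <- function(config) {
  k <- config$kernel_size; f <- config$conv_filters
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  list(Wc = he(k * 4L, f), gamma = rep(1, f), beta = rep(0, f),
       W1 = he(f, 100L), b1 = rep(0, 100L),
       W2 = he(100L, 23L), b2 = rep(0, 23L),
       W3 = he(23L, 1L), b3 = 0,
       run_mean = rep(0, f), run_var = rep(1, f))
}

# forward pass; returns scores plus the intermediates needed for backprop
.cnn_forward <- function(w, xc, n, n_win, training = FALSE, drop_mask = NULL) {
  eps <- 1e-5
  zc <- xc %*% w$Wc
  if (training) {
    mu <- colMeans(zc)
    v <- colMeans(zc * zc) - mu * mu
  } else { mu <- w$run_mean; v <- w$run_var }
  zh <- sweep(sweep(zc, 2, mu), 2, sqrt(v + eps), "/")
  zb <- sweep(sweep(zh, 2, w$gamma, "*"), 2, w$beta, "+")
  a <- pmax(zb, 0)
  f <- ncol(a)
  arr <- array(a, c(n_win, n, f))
  pool <- arr[1L, , , drop = FALSE][1, , , drop = TRUE]
  if (is.null(dim(pool))) pool <- matrix(pool, n, f)
  argm <- matrix(1L, n, f)
  if (n_win > 1L) for (p in 2:n_win) {
    ap <- arr[p, , , drop = FALSE][1, , , drop = TRUE]
    if (is.null(dim(ap))) ap <- matrix(ap, n, f)
    upd <- ap > pool
    pool[upd] <- ap[upd]; argm[upd] <- p
  }
  h1 <- pmax(sweep(pool %*% w$W1, 2, w$b1, "+"), 0)
  h2 <- pmax(sweep(h1 %*% w$W2, 2, w$b2, "+"), 0)
  h2d <- if (training && !is.null(drop_mask)) h2 * drop_mask else h2
  logits <- as.vector(h2d %*% w$W3) + w$b3
  list(scores = .sigmoid(logits), zc = zc, zh = zh, zb = zb, mu = mu, v = v,
       pool = pool, argm = argm, h1 = h1, h2 = h2, h2d = h2d)
}

#' Train the off-target CNN
#'
#' Binary cross-entropy objective minimised with Adam over minibatches;
#' batch-norm running statistics (momentum 0.9) are used at inference.
#' Fully deterministic for a fixed config seed.
#'
#' @param config a \code{\link{cnn_config}}.
#' @param data output of \code{\link{build_training_set}} (or any list with
#'   \code{x} n x 23 x 4 and \code{labels} in \{0,1\}).
#' @return object of class \code{cnn_model} with \code{history}
#'   (data.table: epoch, loss, accuracy on the full training set in
#'   inference mode after each epoch). \code{epochs = 0} returns the
#'   untrained model with an empty history.
#' @export
cnn_train <- function(config, data) {
  stopifnot(inherits(config, "cnn_config"))
  y <- as.numeric(data$labels)
  if (length(unique(y)) < 2L)
    stop("training data must contain both labels", call. = FALSE)
  n <- dim(data$x)[1]
  k <- config$kernel_size; n_win <- 23L - k + 1L; f <- config$conv_filters
  xc_all <- .im2col(data$x, k)
  with_seed(config$seed, {
    w <- .cnn_init(config)
    adam <- list(); t_step <- 0
    b1a <- 0.9; b2a <- 0.999; eps_a <- 1e-8; lr <- config$learning_rate
    upd <- function(name, grad) {
      if (is.null(adam[[name]]))
        adam[[name]] <<- list(m = grad * 0, v = grad * 0)
      st <- adam[[name]]
      st$m <- b1a * st$m + (1 - b1a) * grad
      st$v <- b2a * st$v + (1 - b2a) * grad^2
      adam[[name]] <<- st
      mh <- st$m / (1 - b1a^t_step); vh <- st$v / (1 - b2a^t_step)
      w[[name]] <<- w[[name]] - lr * mh / (sqrt(vh) + eps_a)
    }
    hist_loss <- numeric(config$epochs)
    hist_acc <- numeric(config$epochs)
    if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      for (bs in seq(1L, n, by = config$batch_size)) {
        idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
        nb <- length(idx)
        rows <- as.vector(vapply(idx, function(i)
          ((i - 1L) * n_win + 1L):(i * n_win), integer(n_win)))
        xc <- xc_all[rows, , drop = FALSE]
        yb <- y[idx]
        mask <- matrix((runif(nb * 23L) >= config$dropout_rate) /
                         (1 - config$dropout_rate), nb, 23L)
        fw <- .cnn_forward(w, xc, nb, n_win, training = TRUE,
                           drop_mask = mask)
        # running BN stats
        w$run_mean <- 0.9 * w$run_mean + 0.1 * fw$mu
        w$run_var <- 0.9 * w$run_var + 0.1 * fw$v
        t_step <- t_step + 1
        # --- backprop ---
        dlog <- (fw$scores - yb) / nb                       # nb
        dW3 <- t(fw$h2d) %*% dlog; db3 <- sum(dlog)
        dh2 <- (dlog %*% t(w$W3)) * mask * (fw$h2 > 0)
        dW2 <- t(fw$h1) %*% dh2; db2 <- colSums(dh2)
        dh1 <- (dh2 %*% t(w$W2)) * (fw$h1 > 0)
        dW1 <- t(fw$pool) %*% dh1; db1 <- colSums(dh1)
        dpool <- dh1 %*% t(w$W1)                            # nb x f
        da <- matrix(0, nb * n_win, f)
        rws <- (rep(seq_len(nb), times = f) - 1L) * n_win + as.vector(fw$argm)
        da[cbind(rws, rep(seq_len(f), each = nb))] <- as.vector(dpool)
        dzb <- da * (fw$zb > 0)
        dgamma <- colSums(dzb * fw$zh); dbeta <- colSums(dzb)
        dzh <- sweep(dzb, 2, w$gamma, "*")
        inv_sd <- 1 / sqrt(fw$v + 1e-5)
        dzc <- sweep(dzh, 2, colMeans(dzh)) -
          fw$zh * matrix(colMeans(dzh * fw$zh), nrow(dzh), f, byrow = TRUE)
        dzc <- sweep(dzc, 2, inv_sd, "*")
        dWc <- t(xc) %*% dzc
        upd("Wc", dWc); upd("gamma", dgamma); upd("beta", dbeta)
        upd("W1", dW1); upd("b1", db1)
        upd("W2", dW2); upd("b2", db2)
        upd("W3", dW3); upd("b3", db3)
      }
      # epoch metrics on the full set, inference mode
      fw <- .cnn_forward(w, xc_all, n, n_win, training = FALSE)
      p <- pmin(pmax(fw$scores, 1e-12), 1 - 1e-12)
      hist_loss[ep] <- -mean(y * log(p) + (1 - y) * log(1 - p))
      hist_acc[ep] <- mean((fw$scores > 0.5) == (y == 1))
    }
    structure(list(weights = w, config = config,
                   history = data.table(epoch = seq_len(config$epochs),
                                        loss = hist_loss,
                                        accuracy = hist_acc)),
              class = "cnn_model")
  })
}

#' Score 23-nt sites with a trained model
#' @param model a \code{cnn_model}.
#' @param sequences character vector of 23-mers, or an n x 23 x 4 array.
#' @return numeric sigmoid scores in [0, 1].
#' @export
cnn_predict <- function(model, sequences) {
  stopifnot(inherits(model, "cnn_model"))
  x <- if (is.character(sequences)) {
    a <- array(0, dim = c(length(sequences), 23L, 4L))
    for (i in seq_along(sequences)) a[i, , ] <- encode_site(sequences[i])
    a
  } else sequences
  n <- dim(x)[1]
  if (n == 0L) return(numeric())
  k <- model$config$kernel_size
  fw <- .cnn_forward(model$weights, .im2col(x, k), n, 23L - k + 1L,
                     training = FALSE)
  fw$scores
}

#' Rank candidate sites by sigmoid score
#'
#' @param model a trained \code{cnn_model}.
#' @param candidates table from \code{\link{enumerate_candidates}} (built
#'   with the same "< 8 mismatches" retrieval rule the model expects).
#' @return candidates with appended \code{score} and \code{rank} columns,
#'   sorted by descending score; ties broken by (chrom, start).
#' @export
predict_rank <- function(model, candidates) {
  cand <- as.data.table(candidates)
  if (nrow(cand) == 0L) {
    cand[, `:=`(score = numeric(), rank = integer())]
    return(cand[])
  }
  cand <- copy(cand)
  cand[, score := cnn_predict(model, sequence_23)]
  setorder(cand, -score, chrom, start)
  cand[, rank := .I]
  cand[]
}

#' Recall-at-rank curve
#'
#' For each rank cutoff k, the number of true off-targets among the top-k
#' predictions. Truth sites are identified by (chrom, start, strand); truths
#' absent from the candidate list are flagged and never recovered.
#'
#' @param ranked output of \code{\link{predict_rank}}.
#' @param truth table with chrom, start, strand of the true sites.
#' @return list(curve = data.table(rank, recovered), n_truth,
#'   missing_truths).
#' @export
recall_at_rank <- function(ranked, truth) {
  r <- as.data.table(ranked)
  tr <- unique(as.data.table(truth)[, .(chrom, start, strand)])
  key_r <- paste(r$chrom, r$start, r$strand)
  key_t <- paste(tr$chrom, tr$start, tr$strand)
  missing <- setdiff(key_t, key_r)
  if (length(missing))
    warning(length(missing), " truth site(s) absent from candidates",
            call. = FALSE)
  hit <- key_r %in% key_t
  list(curve = data.table(rank = seq_len(nrow(r)), recovered = cumsum(hit)),
       n_truth = length(key_t), missing_truths = length(missing))
}

#' Area under the ROC curve via the rank statistic
#' @param scores numeric prediction scores.
#' @param labels 0/1 truth labels.
#' @return AUROC in [0, 1].
#' @export
rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Save / load a trained model as plain text (JSON weights)
#' @param model a \code{cnn_model}.
#' @param path output .json path.
#' @export
write_cnn_model <- function(model, path) {
  w <- model$weights
  ser <- lapply(w, function(x) if (is.matrix(x))
    list(dim = dim(x), data = as.vector(x)) else list(data = as.numeric(x)))
  jsonlite::write_json(list(weights = ser, config = unclass(model$config),
                            history = model$history),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cnn_model
#' @export
read_cnn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- lapply(obj$weights, function(e) {
    if (!is.null(e$dim) && length(e$dim)) matrix(e$data, e$dim[1], e$dim[2])
    else as.numeric(e$data)
  })
  cfg <- do.call(cnn_config, obj$config[names(formals(cnn_config))])
  structure(list(weights = w, config = cfg,
                 history = as.data.table(obj$history)),
            class = "cnn_model")
}
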