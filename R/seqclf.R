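#' One-hot encode DNA sequences
#'
#' @param seqs Character vector of equal-length sequences.
#' @return Numeric array `N x L x 4` (channels A, C, G, T); positions with
#'   any other letter are all-zero.
#' @examples
#' one_hot("ACGT")[1, , ]
#' @export
one_hot <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) abort("sequences must have equal length.")
  n <- length(seqs)
  code <- as.integer(charToRaw(paste(toupper(seqs), collapse = "")))
  x <- array(0, dim = c(n, L, 4), dimnames = list(NULL, NULL, DNA_BASES))
  codes <- c(A = 65L, C = 67L, G = 71L, T = 84L)
  pos <- rep(seq_len(L), times = n)
  idx <- rep(seq_len(n), each = L)
  for (b in seq_along(codes)) {
    hit <- code == codes[b]
    x[cbind(idx[hit], pos[hit], b)] <- 1
  }
  x
}

#' Extract fixed-width one-hot windows around cluster midpoints
#'
#' Builds the balanced training set for enzyme attribution: positive
#' windows centred on one enzyme's cluster midpoints, negative windows on
#' clusters from the other enzymes, subsampled without replacement to
#' match the positive count. Windows extending past either sequence end
#' are dropped.
#'
#' @param positives,negatives Cluster tibbles (`ref`, `start`, `end`).
#' @param reference Named character vector, DNAStringSet or FASTA path.
#' @param width Window width in bp (default 200).
#' @param seed Seed for negative subsampling.
#' @return Tibble of class `clf_windows`: `label` (1/0), `ref`, `start`,
#'   `end`, `seq`; the one-hot encoding is computed at training time with
#'   [one_hot()].
#' @export
make_windows <- function(positives, negatives, reference, width = 200,
                         seed = 1L) {
  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- read_reference_fasta(reference)
  }
  reference <- as_reference(reference)
  if (width > max(nchar(reference))) {
    abort("`width` exceeds every reference length.",
          class = "stamper_input_error")
  }
  half <- width %/% 2
  cut_windows <- function(cl, label) {
    if (nrow(cl) == 0) return(tibble())
    mid <- floor((cl$start + cl$end) / 2)
    start <- mid - half
    end <- start + width
    ok <- start >= 0 & end <= nchar(reference)[cl$ref]
    s0 <- start[ok]
    e0 <- end[ok]
    rf <- cl$ref[ok]
    tibble(label = label, ref = rf, start = s0, end = e0,
           seq = substr(reference[rf], s0 + 1, e0))
  }
  pos <- cut_windows(positives, 1L)
  neg <- cut_windows(negatives, 0L)
  if (nrow(neg) > nrow(pos)) {
    keep <- with_seed(seed, sample.int(nrow(neg), nrow(pos)))
    neg <- neg[sort(keep), , drop = FALSE]
  }
  out <- bind_rows(pos, neg)
  class(out) <- c("clf_windows", class(out))
  out
}

# ---- compact two-layer 1-D CNN, base matrix ops ------------------------

#' @noRd
im2col_rows <- function(n, L, fw) {
  # global row indices of sliding windows over n stacked length-L signals
  Lw <- L - fw + 1
  base <- rep(seq_len(Lw), times = n) + rep((seq_len(n) - 1) * L, each = Lw)
  outer(base, 0:(fw - 1), `+`)
}

#' @noRd
cnn_init <- function(fw, f1, f2, seed) {
  with_seed(seed, list(
    W1 = matrix(rnorm(fw * 4 * f1, sd = sqrt(2 / (fw * 4))), fw * 4, f1),
    b1 = numeric(f1),
    W2 = matrix(rnorm(fw * f1 * f2, sd = sqrt(2 / (fw * f1))), fw * f1, f2),
    b2 = numeric(f2),
    w3 = matrix(rnorm(f2, sd = sqrt(1 / f2)), f2, 1),
    b3 = 0
  ))
}

#' @noRd
cnn_forward <- function(par, P1, R2, n, L1, L2, fw, keep = FALSE) {
  f1 <- ncol(par$W1); f2 <- ncol(par$W2)
  Z1 <- sweep(P1 %*% par$W1, 2, par$b1, `+`)
  A1 <- pmax(Z1, 0)
  tmp <- A1[as.vector(R2), , drop = FALSE]
  P2 <- matrix(array(tmp, c(nrow(R2), fw, f1)), nrow(R2), fw * f1)
  Z2 <- sweep(P2 %*% par$W2, 2, par$b2, `+`)
  A2 <- pmax(Z2, 0)
  arr <- array(A2, c(L2, n, f2))
  amax <- apply(arr, c(2, 3), which.max)
  pooled <- apply(arr, c(2, 3), max)
  score <- drop(pooled %*% par$w3) + par$b3
  out <- list(p = stats::plogis(score), score = score)
  if (keep) {
    out <- c(out, list(Z1 = Z1, P2 = P2, Z2 = Z2, amax = amax,
                       pooled = pooled))
  }
  out
}

#' @noRd
cnn_backward <- function(par, fw, P1, R2, n, L2, fwd, y) {
  f1 <- ncol(par$W1); f2 <- ncol(par$W2)
  dz3 <- matrix((fwd$p - y) / n, n, 1)
  g <- list(w3 = t(fwd$pooled) %*% dz3, b3 = sum(dz3))
  dmax <- dz3 %*% t(par$w3)                       # n x f2
  dA2 <- matrix(0, n * L2, f2)
  rows <- as.vector((seq_len(n) - 1) * L2 + fwd$amax)
  dA2[cbind(rows, rep(seq_len(f2), each = n))] <- as.vector(dmax)
  dZ2 <- dA2 * (fwd$Z2 > 0)
  g$W2 <- t(fwd$P2) %*% dZ2
  g$b2 <- colSums(dZ2)
  dP2 <- dZ2 %*% t(par$W2)
  dA1 <- matrix(0, nrow(fwd$Z1), f1)
  for (j in seq_len(fw)) {
    q <- j + (seq_len(f1) - 1) * fw
    dA1[R2[, j], ] <- dA1[R2[, j], ] + dP2[, q, drop = FALSE]
  }
  dZ1 <- dA1 * (fwd$Z1 > 0)
  g$W1 <- t(P1) %*% dZ1
  g$b1 <- colSums(dZ1)
  g
}

#' @noRd
cnn_prepare <- function(x, fw) {
  n <- dim(x)[1]; L <- dim(x)[2]
  # stack samples: rows (sample-major) x 4 channels
  X <- matrix(aperm(x, c(2, 1, 3)), n * L, 4)
  R1 <- im2col_rows(n, L, fw)
  tmp <- X[as.vector(R1), , drop = FALSE]
  P1 <- matrix(array(tmp, c(nrow(R1), fw, 4)), nrow(R1), fw * 4)
  L1 <- L - fw + 1
  R2 <- im2col_rows(n, L1, fw)
  list(P1 = P1, R2 = R2, n = n, L1 = L1, L2 = L1 - fw + 1)
}

#' @noRd
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the two-layer convolutional edit-cluster classifier
#'
#' Fits a compact 1-D convolutional network (two convolution layers of
#' `filters` filters of width `filter_width` with ReLU activations, global
#' max pooling, and a single sigmoid output) to distinguish which enzyme
#' produced a cluster from its surrounding sequence. Training minimises
#' binary cross-entropy with full-batch Adam and stops early once the
#' validation loss has improved by less than `tol` for `patience`
#' consecutive epochs. The split is stratified by label and every source
#' of randomness is seeded, so identical inputs and seed reproduce the
#' reported AUC.
#'
#' @param windows A [make_windows()] tibble (`label`, `seq`).
#' @param split_fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @param filters,filter_width Convolution layer size (defaults 16 and 8).
#' @param lr Adam learning rate.
#' @param max_epochs Maximum training epochs.
#' @param patience,tol Early-stopping contract (see above).
#' @param min_epochs Epochs to run before early stopping can trigger
#'   (lets the validation loss settle past its initial fluctuation).
#' @return An object of class `stamper_cnn`: fitted parameters, `width`,
#'   `history` (per-epoch train/validation loss), `auc_test`, `split`
#'   indices, and `seed`. [glance()] summarises, [tidy()] returns the
#'   training curve, `predict()` scores new sequences.
#' @export
train_classifier <- function(windows, split_fractions = c(0.7, 0.15, 0.15),
                             seed = 1L, filters = 16, filter_width = 8,
                             lr = 0.01, max_epochs = 150, patience = 5,
                             tol = 1e-4, min_epochs = 20) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8)
  y <- windows$label
  n <- length(y)
  idx <- with_seed(child_seed(seed, 1), {
    assign_split <- function(ii) {
      ii <- sample(ii)
      k1 <- round(length(ii) * split_fractions[1])
      k2 <- round(length(ii) * split_fractions[2])
      list(train = ii[seq_len(k1)],
           validation = ii[k1 + seq_len(k2)],
           test = ii[-seq_len(k1 + k2)])
    }
    a <- assign_split(which(y == 1))
    b <- assign_split(which(y == 0))
    purrr::map2(a, b, c)
  })
  for (s in names(idx)) {
    if (length(unique(y[idx[[s]]])) < 2) {
      abort(paste0("split '", s, "' contains a single class."),
            class = "stamper_input_error")
    }
  }

  x <- one_hot(windows$seq)
  L <- dim(x)[2]
  fw <- filter_width
  prep <- lapply(idx, function(ii) cnn_prepare(x[ii, , , drop = FALSE], fw))
  ys <- lapply(idx, function(ii) y[ii])

  par <- cnn_init(fw, filters, filters, child_seed(seed, 2))
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  best <- list(par = par, val = Inf, epoch = 0)
  stall <- 0
  history <- list()
  tr <- prep$train
  for (epoch in seq_len(max_epochs)) {
    fwd <- cnn_forward(par, tr$P1, tr$R2, tr$n, tr$L1, tr$L2, fw,
                       keep = TRUE)
    g <- cnn_backward(par, fw, tr$P1, tr$R2, tr$n, tr$L2, fwd, ys$train)
    for (nm in names(par)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
      mh <- m[[nm]] / (1 - beta1^epoch)
      vh <- v[[nm]] / (1 - beta2^epoch)
      par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
    val <- cnn_forward(par, prep$validation$P1, prep$validation$R2,
                       prep$validation$n, prep$validation$L1,
                       prep$validation$L2, fw)
    vl <- bce_loss(val$p, ys$validation)
    history[[epoch]] <- tibble(epoch = epoch,
                               train_loss = bce_loss(fwd$p, ys$train),
                               val_loss = vl)
    if (vl < best$val - tol) {
      best <- list(par = par, val = vl, epoch = epoch)
      stall <- 0
    } else {
      stall <- stall + 1
      if (epoch >= min_epochs && stall >= patience) break
    }
  }

  model <- structure(list(
    par = best$par, width = L, filters = filters, filter_width = fw,
    history = bind_rows(history), best_epoch = best$epoch,
    val_loss = best$val, seed = seed, split = idx
  ), class = "stamper_cnn")
  te <- prep$test
  p_test <- cnn_forward(best$par, te$P1, te$R2, te$n, te$L1, te$L2, fw)$p
  model$auc_test <- auc_rank(p_test, ys$test)
  model
}

#' @export
print.stamper_cnn <- function(x, ...) {
  cat(sprintf(
    "<stamper_cnn> %d-bp windows, 2x(%d filters, width %d); %d epochs (best %d), val loss %.4f, test AUC %.3f\n",
    x$width, x$filters, x$filter_width, max(x$history$epoch), x$best_epoch,
    x$val_loss, x$auc_test))
  invisible(x)
}

#' Score sequences with a trained classifier
#'
#' @param object A `stamper_cnn`.
#' @param windows A [make_windows()] tibble, or a character vector of
#'   sequences of the model's window width.
#' @param ... Unused.
#' @return Numeric vector of per-window scores in (0, 1).
#' @export
predict.stamper_cnn <- function(object, windows, ...) {
  seqs <- if (is.character(windows)) windows else windows$seq
  if (any(nchar(seqs) != object$width)) {
    abort("window width does not match the model.",
          class = "stamper_input_error")
  }
  x <- one_hot(seqs)
  pr <- cnn_prepare(x, object$filter_width)
  cnn_forward(object$par, pr$P1, pr$R2, pr$n, pr$L1, pr$L2,
              object$filter_width)$p
}

#' Evaluate a trained classifier on another window set
#'
#' Scores the windows with no retraining and returns the AUC — e.g. a
#' model trained on free-editor clusters evaluated on fusion clusters.
#'
#' @param model A `stamper_cnn`.
#' @param windows A labelled [make_windows()] tibble.
#' @return AUC in `[0, 1]`.
#' @export
cross_evaluate <- function(model, windows) {
  auc_rank(predict(model, windows), windows$label)
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUC; ties handled by midranks.
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes required for AUC.")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
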