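#' Hyperparameters for the dense text classifiers
#'
#' Defaults: embedding dimension 32, one hidden layer of 64 rectified
#' units, Adam (lr 1e-3), 10 epochs, batch size 32, 10% validation
#' split.  The output head is sigmoid + binary cross-entropy for a
#' 1-node model and softmax + categorical cross-entropy otherwise.
#'
#' @param embedding_dim Embedding vector length per token.
#' @param hidden Hidden-layer width.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param val_split Fraction of entries held out for the training
#'   history (not used for weight updates).
#' @param max_len Token-sequence pad length.
#' @return A list of hyperparameters.
#' @export
nlp_hyper <- function(embedding_dim = 32L, hidden = 64L, epochs = 10L,
                      batch_size = 32L, lr = 1e-3, val_split = 0.1,
                      max_len = 40L) {
  list(embedding_dim = embedding_dim, hidden = hidden, epochs = epochs,
       batch_size = batch_size, lr = lr, val_split = val_split,
       max_len = max_len)
}

# --- internal dense network ------------------------------------------------

# Embedding lookup + flatten for a batch of id rows (B x L) -> B x (L*d).
.embed_flatten <- function(E, ids) {
  idx <- as.vector(t(ids)) + 1L           # position-major within sample
  emb <- E[idx, , drop = FALSE]           # (B*L) x d
  matrix(as.vector(t(emb)), nrow = nrow(ids), byrow = TRUE)
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# Train an embedding -> flatten -> dense(relu) -> dense head network by
# minibatch backprop with Adam.  n_out == 1 gives a sigmoid head trained
# on binary cross-entropy; n_out > 1 a softmax head on categorical
# cross-entropy.  y is 0/1 for binary, class index 1..K otherwise.
train_dense_net <- function(x, y, vocab_size, n_out, hyper, seed) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  L <- ncol(x)
  d <- hyper$embedding_dim
  h <- hyper$hidden
  set.seed(seed)
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  params <- list(
    E  = matrix(stats::runif(vocab_size * d, -0.05, 0.05), vocab_size, d),
    W1 = glorot(L * d, h), b1 = rep(0, h),
    W2 = glorot(h, n_out), b2 = rep(0, n_out)
  )
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  b1c <- 0.9; b2c <- 0.999; eps <- 1e-8
  step <- 0

  n <- nrow(x)
  perm <- sample.int(n)
  n_val <- floor(n * hyper$val_split)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))

  forward <- function(p, ids) {
    Xf <- .embed_flatten(p$E, ids)
    H <- Xf %*% p$W1
    H <- sweep(H, 2, p$b1, `+`)
    H[H < 0] <- 0
    Z <- sweep(H %*% p$W2, 2, p$b2, `+`)
    P <- if (n_out == 1) 1 / (1 + exp(-Z)) else .softmax_rows(Z)
    list(Xf = Xf, H = H, P = P)
  }
  loss_of <- function(P, yb) {
    eps0 <- 1e-12
    if (n_out == 1) {
      -mean(yb * log(P + eps0) + (1 - yb) * log(1 - P + eps0))
    } else {
      -mean(log(P[cbind(seq_along(yb), yb)] + eps0))
    }
  }

  for (epoch in seq_len(hyper$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    batches <- split(ord, ceiling(seq_along(ord) / hyper$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      ids <- x[b, , drop = FALSE]
      yb <- y[b]
      B <- length(b)
      fw <- forward(params, ids)
      epoch_loss <- epoch_loss + loss_of(fw$P, yb) * B
      # gradient of mean cross-entropy wrt logits
      dZ <- if (n_out == 1) {
        matrix(fw$P - yb, ncol = 1) / B
      } else {
        D <- fw$P
        D[cbind(seq_len(B), yb)] <- D[cbind(seq_len(B), yb)] - 1
        D / B
      }
      grads <- list()
      grads$W2 <- crossprod(fw$H, dZ)
      grads$b2 <- colSums(dZ)
      dH <- dZ %*% t(params$W2)
      dH[fw$H <= 0] <- 0
      grads$W1 <- crossprod(fw$Xf, dH)
      grads$b1 <- colSums(dH)
      dXf <- dH %*% t(params$W1)
      dEmb <- matrix(as.vector(t(dXf)), ncol = hyper$embedding_dim,
                     byrow = TRUE)
      idx <- as.vector(t(ids)) + 1L
      gE <- rowsum(dEmb, group = idx)
      GE <- params$E * 0
      GE[as.integer(rownames(gE)), ] <- gE
      grads$E <- GE
      # Adam update
      step <- step + 1
      for (nm in names(params)) {
        adam_m[[nm]] <- b1c * adam_m[[nm]] + (1 - b1c) * grads[[nm]]
        adam_v[[nm]] <- b2c * adam_v[[nm]] + (1 - b2c) * grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1c^step)
        vhat <- adam_v[[nm]] / (1 - b2c^step)
        params[[nm]] <- params[[nm]] - hyper$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_loss <- NA_real_; val_acc <- NA_real_
    if (length(val_idx)) {
      fv <- forward(params, x[val_idx, , drop = FALSE])
      yv <- y[val_idx]
      val_loss <- loss_of(fv$P, yv)
      pred <- if (n_out == 1) as.integer(fv$P[, 1] > 0.5)
              else max.col(fv$P, ties.method = "first")
      val_acc <- mean(pred == yv)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = epoch_loss / length(tr_idx),
      val_loss = val_loss, val_acc = val_acc))
  }
  structure(list(params = params, n_out = n_out, hyper = hyper,
                 seed = seed, history = history),
            class = "sig_dense_net")
}

# Predict probabilities from a fitted dense net for an id matrix.
predict_dense_net <- function(model, x) {
  p <- model$params
  Xf <- .embed_flatten(p$E, x)
  H <- sweep(Xf %*% p$W1, 2, p$b1, `+`)
  H[H < 0] <- 0
  Z <- sweep(H %*% p$W2, 2, p$b2, `+`)
  if (model$n_out == 1) as.vector(1 / (1 + exp(-Z))) else .softmax_rows(Z)
}

# --- public model surface --------------------------------------------------

#' Train the informativeness model (stage 1)
#'
#' A densely connected network trained by back-propagation that outputs
#' the probability that a dosing text is non-informative (inadequate to
#' determine daily dosage).  Texts pass through an embedding layer, a
#' flattening layer, one hidden layer and a 1-node sigmoid output.
#'
#' @param texts Character vector of (titration-split) entry texts.
#' @param informative Logical gold labels (TRUE = informative).
#' @param vocab Vocabulary built from the training corpus.
#' @param hyper Hyperparameters ([nlp_hyper()]).
#' @param seed Integer seed; training is deterministic given
#'   (data, hyper, seed).
#' @return An object of class `nlp1_model` carrying the network, the
#'   vocabulary and the per-epoch training history.
#' @export
train_nlp1 <- function(texts, informative, vocab, hyper = nlp_hyper(),
                       seed = 1L) {
  stopifnot(length(texts) == length(informative))
  if (length(unique(informative)) < 2)
    stop("training data must contain both informative and non-informative texts")
  x <- encode_corpus(normalize_text(texts), vocab, hyper$max_len)
  y <- as.numeric(!informative)   # predicts P(non-informative)
  net <- train_dense_net(x, y, vocab$size, 1L, hyper, seed)
  structure(list(net = net, vocab = vocab, hyper = hyper),
            class = "nlp1_model")
}

#' Train the dosage-class model (stage 2)
#'
#' Same architecture as stage 1 with a 16-node softmax output over the
#' daily-dosage classes of [dosage_codec()].  Trained on informative
#' entries only; classes absent from the training data remain
#' representable (probability near 0).
#'
#' @param texts Entry texts (informative only).
#' @param dosage_class Gold class labels (codec labels).
#' @param vocab Vocabulary built from the training corpus.
#' @param hyper Hyperparameters.
#' @param seed Integer seed.
#' @param codec Dosage-class codec.
#' @return An object of class `nlp2_model`.
#' @export
train_nlp2 <- function(texts, dosage_class, vocab, hyper = nlp_hyper(),
                       seed = 1L, codec = dosage_codec()) {
  stopifnot(length(texts) == length(dosage_class))
  y <- match(dosage_class, codec$labels)
  if (anyNA(y)) stop("unknown dosage class label in training data")
  if (length(unique(y)) < 2)
    stop("training data must contain at least 2 dosage classes")
  x <- encode_corpus(normalize_text(texts), vocab, hyper$max_len)
  net <- train_dense_net(x, y, vocab$size, length(codec$labels), hyper, seed)
  structure(list(net = net, vocab = vocab, hyper = hyper, codec = codec),
            class = "nlp2_model")
}

#' Two-stage dosage classification with 0.5 thresholds
#'
#' Applies the decision cascade: texts with stage-1 probability of
#' non-informativeness above `threshold` are left unresolved for the
#' fallback step; the rest get stage-2 class probabilities, and the
#' highest-probability class is accepted only when it reaches
#' `threshold` — otherwise the entry is likewise unresolved.  Ties in
#' the argmax are broken toward the lower dosage class (minimum-dosage
#' convention).  Probability exactly 0.5 counts as informative in stage
#' 1 and as confident in stage 2.
#'
#' @param texts Character vector of entry texts.
#' @param nlp1 A [train_nlp1()] model.
#' @param nlp2 A [train_nlp2()] model (same vocabulary).
#' @param threshold Decision threshold (default 0.5).
#' @return A data.frame with `p_noninformative`, `final_class`,
#'   `pills_per_day`, `max_class_prob` and `source`
#'   (`"nlp2"`/`"unresolved"`); the 16-column class-probability matrix
#'   is attached as attribute `class_probs`.
#' @export
classify_entries <- function(texts, nlp1, nlp2, threshold = 0.5) {
  if (!identical(nlp1$vocab$index, nlp2$vocab$index))
    stop("nlp1 and nlp2 were trained with different vocabularies")
  toks <- normalize_text(texts)
  x1 <- encode_corpus(toks, nlp1$vocab, nlp1$hyper$max_len)
  p_non <- predict_dense_net(nlp1$net, x1)
  x2 <- encode_corpus(toks, nlp2$vocab, nlp2$hyper$max_len)
  probs <- predict_dense_net(nlp2$net, x2)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  colnames(probs) <- nlp2$codec$labels
  best <- max.col(probs, ties.method = "first")   # columns in ascending dose
  best_p <- probs[cbind(seq_len(nrow(probs)), best)]
  informative <- p_non <= threshold
  confident <- best_p >= threshold
  resolved <- informative & confident
  out <- data.frame(
    p_noninformative = p_non,
    final_class = ifelse(resolved, nlp2$codec$labels[best], NA_character_),
    pills_per_day = ifelse(resolved, nlp2$codec$pills[best], NA_real_),
    max_class_prob = best_p,
    source = ifelse(resolved, "nlp2", "unresolved"),
    stringsAsFactors = FALSE
  )
  attr(out, "class_probs") <- probs
  out
}
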