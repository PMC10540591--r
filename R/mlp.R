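# Small feed-forward multilayer perceptron classifier with two hidden
# layers, softmax output over the 8 stress levels, ReLU activations and
# full-batch Adam on the cross-entropy loss. Written in plain matrix
# algebra; initialization and training are fully determined by the seed.

mlp_init <- function(p, hidden, n_out, seed) {
  sizes <- c(p, hidden, n_out)
  with_seed(seed, {
    W <- list(); b <- list()
    for (i in seq_len(length(sizes) - 1)) {
      # He-style scaling keeps early activations well-conditioned
      W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1],
                                    sd = sqrt(2 / sizes[i])),
                       nrow = sizes[i])
      b[[i]] <- rep(0, sizes[i + 1])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- list(X)
  for (i in seq_len(L)) {
    Z <- sweep(A[[i]] %*% par$W[[i]], 2, par$b[[i]], "+")
    A[[i + 1]] <- if (i < L) pmax(Z, 0) else Z
  }
  logits <- A[[L + 1]]
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(A = A, probs = probs)
}

mlp_train <- function(X, y_onehot, hidden = c(32, 16), epochs = 200,
                      lr = 1e-3, weight_decay = 1e-4, seed = 1) {
  n <- nrow(X); p <- ncol(X); n_out <- ncol(y_onehot)
  par <- mlp_init(p, hidden, n_out, seed)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(epochs)) {
    fw <- mlp_forward(par, X)
    delta <- (fw$probs - y_onehot) / n
    gW <- vector("list", L); gb <- vector("list", L)
    for (i in L:1) {
      gW[[i]] <- t(fw$A[[i]]) %*% delta + weight_decay * par$W[[i]]
      gb[[i]] <- colSums(delta)
      if (i > 1)
        delta <- (delta %*% t(par$W[[i]])) * (fw$A[[i]] > 0)
    }
    corr1 <- 1 - b1^ep; corr2 <- 1 - b2^ep
    for (i in seq_len(L)) {
      mW[[i]] <- b1 * mW[[i]] + (1 - b1) * gW[[i]]
      vW[[i]] <- b2 * vW[[i]] + (1 - b2) * gW[[i]]^2
      mb[[i]] <- b1 * mb[[i]] + (1 - b1) * gb[[i]]
      vb[[i]] <- b2 * vb[[i]] + (1 - b2) * gb[[i]]^2
      par$W[[i]] <- par$W[[i]] - lr * (mW[[i]] / corr1) /
        (sqrt(vW[[i]] / corr2) + eps)
      par$b[[i]] <- par$b[[i]] - lr * (mb[[i]] / corr1) /
        (sqrt(vb[[i]] / corr2) + eps)
    }
  }
  par
}

mlp_predict <- function(par, X, classes) {
  fw <- mlp_forward(par, X)
  classes[max.col(fw$probs, ties.method = "first")]
}
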