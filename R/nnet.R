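#' @title Minimal multilayer-perceptron toolkit
#'
#' @description Internal feed-forward network primitives used by the
#' diagnostic model, the product-of-experts VAE and the actor-critic
#' networks. Networks are plain lists of weight matrices and bias vectors;
#' all operations are vectorized over rows (samples). A "k-layer MLP" has k
#' weight layers, i.e. k-1 hidden ReLU layers followed by a linear output
#' (softmax / sigmoid heads are applied by the caller).
#'
#' @name nnet-toolkit
#' @keywords internal
NULL

#' Create a new MLP
#'
#' @param sizes integer vector of layer widths, input first, output last;
#'   a network with `length(sizes) - 1` weight layers.
#' @param seed integer seed for He-scaled Gaussian initialization.
#' @return an object of class `idx_mlp`.
#' @keywords internal
mlp_new <- function(sizes, seed = 1L) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  set.seed(seed)
  n_layers <- length(sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l], ncol = sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(W = W, b = b, sizes = as.integer(sizes)), class = "idx_mlp")
}

#' Forward pass
#'
#' @param net an `idx_mlp`.
#' @param X numeric matrix, samples in rows (`ncol(X) == sizes[1]`).
#' @return list with `out` (linear output matrix) and `cache` (activations
#'   per layer, consumed by [mlp_backward()]).
#' @keywords internal
mlp_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  stopifnot(ncol(X) == net$sizes[1L])
  n_layers <- length(net$W)
  A <- vector("list", n_layers + 1L)
  A[[1L]] <- X
  for (l in seq_len(n_layers)) {
    Z <- A[[l]] %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], `+`)
    A[[l + 1L]] <- if (l < n_layers) pmax(Z, 0) else Z
  }
  list(out = A[[n_layers + 1L]], cache = A)
}

#' Backward pass
#'
#' @param net an `idx_mlp`.
#' @param cache activation list from [mlp_forward()].
#' @param d_out gradient of the loss w.r.t. the linear output (same shape).
#' @return list with `grads` (dW, db per layer) and `d_in` (gradient w.r.t.
#'   the input matrix, for nesting networks).
#' @keywords internal
mlp_backward <- function(net, cache, d_out) {
  n_layers <- length(net$W)
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  delta <- d_out
  for (l in rev(seq_len(n_layers))) {
    dW[[l]] <- crossprod(cache[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (cache[[l]] > 0)
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(grads = list(dW = dW, db = db), d_in = delta)
}

#' Adam optimizer state for an MLP
#' @keywords internal
adam_new <- function(net) {
  zeros_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zeros_like(net$W), vW = zeros_like(net$W),
       mb = zeros_like(net$b), vb = zeros_like(net$b), t = 0L)
}

#' One Adam update
#'
#' @param net `idx_mlp`; `grads` from [mlp_backward()]; `opt` from
#'   [adam_new()]; `lr` learning rate.
#' @return list `net`, `opt` (updated).
#' @keywords internal
adam_step <- function(net, grads, opt, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (opt$mW[[l]] / bc1) / (sqrt(opt$vW[[l]] / bc2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grads$db[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (opt$mb[[l]] / bc1) / (sqrt(opt$vb[[l]] / bc2) + eps)
  }
  list(net = net, opt = opt)
}

#' Flatten all parameters of an MLP to one numeric vector
#'
#' Used for exact (bitwise) frozen-parameter comparisons.
#' @keywords internal
mlp_params <- function(net) {
  c(unlist(lapply(net$W, as.numeric)), unlist(lapply(net$b, as.numeric)))
}

#' Row-wise softmax with optional legality mask
#'
#' @param Z logits matrix; `mask` optional logical matrix of the same shape;
#'   masked-out entries get probability exactly 0.
#' @return matrix of row distributions summing to 1.
#' @keywords internal
softmax_rows <- function(Z, mask = NULL) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  if (!is.null(mask)) {
    if (is.null(dim(mask))) mask <- matrix(mask, nrow = nrow(Z), ncol = ncol(Z), byrow = TRUE)
    if (any(rowSums(mask) == 0)) stop("softmax_rows: a row has no legal entry")
    Z[!mask] <- -Inf
  }
  m <- apply(Z, 1L, max)
  E <- exp(Z - m)
  E[!is.finite(E)] <- 0
  P <- E / rowSums(E)
  P
}

#' Numerically safe log
#' @keywords internal
safe_log <- function(p, eps = 1e-12) log(pmax(p, eps))

#' Cross-entropy loss and logit gradient for softmax output
#'
#' @param logits matrix n x K; `y` integer class index per row (1-based).
#' @return list `loss` (mean CE in nats), `probs`, `d_logits` (already
#'   divided by n).
#' @keywords internal
softmax_xent <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(safe_log(P[idx]))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, probs = P, d_logits = G / n)
}
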