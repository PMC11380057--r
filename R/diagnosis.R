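#' State encoding and the diagnostic prediction model
#'
#' A state vector encodes a partial observation of one patient: for every
#' catalog feature (fixed lexicographic order) a value block — length 1 for
#' binary (1 = positive), a one-hot of length 3 for tri-level
#' (low/normal/high), length k for categorical — plus a per-feature observed
#' bit, plus a demographic block (age/100, gender one-hot male/female/
#' unknown). An unobserved feature has bit 0 and an all-zero block; a feature
#' asked but never recorded by the physician (`asked_negative`) has bit 1
#' and an all-zero block, which for binary coincides with an explicit
#' negative finding.
#'
#' The diagnostic model `D` is a 5-layer MLP with softmax output trained
#' with cross-entropy on state vectors whose features are randomly masked
#' (per sample, each feature kept with probability drawn uniformly from
#' `mask_range`) so that it handles the arbitrary partial observations the
#' inquiry agent induces.
#'
#' @name diagnosis
NULL

ASKED_NEGATIVE <- "asked_negative"

#' Column layout of the state vector for a catalog
#'
#' @param cat a `FeatureCatalog`.
#' @return list: `block_cols` (per-feature value-block column indices),
#'   `bit_cols` (observed-bit column per feature), `demo_cols`, `total`.
#' @export
state_layout <- function(cat) {
  fids <- feature_ids(cat)
  block_len <- ifelse(cat$features$domain == "binary", 1L,
                      lengths(cat$levels))
  ends <- cumsum(block_len)
  starts <- ends - block_len + 1L
  block_cols <- lapply(seq_along(fids), function(i) starts[i]:ends[i])
  names(block_cols) <- fids
  n_val <- ends[length(ends)]
  bit_cols <- n_val + seq_along(fids)
  names(bit_cols) <- fids
  demo_cols <- n_val + length(fids) + 1:4
  list(block_cols = block_cols, bit_cols = bit_cols, demo_cols = demo_cols,
       total = n_val + length(fids) + 4L, n_val = n_val)
}

encode_value_block <- function(value, feature, cat) {
  i <- match(feature, feature_ids(cat))
  dom <- cat$features$domain[i]
  if (identical(value, ASKED_NEGATIVE)) {
    return(numeric(if (dom == "binary") 1L else length(cat$levels[[i]])))
  }
  if (dom == "binary") {
    return(as.numeric(value %in% c(1, "1", TRUE)))
  }
  block <- numeric(length(cat$levels[[i]]))
  j <- match(as.character(value), cat$levels[[i]])
  if (is.na(j)) stop("value out of domain for ", feature, ": ", value)
  block[j] <- 1
  block
}

#' Encode one partial observation as a state vector
#'
#' @param observations named list feature id -> value (possibly the
#'   `asked_negative` sentinel).
#' @param demographics list with `age` and `gender` (or NULL for zeros).
#' @param cat a `FeatureCatalog`; `layout` optional precomputed
#'   [state_layout()].
#' @return numeric vector of length `layout$total`.
#' @export
encode_state <- function(observations, demographics, cat, layout = state_layout(cat)) {
  v <- numeric(layout$total)
  for (f in names(observations)) {
    if (is.null(layout$block_cols[[f]])) stop("unknown feature: ", f)
    v[layout$block_cols[[f]]] <- encode_value_block(observations[[f]], f, cat)
    v[layout$bit_cols[[f]]] <- 1
  }
  if (!is.null(demographics)) {
    g <- match(demographics$gender, GENDERS)
    demo <- c(min(demographics$age, 100) / 100,
              as.numeric(seq_len(3) == g))
    v[layout$demo_cols] <- demo
  }
  v
}

#' Encode many observations into a matrix (rows = samples)
#' @keywords internal
encode_states <- function(obs_list, demo_list, cat, layout = state_layout(cat)) {
  t(vapply(seq_along(obs_list), function(i) {
    encode_state(obs_list[[i]], demo_list[[i]], cat, layout)
  }, numeric(layout$total)))
}

record_state <- function(rec) {
  list(obs = rec$extracted, demo = list(age = rec$age, gender = rec$gender))
}

#' Full-observation design matrix and labels for a record set
#' @keywords internal
records_design <- function(records, cat, layout = state_layout(cat)) {
  X <- encode_states(lapply(records, function(r) r$extracted),
                     lapply(records, function(r) list(age = r$age, gender = r$gender)),
                     cat, layout)
  y <- vapply(records, function(r) as.integer(r$diagnosis$label_id), integer(1))
  list(X = X, y = y)
}

mask_states <- function(X, layout, keep_range = c(0.2, 1.0),
                        sentinel_range = c(0, 0.5)) {
  n <- nrow(X)
  keep_p <- stats::runif(n, keep_range[1], keep_range[2])
  n_feat <- length(layout$bit_cols)
  keep <- matrix(stats::runif(n * n_feat), n, n_feat) < keep_p
  # inquiry states also contain asked-but-unrecorded features (observed bit
  # set, value block zero); expose D to them during training
  sent_p <- stats::runif(n, sentinel_range[1], sentinel_range[2])
  sentinel <- matrix(stats::runif(n * n_feat), n, n_feat) < sent_p
  for (j in seq_len(n_feat)) {
    drop <- !keep[, j] | X[, layout$bit_cols[j]] == 0
    if (any(drop)) {
      X[drop, layout$block_cols[[j]]] <- 0
      X[drop, layout$bit_cols[j]] <- ifelse(sentinel[drop, j], 1, 0)
    }
  }
  X
}

#' Train the diagnostic prediction model
#'
#' @param records training records (full extracted observations).
#' @param cat the `FeatureCatalog`.
#' @param n_classes number of diagnosis label classes.
#' @param hidden hidden width (the model is a 5-layer MLP: 4 hidden ReLU
#'   layers of this width plus the softmax output layer).
#' @param epochs,batch_size,lr optimizer settings (Adam).
#' @param mask_range per-sample feature keep-probability range used to mimic
#'   partial observation during training; NULL disables masking.
#' @param val_records optional validation records for early model selection
#'   (best-epoch weights kept by validation cross-entropy).
#' @param seed integer seed (training is deterministic given it).
#' @return a `DiagnosisModel`.
#' @export
train_diagnosis_model <- function(records, cat, n_classes,
                                  hidden = 64L, epochs = 30L,
                                  batch_size = 64L, lr = 1e-3,
                                  mask_range = c(0.2, 1.0),
                                  val_records = NULL, seed = 1L) {
  layout <- state_layout(cat)
  d <- records_design(records, cat, layout)
  if (length(unique(d$y)) < 2) stop("need at least 2 classes to train")
  net <- mlp_new(c(layout$total, rep(hidden, 4L), n_classes), seed = seed)
  opt <- adam_new(net)
  set.seed(seed + 1L)
  val <- if (!is.null(val_records)) records_design(val_records, cat, layout)
  best <- list(net = net, loss = Inf)
  n <- nrow(d$X)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      Xb <- d$X[idx, , drop = FALSE]
      if (!is.null(mask_range)) Xb <- mask_states(Xb, layout, mask_range)
      fw <- mlp_forward(net, Xb)
      ce <- softmax_xent(fw$out, d$y[idx])
      bw <- mlp_backward(net, fw$cache, ce$d_logits)
      st <- adam_step(net, bw$grads, opt, lr = lr)
      net <- st$net; opt <- st$opt
    }
    ep_loss <- if (!is.null(val)) {
      softmax_xent(mlp_forward(net, val$X)$out, val$y)$loss
    } else {
      softmax_xent(mlp_forward(net, d$X)$out, d$y)$loss
    }
    history[ep] <- ep_loss
    if (ep_loss < best$loss) best <- list(net = net, loss = ep_loss)
  }
  structure(list(net = best$net, n_classes = as.integer(n_classes),
                 layout = layout, catalog_hash = catalog_hash(cat),
                 val_loss = best$loss, history = history,
                 hyper = list(hidden = hidden, epochs = epochs,
                              batch_size = batch_size, lr = lr,
                              mask_range = mask_range, seed = seed)),
            class = "DiagnosisModel")
}

#' Content hash of a catalog (serialization-based)
#' @keywords internal
catalog_hash <- function(cat) {
  sum(as.numeric(utils::head(serialize(catalog_to_list(cat), NULL), 1e6)) *
        seq_len(min(length(serialize(catalog_to_list(cat), NULL)), 1e6))) %% 2^31
}

#' @export
print.DiagnosisModel <- function(x, ...) {
  cat(sprintf("DiagnosisModel: 5-layer MLP (%d -> %s -> %d), val CE %.4f\n",
              x$layout$total, paste(rep(x$hyper$hidden, 4), collapse = "-"),
              x$n_classes, x$val_loss))
  invisible(x)
}

#' Predict diagnosis probabilities for encoded states
#'
#' @param D a `DiagnosisModel`.
#' @param states numeric vector (one state) or matrix (rows = states).
#' @return probability matrix, rows summing to 1.
#' @export
predict_proba <- function(D, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  if (ncol(states) != D$layout$total) stop("state dimension mismatch")
  softmax_rows(mlp_forward(D$net, states)$out)
}

#' Fine-tune D on agent-collected terminal observations
#'
#' Used between training epochs of the inquiry agent: the partial
#' observation sets present when the agent terminated, with their reference
#' labels, adapt D to the agent's own inquiry patterns. The buffer
#' cross-entropy is measured before and after; if an update would leave the
#' buffer loss higher than before, the pre-update weights are kept, so the
#' post-fine-tuning loss on the buffer never exceeds the pre-loss.
#'
#' @param D a `DiagnosisModel`.
#' @param states encoded terminal states (matrix); `labels` class indices.
#' @param epochs,lr,batch_size fine-tuning settings.
#' @return the updated `DiagnosisModel`, with attribute `finetune_loss`
#'   holding `c(pre, post)`; empty buffer returns D unchanged with a warning.
#' @export
finetune_on_collected <- function(D, states, labels, epochs = 3L,
                                  lr = 3e-4, batch_size = 64L) {
  if (is.null(states) || NROW(states) == 0) {
    warning("empty fine-tuning buffer; model unchanged")
    return(D)
  }
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  net <- D$net
  opt <- adam_new(net)
  pre <- softmax_xent(mlp_forward(net, states)$out, labels)$loss
  n <- nrow(states)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      fw <- mlp_forward(net, states[idx, , drop = FALSE])
      ce <- softmax_xent(fw$out, labels[idx])
      bw <- mlp_backward(net, fw$cache, ce$d_logits)
      st <- adam_step(net, bw$grads, opt, lr = lr)
      net <- st$net; opt <- st$opt
    }
  }
  post <- softmax_xent(mlp_forward(net, states)$out, labels)$loss
  if (post <= pre) D$net <- net else post <- pre
  attr(D, "finetune_loss") <- c(pre = pre, post = post)
  D
}

#' Built-in simulated-physician baseline model families
#'
#' Each family is a list with `name`, `fit(X, y, seed)` and
#' `predict(model, X)` returning a probability matrix over classes 1..K.
#' @param n_classes number of label classes.
#' @export
baseline_families <- function(n_classes) {
  list(
    logistic = list(
      name = "multinomial logistic regression",
      fit = function(X, y, seed) {
        df <- data.frame(y = factor(y, levels = seq_len(n_classes)), X)
        utils::capture.output(
          m <- nnet::multinom(y ~ ., data = df, MaxNWts = 1e5, maxit = 200,
                              trace = FALSE))
        m
      },
      predict = function(model, X) {
        p <- stats::predict(model, newdata = data.frame(X), type = "probs")
        if (is.null(dim(p))) p <- cbind(1 - p, p)
        as.matrix(p)
      }),
    random_forest = list(
      name = "random forest",
      fit = function(X, y, seed) {
        ranger::ranger(x = data.frame(X),
                       y = factor(y, levels = seq_len(n_classes)),
                       probability = TRUE, num.trees = 300,
                       num.threads = 1, seed = seed)
      },
      predict = function(model, X) {
        as.matrix(stats::predict(model, data = data.frame(X),
                                 num.threads = 1)$predictions)
      })
  )
}

#' Train and select the simulated-physician baseline classifier
#'
#' Fits each candidate family on full extracted-feature state vectors and
#' keeps the one with the best validation macro AUROC. This classifier
#' approximates the recorded physicians' diagnostic ability and serves as
#' the reference the agent is compared against.
#'
#' @param train_records,val_records record lists.
#' @param cat the `FeatureCatalog`; `n_classes` label count.
#' @param families candidate families (default [baseline_families()]);
#'   at least 2.
#' @param seed integer seed.
#' @return list with `model`, `family`, `predict(states)` closure,
#'   `val_auroc`, and a machine-readable `card` describing the selection.
#' @export
train_physician_baseline <- function(train_records, val_records, cat, n_classes,
                                     families = baseline_families(n_classes),
                                     seed = 1L) {
  if (length(families) < 2) stop("need at least 2 candidate families")
  layout <- state_layout(cat)
  tr <- records_design(train_records, cat, layout)
  va <- records_design(val_records, cat, layout)
  results <- lapply(names(families), function(fn) {
    fam <- families[[fn]]
    model <- try(fam$fit(tr$X, tr$y, seed), silent = TRUE)
    if (inherits(model, "try-error")) return(list(id = fn, auroc = -Inf))
    probs <- fam$predict(model, va$X)
    list(id = fn, model = model, fam = fam,
         auroc = macro_auroc(probs, va$y, n_classes))
  })
  aurocs <- vapply(results, function(r) r$auroc, numeric(1))
  if (all(!is.finite(aurocs))) stop("all baseline families failed to fit")
  best <- results[[which.max(aurocs)]]
  fam <- best$fam
  model <- best$model
  list(model = model, family = best$id,
       predict = function(states) fam$predict(model, states),
       val_auroc = best$auroc,
       card = list(selected = best$id, name = fam$name,
                   candidates = stats::setNames(aurocs, names(families)),
                   criterion = "validation macro AUROC", seed = seed))
}
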