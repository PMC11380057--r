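test_that("state encoding follows the declared block conventions", {
  cat_ <- toy_catalog()
  layout <- state_layout(cat_)

  v0 <- encode_state(list(), NULL, cat_, layout)
  expect_equal(v0, numeric(layout$total))

  v1 <- encode_state(list(smh_a = "1"), NULL, cat_, layout)
  expect_equal(v1[layout$block_cols[["smh_a"]]], 1)
  expect_equal(v1[layout$bit_cols[["smh_a"]]], 1)

  v2 <- encode_state(list(ae_f = "high"), NULL, cat_, layout)
  expect_equal(v2[layout$block_cols[["ae_f"]]], c(0, 0, 1))

  v3 <- encode_state(list(pe_d = "asked_negative"),
                     list(age = 50, gender = "male"), cat_, layout)
  expect_equal(v3[layout$block_cols[["pe_d"]]], 0)
  expect_equal(v3[layout$bit_cols[["pe_d"]]], 1)
  expect_equal(v3[layout$demo_cols], c(0.5, 1, 0, 0))

  expect_error(encode_state(list(nope = "1"), NULL, cat_, layout), "unknown feature")
})

test_that("diagnosis training is seed-deterministic and errors on one class", {
  b <- shared_bench()
  recs <- b$splits$train[1:80]
  d1 <- train_diagnosis_model(recs, b$world$catalog, nrow(b$world$labels),
                              hidden = 16L, epochs = 2L, seed = 9L)
  d2 <- train_diagnosis_model(recs, b$world$catalog, nrow(b$world$labels),
                              hidden = 16L, epochs = 2L, seed = 9L)
  expect_identical(d1$history, d2$history)
  expect_identical(mlp_params(d1$net), mlp_params(d2$net))

  one_class <- Filter(function(r) r$diagnosis$label_id == 1L, b$splits$train)
  expect_error(train_diagnosis_model(one_class, b$world$catalog,
                                     nrow(b$world$labels), epochs = 1L),
               "2 classes")
})

test_that("label-permuted training collapses to chance accuracy", {
  b <- shared_bench()
  K <- nrow(b$world$labels)
  set.seed(41)
  shuffled <- lapply(b$splits$train, function(r) {
    r$diagnosis$label_id <- sample.int(K, 1L)
    r
  })
  D0 <- train_diagnosis_model(shuffled, b$world$catalog, K, hidden = 24L,
                              epochs = 5L, seed = 42L)
  td <- inquirydx:::records_design(b$splits$test, b$world$catalog)
  pred <- max.col(predict_proba(D0, td$X), ties.method = "first")
  acc <- mean(pred == td$y)
  se <- sqrt((1 / K) * (1 - 1 / K) / length(td$y))
  expect_lt(abs(acc - 1 / K), 3 * se + 0.02)
})

test_that("probability outputs are valid, repeatable, and permutation-equivariant", {
  D <- shared_D()
  b <- shared_bench()
  td <- inquirydx:::records_design(b$splits$test[1:30], b$world$catalog)
  P <- predict_proba(D, td$X)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  expect_identical(P, predict_proba(D, td$X))
  expect_error(predict_proba(D, td$X[, -1]), "dimension")

  # permuting the output layer permutes the predicted distribution
  perm <- c(3, 1, 2, seq_len(D$n_classes)[-(1:3)])
  D2 <- D
  L <- length(D2$net$W)
  D2$net$W[[L]] <- D2$net$W[[L]][, perm]
  D2$net$b[[L]] <- D2$net$b[[L]][perm]
  expect_equal(predict_proba(D2, td$X), P[, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("mean cross-entropy falls as more signature features are observed", {
  bench <- memo("bench_sig4",
                make_benchmark(world_config(sig_smh = 3, seed = 104L), 700L))
  w <- bench$world
  D <- train_diagnosis_model(bench$splits$train, w$catalog, nrow(w$labels),
                             hidden = 48L, epochs = 10L, seed = 105L)
  layout <- state_layout(w$catalog)
  recs <- bench$splits$test
  ce_at <- function(k) {
    states <- t(vapply(recs, function(r) {
      cons <- unlist(r$diagnosis$constituents)
      sig <- unique(unlist(c(w$signatures$smh[cons], w$signatures$pe[cons])))
      sig <- utils::head(intersect(sig, names(r$extracted)), k)
      obs <- r$extracted[sig]
      encode_state(obs, list(age = r$age, gender = r$gender), w$catalog, layout)
    }, numeric(layout$total)))
    y <- vapply(recs, function(r) as.integer(r$diagnosis$label_id), integer(1))
    P <- predict_proba(D, states)
    -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-12)))
  }
  ce <- c(ce_at(0), ce_at(2), ce_at(4))
  expect_true(all(diff(ce) < 0))
})

test_that("observing all of a class's signature features pins the prediction (Bayes check)", {
  bench <- memo("bench_sep95",
                make_benchmark(world_config(separability = 0.95, seed = 106L), 700L))
  w <- bench$world
  D <- train_diagnosis_model(bench$splits$train, w$catalog, nrow(w$labels),
                             hidden = 48L, epochs = 12L, seed = 107L)
  layout <- state_layout(w$catalog)
  c_idx <- 1L
  sig <- c(w$signatures$smh[["dis01"]], w$signatures$pe[["dis01"]])
  obs <- stats::setNames(as.list(rep("1", length(sig))), sig)
  # exact Bayes posterior over labels given these observed binary values
  lik <- apply(w$theta[, sig, drop = FALSE], 1L, prod)
  bayes <- lik * w$prior / sum(lik * w$prior)
  expect_equal(unname(which.max(bayes)), c_idx)

  set.seed(108)
  agree <- vapply(1:100, function(i) {
    r <- sample_record(w)
    s <- encode_state(obs, list(age = r$age, gender = r$gender), w$catalog, layout)
    which.max(predict_proba(D, s)[1, ]) == which.max(bayes)
  }, logical(1))
  expect_gte(sum(agree), 99)
})

test_that("fine-tuning never worsens buffer loss and no-ops on empty buffers", {
  D <- shared_D()
  b <- shared_bench()
  layout <- D$layout
  d <- inquirydx:::records_design(b$splits$validation, b$world$catalog, layout)

  D2 <- finetune_on_collected(D, d$X, d$y, epochs = 2L)
  fl <- attr(D2, "finetune_loss")
  expect_lte(fl[["post"]], fl[["pre"]])

  expect_warning(D3 <- finetune_on_collected(D, NULL, integer(0)), "empty")
  expect_identical(mlp_params(D3$net), mlp_params(D$net))
})

test_that("fine-tuning on SMH-only observations helps like-masked states", {
  D <- shared_D()
  b <- shared_bench()
  w <- b$world
  layout <- D$layout
  smh_only <- function(records) {
    obs <- lapply(records, function(r) {
      keep <- names(r$extracted)[stage_of(names(r$extracted), w$catalog) == "SMH"]
      r$extracted[keep]
    })
    demo <- lapply(records, function(r) list(age = r$age, gender = r$gender))
    list(X = inquirydx:::encode_states(obs, demo, w$catalog, layout),
         y = vapply(records, function(r) as.integer(r$diagnosis$label_id),
                    integer(1)))
  }
  buf <- smh_only(b$splits$train[1:300])
  val <- smh_only(b$splits$test)
  pre <- inquirydx:::softmax_xent(inquirydx:::mlp_forward(D$net, val$X)$out, val$y)$loss
  set.seed(109)
  D2 <- finetune_on_collected(D, buf$X, buf$y, epochs = 3L)
  post <- inquirydx:::softmax_xent(inquirydx:::mlp_forward(D2$net, val$X)$out, val$y)$loss
  expect_lte(post, pre)
})

test_that("baseline selection picks the informative family and meets the learnability gate", {
  b <- shared_bench()
  K <- nrow(b$world$labels)
  const_family <- list(
    name = "constant predictor",
    fit = function(X, y, seed) table(y),
    predict = function(model, X) {
      matrix(1 / K, nrow(X), K)
    })
  fams <- c(baseline_families(K)["logistic"], list(constant = const_family))
  bl <- train_physician_baseline(b$splits$train, b$splits$validation,
                                 b$world$catalog, K, families = fams, seed = 7L)
  expect_equal(bl$family, "logistic")
  expect_named(bl$card, c("selected", "name", "candidates", "criterion", "seed"))

  expect_error(train_physician_baseline(b$splits$train, b$splits$validation,
                                        b$world$catalog, K,
                                        families = fams["logistic"]),
               "at least 2")

  # learnability gate: full information on a separability-0.9 world
  bl_full <- memo("baseline_full", train_physician_baseline(
    b$splits$train, b$splits$validation, b$world$catalog, K, seed = 8L))
  td <- inquirydx:::records_design(b$splits$test, b$world$catalog)
  expect_gte(macro_auroc(bl_full$predict(td$X), td$y, K), 0.95)
})
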