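test_that("expert encoding yields one deterministic expert per observed feature", {
  cat_ <- toy_catalog()
  vae <- poe_vae_new(cat_, d_z = 8L, d_e = 8L, hidden = 16L, seed = 1L)
  e0 <- encode_experts(vae, list(), cat_)
  expect_equal(nrow(e0$mu), 0L)

  obs <- list(smh_a = "1", ae_f = "high", pe_d = "0")
  ek <- encode_experts(vae, obs, cat_)
  expect_equal(nrow(ek$mu), 3L)
  expect_true(all(ek$V > 0))
  expect_identical(ek, encode_experts(vae, obs, cat_))
})

test_that("product of experts matches the precision-weighted closed form", {
  d <- 4L
  one <- list(mu = matrix(2, 1, d), V = matrix(1, 1, d))
  post <- product_of_experts(one)
  expect_equal(post$mu, rep(1, d))
  expect_equal(post$var, rep(0.5, d))

  two <- list(mu = matrix(0, 2, d), V = matrix(1, 2, d))
  expect_equal(product_of_experts(two)$var, rep(1 / 3, d))

  empty <- list(mu = matrix(0, 0, d), V = matrix(0, 0, d))
  expect_identical(product_of_experts(empty, prior_mu = rep(0, d),
                                      prior_var = rep(1, d)),
                   list(mu = rep(0, d), var = rep(1, d)))

  bad <- list(mu = matrix(0, 1, d), V = matrix(-1, 1, d))
  expect_error(product_of_experts(bad), "variance")

  # fuzz against an independent scalar-loop transcription
  set.seed(2)
  for (i in 1:100) {
    k <- sample(0:5, 1)
    mu <- matrix(stats::rnorm(k * d), k, d)
    V <- matrix(stats::runif(k * d, 0.1, 3), k, d)
    got <- product_of_experts(list(mu = mu, V = V))
    for (j in seq_len(d)) {
      prec <- 1
      wsum <- 0
      for (e in seq_len(k)) {
        prec <- prec + 1 / V[e, j]
        wsum <- wsum + mu[e, j] / V[e, j]
      }
      expect_lt(abs(got$var[j] - 1 / prec), 1e-9)
      expect_lt(abs(got$mu[j] - wsum / prec), 1e-9)
    }
  }
})

test_that("posterior sampling degenerates to the mean, is seeded, and obeys the CLT", {
  post <- list(mu = rep(1, 8), var = rep(1e-14, 8))
  set.seed(3)
  expect_lt(max(abs(sample_posterior(post) - post$mu)), 1e-6)

  post2 <- list(mu = rep(1, 1), var = rep(0.5, 1))
  set.seed(4); z1 <- sample_posterior(post2)
  set.seed(4); z2 <- sample_posterior(post2)
  expect_identical(z1, z2)

  set.seed(5)
  draws <- replicate(10000, sample_posterior(post2))
  expect_lt(abs(mean(draws) - 1), 3 * sqrt(0.5 / 10000))
})

test_that("KL to the prior is non-negative and zero exactly at the prior", {
  expect_equal(kl_to_prior(rep(0, 16), rep(1, 16)), 0)
  e0 <- product_of_experts(list(mu = matrix(0, 0, 16), V = matrix(0, 0, 16)),
                           prior_mu = rep(0, 16), prior_var = rep(1, 16))
  expect_lt(abs(kl_to_prior(e0$mu, e0$var)), 1e-9)
  set.seed(6)
  for (i in 1:50) {
    expect_gte(kl_to_prior(stats::rnorm(8), stats::runif(8, 0.05, 4)), 0)
  }
})

test_that("decoded outputs are valid per-feature distributions", {
  cat_ <- toy_catalog()
  vae <- poe_vae_new(cat_, d_z = 8L, d_e = 8L, hidden = 16L, seed = 7L)
  set.seed(8)
  Z <- matrix(stats::rnorm(5 * 8, sd = 2), 5, 8)
  P <- vae_decode(vae, Z)
  layout <- vae$layout
  for (f in names(layout$block_cols)) {
    cols <- layout$block_cols[[f]]
    if (vae$domains[[f]] == "binary") {
      expect_true(all(P[, cols] >= 0 & P[, cols] <= 1))
    } else {
      expect_equal(rowSums(P[, cols, drop = FALSE]), rep(1, 5), tolerance = 1e-6)
    }
  }
  expect_identical(P, vae_decode(vae, Z))
  expect_error(vae_decode(vae, matrix(0, 1, 5)), "dimension")
})

test_that("VAE training improves the ELBO and is reproducible under a seed", {
  b <- shared_bench()
  recs <- b$splits$train[1:150]
  v1 <- train_vae(recs, b$world$catalog, d_z = 8L, d_e = 8L, hidden = 16L,
                  epochs = 5L, seed = 21L)
  expect_gte(v1$elbo_history[5], v1$elbo_history[1])

  v2 <- train_vae(recs, b$world$catalog, d_z = 8L, d_e = 8L, hidden = 16L,
                  epochs = 5L, seed = 21L)
  expect_identical(v1$elbo_history, v2$elbo_history)
})

test_that("imputation concentrates on a disease's features as its evidence accumulates", {
  b <- shared_bench()
  w <- b$world
  vae <- shared_vae()
  layout <- vae$layout
  sig_all <- c(w$signatures$smh[["dis01"]], w$signatures$pe[["dis01"]])
  target <- sig_all[length(sig_all)]
  given <- sig_all[-length(sig_all)]
  t_col <- layout$block_cols[[target]]

  p_target <- function(obs) {
    imp <- impute_unobserved(vae, obs, w$catalog, deterministic = TRUE)
    imp$probs[t_col]
  }
  p_marg <- p_target(list())
  obs1 <- stats::setNames(as.list(rep("1", 1)), given[1])
  obs2 <- stats::setNames(as.list(rep("1", length(given))), given)
  # deterministic imputation: same value for every case, so compare directly
  expect_gt(p_target(obs2), p_marg)
  expect_gt(p_target(obs2), p_target(obs1))
})

test_that("reconstruction of a held-out signature feature improves with conditioning", {
  b <- shared_bench()
  w <- b$world
  vae <- shared_vae()
  layout <- vae$layout
  set.seed(23)
  recs <- Filter(function(r) "dis01" %in% unlist(r$diagnosis$constituents),
                 sample_records(w, 1200L, seed = 24L))
  sig_all <- c(w$signatures$smh[["dis01"]], w$signatures$pe[["dis01"]])
  target <- sig_all[1]
  t_col <- layout$block_cols[[target]]
  p_marg <- impute_unobserved(vae, list(), w$catalog, deterministic = TRUE)$probs[t_col]
  cases <- utils::head(Filter(function(r) target %in% names(r$extracted) &&
                                r$extracted[[target]] == "1", recs), 200L)
  expect_gte(length(cases), 50L)
  p_cond <- vapply(cases, function(r) {
    obs <- r$extracted[setdiff(intersect(sig_all, names(r$extracted)), target)]
    impute_unobserved(vae, obs, w$catalog, deterministic = TRUE)$probs[t_col]
  }, numeric(1))
  expect_gt(mean(p_cond), p_marg)
})
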