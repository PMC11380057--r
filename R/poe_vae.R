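#' Product-of-experts variational autoencoder over feature vectors
#'
#' Generative model: latent `z` (spherical Gaussian prior) is decoded by a
#' 4-layer MLP into per-feature value distributions (sigmoid for binary
#' features, softmax over the level block for tri-level/categorical).
#' Each observed feature i contributes a Gaussian "expert" in latent space:
#' a shared 4-layer MLP encoder maps `c_i = [x_i, e_i]` — the feature's
#' one-hot value block padded to a common width, concatenated with a learned
#' per-feature embedding `e_i` — to a mean vector and a positive variance
#' vector (softplus with a floor). Arbitrary partial observations are
#' handled by combining the observed experts with the prior in closed form:
#' precisions add, means are precision-weighted. Defaults follow the
#' reference architecture: 64-dimensional latent and embeddings.
#'
#' @name poe-vae
NULL

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Create an untrained PoE-VAE for a catalog
#'
#' @param cat a `FeatureCatalog`.
#' @param d_z latent dimension (default 64).
#' @param d_e feature-embedding dimension (default 64).
#' @param hidden hidden width of encoder/decoder MLPs.
#' @param var_floor positive floor added to softplus-parameterized expert
#'   variances.
#' @param include_prior should the prior participate as an expert in the
#'   product (standard PoE-VAE practice)?
#' @param seed integer seed for initialization.
#' @return a `PoEVAE`.
#' @export
poe_vae_new <- function(cat, d_z = 64L, d_e = 64L, hidden = 64L,
                        var_floor = 1e-6, include_prior = TRUE, seed = 1L) {
  layout <- state_layout(cat)
  max_block <- max(lengths(layout$block_cols))
  # 4-layer MLPs: 3 hidden ReLU layers + linear output
  enc <- mlp_new(c(max_block + d_e, rep(hidden, 3L), 2L * d_z), seed = seed)
  # start experts sharp (softplus(-2) ~ 0.13) so the latent carries
  # information from the first updates and the posterior does not collapse
  enc$b[[length(enc$b)]][d_z + seq_len(d_z)] <- -2
  dec <- mlp_new(c(d_z, rep(hidden, 3L), layout$n_val), seed = seed + 1L)
  set.seed(seed + 2L)
  n_feat <- length(feature_ids(cat))
  embed <- matrix(stats::rnorm(n_feat * d_e, sd = 0.1), n_feat, d_e,
                  dimnames = list(feature_ids(cat), NULL))
  structure(list(enc = enc, dec = dec, embed = embed,
                 d_z = as.integer(d_z), d_e = as.integer(d_e),
                 max_block = max_block, layout = layout,
                 domains = stats::setNames(cat$features$domain, feature_ids(cat)),
                 var_floor = var_floor, include_prior = include_prior,
                 catalog_hash = catalog_hash(cat)),
            class = "PoEVAE")
}

#' @export
print.PoEVAE <- function(x, ...) {
  cat(sprintf("PoEVAE: z %d-d, embeddings %d-d, %d features, decoder out %d\n",
              x$d_z, x$d_e, nrow(x$embed), x$layout$n_val))
  invisible(x)
}

# rows of [padded value block, embedding] for a set of (feature, value) pairs
expert_inputs <- function(vae, features, values, cat) {
  k <- length(features)
  C <- matrix(0, k, vae$max_block + vae$d_e)
  for (i in seq_len(k)) {
    blk <- encode_value_block(values[[i]], features[i], cat)
    C[i, seq_along(blk)] <- blk
    C[i, vae$max_block + seq_len(vae$d_e)] <- vae$embed[features[i], ]
  }
  C
}

#' Encode observed features into Gaussian experts
#'
#' One expert per observed feature; deterministic. Zero observations yield
#' an empty expert set.
#'
#' @param vae a `PoEVAE`; `observations` named list feature -> value;
#'   `cat` the catalog.
#' @return list `features`, `mu` (k x d_z), `V` (k x d_z, all > 0).
#' @export
encode_experts <- function(vae, observations, cat) {
  feats <- names(observations)
  feats <- if (is.null(feats)) character(0) else sort(feats, method = "radix")
  if (!length(feats)) {
    return(list(features = character(0),
                mu = matrix(0, 0, vae$d_z), V = matrix(0, 0, vae$d_z)))
  }
  C <- expert_inputs(vae, feats, observations[feats], cat)
  out <- mlp_forward(vae$enc, C)$out
  mu <- out[, seq_len(vae$d_z), drop = FALSE]
  V <- softplus(out[, vae$d_z + seq_len(vae$d_z), drop = FALSE]) + vae$var_floor
  list(features = feats, mu = mu, V = V)
}

#' Combine Gaussian experts by product of experts
#'
#' Closed form for diagonal Gaussians: posterior precision is the sum of
#' expert precisions (plus the prior's when it participates); the posterior
#' mean is the precision-weighted mean. An empty expert set returns the
#' prior exactly.
#'
#' @param experts list as returned by [encode_experts()] (fields `mu`, `V`
#'   as k x d matrices).
#' @param prior_mu,prior_var prior mean/variance (scalars or d-vectors;
#'   default standard Gaussian).
#' @param include_prior include the prior as an expert (default TRUE; with
#'   FALSE the prior is still returned for an empty expert set).
#' @return list `mu`, `var` (d-vectors).
#' @export
product_of_experts <- function(experts, prior_mu = 0, prior_var = 1,
                               include_prior = TRUE) {
  k <- nrow(experts$mu)
  d <- if (is.matrix(experts$mu) && ncol(experts$mu) > 0) {
    ncol(experts$mu)
  } else {
    max(length(prior_mu), length(prior_var))
  }
  prior_mu <- rep_len(prior_mu, d)
  prior_var <- rep_len(prior_var, d)
  if (is.null(k) || k == 0) {
    return(list(mu = prior_mu, var = prior_var))
  }
  if (any(experts$V <= 0) || any(prior_var <= 0)) stop("non-positive variance")
  prec <- colSums(1 / experts$V)
  wmean <- colSums(experts$mu / experts$V)
  if (include_prior) {
    prec <- prec + 1 / prior_var
    wmean <- wmean + prior_mu / prior_var
  }
  list(mu = wmean / prec, var = 1 / prec)
}

#' Reparameterized sample from a diagonal Gaussian posterior
#'
#' @param posterior list `mu`, `var`; uses the current RNG state.
#' @return numeric vector `mu + sqrt(var) * eps`.
#' @export
sample_posterior <- function(posterior) {
  posterior$mu + sqrt(posterior$var) * stats::rnorm(length(posterior$mu))
}

#' KL divergence from a diagonal Gaussian to the standard spherical prior
#' @param mu,var mean/variance vectors.
#' @export
kl_to_prior <- function(mu, var) 0.5 * sum(var + mu^2 - 1 - log(var))

# turn linear decoder output into valid per-feature distributions
decode_activate <- function(vae, O) {
  P <- O
  for (f in names(vae$layout$block_cols)) {
    cols <- vae$layout$block_cols[[f]]
    if (vae$domains[[f]] == "binary") {
      P[, cols] <- 1 / (1 + exp(-O[, cols]))
    } else {
      P[, cols] <- softmax_rows(O[, cols, drop = FALSE])
    }
  }
  P
}

#' Decode latent vectors into per-feature reconstruction distributions
#'
#' @param vae a `PoEVAE`; `z` a d_z vector or matrix of rows.
#' @return matrix over value-block columns: binary columns are Bernoulli
#'   probabilities, tri-level/categorical blocks sum to 1.
#' @export
vae_decode <- function(vae, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != vae$d_z) stop("latent dimension mismatch")
  decode_activate(vae, mlp_forward(vae$dec, z)$out)
}

#' Impute unobserved features from a partial observation
#'
#' Composition encode -> product of experts -> sample (or posterior mean)
#' -> decode. The decoded vector over all features is what the actor
#' consumes; the posterior is also returned for the critic's latent input.
#'
#' @param vae a `PoEVAE`; `observations` named list; `cat` the catalog.
#' @param deterministic use the posterior mean instead of a sample.
#' @return list `probs` (decoded vector), `z`, `posterior`.
#' @export
impute_unobserved <- function(vae, observations, cat, deterministic = FALSE) {
  experts <- encode_experts(vae, observations, cat)
  post <- product_of_experts(experts, include_prior = vae$include_prior)
  z <- if (deterministic) post$mu else sample_posterior(post)
  list(probs = as.numeric(vae_decode(vae, z)), z = z, posterior = post)
}

# reconstruction log-likelihood and output-gradient for a batch.
# X: full value-block matrix (targets); obs_mask: n x n_feat observed flags.
recon_loss_grad <- function(vae, O, X, obs_mask) {
  n <- nrow(O)
  G <- matrix(0, n, ncol(O))
  ll <- numeric(n)
  fids <- names(vae$layout$block_cols)
  for (j in seq_along(fids)) {
    cols <- vae$layout$block_cols[[j]]
    w <- obs_mask[, j]
    if (!any(w)) next
    if (vae$domains[[j]] == "binary") {
      p <- 1 / (1 + exp(-O[, cols]))
      x <- X[, cols]
      ll <- ll + w * (x * safe_log(p) + (1 - x) * safe_log(1 - p))
      G[, cols] <- w * (p - x)
    } else {
      P <- softmax_rows(O[, cols, drop = FALSE])
      Xb <- X[, cols, drop = FALSE]
      ll <- ll + w * rowSums(Xb * safe_log(P))
      G[, cols] <- w * (P - Xb)
    }
  }
  list(ll = ll, d_out = G)
}

#' Train the PoE-VAE on patient records
#'
#' Optimizes the evidence lower bound: the reconstruction term over each
#' record's observed (extracted) features plus the KL of the PoE posterior
#' to the prior. Arbitrary partial observation during inquiry is simulated
#' by a dropout schedule: per sample a keep-probability is drawn uniformly
#' from `keep_range` and each observed feature is kept independently with
#' that probability (the reconstruction target remains the full observed
#' set). Gradients flow through the closed-form product of experts and the
#' reparameterized sample into the shared encoder and the feature
#' embeddings.
#'
#' @param records training records; `cat` the catalog.
#' @param d_z,d_e,hidden architecture (see [poe_vae_new()]).
#' @param epochs,batch_size,lr Adam settings.
#' @param keep_range dropout schedule bounds.
#' @param kl_warmup fraction of epochs over which the KL term is annealed
#'   linearly from 0 to `kl_weight`.
#' @param kl_weight weight of the KL term in the training objective.
#'   Down-weighting the KL (beta-style) is what lets the latent stay
#'   informative at this data scale: at full weight the optimizer collapses
#'   the posterior onto the prior (expert variances grow unboundedly and
#'   imputation degenerates to marginals). The reported ELBO is always the
#'   unweighted bound.
#' @param val_records optional records for a per-epoch validation ELBO.
#' @param seed integer seed.
#' @return a trained `PoEVAE` with `elbo_history` (training) and
#'   `val_elbo_history` attached.
#' @export
train_vae <- function(records, cat, d_z = 64L, d_e = 64L, hidden = 64L,
                      epochs = 20L, batch_size = 32L, lr = 1e-3,
                      keep_range = c(0.1, 1.0), kl_warmup = 0.3,
                      kl_weight = 0.1, val_records = NULL, seed = 1L) {
  stopifnot(length(records) > 0)
  vae <- poe_vae_new(cat, d_z = d_z, d_e = d_e, hidden = hidden, seed = seed)
  opt_enc <- adam_new(vae$enc)
  opt_dec <- adam_new(vae$dec)
  m_emb <- vae$embed * 0; v_emb <- vae$embed * 0; t_emb <- 0L

  fids <- names(vae$layout$block_cols)
  obs_sets <- lapply(records, function(r) r$extracted)
  set.seed(seed + 3L)
  n <- length(records)
  elbo_hist <- numeric(epochs)
  val_hist <- numeric(epochs)

  warm <- max(1L, floor(epochs * kl_warmup))
  for (ep in seq_len(epochs)) {
    beta <- kl_weight * min(1, ep / warm)
    perm <- sample.int(n)
    ep_elbo <- 0; ep_cnt <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      nb <- length(idx)
      # per-sample dropout of observed features
      kept <- lapply(idx, function(i) {
        feats <- names(obs_sets[[i]])
        kp <- stats::runif(1, keep_range[1], keep_range[2])
        feats[stats::runif(length(feats)) < kp]
      })
      step <- vae_batch_step(vae, obs_sets[idx], kept, cat, beta = beta)
      ep_elbo <- ep_elbo + step$elbo * nb; ep_cnt <- ep_cnt + nb

      st <- adam_step(vae$enc, step$enc_grads, opt_enc, lr = lr)
      vae$enc <- st$net; opt_enc <- st$opt
      st <- adam_step(vae$dec, step$dec_grads, opt_dec, lr = lr)
      vae$dec <- st$net; opt_dec <- st$opt
      # Adam on the embedding table
      t_emb <- t_emb + 1L
      g <- step$emb_grad
      m_emb <- 0.9 * m_emb + 0.1 * g
      v_emb <- 0.999 * v_emb + 0.001 * g^2
      vae$embed <- vae$embed - lr * (m_emb / (1 - 0.9^t_emb)) /
        (sqrt(v_emb / (1 - 0.999^t_emb)) + 1e-8)
    }
    elbo_hist[ep] <- ep_elbo / ep_cnt
    if (!is.null(val_records)) {
      val_hist[ep] <- vae_elbo(vae, val_records, cat)
    }
  }
  vae$elbo_history <- elbo_hist
  vae$val_elbo_history <- if (is.null(val_records)) NULL else val_hist
  vae
}

# one forward/backward pass over a minibatch; returns grads and mean ELBO.
# beta scales the KL term in the loss (annealing); the reported ELBO is
# always unscaled.
vae_batch_step <- function(vae, obs_sets, kept_sets, cat, beta = 1) {
  nb <- length(obs_sets)
  fids <- names(vae$layout$block_cols)
  d_z <- vae$d_z

  # stack (sample, kept feature) expert rows
  samp_idx <- integer(0); feat_names <- character(0); vals <- list()
  for (i in seq_len(nb)) {
    ks <- kept_sets[[i]]
    samp_idx <- c(samp_idx, rep(i, length(ks)))
    feat_names <- c(feat_names, ks)
    vals <- c(vals, obs_sets[[i]][ks])
  }
  has_experts <- length(samp_idx) > 0

  if (has_experts) {
    C <- expert_inputs(vae, feat_names, vals, cat)
    enc_fw <- mlp_forward(vae$enc, C)
    mu_i <- enc_fw$out[, seq_len(d_z), drop = FALSE]
    s_i <- enc_fw$out[, d_z + seq_len(d_z), drop = FALSE]
    V_i <- softplus(s_i) + vae$var_floor
    P_i <- 1 / V_i
    grp <- factor(samp_idx, levels = seq_len(nb))
    prec <- matrix(1, nb, d_z)            # prior precision
    wmean <- matrix(0, nb, d_z)           # prior mean 0
    agg_p <- rowsum(P_i, grp)             # empty groups are dropped
    rows <- as.integer(rownames(agg_p))
    prec[rows, ] <- prec[rows, ] + agg_p
    wmean[rows, ] <- rowsum(P_i * mu_i, grp)
  } else {
    prec <- matrix(1, nb, d_z)
    wmean <- matrix(0, nb, d_z)
  }
  mu_post <- wmean / prec
  V_post <- 1 / prec
  eps <- matrix(stats::rnorm(nb * d_z), nb, d_z)
  Z <- mu_post + sqrt(V_post) * eps

  # decode and reconstruction over all observed features
  dec_fw <- mlp_forward(vae$dec, Z)
  X <- matrix(0, nb, vae$layout$n_val)
  obs_mask <- matrix(FALSE, nb, length(fids))
  for (i in seq_len(nb)) {
    for (f in names(obs_sets[[i]])) {
      j <- match(f, fids)
      X[i, vae$layout$block_cols[[j]]] <- encode_value_block(obs_sets[[i]][[f]], f, cat)
      obs_mask[i, j] <- TRUE
    }
  }
  rec <- recon_loss_grad(vae, dec_fw$out, X, obs_mask)
  kl <- 0.5 * rowSums(V_post + mu_post^2 - 1 - log(V_post))
  elbo <- mean(rec$ll - kl)

  # --- backward (loss = -(ll - kl)/nb) ---
  dec_bw <- mlp_backward(vae$dec, dec_fw$cache, rec$d_out / nb)
  dZ <- dec_bw$d_in
  d_mu_post <- dZ + beta * mu_post / nb                # KL term: d/dmu = mu
  d_V_post <- dZ * eps / (2 * sqrt(V_post)) +
    beta * 0.5 * (1 - 1 / V_post) / nb

  enc_grads <- list(dW = lapply(vae$enc$W, function(w) w * 0),
                    db = lapply(vae$enc$b, function(b) b * 0))
  emb_grad <- vae$embed * 0
  if (has_experts) {
    # per-expert chain through the PoE closed form
    gm <- d_mu_post[samp_idx, , drop = FALSE]
    gv <- d_V_post[samp_idx, , drop = FALSE]
    Pm <- prec[samp_idx, , drop = FALSE]
    mu_p <- mu_post[samp_idx, , drop = FALSE]
    d_mu_i <- gm * P_i / Pm
    d_P_i <- gm * (mu_i - mu_p) / Pm - gv / Pm^2
    d_V_i <- d_P_i * (-1 / V_i^2)
    d_s_i <- d_V_i * (1 / (1 + exp(-s_i)))             # softplus'
    enc_bw <- mlp_backward(vae$enc, enc_fw$cache, cbind(d_mu_i, d_s_i))
    enc_grads <- enc_bw$grads
    d_emb_rows <- enc_bw$d_in[, vae$max_block + seq_len(vae$d_e), drop = FALSE]
    agg <- rowsum(d_emb_rows, factor(feat_names, levels = fids))
    keep <- rownames(agg)
    emb_grad[keep, ] <- emb_grad[keep, ] + agg
  }
  list(elbo = elbo, enc_grads = enc_grads, dec_grads = dec_bw$grads,
       emb_grad = emb_grad)
}

#' Mean ELBO of a record set under a fitted VAE (full observations, no dropout)
#' @param vae a `PoEVAE`; `records` record list; `cat` the catalog.
#' @export
vae_elbo <- function(vae, records, cat) {
  obs <- lapply(records, function(r) r$extracted)
  vals <- vapply(seq_along(obs), function(i) {
    imp <- impute_unobserved(vae, obs[[i]], cat, deterministic = TRUE)
    X <- matrix(0, 1, vae$layout$n_val)
    mask <- matrix(FALSE, 1, length(vae$layout$block_cols))
    fids <- names(vae$layout$block_cols)
    for (f in names(obs[[i]])) {
      j <- match(f, fids)
      X[1, vae$layout$block_cols[[j]]] <- encode_value_block(obs[[i]][[f]], f, cat)
      mask[1, j] <- TRUE
    }
    O <- mlp_forward(vae$dec, matrix(imp$z, 1))$out
    rec <- recon_loss_grad(vae, O, X, mask)
    rec$ll - kl_to_prior(imp$posterior$mu, imp$posterior$var)
  }, numeric(1))
  mean(vals)
}
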