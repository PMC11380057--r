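#' Actor-critic inquiry agent trained with PPO
#'
#' The actor nests the pretrained PoE-VAE: at each step the observed
#' features are encoded to the PoE posterior, a latent sample is decoded
#' into imputed distributions over all features, and that decoded vector —
#' concatenated with the current diagnostic confidence `D(s_t)` and the
#' budget ratio `n_t = t / N_T` — is mapped by a 2-layer MLP head with
#' masked softmax to the action space. The critic is a 5-layer MLP over
#' `[s_t, D(s_t), n_t, z_t]`. During PPO training only the nested VAE
#' decoder, the actor head and the critic receive gradients; the VAE encoder
#' and the feature embeddings stay frozen at their pretrained values.
#'
#' @name agent-ppo
NULL

#' PPO configuration
#'
#' Hyperparameters of the policy-optimization loop, all config-exposed with
#' standard defaults: clipped surrogate with clip ratio 0.2, generalized
#' advantage estimation (lambda 0.95), discount 0.99, 4 update epochs per
#' batch with per-batch advantage normalization, entropy coefficient 0.01.
#'
#' @param gamma,gae_lambda discount and GAE lambda, in (0, 1].
#' @param clip_ratio PPO clip parameter (> 0).
#' @param update_epochs gradient passes per collected batch.
#' @param entropy_coef entropy-bonus coefficient.
#' @param lr_actor,lr_critic Adam learning rates.
#' @param episodes_per_epoch rollout episodes collected per training epoch.
#' @param epochs training epochs.
#' @param seed integer seed for the whole training run.
#' @export
ppo_config <- function(gamma = 0.99, gae_lambda = 0.95, clip_ratio = 0.2,
                       update_epochs = 4L, entropy_coef = 0.01,
                       lr_actor = 3e-4, lr_critic = 1e-3,
                       episodes_per_epoch = 64L, epochs = 30L, seed = 1L) {
  stopifnot(clip_ratio > 0, gamma > 0, gamma <= 1, gae_lambda > 0, gae_lambda <= 1)
  structure(list(gamma = gamma, gae_lambda = gae_lambda,
                 clip_ratio = clip_ratio, update_epochs = as.integer(update_epochs),
                 entropy_coef = entropy_coef, lr_actor = lr_actor,
                 lr_critic = lr_critic,
                 episodes_per_epoch = as.integer(episodes_per_epoch),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "PPOConfig")
}

#' Create an untrained agent around a pretrained VAE
#'
#' @param vae a trained `PoEVAE`.
#' @param cat the `FeatureCatalog`; `n_classes` diagnosis label count.
#' @param head_hidden actor-head hidden width (2-layer MLP).
#' @param critic_hidden critic hidden width (5-layer MLP).
#' @param seed integer initialization seed.
#' @return an `InquiryAgent`.
#' @export
agent_new <- function(vae, cat, n_classes, head_hidden = 64L,
                      critic_hidden = 64L, seed = 1L) {
  actions <- action_table(cat)
  layout <- state_layout(cat)
  n_actions <- nrow(actions)
  head_in <- vae$layout$n_val + n_classes + 1L
  head <- mlp_new(c(head_in, head_hidden, n_actions), seed = seed)
  critic_in <- layout$total + n_classes + 1L + vae$d_z
  critic <- mlp_new(c(critic_in, rep(critic_hidden, 4L), 1L), seed = seed + 1L)
  structure(list(vae = vae, head = head, critic = critic,
                 actions = actions, layout = layout,
                 n_classes = as.integer(n_classes),
                 catalog_hash = vae$catalog_hash),
            class = "InquiryAgent")
}

#' @export
print.InquiryAgent <- function(x, ...) {
  cat(sprintf("InquiryAgent: %d actions, head %s, critic width %d, z %d-d\n",
              nrow(x$actions), paste(x$head$sizes, collapse = "-"),
              x$critic$sizes[2], x$vae$d_z))
  invisible(x)
}

#' Actor forward pass
#'
#' @param agent an `InquiryAgent`.
#' @param decoded decoded (imputed) feature matrix from the nested VAE,
#'   rows = states.
#' @param d_probs diagnostic confidence matrix `D(s_t)`; `n_t` budget-ratio
#'   vector; `mask` logical legality matrix (rows = states).
#' @return action probability matrix: masked entries exactly 0, rows sum
#'   to 1.
#' @export
actor_forward <- function(agent, decoded, d_probs, n_t, mask) {
  if (is.null(dim(decoded))) decoded <- matrix(decoded, nrow = 1L)
  if (is.null(dim(d_probs))) d_probs <- matrix(d_probs, nrow = 1L)
  if (is.null(dim(mask))) mask <- matrix(mask, nrow = 1L)
  X <- cbind(decoded, d_probs, n_t)
  softmax_rows(mlp_forward(agent$head, X)$out, mask)
}

#' Critic forward pass
#'
#' @param agent an `InquiryAgent`; `state_enc` encoded state matrix;
#'   `d_probs`, `n_t` as in [actor_forward()]; `z` posterior latent matrix.
#' @return numeric vector of state values.
#' @export
critic_forward <- function(agent, state_enc, d_probs, n_t, z) {
  if (is.null(dim(state_enc))) state_enc <- matrix(state_enc, nrow = 1L)
  if (is.null(dim(d_probs))) d_probs <- matrix(d_probs, nrow = 1L)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  as.numeric(mlp_forward(agent$critic, cbind(state_enc, d_probs, n_t, z))$out)
}

#' Collect rollouts from the current policy
#'
#' Runs episodes in lockstep over a set of records: actions are sampled
#' from the masked actor distribution (or taken greedily), transitions are
#' rewarded with the short-term information-gain reward and the long-term
#' termination reward, and the observation sets present at termination are
#' buffered for the diagnostic model's per-epoch fine-tuning. Forced
#' termination at the budget adds the long-term reward to the final step
#' exactly as if terminate had been chosen.
#'
#' @param agent an `InquiryAgent`; `D` a `DiagnosisModel`; `records` the
#'   episode records; `cat` the catalog; `reward_cfg` a [reward_config()].
#' @param deterministic greedy argmax actions (evaluation mode; ties break
#'   to the lowest action index) instead of sampling.
#' @param collect_transitions keep per-step tensors for PPO (disable for
#'   pure evaluation).
#' @return list `traces` (one `EpisodeTrace` per record), `transitions`
#'   (list of stacked tensors or NULL), `buffer` (terminal encoded states +
#'   labels).
#' @export
collect_rollouts <- function(agent, D, records, cat, reward_cfg,
                             deterministic = FALSE,
                             collect_transitions = TRUE) {
  n_ep <- length(records)
  actions <- agent$actions
  layout <- agent$layout
  term_idx <- which(actions$kind == "terminate")
  n_t_max <- reward_cfg$n_t_max
  y <- vapply(records, function(r) as.integer(r$diagnosis$label_id), integer(1))

  states <- lapply(records, env_reset, cat = cat, n_t_max = n_t_max)
  S <- encode_states(lapply(states, `[[`, "observations"),
                     lapply(states, `[[`, "demo"), cat, layout)
  cur_probs <- predict_proba(D, S)
  active <- rep(TRUE, n_ep)

  traces <- lapply(seq_len(n_ep), function(i) {
    list(record = i, steps = list(), asked = character(0),
         terminal_probs = NULL, predicted_class = NA_integer_,
         forced = FALSE, n_revealed = 0L)
  })
  tr <- list(S = list(), Z = list(), Dp = list(), n_t = list(), mask = list(),
             action = list(), logp = list(), reward = list(), done = list(),
             ep = list())
  buf_states <- list(); buf_labels <- integer(0)

  while (any(active)) {
    act_ids <- which(active)
    na <- length(act_ids)
    Z <- matrix(0, na, agent$vae$d_z)
    for (k in seq_len(na)) {
      i <- act_ids[k]
      imp <- impute_unobserved(agent$vae, states[[i]]$observations, cat,
                               deterministic = deterministic)
      Z[k, ] <- imp$z
    }
    decoded <- vae_decode(agent$vae, Z)
    n_t_vec <- vapply(act_ids, function(i) states[[i]]$n_t, numeric(1))
    mask <- t(vapply(act_ids, function(i) {
      legal_action_mask(states[[i]], cat, actions)
    }, logical(nrow(actions))))
    probs <- actor_forward(agent, decoded, cur_probs[act_ids, , drop = FALSE],
                           n_t_vec, mask)
    chosen <- integer(na)
    for (k in seq_len(na)) {
      chosen[k] <- if (deterministic) {
        which.max(probs[k, ])
      } else {
        sample.int(ncol(probs), 1L, prob = probs[k, ])
      }
    }

    step_info <- vector("list", na)
    for (k in seq_len(na)) {
      i <- act_ids[k]
      counts <- missed_counts(states[[i]]$asked, records[[i]], cat)
      S_pre <- S[i, ]
      if (chosen[k] == term_idx) {
        pred <- which.max(cur_probs[i, ])
        reward <- r_long(states[[i]]$stage, pred, y[i], counts, reward_cfg)
        res <- env_step(states[[i]], term_idx, records[[i]], cat, actions)
        states[[i]] <- res$state
        step_info[[k]] <- list(info = res$info, reward = reward,
                               counts = counts, terminal = TRUE, pred = pred,
                               S_pre = S_pre)
        active[i] <- FALSE
      } else {
        res <- env_step(states[[i]], chosen[k], records[[i]], cat, actions)
        states[[i]] <- res$state
        step_info[[k]] <- list(info = res$info, reward = NA_real_,
                               counts = counts, terminal = FALSE,
                               S_pre = S_pre)
        S[i, ] <- encode_state(states[[i]]$observations, states[[i]]$demo,
                               cat, layout)
      }
    }
    stepped <- act_ids[!vapply(step_info, `[[`, logical(1), "terminal")]
    next_probs <- cur_probs
    if (length(stepped)) {
      next_probs[stepped, ] <- predict_proba(D, S[stepped, , drop = FALSE])
    }

    for (k in seq_len(na)) {
      i <- act_ids[k]
      si <- step_info[[k]]
      if (!si$terminal) {
        dv <- diff_reward(y[i], cur_probs[i, ], next_probs[i, ],
                          si$info$in_extracted)
        reward <- r_short(si$info$stage_t, si$info$stage_t1, dv,
                          si$info$i_phy, si$counts, reward_cfg)
        if (si$info$forced) {
          pred <- which.max(next_probs[i, ])
          counts_after <- missed_counts(states[[i]]$asked, records[[i]], cat)
          reward <- reward + r_long(si$info$stage_t1, pred, y[i],
                                    counts_after, reward_cfg)
          states[[i]]$done <- TRUE
          active[i] <- FALSE
          traces[[i]]$forced <- TRUE
          traces[[i]]$terminal_probs <- next_probs[i, ]
          traces[[i]]$predicted_class <- pred
        }
        si$reward <- reward
        traces[[i]]$asked <- c(traces[[i]]$asked, si$info$target)
        traces[[i]]$n_revealed <- traces[[i]]$n_revealed + length(si$info$revealed)
      } else {
        traces[[i]]$terminal_probs <- cur_probs[i, ]
        traces[[i]]$predicted_class <- si$pred
      }
      traces[[i]]$steps[[length(traces[[i]]$steps) + 1L]] <-
        list(kind = si$info$kind, target = si$info$target,
             stage_t = si$info$stage_t, stage_t1 = si$info$stage_t1,
             i_phy = si$info$i_phy, in_extracted = si$info$in_extracted,
             reward = si$reward)
      if (!active[i]) {
        buf_states[[length(buf_states) + 1L]] <- S[i, ]
        buf_labels <- c(buf_labels, y[i])
      }
      if (collect_transitions) {
        p <- length(tr$S) + 1L
        tr$S[[p]] <- si$S_pre
        tr$Z[[p]] <- Z[k, ]
        tr$Dp[[p]] <- cur_probs[i, ]
        tr$n_t[[p]] <- n_t_vec[k]
        tr$mask[[p]] <- mask[k, ]
        tr$action[[p]] <- chosen[k]
        tr$logp[[p]] <- safe_log(probs[k, chosen[k]])
        tr$reward[[p]] <- si$reward
        tr$done[[p]] <- !active[i]
        tr$ep[[p]] <- i
      }
    }
    cur_probs <- next_probs
  }

  traces <- lapply(seq_len(n_ep), function(i) {
    t_i <- traces[[i]]
    t_i$total_reward <- sum(vapply(t_i$steps, `[[`, numeric(1), "reward"))
    class(t_i) <- "EpisodeTrace"
    t_i
  })
  transitions <- NULL
  if (collect_transitions && length(tr$S)) {
    transitions <- list(S = do.call(rbind, tr$S), Z = do.call(rbind, tr$Z),
                        Dp = do.call(rbind, tr$Dp),
                        n_t = unlist(tr$n_t),
                        mask = do.call(rbind, tr$mask),
                        action = unlist(tr$action), logp = unlist(tr$logp),
                        reward = unlist(tr$reward), done = unlist(tr$done),
                        ep = unlist(tr$ep))
  }
  list(traces = traces,
       transitions = transitions,
       buffer = list(states = if (length(buf_states)) do.call(rbind, buf_states),
                     labels = buf_labels))
}

#' @export
print.EpisodeTrace <- function(x, ...) {
  cat(sprintf("EpisodeTrace: %d steps (%d inquiries), return %.3f, predicted class %d%s\n",
              length(x$steps), length(x$asked), x$total_reward,
              x$predicted_class, if (x$forced) " (forced)" else ""))
  invisible(x)
}

# generalized advantage estimation over stacked transitions
compute_gae <- function(values, rewards, done, ep, gamma, lam) {
  n <- length(rewards)
  adv <- numeric(n)
  last_adv <- 0
  for (t in rev(seq_len(n))) {
    if (done[t]) {
      delta <- rewards[t] - values[t]
      last_adv <- delta
    } else {
      delta <- rewards[t] + gamma * values[t + 1L] - values[t]
      last_adv <- delta + gamma * lam * last_adv
    }
    adv[t] <- last_adv
  }
  adv
}

#' One PPO update on a collected batch
#'
#' Clipped-surrogate policy loss with entropy bonus for the actor (gradients
#' reach the head and the nested VAE decoder only; the encoder and feature
#' embeddings are frozen) and mean-squared-error value loss for the critic.
#'
#' @param agent an `InquiryAgent`; `transitions` the stacked tensors from
#'   [collect_rollouts()]; `cfg` a [ppo_config()].
#' @param opt_state optional optimizer state carried across epochs.
#' @return list `agent`, `opt_state`, `diagnostics` (policy KL, losses,
#'   entropy).
#' @export
ppo_update <- function(agent, transitions, cfg, opt_state = NULL) {
  tx <- transitions
  stopifnot(length(tx$reward) > 0)
  n <- length(tx$reward)
  critic_in <- cbind(tx$S, tx$Dp, tx$n_t, tx$Z)
  values <- as.numeric(mlp_forward(agent$critic, critic_in)$out)
  adv <- compute_gae(values, tx$reward, tx$done, tx$ep,
                     cfg$gamma, cfg$gae_lambda)
  returns <- adv + values
  adv_n <- if (n > 1 && stats::sd(adv) > 0) (adv - mean(adv)) / stats::sd(adv) else adv

  if (is.null(opt_state)) {
    opt_state <- list(head = adam_new(agent$head), dec = adam_new(agent$vae$dec),
                      critic = adam_new(agent$critic))
  }
  idx <- cbind(seq_len(n), tx$action)
  diag_kl <- NA_real_; pol_loss <- NA_real_; ent_mean <- NA_real_

  for (pass in seq_len(cfg$update_epochs)) {
    dec_fw <- mlp_forward(agent$vae$dec, tx$Z)
    decoded <- decode_activate(agent$vae, dec_fw$out)
    head_in <- cbind(decoded, tx$Dp, tx$n_t)
    head_fw <- mlp_forward(agent$head, head_in)
    probs <- softmax_rows(head_fw$out, tx$mask)
    logp_new <- safe_log(probs[idx])
    ratio <- exp(logp_new - tx$logp)
    unclipped <- ratio * adv_n
    clipped <- pmin(pmax(ratio, 1 - cfg$clip_ratio), 1 + cfg$clip_ratio) * adv_n
    pol_loss <- -mean(pmin(unclipped, clipped))
    logp_safe <- ifelse(probs > 0, log(pmax(probs, 1e-12)), 0)
    ent <- -rowSums(probs * logp_safe)
    ent_mean <- mean(ent)
    if (!is.finite(pol_loss)) stop("PPO policy loss is not finite")

    # gradient of the clipped surrogate w.r.t. logits
    active_grad <- (adv_n >= 0 & ratio <= 1 + cfg$clip_ratio) |
      (adv_n < 0 & ratio >= 1 - cfg$clip_ratio)
    coef <- ifelse(active_grad, ratio * adv_n, 0)
    onehot <- matrix(0, n, ncol(probs)); onehot[idx] <- 1
    d_logits <- -(coef / n) * (onehot - probs)
    d_ent <- -probs * (logp_safe + ent)          # dH/dlogits
    d_logits <- d_logits - (cfg$entropy_coef / n) * d_ent
    d_logits[!tx$mask] <- 0

    head_bw <- mlp_backward(agent$head, head_fw$cache, d_logits)
    st <- adam_step(agent$head, head_bw$grads, opt_state$head, lr = cfg$lr_actor)
    agent$head <- st$net; opt_state$head <- st$opt

    # propagate into the nested decoder through the activation layer
    d_decoded <- head_bw$d_in[, seq_len(agent$vae$layout$n_val), drop = FALSE]
    d_dec_out <- d_decoded * 0
    for (f in names(agent$vae$layout$block_cols)) {
      cols <- agent$vae$layout$block_cols[[f]]
      if (agent$vae$domains[[f]] == "binary") {
        p <- decoded[, cols]
        d_dec_out[, cols] <- d_decoded[, cols] * p * (1 - p)
      } else {
        P <- decoded[, cols, drop = FALSE]
        g <- d_decoded[, cols, drop = FALSE]
        d_dec_out[, cols] <- P * (g - rowSums(g * P))
      }
    }
    dec_bw <- mlp_backward(agent$vae$dec, dec_fw$cache, d_dec_out)
    st <- adam_step(agent$vae$dec, dec_bw$grads, opt_state$dec, lr = cfg$lr_actor)
    agent$vae$dec <- st$net; opt_state$dec <- st$opt

    # critic
    c_fw <- mlp_forward(agent$critic, critic_in)
    v <- as.numeric(c_fw$out)
    d_v <- matrix(2 * (v - returns) / n, ncol = 1)
    c_bw <- mlp_backward(agent$critic, c_fw$cache, d_v)
    st <- adam_step(agent$critic, c_bw$grads, opt_state$critic, lr = cfg$lr_critic)
    agent$critic <- st$net; opt_state$critic <- st$opt

    diag_kl <- mean(tx$logp - logp_new)
  }
  value_loss <- mean((as.numeric(mlp_forward(agent$critic, critic_in)$out) - returns)^2)
  list(agent = agent, opt_state = opt_state,
       diagnostics = list(policy_kl = diag_kl, policy_loss = pol_loss,
                          value_loss = value_loss, entropy = ent_mean))
}

#' Train the inquiry agent
#'
#' Alternates per epoch: rollout collection under the current policy, PPO
#' updates on the collected batch, and fine-tuning of the diagnostic model
#' on the terminal-observation buffer. The VAE encoder and embeddings are
#' asserted frozen (bitwise) every epoch.
#'
#' @param records training records; `cat` the catalog.
#' @param D a pretrained `DiagnosisModel`; `vae` a pretrained `PoEVAE`.
#' @param n_classes diagnosis label count.
#' @param reward_cfg a [reward_config()]; `ppo_cfg` a [ppo_config()].
#' @param head_hidden,critic_hidden network widths.
#' @param finetune_d fine-tune D between epochs (the reference procedure).
#' @param verbose print per-epoch diagnostics.
#' @return list `agent`, `D` (fine-tuned), `curves` (per-epoch mean return,
#'   policy KL, losses), `reward_cfg`, `ppo_cfg`.
#' @export
train_agent <- function(records, cat, D, vae, n_classes, reward_cfg,
                        ppo_cfg = ppo_config(), head_hidden = 64L,
                        critic_hidden = 64L, finetune_d = TRUE,
                        verbose = FALSE) {
  set.seed(ppo_cfg$seed)
  agent <- agent_new(vae, cat, n_classes, head_hidden = head_hidden,
                     critic_hidden = critic_hidden, seed = ppo_cfg$seed)
  enc_ref <- mlp_params(agent$vae$enc)
  emb_ref <- as.numeric(agent$vae$embed)
  opt_state <- NULL
  curves <- data.frame(epoch = seq_len(ppo_cfg$epochs), mean_return = NA_real_,
                       policy_kl = NA_real_, value_loss = NA_real_,
                       entropy = NA_real_, d_loss_post = NA_real_)
  for (ep in seq_len(ppo_cfg$epochs)) {
    ep_records <- records[sample.int(length(records),
                                     min(ppo_cfg$episodes_per_epoch, length(records)))]
    roll <- collect_rollouts(agent, D, ep_records, cat, reward_cfg,
                             deterministic = FALSE)
    upd <- ppo_update(agent, roll$transitions, ppo_cfg, opt_state)
    agent <- upd$agent; opt_state <- upd$opt_state
    if (finetune_d && NROW(roll$buffer$states) > 0) {
      D <- finetune_on_collected(D, roll$buffer$states, roll$buffer$labels,
                                 epochs = 1L)
      curves$d_loss_post[ep] <- attr(D, "finetune_loss")[["post"]]
    }
    stopifnot(identical(mlp_params(agent$vae$enc), enc_ref),
              identical(as.numeric(agent$vae$embed), emb_ref))
    curves$mean_return[ep] <- mean(vapply(roll$traces, `[[`, numeric(1), "total_reward"))
    curves$policy_kl[ep] <- upd$diagnostics$policy_kl
    curves$value_loss[ep] <- upd$diagnostics$value_loss
    curves$entropy[ep] <- upd$diagnostics$entropy
    if (verbose) {
      message(sprintf("epoch %d: return %.3f, KL %.4f, H %.3f", ep,
                      curves$mean_return[ep], curves$policy_kl[ep],
                      curves$entropy[ep]))
    }
  }
  list(agent = agent, D = D, curves = curves,
       reward_cfg = reward_cfg, ppo_cfg = ppo_cfg)
}
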