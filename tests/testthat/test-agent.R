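make_toy_agent <- function(seed = 1L) {
  b <- shared_bench()
  vae <- shared_vae()
  agent_new(vae, b$world$catalog, nrow(b$world$labels),
            head_hidden = 16L, critic_hidden = 16L, seed = seed)
}

test_that("the actor masks illegal actions to exactly zero and normalizes", {
  b <- shared_bench()
  agent <- make_toy_agent()
  K <- nrow(b$world$labels)
  n_act <- nrow(agent$actions)
  set.seed(81)
  decoded <- matrix(stats::runif(3 * agent$vae$layout$n_val), 3)
  dp <- matrix(1 / K, 3, K)
  mask <- matrix(TRUE, 3, n_act)
  mask[1, 1:5] <- FALSE
  mask[2, seq(2, n_act, 2)] <- FALSE
  p <- actor_forward(agent, decoded, dp, c(0, 0.5, 1), mask)
  expect_true(all(p[!mask] == 0))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_identical(p, actor_forward(agent, decoded, dp, c(0, 0.5, 1), mask))
  expect_error(actor_forward(agent, decoded[1, , drop = FALSE],
                             dp[1, , drop = FALSE], 0,
                             matrix(FALSE, 1, n_act)),
               "no legal")
})

test_that("the critic returns finite, repeatable state values", {
  b <- shared_bench()
  agent <- make_toy_agent()
  K <- nrow(b$world$labels)
  layout <- agent$layout
  set.seed(82)
  S <- matrix(stats::runif(200 * layout$total), 200)
  dp <- matrix(1 / K, 200, K)
  Z <- matrix(stats::rnorm(200 * agent$vae$d_z), 200)
  n_t <- stats::runif(200)
  v <- critic_forward(agent, S, dp, n_t, Z)
  expect_true(all(is.finite(v)))
  expect_identical(v, critic_forward(agent, S, dp, n_t, Z))
  v2 <- critic_forward(agent, S[1, ], dp[1, ], 0.5, Z[1, ])
  expect_identical(v2, critic_forward(agent, S[1, ], dp[1, ], 0.5, Z[1, ]))
})

test_that("rollout collection produces monotone traces, a full buffer, and is seeded", {
  b <- shared_bench()
  agent <- make_toy_agent()
  D <- shared_D()
  rc <- reward_config(n_t_max = 6L)
  recs <- b$splits$test[1:12]
  set.seed(83)
  roll <- collect_rollouts(agent, D, recs, b$world$catalog, rc)
  expect_length(roll$traces, 12L)
  expect_equal(NROW(roll$buffer$states), 12L)
  for (t_i in roll$traces) {
    stages <- vapply(t_i$steps, `[[`, character(1), "stage_t1")
    expect_false(is.unsorted(match(stages, c("SMH", "PE", "AE"))))
    expect_equal(sum(vapply(t_i$steps, `[[`, character(1), "kind") == "terminate") +
                   as.integer(t_i$forced), 1L)
    expect_length(t_i$terminal_probs, nrow(b$world$labels))
  }
  set.seed(83)
  roll2 <- collect_rollouts(agent, D, recs, b$world$catalog, rc)
  expect_identical(roll$transitions$reward, roll2$transitions$reward)
  expect_identical(roll$transitions$action, roll2$transitions$action)
})

test_that("a zero-advantage batch leaves the policy unchanged without entropy", {
  b <- shared_bench()
  agent <- make_toy_agent()
  D <- shared_D()
  rc <- reward_config(n_t_max = 5L)
  set.seed(84)
  roll <- collect_rollouts(agent, D, b$splits$test[1:8], b$world$catalog, rc)
  tx <- roll$transitions
  # every transition its own episode with reward equal to the critic's value:
  # advantages are identically zero
  v <- critic_forward(agent, tx$S, tx$Dp, tx$n_t, tx$Z)
  tx$reward <- v
  tx$done <- rep(TRUE, length(v))
  tx$ep <- seq_along(v)
  cfg <- ppo_config(entropy_coef = 0, update_epochs = 1L)
  before_head <- mlp_params(agent$head)
  before_dec <- mlp_params(agent$vae$dec)
  upd <- ppo_update(agent, tx, cfg)
  expect_lt(max(abs(mlp_params(upd$agent$head) - before_head)), 1e-8)
  expect_lt(max(abs(mlp_params(upd$agent$vae$dec) - before_dec)), 1e-8)
})

test_that("PPO updates touch only the decoder, head and critic, with bounded policy drift", {
  b <- shared_bench()
  agent <- make_toy_agent()
  D <- shared_D()
  rc <- reward_config(n_t_max = 6L)
  set.seed(85)
  roll <- collect_rollouts(agent, D, b$splits$test[1:16], b$world$catalog, rc)
  enc_before <- mlp_params(agent$vae$enc)
  emb_before <- as.numeric(agent$vae$embed)
  head_before <- mlp_params(agent$head)
  upd <- ppo_update(agent, roll$transitions, ppo_config())
  expect_identical(mlp_params(upd$agent$vae$enc), enc_before)
  expect_identical(as.numeric(upd$agent$vae$embed), emb_before)
  expect_false(identical(mlp_params(upd$agent$head), head_before))
  expect_true(is.finite(upd$diagnostics$policy_kl))
  expect_lt(abs(upd$diagnostics$policy_kl), 0.5)
})

test_that("the value head learns a constant-reward environment", {
  b <- shared_bench()
  agent <- make_toy_agent(seed = 5L)
  D <- shared_D()
  rc <- reward_config(n_t_max = 5L)
  set.seed(86)
  roll <- collect_rollouts(agent, D, b$splits$test[1:16], b$world$catalog, rc)
  tx <- roll$transitions
  tx$reward <- rep(1, length(tx$reward))
  tx$done <- rep(TRUE, length(tx$reward))
  tx$ep <- seq_along(tx$reward)
  cfg <- ppo_config(entropy_coef = 0, update_epochs = 1L, lr_critic = 3e-3)
  opt <- NULL
  for (i in 1:150) {
    upd <- ppo_update(agent, tx, cfg, opt)
    agent <- upd$agent
    opt <- upd$opt_state
  }
  v <- critic_forward(agent, tx$S, tx$Dp, tx$n_t, tx$Z)
  expect_lt(mean(abs(v - 1)), 0.1)
})

test_that("agent training is reproducible end to end and keeps the encoder frozen", {
  b <- shared_bench()
  vae <- shared_vae()
  D <- shared_D()
  rc <- reward_config(n_t_max = 6L)
  pc <- ppo_config(epochs = 3L, episodes_per_epoch = 12L, seed = 87L)
  r1 <- train_agent(b$splits$train[1:60], b$world$catalog, D, vae,
                    nrow(b$world$labels), rc, pc,
                    head_hidden = 16L, critic_hidden = 16L)
  r2 <- train_agent(b$splits$train[1:60], b$world$catalog, D, vae,
                    nrow(b$world$labels), rc, pc,
                    head_hidden = 16L, critic_hidden = 16L)
  expect_equal(r1$curves$mean_return, r2$curves$mean_return, tolerance = 1e-6)
  expect_identical(mlp_params(r1$agent$vae$enc), mlp_params(vae$enc))
  expect_identical(as.numeric(r1$agent$vae$embed), as.numeric(vae$embed))
  expect_true(all(is.finite(r1$curves$mean_return)))
})
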