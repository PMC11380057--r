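test_that("diagnostic metrics behave at the boundaries", {
  y <- rep(1:2, each = 50)
  perfect <- cbind(c(rep(0.99, 50), rep(0.01, 50)),
                   c(rep(0.01, 50), rep(0.99, 50)))
  m <- evaluate_diagnosis(perfect, y)
  expect_equal(m$auroc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)

  set.seed(91)
  y2 <- sample(rep(1:2, each = 1000))
  noise <- stats::runif(2000)
  uniform <- cbind(noise, 1 - noise)
  m2 <- evaluate_diagnosis(uniform, y2)
  expect_lt(abs(m2$auroc - 0.5), 3 * sqrt(1 / 12 / 1000))

  one_class <- cbind(rep(0.9, 100), rep(0.1, 100))
  y3 <- c(rep(1, 70), rep(2, 30))
  expect_equal(evaluate_diagnosis(one_class, y3)$accuracy, 0.7)

  expect_error(evaluate_diagnosis(perfect, rep(1, 100)), "2 classes")
  expect_warning(macro_auroc(cbind(perfect, 0), c(y), n_classes = 3),
                 "excluded")
})

test_that("general accuracy credits constituent overlap with singles", {
  # naming one constituent of a compound is partially correct
  expect_equal(general_accuracy(list("bronchitis"),
                                list(c("aurti", "bronchitis"))), 1)
  # a compound containing the single true disease is partially correct
  expect_equal(general_accuracy(list(c("aurti", "bronchitis")), list("aurti")), 1)
  expect_equal(general_accuracy(list("aurti"), list("aurti")), 1)
  expect_equal(general_accuracy(list("gastritis"), list(c("aurti", "bronchitis"))), 0)
  # two different compounds sharing one disease are not credited
  expect_equal(general_accuracy(list(c("a", "b")), list(c("b", "c"))), 0)

  # general accuracy >= plain accuracy on random label sets
  set.seed(92)
  pool <- list("a", "b", "c", c("a", "b"), c("b", "c"))
  for (rep in 1:20) {
    pred <- pool[sample.int(5, 40, replace = TRUE)]
    ref <- pool[sample.int(5, 40, replace = TRUE)]
    plain <- mean(mapply(function(p, r) identical(sort(p), sort(r)), pred, ref))
    expect_gte(general_accuracy(pred, ref), plain)
  }
})

test_that("inquiry statistics count matches, panels, and positive recalls", {
  cat_ <- toy_catalog()
  rec <- patient_record(
    gender = "male", age = 4,
    chief_concerns = list(smh_a = "1"),
    extracted = list(smh_a = "1", smh_b = "0", pe_d = "1",
                     ae_f = "high", ae_g = "normal", ae_h = "low",
                     ae_i = "normal"),
    physician_sequence = c("smh_b", "pe_d", "p1", "p2"),
    diagnosis = list(constituents = "dis01", label_id = 1L))
  trace <- structure(list(record = 1L, steps = list(),
                          asked = c("smh_b", "pe_d", "p1", "p2"),
                          terminal_probs = c(1, 0), predicted_class = 1L,
                          forced = FALSE, total_reward = 0),
                     class = "EpisodeTrace")
  st <- inquiry_statistics(list(trace), list(rec), cat_)
  expect_equal(st$per_episode$n_inquiries, 4)
  expect_equal(st$per_episode$n_matching, 4)
  # p1 reveals 3 features, p2 reveals 1 extracted member; chief concern excluded
  expect_equal(st$per_episode$n_recalled, 2 + 3 + 1)
  expect_equal(st$per_episode$recalled_ae, 4)
  # positive = exhibited symptom or out-of-range lab
  expect_equal(st$per_episode$positive_recalled, 1 + 2)
  expect_equal(st$per_episode$positive_ae, 2)

  none <- structure(list(record = 1L, steps = list(), asked = character(0),
                         terminal_probs = c(1, 0), predicted_class = 1L,
                         forced = FALSE, total_reward = 0),
                    class = "EpisodeTrace")
  st0 <- inquiry_statistics(list(none), list(rec), cat_)
  expect_equal(st0$per_episode$n_inquiries, 0)
  expect_equal(st0$per_episode$n_recalled, 0)

  single_panel <- structure(list(record = 1L, steps = list(), asked = "p1",
                                 terminal_probs = c(1, 0), predicted_class = 1L,
                                 forced = FALSE, total_reward = 0),
                            class = "EpisodeTrace")
  st1 <- inquiry_statistics(list(single_panel), list(rec), cat_)
  expect_equal(st1$per_episode$n_inquiries, 1)
  expect_equal(st1$per_episode$n_recalled, 3)
})

test_that("normalized Kendall tau matches brute-force pair counting", {
  expect_equal(as.numeric(kendall_tau_normalized(letters[1:5], letters[1:5])), 0)
  expect_equal(as.numeric(kendall_tau_normalized(letters[1:5], rev(letters[1:5]))), 1)
  expect_equal(as.numeric(kendall_tau_normalized(c("a", "b", "c", "d"),
                                                 c("a", "c", "b", "d"))), 1 / 6)
  expect_error(kendall_tau_normalized(c("a", "b"), c("c", "d")), "common")
  expect_error(kendall_tau_normalized(c("a", "a"), c("a", "b")), "duplicates")

  brute <- function(sa, sb) {
    common <- intersect(sa, sb)
    disc <- 0; tot <- 0
    for (i in seq_along(common)) {
      for (j in seq_along(common)) {
        if (i < j) {
          tot <- tot + 1
          a_order <- match(common[i], sa) < match(common[j], sa)
          b_order <- match(common[i], sb) < match(common[j], sb)
          if (a_order != b_order) disc <- disc + 1
        }
      }
    }
    disc / tot
  }
  set.seed(93)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    univ <- paste0("f", 1:15)
    sa <- sample(univ, n)
    sb <- sample(univ, sample(2:15, 1))
    if (length(intersect(sa, sb)) < 2) next
    expect_equal(as.numeric(kendall_tau_normalized(sa, sb)), brute(sa, sb))
  }
})

test_that("bootstrap CIs are percentile-based, seeded, and contain the point", {
  ci <- bootstrap_ci(rep(3.5, 40), seed = 94L)
  expect_equal(unname(ci), c(3.5, 3.5, 3.5))

  set.seed(95)
  for (i in 1:50) {
    x <- stats::rnorm(30, mean = stats::runif(1, -5, 5))
    ci <- bootstrap_ci(x, n_boot = 200L, seed = i)
    expect_gte(ci[["point"]], ci[["low"]])
    expect_lte(ci[["point"]], ci[["high"]])
  }
  expect_identical(bootstrap_ci(1:20, seed = 96L), bootstrap_ci(1:20, seed = 96L))
  expect_error(bootstrap_ci(numeric(0)), "empty")
})

test_that("step-frequency tables are one-hot for a deterministic agent and stage-consistent", {
  tr1 <- structure(list(record = 1L, asked = c("smh_b", "pe_d", "p1")),
                   class = "EpisodeTrace")
  M <- feature_frequency_table(list(tr1), c("smh_b", "pe_d", "p1", "p2"))
  expect_equal(dim(M), c(3L, 4L))
  expect_equal(rowSums(M), rep(1, 3))
  expect_equal(unname(M[1, "smh_b"]), 1)
  expect_equal(unname(M[2, "pe_d"]), 1)

  b <- shared_bench()
  cat_ <- b$world$catalog
  set.seed(97)
  traces <- lapply(1:300, function(i) {
    rec <- b$records[[sample.int(length(b$records), 1L)]]
    ro <- random_rollout(rec, cat_, 8L)
    structure(list(record = i, asked = ro$asked), class = "EpisodeTrace")
  })
  fids <- feature_ids(cat_)
  smh <- fids[cat_$features$stage == "SMH"]
  Mx <- feature_frequency_table(traces, c(smh, names(cat_$panels)))
  expect_true(all(rowSums(Mx) <= 1 + 1e-12))
  # SMH columns carry no mass once a later stage has begun, in any trace
  for (t_i in traces) {
    st <- stage_of(t_i$asked, cat_)
    first_later <- which(st != "SMH")[1]
    if (!is.na(first_later) && first_later < length(t_i$asked)) {
      expect_true(all(st[first_later:length(st)] != "SMH"))
    }
  }
})

test_that("collaboration picks unasked extracted items, never repeats, and is seeded", {
  b <- shared_bench()
  agent <- agent_new(shared_vae(), b$world$catalog, nrow(b$world$labels),
                     head_hidden = 16L, critic_hidden = 16L, seed = 98L)
  D <- shared_D()
  rc <- reward_config(n_t_max = 8L)
  recs <- b$splits$test[1:20]
  tr1 <- collaborate_rollouts(agent, D, recs, b$world$catalog, rc, seed = 99L)
  tr2 <- collaborate_rollouts(agent, D, recs, b$world$catalog, rc, seed = 99L)
  expect_equal(lapply(tr1, `[[`, "asked"), lapply(tr2, `[[`, "asked"))
  for (i in seq_along(tr1)) {
    t_i <- tr1[[i]]
    expect_equal(anyDuplicated(t_i$asked), 0L)
    phy_items <- t_i$asked[t_i$physician_steps]
    for (it in phy_items) {
      if (it %in% names(b$world$catalog$panels)) {
        expect_true(it %in% recs[[i]]$physician_sequence)
      } else {
        expect_true(it %in% names(recs[[i]]$extracted))
      }
    }
  }
})
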