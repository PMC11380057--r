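#' Reward shaping for staged inquiry
#'
#' Two reward channels drive learning. The short-term reward for asking an
#' item combines three terms: `Diff`, the diagnostic-information gain — the
#' absolute change in KL divergence from the one-hot reference diagnosis to
#' the diagnostic model's output across the transition (for a one-hot
#' reference on class c this collapses to `|log p'[c] - log p[c]|`, in nats);
#' `alpha * I_phy`, a bonus when the asked item is one the physician also
#' asked; and stage-skip penalties `-m * M_stage` charged on hasty stage
#' transitions, where `M_SMH/M_PE/M_AE` count physician items of a stage the
#' agent has not (yet) asked — AE counted at panel granularity, one unit per
#' lab panel. The long-term reward on termination pays a fixed match reward
#' when the predicted diagnosis equals the reference, and otherwise charges
#' `-m` times the missed counts from the current stage onward.
#'
#' Named presets: `"emergency"` (alpha 0.2, m 0.2, match reward 2, budget
#' N_T 21) and `"pediatrics"` (alpha 0.2, m 0.3, match reward 3, N_T 26).
#'
#' @name rewards
NULL

#' Reward configuration
#'
#' @param alpha bonus for physician-matching inquiries (>= 0).
#' @param m per-item stage-skip penalty (>= 0).
#' @param r_long_match terminal reward for a correct diagnosis.
#' @param gamma discount factor in (0, 1].
#' @param n_t_max budget N_T: maximum number of inquiry actions.
#' @param pe_to_ae_penalty which missed count the PE->AE transition charges:
#'   `"M_AE"` (as printed) or `"M_PE"` (erratum mode, matching the
#'   previous-stage pattern of the other cases).
#' @export
reward_config <- function(alpha = 0.2, m = 0.2, r_long_match = 2,
                          gamma = 0.99, n_t_max = 21L,
                          pe_to_ae_penalty = c("M_AE", "M_PE")) {
  pe_to_ae_penalty <- match.arg(pe_to_ae_penalty)
  stopifnot(alpha >= 0, m >= 0, gamma > 0, gamma <= 1, n_t_max >= 1)
  structure(list(alpha = alpha, m = m, r_long_match = r_long_match,
                 gamma = gamma, n_t_max = as.integer(n_t_max),
                 pe_to_ae_penalty = pe_to_ae_penalty),
            class = "RewardConfig")
}

#' Preset reward configurations
#' @param preset `"emergency"` or `"pediatrics"`.
#' @export
reward_preset <- function(preset = c("emergency", "pediatrics")) {
  preset <- match.arg(preset)
  if (preset == "emergency") {
    reward_config(alpha = 0.2, m = 0.2, r_long_match = 2, n_t_max = 21L)
  } else {
    reward_config(alpha = 0.2, m = 0.3, r_long_match = 3, n_t_max = 26L)
  }
}

#' Missed-inquiry counts at a state
#'
#' Counts physician-sequence items the agent has not asked, per stage.
#' SMH and PE are counted per feature; AE per panel ("all features within a
#' laboratory test are considered as a unit").
#'
#' @param asked character vector of feature/panel ids the agent has asked
#'   (including chief-concern features revealed at reset).
#' @param record the `PatientRecord`; `cat` the `FeatureCatalog`.
#' @return list `M_SMH`, `M_PE`, `M_AE` of non-negative integers.
#' @export
missed_counts <- function(asked, record, cat) {
  items <- record$physician_sequence
  stages <- stage_of(items, cat)
  missing <- !items %in% asked
  list(M_SMH = sum(missing & stages == "SMH"),
       M_PE = sum(missing & stages == "PE"),
       M_AE = sum(missing & stages == "AE"))
}

#' Diagnostic-information gain of one inquiry
#'
#' `|D_KL(y || p_t) - D_KL(y || p_t1)|` with one-hot reference `y`,
#' in nats; equals `|log p_t1[c] - log p_t[c]|` for reference class c.
#' Zero when the asked item is not in the record's extracted set.
#'
#' @param y_class 1-based reference class index.
#' @param p_t,p_t1 probability vectors before/after the inquiry.
#' @param in_extracted logical: does the asked item belong to the extracted
#'   features (for a panel: did the physician order the panel)?
#' @param eps clamp for zero probabilities (warns when hit).
#' @export
diff_reward <- function(y_class, p_t, p_t1, in_extracted, eps = 1e-12) {
  if (!in_extracted) return(0)
  stopifnot(length(p_t) == length(p_t1), y_class >= 1, y_class <= length(p_t))
  if (p_t[y_class] < eps || p_t1[y_class] < eps) {
    warning("diff_reward: clamping zero probability at eps")
  }
  abs(log(max(p_t1[y_class], eps)) - log(max(p_t[y_class], eps)))
}

#' Short-term reward for an inquiry action
#'
#' @param stage_t,stage_t1 stages (`"SMH"`, `"PE"`, `"AE"`) before/after the
#'   action; `stage_t1` must not precede `stage_t`.
#' @param diff_value output of [diff_reward()].
#' @param i_phy 0/1: did the physician ask this item?
#' @param counts [missed_counts()] at the state before the action.
#' @param cfg a [reward_config()].
#' @export
r_short <- function(stage_t, stage_t1, diff_value, i_phy, counts, cfg) {
  it <- match(stage_t, STAGES)
  it1 <- match(stage_t1, STAGES)
  if (is.na(it) || is.na(it1) || it1 < it) {
    stop("illegal stage pair: ", stage_t, " -> ", stage_t1)
  }
  base <- diff_value + cfg$alpha * i_phy
  if (stage_t == "SMH" && stage_t1 == "PE") {
    base - cfg$m * counts$M_SMH
  } else if (stage_t == "SMH" && stage_t1 == "AE") {
    base - cfg$m * (counts$M_SMH + counts$M_PE)
  } else if (stage_t == "PE" && stage_t1 == "AE") {
    pen <- if (cfg$pe_to_ae_penalty == "M_AE") counts$M_AE else counts$M_PE
    base - cfg$m * pen
  } else {
    base
  }
}

#' Long-term reward on termination
#'
#' @param stage_t stage from which the agent terminated.
#' @param predicted_class,reference_class 1-based label indices.
#' @param counts [missed_counts()] at termination.
#' @param cfg a [reward_config()].
#' @export
r_long <- function(stage_t, predicted_class, reference_class, counts, cfg) {
  if (predicted_class == reference_class) return(cfg$r_long_match)
  switch(stage_t,
         SMH = -cfg$m * (counts$M_SMH + counts$M_PE + counts$M_AE),
         PE = -cfg$m * (counts$M_PE + counts$M_AE),
         AE = -cfg$m * counts$M_AE,
         stop("invalid termination stage: ", stage_t))
}

#' Discounted return of a reward sequence
#' @param rewards numeric vector in time order; `gamma` discount in (0, 1].
#' @export
discounted_return <- function(rewards, gamma) {
  stopifnot(gamma > 0, gamma <= 1)
  if (!length(rewards)) return(0)
  sum(gamma^(seq_along(rewards) - 1) * rewards)
}
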