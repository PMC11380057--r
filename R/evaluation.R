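#' Evaluation statistics for inquiry agents
#'
#' Diagnostic metrics (macro AUROC one-vs-rest, macro F1, accuracy, and
#' general accuracy with partial credit for compound diagnoses), inquiry
#' consistency metrics (inquiry counts, physician-matching counts, recalled
#' features overall / by stage / positive-only), the simulated
#' physician-agent collaboration protocol, the normalized Kendall tau
#' distance between inquiry orders, and percentile bootstrap confidence
#' intervals.
#'
#' @name evaluation
NULL

#' Macro AUROC, one-vs-rest
#'
#' Classes absent from the labels (or without both positives and negatives)
#' are excluded from the macro average with a warning.
#'
#' @param probs probability matrix (rows = cases, cols = classes).
#' @param labels integer class indices; `n_classes` total classes.
#' @export
macro_auroc <- function(probs, labels, n_classes = ncol(probs)) {
  aucs <- c()
  skipped <- c()
  for (k in seq_len(n_classes)) {
    resp <- as.integer(labels == k)
    if (length(unique(resp)) < 2) {
      skipped <- c(skipped, k)
      next
    }
    a <- suppressMessages(pROC::auc(resp, probs[, k], quiet = TRUE,
                                    direction = "<", levels = c(0, 1)))
    aucs <- c(aucs, as.numeric(a))
  }
  if (length(skipped)) {
    warning("classes excluded from macro AUROC (absent or single-class): ",
            paste(skipped, collapse = ", "))
  }
  mean(aucs)
}

#' Diagnostic metrics: macro AUROC, macro F1, accuracy
#'
#' @param probs probability matrix over classes; `labels` integer indices.
#' @param n_classes total classes.
#' @return list `auroc`, `f1`, `accuracy`.
#' @export
evaluate_diagnosis <- function(probs, labels, n_classes = ncol(probs)) {
  if (length(unique(labels)) < 2) stop("need at least 2 classes in labels")
  pred <- max.col(probs, ties.method = "first")
  acc <- mean(pred == labels)
  f1s <- vapply(sort(unique(labels)), function(k) {
    tp <- sum(pred == k & labels == k)
    fp <- sum(pred == k & labels != k)
    fn <- sum(pred != k & labels == k)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(auroc = macro_auroc(probs, labels, n_classes),
       f1 = mean(f1s), accuracy = acc)
}

#' General accuracy with partial credit for compound diagnoses
#'
#' A prediction with constituent set P against reference R scores 1 when
#' P = R (fully correct), or when P and R share a constituent and one of
#' them is a single disease (partially correct: naming one constituent of a
#' compound diagnosis, or a compound containing the single true disease);
#' otherwise 0.
#'
#' @param pred_constituents,ref_constituents lists of character vectors of
#'   atomic disease ids.
#' @return proportion correct.
#' @export
general_accuracy <- function(pred_constituents, ref_constituents) {
  stopifnot(length(pred_constituents) == length(ref_constituents))
  mean(mapply(function(P, R) {
    P <- sort(as.character(P)); R <- sort(as.character(R))
    if (identical(P, R)) return(1)
    if (length(intersect(P, R)) > 0 && (length(P) == 1 || length(R) == 1)) return(1)
    0
  }, pred_constituents, ref_constituents))
}

#' Constituent sets for label indices
#' @param label_ids integer vector; `labels_table` the world's label table.
#' @export
constituents_of <- function(label_ids, labels_table) {
  labels_table$constituents[match(label_ids, labels_table$label_id)]
}

trace_match_flags <- function(asked, record, cat) {
  stages <- stage_of(asked, cat)
  vapply(seq_along(asked), function(j) {
    it <- asked[j]
    if (stages[j] == "AE") it %in% record$physician_sequence
    else it %in% names(record$extracted)
  }, logical(1))
}

recalled_features <- function(asked, record, cat) {
  feats <- character(0)
  for (it in asked) {
    if (it %in% names(cat$panels)) {
      feats <- c(feats, intersect(cat$panels[[it]], names(record$extracted)))
    } else if (it %in% names(record$extracted)) {
      feats <- c(feats, it)
    }
  }
  unique(feats)
}

is_positive_value <- function(values) {
  as.character(values) %in% c("1", "low", "high", "TRUE")
}

#' Per-episode inquiry statistics
#'
#' For each trace: number of inquiries, number matching the record
#' (features in the extracted set; panels ordered by the physician), number
#' of physician-conducted inquiries (0 for solo traces), recalled features
#' (revealed extracted features beyond the chief concerns) overall, by
#' stage, and positive-only (exhibited symptoms or out-of-range results).
#'
#' @param traces list of `EpisodeTrace`; `records` the paired records
#'   (matched by the traces' `record` index); `cat` the catalog.
#' @return list `per_episode` (data.frame) and `means`.
#' @export
inquiry_statistics <- function(traces, records, cat) {
  rows <- lapply(traces, function(t_i) {
    rec <- records[[t_i$record]]
    if (is.null(rec)) stop("trace not paired with a record")
    asked <- t_i$asked
    match_flags <- if (length(asked)) trace_match_flags(asked, rec, cat) else logical(0)
    rf <- recalled_features(asked, rec, cat)
    rf <- setdiff(rf, names(rec$chief_concerns))
    rf_stage <- stage_of(rf, cat)
    rf_pos <- rf[is_positive_value(unlist(rec$extracted[rf], use.names = FALSE))]
    pos_stage <- stage_of(rf_pos, cat)
    n_phy <- if (!is.null(t_i$physician_steps)) sum(t_i$physician_steps) else 0L
    data.frame(
      n_inquiries = length(asked),
      n_matching = sum(match_flags),
      n_physician = n_phy,
      n_recalled = length(rf),
      recalled_smh = sum(rf_stage == "SMH"),
      recalled_pe = sum(rf_stage == "PE"),
      recalled_ae = sum(rf_stage == "AE"),
      positive_recalled = length(rf_pos),
      positive_smh = sum(pos_stage == "SMH"),
      positive_pe = sum(pos_stage == "PE"),
      positive_ae = sum(pos_stage == "AE"))
  })
  per_episode <- do.call(rbind, rows)
  list(per_episode = per_episode, means = colMeans(per_episode))
}

#' Simulate physician-agent collaborative inquiry
#'
#' At each step the agent recommends its highest-probability legal action.
#' Terminate ends the episode. A recommendation matching the record
#' (feature in the extracted set; panel ordered by the physician) is
#' accepted as an agent inquiry. A mismatch makes the simulated physician
#' select, uniformly at random, an unasked extracted item from the earliest
#' stage at or after the current stage (so environment actions stay legal);
#' that step counts as a physician inquiry. When no extracted items remain
#' unasked and the recommendation mismatches, the episode terminates. The
#' action budget applies as usual. Physician randomness uses the current
#' RNG state.
#'
#' @param agent an `InquiryAgent`; `D` a `DiagnosisModel`; `record` the
#'   episode record; `cat` the catalog; `reward_cfg` a [reward_config()]
#'   (for the budget).
#' @param record_index index stored in the trace for pairing.
#' @return an `EpisodeTrace` with `physician_steps` (logical per inquiry).
#' @export
simulate_collaboration <- function(agent, D, record, cat, reward_cfg,
                                   record_index = 1L) {
  actions <- agent$actions
  layout <- agent$layout
  term_idx <- which(actions$kind == "terminate")
  state <- env_reset(record, cat, reward_cfg$n_t_max)
  S <- encode_state(state$observations, state$demo, cat, layout)
  probs_d <- predict_proba(D, S)
  asked <- character(0)
  physician_steps <- logical(0)
  steps <- list()
  forced <- FALSE

  repeat {
    mask <- legal_action_mask(state, cat, actions)
    imp <- impute_unobserved(agent$vae, state$observations, cat,
                             deterministic = TRUE)
    p_act <- actor_forward(agent, matrix(imp$probs, 1), probs_d,
                           state$n_t, mask)
    top <- which.max(p_act[1, ])
    if (top == term_idx) break
    tgt <- actions$target[top]
    matches <- if (actions$kind[top] == "ask_panel") {
      tgt %in% record$physician_sequence
    } else {
      tgt %in% names(record$extracted)
    }
    if (matches) {
      idx <- top
      phy <- FALSE
    } else {
      idx <- physician_pick(state, record, cat, actions)
      if (is.na(idx)) break
      phy <- TRUE
    }
    res <- env_step(state, idx, record, cat, actions)
    state <- res$state
    asked <- c(asked, res$info$target)
    physician_steps <- c(physician_steps, phy)
    steps[[length(steps) + 1L]] <- list(kind = res$info$kind,
                                        target = res$info$target,
                                        stage_t = res$info$stage_t,
                                        stage_t1 = res$info$stage_t1,
                                        physician = phy,
                                        reward = NA_real_)
    S <- encode_state(state$observations, state$demo, cat, layout)
    probs_d <- predict_proba(D, S)
    if (state$forced) { forced <- TRUE; break }
  }
  structure(list(record = record_index, steps = steps, asked = asked,
                 physician_steps = physician_steps,
                 terminal_probs = probs_d[1, ],
                 predicted_class = which.max(probs_d[1, ]),
                 forced = forced,
                 total_reward = NA_real_),
            class = "EpisodeTrace")
}

# earliest stage >= current with unasked extracted items; uniform pick
physician_pick <- function(state, record, cat, actions) {
  cur <- match(state$stage, STAGES)
  for (s in cur:3) {
    stage <- STAGES[s]
    if (stage == "AE") {
      pnls <- unique(stats::na.omit(panel_of(
        intersect(names(record$extracted), feature_ids(cat)), cat)))
      pnls <- setdiff(pnls[vapply(pnls, function(p) {
        any(cat$panels[[p]] %in% names(record$extracted))
      }, logical(1))], state$asked)
      # only panels the physician actually ordered count as extracted items
      pnls <- intersect(pnls, record$physician_sequence)
      if (length(pnls)) {
        tgt <- pnls[sample.int(length(pnls), 1L)]
        return(which(actions$kind == "ask_panel" & actions$target == tgt))
      }
    } else {
      fids <- feature_ids(cat)
      cand <- names(record$extracted)
      cand <- cand[cat$features$stage[match(cand, fids)] == stage]
      cand <- setdiff(cand, state$asked)
      if (length(cand)) {
        tgt <- cand[sample.int(length(cand), 1L)]
        return(which(actions$kind == "ask_feature" & actions$target == tgt))
      }
    }
  }
  NA_integer_
}

#' Collaboration traces over a record set
#' @param agent,D,records,cat,reward_cfg as in [simulate_collaboration()].
#' @param seed integer seed for the simulated physician's randomness.
#' @export
collaborate_rollouts <- function(agent, D, records, cat, reward_cfg, seed = 1L) {
  set.seed(seed)
  lapply(seq_along(records), function(i) {
    simulate_collaboration(agent, D, records[[i]], cat, reward_cfg,
                           record_index = i)
  })
}

#' Normalized Kendall tau distance between two inquiry sequences
#'
#' Both sequences are restricted to their common items; the number of
#' discordantly ordered pairs is divided by the number of all pairs
#' C(n, 2). 0 = identical order, 1 = exact reversal. The fraction of
#' `seq_a` items shared with `seq_b` is attached as attribute
#' `match_fraction`.
#'
#' @param seq_a,seq_b character vectors without duplicates.
#' @return scalar in `[0, 1]`.
#' @export
kendall_tau_normalized <- function(seq_a, seq_b) {
  if (anyDuplicated(seq_a) || anyDuplicated(seq_b)) stop("sequences must not contain duplicates")
  common <- intersect(seq_a, seq_b)
  n <- length(common)
  if (n < 2) stop("need at least 2 common items")
  ra <- match(common, seq_a)
  rb <- match(common, seq_b)
  disc <- sum(outer(ra, ra, `<`) & outer(rb, rb, `>`))
  out <- disc / choose(n, 2)
  attr(out, "match_fraction") <- if (length(seq_a)) n / length(seq_a) else NA_real_
  out
}

#' Percentile bootstrap confidence interval
#'
#' 1000 resamples with replacement at the original sample size; the CI is
#' the percentile interval of the resampled statistic.
#'
#' @param x numeric vector (per-item values).
#' @param stat statistic function of a numeric vector (default mean).
#' @param n_boot number of bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return named vector `point`, `low`, `high`.
#' @export
bootstrap_ci <- function(x, stat = mean, n_boot = 1000L, conf = 0.95,
                         seed = 1L) {
  if (!length(x)) stop("empty sample")
  set.seed(seed)
  n <- length(x)
  boots <- vapply(seq_len(n_boot), function(b) {
    stat(x[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  q <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(point = stat(x), low = q[1], high = q[2])
}

#' Step-by-feature inquiry frequency matrix
#'
#' Rows are inquiry step indices, columns features (or panels), cells the
#' frequency with which the item was asked at that step across traces
#' (heat-map data export). Row sums are at most 1.
#'
#' @param traces list of `EpisodeTrace`.
#' @param items character vector of feature/panel ids (columns).
#' @export
feature_frequency_table <- function(traces, items) {
  stopifnot(length(traces) > 0)
  max_steps <- max(vapply(traces, function(t_i) length(t_i$asked), integer(1)))
  M <- matrix(0, nrow = max_steps, ncol = length(items),
              dimnames = list(NULL, items))
  if (max_steps == 0) return(M)
  for (t_i in traces) {
    for (s in seq_along(t_i$asked)) {
      it <- t_i$asked[s]
      if (it %in% items) M[s, it] <- M[s, it] + 1
    }
  }
  M / length(traces)
}

#' Full evaluation report for a set of traces
#'
#' Diagnostic metrics from the terminal diagnosis distributions, general
#' accuracy over constituent sets, inquiry statistics, each with a
#' percentile bootstrap CI.
#'
#' @param traces list of `EpisodeTrace`; `records` paired records;
#'   `cat` the catalog; `labels_table` the label table (with
#'   `label_id`, `constituents`); `n_classes` label count.
#' @param n_boot,conf,seed bootstrap settings.
#' @return an `EvaluationReport` list.
#' @export
evaluation_report <- function(traces, records, cat, labels_table,
                              n_classes = nrow(labels_table),
                              n_boot = 1000L, conf = 0.95, seed = 1L) {
  probs <- do.call(rbind, lapply(traces, `[[`, "terminal_probs"))
  labels <- vapply(traces, function(t_i) {
    as.integer(records[[t_i$record]]$diagnosis$label_id)
  }, integer(1))
  pred <- vapply(traces, `[[`, integer(1), "predicted_class")
  dx <- evaluate_diagnosis(probs, labels, n_classes)
  gacc <- general_accuracy(constituents_of(pred, labels_table),
                           constituents_of(labels, labels_table))
  stats_ <- inquiry_statistics(traces, records, cat)
  correct <- as.numeric(pred == labels)
  gcorrect <- mapply(function(P, R) general_accuracy(list(P), list(R)),
                     constituents_of(pred, labels_table),
                     constituents_of(labels, labels_table))
  cis <- list(
    accuracy = bootstrap_ci(correct, n_boot = n_boot, conf = conf, seed = seed),
    general_accuracy = bootstrap_ci(gcorrect, n_boot = n_boot, conf = conf,
                                    seed = seed + 1L),
    n_inquiries = bootstrap_ci(stats_$per_episode$n_inquiries, n_boot = n_boot,
                               conf = conf, seed = seed + 2L),
    n_recalled = bootstrap_ci(stats_$per_episode$n_recalled, n_boot = n_boot,
                              conf = conf, seed = seed + 3L))
  structure(list(auroc = dx$auroc, f1 = dx$f1, accuracy = dx$accuracy,
                 general_accuracy = gacc, inquiry = stats_$means,
                 ci = cis, n_episodes = length(traces)),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf(paste0(
    "EvaluationReport (%d episodes)\n",
    "  macro AUROC %.3f | macro F1 %.3f | accuracy %.3f | general accuracy %.3f\n",
    "  inquiries %.2f (matching %.2f, physician %.2f) | recalled features %.2f\n"),
    x$n_episodes, x$auroc, x$f1, x$accuracy, x$general_accuracy,
    x$inquiry[["n_inquiries"]], x$inquiry[["n_matching"]],
    x$inquiry[["n_physician"]], x$inquiry[["n_recalled"]]))
  invisible(x)
}
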