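#' The staged inquiry environment
#'
#' A deterministic Markov decision process over one patient record. The
#' agent starts from the patient's demographics plus chief-concern features,
#' then asks SMH features, PE features and AE panels (one action per panel:
#' recommending any feature of an auxiliary examination recommends the whole
#' examination), and finally terminates with a diagnosis. Stages only move
#' forward: once the inquiry has advanced to a stage, actions of earlier
#' stages are masked to probability exactly zero. Answers come verbatim from
#' the record's extracted set; an item the physician never recorded is
#' answered with the `asked_negative` sentinel. An episode is forcibly
#' terminated when the action budget N_T is exhausted and is then scored
#' exactly as if the agent had chosen to terminate.
#'
#' @name inquiry-env
NULL

#' Action table of a catalog
#'
#' One `ask_feature` action per SMH/PE feature (catalog index order), one
#' `ask_panel` action per AE panel, and a final `terminate` action.
#'
#' @param cat a `FeatureCatalog`.
#' @return data.frame with columns `kind`, `target`, `stage`.
#' @export
action_table <- function(cat) {
  fids <- feature_ids(cat)
  smh_pe <- fids[cat$features$stage != "AE"]
  data.frame(
    kind = c(rep("ask_feature", length(smh_pe)),
             rep("ask_panel", length(cat$panels)), "terminate"),
    target = c(smh_pe, names(cat$panels), NA_character_),
    stage = c(cat$features$stage[match(smh_pe, fids)],
              rep("AE", length(cat$panels)), NA_character_),
    stringsAsFactors = FALSE)
}

#' Reset the environment on a record
#'
#' @param record a validated `PatientRecord`.
#' @param cat the `FeatureCatalog`.
#' @param n_t_max budget N_T (maximum number of inquiry actions).
#' @return an `InquiryState`: observations = chief concerns, demographics
#'   attached, stage SMH, step counter 0.
#' @export
env_reset <- function(record, cat, n_t_max) {
  stopifnot(n_t_max >= 1)
  structure(list(observations = record$chief_concerns,
                 demo = list(age = record$age, gender = record$gender),
                 asked = names(record$chief_concerns),
                 stage = "SMH", t = 0L, n_t = 0,
                 n_t_max = as.integer(n_t_max),
                 done = FALSE, forced = FALSE),
            class = "InquiryState")
}

#' Legal-action mask at a state
#'
#' Features of stages earlier than the current stage and already-asked
#' items are illegal; terminate is always legal.
#'
#' @param state an `InquiryState`; `cat` the catalog;
#'   `actions` optional precomputed [action_table()].
#' @return logical vector over the action table rows.
#' @export
legal_action_mask <- function(state, cat, actions = action_table(cat)) {
  if (state$done) stop("terminal state has no legal actions")
  stage_idx <- match(state$stage, STAGES)
  legal <- rep(TRUE, nrow(actions))
  ask <- actions$kind != "terminate"
  legal[ask] <- match(actions$stage[ask], STAGES) >= stage_idx &
    !(actions$target[ask] %in% state$asked)
  legal
}

#' One environment transition
#'
#' Deterministic given (state, action, record). Asking a feature reveals its
#' extracted value or marks it `asked_negative`; asking a panel reveals all
#' its extracted features in one step (unrecorded members get the
#' sentinel). The stage advances to the action's stage when later. The step
#' counter increments for inquiries; terminate does not consume a step.
#'
#' @param state an `InquiryState`; `action_idx` row of the action table
#'   (must be legal); `record` the `PatientRecord`; `cat` the catalog;
#'   `actions` optional precomputed table.
#' @return list `state` (next state) and `info` with `kind`, `target`,
#'   `stage_t`, `stage_t1`, `in_extracted`, `i_phy`, `revealed` (named list
#'   of new observations), `forced`.
#' @export
env_step <- function(state, action_idx, record, cat, actions = action_table(cat)) {
  if (state$done) stop("episode already terminated")
  if (!legal_action_mask(state, cat, actions)[action_idx]) {
    stop("illegal action: index ", action_idx)
  }
  act <- actions[action_idx, ]
  stage_t <- state$stage

  if (act$kind == "terminate") {
    state$done <- TRUE
    return(list(state = state,
                info = list(kind = "terminate", target = NA_character_,
                            stage_t = stage_t, stage_t1 = stage_t,
                            in_extracted = FALSE, i_phy = 0,
                            revealed = list(), forced = FALSE)))
  }

  revealed <- list()
  if (act$kind == "ask_feature") {
    f <- act$target
    revealed[[f]] <- if (f %in% names(record$extracted)) {
      record$extracted[[f]]
    } else ASKED_NEGATIVE
    in_extracted <- f %in% names(record$extracted)
    i_phy <- as.numeric(in_extracted)
    state$asked <- c(state$asked, f)
  } else {
    p <- act$target
    for (f in cat$panels[[p]]) {
      revealed[[f]] <- if (f %in% names(record$extracted)) {
        record$extracted[[f]]
      } else ASKED_NEGATIVE
    }
    in_extracted <- p %in% record$physician_sequence
    i_phy <- as.numeric(in_extracted)
    state$asked <- c(state$asked, p)
  }
  state$observations[names(revealed)] <- revealed
  new_stage_idx <- max(match(state$stage, STAGES), match(act$stage, STAGES))
  state$stage <- STAGES[new_stage_idx]
  state$t <- state$t + 1L
  state$n_t <- state$t / state$n_t_max
  if (state$t >= state$n_t_max) state$forced <- TRUE

  list(state = state,
       info = list(kind = act$kind, target = act$target,
                   stage_t = stage_t, stage_t1 = state$stage,
                   in_extracted = in_extracted, i_phy = i_phy,
                   revealed = revealed, forced = state$forced))
}

#' Roll out a uniformly random legal policy
#'
#' Used as the random-legal-action baseline and for stage-machine fuzzing.
#'
#' @param record,cat,n_t_max as in [env_reset()].
#' @param p_terminate probability of picking terminate when legal inquiry
#'   actions remain; `NULL` (default) draws uniformly over all legal
#'   actions, terminate included; `0` inquires until the budget forces
#'   termination.
#' @param actions optional precomputed action table.
#' @return list `state` (terminal), `steps` (list of step infos),
#'   `asked` (in order).
#' @export
random_rollout <- function(record, cat, n_t_max, p_terminate = NULL,
                           actions = action_table(cat)) {
  state <- env_reset(record, cat, n_t_max)
  term_idx <- which(actions$kind == "terminate")
  steps <- list()
  asked <- character(0)
  repeat {
    mask <- legal_action_mask(state, cat, actions)
    inquiries <- setdiff(which(mask), term_idx)
    idx <- if (!length(inquiries)) {
      term_idx
    } else if (is.null(p_terminate)) {
      legal <- which(mask)
      legal[sample.int(length(legal), 1L)]
    } else if (stats::runif(1) < p_terminate) {
      term_idx
    } else {
      inquiries[sample.int(length(inquiries), 1L)]
    }
    res <- env_step(state, idx, record, cat, actions)
    state <- res$state
    steps[[length(steps) + 1L]] <- res$info
    if (!is.na(res$info$target)) asked <- c(asked, res$info$target)
    if (state$done || state$forced) break
  }
  list(state = state, steps = steps, asked = asked)
}
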