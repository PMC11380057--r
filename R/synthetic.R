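#' Synthetic EHR worlds
#'
#' A synthetic world stands in for a hospital's outpatient record
#' distribution: a feature catalog, a prior over diagnosis labels (single
#' diseases and two-disease combinations, each combination a class of its
#' own), disease-conditional feature emission, and a stochastic physician
#' policy that decides which items get asked — and therefore which features
#' end up in a record's extracted set. Records sampled from a world have the
#' structure the inquiry agent assumes: chief concerns are a small set of
#' positive symptom features, physician sequences are stage-ordered
#' (SMH, then PE, then AE panels), and one AE panel inquiry yields all of the
#' panel's recorded features.
#'
#' Emission is parameterized by a per-(label, feature) positivity rate:
#' signature features of a disease are positive with probability
#' `0.5 + 0.45 * separability` against a background of
#' `0.5 - 0.45 * separability`, so `separability = 1` gives the 0.95-vs-0.05
#' extremes. The default world is history-rich and syndromic, mirroring a
#' department whose prevalent diseases present alike: a pool of "common
#' symptoms" (fever/cough analogues) is frequently positive under every
#' disease and is what patients lead with as chief concerns, so the initial
#' state is only weakly disease-identifying; the discriminative signal sits
#' mainly in per-disease signature SMH features that surface only on
#' questioning, plus one signature PE finding per disease, while the AE
#' panels are nonspecific routine labs. Because the inquiry stages only move
#' forward, an agent that rushes past the history forfeits most of the
#' attainable information — the structure that separates a considered
#' inquiry policy from random probing. Tri-level lab features split their
#' positive mass
#' 0.8 high / 0.2 low. Compound labels emit the union of their constituents'
#' signatures (element-wise maximum rate).
#'
#' @name synthetic-world
NULL

#' World generator configuration
#'
#' @param n_diseases number of atomic diseases (= number of label classes).
#' @param n_smh,n_pe,n_ae feature counts per stage.
#' @param n_panels number of AE panels; `panel_sizes` must partition `n_ae`
#'   (default near-equal).
#' @param separability contrast between signature and background emission
#'   rates, in (0, 1].
#' @param compound_fraction probability that a label class is a two-disease
#'   combination.
#' @param seed integer seed; the world is a deterministic function of the
#'   config.
#' @param sig_smh,sig_pe,sig_panels signature items per atomic disease.
#' @param n_common SMH features shared as common symptoms across all diseases.
#' @param p_sig,p_noise physician ask-probabilities for signature/common vs
#'   other items.
#' @param common_rate positivity rate of common symptoms under every disease.
#' @param chief_common_first patients lead with common symptoms: chief
#'   concerns are drawn from positive common symptoms whenever any exist,
#'   so specific complaints surface only on questioning.
#' @param chief_range min/max number of chief concerns.
#' @return a `WorldConfig` list.
#' @export
world_config <- function(n_diseases = 4, n_smh = 14, n_pe = 8, n_ae = 8,
                         n_panels = 3, panel_sizes = NULL,
                         separability = 0.9, compound_fraction = 0.25,
                         seed = 1L,
                         sig_smh = 2, sig_pe = 1, sig_panels = 0,
                         n_common = min(4, n_smh),
                         p_sig = 0.9, p_noise = 0.15, common_rate = 0.6,
                         chief_common_first = TRUE, chief_range = c(1, 3)) {
  if (is.null(panel_sizes)) {
    base <- n_ae %/% n_panels
    panel_sizes <- rep(base, n_panels)
    extra <- n_ae - sum(panel_sizes)
    if (extra > 0) panel_sizes[seq_len(extra)] <- panel_sizes[seq_len(extra)] + 1
  }
  if (sum(panel_sizes) != n_ae) stop("panel sizes must sum to n_ae")
  stopifnot(n_diseases >= 2, n_smh >= 1, n_pe >= 1, n_ae >= 1,
            separability > 0, separability <= 1,
            compound_fraction >= 0, compound_fraction <= 1)
  structure(list(n_diseases = n_diseases, n_smh = n_smh, n_pe = n_pe,
                 n_ae = n_ae, n_panels = n_panels, panel_sizes = panel_sizes,
                 separability = separability,
                 compound_fraction = compound_fraction, seed = as.integer(seed),
                 sig_smh = sig_smh, sig_pe = sig_pe, sig_panels = sig_panels,
                 n_common = n_common, p_sig = p_sig, p_noise = p_noise,
                 common_rate = common_rate,
                 chief_common_first = chief_common_first,
                 chief_range = chief_range),
            class = "WorldConfig")
}

pad_ids <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))

deal_items <- function(pool, n_groups, per_group) {
  # deal items round-robin from a shuffled pool, reshuffling when exhausted,
  # so signatures spread across diseases before any overlap appears
  out <- vector("list", n_groups)
  bag <- sample(pool)
  for (g in seq_len(n_groups)) {
    take <- character(0)
    while (length(take) < per_group) {
      if (!length(bag)) bag <- sample(pool)
      k <- min(per_group - length(take), length(bag))
      take <- unique(c(take, bag[seq_len(k)]))
      bag <- bag[-seq_len(k)]
    }
    out[[g]] <- take
  }
  out
}

#' Generate a synthetic world
#'
#' Deterministic under `cfg$seed`. Each atomic disease gets designated
#' signature SMH/PE features and signature AE panels whose emission rate
#' exceeds the background by an amount monotone in `separability`.
#'
#' @param cfg a [world_config()].
#' @return a `SyntheticWorld`.
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "WorldConfig"))
  set.seed(cfg$seed)

  smh_ids <- pad_ids("smh", cfg$n_smh)
  pe_ids <- pad_ids("pe", cfg$n_pe)
  ae_ids <- pad_ids("ae", cfg$n_ae)
  panel_ids <- pad_ids("pnl", cfg$n_panels)
  panel_assign <- rep(panel_ids, times = cfg$panel_sizes)

  features <- data.frame(
    id = c(smh_ids, pe_ids, ae_ids),
    stage = c(rep("SMH", cfg$n_smh), rep("PE", cfg$n_pe), rep("AE", cfg$n_ae)),
    domain = c(rep("binary", cfg$n_smh + cfg$n_pe), rep("tri_level", cfg$n_ae)),
    panel = c(rep(NA_character_, cfg$n_smh + cfg$n_pe), panel_assign),
    stringsAsFactors = FALSE)
  cat <- feature_catalog(features)

  diseases <- pad_ids("dis", cfg$n_diseases)
  common <- smh_ids[seq_len(cfg$n_common)]
  sig_pool_smh <- setdiff(smh_ids, common)
  if (!length(sig_pool_smh)) sig_pool_smh <- smh_ids

  sig_smh <- deal_items(sig_pool_smh, cfg$n_diseases, min(cfg$sig_smh, length(sig_pool_smh)))
  sig_pe <- deal_items(pe_ids, cfg$n_diseases, min(cfg$sig_pe, length(pe_ids)))
  sig_pnl <- deal_items(panel_ids, cfg$n_diseases, min(cfg$sig_panels, length(panel_ids)))
  names(sig_smh) <- names(sig_pe) <- names(sig_pnl) <- diseases

  # label classes: every atomic disease, plus two-disease combinations as
  # separate categories (each disease spawns a combination with probability
  # compound_fraction)
  constituents <- as.list(diseases)
  for (i in seq_len(cfg$n_diseases)) {
    if (cfg$n_diseases >= 2 && stats::runif(1) < cfg$compound_fraction) {
      partner <- sample(setdiff(diseases, diseases[i]), 1L)
      cand <- sort(c(diseases[i], partner))
      if (!canonical_label(cand) %in% vapply(constituents, canonical_label,
                                             character(1))) {
        constituents[[length(constituents) + 1L]] <- cand
      }
    }
  }
  labels <- data.frame(label_id = seq_along(constituents),
                       label = vapply(constituents, canonical_label, character(1)),
                       stringsAsFactors = FALSE)
  labels$constituents <- constituents

  theta_sig <- 0.5 + 0.45 * cfg$separability
  theta_bg <- 0.5 - 0.45 * cfg$separability
  fids <- feature_ids(cat)
  theta <- matrix(theta_bg, nrow = nrow(labels), ncol = length(fids),
                  dimnames = list(labels$label, fids))
  theta[, common] <- cfg$common_rate
  for (i in seq_len(nrow(labels))) {
    for (d in constituents[[i]]) {
      sig_feats <- c(sig_smh[[d]], sig_pe[[d]],
                     unlist(cat$panels[sig_pnl[[d]]], use.names = FALSE))
      theta[i, sig_feats] <- pmax(theta[i, sig_feats], theta_sig)
    }
  }

  # combinations are less frequent than single diseases
  prior <- ifelse(lengths(constituents) == 2, 0.5, 1)
  prior <- prior / sum(prior)

  world <- structure(list(
    catalog = cat, diseases = diseases, labels = labels, prior = prior,
    theta = theta, theta_sig = theta_sig, theta_bg = theta_bg,
    common = common,
    signatures = list(smh = sig_smh, pe = sig_pe, panels = sig_pnl),
    policy = list(p_sig = cfg$p_sig, p_noise = cfg$p_noise),
    chief_range = cfg$chief_range,
    pos_split = c(high = 0.8, low = 0.2),
    cfg = cfg), class = "SyntheticWorld")
  world$mi <- feature_mutual_information(world)
  world
}

#' @export
print.SyntheticWorld <- function(x, ...) {
  cat(sprintf("SyntheticWorld: %d labels (%d compound), %d features, %d panels, separability %.2f\n",
              nrow(x$labels), sum(lengths(x$labels$constituents) == 2),
              nrow(x$catalog$features), length(x$catalog$panels),
              x$cfg$separability))
  invisible(x)
}

#' Per-level emission distribution of a feature under each label
#' @keywords internal
emission_dist <- function(world, feature) {
  th <- world$theta[, feature]
  i <- match(feature, feature_ids(world$catalog))
  if (world$catalog$features$domain[i] == "binary") {
    cbind(`0` = 1 - th, `1` = th)
  } else {
    cbind(low = th * world$pos_split[["low"]], normal = 1 - th,
          high = th * world$pos_split[["high"]])
  }
}

#' Mutual information of each feature with the diagnosis label
#' @keywords internal
feature_mutual_information <- function(world) {
  fids <- feature_ids(world$catalog)
  vapply(fids, function(f) {
    pvd <- emission_dist(world, f)              # labels x levels
    pv <- colSums(world$prior * pvd)            # marginal over levels
    ratio <- sweep(pvd, 2L, pv, `/`)
    sum(world$prior * rowSums(ifelse(pvd > 0, pvd * log(ratio), 0)))
  }, numeric(1))
}

order_by_informativeness <- function(items, mi_vals) {
  items[order(-mi_vals, items, method = "radix")]
}

#' Sample one patient record from a world
#'
#' Uses the current RNG state (seed at the call site for reproducibility).
#' The diagnosis is drawn from the world prior, feature values from the
#' label-conditional emission, the asked set from the physician policy
#' (signature and common items with probability `p_sig`, others `p_noise`;
#' AE at panel granularity), and 1-3 positive extracted SMH features become
#' the chief concerns. Records without a positive SMH feature are resampled
#' (bounded retries).
#'
#' @param world a `SyntheticWorld`.
#' @param max_retries resampling bound.
#' @return a validated `PatientRecord`.
#' @export
sample_record <- function(world, max_retries = 100L) {
  for (attempt in seq_len(max_retries)) {
    rec <- try_sample_record(world)
    if (!is.null(rec)) return(rec)
  }
  stop("failed to sample a record with a positive SMH feature after ",
       max_retries, " retries")
}

try_sample_record <- function(world) {
  cat <- world$catalog
  fids <- feature_ids(cat)
  li <- sample.int(nrow(world$labels), 1L, prob = world$prior)
  cons <- world$labels$constituents[[li]]

  # latent true values for every feature
  th <- world$theta[li, ]
  positive <- stats::runif(length(fids)) < th
  names(positive) <- fids
  values <- vapply(fids, function(f) {
    i <- match(f, fids)
    if (cat$features$domain[i] == "binary") {
      if (positive[f]) "1" else "0"
    } else if (positive[f]) {
      if (stats::runif(1) < world$pos_split[["high"]]) "high" else "low"
    } else "normal"
  }, character(1))

  sig_items <- unique(unlist(lapply(cons, function(d) {
    c(world$signatures$smh[[d]], world$signatures$pe[[d]])
  })))
  sig_panels <- unique(unlist(lapply(cons, function(d) world$signatures$panels[[d]])))

  smh_pe <- fids[cat$features$stage != "AE"]
  ask_p <- ifelse(smh_pe %in% c(sig_items, world$common),
                  world$policy$p_sig, world$policy$p_noise)
  asked_feats <- smh_pe[stats::runif(length(smh_pe)) < ask_p]

  panel_ids <- names(cat$panels)
  ask_p_pnl <- ifelse(panel_ids %in% sig_panels, world$policy$p_sig, world$policy$p_noise)
  asked_panels <- panel_ids[stats::runif(length(panel_ids)) < ask_p_pnl]

  extracted_ids <- c(asked_feats, unlist(cat$panels[asked_panels], use.names = FALSE))
  extracted <- as.list(values[extracted_ids])

  pos_smh <- asked_feats[cat$features$stage[match(asked_feats, fids)] == "SMH" &
                           values[asked_feats] == "1"]
  if (!length(pos_smh)) return(NULL)
  pool <- if (world$cfg$chief_common_first) {
    pc <- pos_smh[pos_smh %in% world$common]
    if (length(pc)) pc else pos_smh
  } else pos_smh
  n_cc <- min(length(pool),
              sample(seq(world$chief_range[1], world$chief_range[2]), 1L))
  cc_ids <- pool[sample.int(length(pool), n_cc)]
  chief <- as.list(values[cc_ids])

  seq_smh <- order_by_informativeness(
    asked_feats[cat$features$stage[match(asked_feats, fids)] == "SMH"],
    world$mi[asked_feats[cat$features$stage[match(asked_feats, fids)] == "SMH"]])
  seq_pe <- order_by_informativeness(
    asked_feats[cat$features$stage[match(asked_feats, fids)] == "PE"],
    world$mi[asked_feats[cat$features$stage[match(asked_feats, fids)] == "PE"]])
  pnl_mi <- vapply(asked_panels, function(p) max(world$mi[cat$panels[[p]]]), numeric(1))
  seq_ae <- if (length(asked_panels)) order_by_informativeness(asked_panels, pnl_mi) else character(0)

  rec <- patient_record(
    gender = if (stats::runif(1) < 0.55) "male" else "female",
    age = round(min(stats::rlnorm(1, log(5), 0.9), 95), 1),
    chief_concerns = chief, extracted = extracted,
    physician_sequence = c(seq_smh, seq_pe, seq_ae),
    diagnosis = list(constituents = cons, label_id = li))
  validate_record(rec, cat)
}

#' Sample many records under a fixed seed
#' @param world a `SyntheticWorld`; `n` count; `seed` integer.
#' @export
sample_records <- function(world, n, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) sample_record(world))
}

#' Generate a complete benchmark: world, records, splits, manifest
#'
#' Seeds for the record sample and the split are derived deterministically
#' from the config seed (`seed + 1` and `seed + 2`), so a benchmark is fully
#' reproducible from its manifest.
#'
#' @param cfg a [world_config()].
#' @param n number of records.
#' @param out optional directory; if given, writes `world.json` (config),
#'   `records.jsonl` and `manifest.json`.
#' @return list `world`, `records`, `splits`, `manifest`.
#' @export
make_benchmark <- function(cfg, n, out = NULL) {
  world <- generate_world(cfg)
  rec_seed <- cfg$seed + 1L
  split_seed <- cfg$seed + 2L
  records <- sample_records(world, n, seed = rec_seed)
  splits <- split_dataset(records, seed = split_seed)
  manifest <- list(cfg = unclass(cfg), n = n,
                   seeds = list(world = cfg$seed, records = rec_seed,
                                split = split_seed),
                   sizes = lengths(splits))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_catalog(world$catalog, file.path(out, "catalog.json"))
    write_records(records, file.path(out, "records.jsonl"))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(world = world, records = records, splits = splits, manifest = manifest)
}
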