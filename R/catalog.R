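#' Feature catalogs and patient records
#'
#' The feature catalog is the shared vocabulary of the whole system: every
#' inquirable item, its inquiry stage, its value domain, and — for auxiliary
#' examinations — the lab panel it belongs to. Features come in three stages:
#' \describe{
#'   \item{SMH}{symptom and medical history: questions the patient can answer.}
#'   \item{PE}{physical examination findings.}
#'   \item{AE}{auxiliary examinations: lab/imaging features grouped into
#'     panels; one panel inquiry reveals all its recorded features.}
#' }
#' Value domains are `binary` (0/1), `tri_level` (`"low"/"normal"/"high"`,
#' as for a lab value against its reference range), or `categorical` with k
#' named levels.
#'
#' @name catalog
NULL

STAGES <- c("SMH", "PE", "AE")
TRI_LEVELS <- c("low", "normal", "high")
GENDERS <- c("male", "female", "unknown")

#' Construct a feature catalog
#'
#' @param features data.frame with columns `id` (ASCII token), `stage`
#'   (`"SMH"`, `"PE"`, `"AE"`), `domain` (`"binary"`, `"tri_level"`,
#'   `"categorical"`), optionally `panel` (required iff stage is AE) and a
#'   list-column `levels` (required iff domain is categorical, k >= 2).
#' @param panels named list mapping panel id to character vector of AE
#'   feature ids. May be omitted: it is then derived from the `panel` column.
#' @return a `FeatureCatalog`: features reordered lexicographically by id
#'   (the fixed index order used by every vector in the system), with the
#'   panel map and per-feature level sets attached.
#' @export
feature_catalog <- function(features, panels = NULL) {
  stopifnot(is.data.frame(features), all(c("id", "stage", "domain") %in% names(features)))
  features$id <- as.character(features$id)
  if (anyDuplicated(features$id)) {
    stop("duplicate feature id(s): ",
         paste(unique(features$id[duplicated(features$id)]), collapse = ", "))
  }
  if (any(grepl("\\s", features$id)) || any(!validEnc(features$id))) {
    stop("feature ids must be ASCII tokens without whitespace")
  }
  bad <- !features$stage %in% STAGES
  if (any(bad)) stop("unknown stage for feature ", features$id[which(bad)[1L]])
  bad <- !features$domain %in% c("binary", "tri_level", "categorical")
  if (any(bad)) stop("unknown domain for feature ", features$id[which(bad)[1L]])

  if (!"panel" %in% names(features)) features$panel <- NA_character_
  features$panel[features$panel %in% ""] <- NA_character_
  ae <- features$stage == "AE"
  if (any(ae & is.na(features$panel))) {
    stop("AE feature without panel: ", features$id[which(ae & is.na(features$panel))[1L]])
  }
  if (any(!ae & !is.na(features$panel))) {
    stop("non-AE feature with panel: ", features$id[which(!ae & !is.na(features$panel))[1L]])
  }

  levels_list <- vector("list", nrow(features))
  names(levels_list) <- features$id
  if ("levels" %in% names(features)) {
    for (i in seq_len(nrow(features))) {
      lv <- features$levels[[i]]
      if (!is.null(lv) && length(lv)) levels_list[[i]] <- as.character(lv)
    }
  }
  for (i in seq_len(nrow(features))) {
    levels_list[[i]] <- switch(features$domain[i],
      binary = c("0", "1"),
      tri_level = TRI_LEVELS,
      categorical = {
        lv <- levels_list[[i]]
        if (is.null(lv) || length(lv) < 2) {
          stop("categorical feature needs >= 2 levels: ", features$id[i])
        }
        lv
      })
  }

  ord <- order(features$id, method = "radix")
  features <- features[ord, c("id", "stage", "domain", "panel"), drop = FALSE]
  rownames(features) <- NULL
  levels_list <- levels_list[features$id]

  derived <- split(features$id[features$stage == "AE"], features$panel[features$stage == "AE"])
  if (is.null(panels)) {
    panels <- derived
  } else {
    panels <- lapply(panels, as.character)
    if (!setequal(names(panels), names(derived)) ||
        !all(vapply(names(derived), function(p) setequal(panels[[p]], derived[[p]]), logical(1)))) {
      stop("panel map disagrees with per-feature panel assignments")
    }
  }
  if (any(lengths(panels) == 0)) stop("empty panel")
  panels <- lapply(panels[order(names(panels), method = "radix")],
                   function(x) sort(x, method = "radix"))

  structure(list(features = features, levels = levels_list, panels = panels),
            class = "FeatureCatalog")
}

validEnc <- function(x) !is.na(iconv(x, "UTF-8", "ASCII"))

#' @export
print.FeatureCatalog <- function(x, ...) {
  tab <- table(factor(x$features$stage, levels = STAGES))
  cat(sprintf("FeatureCatalog: %d features (SMH %d, PE %d, AE %d), %d panels\n",
              nrow(x$features), tab[["SMH"]], tab[["PE"]], tab[["AE"]],
              length(x$panels)))
  invisible(x)
}

#' Feature ids of a catalog in fixed index order
#' @param cat a `FeatureCatalog`.
#' @export
feature_ids <- function(cat) cat$features$id

#' Stage of a feature or panel id
#' @param item feature or panel id.
#' @param cat a `FeatureCatalog`.
#' @return `"SMH"`, `"PE"` or `"AE"`.
#' @export
stage_of <- function(item, cat) {
  out <- character(length(item))
  is_panel <- item %in% names(cat$panels)
  out[is_panel] <- "AE"
  rest <- !is_panel
  if (any(rest)) {
    m <- match(item[rest], cat$features$id)
    if (anyNA(m)) stop("unknown item: ", item[rest][which(is.na(m))[1L]])
    out[rest] <- cat$features$stage[m]
  }
  out
}

#' Panel of an AE feature
#' @keywords internal
panel_of <- function(feature, cat) {
  m <- match(feature, cat$features$id)
  cat$features$panel[m]
}

catalog_to_list <- function(cat) {
  feats <- lapply(seq_len(nrow(cat$features)), function(i) {
    f <- list(id = cat$features$id[i], stage = cat$features$stage[i],
              domain = cat$features$domain[i])
    if (f$domain == "categorical") f$levels <- cat$levels[[i]]
    if (!is.na(cat$features$panel[i])) f$panel <- cat$features$panel[i]
    f
  })
  list(features = feats, panels = cat$panels)
}

#' Write a catalog to JSON
#' @param cat a `FeatureCatalog`; `path` output file.
#' @export
write_catalog <- function(cat, path) {
  jsonlite::write_json(catalog_to_list(cat), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a feature catalog from JSON
#'
#' Schema: `{"features": [{"id", "stage", "domain", "levels"?, "panel"?}],
#' "panels": {panel_id: [feature ids]}}`. All invariants are validated and
#' the feature index order is fixed (lexicographic by id).
#' @param path JSON file path.
#' @return a `FeatureCatalog`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::read_json(path)
  if (is.null(raw$features)) stop("catalog JSON lacks 'features'")
  df <- data.frame(
    id = vapply(raw$features, function(f) as.character(f$id %||% stop("feature without id")), character(1)),
    stage = vapply(raw$features, function(f) as.character(f$stage %||% NA_character_), character(1)),
    domain = vapply(raw$features, function(f) as.character(f$domain %||% NA_character_), character(1)),
    panel = vapply(raw$features, function(f) as.character(f$panel %||% NA_character_), character(1)),
    stringsAsFactors = FALSE)
  df$levels <- lapply(raw$features, function(f) unlist(f$levels))
  feature_catalog(df, panels = lapply(raw$panels, unlist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a patient record
#'
#' One consultation: demographics, the presenting chief concerns, the full
#' extracted feature:value set (the ground truth a simulated patient can
#' reveal, including explicitly negative findings), the ordered physician
#' inquiry sequence (feature ids for SMH/PE, panel ids for AE), and the
#' reference diagnosis.
#'
#' @param gender `"male"`, `"female"` or `"unknown"`.
#' @param age non-negative years (fractional allowed).
#' @param chief_concerns named list, feature id -> value; subset of `extracted`.
#' @param extracted named list, feature id -> value.
#' @param physician_sequence character vector of inquiry items in the order
#'   the physician asked them (stage-ordered SMH, then PE, then AE panels).
#' @param diagnosis list with `constituents` (1-2 atomic disease ids) and
#'   `label_id` (dense class index over distinct single/compound labels).
#' @export
patient_record <- function(gender, age, chief_concerns, extracted,
                           physician_sequence, diagnosis) {
  structure(list(gender = gender, age = age,
                 chief_concerns = as.list(chief_concerns),
                 extracted = as.list(extracted),
                 physician_sequence = as.character(physician_sequence),
                 diagnosis = diagnosis),
            class = "PatientRecord")
}

#' @export
print.PatientRecord <- function(x, ...) {
  cat(sprintf("PatientRecord: %s, %.1f y; %d chief concerns; %d extracted; %d inquiries; dx=%s\n",
              x$gender, x$age, length(x$chief_concerns), length(x$extracted),
              length(x$physician_sequence),
              paste(x$diagnosis$constituents, collapse = "+")))
  invisible(x)
}

value_in_domain <- function(value, feature, cat) {
  i <- match(feature, cat$features$id)
  if (is.na(i)) return(FALSE)
  if (cat$features$domain[i] == "binary") {
    return(isTRUE(value %in% c(0, 1, "0", "1", TRUE, FALSE)))
  }
  isTRUE(as.character(value) %in% cat$levels[[i]])
}

#' Validate a patient record against a catalog
#'
#' Checks that every value lies in its feature's declared domain, chief
#' concerns are a subset of the extracted set, every physician-sequence item
#' resolves to extracted features (panels to at least one extracted panel
#' member), and the sequence is stage-ordered SMH before PE before AE.
#'
#' @param rec a `PatientRecord`; `cat` a `FeatureCatalog`.
#' @return the record, unchanged, if valid; otherwise an error.
#' @export
validate_record <- function(rec, cat) {
  stopifnot(inherits(rec, "PatientRecord"), inherits(cat, "FeatureCatalog"))
  if (!rec$gender %in% GENDERS) stop("invalid gender: ", rec$gender)
  if (!is.numeric(rec$age) || rec$age < 0) stop("invalid age")
  for (f in names(rec$extracted)) {
    if (!value_in_domain(rec$extracted[[f]], f, cat)) {
      stop("value out of domain for feature ", f, ": ", rec$extracted[[f]])
    }
  }
  for (f in names(rec$chief_concerns)) {
    if (!f %in% names(rec$extracted) ||
        !identical(as.character(rec$chief_concerns[[f]]), as.character(rec$extracted[[f]]))) {
      stop("chief concern not in extracted: ", f)
    }
  }
  seq_items <- rec$physician_sequence
  if (anyDuplicated(seq_items)) stop("duplicate item in physician_sequence")
  stages <- stage_of(seq_items, cat)
  if (is.unsorted(match(stages, STAGES))) {
    stop("physician_sequence violates stage order SMH -> PE -> AE")
  }
  for (i in seq_along(seq_items)) {
    it <- seq_items[i]
    if (stages[i] == "AE") {
      if (!it %in% names(cat$panels)) stop("AE item is not a panel id: ", it)
      if (!any(cat$panels[[it]] %in% names(rec$extracted))) {
        stop("physician panel with no extracted feature: ", it)
      }
    } else if (!it %in% names(rec$extracted)) {
      stop("physician item not in extracted: ", it)
    }
  }
  ncons <- length(rec$diagnosis$constituents)
  if (ncons < 1 || ncons > 2) stop("diagnosis must have 1-2 constituents")
  rec
}

#' Canonical label string for a constituent set
#' @param constituents character vector of atomic disease ids.
#' @export
canonical_label <- function(constituents) {
  paste(sort(as.character(constituents), method = "radix"), collapse = "+")
}

record_to_list <- function(rec) {
  list(gender = rec$gender, age = rec$age,
       chief_concerns = rec$chief_concerns[order(names(rec$chief_concerns), method = "radix")],
       extracted = rec$extracted[order(names(rec$extracted), method = "radix")],
       physician_sequence = as.list(rec$physician_sequence),
       diagnosis = list(constituents = as.list(rec$diagnosis$constituents),
                        label_id = rec$diagnosis$label_id))
}

#' Write patient records to JSON lines
#' @param records list of `PatientRecord`; `path` output `.jsonl` file.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read patient records from JSON lines
#' @param path `.jsonl` file, one record per line.
#' @return list of `PatientRecord`.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lapply(readLines(path, warn = FALSE), function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    patient_record(gender = r$gender, age = r$age,
                   chief_concerns = r$chief_concerns, extracted = r$extracted,
                   physician_sequence = unlist(r$physician_sequence),
                   diagnosis = list(constituents = unlist(r$diagnosis$constituents),
                                    label_id = as.integer(r$diagnosis$label_id)))
  })
}

#' Split records into train/validation/test
#'
#' Random disjoint partition in proportions 75/10/15 using largest-remainder
#' rounding, reproducible under a fixed seed.
#'
#' @param records list of records (length >= 20).
#' @param seed integer seed.
#' @param props length-3 proportions summing to 1.
#' @return named list `train`, `validation`, `test`.
#' @export
split_dataset <- function(records, seed, props = c(0.75, 0.10, 0.15)) {
  n <- length(records)
  if (n == 0) stop("empty input")
  if (n < 20) stop("need at least 20 records to split")
  stopifnot(abs(sum(props) - 1) < 1e-9)
  sizes <- largest_remainder(n, props)
  set.seed(seed)
  perm <- sample.int(n)
  cut1 <- sizes[1L]
  cut2 <- sizes[1L] + sizes[2L]
  list(train = records[perm[seq_len(cut1)]],
       validation = records[perm[(cut1 + 1L):cut2]],
       test = records[perm[(cut2 + 1L):n]])
}

#' Largest-remainder apportionment of n items to proportions
#' @keywords internal
largest_remainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    give <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}
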