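#' Split free text into sentences
#'
#' Deliberately simple, punctuation-level segmentation (periods, semicolons
#' and newlines) matching a regex-level extraction algorithm. Colons do not
#' end a sentence, so list-style clinical shorthand ("CT: SDH and SAH")
#' stays in one sentence.
#'
#' @param text character scalar (may be empty or `NA`).
#' @return Character vector of trimmed, non-empty sentences.
#' @keywords internal
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  out <- trimws(strsplit(text, "[.;\n]+")[[1]])
  out[nzchar(out)]
}

#' Extract lexicon term hits from a clinical narrative
#'
#' Scans a free-text narrative for every lexicon pattern (case-insensitive,
#' word-bounded) and records one hit per match together with the enclosing
#' sentence for context, mirroring an auditable search-then-review workflow.
#' Negation is not assessed here; see [filter_false_positives()].
#'
#' @param narrative character scalar of free text; may be empty.
#' @param lexicon a [read_lexicon()] object.
#' @param subject_id identifier attached to the hits (default `NA`).
#' @return A `term_hits` data frame with columns `subject_id`,
#'   `canonical_term`, `category`, `pathology_code`, `matched_text`,
#'   `sentence`, `match_start` (character offset of the match within the
#'   sentence) and `negated` (all `NA` until filtered).
#' @examples
#' lex <- read_lexicon()
#' extract_term_hits("Large acute subdural haematoma evacuated.", lex)
#' @export
extract_term_hits <- function(narrative, lexicon, subject_id = NA_character_) {
  stopifnot(length(narrative) == 1)
  extract_term_hits_bulk(
    data.frame(subject_id = as.character(subject_id),
               narrative = as.character(narrative),
               stringsAsFactors = FALSE),
    lexicon)
}

# Vectorised extraction over many subjects: one gregexpr call per lexicon
# pattern across all sentences, rather than per narrative.
extract_term_hits_bulk <- function(subjects, lexicon) {
  stopifnot(all(c("subject_id", "narrative") %in% names(subjects)))
  sent_list <- lapply(subjects$narrative, split_sentences)
  n_sent <- lengths(sent_list)
  sents <- data.frame(subject_id = rep(subjects$subject_id, n_sent),
                      sentence = unlist(sent_list, use.names = FALSE),
                      stringsAsFactors = FALSE)
  empty <- empty_hits()
  if (nrow(sents) == 0) return(empty)
  pats <- lexicon$patterns
  out <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    rx <- pattern_regex(pats$pattern[i])
    m <- gregexpr(rx, sents$sentence, perl = TRUE)
    starts <- lapply(m, function(x) if (x[1] == -1) integer(0) else as.integer(x))
    lens <- lapply(m, function(x) if (x[1] == -1) integer(0) else attr(x, "match.length"))
    k <- lengths(starts)
    if (sum(k) == 0) next
    rows <- rep(seq_len(nrow(sents)), k)
    st <- unlist(starts)
    ln <- unlist(lens)
    out[[i]] <- data.frame(
      subject_id = sents$subject_id[rows],
      canonical_term = pats$canonical_term[i],
      category = pats$category[i],
      pathology_code = pats$pathology_code[i],
      matched_text = substr(sents$sentence[rows], st, st + ln - 1L),
      sentence = sents$sentence[rows],
      match_start = st,
      negated = NA,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  hits <- do.call(rbind, out)
  hits <- hits[order(match(hits$subject_id, subjects$subject_id),
                     hits$sentence, hits$match_start), ]
  rownames(hits) <- NULL
  class(hits) <- c("term_hits", "data.frame")
  hits
}

empty_hits <- function() {
  h <- data.frame(subject_id = character(0), canonical_term = character(0),
                  category = character(0), pathology_code = character(0),
                  matched_text = character(0), sentence = character(0),
                  match_start = integer(0), negated = logical(0),
                  stringsAsFactors = FALSE)
  class(h) <- c("term_hits", "data.frame")
  h
}

#' Remove negated term hits
#'
#' Marks a hit as negated (a false positive) when a negation cue token
#' ("no", "not", "denies", ...) occurs in the same sentence, before the
#' match, within a window of three tokens, and with no intervening clause
#' punctuation (comma or colon). Clause punctuation ends the negation scope,
#' so "Not obviously related: subarachnoid haemorrhage present" retains the
#' hit. All non-negated hits pass through unchanged.
#'
#' @param hits a `term_hits` data frame from [extract_term_hits()].
#' @param lexicon a [read_lexicon()] object supplying the negation cues.
#' @param keep_negated if `TRUE`, return all hits with the `negated` flag
#'   filled in (for audit logs); if `FALSE` (default) drop negated hits.
#' @return The surviving `term_hits`, `negated` column filled in.
#' @examples
#' lex <- read_lexicon()
#' h <- extract_term_hits("No subdural haematoma seen.", lex)
#' filter_false_positives(h, lex)            # empty
#' filter_false_positives(h, lex, TRUE)      # flagged, retained for audit
#' @export
filter_false_positives <- function(hits, lexicon, keep_negated = FALSE) {
  if (nrow(hits) == 0) return(hits)
  stopifnot(all(!is.na(hits$sentence)))
  hits$negated <- vapply(seq_len(nrow(hits)), function(i) {
    is_negated(hits$sentence[i], hits$match_start[i], lexicon$negation_cues)
  }, logical(1))
  if (!keep_negated) hits <- hits[!hits$negated, , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("term_hits", "data.frame")
  hits
}

# negation window: cue token among the 3 tokens before the match, same
# sentence, no comma/colon between cue and match
is_negated <- function(sentence, match_start, cues, window = 3L) {
  before <- substr(sentence, 1, match_start - 1L)
  m <- gregexpr("\\S+", before, perl = TRUE)[[1]]
  if (m[1] == -1) return(FALSE)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- substr(rep(before, length(starts)), starts, starts + lens - 1L)
  take <- max(1L, length(toks) - window + 1L):length(toks)
  for (j in take) {
    clean <- gsub("[^a-z]", "", tolower(toks[j]))
    if (clean %in% cues) {
      between <- substr(sentence, starts[j] + lens[j], match_start - 1L)
      if (!grepl("[,:]", between)) return(TRUE)
    }
  }
  FALSE
}

#' Build a per-subject TBI profile from surviving term hits
#'
#' Combines surviving (non-negated) hits into per-subject pathology and
#' symptom flags, determines the skull-fracture subtype from the matched
#' text, and copies the clinical fields through. The Mayo severity slot is
#' left unset until [classify_mayo()].
#'
#' @param hits `term_hits` for a single subject (may be empty).
#' @param clinical named list with `gcs`, `loc_minutes`, `pta_hours`,
#'   `death_due_to_tbi`; missing elements are treated as unknown.
#' @param subject_id subject identifier; required when `hits` is empty.
#' @return A `tbi_profile` list: `subject_id`, logical pathology flags
#'   (`SDH`, `SAH`, `EDH`, `focal`, `DAI`, `skull_fracture`),
#'   `fracture_subtype`, named logical `symptoms`, clinical fields and
#'   `mayo_severity = NA`.
#' @export
build_tbi_profile <- function(hits, clinical = list(), subject_id = NULL) {
  ids <- unique(hits$subject_id[!is.na(hits$subject_id)])
  if (length(ids) > 1)
    stop("hits belong to multiple subjects: ", paste(ids, collapse = ", "))
  if (is.null(subject_id)) subject_id <- if (length(ids)) ids else NA_character_
  path_hits <- hits[hits$category == "pathology", , drop = FALSE]
  flags <- setNames(pathology_codes %in% path_hits$pathology_code, pathology_codes)
  subtype <- "none"
  if (flags[["skull_fracture"]]) {
    sf <- path_hits[path_hits$pathology_code == "skull_fracture", , drop = FALSE]
    txt <- tolower(paste(sf$sentence, collapse = " "))
    subtype <- if (grepl("depressed", txt)) "depressed"
      else if (grepl("basilar|base of skull|\\bbos\\b", txt)) "basilar"
      else if (grepl("linear", txt)) "linear"
      else "unspecified"
  }
  sym_hits <- hits[hits$category == "symptom", , drop = FALSE]
  symptoms <- setNames(symptom_terms %in% sym_hits$canonical_term, symptom_terms)
  structure(list(
    subject_id = subject_id,
    SDH = unname(flags[["SDH"]]), SAH = unname(flags[["SAH"]]),
    EDH = unname(flags[["EDH"]]), focal = unname(flags[["focal"]]),
    DAI = unname(flags[["DAI"]]),
    skull_fracture = unname(flags[["skull_fracture"]]),
    fracture_subtype = subtype,
    symptoms = symptoms,
    death_due_to_tbi = isTRUE(clinical$death_due_to_tbi),
    gcs_worst = clinical$gcs %||% NA_real_,
    loc_minutes = clinical$loc_minutes %||% NA_real_,
    pta_hours = clinical$pta_hours %||% NA_real_,
    mayo_severity = NA_character_), class = "tbi_profile")
}

#' Mayo classification rule table
#'
#' The Mayo Clinic system thresholds encoded as data so they are auditable
#' and overridable: moderate-severe requires death due to TBI, loss of
#' consciousness of 30 min or more, post-traumatic amnesia of 24 h or more,
#' worst GCS below 13, or intracranial pathology (SDH, SAH, EDH, focal
#' injury or DAI); mild (probable) requires briefer LOC or amnesia, or a
#' skull fracture; symptomatic (possible) requires at least one symptom.
#'
#' @return Named list of thresholds used by [classify_mayo()].
#' @export
mayo_rules <- function() {
  list(loc_modsev_min = 30, pta_modsev_hours = 24, gcs_modsev_below = 13,
       intracranial = c("SDH", "SAH", "EDH", "focal", "DAI"),
       mild_fracture = TRUE)
}

#' Classify Mayo TBI severity from a profile
#'
#' Applies the Mayo Clinic classification to a [build_tbi_profile()] object.
#' Missing clinical fields are treated as not satisfying their criterion,
#' so classification is conservative under incomplete records. The
#' intracranial-pathology criterion dominates: any of SDH/SAH/EDH/focal/DAI
#' forces `moderate_severe` regardless of GCS or LOC.
#'
#' @param profile a `tbi_profile`.
#' @param rules rule table, default [mayo_rules()].
#' @return One of `"none"`, `"symptomatic_possible"`, `"mild_probable"`,
#'   `"moderate_severe"`.
#' @examples
#' lex <- read_lexicon()
#' h <- filter_false_positives(extract_term_hits("Acute SDH on CT.", lex), lex)
#' classify_mayo(build_tbi_profile(h))
#' @export
classify_mayo <- function(profile, rules = mayo_rules()) {
  ge <- function(x, t) !is.na(x) && x >= t
  between <- function(x, lo, hi) !is.na(x) && x > lo && x < hi
  intracranial <- any(vapply(rules$intracranial, function(f) isTRUE(profile[[f]]),
                             logical(1)))
  if (isTRUE(profile$death_due_to_tbi) ||
      ge(profile$loc_minutes, rules$loc_modsev_min) ||
      ge(profile$pta_hours, rules$pta_modsev_hours) ||
      (!is.na(profile$gcs_worst) && profile$gcs_worst < rules$gcs_modsev_below) ||
      intracranial)
    return("moderate_severe")
  if (between(profile$loc_minutes, 0, rules$loc_modsev_min) ||
      between(profile$pta_hours, 0, rules$pta_modsev_hours) ||
      (rules$mild_fracture && isTRUE(profile$skull_fracture)))
    return("mild_probable")
  if (any(profile$symptoms)) return("symptomatic_possible")
  "none"
}

#' @export
print.tbi_profile <- function(x, ...) {
  flags <- pathology_codes[vapply(pathology_codes, function(f) isTRUE(x[[f]]), logical(1))]
  cat("TBI profile for subject", x$subject_id, "\n")
  cat("  pathology:", if (length(flags)) paste(flags, collapse = ", ") else "none", "\n")
  cat("  symptoms:", if (any(x$symptoms)) paste(names(x$symptoms)[x$symptoms], collapse = ", ") else "none", "\n")
  cat("  GCS", x$gcs_worst, "| LOC", x$loc_minutes, "min | PTA", x$pta_hours, "h\n")
  cat("  Mayo severity:", x$mayo_severity, "\n")
  invisible(x)
}

#' Classify a table of subjects from their narratives
#'
#' Runs the full free-text pipeline (extraction, negation filtering, profile
#' construction, Mayo classification) over a subject table, one row per
#' subject. This is the driver used by the pipeline and by the round-trip
#' validation against the synthetic generator's ground truth.
#'
#' @param subjects data frame with `subject_id`, `narrative` and optional
#'   clinical columns `gcs`, `loc_minutes`, `pta_hours`, `death_due_to_tbi`.
#' @param lexicon a [read_lexicon()] object.
#' @return A list with `profiles` (data frame: subject_id, pathology flags,
#'   fracture subtype, symptom count, `mayo_severity`) and `hits` (the full
#'   annotated hit log for audit, negated rows included).
#' @export
classify_subjects <- function(subjects, lexicon) {
  stopifnot(all(c("subject_id", "narrative") %in% names(subjects)))
  hits <- extract_term_hits_bulk(subjects, lexicon)
  hits <- filter_false_positives(hits, lexicon, keep_negated = TRUE)
  surviving <- hits[!hits$negated, , drop = FALSE]
  by_subject <- split(seq_len(nrow(surviving)), surviving$subject_id)
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    sid <- as.character(subjects$subject_id[i])
    idx <- by_subject[[sid]] %||% integer(0)
    clinical <- list(
      gcs = if ("gcs" %in% names(subjects)) subjects$gcs[i] else NA,
      loc_minutes = if ("loc_minutes" %in% names(subjects)) subjects$loc_minutes[i] else NA,
      pta_hours = if ("pta_hours" %in% names(subjects)) subjects$pta_hours[i] else NA,
      death_due_to_tbi = if ("death_due_to_tbi" %in% names(subjects))
        isTRUE(subjects$death_due_to_tbi[i]) else FALSE)
    prof <- build_tbi_profile(surviving[idx, , drop = FALSE], clinical, subject_id = sid)
    prof$mayo_severity <- classify_mayo(prof)
    data.frame(subject_id = sid,
               SDH = prof$SDH, SAH = prof$SAH, EDH = prof$EDH,
               focal = prof$focal, DAI = prof$DAI,
               skull_fracture = prof$skull_fracture,
               fracture_subtype = prof$fracture_subtype,
               n_symptoms = sum(prof$symptoms),
               mayo_severity = prof$mayo_severity,
               stringsAsFactors = FALSE)
  })
  list(profiles = do.call(rbind, rows), hits = hits)
}
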