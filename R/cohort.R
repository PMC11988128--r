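# Cohort preparation: inclusion criteria, observation windows, SOEP document
# construction, extreme-length exclusion and the stratified three-way split.

#' Index date of a patient record
#'
#' The anchor for observation windows and age: the diagnosis date for cases,
#' the last GP visit for controls.
#'
#' @param record A patient record (see [generate_corpus()]).
#' @return A `Date`.
#' @export
index_date <- function(record) {
  if (!is.null(record$diagnosis_date)) record$diagnosis_date else record$last_visit_date
}

age_at <- function(record, date) {
  as.numeric(date - record$birth_date) / 365.25
}

#' Apply the cohort inclusion criteria
#'
#' Retains patients older than 30 years at the index date. Cases must in
#' addition have at least one note before diagnosis and have joined (first
#' visit) at least 5 months before diagnosis. Months are 30-day intervals.
#'
#' @param records List of patient records.
#' @return The retained records (possibly empty).
#' @export
apply_inclusion_criteria <- function(records) {
  keep <- vapply(records, function(r) {
    idx <- index_date(r)
    if (age_at(r, idx) <= 30) return(FALSE)
    if (!is.null(r$diagnosis_date)) {
      vdates <- vapply(r$visits, function(v) as.numeric(v$date), numeric(1))
      if (!any(vdates < as.numeric(r$diagnosis_date))) return(FALSE)
      if (min(vdates) > as.numeric(r$diagnosis_date) - months_to_days(5)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  records[keep]
}

observation_window <- function(record) {
  if (!is.null(record$diagnosis_date)) {
    # two years of history ending 5 months before diagnosis
    c(record$diagnosis_date - months_to_days(29),
      record$diagnosis_date - months_to_days(5))
  } else {
    # the same two-year length, ending one month before the last visit
    c(record$last_visit_date - months_to_days(25),
      record$last_visit_date - months_to_days(1))
  }
}

#' Restrict a record to its observation window
#'
#' Cases keep visits dated within \[diagnosis - 29 months, diagnosis - 5
#' months\]; controls within \[last visit - 25 months, last visit - 1 month\]
#' (30-day months, both ends inclusive). Patients with no visits in the window
#' are dropped.
#'
#' @param record A patient record that passed inclusion.
#' @return The record with `visits` filtered, or `NULL` if no visit survives.
#' @export
extract_observation_window <- function(record) {
  w <- observation_window(record)
  keep <- vapply(record$visits,
                 function(v) v$date >= w[1] && v$date <= w[2], logical(1))
  if (!any(keep)) return(NULL)
  record$visits <- record$visits[keep]
  record
}

filter_observation_windows <- function(records) {
  out <- lapply(records, extract_observation_window)
  out[!vapply(out, is.null, logical(1))]
}

#' Tokenize free text for document construction
#'
#' Lowercases, splits on whitespace, strips leading/trailing punctuation and
#' keeps internal hyphens; suitable for unigram embedding training.
#'
#' @param x Character vector of raw text.
#' @return Character vector of tokens.
#' @export
tokenize_text <- function(x) {
  toks <- unlist(strsplit(tolower(paste(x, collapse = " ")), "\\s+"))
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Build the model input document for one patient
#'
#' Each in-window visit becomes one sentence: the literal marker tokens
#' `"S"`, `"O"`, `"E"`, `"P"`, each followed by that field's tokens (an empty
#' field contributes its marker only), in date order. Structured predictors
#' are computed at the index date: age in years, sex (male = 1), and counts of
#' the eleven ICPC codes restricted to the same observation window.
#'
#' @param record A record with in-window visits (see
#'   [extract_observation_window()]).
#' @return A list of class `"soep_document"` with fields `patient_id`,
#'   `sentences` (list of token vectors), `dates`, `structured` (named numeric,
#'   length 13) and `label`.
#' @export
build_document <- function(record) {
  stopifnot(length(record$visits) >= 1L)
  ord <- order(vapply(record$visits, function(v) as.numeric(v$date), numeric(1)))
  visits <- record$visits[ord]
  sentences <- lapply(visits, function(v) {
    c("S", v$s_field, "O", v$o_field, "E", v$e_field, "P", v$p_field)
  })
  w <- observation_window(record)
  ev <- record$icpc_events
  in_w <- ev$date >= w[1] & ev$date <= w[2]
  counts <- table(factor(ev$code[in_w], levels = icpc_codes()))
  structured <- c(
    age = age_at(record, index_date(record)),
    sex = as.numeric(identical(record$sex, "male")),
    as.numeric(counts)
  )
  names(structured) <- c("age", "sex", icpc_codes())
  doc <- list(
    patient_id = record$patient_id,
    sentences = sentences,
    dates = as.Date(vapply(visits, function(v) format(v$date), character(1))),
    structured = structured,
    label = as.integer(record$label)
  )
  class(doc) <- "soep_document"
  doc
}

doc_word_count <- function(doc) sum(lengths(doc$sentences))

#' Exclude extreme-length documents
#'
#' Removes documents whose total word count lies strictly above the empirical
#' `quantile` (default 99.7th, the 3-sigma convention) of per-patient word
#' counts, recomputed on the corpus at hand.
#'
#' @param documents List of `soep_document`s.
#' @param quantile Percentile above which documents are excluded.
#' @return The retained documents.
#' @export
exclude_long_documents <- function(documents, quantile = 0.997) {
  stopifnot(length(documents) >= 1L)
  counts <- vapply(documents, doc_word_count, numeric(1))
  thr <- stats::quantile(counts, quantile, names = FALSE)
  documents[counts <= thr]
}

#' Outcome-stratified 60/20/20 split
#'
#' Assigns each patient to the training (60%), tuning (20%) or testing (20%)
#' fold, preserving the case fraction in each fold within integer rounding.
#'
#' @param documents List of `soep_document`s (or any list with `patient_id`
#'   and `label` fields).
#' @param seed Integer seed; the assignment is reproducible.
#' @param props Fold proportions (train, tune, test), summing to 1.
#' @return A data.frame with columns `patient_id` and `fold`
#'   (`train`/`tune`/`test`), with the seed stored in attribute `split_seed`.
#' @export
stratified_split <- function(documents, seed, props = c(0.6, 0.2, 0.2)) {
  stopifnot(abs(sum(props) - 1) < 1e-8)
  ids <- vapply(documents, function(d) d$patient_id, character(1))
  labels <- vapply(documents, function(d) as.integer(d$label), integer(1))
  stopifnot(!anyDuplicated(ids))
  n_case <- sum(labels == 1L)
  if (n_case > 0L && any(labels == 0L) && n_case < 3L) {
    stop_config("stratified_split: fewer cases (%d) than splits", n_case)
  }
  fold <- character(length(ids))
  with_seed(seed, {
    for (lab in unique(labels)) {
      at <- which(labels == lab)
      at <- at[sample.int(length(at))]
      m <- length(at)
      b1 <- round(props[1] * m)
      b2 <- round((props[1] + props[2]) * m)
      fold[at[seq_len(b1)]] <- "train"
      if (b2 > b1) fold[at[(b1 + 1):b2]] <- "tune"
      if (m > b2) fold[at[(b2 + 1):m]] <- "test"
    }
  })
  out <- data.frame(patient_id = ids, fold = fold, stringsAsFactors = FALSE)
  attr(out, "split_seed") <- as.integer(seed)
  out
}

#' Full cohort preparation pipeline
#'
#' Inclusion criteria, observation windows, document construction,
#' extreme-length exclusion and the stratified split, in order.
#'
#' @param records Corpus from [generate_corpus()] or [read_corpus()].
#' @param seed Seed for the split.
#' @param length_quantile Passed to [exclude_long_documents()].
#' @return List with `documents` and `split`.
#' @export
prepare_cohort <- function(records, seed, length_quantile = 0.997) {
  records <- apply_inclusion_criteria(records)
  records <- filter_observation_windows(records)
  if (length(records) == 0L) stop_config("prepare_cohort: no patients survive windowing")
  documents <- lapply(records, build_document)
  documents <- exclude_long_documents(documents, length_quantile)
  split <- stratified_split(documents, seed)
  list(documents = documents, split = split)
}

split_docs <- function(documents, split, fold) {
  ids <- split$patient_id[split$fold == fold]
  documents[vapply(documents, function(d) d$patient_id %in% ids, logical(1))]
}
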