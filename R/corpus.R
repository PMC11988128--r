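#' ICPC symptom codes used as structured predictors
#'
#' The eleven International Classification of Primary Care codes linked to
#' lung cancer that the pipeline counts as structured predictors: A04
#' (fatigue/weakness), B80 (iron deficiency anemia), B82 (other anemia), P17
#' (nicotine dependence), R02 (dyspnea), R05 (cough), R24 (haemoptysis), R95
#' (emphysema/COPD), T03 (reduced appetite), T08 (weight loss) and L04 (chest
#' symptoms/complaints).
#'
#' @format Character vector of length 11, in fixed predictor order.
#' @export
icpc_codes <- function() {
  c("A04", "B80", "B82", "P17", "R02", "R05", "R24", "R95", "T03", "T08", "L04")
}

#' Configuration for the synthetic SOEP-note cohort generator
#'
#' Builds a validated configuration for [generate_corpus()]. Defaults emulate
#' the target population: ~0.4% outcome prevalence, cases about 16 years older
#' than controls (medians 68 vs 52), multi-year visit histories, and
#' case-elevated ICPC code counts. Signal tokens are planted per sentence with
#' class-dependent emission probabilities, preferentially in the S
#' (subjective) and E (evaluation) fields.
#'
#' @param n_patients Number of patients to simulate.
#' @param prevalence Probability that a patient is a case (label 1).
#' @param seed Integer seed; the generator is fully reproducible given the
#'   configuration.
#' @param vocab_size_background Size of the background (non-signal) vocabulary.
#' @param signal_tokens Character vector of tokens enriched in case notes.
#' @param signal_rate_case,signal_rate_control Per-sentence probability of
#'   emitting one signal token, for case visits inside the case observation
#'   window and for everything else respectively. Must satisfy
#'   `signal_rate_case >= signal_rate_control >= 0`.
#' @param visits_per_patient Named vector `c(mean=, dispersion=)`; visit counts
#'   are negative-binomial with this mean and size (dispersion), truncated at 1.
#' @param words_per_field Named vector `c(mean=)`; per-field word counts are
#'   Poisson with this mean (fields may be empty).
#' @param age_params_case,age_params_control Named vectors `c(mean=, sd=)` for
#'   normal age-at-index distributions, in years.
#' @param icpc_rate_case,icpc_rate_control Per-code Poisson means for ICPC
#'   event counts; scalars or vectors of length 11 (recycled).
#' @param span_months Length of simulated visit history before the index date,
#'   in 30-day months.
#' @param signal_fields Named weights over SOEP fields (`s`,`o`,`e`,`p`) for
#'   where a planted signal token lands.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_patients = 1000L,
                             prevalence = 0.0039,
                             seed = 1L,
                             vocab_size_background = 2000L,
                             signal_tokens = c("hoestbloed", "kortademig",
                                               "piepend", "vermoeidheid"),
                             signal_rate_case = 0.35,
                             signal_rate_control = 0.05,
                             visits_per_patient = c(mean = 10, dispersion = 4),
                             words_per_field = c(mean = 5),
                             age_params_case = c(mean = 68, sd = 11.1),
                             age_params_control = c(mean = 52, sd = 17.8),
                             icpc_rate_case = 0.8,
                             icpc_rate_control = 0.3,
                             span_months = 36,
                             signal_fields = c(s = 0.5, o = 0, e = 0.5, p = 0)) {
  assert_count(n_patients, "n_patients")
  assert_probability(prevalence, "prevalence")
  assert_count(vocab_size_background, "vocab_size_background")
  assert_probability(signal_rate_case, "signal_rate_case")
  assert_probability(signal_rate_control, "signal_rate_control")
  if (signal_rate_case < signal_rate_control) {
    stop_config("configuration error: signal_rate_case must be >= signal_rate_control")
  }
  if (!is.character(signal_tokens) || length(signal_tokens) < 1L ||
      any(grepl("\\s", signal_tokens))) {
    stop_config("configuration error: signal_tokens must be whitespace-free strings")
  }
  if (visits_per_patient[["mean"]] <= 0 || visits_per_patient[["dispersion"]] <= 0) {
    stop_config("configuration error: visits_per_patient parameters must be positive")
  }
  if (words_per_field[["mean"]] <= 0) {
    stop_config("configuration error: words_per_field mean must be positive")
  }
  if (span_months <= 0) stop_config("configuration error: span_months must be positive")
  if (any(icpc_rate_case < 0) || any(icpc_rate_control < 0)) {
    stop_config("configuration error: ICPC rates must be nonnegative")
  }
  cfg <- list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    seed = as.integer(seed),
    vocab_size_background = as.integer(vocab_size_background),
    signal_tokens = signal_tokens,
    signal_rate_case = signal_rate_case,
    signal_rate_control = signal_rate_control,
    visits_per_patient = visits_per_patient,
    words_per_field = words_per_field,
    age_params_case = age_params_case,
    age_params_control = age_params_control,
    icpc_rate_case = rep_len(icpc_rate_case, 11L),
    icpc_rate_control = rep_len(icpc_rate_control, 11L),
    span_months = span_months,
    signal_fields = signal_fields / sum(signal_fields)
  )
  class(cfg) <- "generator_config"
  cfg
}

# Deterministic pseudo-Dutch background vocabulary: onset + (optional middle)
# + coda syllables indexed positionally, with any collision against the signal
# tokens dropped.
background_vocab <- function(size, signal_tokens) {
  onset <- c("ho", "ke", "za", "lu", "mi", "po", "ra", "ve", "wa", "de",
             "bu", "ni", "ka", "te", "ge", "stu", "klo", "bre", "vri", "sno")
  mid <- c("", "er", "en", "el", "ig", "ver", "ont", "be", "ge", "uit")
  coda <- c("st", "gen", "ter", "land", "pijn", "hoest", "keel", "long",
            "maag", "drag", "ling", "heid", "sel", "tje", "baar", "dig",
            "end", "oor", "uch", "zicht")
  grid <- expand.grid(o = onset, m = mid, c = coda,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  toks <- unique(paste0(grid$o, grid$m, grid$c))
  toks <- setdiff(toks, signal_tokens)
  if (size > length(toks)) {
    extra <- paste0(rep(toks, length.out = size - length(toks)), "s")
    toks <- unique(c(toks, setdiff(extra, signal_tokens)))
  }
  toks[seq_len(size)]
}

#' Generate a synthetic longitudinal SOEP-note cohort
#'
#' Simulates patient records with dated SOEP visits, ICPC-coded events,
#' demographics and a rare binary outcome. Case notes carry planted signal
#' tokens at an elevated per-sentence rate inside the case observation window
#' (diagnosis minus 29 to minus 5 months, in 30-day months); everything else
#' emits signal at the control rate. Background text follows a Zipf-like
#' frequency law over a synthetic vocabulary, so embedding training sees
#' realistic heavy-tailed token frequencies.
#'
#' @param config A [generator_config()].
#' @return A list of patient records. Each record is a list with fields
#'   `patient_id`, `sex` (`"female"`/`"male"`), `birth_date` (`Date`), `visits`
#'   (date-ascending list of visits, each with `date` and token vectors
#'   `s_field`, `o_field`, `e_field`, `p_field`), `icpc_events` (data.frame
#'   `code`, `date`), `last_visit_date`, `label` (0/1) and, for cases only,
#'   `diagnosis_date`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    vocab <- background_vocab(config$vocab_size_background, config$signal_tokens)
    zipf_w <- 1 / seq_along(vocab)^1.05
    zipf_w <- zipf_w / sum(zipf_w)
    span_days <- months_to_days(config$span_months)
    n <- config$n_patients
    field_names <- c("s_field", "o_field", "e_field", "p_field")
    anchor0 <- as.Date("2019-01-01")

    # draw everything up front (single large calls keep Zipf sampling O(1)/token)
    labels <- stats::rbinom(n, 1L, config$prevalence)
    index_dates <- anchor0 + sample.int(912L, n, replace = TRUE) # 2019-2021
    is_case <- labels == 1L
    ages <- pmax(1, stats::rnorm(
      n,
      mean = ifelse(is_case, config$age_params_case[["mean"]],
                    config$age_params_control[["mean"]]),
      sd = ifelse(is_case, config$age_params_case[["sd"]],
                  config$age_params_control[["sd"]])))
    sexes <- ifelse(stats::runif(n) < 0.5, "female", "male")
    n_visits <- pmax(1L, stats::rnbinom(
      n, size = config$visits_per_patient[["dispersion"]],
      mu = config$visits_per_patient[["mean"]]))
    tot_visits <- sum(n_visits)
    pat_of_visit <- rep.int(seq_len(n), n_visits)
    offsets <- sample.int(span_days, tot_visits, replace = TRUE)
    n_words <- stats::rpois(tot_visits * 4L, config$words_per_field[["mean"]])
    pool <- sample(vocab, sum(n_words), replace = TRUE, prob = zipf_w)
    u_emit <- stats::runif(tot_visits)
    sig_tok <- config$signal_tokens[
      sample.int(length(config$signal_tokens), tot_visits, replace = TRUE)]
    sig_fld <- sample.int(4L, tot_visits, replace = TRUE,
                          prob = config$signal_fields)
    u_pos <- stats::runif(tot_visits)
    rate_mat <- rbind(config$icpc_rate_control, config$icpc_rate_case)
    icpc_counts <- matrix(stats::rpois(11L * n, t(rate_mat[labels + 1L, ])),
                          nrow = 11L)
    tot_events <- colSums(icpc_counts)
    ev_offsets <- sample.int(span_days, sum(tot_events), replace = TRUE)

    records <- vector("list", n)
    visit_at <- 0L
    word_at <- 0L
    ev_at <- 0L
    for (i in seq_len(n)) {
      nv <- n_visits[i]
      vi <- visit_at + seq_len(nv)
      off <- sort(offsets[vi], decreasing = TRUE)
      dates <- index_dates[i] - off
      # per-sentence signal rate: elevated only for case visits inside the
      # window that cohort preparation will select for cases
      in_case_window <- is_case[i] &
        off >= months_to_days(5) & off <= months_to_days(29)
      rate <- ifelse(in_case_window, config$signal_rate_case,
                     config$signal_rate_control)
      emit <- u_emit[vi] < rate
      visits <- vector("list", nv)
      for (v in seq_len(nv)) {
        fields <- vector("list", 4L)
        for (f in 1:4) {
          k <- n_words[(visit_at + v - 1L) * 4L + f]
          fields[[f]] <- if (k > 0L) pool[word_at + seq_len(k)] else character(0)
          word_at <- word_at + k
        }
        names(fields) <- field_names
        if (emit[v]) {
          gi <- vi[v]
          cur <- fields[[sig_fld[gi]]]
          pos <- floor(u_pos[gi] * (length(cur) + 1L))
          fields[[sig_fld[gi]]] <- append(cur, sig_tok[gi], after = pos)
        }
        visits[[v]] <- c(list(date = dates[v]), fields)
      }
      visit_at <- visit_at + nv
      ne <- tot_events[i]
      codes <- rep(icpc_codes(), icpc_counts[, i])
      ev_dates <- index_dates[i] - ev_offsets[ev_at + seq_len(ne)]
      ev_at <- ev_at + ne
      ord <- order(ev_dates)
      icpc_events <- data.frame(code = codes[ord], date = ev_dates[ord],
                                stringsAsFactors = FALSE)
      rec <- list(
        patient_id = sprintf("P%06d", i),
        sex = sexes[i],
        birth_date = index_dates[i] - round(ages[i] * 365.25),
        visits = visits,
        icpc_events = icpc_events,
        last_visit_date = max(dates),
        label = labels[i]
      )
      if (is_case[i]) rec$diagnosis_date <- index_dates[i]
      records[[i]] <- rec
    }
    records
  })
}

record_to_json <- function(rec) {
  x <- list(
    patient_id = rec$patient_id,
    sex = rec$sex,
    birth_date = format(rec$birth_date),
    visits = lapply(rec$visits, function(v) list(
      date = format(v$date),
      s_field = as.list(v$s_field), o_field = as.list(v$o_field),
      e_field = as.list(v$e_field), p_field = as.list(v$p_field)
    )),
    icpc_events = lapply(seq_len(nrow(rec$icpc_events)), function(j) list(
      code = rec$icpc_events$code[j], date = format(rec$icpc_events$date[j])
    )),
    last_visit_date = format(rec$last_visit_date),
    label = rec$label
  )
  if (!is.null(rec$diagnosis_date)) x$diagnosis_date <- format(rec$diagnosis_date)
  jsonlite::toJSON(x, auto_unbox = TRUE)
}

json_to_record <- function(x) {
  tok <- function(v) as.character(unlist(v, use.names = FALSE))
  ev <- x$icpc_events
  rec <- list(
    patient_id = x$patient_id,
    sex = x$sex,
    birth_date = as.Date(x$birth_date),
    visits = lapply(x$visits, function(v) list(
      date = as.Date(v$date),
      s_field = tok(v$s_field), o_field = tok(v$o_field),
      e_field = tok(v$e_field), p_field = tok(v$p_field)
    )),
    icpc_events = data.frame(
      code = vapply(ev, function(e) e$code, character(1)),
      date = as.Date(vapply(ev, function(e) e$date, character(1))),
      stringsAsFactors = FALSE
    ),
    last_visit_date = as.Date(x$last_visit_date),
    label = as.integer(x$label)
  )
  if (!is.null(x$diagnosis_date)) rec$diagnosis_date <- as.Date(x$diagnosis_date)
  rec
}

#' Write / read a patient corpus as JSON lines
#'
#' One JSON object per line, dates in ISO-8601; the on-disk schema matches the
#' record structure of [generate_corpus()] exactly, and an absent
#' `diagnosis_date` stays absent (it is never null-coerced). `read_corpus()`
#' reports the line number of any malformed record.
#'
#' @param records List of patient records.
#' @param path File path.
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()` returns
#'   the list of records.
#' @export
write_corpus <- function(records, path) {
  lines <- vapply(records, function(r) as.character(record_to_json(r)), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) NULL)
    if (is.null(x) || is.null(x$patient_id)) {
      stop_config("parse error in '%s' at line %d", path, i)
    }
    out[[i]] <- json_to_record(x)
  }
  out
}
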