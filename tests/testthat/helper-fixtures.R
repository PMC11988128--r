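# Shared fixtures: tiny embedding models, documents and patient records built
# in code at test time.

# A deterministic fake embedding model over tokens t1..tV.
toy_embeddings <- function(V = 30L, d = 8L, seed = 1L) {
  set.seed(seed)
  W <- matrix(rnorm(V * d, sd = 0.3), V, d)
  toks <- paste0("t", seq_len(V))
  rownames(W) <- toks
  structure(list(vocab = stats::setNames(seq_len(V), toks), matrix = W,
                 dim = as.integer(d), window = 2L, min_count = 1L, seed = seed),
            class = "embedding_model")
}

# A synthetic document with S sentences drawn from the toy vocabulary.
toy_document <- function(id = "P1", S = 3L, label = 0L, V = 30L,
                         len_range = 3:6) {
  toks <- paste0("t", seq_len(V))
  structure(list(
    patient_id = id,
    sentences = lapply(seq_len(S), function(s) {
      sample(toks, sample(len_range, 1L), replace = TRUE)
    }),
    dates = as.Date("2020-01-01") + seq_len(S),
    structured = stats::setNames(
      c(runif(1, 40, 80), rbinom(1, 1, 0.5), rpois(11, 0.5)),
      c("age", "sex", icpc_codes())),
    label = as.integer(label)
  ), class = "soep_document")
}

toy_documents <- function(n, seed = 1L, ...) {
  set.seed(seed)
  lapply(seq_len(n), function(i) toy_document(sprintf("P%03d", i),
                                              S = sample(2:4, 1L),
                                              label = i %% 2L, ...))
}

# Hand-built patient record with full control over dates.
make_record <- function(id = "R1", birth = "1950-01-01",
                        visit_dates = "2019-01-01",
                        diagnosis = NULL, label = NULL,
                        icpc = data.frame(code = character(0),
                                          date = as.Date(character(0)),
                                          stringsAsFactors = FALSE),
                        sex = "female",
                        fields = NULL) {
  visit_dates <- as.Date(visit_dates)
  visits <- lapply(seq_along(visit_dates), function(i) {
    f <- if (is.null(fields)) {
      list(s_field = c("klacht"), o_field = character(0),
           e_field = c("beoordeling"), p_field = c("plan"))
    } else fields[[i]]
    c(list(date = visit_dates[i]), f)
  })
  rec <- list(patient_id = id, sex = sex, birth_date = as.Date(birth),
              visits = visits, icpc_events = icpc,
              last_visit_date = max(visit_dates),
              label = if (is.null(label)) as.integer(!is.null(diagnosis)) else label)
  if (!is.null(diagnosis)) rec$diagnosis_date <- as.Date(diagnosis)
  rec
}

# Separable corpus generator configuration used by several suites: every
# in-window case sentence carries a signal token, no control sentence does.
separable_config <- function(n_patients, seed, prevalence = 0.2) {
  generator_config(
    n_patients = n_patients, prevalence = prevalence, seed = seed,
    signal_rate_case = 1, signal_rate_control = 0,
    visits_per_patient = c(mean = 6, dispersion = 4),
    words_per_field = c(mean = 4)
  )
}

fold_docs <- function(prep, fold) {
  ids <- prep$split$patient_id[prep$split$fold == fold]
  prep$documents[vapply(prep$documents,
                        function(d) d$patient_id %in% ids, logical(1))]
}

label_of <- function(docs) vapply(docs, `[[`, integer(1), "label")
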