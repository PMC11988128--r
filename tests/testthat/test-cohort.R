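# Inclusion criteria, observation windows, document construction, length
# exclusion and the stratified split.

days <- function(m) round(m * 30)

test_that("inclusion criteria retain exactly the compliant patients", {
  expect_identical(apply_inclusion_criteria(list()), list())
  diag <- as.Date("2020-06-01")
  recs <- list(
    # aged 28 at index -> excluded
    make_record("too_young", birth = format(diag - round(28 * 365.25)),
                visit_dates = format(diag - days(10)), diagnosis = format(diag)),
    # aged 30 to the day -> excluded (strictly older than 30 required)
    make_record("age_30", birth = format(diag - 10957),
                visit_dates = format(diag - days(10)), diagnosis = format(diag)),
    # no note before diagnosis -> excluded
    make_record("no_prior_note", birth = "1950-01-01",
                visit_dates = format(diag + 10), diagnosis = format(diag)),
    # joined after diagnosis - 5 months -> excluded
    make_record("late_joiner", birth = "1950-01-01",
                visit_dates = format(diag - days(3)), diagnosis = format(diag)),
    # young control -> excluded on age at last visit
    make_record("young_control", birth = "2000-01-01",
                visit_dates = "2020-01-01"),
    # compliant case
    make_record("ok_case", birth = "1950-01-01",
                visit_dates = format(diag - days(c(20, 8))),
                diagnosis = format(diag)),
    # compliant control
    make_record("ok_control", birth = "1950-01-01",
                visit_dates = c("2019-01-01", "2020-01-01"))
  )
  kept <- vapply(apply_inclusion_criteria(recs), `[[`, character(1),
                 "patient_id")
  expect_setequal(kept, c("ok_case", "ok_control"))
})

test_that("case observation window is [diagnosis - 29 mo, diagnosis - 5 mo]", {
  diag <- as.Date("2020-06-01")
  rec <- make_record("c", birth = "1950-01-01",
                     visit_dates = format(diag - days(c(31, 20, 8, 4))),
                     diagnosis = format(diag))
  out <- extract_observation_window(rec)
  kept_off <- as.numeric(diag) -
    vapply(out$visits, function(v) as.numeric(v$date), numeric(1))
  # the 4-month visit (too close to diagnosis) and the 31-month visit drop
  expect_identical(kept_off, as.numeric(days(c(20, 8))))
  # in-window visits are retained untouched, order preserved
  allin <- make_record("c2", birth = "1950-01-01",
                       visit_dates = format(diag - days(c(24, 12, 6))),
                       diagnosis = format(diag))
  expect_identical(extract_observation_window(allin)$visits, allin$visits)
})

test_that("control window is [last visit - 25 mo, last visit - 1 mo]", {
  last <- as.Date("2021-03-01")
  rec <- make_record("ctl", birth = "1950-01-01",
                     visit_dates = format(last - days(c(26, 2, 0.5, 0))))
  out <- extract_observation_window(rec)
  kept_off <- as.numeric(last - vapply(out$visits, function(v) v$date, last))
  expect_identical(kept_off, days(2))
  # a patient with nothing in-window is dropped
  lone <- make_record("lone", birth = "1950-01-01", visit_dates = format(last))
  expect_null(extract_observation_window(lone))
})

test_that("window filtering is idempotent", {
  corp <- generate_corpus(generator_config(n_patients = 60, prevalence = 0.3,
                                           seed = 13))
  once <- hanrisk:::filter_observation_windows(apply_inclusion_criteria(corp))
  twice <- hanrisk:::filter_observation_windows(once)
  expect_identical(once, twice)
})

test_that("no case document token is dated after diagnosis - 5 months", {
  corp <- generate_corpus(generator_config(n_patients = 300, prevalence = 0.3,
                                           seed = 17))
  recs <- hanrisk:::filter_observation_windows(apply_inclusion_criteria(corp))
  for (r in recs) {
    if (is.null(r$diagnosis_date)) next
    d <- build_document(r)
    expect_true(all(d$dates <= r$diagnosis_date - days(5)))
  }
})

test_that("sentences preserve the SOEP order with literal marker tokens", {
  diag <- as.Date("2020-06-01")
  rec <- make_record("soep", birth = "1950-01-01",
                     visit_dates = format(diag - days(10)),
                     diagnosis = format(diag),
                     fields = list(list(s_field = "hoest",
                                        o_field = c("geen", "koorts"),
                                        e_field = character(0),
                                        p_field = "afwachten")))
  doc <- build_document(extract_observation_window(rec))
  expect_identical(doc$sentences[[1]],
                   c("S", "hoest", "O", "geen", "koorts", "E", "P", "afwachten"))
  # minimal document: single visit, single token
  min_rec <- make_record("min", birth = "1950-01-01",
                         visit_dates = format(diag - days(10)),
                         diagnosis = format(diag),
                         fields = list(list(s_field = "moe",
                                            o_field = character(0),
                                            e_field = character(0),
                                            p_field = character(0))))
  min_doc <- build_document(extract_observation_window(min_rec))
  expect_identical(min_doc$sentences, list(c("S", "moe", "O", "E", "P")))
})

test_that("visits arriving out of order are sorted into date order", {
  diag <- as.Date("2020-06-01")
  rec <- make_record("swap", birth = "1950-01-01",
                     visit_dates = format(diag - days(c(20, 8))),
                     diagnosis = format(diag),
                     fields = list(list(s_field = "eerste", o_field = character(0),
                                        e_field = character(0), p_field = character(0)),
                                   list(s_field = "tweede", o_field = character(0),
                                        e_field = character(0), p_field = character(0))))
  rec$visits <- rev(rec$visits) # scramble input order
  doc <- build_document(rec)
  expect_identical(doc$sentences[[1]][2], "eerste")
  expect_identical(doc$sentences[[2]][2], "tweede")
  expect_true(!is.unsorted(doc$dates))
})

test_that("structured predictors: age at index, sex code, windowed ICPC counts", {
  diag <- as.Date("2020-06-01")
  ev <- data.frame(code = c("R05", "R05", "A04", "R05"),
                   date = c(diag - days(10), diag - days(20), diag - days(8),
                            diag - days(2)), # last one outside the window
                   stringsAsFactors = FALSE)
  rec <- make_record("sp", birth = "1960-06-01",
                     visit_dates = format(diag - days(10)),
                     diagnosis = format(diag), icpc = ev, sex = "male")
  doc <- build_document(extract_observation_window(rec))
  expect_length(doc$structured, 13L)
  expect_equal(unname(doc$structured["age"]), 60, tolerance = 0.01)
  expect_identical(unname(doc$structured["sex"]), 1)
  expect_identical(unname(doc$structured["R05"]), 2) # in-window only
  expect_identical(unname(doc$structured["A04"]), 1)
  expect_identical(unname(doc$structured["B80"]), 0)
})

test_that("long-document exclusion removes only counts above the 99.7th percentile", {
  base <- toy_documents(1000, seed = 31)
  expect_identical(exclude_long_documents(base), base) # near-tie lengths: none removed
  # plant 5 extreme documents
  long <- base
  for (i in 1:5) {
    long[[i]]$sentences <- replicate(60, paste0("t", 1:40), simplify = FALSE)
  }
  counts <- vapply(long, function(d) sum(lengths(d$sentences)), numeric(1))
  thr <- quantile(counts, 0.997, names = FALSE)
  kept <- exclude_long_documents(long)
  expect_identical(length(kept), sum(counts <= thr))
  frac_removed <- 1 - length(kept) / length(long)
  expect_lte(frac_removed, 0.003 + 5 / 1000) # quantile definition + tie slack
  # equal-length corpus: the degenerate distribution removes nothing
  set.seed(32)
  eq <- lapply(1:200, function(i) toy_document(sprintf("e%03d", i), S = 3L,
                                               len_range = 4L))
  expect_identical(length(exclude_long_documents(eq)), 200L)
})

test_that("stratified split yields 60/20/20 with preserved case fraction", {
  docs <- c(lapply(1:90, function(i) toy_document(sprintf("n%02d", i), label = 0L)),
            lapply(1:10, function(i) toy_document(sprintf("c%02d", i), label = 1L)))
  sp <- stratified_split(docs, seed = 4)
  expect_identical(as.integer(table(sp$fold)[c("train", "tune", "test")]),
                   c(60L, 20L, 20L))
  lab <- setNames(label_of(docs), vapply(docs, `[[`, character(1), "patient_id"))
  for (f in c("train", "tune", "test")) {
    ids <- sp$patient_id[sp$fold == f]
    expect_identical(sum(lab[ids]), if (f == "train") 6L else 2L)
  }
  # partition: every patient in exactly one fold
  expect_setequal(sp$patient_id, names(lab))
  expect_identical(anyDuplicated(sp$patient_id), 0L)
  # determinism
  expect_identical(stratified_split(docs, seed = 4), sp)
  expect_false(identical(stratified_split(docs, seed = 5)$fold, sp$fold))
})

test_that("single-stratum corpora split plainly; too few cases error", {
  same <- lapply(1:20, function(i) toy_document(sprintf("s%02d", i), label = 0L))
  sp <- stratified_split(same, seed = 1)
  expect_identical(as.integer(table(sp$fold)[c("train", "tune", "test")]),
                   c(12L, 4L, 4L))
  mixed <- c(same, list(toy_document("case1", label = 1L)))
  expect_error(stratified_split(mixed, seed = 1), "fewer cases")
})
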