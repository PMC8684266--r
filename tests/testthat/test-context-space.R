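test_that("default registry defines the ten contexts in canonical order", {
  reg <- defaultContextRegistry()
  expect_identical(contextIds(reg),
                   c("department", "staff", "icd_event", "cpt_event",
                     "chief_complaint", "age", "gender", "note_type",
                     "note_section", "top_note_section"))
  expect_identical(ageBinLabels(reg),
                   c("0-9", "10-19", "20-29", "30-39", "40-49", "50-59",
                     "60-69", "70-79", "80-89", "90+"))
  expect_length(keySections(reg), 5L)
})

test_that("active attributes resolve note-level labels and the event window", {
  reg <- defaultContextRegistry()
  ev <- data.frame(
    system = c("ICD", "ICD", "CPT", "chief_complaint"),
    code = c("far.icd", "near.icd", "near.cpt", "headache"),
    timestamp = as.POSIXct("2016-06-01 12:00:00", tz = "UTC") +
      c(-49, -47, 10, 48) * 3600,
    stringsAsFactors = FALSE)
  note <- make_note(department = "Neuro-Epilepsy", patient_age_years = 26L,
                    patient_gender = "male", events = ev,
                    timestamp = "2016-06-01T12:00:00")
  a <- activeAttributes(note, reg)
  expect_identical(a$department, "Neuro-Epilepsy")
  expect_identical(a$age, "20-29")
  expect_identical(a$gender, "male")
  # 49 h-old code is outside the 48 h window; the boundary itself is inside
  expect_identical(a$icd_event, "near.icd")
  expect_identical(a$chief_complaint, "headache")
  # widening the window pulls the far code in
  a96 <- activeAttributes(note, defaultContextRegistry(event_window_hours = 96))
  expect_setequal(a96$icd_event, c("far.icd", "near.icd"))
  # a note with no in-window events yields an empty set, not an error
  a0 <- activeAttributes(make_note(), reg)
  expect_identical(a0$icd_event, character(0))

  bad <- note
  bad$patient_age_years <- -1L
  expect_error(activeAttributes(bad, reg), ">= 0")
})

test_that("accumulation attributes occurrences per context scope", {
  # department counts collect every occurrence in the note
  note <- make_note(department = "Neuro-Epilepsy",
                    text = "a EEG showed eeg artifact; repeat EEG and eeg")
  counts <- accumulateContexts(list(note))
  m <- contextMatrix(counts, "department")
  expect_equal(m["eeg", "Neuro-Epilepsy"], 4)

  # each in-window code of a system receives the full token count
  ev <- data.frame(system = c("ICD", "ICD"), code = c("c1", "c2"),
                   timestamp = rep(as.POSIXct("2016-06-01 12:00:00",
                                              tz = "UTC"), 2),
                   stringsAsFactors = FALSE)
  note2 <- make_note("n2", events = ev, text = "pain",
                     timestamp = "2016-06-01T12:00:00")
  c2 <- accumulateContexts(list(note2))
  icd <- contextMatrix(c2, "icd_event")
  expect_equal(unname(icd["pain", c("c1", "c2")]), c(1, 1))

  # section context splits by section; top section requires a key section
  note3 <- make_note("n3", sections = data.frame(
    section_name = c("Assessment", "plan"),
    text = c("seizure noted", "seizure precautions"),
    stringsAsFactors = FALSE))
  c3 <- accumulateContexts(list(note3))
  ns <- contextMatrix(c3, "note_section")
  expect_equal(ns["seizure", "assessment"], 1)
  expect_equal(ns["seizure", "plan"], 1)
  top <- contextMatrix(c3, "top_note_section")
  expect_identical(colnames(top), "assessment")
  expect_equal(top["seizure", "assessment"], 1)

  # empty corpus
  c0 <- accumulateContexts(list())
  expect_length(vocabulary(c0), 0L)
  expect_true(all(dimensionSummary(c0) == 0L))
})

test_that("accumulated totals match a brute-force corpus pass", {
  spec <- syntheticSpec(seed = 42L, n_notes = 40L, vocab_size = 60L,
                        n_related_terms = 5L)
  notes <- generateNotes(spec, sampleTermProfiles(spec))
  reg <- defaultContextRegistry()
  counts <- accumulateContexts(notes, reg)
  oracle <- brute_force_counts(notes, reg)
  total_pkg <- sum(vapply(contextIds(counts),
                          function(ctx) sum(contextMatrix(counts, ctx)),
                          numeric(1)))
  expect_equal(total_pkg, sum(unlist(oracle)))
  # spot-check every oracle cell
  for (key in names(oracle)) {
    p <- strsplit(key, "\r", fixed = TRUE)[[1]]
    expect_equal(contextMatrix(counts, p[2])[p[1], p[3]], oracle[[key]],
                 info = key)
  }
})

test_that("accumulation is additive over corpora and order-invariant", {
  spec <- syntheticSpec(seed = 7L, n_notes = 12L, vocab_size = 40L,
                        n_related_terms = 3L)
  notes <- generateNotes(spec, sampleTermProfiles(spec))
  a <- notes[1:5]; b <- notes[6:12]
  cAB <- accumulateContexts(notes)
  cA <- accumulateContexts(a)
  cB <- accumulateContexts(b)
  for (ctx in contextIds(cAB)) {
    mAB <- contextMatrix(cAB, ctx)
    mA <- contextMatrix(cA, ctx); mB <- contextMatrix(cB, ctx)
    sum_split <- matrix(0, nrow(mAB), ncol(mAB), dimnames = dimnames(mAB))
    sum_split[rownames(mA), colnames(mA)] <-
      sum_split[rownames(mA), colnames(mA)] + as.matrix(mA)
    sum_split[rownames(mB), colnames(mB)] <-
      sum_split[rownames(mB), colnames(mB)] + as.matrix(mB)
    expect_equal(as.matrix(mAB), sum_split)
  }
  cPerm <- accumulateContexts(rev(notes))
  for (ctx in contextIds(cAB))
    expect_equal(as.matrix(contextMatrix(cAB, ctx)),
                 as.matrix(contextMatrix(cPerm, ctx)))
})

test_that("normalization yields per-context proportions, preserving zeros", {
  n1 <- make_note("n1", department = "A", text = "eeg eeg eeg pain")
  n2 <- make_note("n2", department = "B", text = "eeg")
  space <- buildContextSpace(list(n1, n2))
  dep <- contextMatrix(space, "department")
  expect_equal(unname(dep["eeg", c("A", "B")]), c(0.75, 0.25))
  # pain occurs only in department A
  expect_equal(unname(dep["pain", c("A", "B")]), c(1, 0))
  # no events anywhere: event context vectors stay all-zero
  expect_identical(ncol(contextMatrix(space, "icd_event")), 0L)

  # counts {2, 2, 4} in one context divide by their sum of 8
  n3 <- make_note("m1", department = "X", text = "eeg eeg")
  n4 <- make_note("m2", department = "Y", text = "eeg eeg")
  n5 <- make_note("m3", department = "Z", text = "eeg eeg eeg eeg")
  sp <- buildContextSpace(list(n3, n4, n5))
  expect_equal(unname(contextMatrix(sp, "department")["eeg", c("X","Y","Z")]),
               c(0.25, 0.25, 0.5))
})

test_that("every nonzero normalized vector sums to one", {
  space <- get_bundle()$space
  for (ctx in contextIds(space)) {
    m <- contextMatrix(space, ctx)
    if (ncol(m) == 0L) next
    rs <- Matrix::rowSums(m)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-9), info = ctx)
    expect_true(all(m@x >= 0 & m@x <= 1 + 1e-12), info = ctx)
  }
})

test_that("dimension summaries count observed catalog labels", {
  notes <- list(
    make_note("n1", department = "A", patient_gender = "male"),
    make_note("n2", department = "B", patient_gender = "female"),
    make_note("n3", department = "C", patient_gender = "unknown"))
  counts <- accumulateContexts(notes)
  ds <- dimensionSummary(counts)
  expect_identical(ds[["department"]], 3L)
  expect_identical(ds[["gender"]], 3L)
  expect_identical(ds[["icd_event"]], 0L)
})

test_that("topDimensions ranks proportions with label tie-breaks", {
  notes <- list(make_note("n1", department = "A", text = "eeg eeg"),
                make_note("n2", department = "B", text = "eeg eeg"),
                make_note("n3", department = "C", text = "eeg"))
  space <- buildContextSpace(notes)
  td <- topDimensions(space, "eeg", "department", k = 2)
  # A and B tie at 0.4; label order breaks the tie
  expect_identical(td$dimension, c("A", "B"))
  expect_equal(td$proportion, c(0.4, 0.4))
  expect_identical(nrow(topDimensions(space, "eeg", "icd_event", k = 3)), 0L)
  expect_error(topDimensions(space, "absent", "department"), "unknown term")
})

test_that("vector-space archives round-trip bit-for-bit", {
  space <- buildContextSpace(list(
    make_note("n1", text = "eeg seizure keppra"),
    make_note("n2", department = "neuro", text = "eeg vimpat")))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  saveContextSpace(space, p1)
  back <- loadContextSpace(p1)
  expect_identical(vocabulary(back), vocabulary(space))
  for (ctx in contextIds(space))
    expect_equal(as.matrix(contextMatrix(back, ctx)),
                 as.matrix(contextMatrix(space, ctx)))
  saveContextSpace(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})
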