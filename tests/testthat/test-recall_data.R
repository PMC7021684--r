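# Data model: response matching, loading, validation, round trips.

test_that("match_responses matches exactly after trim and case-fold, flags intrusions and repeats", {
  items <- sprintf("w%02d", 1:16)
  m <- match_responses(c("W16", " w15 ", "w14"), items)
  expect_equal(m$matched_serial_position, c(16L, 15L, 14L))
  expect_false(any(m$is_intrusion) || any(m$is_repeat))

  m <- match_responses(c("w07", "XYZ", "w07"), items)
  expect_equal(m$matched_serial_position, c(7L, NA, 7L))
  expect_equal(m$is_intrusion, c(FALSE, TRUE, FALSE))
  expect_equal(m$is_repeat, c(FALSE, FALSE, TRUE))

  expect_equal(nrow(match_responses(character(0), items)), 0L)
})

test_that("a pluggable matcher can override exact matching", {
  items <- c("apple", "banana")
  sloppy <- function(tok, its) {
    hits <- which(startsWith(its, substr(tok, 1, 3)))
    if (length(hits) == 1L) hits else NA_integer_
  }
  m <- match_responses(c("appel", "banan", "pear"), items, matcher = sloppy)
  expect_equal(m$matched_serial_position, c(1L, 2L, NA))
})

test_that("load_sessions preserves counts and validates integrity", {
  dir <- withr::local_tempdir()
  study <- data.frame(subject_id = "s1", list_id = 1L, condition = "order",
                      serial_position = 1:16, item = sprintf("w%02d", 1:16))
  recalls <- data.frame(subject_id = "s1", list_id = 1L,
                        output_position = 1:10,
                        response = sprintf("w%02d", c(16, 15, 14, 12, 4, 7, 8, 2, 10, 13)))
  ordering <- data.frame(subject_id = "s1", list_id = 1L, trial_index = 1L,
                         item_a_serial = 7L, item_b_serial = 8L,
                         slot_a = 7L, slot_b = 8L, first_placed = "a")
  write.csv(study, file.path(dir, "study.csv"), row.names = FALSE)
  write.csv(recalls, file.path(dir, "recalls.csv"), row.names = FALSE)
  write.csv(ordering, file.path(dir, "ordering.csv"), row.names = FALSE)

  ds <- load_sessions(file.path(dir, "study.csv"), file.path(dir, "recalls.csv"),
                      file.path(dir, "ordering.csv"))
  expect_s3_class(ds, "recall_dataset")
  expect_equal(nrow(ds$recalls), 10L)
  expect_equal(ds$recalls$matched_serial_position,
               c(16L, 15L, 14L, 12L, 4L, 7L, 8L, 2L, 10L, 13L))
  expect_length(audit_dataset(ds), 0L)

  # token absent from the study list becomes an intrusion
  recalls2 <- rbind(recalls,
                    data.frame(subject_id = "s1", list_id = 1L,
                               output_position = 11L, response = "zebra"))
  write.csv(recalls2, file.path(dir, "recalls.csv"), row.names = FALSE)
  ds2 <- load_sessions(file.path(dir, "study.csv"), file.path(dir, "recalls.csv"))
  expect_true(ds2$recalls$is_intrusion[11])

  # slot_a == slot_b is an integrity error with a row number
  ordering$slot_b <- 7L
  write.csv(ordering, file.path(dir, "ordering.csv"), row.names = FALSE)
  expect_error(load_sessions(file.path(dir, "study.csv"),
                             file.path(dir, "recalls.csv"),
                             file.path(dir, "ordering.csv")),
               "slot_a == slot_b")

  # schema and duplicate-serial errors
  write.csv(study[, -5], file.path(dir, "study_bad.csv"), row.names = FALSE)
  expect_error(load_sessions(file.path(dir, "study_bad.csv"),
                             file.path(dir, "recalls.csv")),
               "schema error")
  study_dup <- rbind(study, study[1, ])
  write.csv(study_dup, file.path(dir, "study.csv"), row.names = FALSE)
  expect_error(load_sessions(file.path(dir, "study.csv"),
                             file.path(dir, "recalls.csv")),
               "integrity error")
})

test_that("fractional slot placements are rejected", {
  ds <- tiny_dataset()
  ordering <- data.frame(subject_id = "sA", list_id = 1L, trial_index = 1L,
                         item_a_serial = 7L, item_b_serial = 8L,
                         slot_a = 7.5, slot_b = 9, first_placed = "a")
  expect_error(recall_dataset(ds$study,
                              cbind(ds$recalls[c("subject_id", "list_id",
                                                 "output_position", "response")]),
                              ordering),
               "fractional")
})

test_that("write + load round-trips a simulated dataset field-for-field", {
  sim <- sim_fixture(n_subjects = 3, n_lists = 6, n_order_lists = 4)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(sim, dir)
  expect_true(all(file.exists(manifest$file)))
  ds <- load_sessions(file.path(dir, "study.csv"), file.path(dir, "recalls.csv"),
                      file.path(dir, "ordering.csv"))
  expect_equal(ds$study, sim$dataset$study)
  expect_equal(ds$ordering, sim$dataset$ordering)
  expect_equal(ds$recalls$matched_serial_position,
               sim$dataset$recalls$matched_serial_position)
  expect_equal(ds$recalls$is_intrusion, sim$dataset$recalls$is_intrusion)
  expect_equal(ds$recalls$is_repeat, sim$dataset$recalls$is_repeat)
  expect_length(audit_dataset(ds), 0L)
})

test_that("write_scored_tables emits a manifest with matching row counts", {
  sim <- sim_fixture(n_subjects = 3, n_lists = 6, n_order_lists = 4)
  scores <- score_pairs(sim$dataset, sim$pairs)
  dir <- withr::local_tempdir()
  manifest <- write_scored_tables(sim$dataset, scores, dir,
                                  summaries = subject_summary(sim$dataset))
  expect_setequal(basename(manifest$file),
                  c("study.csv", "recalls.csv", "ordering.csv",
                    "pair_scores.csv", "subject_summary.csv"))
  back <- read.csv(file.path(dir, "pair_scores.csv"))
  expect_equal(nrow(back), nrow(scores))
  expect_equal(manifest$rows[manifest$file == file.path(dir, "pair_scores.csv")],
               nrow(scores))
})
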