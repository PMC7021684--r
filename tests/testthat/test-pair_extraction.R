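# Transition enumeration, the four contiguity categories, and exact
# item-disjoint selection.

test_that("the worked recall sequence yields the printed transition lags", {
  tr <- enumerate_transitions(worked_sequence())
  expect_equal(tr$encoding_lag, c(-1, -1, -2, -8, 3, 1, -6, 8, 3))
  expect_equal(nrow(tr), 9L)
})

test_that("transitions never bridge across intrusions or repeats", {
  expect_equal(nrow(enumerate_transitions(recall_sequence(c(1, NA, 2)))), 0L)
  expect_equal(nrow(enumerate_transitions(recall_sequence(c(5)))), 0L)
  tr <- enumerate_transitions(recall_sequence(c(3, 3, 5)))  # repeat in middle
  expect_equal(nrow(tr), 0L)
  tr <- enumerate_transitions(recall_sequence(c(3, 4, 4, 5)))
  expect_equal(tr$encoding_lag, 1L)  # only 3 -> 4 survives
})

test_that("the worked sequence classifies the four printed example pairs", {
  cand <- categorize_pairs(worked_sequence(), 16L)
  cat_of <- function(a, b) {
    hit <- (cand$item_a_serial == a & cand$item_b_serial == b) |
      (cand$item_a_serial == b & cand$item_b_serial == a)
    cand$category[hit]
  }
  expect_equal(cat_of(7, 8), "cont_enc_ret")
  expect_equal(cat_of(2, 10), "cont_ret")
  expect_equal(cat_of(12, 13), "cont_enc")
  expect_equal(cat_of(16, 15), "first_three")
})

test_that("first-three precedence consumes lag-defined candidates", {
  cand <- categorize_pairs(recall_sequence(1:16), 16L)
  # 15 adjacent transitions minus the two consumed by first-three pairs
  expect_equal(sum(cand$category == "cont_enc_ret"), 13L)
  expect_equal(sum(cand$category == "first_three"), 3L)
  expect_equal(sum(cand$category == "cont_ret"), 0L)
  # merging first-three restores the lag-defined categories
  merged <- ordermem:::merge_first_three_pairs(cand)
  expect_equal(sum(merged$category == "cont_enc_ret"), 15L)
  expect_equal(sum(merged$category == "first_three"), 0L)
})

test_that("distant transitions past the first three outputs are cont_ret", {
  cand <- categorize_pairs(recall_sequence(c(5, 6, 7, 1, 16)), 16L)
  hit <- cand[cand$item_a_serial == 1 & cand$item_b_serial == 16, ]
  expect_equal(hit$category, "cont_ret")
  expect_equal(hit$encoding_lag, 15L)
  expect_equal(hit$direction, "forward")
  # with only two outputs both members sit among the first three recalls,
  # so first-three precedence absorbs the pair
  cand2 <- categorize_pairs(recall_sequence(c(1, 16)), 16L)
  expect_equal(cand2$category, "first_three")
})

test_that("category invariants hold on simulated recalls", {
  sim <- sim_fixture(n_subjects = 4, n_lists = 8, n_order_lists = 8)
  pairs <- sim$pairs
  adj_out <- abs(pairs$output_a - pairs$output_b) == 1L
  adj_ser <- abs(pairs$item_a_serial - pairs$item_b_serial) == 1L
  cer <- pairs$category == "cont_enc_ret"
  cret <- pairs$category == "cont_ret"
  ce <- pairs$category == "cont_enc"
  expect_true(all(abs(pairs$encoding_lag[cer]) == 1L))
  expect_true(all(adj_out[cer]))
  expect_true(all(abs(pairs$encoding_lag[cret]) >= 2L))
  expect_true(all(adj_out[cret]))
  expect_true(all(adj_ser[ce]))
  expect_true(all(!adj_out[ce]))
  expect_true(all((pairs$encoding_lag > 0)[pairs$direction == "forward"],
                  na.rm = TRUE))
})

test_that("selection is item-disjoint on every simulated list", {
  sim <- sim_fixture(n_subjects = 4, n_lists = 8, n_order_lists = 8)
  sel <- sim$pairs[sim$pairs$selected, ]
  for (k in unique(paste(sel$subject_id, sel$list_id))) {
    grp <- sel[paste(sel$subject_id, sel$list_id) == k, ]
    expect_false(anyDuplicated(c(grp$item_a_serial, grp$item_b_serial)) > 0)
  }
})

test_that("shared items force a choice between overlapping candidates", {
  cand <- data.frame(item_a_serial = c(7L, 8L), item_b_serial = c(8L, 9L),
                     category = c("cont_enc_ret", "cont_enc"),
                     encoding_lag = c(1L, NA), direction = c("forward", "none"),
                     output_a = c(1L, 2L), output_b = c(2L, 5L),
                     stringsAsFactors = FALSE)
  sel <- select_pairs(cand)
  expect_equal(sum(sel$selected), 1L)
  # the three mutually disjoint example pairs are all selected
  cand3 <- data.frame(item_a_serial = c(7L, 2L, 12L), item_b_serial = c(8L, 10L, 13L),
                      category = c("cont_enc_ret", "cont_ret", "cont_enc"),
                      encoding_lag = c(1L, 8L, NA),
                      direction = c("forward", "forward", "none"),
                      output_a = c(1L, 3L, 5L), output_b = c(2L, 4L, 9L),
                      stringsAsFactors = FALSE)
  expect_true(all(select_pairs(cand3)$selected))
})

test_that("selection matches the brute-force lexicographic optimum", {
  set.seed(20)
  for (rep in 1:60) {
    cand <- random_candidates(sample(4:12, 1))
    sel <- select_pairs(cand)
    expect_equal(selection_key(sel), oracle_select_key(cand))
    # disjointness always holds
    picked <- sel[sel$selected, ]
    expect_false(anyDuplicated(c(picked$item_a_serial,
                                 picked$item_b_serial)) > 0)
  }
})

test_that("selection is deterministic and seed-independent", {
  set.seed(33)
  cand <- random_candidates(10)
  s1 <- select_pairs(cand, seed = 1)
  s2 <- select_pairs(cand, seed = 999)
  expect_identical(s1, s2)
})

test_that("pair counts per category feed the inclusion filter", {
  sim <- sim_fixture(n_subjects = 4, n_lists = 8, n_order_lists = 8)
  counts <- count_pairs_per_category(sim$pairs)
  expect_setequal(names(counts),
                  c("subject_id", "cont_enc_ret", "cont_ret", "cont_enc"))
  sel <- sim$pairs[sim$pairs$selected & sim$pairs$category == "cont_ret", ]
  expect_equal(counts$cont_ret[counts$subject_id == "s001"],
               sum(sel$subject_id == "s001"))
  empty <- count_pairs_per_category(sim$pairs[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("categorization depends on positions, not tokens", {
  items1 <- sprintf("w%02d", 1:16)
  items2 <- paste0("token_", letters[1:16])
  pos <- c(16, 15, 14, 12, 4, 7, 8, 2, 10, 13)
  m1 <- match_responses(items1[pos], items1)
  m2 <- match_responses(items2[pos], items2)
  m1$subject_id <- m2$subject_id <- "s"; m1$list_id <- m2$list_id <- 1L
  expect_equal(categorize_pairs(m1, 16L), categorize_pairs(m2, 16L))
})
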