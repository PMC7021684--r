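# Recall-transition enumeration, pair categorization and exact selection of
# an item-disjoint, category-balanced pair set.
#
# Category definitions (L = list length, lag = difference in study serial
# positions of two successively recalled items):
#   cont_enc_ret  recalled at adjacent output positions AND |lag| = 1
#   cont_ret      recalled at adjacent output positions AND |lag| >= 2
#   cont_enc      studied adjacently (|serial diff| = 1), both recalled, but
#                 not at adjacent output positions
#   first_three   both members among the first three (correct) recall
#                 outputs, regardless of lag; takes precedence over the
#                 lag-defined categories

#' Enumerate recall transitions for one list
#'
#' A transition is a pair of correct, non-repeat responses at adjacent output
#' positions. Outputs flagged as intrusions or repeats never participate and
#' are not bridged across: `1, <intrusion>, 2` yields no transition.
#'
#' @param seq matched recall rows for a single (subject, list), as produced
#'   by [match_responses()] or [recall_sequence()].
#' @return A data frame with one row per transition: `from_serial`,
#'   `to_serial`, `from_output`, `to_output`, `encoding_lag`
#'   (`to_serial - from_serial`).
#' @examples
#' enumerate_transitions(recall_sequence(c(16, 15, 14, 12, 4, 7, 8, 2, 10, 13)))
#' @export
enumerate_transitions <- function(seq) {
  ok <- !seq$is_intrusion & !seq$is_repeat
  n <- nrow(seq)
  empty <- data.frame(from_serial = integer(0), to_serial = integer(0),
                      from_output = integer(0), to_output = integer(0),
                      encoding_lag = integer(0))
  if (n < 2L) return(empty)
  i <- which(ok[-n] & ok[-1])
  if (!length(i)) return(empty)
  data.frame(from_serial = seq$matched_serial_position[i],
             to_serial = seq$matched_serial_position[i + 1L],
             from_output = seq$output_position[i],
             to_output = seq$output_position[i + 1L],
             encoding_lag = seq$matched_serial_position[i + 1L] -
               seq$matched_serial_position[i])
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

#' Categorize candidate pairs from one recall sequence
#'
#' Builds all candidate pairs of one list's recall in the four contiguity
#' categories. First-three pairs (both members among the first three correct
#' outputs) take precedence: a pair classified `first_three` is listed under
#' no other category. Remaining transitions become `cont_enc_ret`
#' (|lag| = 1) or `cont_ret` (|lag| >= 2); study-adjacent pairs whose members
#' were both recalled but not at adjacent output positions become
#' `cont_enc`. Categorization depends only on positions, never on item
#' tokens.
#'
#' @inheritParams enumerate_transitions
#' @param L list length.
#' @return A data frame of candidate pairs: `item_a_serial`, `item_b_serial`
#'   (a = the earlier-recalled member), `category`, `encoding_lag` (signed,
#'   `NA` for `cont_enc`), `direction` (`forward`/`backward` for
#'   transition-born pairs, else `none`), `output_a`, `output_b`.
#' @export
categorize_pairs <- function(seq, L = 16L) {
  ok <- which(!seq$is_intrusion & !seq$is_repeat)
  serial <- seq$matched_serial_position
  out_pos <- seq$output_position
  a <- integer(0); b <- integer(0); category <- character(0)
  lag <- integer(0); direction <- character(0)
  oa <- integer(0); ob <- integer(0)

  first3 <- utils::head(ok, 3L)
  f3_keys <- character(0)
  if (length(first3) >= 2L) {
    combos <- utils::combn(first3, 2L)
    i1 <- combos[1, ]; i2 <- combos[2, ]
    f3_keys <- pair_key(serial[i1], serial[i2])
    a <- serial[i1]; b <- serial[i2]
    category <- rep("first_three", length(i1))
    lag <- serial[i2] - serial[i1]
    direction <- rep("none", length(i1))
    oa <- out_pos[i1]; ob <- out_pos[i2]
  }

  tr <- enumerate_transitions(seq)
  if (nrow(tr)) {
    keep <- !pair_key(tr$from_serial, tr$to_serial) %in% f3_keys
    tr <- tr[keep, , drop = FALSE]
    if (nrow(tr)) {
      a <- c(a, tr$from_serial); b <- c(b, tr$to_serial)
      category <- c(category,
                    ifelse(abs(tr$encoding_lag) == 1L, "cont_enc_ret",
                           "cont_ret"))
      lag <- c(lag, tr$encoding_lag)
      direction <- c(direction,
                     ifelse(tr$encoding_lag > 0L, "forward", "backward"))
      oa <- c(oa, tr$from_output); ob <- c(ob, tr$to_output)
    }
  }

  # cont_enc: study-adjacent, both recalled, not output-adjacent, not first-three
  recalled <- serial[ok]
  out_of <- integer(max(c(recalled, 0L)))
  out_of[recalled] <- out_pos[ok]
  lo <- sort(recalled[(recalled + 1L) %in% recalled])
  if (length(lo)) {
    o1 <- out_of[lo]; o2 <- out_of[lo + 1L]
    keep <- abs(o1 - o2) != 1L & !pair_key(lo, lo + 1L) %in% f3_keys
    lo <- lo[keep]; o1 <- o1[keep]; o2 <- o2[keep]
    if (length(lo)) {
      first_is_lo <- o1 <= o2
      a <- c(a, ifelse(first_is_lo, lo, lo + 1L))
      b <- c(b, ifelse(first_is_lo, lo + 1L, lo))
      category <- c(category, rep("cont_enc", length(lo)))
      lag <- c(lag, rep(NA_integer_, length(lo)))
      direction <- c(direction, rep("none", length(lo)))
      oa <- c(oa, pmin(o1, o2)); ob <- c(ob, pmax(o1, o2))
    }
  }

  data.frame(item_a_serial = as.integer(a), item_b_serial = as.integer(b),
             category = category, encoding_lag = as.integer(lag),
             direction = direction, output_a = as.integer(oa),
             output_b = as.integer(ob), stringsAsFactors = FALSE)
}

# Reassign first_three pairs to their lag-defined categories (merge mode):
# output-adjacent pairs by |lag|; study-adjacent non-output-adjacent pairs to
# cont_enc; the remainder fits no category and is dropped.
merge_first_three_pairs <- function(candidates) {
  f3 <- candidates$category == "first_three"
  if (!any(f3)) return(candidates)
  lag <- candidates$encoding_lag
  adj_out <- abs(candidates$output_a - candidates$output_b) == 1L
  adj_ser <- abs(candidates$item_a_serial - candidates$item_b_serial) == 1L
  cat_new <- ifelse(adj_out & abs(lag) == 1L, "cont_enc_ret",
             ifelse(adj_out, "cont_ret",
             ifelse(adj_ser, "cont_enc", NA_character_)))
  candidates$category[f3] <- cat_new[f3]
  candidates$direction[f3] <- ifelse(adj_out[f3],
                                     ifelse(lag[f3] > 0L, "forward", "backward"),
                                     "none")
  candidates$encoding_lag[f3 & candidates$category %in% "cont_enc"] <- NA_integer_
  candidates[!is.na(candidates$category), , drop = FALSE]
}

#' Select an item-disjoint, category-balanced set of pairs
#'
#' Chooses, among all item-disjoint subsets of the candidate pairs (no serial
#' position used twice), one that lexicographically maximizes first the
#' minimum per-category count and then the total count. The search is an
#' exact depth-first branch-and-bound, so on any instance the result attains
#' the brute-force optimum; candidates are visited in a fixed order
#' (category, earliest output position, serial positions), which makes the
#' selection fully deterministic.
#'
#' @param candidates candidate data frame from [categorize_pairs()] (one
#'   list's worth; the item-disjointness constraint is per list).
#' @param seed unused (selection is deterministic); kept so callers may pass
#'   a seed uniformly across pipeline stages.
#' @param balance_categories categories participating in the max-min
#'   objective; defaults to all categories present among the candidates.
#' @return `candidates` with a logical `selected` column.
#' @export
select_pairs <- function(candidates, seed = NULL, balance_categories = NULL) {
  n <- nrow(candidates)
  candidates$selected <- logical(n)
  if (n == 0L) return(candidates)
  if (is.null(balance_categories)) {
    balance_categories <- intersect(PAIR_CATEGORIES, unique(candidates$category))
  }
  ord <- order(match(candidates$category, PAIR_CATEGORIES),
               pmin(candidates$output_a, candidates$output_b),
               candidates$item_a_serial, candidates$item_b_serial)
  cand <- candidates[ord, , drop = FALSE]
  cat_idx <- match(cand$category, balance_categories)  # NA: counts only in total
  cat_idx[is.na(cat_idx)] <- 0L
  sel <- .select_engine(cand$item_a_serial, cand$item_b_serial,
                        cat_idx - 1L, length(balance_categories))
  res <- candidates
  res$selected[ord] <- sel
  res
}

#' Extract and select pairs for every list of a dataset
#'
#' Runs [categorize_pairs()] and [select_pairs()] per (subject, list) and
#' binds the results, stamping identifiers and the study condition.
#'
#' @param dataset a `recall_dataset`.
#' @param merge_first_three if `TRUE`, first-three pairs are folded into
#'   their lag-defined categories before selection instead of being kept as
#'   their own category.
#' @param seed forwarded to [select_pairs()] (selection is deterministic).
#' @return A pair table with columns `subject_id`, `list_id`, `condition`,
#'   the [categorize_pairs()] columns, and `selected`.
#' @export
extract_pairs <- function(dataset, merge_first_three = FALSE, seed = NULL) {
  L_of <- list_lengths(dataset$study)
  cond_of <- tapply(dataset$study$condition,
                    paste(dataset$study$subject_id, dataset$study$list_id,
                          sep = "\r"),
                    function(x) x[1])
  key <- paste(dataset$recalls$subject_id, dataset$recalls$list_id, sep = "\r")
  chunks <- lapply(split(seq_len(nrow(dataset$recalls)), key), function(rows) {
    rows <- rows[order(dataset$recalls$output_position[rows])]
    seq <- dataset$recalls[rows, , drop = FALSE]
    k <- key[rows[1]]
    cand <- categorize_pairs(seq, L = L_of[[k]])
    if (merge_first_three) cand <- merge_first_three_pairs(cand)
    cand <- select_pairs(cand, seed = seed)
    if (nrow(cand) == 0L) return(NULL)
    cbind(data.frame(subject_id = seq$subject_id[1], list_id = seq$list_id[1],
                     condition = cond_of[[k]], stringsAsFactors = FALSE),
          cand)
  })
  chunks <- Filter(Negate(is.null), chunks)
  out <- if (length(chunks)) do.call(rbind, chunks) else
    cbind(data.frame(subject_id = character(0), list_id = integer(0),
                     condition = character(0), stringsAsFactors = FALSE),
          select_pairs(categorize_pairs(recall_sequence(integer(0)))))
  rownames(out) <- NULL
  out
}

#' Count selected pairs per subject and category
#'
#' Feeds the inclusion filters: the main analyses require a minimum number of
#' selected pairs in every analysis category.
#'
#' @param pairs pair table from [extract_pairs()] (or a compatible frame).
#' @param categories categories to tabulate; defaults to the three analysis
#'   categories (first-three pairs are excluded from main analyses).
#' @param selected_only count only selected pairs (default `TRUE`).
#' @return A data frame with `subject_id` and one integer column per
#'   category; subjects present in `pairs` but with no pair in a category get
#'   zero.
#' @export
count_pairs_per_category <- function(pairs,
                                     categories = ANALYSIS_CATEGORIES,
                                     selected_only = TRUE) {
  if (selected_only && "selected" %in% names(pairs)) {
    pairs <- pairs[pairs$selected, , drop = FALSE]
  }
  subjects <- sort(unique(pairs$subject_id))
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (cat in categories) {
    tab <- table(pairs$subject_id[pairs$category == cat])
    out[[cat]] <- as.integer(tab[subjects])
    out[[cat]][is.na(out[[cat]])] <- 0L
  }
  out
}
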