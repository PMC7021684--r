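# Explicit sequence-memory scores from ordering-task placements.
#
# relative_score    1 if the slot order of the two members matches their
#                   study order, else 0
# absolute_deviation |slot - serial| of one item (slots)
# absolute_score    1 - deviation / max possible deviation for that serial
#                   position; in [0, 1], with 1 = perfect placement
# distance_score    |slot_a - slot_b| - |serial_a - serial_b|; negative
#                   means the pair was placed closer than studied
# perfect_pair      relative_score == 1 AND distance_score == 0

check_positions <- function(x, L, what) {
  if (any(is.na(x)) || any(x < 1L | x > L)) {
    stop(sprintf("domain error: %s outside 1..%d", what, L), call. = FALSE)
  }
  if (any(x != as.integer(x))) {
    stop(sprintf("domain error: %s must be integer", what), call. = FALSE)
  }
}

#' Relative order score of a placed pair
#'
#' Returns 1 when the two members' slot order matches their study order and
#' 0 otherwise; the magnitude of the placements is irrelevant, so items with
#' serial positions 7 and 8 placed at slots 1 and 16, or at slots 2 and 3,
#' both score 1.
#'
#' @param serial_a,serial_b study serial positions of the two members.
#' @param slot_a,slot_b their placed slots (equal slots are invalid).
#' @param L list length (slot-grid size).
#' @return Integer vector of 0/1 scores.
#' @export
relative_score <- function(serial_a, serial_b, slot_a, slot_b, L = 16L) {
  check_positions(serial_a, L, "serial_a"); check_positions(serial_b, L, "serial_b")
  check_positions(slot_a, L, "slot_a"); check_positions(slot_b, L, "slot_b")
  if (any(slot_a == slot_b)) {
    stop("invalid placement: slot_a == slot_b", call. = FALSE)
  }
  if (any(serial_a == serial_b)) {
    stop("invalid pair: serial_a == serial_b", call. = FALSE)
  }
  as.integer(sign(slot_a - slot_b) == sign(serial_a - serial_b))
}

#' Absolute placement deviation of one item
#'
#' The unsigned slot distance between an item's placement and its study
#' position.
#'
#' @param serial study serial position.
#' @param slot placed slot.
#' @inheritParams relative_score
#' @return Integer vector of deviations (>= 0, in slots).
#' @export
absolute_deviation <- function(serial, slot, L = 16L) {
  check_positions(serial, L, "serial"); check_positions(slot, L, "slot")
  abs(slot - serial)
}

#' Normalized absolute placement score of one item
#'
#' `1 - deviation / max deviation`, where the maximal possible deviation for
#' serial position p on an L-slot grid is `max(p - 1, L - p)`. This
#' normalization removes the confound that end-of-list items can deviate
#' farther than mid-list items: the score is 1 for perfect placement and
#' exactly 0 for the largest deviation attainable from that position.
#'
#' @inheritParams absolute_deviation
#' @return Numeric vector in \[0, 1\].
#' @export
absolute_score <- function(serial, slot, L = 16L) {
  dev <- absolute_deviation(serial, slot, L)
  1 - dev / pmax(serial - 1L, L - serial)
}

#' Inter-item distance score of a placed pair
#'
#' Placed slot distance minus studied serial distance. Zero means the pair
#' was placed at its studied distance; negative values mean the members were
#' placed closer together than they appeared at study (compression),
#' positive values farther apart. For study-adjacent pairs the score cannot
#' be negative (two items cannot share a slot).
#'
#' @inheritParams relative_score
#' @return Integer vector of signed distances (slots).
#' @export
distance_score <- function(serial_a, serial_b, slot_a, slot_b, L = 16L) {
  check_positions(serial_a, L, "serial_a"); check_positions(serial_b, L, "serial_b")
  check_positions(slot_a, L, "slot_a"); check_positions(slot_b, L, "slot_b")
  if (any(slot_a == slot_b)) {
    stop("invalid placement: slot_a == slot_b", call. = FALSE)
  }
  abs(slot_a - slot_b) - abs(serial_a - serial_b)
}

#' Score one ordering placement against its pair record
#'
#' Computes all pair scores for a single placement. Absolute measures are
#' attached to the first-placed item only: the second item's placement is
#' anchored by the first and does not isolate absolute position memory.
#'
#' @param placement one-row data frame (or list) with `item_a_serial`,
#'   `item_b_serial`, `slot_a`, `slot_b`, `first_placed` (`"a"` or `"b"`).
#' @param pair optional pair record with `item_a_serial`/`item_b_serial`;
#'   when given, membership must match the placement.
#' @inheritParams relative_score
#' @return A one-row data frame: `relative_score`, `absolute_score`,
#'   `absolute_deviation`, `distance_score`, `perfect_pair`,
#'   `first_serial`, `first_slot`.
#' @export
score_pair <- function(placement, pair = NULL, L = 16L) {
  if (!is.null(pair)) {
    same <- setequal(c(placement$item_a_serial, placement$item_b_serial),
                     c(pair$item_a_serial, pair$item_b_serial))
    if (!same) stop("integrity error: placement does not match pair membership",
                    call. = FALSE)
  }
  first_a <- identical(placement$first_placed, "a") ||
    (length(placement$first_placed) == 1L && placement$first_placed == "a")
  fs <- if (first_a) placement$item_a_serial else placement$item_b_serial
  fl <- if (first_a) placement$slot_a else placement$slot_b
  rel <- relative_score(placement$item_a_serial, placement$item_b_serial,
                        placement$slot_a, placement$slot_b, L)
  dist <- distance_score(placement$item_a_serial, placement$item_b_serial,
                         placement$slot_a, placement$slot_b, L)
  data.frame(relative_score = rel,
             absolute_score = absolute_score(fs, fl, L),
             absolute_deviation = absolute_deviation(fs, fl, L),
             distance_score = dist,
             perfect_pair = rel == 1L & dist == 0L,
             first_serial = fs, first_slot = fl)
}

#' Score all ordering placements of a dataset
#'
#' Joins the ordering table onto the selected pairs (unordered membership
#' match within subject and list) and computes every pair score. Pairs never
#' presented in the ordering task are dropped; placements without a matching
#' selected pair raise an integrity error.
#'
#' @param dataset a `recall_dataset` with a non-empty ordering table.
#' @param pairs selected pair table from [extract_pairs()].
#' @param include_second if `TRUE`, also emit the second-placed item's
#'   absolute score/deviation (`absolute_score_second`,
#'   `absolute_deviation_second`) for exploration; these never enter the
#'   default analyses.
#' @return The pair rows joined with their placement and all score columns.
#' @export
score_pairs <- function(dataset, pairs, include_second = FALSE) {
  ord <- dataset$ordering
  if (nrow(ord) == 0L) {
    stop("scoring requires a non-empty ordering table", call. = FALSE)
  }
  L_of <- list_lengths(dataset$study)
  sel <- pairs[pairs$selected, , drop = FALSE]
  okey <- paste(ord$subject_id, ord$list_id,
                pair_key(ord$item_a_serial, ord$item_b_serial), sep = "\r")
  pkey <- paste(sel$subject_id, sel$list_id,
                pair_key(sel$item_a_serial, sel$item_b_serial), sep = "\r")
  idx <- match(okey, pkey)
  if (anyNA(idx)) {
    stop_integrity("ordering table",
                   "placement without a matching selected pair", which(is.na(idx)))
  }
  out <- sel[idx, , drop = FALSE]
  # align slots to the pair's (a, b) labelling
  flipped <- ord$item_a_serial != out$item_a_serial
  slot_a <- ifelse(flipped, ord$slot_b, ord$slot_a)
  slot_b <- ifelse(flipped, ord$slot_a, ord$slot_b)
  first_placed <- ifelse(flipped,
                         ifelse(ord$first_placed == "a", "b", "a"),
                         ord$first_placed)
  L <- as.integer(L_of[paste(ord$subject_id, ord$list_id, sep = "\r")])
  if (length(unique(L)) > 1L) {
    stop("scoring across lists of different lengths is not supported",
         call. = FALSE)
  }
  L1 <- L[1]
  out$trial_index <- ord$trial_index
  out$slot_a <- slot_a
  out$slot_b <- slot_b
  out$first_placed <- first_placed
  fs <- ifelse(first_placed == "a", out$item_a_serial, out$item_b_serial)
  fl <- ifelse(first_placed == "a", slot_a, slot_b)
  out$relative_score <- relative_score(out$item_a_serial, out$item_b_serial,
                                       slot_a, slot_b, L1)
  out$absolute_score <- absolute_score(fs, fl, L1)
  out$absolute_deviation <- absolute_deviation(fs, fl, L1)
  out$distance_score <- distance_score(out$item_a_serial, out$item_b_serial,
                                       slot_a, slot_b, L1)
  out$perfect_pair <- out$relative_score == 1L & out$distance_score == 0L
  if (include_second) {
    ss <- ifelse(first_placed == "a", out$item_b_serial, out$item_a_serial)
    sl <- ifelse(first_placed == "a", slot_b, slot_a)
    out$absolute_score_second <- absolute_score(ss, sl, L1)
    out$absolute_deviation_second <- absolute_deviation(ss, sl, L1)
  }
  rownames(out) <- NULL
  out
}
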