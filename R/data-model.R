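# Data model, validation and IO for study / recall / ordering event tables.
#
# The on-disk contract is three UTF-8 comma-delimited tables with headers:
#   study.csv    subject_id, list_id, condition, serial_position, item
#   recalls.csv  subject_id, list_id, output_position, response
#   ordering.csv subject_id, list_id, trial_index, item_a_serial,
#                item_b_serial, slot_a, slot_b, first_placed
# All positions (serial, output, slot) are 1-based.

CONDITIONS <- c("order", "no_order")
PAIR_CATEGORIES <- c("cont_enc_ret", "cont_ret", "cont_enc", "first_three")
ANALYSIS_CATEGORIES <- c("cont_enc_ret", "cont_ret", "cont_enc")

norm_token <- function(x) tolower(trimws(x))

stop_schema <- function(what, missing) {
  stop(sprintf("schema error in %s: missing required column(s) %s",
               what, paste(missing, collapse = ", ")), call. = FALSE)
}

stop_integrity <- function(what, msg, rows = NULL) {
  loc <- if (length(rows)) sprintf(" (rows %s)", paste(utils::head(rows, 10L), collapse = ", ")) else ""
  stop(sprintf("integrity error in %s: %s%s", what, msg, loc), call. = FALSE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) stop_schema(what, missing)
  invisible(df)
}

#' Match typed recall responses against a study list
#'
#' Tokens are compared to study items by exact string equality after
#' whitespace trimming and case folding. The second and later occurrences of
#' an already-matched item are flagged as repeats; unmatched tokens are
#' flagged as intrusions. No fuzzy matching is performed by default; a
#' pluggable `matcher` hook is exposed for corpora where normalization beyond
#' trim + case-fold is required.
#'
#' @param raw_tokens character vector of typed responses in output order.
#' @param study_items character vector of studied items in serial order
#'   (serial position = index).
#' @param matcher optional `function(token, study_items)` returning a matched
#'   serial position or `NA`; defaults to exact trim + case-fold matching.
#' @return A data frame with one row per response: `output_position`,
#'   `response`, `matched_serial_position`, `is_intrusion`, `is_repeat`.
#' @examples
#' match_responses(c("Fox ", "owl", "fox"), c("fox", "hen", "owl"))
#' @export
match_responses <- function(raw_tokens, study_items, matcher = NULL) {
  raw_tokens <- as.character(raw_tokens)
  if (length(raw_tokens) == 0L) {
    return(data.frame(output_position = integer(0), response = character(0),
                      matched_serial_position = integer(0),
                      is_intrusion = logical(0), is_repeat = logical(0),
                      stringsAsFactors = FALSE))
  }
  key <- norm_token(study_items)
  if (anyDuplicated(key)) {
    stop_integrity("study list", "items are not unique after normalization")
  }
  if (is.null(matcher)) {
    matched <- match(norm_token(raw_tokens), key)
  } else {
    matched <- vapply(raw_tokens, function(tok) {
      m <- matcher(tok, study_items)
      if (is.null(m) || is.na(m)) NA_integer_ else as.integer(m)
    }, integer(1), USE.NAMES = FALSE)
  }
  seen <- logical(length(study_items))
  is_repeat <- logical(length(raw_tokens))
  for (i in seq_along(matched)) {
    if (!is.na(matched[i])) {
      if (seen[matched[i]]) is_repeat[i] <- TRUE
      seen[matched[i]] <- TRUE
    }
  }
  data.frame(output_position = seq_along(raw_tokens),
             response = raw_tokens,
             matched_serial_position = as.integer(matched),
             is_intrusion = is.na(matched),
             is_repeat = is_repeat,
             stringsAsFactors = FALSE)
}

#' Build a matched recall table directly from serial positions
#'
#' Convenience constructor used by the simulator and by tests: turns a vector
#' of recalled serial positions (with `NA` marking an intrusion) into the
#' matched recall rows that [match_responses()] would produce.
#'
#' @param positions integer vector of recalled serial positions in output
#'   order; `NA` denotes an intrusion.
#' @param subject_id,list_id identifiers stamped on every row.
#' @return A matched recall data frame (see [match_responses()]) with
#'   `subject_id` and `list_id` columns prepended.
#' @export
recall_sequence <- function(positions, subject_id = "s1", list_id = 1L) {
  positions <- as.integer(positions)
  n <- length(positions)
  rep_flag <- logical(n)
  if (n) rep_flag <- duplicated(positions) & !is.na(positions)
  out <- data.frame(subject_id = as.character(subject_id),
                    list_id = as.integer(list_id),
                    output_position = seq_len(n)[seq_len(n)],
                    response = ifelse(is.na(positions), "<intrusion>",
                                      sprintf("w%02d", positions)),
                    matched_serial_position = positions,
                    is_intrusion = is.na(positions),
                    is_repeat = rep_flag,
                    stringsAsFactors = FALSE)
  if (n == 0L) out <- out[0, , drop = FALSE]
  out
}

validate_study <- function(study) {
  check_columns(study, c("subject_id", "list_id", "condition",
                         "serial_position", "item"), "study table")
  study$subject_id <- as.character(study$subject_id)
  study$list_id <- as.integer(study$list_id)
  study$serial_position <- as.integer(study$serial_position)
  study$item <- as.character(study$item)
  bad_cond <- which(!study$condition %in% CONDITIONS)
  if (length(bad_cond)) {
    stop_integrity("study table",
                   sprintf("condition must be one of {%s}",
                           paste(CONDITIONS, collapse = ", ")), bad_cond)
  }
  key <- paste(study$subject_id, study$list_id, study$serial_position)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_integrity("study table",
                   "duplicate (subject_id, list_id, serial_position)", dup)
  }
  by_list <- split(seq_len(nrow(study)),
                   paste(study$subject_id, study$list_id, sep = "\r"))
  for (rows in by_list) {
    sp <- sort(study$serial_position[rows])
    L <- length(sp)
    if (L < 2L || !identical(sp, seq_len(L))) {
      stop_integrity("study table",
                     "serial positions must be contiguous 1..L with L >= 2",
                     rows[1])
    }
    if (anyDuplicated(norm_token(study$item[rows]))) {
      stop_integrity("study table", "items not unique within a list", rows[1])
    }
    conds <- unique(study$condition[rows])
    if (length(conds) != 1L) {
      stop_integrity("study table", "one condition per list required", rows[1])
    }
  }
  study
}

validate_ordering <- function(ordering, study) {
  check_columns(ordering, c("subject_id", "list_id", "trial_index",
                            "item_a_serial", "item_b_serial",
                            "slot_a", "slot_b", "first_placed"),
                "ordering table")
  if (nrow(ordering) == 0L) return(ordering)
  ordering$subject_id <- as.character(ordering$subject_id)
  for (col in c("list_id", "trial_index", "item_a_serial", "item_b_serial",
                "slot_a", "slot_b")) {
    val <- ordering[[col]]
    if (any(as.integer(val) != val, na.rm = TRUE)) {
      stop_integrity("ordering table",
                     sprintf("%s must be integer (fractional placements rejected)", col),
                     which(as.integer(val) != val))
    }
    ordering[[col]] <- as.integer(val)
  }
  bad <- which(ordering$slot_a == ordering$slot_b)
  if (length(bad)) stop_integrity("ordering table", "slot_a == slot_b", bad)
  bad <- which(ordering$item_a_serial == ordering$item_b_serial)
  if (length(bad)) stop_integrity("ordering table", "item_a_serial == item_b_serial", bad)
  bad <- which(!ordering$first_placed %in% c("a", "b"))
  if (length(bad)) stop_integrity("ordering table", "first_placed must be 'a' or 'b'", bad)
  L_of <- list_lengths(study)
  key <- paste(ordering$subject_id, ordering$list_id, sep = "\r")
  L <- L_of[key]
  if (anyNA(L)) {
    stop_integrity("ordering table", "(subject_id, list_id) absent from study table",
                   which(is.na(L)))
  }
  for (col in c("item_a_serial", "item_b_serial", "slot_a", "slot_b")) {
    bad <- which(ordering[[col]] < 1L | ordering[[col]] > L)
    if (length(bad)) {
      stop_integrity("ordering table", sprintf("%s outside 1..L", col), bad)
    }
  }
  ordering
}

# Named vector of list lengths keyed by "subject\rlist".
list_lengths <- function(study) {
  key <- paste(study$subject_id, study$list_id, sep = "\r")
  tapply(study$serial_position, key, max)
}

#' Load and validate a session dataset from CSV files
#'
#' Reads the study, recall and (optionally) ordering event tables, validates
#' every structural invariant (contiguous 1-based serial positions, unique
#' items within a list, legal slots, known conditions), and matches raw typed
#' responses against their study list, flagging intrusions and repeats.
#' Malformed rows are reported with their row numbers.
#'
#' @param study_path,recall_path,ordering_path file paths; `ordering_path`
#'   may be `NULL` for recall-only datasets.
#' @param matcher optional response matcher passed to [match_responses()].
#' @return An object of class `recall_dataset`: a list with components
#'   `study`, `recalls` (matched, see [match_responses()]) and `ordering`.
#' @seealso [simulate_dataset()] to generate a dataset, [write_dataset()] for
#'   the inverse operation.
#' @export
load_sessions <- function(study_path, recall_path, ordering_path = NULL,
                          matcher = NULL) {
  for (p in c(study_path, recall_path, ordering_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  study <- read.csv(study_path, stringsAsFactors = FALSE)
  recalls_raw <- read.csv(recall_path, stringsAsFactors = FALSE,
                          colClasses = c(response = "character"))
  ordering <- if (is.null(ordering_path)) empty_ordering() else
    read.csv(ordering_path, stringsAsFactors = FALSE)
  recall_dataset(study, recalls_raw, ordering, matcher = matcher)
}

empty_ordering <- function() {
  data.frame(subject_id = character(0), list_id = integer(0),
             trial_index = integer(0), item_a_serial = integer(0),
             item_b_serial = integer(0), slot_a = integer(0),
             slot_b = integer(0), first_placed = character(0),
             stringsAsFactors = FALSE)
}

#' Assemble a validated dataset from in-memory tables
#'
#' @param study,recalls,ordering event tables following the CSV schemas (see
#'   [load_sessions()]); `recalls` holds raw responses which are matched here.
#' @inheritParams load_sessions
#' @return A `recall_dataset` object.
#' @export
recall_dataset <- function(study, recalls, ordering = empty_ordering(),
                           matcher = NULL) {
  study <- validate_study(study)
  check_columns(recalls, c("subject_id", "list_id", "output_position",
                           "response"), "recall table")
  recalls$subject_id <- as.character(recalls$subject_id)
  recalls$list_id <- as.integer(recalls$list_id)
  recalls$output_position <- as.integer(recalls$output_position)
  recalls$response <- as.character(recalls$response)

  skey <- paste(study$subject_id, study$list_id, sep = "\r")
  rkey <- paste(recalls$subject_id, recalls$list_id, sep = "\r")
  unknown <- which(!rkey %in% skey)
  if (length(unknown)) {
    stop_integrity("recall table", "(subject_id, list_id) absent from study table",
                   unknown)
  }
  items_of <- split(study$item[order(study$serial_position)],
                    skey[order(study$serial_position)])
  matched <- lapply(split(seq_len(nrow(recalls)), rkey), function(rows) {
    rows <- rows[order(recalls$output_position[rows])]
    op <- recalls$output_position[rows]
    if (!identical(as.integer(op), seq_along(op))) {
      stop_integrity("recall table",
                     "output positions must be contiguous 1..k", rows[1])
    }
    m <- match_responses(recalls$response[rows],
                         items_of[[rkey[rows[1]]]], matcher = matcher)
    cbind(data.frame(subject_id = recalls$subject_id[rows[1]],
                     list_id = recalls$list_id[rows[1]],
                     stringsAsFactors = FALSE), m)
  })
  recalls <- if (length(matched)) do.call(rbind, matched) else
    recall_sequence(integer(0))[0, ]
  rownames(recalls) <- NULL
  ordering <- validate_ordering(ordering, study)
  structure(list(study = study, recalls = recalls, ordering = ordering),
            class = "recall_dataset")
}

#' @export
print.recall_dataset <- function(x, ...) {
  ns <- length(unique(x$study$subject_id))
  nl <- nrow(unique(x$study[c("subject_id", "list_id")]))
  cat(sprintf("<recall_dataset> %d subject(s), %d list(s), %d recall row(s), %d ordering trial(s)\n",
              ns, nl, nrow(x$recalls), nrow(x$ordering)))
  invisible(x)
}

#' Audit a dataset against its structural invariants
#'
#' Dataset-wide re-check that every matched serial position exists in its
#' study list, that intrusion/repeat flags are internally consistent, and
#' that ordering trials reference recalled items. Used by tests and by
#' [run_pipeline()] as a gate before scoring.
#'
#' @param dataset a `recall_dataset`.
#' @return Invisibly, a character vector of violations (empty when clean).
#' @export
audit_dataset <- function(dataset) {
  problems <- character(0)
  r <- dataset$recalls
  L_of <- list_lengths(dataset$study)
  key <- paste(r$subject_id, r$list_id, sep = "\r")
  bad <- !is.na(r$matched_serial_position) &
    (r$matched_serial_position < 1L | r$matched_serial_position > L_of[key])
  if (any(bad)) problems <- c(problems, "matched serial position outside 1..L")
  if (any(r$is_intrusion != is.na(r$matched_serial_position))) {
    problems <- c(problems, "is_intrusion inconsistent with matched_serial_position")
  }
  for (rows in split(seq_len(nrow(r)), key)) {
    sp <- r$matched_serial_position[rows]
    rep_ok <- r$is_repeat[rows] == (duplicated(sp) & !is.na(sp))
    if (!all(rep_ok)) {
      problems <- c(problems, "is_repeat inconsistent with earlier outputs")
      break
    }
  }
  if (length(problems)) warning(paste(problems, collapse = "; "), call. = FALSE)
  invisible(problems)
}

#' Write scored tables to a directory
#'
#' Emits tidy CSVs (per-pair scores and per-subject summaries, plus the raw
#' event tables when present) and returns a manifest of files and row counts.
#'
#' @param dataset a `recall_dataset`.
#' @param scores per-pair score table from [score_pairs()], or `NULL`.
#' @param out_dir output directory, created if needed.
#' @param summaries optional per-subject summary table from
#'   [subject_summary()].
#' @return A data frame manifest with columns `file` and `rows`.
#' @export
write_scored_tables <- function(dataset, scores = NULL, out_dir,
                                summaries = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  }
  tables <- list(study = dataset$study, recalls = dataset$recalls,
                 ordering = dataset$ordering)
  if (!is.null(scores)) tables$pair_scores <- scores
  if (!is.null(summaries)) tables$subject_summary <- summaries
  manifest <- data.frame(file = character(0), rows = integer(0),
                         stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    ok <- tryCatch({
      write.csv(tables[[nm]], path, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop(sprintf("I/O error writing %s", path), call. = FALSE)
    manifest <- rbind(manifest,
                      data.frame(file = path, rows = nrow(tables[[nm]]),
                                 stringsAsFactors = FALSE))
  }
  manifest
}
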