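# Temporal clustering score and recall-performance summaries.
#
# Each recall transition is scored as the percentile rank of its absolute
# lag among the absolute lags of all still-available items (tied lags get
# average rank). 1 means the closest available item was recalled, 0 the
# farthest; averaging over transitions gives a per-subject score whose
# chance level is exactly 0.5 and whose optimum (perfectly serial recall
# from position 1) is exactly 1.

#' Percentile rank of one recall transition
#'
#' Ranks the candidate absolute lags `|p - from|` over the available items
#' ascending, with ties given their average rank, and returns
#' `1 - (rank(actual) - 1) / (n - 1)` where `n` is the number of available
#' items. The average-rank tie convention is what makes the expected value
#' under uniformly random transitions exactly 0.5.
#'
#' @param from_serial serial position just recalled (not in `available`).
#' @param to_serial serial position recalled next (must be in `available`).
#' @param available integer vector of serial positions not yet recalled.
#' @return A value in \[0, 1\], or `NA` when only one item is available
#'   (the percentile is undefined and the transition is skipped by callers).
#' @export
transition_percentile <- function(from_serial, to_serial, available) {
  available <- as.integer(available)
  if (from_serial %in% available) {
    stop("from_serial must not be in the available set", call. = FALSE)
  }
  if (!to_serial %in% available) {
    stop("to_serial must be in the available set", call. = FALSE)
  }
  n <- length(available)
  if (n < 2L) return(NA_real_)
  lags <- abs(available - from_serial)
  rk <- rank(lags, ties.method = "average")
  actual <- rk[match(to_serial, available)]
  1 - (actual - 1) / (n - 1)
}

# Percentiles of every valid transition of one list's matched recall rows.
# Available set = study items not yet correctly recalled (intrusions do not
# shrink it); transitions are not bridged across intrusions/repeats;
# transitions with a single available item are skipped.
list_transition_percentiles <- function(seq, L) {
  ok <- !seq$is_intrusion & !seq$is_repeat
  serial <- seq$matched_serial_position
  recalled <- logical(L)
  res <- numeric(0)
  n <- nrow(seq)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    if (i > 1L && ok[i - 1L]) {
      avail <- which(!recalled)
      if (length(avail) >= 2L) {
        p <- transition_percentile(serial[i - 1L], serial[i], avail)
        if (!is.na(p)) res <- c(res, p)
      }
    }
    recalled[serial[i]] <- TRUE
  }
  res
}

#' Temporal clustering score per subject
#'
#' Pools every valid transition of a subject's lists (within the given
#' scope) and averages their percentile ranks. Pooling before averaging
#' weights each transition equally, which stabilizes the estimate for lists
#' with few recalls. A score of 1 reflects maximal reliance on temporal
#' context (always the nearest available item); 0.5 is chance.
#'
#' @param recalls matched recall rows (any number of subjects and lists).
#' @param L list length, or a named vector from [list_lengths()] keyed by
#'   `"subject\rlist"`.
#' @return Named numeric vector of scores by subject; `NA` for subjects with
#'   no valid transition (a warning lists them).
#' @export
temporal_score <- function(recalls, L = 16L) {
  key <- paste(recalls$subject_id, recalls$list_id, sep = "\r")
  per_subj <- split(seq_len(nrow(recalls)), recalls$subject_id)
  out <- vapply(per_subj, function(rows) {
    ps <- unlist(lapply(split(rows, key[rows]), function(lr) {
      lr <- lr[order(recalls$output_position[lr])]
      Lk <- if (length(L) == 1L) L else L[[key[lr[1]]]]
      list_transition_percentiles(recalls[lr, , drop = FALSE], Lk)
    }))
    if (length(ps)) mean(ps) else NA_real_
  }, numeric(1))
  if (anyNA(out)) {
    warning(sprintf("no valid transitions for subject(s): %s",
                    paste(names(out)[is.na(out)], collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Mean correct recalls per list
#'
#' Counts unique correct (non-intrusion, non-repeat) items per list and
#' averages over the lists present in the recall table.
#'
#' @inheritParams temporal_score
#' @return Named numeric vector of mean correct recalls by subject.
#' @export
recall_performance <- function(recalls) {
  key <- paste(recalls$subject_id, recalls$list_id, sep = "\r")
  per_subj <- split(seq_len(nrow(recalls)), recalls$subject_id)
  vapply(per_subj, function(rows) {
    counts <- vapply(split(rows, key[rows]), function(lr) {
      sp <- recalls$matched_serial_position[lr]
      length(unique(sp[!is.na(sp)]))
    }, numeric(1))
    mean(counts)
  }, numeric(1))
}

#' Per-subject, per-condition summary of recall behaviour
#'
#' Computes the temporal score and mean recall per subject within each
#' condition, plus an `"all"` row pooling both conditions (used for the
#' between-subject correlation analyses).
#'
#' @param dataset a `recall_dataset`.
#' @return A data frame with `subject_id`, `condition` (including `"all"`),
#'   `temporal_score`, `mean_recall`.
#' @export
subject_summary <- function(dataset) {
  L_of <- list_lengths(dataset$study)
  cond_of <- tapply(dataset$study$condition,
                    paste(dataset$study$subject_id, dataset$study$list_id,
                          sep = "\r"), function(x) x[1])
  r <- dataset$recalls
  cond <- cond_of[paste(r$subject_id, r$list_id, sep = "\r")]
  pieces <- lapply(c(CONDITIONS, "all"), function(cd) {
    sub <- if (cd == "all") r else r[cond == cd, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    ts <- suppressWarnings(temporal_score(sub, L = L_of))
    mr <- recall_performance(sub)
    data.frame(subject_id = names(ts), condition = cd,
               temporal_score = unname(ts),
               mean_recall = unname(mr[names(ts)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), pieces))
  rownames(out) <- NULL
  out
}

#' Condition-difference covariates per subject
#'
#' Signed differences (order minus no-order) in mean recall and temporal
#' score, used as between-subject covariates to rule out that introducing
#' the ordering task changed recall behaviour.
#'
#' @param summaries output of [subject_summary()].
#' @return A data frame `subject_id`, `diff_recall`, `diff_temporal`;
#'   subjects lacking either condition get `NA` (and are excluded from
#'   covariate-adjusted models by the caller).
#' @export
condition_covariates <- function(summaries) {
  subjects <- unique(summaries$subject_id)
  pick <- function(sid, cd, col) {
    v <- summaries[[col]][summaries$subject_id == sid &
                            summaries$condition == cd]
    if (length(v) == 1L) v else NA_real_
  }
  data.frame(
    subject_id = subjects,
    diff_recall = vapply(subjects, function(s)
      pick(s, "order", "mean_recall") - pick(s, "no_order", "mean_recall"),
      numeric(1)),
    diff_temporal = vapply(subjects, function(s)
      pick(s, "order", "temporal_score") - pick(s, "no_order", "temporal_score"),
      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
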