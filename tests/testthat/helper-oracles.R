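# Independent oracles and fixture builders used across the test files.

# The recall sequence printed in the task's worked walkthrough, labelled by
# study serial position.
worked_sequence <- function() recall_sequence(c(16, 15, 14, 12, 4, 7, 8, 2, 10, 13))

# Count-based percentile oracle: average rank computed from explicit
# smaller/equal counts rather than rank().
oracle_percentile <- function(from, to, available) {
  n <- length(available)
  if (n < 2L) return(NA_real_)
  lags <- abs(available - from)
  actual <- abs(to - from)
  rk <- sum(lags < actual) + (sum(lags == actual) + 1) / 2
  1 - (rk - 1) / (n - 1)
}

# Exhaustive enumeration of all disjoint candidate subsets; returns the best
# lexicographic (min per balanced category, total) key.
oracle_select_key <- function(candidates,
                              balance = intersect(ordermem:::PAIR_CATEGORIES,
                                                  unique(candidates$category))) {
  n <- nrow(candidates)
  best <- c(-1L, -1L)
  a <- candidates$item_a_serial; b <- candidates$item_b_serial
  cat <- match(candidates$category, balance)
  recurse <- function(i, used, counts, total) {
    if (i > n) {
      key <- c(if (length(balance)) min(counts) else 0L, total)
      if (key[1] > best[1] || (key[1] == best[1] && key[2] > best[2])) {
        best <<- key
      }
      return(invisible(NULL))
    }
    if (!a[i] %in% used && !b[i] %in% used) {
      counts2 <- counts
      if (!is.na(cat[i])) counts2[cat[i]] <- counts2[cat[i]] + 1L
      recurse(i + 1L, c(used, a[i], b[i]), counts2, total + 1L)
    }
    recurse(i + 1L, used, counts, total)
  }
  recurse(1L, integer(0), integer(length(balance)), 0L)
  best
}

selection_key <- function(selected,
                          balance = intersect(ordermem:::PAIR_CATEGORIES,
                                              unique(selected$category))) {
  sel <- selected[selected$selected, , drop = FALSE]
  counts <- vapply(balance, function(cc) sum(sel$category == cc), integer(1))
  c(if (length(balance)) min(counts) else 0L, nrow(sel))
}

# Random candidate instance on a 16-position grid.
random_candidates <- function(n_cand, L = 16L) {
  a <- integer(0); b <- integer(0)
  while (length(a) < n_cand) {
    p <- sort(sample.int(L, 2L))
    key <- paste(p[1], p[2])
    if (!key %in% paste(pmin(a, b), pmax(a, b))) {
      a <- c(a, p[1]); b <- c(b, p[2])
    }
  }
  data.frame(item_a_serial = a, item_b_serial = b,
             category = sample(ordermem:::PAIR_CATEGORIES[1:3], n_cand,
                               replace = TRUE),
             encoding_lag = b - a,
             direction = "none",
             output_a = sample.int(12L, n_cand, replace = TRUE),
             output_b = sample.int(12L, n_cand, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Small fully in-code dataset: 2 subjects x 2 lists (one per condition),
# known recalls and hand-made placements.
tiny_dataset <- function() {
  study <- do.call(rbind, lapply(c("sA", "sB"), function(sid) {
    do.call(rbind, lapply(1:2, function(l) {
      data.frame(subject_id = sid, list_id = l,
                 condition = c("order", "no_order")[l],
                 serial_position = 1:16,
                 item = sprintf("%s_l%d_w%02d", sid, l, 1:16),
                 stringsAsFactors = FALSE)
    }))
  }))
  pos <- list(sA = list(c(16, 15, 14, 12, 4, 7, 8, 2, 10, 13), c(1, 2, 3, 5)),
              sB = list(c(5, 6, 7, 1, 2), c(16, 15, 3, 4)))
  recalls <- do.call(rbind, lapply(names(pos), function(sid) {
    do.call(rbind, lapply(1:2, function(l) {
      p <- pos[[sid]][[l]]
      items <- study$item[study$subject_id == sid & study$list_id == l]
      data.frame(subject_id = sid, list_id = l,
                 output_position = seq_along(p), response = items[p],
                 stringsAsFactors = FALSE)
    }))
  }))
  recall_dataset(study, recalls)
}

# Simulated dataset cached per options (speeds up files sharing a fixture).
sim_fixture <- local({
  cache <- list()
  function(..., seed = 101) {
    key <- paste(deparse(list(...)), seed, collapse = ";")
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_dataset(simulation_params(..., seed = seed))
    }
    cache[[key]]
  }
})
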