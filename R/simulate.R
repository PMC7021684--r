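# Generative simulator of participants: study lists, contiguity-structured
# recall, and category-dependent ordering placements with known parameters.
#
# Recall is a minimal lag-based sampler (weight ~ exp(-|lag|/tau), forward
# lags multiplied by an asymmetry factor), not a full retrieved-context
# model: the analyses only consume contiguity structure. Ordering follows a
# two-part pair model: the first-placed item lands near its true position
# (identical for all categories, so absolute measures carry no category
# signal by construction), and the second member is placed relative to the
# first with a remembered direction and a Weber-scaled remembered distance.
# Shared-context binding enters only at the pair level: study-adjacent pairs
# get lower pair noise (shared_context_bonus), and contiguously
# encoded-and-retrieved pairs may be "glued" to the adjacent slot on the
# correct side (glue_prob).

#' Simulation parameters
#'
#' Validated parameter container for [simulate_dataset()]. Defaults emulate
#' a session of 28 test lists of 16 words (19 with an ordering task, 9
#' without) and are calibrated so the expected score profile matches typical
#' human performance on this task family (relative score around 0.8 for
#' study-adjacent pairs and 0.65 otherwise, mean absolute deviation around
#' 1.3 slots).
#'
#' @param n_subjects number of simulated participants.
#' @param n_lists test lists per participant.
#' @param n_order_lists how many of the lists carry an ordering task.
#' @param L list length (slot-grid size).
#' @param condition_schedule `"intermixed"` (order / no-order lists randomly
#'   interleaved) or `"blocked"` (all no-order lists first).
#' @param tau contiguity scale (> 0, may be `Inf`): transition weight is
#'   proportional to `exp(-|lag|/tau)`; small tau = strong contiguity.
#' @param asymmetry multiplier (>= 1) applied to forward (positive) lags,
#'   producing the forward asymmetry of free recall.
#' @param recency_start probability in \[0, 1\] that the first recall is
#'   drawn uniformly from the last three studied positions.
#' @param stop_prob per-output stopping probability in (0, 1).
#' @param placement_noise_sd sd (slots) of the first-placed item's placement
#'   around its true position.
#' @param pair_noise_sd sd (slots, per unit of studied distance) of the
#'   remembered within-pair displacement.
#' @param shared_context_bonus reduction of `pair_noise_sd` for
#'   study-adjacent pairs (floored at 0).
#' @param glue_prob probability in \[0, 1\] that a cont-enc-ret pair's second
#'   member is placed in the adjacent slot on the correct side.
#' @param distance_weber_exp exponent on studied distance in the pair noise
#'   (1 = noise proportional to distance, which makes relative-order
#'   accuracy independent of lag; > 1 makes long-lag pairs noisier).
#' @param distance_compression multiplicative bias (0, 1] on the remembered
#'   distance of non-adjacent pairs; < 1 reproduces the compression
#'   (negative distance scores) typical of pairs retrieved contiguously but
#'   studied far apart.
#' @param subject_sd sd of a log-normal per-subject fidelity factor that
#'   jointly scales contiguity and placement precision (creates realistic
#'   between-subject correlations between temporal and order scores).
#' @param intrusion_rate,repeat_rate per-output probabilities of inserting
#'   an extra-list intrusion / a repeated item (0 by default; used to
#'   exercise the validators).
#' @param pool_size size of the synthetic word pool sampled without
#'   replacement for each participant's lists.
#' @param experiment experiment label stamped on the subject parameter
#'   table (pooled analyses may use it as a covariate).
#' @param seed integer seed; identical parameters including the seed yield a
#'   bit-identical dataset.
#' @return An object of class `simulation_params` (a validated list).
#' @export
simulation_params <- function(n_subjects = 30L, n_lists = 28L,
                              n_order_lists = 19L, L = 16L,
                              condition_schedule = c("intermixed", "blocked"),
                              tau = 2, asymmetry = 1.5, recency_start = 0.7,
                              stop_prob = 0.1,
                              placement_noise_sd = 1.6, pair_noise_sd = 2.6,
                              shared_context_bonus = 1.3, glue_prob = 0.2,
                              distance_weber_exp = 1,
                              distance_compression = 0.65,
                              subject_sd = 0.25,
                              intrusion_rate = 0, repeat_rate = 0,
                              pool_size = 661L, experiment = 1L,
                              seed = NULL) {
  condition_schedule <- match.arg(condition_schedule)
  stopifnot(n_subjects >= 1, n_lists >= 1, L >= 2,
            n_order_lists >= 0, n_order_lists <= n_lists,
            tau > 0, asymmetry >= 1,
            recency_start >= 0, recency_start <= 1,
            stop_prob > 0, stop_prob < 1,
            placement_noise_sd >= 0, pair_noise_sd >= 0,
            shared_context_bonus >= 0,
            glue_prob >= 0, glue_prob <= 1,
            distance_weber_exp > 0,
            distance_compression > 0, distance_compression <= 1,
            subject_sd >= 0,
            intrusion_rate >= 0, intrusion_rate < 1,
            repeat_rate >= 0, repeat_rate < 1)
  if (pool_size < n_lists * L) {
    stop("configuration error: word pool smaller than n_lists * L",
         call. = FALSE)
  }
  p <- as.list(environment())
  structure(p, class = "simulation_params")
}

#' @export
print.simulation_params <- function(x, ...) {
  cat(sprintf(paste0("<simulation_params> %d subjects x %d lists (L = %d, ",
                     "%d with ordering, %s)\n"),
              x$n_subjects, x$n_lists, x$L, x$n_order_lists,
              x$condition_schedule))
  cat(sprintf("  recall: tau = %.3g, asymmetry = %.2f, recency_start = %.2f, stop = %.2f\n",
              x$tau, x$asymmetry, x$recency_start, x$stop_prob))
  cat(sprintf("  ordering: item sd = %.2f, pair sd = %.2f, bonus = %.2f, glue = %.2f\n",
              x$placement_noise_sd, x$pair_noise_sd, x$shared_context_bonus,
              x$glue_prob))
  invisible(x)
}

#' Simulate the study phase for one participant
#'
#' Samples `n_lists` lists of `L` unique tokens without replacement from the
#' synthetic pool and assigns conditions per the schedule (blocked: all
#' no-order lists first; intermixed: random interleaving).
#'
#' @param params a [simulation_params()] object.
#' @param subject_id identifier stamped on the rows.
#' @return A study table (see [load_sessions()] for the schema).
#' @export
simulate_study_phase <- function(params, subject_id = "s01") {
  pool <- sprintf("noun%04d", seq_len(params$pool_size))
  words <- sample(pool, params$n_lists * params$L)
  n_no <- params$n_lists - params$n_order_lists
  cond <- if (params$condition_schedule == "blocked") {
    rep(CONDITIONS[c(2, 1)], c(n_no, params$n_order_lists))
  } else {
    sample(rep(CONDITIONS[c(2, 1)], c(n_no, params$n_order_lists)))
  }
  data.frame(subject_id = subject_id,
             list_id = rep(seq_len(params$n_lists), each = params$L),
             condition = rep(cond, each = params$L),
             serial_position = rep(seq_len(params$L), params$n_lists),
             item = words,
             stringsAsFactors = FALSE)
}

# One list's recall as a vector of serial positions; NA marks an intrusion,
# duplicated values mark repeats.
simulate_recall_positions <- function(params, tau = params$tau) {
  L <- params$L
  first <- if (runif(1) < params$recency_start) {
    sample((L - 2L):L, 1L)
  } else {
    sample.int(L, 1L)
  }
  out <- first
  current <- first
  remaining <- setdiff(seq_len(L), first)
  while (length(remaining) > 0L) {
    if (runif(1) < params$stop_prob) break
    lag <- remaining - current
    logw <- -abs(lag) / tau + ifelse(lag > 0L, log(params$asymmetry), 0)
    w <- exp(logw - max(logw))
    nxt <- if (length(remaining) == 1L) remaining else
      sample(remaining, 1L, prob = w)
    out <- c(out, nxt)
    current <- nxt
    remaining <- setdiff(remaining, nxt)
  }
  if (params$intrusion_rate > 0 || params$repeat_rate > 0) {
    final <- integer(0)
    for (i in seq_along(out)) {
      final <- c(final, out[i])
      if (runif(1) < params$intrusion_rate) final <- c(final, NA_integer_)
      if (i > 1L && runif(1) < params$repeat_rate) {
        final <- c(final, out[sample.int(i, 1L)])
      }
    }
    out <- final
  }
  out
}

#' Simulate recall of one study list
#'
#' Draws a recall sequence under the contiguity model: the first item comes
#' from the last three positions with probability `recency_start` (else
#' uniformly), each next item is sampled without replacement with weight
#' `exp(-|lag|/tau)` times the forward-asymmetry multiplier, and recall
#' halts on a per-output stop draw or exhaustion.
#'
#' @inheritParams simulate_study_phase
#' @param tau contiguity scale override (defaults to `params$tau`).
#' @param subject_id,list_id identifiers stamped on the rows.
#' @return A matched recall table (see [recall_sequence()]).
#' @export
simulate_recall <- function(params, tau = params$tau, subject_id = "s01",
                            list_id = 1L) {
  recall_sequence(simulate_recall_positions(params, tau = tau),
                  subject_id = subject_id, list_id = list_id)
}

# Place one pair. Returns slots + first_placed + ground-truth draws.
place_pair <- function(p_a, p_b, category, params, place_sd, pair_sd) {
  L <- params$L
  first_a <- runif(1) < 0.5
  p1 <- if (first_a) p_a else p_b
  p2 <- if (first_a) p_b else p_a
  slot1 <- min(L, max(1L, as.integer(round(p1 + rnorm(1, 0, place_sd)))))
  d <- abs(p2 - p1)
  sgn <- sign(p2 - p1)
  adj <- d == 1L
  glued <- category == "cont_enc_ret" && runif(1) < params$glue_prob
  if (glued) {
    dir <- sgn
    m <- 1L
  } else {
    sd_dir <- max(pair_sd - params$shared_context_bonus * adj, 0) *
      d^params$distance_weber_exp
    q <- if (sd_dir == 0) 1 else pnorm(d / sd_dir)
    dir <- if (runif(1) < q) sgn else -sgn
    kappa <- if (adj) 1 else params$distance_compression
    m <- max(1L, as.integer(round(kappa * d + rnorm(1, 0, sd_dir))))
  }
  target <- slot1 + dir * m
  slot2 <- min(L, max(1L, target))
  if (slot2 == slot1) {
    # the drawn side has no room (first item on the boundary slot): shift
    # the first item one slot inward so the remembered direction survives
    slot1 <- slot1 - dir
    slot2 <- slot1 + dir
  }
  list(slot_a = if (first_a) slot1 else slot2,
       slot_b = if (first_a) slot2 else slot1,
       first_placed = if (first_a) "a" else "b",
       glued = glued, dir_correct = dir == sgn, remembered_distance = m)
}

#' Simulate ordering-task placements for selected pairs
#'
#' Places every selected pair of one list on the slot grid under the pair
#' placement model (see the package vignette): first-placed member near its
#' true position, second member at a remembered signed displacement from the
#' first, with glue and shared-context bonus for contiguously encoded pairs.
#'
#' @inheritParams simulate_study_phase
#' @param pairs selected pair rows for one (subject, list) from
#'   [select_pairs()] / [extract_pairs()].
#' @return A list: `ordering` (schema of [load_sessions()]) and `truth`
#'   (per-trial generative draws).
#' @export
simulate_ordering <- function(pairs, params, place_sd = params$placement_noise_sd,
                              pair_sd = params$pair_noise_sd) {
  pairs <- pairs[pairs$selected, , drop = FALSE]
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(ordering = empty_ordering(), truth = NULL))
  }
  trial_order <- sample.int(n)
  pairs <- pairs[trial_order, , drop = FALSE]
  slot_a <- integer(n); slot_b <- integer(n); first_placed <- character(n)
  glued <- logical(n); dir_correct <- logical(n); rem_dist <- integer(n)
  for (t in seq_len(n)) {
    pl <- place_pair(pairs$item_a_serial[t], pairs$item_b_serial[t],
                     pairs$category[t], params, place_sd, pair_sd)
    slot_a[t] <- pl$slot_a; slot_b[t] <- pl$slot_b
    first_placed[t] <- pl$first_placed
    glued[t] <- pl$glued; dir_correct[t] <- pl$dir_correct
    rem_dist[t] <- pl$remembered_distance
  }
  list(ordering = data.frame(subject_id = pairs$subject_id,
                             list_id = pairs$list_id,
                             trial_index = seq_len(n),
                             item_a_serial = pairs$item_a_serial,
                             item_b_serial = pairs$item_b_serial,
                             slot_a = slot_a, slot_b = slot_b,
                             first_placed = first_placed,
                             stringsAsFactors = FALSE),
       truth = data.frame(subject_id = pairs$subject_id,
                          list_id = pairs$list_id,
                          trial_index = seq_len(n),
                          category = pairs$category,
                          glued = glued, dir_correct = dir_correct,
                          remembered_distance = rem_dist,
                          stringsAsFactors = FALSE))
}

#' Simulate a complete multi-subject dataset
#'
#' End-to-end generation: study lists, contiguity-structured recall,
#' item-disjoint pair selection (via [extract_pairs()]), and ordering
#' placements for lists in the order condition. The returned dataset has
#' passed the full [recall_dataset()] validation, and the ground truth is
#' sufficient to audit every generated observation.
#'
#' @param params a [simulation_params()] object.
#' @return An object of class `ordermem_sim`: a list with `dataset` (a
#'   `recall_dataset`), `pairs` (selected pair table), `subject_params`
#'   (per-subject fidelity / contiguity draws), `truth` (per-trial
#'   generative draws) and `params`.
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  subjects <- sprintf("s%03d", seq_len(params$n_subjects))
  phi <- exp(rnorm(params$n_subjects, 0, params$subject_sd))
  subject_params <- data.frame(subject_id = subjects,
                               experiment = params$experiment,
                               fidelity = phi,
                               tau = params$tau / phi,
                               placement_noise_sd = params$placement_noise_sd / phi,
                               pair_noise_sd = params$pair_noise_sd / phi,
                               stringsAsFactors = FALSE)
  study_all <- vector("list", params$n_subjects)
  recall_all <- vector("list", params$n_subjects)
  intr_counter <- 0L
  for (i in seq_len(params$n_subjects)) {
    st <- simulate_study_phase(params, subject_id = subjects[i])
    study_all[[i]] <- st
    items_by_list <- split(st$item[order(st$serial_position)],
                           st$list_id[order(st$serial_position)])
    rec <- vector("list", params$n_lists)
    for (l in seq_len(params$n_lists)) {
      pos <- simulate_recall_positions(params, tau = subject_params$tau[i])
      resp <- character(length(pos))
      for (k in seq_along(pos)) {
        if (is.na(pos[k])) {
          intr_counter <- intr_counter + 1L
          resp[k] <- sprintf("zz_intrusion%04d", intr_counter)
        } else {
          resp[k] <- items_by_list[[l]][pos[k]]
        }
      }
      m <- recall_sequence(pos, subject_id = subjects[i], list_id = l)
      m$response <- resp
      rec[[l]] <- m
    }
    recall_all[[i]] <- do.call(rbind, rec)
  }
  study <- do.call(rbind, study_all)
  recalls <- do.call(rbind, recall_all)
  rownames(recalls) <- NULL

  base <- structure(list(study = validate_study(study), recalls = recalls,
                         ordering = empty_ordering()),
                    class = "recall_dataset")
  pairs <- extract_pairs(base)
  order_keys <- unique(paste(study$subject_id, study$list_id, sep = "\r")[
    study$condition == "order"])
  pkey <- paste(pairs$subject_id, pairs$list_id, sep = "\r")
  pairs$selected[!pkey %in% order_keys] <- FALSE  # no ordering task given

  ord_pieces <- list(); truth_pieces <- list()
  sel <- pairs[pairs$selected, , drop = FALSE]
  if (nrow(sel)) {
    skey <- paste(sel$subject_id, sel$list_id, sep = "\r")
    for (k in sort(unique(skey))) {
      grp <- sel[skey == k, , drop = FALSE]
      i <- match(grp$subject_id[1], subjects)
      res <- simulate_ordering(grp, params,
                               place_sd = subject_params$placement_noise_sd[i],
                               pair_sd = subject_params$pair_noise_sd[i])
      ord_pieces[[k]] <- res$ordering
      truth_pieces[[k]] <- res$truth
    }
  }
  ordering <- if (length(ord_pieces)) do.call(rbind, ord_pieces) else
    empty_ordering()
  rownames(ordering) <- NULL
  dataset <- base
  dataset$ordering <- validate_ordering(ordering, dataset$study)
  structure(list(dataset = dataset, pairs = pairs,
                 subject_params = subject_params,
                 truth = if (length(truth_pieces))
                   do.call(rbind, truth_pieces) else NULL,
                 params = params),
            class = "ordermem_sim")
}

#' @export
print.ordermem_sim <- function(x, ...) {
  cat("<ordermem_sim>\n")
  print(x$params)
  print(x$dataset)
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Emits the three event CSVs in the [load_sessions()] schemas plus
#' `pairs.csv`, `params.json` and `ground_truth.json`.
#'
#' @param sim an `ordermem_sim` from [simulate_dataset()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the manifest data frame (`file`, `rows`).
#' @export
write_dataset <- function(sim, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  }
  raw_recalls <- sim$dataset$recalls[, c("subject_id", "list_id",
                                         "output_position", "response")]
  tabs <- list(study = sim$dataset$study, recalls = raw_recalls,
               ordering = sim$dataset$ordering, pairs = sim$pairs)
  manifest <- data.frame(file = character(0), rows = integer(0))
  for (nm in names(tabs)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tabs[[nm]], path, row.names = FALSE)
    manifest <- rbind(manifest, data.frame(file = path, rows = nrow(tabs[[nm]])))
  }
  par <- sim$params; class(par) <- NULL
  jsonlite::write_json(par[!vapply(par, is.null, logical(1))],
                       file.path(out_dir, "params.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(subject_params = sim$subject_params,
                            trials = sim$truth),
                       file.path(out_dir, "ground_truth.json"),
                       dataframe = "rows")
  invisible(manifest)
}
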