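# Group-level contrasts, splits and correlations over scored pairs and
# subject summaries.
#
# The within-subject machinery is the classical multivariate formulation of
# the repeated-measures ANOVA (type III, car::Anova on an mlm fit), with
# Mauchly's sphericity test and the Greenhouse-Geisser correction applied on
# violation when a factor has 3+ levels. Between-subject covariates are
# mean-centered so the within-subject effects are evaluated at the covariate
# mean.

#' Per-subject mean score per pair category
#'
#' @param scores scored pair table from [score_pairs()].
#' @param measure score column to average (e.g. `"relative_score"`).
#' @param categories categories to tabulate; defaults to the three analysis
#'   categories (first-three pairs are excluded from main analyses).
#' @param selected_only use only selected pairs (default `TRUE`).
#' @return A long data frame `subject_id`, `category`, `mean`, `n_pairs`
#'   (missing cells absent). Group means/SEMs are available via
#'   [category_group_stats()].
#' @export
subject_category_means <- function(scores, measure = "relative_score",
                                   categories = ANALYSIS_CATEGORIES,
                                   selected_only = TRUE) {
  if (!measure %in% names(scores)) {
    stop(sprintf("unknown measure: %s", measure), call. = FALSE)
  }
  if (selected_only && "selected" %in% names(scores)) {
    scores <- scores[scores$selected, , drop = FALSE]
  }
  scores <- scores[scores$category %in% categories, , drop = FALSE]
  if (nrow(scores) == 0L) {
    return(data.frame(subject_id = character(0), category = character(0),
                      mean = numeric(0), n_pairs = integer(0),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate(scores[[measure]],
                   by = list(subject_id = scores$subject_id,
                             category = scores$category),
                   FUN = mean)
  cnt <- aggregate(scores[[measure]],
                   by = list(subject_id = scores$subject_id,
                             category = scores$category),
                   FUN = length)
  out <- data.frame(subject_id = agg$subject_id, category = agg$category,
                    mean = agg$x, n_pairs = as.integer(cnt$x),
                    stringsAsFactors = FALSE)
  out[order(out$subject_id, match(out$category, categories)), , drop = FALSE]
}

#' Group mean and SEM per category
#'
#' @param long output of [subject_category_means()].
#' @return A data frame `category`, `mean`, `sem` (sd / sqrt(n)), `n_subjects`.
#' @export
category_group_stats <- function(long) {
  split_means <- split(long$mean, long$category)
  data.frame(category = names(split_means),
             mean = vapply(split_means, mean, numeric(1)),
             sem = vapply(split_means, function(v) sd(v) / sqrt(length(v)),
                          numeric(1)),
             n_subjects = vapply(split_means, length, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# long -> wide (subject_id + one column per category, NA for missing cells)
pivot_wide <- function(long, levels) {
  subjects <- unique(long$subject_id)
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (lv in levels) {
    v <- long$mean[long$category == lv]
    names(v) <- long$subject_id[long$category == lv]
    out[[lv]] <- unname(v[subjects])
  }
  out
}

#' Apply a minimum-observation inclusion filter
#'
#' Subjects must have at least `threshold` observations in every required
#' category; the main contrasts use 5, the split sub-analyses 3 per bin.
#'
#' @param counts wide count table from [count_pairs_per_category()].
#' @param threshold minimum count per category.
#' @param categories columns of `counts` that must pass; defaults to all
#'   count columns.
#' @return A list with `retained` (subject ids), `excluded` (data frame of
#'   subject, failing category, count — the filter log).
#' @export
apply_inclusion_filter <- function(counts, threshold = 5L, categories = NULL) {
  if (is.null(categories)) categories <- setdiff(names(counts), "subject_id")
  log <- data.frame(subject_id = character(0), category = character(0),
                    count = integer(0), stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(counts))
  for (cat in categories) {
    fail <- counts[[cat]] < threshold
    if (any(fail)) {
      log <- rbind(log, data.frame(subject_id = counts$subject_id[fail],
                                   category = cat,
                                   count = counts[[cat]][fail],
                                   stringsAsFactors = FALSE))
      keep <- keep & !fail
    }
  }
  list(retained = counts$subject_id[keep], excluded = log)
}

# Core within-subject ANOVA on an mlm fit. Y: n x m response matrix whose
# columns follow idata row order; idesign e.g. ~category or
# ~category * direction; covariates: data frame of numeric covariates
# (mean-centered here). Returns one row per within-subject effect.
rm_anova_mlm <- function(Y, idata, idesign, covariates = NULL,
                         sphericity = c("auto", "none")) {
  sphericity <- match.arg(sphericity)
  n <- nrow(Y)
  dat <- data.frame(row.names = seq_len(n))
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (sd(v) == 0) next  # constant covariate carries no information
      dat[[nm]] <- v - mean(v)
    }
  }
  form <- if (ncol(dat)) as.formula(paste("Y ~", paste(names(dat), collapse = "+")))
          else Y ~ 1
  mod <- lm(form, data = cbind(dat, list(Y = Y)))
  av <- tryCatch(
    car::Anova(mod, idata = idata, idesign = idesign, type = 3),
    error = function(e) stop(sprintf("degenerate-model error: %s",
                                     conditionMessage(e)), call. = FALSE))
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  within_terms <- attr(stats::terms(idesign), "term.labels")
  effect_rows <- rownames(ut)[rownames(ut) %in% within_terms]
  res <- lapply(effect_rows, function(rn) {
    ss <- ut[rn, "Sum Sq"]; ess <- ut[rn, "Error SS"]
    f <- ut[rn, "F value"]; p <- ut[rn, "Pr(>F)"]
    df1 <- ut[rn, "num Df"]; df2 <- ut[rn, "den Df"]
    if (!is.finite(f) || (ss < 1e-12 && ess < 1e-12)) { f <- 0; p <- 1 }
    correction <- "none"; eps <- NA_real_
    mau_w <- NA_real_; mau_p <- NA_real_
    st <- s$sphericity.tests
    if (!is.null(st) && rn %in% rownames(st)) {
      mau_w <- st[rn, "Test statistic"]; mau_p <- st[rn, "p-value"]
      pa <- s$pval.adjustments
      if (sphericity == "auto" && is.finite(mau_p) && mau_p < 0.05 &&
          !is.null(pa) && rn %in% rownames(pa)) {
        eps <- pa[rn, "GG eps"]
        p <- pa[rn, "Pr(>F[GG])"]
        df1 <- df1 * eps; df2 <- df2 * eps
        correction <- "greenhouse_geisser"
      }
    }
    data.frame(effect = rn, F = f, df1 = df1, df2 = df2, p = p,
               pes = if (ss + ess > 0) ss / (ss + ess) else 0,
               correction = correction, gg_eps = eps,
               mauchly_W = mau_w, mauchly_p = mau_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n") <- n
  attr(out, "covariates") <- names(dat)
  out
}

# Bonferroni-corrected pairwise paired t-tests with Cohen's d (dz).
posthoc_pairwise <- function(wide, levels) {
  combos <- utils::combn(levels, 2L)
  res <- lapply(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    d <- wide[[a]] - wide[[b]]
    d <- d[!is.na(d)]
    if (sd(d) == 0) {
      tt <- list(statistic = 0, parameter = length(d) - 1L, p.value = 1)
      dz <- 0
    } else {
      tt <- t.test(d)
      dz <- mean(d) / sd(d)
    }
    data.frame(level_a = a, level_b = b,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohens_d = dz, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out
}

#' One-way repeated-measures contrast across pair categories
#'
#' Within-subject F test of a score across categories, with optional
#' between-subject covariates (mean-centered; zero-variance covariates are
#' dropped). With 3+ levels Mauchly's test is checked and the
#' Greenhouse-Geisser correction applied on violation. Bonferroni-corrected
#' pairwise paired t-tests with Cohen's d (paired standardizer) are attached
#' as post hocs. Subjects with a missing cell or missing covariate are
#' dropped listwise and logged.
#'
#' @param wide data frame with `subject_id` and one column of per-subject
#'   means per category (see [subject_category_means()] / [pivot_wide()]).
#' @param categories the category columns, in within-factor order.
#' @param covariates optional data frame with `subject_id` and numeric
#'   covariate columns.
#' @param sphericity `"auto"` (Greenhouse-Geisser on Mauchly violation) or
#'   `"none"`.
#' @param posthoc attach pairwise post hocs (default `TRUE`).
#' @return An object of class `rm_contrast`: the effect row (F, dfs, p,
#'   partial eta squared, correction applied), group means/SEMs, post hocs,
#'   retained n and the dropped-subject log.
#' @export
rm_contrast <- function(wide, categories = setdiff(names(wide), "subject_id"),
                        covariates = NULL, sphericity = "auto",
                        posthoc = TRUE) {
  if (length(categories) < 2L) {
    stop("rm_contrast needs at least 2 categories", call. = FALSE)
  }
  dat <- wide[, c("subject_id", categories), drop = FALSE]
  cov_cols <- character(0)
  if (!is.null(covariates)) {
    dat <- merge(dat, covariates, by = "subject_id", all.x = TRUE)
    cov_cols <- setdiff(names(covariates), "subject_id")
  }
  complete <- complete.cases(dat[, c(categories, cov_cols), drop = FALSE])
  dropped <- dat$subject_id[!complete]
  dat <- dat[complete, , drop = FALSE]
  if (nrow(dat) < 3L) {
    stop("rm_contrast: fewer than 3 complete subjects", call. = FALSE)
  }
  Y <- as.matrix(dat[, categories, drop = FALSE])
  idata <- data.frame(category = factor(categories, levels = categories))
  tab <- rm_anova_mlm(Y, idata, ~category,
                      covariates = if (length(cov_cols))
                        dat[, cov_cols, drop = FALSE] else NULL,
                      sphericity = sphericity)
  means <- colMeans(Y)
  sems <- apply(Y, 2, sd) / sqrt(nrow(Y))
  structure(list(effects = tab,
                 n = nrow(dat),
                 categories = categories,
                 means = means, sems = sems,
                 covariates = attr(tab, "covariates"),
                 posthoc = if (posthoc) posthoc_pairwise(dat, categories) else NULL,
                 dropped = dropped),
            class = "rm_contrast")
}

#' @export
print.rm_contrast <- function(x, ...) {
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("%s: F(%.3g, %.3g) = %.3f, p = %.4g, pes = %.3f%s\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i], e$pes[i],
                ifelse(e$correction[i] == "none", "",
                       paste0(" [", e$correction[i], "]"))))
  }
  cat(sprintf("n = %d; category means: %s\n", x$n,
              paste(sprintf("%s = %.3f", x$categories, x$means),
                    collapse = ", ")))
  if (!is.null(x$posthoc)) {
    cat("post hoc (Bonferroni):\n")
    print(x$posthoc, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

# Per-subject tercile boundaries on sorted values; ties go to the lower bin.
tercile_bins <- function(v) {
  s <- sort(v)
  n <- length(s)
  cut1 <- s[ceiling(n / 3)]
  cut2 <- s[ceiling(2 * n / 3)]
  ifelse(v <= cut1, "short", ifelse(v <= cut2, "medium", "long"))
}

#' Split analyses: lag terciles, distance-score median split, direction
#'
#' Three sub-analyses over selected pairs:
#' * `"encoding_lag_terciles"`: cont-ret pairs split per subject into
#'   |lag| terciles (boundary ties to the lower bin), contrasting the score
#'   across short/medium/long lags.
#' * `"distance_score_median"`: all analysis-category pairs split per
#'   subject at the median distance score (pairs equal to the median go to
#'   the "small" bin), contrasting small vs large perceived distance.
#' * `"direction"`: a two-way within-subject design, pair category
#'   (cont-enc-ret / cont-ret) by transition direction (forward / backward).
#'
#' Subjects need `min_pairs_per_bin` pairs in every bin/cell.
#'
#' @param scores scored pair table from [score_pairs()].
#' @param variable which split to run.
#' @param min_pairs_per_bin minimum pairs per bin for a subject to enter.
#' @param measure score column contrasted (default relative score).
#' @param covariates optional between-subject covariates (e.g. an
#'   experiment indicator for pooled samples).
#' @return A list: `bins` (per-subject bin means), `contrast`
#'   (`rm_contrast`), `retained`, `excluded` (filter log).
#' @export
split_analysis <- function(scores,
                           variable = c("encoding_lag_terciles",
                                        "distance_score_median",
                                        "direction"),
                           min_pairs_per_bin = 3L,
                           measure = "relative_score",
                           covariates = NULL) {
  variable <- match.arg(variable)
  if (min_pairs_per_bin < 1L) stop("min_pairs_per_bin must be >= 1", call. = FALSE)
  sel <- scores[scores$selected, , drop = FALSE]

  if (variable == "encoding_lag_terciles") {
    sub <- sel[sel$category == "cont_ret" & !is.na(sel$encoding_lag), ,
               drop = FALSE]
    sub <- do.call(rbind, lapply(split(sub, sub$subject_id), function(d) {
      d$bin <- tercile_bins(abs(d$encoding_lag))
      d
    }))
    levels <- c("short", "medium", "long")
  } else if (variable == "distance_score_median") {
    sub <- sel[sel$category %in% ANALYSIS_CATEGORIES, , drop = FALSE]
    sub <- do.call(rbind, lapply(split(sub, sub$subject_id), function(d) {
      d$bin <- ifelse(d$distance_score <= median(d$distance_score),
                      "small", "large")
      d
    }))
    levels <- c("small", "large")
  } else {
    sub <- sel[sel$category %in% c("cont_enc_ret", "cont_ret") &
                 sel$direction %in% c("forward", "backward"), , drop = FALSE]
    sub$bin <- paste(sub$category, sub$direction, sep = ".")
    levels <- c("cont_enc_ret.forward", "cont_enc_ret.backward",
                "cont_ret.forward", "cont_ret.backward")
  }
  if (is.null(sub) || nrow(sub) == 0L) {
    stop("split_analysis: no eligible pairs", call. = FALSE)
  }

  agg <- aggregate(sub[[measure]],
                   by = list(subject_id = sub$subject_id, category = sub$bin),
                   FUN = mean)
  cnt <- aggregate(sub[[measure]],
                   by = list(subject_id = sub$subject_id, category = sub$bin),
                   FUN = length)
  long <- data.frame(subject_id = agg$subject_id, category = agg$category,
                     mean = agg$x, n_pairs = as.integer(cnt$x),
                     stringsAsFactors = FALSE)
  counts <- pivot_wide(transform(long, mean = n_pairs), levels)
  for (lv in levels) counts[[lv]][is.na(counts[[lv]])] <- 0L
  filt <- apply_inclusion_filter(counts, min_pairs_per_bin, levels)
  wide <- pivot_wide(long, levels)
  wide <- wide[wide$subject_id %in% filt$retained, , drop = FALSE]
  if (nrow(wide) < 3L) {
    stop("split_analysis: fewer than 3 subjects pass the bin filter",
         call. = FALSE)
  }

  if (variable == "direction") {
    dat <- wide
    cov_cols <- character(0)
    if (!is.null(covariates)) {
      dat <- merge(dat, covariates, by = "subject_id")
      cov_cols <- setdiff(names(covariates), "subject_id")
    }
    dat <- dat[complete.cases(dat), , drop = FALSE]
    Y <- as.matrix(dat[, levels, drop = FALSE])
    idata <- data.frame(category = factor(c("cont_enc_ret", "cont_enc_ret",
                                            "cont_ret", "cont_ret")),
                        direction = factor(c("forward", "backward",
                                             "forward", "backward")))
    tab <- rm_anova_mlm(Y, idata, ~category * direction,
                        covariates = if (length(cov_cols))
                          dat[, cov_cols, drop = FALSE] else NULL)
    contrast <- structure(list(effects = tab, n = nrow(dat),
                               categories = levels,
                               means = colMeans(Y),
                               sems = apply(Y, 2, sd) / sqrt(nrow(Y)),
                               covariates = attr(tab, "covariates"),
                               posthoc = NULL, dropped = character(0)),
                          class = "rm_contrast")
  } else {
    contrast <- rm_contrast(wide, levels, covariates = covariates)
  }
  list(variable = variable, bins = long, contrast = contrast,
       retained = filt$retained, excluded = filt$excluded)
}

#' First-order partial correlation
#'
#' Pearson correlation of `x` and `y` after removing the linear effect of a
#' single control variable `z`, with a t-based p value on `n - 3` degrees of
#' freedom.
#'
#' @param x,y,z numeric vectors of equal length (complete cases used).
#' @return A list: `r`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, z) {
  ok <- complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4L) stop("insufficient sample for partial correlation (n < 4)",
                   call. = FALSE)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  tt <- r * sqrt((n - 3) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 3), n = n)
}

#' Correlations between temporal clustering and order memory
#'
#' Across-subject Pearson correlations of the temporal score with relative
#' score, absolute score and absolute deviation, plus the two first-order
#' partial correlations that dissociate relative from absolute order:
#' temporal-relative controlling for absolute, and temporal-absolute
#' controlling for relative.
#'
#' @param summaries data frame with one row per subject and columns
#'   `temporal_score`, `relative_score`, `absolute_score`,
#'   `absolute_deviation` (order scores collapsed across categories).
#' @return A data frame `x`, `y`, `control` (`""` for zero-order), `r`,
#'   `p`, `n`.
#' @export
correlation_suite <- function(summaries) {
  need <- c("temporal_score", "relative_score", "absolute_score",
            "absolute_deviation")
  missing <- setdiff(need, names(summaries))
  if (length(missing)) {
    stop(sprintf("correlation_suite: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  s <- summaries[complete.cases(summaries[need]), need, drop = FALSE]
  if (nrow(s) < 4L) {
    stop("insufficient sample for correlations (n < 4)", call. = FALSE)
  }
  zero_order <- function(ycol) {
    ct <- cor.test(s$temporal_score, s[[ycol]])
    data.frame(x = "temporal_score", y = ycol, control = "",
               r = unname(ct$estimate), p = ct$p.value, n = nrow(s),
               stringsAsFactors = FALSE)
  }
  pc <- function(ycol, zcol) {
    res <- partial_correlation(s$temporal_score, s[[ycol]], s[[zcol]])
    data.frame(x = "temporal_score", y = ycol, control = zcol,
               r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
  }
  rbind(zero_order("relative_score"),
        zero_order("absolute_score"),
        zero_order("absolute_deviation"),
        pc("relative_score", "absolute_score"),
        pc("absolute_score", "relative_score"))
}

#' Proportion of perfect pairs per category
#'
#' A pair is perfect when it has both a perfect relative score and a
#' distance score of zero — the pair "sticks together" in the correct
#' order. Compares per-subject proportions between two categories with a
#' paired t-test (zero-variance differences are reported as no difference).
#'
#' @param scores scored pair table from [score_pairs()].
#' @param categories the two categories to compare.
#' @param min_pairs minimum pairs per category for a subject to enter.
#' @return A list: `proportions` (per subject per category), `t`, `df`,
#'   `p`, `cohens_d`, `means`, `sems`, `n`.
#' @export
perfect_pair_proportion <- function(scores,
                                    categories = c("cont_enc_ret", "cont_enc"),
                                    min_pairs = 1L) {
  if (length(categories) != 2L) stop("exactly two categories required",
                                     call. = FALSE)
  sel <- scores[scores$selected & scores$category %in% categories, ,
                drop = FALSE]
  agg <- aggregate(sel$perfect_pair,
                   by = list(subject_id = sel$subject_id,
                             category = sel$category),
                   FUN = mean)
  cnt <- aggregate(sel$perfect_pair,
                   by = list(subject_id = sel$subject_id,
                             category = sel$category),
                   FUN = length)
  long <- data.frame(subject_id = agg$subject_id, category = agg$category,
                     mean = agg$x, n_pairs = as.integer(cnt$x),
                     stringsAsFactors = FALSE)
  counts <- pivot_wide(transform(long, mean = n_pairs), categories)
  for (cv in categories) counts[[cv]][is.na(counts[[cv]])] <- 0L
  keep <- apply_inclusion_filter(counts, min_pairs, categories)$retained
  wide <- pivot_wide(long, categories)
  wide <- wide[wide$subject_id %in% keep & complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 3L) {
    stop("perfect_pair_proportion: fewer than 3 eligible subjects",
         call. = FALSE)
  }
  d <- wide[[categories[1]]] - wide[[categories[2]]]
  if (sd(d) == 0) {
    t <- 0; df <- length(d) - 1L; p <- 1; dz <- 0
  } else {
    tt <- t.test(d)
    t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    dz <- mean(d) / sd(d)
  }
  list(proportions = wide, t = t, df = df, p = p, cohens_d = dz,
       means = colMeans(wide[categories]),
       sems = apply(wide[categories], 2, sd) / sqrt(nrow(wide)),
       n = nrow(wide))
}
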