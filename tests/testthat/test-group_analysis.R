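# Repeated-measures contrasts, splits, correlations, perfect pairs.

test_that("per-subject category means and group SEM follow the closed forms", {
  scores <- data.frame(subject_id = rep(c("s1", "s2"), each = 5),
                       category = "cont_enc_ret",
                       relative_score = c(1, 1, 0, 1, 1, 1, 0, 0, 1, 0),
                       selected = TRUE)
  long <- subject_category_means(scores, "relative_score")
  expect_equal(long$mean, c(0.8, 0.4))
  gs <- category_group_stats(long)
  expect_equal(gs$mean, 0.6)
  expect_equal(gs$sem, sd(c(0.8, 0.4)) / sqrt(2))
})

test_that("the inclusion filter retains and excludes by per-category counts", {
  counts <- data.frame(subject_id = c("s1", "s2", "s3"),
                       cont_enc_ret = c(5L, 5L, 7L),
                       cont_ret = c(5L, 4L, 9L))
  f <- apply_inclusion_filter(counts, 5L)
  expect_setequal(f$retained, c("s1", "s3"))
  expect_equal(f$excluded$subject_id, "s2")
  f3 <- apply_inclusion_filter(counts, 3L)
  expect_setequal(f3$retained, c("s1", "s2", "s3"))
  expect_error(apply_inclusion_filter(counts, 5L)$retained == character(0), NA)
})

test_that("rm_contrast agrees with aov and the paired-t identity", {
  set.seed(21)
  n <- 14
  wide <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     a = rnorm(n, 0.8, 0.1), b = rnorm(n, 0.7, 0.1),
                     c = rnorm(n, 0.65, 0.12))
  rc <- rm_contrast(wide, c("a", "b", "c"), sphericity = "none",
                    posthoc = FALSE)
  long <- data.frame(y = c(wide$a, wide$b, wide$c),
                     cat = factor(rep(c("a", "b", "c"), each = n)),
                     subj = factor(rep(wide$subject_id, 3)))
  ref <- summary(aov(y ~ cat + Error(subj / cat), data = long))
  ref_tab <- ref[["Error: subj:cat"]][[1]]
  expect_equal(rc$effects$F, ref_tab["cat", "F value"], tolerance = 1e-8)
  expect_equal(rc$effects$p, ref_tab["cat", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(rc$effects$pes,
               ref_tab["cat", "Sum Sq"] /
                 (ref_tab["cat", "Sum Sq"] + ref_tab["Residuals", "Sum Sq"]),
               tolerance = 1e-8)

  # two levels: F is the squared paired t, with or without constant covariates
  rc2 <- rm_contrast(wide, c("a", "b"))
  tt <- t.test(wide$a, wide$b, paired = TRUE)
  expect_equal(rc2$effects$F, unname(tt$statistic)^2, tolerance = 1e-10)
  rc2z <- rm_contrast(wide, c("a", "b"),
                      covariates = data.frame(subject_id = wide$subject_id,
                                              z = 0))
  expect_equal(rc2z$effects$F, rc2$effects$F, tolerance = 1e-10)

  # identical columns: no effect, p = 1
  wide$b2 <- wide$a
  rc0 <- rm_contrast(wide[c("subject_id", "a", "b2")], c("a", "b2"))
  expect_equal(rc0$effects$F, 0)
  expect_equal(rc0$effects$p, 1)
})

test_that("two-way within design agrees with aov on all three effects", {
  set.seed(22)
  n <- 12
  cells <- c("cont_enc_ret.forward", "cont_enc_ret.backward",
             "cont_ret.forward", "cont_ret.backward")
  scores <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(subject_id = sprintf("s%02d", i),
               category = rep(c("cont_enc_ret", "cont_ret"), each = 10),
               direction = rep(rep(c("forward", "backward"), each = 5), 2),
               relative_score = rbinom(20, 1, 0.7),
               distance_score = 0L, encoding_lag = 3L, selected = TRUE)
  }))
  res <- split_analysis(scores, "direction", min_pairs_per_bin = 1L)
  wide <- ordermem:::pivot_wide(res$bins, cells)
  long <- do.call(rbind, lapply(cells, function(cc) {
    parts <- strsplit(cc, ".", fixed = TRUE)[[1]]
    data.frame(y = wide[[cc]], subj = wide$subject_id,
               cat = parts[1], dir = parts[2])
  }))
  ref <- summary(aov(y ~ cat * dir + Error(factor(subj) / (cat * dir)),
                     data = long))
  eff <- res$contrast$effects
  expect_equal(eff$F[eff$effect == "category"],
               ref[["Error: factor(subj):cat"]][[1]]["cat", "F value"],
               tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "direction"],
               ref[["Error: factor(subj):dir"]][[1]]["dir", "F value"],
               tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "category:direction"],
               ref[["Error: factor(subj):cat:dir"]][[1]]["cat:dir", "F value"],
               tolerance = 1e-8)
})

test_that("post hoc Bonferroni p values are never below the uncorrected ones", {
  set.seed(23)
  wide <- data.frame(subject_id = sprintf("s%02d", 1:12),
                     a = rnorm(12, .8, .1), b = rnorm(12, .7, .1),
                     c = rnorm(12, .6, .1))
  rc <- rm_contrast(wide, c("a", "b", "c"))
  expect_true(all(rc$posthoc$p_bonf >= rc$posthoc$p))
  expect_true(all(rc$posthoc$p_bonf <= 1))
})

test_that("lag terciles and the distance median split partition each subject's pairs", {
  lags <- c(2, 3, 4, 7, 8, 9, 12, 14, 15)
  scores <- data.frame(subject_id = "s1", category = "cont_ret",
                       encoding_lag = lags, relative_score = 1,
                       distance_score = 0L, selected = TRUE)
  expect_equal(ordermem:::tercile_bins(abs(lags)),
               rep(c("short", "medium", "long"), each = 3))

  ds <- c(-3, -1, 0, 2)
  scores2 <- data.frame(subject_id = "s1", category = "cont_ret",
                        encoding_lag = 5L, relative_score = 1,
                        distance_score = ds, selected = TRUE)
  med <- median(ds)
  bins <- ifelse(ds <= med, "small", "large")
  expect_equal(bins, c("small", "small", "large", "large"))

  # partition property on simulated data: every pair in exactly one bin
  sim <- sim_fixture(n_subjects = 4, n_lists = 10, n_order_lists = 10)
  sc <- score_pairs(sim$dataset, sim$pairs)
  cret <- sc[sc$selected & sc$category == "cont_ret", ]
  for (sid in unique(cret$subject_id)) {
    v <- abs(cret$encoding_lag[cret$subject_id == sid])
    b <- ordermem:::tercile_bins(v)
    expect_equal(length(b), length(v))
    expect_true(all(b %in% c("short", "medium", "long")))
    if (length(unique(v)) >= 3) {
      expect_true(max(v[b == "short"]) < min(v[b == "long"]))
    }
  }
})

test_that("tercile split recovers a planted lag effect on synthetic data", {
  # pair noise growing faster than studied distance: long-lag pairs are
  # less accurate, the short tercile should come out on top
  sim <- simulate_dataset(simulation_params(
    n_subjects = 30, n_lists = 20, n_order_lists = 20, tau = 3,
    pair_noise_sd = 0.9, shared_context_bonus = 0.3,
    distance_weber_exp = 2.2, glue_prob = 0, subject_sd = 0.1, seed = 303))
  sc <- score_pairs(sim$dataset, sim$pairs)
  res <- split_analysis(sc, "encoding_lag_terciles", min_pairs_per_bin = 3L)
  m <- res$contrast$means
  expect_gt(m[["short"]], m[["long"]])
  expect_gt(m[["short"]], m[["medium"]])
})

test_that("partial correlation matches the residual-based oracle", {
  set.seed(25)
  n <- 40
  z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- -0.3 * z + rnorm(n)
  pc <- partial_correlation(x, y, z)
  r_oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
  expect_equal(pc$r, r_oracle, tolerance = 1e-12)
  # z independent of (x, y): partial equals zero-order
  z2 <- rnorm(n)
  pc2 <- partial_correlation(x, y, z2)
  expect_equal(pc2$r, cor(resid(lm(x ~ z2)), resid(lm(y ~ z2))),
               tolerance = 1e-12)
  expect_error(partial_correlation(1:3, 1:3, 1:3), "insufficient")
})

test_that("correlation_suite reports zero-order and partial rows", {
  set.seed(26)
  n <- 30
  temporal <- rnorm(n, 0.7, 0.1)
  df <- data.frame(subject_id = sprintf("s%02d", 1:n),
                   temporal_score = temporal,
                   relative_score = 0.5 + 0.8 * temporal + rnorm(n, 0, 0.05),
                   absolute_score = rnorm(n, 0.85, 0.05))
  df$absolute_deviation <- (1 - df$absolute_score) * 8
  tab <- correlation_suite(df)
  expect_equal(nrow(tab), 5L)
  r_rel <- tab$r[tab$y == "relative_score" & tab$control == ""]
  expect_equal(r_rel, unname(cor(df$temporal_score, df$relative_score)),
               tolerance = 1e-12)
  expect_error(correlation_suite(df[1:3, ]), "insufficient")
})

test_that("a temporal-driven relative score shows the dissociation in partials", {
  set.seed(27)
  hits <- replicate(30, {
    n <- 50
    temporal <- rnorm(n)
    rel <- 0.6 * temporal + rnorm(n, 0, 0.6)
    abso <- rnorm(n)
    df <- data.frame(subject_id = seq_len(n), temporal_score = temporal,
                     relative_score = rel, absolute_score = abso,
                     absolute_deviation = -abso)
    tab <- correlation_suite(df)
    c(rel_part = tab$p[tab$y == "relative_score" & tab$control != ""] < 0.05,
      abs_part = tab$p[tab$y == "absolute_score" & tab$control != ""] < 0.05)
  })
  expect_gt(mean(hits["rel_part", ]), mean(hits["abs_part", ]))
  expect_gt(mean(hits["rel_part", ]), 0.8)
})

test_that("perfect-pair proportions and their paired comparison behave", {
  scores <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 20),
    category = rep(rep(c("cont_enc_ret", "cont_enc"), each = 10), 3),
    perfect_pair = c(rep(c(TRUE, FALSE), c(7, 3)), rep(TRUE, 10),
                     rep(c(TRUE, FALSE), c(5, 5)), rep(TRUE, 10),
                     rep(c(TRUE, FALSE), c(9, 1)), rep(TRUE, 10)),
    selected = TRUE)
  res <- perfect_pair_proportion(scores)
  expect_equal(sort(res$proportions$cont_enc_ret), c(0.5, 0.7, 0.9))
  expect_equal(res$n, 3L)
  # all-perfect in both categories: reported as no difference
  allp <- scores; allp$perfect_pair <- TRUE
  res0 <- perfect_pair_proportion(allp)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
})

test_that("a planted category effect is detected with high power", {
  rejected <- vapply(1:10, function(i) {
    sim <- simulate_dataset(simulation_params(
      n_subjects = 16, n_lists = 16, n_order_lists = 16, seed = 500 + i))
    sc <- score_pairs(sim$dataset, sim$pairs)
    cats <- c("cont_enc_ret", "cont_ret", "cont_enc")
    keep <- apply_inclusion_filter(count_pairs_per_category(sc, cats), 5L,
                                   cats)$retained
    s <- sc[sc$subject_id %in% keep, ]
    rc <- rm_contrast(ordermem:::pivot_wide(
      subject_category_means(s, "relative_score", cats), cats), cats,
      posthoc = FALSE)
    rc$effects$p[1] < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.8)
})
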