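# End-to-end analysis over a dataset: the seven planned contrasts plus the
# two control analyses, with inclusion filters and a machine-readable
# report.

contrast_entry <- function(x) {
  if (is.null(x)) return(NULL)
  list(effects = x$effects, n = x$n,
       means = as.list(x$means), sems = as.list(x$sems),
       covariates = x$covariates,
       posthoc = x$posthoc,
       dropped = x$dropped)
}

#' Run the full group analysis over a scored dataset
#'
#' Executes, over the selected and scored pairs of a dataset:
#'
#' 1. Relative-order contrast across pair categories (with the
#'    condition-difference covariates when both conditions are present).
#' 2. Relative order across encoding-lag terciles within cont-ret pairs.
#' 3. Relative order across a per-subject distance-score median split.
#' 4. Absolute-order contrast across categories (score and deviation).
#' 5. Correlations of the temporal score with relative and absolute order,
#'    plus the dissociating partial correlations.
#' 6. Cont-enc-ret vs cont-enc post hoc on relative order.
#' 7. Distance-score comparison and perfect-pair proportions for
#'    cont-enc-ret vs cont-enc.
#'
#' Controls: (1A) the two-way category-by-direction design probing a testing
#' effect; (1B) the covariate-adjusted category contrast.
#'
#' @param dataset a `recall_dataset` with ordering data.
#' @param min_pairs minimum selected pairs per category for the main
#'   contrasts (inclusion filter).
#' @param split_min minimum pairs per bin/cell for the split analyses.
#' @param merge_first_three fold first-three pairs into their lag-defined
#'   categories instead of excluding them.
#' @param experiment optional data frame `subject_id`, `experiment` used as
#'   a between-subject covariate in the pooled split analyses.
#' @param seed forwarded to pair selection (which is deterministic).
#' @return An object of class `ordermem_report`: a list of analysis entries
#'   plus `scores`, `summaries`, `counts` and the filter log.
#' @export
analyze_dataset <- function(dataset, min_pairs = 5L, split_min = 3L,
                            merge_first_three = FALSE, experiment = NULL,
                            seed = NULL) {
  if (min_pairs < 1L || split_min < 1L) {
    stop("thresholds must be >= 1", call. = FALSE)
  }
  pairs <- extract_pairs(dataset, merge_first_three = merge_first_three,
                         seed = seed)
  scores <- score_pairs(dataset, pairs)
  summaries <- subject_summary(dataset)
  covs <- condition_covariates(summaries)

  cats <- intersect(ANALYSIS_CATEGORIES, unique(scores$category))
  counts <- count_pairs_per_category(scores, categories = cats)
  filt <- apply_inclusion_filter(counts, min_pairs, cats)
  if (length(filt$retained) == 0L) {
    stop(sprintf(paste0("no subject passes the inclusion filter ",
                        "(>= %d pairs in each of: %s)"),
                 min_pairs, paste(cats, collapse = ", ")), call. = FALSE)
  }
  keep_scores <- scores[scores$subject_id %in% filt$retained, , drop = FALSE]

  have_covs <- all(c("order", "no_order") %in% summaries$condition) &&
    sum(complete.cases(covs[c("diff_recall", "diff_temporal")])) >= 3L
  cov_df <- if (have_covs) covs else NULL

  exp_cov <- NULL
  if (!is.null(experiment) && length(unique(experiment$experiment)) > 1L) {
    exp_cov <- data.frame(subject_id = experiment$subject_id,
                          experiment = as.numeric(as.factor(experiment$experiment)),
                          stringsAsFactors = FALSE)
  }

  run <- function(expr) tryCatch(expr, error = function(e)
    list(skipped = conditionMessage(e)))

  wide_of <- function(measure) {
    pivot_wide(subject_category_means(keep_scores, measure, cats), cats)
  }

  rel_wide <- wide_of("relative_score")
  relative_contrast <- run(rm_contrast(rel_wide, cats, covariates = cov_df))
  lag_terciles <- run(split_analysis(keep_scores, "encoding_lag_terciles",
                                     min_pairs_per_bin = split_min,
                                     covariates = exp_cov))
  distance_split <- run(split_analysis(keep_scores, "distance_score_median",
                                       min_pairs_per_bin = split_min,
                                       covariates = exp_cov))
  absolute_contrast <- run(rm_contrast(wide_of("absolute_score"), cats,
                                       covariates = cov_df))
  deviation_contrast <- run(rm_contrast(wide_of("absolute_deviation"), cats,
                                        covariates = cov_df))

  corr <- run({
    overall <- summaries[summaries$condition == "all", , drop = FALSE]
    pooled <- keep_scores[keep_scores$category %in% cats, , drop = FALSE]
    pool_mean <- function(col) {
      v <- tapply(pooled[[col]], pooled$subject_id, mean)
      data.frame(subject_id = names(v), x = as.numeric(v),
                 stringsAsFactors = FALSE)
    }
    tab <- Reduce(function(a, b) merge(a, b, by = "subject_id"),
                  list(setNames(pool_mean("relative_score"),
                                c("subject_id", "relative_score")),
                       setNames(pool_mean("absolute_score"),
                                c("subject_id", "absolute_score")),
                       setNames(pool_mean("absolute_deviation"),
                                c("subject_id", "absolute_deviation")),
                       overall[c("subject_id", "temporal_score")]))
    correlation_suite(tab)
  })

  enc_vs_ret <- NULL
  distance_cmp <- NULL
  perfect <- NULL
  if (all(c("cont_enc_ret", "cont_enc") %in% cats)) {
    enc_vs_ret <- run({
      ph <- posthoc_pairwise(rel_wide[complete.cases(rel_wide), ],
                             c("cont_enc_ret", "cont_enc"))
      ph
    })
    distance_cmp <- run({
      dw <- pivot_wide(subject_category_means(keep_scores, "distance_score",
                                              c("cont_enc_ret", "cont_enc")),
                       c("cont_enc_ret", "cont_enc"))
      dw <- dw[complete.cases(dw), , drop = FALSE]
      d <- dw$cont_enc_ret - dw$cont_enc
      tt <- t.test(d)
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, cohens_d = mean(d) / sd(d),
           means = colMeans(dw[c("cont_enc_ret", "cont_enc")]),
           sems = apply(dw[c("cont_enc_ret", "cont_enc")], 2, sd) /
             sqrt(nrow(dw)),
           n = nrow(dw))
    })
    perfect <- run(perfect_pair_proportion(keep_scores,
                                           c("cont_enc_ret", "cont_enc")))
  }

  direction_design <- run(split_analysis(
    keep_scores, "direction", min_pairs_per_bin = split_min,
    covariates = exp_cov))

  structure(list(
    relative_contrast = relative_contrast,
    lag_terciles = lag_terciles,
    distance_split = distance_split,
    absolute_contrast = absolute_contrast,
    deviation_contrast = deviation_contrast,
    correlations = corr,
    encoding_vs_retrieval = enc_vs_ret,
    distance_comparison = distance_cmp,
    perfect_pairs = perfect,
    direction_design = direction_design,
    covariates_used = have_covs,
    categories = cats,
    filter = list(min_pairs = min_pairs, split_min = split_min,
                  retained = filt$retained, excluded = filt$excluded),
    counts = counts,
    scores = scores,
    summaries = summaries),
    class = "ordermem_report")
}

#' @export
print.ordermem_report <- function(x, ...) {
  cat(sprintf("<ordermem_report> categories: %s; retained subjects: %d (min %d pairs/category)\n",
              paste(x$categories, collapse = ", "),
              length(x$filter$retained), x$filter$min_pairs))
  show <- function(label, obj) {
    cat("\n--", label, "--\n")
    if (is.null(obj)) cat("(not applicable)\n")
    else if (!is.null(obj$skipped)) cat("skipped:", obj$skipped, "\n")
    else if (inherits(obj, "rm_contrast")) print(obj)
    else if (is.data.frame(obj)) print(obj, row.names = FALSE, digits = 3)
    else if (!is.null(obj$contrast)) print(obj$contrast)
    else if (!is.null(obj$t)) {
      cat(sprintf("t(%d) = %.3f, p = %.4g, d = %.3f; means: %s\n",
                  obj$df, obj$t, obj$p, obj$cohens_d,
                  paste(sprintf("%.3f", obj$means), collapse = " vs ")))
    }
  }
  show("relative order by category", x$relative_contrast)
  show("relative order by lag tercile (cont-ret)", x$lag_terciles)
  show("relative order by distance-score split", x$distance_split)
  show("absolute order by category", x$absolute_contrast)
  show("temporal-score correlations", x$correlations)
  show("distance: cont-enc-ret vs cont-enc", x$distance_comparison)
  show("perfect-pair proportions", x$perfect_pairs)
  show("category x direction design", x$direction_design)
  invisible(x)
}

report_to_list <- function(report) {
  conv <- function(obj) {
    if (is.null(obj)) return(NULL)
    if (inherits(obj, "rm_contrast")) return(contrast_entry(obj))
    if (is.list(obj) && !is.null(obj$contrast)) {
      return(list(variable = obj$variable, bins = obj$bins,
                  contrast = contrast_entry(obj$contrast),
                  retained = obj$retained, excluded = obj$excluded))
    }
    obj
  }
  list(
    relative_contrast = conv(report$relative_contrast),
    lag_terciles = conv(report$lag_terciles),
    distance_split = conv(report$distance_split),
    absolute_contrast = conv(report$absolute_contrast),
    deviation_contrast = conv(report$deviation_contrast),
    correlations = report$correlations,
    encoding_vs_retrieval = report$encoding_vs_retrieval,
    distance_comparison = report$distance_comparison,
    perfect_pairs = conv(report$perfect_pairs),
    direction_design = conv(report$direction_design),
    covariates_used = report$covariates_used,
    categories = report$categories,
    filter = report$filter,
    counts = report$counts)
}

#' Write an analysis report to JSON
#'
#' @param report an `ordermem_report` from [analyze_dataset()].
#' @param path output path for the JSON file.
#' @return Invisibly, `path`.
#' @export
write_analysis_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA, null = "null",
                       force = TRUE)
  invisible(path)
}

#' Run the simulate / load - extract - score - analyze - report pipeline
#'
#' One call orchestrating every stage. The configuration is a named list
#' (or a YAML file with the same keys):
#'
#' * `simulate`: list of [simulation_params()] arguments, **or**
#' * `study`, `recalls`, `ordering`: CSV paths of an existing dataset;
#' * `out_dir`: output directory (required);
#' * `min_pairs` (default 5), `split_min` (default 3),
#'   `merge_first_three` (default `FALSE`), `seed`.
#'
#' Explicit arguments override configuration-file values, which override
#' defaults; the effective configuration is echoed to
#' `out_dir/config_used.yaml`. All tables, the JSON report and the filter
#' log are written to `out_dir`.
#'
#' @param config named list or path to a YAML configuration file.
#' @param ... overrides of individual configuration keys.
#' @return Invisibly, the `ordermem_report`.
#' @export
run_pipeline <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(config, list(...))
  defaults <- list(min_pairs = 5L, split_min = 3L, merge_first_three = FALSE,
                   seed = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out_dir)) stop("config error: out_dir is required",
                                    call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  experiment <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    params <- do.call(simulation_params, sim_args)
    sim <- simulate_dataset(params)
    dataset <- sim$dataset
    write_dataset(sim, file.path(config$out_dir, "dataset"))
    experiment <- sim$subject_params[c("subject_id", "experiment")]
  } else {
    dataset <- load_sessions(config$study, config$recalls, config$ordering)
  }
  audit_dataset(dataset)

  report <- analyze_dataset(dataset,
                            min_pairs = config$min_pairs,
                            split_min = config$split_min,
                            merge_first_three = isTRUE(config$merge_first_three),
                            experiment = experiment,
                            seed = config$seed)
  write_scored_tables(dataset, scores = report$scores, config$out_dir,
                      summaries = report$summaries)
  write_analysis_report(report, file.path(config$out_dir,
                                          "analysis_report.json"))
  cfg_echo <- config
  cfg_echo$simulate <- lapply(config$simulate, identity)
  yaml::write_yaml(cfg_echo[!vapply(cfg_echo, is.null, logical(1))],
                   file.path(config$out_dir, "config_used.yaml"))
  invisible(report)
}
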