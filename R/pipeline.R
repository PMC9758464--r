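#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end pipeline for one experiment on simulated data:
#' (1) counterbalanced designs, (2) dataset simulation, (3) response coding
#' and MPT count tabulation, (4) overall mixed models for real-news recall,
#' intrusions and fake-news recall, (5) conditional (headline type x
#' classification) recall and intrusion models, (6) the hierarchical MPT with
#' its condition contrasts, (7) belief models (overall response type x
#' headline type, and conditional per response type). Stage outputs are
#' written as CSV/JSON under `out_dir` and linked by a single
#' `manifest.json`; a stage failure is recorded in the manifest and later
#' independent stages still run.
#'
#' @param experiment 1 or 2 (ignored when `config` is given).
#' @param config Optional `generator_config`; defaults to
#'   `default_config(experiment)` reseeded with `seed`.
#' @param seed Integer seed echoed into the config and the MPT sampler.
#' @param out_dir Output directory (created if needed).
#' @param mpt_control List of sampler settings for [fit_hierarchical()].
#' @param recovery_replicates If > 0, also run [recover_parameters()] with
#'   that many replicates (off by default; it refits the MPT repeatedly).
#' @return A `pipeline_result` list: `manifest`, `design_summary`, `digest`,
#'   `models` (named list of `model_estimates`), `mpt` (`mpt_posterior`),
#'   `mpt_differences`, `recovery` (or `NULL`), `trials`, `config`.
#' @export
run_pipeline <- function(experiment = 1, config = NULL, seed = 1L,
                         out_dir = tempfile("correctmem_"),
                         mpt_control = list(), recovery_replicates = 0L) {
  if (is.null(config)) {
    config <- default_config(experiment)
    config$seed <- as.integer(seed)
  }
  validate_config(config)
  experiment <- config$experiment
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  config_path <- file.path(out_dir, "config.json")
  write_config(config, config_path)
  config_hash <- unname(tools::md5sum(config_path))

  stages <- list()
  result <- list(config = config)
  t_start <- Sys.time()
  stage <- function(name, paths, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) e)
    rec <- list(name = name,
                outputs = as.list(paths),
                seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
                status = if (inherits(out, "error")) "failed" else "ok")
    if (inherits(out, "error")) {
      rec$error <- conditionMessage(out)
      message("stage `", name, "` failed: ", rec$error)
      out <- NULL
    }
    stages[[length(stages) + 1L]] <<- rec
    out
  }

  # 1. design
  designs <- stage("design", "designs.csv", {
    ds <- lapply(0:3, function(cb) build_design(experiment, cb, seed = config$seed + cb))
    df <- do.call(rbind, lapply(ds, function(d)
      cbind(counterbalance_index = d$counterbalance_index, as.data.frame(d))))
    utils::write.csv(df, file.path(out_dir, "designs.csv"), row.names = FALSE)
    ds
  })
  result$design_summary <- if (!is.null(designs)) {
    lapply(designs, function(d)
      list(counterbalance_index = d$counterbalance_index,
           violations = validate_design(d)))
  }

  # 2. dataset
  trials <- stage("dataset", "trials.csv", {
    tr <- simulate_dataset(config)
    write_trials(tr, file.path(out_dir, "trials.csv"))
    tr
  })
  result$trials <- trials
  result$digest <- if (!is.null(trials)) {
    list(rows = nrow(trials),
         participants = length(unique(trials$participant_id)),
         per_condition = as.list(table(trials$condition)),
         category_freq = as.list(table(trials$response_category)),
         md5 = unname(tools::md5sum(file.path(out_dir, "trials.csv"))))
  }

  # 3. coding
  coding_out <- if (!is.null(trials)) stage("coding", "mpt_counts.csv", {
    coded <- code_trials(trials)
    write_trials(coded, file.path(out_dir, "trials.csv"))
    cnt <- tabulate_mpt(coded)
    write_mpt_counts(cnt, file.path(out_dir, "mpt_counts.csv"))
    list(coded = coded, counts = cnt)
  })
  counts <- coding_out$counts
  if (!is.null(coding_out)) {
    trials <- coding_out$coded
    result$trials <- trials
  }

  models <- list()
  # 4. overall glmms
  if (!is.null(trials)) {
    overall <- stage("glmm_overall", "glmm_overall.csv", {
      corr <- trials$condition != "REP"
      m <- list(
        recall = fit_binomial_mixed(trials, "real_recalled"),
        intrusion = local({
          d <- trials[corr, , drop = FALSE]
          d$intrusion <- as.integer(d$response_category == "INTRUSION")
          fit_binomial_mixed(d, "intrusion")
        }),
        fake_recall = fit_binomial_mixed(trials[corr, , drop = FALSE], "fake_recalled"))
      write_estimates_csv(m, file.path(out_dir, "glmm_overall.csv"))
      m
    })
    models <- c(models, overall)
  }

  # 5. conditional glmms
  if (!is.null(trials)) {
    conditional <- stage("glmm_conditional", "glmm_conditional.csv", {
      m <- list(conditional_recall = conditional_models(trials, "real_recalled"),
                conditional_intrusion = conditional_models(trials, "intrusion"))
      write_estimates_csv(m, file.path(out_dir, "glmm_conditional.csv"))
      m
    })
    models <- c(models, conditional)
  }

  # 6. hierarchical MPT
  if (!is.null(counts)) {
    mpt_out <- stage("mpt", c("mpt_posterior.csv", "mpt_differences.csv",
                              "mpt_diagnostics.json"), {
      post <- do.call(fit_hierarchical,
                      c(list(counts = counts, seed = config$seed), mpt_control))
      utils::write.csv(post$summary, file.path(out_dir, "mpt_posterior.csv"),
                       row.names = FALSE)
      diffs <- mpt_difference_table(post)
      utils::write.csv(diffs, file.path(out_dir, "mpt_differences.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(rhat = as.list(post$diagnostics$rhat),
             ess = as.list(post$diagnostics$ess),
             sampler = post$sampler),
        file.path(out_dir, "mpt_diagnostics.json"), auto_unbox = TRUE, digits = NA)
      list(post = post, diffs = diffs)
    })
    result$mpt <- mpt_out$post
    result$mpt_differences <- mpt_out$diffs
  }

  # 7. beliefs
  if (!is.null(trials)) {
    beliefs <- stage("beliefs", "beliefs.csv", {
      rec_int <- trials$response_category %in% c("REAL_RECALL", "INTRUSION") &
        trials$condition != "REP"
      real_rows <- rec_int & trials$response_category == "REAL_RECALL"
      intr_rows <- rec_int & trials$response_category == "INTRUSION" &
        trials$conditional_class != "CORR_FN_RECALLED"
      m <- list(
        belief_overall = fit_gaussian_mixed(trials[rec_int, , drop = FALSE],
                                            fixed = c("response_category", "condition")),
        belief_real = fit_gaussian_mixed(
          trials[real_rows, , drop = FALSE],
          fixed = c("condition", "conditional_class")),
        belief_intrusion = fit_gaussian_mixed(
          trials[intr_rows, , drop = FALSE],
          fixed = c("condition", "conditional_class")))
      write_estimates_csv(m, file.path(out_dir, "beliefs.csv"))
      m
    })
    models <- c(models, beliefs)
  }
  result$models <- models

  if (recovery_replicates > 0L) {
    result$recovery <- stage("recovery", "recovery.json", {
      rep <- do.call(recover_parameters,
                     c(list(config = config, n_replicates = recovery_replicates,
                            seed = config$seed), mpt_control))
      write_recovery(rep, file.path(out_dir, "recovery.json"))
      rep
    })
  }

  manifest <- list(
    experiment = experiment,
    seed = config$seed,
    config = "config.json",
    config_md5 = config_hash,
    created = format(t_start, "%Y-%m-%d %H:%M:%S"),
    total_seconds = round(as.numeric(Sys.time() - t_start, units = "secs"), 2),
    package_version = as.character(utils::packageVersion("correctmem")),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  result$manifest <- manifest
  result$out_dir <- out_dir
  structure(result, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result (experiment %d, seed %d)\n",
              x$manifest$experiment, x$manifest$seed))
  for (s in x$manifest$stages)
    cat(sprintf("  %-16s %-8s %6.1fs\n", s$name, s$status, s$seconds))
  cat("outputs in", x$out_dir, "\n")
  invisible(x)
}

mpt_difference_table <- function(post) {
  conds <- post$conditions
  rows <- list()
  for (param in c("r", "f")) {
    for (i in seq_along(conds)) for (j in seq_along(conds)) {
      if (i >= j) next
      d <- credible_difference(post, param, conds[j], conds[i])
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, cond_a = conds[j], cond_b = conds[i],
        mean = d$mean, ci_low = d$ci[1L], ci_high = d$ci[2L],
        credible = d$credible, stringsAsFactors = FALSE)
    }
    # unlabeled correction vs the average of the other corrections
    others <- setdiff(conds, "UC")
    d <- credible_difference(post, param, "UC", others)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = param, cond_a = "UC", cond_b = paste(others, collapse = "+"),
      mean = d$mean, ci_low = d$ci[1L], ci_high = d$ci[2L],
      credible = d$credible, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

write_estimates_csv <- function(models, path) {
  rows <- lapply(names(models), function(nm) {
    est <- models[[nm]]$estimates
    level_cols <- setdiff(names(est), c("estimate", "ci_low", "ci_high", "n",
                                        "marginal"))
    data.frame(analysis = nm,
               level = do.call(paste, c(est[level_cols], sep = ":")),
               estimate = est$estimate, ci_low = est$ci_low,
               ci_high = est$ci_high, n = est$n, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Model-results tables
#'
#' Collapses the fitted mixed models of a [run_pipeline()] result into the
#' two compact effect tables the analyses report: one for the Phase-3 memory
#' measures (overall recall / intrusions / fake recall: headline type;
#' conditional recall and intrusions: headline type, classification, and
#' their interaction) and one for beliefs (overall: response type, headline
#' type, interaction; conditional per response type). Each row is an
#' analysis x effect with a Wald chi-square, its df, and p (car::Anova, type
#' III). Missing models produce all-NA rows rather than dropping silently.
#'
#' @param result A `pipeline_result`.
#' @return List of two data frames, `memory` and `beliefs`, with columns
#'   `analysis`, `effect`, `chisq`, `df`, `p`.
#' @export
make_tables <- function(result) {
  models <- result$models
  anova_rows <- function(analysis, est) {
    if (is.null(est))
      return(data.frame(analysis = analysis, effect = NA_character_,
                        chisq = NA_real_, df = NA_integer_, p = NA_real_))
    a <- car::Anova(est$fit, type = 3)
    a <- a[setdiff(rownames(a), "(Intercept)"), , drop = FALSE]
    data.frame(analysis = analysis, effect = rownames(a),
               chisq = a[["Chisq"]], df = a[["Df"]],
               p = a[["Pr(>Chisq)"]], row.names = NULL,
               stringsAsFactors = FALSE)
  }
  memory <- do.call(rbind, list(
    anova_rows("overall_real_recall", models$recall),
    anova_rows("overall_intrusions", models$intrusion),
    anova_rows("overall_fake_recall", models$fake_recall),
    anova_rows("conditional_real_recall", models$conditional_recall),
    anova_rows("conditional_intrusions", models$conditional_intrusion)))
  beliefs <- do.call(rbind, list(
    anova_rows("belief_overall", models$belief_overall),
    anova_rows("conditional_belief_real_recall", models$belief_real),
    anova_rows("conditional_belief_intrusions", models$belief_intrusion)))
  list(memory = memory, beliefs = beliefs)
}

#' Figure-style tidy summaries
#'
#' Emits one tidy data frame per figure-style view of a [run_pipeline()]
#' result: `fig2` (overall recall / intrusion / fake-recall probabilities per
#' correction condition), `fig3` (conditional recall and intrusion
#' probabilities per condition x classification cell, intrusions excluding
#' the redundant `CORR_FN_RECALLED` cells), `fig4` (MPT posterior r and f per
#' condition), `fig5` (belief ratings per response type x condition), `fig6`
#' (conditional beliefs per response type x condition x classification).
#' Cell-proportion columns (`cell_prop`) give each cell's share of
#' observations within its conditioning family and sum to 1 there; sparse
#' cells (n < `sparse_n`) are flagged.
#'
#' @param result A `pipeline_result`.
#' @param sparse_n Threshold below which a cell is flagged sparse.
#' @return Named list of data frames `fig2` ... `fig6` (entries `NULL` when
#'   the corresponding stage failed).
#' @export
summarize_figures <- function(result, sparse_n = 10L) {
  models <- result$models
  out <- list()

  grab <- function(est, outcome_label) {
    if (is.null(est)) return(NULL)
    df <- est$estimates
    df$outcome <- outcome_label
    df
  }
  fig2 <- rbind(
    grab(models$intrusion, "intrusion"),
    grab(models$fake_recall, "fake_recall"),
    local({
      d <- grab(models$recall, "real_recall")
      if (!is.null(d)) d[d$condition != "REP", , drop = FALSE]
    }))
  if (!is.null(fig2)) {
    fig2 <- fig2[, c("outcome", "condition", "estimate", "ci_low", "ci_high", "n")]
  }
  out$fig2 <- fig2

  cond_fig <- function(est, outcome_label) {
    if (is.null(est)) return(NULL)
    df <- est$estimates
    df$outcome <- outcome_label
    df$cell_prop <- df$n / sum(df$n)
    df$sparse <- df$n < sparse_n
    df[, c("outcome", "condition", "conditional_class", "estimate",
           "ci_low", "ci_high", "n", "cell_prop", "sparse")]
  }
  out$fig3 <- rbind(cond_fig(models$conditional_recall, "real_recall"),
                    cond_fig(models$conditional_intrusion, "intrusion"))

  out$fig4 <- if (!is.null(result$mpt)) result$mpt$summary

  out$fig5 <- if (!is.null(models$belief_overall)) {
    df <- models$belief_overall$estimates
    fam <- stats::ave(df$n, df$response_category, FUN = sum)
    df$cell_prop <- df$n / fam
    df[, c("response_category", "condition", "estimate", "ci_low", "ci_high",
           "n", "cell_prop")]
  }

  fig6_part <- function(est, label) {
    if (is.null(est)) return(NULL)
    df <- est$estimates
    df$response_type <- label
    df$cell_prop <- df$n / sum(df$n)
    df$sparse <- df$n < sparse_n
    df[, c("response_type", "condition", "conditional_class", "estimate",
           "ci_low", "ci_high", "n", "cell_prop", "sparse")]
  }
  out$fig6 <- rbind(fig6_part(models$belief_real, "real_recall"),
                    fig6_part(models$belief_intrusion, "intrusion"))
  out
}
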