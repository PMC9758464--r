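#' Logistic mixed model for a binary trial outcome
#'
#' Fits `outcome ~ fixed factors + (1 | participant_id) + (1 | topic_id)` by
#' Laplace-approximated maximum likelihood (lme4::glmer, logit link) and
#' summarizes it the way the analyses report results: per-level estimated
#' probabilities are the inverse link of the fixed-effect predictor at random
#' effects zero (the conditional, typical-participant/typical-item estimate,
#' via emmeans), with Wald 95% confidence intervals, and all pairwise
#' contrasts as Wald z statistics under the configured multiplicity
#' adjustment.
#'
#' Degenerate inputs are reported, not silently absorbed: a fixed-effect cell
#' whose outcome is constant triggers a complete-separation error before
#' fitting, and optimizer non-convergence is recorded in `convergence` and
#' surfaced as a warning.
#'
#' @param trials Trial data frame.
#' @param outcome Name of the binary outcome column.
#' @param fixed Character vector of fixed-factor column names (default
#'   `"condition"`); several names produce a full factorial.
#' @param adjust Multiplicity adjustment for the all-pairs contrasts
#'   (`"tukey"`, `"holm"`, or `"none"`).
#' @param marginal If `TRUE`, also report population-averaged probabilities
#'   obtained by logit-normal approximation (fixed-effect predictor shrunk by
#'   `sqrt(1 + c^2 * (sd_participant^2 + sd_item^2))`, c = 16 sqrt(3) / (15
#'   pi)) in a `marginal` column.
#' @param subset_expr Optional logical vector restricting the rows used.
#' @return A `model_estimates` object: list with `outcome`, `scale`
#'   (`"probability"`), `estimates` (level, estimate, ci_low, ci_high, and
#'   cell counts), `contrasts` (level pair, estimate on the link scale,
#'   statistic, adjusted p), `adjustment`, `convergence` (messages, empty
#'   when clean), and the underlying `fit`.
#' @examples
#' \dontrun{
#' est <- fit_binomial_mixed(simulate_dataset(default_config(1)), "real_recalled")
#' est$estimates
#' }
#' @export
fit_binomial_mixed <- function(trials, outcome, fixed = "condition",
                               adjust = c("tukey", "holm", "none"),
                               marginal = FALSE, subset_expr = NULL) {
  adjust <- match.arg(adjust)
  dat <- prepare_model_frame(trials, outcome, fixed, subset_expr)
  check_separation(dat, outcome, fixed)

  form <- stats::as.formula(paste(
    outcome, "~", paste(fixed, collapse = " * "),
    "+ (1 | participant_id) + (1 | topic_id)"))
  conv <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = dat, family = stats::binomial(),
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             optCtrl = list(maxfun = 1e5))),
    warning = function(w) {
      conv <<- c(conv, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      conv <<- c(conv, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  if (length(conv))
    warning("glmer reported: ", paste(unique(conv), collapse = "; "),
            call. = FALSE)

  emm <- emmeans::emmeans(fit, stats::as.formula(paste("~", paste(fixed, collapse = " * "))))
  est <- as.data.frame(stats::confint(emm))
  estimates <- data.frame(
    level_frame(est, fixed),
    estimate = invlogit(est$emmean),
    ci_low = invlogit(est$asymp.LCL),
    ci_high = invlogit(est$asymp.UCL),
    stringsAsFactors = FALSE)
  estimates$n <- cell_counts(dat, fixed, estimates)
  if (marginal) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    c2 <- (16 * sqrt(3) / (15 * pi))^2
    shrink <- sqrt(1 + c2 * sum(vc$vcov))
    estimates$marginal <- invlogit(est$emmean / shrink)
  }

  new_model_estimates(outcome = outcome, scale = "probability",
                      estimates = estimates,
                      contrasts = contrast_table(emm, adjust),
                      adjustment = adjust, convergence = conv,
                      fit = fit, emm = emm, fixed = fixed)
}

#' Gaussian mixed model for belief ratings
#'
#' Fits `outcome ~ fixed factors + (1 | participant_id) + (1 | topic_id)`
#' with lmerTest (REML), reporting per-level estimated ratings with 95%
#' confidence intervals and all pairwise contrasts as t statistics with
#' Satterthwaite degrees of freedom. Ratings are analyzed as Gaussian, the
#' convention the reported t statistics imply, even though the generator is
#' ordinal underneath.
#'
#' @inheritParams fit_binomial_mixed
#' @param outcome Rating column (default `"belief_rating"`).
#' @return A `model_estimates` object with `scale = "rating"`.
#' @export
fit_gaussian_mixed <- function(trials, outcome = "belief_rating",
                               fixed = "condition",
                               adjust = c("tukey", "holm", "none"),
                               subset_expr = NULL) {
  adjust <- match.arg(adjust)
  dat <- prepare_model_frame(trials, outcome, fixed, subset_expr)
  if (!all(dat[[outcome]] %in% 1:6))
    stop("`", outcome, "` must contain ratings in 1..6", call. = FALSE)

  form <- stats::as.formula(paste(
    outcome, "~", paste(fixed, collapse = " * "),
    "+ (1 | participant_id) + (1 | topic_id)"))
  conv <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = dat),
    warning = function(w) {
      conv <<- c(conv, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      conv <<- c(conv, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })

  emm <- emmeans::emmeans(fit, stats::as.formula(paste("~", paste(fixed, collapse = " * "))),
                          lmer.df = "satterthwaite")
  est <- as.data.frame(stats::confint(emm))
  lcl <- if ("lower.CL" %in% names(est)) est$lower.CL else est$asymp.LCL
  ucl <- if ("upper.CL" %in% names(est)) est$upper.CL else est$asymp.UCL
  estimates <- data.frame(
    level_frame(est, fixed),
    estimate = est$emmean, ci_low = lcl, ci_high = ucl,
    stringsAsFactors = FALSE)
  estimates$n <- cell_counts(dat, fixed, estimates)

  new_model_estimates(outcome = outcome, scale = "rating",
                      estimates = estimates,
                      contrasts = contrast_table(emm, adjust),
                      adjustment = adjust, convergence = conv,
                      fit = fit, emm = emm, fixed = fixed)
}

#' Conditional recall / intrusion models
#'
#' The conditional analyses model a Phase-3 outcome with the headline type x
#' conditional classification interaction on correction trials only. For the
#' intrusion outcome the `CORR_FN_RECALLED` cells are dropped: once the fake
#' detail has been recalled at the fake-recall prompt, reporting it as the
#' real-news answer is redundant and those intrusions seldom occur.
#' Fixed-effect cells with no observations are flagged in `empty_cells` and
#' excluded from the estimate and contrast tables.
#'
#' @param trials Coded trial data frame (see [code_trials()]).
#' @param outcome `"real_recalled"` for conditional recall or `"intrusion"`
#'   for conditional intrusions (`response_category == "INTRUSION"`).
#' @inheritParams fit_binomial_mixed
#' @return A `model_estimates` object (cells = condition x conditional
#'   class), with an `empty_cells` element listing flagged cells.
#' @export
conditional_models <- function(trials, outcome = c("real_recalled", "intrusion"),
                               adjust = c("tukey", "holm", "none")) {
  outcome <- match.arg(outcome)
  adjust <- match.arg(adjust)
  if (is.null(trials$conditional_class)) trials <- code_trials(trials)
  dat <- trials[trials$condition != "REP", , drop = FALSE]
  dat$condition <- droplevels(dat$condition)
  if (outcome == "intrusion") {
    dat <- dat[dat$conditional_class != "CORR_FN_RECALLED", , drop = FALSE]
    dat$intrusion <- as.integer(dat$response_category == "INTRUSION")
  }
  dat$conditional_class <- droplevels(dat$conditional_class)

  cells <- table(dat$condition, dat$conditional_class)
  empty <- which(cells == 0, arr.ind = TRUE)
  empty_cells <- if (nrow(empty)) {
    data.frame(condition = rownames(cells)[empty[, 1L]],
               conditional_class = colnames(cells)[empty[, 2L]],
               stringsAsFactors = FALSE)
  } else data.frame(condition = character(0), conditional_class = character(0))

  est <- fit_binomial_mixed(dat, outcome,
                            fixed = c("condition", "conditional_class"),
                            adjust = adjust)
  if (nrow(empty_cells)) {
    keep <- !paste(est$estimates$condition, est$estimates$conditional_class) %in%
      paste(empty_cells$condition, empty_cells$conditional_class)
    est$estimates <- est$estimates[keep, , drop = FALSE]
    est$contrasts <- est$contrasts[is.finite(est$contrasts$statistic), , drop = FALSE]
  }
  est$empty_cells <- empty_cells
  est
}

#' All-pairs contrasts of a fitted model
#'
#' Re-derives the pairwise contrast table of a `model_estimates` object under
#' a different multiplicity adjustment. Adjusted p values are monotone in the
#' raw p values within the family.
#'
#' @param est A `model_estimates` object.
#' @param adjust `"tukey"`, `"holm"`, or `"none"`.
#' @return Data frame of level pairs with link-scale estimate, test
#'   statistic, and adjusted p value.
#' @export
pairwise_contrasts <- function(est, adjust = c("tukey", "holm", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(est, "model_estimates"))
  contrast_table(est$emm, adjust)
}

new_model_estimates <- function(...) {
  structure(list(...), class = "model_estimates")
}

#' @export
print.model_estimates <- function(x, ...) {
  cat(sprintf("Mixed-model estimates for `%s` (%s scale)\n", x$outcome, x$scale))
  print(x$estimates, row.names = FALSE, digits = 3)
  cat(sprintf("%d pairwise contrasts (%s-adjusted)\n", nrow(x$contrasts),
              x$adjustment))
  if (length(x$convergence))
    cat("convergence notes:", paste(x$convergence, collapse = "; "), "\n")
  invisible(x)
}

prepare_model_frame <- function(trials, outcome, fixed, subset_expr = NULL) {
  if (!is.null(subset_expr)) trials <- trials[subset_expr, , drop = FALSE]
  need <- c(outcome, fixed, "participant_id", "topic_id")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  dat <- trials
  for (fx in fixed) dat[[fx]] <- droplevels(factor(dat[[fx]]))
  for (fx in fixed)
    if (nlevels(dat[[fx]]) < 2L)
      stop("fixed factor `", fx, "` needs at least 2 levels", call. = FALSE)
  dat$participant_id <- factor(dat$participant_id)
  dat$topic_id <- factor(dat$topic_id)
  dat
}

check_separation <- function(dat, outcome, fixed) {
  y <- dat[[outcome]]
  if (!all(y %in% 0:1))
    stop("`", outcome, "` must be binary (0/1)", call. = FALSE)
  cell <- interaction(dat[fixed], drop = TRUE)
  means <- tapply(y, cell, mean)
  flat <- means %in% c(0, 1)
  if (any(flat))
    stop("complete separation: outcome `", outcome, "` is constant in cell(s) ",
         paste(names(means)[flat], collapse = ", "),
         "; the logistic fixed effect is unidentified there", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("`", outcome, "` is constant; nothing to model", call. = FALSE)
}

level_frame <- function(emm_df, fixed) {
  out <- emm_df[, fixed, drop = FALSE]
  for (fx in fixed) out[[fx]] <- as.character(out[[fx]])
  out
}

cell_counts <- function(dat, fixed, estimates) {
  key_dat <- do.call(paste, dat[fixed])
  key_est <- do.call(paste, estimates[fixed])
  as.integer(table(key_dat)[key_est])
}

contrast_table <- function(emm, adjust) {
  ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  stat_col <- intersect(c("z.ratio", "t.ratio"), names(ct))[1L]
  out <- data.frame(contrast = as.character(ct$contrast),
                    estimate = ct$estimate,
                    statistic = ct[[stat_col]],
                    adjusted_p = ct$p.value,
                    stringsAsFactors = FALSE)
  if ("df" %in% names(ct)) out$df <- ct$df
  out
}
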