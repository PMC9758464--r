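#' Default generator calibration
#'
#' Returns the documented default [generator configuration][validate_config]
#' for one experiment. The calibration is built around the published
#' condition-level *difference* estimates for the latent recollection (r) and
#' familiarity (f) parameters, which are the quantities the recovery
#' harnesses target; the absolute anchors are package design choices (the
#' study reports differences and intervals, not absolute levels):
#'
#' * Experiment 1: r = (UC 0.25, LC 0.40, FRLC 0.51), so that
#'   r(LC) - r(UC) = 0.15 and r(FRLC) - r(LC) = 0.11;
#'   f = (UC 0.30, LC 0.12, FRLC 0.12), so that f(UC) minus the mean of the
#'   other two is 0.18; repetition recall 0.76.
#' * Experiment 2: r = (UC 0.28, LFN 0.33, FRLC 0.51), so that
#'   r(LFN) - r(UC) = 0.05 and the smallest reminder advantage across both
#'   experiments is 0.11; f = (UC 0.15, LFN 0.12, FRLC 0.12) (no reliable
#'   familiarity differences); repetition recall 0.70.
#'
#' All r, f and repetition-recall values are conditional probabilities at
#' participant and item random effects of zero, matching the convention under
#' which the mixed models and the hierarchical MPT report estimates.
#'
#' @param experiment Integer, 1 or 2.
#' @return A `generator_config` list; see [validate_config()] for the fields.
#' @examples
#' cfg <- default_config(1)
#' cfg$r_by_condition
#' @export
default_config <- function(experiment) {
  experiment <- check_experiment(experiment)
  corr <- correction_conditions(experiment)
  conds <- condition_levels(experiment)

  if (experiment == 1L) {
    r <- c(UC = 0.25, LC = 0.40, FRLC = 0.51)
    f <- c(UC = 0.30, LC = 0.12, FRLC = 0.12)
    p_rep <- 0.76
    # belief latent means (1-6 latent scale) per response category x condition
    belief <- rbind(
      REAL_RECALL = c(REP = 5.0, UC = 4.6, LC = 4.8, FRLC = 5.0),
      INTRUSION   = c(REP = 3.5, UC = 3.4, LC = 3.0, FRLC = 2.9),
      OTHER       = c(REP = 3.5, UC = 3.5, LC = 3.5, FRLC = 3.5))
  } else {
    r <- c(UC = 0.28, LFN = 0.33, FRLC = 0.51)
    f <- c(UC = 0.15, LFN = 0.12, FRLC = 0.12)
    p_rep <- 0.70
    belief <- rbind(
      REAL_RECALL = c(REP = 5.0, UC = 4.8, LFN = 4.8, FRLC = 4.9),
      INTRUSION   = c(REP = 3.5, UC = 3.5, LFN = 2.7, FRLC = 3.1),
      OTHER       = c(REP = 3.5, UC = 3.5, LFN = 3.5, FRLC = 3.5))
  }
  colnames(belief) <- conds

  cfg <- structure(list(
    experiment = experiment,
    n_participants = 96L,
    r_by_condition = r,
    f_by_condition = f,
    p_repetition_recall = p_rep,
    sd_participant = 0.8,
    sd_item = 0.5,
    p_classify_given_recollect = 0.9,
    p_classify_given_no_recollect = 0.2,
    p_classify_repetition = 0.1,
    p_fakerecall_given_classified =
      stats::setNames(ifelse(corr == "FRLC", 0.75, ifelse(corr == "UC", 0.35, 0.5)), corr),
    belief_means = belief,
    belief_sd = 1.0,
    sd_participant_belief = 0.5,
    belief_cutpoints = c(1.5, 2.5, 3.5, 4.5, 5.5),
    phase1_belief_means = c(real_unlabeled = 4.0, fake_unlabeled = 3.2,
                            fake_labeled = 1.8),
    phase1_familiarity_means = c(real = 3.6, fake = 2.8),
    seed = 1L), class = "generator_config")
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' A `generator_config` describes the generative model of the simulator:
#'
#' * `experiment`, `n_participants`, `seed`;
#' * `r_by_condition`, `f_by_condition`: latent recollection and familiarity
#'   probabilities (at random effects zero), named by the experiment's three
#'   correction conditions;
#' * `p_repetition_recall`: correct-recall probability for repetition trials;
#' * `sd_participant`, `sd_item`: logit-scale SDs of the crossed participant
#'   and topic random intercepts;
#' * `p_classify_given_recollect`, `p_classify_given_no_recollect`,
#'   `p_classify_repetition`: correction-classification probabilities;
#' * `p_fakerecall_given_classified`: per correction condition, probability of
#'   recalling the fake detail once the topic is classified as corrected;
#' * `belief_means` (response category x condition latent means), `belief_sd`,
#'   `sd_participant_belief`, `belief_cutpoints` (5 increasing thresholds
#'   mapping the latent scale to 1-6 ratings);
#' * `phase1_belief_means` (real/fake unlabeled, fake labeled) and
#'   `phase1_familiarity_means` (real, fake) for the Phase-1 baseline ratings.
#'
#' @param cfg A `generator_config`.
#' @return `cfg` invisibly; raises an informative error when invalid.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "generator_config"))
    stop("`cfg` must be a generator_config (see default_config())", call. = FALSE)
  check_experiment(cfg$experiment)
  corr <- correction_conditions(cfg$experiment)
  probs <- c(cfg$r_by_condition, cfg$f_by_condition, cfg$p_repetition_recall,
             cfg$p_classify_given_recollect, cfg$p_classify_given_no_recollect,
             cfg$p_classify_repetition, cfg$p_fakerecall_given_classified)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  for (field in c("r_by_condition", "f_by_condition", "p_fakerecall_given_classified"))
    if (!setequal(names(cfg[[field]]), corr))
      stop(sprintf("`%s` must be named by exactly the correction conditions {%s}",
                   field, paste(corr, collapse = ", ")), call. = FALSE)
  if (cfg$sd_participant < 0 || cfg$sd_item < 0 || cfg$belief_sd < 0 ||
      cfg$sd_participant_belief < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (length(cfg$belief_cutpoints) != 5L || is.unsorted(cfg$belief_cutpoints, strictly = TRUE))
    stop("`belief_cutpoints` must be 5 strictly increasing thresholds", call. = FALSE)
  if (!all(response_categories() %in% rownames(cfg$belief_means)) ||
      !all(condition_levels(cfg$experiment) %in% colnames(cfg$belief_means)))
    stop("`belief_means` must cover all response categories and conditions", call. = FALSE)
  if (cfg$n_participants < 1)
    stop("`n_participants` must be positive", call. = FALSE)
  invisible(cfg)
}

#' Read or write a generator configuration
#'
#' Configurations round-trip through YAML (`.yaml`/`.yml`) or JSON files whose
#' keys mirror the `generator_config` fields; `belief_means` is stored as a
#' map of response category to per-condition means.
#'
#' @param cfg A `generator_config`.
#' @param path File path; the extension selects the format.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   validated `generator_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  out <- lapply(unclass(cfg), function(x) if (!is.null(names(x))) as.list(x) else x)
  out$belief_means <- apply(cfg$belief_means, 1L, as.list, simplify = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  cfg <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  cfg$belief_means <- do.call(rbind, lapply(raw$belief_means, unlist))
  cfg$experiment <- as.integer(cfg$experiment)
  cfg$n_participants <- as.integer(cfg$n_participants)
  cfg$seed <- as.integer(cfg$seed)
  cfg <- structure(cfg, class = "generator_config")
  validate_config(cfg)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Generator configuration (experiment %d, %d participants, seed %d)\n",
              x$experiment, x$n_participants, x$seed))
  cat("  recollection r:", paste(sprintf("%s=%.2f", names(x$r_by_condition),
                                         x$r_by_condition), collapse = " "), "\n")
  cat("  familiarity  f:", paste(sprintf("%s=%.2f", names(x$f_by_condition),
                                         x$f_by_condition), collapse = " "), "\n")
  cat(sprintf("  repetition recall %.2f; sd_participant %.2f, sd_item %.2f\n",
              x$p_repetition_recall, x$sd_participant, x$sd_item))
  invisible(x)
}
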