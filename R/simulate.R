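#' Simulate a trial-level dataset
#'
#' Generates one participant x topic long-format dataset under the
#' dual-process generative model that the analysis pipeline assumes.
#'
#' Participants are assigned round-robin to the four counterbalance lists, so
#' that each topic serves each condition for (close to) a quarter of the
#' sample. Each participant p draws a logit-scale memory intercept
#' u_p ~ N(0, sd_participant^2) and a belief intercept
#' b_p ~ N(0, sd_participant_belief^2); each topic i draws a logit-scale item
#' intercept w_i ~ N(0, sd_item^2).
#'
#' Correction trials follow the processing tree: recollection fires with
#' probability invlogit(logit(r_c) + u_p + w_i); a recollected trial yields
#' correct real-news recall and is classified as a correction with probability
#' `p_classify_given_recollect`. Without recollection, familiarity fires with
#' probability invlogit(logit(f_c) + u_p + w_i) and misattributes the fake
#' detail (an intrusion); otherwise the trial is coded `OTHER`. Trials without
#' recollection are classified with probability
#' `p_classify_given_no_recollect`. The fake-recall prompt only appears after
#' a "yes" classification, so `fake_recalled` is drawn (per-condition
#' probability) only when `classified_correction = 1` and is structurally 0
#' otherwise. Repetition trials have no fake counterpart: recall is Bernoulli
#' at invlogit(logit(p_repetition_recall) + u_p + w_i), intrusions are
#' impossible, and classifications are rare false alarms
#' (`p_classify_repetition`).
#'
#' Phase-3 belief ratings come from a latent Normal centred at
#' `belief_means[response category, condition] + b_p` with SD `belief_sd`,
#' thresholded at `belief_cutpoints` into 1-6. Phase-1 familiarity and belief
#' ratings are drawn analogously from `phase1_familiarity_means` (by
#' veracity) and `phase1_belief_means`, with labeled fake news (`LFN`,
#' Experiment 2) given the markedly lower `fake_labeled` mean.
#'
#' @param config A `generator_config`, e.g. [default_config()]. `config$seed`
#'   drives all trial-level randomness.
#' @param design_seed Integer seed for the four counterbalanced designs
#'   (list `cb` uses `design_seed + cb`). Defaults to `config$seed`.
#' @return A data frame with one row per participant x topic:
#'   `participant_id`, `topic_id`, `experiment`, `condition`,
#'   `phase1_familiarity`, `phase1_belief`, `real_recalled`, `belief_rating`,
#'   `classified_correction`, `fake_recalled`, `response_category`.
#' @examples
#' trials <- simulate_dataset(default_config(1))
#' nrow(trials)  # 96 x 60
#' @export
simulate_dataset <- function(config, design_seed = config$seed) {
  validate_config(config)
  designs <- lapply(0:3, function(cb)
    build_design(config$experiment, cb, seed = design_seed + cb))

  P <- config$n_participants
  local_seed(config$seed, {
    u <- stats::rnorm(P, 0, config$sd_participant)
    b <- stats::rnorm(P, 0, config$sd_participant_belief)
    w <- stats::rnorm(60, 0, config$sd_item)

    cb_of <- (seq_len(P) - 1L) %% 4L
    participant_id <- rep(seq_len(P), each = 60L)
    topic_id <- rep(1:60, times = P)
    condition <- unlist(lapply(seq_len(P), function(p)
      unname(designs[[cb_of[p] + 1L]]$condition_of)), use.names = FALSE)
    veracity <- unlist(lapply(seq_len(P), function(p)
      unname(designs[[cb_of[p] + 1L]]$phase1_veracity)), use.names = FALSE)

    n <- P * 60L
    eta <- u[participant_id] + w[topic_id]
    is_rep <- condition == "REP"

    r_c <- f_c <- rep(NA_real_, n)
    r_c[!is_rep] <- config$r_by_condition[condition[!is_rep]]
    f_c[!is_rep] <- config$f_by_condition[condition[!is_rep]]

    recollected <- familiar <- integer(n)
    recollected[!is_rep] <-
      stats::rbinom(sum(!is_rep), 1L, invlogit(logit(r_c[!is_rep]) + eta[!is_rep]))
    no_rec <- !is_rep & recollected == 0L
    familiar[no_rec] <-
      stats::rbinom(sum(no_rec), 1L, invlogit(logit(f_c[no_rec]) + eta[no_rec]))

    real_recalled <- integer(n)
    real_recalled[is_rep] <-
      stats::rbinom(sum(is_rep), 1L,
                    invlogit(logit(config$p_repetition_recall) + eta[is_rep]))
    real_recalled[!is_rep] <- recollected[!is_rep]

    response_category <- rep("OTHER", n)
    response_category[real_recalled == 1L] <- "REAL_RECALL"
    response_category[familiar == 1L] <- "INTRUSION"

    p_class <- rep(config$p_classify_repetition, n)
    p_class[!is_rep] <- ifelse(recollected[!is_rep] == 1L,
                               config$p_classify_given_recollect,
                               config$p_classify_given_no_recollect)
    classified_correction <- stats::rbinom(n, 1L, p_class)

    fake_recalled <- integer(n)
    eligible <- !is_rep & classified_correction == 1L
    fake_recalled[eligible] <-
      stats::rbinom(sum(eligible), 1L,
                    config$p_fakerecall_given_classified[condition[eligible]])

    belief_mu <- config$belief_means[cbind(response_category, condition)] +
      b[participant_id]
    belief_rating <- cut_rating(stats::rnorm(n, belief_mu, config$belief_sd),
                                config$belief_cutpoints)

    p1_class <- ifelse(veracity == "real", "real_unlabeled",
                       ifelse(condition == "LFN", "fake_labeled", "fake_unlabeled"))
    p1_belief_mu <- config$phase1_belief_means[p1_class] + b[participant_id]
    phase1_belief <- cut_rating(stats::rnorm(n, p1_belief_mu, config$belief_sd),
                                config$belief_cutpoints)
    p1_fam_mu <- config$phase1_familiarity_means[veracity] + b[participant_id]
    phase1_familiarity <- cut_rating(stats::rnorm(n, p1_fam_mu, config$belief_sd),
                                     config$belief_cutpoints)

    data.frame(
      participant_id = participant_id,
      topic_id = topic_id,
      experiment = config$experiment,
      condition = factor(condition, levels = condition_levels(config$experiment)),
      phase1_familiarity = phase1_familiarity,
      phase1_belief = phase1_belief,
      real_recalled = real_recalled,
      belief_rating = belief_rating,
      classified_correction = classified_correction,
      fake_recalled = fake_recalled,
      response_category = factor(response_category, levels = response_categories()),
      stringsAsFactors = FALSE)
  })
}

# threshold a latent draw into a 1-6 rating
cut_rating <- function(latent, cutpoints) {
  findInterval(latent, cutpoints) + 1L
}

#' Write or read a trial table
#'
#' The CSV schema has one row per participant x topic and columns
#' `participant_id, topic_id, experiment, condition, phase1_familiarity,
#' phase1_belief, real_recalled, belief_rating, classified_correction,
#' fake_recalled` plus the optional precoded `response_category` column
#' (written by default; accepted on read so that scored exports of real data
#' can enter the pipeline without free-text scoring). `read_trials()`
#' validates the schema and the structural invariants - ratings in 1..6,
#' binary outcomes, fake recall only after a "yes" classification, no
#' intrusions on repetition trials - and names the first offending row in its
#' error.
#'
#' @param trials Trial data frame as from [simulate_dataset()].
#' @param path CSV file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` the
#'   validated data frame (with `condition` and `response_category` as
#'   factors).
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  required <- c("participant_id", "topic_id", "experiment", "condition",
                "phase1_familiarity", "phase1_belief", "real_recalled",
                "belief_rating", "classified_correction", "fake_recalled")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("malformed trial file: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)

  fail <- function(rows, what) {
    if (any(rows))
      stop(sprintf("trial schema violation (%s) at row %d of %s",
                   what, which(rows)[1L], basename(path)), call. = FALSE)
  }
  exps <- unique(df$experiment)
  if (length(exps) != 1L || !exps %in% 1:2)
    stop("trial file must contain a single experiment (1 or 2)", call. = FALSE)
  levels_ok <- condition_levels(exps)
  fail(!df$condition %in% levels_ok, "unknown condition code")
  for (col in c("phase1_familiarity", "phase1_belief", "belief_rating"))
    fail(!df[[col]] %in% 1:6, paste(col, "outside 1..6"))
  for (col in c("real_recalled", "classified_correction", "fake_recalled"))
    fail(!df[[col]] %in% 0:1, paste(col, "not binary"))
  fail(df$fake_recalled == 1L & df$classified_correction == 0L,
       "fake_recalled without classified_correction")
  fail(df$fake_recalled == 1L & df$condition == "REP",
       "fake_recalled on a repetition trial")
  if ("response_category" %in% names(df)) {
    fail(!df$response_category %in% response_categories(), "unknown response_category")
    fail(df$response_category == "INTRUSION" & df$condition == "REP",
         "intrusion coded on a repetition trial")
    df$response_category <- factor(df$response_category, levels = response_categories())
  }
  df$condition <- factor(df$condition, levels = levels_ok)
  df
}
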