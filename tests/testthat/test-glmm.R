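# build a flat (no-heterogeneity) binary dataset with known cell
# probabilities, crossed participants and topics
flat_binary <- function(p_by_level, n_participants = 60, n_topics = 40,
                        seed = 42) {
  levels_ <- names(p_by_level)
  dat <- expand.grid(participant_id = seq_len(n_participants),
                     topic_id = seq_len(n_topics))
  dat$condition <- factor(levels_[1L + (dat$topic_id %% length(levels_))],
                          levels = levels_)
  local_seed_ <- function(expr) { set.seed(seed); expr }
  dat$y <- local_seed_(rbinom(nrow(dat), 1L, p_by_level[as.character(dat$condition)]))
  dat
}

test_that("with no heterogeneity, estimates match the pooled closed form", {
  dat <- flat_binary(c(low = 0.2, high = 0.8))
  est <- suppressWarnings(fit_binomial_mixed(dat, "y", fixed = "condition"))
  expect_equal(est$scale, "probability")
  pooled <- tapply(dat$y, dat$condition, mean)
  got <- setNames(est$estimates$estimate, est$estimates$condition)
  # recovery of the generating probabilities
  expect_lt(max(abs(got[names(pooled)] - c(0.2, 0.8))), 0.03)
  # agreement with the pooled-proportion closed form (random variances ~ 0)
  expect_lt(max(abs(got[names(pooled)] - pooled)), 1e-3)
  expect_true(all(est$estimates$ci_low < est$estimates$estimate &
                    est$estimates$estimate < est$estimates$ci_high))
})

test_that("complete separation is detected before fitting", {
  dat <- flat_binary(c(low = 0.3, high = 0.6))
  dat$y[dat$condition == "high"] <- 1L
  expect_error(fit_binomial_mixed(dat, "y"), "separation")
})

test_that("estimates are invariant to row order and id relabeling", {
  dat <- flat_binary(c(a = 0.3, b = 0.5, c = 0.7), n_participants = 30,
                     n_topics = 24)
  est1 <- suppressWarnings(fit_binomial_mixed(dat, "y"))
  shuffled <- dat[sample(nrow(dat)), ]
  shuffled$participant_id <- shuffled$participant_id + 1000L
  est2 <- suppressWarnings(fit_binomial_mixed(shuffled, "y"))
  expect_equal(est1$estimates$estimate, est2$estimates$estimate,
               tolerance = 1e-6)
})

test_that("gaussian fits reduce to cell means in the OLS limit", {
  dat <- expand.grid(participant_id = 1:40, topic_id = 1:10)
  dat$g <- factor(ifelse(dat$topic_id <= 5, "x", "y"))
  set.seed(1)
  dat$belief_rating <- pmin(6L, pmax(1L, round(ifelse(dat$g == "x", 3, 5) +
                                                 rnorm(nrow(dat), 0, 0.4))))
  est <- suppressWarnings(fit_gaussian_mixed(dat, fixed = "g"))
  cell_means <- tapply(dat$belief_rating, dat$g, mean)
  got <- setNames(est$estimates$estimate, est$estimates$g)
  expect_lt(max(abs(got[names(cell_means)] - cell_means)), 0.02)
  expect_equal(est$scale, "rating")
  # t statistics with finite dfs for the contrast
  expect_true(all(is.finite(est$contrasts$statistic)))
  expect_true(all(est$contrasts$df > 0))
})

test_that("fitted belief gaps match the threshold-model expectation", {
  cfg <- small_config(1, n_participants = 80, seed = 33,
                      sd_participant_belief = 0.1)
  cfg$belief_means["REAL_RECALL", ] <- 4.8
  cfg$belief_means["INTRUSION", ] <- 3.0
  tr <- simulate_dataset(cfg)
  sub <- tr$response_category %in% c("REAL_RECALL", "INTRUSION") &
    tr$condition != "REP"
  est <- suppressWarnings(
    fit_gaussian_mixed(tr[sub, ], fixed = "response_category"))
  got <- setNames(est$estimates$estimate, est$estimates$response_category)
  gap <- got[["REAL_RECALL"]] - got[["INTRUSION"]]
  oracle_gap <- expected_rating(4.8) - expected_rating(3.0)
  expect_lt(abs(gap - oracle_gap), 0.15)
  expect_lt(abs(oracle_gap - 1.8), 0.15)
  # belief accuracy: recalled real news is believed more than intrusions
  expect_gt(got[["REAL_RECALL"]], got[["INTRUSION"]])
})

test_that("conditional models reflect classification accuracy", {
  # with perfect classification of recollected trials, almost every trial in
  # an accurately-classified cell is recollected, so recall there approaches
  # 1 (the unclassified cells then contain no recalls at all, which is
  # exactly the separation the model-level check must flag)
  cfg <- small_config(1, n_participants = 48, seed = 21,
                      p_classify_given_recollect = 1,
                      p_classify_given_no_recollect = 0.02)
  tr <- code_trials(simulate_dataset(cfg))
  fn_rec <- tr$conditional_class == "CORR_FN_RECALLED" & !is.na(tr$conditional_class)
  expect_gt(mean(tr$real_recalled[fn_rec]), 0.9)
  expect_error(conditional_models(tr, "real_recalled"), "separation")

  est2 <- suppressWarnings(
    conditional_models(simulate_dataset(small_config(1, n_participants = 48,
                                                     seed = 22)),
                       "real_recalled"))
  cells2 <- est2$estimates
  by_class <- tapply(cells2$estimate, cells2$conditional_class, mean)
  expect_gt(by_class[["CORR_FN_RECALLED"]], by_class[["NOTCORR_FN_NOT_RECALLED"]])
})

test_that("conditional intrusion models drop the redundant cells", {
  tr <- code_trials(simulate_dataset(small_config(1, n_participants = 48,
                                                  seed = 3)))
  est <- suppressWarnings(conditional_models(tr, "intrusion"))
  expect_false("CORR_FN_RECALLED" %in% est$estimates$conditional_class)
  expect_equal(sort(unique(est$estimates$conditional_class)),
               c("CORR_FN_NOT_RECALLED", "NOTCORR_FN_NOT_RECALLED"))
})

test_that("empty design cells are flagged and excluded", {
  tr <- code_trials(simulate_dataset(small_config(1, n_participants = 40,
                                                  seed = 8)))
  drop <- tr$condition == "UC" & tr$conditional_class == "CORR_FN_RECALLED"
  est <- suppressWarnings(conditional_models(tr[!drop, ], "real_recalled"))
  expect_equal(est$empty_cells,
               data.frame(condition = "UC",
                          conditional_class = "CORR_FN_RECALLED"))
  expect_false(any(est$estimates$condition == "UC" &
                     est$estimates$conditional_class == "CORR_FN_RECALLED"))
})

test_that("multiplicity adjustment behaves as an adjustment should", {
  dat <- flat_binary(c(a = 0.45, b = 0.45, c = 0.7), n_participants = 40,
                     n_topics = 30, seed = 9)
  est <- suppressWarnings(fit_binomial_mixed(dat, "y", adjust = "none"))
  raw <- pairwise_contrasts(est, "none")
  tuk <- pairwise_contrasts(est, "tukey")
  hol <- pairwise_contrasts(est, "holm")
  expect_true(all(tuk$adjusted_p >= raw$adjusted_p - 1e-12))
  expect_true(all(hol$adjusted_p >= raw$adjusted_p - 1e-12))
  # monotone in the raw p values
  expect_false(is.unsorted(hol$adjusted_p[order(raw$adjusted_p)]))
  # two levels generated identically: small statistic, large adjusted p
  ab <- tuk[tuk$contrast == "a - b", ]
  expect_lt(abs(ab$statistic), 2.5)
  expect_gt(ab$adjusted_p, 0.05)
})
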