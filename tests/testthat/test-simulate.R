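test_that("default calibrations encode the published difference structure", {
  c1 <- default_config(1)
  expect_equal(unname(c1$r_by_condition["LC"] - c1$r_by_condition["UC"]), 0.15)
  expect_equal(unname(c1$r_by_condition["FRLC"] - c1$r_by_condition["LC"]), 0.11)
  expect_equal(unname(c1$f_by_condition["UC"] -
                        mean(c1$f_by_condition[c("LC", "FRLC")])), 0.18)
  expect_equal(c1$p_repetition_recall, 0.76)

  c2 <- default_config(2)
  expect_equal(unname(c2$r_by_condition["LFN"] - c2$r_by_condition["UC"]), 0.05)
  expect_equal(c2$p_repetition_recall, 0.70)
  # smallest reminder advantage across both experiments is 0.11
  adv <- c(c1$r_by_condition["FRLC"] - c1$r_by_condition[c("UC", "LC")],
           c2$r_by_condition["FRLC"] - c2$r_by_condition[c("UC", "LFN")])
  expect_equal(unname(min(adv)), 0.11)
})

test_that("invalid configurations are rejected", {
  cfg <- default_config(1)
  cfg$r_by_condition["UC"] <- 1.2
  expect_error(validate_config(cfg), "\\[0, 1\\]")
  cfg <- default_config(1)
  cfg$belief_cutpoints <- c(1.5, 2.5, 2.5, 4.5, 5.5)
  expect_error(validate_config(cfg), "strictly increasing")
  cfg <- default_config(2)
  names(cfg$f_by_condition) <- c("UC", "LC", "FRLC")  # LC is not an Exp-2 condition
  expect_error(validate_config(cfg), "correction conditions")
})

test_that("configurations round-trip through YAML and JSON", {
  cfg <- small_config(2, n_participants = 12)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_config(cfg, path)
    back <- read_config(path)
    expect_equal(back$r_by_condition, cfg$r_by_condition)
    expect_equal(back$belief_means, cfg$belief_means)
    expect_identical(simulate_dataset(back), simulate_dataset(cfg))
  }
})

test_that("simulated datasets have the right shape and are seed-deterministic", {
  cfg <- small_config(1, n_participants = 8)
  tr <- simulate_dataset(cfg)
  expect_equal(nrow(tr), 8L * 60L)
  expect_identical(tr, simulate_dataset(cfg))
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L
  expect_false(identical(tr$real_recalled, simulate_dataset(cfg2)$real_recalled))
  expect_true(all(table(tr$participant_id, tr$condition) == 15L))
})

test_that("structural invariants hold in every generated row", {
  for (experiment in 1:2) {
    tr <- simulate_dataset(small_config(experiment, n_participants = 30))
    expect_true(all(tr$fake_recalled <= tr$classified_correction))
    rep_rows <- tr$condition == "REP"
    expect_true(all(tr$fake_recalled[rep_rows] == 0L))
    expect_false(any(tr$response_category[rep_rows] == "INTRUSION"))
    for (col in c("phase1_familiarity", "phase1_belief", "belief_rating"))
      expect_true(all(tr[[col]] %in% 1:6))
    expect_true(all((tr$real_recalled == 1L) ==
                      (tr$response_category == "REAL_RECALL")))
  }
})

test_that("degenerate recollection/familiarity settings force their branches", {
  cfg <- small_config(1, n_participants = 6)
  cfg$r_by_condition[] <- 1
  tr <- simulate_dataset(cfg)
  expect_true(all(tr$real_recalled[tr$condition != "REP"] == 1L))

  cfg$r_by_condition[] <- 0
  cfg$f_by_condition[] <- 1
  cfg$sd_participant <- 0
  cfg$sd_item <- 0
  tr <- simulate_dataset(cfg)
  corr <- tr$condition != "REP"
  expect_true(all(tr$response_category[corr] == "INTRUSION"))
})

test_that("without heterogeneity, category frequencies converge to the tree", {
  cfg <- small_config(1, n_participants = 2000, seed = 7,
                      sd_participant = 0, sd_item = 0)
  tr <- simulate_dataset(cfg)
  for (cond in correction_conditions(1)) {
    r <- cfg$r_by_condition[cond]
    f <- cfg$f_by_condition[cond]
    freqs <- prop.table(table(tr$response_category[tr$condition == cond]))
    expect_lt(abs(freqs[["REAL_RECALL"]] - r), 0.01)
    expect_lt(abs(freqs[["INTRUSION"]] - (1 - r) * f), 0.01)
    expect_lt(abs(freqs[["OTHER"]] - (1 - r) * (1 - f)), 0.01)
  }
})

test_that("expected belief ratings are monotone in the latent mean", {
  base <- small_config(1, n_participants = 200, seed = 11)
  bumped <- base
  bumped$belief_means["INTRUSION", "UC"] <-
    base$belief_means["INTRUSION", "UC"] + 1
  mean_intrusion_rating <- function(cfg) {
    tr <- simulate_dataset(cfg)
    mean(tr$belief_rating[tr$condition == "UC" &
                            tr$response_category == "INTRUSION"])
  }
  expect_gt(mean_intrusion_rating(bumped), mean_intrusion_rating(base))
})

test_that("trial tables round-trip through CSV and the schema is enforced", {
  tr <- simulate_dataset(small_config(2, n_participants = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back, tr)

  bad <- tr
  bad$belief_rating[5L] <- 7L
  write_trials(bad, path)
  expect_error(read_trials(path), "belief_rating outside 1\\.\\.6.*row 5")

  bad <- tr
  row <- which(bad$classified_correction == 1L & bad$condition != "REP")[1L]
  bad$fake_recalled[row] <- 1L
  bad$classified_correction[row] <- 0L
  write_trials(bad, path)
  expect_error(read_trials(path), "fake_recalled without classified_correction")

  write.csv(tr[, -2], path, row.names = FALSE)
  expect_error(read_trials(path), "missing column")
})
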