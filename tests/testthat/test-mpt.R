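test_that("tree probabilities follow the dual-process structure", {
  expect_equal(category_probs(0.5, 0.4),
               c(P_real = 0.5, P_intrusion = 0.2, P_other = 0.3))
  expect_equal(unname(category_probs(1, 0.7)), c(1, 0, 0))
  expect_equal(unname(category_probs(0, 1)), c(0, 1, 0))

  grid <- expand.grid(r = seq(0, 1, length.out = 101),
                      f = seq(0, 1, length.out = 101))
  probs <- category_probs(grid$r, grid$f)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))
  expect_true(all(probs >= 0))
  # monotonicity: P_real increasing in r; P_intrusion increasing in f at fixed r
  r_grid <- seq(0, 1, length.out = 101)
  expect_true(all(diff(category_probs(r_grid, 0.3)[, "P_real"]) >= 0))
  expect_true(all(diff(category_probs(rep(0.3, 101), r_grid)[, "P_intrusion"]) >= 0))
})

test_that("the multinomial log-likelihood matches brute-force evaluation", {
  cnt <- function(a, b, c) data.frame(participant_id = 1L, condition = "UC",
                                      n_real = a, n_intrusion = b, n_other = c)
  params <- function(r, f) list(r = c(UC = r), f = c(UC = f))
  expect_equal(mpt_loglik(cnt(1, 0, 0), params(1, 0.5)), 0)
  expect_equal(mpt_loglik(cnt(0, 1, 0), params(1, 0.5)), -Inf)
  expect_equal(mpt_loglik(cnt(30, 12, 18), params(0.5, 0.4)),
               30 * log(0.5) + 12 * log(0.2) + 18 * log(0.3))
  # invariant to how counts are split across participants
  split_cnt <- rbind(cnt(10, 4, 6), cnt(20, 8, 12))
  split_cnt$participant_id <- 1:2
  expect_equal(mpt_loglik(split_cnt, params(0.5, 0.4)),
               mpt_loglik(cnt(30, 12, 18), params(0.5, 0.4)))
})

test_that("moment estimation exactly inverts the tree", {
  cnt <- data.frame(participant_id = 1L, condition = "UC",
                    n_real = 30L, n_intrusion = 12L, n_other = 18L)
  est <- moment_estimates(cnt)
  expect_equal(unname(est$r), 0.5)
  expect_equal(unname(est$f), 0.4)

  # exhaustive round trip over all count triples with n <= 12 (the
  # study-scale exhaustive check up to n = 30 runs in the acceptance suite)
  for (n in 1:12) {
    for (a in 0:(n - 1)) for (b in 0:(n - a)) {
      cc <- data.frame(participant_id = 1L, condition = "X",
                       n_real = a, n_intrusion = b, n_other = n - a - b)
      e <- moment_estimates(cc)
      expect_equal(unname(category_probs(unname(e$r), unname(e$f)) * n),
                   c(a, b, n - a - b))
    }
  }

  all_real <- data.frame(participant_id = 1L, condition = "UC",
                         n_real = 15L, n_intrusion = 0L, n_other = 0L)
  e <- moment_estimates(all_real)
  expect_false(e$f_defined)
  expect_true(is.na(e$f))
  none <- data.frame(participant_id = 1L, condition = "UC",
                     n_real = 0L, n_intrusion = 0L, n_other = 60L)
  e0 <- moment_estimates(none)
  expect_equal(unname(c(e0$r, e0$f)), c(0, 0))
})

test_that("the hierarchical fit is seeded, bounded, and diagnosed", {
  cfg <- small_config(1, n_participants = 30, seed = 9)
  counts <- tabulate_mpt(simulate_dataset(cfg))
  post <- fit_quick(counts, seed = 5)
  expect_s3_class(post, "mpt_posterior")
  expect_true(all(post$summary$mean >= 0 & post$summary$mean <= 1))
  expect_true(all(post$summary$ci_low <= post$summary$mean &
                    post$summary$mean <= post$summary$ci_high))
  expect_setequal(post$conditions, correction_conditions(1))
  expect_true(all(is.finite(post$diagnostics$rhat)))
  expect_true(all(post$diagnostics$ess > 0))

  post2 <- fit_quick(counts, seed = 5)
  expect_identical(post$draws, post2$draws)
  post3 <- fit_quick(counts, seed = 6)
  expect_false(identical(post$draws, post3$draws))
})

test_that("the fit rejects degenerate inputs and unknown conditions", {
  cnt1 <- data.frame(participant_id = 1L, condition = "UC",
                     n_real = 5L, n_intrusion = 5L, n_other = 5L)
  expect_error(fit_hierarchical(cnt1), "at least 2 participants")

  counts <- tabulate_mpt(simulate_dataset(small_config(1, n_participants = 20)))
  post <- fit_quick(counts)
  expect_error(credible_difference(post, "r", "LFN", "UC"), "unknown condition")
})

test_that("credible differences are draw-wise and self-consistent", {
  counts <- tabulate_mpt(simulate_dataset(small_config(1, n_participants = 30)))
  post <- fit_quick(counts)
  d_self <- credible_difference(post, "r", "UC", "UC")
  expect_equal(d_self$mean, 0)
  expect_false(d_self$credible)

  d <- credible_difference(post, "r", "FRLC", "UC")
  expect_equal(d$mean, mean(d$draws))
  expect_equal(d$credible, d$ci[1] > 0 || d$ci[2] < 0)
  # averaging comparator: UC vs mean of the others matches manual computation
  d_avg <- credible_difference(post, "f", "UC", c("LC", "FRLC"))
  i <- match(c("UC", "LC", "FRLC"), post$conditions)
  manual <- plogis(post$draws[, sprintf("mu_f[%d]", i[1])]) -
    (plogis(post$draws[, sprintf("mu_f[%d]", i[2])]) +
       plogis(post$draws[, sprintf("mu_f[%d]", i[3])])) / 2
  expect_equal(d_avg$mean, mean(manual))
})

test_that("an empty recovery request returns an empty report", {
  rep0 <- recover_parameters(small_config(1, n_participants = 10), 0L)
  expect_s3_class(rep0, "recovery_report")
  expect_equal(nrow(rep0), 0L)
  expect_length(attr(rep0, "failures"), 0L)
})
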