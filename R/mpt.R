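#' Category probabilities of the dual-process tree
#'
#' The processing tree behind Phase-3 cued recall of corrections assumes that
#' recalling the real-news detail requires recollection of the correction to
#' override the familiarity of the fake headline: with recollection
#' probability r and familiarity probability f,
#'
#' * P(real recall) = r
#' * P(intrusion)   = (1 - r) f
#' * P(other)       = (1 - r)(1 - f)
#'
#' The tree is saturated per condition (three categories, two parameters plus
#' the sum constraint), so it cannot show lack of fit; all inferential
#' content lies in the hierarchical structure over participants.
#'
#' @param r,f Recollection and familiarity probabilities (vectorized).
#' @return For scalar input a named numeric triple `(P_real, P_intrusion,
#'   P_other)`; for vector input a matrix with those columns. Rows always sum
#'   to 1.
#' @examples
#' category_probs(0.5, 0.4)  # 0.5, 0.2, 0.3
#' @export
category_probs <- function(r, f) {
  stopifnot(all(r >= 0 & r <= 1), all(f >= 0 & f <= 1))
  out <- cbind(P_real = r, P_intrusion = (1 - r) * f, P_other = (1 - r) * (1 - f))
  if (length(r) == 1L && length(f) == 1L) out[1L, ] else out
}

#' Multinomial log-likelihood of MPT counts
#'
#' Sum over participant x condition cells of the multinomial log-kernel
#' `sum(counts * log(category probability))`. Cells where a zero-probability
#' category has a positive count contribute `-Inf`; zero counts contribute
#' nothing regardless of the probability (0 log 0 = 0 convention).
#'
#' @param counts An `mpt_counts` data frame (or any data frame with
#'   `condition`, `n_real`, `n_intrusion`, `n_other`).
#' @param params Parameters per condition: either a list with named vectors
#'   `r` and `f` (names = condition codes) or a data frame with columns
#'   `condition`, `r`, `f`, e.g. the output of [moment_estimates()].
#' @return Log-likelihood value (may be `-Inf`).
#' @export
mpt_loglik <- function(counts, params) {
  if (!is.null(params$condition)) {
    idx <- match(counts$condition, params$condition)
    r <- params$r[idx]
    f <- params$f[idx]
  } else {
    r <- params$r[counts$condition]
    f <- params$f[counts$condition]
  }
  if (anyNA(r) || anyNA(f))
    stop("`params` must provide r and f for every condition in `counts`",
         call. = FALSE)
  probs <- category_probs(r, f)
  if (length(r) == 1L) probs <- matrix(probs, nrow = 1L)
  y <- as.matrix(counts[, c("n_real", "n_intrusion", "n_other")])
  terms <- y * log(probs)
  terms[y == 0] <- 0
  sum(terms)
}

#' Closed-form moment estimator of the tree parameters
#'
#' Inverts the tree at the pooled empirical category frequencies: with pooled
#' counts (n_real, n_intrusion, n_other) per condition and n their sum,
#' `r = n_real / n` and `f = n_intrusion / (n - n_real)`. This is the exact
#' inverse of [category_probs()] at the observed frequencies and serves as
#' the independent oracle for the hierarchical fit in the no-heterogeneity
#' limit. When every trial was a real recall (`n_real == n`) familiarity is
#' undefined and reported as `NA` with `f_defined = FALSE`.
#'
#' @param counts An `mpt_counts` data frame; counts are pooled within
#'   condition across participants.
#' @return Data frame with one row per condition: `condition`, `n`, `r`, `f`,
#'   `f_defined`. Also usable as `params` for [mpt_loglik()] via its named
#'   `r`/`f` columns.
#' @examples
#' cnt <- data.frame(participant_id = 1, condition = "UC",
#'                   n_real = 30, n_intrusion = 12, n_other = 18)
#' moment_estimates(cnt)  # r = 0.5, f = 0.4
#' @export
moment_estimates <- function(counts) {
  pooled <- rowsum(as.matrix(counts[, c("n_real", "n_intrusion", "n_other")]),
                   group = counts$condition)
  n <- rowSums(pooled)
  r <- pooled[, "n_real"] / n
  denom <- n - pooled[, "n_real"]
  f_defined <- denom > 0
  f <- ifelse(f_defined, pooled[, "n_intrusion"] / denom, NA_real_)
  out <- data.frame(condition = rownames(pooled), n = as.integer(n),
                    r = unname(r), f = unname(f),
                    f_defined = unname(f_defined), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# JAGS specification of the hierarchical logit-normal (latent-trait) MPT.
# Non-centered participant effects (delta = sigma * z) — the centered form
# mixes poorly for the dispersion parameters under weak per-cell
# information. The recollection and familiarity effects of a participant are
# correlated (rho): without this, participants who recollect often contribute
# few familiarity-informative trials while having atypical familiarity, and
# the familiarity locations are biased by that informative cluster size.
mpt_model_string <- function() {
"model {
  for (c in 1:C) {
    mu_r[c] ~ dnorm(0, mu_prec)
    mu_f[c] ~ dnorm(0, mu_prec)
  }
  sigma_r ~ dnorm(0, sigma_prec) T(0,)
  sigma_f ~ dnorm(0, sigma_prec) T(0,)
  rho ~ dunif(-1, 1)
  for (p in 1:P) {
    for (c in 1:C) {
      zr[p, c] ~ dnorm(0, 1)
      z2[p, c] ~ dnorm(0, 1)
      zf[p, c] <- rho * zr[p, c] + sqrt(1 - rho^2) * z2[p, c]
    }
  }
  for (i in 1:N) {
    r[i] <- ilogit(mu_r[cond[i]] + sigma_r * zr[pid[i], cond[i]])
    f[i] <- ilogit(mu_f[cond[i]] + sigma_f * zf[pid[i], cond[i]])
    pr[i, 1] <- r[i]
    pr[i, 2] <- (1 - r[i]) * f[i]
    pr[i, 3] <- (1 - r[i]) * (1 - f[i])
    y[i, 1:3] ~ dmulti(pr[i, 1:3], ntrials[i])
  }
}"
}

#' Fit the hierarchical Bayesian MPT
#'
#' Participant x condition count triples are multinomial with category
#' probabilities from [category_probs()] evaluated at
#' invlogit(mu_param\[c\] + delta_param\[p, c\]), where the group-level
#' locations mu are on the logit scale and the participant effects delta are
#' Normal(0, sigma_param^2) per parameter and condition, with the
#' recollection and familiarity effects of the same participant-condition
#' cell correlated (latent-trait correlation rho, shared across conditions).
#' The correlation matters for more than realism: the number of trials
#' informing a participant's familiarity is the number of non-recollected
#' trials, so when memory abilities covary, cluster size is informative and
#' an independence hierarchy biases the familiarity locations downward.
#' Priors are weakly informative: mu ~ Normal(0, `prior_mu_sd`^2)
#' (near-uniform on the probability scale at the default 1.5), sigma ~
#' Half-Normal(`prior_sigma_sd`), rho ~ Uniform(-1, 1). Sampling is MCMC via
#' JAGS with a non-centered parameterization; the population estimate
#' reported for each condition is the posterior mean of invlogit(mu), i.e.
#' the median-participant probability, matching the conditional
#' (random-effects-at-zero) convention of the mixed models.
#'
#' Convergence is checked with split-R-hat and effective sample size (coda);
#' the fit raises an error when any monitored R-hat exceeds `rhat_max`
#' (divergent-transition counts are a Hamiltonian-Monte-Carlo concept and
#' have no analogue under JAGS's conjugate/slice samplers).
#'
#' @param counts An `mpt_counts` data frame (>= 2 participants).
#' @param prior_mu_sd,prior_sigma_sd Prior scales (logit scale).
#' @param chains,draws Number of chains and post-warmup draws per chain.
#' @param adapt,warmup Adaptation and burn-in iterations.
#' @param seed Integer; chain RNGs are seeded deterministically from it.
#' @param rhat_max Convergence gate; set `Inf` to disable.
#' @return An `mpt_posterior` object: list with `summary` (per condition and
#'   parameter: posterior mean, 95% central credible interval),
#'   `draws` (matrix of monitored draws, all chains stacked), `chain` (chain
#'   index per draw), `conditions`, `diagnostics` (R-hat, ESS per monitored
#'   node), and the sampler settings.
#' @seealso [credible_difference()], [moment_estimates()]
#' @export
fit_hierarchical <- function(counts, prior_mu_sd = 1.5, prior_sigma_sd = 1,
                             chains = 4L, draws = 1000L, adapt = 1000L,
                             warmup = 1500L, seed = 1L, rhat_max = 1.05) {
  stopifnot(inherits(counts, "data.frame"))
  if (length(unique(counts$participant_id)) < 2L)
    stop("the hierarchical MPT needs at least 2 participants", call. = FALSE)
  conds <- if (!is.null(attr(counts, "experiment")) &&
               !is.na(attr(counts, "experiment")))
    correction_conditions(attr(counts, "experiment"))
  else sort(unique(counts$condition))
  cond_idx <- match(counts$condition, conds)
  if (anyNA(cond_idx)) stop("unknown condition code in `counts`", call. = FALSE)
  pid <- match(counts$participant_id, unique(counts$participant_id))
  y <- as.matrix(counts[, c("n_real", "n_intrusion", "n_other")])
  storage.mode(y) <- "integer"

  data <- list(C = length(conds), P = max(pid), N = nrow(y),
               cond = cond_idx, pid = pid, y = y, ntrials = rowSums(y),
               mu_prec = 1 / prior_mu_sd^2, sigma_prec = 1 / prior_sigma_sd^2)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) * 1000L + ch) %% .Machine$integer.max))

  jm <- rjags::jags.model(textConnection(mpt_model_string()), data = data,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  monitors <- c("mu_r", "mu_f", "sigma_r", "sigma_f", "rho")
  samp <- rjags::coda.samples(jm, monitors, n.iter = draws, progress.bar = "none")

  rhat <- if (chains > 1L)
    coda::gelman.diag(samp, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1L]
  else stats::setNames(rep(NA_real_, coda::nvar(samp)), coda::varnames(samp))
  ess <- coda::effectiveSize(samp)
  m <- as.matrix(samp)
  chain <- rep(seq_len(chains), each = draws)

  summary <- do.call(rbind, lapply(c(r = "mu_r", f = "mu_f"), function(node) {
    do.call(rbind, lapply(seq_along(conds), function(ci) {
      p <- invlogit(m[, sprintf("%s[%d]", node, ci)])
      data.frame(condition = conds[ci],
                 parameter = if (node == "mu_r") "r" else "f",
                 mean = mean(p),
                 ci_low = unname(stats::quantile(p, 0.025)),
                 ci_high = unname(stats::quantile(p, 0.975)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL

  post <- structure(
    list(summary = summary, draws = m, chain = chain, conditions = conds,
         diagnostics = list(rhat = rhat, ess = ess),
         sampler = list(chains = chains, draws = draws, adapt = adapt,
                        warmup = warmup, seed = as.integer(seed),
                        prior_mu_sd = prior_mu_sd,
                        prior_sigma_sd = prior_sigma_sd)),
    class = "mpt_posterior")

  if (is.finite(rhat_max) && chains > 1L && any(rhat > rhat_max, na.rm = TRUE)) {
    worst <- names(which.max(rhat))
    stop(sprintf(paste0("hierarchical MPT did not converge: split-R-hat %.3f ",
                        "for %s exceeds %.2f (increase warmup/draws); ",
                        "R-hat range [%.3f, %.3f], min ESS %.0f"),
                 max(rhat, na.rm = TRUE), worst, rhat_max,
                 min(rhat, na.rm = TRUE), max(rhat, na.rm = TRUE),
                 min(ess)), call. = FALSE)
  }
  post
}

#' @export
print.mpt_posterior <- function(x, ...) {
  cat(sprintf("Hierarchical MPT posterior (%d chains x %d draws, seed %d)\n",
              x$sampler$chains, x$sampler$draws, x$sampler$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s[%s] = %.3f [%.3f, %.3f]\n", s$parameter[i],
                s$condition[i], s$mean[i], s$ci_low[i], s$ci_high[i]))
  cat(sprintf("  max R-hat %.3f, min ESS %.0f\n",
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
              min(x$diagnostics$ess)))
  invisible(x)
}

#' Posterior difference between conditions on the probability scale
#'
#' Computes, draw by draw, invlogit(mu_param) for condition `cond_a` minus
#' the mean of invlogit(mu_param) over the conditions in `cond_b`, and
#' summarizes the posterior of that difference. A difference is flagged
#' *credible* when its 95% central credible interval excludes zero.
#'
#' @param post An `mpt_posterior`.
#' @param param `"r"` (recollection) or `"f"` (familiarity).
#' @param cond_a Single condition code.
#' @param cond_b One or more condition codes; with several, the comparison is
#'   against their draw-wise average (used for, e.g., familiarity of
#'   unlabeled corrections versus the mean of the other corrections).
#' @return List with `mean`, `ci` (length-2), `credible` (logical), `param`,
#'   `cond_a`, `cond_b`, and the draw vector `draws`.
#' @examples
#' \dontrun{
#' post <- fit_hierarchical(tabulate_mpt(simulate_dataset(default_config(1))))
#' credible_difference(post, "r", "LC", "UC")
#' }
#' @export
credible_difference <- function(post, param = c("r", "f"), cond_a, cond_b) {
  param <- match.arg(param)
  node <- if (param == "r") "mu_r" else "mu_f"
  idx_a <- match(cond_a, post$conditions)
  idx_b <- match(cond_b, post$conditions)
  if (anyNA(c(idx_a, idx_b)) || length(cond_a) != 1L)
    stop("unknown condition code(s) for this posterior", call. = FALSE)
  a <- invlogit(post$draws[, sprintf("%s[%d]", node, idx_a)])
  b <- rowMeans(invlogit(post$draws[, sprintf("%s[%d]", node, idx_b),
                                    drop = FALSE]))
  d <- a - b
  ci <- unname(stats::quantile(d, c(0.025, 0.975)))
  list(mean = mean(d), ci = ci, credible = ci[1L] > 0 || ci[2L] < 0,
       param = param, cond_a = cond_a, cond_b = cond_b, draws = d)
}

#' Parameter-recovery study for the hierarchical MPT
#'
#' Simulates `n_replicates` datasets from `config`, fits the hierarchical MPT
#' to each, and reports per condition and parameter the bias and RMSE of the
#' posterior-mean estimates around the generating values and the coverage of
#' the 95% credible intervals.
#'
#' @param config A `generator_config`; its `r_by_condition`/`f_by_condition`
#'   are the generating truths.
#' @param n_replicates Number of replicates (0 returns an empty report).
#' @param seed Base seed; replicate k simulates with `seed + k` and samples
#'   with an offset of that.
#' @param ... Sampler settings passed to [fit_hierarchical()] (e.g. `chains`,
#'   `draws`).
#' @return A `recovery_report` data frame: `condition`, `parameter`, `truth`,
#'   `mean_estimate`, `bias`, `rmse`, `coverage`, `n_replicates`; attribute
#'   `failures` records replicate indices whose fit raised, with the message.
#' @export
recover_parameters <- function(config, n_replicates, seed = 1L, ...) {
  validate_config(config)
  empty <- data.frame(condition = character(0), parameter = character(0),
                      truth = numeric(0), mean_estimate = numeric(0),
                      bias = numeric(0), rmse = numeric(0),
                      coverage = numeric(0), n_replicates = integer(0))
  if (n_replicates == 0L)
    return(structure(empty, failures = list(), class = c("recovery_report", "data.frame")))

  truths <- rbind(
    data.frame(condition = names(config$r_by_condition), parameter = "r",
               truth = unname(config$r_by_condition)),
    data.frame(condition = names(config$f_by_condition), parameter = "f",
               truth = unname(config$f_by_condition)))

  ests <- vector("list", n_replicates)
  failures <- list()
  for (k in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seed + k)
    res <- tryCatch({
      post <- fit_hierarchical(tabulate_mpt(simulate_dataset(cfg)),
                               seed = seed + k, ...)
      merge(post$summary, truths, by = c("condition", "parameter"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(replicate = k,
                                                message = conditionMessage(res))
    } else ests[[k]] <- res
  }
  ests <- do.call(rbind, ests)
  if (is.null(ests))
    stop("every recovery replicate failed; first failure: ",
         failures[[1L]]$message, call. = FALSE)

  agg <- do.call(rbind, lapply(split(ests, ests[, c("condition", "parameter")],
                                     drop = TRUE), function(g) {
    data.frame(condition = g$condition[1L], parameter = g$parameter[1L],
               truth = g$truth[1L], mean_estimate = mean(g$mean),
               bias = mean(g$mean - g$truth),
               rmse = sqrt(mean((g$mean - g$truth)^2)),
               coverage = mean(g$ci_low <= g$truth & g$truth <= g$ci_high),
               n_replicates = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(agg, failures = failures,
            class = c("recovery_report", "data.frame"))
}

#' Serialize a recovery report to JSON
#'
#' @param report A `recovery_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recovery <- function(report, path) {
  jsonlite::write_json(
    list(report = as.data.frame(report), failures = attr(report, "failures")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
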