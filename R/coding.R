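#' Code Phase-3 responses into the three response categories
#'
#' Maps trial outcomes to `REAL_RECALL` / `INTRUSION` / `OTHER`. A trial is
#' `REAL_RECALL` iff the real-news detail was recalled. Distinguishing
#' `INTRUSION` from `OTHER` among recall failures requires knowing whether the
#' fake detail was produced as the answer; on simulated data that is the
#' generator's `response_category` flag, and on scored exports of real data it
#' is the precoded `response_category` column accepted by [read_trials()]
#' (free-text scoring is outside this package). Repetition trials have no
#' fake counterpart and are never intrusions.
#'
#' @param trials Trial data frame containing `real_recalled`, `condition` and
#'   a `response_category` column.
#' @return Factor of response categories, one per row, with the input's
#'   consistency validated (recall flag agreeing with the category;
#'   no repetition intrusions).
#' @export
code_category <- function(trials) {
  if (is.null(trials$response_category))
    stop("`trials` must carry a response_category column (generator flag or ",
         "precoded scoring); free-text scoring is out of scope", call. = FALSE)
  cat <- factor(as.character(trials$response_category),
                levels = response_categories())
  if (anyNA(cat))
    stop("unknown response_category value", call. = FALSE)
  if (any((trials$real_recalled == 1L) != (cat == "REAL_RECALL")))
    stop("response_category inconsistent with real_recalled", call. = FALSE)
  if (any(cat == "INTRUSION" & trials$condition == "REP"))
    stop("repetition trials can never be intrusions", call. = FALSE)
  cat
}

#' Cross-classify correction trials by classification and fake recall
#'
#' Assigns each correction-condition trial to one of the three conditional
#' classes used by the conditional recall/intrusion and belief analyses:
#' `CORR_FN_RECALLED` (classified as a correction and the fake detail
#' recalled), `CORR_FN_NOT_RECALLED` (classified, fake detail not recalled),
#' `NOTCORR_FN_NOT_RECALLED` (not classified, so the fake-recall prompt never
#' appeared). The classes are undefined for repetition trials: passing any
#' raises an error.
#'
#' @param trials Trial data frame restricted to correction conditions.
#' @return Factor of conditional classes, one per row.
#' @export
conditional_class <- function(trials) {
  if (any(trials$condition == "REP"))
    stop("conditional classes are undefined for repetition trials", call. = FALSE)
  out <- ifelse(trials$classified_correction == 0L, "NOTCORR_FN_NOT_RECALLED",
                ifelse(trials$fake_recalled == 1L, "CORR_FN_RECALLED",
                       "CORR_FN_NOT_RECALLED"))
  factor(out, levels = conditional_classes())
}

#' Add coded-category columns to a trial table
#'
#' Convenience wrapper: validates/attaches `response_category` via
#' [code_category()] and adds `conditional_class` (NA on repetition trials).
#'
#' @param trials Trial data frame.
#' @return The input with validated `response_category` and a
#'   `conditional_class` column.
#' @export
code_trials <- function(trials) {
  trials$response_category <- code_category(trials)
  cc <- factor(rep(NA_character_, nrow(trials)), levels = conditional_classes())
  corr <- trials$condition != "REP"
  cc[corr] <- conditional_class(trials[corr, , drop = FALSE])
  trials$conditional_class <- cc
  trials
}

#' Tabulate MPT category counts
#'
#' Aggregates coded correction trials into the per-participant, per-condition
#' 3-category count table the hierarchical MPT consumes: `n_real`
#' (`REAL_RECALL`), `n_intrusion` (`INTRUSION`) and `n_other`, which sum to
#' the participant's number of trials in that condition (15 at the full
#' design). Repetition trials are excluded; they do not enter the tree.
#'
#' @param trials Trial data frame with a `response_category` column.
#' @return An `mpt_counts` data frame with columns `participant_id`,
#'   `condition`, `n_real`, `n_intrusion`, `n_other` and attribute
#'   `experiment`.
#' @examples
#' counts <- tabulate_mpt(simulate_dataset(default_config(1)))
#' head(counts)
#' @export
tabulate_mpt <- function(trials) {
  trials$response_category <- code_category(trials)
  corr <- trials[trials$condition != "REP", , drop = FALSE]
  corr$condition <- droplevels(corr$condition)
  tab <- as.data.frame(table(participant_id = corr$participant_id,
                             condition = corr$condition,
                             category = corr$response_category))
  wide <- stats::reshape(tab, idvar = c("participant_id", "condition"),
                         timevar = "category", direction = "wide")
  names(wide) <- sub("^Freq\\.", "", names(wide))
  out <- data.frame(
    participant_id = as.integer(as.character(wide$participant_id)),
    condition = as.character(wide$condition),
    n_real = wide$REAL_RECALL,
    n_intrusion = wide$INTRUSION,
    n_other = wide$OTHER,
    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, match(out$condition, levels(corr$condition))), ]
  rownames(out) <- NULL
  exp <- unique(trials$experiment)
  structure(out, experiment = if (length(exp) == 1L) as.integer(exp) else NA_integer_,
            class = c("mpt_counts", "data.frame"))
}

#' Write or read an MPT count table
#'
#' @param counts An `mpt_counts` data frame.
#' @param path CSV path.
#' @param experiment Experiment number used to re-attach the attribute on read
#'   (inferred from the condition codes when omitted).
#' @return `write_mpt_counts()` returns `path` invisibly; `read_mpt_counts()`
#'   the `mpt_counts` data frame.
#' @export
write_mpt_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mpt_counts
#' @export
read_mpt_counts <- function(path, experiment = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "n_real", "n_intrusion", "n_other")
  if (!all(need %in% names(df)))
    stop("malformed MPT count file: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(experiment))
    experiment <- if ("LFN" %in% df$condition) 2L else 1L
  structure(df, experiment = as.integer(experiment),
            class = c("mpt_counts", "data.frame"))
}
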