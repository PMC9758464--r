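#' Headline-type conditions
#'
#' The paradigm manipulates, within participants, how a news topic is treated
#' across the three phases. Conditions are identified throughout the package
#' by short codes:
#'
#' * `REP`  - Repetition: real news in Phase 1, repeated verbatim in Phase 2.
#' * `UC`   - Unlabeled Correction: fake news in Phase 1, corrected without a
#'   veracity label in Phase 2.
#' * `LC`   - Labeled Correction (Experiment 1 only): the Phase-2 correction
#'   carries a veracity label.
#' * `LFN`  - Labeled Fake News (Experiment 2 only): the Phase-1 fake headline
#'   is labeled false on its debut; its Phase-2 correction is unlabeled.
#' * `FRLC` - Fake News Reminder + Labeled Correction: the fake headline is
#'   shown again immediately before its labeled Phase-2 correction.
#'
#' @param experiment Integer, 1 or 2.
#' @return `condition_levels()` returns the four condition codes of the
#'   experiment in canonical order (`REP` first); `correction_conditions()`
#'   returns the three non-repetition (correction) codes.
#' @examples
#' condition_levels(1)
#' correction_conditions(2)
#' @export
condition_levels <- function(experiment) {
  check_experiment(experiment)
  if (experiment == 1L) c("REP", "UC", "LC", "FRLC") else c("REP", "UC", "LFN", "FRLC")
}

#' @rdname condition_levels
#' @export
correction_conditions <- function(experiment) {
  setdiff(condition_levels(experiment), "REP")
}

#' Long condition labels
#'
#' @return Named character vector mapping short codes to descriptive labels.
#' @export
condition_labels <- function() {
  c(REP  = "Repetition",
    UC   = "Unlabeled Correction",
    LC   = "Labeled Correction",
    LFN  = "Labeled Fake News",
    FRLC = "Fake News Reminder + Labeled Correction")
}

#' Response categories of the Phase-3 cued-recall test
#'
#' Every Phase-3 trial is coded into exactly one of three categories:
#' `REAL_RECALL` (the Phase-2 real-news detail was produced), `INTRUSION`
#' (the Phase-1 fake detail was produced instead), or `OTHER` (anything
#' else, including omissions). Repetition trials have no fake counterpart
#' and therefore can never be intrusions.
#'
#' @return Character vector of the category codes.
#' @export
response_categories <- function() c("REAL_RECALL", "INTRUSION", "OTHER")

#' Conditional classification classes
#'
#' Correction trials are cross-classified by whether the participant
#' classified the topic as corrected and, if so, whether the fake-news detail
#' was recalled: `CORR_FN_RECALLED` (classified as a correction, fake detail
#' recalled), `CORR_FN_NOT_RECALLED` (classified, fake detail not recalled),
#' `NOTCORR_FN_NOT_RECALLED` (not classified; the fake-recall prompt never
#' appears). Undefined for repetition trials.
#'
#' @return Character vector of the class codes.
#' @export
conditional_classes <- function() {
  c("CORR_FN_RECALLED", "CORR_FN_NOT_RECALLED", "NOTCORR_FN_NOT_RECALLED")
}

check_experiment <- function(experiment) {
  if (length(experiment) != 1L || !experiment %in% c(1L, 2L))
    stop("`experiment` must be 1 or 2", call. = FALSE)
  invisible(as.integer(experiment))
}

# probability -> logit and back; kept as thin aliases so intent reads clearly
logit <- function(p) stats::qlogis(p)
invlogit <- function(x) stats::plogis(x)
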