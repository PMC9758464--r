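#' Build a counterbalanced list design
#'
#' Constructs the assignment of the 60 headline topics to the four
#' within-participant headline-type conditions and the constrained
#' presentation orders for the three phases.
#'
#' Topics are partitioned into four fixed sets of 15 (1-15, 16-30, 31-45,
#' 46-60) and rotated through the conditions by a Latin square over
#' `counterbalance_index`, so that across the four indices every topic serves
#' every condition exactly once. Phase orders are fixed random permutations
#' subject to two constraints: no more than three consecutive topics from the
#' same condition, and the mean list position of each condition within 2
#' positions of the grand mean (30.5 for 60 items), to control serial-position
#' effects. Orders are found by rejection sampling with local swap repair of
#' over-long runs, restarting up to `max_restarts` times.
#'
#' Phase 1 presents the repetition topics as real news and the other 45 as
#' fake news. Fake-news reminders in Phase 2 are treated as an attribute of
#' `FRLC` trials (the reminder immediately precedes the correction and shares
#' its list position), not as separate order slots.
#'
#' @param experiment Integer, 1 or 2 (determines the condition set).
#' @param counterbalance_index Integer 0-3 selecting the Latin-square rotation.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param max_restarts Maximum order-sampling restarts per phase before
#'   signalling an impossible constraint configuration.
#' @return An object of class `design_list`: a list with elements
#'   `experiment`, `counterbalance_index`, `topic_ids`, `condition_of` (named
#'   character vector, topic -> condition code), `phase1_order`,
#'   `phase2_order`, `phase3_order` (permutations of topic ids in
#'   presentation sequence), and `phase1_veracity` (named, topic ->
#'   `"real"`/`"fake"`).
#' @seealso [validate_design()], [mean_positions()], [write_design()]
#' @examples
#' d <- build_design(1, 0, seed = 7)
#' table(d$condition_of)
#' @export
build_design <- function(experiment, counterbalance_index, seed,
                         max_restarts = 10000L) {
  experiment <- check_experiment(experiment)
  if (length(counterbalance_index) != 1L || !counterbalance_index %in% 0:3)
    stop("`counterbalance_index` must be an integer in 0..3", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L)

  conds <- condition_levels(experiment)
  non_rep <- correction_conditions(experiment)
  topic_ids <- 1:60
  sets <- split(topic_ids, rep(1:4, each = 15))
  # Latin square: set s gets condition (s - 1 + cb) mod 4
  condition_of <- character(60)
  for (s in 1:4) {
    condition_of[sets[[s]]] <- conds[((s - 1L + counterbalance_index) %% 4L) + 1L]
  }
  names(condition_of) <- topic_ids

  phase1_veracity <- ifelse(condition_of == "REP", "real", "fake")
  names(phase1_veracity) <- topic_ids

  orders <- local_seed(seed, {
    lapply(1:3, function(phase) {
      constrained_order(condition_of, max_restarts = max_restarts)
    })
  })

  structure(
    list(experiment = experiment,
         counterbalance_index = as.integer(counterbalance_index),
         topic_ids = topic_ids,
         condition_of = condition_of,
         phase1_order = orders[[1L]],
         phase2_order = orders[[2L]],
         phase3_order = orders[[3L]],
         phase1_veracity = phase1_veracity),
    class = "design_list")
}

# Draw one presentation order satisfying the run-length and position-balance
# constraints. Rejection sampling; runs longer than 3 are first repaired by
# swapping a run member with a randomly chosen position outside the run.
constrained_order <- function(condition_of, max_run = 3L, balance_tol = 2.0,
                              max_restarts = 10000L) {
  n <- length(condition_of)
  topic_ids <- as.integer(names(condition_of))
  for (restart in seq_len(max_restarts)) {
    ord <- sample(topic_ids)
    for (rep_i in 1:50) {
      runs <- rle(unname(condition_of[as.character(ord)]))
      if (max(runs$lengths) <= max_run) break
      ends <- cumsum(runs$lengths)
      bad <- which(runs$lengths > max_run)[1L]
      pos <- ends[bad]                      # last element of the offending run
      other <- sample(setdiff(seq_len(n), pos), 1L)
      ord[c(pos, other)] <- ord[c(other, pos)]
    }
    if (order_satisfies(ord, condition_of, max_run, balance_tol)) return(ord)
  }
  stop("could not generate a presentation order satisfying the run-length ",
       "and position-balance constraints after ", max_restarts, " restarts",
       call. = FALSE)
}

order_satisfies <- function(ord, condition_of, max_run = 3L, balance_tol = 2.0) {
  conds_seq <- unname(condition_of[as.character(ord)])
  if (max(rle(conds_seq)$lengths) > max_run) return(FALSE)
  pos_means <- tapply(seq_along(ord), conds_seq, mean)
  all(abs(pos_means - mean(seq_along(ord))) <= balance_tol)
}

#' Validate a list design
#'
#' Checks a `design_list` against the structural invariants of the paradigm
#' and returns a report of violations (an empty character vector when valid):
#' 60 topics; exactly 15 per condition; the condition set matching the
#' experiment; 15 real and 45 fake Phase-1 headlines; each phase order a
#' permutation of the topics; no run of more than 3 consecutive same-condition
#' topics; and per-condition mean list position within 2 of the grand mean.
#'
#' @param d A `design_list`.
#' @return Character vector naming each violated invariant once.
#' @export
validate_design <- function(d) {
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  if (length(d$topic_ids) != 60L || anyDuplicated(d$topic_ids))
    note("topics: expected 60 distinct topic ids")
  tab <- table(d$condition_of)
  if (!all(tab == 15L))
    note("set sizes: expected exactly 15 topics per condition")
  if (!setequal(names(tab), condition_levels(d$experiment)))
    note(sprintf("condition set: expected {%s} for experiment %d",
                 paste(condition_levels(d$experiment), collapse = ", "),
                 d$experiment))
  ver <- table(factor(d$phase1_veracity, levels = c("real", "fake")))
  if (ver[["real"]] != 15L || ver[["fake"]] != 45L)
    note("phase-1 veracity: expected 15 real and 45 fake headlines")
  if (any(d$phase1_veracity[d$condition_of == "REP"] != "real"))
    note("phase-1 veracity: repetition topics must be real news")

  for (phase in 1:3) {
    ord <- d[[paste0("phase", phase, "_order")]]
    if (!setequal(ord, d$topic_ids) || length(ord) != length(d$topic_ids)) {
      note(sprintf("phase-%d order: not a permutation of the topics", phase))
      next
    }
    conds_seq <- unname(d$condition_of[as.character(ord)])
    if (max(rle(conds_seq)$lengths) > 3L)
      note(sprintf("phase-%d order: run of more than 3 consecutive same-condition topics", phase))
    if (any(abs(mean_positions(d, phase) - mean(seq_along(ord))) > 2.0))
      note(sprintf("phase-%d order: per-condition mean position deviates from the grand mean by more than 2", phase))
  }
  bad
}

#' Per-condition mean list positions
#'
#' The mean presentation position of each condition's topics in one phase
#' order. For a balanced 60-item order the grand mean is 30.5; the design
#' generator keeps every condition mean within 2 positions of it.
#'
#' @param d A `design_list`.
#' @param phase Integer 1, 2 or 3.
#' @return Named numeric vector of mean positions, one per condition.
#' @export
mean_positions <- function(d, phase) {
  stopifnot(phase %in% 1:3)
  ord <- d[[paste0("phase", phase, "_order")]]
  conds_seq <- unname(d$condition_of[as.character(ord)])
  tapply(seq_along(ord), conds_seq, mean)
}

#' @export
print.design_list <- function(x, ...) {
  cat(sprintf("Counterbalanced list design (experiment %d, list %d)\n",
              x$experiment, x$counterbalance_index))
  cat(sprintf("  %d topics, conditions: %s\n", length(x$topic_ids),
              paste(sprintf("%s=%d", names(table(x$condition_of)),
                            table(x$condition_of)), collapse = " ")))
  for (phase in 1:3) {
    mp <- mean_positions(x, phase)
    cat(sprintf("  phase %d mean positions: %s\n", phase,
                paste(sprintf("%s=%.1f", names(mp), mp), collapse = " ")))
  }
  invisible(x)
}

#' Tidy data-frame view of a design
#'
#' @param x A `design_list`.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return A data frame with one row per topic: `topic_id`, `condition`,
#'   `phase1_pos`, `phase2_pos`, `phase3_pos`, `phase1_veracity`.
#' @export
as.data.frame.design_list <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    topic_id = x$topic_ids,
    condition = unname(x$condition_of),
    phase1_pos = match(x$topic_ids, x$phase1_order),
    phase2_pos = match(x$topic_ids, x$phase2_order),
    phase3_pos = match(x$topic_ids, x$phase3_order),
    phase1_veracity = unname(x$phase1_veracity),
    stringsAsFactors = FALSE)
}

#' Serialize a design to JSON or CSV
#'
#' JSON keeps the list structure (keys `experiment`, `counterbalance_index`,
#' `topics`, `conditions`, `orders`, `phase1_veracity`); CSV writes the tidy
#' per-topic table of [as.data.frame.design_list()].
#'
#' @param d A `design_list`.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`; defaults from the path extension.
#' @return `path`, invisibly.
#' @export
write_design <- function(d, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "csv") {
    utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(experiment = d$experiment,
           counterbalance_index = d$counterbalance_index,
           topics = d$topic_ids,
           conditions = as.list(d$condition_of),
           orders = list(phase1 = d$phase1_order, phase2 = d$phase2_order,
                         phase3 = d$phase3_order),
           phase1_veracity = as.list(d$phase1_veracity)),
      path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
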