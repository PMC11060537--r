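# ---- design constants -------------------------------------------------------

#' FT-IRAP trial types
#'
#' The four sample-by-valence pairings presented by the task. The order used
#' here is the canonical reporting order and is preserved by every function in
#' the package that returns one value per trial type.
#'
#' @format Character vector of length 4.
#' @export
TRIAL_TYPES <- c("expect-positive", "expect-negative",
                 "dont-expect-positive", "dont-expect-negative")

#' Block-level feedback thresholds shown to participants
#'
#' Stored as design metadata: a mean latency target (ms) and a minimum
#' accuracy per block. They are displayed as feedback during the task and are
#' not enforced at schedule-generation time; the related participant-level
#' exclusion rule lives in [apply_exclusions()].
#'
#' @format Named list with `mean_rt_ms` (2000) and `accuracy` (0.80).
#' @export
FEEDBACK_THRESHOLDS <- list(mean_rt_ms = 2000, accuracy = 0.80)

#' Construct a validated FT-IRAP stimulus set
#'
#' A stimulus set consists of the two sample phrases ("I expect" /
#' "I don't expect") and six positive plus six negative single-word future
#' outcomes. Each block presents every target twice, once under each sample.
#'
#' @param samples Character vector of length 2: the expect and don't-expect
#'   sample phrases.
#' @param positive_targets Character vector of 6 distinct positive outcome
#'   words.
#' @param negative_targets Character vector of 6 distinct negative outcome
#'   words.
#' @return An object of class `"ftirap_stimuli"`: a list with elements
#'   `samples`, `positive_targets`, `negative_targets`.
#' @examples
#' stim <- ftirap_stimuli()
#' stim$positive_targets
#' @export
ftirap_stimuli <- function(samples = c("I expect", "I don't expect"),
                           positive_targets = c("friendship", "enjoyment",
                                                "happiness", "wealth",
                                                "success", "love"),
                           negative_targets = c("worry", "loneliness",
                                                "failure", "stress",
                                                "sadness", "illness")) {
  if (length(samples) != 2L || anyDuplicated(samples))
    stop("'samples' must be 2 distinct label strings", call. = FALSE)
  if (length(positive_targets) != 6L || length(negative_targets) != 6L)
    stop("stimulus set needs exactly 6 positive and 6 negative targets",
         call. = FALSE)
  targets <- c(positive_targets, negative_targets)
  if (anyDuplicated(targets))
    stop("target words must all be distinct", call. = FALSE)
  structure(list(samples = samples,
                 positive_targets = positive_targets,
                 negative_targets = negative_targets),
            class = "ftirap_stimuli")
}

# condition of block i when block 1 has condition `first`
.block_condition <- function(index, first) {
  other <- if (first == "consistent") "inconsistent" else "consistent"
  ifelse(index %% 2L == 1L, first, other)
}

.match_condition <- function(x) {
  out <- match.arg(tolower(as.character(x)), c("consistent", "inconsistent"),
                   several.ok = TRUE)
  out
}

#' Required response under a block condition
#'
#' Consistent blocks demand the optimistic pattern: affirm expecting positive
#' outcomes and affirm not expecting negative ones (expect-positive -> TRUE,
#' expect-negative -> FALSE, dont-expect-positive -> FALSE,
#' dont-expect-negative -> TRUE). Inconsistent blocks demand the converse,
#' pessimistic, pattern.
#'
#' @param trial_type Character vector of trial types (see [TRIAL_TYPES]).
#' @param condition `"consistent"` or `"inconsistent"` (recycled).
#' @return Logical vector: `TRUE` means the correct key is "true".
#' @examples
#' correct_response("expect-positive", "consistent")     # TRUE
#' correct_response("dont-expect-negative", "consistent") # TRUE
#' @export
correct_response <- function(trial_type, condition) {
  idx <- match(trial_type, TRIAL_TYPES)
  if (anyNA(idx)) stop("unknown trial type: ",
                       paste(unique(trial_type[is.na(idx)]), collapse = ", "),
                       call. = FALSE)
  condition <- match(condition, c("consistent", "inconsistent"))
  if (anyNA(condition)) stop("condition must be consistent or inconsistent",
                             call. = FALSE)
  consistent_truth <- c(TRUE, FALSE, FALSE, TRUE)[idx]
  ifelse(condition == 1L, consistent_truth, !consistent_truth)
}

# one 24-trial block: 6 per trial type, every target twice (once per sample)
.block_trials <- function(stimuli) {
  pos <- stimuli$positive_targets
  neg <- stimuli$negative_targets
  data.frame(
    trial_type = rep(TRIAL_TYPES, each = 6L),
    sample = rep(stimuli$samples, each = 12L),
    target = c(pos, neg, pos, neg),
    stringsAsFactors = FALSE)
}

#' Build an FT-IRAP block schedule
#'
#' Generates the four test blocks of one FT-IRAP administration (24 trials
#' each: 6 per trial type, every target twice), with conditions strictly
#' alternating from `first_block_condition` and trial order shuffled within
#' each block by the seed. Optionally prepends two practice blocks with the
#' same 24-trial structure, flagged `practice = TRUE`; practice blocks mirror
#' the first two test-block conditions.
#'
#' @param stimuli An [ftirap_stimuli()] object.
#' @param first_block_condition Condition of the first (practice and test)
#'   block; counterbalance across participants at the call site.
#' @param seed Integer seed controlling the within-block shuffles.
#' @param include_practice Prepend two flagged practice blocks?
#' @return A data.frame with columns `block_index`, `condition`,
#'   `trial_index`, `trial_type`, `sample`, `target`, `correct_response`,
#'   `practice`. Practice blocks have `block_index` 0 and -1 is not used;
#'   they are numbered 1..2 with `practice = TRUE`, test blocks 1..4 with
#'   `practice = FALSE`.
#' @examples
#' sched <- ftirap_schedule(seed = 1)
#' table(sched$condition, sched$block_index)
#' @export
ftirap_schedule <- function(stimuli = ftirap_stimuli(),
                            first_block_condition = c("consistent",
                                                      "inconsistent"),
                            seed = 1L,
                            include_practice = FALSE) {
  if (!inherits(stimuli, "ftirap_stimuli"))
    stimuli <- do.call(ftirap_stimuli, stimuli)
  first <- match.arg(first_block_condition)
  base <- .block_trials(stimuli)
  rng <- .new_rng(seed)
  build <- function(n_blocks, practice) {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      ord <- .rng_shuffle(rng, nrow(base))
      out <- base[ord, , drop = FALSE]
      out$block_index <- b
      out$condition <- .block_condition(b, first)
      out$trial_index <- seq_len(nrow(base))
      out$practice <- practice
      out
    })
    do.call(rbind, blocks)
  }
  sched <- if (include_practice) rbind(build(2L, TRUE), build(4L, FALSE))
           else build(4L, FALSE)
  sched$correct_response <- correct_response(sched$trial_type,
                                             sched$condition)
  rownames(sched) <- NULL
  sched[, c("block_index", "condition", "trial_index", "trial_type",
            "sample", "target", "correct_response", "practice")]
}

#' Build a PST or neutral-imagery cue schedule
#'
#' Both imagery tasks present 5 practice cues followed by a main block of 30
#' trials: 10 cue words, each shown three times in a seeded random order, with
#' a nominal 15 s imagery period per cue.
#'
#' @param kind `"pst"` (positive simulation training) or `"neutral"`.
#' @param seed Integer seed for the cue order.
#' @param cues Optional character vector of exactly 10 cue words; defaults to
#'   built-in cue lists for each kind.
#' @return Data.frame with columns `trial_index`, `cue`, `practice`,
#'   `duration_s` (all 15).
#' @examples
#' sched <- imagery_schedule("pst", seed = 3)
#' table(sched$cue[!sched$practice])
#' @export
imagery_schedule <- function(kind = c("pst", "neutral"), seed = 1L,
                             cues = NULL) {
  kind <- match.arg(kind)
  if (is.null(cues)) {
    cues <- if (kind == "pst")
      c("family", "proud", "holiday", "celebrate", "friends",
        "achievement", "laughter", "relaxed", "surprise", "adventure")
    else
      c("a loaded fruit bowl", "the baggage claim area at an airport",
        "a slowly rotating ceiling fan", "a row of shampoo bottles",
        "a supermarket checkout queue", "clouds forming in the sky",
        "a lorry on a motorway", "an office photocopier",
        "raindrops on a window", "a kettle coming to the boil")
  }
  if (length(cues) != 10L || anyDuplicated(cues))
    stop("'cues' must be 10 distinct cue strings", call. = FALSE)
  rng <- .new_rng(seed)
  practice <- cues[.rng_shuffle(rng, 10L)][1:5]
  main <- rep(cues, times = 3L)
  main <- main[.rng_shuffle(rng, 30L)]
  data.frame(trial_index = seq_len(35L),
             cue = c(practice, main),
             practice = rep(c(TRUE, FALSE), c(5L, 30L)),
             duration_s = 15,
             stringsAsFactors = FALSE)
}
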