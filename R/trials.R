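# Cross-situational learning events: two word forms, two referents, one true
# mapping per trial, with prosodic / gestural / distributional cue markup.

#' Define a training condition
#'
#' A condition fixes the per-trial presence probability of each cue plus the
#' training bounds. Intrinsic cues (prosody, gesture) double the activation
#' of the target form or referent; the extrinsic distributional cue activates
#' the unit coding the target's category.
#'
#' @param name Condition label.
#' @param p_distributional,p_prosody,p_gesture Per-trial presence
#'   probabilities, each in \[0, 1\].
#' @param max_epochs Epoch cap; runs that never reach criterion are censored
#'   here (default 100000).
#' @param criterion_run Number of consecutive perfect epochs that define the
#'   learning criterion (default 5).
#' @return A `"condition_config"` list.
#' @export
condition_config <- function(name, p_distributional, p_prosody, p_gesture,
                             max_epochs = 100000L, criterion_run = 5L) {
  p <- c(p_distributional, p_prosody, p_gesture)
  if (any(p < 0) || any(p > 1)) stop("cue probabilities must lie in [0, 1]")
  structure(list(name = as.character(name),
                 p_distributional = p_distributional,
                 p_prosody = p_prosody,
                 p_gesture = p_gesture,
                 max_epochs = as.integer(max_epochs),
                 criterion_run = as.integer(criterion_run)),
            class = "condition_config")
}

#' The eight standard cue-reliability conditions
#'
#' The full grid: a no-cue baseline, the three single fully reliable cues,
#' and four combined-cue conditions in which all three cues appear
#' independently with reliability 0.25, 0.50, 0.75 or 1.00.
#'
#' @param max_epochs,criterion_run Passed to every [condition_config()].
#' @return Named list of eight `"condition_config"` objects.
#' @export
cue_conditions <- function(max_epochs = 100000L, criterion_run = 5L) {
  grid <- list(
    no_cue        = c(0, 0, 0),
    dist_cue      = c(1, 0, 0),
    prosodic_cue  = c(0, 1, 0),
    gestural_cue  = c(0, 0, 1),
    combined_0.25 = c(0.25, 0.25, 0.25),
    combined_0.50 = c(0.50, 0.50, 0.50),
    combined_0.75 = c(0.75, 0.75, 0.75),
    combined_1.00 = c(1, 1, 1))
  out <- lapply(names(grid), function(nm) {
    p <- grid[[nm]]
    condition_config(nm, p[1], p[2], p[3], max_epochs, criterion_run)
  })
  names(out) <- names(grid)
  out
}

#' Sample cue presence flags for one trial
#'
#' Each cue is present independently with its condition probability
#' (Bernoulli draws from the current RNG stream).
#'
#' @param condition A `"condition_config"`.
#' @return Logical vector `c(prosody, gesture, distributional)`.
#' @export
sample_cue_flags <- function(condition) {
  c(prosody = stats::runif(1) < condition$p_prosody,
    gesture = stats::runif(1) < condition$p_gesture,
    distributional = stats::runif(1) < condition$p_distributional)
}

#' Sample one cross-situational learning trial
#'
#' The target word's form goes to a random word slot and its referent to a
#' random object slot; a foil form and a foil referent are drawn
#' independently and uniformly from the other words (so they may or may not
#' come from the same foil word), and cue flags are drawn per
#' [sample_cue_flags()].
#'
#' @param lexicon A `"lexicon"`.
#' @param condition A `"condition_config"`.
#' @param target_index Index of the target word (1-based).
#' @return A `"trial_spec"` list with fields `target`, `foil_form`,
#'   `foil_referent` (word indices), `target_form_slot` and
#'   `target_object_slot` (1 or 2), and logical `prosody`, `gesture`,
#'   `distributional`.
#' @export
sample_trial <- function(lexicon, condition, target_index) {
  n <- lexicon$n_words
  stopifnot(target_index >= 1L, target_index <= n)
  others <- if (n == 2L) rep(setdiff(1:2, target_index), 2L) else
    sample(seq_len(n)[-target_index], 2L, replace = TRUE)
  flags <- sample_cue_flags(condition)
  structure(list(target = as.integer(target_index),
                 foil_form = as.integer(others[1L]),
                 foil_referent = as.integer(others[2L]),
                 target_form_slot = sample.int(2L, 1L),
                 target_object_slot = sample.int(2L, 1L),
                 prosody = unname(flags["prosody"]),
                 gesture = unname(flags["gesture"]),
                 distributional = unname(flags["distributional"])),
            class = "trial_spec")
}

#' Assemble the network input for a trial
#'
#' Places the target form in its slot and the foil form in the other, and
#' likewise the referents. A prosodic cue doubles the activation of the
#' target form's entries; a gestural cue doubles the target referent's
#' entries; the distributional cue activates the unit matching the target's
#' category (unit 1 for `"A"`, unit 2 for `"B"`), otherwise both units are 0.
#' Foil-slot activations are never modified.
#'
#' @param trial A `"trial_spec"`.
#' @param lexicon The `"lexicon"` the trial indexes into.
#' @return An `"input_vector"`: list with `phonology` (length 40), `visual`
#'   (length 40) and `distributional` (length 2).
#' @export
assemble_input <- function(trial, lexicon) {
  tform <- lexicon$forms[trial$target, ]
  tref <- lexicon$referents[trial$target, ]
  fform <- lexicon$forms[trial$foil_form, ]
  fref <- lexicon$referents[trial$foil_referent, ]
  if (isTRUE(trial$prosody)) tform <- 2 * tform
  if (isTRUE(trial$gesture)) tref <- 2 * tref

  phon <- numeric(40L)
  vis <- numeric(40L)
  fslot <- trial$target_form_slot
  oslot <- trial$target_object_slot
  phon[.slot_idx(fslot)] <- tform
  phon[.slot_idx(3L - fslot)] <- fform
  vis[.slot_idx(oslot)] <- tref
  vis[.slot_idx(3L - oslot)] <- fref

  dist <- numeric(2L)
  if (isTRUE(trial$distributional))
    dist[if (lexicon$category[trial$target] == "A") 1L else 2L] <- 1
  structure(list(phonology = phon, visual = vis, distributional = dist),
            class = "input_vector")
}

.slot_idx <- function(slot) ((slot - 1L) * 20L + 1L):(slot * 20L)

#' Build a deterministic cue-free test input
#'
#' Used by the robustness test: the same slot-placement logic as
#' [assemble_input()], with all three cues switched off. Fully determined by
#' its arguments.
#'
#' @param target_index,foil_form_index,foil_referent_index Word indices;
#'   foils must differ from the target.
#' @param form_slot,object_slot Slot (1 or 2) holding the target form and
#'   the target referent.
#' @param lexicon The `"lexicon"`.
#' @return An `"input_vector"` with binary entries and `distributional`
#'   equal to `c(0, 0)`.
#' @export
make_test_input <- function(target_index, foil_form_index,
                            foil_referent_index, form_slot, object_slot,
                            lexicon) {
  stopifnot(foil_form_index != target_index,
            foil_referent_index != target_index)
  trial <- structure(list(target = as.integer(target_index),
                          foil_form = as.integer(foil_form_index),
                          foil_referent = as.integer(foil_referent_index),
                          target_form_slot = as.integer(form_slot),
                          target_object_slot = as.integer(object_slot),
                          prosody = FALSE, gesture = FALSE,
                          distributional = FALSE),
                     class = "trial_spec")
  assemble_input(trial, lexicon)
}

#' Flatten an input vector for the network
#'
#' Concatenates phonology (40), visual (40) and distributional (2) channels
#' into the length-82 vector the input layer receives.
#'
#' @param x An `"input_vector"`.
#' @return Numeric vector of length 82.
#' @export
as_network_input <- function(x) {
  stopifnot(inherits(x, "input_vector"))
  c(x$phonology, x$visual, x$distributional)
}

#' Dump a trial and its assembled input as JSON
#'
#' Debug helper: renders the trial spec fields together with the assembled
#' input channels.
#'
#' @param trial A `"trial_spec"`.
#' @param lexicon The `"lexicon"`.
#' @return JSON string (invisibly printed with `cat` when interactive use
#'   captures it).
#' @export
dump_trial <- function(trial, lexicon) {
  x <- assemble_input(trial, lexicon)
  as.character(jsonlite::toJSON(
    list(spec = unclass(trial),
         input = list(phonology = x$phonology, visual = x$visual,
                      distributional = x$distributional)),
    auto_unbox = TRUE))
}
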