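# Experiment harness: epochs, the learning criterion, cue-free robustness
# testing, replicates, and the matched-training control.

#' Classify a forward trace
#'
#' The model is correct on a trial iff the semantic unit of the target word
#' is strictly more active than every other semantic unit at the final time
#' step. Ties count as incorrect.
#'
#' @param trace An `"activation_trace"` from [net_forward()].
#' @param target_index 1-based index of the target word / semantic unit.
#' @return Logical scalar.
#' @export
classify_output <- function(trace, target_index) {
  out <- trace$semantic[, ncol(trace$semantic)]
  all(out[target_index] > out[-target_index])
}

#' Derive the per-replicate seed bundle
#'
#' All randomness in a replicate flows from four seeds derived from the
#' master seed by a fixed counter scheme, so the pseudopattern lexicon, the
#' starting weights, the training-trial stream and the robustness
#' evaluation are independently reproducible. Replicates share their
#' lexicon and weight seeds across conditions, which makes the replicate a
#' within-subject unit for the condition comparisons.
#'
#' @param master_seed Integer master seed.
#' @param replicate_id 1-based replicate number.
#' @return List of integer seeds: `lexicon`, `weights`, `stream`, `eval`.
#' @export
replicate_seeds <- function(master_seed, replicate_id) {
  base <- (abs(as.numeric(master_seed)) + 104729 * replicate_id) %% 2147483000
  list(lexicon = as.integer(base + 1),
       weights = as.integer(base + 2),
       stream = as.integer(base + 3),
       eval = as.integer(base + 4))
}

#' Sample all trials of one training epoch
#'
#' Each word of the lexicon occurs exactly once as target, in a fresh random
#' order; foils, slot assignments and cue flags are drawn per trial via
#' [sample_trial()].
#'
#' @param lexicon A `"lexicon"`.
#' @param condition A `"condition_config"`.
#' @return Integer matrix with one row per trial and columns `target`,
#'   `foil_form`, `foil_referent`, `form_slot`, `object_slot`, `prosody`,
#'   `gesture`, `distributional`.
#' @export
sample_epoch_trials <- function(lexicon, condition) {
  n <- lexicon$n_words
  perm <- sample.int(n)
  m <- matrix(0L, nrow = n, ncol = 8L,
              dimnames = list(NULL, c("target", "foil_form", "foil_referent",
                                      "form_slot", "object_slot", "prosody",
                                      "gesture", "distributional")))
  for (i in seq_len(n)) {
    tr <- sample_trial(lexicon, condition, perm[i])
    m[i, ] <- c(tr$target, tr$foil_form, tr$foil_referent,
                tr$target_form_slot, tr$target_object_slot,
                as.integer(tr$prosody), as.integer(tr$gesture),
                as.integer(tr$distributional))
  }
  m
}

#' Train for one epoch
#'
#' Iterates over a random permutation of all words, building one
#' cross-situational trial per word and applying one online BPTT update per
#' trial. Accuracy is the proportion of the epoch's own trials classified
#' correctly on the forward pass *before* that trial's update.
#'
#' @param w `"network_weights"`.
#' @param lexicon A `"lexicon"`.
#' @param condition A `"condition_config"`.
#' @param hp `"net_hyperparameters"`; `hp$n_semantic` must equal the lexicon
#'   size.
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference path built
#'   from [net_forward()], [bptt_gradients()] and [sgd_update()]); both
#'   consume the identical trial stream and produce the same numbers.
#' @return List with updated `weights`, scalar `accuracy`, and the logical
#'   per-trial `correct` vector.
#' @export
run_epoch <- function(w, lexicon, condition, hp,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  trials <- sample_epoch_trials(lexicon, condition)
  if (engine == "cpp") {
    res <- cpp_run_trials(w, trials, lexicon$forms, lexicon$referents,
                          as.integer(lexicon$category == "A"),
                          hp$timesteps, hp$error_window,
                          hp$learning_rate, TRUE)
    weights <- structure(res[c("W_in", "W_hh", "W_hs", "b_h", "b_s")],
                         class = "network_weights")
    correct <- res$correct
  } else {
    correct <- logical(nrow(trials))
    for (i in seq_len(nrow(trials))) {
      spec <- .row_to_trial(trials[i, ])
      x <- assemble_input(spec, lexicon)
      tr <- net_forward(w, x, hp)
      correct[i] <- classify_output(tr, spec$target)
      target <- numeric(hp$n_semantic)
      target[spec$target] <- 1
      g <- bptt_gradients(w, x, target, hp)
      w <- sgd_update(w, g, hp$learning_rate)
    }
    weights <- w
  }
  list(weights = weights, accuracy = mean(correct), correct = correct)
}

.row_to_trial <- function(row) {
  structure(list(target = row[["target"]],
                 foil_form = row[["foil_form"]],
                 foil_referent = row[["foil_referent"]],
                 target_form_slot = row[["form_slot"]],
                 target_object_slot = row[["object_slot"]],
                 prosody = row[["prosody"]] == 1L,
                 gesture = row[["gesture"]] == 1L,
                 distributional = row[["distributional"]] == 1L),
            class = "trial_spec")
}

#' Find the epoch at which the learning criterion is met
#'
#' The criterion is `criterion_run` consecutive epochs with accuracy exactly
#' 1 (every word classified correctly); the time-to-criterion is the first
#' epoch of the first such run.
#'
#' @param accuracy_by_epoch Numeric vector of per-epoch accuracies.
#' @param criterion_run Required run length (default 5).
#' @return 1-based epoch index, or `NA_integer_` when censored (no
#'   qualifying run).
#' @export
detect_criterion <- function(accuracy_by_epoch, criterion_run = 5L) {
  stopifnot(criterion_run >= 1L)
  perfect <- accuracy_by_epoch == 1
  run <- 0L
  for (i in seq_along(perfect)) {
    run <- if (perfect[i]) run + 1L else 0L
    if (run == criterion_run) return(i - criterion_run + 1L)
  }
  NA_integer_
}

#' Cue-free robustness test
#'
#' Measures post-training accuracy with every cue withheld: for each word,
#' `repeats_per_word` test inputs are built with random foils and slots
#' drawn from a dedicated evaluation seed, and classified without any weight
#' update. The RNG state of the caller is left untouched.
#'
#' @param w Trained `"network_weights"`.
#' @param lexicon The `"lexicon"` the model was trained on.
#' @param hp `"net_hyperparameters"`.
#' @param eval_seed Integer seed fixing the test foils and slots.
#' @param repeats_per_word Test trials per word (default 10).
#' @param engine `"cpp"` or `"r"`.
#' @return Proportion of test trials classified correctly.
#' @export
robustness_test <- function(w, lexicon, hp, eval_seed,
                            repeats_per_word = 10L,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(eval_seed))
  no_cue <- condition_config("test", 0, 0, 0)
  n <- lexicon$n_words
  trials <- matrix(0L, nrow = n * repeats_per_word, ncol = 8L)
  k <- 0L
  for (word in seq_len(n)) {
    for (r in seq_len(repeats_per_word)) {
      tr <- sample_trial(lexicon, no_cue, word)
      k <- k + 1L
      trials[k, ] <- c(tr$target, tr$foil_form, tr$foil_referent,
                       tr$target_form_slot, tr$target_object_slot,
                       0L, 0L, 0L)
    }
  }
  if (engine == "cpp") {
    res <- cpp_run_trials(w, trials, lexicon$forms, lexicon$referents,
                          as.integer(lexicon$category == "A"),
                          hp$timesteps, hp$error_window, 0, FALSE)
    mean(res$correct)
  } else {
    correct <- logical(nrow(trials))
    for (i in seq_len(nrow(trials))) {
      spec <- .row_to_trial(stats::setNames(
        trials[i, ], c("target", "foil_form", "foil_referent", "form_slot",
                       "object_slot", "prosody", "gesture",
                       "distributional")))
      tr <- net_forward(w, assemble_input(spec, lexicon), hp)
      correct[i] <- classify_output(tr, spec$target)
    }
    mean(correct)
  }
}

#' Run one condition across replicates
#'
#' Each replicate builds a fresh lexicon, fresh starting weights and a fresh
#' trial stream from its [replicate_seeds()] bundle, trains online epoch by
#' epoch, stops once the criterion run is confirmed (or at the epoch cap),
#' and finishes with the cue-free [robustness_test()]. Replicates that never
#' reach criterion are censored at the cap.
#'
#' @param condition A `"condition_config"`.
#' @param n_replicates Number of model replicates (default 20).
#' @param hp `"net_hyperparameters"` with `n_semantic` equal to `n_words`.
#' @param master_seed Master seed for the whole run.
#' @param n_words Lexicon size (default `hp$n_semantic`).
#' @param repeats_per_word Robustness test repeats (default 10).
#' @param verbose Print per-replicate progress.
#' @return List of `"run_record"`s, each with `replicate_id`, `condition`,
#'   `accuracy_by_epoch`, `epochs_to_criterion` (`NA` when censored),
#'   `censored`, `epochs_run`, `robustness_accuracy` and `seeds`.
#' @export
run_condition <- function(condition, n_replicates = 20L, hp, master_seed,
                          n_words = hp$n_semantic, repeats_per_word = 10L,
                          verbose = FALSE) {
  stopifnot(n_replicates >= 1L, hp$n_semantic == n_words)
  lapply(seq_len(n_replicates), function(rep_id) {
    rec <- .train_replicate(condition, hp, master_seed, rep_id, n_words,
                            total_epochs = NULL,
                            repeats_per_word = repeats_per_word)
    if (verbose)
      message(sprintf("%s replicate %d: %s after %d epochs, robustness %.3f",
                      condition$name, rep_id,
                      if (rec$censored) "censored" else
                        paste0("criterion at ", rec$epochs_to_criterion),
                      rec$epochs_run, rec$robustness_accuracy))
    rec
  })
}

#' Matched-training control
#'
#' Ignores the criterion stop: every replicate of every condition trains for
#' exactly `total_epochs` epochs before the cue-free robustness test,
#' equating the amount of training across conditions.
#'
#' @param conditions List of `"condition_config"`s.
#' @param total_epochs Fixed number of training epochs for every run.
#' @inheritParams run_condition
#' @return Named list (by condition) of lists of `"run_record"`s.
#' @export
run_matched_training <- function(conditions, total_epochs, n_replicates = 20L,
                                 hp, master_seed,
                                 n_words = hp$n_semantic,
                                 repeats_per_word = 10L) {
  stopifnot(total_epochs >= 0L)
  out <- lapply(conditions, function(cond) {
    lapply(seq_len(n_replicates), function(rep_id)
      .train_replicate(cond, hp, master_seed, rep_id, n_words,
                       total_epochs = total_epochs,
                       repeats_per_word = repeats_per_word))
  })
  names(out) <- vapply(conditions, `[[`, "", "name")
  out
}

# Shared trainer for the criterion-stopped and matched-training regimes.
.train_replicate <- function(condition, hp, master_seed, rep_id, n_words,
                             total_epochs, repeats_per_word) {
  seeds <- replicate_seeds(master_seed, rep_id)
  lexicon <- build_lexicon(n_words, seed = seeds$lexicon)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seeds$weights)
  w <- init_weights(hp)

  set.seed(seeds$stream)
  cap <- if (is.null(total_epochs)) condition$max_epochs else
    as.integer(total_epochs)
  acc <- numeric(cap)
  run <- 0L
  epochs_run <- 0L
  for (epoch in seq_len(cap)) {
    res <- run_epoch(w, lexicon, condition, hp)
    w <- res$weights
    acc[epoch] <- res$accuracy
    epochs_run <- epoch
    run <- if (res$accuracy == 1) run + 1L else 0L
    if (is.null(total_epochs) && run == condition$criterion_run) break
  }
  acc <- acc[seq_len(epochs_run)]

  crit <- detect_criterion(acc, condition$criterion_run)
  structure(list(replicate_id = rep_id,
                 condition = condition$name,
                 accuracy_by_epoch = acc,
                 epochs_to_criterion = crit,
                 censored = is.na(crit),
                 epochs_run = epochs_run,
                 robustness_accuracy = robustness_test(
                   w, lexicon, hp, seeds$eval,
                   repeats_per_word = repeats_per_word),
                 seeds = seeds,
                 weights = w),
            class = "run_record")
}

#' Tabulate an outcome across conditions for analysis
#'
#' Builds the replicates x conditions matrix the repeated-measures analyses
#' consume. For `"epochs_to_criterion"`, censored replicates enter at the
#' condition's epoch cap.
#'
#' @param records Named list (by condition) of lists of `"run_record"`s.
#' @param measure `"epochs_to_criterion"` or `"robustness_accuracy"`.
#' @param cap Cap value substituted for censored times (default: the
#'   maximum `epochs_run` observed, which equals the configured cap for
#'   censored runs).
#' @return Numeric matrix, rows = replicates, columns = conditions.
#' @export
outcome_table <- function(records,
                          measure = c("epochs_to_criterion",
                                      "robustness_accuracy"),
                          cap = NULL) {
  measure <- match.arg(measure)
  cols <- lapply(records, function(recs) {
    vapply(recs, function(r) {
      v <- r[[measure]]
      if (measure == "epochs_to_criterion" && is.na(v))
        v <- if (is.null(cap)) r$epochs_run else cap
      as.numeric(v)
    }, numeric(1))
  })
  do.call(cbind, cols)
}
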