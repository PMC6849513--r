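mk_trace <- function(out) structure(list(semantic = matrix(out, ncol = 1)),
                                    class = "activation_trace")

test_that("classify_output requires a strict maximum on the target unit", {
  expect_true(classify_output(mk_trace(c(0.9, 0.3, 0.2)), 1L))
  expect_false(classify_output(mk_trace(c(0.5, 0.5, 0.2)), 1L))  # tie
  expect_false(classify_output(mk_trace(rep(0.4, 5)), 2L))       # uniform
  # only the final step counts
  tr <- structure(list(semantic = cbind(c(1, 0), c(0.2, 0.6))),
                  class = "activation_trace")
  expect_false(classify_output(tr, 1L))
  expect_true(classify_output(tr, 2L))
})

test_that("detect_criterion finds the first qualifying run", {
  expect_equal(detect_criterion(c(.8, 1, 1, 1, 1, 1), 5L), 2L)
  expect_equal(detect_criterion(rep(1, 5), 5L), 1L)
  expect_true(is.na(detect_criterion(c(1, 1, 1, 1, .99, 1, 1, 1, 1), 5L)))
  expect_true(is.na(detect_criterion(numeric(0), 5L)))
  expect_equal(detect_criterion(c(0, 0, 1), 1L), 3L)
  expect_error(detect_criterion(c(1, 1), 0L))
})

test_that("run_epoch visits every word once and starts at chance", {
  lex <- build_lexicon(40L, seed = 7L)
  hp <- net_hyperparameters(n_hidden = 20L, n_semantic = 40L)
  cond <- condition_config("c", 0.5, 0.5, 0.5)
  accs <- vapply(1:5, function(s) {
    set.seed(200 + s)
    w <- init_weights(hp)
    res <- run_epoch(w, lex, cond, hp)
    expect_length(res$correct, 40L)
    res$accuracy
  }, numeric(1))
  expect_true(all(accs < 0.10))  # chance is 1/40 for an untrained net

  set.seed(3)
  t1 <- sample_epoch_trials(lex, cond)
  t2 <- sample_epoch_trials(lex, cond)
  expect_equal(sort(t1[, "target"]), 1:40)
  expect_equal(sort(t2[, "target"]), 1:40)
  expect_false(identical(t1[, "target"], t2[, "target"]))
})

test_that("robustness_test is deterministic, cue-free and at chance untrained", {
  lex <- tiny_lexicon(n_words = 10L)
  hp <- tiny_hp(n_words = 10L)
  accs <- vapply(1:5, function(s) {
    set.seed(300 + s)
    w <- init_weights(hp)
    robustness_test(w, lex, hp, eval_seed = 42L, repeats_per_word = 10L)
  }, numeric(1))
  expect_true(mean(accs) < 0.25)  # chance is 1/10 per trial

  set.seed(400)
  w <- init_weights(hp)
  set.seed(12345)  # caller RNG must not influence or be consumed
  before <- .Random.seed
  r1 <- robustness_test(w, lex, hp, eval_seed = 9L)
  expect_identical(.Random.seed, before)
  r2 <- robustness_test(w, lex, hp, eval_seed = 9L)
  expect_equal(r1, r2)
})

test_that("run_condition produces reproducible, correctly censored records", {
  hp <- tiny_hp(n_words = 10L, n_hidden = 8L, lr = 0.05)
  cond <- condition_config("c", 0.5, 0.5, 0.5, max_epochs = 3L)
  recs <- run_condition(cond, n_replicates = 2L, hp = hp, master_seed = 11L,
                        n_words = 10L)
  expect_length(recs, 2L)
  # impossible criterion within 3 epochs: all censored at the cap
  for (r in recs) {
    expect_true(r$censored)
    expect_equal(r$epochs_run, 3L)
    expect_length(r$accuracy_by_epoch, 3L)
  }
  # distinct seed bundles per replicate
  expect_false(identical(recs[[1]]$seeds, recs[[2]]$seeds))

  again <- run_condition(cond, n_replicates = 2L, hp = hp,
                         master_seed = 11L, n_words = 10L)
  for (i in 1:2) {
    expect_identical(recs[[i]]$accuracy_by_epoch,
                     again[[i]]$accuracy_by_epoch)
    expect_identical(recs[[i]]$robustness_accuracy,
                     again[[i]]$robustness_accuracy)
  }
})

test_that("run_condition stops right after the criterion run is confirmed", {
  hp <- tiny_hp(n_words = 10L, n_hidden = 10L, lr = 0.2)
  cond <- condition_config("easy", 1, 1, 1, max_epochs = 2000L,
                           criterion_run = 5L)
  rec <- run_condition(cond, n_replicates = 1L, hp = hp, master_seed = 2L,
                       n_words = 10L)[[1]]
  expect_false(rec$censored)
  expect_equal(rec$epochs_run, rec$epochs_to_criterion + 4L)
  expect_true(all(rec$accuracy_by_epoch[rec$epochs_to_criterion +
                                          0:4] == 1))
})

test_that("matched training equates epochs and reproduces exactly", {
  hp <- tiny_hp(n_words = 10L, n_hidden = 8L, lr = 0.1)
  conds <- list(condition_config("a", 0, 0, 0),
                condition_config("b", 1, 1, 1))
  recs <- run_matched_training(conds, total_epochs = 4L, n_replicates = 2L,
                               hp = hp, master_seed = 5L, n_words = 10L)
  expect_named(recs, c("a", "b"))
  for (cond in recs) for (r in cond) expect_equal(r$epochs_run, 4L)

  again <- run_matched_training(conds, total_epochs = 4L, n_replicates = 2L,
                                hp = hp, master_seed = 5L, n_words = 10L)
  expect_equal(recs$a[[1]]$robustness_accuracy,
               again$a[[1]]$robustness_accuracy)

  # zero training epochs: robustness at chance
  zero <- run_matched_training(conds[1], total_epochs = 0L,
                               n_replicates = 2L, hp = hp, master_seed = 5L,
                               n_words = 10L)
  for (r in zero[[1]]) expect_lt(r$robustness_accuracy, 0.3)
})

test_that("outcome_table substitutes the cap for censored replicates", {
  hp <- tiny_hp(n_words = 10L, n_hidden = 8L, lr = 0.05)
  cond <- condition_config("c", 0, 0, 0, max_epochs = 3L)
  recs <- list(c = run_condition(cond, n_replicates = 2L, hp = hp,
                                 master_seed = 1L, n_words = 10L))
  tab <- outcome_table(recs, "epochs_to_criterion")
  expect_equal(dim(tab), c(2L, 1L))
  expect_true(all(tab == 3))
  rob <- outcome_table(recs, "robustness_accuracy")
  expect_true(all(rob >= 0 & rob <= 1))
})

test_that("training accuracy trends upward over a run", {
  hp <- tiny_hp(n_words = 10L, n_hidden = 10L, lr = 0.2)
  for (p in list(c(0, 0, 0), c(1, 1, 1))) {
    cond <- condition_config("c", p[1], p[2], p[3], max_epochs = 300L)
    rec <- run_condition(cond, n_replicates = 1L, hp = hp, master_seed = 8L,
                         n_words = 10L)[[1]]
    acc <- rec$accuracy_by_epoch
    n10 <- max(1L, length(acc) %/% 10L)
    expect_gte(mean(utils::tail(acc, n10)), mean(utils::head(acc, n10)))
  }
})
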