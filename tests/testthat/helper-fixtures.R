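# Shared fixtures: everything is generated in code under fixed seeds.

tiny_lexicon <- function(n_words = 10L, seed = 101L) {
  build_lexicon(n_words, seed = seed)
}

tiny_hp <- function(n_words = 10L, n_hidden = 7L, lr = 0.1) {
  net_hyperparameters(n_hidden = n_hidden, n_semantic = n_words,
                      learning_rate = lr)
}

# A small random network for gradient work, detached from the lexicon task.
tiny_net <- function(seed, n_input = 5L, n_hidden = 3L, n_semantic = 2L) {
  set.seed(seed)
  hp <- net_hyperparameters(n_input = n_input, n_hidden = n_hidden,
                            n_semantic = n_semantic)
  list(hp = hp, w = init_weights(hp),
       x = runif(n_input, 0, 2),
       target = as.numeric(seq_len(n_semantic) ==
                             sample.int(n_semantic, 1L)))
}

# Build a trial_spec directly, bypassing sampling.
fixed_trial <- function(target, foil_form, foil_referent, form_slot = 1L,
                        object_slot = 1L, prosody = FALSE, gesture = FALSE,
                        distributional = FALSE) {
  structure(list(target = as.integer(target),
                 foil_form = as.integer(foil_form),
                 foil_referent = as.integer(foil_referent),
                 target_form_slot = as.integer(form_slot),
                 target_object_slot = as.integer(object_slot),
                 prosody = prosody, gesture = gesture,
                 distributional = distributional),
            class = "trial_spec")
}
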