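# Embedding-shift-only dataset shared across the classifier tests: the class
# signal lives purely in the indel-region embeddings, invisible to the
# zero-shot probability scores.
shift_data <- local({
  spec <- synthetic_spec(seed = 202, embed_dim = 16L, effect_size = 0,
                         embedding_shift = 1.5)
  ds <- generate_labeled_dataset(spec, 240)
  sa <- assign_splits(ds$records, ds$clusters, seed = 3)
  split_of <- sa$assignment[ds$records$variant_id]
  list(ds = ds, split_of = split_of)
})

bundles_for <- function(model_id, subset = NULL) {
  idx <- if (is.null(subset)) seq_along(shift_data$ds$variants) else
    which(shift_data$split_of == subset)
  build_feature_set(shift_data$ds$variants[idx], shift_data$ds$provider,
                    model_id)
}

test_that("feature bundles follow the four model configurations", {
  pc <- synthetic_provider(synthetic_spec(seed = 1, embed_dim = 3L, constant = 4))
  v <- protein_variant("v", "ACDEF", "ACEF")
  b1 <- build_features(v, pc, 1L)
  expect_equal(b1$wt_repr, rep(4, 3))
  expect_equal(b1$mut_repr, rep(4, 3))
  expect_null(b1$indel_repr)
  expect_length(b1$scalars, 0)

  # D = 2 toy with explicit embeddings, deletion of wt position 2
  toy <- protein_variant("t", "ACD", "AD")
  emb <- fixed_provider(
    obs = list(),
    embeds = list("ACD" = matrix(c(1, 0, 9, 9, 5, 4), 3, 2, byrow = TRUE),
                  "AD" = matrix(c(1, 0, 5, 4), 2, 2, byrow = TRUE)),
    embed_dim = 2L)
  b4 <- build_features(toy, emb, 4L)
  expect_equal(b4$wt_repr, c(3, 2))       # mean of rows 1 and 3
  expect_equal(b4$indel_repr, c(9, 9))    # the deleted residue's row
  expect_equal(b4$mut_repr, c(3, 2))
  expect_equal(unname(b4$scalars), c(0, 1))  # deletion, length 1

  ins <- protein_variant("i", "ACEF", "ACWYEF")
  b3 <- build_features(ins, synthetic_provider(synthetic_spec(seed = 2)), 3L)
  expect_equal(unname(b3$scalars[c("indel_type", "indel_length")]), c(1, 2))
  expect_true("indellm_score" %in% names(b3$scalars))
  b2 <- build_features(ins, synthetic_provider(synthetic_spec(seed = 2)), 2L,
                       indellm_score = -1.25)
  expect_equal(unname(b2$scalars), -1.25)
  expect_length(build_features(ins, synthetic_provider(synthetic_spec(seed = 2)),
                               4L)$scalars, 2)  # no probability score in model 4
})

test_that("feature means equal an explicit loop over mapped positions", {
  prov <- synthetic_provider(synthetic_spec(seed = 55, embed_dim = 5L))
  set.seed(8)
  for (i in 1:20) {
    v <- random_variant()
    b <- build_features(v, prov, 4L)
    e_wt <- prov$embed(v$wt_sequence)
    e_mut <- prov$embed(v$mut_sequence)
    om <- build_overlap_map(v)
    brute_wt <- rep(0, 5); brute_mut <- rep(0, 5)
    for (r in seq_len(nrow(om))) {
      brute_wt <- brute_wt + e_wt[om$wt_pos[r], ]
      brute_mut <- brute_mut + e_mut[om$mut_pos[r], ]
    }
    expect_equal(b$wt_repr, brute_wt / nrow(om), tolerance = 1e-12)
    expect_equal(b$mut_repr, brute_mut / nrow(om), tolerance = 1e-12)
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  tr <- bundles_for(4L, "train")[1:60]
  va <- bundles_for(4L, "validation")
  hp <- siamese_hyperparams(max_epochs = 15L)
  m1 <- train_classifier(tr, va, hp, seed = 9)
  m2 <- train_classifier(tr, va, hp, seed = 9)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  m3 <- train_classifier(tr, va, hp, seed = 10)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("patience zero stops at the first non-improving epoch", {
  tr <- bundles_for(4L, "train")[1:60]
  va <- bundles_for(4L, "validation")
  m <- train_classifier(tr, va, siamese_hyperparams(patience = 0L,
                                                    max_epochs = 50L),
                        seed = 4)
  expect_equal(length(m$history), m$best_epoch + 1L)
  expect_equal(m$val_auc, max(m$history))
})

test_that("single-class training sets are rejected", {
  tr <- bundles_for(4L, "train")
  lab <- vapply(tr, `[[`, character(1), "label")
  expect_error(train_classifier(tr[lab == "benign"],
                                bundles_for(4L, "validation")),
               "DegenerateLabels")
})

test_that("classifier recovers an indel-embedding signal invisible to zero-shot scoring", {
  m4 <- train_classifier(bundles_for(4L, "train"),
                         bundles_for(4L, "validation"), seed = 1)
  expect_gte(m4$val_auc, 0.95)
  # the same dataset carries no probability signal
  sc <- vapply(shift_data$ds$variants, function(v)
    score_variant(v, shift_data$ds$provider, "indellm")$score, numeric(1))
  y <- as.integer(shift_data$ds$records$label == "pathogenic")
  expect_lt(abs(roc_and_auc(sc, y, "lower_is_pathogenic")$auc - 0.5), 0.1)
})

test_that("model 4 does not trail model 1 when the signal sits in the indel region", {
  va1 <- train_classifier(bundles_for(1L, "train"),
                          bundles_for(1L, "validation"), seed = 2)$val_auc
  va4 <- train_classifier(bundles_for(4L, "train"),
                          bundles_for(4L, "validation"), seed = 2)$val_auc
  expect_gte(va4, va1)
})

test_that("prediction is deterministic, probabilistic, and threshold-aware", {
  tr <- bundles_for(4L, "train")
  va <- bundles_for(4L, "validation")
  m <- train_classifier(tr, va, siamese_hyperparams(max_epochs = 20L), seed = 6)
  p1 <- predict_pathogenicity(m, va)
  p2 <- predict_pathogenicity(m, va)
  expect_identical(p1, p2)                       # dropout off at inference
  expect_true(all(p1$pathogenic_probability >= 0 &
                    p1$pathogenic_probability <= 1))
  expect_equal(p1$call, ifelse(p1$pathogenic_probability > 0.46,
                               "pathogenic", "benign"))
  # a probability exactly at the threshold is benign
  pr <- 0.46
  expect_equal(ifelse(pr > 0.46, "pathogenic", "benign"), "benign")
  expect_error(predict_pathogenicity(m, bundles_for(1L, "validation")),
               "ShapeMismatch")
})

test_that("training never mutates the provider's embeddings", {
  v <- shift_data$ds$variants[[1]]
  before <- shift_data$ds$provider$embed(v$wt_sequence)
  invisible(train_classifier(bundles_for(4L, "train")[1:40],
                             bundles_for(4L, "validation"),
                             siamese_hyperparams(max_epochs = 5L), seed = 3))
  expect_identical(shift_data$ds$provider$embed(v$wt_sequence), before)
})

test_that("replicate runs aggregate metrics over distinct seeds", {
  tr <- bundles_for(4L, "train")
  va <- bundles_for(4L, "validation")
  te <- bundles_for(4L, "test")
  hp <- siamese_hyperparams()
  rr <- replicate_runs(tr, va, te, hp, n_replicates = 3L, base_seed = 11)
  expect_length(rr$models, 3L)
  expect_equal(vapply(rr$models, `[[`, integer(1), "seed"), 11:13)
  expect_lt(rr$summary$sd[rr$summary$metric == "auc"], 0.05)
  one <- replicate_runs(tr, va, te, hp, n_replicates = 1L, base_seed = 11)
  expect_equal(one$summary$mean,
               unlist(one$metrics[1, c("mcc", "f1", "auc")],
                      use.names = FALSE))
  expect_equal(one$summary$sd, rep(0, 3))
})

test_that("grid search returns the argmax of validation AUC", {
  tr <- bundles_for(4L, "train")[1:60]
  va <- bundles_for(4L, "validation")
  single <- grid_search(data.frame(learning_rate = 5e-3), tr, va, seed = 2)
  expect_equal(single$best$learning_rate, 5e-3)
  two <- grid_search(data.frame(learning_rate = c(0, 5e-3),
                                max_epochs = c(10L, 10L)), tr, va, seed = 2)
  expect_equal(two$best$learning_rate, 5e-3)     # lr 0 cannot leave init
  expect_equal(nrow(two$log), 2L)
  expect_equal(which.max(two$log$val_auc), 2L)
  expect_error(grid_search(data.frame(), tr, va), "EmptyGrid")
})
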