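# tiny separable two-class bag set for optimization tests
toy_problem <- function(n_per_class = 6, n_tiles = 15, d = 8, seed = 1) {
  set.seed(seed)
  shift <- c(rep(4, 4), rep(0, d - 4))
  bags <- list()
  labels <- character()
  for (i in seq_len(2 * n_per_class)) {
    pos <- i > n_per_class
    X <- matrix(rnorm(n_tiles * d), n_tiles, d)
    if (pos) X[1:3, ] <- X[1:3, ] + matrix(shift, 3, d, byrow = TRUE)
    id <- sprintf("t%02d", i)
    bags[[id]] <- X
    labels <- c(labels, if (pos) "high" else "neg")
  }
  labels <- factor(labels, levels = c("neg", "high"))
  names(labels) <- names(bags)
  list(bags = bags, labels = labels)
}

test_that("training reduces the loss on a separable toy problem", {
  toy <- toy_problem()
  ids <- names(toy$bags)
  fit <- train_fold(toy$bags, toy$labels, train_ids = ids[1:10],
                    val_ids = ids[11:12], config = tiny_mil_cfg(),
                    train = train_config(max_epochs = 25, patience = 24,
                                         min_epochs = 25, seed = 3))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[2])  # epoch 1 row is index 2
  expect_lte(fit$best_val_loss, min(h$val_loss))
})

test_that("early stopping halts immediately when nothing improves", {
  toy <- toy_problem()
  ids <- names(toy$bags)
  # a vanishing learning rate freezes the parameters, so the validation
  # loss never improves on its epoch-0 baseline
  fit <- train_fold(toy$bags, toy$labels, ids[1:10], ids[11:12],
                    tiny_mil_cfg(),
                    train_config(max_epochs = 50, learning_rate = 1e-30,
                                 patience = 0, min_epochs = 0, seed = 2))
  expect_equal(max(fit$history$epoch), 1L)
  expect_equal(fit$best_epoch, 0L)
})

test_that("identical seeds give bitwise-identical training histories", {
  toy <- toy_problem()
  ids <- names(toy$bags)
  run <- function() {
    train_fold(toy$bags, toy$labels, ids[1:10], ids[11:12], tiny_mil_cfg(),
               train_config(max_epochs = 5, patience = 4, min_epochs = 5,
                            seed = 77))
  }
  a <- run()
  b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$params$W1, b$params$W1)
})

test_that("an empty validation set disables early stopping with a warning", {
  toy <- toy_problem()
  ids <- names(toy$bags)
  expect_warning(
    fit <- train_fold(toy$bags, toy$labels, ids[1:12], character(),
                      tiny_mil_cfg(),
                      train_config(max_epochs = 3, patience = 2,
                                   min_epochs = 3, seed = 4)),
    "empty validation"
  )
  expect_equal(fit$best_epoch, 3L)
  expect_true(all(is.na(fit$history$val_loss)))
})

test_that("single-class training sets are rejected", {
  toy <- toy_problem()
  ids <- names(toy$bags)
  expect_error(
    train_fold(toy$bags, toy$labels, ids[1:5], ids[11:12], tiny_mil_cfg(),
               train_config(seed = 1)),
    "2 classes"
  )
})

test_that("AUROC matches the rank-sum hand calculation", {
  # 4 slides: labels (+,-,+,-), scores (0.9, 0.6, 0.4, 0.2)
  # concordant positive-negative pairs: 3 of 4 -> AUROC 0.75
  expect_equal(auroc_score(c(TRUE, FALSE, TRUE, FALSE),
                           c(0.9, 0.6, 0.4, 0.2)), 0.75)
  # perfect separation
  expect_equal(auroc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  # label-independent scores concentrate near 0.5
  set.seed(123)
  truth <- rep(c(TRUE, FALSE), 1000)
  expect_lt(abs(auroc_score(truth, runif(2000)) - 0.5), 0.05)
  expect_error(auroc_score(rep(TRUE, 4), runif(4)), "both classes")
})

test_that("evaluate reports per-class and aggregate AUROC", {
  toy <- toy_problem()
  ids <- names(toy$bags)
  fit <- train_fold(toy$bags, toy$labels, ids[1:10], ids[11:12],
                    tiny_mil_cfg(),
                    train_config(max_epochs = 30, patience = 29,
                                 min_epochs = 30, seed = 5))
  rep <- evaluate(fit$params, toy$bags, toy$labels)
  expect_true(rep$auroc >= 0 && rep$auroc <= 1)
  expect_named(rep$per_class, c("neg", "high"))
  expect_equal(dim(rep$probs), c(12L, 2L))
  expect_named(rep$pr, c("neg", "high"))
  one_class <- toy$labels[toy$labels == "neg"]
  expect_error(evaluate(fit$params, toy$bags[names(one_class)], one_class),
               ">= 2 classes")
})

test_that("run_experiment emits the per-fold table and summary deterministically", {
  syn <- generate_cohort(synth_config(n_per_class = 8,
                                      tiles_range = c(10L, 20L), d = 8,
                                      seed = 6))
  run <- function() {
    run_experiment(syn$records, syn$bags, model_ids = c("M2", "M6"),
                   plan = split_plan(seed = 6, n_folds = 2),
                   train = train_config(max_epochs = 4, patience = 3,
                                        min_epochs = 4, seed = 6),
                   d_proj = 8, d_attn = 4)
  }
  a <- run()
  expect_equal(nrow(a$folds), 4L)  # 2 scenarios x 2 folds
  expect_setequal(a$summary$model_id, c("M2", "M6"))
  expect_true(all(a$folds$auroc >= 0 & a$folds$auroc <= 1))
  b <- run()
  expect_identical(a$folds, b$folds)
  # different scenarios use different slide subsets
  m2 <- build_partition("M2", syn$records)$records$slide_id
  m6 <- build_partition("M6", syn$records)$records$slide_id
  expect_true(length(m2) < length(m6))
})
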