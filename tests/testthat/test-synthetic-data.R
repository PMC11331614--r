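test_that("cohort generation is deterministic and label-consistent", {
  cfg <- synth_config(n_per_class = 3, tiles_range = c(5L, 10L), d = 6,
                      seed = 12)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$bags[[1]]$features, b$bags[[1]]$features)
  # every record is a legal assay cell and derivable
  expect_silent(assign_her2_group(a$records$ihc, a$records$ish))
  # bag invariants: rows match coords, finite
  for (sid in names(a$bags)) {
    bag <- a$bags[[sid]]
    expect_equal(nrow(bag$features), nrow(bag$coords))
    expect_true(all(is.finite(bag$features)))
    expect_length(a$witness[[sid]], nrow(bag$features))
  }
})

test_that("noise-free negative slides have IHC 0 and no witness tiles", {
  syn <- generate_cohort(synth_config(n_per_class = 5,
                                      tiles_range = c(5L, 10L), d = 6,
                                      label_noise = 0, seed = 3))
  negs <- syn$records[syn$records$latent_class == "neg", ]
  expect_true(all(negs$ihc == "0"))
  expect_true(all(negs$witness_fraction == 0))
  for (sid in negs$slide_id) expect_false(any(syn$witness[[sid]]))
})

test_that("label noise only ever swaps IHC 0 and 1+", {
  clean <- generate_cohort(synth_config(n_per_class = 20,
                                        tiles_range = c(2L, 3L), d = 2,
                                        label_noise = 0, seed = 9))
  noisy <- generate_cohort(synth_config(n_per_class = 20,
                                        tiles_range = c(2L, 3L), d = 2,
                                        label_noise = 0.5, seed = 9))
  # high-class calls (2+/pos, 3+) are never touched by the noise model
  expect_true(all(noisy$records$ihc[noisy$records$latent_class == "high"]
                  %in% c("2+", "3+")))
  expect_true(all(noisy$records$ihc[noisy$records$latent_class == "neg"]
                  %in% c("0", "1+")))
  # some swaps actually happened at this rate
  expect_gt(sum(noisy$records$ihc != clean$records$ihc), 0)
})

test_that("per-slide witness prevalence matches its Beta model", {
  # 500 latent-high slides; tiny bags keep this cheap
  cfg <- synth_config(n_per_class = 250, tiles_range = c(2L, 3L), d = 2,
                      seed = 21)
  syn <- generate_cohort(cfg)
  fr <- syn$records$witness_fraction[syn$records$latent_class == "high"]
  expect_length(fr, 500L)
  p <- cfg$p_high
  conc <- cfg$beta_concentration
  se <- sqrt(p * (1 - p) / (conc + 1)) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - p), 3 * se)
})

test_that("the MIL task is linearly solvable from mean bag embeddings", {
  syn <- generate_cohort(synth_config(seed = 4))
  means <- t(sapply(syn$bags, function(b) colMeans(b$features)))
  df <- data.frame(means, y = factor(syn$records$latent_class))
  fit <- nnet::multinom(y ~ ., df, trace = FALSE, MaxNWts = 10000)
  expect_equal(mean(predict(fit) == df$y), 1)
})

test_that("synthetic tile images honor their construction guarantees", {
  timg <- generate_tile_images(n_per_class = 10, tile_px = 16, seed = 2)
  bg <- timg$patches[timg$labels == "background"]
  for (p in bg) expect_gt(min(apply(p, 3, mean)), 230)
  # tumor (hematoxylin purple) has relatively more blue than non-tumor pink
  blue_excess <- function(p) mean(p[, , 3]) - mean(p[, , 1])
  tum <- sapply(timg$patches[timg$labels == "tumor"], blue_excess)
  non <- sapply(timg$patches[timg$labels == "non_tumor"], blue_excess)
  expect_gt(min(tum), max(non))
  # the recorded stain matrix is the canonical generator truth
  expect_equal(timg$stain_matrix, hemil:::canonical_he_matrix())
})
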