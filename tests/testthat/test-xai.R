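# hand-built MIL output wrapper for selection tests
fake_output <- function(attention, instance_probs) {
  structure(list(attention = rbind(attention),
                 instance_probs = rbind(instance_probs)),
            class = "mil_output")
}

fake_bag <- function(n, d = 4, seed = 1) {
  set.seed(seed)
  feature_bag("s1", matrix(rnorm(n * d), n, d),
              cbind((seq_len(n) - 1L) * 128L, 0L))
}

test_that("actionable tiles respect the strict probability filter and cap", {
  n <- 20
  att <- seq(n, 1) / sum(seq(n, 1))
  # 10 qualify -> all returned
  ip <- c(rep(0.9, 10), rep(0.1, 10))
  sel <- select_actionable(fake_output(att, ip), fake_bag(n), 1, "high")
  expect_equal(nrow(sel), 10L)
  # 20 qualify -> top 15 by attention
  sel2 <- select_actionable(fake_output(att, rep(0.8, n)), fake_bag(n), 1)
  expect_equal(nrow(sel2), 15L)
  expect_equal(sel2$tile_index, order(att, decreasing = TRUE)[1:15])
  expect_true(all(diff(sel2$attention) <= 0))
  # probability exactly 0.5 is excluded
  ip3 <- c(0.5, rep(0.9, n - 1))
  sel3 <- select_actionable(fake_output(att, ip3), fake_bag(n), 1)
  expect_false(1L %in% sel3$tile_index)
  # embeddings aligned with rows
  expect_equal(nrow(attr(sel3, "embeddings")), nrow(sel3))
})

test_that("attention heatmaps are normalized, averaged on overlaps, and order-invariant", {
  # singleton -> footprint uniformly 1
  hm1 <- attention_heatmap(cbind(0, 0), 0.37, 256, 256, tile_px = 256)
  expect_true(all(hm1 == 1))
  # two non-overlapping tiles with attentions (0.2, 0.8) -> values (0, 1)
  hm2 <- attention_heatmap(rbind(c(0, 0), c(256, 0)), c(0.2, 0.8),
                           512, 256, tile_px = 256)
  expect_equal(unique(as.numeric(hm2[, 1:256])), 0)
  expect_equal(unique(as.numeric(hm2[, 257:512])), 1)
  # 50% overlap region averages the two normalized values
  hm3 <- attention_heatmap(rbind(c(0, 0), c(128, 0)), c(0.2, 0.8),
                           384, 256, tile_px = 256)
  expect_equal(unique(as.numeric(hm3[, 129:256])), 0.5)
  expect_true(all(hm3 >= 0 & hm3 <= 1))
  # enumeration order does not matter
  hm3r <- attention_heatmap(rbind(c(128, 0), c(0, 0)), c(0.8, 0.2),
                            384, 256, tile_px = 256)
  expect_identical(hm3, hm3r)
  expect_error(attention_heatmap(cbind(0, 0), c(1, 2), 256, 256),
               "does not match")
})

test_that("PC binning conserves counts and handles known configurations", {
  set.seed(8)
  emb <- matrix(rnorm(60 * 6), 60, 6)
  tiles <- data.frame(class = sample(c("neg", "low", "high"), 60, TRUE),
                      model_id = sample(c("M2", "M6"), 60, TRUE),
                      fold = sample(1:3, 60, TRUE))
  bm <- project_and_bin(tiles, emb)
  expect_equal(sum(bm$cells$n), 60L)
  # conservation under subsetting by scenario
  for (m in c("M2", "M6")) {
    expect_equal(sum(bm$cells$n[bm$cells$model_id == m]),
                 sum(tiles$model_id == m))
  }
  # duplicating every point doubles every bin count
  bm2 <- project_and_bin(rbind(tiles, tiles), rbind(emb, emb))
  agg <- function(b) {
    o <- b$cells[order(b$cells$model_id, b$cells$fold, b$cells$class,
                       b$cells$bin_x, b$cells$bin_y), ]
    rownames(o) <- NULL
    o
  }
  a1 <- agg(bm); a2 <- agg(bm2)
  expect_equal(a2$n, 2L * a1$n)
  expect_equal(a2[, 1:5], a1[, 1:5])
  # 2-D input: the PCA rotation preserves pairwise distances
  pts <- rbind(c(0, 0), c(4, 0), c(0, 2), c(4, 2))
  bm3 <- project_and_bin(data.frame(class = rep("low", 4)), pts, n_bins = 2)
  expect_equal(as.numeric(dist(bm3$points[, c("pc1", "pc2")])),
               as.numeric(dist(pts)), tolerance = 1e-12)
  # corners land in the four distinct bins; max edge in the last bin
  expect_equal(sort(unique(paste(bm3$points$bin_x, bm3$points$bin_y))),
               c("1 1", "1 2", "2 1", "2 2"))
  expect_error(project_and_bin(data.frame(class = rep("low", 4)),
                               matrix(1, 4, 3)), "degenerate")
})

test_that("bin coloring rules reproduce the documented thresholds", {
  cells <- data.frame(
    model_id = "M6", fold = 1L,
    class = c("low", "high"), bin_x = 5L, bin_y = 5L, n = c(3L, 1L)
  )
  bm <- structure(list(cells = cells, n_bins = 30L), class = "bin_map")
  maj <- color_bins(bm, "majority_class")
  expect_equal(maj$color, "low")
  # tie breaks by fixed class order neg < low < high
  bm$cells$n <- c(2L, 2L)
  expect_equal(color_bins(bm, "majority_class")$color, "low")
  bm$cells$class <- c("neg", "high")
  expect_equal(color_bins(bm, "majority_class")$color, "neg")

  # fold consistency: present in 5 of 10 folds is colored, 4 is not
  mk <- function(nf) {
    data.frame(model_id = "M2", fold = seq_len(nf), class = "high",
               bin_x = 1L, bin_y = 1L, n = 1L)
  }
  bm5 <- structure(list(cells = mk(5), n_bins = 30L), class = "bin_map")
  bm4 <- structure(list(cells = mk(4), n_bins = 30L), class = "bin_map")
  expect_true(color_bins(bm5, "fold_consistency", n_folds = 10)$colored)
  expect_false(color_bins(bm4, "fold_consistency", n_folds = 10)$colored)

  # model agreement levels: exactly 2 scenarios -> level 2+, not 3+
  cells2 <- data.frame(model_id = c("M1", "M2"), fold = 1L, class = "high",
                       bin_x = 2L, bin_y = 3L, n = 1L)
  bmA <- structure(list(cells = cells2, n_bins = 30L), class = "bin_map")
  agr <- color_bins(bmA, "model_agreement")
  expect_true(agr$level_2_plus)
  expect_false(agr$level_3_plus)
  expect_false(agr$level_4_plus)
  expect_error(color_bins(bmA, "nope"))
})

test_that("bin maps serialize to JSON", {
  set.seed(4)
  bm <- project_and_bin(data.frame(class = rep(c("neg", "high"), 10)),
                        matrix(rnorm(20 * 4), 20, 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_bin_map(bm, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_bins, 30L)
  expect_equal(sum(back$cells$n), 20L)
})
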