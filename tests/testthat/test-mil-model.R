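test_that("parameter count follows the closed-form tensor enumeration", {
  count_formula <- function(d_in, d_proj, d_attn, K) {
    d_in * d_proj + d_proj +              # shared projection
      2 * (d_proj * d_attn + d_attn) +    # tanh and sigmoid gates
      K * (d_attn + 1) +                  # per-class attention heads
      K * (d_proj + 1) +                  # per-class bag classifiers
      K * 2 * (d_proj + 1)                # per-class 2-way instance heads
  }
  for (dims in list(c(8, 6, 4, 2), c(16, 12, 5, 3), c(1024, 1024, 512, 3))) {
    cfg <- mil_config(d_in = dims[1], d_proj = dims[2], d_attn = dims[3],
                      n_classes = dims[4])
    expect_equal(mil_n_params(cfg),
                 count_formula(dims[1], dims[2], dims[3], dims[4]))
  }
  expect_equal(mil_n_params(mil_config()), 2109964L)
})

test_that("gated attention reproduces hand-computed scores", {
  # 2 tiles, V = identity, U = 0 (gates 0.5), w = (1,0):
  # scores (0.5 * tanh(1), 0) -> softmax = (0.5941, 0.4059)
  H <- rbind(c(1, 0), c(0, 1))
  a <- gated_attention(H, Wv = diag(2), bv = c(0, 0),
                       Wu = matrix(0, 2, 2), bu = c(0, 0), w = c(1, 0))
  s <- 0.5 * tanh(1)
  expect_equal(a, as.numeric(exp(c(s, 0)) / sum(exp(c(s, 0)))),
               tolerance = 1e-12)
  expect_equal(round(a, 4), c(0.5941, 0.4059))
  # identical tiles -> uniform attention
  Hn <- matrix(1, 7, 2)
  an <- gated_attention(Hn, diag(2), c(0, 0), matrix(0, 2, 2), c(0, 0),
                        c(1, 0))
  expect_equal(an, rep(1 / 7, 7))
  # shift invariance via the bias term
  a_shift <- gated_attention(H, diag(2), c(0, 0), matrix(0, 2, 2), c(0, 0),
                             c(1, 0), b = 5)
  expect_equal(a_shift, a)
  expect_error(gated_attention(H[0, , drop = FALSE], diag(2), c(0, 0),
                               matrix(0, 2, 2), c(0, 0), c(1, 0)),
               "empty bag")
})

test_that("forward pass respects MIL structure", {
  cfg <- tiny_mil_cfg(n_classes = 3)
  p <- mil_init(cfg, seed = 4)
  set.seed(9)
  X <- matrix(rnorm(10 * 8), 10, 8)
  out <- mil_forward(p, X)
  # probability structure
  expect_equal(unname(rowSums(out$attention)), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  expect_true(all(out$attention >= 0))
  expect_true(all(is.finite(out$instance_probs)))
  # permutation invariance
  perm <- sample(10)
  out_p <- mil_forward(p, X[perm, ])
  expect_equal(out_p$probs, out$probs, tolerance = 1e-12)
  expect_equal(out_p$attention[, order(perm)], out$attention,
               tolerance = 1e-12)
  # single-tile bag: slide vector equals the projected tile for every class
  out1 <- mil_forward(p, X[1, , drop = FALSE])
  H1 <- pmax(X[1, , drop = FALSE] %*% p$W1 +
             matrix(p$b1, 1, cfg$d_proj, byrow = TRUE), 0)
  for (c in 1:3) expect_equal(unname(out1$slide_vectors[c, ]),
                              unname(H1[1, ]), tolerance = 1e-12)
  expect_error(mil_forward(p, matrix(0, 2, 5)), "does not match")
})

test_that("smooth SVM loss matches its closed forms and limits", {
  # s = (0, 0), y = 1: log(1 + e)
  expect_equal(smooth_svm_loss(c(0, 0), 1), log(1 + exp(1)),
               tolerance = 1e-12)
  # margin 0, tau 1 equals cross-entropy
  set.seed(3)
  for (i in 1:10) {
    s <- rnorm(4)
    y <- sample(4, 1)
    expect_equal(smooth_svm_loss(s, y, margin = 0, tau = 1),
                 -log(exp(s[y]) / sum(exp(s))), tolerance = 1e-10)
  }
  # tau -> 0 approaches the hinge loss
  hinge <- function(s, y, m = 1) {
    max(s + m * (seq_along(s) != y)) - s[y]
  }
  expect_lt(smooth_svm_loss(c(2, 0), 1, tau = 0.01), 1e-3)  # hinge = 0
  for (i in 1:20) {
    s <- rnorm(3)
    y <- sample(3, 1)
    l_prev <- Inf
    for (tau in c(1, 0.3, 0.1, 0.03)) {
      l <- smooth_svm_loss(s, y, tau = tau)
      expect_gte(l + 1e-12, hinge(s, y))  # smooth loss bounds hinge
      expect_lte(l, l_prev + 1e-12)       # monotone in tau
      l_prev <- l
    }
  }
})

test_that("instance targets follow the attention ranking", {
  sel <- instance_targets(c(0.7, 0.2, 0.1), in_class = TRUE, k_sample = 1)
  expect_equal(sel$index, c(1L, 3L))
  expect_equal(sel$target, c(1L, 0L))
  # out-of-class branch suppresses the top tiles
  sel2 <- instance_targets(c(0.7, 0.2, 0.1, 0.05), in_class = FALSE,
                           k_sample = 2)
  expect_equal(sel2$index, c(1L, 2L))
  expect_equal(sel2$target, c(0L, 0L))
  # k clips to half the bag
  sel3 <- instance_targets(runif(5), in_class = TRUE, k_sample = 10)
  expect_length(sel3$index, 4L)  # k = floor(5/2) = 2, top + bottom
  # admil variant: no instance loss
  sel4 <- instance_targets(runif(5), in_class = TRUE, variant = "admil")
  expect_length(sel4$index, 0L)
})

test_that("total loss is the documented convex combination", {
  expect_equal(total_loss(1, 1), 1)
  expect_equal(total_loss(2, 0), 1.4)       # 0.7 * 2
  expect_equal(total_loss(5, numeric(0)), 5)  # no instance branch
  expect_equal(total_loss(1, c(2, 4), bag_weight = 0.5), 0.5 + 1.5)
})

test_that("analytic gradients agree with finite differences", {
  for (K in 2:3) {
    cfg <- tiny_mil_cfg(n_classes = K)
    p <- mil_init(cfg, seed = 5 + K)
    set.seed(K)
    X <- matrix(rnorm(9 * 8), 9, 8)
    res <- hemil:::mil_loss_grads(p, X, y = K)
    eps <- 1e-6
    for (k in names(p)) {
      idx <- sample(length(p[[k]]), min(4, length(p[[k]])))
      for (i in idx) {
        p_hi <- p; p_hi[[k]][i] <- p_hi[[k]][i] + eps
        p_lo <- p; p_lo[[k]][i] <- p_lo[[k]][i] - eps
        fd <- (hemil:::mil_loss_grads(p_hi, X, K)$loss -
               hemil:::mil_loss_grads(p_lo, X, K)$loss) / (2 * eps)
        expect_equal(res$grads[[k]][i], fd, tolerance = 1e-4,
                     info = sprintf("K=%d %s[%d]", K, k, i))
      }
    }
  }
})

test_that("checkpoints round-trip parameters and config", {
  cfg <- tiny_mil_cfg(n_classes = 3)
  p <- mil_init(cfg, seed = 11)
  path <- withr::local_tempfile(fileext = ".ckpt")
  write_checkpoint(p, path, encoder_id = "encX")
  q <- read_checkpoint(path)
  for (k in names(p)) expect_equal(q[[k]], p[[k]], info = k)
  expect_equal(attr(q, "config")$n_classes, 3L)
  expect_equal(attr(q, "encoder_id"), "encX")
})
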