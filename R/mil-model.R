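#' Configuration of the gated-attention MIL classifier
#'
#' The model is a clustering-constrained attention MIL network: a shared
#' linear projection with ReLU, a gated attention backbone (tanh branch
#' times sigmoid gate) shared across classes with one attention scoring
#' head per class, one linear bag classifier per class applied to that
#' class's attention-weighted slide vector, and one 2-way linear instance
#' classifier per class used as a clustering regularizer during training
#' and a tile-level detector afterwards.
#'
#' With the defaults (`d_in = 1024`, `d_proj = 1024`, `d_attn = 512`,
#' `n_classes = 3`) the model has 2,109,964 trainable parameters.
#'
#' @param d_in input embedding dimension (default 1024).
#' @param d_proj shared projection width (default 1024).
#' @param d_attn attention gate hidden width (default 512).
#' @param n_classes 2 or 3.
#' @param k_sample instances sampled per branch for the instance loss
#'   (default 8; clipped to half the bag size).
#' @param bag_weight weight of the bag cross-entropy in the total loss
#'   (default 0.7; the instance loss gets `1 - bag_weight`).
#' @param variant `"clam"` (default) or `"admil"` — the latter is the
#'   plain attention-MIL baseline: a single shared attention branch and no
#'   instance loss.
#' @return an object of class `mil_config`.
#' @export
mil_config <- function(d_in = 1024L, d_proj = 1024L, d_attn = 512L,
                       n_classes = 3L, k_sample = 8L, bag_weight = 0.7,
                       variant = c("clam", "admil")) {
  variant <- match.arg(variant)
  stopifnot(n_classes >= 2L, d_in >= 1L, d_proj >= 1L, d_attn >= 1L,
            bag_weight >= 0, bag_weight <= 1)
  structure(
    list(d_in = as.integer(d_in), d_proj = as.integer(d_proj),
         d_attn = as.integer(d_attn), n_classes = as.integer(n_classes),
         k_sample = as.integer(k_sample), bag_weight = bag_weight,
         variant = variant,
         n_branches = if (variant == "admil") 1L else as.integer(n_classes)),
    class = "mil_config"
  )
}

#' Trainable parameter count of a MIL configuration
#'
#' Enumerates every trainable tensor (shared projection, gated-attention
#' backbone, per-class attention heads, per-class bag classifiers,
#' per-class instance classifiers) and sums element counts.
#'
#' @param config a [mil_config()].
#' @return integer parameter count.
#' @examples
#' mil_n_params(mil_config())  # 2109964
#' @export
mil_n_params <- function(config) {
  p <- mil_init(config, seed = 1L)
  sum(vapply(p, length, integer(1)))
}

#' Initialize MIL parameters
#'
#' Weights are He-scaled Gaussian; biases start at zero. Fully
#' deterministic given the seed.
#'
#' @param config a [mil_config()].
#' @param seed integer seed.
#' @return named list of parameter arrays (class `mil_params`), with the
#'   config attached as attribute `config`.
#' @export
mil_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mil_config"))
  cfg <- config
  rmat <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  }
  params <- with_seed(seed, {
    p <- list(
      W1 = rmat(cfg$d_in, cfg$d_proj), b1 = numeric(cfg$d_proj),
      Wv = rmat(cfg$d_proj, cfg$d_attn), bv = numeric(cfg$d_attn),
      Wu = rmat(cfg$d_proj, cfg$d_attn), bu = numeric(cfg$d_attn),
      # attention heads start near zero so initial attention is close to
      # uniform; early training is then driven by bag-level evidence
      # rather than by arbitrarily peaked initial attention, which the
      # instance loss would otherwise self-reinforce
      Wa = rmat(cfg$d_attn, cfg$n_branches) * 0.01,
      ba = numeric(cfg$n_branches),
      Wbag = rmat(cfg$d_proj, cfg$n_classes), bbag = numeric(cfg$n_classes)
    )
    p$Winst <- array(stats::rnorm(cfg$d_proj * 2L * cfg$n_classes,
                                  sd = sqrt(2 / cfg$d_proj)),
                     c(cfg$d_proj, 2L, cfg$n_classes))
    p$binst <- matrix(0, 2L, cfg$n_classes)
    p
  })
  attr(params, "config") <- cfg
  class(params) <- "mil_params"
  params
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# softmax with max subtraction, by column of a matrix or over a vector
softmax <- function(x) {
  if (is.matrix(x)) {
    x <- sweep(x, 2L, apply(x, 2L, max))
    e <- exp(x)
    sweep(e, 2L, colSums(e), "/")
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

#' Gated attention scores for one class branch
#'
#' Computes `a_k = softmax_k( w . ( tanh(V h_k) * sigmoid(U h_k) ) )` over
#' the tiles of a bag: a probability vector summing to 1.
#'
#' @param H projected tile matrix `n_tiles x d_proj`.
#' @param Wv,bv tanh branch weights (`d_proj x d_attn`) and bias.
#' @param Wu,bu sigmoid gate weights and bias.
#' @param w,b attention scoring head (`d_attn` vector, scalar bias).
#' @return numeric vector of `n_tiles` attention weights.
#' @export
gated_attention <- function(H, Wv, bv, Wu, bu, w, b = 0) {
  if (nrow(H) < 1L) stop("empty bag: attention undefined")
  G <- tanh(sweep(H %*% Wv, 2L, bv, "+")) *
       sigmoid(sweep(H %*% Wu, 2L, bu, "+"))
  as.numeric(softmax(as.numeric(G %*% w + b)))
}

#' Forward pass of the MIL classifier
#'
#' @param params a [mil_init()] parameter set.
#' @param X bag feature matrix `n_tiles x d_in` (or a [feature_bag()]).
#' @return list of class `mil_output`: `attention` (`n_classes x n_tiles`,
#'   rows sum to 1), `slide_vectors` (`n_classes x d_proj`), `logits`,
#'   `probs` (softmax over classes), `instance_probs`
#'   (`n_classes x n_tiles`, per-class positive-instance probability) and
#'   `cache` (internal activations reused by the backward pass).
#' @export
mil_forward <- function(params, X) {
  cfg <- attr(params, "config")
  if (inherits(X, "feature_bag")) X <- X$features
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) < 1L) stop("empty bag")
  if (ncol(X) != cfg$d_in) {
    stop("bag dimension ", ncol(X), " does not match model d_in ", cfg$d_in)
  }
  n <- nrow(X)
  H0 <- sweep(X %*% params$W1, 2L, params$b1, "+")
  H <- pmax(H0, 0)
  Tt <- tanh(sweep(H %*% params$Wv, 2L, params$bv, "+"))
  S <- sigmoid(sweep(H %*% params$Wu, 2L, params$bu, "+"))
  G <- Tt * S
  E <- sweep(G %*% params$Wa, 2L, params$ba, "+")   # n x n_branches
  A <- softmax(E)                                    # columns sum to 1
  M <- crossprod(A, H)                               # n_branches x d_proj
  branch_of <- if (cfg$n_branches == 1L) rep(1L, cfg$n_classes)
               else seq_len(cfg$n_classes)
  logits <- vapply(seq_len(cfg$n_classes), function(c) {
    sum(M[branch_of[c], ] * params$Wbag[, c]) + params$bbag[c]
  }, numeric(1))
  probs <- as.numeric(softmax(logits))
  inst <- matrix(NA_real_, cfg$n_classes, n)
  Zs <- vector("list", cfg$n_classes)
  for (c in seq_len(cfg$n_classes)) {
    Z <- sweep(H %*% params$Winst[, , c], 2L, params$binst[, c], "+")
    Zs[[c]] <- Z
    inst[c, ] <- 1 / (1 + exp(Z[, 1] - Z[, 2]))  # softmax positive unit
  }
  structure(
    list(attention = t(A)[branch_of, , drop = FALSE],
         slide_vectors = M[branch_of, , drop = FALSE],
         logits = logits, probs = probs, instance_probs = inst,
         cache = list(X = X, H0 = H0, H = H, Tt = Tt, S = S, G = G,
                      A = A, M = M, Z = Zs, branch_of = branch_of)),
    class = "mil_output"
  )
}

#' Smooth multiclass SVM loss
#'
#' `L = tau * log sum_j exp((s_j + margin * 1[j != y] - s_y) / tau)`: a
#' temperature-smoothed margin loss that approaches the multiclass hinge
#' loss as `tau -> 0` and equals cross-entropy at `margin = 0, tau = 1`.
#'
#' @param scores numeric score vector.
#' @param y 1-based index of the true class.
#' @param margin margin (default 1).
#' @param tau temperature, > 0 (default 1).
#' @return scalar loss.
#' @export
smooth_svm_loss <- function(scores, y, margin = 1, tau = 1) {
  stopifnot(tau > 0, margin >= 0, y >= 1, y <= length(scores))
  u <- (scores + margin * (seq_along(scores) != y) - scores[y]) / tau
  m <- max(u)
  tau * (m + log(sum(exp(u - m))))
}

# gradient of smooth_svm_loss wrt scores
smooth_svm_grad <- function(scores, y, margin = 1, tau = 1) {
  u <- (scores + margin * (seq_along(scores) != y) - scores[y]) / tau
  q <- exp(u - max(u)); q <- q / sum(q)
  g <- q
  g[y] <- g[y] - 1
  g
}

#' Instance-classifier targets from an attention row
#'
#' For the bag's true class, the `k` most-attended tiles are positive
#' targets and the `k` least-attended are negatives; for every other
#' class branch the `k` most-attended tiles are negatives (out-of-class
#' suppression). `k` is clipped to half the bag size. The `admil` variant
#' has no instance loss and returns an empty selection.
#'
#' @param attention attention weight vector for the branch.
#' @param in_class `TRUE` when the branch matches the bag label.
#' @param k_sample requested k (default 8).
#' @param variant `"clam"` or `"admil"`.
#' @return list with integer `index` and 0/1 `target` vectors.
#' @export
instance_targets <- function(attention, in_class, k_sample = 8L,
                             variant = "clam") {
  if (variant == "admil") {
    return(list(index = integer(), target = integer()))
  }
  n <- length(attention)
  k <- min(as.integer(k_sample), n %/% 2L)
  if (k < 1L) return(list(index = integer(), target = integer()))
  ord <- order(attention, decreasing = TRUE)
  top <- ord[seq_len(k)]
  if (in_class) {
    bottom <- ord[seq.int(n - k + 1L, n)]
    list(index = c(top, bottom), target = c(rep(1L, k), rep(0L, k)))
  } else {
    list(index = top, target = rep(0L, k))
  }
}

#' Combine bag and instance losses
#'
#' `L = bag_weight * L_bag + (1 - bag_weight) * mean(L_inst)`; with no
#' instance losses (the `admil` variant) the bag loss is returned alone.
#'
#' @param bag_loss scalar bag cross-entropy.
#' @param inst_losses numeric vector of per-branch instance losses (may be
#'   empty).
#' @param bag_weight default 0.7.
#' @return scalar total loss.
#' @export
total_loss <- function(bag_loss, inst_losses, bag_weight = 0.7) {
  if (length(inst_losses) == 0L) return(bag_loss)
  bag_weight * bag_loss + (1 - bag_weight) * mean(inst_losses)
}

# Forward + analytic backward for one bag. Returns loss components and
# gradients shaped like `params`. Instance-target selection is treated as
# constant (no gradient through the argsort), as is standard.
mil_loss_grads <- function(params, X, y) {
  cfg <- attr(params, "config")
  out <- mil_forward(params, X)
  ca <- out$cache
  n <- nrow(ca$H)
  g <- lapply(params, function(p) { p[] <- 0; p })

  bag_loss <- -log(max(out$probs[y], 1e-12))
  use_inst <- cfg$variant != "admil" && cfg$bag_weight < 1
  bw <- if (use_inst) cfg$bag_weight else 1

  # ---- bag branch ----
  glogits <- bw * (out$probs - as.numeric(seq_len(cfg$n_classes) == y))
  gM <- matrix(0, cfg$n_branches, cfg$d_proj)
  for (c in seq_len(cfg$n_classes)) {
    b <- ca$branch_of[c]
    g$Wbag[, c] <- glogits[c] * ca$M[b, ]
    g$bbag[c] <- glogits[c]
    gM[b, ] <- gM[b, ] + glogits[c] * params$Wbag[, c]
  }
  gH <- ca$A %*% gM                     # n x d_proj
  gA <- ca$H %*% t(gM)                  # n x n_branches
  gE <- matrix(0, n, cfg$n_branches)
  for (b in seq_len(cfg$n_branches)) {
    a <- ca$A[, b]
    gE[, b] <- a * (gA[, b] - sum(gA[, b] * a))
  }
  gG <- gE %*% t(params$Wa)
  g$Wa <- crossprod(ca$G, gE)
  g$ba <- colSums(gE)

  # ---- instance branch ----
  inst_losses <- numeric(0)
  if (use_inst) {
    iw <- (1 - cfg$bag_weight) / cfg$n_classes
    for (c in seq_len(cfg$n_classes)) {
      b <- ca$branch_of[c]
      sel <- instance_targets(ca$A[, b], in_class = (c == y),
                              k_sample = cfg$k_sample, variant = cfg$variant)
      m <- length(sel$index)
      if (m == 0L) next
      Z <- ca$Z[[c]][sel$index, , drop = FALSE]
      li <- 0
      gZ <- matrix(0, m, 2L)
      for (i in seq_len(m)) {
        yy <- sel$target[i] + 1L
        li <- li + smooth_svm_loss(Z[i, ], yy)
        gZ[i, ] <- smooth_svm_grad(Z[i, ], yy)
      }
      inst_losses <- c(inst_losses, li / m)
      gZ <- gZ * (iw / m)
      g$Winst[, , c] <- crossprod(ca$H[sel$index, , drop = FALSE], gZ)
      g$binst[, c] <- colSums(gZ)
      gH[sel$index, ] <- gH[sel$index, ] +
        gZ %*% t(params$Winst[, , c])
    }
  }

  # ---- gate backward ----
  gT <- gG * ca$S
  gS <- gG * ca$Tt
  gHv <- gT * (1 - ca$Tt^2)
  gHu <- gS * ca$S * (1 - ca$S)
  g$Wv <- crossprod(ca$H, gHv); g$bv <- colSums(gHv)
  g$Wu <- crossprod(ca$H, gHu); g$bu <- colSums(gHu)
  gH <- gH + gHv %*% t(params$Wv) + gHu %*% t(params$Wu)

  # ---- projection backward ----
  gH0 <- gH * (ca$H0 > 0)
  g$W1 <- crossprod(ca$X, gH0)
  g$b1 <- colSums(gH0)

  loss <- if (use_inst) total_loss(bag_loss, inst_losses, cfg$bag_weight)
          else bag_loss
  list(loss = loss, bag_loss = bag_loss, inst_losses = inst_losses,
       grads = g, output = out)
}

# ---- ADAM optimizer (decoupled L2 folded into the gradient, as in the
# reference Adam-with-weight-decay formulation) ----

adam_init <- function(params) {
  zero <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, weight_decay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    gk <- grads[[k]] + weight_decay * params[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Save / load a model checkpoint
#'
#' A single-file serialized parameter set with a JSON config header
#' (dimensions, class count, variant, encoder id).
#'
#' @param params a `mil_params` object.
#' @param path checkpoint file path.
#' @param encoder_id optional encoder identifier recorded in the header.
#' @export
write_checkpoint <- function(params, path, encoder_id = "unknown") {
  cfg <- attr(params, "config")
  header <- jsonlite::toJSON(
    list(d_in = cfg$d_in, d_proj = cfg$d_proj, d_attn = cfg$d_attn,
         n_classes = cfg$n_classes, k_sample = cfg$k_sample,
         bag_weight = cfg$bag_weight, variant = cfg$variant,
         encoder_id = encoder_id),
    auto_unbox = TRUE
  )
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con)
  writeBin(hraw, con)
  for (k in names(params)) {
    writeBin(length(params[[k]]), con)
    writeBin(as.numeric(params[[k]]), con)
  }
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer")
  hd <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), hlen)))
  cfg <- mil_config(d_in = hd$d_in, d_proj = hd$d_proj, d_attn = hd$d_attn,
                    n_classes = hd$n_classes, k_sample = hd$k_sample,
                    bag_weight = hd$bag_weight, variant = hd$variant)
  params <- mil_init(cfg, seed = 1L)
  for (k in names(params)) {
    len <- readBin(con, "integer")
    vals <- readBin(con, "numeric", n = len)
    params[[k]][] <- vals
  }
  attr(params, "encoder_id") <- hd$encoder_id
  params
}
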