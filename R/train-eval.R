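#' Training configuration
#'
#' Optimization follows the fixed-hyper-parameter regime used for all
#' scenarios: ADAM with learning rate 1e-4 and weight decay 1e-4, bag
#' cross-entropy weighted 0.7 against the smooth-SVM instance loss, up to
#' 200 epochs with early stopping on the validation loss. One slide (bag)
#' per optimization step.
#'
#' @param max_epochs epoch cap (default 200).
#' @param learning_rate ADAM learning rate (default 1e-4).
#' @param weight_decay L2 weight decay (default 1e-4).
#' @param patience epochs without validation improvement tolerated after
#'   `min_epochs` (default 20).
#' @param min_epochs epochs before early stopping may trigger (default
#'   50).
#' @param seed integer seed controlling initialization and bag order.
#' @return an object of class `train_config`.
#' @export
train_config <- function(max_epochs = 200L, learning_rate = 1e-4,
                         weight_decay = 1e-4, patience = 20L,
                         min_epochs = 50L, seed = 1L) {
  stopifnot(learning_rate > 0, patience < max_epochs)
  structure(
    list(max_epochs = as.integer(max_epochs), learning_rate = learning_rate,
         weight_decay = weight_decay, patience = as.integer(patience),
         min_epochs = as.integer(min_epochs), seed = as.integer(seed)),
    class = "train_config"
  )
}

# total loss of one bag without gradient bookkeeping
mil_bag_loss <- function(params, X, y) {
  cfg <- attr(params, "config")
  out <- mil_forward(params, X)
  bag_loss <- -log(max(out$probs[y], 1e-12))
  if (cfg$variant == "admil" || cfg$bag_weight >= 1) return(bag_loss)
  inst <- numeric(0)
  for (c in seq_len(cfg$n_classes)) {
    b <- out$cache$branch_of[c]
    sel <- instance_targets(out$cache$A[, b], in_class = (c == y),
                            k_sample = cfg$k_sample, variant = cfg$variant)
    if (length(sel$index) == 0L) next
    Z <- out$cache$Z[[c]][sel$index, , drop = FALSE]
    li <- vapply(seq_along(sel$index), function(i) {
      smooth_svm_loss(Z[i, ], sel$target[i] + 1L)
    }, numeric(1))
    inst <- c(inst, mean(li))
  }
  total_loss(bag_loss, inst, cfg$bag_weight)
}

#' Train one cross-validation fold
#'
#' One bag per ADAM step; epochs shuffle the bag order. The validation
#' loss is evaluated before training (epoch 0) and after every epoch; the
#' checkpoint returned is the one with the best validation loss. Training
#' stops early when the validation loss has not improved for more than
#' `patience` epochs, once at least `min_epochs` epochs have run.
#'
#' @param bags named list of bag feature matrices (or [feature_bag()]s),
#'   keyed by slide id.
#' @param labels named factor of slide labels (levels = class order).
#' @param train_ids,val_ids slide ids of the training and validation sets.
#' @param config a [mil_config()].
#' @param train a [train_config()].
#' @return list with `params` (best checkpoint), `history` (data.frame
#'   `epoch`, `train_loss`, `val_loss`), `best_epoch`, `best_val_loss`,
#'   `seed`.
#' @export
train_fold <- function(bags, labels, train_ids, val_ids, config,
                       train = train_config()) {
  stopifnot(inherits(config, "mil_config"), inherits(train, "train_config"))
  bagmat <- function(b) if (inherits(b, "feature_bag")) b$features else b
  y_all <- as.integer(labels)
  names(y_all) <- names(labels)
  if (length(unique(y_all[train_ids])) < 2L) {
    stop("training set must contain at least 2 classes")
  }
  has_val <- length(val_ids) > 0L
  if (!has_val) {
    warning("empty validation set: early stopping disabled, ",
            "final-epoch parameters returned")
  }
  with_seed(train$seed, {
    params <- mil_init(config, seed = train$seed)
    state <- adam_init(params)
    val_loss_of <- function(p) {
      if (!has_val) return(NA_real_)
      mean(vapply(val_ids, function(id) {
        mil_bag_loss(p, bagmat(bags[[id]]), y_all[[id]])
      }, numeric(1)))
    }
    best_val <- val_loss_of(params)
    best_params <- params
    best_epoch <- 0L
    since_best <- 0L
    history <- data.frame(epoch = 0L, train_loss = NA_real_,
                          val_loss = best_val)
    for (epoch in seq_len(train$max_epochs)) {
      order_ids <- sample(train_ids)
      tl <- 0
      for (id in order_ids) {
        res <- mil_loss_grads(params, bagmat(bags[[id]]), y_all[[id]])
        tl <- tl + res$loss
        st <- adam_step(params, res$grads, state,
                        lr = train$learning_rate,
                        weight_decay = train$weight_decay)
        params <- st$params
        state <- st$state
      }
      vl <- val_loss_of(params)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = tl / length(train_ids),
                                           val_loss = vl))
      if (!has_val) {
        best_params <- params
        best_epoch <- epoch
      } else if (vl < best_val) {
        best_val <- vl
        best_params <- params
        best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (has_val && epoch >= train$min_epochs &&
          since_best > train$patience) break
    }
    list(params = best_params, history = history, best_epoch = best_epoch,
         best_val_loss = best_val, seed = train$seed)
  })
}

#' Area under the ROC curve for a binary score
#'
#' @param truth logical (or 0/1) vector: positive class membership.
#' @param scores numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc_score <- function(truth, scores) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2L) stop("AUROC needs both classes present")
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

# precision-recall coordinates by descending score threshold
pr_curve <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  truth <- as.logical(truth)[ord]
  tp <- cumsum(truth)
  fp <- cumsum(!truth)
  data.frame(recall = tp / sum(truth), precision = tp / (tp + fp))
}

#' Evaluate a trained model on labeled bags
#'
#' Binary scenarios report the standard AUROC on the positive (last)
#' class; 3-class scenarios report the macro one-vs-rest AUROC (mean of
#' the three per-class AUROCs), with micro averaging available.
#'
#' @param params trained `mil_params`.
#' @param bags named list of bag matrices / [feature_bag()]s.
#' @param labels named factor with the scenario's class levels.
#' @param average `"macro"` (default) or `"micro"` for multiclass.
#' @return list of class `eval_report`: `auroc`, `per_class` (named
#'   per-class one-vs-rest AUROCs), `probs` (slides x classes), `pr`
#'   (per-class precision-recall curves).
#' @export
evaluate <- function(params, bags, labels, average = c("macro", "micro")) {
  average <- match.arg(average)
  cfg <- attr(params, "config")
  classes <- levels(labels)
  if (length(unique(labels)) < 2L) stop("evaluation needs >= 2 classes")
  stopifnot(length(classes) == cfg$n_classes)
  ids <- names(labels)
  probs <- t(vapply(ids, function(id) {
    b <- bags[[id]]
    mil_forward(params, if (inherits(b, "feature_bag")) b$features else b)$probs
  }, numeric(cfg$n_classes)))
  colnames(probs) <- classes
  per_class <- vapply(classes, function(cl) {
    auroc_score(labels == cl, probs[, cl])
  }, numeric(1))
  auroc <- if (cfg$n_classes == 2L) {
    per_class[[length(classes)]]
  } else if (average == "macro") {
    mean(per_class)
  } else {
    truth <- as.numeric(rep(classes, each = nrow(probs)) ==
                        rep(as.character(labels), times = length(classes)))
    auroc_score(truth, as.numeric(probs))
  }
  pr <- lapply(stats::setNames(classes, classes), function(cl) {
    pr_curve(labels == cl, probs[, cl])
  })
  structure(list(auroc = auroc, per_class = per_class, probs = probs,
                 pr = pr), class = "eval_report")
}

#' Cross-validated experiment over one or more scenarios
#'
#' For each scenario: restrict the manifest to the scenario's assay
#' cells, build patient-level stratified splits, train one model per
#' fold, and evaluate each on the internal hold-out set (and on
#' external-flagged cohorts, when present). Reports per-fold AUROCs plus
#' a median and standard deviation summary.
#'
#' @param records slide manifest data.frame (`slide_id`, `patient_id`,
#'   `cohort`, `ihc`, `ish`).
#' @param bags named list of bag feature matrices keyed by slide id.
#' @param model_ids character vector over `"M1"`..`"M6"`.
#' @param plan a [split_plan()].
#' @param train a [train_config()]; fold seeds are derived from its seed.
#' @param d_proj,d_attn,k_sample,bag_weight,variant passed to
#'   [mil_config()] (class count comes from each scenario).
#' @param keep_models when `TRUE`, the trained per-fold parameter sets are
#'   returned under `models` (a list keyed `"<model_id>/<fold>"`).
#' @return list of class `experiment_report`: `folds` (data.frame
#'   `model_id`, `fold`, `auroc`, `best_epoch`, `seed`), `summary`
#'   (data.frame `model_id`, `median_auroc`, `sd_auroc`), `external`
#'   (data.frame or NULL), `holdout_ids` (named by model id), and
#'   optionally `models`.
#' @export
run_experiment <- function(records, bags, model_ids = "M6",
                           plan = split_plan(), train = train_config(),
                           d_proj = 64L, d_attn = 32L, k_sample = 8L,
                           bag_weight = 0.7, variant = "clam",
                           keep_models = FALSE) {
  d_in <- ncol(if (inherits(bags[[1]], "feature_bag")) bags[[1]]$features
               else bags[[1]])
  fold_rows <- list()
  ext_rows <- list()
  models <- list()
  holdouts <- list()
  labels_by_model <- list()
  for (mid in model_ids) {
    part <- build_partition(mid, records)
    recs <- part$records
    labels <- factor(as.character(recs$label), levels = part$spec$classes)
    names(labels) <- recs$slide_id
    splits <- make_splits(recs, plan)
    holdout_ids <- recs$slide_id[recs$patient_id %in% splits$holdout]
    holdouts[[mid]] <- holdout_ids
    labels_by_model[[mid]] <- labels
    cfg <- mil_config(d_in = d_in, d_proj = d_proj, d_attn = d_attn,
                      n_classes = part$spec$n_classes, k_sample = k_sample,
                      bag_weight = bag_weight, variant = variant)
    seeds <- derive_seeds(train$seed, plan$n_folds)
    for (k in seq_len(plan$n_folds)) {
      tr_ids <- recs$slide_id[recs$patient_id %in% splits$folds[[k]]$train]
      va_ids <- recs$slide_id[recs$patient_id %in% splits$folds[[k]]$val]
      tcfg <- train
      tcfg$seed <- seeds[k]
      fit <- train_fold(bags, labels, tr_ids, va_ids, cfg, tcfg)
      if (keep_models) models[[sprintf("%s/%d", mid, k)]] <- fit$params
      rep_k <- evaluate(fit$params, bags[holdout_ids], labels[holdout_ids])
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        model_id = mid, fold = k, auroc = rep_k$auroc,
        best_epoch = fit$best_epoch, seed = seeds[k]
      )
      if (length(splits$external)) {
        ext_ids <- recs$slide_id[recs$patient_id %in% splits$external]
        if (length(unique(labels[ext_ids])) >= 2L) {
          rep_e <- evaluate(fit$params, bags[ext_ids], labels[ext_ids])
          ext_rows[[length(ext_rows) + 1L]] <- data.frame(
            model_id = mid, fold = k, auroc = rep_e$auroc
          )
        }
      }
    }
  }
  folds <- do.call(rbind, fold_rows)
  summary <- do.call(rbind, lapply(split(folds, folds$model_id), function(df) {
    data.frame(model_id = df$model_id[1],
               median_auroc = stats::median(df$auroc),
               sd_auroc = stats::sd(df$auroc))
  }))
  rownames(summary) <- NULL
  structure(
    list(folds = folds, summary = summary,
         external = if (length(ext_rows)) do.call(rbind, ext_rows) else NULL,
         holdout_ids = holdouts, labels = labels_by_model,
         models = if (keep_models) models else NULL),
    class = "experiment_report"
  )
}
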