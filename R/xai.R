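#' Select actionable tiles for one slide and class
#'
#' Actionable tiles are the tiles a trained model relies on for a class:
#' tiles whose per-class instance probability is strictly above 0.5,
#' ranked by the class's attention weight, capped at the `top_k` highest.
#' Selection is per slide and per class, regardless of the slide's final
#' whole-slide classification.
#'
#' @param output a [mil_forward()] result.
#' @param bag the [feature_bag()] the output was computed on (supplies
#'   coordinates and embeddings).
#' @param class_index 1-based class branch.
#' @param class_label label string recorded in the result.
#' @param top_k attention cap (default 15).
#' @return data.frame of class `actionable_tiles` with columns
#'   `slide_id`, `x`, `y`, `class`, `attention`, `instance_prob`,
#'   `tile_index`; the matching embeddings are attached as attribute
#'   `embeddings` (rows aligned). May be empty.
#' @export
select_actionable <- function(output, bag, class_index, class_label = NULL,
                              top_k = 15L) {
  stopifnot(inherits(output, "mil_output"), inherits(bag, "feature_bag"))
  att <- output$attention[class_index, ]
  ip <- output$instance_probs[class_index, ]
  if (is.null(class_label)) class_label <- as.character(class_index)
  qual <- which(ip > 0.5)
  qual <- qual[order(att[qual], decreasing = TRUE)]
  keep <- qual[seq_len(min(top_k, length(qual)))]
  out <- data.frame(
    slide_id = rep(bag$slide_id, length(keep)),
    x = bag$coords[keep, 1], y = bag$coords[keep, 2],
    class = rep(class_label, length(keep)),
    attention = att[keep], instance_prob = ip[keep],
    tile_index = keep
  )
  rownames(out) <- NULL
  attr(out, "embeddings") <- bag$features[keep, , drop = FALSE]
  class(out) <- c("actionable_tiles", class(out))
  out
}

#' Collect actionable tiles across an experiment's fold models
#'
#' Runs every kept fold model of an [run_experiment()] report over its
#' scenario's hold-out slides and pools the per-slide, per-class
#' actionable tiles, tagged with scenario and fold.
#'
#' @param report an `experiment_report` produced with
#'   `keep_models = TRUE`.
#' @param bags named list of [feature_bag()]s keyed by slide id.
#' @param top_k per-(slide, class) attention cap (default 15).
#' @return data.frame with columns `model_id`, `fold`, `slide_id`, `x`,
#'   `y`, `class`, `attention`, `instance_prob`, `tile_index`; pooled
#'   embeddings attached as attribute `embeddings`.
#' @export
collect_actionable <- function(report, bags, top_k = 15L) {
  stopifnot(inherits(report, "experiment_report"), !is.null(report$models))
  rows <- list()
  embs <- list()
  for (key in names(report$models)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    mid <- parts[1]; fold <- as.integer(parts[2])
    params <- report$models[[key]]
    cfg <- attr(params, "config")
    classes <- levels(report$labels[[mid]])
    for (sid in report$holdout_ids[[mid]]) {
      bag <- bags[[sid]]
      out <- mil_forward(params, bag$features)
      for (ci in seq_len(cfg$n_classes)) {
        at <- select_actionable(out, bag, ci, class_label = classes[ci],
                                top_k = top_k)
        if (nrow(at) == 0L) next
        at$model_id <- mid
        at$fold <- fold
        rows[[length(rows) + 1L]] <- at
        embs[[length(embs) + 1L]] <- attr(at, "embeddings")
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(model_id = character(), fold = integer(),
                      slide_id = character(), x = integer(), y = integer(),
                      class = character(), attention = numeric(),
                      instance_prob = numeric(), tile_index = integer())
    attr(out, "embeddings") <- matrix(numeric(), 0, 0)
    return(out)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    class(r) <- "data.frame"
    attr(r, "embeddings") <- NULL
    r
  }))
  out <- out[, c("model_id", "fold", "slide_id", "x", "y", "class",
                 "attention", "instance_prob", "tile_index")]
  rownames(out) <- NULL
  attr(out, "embeddings") <- do.call(rbind, embs)
  out
}

#' Render a slide-level attention heatmap
#'
#' Attention weights are min-max normalized to `[0, 1]` over the slide
#' (a single tile maps to 1) and painted onto each tile's footprint;
#' where footprints of overlapping tiles meet, values are averaged.
#' Pixels covered by no tile are 0.
#'
#' @param coords `n x 2` matrix/data.frame of tile origins (level 0,
#'   0-based).
#' @param attention attention weight vector aligned with `coords`.
#' @param width_px,height_px slide dimensions.
#' @param tile_px tile side length (default 256).
#' @param downsample integer rendering downsample factor (default 1;
#'   coordinates and tile size must be multiples of it).
#' @return numeric matrix `height x width` (after downsampling) in
#'   `[0, 1]`.
#' @export
attention_heatmap <- function(coords, attention, width_px, height_px,
                              tile_px = 256L, downsample = 1L) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(attention)) {
    stop("attention length does not match number of tiles")
  }
  rng <- range(attention)
  norm <- if (diff(rng) == 0) rep(1, length(attention))
          else (attention - rng[1]) / diff(rng)
  w <- width_px %/% downsample
  h <- height_px %/% downsample
  tp <- tile_px %/% downsample
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  for (i in seq_along(norm)) {
    x0 <- coords[i, 1] %/% downsample
    y0 <- coords[i, 2] %/% downsample
    rows <- (y0 + 1L):(y0 + tp)
    cols <- (x0 + 1L):(x0 + tp)
    acc[rows, cols] <- acc[rows, cols] + norm[i]
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  out <- acc
  out[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  out
}

#' Project actionable tiles to PC space and bin them
#'
#' Fits a PCA on the pooled actionable-tile embeddings (all scenarios and
#' folds together, so bins are comparable across panels), projects each
#' tile onto the first two principal components, and discretizes the
#' plane into an `n_bins x n_bins` equal-width grid over the pooled
#' min/max ranges. Points on the max edge fall in the last bin.
#'
#' @param tiles data.frame with columns `class` and optionally `model_id`
#'   and `fold` (one row per actionable tile).
#' @param embeddings numeric matrix, one row per tile.
#' @param n_bins grid resolution per axis (default 30).
#' @return object of class `bin_map`: list with `cells` (data.frame
#'   `model_id`, `fold`, `class`, `bin_x`, `bin_y`, `n`), `bounds`
#'   (PC1/PC2 min and max), `n_bins`, `pca` (the `prcomp` rotation), and
#'   `points` (per-tile `pc1`, `pc2`, `bin_x`, `bin_y`).
#' @export
project_and_bin <- function(tiles, embeddings, n_bins = 30L) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 3L) stop("need at least 3 tiles to fit a PCA")
  if (all(apply(embeddings, 2L, stats::var) < .Machine$double.eps)) {
    stop("degenerate PCA: all embeddings identical")
  }
  pca <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE, rank. = 2L)
  pc <- pca$x[, 1:2, drop = FALSE]
  bounds <- data.frame(min = apply(pc, 2L, min), max = apply(pc, 2L, max))
  bin_of <- function(v, lo, hi) {
    if (hi == lo) return(rep(1L, length(v)))
    pmin(pmax(floor((v - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
  }
  bx <- bin_of(pc[, 1], bounds$min[1], bounds$max[1])
  by <- bin_of(pc[, 2], bounds$min[2], bounds$max[2])
  pts <- data.frame(pc1 = pc[, 1], pc2 = pc[, 2], bin_x = bx, bin_y = by)
  meta <- data.frame(
    model_id = if (!is.null(tiles$model_id)) tiles$model_id else "M",
    fold = if (!is.null(tiles$fold)) tiles$fold else 1L,
    class = tiles$class, bin_x = bx, bin_y = by
  )
  cells <- stats::aggregate(list(n = rep(1L, nrow(meta))),
                            meta, FUN = sum)
  structure(list(cells = cells, bounds = bounds, n_bins = as.integer(n_bins),
                 pca = pca, points = pts),
            class = "bin_map")
}

her2_class_order <- function() c("neg", "low", "high")

#' Color the bins of a PC-space map
#'
#' Three coloring rules reproduce the panel logic of the explainability
#' figure:
#' \describe{
#'   \item{majority_class}{per (scenario, fold), each occupied bin takes
#'     the most frequent HER2 group among its tiles; ties break by the
#'     fixed class order neg < low < high.}
#'   \item{fold_consistency}{per scenario and class, a bin is colored iff
#'     at least `fold_threshold` (default 50%, inclusive) of the folds
#'     have at least one tile of that class there.}
#'   \item{model_agreement}{per class, a bin is flagged at agreement
#'     level `L` when at least `L` distinct scenarios use it for that
#'     class; levels default to 2, 3 and 4 or more.}
#' }
#'
#' @param bin_map a [project_and_bin()] result.
#' @param rule one of `"majority_class"`, `"fold_consistency"`,
#'   `"model_agreement"`.
#' @param fold_threshold fraction of folds required under
#'   `fold_consistency` (default 0.5, inclusive).
#' @param n_folds total folds per scenario (default: max fold index seen).
#' @param levels agreement thresholds under `model_agreement` (default
#'   `c(2, 3, 4)`).
#' @return a data.frame; columns depend on the rule (see Details).
#' @export
color_bins <- function(bin_map, rule = c("majority_class", "fold_consistency",
                                         "model_agreement"),
                       fold_threshold = 0.5, n_folds = NULL,
                       levels = c(2L, 3L, 4L)) {
  rule <- match.arg(rule)
  cells <- bin_map$cells
  ord <- her2_class_order()
  if (rule == "majority_class") {
    groups <- split(cells,
                    list(cells$model_id, cells$fold, cells$bin_x, cells$bin_y),
                    drop = TRUE)
    out <- do.call(rbind, lapply(groups, function(df) {
      tot <- tapply(df$n, df$class, sum)
      best <- max(tot)
      winner <- intersect(ord, names(tot)[tot == best])[1]
      data.frame(model_id = df$model_id[1], fold = df$fold[1],
                 bin_x = df$bin_x[1], bin_y = df$bin_y[1], color = winner)
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (rule == "fold_consistency") {
    if (is.null(n_folds)) n_folds <- max(cells$fold)
    need <- fold_threshold * n_folds
    groups <- split(cells,
                    list(cells$model_id, cells$class, cells$bin_x,
                         cells$bin_y), drop = TRUE)
    out <- do.call(rbind, lapply(groups, function(df) {
      nf <- length(unique(df$fold[df$n > 0]))
      data.frame(model_id = df$model_id[1], class = df$class[1],
                 bin_x = df$bin_x[1], bin_y = df$bin_y[1],
                 n_folds_present = nf, colored = nf >= need)
    }))
    rownames(out) <- NULL
    return(out)
  }
  # model_agreement
  groups <- split(cells, list(cells$class, cells$bin_x, cells$bin_y),
                  drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(df) {
    nm <- length(unique(df$model_id[df$n > 0]))
    row <- data.frame(class = df$class[1], bin_x = df$bin_x[1],
                      bin_y = df$bin_y[1], n_models = nm)
    for (L in levels) row[[sprintf("level_%d_plus", L)]] <- nm >= L
    row
  }))
  rownames(out) <- NULL
  out
}

#' Serialize a bin map as JSON
#'
#' @param bin_map a [project_and_bin()] result.
#' @param path output path.
#' @export
write_bin_map <- function(bin_map, path) {
  jsonlite::write_json(
    list(n_bins = bin_map$n_bins, bounds = bin_map$bounds,
         cells = bin_map$cells),
    path, digits = NA
  )
  invisible(path)
}
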