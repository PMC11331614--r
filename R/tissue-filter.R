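#' Tile filtering configuration
#'
#' Three strategies are supported: `TUMO` keeps tumor tiles only, `NOBG`
#' keeps tumor and non-tumor tissue (drops background only), `ALL` keeps
#' everything. Independently of the strategy, slides whose tumor-tile
#' count falls below `min_tumor_tiles` are excluded from analysis
#' (strictly fewer than the threshold).
#'
#' @param strategy one of `"TUMO"`, `"NOBG"`, `"ALL"`.
#' @param min_tumor_tiles minimum tumor-tile count per slide (default
#'   1000).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(strategy = c("TUMO", "NOBG", "ALL"),
                          min_tumor_tiles = 1000L) {
  strategy <- match.arg(strategy)
  stopifnot(min_tumor_tiles >= 0)
  structure(list(strategy = strategy,
                 min_tumor_tiles = as.integer(min_tumor_tiles)),
            class = "filter_config")
}

region_classes <- function() c("tumor", "non_tumor", "background")

# Color / optical-density summary features of one RGB tile (0..255).
patch_features <- function(tile) {
  px <- matrix(tile, ncol = 3L)
  od <- rgb_to_od(px)
  m <- colMeans(px)
  s <- apply(px, 2L, stats::sd)
  odm <- colMeans(od)
  c(mean_r = m[1], mean_g = m[2], mean_b = m[3],
    sd_r = s[1], sd_g = s[2], sd_b = s[3],
    od_r = odm[1], od_g = odm[2], od_b = odm[3],
    od_total = mean(rowSums(od)),
    rg = m[1] - m[2], bg = m[3] - m[2])
}

#' Train the tumor / non-tumor / background patch classifier
#'
#' A multinomial logistic model on color and optical-density summary
#' features of each patch. The interface is pluggable: any object with a
#' `predict_patches` method returning the three class probabilities can
#' stand in for real-data work (e.g. a CNN exported from another
#' framework).
#'
#' @param patches list of RGB tiles (`h x w x 3`, 0..255).
#' @param labels factor or character vector over
#'   `c("tumor", "non_tumor", "background")`; all three classes must be
#'   present.
#' @return an object of class `patch_classifier`.
#' @export
train_patch_classifier <- function(patches, labels) {
  labels <- factor(as.character(labels), levels = region_classes())
  if (any(is.na(labels))) stop("labels must be tumor/non_tumor/background")
  if (nlevels(droplevels(labels)) < 3L) {
    stop("all three region classes must be present in the training patches")
  }
  X <- t(vapply(patches, patch_features, numeric(12L)))
  df <- data.frame(X, label = labels)
  fit <- nnet::multinom(label ~ ., data = df, trace = FALSE,
                        maxit = 300, MaxNWts = 10000)
  structure(list(fit = fit, feature_names = colnames(X)),
            class = "patch_classifier")
}

#' Classify patches into tumor / non-tumor / background
#'
#' @param classifier a [train_patch_classifier()] object.
#' @param patches list of RGB tiles.
#' @param coords optional data.frame with `x`, `y` tile origins, carried
#'   through to the output.
#' @return data.frame with columns `region_class`, `p_tumor`,
#'   `p_nontumor`, `p_background` (rows sum to 1), plus `x`/`y` when
#'   `coords` is given.
#' @export
classify_patches <- function(classifier, patches, coords = NULL) {
  stopifnot(inherits(classifier, "patch_classifier"))
  X <- t(vapply(patches, patch_features, numeric(12L)))
  colnames(X) <- classifier$feature_names
  pr <- stats::predict(classifier$fit, newdata = data.frame(X), type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L,
                                     dimnames = list(NULL, names(pr)))
  pr <- pr[, region_classes(), drop = FALSE]
  out <- data.frame(
    region_class = region_classes()[max.col(pr, ties.method = "first")],
    p_tumor = pr[, "tumor"],
    p_nontumor = pr[, "non_tumor"],
    p_background = pr[, "background"]
  )
  if (!is.null(coords)) out <- cbind(coords[, c("x", "y")], out)
  rownames(out) <- NULL
  out
}

#' Apply a tile filtering strategy
#'
#' @param tile_labels data.frame with a `region_class` column (e.g. from
#'   [classify_patches()]).
#' @param config a [filter_config()].
#' @return the kept rows of `tile_labels`.
#' @export
apply_filter <- function(tile_labels, config) {
  stopifnot(inherits(config, "filter_config"),
            "region_class" %in% names(tile_labels))
  keep <- switch(config$strategy,
    TUMO = tile_labels$region_class == "tumor",
    NOBG = tile_labels$region_class %in% c("tumor", "non_tumor"),
    ALL  = rep(TRUE, nrow(tile_labels))
  )
  out <- tile_labels[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude slides with too few tumor tiles
#'
#' A slide is retained iff its tumor-tile count is at least
#' `min_tumor_tiles`; counts are taken at the tumor level regardless of
#' the downstream filtering strategy.
#'
#' @param tumor_tile_counts named integer vector (names are slide ids).
#' @param min_tumor_tiles threshold (default 1000); `count < threshold`
#'   excludes the slide.
#' @return character vector of retained slide ids.
#' @export
exclude_sparse_slides <- function(tumor_tile_counts, min_tumor_tiles = 1000L) {
  stopifnot(all(tumor_tile_counts >= 0))
  names(tumor_tile_counts)[tumor_tile_counts >= min_tumor_tiles]
}
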