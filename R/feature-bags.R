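#' Per-slide bag of tile embeddings
#'
#' A feature bag holds one embedding row per kept tile together with the
#' tile's level-0 origin. Features are stored in 32-bit precision (values
#' are snapped to float32 on construction so container round-trips are
#' bitwise lossless).
#'
#' @param slide_id slide identifier.
#' @param features numeric matrix `n_tiles x d`, finite.
#' @param coords integer matrix or data.frame `n_tiles x 2` (`x`, `y`),
#'   same row order as `features`.
#' @param encoder_id identifier of the encoder that produced the rows.
#' @return an object of class `feature_bag`.
#' @export
feature_bag <- function(slide_id, features, coords, encoder_id = "unknown") {
  features <- as.matrix(features)
  if (nrow(features) < 1L) stop("a feature bag needs at least one tile")
  if (any(!is.finite(features))) {
    stop("non-finite values in features for slide ", slide_id)
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (nrow(coords) != nrow(features) || ncol(coords) != 2L) {
    stop("coords must be n_tiles x 2, aligned with features")
  }
  colnames(coords) <- c("x", "y")
  structure(
    list(slide_id = slide_id, features = float32_snap(features),
         coords = coords, encoder_id = encoder_id),
    class = "feature_bag"
  )
}

# Snap doubles to the nearest float32 value (round trip through 4-byte IEEE).
float32_snap <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
               "numeric", n = length(x), size = 4L)
  dim(y) <- d
  y
}

#' Deterministic color-histogram tile encoder
#'
#' Embeds a tile as the seeded random projection of its 3 x `bins`
#' per-channel intensity histogram. This is the default synthetic-mode
#' encoder; any pathology foundation model can be plugged in through the
#' same interface (a list with `id`, `dim` and `encode(tile)`).
#'
#' @param dim output embedding dimension (default 1024, matching the
#'   feature width the MIL model expects).
#' @param bins histogram bins per channel (default 16).
#' @param seed seed fixing the projection matrix.
#' @return an encoder object of class `tile_encoder`.
#' @export
histogram_encoder <- function(dim = 1024L, bins = 16L, seed = 42L) {
  proj <- with_seed(seed, matrix(stats::rnorm(3L * bins * dim), 3L * bins, dim))
  encode <- function(tile) {
    h <- unlist(lapply(1:3, function(ch) {
      tabulate(pmin(floor(tile[, , ch] / (256 / bins)) + 1L, bins), bins)
    }))
    as.numeric((h / sum(h)) %*% proj)
  }
  structure(list(id = sprintf("hist%d-rp%d-seed%d", bins, dim, seed),
                 dim = as.integer(dim), encode = encode),
            class = "tile_encoder")
}

#' Encode tiles into a feature bag
#'
#' @param tiles list of RGB tiles (`h x w x 3`, 0..255).
#' @param encoder a `tile_encoder` (see [histogram_encoder()]).
#' @param coords `n x 2` tile origins aligned with `tiles`.
#' @param slide_id slide identifier.
#' @return a [feature_bag()].
#' @export
encode_tiles <- function(tiles, encoder, coords, slide_id) {
  stopifnot(inherits(encoder, "tile_encoder"))
  feats <- t(vapply(tiles, function(tl) {
    v <- encoder$encode(tl)
    if (length(v) != encoder$dim) {
      stop("encoder returned ", length(v), " values, declared dim is ",
           encoder$dim)
    }
    v
  }, numeric(encoder$dim)))
  feature_bag(slide_id, feats, coords, encoder_id = encoder$id)
}

#' Feature-bag store
#'
#' A directory-backed container with one group per slide holding the
#' `features` (float32) and `coords` (int32) datasets, plus a CSV
#' manifest. Round-trips are bitwise lossless at 32-bit precision.
#'
#' @param dir directory path (created if missing).
#' @return an object of class `bag_store`.
#' @export
bag_store <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  structure(list(dir = dir), class = "bag_store")
}

store_manifest_path <- function(store) file.path(store$dir, "manifest.csv")

read_store_manifest <- function(store) {
  p <- store_manifest_path(store)
  if (!file.exists(p)) {
    return(data.frame(slide_id = character(), n_tiles = integer(),
                      dim = integer(), encoder_id = character()))
  }
  utils::read.csv(p, colClasses = c("character", "integer", "integer",
                                    "character"))
}

#' Write a feature bag into a store
#'
#' @param store a [bag_store()].
#' @param bag a [feature_bag()].
#' @export
write_bag <- function(store, bag) {
  stopifnot(inherits(store, "bag_store"), inherits(bag, "feature_bag"))
  base <- file.path(store$dir, bag$slide_id)
  con <- file(paste0(base, ".feat"), "wb")
  writeBin(as.numeric(t(bag$features)), con, size = 4L)
  close(con)
  con <- file(paste0(base, ".coords"), "wb")
  writeBin(as.integer(t(bag$coords)), con, size = 4L)
  close(con)
  man <- read_store_manifest(store)
  man <- man[man$slide_id != bag$slide_id, , drop = FALSE]
  man <- rbind(man, data.frame(slide_id = bag$slide_id,
                               n_tiles = nrow(bag$features),
                               dim = ncol(bag$features),
                               encoder_id = bag$encoder_id))
  utils::write.csv(man, store_manifest_path(store), row.names = FALSE)
  invisible(store)
}

#' Read a feature bag back from a store
#'
#' @param store a [bag_store()].
#' @param slide_id slide identifier.
#' @return a [feature_bag()].
#' @export
read_bag <- function(store, slide_id) {
  stopifnot(inherits(store, "bag_store"))
  man <- read_store_manifest(store)
  row <- man[man$slide_id == slide_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("slide '", slide_id, "' not found in bag store")
  n <- row$n_tiles; d <- row$dim
  fpath <- file.path(store$dir, paste0(slide_id, ".feat"))
  cpath <- file.path(store$dir, paste0(slide_id, ".coords"))
  if (!file.exists(fpath) || file.info(fpath)$size != 4 * n * d) {
    stop("corrupt bag container for slide '", slide_id,
         "': feature dataset missing or truncated")
  }
  if (!file.exists(cpath) || file.info(cpath)$size != 4 * n * 2) {
    stop("corrupt bag container for slide '", slide_id,
         "': coords dataset missing or truncated")
  }
  feats <- matrix(readBin(fpath, "numeric", n = n * d, size = 4L),
                  nrow = n, byrow = TRUE)
  coords <- matrix(readBin(cpath, "integer", n = n * 2L, size = 4L),
                   nrow = n, byrow = TRUE)
  feature_bag(slide_id, feats, coords, encoder_id = row$encoder_id)
}

#' List slide ids available in a store
#'
#' @param store a [bag_store()].
#' @return character vector of slide ids.
#' @export
list_bags <- function(store) {
  read_store_manifest(store)$slide_id
}
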