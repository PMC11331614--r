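#' Optical density conversion
#'
#' Beer-Lambert optical density per channel, `OD = -log10((I + 1) / 256)`
#' for intensities `I` in 0..255 (the +1 offset avoids `log(0)` on pure
#' black).
#'
#' @param img numeric array or matrix of intensities in 0..255.
#' @return same shape, optical densities (>= 0).
#' @export
rgb_to_od <- function(img) {
  -log10((img + 1) / 256)
}

#' @rdname rgb_to_od
#' @param od optical densities.
#' @return intensities in 0..255 (not rounded).
#' @export
od_to_rgb <- function(od) {
  pmin(pmax(256 * 10^(-od) - 1, 0), 255)
}

# canonical H&E stain directions in OD space (unit columns, H first)
canonical_he_matrix <- function() {
  m <- cbind(H = c(0.65, 0.70, 0.29), E = c(0.07, 0.99, 0.11))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Estimate an H&E stain profile from an RGB image (Macenko method)
#'
#' Projects tissue pixels into optical-density space, finds the top-2
#' singular plane, and takes the extreme angle percentiles of the pixel
#' projections as the hematoxylin and eosin directions. Per-stain robust
#' maximum concentrations (99th percentile) complete the profile.
#'
#' @param img numeric array `H x W x 3` (or `n x 3` matrix) in 0..255.
#' @param od_threshold pixels whose maximum channel OD falls below this are
#'   treated as background and excluded (default 0.15).
#' @param angle_percentiles lower/upper angle percentiles defining the two
#'   stain directions (default `c(0.01, 0.99)`).
#' @param min_tissue_px minimum number of tissue pixels required (default
#'   100).
#' @return an object of class `stain_profile`: list with `stain_matrix`
#'   (3 x 2 unit columns, hematoxylin first — the column with the larger
#'   red-channel OD) and `max_conc` (length-2 positive vector).
#' @export
estimate_stain_profile <- function(img, od_threshold = 0.15,
                                   angle_percentiles = c(0.01, 0.99),
                                   min_tissue_px = 100L) {
  px <- if (is.matrix(img)) img else matrix(img, ncol = 3L)
  od <- rgb_to_od(px)
  tissue <- od[apply(od, 1L, max) >= od_threshold, , drop = FALSE]
  if (nrow(tissue) < min_tissue_px) {
    stop("background-only tile: too few pixels above the OD threshold")
  }
  sv <- svd(tissue, nu = 0, nv = 2)
  V <- sv$v  # 3 x 2 basis of the stain plane
  # orient the basis so projections land in a consistent half-plane
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  proj <- tissue %*% V
  ang <- atan2(proj[, 2], proj[, 1])
  qa <- stats::quantile(ang, angle_percentiles, names = FALSE)
  dir1 <- V %*% c(cos(qa[1]), sin(qa[1]))
  dir2 <- V %*% c(cos(qa[2]), sin(qa[2]))
  fix <- function(v) {
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    v / sqrt(sum(v^2))
  }
  dirs <- cbind(fix(dir1), fix(dir2))
  # hematoxylin absorbs red: larger red-channel OD goes first
  if (dirs[1, 1] < dirs[1, 2]) dirs <- dirs[, 2:1]
  colnames(dirs) <- c("H", "E")
  conc <- stain_concentrations(tissue, dirs)
  max_conc <- apply(conc, 2L, stats::quantile, probs = 0.99, names = FALSE)
  max_conc <- pmax(max_conc, .Machine$double.eps)
  structure(list(stain_matrix = dirs, max_conc = max_conc),
            class = "stain_profile")
}

# Non-negative least squares of OD pixels (n x 3) against a 3 x 2 stain
# matrix, solved exactly per pixel: unconstrained 2x2 solve, then the
# active-set fix-up for the (at most one) negative coordinate.
stain_concentrations <- function(od, stain_matrix) {
  M <- stain_matrix
  G <- crossprod(M)          # 2 x 2
  Gi <- solve(G)
  C <- od %*% M %*% Gi       # unconstrained solution, n x 2
  m11 <- sum(M[, 1]^2); m22 <- sum(M[, 2]^2)
  neg1 <- C[, 1] < 0
  if (any(neg1)) {
    C[neg1, 1] <- 0
    C[neg1, 2] <- pmax(0, od[neg1, , drop = FALSE] %*% M[, 2] / m22)
  }
  neg2 <- !neg1 & C[, 2] < 0
  if (any(neg2)) {
    C[neg2, 2] <- 0
    C[neg2, 1] <- pmax(0, od[neg2, , drop = FALSE] %*% M[, 1] / m11)
  }
  colnames(C) <- colnames(M)
  C
}

#' Normalize a tile's stain to a reference profile
#'
#' Solves per-pixel stain concentrations against the source profile,
#' rescales each stain by the ratio of reference to source maximum
#' concentration, and re-renders with the reference stain matrix.
#' Background pixels carry near-zero concentrations and pass through
#' near-white.
#'
#' @param tile numeric array `h x w x 3` in 0..255.
#' @param source_profile,reference_profile `stain_profile` objects.
#' @return array of the same shape, integer-valued in 0..255.
#' @export
normalize_tile <- function(tile, source_profile, reference_profile) {
  stopifnot(inherits(source_profile, "stain_profile"),
            inherits(reference_profile, "stain_profile"))
  dims <- dim(tile)
  px <- matrix(tile, ncol = 3L)
  conc <- stain_concentrations(rgb_to_od(px), source_profile$stain_matrix)
  scale <- reference_profile$max_conc / source_profile$max_conc
  conc <- sweep(conc, 2L, scale, "*")
  out <- od_to_rgb(conc %*% t(reference_profile$stain_matrix))
  array(round(out), dims)
}

#' Synthetic H&E-like reference tile
#'
#' A deterministic Beer-Lambert rendering from the canonical H&E stain
#' matrix, used as the bundled normalization reference. It is a synthetic
#' stand-in: any real reference image can be supplied instead.
#'
#' @param size image side in pixels (default 64).
#' @param seed RNG seed (default 7).
#' @return numeric array `size x size x 3` in 0..255.
#' @export
synthetic_reference_tile <- function(size = 64L, seed = 7L) {
  with_seed(seed, {
    n <- size * size
    # mixture of hematoxylin-rich, eosin-rich and pale pixels
    kind <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    cH <- ifelse(kind == 1, 0.9 + 0.4 * stats::runif(n),
          ifelse(kind == 2, 0.15 * stats::runif(n), 0.02 * stats::runif(n)))
    cE <- ifelse(kind == 2, 0.7 + 0.3 * stats::runif(n),
          ifelse(kind == 1, 0.2 * stats::runif(n), 0.02 * stats::runif(n)))
    od <- cbind(cH, cE) %*% t(canonical_he_matrix())
    array(round(od_to_rgb(od)), c(size, size, 3L))
  })
}

#' Default reference stain profile
#'
#' The Macenko profile of [synthetic_reference_tile()].
#'
#' @return a `stain_profile`.
#' @export
default_reference_profile <- function() {
  estimate_stain_profile(synthetic_reference_tile())
}

#' Serialize / restore a stain profile as JSON
#'
#' @param profile a `stain_profile`.
#' @param path JSON file path.
#' @export
write_stain_profile <- function(profile, path) {
  jsonlite::write_json(
    list(stain_matrix = profile$stain_matrix, max_conc = profile$max_conc),
    path, digits = NA
  )
  invisible(path)
}

#' @rdname write_stain_profile
#' @export
read_stain_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(x$stain_matrix), ncol = 2L)
  colnames(m) <- c("H", "E")
  structure(list(stain_matrix = m,
                 max_conc = stats::setNames(as.numeric(x$max_conc),
                                            c("H", "E"))),
            class = "stain_profile")
}
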