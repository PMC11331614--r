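#' Synthetic cohort configuration
#'
#' The generator emulates the statistical structure the analysis assumes:
#' each slide is a bag of tile embeddings drawn from `n_bg_clusters`
#' background Gaussian clusters shared by all classes, plus a
#' class-specific "witness" cluster (mean shifted by `delta`) present
#' only on HER2-low and HER2-high slides at a per-slide prevalence drawn
#' from a Beta distribution centered on `p_low` / `p_high`. Observed
#' IHC/ISH results follow a simple assay model (high: 3+ with
#' probability 0.7, else 2+/ISH-pos; low: 1+ with probability 0.6, else
#' 2+/ISH-neg; neg: 0), after which IHC 0 and 1+ calls are swapped with
#' probability `label_noise` — mimicking the documented interobserver
#' disagreement between HER2 0 and 1+ while 2+/3+ calls stay clean.
#'
#' @param n_per_class slides per latent class per synthetic site
#'   (default 10; two sites, three classes — 60 slides).
#' @param cohorts synthetic site names, round-robined over slides.
#' @param tiles_range min/max tiles per slide (default `c(50, 200)`).
#' @param d embedding dimension (default 32; paper-scale work uses 1024).
#' @param n_bg_clusters shared background clusters (default 10).
#' @param delta witness mean-shift magnitude (default 6, i.e. 6 sigma:
#'   clearly separable witnesses).
#' @param sigma within-cluster standard deviation (default 1).
#' @param p_low,p_high mean witness prevalence on low/high slides
#'   (defaults 0.10, 0.20).
#' @param beta_concentration concentration of the per-slide prevalence
#'   Beta (default 20).
#' @param p_3plus_given_high,p_1plus_given_low assay model probabilities
#'   (defaults 0.7, 0.6).
#' @param label_noise probability of swapping an observed IHC 0 with 1+
#'   (default 0).
#' @param seed integer seed; the generator is fully deterministic.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 10L, cohorts = c("SYNTH_A", "SYNTH_B"),
                         tiles_range = c(50L, 200L), d = 32L,
                         n_bg_clusters = 10L, delta = 6, sigma = 1,
                         p_low = 0.10, p_high = 0.20,
                         beta_concentration = 20,
                         p_3plus_given_high = 0.7, p_1plus_given_low = 0.6,
                         label_noise = 0, seed = 1L) {
  stopifnot_scalar_prob(p_low, "p_low")
  stopifnot_scalar_prob(p_high, "p_high")
  stopifnot_scalar_prob(label_noise, "label_noise")
  stopifnot_scalar_prob(p_3plus_given_high, "p_3plus_given_high")
  stopifnot_scalar_prob(p_1plus_given_low, "p_1plus_given_low")
  stopifnot(delta > 0, sigma > 0, tiles_range[1] >= 2,
            tiles_range[2] >= tiles_range[1])
  structure(
    list(n_per_class = as.integer(n_per_class), cohorts = cohorts,
         tiles_range = as.integer(tiles_range), d = as.integer(d),
         n_bg_clusters = as.integer(n_bg_clusters), delta = delta,
         sigma = sigma, p_low = p_low, p_high = p_high,
         beta_concentration = beta_concentration,
         p_3plus_given_high = p_3plus_given_high,
         p_1plus_given_low = p_1plus_given_low,
         label_noise = label_noise, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic cohort of slide records and feature bags
#'
#' @param config a [synth_config()].
#' @return list with `records` (slide manifest data.frame with extra
#'   columns `latent_class` and `witness_fraction`), `bags` (named list
#'   of [feature_bag()]s keyed by slide id) and `witness` (named list of
#'   logical vectors flagging the planted witness tiles of each bag).
#' @export
generate_cohort <- function(config = synth_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    mu_bg <- matrix(stats::rnorm(cfg$n_bg_clusters * cfg$d, sd = 2),
                    cfg$n_bg_clusters, cfg$d)
    unit <- function() {
      v <- stats::rnorm(cfg$d)
      v / sqrt(sum(v^2))
    }
    mu_wit <- list(low = unit() * cfg$delta, high = unit() * cfg$delta)

    classes <- rep(c("neg", "low", "high"),
                   each = cfg$n_per_class * length(cfg$cohorts))
    n_slides <- length(classes)
    cohort <- cfg$cohorts[((seq_len(n_slides) - 1L) %% length(cfg$cohorts)) + 1L]

    records <- list()
    bags <- list()
    witness <- list()
    for (i in seq_len(n_slides)) {
      sid <- sprintf("S%03d", i)
      cl <- classes[i]
      n_tiles <- sample(cfg$tiles_range[1]:cfg$tiles_range[2], 1L)
      p_c <- switch(cl, neg = 0, low = cfg$p_low, high = cfg$p_high)
      frac <- if (p_c > 0) {
        stats::rbeta(1, p_c * cfg$beta_concentration,
                     (1 - p_c) * cfg$beta_concentration)
      } else 0
      n_wit <- round(frac * n_tiles)
      is_wit <- rep(FALSE, n_tiles)
      if (n_wit > 0) is_wit[sample.int(n_tiles, n_wit)] <- TRUE
      X <- matrix(0, n_tiles, cfg$d)
      n_bg <- sum(!is_wit)
      if (n_bg > 0) {
        cid <- sample.int(cfg$n_bg_clusters, n_bg, replace = TRUE)
        X[!is_wit, ] <- mu_bg[cid, , drop = FALSE] +
          matrix(stats::rnorm(n_bg * cfg$d, sd = cfg$sigma), n_bg, cfg$d)
      }
      if (n_wit > 0) {
        X[is_wit, ] <- matrix(mu_wit[[cl]], n_wit, cfg$d, byrow = TRUE) +
          matrix(stats::rnorm(n_wit * cfg$d, sd = cfg$sigma), n_wit, cfg$d)
      }
      idx <- seq_len(n_tiles) - 1L
      coords <- cbind(x = (idx %% 20L) * 128L, y = (idx %/% 20L) * 128L)

      # assay model
      if (cl == "high") {
        if (stats::runif(1) < cfg$p_3plus_given_high) {
          ihc <- "3+"; ish <- "absent"
        } else {
          ihc <- "2+"; ish <- "pos"
        }
      } else if (cl == "low") {
        if (stats::runif(1) < cfg$p_1plus_given_low) {
          ihc <- "1+"; ish <- "absent"
        } else {
          ihc <- "2+"; ish <- "neg"
        }
      } else {
        ihc <- "0"; ish <- "absent"
      }
      if (ihc %in% c("0", "1+") && stats::runif(1) < cfg$label_noise) {
        ihc <- if (ihc == "0") "1+" else "0"
      }

      records[[i]] <- data.frame(
        slide_id = sid, patient_id = sprintf("P%03d", i),
        cohort = cohort[i], ihc = ihc, ish = ish,
        latent_class = cl, witness_fraction = frac
      )
      bags[[sid]] <- feature_bag(sid, X, coords, encoder_id = "synthetic")
      witness[[sid]] <- is_wit
    }
    list(records = do.call(rbind, records), bags = bags, witness = witness)
  })
}

#' Generate labeled synthetic RGB patches
#'
#' Fixture patches for the tissue filter and stain normalization stages:
#' near-white background, eosin-dominant (pink) non-tumor tissue and
#' hematoxylin-dominant (purple) tumor tissue, rendered by Beer-Lambert
#' mixing from a known stain matrix which is recorded in the result so
#' stain-vector recovery can be verified.
#'
#' @param n_per_class patches per region class (default 20).
#' @param tile_px patch side in pixels (default 32).
#' @param seed integer seed.
#' @return list with `patches` (list of `tile_px x tile_px x 3` arrays in
#'   0..255), `labels` (factor over tumor/non_tumor/background) and
#'   `stain_matrix` (the 3 x 2 ground-truth matrix).
#' @export
generate_tile_images <- function(n_per_class = 20L, tile_px = 32L, seed = 1L) {
  M <- canonical_he_matrix()
  with_seed(seed, {
    n_px <- tile_px * tile_px
    render <- function(cH, cE) {
      od <- cbind(cH, cE) %*% t(M)
      array(round(od_to_rgb(od)), c(tile_px, tile_px, 3L))
    }
    make <- function(kind) {
      switch(kind,
        background = {
          base <- 245 + stats::rnorm(n_px * 3, sd = 3)
          array(round(pmin(pmax(base, 0), 255)), c(tile_px, tile_px, 3L))
        },
        # concentration ranges reach ~0 so tiles contain near-pure-stain
        # pixels (nuclei-only / stroma-only regions), as the angle-extreme
        # estimation of the stain directions requires
        non_tumor = render(0.12 * stats::runif(n_px),
                           0.55 + 0.35 * stats::runif(n_px)),
        tumor = render(0.65 + 0.45 * stats::runif(n_px),
                       0.20 * stats::runif(n_px))
      )
    }
    kinds <- rep(region_classes(), each = n_per_class)
    patches <- lapply(kinds, make)
    list(patches = patches,
         labels = factor(kinds, levels = region_classes()),
         stain_matrix = M)
  })
}
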