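# Small handcrafted manifest covering all five assay cells and two sites.
tiny_manifest <- function() {
  data.frame(
    slide_id = sprintf("sl%02d", 1:12),
    patient_id = c("p01", "p02", "p03", "p04", "p05", "p06",
                   "p07", "p08", "p09", "p10", "p10", "p11"),
    cohort = rep(c("A", "B"), 6),
    ihc = c("0", "0", "1+", "1+", "2+", "2+", "2+", "2+", "3+", "3+",
            "3+", "0"),
    ish = c("absent", "absent", "absent", "absent", "neg", "neg", "pos",
            "pos", "absent", "absent", "absent", "absent"),
    stringsAsFactors = FALSE
  )
}

# Random bags for shape/permutation tests.
tiny_bags <- function(n_slides = 6, n_tiles = 12, d = 8, seed = 1) {
  set.seed(seed)
  bags <- lapply(seq_len(n_slides), function(i) {
    matrix(rnorm(n_tiles * d), n_tiles, d)
  })
  names(bags) <- sprintf("sl%02d", seq_len(n_slides))
  bags
}

tiny_mil_cfg <- function(n_classes = 2, ...) {
  mil_config(d_in = 8, d_proj = 6, d_attn = 4, n_classes = n_classes,
             k_sample = 2, ...)
}

angle_between <- function(a, b) acos(pmin(1, abs(sum(a * b))))
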