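#' Hold-out and cross-validation split plan
#'
#' Cases are first stratified by (class label, cohort); 15% of each stratum
#' is set aside as a hold-out test set. The remaining cases are then split,
#' independently for each of `n_folds` folds, into a training (85%) and a
#' validation (15%) set within each stratum, so label distribution and
#' cohort proportion are preserved everywhere. Assignment is done at the
#' patient level: all slides of one patient share one role, so no patient
#' can leak across train/validation/hold-out.
#'
#' @param holdout_fraction fraction of cases per stratum held out (default
#'   0.15).
#' @param n_folds number of cross-validation folds (default 10).
#' @param val_fraction fraction of the non-hold-out cases used as the
#'   validation set within each fold (default 0.15).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param external_cohorts cohort names reserved as external test sets;
#'   their slides are never placed in folds or the hold-out.
#' @return an object of class `split_plan`.
#' @export
split_plan <- function(holdout_fraction = 0.15, n_folds = 10,
                       val_fraction = 0.15, seed = 1L,
                       external_cohorts = character()) {
  stopifnot_scalar_prob(holdout_fraction, "holdout_fraction")
  stopifnot_scalar_prob(val_fraction, "val_fraction")
  stopifnot(n_folds >= 1)
  structure(
    list(holdout_fraction = holdout_fraction, n_folds = as.integer(n_folds),
         val_fraction = val_fraction, seed = as.integer(seed),
         external_cohorts = external_cohorts),
    class = "split_plan"
  )
}

# Sample `k` patients from `ids` (ids are pre-sorted for determinism).
sample_ids <- function(ids, k) {
  if (k <= 0L) return(character())
  if (k >= length(ids)) return(ids)
  ids[sample.int(length(ids), k)]
}

#' Assign slides to hold-out, fold training and fold validation sets
#'
#' @param records data.frame with `slide_id`, `patient_id`, `cohort` and a
#'   `label` column (e.g. from [build_partition()]); a `her2_group` column
#'   is used when `label` is absent.
#' @param plan a [split_plan()].
#' @return an object of class `split_assignment`: list with `holdout`
#'   (patient ids), `folds` (list of `list(train=, val=)` patient ids),
#'   `external` (patient ids), `table` (long data.frame `slide_id`,
#'   `patient_id`, `role`) and `seed`.
#' @details Strata with fewer than 2 patients are merged, with a warning,
#'   into the largest stratum carrying the same label (or the overall
#'   largest stratum if none). Per-stratum counts are rounded half-up; this
#'   keeps train/validation class proportions within one case of each
#'   other.
#' @export
make_splits <- function(records, plan = split_plan()) {
  stopifnot(inherits(plan, "split_plan"))
  if (is.null(records$label)) {
    if (is.null(records$her2_group)) {
      records$her2_group <- assign_her2_group(records$ihc, records$ish)
    }
    records$label <- records$her2_group
  }
  records$label <- as.character(records$label)

  external <- records$cohort %in% plan$external_cohorts
  ext_recs <- records[external, , drop = FALSE]
  records <- records[!external, , drop = FALSE]
  if (nrow(records) == 0L) stop("no non-external cases to split")

  # one row per patient; a patient's stratum comes from its first slide
  ord <- order(records$patient_id, records$slide_id)
  records <- records[ord, , drop = FALSE]
  pat <- records[!duplicated(records$patient_id), , drop = FALSE]
  multi <- tapply(records$label, records$patient_id,
                  function(x) length(unique(x)))
  if (any(multi > 1L)) {
    warning("patients with conflicting labels across slides; ",
            "first slide's label used for stratification")
  }
  pat$stratum <- paste(pat$label, pat$cohort, sep = "|")

  # merge degenerate strata (< 2 patients) into the nearest one by label
  counts <- table(pat$stratum)
  small <- names(counts)[counts < 2L]
  for (s in small) {
    lab <- sub("\\|.*$", "", s)
    cand <- setdiff(names(counts)[counts >= 2L], s)
    same_lab <- cand[sub("\\|.*$", "", cand) == lab]
    target <- if (length(same_lab)) {
      same_lab[which.max(counts[same_lab])]
    } else if (length(cand)) {
      cand[which.max(counts[cand])]
    } else {
      NA_character_
    }
    if (!is.na(target)) {
      warning(sprintf("stratum '%s' has < 2 cases; merged into '%s'", s, target))
      pat$stratum[pat$stratum == s] <- target
      counts <- table(pat$stratum)
    }
  }

  strata <- sort(unique(pat$stratum))
  res <- with_seed(plan$seed, {
    holdout <- character()
    for (s in strata) {
      ids <- sort(pat$patient_id[pat$stratum == s])
      n_hold <- round_half_up(plan$holdout_fraction * length(ids))
      holdout <- c(holdout, sample_ids(ids, n_hold))
    }
    remaining <- pat[!pat$patient_id %in% holdout, , drop = FALSE]
    folds <- vector("list", plan$n_folds)
    for (k in seq_len(plan$n_folds)) {
      val <- character()
      for (s in strata) {
        ids <- sort(remaining$patient_id[remaining$stratum == s])
        n_val <- round_half_up(plan$val_fraction * length(ids))
        val <- c(val, sample_ids(ids, n_val))
      }
      folds[[k]] <- list(train = setdiff(remaining$patient_id, val),
                         val = val)
    }
    list(holdout = holdout, folds = folds)
  })

  role_of <- function(pids, role) {
    rows <- records[records$patient_id %in% pids, c("slide_id", "patient_id")]
    if (nrow(rows)) rows$role <- role
    rows
  }
  tabs <- list(role_of(res$holdout, "holdout"))
  for (k in seq_len(plan$n_folds)) {
    tabs <- c(tabs, list(role_of(res$folds[[k]]$train, sprintf("fold_%d_train", k)),
                         role_of(res$folds[[k]]$val, sprintf("fold_%d_val", k))))
  }
  if (nrow(ext_recs)) {
    er <- ext_recs[, c("slide_id", "patient_id")]
    er$role <- "external"
    tabs <- c(tabs, list(er))
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL

  structure(
    list(holdout = res$holdout, folds = res$folds,
         external = unique(ext_recs$patient_id), table = table,
         seed = plan$seed, n_folds = plan$n_folds),
    class = "split_assignment"
  )
}

#' Write split assignments to CSV
#'
#' One row per (slide, role); the seed is recorded in a comment-free
#' sidecar column so the file is self-describing.
#'
#' @param splits a `split_assignment` from [make_splits()].
#' @param path output CSV path.
#' @export
write_splits <- function(splits, path) {
  tab <- splits$table
  tab$seed <- splits$seed
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
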