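#' Derive the HER2 group from IHC score and ISH status
#'
#' Clinical HER2 assessment uses a four-tier immunohistochemistry (IHC)
#' score (0, 1+, 2+, 3+); equivocal 2+ cases are resolved by an in-situ
#' hybridization (ISH) assay. The three therapeutic groups are derived as:
#' IHC 0 is HER2-negative; IHC 1+ and IHC 2+/ISH-negative are HER2-low;
#' IHC 2+/ISH-positive and IHC 3+ are HER2-high.
#'
#' @param ihc character vector of IHC scores, one of `"0"`, `"1+"`, `"2+"`,
#'   `"3+"`.
#' @param ish character vector of ISH statuses, one of `"neg"`, `"pos"`,
#'   `"absent"` (`NA` is treated as `"absent"`). Required (non-absent) when
#'   `ihc == "2+"`.
#' @return character vector with values `"neg"`, `"low"`, `"high"`.
#' @examples
#' assign_her2_group("2+", "neg")   # "low"
#' assign_her2_group("0", "absent") # "neg"
#' @export
assign_her2_group <- function(ihc, ish) {
  ihc <- as.character(ihc)
  ish <- as.character(ish)
  ish[is.na(ish)] <- "absent"
  if (length(ish) == 1L && length(ihc) > 1L) ish <- rep(ish, length(ihc))
  stopifnot(length(ihc) == length(ish))
  bad_ihc <- !ihc %in% c("0", "1+", "2+", "3+")
  if (any(bad_ihc)) {
    stop("invalid IHC score(s): ", paste(unique(ihc[bad_ihc]), collapse = ", "))
  }
  bad_ish <- !ish %in% c("neg", "pos", "absent")
  if (any(bad_ish)) {
    stop("invalid ISH status(es): ", paste(unique(ish[bad_ish]), collapse = ", "))
  }
  if (any(ihc == "2+" & ish == "absent")) {
    stop("IHC 2+ is equivocal: ISH status required to resolve HER2 group")
  }
  out <- character(length(ihc))
  out[ihc == "0"] <- "neg"
  out[ihc == "1+"] <- "low"
  out[ihc == "2+" & ish == "neg"] <- "low"
  out[ihc == "2+" & ish == "pos"] <- "high"
  out[ihc == "3+"] <- "high"
  out
}

# The five legal (ihc, ish) assay cells, in fixed display order.
her2_cells <- function() {
  c("0", "1+", "2+/neg", "2+/pos", "3+")
}

# Map a record's (ihc, ish) to its assay cell key.
her2_cell_of <- function(ihc, ish) {
  ish <- as.character(ish)
  ish[is.na(ish)] <- "absent"
  ifelse(ihc == "2+", paste0("2+/", ish), as.character(ihc))
}

#' Partition definitions for the six HER2 training scenarios
#'
#' Each scenario trains on a different subset of the five assay cells
#' \{IHC 0, 1+, 2+/ISH-neg, 2+/ISH-pos, 3+\} and maps the included cells to
#' two or three HER2 classes:
#' \describe{
#'   \item{M1}{2+/neg -> low vs 2+/pos, 3+ -> high (binary; the equivocal-2+
#'     triage scenario).}
#'   \item{M2}{0 -> neg vs 2+/pos, 3+ -> high (binary).}
#'   \item{M3}{1+, 2+/neg -> low vs 2+/pos, 3+ -> high (binary).}
#'   \item{M4}{0 -> neg, 1+ and 2+/neg -> low, 3+ -> high (3-class;
#'     HER2-high restricted to IHC 3+, see the methods vignette).}
#'   \item{M5}{0 -> neg vs 1+, 2+/neg -> low (binary; the hard
#'     neg-versus-low scenario).}
#'   \item{M6}{all five cells, 3 classes.}
#' }
#'
#' @param model_id one of `"M1"`..`"M6"`.
#' @param m4_cells optional override for the M4 cell-to-class map, a named
#'   character vector `c(cell = class, ...)` over assay cells.
#' @return an object of class `partition_spec`: list with `model_id`,
#'   `class_map` (named character vector, names are assay cells), `classes`
#'   (ordered levels actually used) and `n_classes`.
#' @export
partition_spec <- function(model_id, m4_cells = NULL) {
  maps <- list(
    M1 = c("2+/neg" = "low", "2+/pos" = "high", "3+" = "high"),
    M2 = c("0" = "neg", "2+/pos" = "high", "3+" = "high"),
    M3 = c("1+" = "low", "2+/neg" = "low", "2+/pos" = "high", "3+" = "high"),
    M4 = c("0" = "neg", "1+" = "low", "2+/neg" = "low", "3+" = "high"),
    M5 = c("0" = "neg", "1+" = "low", "2+/neg" = "low"),
    M6 = c("0" = "neg", "1+" = "low", "2+/neg" = "low",
           "2+/pos" = "high", "3+" = "high")
  )
  if (!model_id %in% names(maps)) {
    stop("unknown model_id: ", model_id, " (expected M1..M6)")
  }
  class_map <- maps[[model_id]]
  if (model_id == "M4" && !is.null(m4_cells)) {
    if (!all(names(m4_cells) %in% her2_cells())) {
      stop("m4_cells names must be assay cells: ",
           paste(her2_cells(), collapse = ", "))
    }
    class_map <- m4_cells
  }
  classes <- intersect(c("neg", "low", "high"), unique(unname(class_map)))
  structure(
    list(model_id = model_id, class_map = class_map,
         classes = classes, n_classes = length(classes)),
    class = "partition_spec"
  )
}

#' Restrict a slide manifest to one training partition
#'
#' Drops slides whose assay cell is not part of the scenario and attaches
#' the scenario class label. Excluded cells are dropped, never relabeled.
#'
#' @param model_id `"M1"`..`"M6"`.
#' @param records slide manifest data.frame with columns `slide_id`,
#'   `patient_id`, `cohort`, `ihc`, `ish` (see [read_manifest()]).
#' @param m4_cells passed to [partition_spec()].
#' @return list with `records` (the retained rows plus columns `cell`,
#'   `her2_group`, `label`) and `spec` (the [partition_spec()]).
#' @export
build_partition <- function(model_id, records, m4_cells = NULL) {
  spec <- partition_spec(model_id, m4_cells = m4_cells)
  records$cell <- her2_cell_of(records$ihc, records$ish)
  records$her2_group <- assign_her2_group(records$ihc, records$ish)
  keep <- records$cell %in% names(spec$class_map)
  out <- records[keep, , drop = FALSE]
  out$label <- factor(unname(spec$class_map[out$cell]), levels = spec$classes)
  rownames(out) <- NULL
  list(records = out, spec = spec)
}

#' Read / write a slide manifest
#'
#' The manifest is a CSV with header `slide_id,patient_id,cohort,ihc,ish`;
#' `ihc` is serialized as `0/1/2/3` and `ish` as `neg/pos/NA`.
#'
#' @param path file path.
#' @return data.frame with character columns `slide_id`, `patient_id`,
#'   `cohort`, `ihc` (as `"0"`, `"1+"`, ...), `ish` (`"neg"`, `"pos"`,
#'   `"absent"`).
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("slide_id", "patient_id", "cohort", "ihc", "ish")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  plus <- c("0" = "0", "1" = "1+", "2" = "2+", "3" = "3+")
  df$ihc <- ifelse(df$ihc %in% names(plus), plus[df$ihc], df$ihc)
  df$ish[df$ish == "" | is.na(df$ish) | df$ish == "NA"] <- "absent"
  df
}

#' @rdname read_manifest
#' @param records manifest data.frame.
#' @export
write_manifest <- function(records, path) {
  out <- records[, c("slide_id", "patient_id", "cohort", "ihc", "ish")]
  out$ihc <- sub("\\+$", "", out$ihc)
  out$ish[out$ish == "absent"] <- NA
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}
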