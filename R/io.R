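# Delimited-table I/O for the dataset ------------------------------------
#
# File layout (all CSV, documented column names, stable across versions):
#   npx_wide.csv    sample_id + one numeric column per protein
#   sample_meta.csv sample_id, group, age, race, batch, is_bridging, pcl, moca
#   panel_map.csv   protein, panel
#   lod.csv         protein, batch ("all" = global), lod
#   below_lod.csv   sample_id + one 0/1 column per protein
#   truth.json      simulation ground truth (only for synthetic datasets)

#' Write a dataset to a directory
#'
#' @param data list with `expr` ([npx_matrix()]), `meta`, and optionally
#'   `truth` (written as JSON).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- data$expr
  stopifnot(inherits(x, "npx_matrix"))
  wide <- data.frame(sample_id = rownames(x$values), x$values,
                     check.names = FALSE)
  utils::write.csv(wide, file.path(dir, "npx_wide.csv"), row.names = FALSE)
  utils::write.csv(data$meta, file.path(dir, "sample_meta.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(protein = names(x$panel),
                              panel = unname(x$panel)),
                   file.path(dir, "panel_map.csv"), row.names = FALSE)
  utils::write.csv(x$lod, file.path(dir, "lod.csv"), row.names = FALSE)
  mask <- data.frame(sample_id = rownames(x$values),
                     1L * x$below_lod, check.names = FALSE)
  utils::write.csv(mask, file.path(dir, "below_lod.csv"), row.names = FALSE)
  if (!is.null(data$truth)) {
    truth <- data$truth
    # serialize named vectors as two-column tables so names survive JSON
    truth$true_burden_model <- data.frame(
      protein = names(truth$true_burden_model),
      model = unname(truth$true_burden_model))
    truth$baseline <- data.frame(protein = names(truth$baseline),
                                 baseline = unname(truth$baseline))
    truth$group_effects <- NULL
    truth$batch_shifts <- data.frame(batch = rownames(truth$batch_shifts),
                                     truth$batch_shifts,
                                     check.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a dataset from a directory
#'
#' Validates the schema (named errors for missing columns, duplicate sample
#' ids and protein/panel mismatches), aligns the metadata with the
#' expression rows, and reports dropped/unmatched ids.
#'
#' @param dir directory written by [write_dataset()] (or with the same
#'   layout).
#' @param check_cutoffs verify PCL/MoCA consistency with group labels.
#' @return list with `expr` ([npx_matrix()]) and `meta`.
#' @export
read_dataset <- function(dir, check_cutoffs = TRUE) {
  need <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing dataset file: ", f)
    path
  }
  wide <- utils::read.csv(need("npx_wide.csv"), check.names = FALSE)
  if (!"sample_id" %in% names(wide))
    stop("npx_wide.csv is missing required column: sample_id")
  meta <- utils::read.csv(need("sample_meta.csv"))
  panel_map <- utils::read.csv(need("panel_map.csv"))
  if (!all(c("protein", "panel") %in% names(panel_map)))
    stop("panel_map.csv is missing required column(s): ",
         paste(setdiff(c("protein", "panel"), names(panel_map)),
               collapse = ", "))
  lod <- utils::read.csv(need("lod.csv"))
  if (!all(c("protein", "batch", "lod") %in% names(lod)))
    stop("lod.csv is missing required column(s): ",
         paste(setdiff(c("protein", "batch", "lod"), names(lod)),
               collapse = ", "))

  values <- as.matrix(wide[, setdiff(names(wide), "sample_id"),
                           drop = FALSE])
  rownames(values) <- wide$sample_id
  if (anyDuplicated(wide$sample_id))
    stop("duplicate sample id(s) in npx_wide.csv: ",
         paste(unique(wide$sample_id[duplicated(wide$sample_id)]),
               collapse = ", "))
  prot <- colnames(values)
  unmapped <- setdiff(prot, panel_map$protein)
  if (length(unmapped))
    stop("protein(s) missing from panel_map.csv: ",
         paste(unmapped, collapse = ", "))
  panel <- stats::setNames(panel_map$panel, panel_map$protein)[prot]

  below <- NULL
  mask_path <- file.path(dir, "below_lod.csv")
  if (file.exists(mask_path)) {
    mw <- utils::read.csv(mask_path, check.names = FALSE)
    below <- as.matrix(mw[, setdiff(names(mw), "sample_id"),
                          drop = FALSE]) == 1
    rownames(below) <- mw$sample_id
    below <- below[rownames(values), prot, drop = FALSE]
  }

  validate_meta(meta, check_cutoffs = check_cutoffs)
  shared <- intersect(rownames(values), meta$sample_id)
  dropped_expr <- setdiff(rownames(values), shared)
  dropped_meta <- setdiff(meta$sample_id, shared)
  if (length(dropped_expr) || length(dropped_meta))
    message(sprintf("read_dataset: dropping %d expression row(s) and %d metadata row(s) without a match",
                    length(dropped_expr), length(dropped_meta)))
  if (!length(shared)) stop("no samples shared between expression and metadata")
  meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
  values <- values[shared, , drop = FALSE]
  if (!is.null(below)) below <- below[shared, , drop = FALSE]

  list(expr = npx_matrix(values, panel, lod, below), meta = meta)
}

#' Pivot a long-format NPX table to an expression matrix
#'
#' Accepts the long export layout (one row per sample x protein) with
#' columns `sample`, `protein`, `panel`, `NPX`, `below_lod`, and optionally
#' `batch`, and pivots it into an [npx_matrix()].
#'
#' @param long data.frame in long format.
#' @param lod optional LOD table (protein, batch, lod).
#' @return an [npx_matrix()].
#' @export
pivot_npx_long <- function(long, lod = NULL) {
  required <- c("sample", "protein", "panel", "NPX", "below_lod")
  missing <- setdiff(required, names(long))
  if (length(missing))
    stop("long-format table is missing required column(s): ",
         paste(missing, collapse = ", "))
  samples <- unique(long$sample)
  prot <- unique(long$protein)
  values <- matrix(NA_real_, length(samples), length(prot),
                   dimnames = list(samples, prot))
  below <- matrix(FALSE, length(samples), length(prot),
                  dimnames = list(samples, prot))
  ij <- cbind(match(long$sample, samples), match(long$protein, prot))
  if (anyDuplicated(ij))
    stop("duplicate sample/protein combination(s) in long-format table")
  values[ij] <- long$NPX
  below[ij] <- long$below_lod == 1 | long$below_lod == TRUE
  if (anyNA(values))
    stop("long-format table does not cover every sample/protein combination")
  panel <- stats::setNames(long$panel[match(prot, long$protein)], prot)
  npx_matrix(values, panel, lod, below)
}
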