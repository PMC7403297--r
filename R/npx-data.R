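#' @keywords internal
"_PACKAGE"

#' Study group labels
#'
#' The four diagnostic groups of the case/control design, ordered so that the
#' ordinal disease-burden coding (control < single disorder < comorbid) follows
#' the vector order.
#'
#' @export
GROUP_LEVELS <- c("control", "PTSD_only", "MCI_only", "PTSD_MCI")

#' Construct an NPX expression matrix
#'
#' Container for a samples x proteins matrix of log2-scale NPX values together
#' with the protein-to-panel map, the limit-of-detection (LOD) table and the
#' below-LOD flag matrix. One NPX unit corresponds to a doubling of protein
#' concentration; all statistics downstream operate on this log2 scale.
#'
#' @param values numeric matrix, samples x proteins, with sample ids as row
#'   names and protein ids as column names.
#' @param panel named character vector mapping every protein id to exactly one
#'   panel label.
#' @param lod data.frame with columns `protein`, `batch`, `lod`. Use
#'   `batch = "all"` for a single global LOD per protein; per-batch rows are
#'   also accepted (then imputation needs sample batch labels).
#' @param below_lod logical matrix, same shape as `values`; `TRUE` marks a
#'   measurement censored below the assay LOD. A value may be both recorded
#'   and flagged; the flag wins at imputation time.
#' @return An object of class `npx_matrix`.
#' @export
npx_matrix <- function(values, panel, lod = NULL, below_lod = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry sample ids as rownames and protein ids as colnames")
  prot <- colnames(values)
  if (anyDuplicated(prot)) stop("duplicate protein ids in 'values'")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids in 'values'")
  if (is.null(names(panel)) || !all(prot %in% names(panel)))
    stop("'panel' must be a named vector covering every protein")
  panel <- panel[prot]
  if (anyNA(panel)) stop("every protein must map to exactly one panel")
  if (is.null(below_lod)) {
    below_lod <- matrix(FALSE, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  }
  if (!identical(dim(below_lod), dim(values)))
    stop("'below_lod' must have the same shape as 'values'")
  dimnames(below_lod) <- dimnames(values)
  if (is.null(lod)) {
    lod <- data.frame(protein = prot, batch = "all", lod = -Inf)
  }
  if (!all(c("protein", "batch", "lod") %in% names(lod)))
    stop("'lod' must have columns protein, batch, lod")
  structure(
    list(values = values, panel = panel, lod = lod, below_lod = below_lod),
    class = "npx_matrix"
  )
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat(sprintf("<npx_matrix> %d samples x %d proteins, %d panel(s), %d value(s) below LOD\n",
              nrow(x$values), ncol(x$values), length(unique(x$panel)),
              sum(x$below_lod)))
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

#' Subset an NPX matrix by sample id
#'
#' @param x an [npx_matrix()].
#' @param samples character vector of sample ids to keep (order preserved).
#' @return An `npx_matrix` restricted to the requested samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "npx_matrix"))
  missing <- setdiff(samples, rownames(x$values))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  npx_matrix(x$values[samples, , drop = FALSE], x$panel, x$lod,
             x$below_lod[samples, , drop = FALSE])
}

#' Validate a sample metadata table
#'
#' Checks the per-sample metadata against the schema used throughout the
#' pipeline and, where both scores are present, that the group label is
#' consistent with the classification cutoffs (PCL > 44 for PTSD groups,
#' PCL < 22 otherwise; MoCA < 22 for MCI groups, MoCA > 26 otherwise).
#'
#' @param meta data.frame with columns `sample_id`, `group`, `age`, `race`,
#'   `batch`, `is_bridging`, `pcl`, `moca`.
#' @param check_cutoffs logical; verify PCL/MoCA consistency with the group
#'   label for non-bridging samples.
#' @return `meta`, invisibly, after validation.
#' @export
validate_meta <- function(meta, check_cutoffs = TRUE) {
  required <- c("sample_id", "group", "age", "race", "batch", "is_bridging",
                "pcl", "moca")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  part <- meta[!meta$is_bridging, , drop = FALSE]
  bad_group <- setdiff(unique(part$group), GROUP_LEVELS)
  if (length(bad_group))
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  if (check_cutoffs && nrow(part)) {
    is_ptsd <- part$group %in% c("PTSD_MCI", "PTSD_only")
    is_mci <- part$group %in% c("PTSD_MCI", "MCI_only")
    ok_pcl <- is.na(part$pcl) | ifelse(is_ptsd, part$pcl > 44, part$pcl < 22)
    ok_moca <- is.na(part$moca) | ifelse(is_mci, part$moca < 22, part$moca > 26)
    bad <- part$sample_id[!(ok_pcl & ok_moca)]
    if (length(bad))
      stop("PCL/MoCA scores inconsistent with group cutoffs for sample(s): ",
           paste(bad, collapse = ", "))
  }
  invisible(meta)
}
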