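# NPX preprocessing: LOD imputation, bridging batch correction, QC ------

# LOD lookup: returns samples x proteins matrix of LOD values.
# Global ("all") rows apply to every sample; per-batch rows need `batches`.
.lod_matrix <- function(x, batches = NULL) {
  prot <- colnames(x$values)
  n <- nrow(x$values)
  lodm <- matrix(NA_real_, n, length(prot),
                 dimnames = dimnames(x$values))
  glob <- x$lod[x$lod$batch == "all", , drop = FALSE]
  if (nrow(glob)) {
    v <- stats::setNames(glob$lod, glob$protein)[prot]
    lodm[] <- matrix(v, n, length(prot), byrow = TRUE)
  }
  per_batch <- x$lod[x$lod$batch != "all", , drop = FALSE]
  if (nrow(per_batch)) {
    if (is.null(batches))
      stop("per-batch LODs require sample batch labels; pass 'batches'")
    key <- paste(per_batch$batch, per_batch$protein, sep = "\r")
    lut <- stats::setNames(per_batch$lod, key)
    for (b in unique(per_batch$batch)) {
      rows <- which(batches == b)
      if (!length(rows)) next
      v <- lut[paste(b, prot, sep = "\r")]
      hit <- !is.na(v)
      lodm[rows, hit] <- matrix(v[hit], length(rows), sum(hit), byrow = TRUE)
    }
  }
  lodm
}

#' Impute below-LOD values at the LOD
#'
#' Every measurement flagged below the limit of detection is replaced by its
#' protein's LOD (per batch where per-batch LODs are supplied); all other
#' values are left untouched. The below-LOD mask is preserved for reporting.
#' Run before [bridge_correct()], which shifts the NPX scale.
#'
#' @param x an [npx_matrix()].
#' @param batches optional character vector of per-sample batch labels
#'   (aligned with `rownames(x$values)`); required only when the LOD table
#'   has per-batch rows.
#' @return The imputed `npx_matrix`.
#' @export
impute_lod <- function(x, batches = NULL) {
  stopifnot(inherits(x, "npx_matrix"))
  mask <- x$below_lod
  if (!any(mask)) return(x)
  lodm <- .lod_matrix(x, batches)
  no_lod <- mask & !is.finite(lodm)
  if (any(no_lod)) {
    bad <- colnames(x$values)[colSums(no_lod) > 0]
    stop("below-LOD value(s) with no usable LOD for protein(s): ",
         paste(bad, collapse = ", "))
  }
  x$values[mask] <- lodm[mask]
  x
}

#' Bridging-sample batch correction
#'
#' For each protein and batch, the adjustment factor is the median NPX of
#' that batch's bridging samples; it is subtracted from every sample in the
#' batch. The result is the "normalized NPX" used by all downstream
#' statistics. The correction is idempotent (post-correction bridging medians
#' are zero) and leaves within-batch differences between samples unchanged.
#'
#' @param x an [npx_matrix()].
#' @param meta sample metadata with `sample_id`, `batch`, `is_bridging`.
#' @return The corrected `npx_matrix`.
#' @export
bridge_correct <- function(x, meta) {
  stopifnot(inherits(x, "npx_matrix"))
  ids <- rownames(x$values)
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(m$sample_id))
    stop("metadata missing for sample(s): ",
         paste(ids[is.na(m$sample_id)], collapse = ", "))
  batches <- unique(m$batch)
  no_bridge <- batches[!vapply(batches, function(b)
    any(m$is_bridging & m$batch == b), logical(1))]
  if (length(no_bridge))
    stop("batch(es) without bridging samples: ",
         paste(no_bridge, collapse = ", "))
  for (b in batches) {
    br <- which(m$is_bridging & m$batch == b)
    adj <- apply(x$values[br, , drop = FALSE], 2, stats::median)
    rows <- which(m$batch == b)
    x$values[rows, ] <- x$values[rows, , drop = FALSE] -
      matrix(adj, length(rows), ncol(x$values), byrow = TRUE)
  }
  x
}

#' Technical-duplicate reproducibility QC
#'
#' Pearson correlation across proteins for each duplicate pair, the mean
#' correlation over pairs, and a flag for pairs below a reproducibility
#' threshold.
#'
#' @param x an [npx_matrix()].
#' @param pairs two-column matrix/data.frame (or list of length-2 vectors) of
#'   sample ids.
#' @param threshold pairs with r below this value are flagged.
#' @return list with `pairs` (data.frame: sample_1, sample_2, r, flagged),
#'   `mean_r`, and `threshold`.
#' @export
duplicate_qc <- function(x, pairs, threshold = 0.9) {
  stopifnot(inherits(x, "npx_matrix"))
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("'pairs' must have two columns of sample ids")
  ids <- rownames(x$values)
  missing <- setdiff(unique(as.vector(pairs)), ids)
  if (length(missing))
    stop("duplicate-pair sample(s) not in the matrix: ",
         paste(missing, collapse = ", "))
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    v1 <- x$values[pairs[i, 1], ]
    v2 <- x$values[pairs[i, 2], ]
    ok <- is.finite(v1) & is.finite(v2)
    if (sum(ok) < 3)
      stop(sprintf("pair (%s, %s) has fewer than 3 shared finite values",
                   pairs[i, 1], pairs[i, 2]))
    stats::cor(v1[ok], v2[ok])
  }, numeric(1))
  tab <- data.frame(sample_1 = pairs[, 1], sample_2 = pairs[, 2], r = r,
                    flagged = r < threshold)
  list(pairs = tab, mean_r = mean(r), threshold = threshold)
}

#' Drop bridging samples after correction
#'
#' Bridging samples are assay controls, not participants; exclude them from
#' every downstream statistic once the batch correction has used them.
#'
#' @param x an [npx_matrix()].
#' @param meta sample metadata.
#' @return list with the participant-only `expr` and `meta`.
#' @export
drop_bridging <- function(x, meta) {
  keep <- meta$sample_id[!meta$is_bridging]
  list(expr = subset_samples(x, keep),
       meta = meta[!meta$is_bridging, , drop = FALSE])
}
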