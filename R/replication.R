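# Monte-Carlo split-half discovery/replication experiment ---------------

#' Monte-Carlo split-half replication
#'
#' Repeatedly partitions a contrast's samples into 50% discovery / 50%
#' replication halves (stratified by arm; an odd arm's extra sample goes to
#' discovery), refits the covariate-adjusted per-protein model in each half,
#' and calls a protein replicated in a partition when both halves reach
#' `p < alpha` with same-sign coefficients. Counts are aggregated over
#' partitions.
#'
#' @param x an [npx_matrix()] of normalized NPX.
#' @param meta sample metadata.
#' @param contrast a [contrast_def()].
#' @param n_partitions number of random partitions (default 100).
#' @param alpha per-half significance threshold (default 0.10).
#' @param seed integer seed; the partition sequence is a deterministic
#'   function of it.
#' @param adjust_covariates keep age and race in the half-sample fits
#'   (default TRUE; covariates that are constant within a half are dropped
#'   for that half, and the number of such halves is reported in a message).
#' @return object of class `replication_result`: data.frame with columns
#'   protein, n_partitions, n_replicated, replication_rate.
#' @export
replicate_mc <- function(x, meta, contrast, n_partitions = 100, alpha = 0.10,
                         seed = 1, adjust_covariates = TRUE) {
  stopifnot(inherits(x, "npx_matrix"), inherits(contrast, "contrast"))
  keep <- !meta$is_bridging &
    meta$group %in% c(contrast$case_group, contrast$control_group)
  m <- meta[keep, , drop = FALSE]
  v <- x$values[m$sample_id, , drop = FALSE]
  case <- as.numeric(m$group == contrast$case_group)
  idx_case <- which(case == 1)
  idx_ctrl <- which(case == 0)
  if (min(length(idx_case), length(idx_ctrl)) < 6)
    stop("arm too small to split: need at least 6 samples per arm so each half retains >= 3")

  set.seed(seed)
  splits <- lapply(seq_len(n_partitions), function(k) {
    pc <- sample(idx_case)
    pk <- sample(idx_ctrl)
    disc <- c(pc[seq_len(ceiling(length(pc) / 2))],
              pk[seq_len(ceiling(length(pk) / 2))])
    list(disc = sort(disc), repl = sort(setdiff(c(idx_case, idx_ctrl), disc)))
  })

  n_dropped_halves <- 0L
  half_fit <- function(rows) {
    d <- if (adjust_covariates)
      .build_design(case[rows], m$age[rows], m$race[rows])
    else .build_design(case[rows])
    if (length(d$dropped)) n_dropped_halves <<- n_dropped_halves + 1L
    .ols_case_stats(d$X, v[rows, , drop = FALSE])
  }

  counts <- integer(ncol(v))
  for (sp in splits) {
    s1 <- half_fit(sp$disc)
    s2 <- half_fit(sp$repl)
    rep_ok <- (s1$p < alpha) & (s2$p < alpha) &
      (sign(s1$beta) == sign(s2$beta)) & (sign(s1$beta) != 0)
    counts <- counts + as.integer(rep_ok)
  }
  if (n_dropped_halves > 0)
    message(sprintf("replicate_mc: a constant covariate was dropped in %d half-sample fit(s)",
                    n_dropped_halves))
  structure(data.frame(
    protein = colnames(v),
    n_partitions = n_partitions,
    n_replicated = counts,
    replication_rate = counts / n_partitions,
    row.names = NULL
  ), class = c("replication_result", "data.frame"))
}
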