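# Elastic-net multiprotein composite score ------------------------------

#' Select candidate features by differential p-value
#'
#' Proteins below the p-value threshold in a contrast's differential table,
#' ranked by p (the study used thresholds of 0.05 and 0.1).
#'
#' @param diff a `diff_result` from [run_contrast()].
#' @param p_threshold inclusion threshold on the unadjusted p-value.
#' @return character vector of protein ids, ranked by p.
#' @export
select_candidates <- function(diff, p_threshold = 0.1) {
  stopifnot(inherits(diff, "diff_result"))
  tab <- diff$table[diff$table$p < p_threshold, , drop = FALSE]
  if (!nrow(tab))
    stop(sprintf("no candidate proteins at P < %g; use a larger threshold",
                 p_threshold))
  tab$protein[order(tab$p)]
}

#' Area under the ROC curve (rank formulation)
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, ties counted half (Mann-Whitney statistic over n_case x
#' n_control pairs).
#'
#' @param cases,controls numeric score vectors; both nonempty.
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(cases, controls) {
  n1 <- length(cases); n0 <- length(controls)
  if (n1 < 1 || n0 < 1) stop("need at least one case and one control score")
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment; every class is spread across folds.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# One inner-CV tuning pass over the mixing grid; returns the winning
# (alpha, lambda) and the fitted cv.glmnet object. The inner criterion is
# cross-validated AUC (glmnet falls back to binomial deviance on very small
# folds; the selection direction follows the measure actually used).
.tune_enet <- function(X, y, foldid, alpha_grid, nlambda) {
  best <- NULL
  for (a in alpha_grid) {
    cvfit <- suppressWarnings(glmnet::cv.glmnet(
      X, y, family = "binomial", type.measure = "auc",
      foldid = foldid, alpha = a, nlambda = nlambda, standardize = TRUE))
    measure <- names(cvfit$name)
    i <- which(cvfit$lambda == cvfit$lambda.min)[1]
    score <- cvfit$cvm[i]
    better <- is.null(best) ||
      (measure == "auc" && score > best$score) ||
      (measure != "auc" && score < best$score)
    if (better)
      best <- list(alpha = a, lambda = cvfit$lambda.min, score = score,
                   measure = measure, fit = cvfit)
  }
  best
}

#' Leave-one-out elastic-net composite score
#'
#' For each of the N case/control samples of a contrast, an elastic-net
#' penalized logistic regression is tuned on the remaining N-1 samples by
#' stratified inner fivefold cross-validation (mixing grid x automatic
#' penalty path, features standardized within each training set), refitted,
#' and used to predict the held-out sample's case probability. Performance
#' is the AUC over all N out-of-fold scores; the scores are also correlated
#' (Pearson) with the PCL and MoCA symptom-severity scores of the same
#' samples.
#'
#' Candidate features are, as in the source protocol, selected on the full
#' dataset before the leave-one-out loop (see [select_candidates()]); this
#' optimism is deliberate and documented. A single-candidate model is fitted
#' by unpenalized logistic regression (the penalized path needs at least two
#' features); this is the penalty-free limit of the same model.
#'
#' @param x an [npx_matrix()] of normalized NPX.
#' @param meta sample metadata.
#' @param contrast a [contrast_def()].
#' @param candidates character vector of candidate protein ids.
#' @param inner_folds inner CV folds for tuning (default 5; reduced with a
#'   warning when the smaller class cannot populate them).
#' @param alpha_grid elastic-net mixing grid.
#' @param nlambda length of the automatic penalty path.
#' @param seed integer seed driving fold assignment.
#' @return object of class `composite_result`: list with `oof_scores` (named
#'   per-sample out-of-fold probabilities), `auc`, `r_pcl`/`p_pcl`,
#'   `r_moca`/`p_moca`, `per_fold` hyperparameter table, and metadata.
#' @export
loo_elastic_net <- function(x, meta, contrast, candidates, inner_folds = 5,
                            alpha_grid = c(0.1, 0.25, 0.5, 0.75, 0.9, 1),
                            nlambda = 50, seed = 1) {
  stopifnot(inherits(x, "npx_matrix"), inherits(contrast, "contrast"))
  missing <- setdiff(candidates, colnames(x$values))
  if (length(missing))
    stop("candidate protein(s) not in the matrix: ",
         paste(missing, collapse = ", "))
  keep <- !meta$is_bridging &
    meta$group %in% c(contrast$case_group, contrast$control_group)
  m <- meta[keep, , drop = FALSE]
  if (!any(m$group == contrast$case_group) ||
      !any(m$group == contrast$control_group))
    stop(sprintf("contrast %s: empty case or control arm", contrast$name))
  X <- x$values[m$sample_id, candidates, drop = FALSE]
  y <- as.numeric(m$group == contrast$case_group)
  n <- nrow(X)

  set.seed(seed)
  oof <- numeric(n)
  per_fold <- vector("list", n)
  single <- length(candidates) == 1L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2)
      stop("degenerate single-class training set in the leave-one-out loop")
    if (single) {
      df_tr <- data.frame(y = ytr, f = X[-i, 1])
      fit <- stats::glm(y ~ f, family = stats::binomial(), data = df_tr)
      oof[i] <- stats::predict(fit, data.frame(f = X[i, 1]),
                               type = "response")
      per_fold[[i]] <- data.frame(fold = i, sample_id = m$sample_id[i],
                                  alpha = NA_real_, lambda = 0,
                                  inner_metric = NA_real_,
                                  measure = "unpenalized")
      next
    }
    k <- inner_folds
    min_class <- min(table(ytr))
    if (min_class < k) {
      k <- max(2L, min_class)
      warning(sprintf("reducing inner folds to %d (smallest class has %d samples)",
                      k, min_class))
    }
    foldid <- .stratified_folds(ytr, k)
    tuned <- .tune_enet(X[-i, , drop = FALSE], ytr, foldid, alpha_grid,
                        nlambda)
    oof[i] <- as.numeric(stats::predict(
      tuned$fit, newx = X[i, , drop = FALSE], s = tuned$lambda,
      type = "response"))
    per_fold[[i]] <- data.frame(fold = i, sample_id = m$sample_id[i],
                                alpha = tuned$alpha, lambda = tuned$lambda,
                                inner_metric = tuned$score,
                                measure = tuned$measure)
  }

  cor_or_na <- function(score, sev) {
    ok <- is.finite(sev)
    if (stats::sd(score[ok]) == 0 || sum(ok) < 3)
      return(list(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(score[ok], sev[ok])
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  rp <- cor_or_na(oof, m$pcl)
  rm_ <- cor_or_na(oof, m$moca)

  structure(list(
    contrast = contrast$name, candidates = candidates,
    sample_id = m$sample_id, y = y,
    oof_scores = stats::setNames(oof, m$sample_id),
    auc = auc_mw(oof[y == 1], oof[y == 0]),
    r_pcl = rp$r, p_pcl = rp$p, r_moca = rm_$r, p_moca = rm_$p,
    per_fold = do.call(rbind, per_fold)
  ), class = "composite_result")
}

#' @export
print.composite_result <- function(x, ...) {
  cat(sprintf("<composite_result> %s: %d candidates, %d samples; LOO AUC %.3f; r(PCL) %.2f, r(MoCA) %.2f\n",
              x$contrast, length(x$candidates), length(x$oof_scores), x$auc,
              x$r_pcl, x$r_moca))
  invisible(x)
}
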