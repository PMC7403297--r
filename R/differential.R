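# Per-protein covariate-adjusted differential analysis ------------------

#' Define a case/control contrast
#'
#' @param name contrast label.
#' @param case_group,control_group group labels; must differ.
#' @return list of class `contrast`.
#' @export
contrast_def <- function(name, case_group, control_group = "control") {
  if (identical(case_group, control_group))
    stop("case and control groups must be disjoint")
  structure(list(name = name, case_group = case_group,
                 control_group = control_group), class = "contrast")
}

#' The three study contrasts
#'
#' Comorbid PTSD-MCI, PTSD-only and MCI-only cases, each versus the
#' unaffected controls.
#'
#' @return named list of [contrast_def()] objects.
#' @export
default_contrasts <- function() {
  list(
    PTSD_MCI_vs_control = contrast_def("PTSD_MCI_vs_control", "PTSD_MCI"),
    PTSD_only_vs_control = contrast_def("PTSD_only_vs_control", "PTSD_only"),
    MCI_only_vs_control = contrast_def("MCI_only_vs_control", "MCI_only")
  )
}

# Build the design matrix [intercept, case, age, race(Other = 1)], dropping
# constant covariates. Returns list(X, dropped).
.build_design <- function(case, age = NULL, race = NULL) {
  X <- cbind(`(Intercept)` = 1, case = as.numeric(case))
  dropped <- character(0)
  if (!is.null(age)) {
    if (stats::var(age) == 0) dropped <- c(dropped, "age")
    else X <- cbind(X, age = as.numeric(age))
  }
  if (!is.null(race)) {
    rr <- if (is.numeric(race)) race else as.numeric(race == "Other")
    if (stats::var(rr) == 0) dropped <- c(dropped, "race")
    else X <- cbind(X, race = rr)
  }
  list(X = X, dropped = dropped)
}

# OLS of each column of Y on X; classical (unscaled-covariance) inference for
# the coefficient in column `coef_col`. QR-based; two-sided t p-values on
# n - ncol(X) df. Constant responses get beta = 0, p = 1.
.ols_case_stats <- function(X, Y, coef_col = 2L) {
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("response and design dimensions differ")
  fit <- stats::lm.fit(X, Y)
  if (fit$rank < ncol(X))
    stop("design matrix is rank deficient after dropping constant covariates")
  piv <- fit$qr$pivot
  R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  cov_u <- chol2inv(R)[order(piv), order(piv), drop = FALSE]
  df <- n - ncol(X)
  res <- as.matrix(fit$residuals)
  rss <- colSums(res^2)
  beta <- as.matrix(fit$coefficients)[coef_col, ]
  cm <- colMeans(Y)
  tss <- colSums((Y - matrix(cm, n, ncol(Y), byrow = TRUE))^2)
  constant <- tss < 1e-20
  sigma2 <- rss / df
  se <- sqrt(sigma2 * cov_u[coef_col, coef_col])
  tval <- ifelse(se > 0, beta / se, ifelse(abs(beta) < 1e-12, 0, Inf * sign(beta)))
  pval <- ifelse(is.finite(tval),
                 2 * stats::pt(abs(tval), df, lower.tail = FALSE), 0)
  beta[constant] <- 0; se[constant] <- 0; tval[constant] <- 0
  pval[constant] <- 1
  list(beta = beta, se = se, t = tval, p = pval, df = df, rss = rss)
}

#' Fit the per-protein differential model
#'
#' Ordinary least squares of one protein's normalized NPX on
#' `[intercept, case, age, race]` with classical standard errors; the
#' reported coefficient is the case/control difference in NPX units, with a
#' two-sided t p-value. Constant covariates are dropped with a warning,
#' never silently; a constant response yields beta = 0, p = 1.
#'
#' @param y numeric NPX vector.
#' @param case 0/1 (or logical) case indicator.
#' @param age optional age in years.
#' @param race optional race; "Other" (or numeric 1) is the indicator level.
#' @return list with `beta`, `se`, `t`, `p`, `df`.
#' @export
fit_protein <- function(y, case, age = NULL, race = NULL) {
  d <- .build_design(case, age, race)
  if (length(d$dropped))
    warning("dropping constant covariate(s): ",
            paste(d$dropped, collapse = ", "))
  s <- .ols_case_stats(d$X, matrix(y, ncol = 1))
  list(beta = unname(s$beta), se = unname(s$se), t = unname(s$t),
       p = unname(s$p), df = s$df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with enforced monotonicity, capped at 1. Applied
#' within each assay panel by [run_contrast()].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run one case/control contrast over all proteins
#'
#' Applies [fit_protein()] to every protein, adjusts p-values by
#' Benjamini-Hochberg separately within each panel (three independent
#' families in the study design), and emits the significant lists at the
#' nominal and FDR thresholds with direction of regulation.
#'
#' @param x an [npx_matrix()] of normalized NPX (bridging samples are
#'   excluded automatically).
#' @param meta sample metadata.
#' @param contrast a [contrast_def()].
#' @param alpha_p nominal significance threshold (default 0.05).
#' @param alpha_fdr within-panel FDR threshold (default 0.1).
#' @param adjust_covariates fit with age and race adjustment (default TRUE).
#' @return object of class `diff_result`: list with `table` (protein, panel,
#'   beta, se, t, p, q, direction, sig_p05, sig_fdr10), `sig_p`, `sig_fdr`,
#'   and the contrast/threshold metadata.
#' @export
run_contrast <- function(x, meta, contrast, alpha_p = 0.05, alpha_fdr = 0.1,
                         adjust_covariates = TRUE) {
  stopifnot(inherits(x, "npx_matrix"), inherits(contrast, "contrast"))
  keep <- !meta$is_bridging &
    meta$group %in% c(contrast$case_group, contrast$control_group)
  m <- meta[keep, , drop = FALSE]
  if (!any(m$group == contrast$case_group) ||
      !any(m$group == contrast$control_group))
    stop(sprintf("contrast %s: empty case or control arm", contrast$name))
  v <- x$values[m$sample_id, , drop = FALSE]
  case <- as.numeric(m$group == contrast$case_group)
  d <- if (adjust_covariates) .build_design(case, m$age, m$race)
       else .build_design(case)
  if (length(d$dropped))
    warning(sprintf("contrast %s: dropping constant covariate(s): %s",
                    contrast$name, paste(d$dropped, collapse = ", ")))
  s <- .ols_case_stats(d$X, v)
  panel <- unname(x$panel[colnames(v)])
  q <- stats::ave(s$p, panel, FUN = bh_adjust)
  tab <- data.frame(
    protein = colnames(v), panel = panel,
    beta = unname(s$beta), se = unname(s$se), t = unname(s$t),
    p = unname(s$p), q = q,
    direction = ifelse(s$beta > 0, "up", "down"),
    sig_p05 = unname(s$p) < alpha_p,
    sig_fdr10 = q < alpha_fdr,
    row.names = NULL
  )
  structure(list(
    contrast = contrast$name, case_group = contrast$case_group,
    control_group = contrast$control_group,
    alpha_p = alpha_p, alpha_fdr = alpha_fdr,
    n_case = sum(case == 1), n_control = sum(case == 0),
    table = tab,
    sig_p = tab$protein[tab$sig_p05],
    sig_fdr = tab$protein[tab$sig_fdr10]
  ), class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("<diff_result> %s: %d cases vs %d controls; %d proteins at P < %g, %d at within-panel FDR < %g\n",
              x$contrast, x$n_case, x$n_control, length(x$sig_p), x$alpha_p,
              length(x$sig_fdr), x$alpha_fdr))
  invisible(x)
}

#' Venn decomposition of per-contrast significant lists
#'
#' @param lists named list of protein-id vectors (typically the three
#'   per-contrast significant lists).
#' @return list with `membership` (union proteins x per-list flags),
#'   `regions` (named counts for every non-empty combination of lists, keys
#'   joined by "&"), and `union` (sorted union).
#' @export
overlap_sets <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2, !is.null(names(lists)))
  u <- sort(unique(unlist(lists)))
  flags <- vapply(lists, function(l) u %in% l, logical(length(u)))
  if (length(u) == 1L) flags <- matrix(flags, nrow = 1,
                                       dimnames = list(NULL, names(lists)))
  membership <- data.frame(protein = u, flags, row.names = NULL,
                           check.names = FALSE)
  nm <- names(lists)
  combos <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, paste, collapse = "&")), use.names = FALSE)
  regions <- stats::setNames(integer(length(combos)), combos)
  if (length(u)) {
    key <- apply(flags, 1, function(f) paste(nm[f], collapse = "&"))
    tab <- table(key)
    regions[names(tab)] <- as.integer(tab)
  }
  list(membership = membership, regions = regions, union = u)
}

#' Cross-contrast correlation of effect estimates
#'
#' Pearson correlation, over all proteins (not only significant ones), of the
#' per-protein case/control coefficients between each pair of contrasts, with
#' two-sided p-values.
#'
#' @param betas named list (or data.frame) of equal-length numeric vectors of
#'   per-protein coefficients, one per contrast.
#' @return data.frame with columns contrast_1, contrast_2, r, p.
#' @export
beta_correlation <- function(betas) {
  betas <- as.data.frame(betas)
  if (ncol(betas) < 2 || nrow(betas) < 3)
    stop("need at least two contrasts and three proteins")
  zv <- vapply(betas, stats::sd, numeric(1)) == 0
  if (any(zv))
    stop("zero-variance coefficient vector(s): ",
         paste(names(betas)[zv], collapse = ", "))
  pairs <- utils::combn(names(betas), 2)
  out <- apply(pairs, 2, function(pr) {
    ct <- stats::cor.test(betas[[pr[1]]], betas[[pr[2]]])
    data.frame(contrast_1 = pr[1], contrast_2 = pr[2],
               r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}

#' Count proteins with sign-consistent effects across contrasts
#'
#' For each protein in `proteins` (default: all shared proteins), checks
#' whether the case/control coefficients share the same sign in every
#' contrast.
#'
#' @param betas named list/data.frame of per-protein coefficient vectors with
#'   protein ids as (row) names.
#' @param proteins optional protein ids to restrict to.
#' @return list with `n_consistent`, `n_total` and the logical `consistent`
#'   vector (named by protein).
#' @export
sign_consistency <- function(betas, proteins = NULL) {
  betas <- as.data.frame(betas)
  if (is.null(proteins)) proteins <- rownames(betas)
  b <- as.matrix(betas[proteins, , drop = FALSE])
  cons <- apply(b, 1, function(v) all(v > 0) || all(v < 0))
  list(n_consistent = sum(cons), n_total = length(cons),
       consistent = stats::setNames(cons, proteins))
}
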