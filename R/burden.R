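# Disease-burden model selection by BIC ---------------------------------
#
# Three competing group codings for {control, middle, PTSD_MCI}:
#   H1: intermediary ordering, numeric 1/2/3 (control/middle/comorbid)
#   H2: case-collapsed binary, control = 0 vs middle-or-comorbid = 1
#   H3: control-collapsed binary, control-or-middle = 0 vs comorbid = 1
# All three estimate the same number of parameters, so ranking by BIC equals
# ranking by residual sum of squares; fits are adjusted for age and race.

.burden_coding <- function(group, middle_group) {
  list(
    H1 = ifelse(group == "control", 1, ifelse(group == middle_group, 2, 3)),
    H2 = as.numeric(group != "control"),
    H3 = as.numeric(group == "PTSD_MCI")
  )
}

#' Fit the three disease-burden codings for one protein
#'
#' OLS of the protein's normalized NPX on each group coding plus age and
#' race, restricted to the control, middle and comorbid PTSD-MCI subgroups.
#' BIC is computed in the Gaussian profile form
#' `n * log(RSS/n) + k * log(n)` with `k` counting all coefficients plus the
#' error variance; the smallest BIC wins (exact ties broken H1 < H2 < H3 for
#' a deterministic label), and every model within `delta_comparable` BIC
#' units of the minimum is reported as comparable.
#'
#' @param y NPX vector aligned with `meta` rows.
#' @param meta sample metadata.
#' @param middle_group `"PTSD_only"` or `"MCI_only"`.
#' @param delta_comparable BIC band for the comparable set (default 2).
#' @param protein_id optional label carried into the result.
#' @return object of class `burden_call`: list with `bic` and `rss` (named
#'   H1/H2/H3), `best`, `comparable`, `n`, `middle_group`, `protein_id`.
#' @export
fit_burden <- function(y, meta, middle_group = "PTSD_only",
                       delta_comparable = 2, protein_id = NA_character_) {
  if (!middle_group %in% c("PTSD_only", "MCI_only"))
    stop("'middle_group' must be PTSD_only or MCI_only")
  if (length(y) != nrow(meta))
    stop("'y' must be aligned with the metadata rows")
  keep <- !meta$is_bridging &
    meta$group %in% c("control", middle_group, "PTSD_MCI")
  m <- meta[keep, , drop = FALSE]
  yy <- y[keep]
  cnt <- table(factor(m$group, levels = c("control", middle_group, "PTSD_MCI")))
  if (any(cnt < 3))
    stop("missing or too-small subgroup(s): ",
         paste(names(cnt)[cnt < 3], collapse = ", "))
  codings <- .burden_coding(m$group, middle_group)
  n <- length(yy)
  fits <- lapply(codings, function(cd) {
    d <- .build_design(cd, m$age, m$race)
    if (length(d$dropped))
      warning("dropping constant covariate(s): ",
              paste(d$dropped, collapse = ", "))
    s <- .ols_case_stats(d$X, matrix(yy, ncol = 1))
    k <- ncol(d$X) + 1  # coefficients + error variance
    list(rss = unname(s$rss), bic = n * log(unname(s$rss) / n) + k * log(n))
  })
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  best <- names(bic)[which.min(bic)]
  structure(list(
    protein_id = protein_id, middle_group = middle_group, n = n,
    bic = bic, rss = rss, best = best,
    comparable = names(bic)[bic - min(bic) <= delta_comparable]
  ), class = "burden_call")
}

#' @export
print.burden_call <- function(x, ...) {
  cat(sprintf("<burden_call> %s (middle = %s): best %s; BIC H1 %.2f, H2 %.2f, H3 %.2f; comparable {%s}\n",
              x$protein_id, x$middle_group, x$best,
              x$bic["H1"], x$bic["H2"], x$bic["H3"],
              paste(x$comparable, collapse = ", ")))
  invisible(x)
}

#' Screen a protein list for disease-burden structure
#'
#' Runs [fit_burden()] for every protein (typically the FDR-significant
#' proteins of the comorbid contrast) with the PTSD-only and, optionally,
#' the MCI-only subgroup as the middle group. Per-protein fit errors are
#' recorded in the output, never abort the screen.
#'
#' @param x an [npx_matrix()] of normalized NPX.
#' @param meta sample metadata.
#' @param proteins nonempty character vector of protein ids.
#' @param middle_groups middle-group labels to analyze.
#' @param delta_comparable BIC band for the comparable set.
#' @return data.frame with one row per protein x middle group: protein,
#'   middle_group, bic_h1, bic_h2, bic_h3, best, comparable
#'   (comma-separated), error (NA unless the fit failed).
#' @export
burden_screen <- function(x, meta, proteins,
                          middle_groups = c("PTSD_only", "MCI_only"),
                          delta_comparable = 2) {
  stopifnot(inherits(x, "npx_matrix"))
  if (!length(proteins)) stop("'proteins' must be nonempty")
  missing <- setdiff(proteins, colnames(x$values))
  if (length(missing))
    stop("unknown protein id(s): ", paste(missing, collapse = ", "))
  v <- x$values[meta$sample_id, , drop = FALSE]
  rows <- list()
  for (mg in middle_groups) {
    for (pr in proteins) {
      call <- tryCatch(
        fit_burden(v[, pr], meta, mg, delta_comparable, protein_id = pr),
        error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(call, "error")) {
        data.frame(protein = pr, middle_group = mg, bic_h1 = NA_real_,
                   bic_h2 = NA_real_, bic_h3 = NA_real_,
                   best = NA_character_, comparable = NA_character_,
                   error = conditionMessage(call))
      } else {
        data.frame(protein = pr, middle_group = mg,
                   bic_h1 = call$bic[["H1"]], bic_h2 = call$bic[["H2"]],
                   bic_h3 = call$bic[["H3"]], best = call$best,
                   comparable = paste(call$comparable, collapse = ","),
                   error = NA_character_)
      }
    }
  }
  do.call(rbind, rows)
}
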