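# Shared fixtures and independent oracles (brute force / hand formulas).

# Small cohort for fast tests; override any field via ...
small_cfg <- function(...) {
  defaults <- list(
    n_per_group = c(PTSD_MCI = 12L, PTSD_only = 12L, MCI_only = 12L,
                    control = 20L),
    n_proteins = 12L, n_panels = 3L,
    n_diff = c(PTSD_MCI = 0L, PTSD_only = 0L, MCI_only = 0L),
    effect_size = 0, n_batches = 2L, n_bridging = 2L,
    batch_shift_sd = 0.5, noise_sd = 1, lod_quantile = 0, seed = 1L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Quick npx_matrix from a bare matrix (single panel unless given).
toy_npx <- function(values, panel = NULL, lod = NULL, below = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("p%02d", seq_len(ncol(values)))
  if (is.null(panel))
    panel <- stats::setNames(rep("panelA", ncol(values)), colnames(values))
  npx_matrix(values, panel, lod, below)
}

# Explicit normal-equations OLS with classical variance: the brute-force
# oracle for the per-protein fit.
oracle_ols <- function(X, y, coef_col = 2L) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- as.vector(xtx_inv %*% t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(xtx_inv))
  tval <- beta / se
  list(beta = unname(beta[coef_col]), se = unname(se[coef_col]),
       t = unname(tval[coef_col]),
       p = unname(2 * stats::pt(abs(tval[coef_col]), df, lower.tail = FALSE)))
}

# Hand-computed step-up Benjamini-Hochberg: sort, p * m / rank, running
# minimum from the largest rank down, cap at 1, unsort.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Brute-force AUC: enumerate all case/control pairs, ties count half.
oracle_auc <- function(cases, controls) {
  wins <- 0
  for (a in cases) for (b in controls)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(cases) * length(controls))
}

# Metadata for a three-subgroup burden toy: control / middle / comorbid.
burden_toy_meta <- function(n_each = 10, middle = "PTSD_only", seed = 1) {
  set.seed(seed)
  n <- 3 * n_each
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("control", middle, "PTSD_MCI"), each = n_each),
    age = stats::rnorm(n, 55, 8),
    race = sample(c("Caucasian", "Other"), n, replace = TRUE,
                  prob = c(0.85, 0.15)),
    batch = "batch1", is_bridging = FALSE, pcl = NA_real_, moca = NA_real_
  )
}
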