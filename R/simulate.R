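# Synthetic NPX cohort generator ---------------------------------------
#
# Emulates the statistical structure the downstream analyses assume: additive
# group and covariate effects on the log2 NPX scale, i.i.d. Gaussian noise,
# additive per-batch shifts observable through noise-free bridging samples,
# left-censoring at an empirical LOD quantile, and PCL/MoCA severity scores
# drawn inside the admissible range of each group's classification cutoffs.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_dataset()]. Defaults
#' reproduce the study design: 34/39/27/81 participants in the comorbid
#' PTSD-MCI, PTSD-only, MCI-only and control groups, 276 proteins in three
#' 92-protein panels, cohort age ~ 55.1 (SD 7.78) years truncated to
#' [30, 80], and a Caucasian/Other race indicator with P(Other) = 28/181.
#'
#' @param n_per_group named integer vector of group sizes, in the order
#'   PTSD_MCI, PTSD_only, MCI_only, control.
#' @param n_proteins number of proteins; must be divisible by `n_panels`.
#' @param n_panels number of equally sized panels.
#' @param n_diff named counts of contrast-specific truly differential proteins
#'   (case group shifted by `effect_size`, random sign), drawn from proteins
#'   with burden pattern "null".
#' @param effect_size group-effect magnitude in NPX units (log2 scale).
#' @param age_mean,age_sd,age_range Gaussian age model, truncated to
#'   `age_range` years.
#' @param age_effect NPX units per year of age (applied to age minus
#'   `age_mean`).
#' @param race_prob probability of race "Other".
#' @param race_effect NPX shift for race "Other".
#' @param n_batches number of assay batches; samples are shuffled then
#'   allocated round-robin.
#' @param batch_shift_sd SD of the additive per-batch per-protein shift (NPX).
#' @param n_bridging bridging (reference) samples per batch; noise-free
#'   replicates of one reference profile plus the batch shift.
#' @param noise_sd SD of the i.i.d. Gaussian measurement/biological noise
#'   (NPX); must be positive.
#' @param lod_quantile fraction of values (per protein) censored at the
#'   empirical LOD; in [0, 1).
#' @param burden_pattern per-protein label in `c("H1","H2","H3","null")`:
#'   "H1" places the single-disorder groups halfway between control and
#'   comorbid, "H2" shifts them like the comorbid group, "H3" leaves them at
#'   control level. `NULL` means all "null"; a length-1 value is recycled.
#' @param severity_r correlation between the latent severity driving PCL/MoCA
#'   and the sample's aggregate true protein signal, in [-1, 1].
#' @param seed integer seed; one global generator drives all randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(PTSD_MCI = 34L, PTSD_only = 39L,
                                       MCI_only = 27L, control = 81L),
                       n_proteins = 276L, n_panels = 3L,
                       n_diff = c(PTSD_MCI = 10L, PTSD_only = 10L,
                                  MCI_only = 10L),
                       effect_size = 1, age_mean = 55.1, age_sd = 7.78,
                       age_range = c(30, 80), age_effect = 0.02,
                       race_prob = 28 / 181, race_effect = 0.2,
                       n_batches = 2L, batch_shift_sd = 0.5, n_bridging = 3L,
                       noise_sd = 1, lod_quantile = 0.02,
                       burden_pattern = NULL, severity_r = 0.5, seed = 1L) {
  bad <- function(field, why)
    stop(sprintf("invalid configuration field '%s': %s", field, why),
         call. = FALSE)
  if (length(n_per_group) != 4L || any(n_per_group < 0))
    bad("n_per_group", "must be 4 non-negative counts")
  if (is.null(names(n_per_group)))
    names(n_per_group) <- c("PTSD_MCI", "PTSD_only", "MCI_only", "control")
  if (!setequal(names(n_per_group), GROUP_LEVELS))
    bad("n_per_group", "names must be the four group labels")
  if (n_proteins < 1) bad("n_proteins", "must be a positive count")
  if (n_panels < 1) bad("n_panels", "must be a positive count")
  if (n_proteins %% n_panels != 0)
    bad("n_proteins", "must be divisible by n_panels")
  if (is.null(names(n_diff)))
    names(n_diff) <- c("PTSD_MCI", "PTSD_only", "MCI_only")
  if (any(n_diff < 0)) bad("n_diff", "counts must be non-negative")
  if (!all(names(n_diff) %in% setdiff(GROUP_LEVELS, "control")))
    bad("n_diff", "names must be case-group labels")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    bad("noise_sd", "must be positive")
  if (lod_quantile < 0 || lod_quantile >= 1)
    bad("lod_quantile", "must be in [0, 1)")
  if (n_batches < 1) bad("n_batches", "must be at least 1")
  if (n_bridging < 0) bad("n_bridging", "must be non-negative")
  if (batch_shift_sd < 0) bad("batch_shift_sd", "must be non-negative")
  if (age_sd <= 0) bad("age_sd", "must be positive")
  if (race_prob < 0 || race_prob > 1) bad("race_prob", "must be in [0, 1]")
  if (abs(severity_r) > 1) bad("severity_r", "must be in [-1, 1]")
  if (is.null(burden_pattern)) burden_pattern <- "null"
  if (length(burden_pattern) == 1L)
    burden_pattern <- rep(burden_pattern, n_proteins)
  if (length(burden_pattern) != n_proteins)
    bad("burden_pattern", "must have length 1 or n_proteins")
  if (!all(burden_pattern %in% c("H1", "H2", "H3", "null")))
    bad("burden_pattern", "labels must be in {H1, H2, H3, null}")
  structure(list(
    n_per_group = as.integer(n_per_group[c("PTSD_MCI", "PTSD_only",
                                           "MCI_only", "control")]) |>
      stats::setNames(c("PTSD_MCI", "PTSD_only", "MCI_only", "control")),
    n_proteins = as.integer(n_proteins), n_panels = as.integer(n_panels),
    n_diff = as.integer(n_diff) |> stats::setNames(names(n_diff)),
    effect_size = effect_size, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, age_effect = age_effect, race_prob = race_prob,
    race_effect = race_effect, n_batches = as.integer(n_batches),
    batch_shift_sd = batch_shift_sd, n_bridging = as.integer(n_bridging),
    noise_sd = noise_sd, lod_quantile = lod_quantile,
    burden_pattern = burden_pattern, severity_r = severity_r,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Truncated-normal draw from a standard-normal latent, by inverse CDF.
# Monotone in `w`, exact truncated-normal marginal, strictly inside (lo, hi).
.rtrunc_from_latent <- function(w, mean, sd, lo, hi) {
  a <- stats::pnorm((lo - mean) / sd)
  b <- stats::pnorm((hi - mean) / sd)
  u <- pmin(pmax(stats::pnorm(w), 1e-12), 1 - 1e-12)
  mean + sd * stats::qnorm(a + u * (b - a))
}

#' Bridging-sample metadata for a configuration
#'
#' Each batch receives `n_bridging` bridging rows; all bridging samples share
#' one noise-free reference profile (plus the batch shift), so the per-batch
#' bridging median identifies the shift exactly.
#'
#' @param cfg a [sim_config()].
#' @return data.frame of bridging-sample metadata (`is_bridging = TRUE`,
#'   clinical fields `NA`).
#' @export
make_bridging_batches <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_bridging == 0L && cfg$n_batches > 1L)
    stop("n_bridging = 0 with multiple batches: batch correction impossible")
  nb <- cfg$n_batches * cfg$n_bridging
  if (nb == 0L) {
    return(data.frame(sample_id = character(0), group = character(0),
                      age = numeric(0), race = character(0),
                      batch = character(0), is_bridging = logical(0),
                      pcl = numeric(0), moca = numeric(0)))
  }
  batch_idx <- rep(seq_len(cfg$n_batches), each = cfg$n_bridging)
  data.frame(
    sample_id = sprintf("BR%d_%d", batch_idx,
                        rep(seq_len(cfg$n_bridging), cfg$n_batches)),
    group = NA_character_, age = NA_real_, race = NA_character_,
    batch = sprintf("batch%d", batch_idx), is_bridging = TRUE,
    pcl = NA_real_, moca = NA_real_
  )
}

#' Simulate a synthetic NPX cohort
#'
#' Generates NPX = baseline + group effect + age effect + race effect +
#' batch shift + Gaussian noise, flags the lowest `lod_quantile` fraction of
#' each protein's values as below LOD, appends noise-free bridging samples,
#' and draws PCL/MoCA scores consistent with each group's classification
#' cutoffs (PCL > 44 / < 22; MoCA < 22 / > 26), correlated with the sample's
#' aggregate true protein signal.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `expr` ([npx_matrix()], participants followed by
#'   bridging rows), `meta` (sample metadata), and `truth` (ground truth:
#'   `true_diff` per contrast with signs, `true_burden_model` per protein,
#'   `batch_shifts` matrix, `baseline` profile).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- cfg$n_proteins
  protein_ids <- sprintf("prot%04d", seq_len(p))
  panel <- stats::setNames(
    rep(sprintf("panel%d", seq_len(cfg$n_panels)), each = p / cfg$n_panels),
    protein_ids)

  baseline <- stats::rnorm(p, 4, 2)
  pattern <- cfg$burden_pattern
  sgn <- sample(c(-1, 1), p, replace = TRUE)
  e <- cfg$effect_size

  eff <- matrix(0, 4, p, dimnames = list(GROUP_LEVELS, protein_ids))
  h1 <- pattern == "H1"; h2 <- pattern == "H2"; h3 <- pattern == "H3"
  eff["PTSD_MCI", h1 | h2 | h3] <- sgn[h1 | h2 | h3] * e
  eff["PTSD_only", h1] <- 0.5 * sgn[h1] * e
  eff["MCI_only", h1] <- 0.5 * sgn[h1] * e
  eff["PTSD_only", h2] <- sgn[h2] * e
  eff["MCI_only", h2] <- sgn[h2] * e

  pool <- which(pattern == "null")
  for (cs in names(cfg$n_diff)) {
    k <- cfg$n_diff[[cs]]
    if (k > length(pool))
      stop(sprintf("invalid configuration field 'n_diff': %d proteins requested for %s but only %d unassigned proteins remain",
                   k, cs, length(pool)), call. = FALSE)
    pick <- if (k > 0) sort(sample(pool, k)) else integer(0)
    pool <- setdiff(pool, pick)
    eff[cs, pick] <- eff[cs, pick] + sgn[pick] * e
  }

  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n <- length(groups)
  sample_ids <- sprintf("S%04d", seq_len(n))
  age <- .rtrunc_from_latent(stats::rnorm(n), cfg$age_mean, cfg$age_sd,
                             cfg$age_range[1], cfg$age_range[2])
  race <- ifelse(stats::rbinom(n, 1, cfg$race_prob) == 1, "Other", "Caucasian")
  perm <- sample.int(n)
  batch_idx <- integer(n)
  batch_idx[perm] <- rep_len(seq_len(cfg$n_batches), n)

  signal <- matrix(baseline, n, p, byrow = TRUE) +
    eff[groups, , drop = FALSE] +
    cfg$age_effect * (age - cfg$age_mean) +
    cfg$race_effect * (race == "Other")
  values <- signal + matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)

  # latent severity: standardized aggregate of the sample's realized signal
  # on the truly affected proteins, direction-weighted
  affected <- which(colSums(abs(eff)) > 0)
  z <- rep(0, n)
  if (length(affected)) {
    dir <- sign(colSums(eff[, affected, drop = FALSE]))
    agg <- as.vector((values[, affected, drop = FALSE] -
                        matrix(baseline[affected], n, length(affected),
                               byrow = TRUE)) %*% dir)
    if (stats::sd(agg) > 0) z <- (agg - mean(agg)) / stats::sd(agg)
  }
  r <- cfg$severity_r
  w_pcl <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
  w_moca <- -r * z + sqrt(1 - r^2) * stats::rnorm(n)
  is_ptsd <- groups %in% c("PTSD_MCI", "PTSD_only")
  is_mci <- groups %in% c("PTSD_MCI", "MCI_only")
  pcl <- moca <- numeric(n)
  pcl[is_ptsd] <- .rtrunc_from_latent(w_pcl[is_ptsd], 60, 9, 44, 85)
  pcl[!is_ptsd] <- .rtrunc_from_latent(w_pcl[!is_ptsd], 19, 1.8, 17, 22)
  moca[is_mci] <- .rtrunc_from_latent(w_moca[is_mci], 18, 2.5, 0, 22)
  moca[!is_mci] <- .rtrunc_from_latent(w_moca[!is_mci], 28, 1.2, 26, 30)

  batch_shifts <- matrix(stats::rnorm(cfg$n_batches * p, 0, cfg$batch_shift_sd),
                         cfg$n_batches, p,
                         dimnames = list(sprintf("batch%d",
                                                 seq_len(cfg$n_batches)),
                                         protein_ids))
  values <- values + batch_shifts[batch_idx, , drop = FALSE]

  meta <- data.frame(
    sample_id = sample_ids, group = groups, age = age, race = race,
    batch = sprintf("batch%d", batch_idx), is_bridging = FALSE,
    pcl = pcl, moca = moca
  )
  br_meta <- make_bridging_batches(cfg)
  if (nrow(br_meta)) {
    br_batch_idx <- as.integer(sub("batch", "", br_meta$batch))
    br_values <- matrix(baseline, nrow(br_meta), p, byrow = TRUE) +
      batch_shifts[br_batch_idx, , drop = FALSE]
    rownames(br_values) <- br_meta$sample_id
    values <- rbind(values, br_values)
    meta <- rbind(meta, br_meta)
  }
  rownames(values) <- meta$sample_id
  colnames(values) <- protein_ids

  if (cfg$lod_quantile > 0) {
    lod <- apply(values[!meta$is_bridging, , drop = FALSE], 2,
                 stats::quantile, probs = cfg$lod_quantile, names = FALSE)
  } else {
    lod <- rep(-Inf, p)
  }
  below <- sweep(values, 2, lod, "<")
  lod_table <- data.frame(protein = protein_ids, batch = "all", lod = lod)

  true_diff <- lapply(stats::setNames(nm = names(cfg$n_diff)), function(cs) {
    idx <- which(eff[cs, ] != 0)
    data.frame(protein = protein_ids[idx], sign = sign(eff[cs, idx]),
               row.names = NULL)
  })

  list(
    expr = npx_matrix(values, panel, lod_table, below),
    meta = meta,
    truth = list(
      true_diff = true_diff,
      true_burden_model = stats::setNames(pattern, protein_ids),
      group_effects = eff,
      batch_shifts = batch_shifts,
      baseline = stats::setNames(baseline, protein_ids)
    )
  )
}
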