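test_that("default configuration reproduces the study design dimensions", {
  d <- simulate_dataset(sim_config(seed = 11))
  part <- d$meta[!d$meta$is_bridging, ]
  expect_equal(nrow(part), 181)
  expect_equal(as.vector(table(part$group)[c("PTSD_MCI", "PTSD_only",
                                             "MCI_only", "control")]),
               c(34, 39, 27, 81))
  expect_equal(ncol(d$expr$values), 276)
  expect_equal(as.vector(table(d$expr$panel)), rep(92, 3))
  expect_equal(sum(d$meta$is_bridging), 2 * 3)
  expect_true(all(part$age >= 30 & part$age <= 80))
})

test_that("identical seeds give bit-identical datasets, different seeds differ", {
  a <- simulate_dataset(small_cfg(seed = 5))
  b <- simulate_dataset(small_cfg(seed = 5))
  c <- simulate_dataset(small_cfg(seed = 6))
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$batch_shifts, b$truth$batch_shifts)
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("null configuration yields pure noise with empty truth", {
  d <- simulate_dataset(small_cfg(effect_size = 0, batch_shift_sd = 0,
                                  lod_quantile = 0, seed = 3))
  expect_true(all(vapply(d$truth$true_diff, nrow, integer(1)) == 0))
  expect_false(any(d$expr$below_lod))
  expect_false(anyNA(d$expr$values))
})

test_that("H1 construction places group means at baseline, +e/2 and +e", {
  cfg <- small_cfg(n_proteins = 1L, n_panels = 1L, burden_pattern = "H1",
                   effect_size = 1, noise_sd = 1e-6, batch_shift_sd = 0,
                   age_effect = 0, race_effect = 0, seed = 9)
  d <- simulate_dataset(cfg)
  part <- d$meta[!d$meta$is_bridging, ]
  v <- d$expr$values[part$sample_id, 1]
  base <- unname(d$truth$baseline[1])
  s <- unname(d$truth$group_effects["PTSD_MCI", 1])  # +1 or -1
  means <- tapply(v, part$group, mean)
  expect_equal(unname(means["control"]), base, tolerance = 1e-4)
  expect_equal(unname(means["PTSD_only"]), base + 0.5 * s, tolerance = 1e-4)
  expect_equal(unname(means["PTSD_MCI"]), base + s, tolerance = 1e-4)
})

test_that("PCL and MoCA scores respect every group's classification cutoffs", {
  d <- simulate_dataset(sim_config(seed = 21))
  part <- d$meta[!d$meta$is_bridging, ]
  expect_silent(validate_meta(d$meta))
  is_ptsd <- part$group %in% c("PTSD_MCI", "PTSD_only")
  is_mci <- part$group %in% c("PTSD_MCI", "MCI_only")
  expect_true(all(part$pcl[is_ptsd] > 44))
  expect_true(all(part$pcl[!is_ptsd] < 22))
  expect_true(all(part$moca[is_mci] < 22))
  expect_true(all(part$moca[!is_mci] > 26))
  expect_true(all(part$pcl >= 17 & part$pcl <= 85))
  expect_true(all(part$moca >= 0 & part$moca <= 30))
})

test_that("severity scores track the planted protein signal", {
  cfg <- sim_config(n_per_group = c(PTSD_MCI = 200L, PTSD_only = 10L,
                                    MCI_only = 10L, control = 50L),
                    n_diff = c(PTSD_MCI = 30L, PTSD_only = 0L, MCI_only = 0L),
                    effect_size = 1.5, severity_r = 0.9, seed = 13)
  d <- simulate_dataset(cfg)
  part <- d$meta[!d$meta$is_bridging & d$meta$group == "PTSD_MCI", ]
  td <- d$truth$true_diff$PTSD_MCI
  sig <- as.vector(d$expr$values[part$sample_id, td$protein] %*% td$sign)
  expect_gt(stats::cor(sig, part$pcl), 0.2)
})

test_that("bridging rows are counted per batch and zero shift makes them equal", {
  br <- make_bridging_batches(small_cfg(n_batches = 2L, n_bridging = 3L))
  expect_equal(nrow(br), 6)
  expect_equal(as.vector(table(br$batch)), c(3, 3))
  expect_error(make_bridging_batches(small_cfg(n_bridging = 0L,
                                               n_batches = 2L)),
               "correction impossible")
  d <- simulate_dataset(small_cfg(batch_shift_sd = 0, seed = 2))
  br_ids <- d$meta$sample_id[d$meta$is_bridging]
  v <- d$expr$values[br_ids, , drop = FALSE]
  for (i in seq_len(nrow(v))) expect_equal(unname(v[i, ]), unname(v[1, ]))
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(small_cfg(noise_sd = 0), "noise_sd")
  expect_error(small_cfg(lod_quantile = 1), "lod_quantile")
  expect_error(sim_config(n_proteins = 10, n_panels = 3), "n_proteins")
  expect_error(small_cfg(burden_pattern = c("H1", "bogus")), "burden_pattern")
  expect_error(simulate_dataset(small_cfg(n_diff = c(PTSD_MCI = 50L,
                                                     PTSD_only = 0L,
                                                     MCI_only = 0L))),
               "n_diff")
})
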