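test_that("below-LOD values are imputed at the LOD and nothing else moves", {
  v <- matrix(c(1.2, 3, 4, 5), 2, 2)
  below <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  x <- toy_npx(v, below = below,
               lod = data.frame(protein = c("p01", "p02"), batch = "all",
                                lod = c(2, 0)))
  out <- impute_lod(x)
  expect_equal(out$values[1, 1], 2.0)
  expect_equal(out$values[-1], x$values[-1])
  expect_identical(out$below_lod, x$below_lod)

  # empty mask: identity
  x2 <- toy_npx(v)
  expect_identical(impute_lod(x2)$values, x2$values)

  # 10% random censoring equals direct masked assignment, and is monotone
  set.seed(4)
  vv <- matrix(rnorm(400, 4, 2), 20, 20)
  lodv <- apply(vv, 2, quantile, 0.1, names = FALSE)
  mask <- sweep(vv, 2, lodv, "<")
  x3 <- toy_npx(vv, below = mask,
                lod = data.frame(protein = sprintf("p%02d", 1:20),
                                 batch = "all", lod = lodv))
  out3 <- impute_lod(x3)
  oracle <- vv
  for (j in 1:20) oracle[mask[, j], j] <- lodv[j]
  dimnames(oracle) <- dimnames(x3$values)
  expect_equal(out3$values, oracle)
  expect_identical(which(out3$values != x3$values), which(mask))
  expect_true(all(out3$values >= x3$values))
})

test_that("imputation with per-batch LODs and missing LODs is handled", {
  v <- matrix(c(1, 10, 2, 20), 2, 2, dimnames = list(c("s1", "s2"), c("pA", "pB")))
  below <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  lod <- data.frame(protein = c("pA", "pA"), batch = c("b1", "b2"),
                    lod = c(1.5, 12))
  x <- npx_matrix(v, c(pA = "panelA", pB = "panelA"), lod, below)
  out <- impute_lod(x, batches = c("b1", "b2"))
  expect_equal(unname(out$values[, "pA"]), c(1.5, 12))
  # no LOD for a flagged protein -> error naming it
  lod_bad <- data.frame(protein = "pB", batch = "all", lod = 0.5)
  x_bad <- npx_matrix(v, c(pA = "panelA", pB = "panelA"), lod_bad, below)
  expect_error(impute_lod(x_bad), "pA")
})

test_that("bridging median subtraction matches the hand-worked toy", {
  v <- matrix(c(1, 2, 3, 5), 4, 1,
              dimnames = list(c("b1", "b2", "b3", "s1"), "pA"))
  meta <- data.frame(sample_id = rownames(v), group = NA, age = NA, race = NA,
                     batch = "batchA", is_bridging = c(TRUE, TRUE, TRUE, FALSE),
                     pcl = NA, moca = NA)
  out <- bridge_correct(npx_matrix(v, c(pA = "panelA")), meta)
  expect_equal(unname(out$values["s1", "pA"]), 3)  # 5 - median(1,2,3)
  expect_equal(median(out$values[1:3, "pA"]), 0)
})

test_that("correction aligns shifted batch copies and is idempotent and shift-invariant", {
  d <- simulate_dataset(small_cfg(seed = 8, batch_shift_sd = 1))
  x <- d$expr
  corr <- bridge_correct(x, d$meta)
  # idempotent: second pass changes nothing
  corr2 <- bridge_correct(corr, d$meta)
  expect_equal(corr2$values, corr$values, tolerance = 1e-12)
  # within-batch differences unchanged
  b1 <- d$meta$sample_id[d$meta$batch == "batch1" & !d$meta$is_bridging][1:2]
  expect_equal(x$values[b1[1], ] - x$values[b1[2], ],
               corr$values[b1[1], ] - corr$values[b1[2], ])
  # noise-free bridging: corrected values equal batch-free values minus the
  # reference (baseline) profile, exactly
  part <- d$meta[!d$meta$is_bridging, ]
  shift <- d$truth$batch_shifts[part$batch, , drop = FALSE]
  batch_free <- x$values[part$sample_id, ] - shift
  recon <- sweep(corr$values[part$sample_id, ], 2, d$truth$baseline, "+")
  expect_equal(recon, batch_free, tolerance = 1e-10)
  # two samples with identical underlying values in different batches agree
  # after correction
  v2 <- rbind(d$expr$values,
              twin = d$expr$values[part$sample_id[1], ] -
                d$truth$batch_shifts[part$batch[1], ] +
                d$truth$batch_shifts["batch2", ])
  rownames(v2)[nrow(v2)] <- "twin"
  meta2 <- rbind(d$meta, data.frame(sample_id = "twin", group = part$group[1],
                                    age = part$age[1], race = part$race[1],
                                    batch = "batch2", is_bridging = FALSE,
                                    pcl = part$pcl[1], moca = part$moca[1]))
  x2 <- npx_matrix(v2, x$panel, x$lod)
  corr_t <- bridge_correct(x2, meta2)
  expect_equal(unname(corr_t$values["twin", ]),
               unname(corr_t$values[part$sample_id[1], ]), tolerance = 1e-10)
  # batch without bridging samples -> error listing the batch
  meta_nb <- d$meta
  meta_nb$is_bridging[meta_nb$batch == "batch2"] <- FALSE
  expect_error(bridge_correct(x, meta_nb), "batch2")
})

test_that("duplicate QC recovers exact, anti- and calibrated correlations", {
  set.seed(10)
  prof <- rnorm(50, 4, 2)
  v <- rbind(a1 = prof, a2 = prof, b1 = prof, b2 = 2 * mean(prof) - prof)
  x <- toy_npx(v)
  qc <- duplicate_qc(x, rbind(c("a1", "a2"), c("b1", "b2")))
  expect_equal(qc$pairs$r, c(1, -1))
  expect_equal(qc$mean_r, 0)
  expect_true(qc$pairs$flagged[2])

  # noise calibrated from r = var_signal / (var_signal + var_noise) = 0.97
  set.seed(11)
  sd_n <- sqrt(4 * 0.03 / 0.97)
  rows <- list()
  for (i in 1:6) {
    pr <- rnorm(276, 4, 2)
    rows[[2 * i - 1]] <- pr + rnorm(276, 0, sd_n)
    rows[[2 * i]] <- pr + rnorm(276, 0, sd_n)
  }
  vv <- do.call(rbind, rows)
  rownames(vv) <- sprintf("d%02d", 1:12)
  pairs <- cbind(sprintf("d%02d", seq(1, 11, 2)), sprintf("d%02d", seq(2, 12, 2)))
  qc2 <- duplicate_qc(toy_npx(vv), pairs)
  expect_equal(qc2$mean_r, 0.97, tolerance = 0.02)

  # too few shared finite values -> error
  v3 <- matrix(c(1, 1, 2, 2, NA, 3), 2, 3,
               dimnames = list(c("x1", "x2"), c("p1", "p2", "p3")))
  expect_error(duplicate_qc(toy_npx(v3), rbind(c("x1", "x2"))), "3 shared")
})
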