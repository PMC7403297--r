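test_that("per-protein fit matches the normal-equations oracle on random toys", {
  set.seed(42)
  for (i in 1:50) {
    n <- 20
    case <- rbinom(n, 1, 0.5)
    if (length(unique(case)) < 2) case[1:2] <- c(0, 1)
    age <- rnorm(n, 55, 8)
    race <- rbinom(n, 1, 0.3)
    if (var(race) == 0) race[1] <- 1 - race[1]
    y <- 0.3 * case + 0.01 * age + rnorm(n)
    got <- fit_protein(y, case, age, race)
    X <- cbind(1, case, age, race)
    want <- oracle_ols(X, y)
    expect_equal(got$beta, want$beta, tolerance = 1e-8)
    expect_equal(got$se, want$se, tolerance = 1e-8)
    expect_equal(got$t, want$t, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
})

test_that("degenerate responses and designs are handled explicitly", {
  case <- rep(c(0, 1), each = 10)
  # constant response: beta 0, p 1
  got <- fit_protein(rep(2.5, 20), case)
  expect_equal(got$beta, 0)
  expect_equal(got$p, 1)
  # exact group separation: beta equals the difference, p ~ 0
  got2 <- fit_protein(2 * case, case)
  expect_equal(got2$beta, 2, tolerance = 1e-10)
  expect_lt(got2$p, 1e-12)
  # two-group fit without covariates equals the difference of group means
  set.seed(1)
  y <- rnorm(20) + case
  got3 <- fit_protein(y, case)
  expect_equal(got3$beta, mean(y[case == 1]) - mean(y[case == 0]),
               tolerance = 1e-12)
  # constant covariate is dropped with a warning naming it
  expect_warning(fit_protein(y, case, age = rep(55, 20)), "age")
})

test_that("BH adjustment matches the hand-computed step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # one strong protein in a 92-protein panel: 0.0005 * 92 / 1 = 0.046 < 0.1
  p_panel <- c(0.0005, seq(0.5, 1, length.out = 91))
  expect_equal(sum(bh_adjust(p_panel) < 0.1), 1)
  set.seed(7)
  for (i in 1:10) {
    p <- runif(40)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))                 # q >= p elementwise
    perm <- sample(40)
    expect_equal(bh_adjust(p[perm]), q[perm])  # permutation equivariance
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("contrast tables carry coherent panels, directions and FDR calls", {
  d <- simulate_dataset(small_cfg(n_diff = c(PTSD_MCI = 2L, PTSD_only = 0L,
                                             MCI_only = 0L),
                                  effect_size = 2, seed = 15))
  pre <- drop_bridging(bridge_correct(d$expr, d$meta), d$meta)
  dr <- run_contrast(pre$expr, pre$meta, default_contrasts()$PTSD_MCI_vs_control)
  tab <- dr$table
  expect_equal(nrow(tab), 12)
  expect_identical(tab$direction, ifelse(tab$beta > 0, "up", "down"))
  expect_true(all(tab$q >= tab$p & tab$q <= 1))
  # q equals within-panel BH, not global BH
  for (pn in unique(tab$panel)) {
    idx <- tab$panel == pn
    expect_equal(tab$q[idx], bh_adjust(tab$p[idx]))
  }
  expect_setequal(dr$sig_p, tab$protein[tab$p < 0.05])
  expect_setequal(dr$sig_fdr, tab$protein[tab$q < 0.1])
  # the two planted proteins are recovered
  expect_true(all(d$truth$true_diff$PTSD_MCI$protein %in% dr$sig_fdr))
  # empty arm -> error
  meta_no_case <- pre$meta[pre$meta$group != "PTSD_MCI", ]
  expect_error(run_contrast(pre$expr, meta_no_case,
                            default_contrasts()$PTSD_MCI_vs_control),
               "empty case or control arm")
})

test_that("Venn decomposition handles disjoint, identical and mixed lists", {
  ov <- overlap_sets(list(A = c("p1", "p2"), B = c("p3", "p4", "p5"),
                          C = c("p6", "p7", "p8", "p9")))
  expect_equal(length(ov$union), 9)
  expect_equal(unname(ov$regions[c("A", "B", "C")]), c(2, 3, 4))
  expect_true(all(ov$regions[c("A&B", "A&C", "B&C", "A&B&C")] == 0))

  same <- list(A = c("p1", "p2"), B = c("p1", "p2"), C = c("p1", "p2"))
  ov2 <- overlap_sets(same)
  expect_equal(unname(ov2$regions["A&B&C"]), 2)
  expect_equal(length(ov2$union), 2)

  ov3 <- overlap_sets(list(A = c("x", "y"), B = c("y", "z")))
  expect_equal(unname(ov3$regions[c("A", "B", "A&B")]), c(1, 1, 1))
  expect_equal(ov3$membership$protein, c("x", "y", "z"))
})

test_that("beta correlations match the direct formula and flag degeneracy", {
  b1 <- c(0.5, -0.2, 0.1, 0.8, -0.4, 0.3, 0.05, -0.6, 0.22, -0.11)
  expect_equal(beta_correlation(list(a = b1, b = b1))$r, 1)
  expect_equal(beta_correlation(list(a = b1, b = -b1))$r, -1)
  set.seed(3)
  b2 <- rnorm(10)
  got <- beta_correlation(list(a = b1, b = b2))
  r_hand <- sum((b1 - mean(b1)) * (b2 - mean(b2))) /
    sqrt(sum((b1 - mean(b1))^2) * sum((b2 - mean(b2))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$p, cor.test(b1, b2)$p.value)
  expect_error(beta_correlation(list(a = b1, b = rep(1, 10))), "zero-variance")
})

test_that("sign consistency counts proteins with a common direction", {
  betas <- data.frame(a = c(1, -1, 2, 0.5), b = c(2, -3, -1, 0.1),
                      c = c(0.5, -0.2, 1, 0.4),
                      row.names = c("p1", "p2", "p3", "p4"))
  sc <- sign_consistency(betas)
  expect_equal(sc$n_consistent, 3)  # p3 flips sign in contrast b
  expect_false(sc$consistent[["p3"]])
  sc2 <- sign_consistency(betas, c("p1", "p3"))
  expect_equal(sc2$n_total, 2)
  expect_equal(sc2$n_consistent, 1)
})
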