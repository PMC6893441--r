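test_that("mann_whitney_u exact branch matches full label enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)    # 2/20 labelings are as extreme
  expect_identical(res$method, "exact")

  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    nx <- sample(1:(n - 1), 1)
    vals <- sample(rnorm(50), n)       # distinct values, no ties
    x <- vals[1:nx]
    y <- vals[(nx + 1):n]
    res <- mann_whitney_u(x, y)
    expect_equal(res$U, mwu_u_stat(x, y))
    if (nx <= 8 && (n - nx) <= 8) {
      expect_identical(res$method, "exact")
      expect_equal(res$p, mwu_oracle_p(x, y))
    }
  }
})

test_that("mann_whitney_u falls back to the tie-corrected normal approximation", {
  x <- c(1, 2, 2, 3)
  y <- c(2, 3, 3, 4)
  res <- mann_whitney_u(x, y)
  expect_identical(res$method, "normal_approx")
  expect_equal(res$U, mwu_u_stat(x, y))    # midrank U

  # identical samples: no location shift detectable
  same <- mann_whitney_u(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_gte(same$p, 0.99)

  # clearly shifted large Gaussians are detected every time
  set.seed(23)
  for (i in 1:10) {
    a <- rnorm(81, mean = 1)
    b <- rnorm(234, mean = 0)
    expect_lt(mann_whitney_u(a, b)$p, 0.001)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("compare_regulators recovers a shifted TF and respects Bonferroni", {
  for (s in 1:5) {
    sim <- simulate_cohorts(small_cfg(seed = 300 + s, n_A = 40, n_B = 60))
    regs <- regulator_set("NR1H3", c("NCOR1", "NCOR2", "LCOR"))
    out <- compare_regulators(sim$expression, sim$annotation, regs)
    tf_row <- out[out$gene == "NR1H3", ]
    expect_lt(tf_row$p_adj, 0.05)
    expect_gt(tf_row$median_A, tf_row$median_B)       # higher in cohort A
    cor_rows <- out[out$role == "corepressor", ]
    expect_true(all(cor_rows$median_A < cor_rows$median_B))
    expect_equal(out$p_adj, pmin(1, out$p_raw * 4))
  }
})

test_that("compare_regulators flags absent regulators and tolerates identical cohorts", {
  sim <- simulate_cohorts(small_cfg(seed = 77))
  out <- compare_regulators(sim$expression, sim$annotation,
                            c("NR1H3", "GHOSTGENE"))
  expect_false(out$present[out$gene == "GHOSTGENE"])
  expect_true(is.na(out$p_adj[out$gene == "GHOSTGENE"]))
  expect_true(out$present[out$gene == "NR1H3"])

  # same distribution in both cohorts: nothing significant after adjustment
  set.seed(4)
  expr <- toy_expr(c("NR1H3", "NCOR1"), 60, seed = 4)
  ann <- data.frame(sample_id = colnames(expr),
                    cohort = rep(c("g1", "g2"), each = 30))
  out2 <- compare_regulators(expr, ann, c("NR1H3", "NCOR1"))
  expect_true(all(out2$p_adj > 0.1))
})

test_that("compare_regulators is invariant to sample order", {
  sim <- simulate_cohorts(small_cfg(seed = 15))
  regs <- regulator_set("NR1H3", c("NCOR1", "NCOR2", "LCOR"))
  a <- compare_regulators(sim$expression, sim$annotation, regs)
  perm <- sample(ncol(sim$expression))
  b <- compare_regulators(sim$expression[, perm],
                          sim$annotation[perm, ], regs)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("regulator roles must be disjoint", {
  expect_error(regulator_set("NR1H3", c("NR1H3", "NCOR1")), "disjoint")
})

test_that("ratio_score is a log-difference: shift-invariant and antisymmetric", {
  expr <- matrix(c(1.2, 0.5,
                   0.2, 0.5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("NR1H3", "NCOR1"), c("s1", "s2")))
  rs <- ratio_score(expr, "NR1H3", "NCOR1")
  expect_equal(rs$score, c(1.0, 0))

  # adding any constant to both genes leaves the score unchanged
  expect_equal(ratio_score(expr + 3.7, "NR1H3", "NCOR1")$score, rs$score)

  # swapping receptor and corepressor flips the sign
  expect_equal(ratio_score(expr, "NCOR1", "NR1H3")$score, -rs$score)

  expect_error(ratio_score(expr, "NR1H3", "LCOR"), "LCOR")
})

test_that("ratio_score over several corepressors uses their mean log expression", {
  expr <- matrix(c(2, 1, 0.5, 1.5), nrow = 4,
                 dimnames = list(c("NR1H3", "NCOR1", "NCOR2", "LCOR"), "s1"))
  rs <- ratio_score(expr, "NR1H3", c("NCOR1", "NCOR2", "LCOR"))
  expect_equal(rs$score, 2 - 1)
  # missing corepressor value propagates to a missing score
  expr["NCOR2", 1] <- NA
  expect_true(is.na(ratio_score(expr, "NR1H3",
                                c("NCOR1", "NCOR2", "LCOR"))$score))
})

test_that("a noiseless monotone target of the ratio correlates perfectly", {
  set.seed(6)
  n <- 40
  expr <- rbind(NR1H3 = rnorm(n, 2, 0.5), NCOR1 = rnorm(n, 1, 0.5))
  expr <- rbind(expr, TGT = 3 * (expr["NR1H3", ] - expr["NCOR1", ]) + 2)
  colnames(expr) <- sprintf("s%02d", 1:n)
  ann <- data.frame(sample_id = colnames(expr),
                    cohort = rep(c("a", "b"), each = n / 2))
  prof <- ratio_score(expr, "NR1H3", "NCOR1")
  rc <- ratio_target_correlation(prof, expr, "TGT", ann)
  expect_equal(rc$r, c(1, 1))
  expect_equal(rc$p, c(0, 0))
})

test_that("in the repressed cohort the ratio out-predicts the receptor alone", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_cohorts(small_cfg(seed = 500 + s, n_targets = 30,
                                      n_decoys = 5, n_B = 120))
    prof <- ratio_score(sim$expression, "NR1H3",
                        c("NCOR1", "NCOR2", "LCOR"))
    rep_label <- sim$truth$config$cohort_labels[2]
    r_ratio <- r_alone <- numeric(30)
    for (i in 1:30) {
      g <- sprintf("TG%03d", i)
      rc <- ratio_target_correlation(prof, sim$expression, g,
                                     sim$annotation)
      r_ratio[i] <- abs(rc$r[rc$cohort == rep_label])
      alone <- run_screen(sim$expression, sim$annotation, "NR1H3", g,
                          fdr_level = 0.5)
      r_alone[i] <- abs(alone$records$r[alone$records$cohort == rep_label])
    }
    hits <- hits + (mean(r_ratio) > mean(r_alone))
  }
  expect_gte(hits, 9)
})

test_that("decoy targets show no systematic ratio correlation", {
  rs <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_cohorts(small_cfg(seed = 700 + s, n_targets = 2,
                                      n_canonical = 1, n_decoys = 3,
                                      n_A = 50, n_B = 50))
    prof <- ratio_score(sim$expression, "NR1H3",
                        c("NCOR1", "NCOR2", "LCOR"))
    rc <- ratio_target_correlation(prof, sim$expression, "DC001",
                                   sim$annotation)
    rs[s] <- mean(rc$r)
  }
  expect_lt(abs(mean(rs)), 0.1)
})
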