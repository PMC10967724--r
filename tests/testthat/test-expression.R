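test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 3), b = c(2, 4))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(1.5, 3.5))
  expect_equal(unname(qn[, "b"]), c(1.5, 3.5))

  ident <- cbind(c(2, 5, 9), c(2, 5, 9))
  expect_equal(quantile_normalize(ident), ident)

  set.seed(11)
  r <- matrix(rlnorm(600), 100, 6)
  qr <- quantile_normalize(r)
  sorted <- apply(qr, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # idempotent
  expect_equal(quantile_normalize(qr), qr, tolerance = 1e-12)
  # constant column (all ties) gets the mean of the target distribution
  ct <- cbind(c(1, 2, 3), c(5, 5, 5))
  expect_silent(qct <- quantile_normalize(ct))
  expect_equal(sort(qct[, 1]), c(3, 3.5, 4))
  expect_equal(qct[, 2], rep(3.5, 3))
  expect_error(quantile_normalize(cbind(c(1, NA), c(1, 2))), "complete")
})

test_that("moderated t collapses to its analytic limits", {
  fx <- tiny_expr(n = 150, seed = 12)
  lmat <- log2(fx$matrix)
  # d0 = 0: ordinary pooled two-sample t
  raw <- moderated_t(lmat, fx$groups, "test", "ref",
                     prior = list(d0 = 0, s0_sq = 1))
  ordinary <- apply(lmat, 1, function(x)
    t.test(x[fx$groups == "test"], x[fx$groups == "ref"],
           var.equal = TRUE)$statistic)
  expect_equal(raw$t, unname(ordinary), tolerance = 1e-10)
  # d0 = Inf: fixed variance, normal reference distribution
  inf <- moderated_t(lmat, fx$groups, "test", "ref",
                     prior = list(d0 = Inf, s0_sq = 0.04))
  expect_true(all(inf$s2_post == 0.04))
  expect_equal(inf$p, 2 * pnorm(-abs(inf$t)), tolerance = 1e-12)
  expect_error(moderated_t(lmat[, 1:3], fx$groups[1:3], "test", "ref"),
               ">= 2 samples")
})

test_that("moderated t is invariant under global intensity scaling", {
  fx <- tiny_expr(n = 100, de_idx = 1:10, seed = 13)
  a <- moderated_t(log2(fx$matrix), fx$groups, "test", "ref")
  b <- moderated_t(log2(fx$matrix * 7), fx$groups, "test", "ref")
  expect_equal(a$p, b$p, tolerance = 1e-9)
  expect_equal(a$t, b$t, tolerance = 1e-9)
})

test_that("variance-prior estimation recovers planted hyperparameters", {
  cfg <- expr_sim_config(n_transcripts = 5000, d0 = 4, s0_sq = 0.05,
                         de_fraction = 0, seed = 14)
  sim <- simulate_expression(cfg)
  lmat <- log2(sim$matrix)
  tt <- moderated_t(lmat, sim$groups, "9d", "6d")
  expect_lt(abs(attr(tt, "d0") - 4) / 4, 0.25)
  expect_lt(abs(attr(tt, "s0_sq") - 0.05) / 0.05, 0.25)
})

test_that("moderated t agrees with the established empirical-Bayes fit", {
  # independent cross-check of the whole moderation path against limma,
  # on data with genuinely heterogeneous per-gene variances (finite d0)
  cfg <- expr_sim_config(n_transcripts = 800, groups = c("ref", "test"),
                         de_fraction = 0.1, d0 = 4, s0_sq = 0.05,
                         seed = 15)
  sim <- simulate_expression(cfg)
  lmat <- log2(sim$matrix)
  grp <- unname(sim$groups)
  ours <- moderated_t(lmat, sim$groups, "test", "ref")

  design <- model.matrix(~ factor(grp, levels = c("ref", "test")))
  fit <- limma::eBayes(limma::lmFit(lmat, design))
  expect_lt(fit$df.prior, 10)  # heterogeneity actually present
  expect_equal(attr(ours, "d0"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(ours, "s0_sq"), fit$s2.prior, tolerance = 1e-4)
  expect_equal(ours$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(ours$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("fold changes are folded ratios of linear group means", {
  m <- rbind(g1 = c(30, 30, 20, 20), g2 = c(20, 20, 30, 30),
             g3 = c(25, 25, 25, 25))
  grp <- c("t", "t", "r", "r")
  fc <- fold_change(m, grp, "t", "r")
  expect_equal(fc$fc, c(1.5, 1.5, 1))
  expect_equal(fc$direction, c("up", "down", "up"))
  expect_error(fold_change(rbind(c(0, 0, 1, 1)), grp, "t", "r"), "> 0")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(16)
  p <- runif(200)^2
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  # BH rejects at least as much as Bonferroni at any alpha
  for (alpha in c(0.01, 0.05, 0.2)) {
    expect_gte(sum(bh_adjust(p) <= alpha),
               sum(p.adjust(p, "bonferroni") <= alpha))
  }
})

test_that("fold-change bins are cumulative with a consistent up/down split", {
  b <- classify_fc_bins(c(1.6, 2.5, 5.1), c("up", "up", "down"))
  expect_equal(unname(b$bins), c(3, 2, 1, 1))
  expect_equal(b$up, 2); expect_equal(b$down, 1)
  e <- classify_fc_bins(numeric(0), character(0))
  expect_equal(unname(e$bins), c(0, 0, 0, 0))
  low <- classify_fc_bins(c(1.1, 1.4), c("up", "down"))
  expect_equal(unname(low$bins), c(0, 0, 0, 0))
  expect_equal(low$up + low$down, 0)
})

test_that("Venn decomposition equals brute-force membership tallies", {
  v <- venn_decompose(list(A = c(1, 2, 3), B = c(2, 3, 4),
                           C = c(3, 4, 5)))
  expect_equal(unname(v$total), c(3, 3, 3))
  expect_equal(unname(v$specific), c(1, 0, 1))
  expect_equal(v$triple, 1)
  expect_equal(v$union_size, 5)
  expect_equal(unname(v$pair_total), c(2, 1, 2))  # A&B, A&C, B&C
  expect_equal(unname(v$pair_only), c(1, 0, 1))

  d <- venn_decompose(list(A = 1:3, B = 4:6))
  expect_equal(unname(d$specific), unname(d$total))

  set.seed(17)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) sample(1:50, sample(5:40, 1)))
    names(sets) <- c("A", "B", "C")
    v <- venn_decompose(sets)
    ids <- 1:50
    memb <- sapply(sets, function(s) ids %in% s)
    code <- memb %*% c(1, 2, 4)
    expect_equal(unname(v$specific),
                 c(sum(code == 1), sum(code == 2), sum(code == 4)))
    expect_equal(v$triple, sum(code == 7))
    expect_equal(v$union_size, sum(code > 0))
    # inclusion-exclusion closes exactly
    expect_equal(v$union_size,
                 sum(v$total) - sum(v$pair_total) + v$triple)
  }
})

test_that("one-way ANOVA matches aov and the two-group t identity", {
  fx <- tiny_expr(n = 60, de_idx = 1:5, seed = 18)
  lmat <- log2(fx$matrix)
  an <- anova_oneway(lmat, fx$groups)
  # oracle: stats::aov on a few transcripts
  for (i in c(1, 3, 50)) {
    fit <- summary(aov(lmat[i, ] ~ factor(fx$groups)))[[1]]
    expect_equal(an$F[i], fit[["F value"]][1], tolerance = 1e-10)
    expect_equal(an$p[i], fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  # F = t^2 for two groups
  tt <- moderated_t(lmat, fx$groups, "test", "ref",
                    prior = list(d0 = 0, s0_sq = 1))
  expect_equal(an$F, tt$t^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p, tolerance = 1e-10)
  # planted effect far beyond noise
  strong <- tiny_expr(n = 20, de_idx = 1, log2fc = 6, sigma = 0.05,
                      seed = 19)
  expect_lt(anova_oneway(log2(strong$matrix), strong$groups)$p[1], 1e-6)
  # degenerate: zero within-group variance but distinct means
  zmat <- rbind(z = c(1, 1, 2, 2))
  expect_equal(anova_oneway(zmat, c("a", "a", "b", "b"))$p, 0)
})

test_that("null data stay calibrated through the full contrast chain", {
  cfg <- expr_sim_config(n_transcripts = 2000, de_fraction = 0,
                         groups = c("ref", "t1"), seed = 20)
  sim <- simulate_expression(cfg)
  de <- run_de_contrasts(sim$matrix, sim$groups, "ref")
  r <- de$results[["t1"]]
  # p-values roughly uniform: fraction <= 0.05 within 2 SE
  frac <- mean(r$p <= 0.05)
  expect_lt(abs(frac - 0.05), 2 * sqrt(0.05 * 0.95 / 2000) + 0.01)
  # combined FC + p gate is conservative under the null
  expect_lt(mean(r$significant), 0.05)
})

test_that("the contrast chain recovers planted fold changes", {
  cfg <- expr_sim_config(n_transcripts = 2000, de_fraction = 0.1,
                         logfc_min = log2(3), logfc_max = log2(3),
                         groups = c("ref", "t1"), s0_sq = 0.02,
                         seed = 22)
  sim <- simulate_expression(cfg)
  # quantile normalization can leave a transcript exactly tied across all
  # samples; the prior fit drops it with a warning, which is fine here
  de <- suppressWarnings(run_de_contrasts(sim$matrix, sim$groups, "ref"))
  r <- de$results[["t1"]]
  tru <- sim$truth
  expect_gte(mean(r$significant[tru$is_de]), 0.9)
  b <- de$bins[["t1"]]
  n_up <- sum(tru$is_de & tru$true_log2fc > 0)
  n_dn <- sum(tru$is_de & tru$true_log2fc < 0)
  expect_lt(abs(b$up - n_up) / n_up, 0.15)
  expect_lt(abs(b$down - n_dn) / n_dn, 0.15)
  # identical copy of the reference yields nothing significant
  m2 <- sim$matrix[, sim$groups == "ref"]
  m <- cbind(m2, m2)
  colnames(m) <- paste0("s", 1:8)
  grp <- setNames(rep(c("ref", "copy"), each = 4), colnames(m))
  de2 <- run_de_contrasts(m, grp, "ref", normalize = FALSE)
  expect_equal(sum(de2$results[["copy"]]$significant), 0)
})
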