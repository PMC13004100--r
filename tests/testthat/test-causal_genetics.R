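exp_rec <- function(beta = 0.2, se = 0.1, ea = "G", oa = "A", eaf = 0.3)
  summary_stat("rs1", "17", 100, ea, oa, eaf, beta, se, n = 5000)

test_that("Wald ratio, SE and F-statistic follow their closed forms", {
  w <- wald_ratio_mr(exp_rec(), summary_stat("rs1", "17", 100, "G", "A",
                                             0.3, 0, 0.05))
  expect_equal(w$ratio, 0)
  expect_equal(w$f_statistic, 4.0)

  w2 <- wald_ratio_mr(exp_rec(beta = 0.25, se = 0.05),
                      summary_stat("rs1", "17", 100, "G", "A", 0.3, -0.1, 0.04))
  expect_equal(w2$ratio, -0.4)
  expect_equal(w2$se_ratio, 0.04 / 0.25)
  expect_equal(w2$p, 2 * pnorm(-abs(-0.4 / (0.04 / 0.25))))
  expect_equal(w2$f_statistic, 25)

  expect_error(wald_ratio_mr(exp_rec(beta = 0), exp_rec()), "undefined instrument")
})

test_that("allele harmonization flips swapped outcomes and rejects mismatches", {
  outc <- summary_stat("rs1", "17", 100, "A", "G", 0.7, 0.1, 0.04)
  w <- wald_ratio_mr(exp_rec(), outc)
  expect_equal(w$ratio, -0.1 / 0.2)  # sign flipped with the allele swap
  direct <- wald_ratio_mr(exp_rec(),
                          summary_stat("rs1", "17", 100, "G", "A", 0.3, -0.1, 0.04))
  expect_equal(w$ratio, direct$ratio)

  expect_error(
    wald_ratio_mr(exp_rec(), summary_stat("rs1", "17", 100, "T", "C", 0.3, 0.1, 0.04)),
    "mismatch")
  expect_warning(
    wald_ratio_mr(exp_rec(ea = "A", oa = "T"),
                  summary_stat("rs1", "17", 100, "A", "T", 0.3, 0.1, 0.04)),
    "strand-ambiguous")
})

test_that("first-order NOME standard error matches a parametric bootstrap", {
  set.seed(41)
  for (i in 1:3) {
    be <- runif(1, 0.1, 0.5) * sample(c(-1, 1), 1)
    so <- runif(1, 0.02, 0.2)
    bo <- rnorm(1, 0, 0.1)
    w <- wald_ratio_mr(exp_rec(beta = be, se = 0.05),
                       summary_stat("rs1", "17", 100, "G", "A", 0.3, bo, so))
    draws <- rnorm(1e5, bo, so) / be   # exposure fixed, per NOME
    expect_lt(abs(w$se_ratio - sd(draws)) / w$se_ratio, 0.01)
  }
})

test_that("Wakefield log-ABF matches numerical quadrature of the Gaussian Bayes factor", {
  quad_labf <- function(beta, se, W) {
    num <- stats::integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, W),
                            -Inf, Inf, rel.tol = 1e-12)$value
    log(num / dnorm(beta, 0, se))
  }
  set.seed(43)
  for (i in 1:10) {
    beta <- rnorm(1, 0, 0.3)
    se <- runif(1, 0.01, 0.3)
    W <- runif(1, 0.05, 0.5)
    expect_equal(wakefield_labf(beta, se, W), quad_labf(beta, se, W),
                 tolerance = 1e-6)
  }
  # null shrinkage: z = 0 gives a negative log-ABF
  expect_lt(wakefield_labf(0, 0.1, 0.2), 0)
  expect_equal(wakefield_labf(0, 0.1, 0.2), 0.5 * log(1 - 0.04 / (0.04 + 0.01)))
  # vanishing prior: no evidence either way
  expect_equal(wakefield_labf(0.3, 0.1, 1e-8), 0, tolerance = 1e-10)
})

test_that("colocalization posteriors normalise and ignore variant order", {
  set.seed(47)
  t1 <- data.frame(variant_id = paste0("v", 1:30),
                   beta = rnorm(30, 0, 0.05), se = runif(30, 0.01, 0.05))
  t2 <- data.frame(variant_id = paste0("v", 1:30),
                   beta = rnorm(30, 0, 0.05), se = runif(30, 0.01, 0.05))
  res <- coloc_abf(t1, t2)
  expect_equal(sum(res$pp), 1, tolerance = 1e-8)
  expect_equal(sum(res$per_variant_pp4), 1, tolerance = 1e-8)
  expect_true(all(res$pp >= 0 & res$pp <= 1))

  perm <- sample(30)
  res_p <- coloc_abf(t1[perm, ], t2)
  expect_equal(res_p$pp, res$pp, tolerance = 1e-12)

  # inflating a null trait's SEs keeps the normalisation
  t2b <- t2; t2b$se <- t2b$se * 10
  expect_equal(sum(coloc_abf(t1, t2b)$pp), 1, tolerance = 1e-8)

  expect_error(coloc_abf(t1[1, , drop = FALSE], t2[1, , drop = FALSE]), ">= 2")
  expect_error(coloc_abf(rbind(t1, t1[1, ]), t2), "duplicate")
})

test_that("credible sets are minimal for random PIP vectors", {
  cs <- credible_set_from_pips(c(a = 1.0))
  expect_equal(nrow(cs$members), 1L)

  cs10 <- credible_set_from_pips(setNames(rep(0.1, 10), paste0("v", 1:10)), 0.95)
  expect_equal(nrow(cs10$members), 10L)
  expect_equal(cs10$cumulative_pip, 1.0)

  expect_error(credible_set_from_pips(c(a = 0.3, b = 0.2), 0.95),
               "achievable coverage is 0.5")

  set.seed(53)
  for (i in 1:1000) {
    p <- runif(sample(3:25, 1))
    p <- p / sum(p) * runif(1, 0.96, 1)
    names(p) <- paste0("v", seq_along(p))
    cs <- credible_set_from_pips(p, 0.95)
    expect_gte(cs$cumulative_pip, 0.95)
    k <- nrow(cs$members)
    if (k > 1)  # dropping the last member must fall below coverage
      expect_lt(cs$members$cumulative_pip[k - 1], 0.95)
    expect_true(all(diff(cs$members$pip) <= 0))
  }
})

test_that("LD r^2 is squared dosage correlation with monomorphic rejection", {
  g <- cbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 1),
             d = c(0, 2, 0, 2))
  r2 <- ld_r2_matrix(g)
  expect_equal(unname(diag(r2)), rep(1, 4))
  expect_equal(r2["a", "b"], 1)            # duplicated column
  expect_equal(r2["a", "c"], cor(g[, "a"], g[, "c"])^2)
  expect_equal(r2["a", "d"], cor(c(0, 1, 2, 1), c(0, 2, 0, 2))^2)

  gm <- cbind(g, e = c(1, 1, 1, 1))
  expect_error(ld_r2_matrix(gm), "monomorphic.*e")

  # independent variants: off-diagonal r^2 vanishes at large n
  set.seed(59)
  gi <- matrix(rbinom(1e4 * 6, 2, 0.3), ncol = 6)
  r2i <- ld_r2_matrix(gi)
  expect_lt(max(r2i[upper.tri(r2i)]), 0.01)
})

test_that("the prioritization rule counts narrow-peak criteria and codes the boundary", {
  recs <- data.frame(
    variant_id = c("nc_none", "nc_one", "nc_two", "coding"),
    is_coding_nonsynonymous = c(FALSE, FALSE, FALSE, TRUE),
    regulatory_overlap = c(FALSE, TRUE, TRUE, FALSE),
    re2g_link = c(FALSE, FALSE, TRUE, FALSE),
    increases_expression = FALSE,
    qtl_colocalizes = FALSE,
    deleterious_votes = c(NA, NA, NA, 7L),
    total_predictors = c(NA, NA, NA, 9L))
  out <- prioritize_variants(recs)
  expect_equal(out$prioritized, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$deleterious_fraction[4], 7 / 9, tolerance = 1e-12)
  expect_equal(round(out$deleterious_fraction[4], 3), 0.778)

  # the published evidence table: no non-coding variant reaches two criteria
  ev <- read.delim(system.file("extdata", "prioritization_evidence.tsv",
                               package = "conformgen"), comment.char = "#")
  pr <- prioritize_variants(ev)
  noncoding <- pr[!pr$is_coding_nonsynonymous, ]
  expect_true(all(!noncoding$prioritized))
  expect_true(all(noncoding$n_criteria_met < 2))
  # gapped-peak-only overlap is recorded but never counted
  expect_true(any(ev$gapped_peak_only))
  expect_equal(pr$n_criteria_met[ev$gapped_peak_only], rep(0, 2))
  coding <- pr[pr$is_coding_nonsynonymous, ]
  expect_true(coding$prioritized)
  expect_equal(coding$deleterious_fraction, 7 / 9, tolerance = 1e-12)

  expect_error(prioritize_variants(recs[, -3]), "missing column")
})
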