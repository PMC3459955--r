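test_that("expected cell means reproduce the path-count identities", {
  base <- list(mu = rep(0, 6), c1 = 0, c2 = 0)
  m <- expected_cell_means(base)
  expect_equal(m, c(rep(1, 8), 2, rep(1, 6)))  # double het carries 2 paths

  m_a <- expected_cell_means(c(base, alpha = log(3)))
  expect_equal(unname(m_a[9]), 4)              # exp(a) + 1 = 4
  expect_equal(unname(m_a[c(3, 6, 11)]), rep(3, 3))
  expect_equal(unname(m_a[c(5, 7, 13)]), rep(1, 3))

  m_b <- expected_cell_means(c(base, beta = log(2)))
  expect_equal(unname(m_b[c(1, 2, 3, 6)]), rep(2, 4))  # M = 2 cells
  expect_equal(unname(m_b[9]), 2)                      # M = 1, unaffected by beta
})

test_that("log_likelihood follows the Poisson convention", {
  params <- list(mu = rep(0, 6), c1 = 0, c2 = 0)
  zero <- cell_table(integer(15))
  # all counts 0: 0 - sum(m) with sum(m) = 16 (double het counts twice)
  expect_equal(log_likelihood(zero, params), -16)
  # zero mean with positive count returns -Inf, not an error
  p0 <- list(mu = c(-Inf, rep(0, 5)), c1 = 0, c2 = 0)
  ct <- cell_table(c(1L, integer(14)))
  expect_equal(log_likelihood(ct, p0), -Inf)
  expect_error(expected_cell_means(list(mu = rep(NaN, 6), c1 = 0, c2 = 0)),
               "non-finite")
})

test_that("fitted means satisfy the score equations per mating type", {
  ct <- cell_table(rep(4L, 15))
  f <- fit_poo(ct)
  cl <- triad_cells()
  for (s in 1:6) {
    expect_equal(sum(f$fitted_means[cl$stratum == s]),
                 sum(ct$counts[cl$stratum == s]), tolerance = 1e-8)
  }
  expect_equal(sum(f$fitted_means), sum(ct$counts), tolerance = 1e-8)
})

test_that("perfect transmission symmetry gives alpha-hat = 0", {
  ct <- cell_table(replace(integer(15), c(11, 13), 6L))
  f <- fit_poo(ct, model_spec(maternal = FALSE))
  expect_equal(unname(f$coefficients["alpha"]), 0, tolerance = 1e-4)
  tt <- lrt_term(ct, "alpha", model_spec(maternal = FALSE))
  expect_identical(tt$lrt_statistic, 0)
  expect_equal(tt$p_value, 1.0)
  expect_equal(tt$odds_ratio, 1.0, tolerance = 1e-4)
})

test_that("a single informative stratum gives the closed-form alpha MLE", {
  # maternal-origin vs paternal-origin counts 9:3 -> alpha = log 3
  ct <- cell_table(replace(integer(15), c(11, 13), c(9L, 3L)))
  f <- fit_poo(ct, model_spec(maternal = FALSE))
  expect_equal(unname(f$coefficients["alpha"]), log(3), tolerance = 1e-3)
})

test_that("terms without informative data are reported inestimable", {
  # no homozygous mothers anywhere -> beta cannot be estimated
  counts <- integer(15)
  counts[c(8, 9, 10, 11, 13, 15)] <- c(3L, 5L, 2L, 4L, 3L, 6L)
  ct <- cell_table(counts)
  f <- fit_poo(ct)
  expect_true("beta" %in% names(f$inestimable_terms))
  tt <- lrt_term(ct, "beta")
  expect_equal(tt$status, "inestimable")
  expect_true(is.na(tt$p_value))
  expect_true(is.na(tt$odds_ratio))

  # all counts in the 0x0 mating type: nothing is estimable
  ct0 <- cell_table(replace(integer(15), 15, 20L))
  f0 <- fit_poo(ct0)
  expect_setequal(names(f0$inestimable_terms), c("alpha", "beta", "gamma"))
})

test_that("model nesting holds: reduced fits never beat the full fit", {
  set.seed(31)
  spec <- model_spec()
  for (i in 1:25) {
    ct <- random_cell_table()
    full <- fit_poo(ct, spec)
    for (trm in c("alpha", "beta", "gamma")) {
      if (trm %in% names(full$inestimable_terms)) next
      red <- fit_poo(ct, spec, drop = trm)
      expect_gte(full$log_likelihood, red$log_likelihood - 1e-8)
      tt <- lrt_term(ct, trm, spec, full = full)
      expect_gte(tt$lrt_statistic, 0)
      expect_true(tt$p_value >= 0 && tt$p_value <= 1)
    }
  }
})

test_that("parent swap negates alpha and preserves the LRT", {
  # swapping M and P permutes the cells; with maternal terms excluded the
  # model is exactly antisymmetric in alpha
  swap_cells <- function(ct) {
    cl <- triad_cells()
    perm <- match(paste(cl$P, cl$M, cl$C), paste(cl$M, cl$P, cl$C))
    cell_table(ct$counts[perm])
  }
  set.seed(17)
  spec <- model_spec(maternal = FALSE)
  for (i in 1:20) {
    ct <- random_cell_table()
    sw <- swap_cells(ct)
    f1 <- fit_poo(ct, spec); f2 <- fit_poo(sw, spec)
    expect_equal(unname(f1$coefficients["alpha"]),
                 -unname(f2$coefficients["alpha"]), tolerance = 1e-5)
    t1 <- lrt_term(ct, "alpha", spec); t2 <- lrt_term(sw, "alpha", spec)
    expect_equal(t1$lrt_statistic, t2$lrt_statistic, tolerance = 1e-6)
    expect_equal(t1$odds_ratio, 1 / t2$odds_ratio, tolerance = 1e-5)
  }
})

test_that("marginal and joint reduced-model conventions both run", {
  set.seed(23)
  ct <- random_cell_table(400)
  tj <- lrt_term(ct, "alpha", model_spec(alternative = "joint"))
  tm <- lrt_term(ct, "alpha", model_spec(alternative = "marginal"))
  expect_equal(tj$status, "ok")
  expect_equal(tm$status, "ok")
  # both are valid chi-square(1) statistics; they need not be equal
  expect_gte(tj$lrt_statistic, 0)
  expect_gte(tm$lrt_statistic, 0)
})

test_that("test_all_terms shares one full fit and reports all three terms", {
  set.seed(29)
  ct <- random_cell_table(300)
  tt <- test_all_terms(ct)
  expect_named(tt[c("alpha", "beta", "gamma")])
  for (trm in c("alpha", "beta", "gamma")) {
    expect_s3_class(tt[[trm]], "term_test")
    expect_equal(tt[[trm]]$df, 1L)
  }
  # the shared fit is the joint full model
  expect_true(all(c("alpha", "beta", "gamma") %in% names(tt$fit$coefficients)))
})

test_that("fit_poo rejects an all-zero table", {
  expect_error(fit_poo(cell_table(integer(15))), "no counts")
})
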