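ct_long <- function(mat) {
  data.frame(sample_id = rep(rownames(mat), ncol(mat)),
             gene = rep(colnames(mat), each = nrow(mat)),
             ct = as.vector(mat), stringsAsFactors = FALSE)
}

test_that("geNorm M ranks a shifted copy as stable and a noisy gene as unstable", {
  # gene C = gene A + constant per-gene shift; gene B fluctuates on its own
  a <- c(20.0, 21.0, 19.5, 20.5)
  b <- a + c(0.0, 1.2, -0.8, 0.9)
  m <- cbind(A = a, B = b, C = a + 3)
  rownames(m) <- paste0("s", 1:4)
  rk <- genorm_stability(m, n_keep = 2)
  expect_equal(rk$m_values[["A"]], rk$m_values[["C"]])
  expect_gt(rk$m_values[["B"]], rk$m_values[["A"]])
  expect_equal(rk$exclusion_order, "B")
  expect_setequal(rk$retained_references, c("A", "C"))
  # hand value: M_A = mean(sd(B - A), sd(C - A)) with sd(C - A) = 0
  expect_equal(rk$m_values[["A"]], mean(c(stats::sd(b - a), 0)))
})

test_that("geNorm M is zero for identical profiles and needs 3 candidates", {
  m <- matrix(rep(c(18, 20, 22, 19), 3), ncol = 3,
              dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  rk <- genorm_stability(m, n_keep = 3)
  expect_true(all(rk$m_values == 0))
  expect_error(genorm_stability(m[, 1:2], n_keep = 2), "at least 3")
})

test_that("geNorm M is invariant to a per-sample constant shift", {
  set.seed(31)
  m <- matrix(rnorm(5 * 4, 20, 1), 5, 4,
              dimnames = list(paste0("s", 1:5), c("A", "B", "C", "D")))
  shifted <- m
  shifted[3, ] <- shifted[3, ] + 2.5  # one sample loaded differently
  expect_equal(genorm_stability(m)$m_values,
               genorm_stability(shifted)$m_values)
})

test_that("relative quantities are calibrated to the least expressed sample", {
  m <- cbind(GALNT14 = c(30, 29, 27, 28), R1 = c(20, 20, 20, 20),
             R2 = c(22, 22, 22, 22))
  rownames(m) <- paste0("s", 1:4)
  prof <- relative_quantity(ct_long(m), "GALNT14", c("R1", "R2"))
  expect_equal(min(prof$relative_quantity[prof$expressed]), 1)
  expect_equal(prof$relative_quantity[1], 1)   # the calibrator itself
  expect_equal(prof$relative_quantity[2], 2)   # one cycle lower = doubling
  # dCt of 7, 5, 4 relative to calibrator dCt 7 -> 1, 4, 8
  m2 <- cbind(GALNT14 = c(27, 25, 24), R1 = c(20, 20, 20))
  rownames(m2) <- paste0("s", 1:3)
  prof2 <- relative_quantity(ct_long(m2), "GALNT14", "R1")
  expect_equal(prof2$relative_quantity, c(1, 4, 8))
})

test_that("undetected targets are not expressed; empty profiles warn", {
  m <- cbind(GALNT14 = c(30, NA, 44), R1 = c(20, 20, 20))
  rownames(m) <- paste0("s", 1:3)
  prof <- relative_quantity(ct_long(m), "GALNT14", "R1", max_ct = 40)
  expect_equal(prof$expressed, c(TRUE, FALSE, FALSE))  # 44 exceeds max Ct
  expect_true(all(is.na(prof$relative_quantity[!prof$expressed])))
  m_none <- cbind(GALNT14 = c(NA_real_, NA_real_), R1 = c(20, 20))
  rownames(m_none) <- c("s1", "s2")
  expect_warning(p0 <- relative_quantity(ct_long(m_none), "GALNT14", "R1"),
                 "no sample expresses")
  expect_equal(sum(p0$expressed), 0)
  # undetected reference is an error, not a silent drop
  m_badref <- cbind(GALNT14 = c(30, 30), R1 = c(NA_real_, 20))
  rownames(m_badref) <- c("s1", "s2")
  expect_error(relative_quantity(ct_long(m_badref), "GALNT14", "R1"),
               "detected in all samples")
})

test_that("positivity percentages reproduce the cohort arithmetic", {
  mk <- function(k, n) data.frame(expressed = rep(c(TRUE, FALSE),
                                                  c(k, n - k)))
  expect_equal(positivity_summary(mk(11, 15))$percent, 73.3)
  expect_equal(positivity_summary(mk(18, 76))$percent, 23.7)
  expect_equal(positivity_summary(mk(0, 5))$percent, 0)
})

test_that("Fisher exact p equals full hypergeometric enumeration", {
  t1 <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(t1)$p_value, 34 / 70)
  expect_equal(fisher_exact_2x2(t1)$p_value, fisher_oracle(t1))
  t2 <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(t2)$p_value, 2 / 252)
  t3 <- matrix(c(2, 2, 2, 2), 2)
  expect_equal(fisher_exact_2x2(t3)$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  set.seed(7)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    if (sum(tab) > 40) next
    expect_equal(fisher_exact_2x2(tab)$p_value, fisher_oracle(tab),
                 tolerance = 1e-10, info = paste(tab, collapse = ","))
  }
})

test_that("Mann-Whitney U is exact for small samples and matches enumeration", {
  res <- rank_and_location_tests(c(1, 2, 3), c(4, 5, 6))
  mw <- res[res$test_name == "mann_whitney", ]
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)  # 2/20 arrangements as extreme
  expect_equal(mw$p_value, mw_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(rank_and_location_tests(c(1, 1, 1), c(2, 2, 2))$statistic[1], 0)
})

test_that("the normal approximation tracks exact enumeration for n 8 to 12", {
  set.seed(11)
  for (i in 1:8) {
    n1 <- sample(4:6, 1); n2 <- sample(4:6, 1)
    x <- round(rnorm(n1, 5, 2), 1); y <- round(rnorm(n2, 6, 2), 1)
    approx_p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(approx_p - mw_oracle(x, y)), 0.05)
  }
})

test_that("Welch t handles constant groups without blowing up", {
  res <- rank_and_location_tests(c(2, 2, 2), c(2, 2, 2))
  tt <- res[res$test_name == "welch_t", ]
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  res2 <- rank_and_location_tests(c(1, 1, 1), c(2, 2, 2))
  tt2 <- res2[res2$test_name == "welch_t", ]
  expect_equal(tt2$p_value, 0)
})

test_that("MYCN association contrasts amplified vs single copy", {
  set.seed(5)
  expressed <- c(rep(TRUE, 10), rep(FALSE, 5),
                 rep(TRUE, 5), rep(FALSE, 10))
  prof <- data.frame(
    sample_id = sprintf("s%02d", 1:30),
    relative_quantity = ifelse(expressed, 2^rnorm(30, 2), NA),
    expressed = expressed,
    mycn_status = c(rep("amplified", 10), rep("gain", 5),
                    rep("single_copy", 15)),
    stringsAsFactors = FALSE)
  res <- mycn_association(prof)
  expect_setequal(res$test_name, c("fisher_exact", "mann_whitney", "welch_t"))
  fisher_row <- res[res$test_name == "fisher_exact", ]
  expect_equal(fisher_row$n1, 10)  # amplified row of the 2x2
  expect_equal(fisher_row$n2, 15)  # single copy; gain samples not tested
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})
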