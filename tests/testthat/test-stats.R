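test_that("Mann-Whitney U reproduces textbook cases", {
  # complete separation: U = 0, exact two-tailed p = 2 / choose(6, 3) = 0.1
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$method, "exact")
  expect_identical(unname(r$statistic), 0)
  expect_equal(r$p_two_tailed, 0.1, tolerance = 1e-12)
  # perfectly interleaved symmetric data: p = 1 under the exact method
  r2 <- mann_whitney_u(c(1, 4), c(2, 3), method = "exact")
  expect_equal(r2$p_two_tailed, 1)
  # identical samples (fully tied): midranks, p = 1 under the approximation
  r3 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_identical(r3$method, "normal_approx")
  expect_true(r3$tie_correction_applied)
  expect_equal(r3$p_two_tailed, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
  expect_error(mann_whitney_u(c(1, 1, 2), c(2, 3), method = "exact"),
               "tie-free")
})

test_that("U statistic symmetry and range invariants hold", {
  set.seed(10)
  for (i in 1:25) {
    n1 <- sample(2:9, 1); n2 <- sample(2:9, 1)
    a <- rnorm(n1); b <- rnorm(n2)
    r_ab <- mann_whitney_u(a, b)
    r_ba <- mann_whitney_u(b, a)
    expect_equal(r_ab$p_two_tailed, r_ba$p_two_tailed, tolerance = 1e-12)
    expect_equal(unname(r_ab$statistic + r_ba$statistic), n1 * n2)
    expect_gte(r_ab$statistic, 0)
    expect_lte(r_ab$statistic, n1 * n2)
    expect_lte(r_ab$p_two_tailed, 1)
  }
})

test_that("exact p agrees with full enumeration of labelings", {
  set.seed(31)
  for (i in 1:30) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    repeat {
      a <- round(rnorm(n1), 6); b <- round(rnorm(n2), 6)
      if (!anyDuplicated(c(a, b))) break
    }
    ours <- mann_whitney_u(a, b, method = "exact")
    oracle <- mwu_enumerate(a, b)
    expect_equal(unname(ours$statistic), oracle$u)
    expect_equal(ours$p_two_tailed, oracle$p, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis H matches the direct rank formula", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- kruskal_wallis(g)
  expect_equal(unname(r$statistic), kw_direct(g), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    g <- lapply(sample(2:8, 3, replace = TRUE), function(n)
      sample(1:10, n, replace = TRUE))  # ties included
    expect_equal(unname(kruskal_wallis(g)$statistic), kw_direct(g),
                 tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("degenerate all-tied data return H = 0, p = 1 with a warning", {
  expect_warning(r <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2))),
                 "identical")
  expect_identical(r$statistic, 0)
  expect_identical(r$p_two_tailed, 1)
})

test_that("two-group K-W equals squared MWU z without continuity correction", {
  set.seed(12)
  for (i in 1:15) {
    a <- rnorm(sample(4:12, 1)); b <- rnorm(sample(4:12, 1))
    p_kw <- kruskal_wallis(list(a, b))$p_two_tailed
    p_mwu <- mann_whitney_u(a, b, method = "normal_approx",
                            continuity = FALSE)$p_two_tailed
    expect_equal(p_kw, p_mwu, tolerance = 1e-6)
  }
})

test_that("p-values are invariant under strictly monotone transforms", {
  set.seed(77)
  a <- rnorm(9); b <- rnorm(7); c_ <- rnorm(8)
  for (f in list(function(x) exp(x), function(x) x^3, function(x) -1 / (x + 10))) {
    expect_equal(mann_whitney_u(a, b)$p_two_tailed,
                 mann_whitney_u(f(a), f(b))$p_two_tailed, tolerance = 1e-12)
    expect_equal(kruskal_wallis(list(a, b, c_))$p_two_tailed,
                 kruskal_wallis(list(f(a), f(b), f(c_)))$p_two_tailed,
                 tolerance = 1e-12)
  }
})

test_that("comparison report lays out omnibus, post hoc and myometrium tests", {
  des <- flat_design(6, c("control_endometrium", "eutopic_endometrium",
                          "ectopic_endometrium", "myometrium"))
  out <- simulate_outcome_table(des, seed = 2)
  rep <- suppressWarnings(compare_tissues(out, outcome_cols = "bvd_per_mm2"))
  t <- rep$tests[rep$tests$stratum == "proliferative", ]
  expect_setequal(t$comparison,
                  c("endometrium_omnibus", "control_vs_eutopic",
                    "control_vs_ectopic", "eutopic_vs_ectopic",
                    "adenomyosis_vs_control_myometrium"))
  expect_identical(t$test[t$comparison == "endometrium_omnibus"],
                   "kruskal_wallis")
  expect_true(all(t$significant == (t$p < rep$alpha)))
  s <- rep$summaries
  expect_true(all(c("n", "median", "min", "max") %in% names(s)))
  expect_identical(unique(s$n[s$stratum == "proliferative" &
                              !grepl("myometrium", s$group)]), 6)
})

test_that("single-specimen groups yield medians and p = 1", {
  des <- flat_design(1, c("control_endometrium", "ectopic_endometrium"))
  out <- simulate_outcome_table(des, seed = 3)
  rep <- suppressWarnings(compare_tissues(out, outcome_cols = "bvd_per_mm2"))
  pw <- rep$tests[rep$tests$comparison == "control_vs_ectopic", ]
  expect_identical(nrow(pw), 1L)
  expect_equal(pw$p, 1)          # n = 1 vs 1 carries no evidence
  expect_false(pw$significant)
})

test_that("strata without two nonempty groups warn and omit tests", {
  des <- flat_design(4, "control_endometrium")
  out <- simulate_outcome_table(des, seed = 4)
  expect_warning(rep <- compare_tissues(out, outcome_cols = "bvd_per_mm2"),
                 "tests omitted")
  expect_null(rep$tests)
})

test_that("Holm adjustment never decreases pairwise p-values", {
  des <- flat_design(8, c("control_endometrium", "eutopic_endometrium",
                          "ectopic_endometrium"),
                     bvd = c(control_endometrium = 20,
                             eutopic_endometrium = 35,
                             ectopic_endometrium = 60))
  out <- simulate_outcome_table(des, seed = 5)
  raw <- suppressWarnings(compare_tissues(out, outcome_cols = "bvd_per_mm2"))
  adj <- suppressWarnings(compare_tissues(out, outcome_cols = "bvd_per_mm2",
                                          adjust = "holm"))
  pair <- raw$tests$comparison != "endometrium_omnibus"
  expect_true(all(adj$tests$p[pair] >= raw$tests$p[pair]))
})

test_that("medication subgroup compares eutopic BVD/LVD pooled over phases", {
  des <- flat_design(10, "eutopic_endometrium")
  des$medication[1:4] <- "antiangiogenic"
  out <- simulate_outcome_table(des, seed = 6)
  rep <- medication_subgroup(out)
  expect_identical(nrow(rep$tests), 2L)
  expect_setequal(rep$tests$outcome, c("bvd_per_mm2", "lvd_per_mm2"))
  expect_identical(rep$summaries$n[rep$summaries$group == "antiangiogenic"],
                   rep(4, 2))
  # all specimens in one subgroup: warning path, tests omitted
  des$medication <- "none_other"
  out2 <- simulate_outcome_table(des, seed = 7)
  w <- capture_warnings(rep2 <- medication_subgroup(out2))
  expect_length(w, 2)                       # one warning per omitted outcome
  expect_match(w, "empty subgroup", all = TRUE)
  expect_null(rep2$tests)
})
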