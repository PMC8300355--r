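# one-gene-per-row count matrix helper with explicit library totals
tiny_cm <- function(counts, conditions, totals) {
  pools <- paste0("P", seq_along(conditions))
  m <- matrix(counts, ncol = length(conditions),
              dimnames = list(sprintf("g%03d", seq_len(length(counts) / length(conditions))),
                              pools))
  count_matrix(m, data.frame(pool = pools, condition = conditions),
               totals = setNames(totals, pools))
}

test_that("condition aggregation sums pool counts and library totals", {
  cm <- tiny_cm(c(3, 7, 4), c("c1", "c1", "c2"), c(100, 200, 150))
  agg <- aggregate_condition(cm, c("c1", "c2"))
  expect_equal(unname(agg$x1), 10)
  expect_equal(agg$N1, 300)
  expect_equal(agg$q1, 2L)
  # single pool per condition: aggregate equals the pool itself
  expect_equal(unname(agg$x2), 4)
  expect_equal(agg$N2, 150)
  expect_error(aggregate_condition(cm, c("c1", "c9")),
               "unknown condition.*c9.*available")
})

test_that("pooled z matches hand-derived values and is exactly antisymmetric", {
  # equal proportions give Z = 0 under both variants
  expect_equal(pooled_z(10, 1000, 20, 2000, "sqrt"), 0)
  expect_equal(pooled_z(10, 1000, 20, 2000, "raw"), 0)
  # frozen arithmetic: (0.1 - sqrt(0.005)) / sqrt(5e-5)
  expect_equal(pooled_z(100, 10000, 50, 10000),
               (sqrt(0.01) - sqrt(0.005)) / sqrt(1 / 40000 + 1 / 40000))
  expect_equal(pooled_z(100, 10000, 50, 10000), 4.142136, tolerance = 1e-6)
  # zero counts stay finite
  expect_true(is.finite(pooled_z(0, 1000, 0, 2000)))

  withr::with_seed(99, {
    for (i in 1:50) {
      N1 <- sample(1e3:1e6, 1); N2 <- sample(1e3:1e6, 1)
      x1 <- rbinom(1, N1, 0.01); x2 <- rbinom(1, N2, 0.01)
      for (v in c("sqrt", "raw")) {
        expect_identical(pooled_z(x1, N1, x2, N2, v),
                         -pooled_z(x2, N2, x1, N1, v))
      }
    }
  })
  expect_error(pooled_z(5, 0, 1, 10), "N must be > 0")
  expect_error(pooled_z(11, 10, 1, 10), "0 <= x <= N")
})

test_that("raw variant is strictly more conservative below proportion 1/4", {
  withr::with_seed(7, {
    for (i in 1:200) {
      N1 <- sample(100:1e5, 1); N2 <- sample(100:1e5, 1)
      x1 <- sample.int(floor(N1 / 4) - 1, 1)
      x2 <- sample.int(floor(N2 / 4) - 1, 1)
      if (x1 / N1 == x2 / N2) next
      expect_lt(abs(pooled_z(x1, N1, x2, N2, "raw")),
                abs(pooled_z(x1, N1, x2, N2, "sqrt")))
    }
  })
})

test_that("|Z| is monotone in the proportion gap at fixed N", {
  N <- 50000
  x2 <- 500
  gaps <- seq(0, 2000, by = 100)
  for (v in c("sqrt", "raw")) {
    zs <- abs(pooled_z(x2 + gaps, N, x2, N, v))
    expect_true(all(diff(zs) >= 0))
  }
})

test_that("two-sided p follows the split normal-CDF rule", {
  expect_equal(two_sided_p(0), 1)
  expect_equal(two_sided_p(1.959964), 0.05, tolerance = 1e-4)
  zs <- c(0.1, 0.5, 1, 2.5, 6, 37)
  expect_identical(two_sided_p(zs), two_sided_p(-zs))
  expect_true(all(two_sided_p(c(-40, 0, 40, 400)) > 0))
  expect_true(all(two_sided_p(seq(-8, 8, 0.5)) <= 1))
  expect_error(two_sided_p(NaN), "finite")
  expect_error(two_sided_p(Inf), "finite")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.001, 100), 0.1)
  expect_equal(bonferroni(0.05, 100), 1)
  expect_equal(bonferroni(0.37, 1), 0.37)
  expect_error(bonferroni(0.05, 0), "n_tests")
  expect_error(bonferroni(0, 10), "p_raw")
})

test_that("fold change reports ratio >= 1 with direction relative to condition 1", {
  # r1 = 2 r2 (pseudocount 0): up, fold 2
  fc <- fold_change(200, 1000, 100, 1000, pseudocount = 0)
  expect_equal(fc$fold, 2); expect_equal(fc$direction, "up")
  fc <- fold_change(100, 1000, 100, 1000, pseudocount = 0)
  expect_equal(fc$fold, 1); expect_equal(fc$direction, "none")
  # pseudocount keeps zero counts finite: (0+0.5) vs (49+0.5) -> fold 99
  fc <- fold_change(0, 1e6, 49, 1e6, pseudocount = 0.5)
  expect_equal(fc$fold, 99); expect_equal(fc$direction, "down")
  # both-zero with no pseudocount is untestable, not NaN
  fc <- fold_change(0, 1000, 0, 1000, pseudocount = 0)
  expect_true(is.na(fc$fold)); expect_equal(fc$direction, "untestable")
  expect_error(fold_change(1, 10, 1, 10, pseudocount = -1), "pseudocount")
})

test_that("run_de filters, corrects over tested genes only, and sorts stably", {
  cm <- tiny_cm(rep(c(500, 100, 2, 500, 800, 3), times = 1),
                c("c1", "c2"),
                c(1e5, 1e5))
  # three genes; gene 3 has x1 + x2 = 5 < 10 and must not be tested
  res <- run_de(cm, c("c1", "c2"))
  expect_equal(attr(res, "n_tested"), 2L)
  expect_equal(nrow(res), 2L)
  expect_false("g003" %in% res$gene)
  expect_equal(res$p_bonf, pmin(1, 2 * res$p_raw))
  expect_false(is.unsorted(res$p_raw))
  # corrected flags are a subset of raw flags at the same cutoff
  expect_true(all(res$gene[res$p_bonf < 0.05] %in% res$gene[res$p_raw < 0.05]))

  # min_total_count filter can empty the table: structured empty result
  cm0 <- tiny_cm(c(1, 1), c("c1", "c2"), c(1e5, 1e5))
  res0 <- run_de(cm0, c("c1", "c2"))
  expect_equal(nrow(res0), 0L)
  expect_equal(attr(res0, "status"), "no_testable_genes")
})

test_that("identical pools yield a perfectly null comparison", {
  m <- matrix(rep(c(100L, 250L, 40L), 2), ncol = 2,
              dimnames = list(c("gA", "gB", "gC"), c("P1", "P2")))
  cm <- count_matrix(m, data.frame(pool = c("P1", "P2"),
                                   condition = c("c1", "c2")))
  res <- run_de(cm, c("c1", "c2"))
  expect_true(all(res$Z == 0))
  expect_true(all(res$p_raw == 1))
  expect_true(all(res$fold == 1))
  expect_false(any(res$flag_p05))
  expect_false(any(res$flag_subset))
})

test_that("exchanging condition labels negates Z and inverts directions", {
  d <- design_spec()
  cfg <- count_sim_config(n_genes = 120, dispersion = 0.05, de_fraction = 0.05,
                          library_depth = 1e5)
  ac <- simulate_animal_counts(cfg, d, seed = 61)
  cm <- form_pool_libraries(ac, assign_pools(d, seed = 62))
  a <- run_de(cm, c("Choice", "Standard"))
  b <- run_de(cm, c("Standard", "Choice"))
  b <- b[match(a$gene, b$gene), ]
  expect_equal(b$Z, -a$Z)
  expect_equal(b$p_raw, a$p_raw)
  expect_equal(b$fold, a$fold)
  flip <- c(up = "down", down = "up", none = "none", untestable = "untestable")
  expect_equal(b$direction, unname(flip[a$direction]))
  expect_equal(b$flag_subset, a$flag_subset)
})

test_that("null p-values are uniform to KS tolerance under Poisson sampling", {
  d <- design_spec(grades = c("c1", "c2"),
                   animals_per_grade = c(c1 = 1, c2 = 1), pools_per_grade = 1)
  cfg <- count_sim_config(n_genes = 10000, baseline_mean = 100, dispersion = 0,
                          de_fraction = 0, effect_folds = c(c1 = 1, c2 = 1),
                          library_depth = 1e6)
  ac <- simulate_animal_counts(cfg, d, seed = 71)
  cm <- form_pool_libraries(ac, assign_pools(d, seed = 72))
  res <- run_de(cm, c("c1", "c2"),
                de_thresholds(min_total_count = 1))
  grid <- seq(0.01, 0.99, by = 0.01)
  ks <- max(abs(vapply(grid, function(q) mean(res$p_raw <= q), 0) - grid))
  expect_lt(ks, 0.02)
})
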