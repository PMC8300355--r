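test_that("calibration recovers the additive decomposition of the printed margins", {
  m <- calibrate_phenotype_model()

  # grand mean is the unweighted mean of the five aging-day shear means
  expect_equal(m$grand_mean, mean(c(89.9, 80.7, 71.0, 65.3, 62.9)))
  expect_equal(m$grand_mean, 73.96)
  # aging effects are exact deviations and sum to zero
  expect_equal(unname(m$aging_effects[["1"]]), 89.9 - 73.96)
  expect_lt(abs(sum(m$aging_effects)), 1e-9)
  # the grade margin shares the same grand mean to within 0.1 N, so grade
  # effects sum to (near) zero rather than exactly zero
  expect_lt(abs(mean(c(66.3, 84.3, 71.3)) - m$grand_mean), 0.1)
  expect_lt(abs(sum(m$grade_effects)), 3 * 0.1)
  expect_equal(unname(m$grade_effects[["Select"]]), 84.3 - 73.96)

  # symmetric toy margins decompose exactly
  toy <- calibrate_phenotype_model(toy_calibration())
  expect_equal(toy$grand_mean, 20)
  expect_equal(unname(toy$aging_effects), c(-10, 0, 10))
  expect_equal(unname(toy$grade_effects), c(-5, 0, 5))
})

test_that("calibration errors name missing levels and inconsistent margins", {
  cal <- toy_calibration()
  cal$shear$aging_means[["2"]] <- NULL
  expect_error(calibrate_phenotype_model(cal), "day: 2")

  cal <- toy_calibration()
  cal$shear$grade_means$B <- NULL
  expect_error(calibrate_phenotype_model(cal), "grade: B")

  cal <- toy_calibration()
  cal$shear$grade_means$B <- 40  # margin grand means now disagree by > 0.1
  expect_error(calibrate_phenotype_model(cal), "disagree")
})

test_that("zero-noise phenotype simulation reproduces the additive model exactly", {
  m <- calibrate_phenotype_model(toy_calibration())
  m$residual_sd[] <- 0
  d <- design_spec(grades = c("A", "B", "C"),
                   animals_per_grade = c(A = 2, B = 2, C = 2))
  ph <- simulate_phenotypes(m, d, seed = 5)
  expected <- m$grand_mean + m$grade_effects[as.character(ph$shear$grade)] +
    m$aging_effects[as.character(ph$shear$aging_day)]
  expect_equal(ph$shear$shear_n, unname(expected))
})

test_that("phenotype simulation is deterministic under the seed and truncates at floors", {
  m <- calibrate_phenotype_model()
  d <- design_spec()
  a <- simulate_phenotypes(m, d, n_steaks_per_cell = 2, seed = 11)
  b <- simulate_phenotypes(m, d, n_steaks_per_cell = 2, seed = 11)
  expect_identical(a, b)
  c <- simulate_phenotypes(m, d, n_steaks_per_cell = 2, seed = 12)
  expect_false(identical(a$shear$shear_n, c$shear$shear_n))
  expect_error(simulate_phenotypes(m, d, n_steaks_per_cell = 0, seed = 1),
               "positive")

  # marbling floored at 100 (below-"Traces" scale bottom), physical traits at 0
  m2 <- m
  m2$trait_params <- lapply(m2$trait_params, function(p) {
    p$mean[] <- 0.1; p$sd[] <- 5; p
  })
  ph <- simulate_phenotypes(m2, d, seed = 3)
  expect_true(all(ph$carcass$marbling >= 100))
  expect_true(all(ph$carcass$rea_cm2 >= 0))
  expect_true(any(ph$carcass$rea_cm2 == 0))  # truncation actually bites
})

test_that("large-sample simulated shear recovers the published Standard mean", {
  m <- calibrate_phenotype_model()
  d <- design_spec(grades = m$grades,
                   animals_per_grade = c(Standard = 20000, Select = 2, Choice = 2))
  ph <- simulate_phenotypes(m, d, seed = 7)
  std <- ph$shear$shear_n[ph$shear$grade == "Standard"]
  mc_se <- m$residual_sd[["Standard"]] / sqrt(length(std))
  expect_lt(abs(mean(std) - 66.3), 3 * mc_se + abs(sum(m$grade_effects)) / 3)
})

test_that("pool assignment is a balanced random partition for every seed", {
  d <- study_design()
  pa <- assign_pools(d, seed = 1)
  sizes <- lapply(split(vapply(pa, function(p) length(p$animal_ids), 0L),
                        vapply(pa, `[[`, "", "grade")),
                  function(x) sort(unname(x)))
  expect_equal(sizes$Choice, c(3L, 3L))
  expect_equal(sizes$Select, c(2L, 3L))
  expect_equal(sizes$Standard, c(2L, 3L))

  # partition property over random designs and seeds
  for (s in 1:20) {
    withr::with_seed(s, {
      n_g <- sample(2:4, 1)
      grades <- paste0("G", seq_len(n_g))
      k <- sample(1:3, 1)
      n_animals <- setNames(sample(k:(k + 5), n_g, replace = TRUE), grades)
      d2 <- design_spec(grades, n_animals, pools_per_grade = k)
    })
    pa2 <- assign_pools(d2, seed = s * 13)
    for (g in d2$grades) {
      members <- lapply(pa2[vapply(pa2, `[[`, "", "grade") == g], `[[`, "animal_ids")
      expect_equal(length(members), d2$pools_per_grade)
      expect_setequal(unlist(members),
                      paste(g, seq_len(d2$animals_per_grade[[g]]), sep = "_"))
      expect_equal(anyDuplicated(unlist(members)), 0L)
      expect_lte(diff(range(lengths(members))), 1L)
    }
  }

  # one pool per grade means each pool is the full grade
  pa1 <- assign_pools(design_spec(pools_per_grade = 1), seed = 4)
  expect_equal(length(pa1), 3L)
  expect_equal(sort(pa1$Choice_P1$animal_ids),
               paste("Choice", 1:6, sep = "_"))
  expect_error(design_spec(pools_per_grade = 7), "fewer animals than pools")
})

test_that("count simulation matches its negative-binomial law and records truth", {
  d1 <- design_spec(grades = "G", animals_per_grade = c(G = 1),
                    pools_per_grade = 1)
  cfg <- count_sim_config(n_genes = 10000, baseline_mean = 100, dispersion = 0,
                          de_fraction = 0, effect_folds = c(G = 1),
                          library_depth = 1e6)
  ac <- simulate_animal_counts(cfg, d1, seed = 21)
  # Poisson: variance/mean ratio ~ 1 over 10,000 draws at mean 100
  ratio <- var(as.numeric(ac$counts)) / mean(ac$counts)
  expect_gt(ratio, 0.95); expect_lt(ratio, 1.05)
  expect_identical(ac$spiked, character(0))

  # dispersion > 0 is visibly overdispersed
  cfg_nb <- count_sim_config(n_genes = 10000, baseline_mean = 100,
                             dispersion = 0.1, de_fraction = 0,
                             effect_folds = c(G = 1), library_depth = 1e6)
  nb <- simulate_animal_counts(cfg_nb, d1, seed = 22)
  expect_gt(var(as.numeric(nb$counts)) / mean(nb$counts), 5)

  # fold-2 spike doubles the spiked/unspiked mean ratio within the grade
  d2 <- design_spec(grades = c("R", "T"), animals_per_grade = c(R = 30, T = 30),
                    pools_per_grade = 1)
  cfg2 <- count_sim_config(n_genes = 100, baseline_mean = 200, dispersion = 0,
                           de_fraction = 0.1, effect_folds = c(R = 1, T = 2),
                           library_depth = 2e4)
  ac2 <- simulate_animal_counts(cfg2, d2, seed = 23)
  t_cols <- ac2$animals$animal_id[ac2$animals$grade == "T"]
  spiked <- rownames(ac2$counts) %in% ac2$spiked
  ratio2 <- mean(ac2$counts[spiked, t_cols]) / mean(ac2$counts[!spiked, t_cols])
  expect_equal(ratio2, 2, tolerance = 0.05)
  expect_length(ac2$spiked, 10L)

  expect_error(count_sim_config(de_fraction = 1), "de_fraction")
  expect_error(count_sim_config(n_genes = 10, de_fraction = 0.15),
               "whole number")
  expect_identical(simulate_animal_counts(cfg2, d2, seed = 23), ac2)
})

test_that("pooled libraries conserve counts and downsample multinomially", {
  d <- study_design()
  cfg <- count_sim_config(n_genes = 50, baseline_mean = 100, dispersion = 0.05,
                          de_fraction = 0, library_depth = 5e3)
  ac <- simulate_animal_counts(cfg, d, seed = 31)
  pa <- assign_pools(d, seed = 32)
  cm <- form_pool_libraries(ac, pa)

  # conservation: pool sums equal the summed member libraries, per gene
  for (p in names(pa)) {
    expect_equal(cm$counts[, p],
                 rowSums(ac$counts[, pa[[p]]$animal_ids, drop = FALSE]))
  }
  grade_of <- vapply(pa, `[[`, "", "grade")
  for (g in d$grades) {
    expect_equal(unname(rowSums(cm$counts[, grade_of == g, drop = FALSE])),
                 unname(rowSums(ac$counts[, ac$animals$grade == g, drop = FALSE])))
  }

  # identity downsample: target equal to each total would need a common
  # total, so check on the smallest and verify totals hit the target exactly
  tgt <- min(colSums(cm$counts))
  dn <- form_pool_libraries(ac, pa, target_depth = tgt, seed = 33)
  expect_true(all(colSums(dn$counts) == tgt))
  expect_error(form_pool_libraries(ac, pa, target_depth = 1e9, seed = 1),
               "exceeds")

  # multinomial expectation: a gene at proportion w keeps expected count
  # w * target over repeated downsampling seeds
  pool1 <- cm$counts[, 1]
  w <- pool1[5] / sum(pool1)
  half <- round(sum(pool1) / 2)
  draws <- vapply(1:400, function(s) {
    form_pool_libraries(ac, pa, target_depth = half, seed = s)$counts[5, 1]
  }, 0)
  se <- sqrt(half * w * (1 - w) / 400)
  expect_lt(abs(mean(draws) - w * half), 3 * se)
})
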