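test_that("top-k overlap handles identical, reversed and random rankings", {
  v <- rnorm(50)
  expect_identical(top_k_overlap(v, v, k = 25), 25L)
  expect_identical(top_k_overlap(v, -v, k = 25), 0L)
  expect_error(top_k_overlap(v, v[-1]), "equal length")
  expect_error(top_k_overlap(v, v, k = 51), "exceeds")
  # ties at rank k break by stable position order
  expect_identical(top_k_overlap(rep(1, 4), c(4, 3, 2, 1), k = 2), 2L)
  # mean overlap of independent rankings follows the hypergeometric k^2/n
  set.seed(1)
  ov <- replicate(600, top_k_overlap(rnorm(100), rnorm(100), k = 25))
  expect_lt(abs(mean(ov) - 6.25), 3 * sd(ov) / sqrt(600))
})

test_that("confidence half-width follows the t formula on folds x reps", {
  expect_equal(accuracy_ci(rep(0.5, 10), folds = 10, reps = 30)$halfwidth, 0)
  # SD 0.05, n = 300: frozen against an independent t-quantile computation
  set.seed(2)
  acc <- as.numeric(scale(rnorm(40))) * 0.05 + 0.5
  ci <- accuracy_ci(acc, folds = 10, reps = 30)
  expect_equal(ci$halfwidth, 0.005680923620906578, tolerance = 1e-9)
  expect_equal(ci$mean, 0.5, tolerance = 1e-12)
  # large n limit: t quantile tends to 1.96
  ci2 <- accuracy_ci(acc, folds = 100, reps = 1000)
  expect_equal(ci2$halfwidth, 1.959988 * 0.05 / sqrt(1e5), tolerance = 1e-4)
  expect_error(accuracy_ci(0.5, 10, 30), "at least 2")
})

test_that("accuracy is the Pearson correlation of the hand oracle", {
  # pred (1,2,3,4) vs ref (1,2,3,5): r = 6.5 / sqrt(5 * 8.75)
  expect_equal(cor(c(1, 2, 3, 4), c(1, 2, 3, 5)), 6.5 / sqrt(43.75),
               tolerance = 1e-12)
  g <- small_panel(n1 = 12, n2 = 12, m = 50, seed = 51)
  sim <- simulate_trait(g, prob_qtl = 0.3, seed = 52)
  res <- run_cross_population(g, sim$trait$phenotypes,
                              model_variant("Baseline"),
                              "IITA", "NaCRRI",
                              reference = sim$trait$genetic_values)
  expect_equal(res$accuracy,
               cor(res$predictions,
                   sim$trait$genetic_values[res$test_idx]))
  # perfectly predicted clones give accuracy 1
  expect_equal(cor(sim$trait$genetic_values[res$test_idx],
                   sim$trait$genetic_values[res$test_idx]), 1)
})

test_that("identity kernels carry no information across populations", {
  g <- small_panel(n1 = 15, n2 = 15, m = 40, seed = 60)
  sim <- simulate_trait(g, prob_qtl = 0.3, seed = 70)
  n <- n_clones(g)
  eye <- list(A = diag(n), D = diag(n))
  res <- suppressWarnings(
    run_cross_population(g, sim$trait$phenotypes,
                         model_variant("Baseline"), "IITA", "NaCRRI",
                         reference = sim$trait$genetic_values,
                         kernels = eye))
  # with no relatedness, masked clones predict exactly zero (mean only)
  expect_lt(max(abs(res$predictions)), 1e-8)
})

test_that("k-fold replication partitions the population and is deterministic", {
  g <- small_panel(n1 = 14, n2 = 14, m = 40, seed = 53)
  sim <- simulate_trait(g, prob_qtl = 0.3, seed = 54)
  r1 <- run_kfold(g, sim$trait$phenotypes, model_variant("Baseline"),
                  population = "IITA", k = 7, reps = 2, seed = 5,
                  reference = sim$trait$genetic_values, top_k = 5)
  r2 <- run_kfold(g, sim$trait$phenotypes, model_variant("Baseline"),
                  population = "IITA", k = 7, reps = 2, seed = 5,
                  reference = sim$trait$genetic_values, top_k = 5)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 2L)
  expect_true(all(r1$accuracy >= -1 & r1$accuracy <= 1))
  expect_true(all(r1$top_k_overlap %in% 0:5))
  # leave-one-out boundary runs
  r3 <- run_kfold(g, sim$trait$phenotypes, model_variant("Baseline"),
                  population = "IITA", k = 14, reps = 1, seed = 6,
                  reference = sim$trait$genetic_values, top_k = 5)
  expect_identical(nrow(r3), 1L)
  expect_error(run_kfold(g, sim$trait$phenotypes, model_variant("Baseline"),
                         population = "IITA", k = 15, reps = 1),
               "exceeds")
})

test_that("simulation study emits the full scheme x variant x replicate grid", {
  g <- small_panel(n1 = 20, n2 = 20, m = 200, seed = 55)
  st <- run_simulation_study(g, prob_qtl_grid = 0.1, reps = 2, seed = 9,
                             k = 4, top_k = 5)
  expect_s3_class(st, "study_result")
  expect_identical(nrow(st$results), 3L * 4L * 2L)
  expect_setequal(unique(st$results$variant),
                  c("Baseline", "QTL", "WeightedQTL"))
  expect_setequal(unique(st$results$scheme), study_schemes(g))
  expect_true(all(st$results$accuracy >= -1 & st$results$accuracy <= 1))
  # summary means equal the means of the per-replicate rows
  for (i in seq_len(nrow(st$summary))) {
    rows <- st$results$scheme == st$summary$scheme[i] &
      st$results$variant == st$summary$variant[i]
    expect_equal(st$summary$mean_accuracy[i],
                 mean(st$results$accuracy[rows]), tolerance = 1e-12)
  }
  # whole-study reproducibility under the master seed
  st2 <- run_simulation_study(g, prob_qtl_grid = 0.1, reps = 2, seed = 9,
                              k = 4, top_k = 5)
  expect_identical(st$results, st2$results)
})

test_that("an empty marker subset is an error", {
  g <- small_panel(m = 20)
  expect_error(build_variant_kernels <- loadgp:::build_variant_kernels(
    g, model_variant("QTL", sites = integer(0))), "empty marker subset")
})

test_that("empirical-style study wires loads as fixed effects and weights into kernels", {
  g <- small_panel(n1 = 25, n2 = 25, m = 120, seed = 57)
  ann <- simulate_annotations(m = 120, chrom_count = 3,
                              prop_deleterious_like = 0.15, seed = 57,
                              site_id = colnames(g$dosages), chrom = g$chrom,
                              maf = g$freqs)
  flags <- classify_deleterious(ann)
  qtl_idx <- which(flags)
  arch <- qtl_architecture(qtl_idx, rep(1.5, length(qtl_idx)),
                           rep(2, length(qtl_idx)))
  gv <- genetic_value(g, arch)
  tr <- simulate_trials(rownames(g$dosages), gv, n_trials = 2,
                        reps_per_trial = 2, blocks_per_rep = 2,
                        variance_config = list(resid_sd = sd(gv)), seed = 58)
  st <- run_empirical_style_study(
    g, ann, tr, marker_sites = seq(1, 120, by = 3),
    imputed_sites = seq_len(120), nonsyn_sites = seq_len(120),
    weights = rep(1, 120), schemes = c("IITA->NaCRRI", "IITA_CV"),
    k = 5, reps = 2, seed = 59, top_k = 5)
  res <- st$results
  # Nonsyn and Weighted_Nonsyn coincide exactly under unit weights
  a <- res[res$variant == "Nonsyn", c("scheme", "replicate", "accuracy")]
  b <- res[res$variant == "Weighted_Nonsyn", c("scheme", "replicate", "accuracy")]
  expect_identical(a$accuracy, b$accuracy)
  a2 <- res[res$variant == "Nonsyn+Load", "accuracy"]
  b2 <- res[res$variant == "Weighted_Nonsyn+Load", "accuracy"]
  expect_identical(a2, b2)
  # the +Load variants differ from their bases only by the two fixed columns
  v_plain <- model_variant("Nonsyn", sites = seq_len(120))
  burden <- compute_burden(g, flags)
  load <- as.matrix(burden[c("hom_load", "het_load")])
  v_load <- model_variant("Nonsyn+Load", sites = seq_len(120), load = load)
  expect_null(v_plain$load)
  expect_identical(colnames(v_load$load), c("hom_load", "het_load"))
  expect_identical(v_plain$sites, v_load$sites)
  # every scheme/variant cell is present
  expect_identical(nrow(res), 6L * (1L + 2L))
})

test_that("knowing recessive deleterious QTL helps cross-population prediction", {
  g <- simulate_population_pair(n1 = 40, n2 = 40, m = 400, seed = 61)
  ann <- simulate_annotations(m = 400, chrom_count = 4,
                              prop_deleterious_like = 0.08, seed = 61,
                              site_id = colnames(g$dosages), chrom = g$chrom,
                              maf = g$freqs)
  flags <- classify_deleterious(ann)
  qtl_idx <- which(flags)
  diffs <- sapply(1:10, function(r) {
    a <- sample_effects(length(qtl_idx), seed = 600 + r)
    d <- sample_dominance(length(qtl_idx), seed = 700 + r)
    arch <- qtl_architecture(qtl_idx, a, d)
    trait <- add_residuals(genetic_value(g, arch), target_h2 = 0.4,
                           seed = 800 + r)
    truth <- trait$genetic_values
    base <- run_cross_population(g, trait$phenotypes,
                                 model_variant("Baseline"), "IITA", "NaCRRI",
                                 reference = truth)$accuracy
    qtl <- run_cross_population(g, trait$phenotypes,
                                model_variant("QTL", sites = qtl_idx),
                                "IITA", "NaCRRI", reference = truth)$accuracy
    qtl - base
  })
  expect_gt(mean(diffs), 0)
})
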