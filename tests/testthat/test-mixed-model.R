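test_that("a constant response drives variance components to the floor", {
  y <- rep(3.7, 12)
  Z <- model.matrix(~ 0 + factor(rep(1:4, each = 3)))
  fit <- fit_reml(y, random = list(g = list(Z = Z, K = NULL)))
  expect_equal(unname(fit$beta[1]), 3.7, tolerance = 1e-8)
  expect_lt(fit$varcomp["g"], 1e-6)
  expect_lt(fit$varcomp["residual"], 1e-6)
})

test_that("balanced one-way REML equals the ANOVA closed forms", {
  set.seed(42)
  gN <- 12; r <- 5
  eff <- rnorm(gN, 0, 1.5)
  grp <- factor(rep(seq_len(gN), each = r))
  y <- eff[grp] + rnorm(gN * r, 0, 0.8)
  Z <- model.matrix(~ 0 + grp)
  fit <- fit_reml(y, random = list(g = list(Z = Z, K = NULL)))
  aov_tab <- anova(lm(y ~ grp))
  msb <- aov_tab$`Mean Sq`[1]; msw <- aov_tab$`Mean Sq`[2]
  expect_equal(unname(fit$varcomp["g"]), (msb - msw) / r, tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["residual"]), msw, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("fixed variance components reproduce the BLUP shrinkage closed form", {
  set.seed(7)
  y <- rnorm(30, 5, 2)
  s2g <- 3; s2e <- 1.5
  fit <- fit_reml(y, random = list(g = list(Z = NULL, K = NULL)),
                  fix_varcomp = c(g = s2g, residual = s2e))
  expect_equal(unname(fit$beta[1]), mean(y), tolerance = 1e-8)
  expect_equal(unname(fit$u$g), s2g / (s2g + s2e) * (y - mean(y)),
               tolerance = 1e-7)
})

test_that("solution satisfies the mixed-model equations at the optimum", {
  g <- small_panel(n1 = 8, n2 = 8, m = 30, seed = 31)
  GA <- additive_grm(g)$values + diag(1e-6, 16)
  set.seed(8)
  y <- rnorm(16)
  fit <- fit_reml(y, random = list(a = list(Z = NULL, K = GA)),
                  bend_kernels = FALSE)
  s2 <- fit$varcomp
  mme <- mme_solve(y, matrix(1, 16, 1), list(diag(16)),
                   list(GA + diag(1e-8, 16)), s2["a"], s2["residual"])
  expect_equal(unname(fit$beta[1]), unname(mme$beta), tolerance = 1e-8)
  expect_equal(unname(fit$u$a), unname(mme$u), tolerance = 1e-8)
})

test_that("masked predictions equal joint MME BLUPs at shared variance components", {
  g <- small_panel(n1 = 10, n2 = 10, m = 40, seed = 32)
  n <- 16
  keep <- seq_len(n)
  GA <- additive_grm(g)$values[keep, keep] + diag(1e-6, n)
  set.seed(9)
  y <- as.numeric(chol(GA) %*% rnorm(n)) + rnorm(n, 0, 0.5)
  masked <- c(3L, 11L, 16L)
  obs <- setdiff(seq_len(n), masked)
  s2g <- 1.2; s2e <- 0.4
  pm <- predict_masked(y, random = list(a = list(Z = NULL, K = GA)),
                       masked = masked,
                       fix_varcomp = c(a = s2g, residual = s2e),
                       bend_kernels = FALSE)
  # oracle: Henderson equations on observed records, all levels in Z columns
  Zobs <- diag(n)[obs, , drop = FALSE]
  mme <- mme_solve(y[obs], matrix(1, length(obs), 1), list(Zobs),
                   list(GA + diag(1e-8, n)), s2g, s2e)
  expect_equal(unname(pm$pred), unname(mme$u[masked]), tolerance = 1e-6)
})

test_that("an identity kernel carries no information to masked units", {
  y <- c(rnorm(10), 0)
  pm <- predict_masked(y, random = list(g = list(Z = NULL, K = diag(11))),
                       masked = 11)
  expect_equal(unname(pm$pred), 0, tolerance = 1e-10)
})

test_that("a duplicated high-heritability clone predicts near its twin's BLUP", {
  n <- 12
  K <- diag(n)
  K[1, n] <- K[n, 1] <- 0.9999
  set.seed(10)
  y <- rnorm(n)
  pm <- predict_masked(y, random = list(g = list(Z = NULL, K = K)),
                       masked = n, fix_varcomp = c(g = 50, residual = 0.01))
  fit_obs <- pm$fit
  expect_equal(unname(pm$pred), unname(fit_obs$u$g[1]), tolerance = 1e-2)
})

test_that("aliased fixed-effect columns are dropped with a warning", {
  y <- rnorm(10)
  X <- cbind(1, rep(1:2, 5), rep(1:2, 5))
  colnames(X) <- c("i", "a", "b")
  expect_warning(fit <- fit_reml(y, X), "aliased")
  expect_true(is.na(fit$beta["b"]))
  expect_false(anyNA(fit$beta[c("i", "a")]))
})

test_that("two-kernel REML recovers simulated variance components", {
  g <- simulate_population_pair(n1 = 100, n2 = 100, m = 600, seed = 33)
  GA <- additive_grm(g)$values
  GD <- dominance_grm(g)$values
  n <- 200
  cA <- chol(GA + diag(1e-6, n)); cD <- chol(GD + diag(1e-6, n))
  ests <- t(sapply(1:12, function(r) {
    set.seed(100 + r)
    y <- as.numeric(crossprod(cA, rnorm(n))) * sqrt(1) +
      as.numeric(crossprod(cD, rnorm(n))) * sqrt(0.5) + rnorm(n, 0, 1)
    fit <- fit_reml(y, random = list(a = list(Z = NULL, K = GA),
                                     d = list(Z = NULL, K = GD)),
                    bend_kernels = FALSE)
    fit$varcomp
  }))
  med <- apply(ests, 2, median)
  expect_lt(abs(med["a"] - 1), 0.35)
  expect_lt(abs(med["d"] - 0.5), 0.25)
  expect_lt(abs(med["residual"] - 1), 0.35)
})

test_that("clone BLUEs match the lme4 fit of the same model", {
  skip_if_not_installed("lme4")
  set.seed(12)
  gv <- setNames(rnorm(25), paste0("c", sprintf("%02d", 1:25)))
  tr <- simulate_trials(names(gv), gv, n_trials = 3, reps_per_trial = 2,
                        blocks_per_rep = 2, seed = 13)
  b <- compute_blues(tr)
  fm <- lme4::lmer(
    phenotype ~ clone_id + trial_id + plants_harvested +
      (1 | rep_id) + (1 | block_id),
    data = tr, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  fe <- lme4::fixef(fm)
  eff <- c(0, unname(fe[grepl("^clone_id", names(fe))]))
  # both sets of clone effects agree up to the common re-centering shift
  ours <- b$blue - mean(b$blue)
  theirs <- eff - mean(eff)
  expect_equal(ours, theirs, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("forcing design variances to zero collapses BLUEs to OLS", {
  set.seed(14)
  gv <- setNames(rnorm(10), paste0("c", 1:10))
  tr <- simulate_trials(names(gv), gv, n_trials = 2, reps_per_trial = 2,
                        blocks_per_rep = 1, seed = 15)
  b <- compute_blues(tr, fix_varcomp = c(rep_in_trial = 1e-10, residual = 1))
  X <- model.matrix(~ clone_id + trial_id + plants_harvested,
                    data = transform(tr, clone_id = factor(clone_id),
                                     trial_id = factor(trial_id)))
  ols <- qr.coef(qr(X), tr$phenotype)
  eff <- c(0, unname(ols[grepl("clone_id", names(ols))]))
  expect_equal(b$blue - mean(b$blue), eff - mean(eff), tolerance = 1e-4,
               ignore_attr = TRUE)
})
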