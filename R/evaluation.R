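#' Prediction model variant
#'
#' A model variant names a marker subset, optional per-site kernel weights
#' and optional load covariates — the knobs that distinguish the compared
#' GBLUP models (baseline genome-wide kernels, causal-site kernels,
#' effect-weighted causal kernels, functionally weighted kernels, and kernels
#' plus fixed load covariates).
#'
#' @param name variant label.
#' @param sites site selector into the panel (integer, logical or character);
#'   `NULL` uses every site.
#' @param weights optional nonnegative weights, one per *selected* site, for
#'   the weighted kernel builders.
#' @param load optional per-clone load covariates: matrix or data.frame with
#'   columns `hom_load` and `het_load`, one row per clone of the panel,
#'   entered as fixed effects and included in predicted values.
#' @return an object of class `model_variant`.
#' @export
model_variant <- function(name, sites = NULL, weights = NULL, load = NULL) {
  if (!is.null(load)) {
    load <- as.matrix(load[, c("hom_load", "het_load")])
    storage.mode(load) <- "double"
  }
  structure(list(name = name, sites = sites, weights = weights, load = load),
            class = "model_variant")
}

# additive + dominance kernels for a variant, over all clones of g
build_variant_kernels <- function(g, variant) {
  gs <- if (is.null(variant$sites)) g else subset_sites(g, variant$sites)
  if (n_sites(gs) == 0) stop("variant '", variant$name, "': empty marker subset")
  if (is.null(variant$weights)) {
    A <- additive_grm(gs)
    D <- dominance_grm(gs)
  } else {
    A <- weighted_additive_grm(gs, variant$weights)
    D <- weighted_dominance_grm(gs, variant$weights)
  }
  list(A = A$values, D = D$values)
}

# fit on train_idx, predict test_idx; phenotypes/reference are per-clone
# vectors aligned with g's clones
gblup_predict <- function(g, phenotypes, kernels, load, train_idx, test_idx,
                          ...) {
  n <- n_clones(g)
  X <- matrix(1, n, 1, dimnames = list(rownames(g$dosages), "(Intercept)"))
  fixed_keep <- character(0)
  if (!is.null(load)) {
    X <- cbind(X, hom_load = load[, "hom_load"], het_load = load[, "het_load"])
    fixed_keep <- c("hom_load", "het_load")
  }
  masked <- setdiff(seq_len(n), train_idx)
  pm <- predict_masked(
    phenotypes, X,
    random = list(additive = list(Z = NULL, K = kernels$A),
                  dominance = list(Z = NULL, K = kernels$D)),
    masked = masked, fixed_keep = fixed_keep, bend_kernels = FALSE, ...)
  pm$pred[match(test_idx, masked)]
}

#' Cross-population prediction accuracy for one model variant
#'
#' Masks every phenotype of the target population, fits the variant's
#' two-kernel GBLUP (plus load covariates when present) on the training
#' population, predicts the target clones, and returns the Pearson
#' correlation between predictions and the target clones' reference values
#' (true genetic values in simulation; BLUEs in empirical-style runs).
#'
#' @param g a two-population [geno_matrix()].
#' @param phenotypes per-clone phenotype vector aligned with the panel.
#' @param variant a [model_variant()].
#' @param train_pop,test_pop population labels.
#' @param reference per-clone reference values; defaults to `phenotypes`.
#' @param kernels optional precomputed kernels (`list(A =, D =)`) to reuse
#'   across calls.
#' @param ... passed to [fit_reml()].
#' @return list with `accuracy`, `predictions` (named, target clones) and
#'   `test_idx`.
#' @export
run_cross_population <- function(g, phenotypes, variant, train_pop, test_pop,
                                 reference = NULL, kernels = NULL, ...) {
  if (is.null(reference)) reference <- phenotypes
  train_idx <- which(g$pop == train_pop)
  test_idx <- which(g$pop == test_pop)
  if (!length(train_idx) || !length(test_idx))
    stop("both populations must be present in the panel")
  if (is.null(kernels)) kernels <- build_variant_kernels(g, variant)
  pred <- gblup_predict(g, phenotypes, kernels, variant$load,
                        train_idx, test_idx, ...)
  list(accuracy = cor(pred, reference[test_idx]),
       predictions = pred, test_idx = test_idx)
}

#' Replicated k-fold within-population prediction
#'
#' Per replicate, the population's clones are partitioned into `k` folds by
#' simple randomization (fold sizes differ by at most one). Each fold is
#' masked in turn and predicted from the remaining clones of the same
#' population; the replicate's accuracy is the correlation between the
#' re-assembled out-of-fold predictions and the reference values, and the
#' replicate's top-k overlap counts truly top clones recovered in the
#' predicted top.
#'
#' @inheritParams run_cross_population
#' @param population population label to cross-validate.
#' @param k number of folds (must not exceed the population size).
#' @param reps number of replicate partitions.
#' @param seed integer seed for the fold draws.
#' @param top_k selection-fraction size for the overlap metric; `NA` skips it.
#' @return data.frame with one row per replicate: `replicate`, `accuracy`,
#'   `top_k_overlap`.
#' @export
run_kfold <- function(g, phenotypes, variant, population, k = 10, reps = 30,
                      seed = 1, reference = NULL, kernels = NULL,
                      top_k = 25, ...) {
  if (is.null(reference)) reference <- phenotypes
  pop_idx <- which(g$pop == population)
  n_pop <- length(pop_idx)
  if (k > n_pop) stop("k exceeds the population size")
  if (is.null(kernels)) kernels <- build_variant_kernels(g, variant)
  set.seed(seed)
  fold_draws <- replicate(reps, sample(rep(seq_len(k), length.out = n_pop)),
                          simplify = FALSE)
  out <- lapply(seq_len(reps), function(r) {
    folds <- fold_draws[[r]]
    pred <- rep(NA_real_, n_pop)
    for (f in seq_len(k)) {
      test_idx <- pop_idx[folds == f]
      train_idx <- pop_idx[folds != f]
      pred[folds == f] <- gblup_predict(g, phenotypes, kernels, variant$load,
                                        train_idx, test_idx, ...)
    }
    stopifnot(!anyNA(pred))   # every clone predicted exactly once
    data.frame(replicate = r,
               accuracy = cor(pred, reference[pop_idx]),
               top_k_overlap = if (is.na(top_k)) NA_integer_
                               else top_k_overlap(pred, reference[pop_idx],
                                                  k = top_k))
  })
  do.call(rbind, out)
}

#' Top-k selection overlap
#'
#' Number of the truly top `k` individuals (by `reference`) recovered among
#' the predicted top `k`. Ties at rank k are broken by stable position order,
#' so the metric is deterministic.
#'
#' @param predicted,reference numeric vectors of equal length `>= k`.
#' @param k selection size.
#' @return integer in `0..k`.
#' @export
top_k_overlap <- function(predicted, reference, k = 25) {
  n <- length(predicted)
  if (length(reference) != n) stop("vectors must have equal length")
  if (k > n) stop("k exceeds the number of individuals")
  top_pred <- order(-predicted, seq_len(n))[seq_len(k)]
  top_ref <- order(-reference, seq_len(n))[seq_len(k)]
  length(intersect(top_pred, top_ref))
}

#' Confidence half-width for replicated cross-validation accuracies
#'
#' `SD / sqrt(n) * t_{1 - alpha/2, n - 1}` with `n = folds * reps` — the
#' convention that treats every fold-by-replicate cell as an observation.
#' Replicated folds are not independent, so this is an indication of
#' variability rather than a calibrated interval.
#'
#' @param per_replicate_accuracies numeric vector (length >= 2).
#' @param folds,reps counts defining `n`.
#' @param alpha two-sided error level.
#' @return list with `mean` and `halfwidth`.
#' @export
accuracy_ci <- function(per_replicate_accuracies, folds, reps, alpha = 0.05) {
  acc <- per_replicate_accuracies
  if (length(acc) < 2) stop("need at least 2 accuracy values")
  n <- folds * reps
  list(mean = mean(acc),
       halfwidth = sd(acc) / sqrt(n) * qt(1 - alpha / 2, df = n - 1))
}

#' Scheme labels for a two-population panel
#'
#' The four evaluation schemes: within-population cross-validation for each
#' population (`<pop>_CV`) and the two cross-population directions
#' (`<pop1>-><pop2>`).
#'
#' @param g a two-population [geno_matrix()].
#' @return character vector of four scheme labels.
#' @export
study_schemes <- function(g) {
  lv <- levels(g$pop)
  c(paste0(lv[1], "_CV"), paste0(lv[2], "_CV"),
    paste0(lv[1], "->", lv[2]), paste0(lv[2], "->", lv[1]))
}

# evaluate one variant under one scheme; folds pre-drawn for CV schemes
eval_variant_scheme <- function(g, phenotypes, variant, kernels, scheme,
                                reference, folds = NULL, top_k = 25, ...) {
  lv <- levels(g$pop)
  if (grepl("->", scheme, fixed = TRUE)) {
    pops <- strsplit(scheme, "->", fixed = TRUE)[[1]]
    res <- run_cross_population(g, phenotypes, variant, pops[1], pops[2],
                                reference = reference, kernels = kernels, ...)
    ov <- if (is.na(top_k)) NA_integer_
          else top_k_overlap(res$predictions, reference[res$test_idx], k = top_k)
    data.frame(accuracy = res$accuracy, top_k_overlap = ov)
  } else {
    population <- sub("_CV$", "", scheme)
    pop_idx <- which(g$pop == population)
    pred <- rep(NA_real_, length(pop_idx))
    k <- max(folds)
    for (f in seq_len(k)) {
      test_idx <- pop_idx[folds == f]
      train_idx <- pop_idx[folds != f]
      pred[folds == f] <- gblup_predict(g, phenotypes, kernels, variant$load,
                                        train_idx, test_idx, ...)
    }
    ov <- if (is.na(top_k)) NA_integer_
          else top_k_overlap(pred, reference[pop_idx], k = top_k)
    data.frame(accuracy = cor(pred, reference[pop_idx]), top_k_overlap = ov)
  }
}

#' Simulation study: value of causal information in genomic prediction
#'
#' For each QTL-architecture setting (per-site QTL probability) and
#' replicate: simulate a trait on the panel, then compare three GBLUP models
#' — `Baseline` (additive + dominance kernels from all sites), `QTL` (kernels
#' from the causal sites only) and `WeightedQTL` (causal-site kernels
#' weighted by absolute additive effect, normalized to max 1) — under
#' cross-population and within-population 10-fold schemes. Accuracy is the
#' correlation between predicted and true simulated genetic values (total,
#' additive + dominance) of the masked clones.
#'
#' @param g a two-population [geno_matrix()].
#' @param prob_qtl_grid per-site QTL probabilities to sweep.
#' @param reps simulation replicates per architecture.
#' @param h2 target heritability of each simulated trait.
#' @param seed master seed; per-replicate sub-seeds are derived as
#'   `seed + 7919 * architecture_index + 127 * replicate` (trait) and that
#'   value plus 31 (fold draws).
#' @param schemes subset of the four scheme labels (see [study_schemes()]
#'   naming: `<pop>_CV`, `<pop1>-><pop2>`).
#' @param k folds for the CV schemes.
#' @param top_k overlap metric size (`NA` to skip).
#' @param ... passed to [fit_reml()].
#' @return list of class `study_result`: `results` (one row per scheme x
#'   variant x architecture x replicate) and `summary` (mean accuracy and CI
#'   half-width per cell, via [accuracy_ci()]).
#' @export
run_simulation_study <- function(g, prob_qtl_grid = c(1e-1, 1e-2, 1e-3, 1e-4),
                                 reps = 50, h2 = 0.3, seed = 1,
                                 schemes = study_schemes(g), k = 10,
                                 top_k = 25, ...) {
  stopifnot(nlevels(g$pop) == 2)
  bad <- setdiff(schemes, study_schemes(g))
  if (length(bad)) stop("unknown scheme(s): ", paste(bad, collapse = ", "))
  base_kernels <- build_variant_kernels(g, model_variant("Baseline"))
  lv <- levels(g$pop)
  rows <- list()
  for (pi in seq_along(prob_qtl_grid)) {
    prob <- prob_qtl_grid[pi]
    for (r in seq_len(reps)) {
      rs <- seed + 7919L * pi + 127L * r
      sim <- simulate_trait(g, prob, h2 = h2, seed = rs)
      truth <- sim$trait$genetic_values
      y <- sim$trait$phenotypes
      w <- abs(sim$arch$add_effects)
      w <- w / max(w)
      variants <- list(
        Baseline = model_variant("Baseline"),
        QTL = model_variant("QTL", sites = sim$arch$qtl_indices),
        WeightedQTL = model_variant("WeightedQTL",
                                    sites = sim$arch$qtl_indices, weights = w))
      kern <- list(
        Baseline = base_kernels,
        QTL = build_variant_kernels(g, variants$QTL),
        WeightedQTL = build_variant_kernels(g, variants$WeightedQTL))
      set.seed(rs + 31L)
      folds <- lapply(setNames(lv, lv), function(p)
        sample(rep(seq_len(k), length.out = sum(g$pop == p))))
      for (sc in schemes) {
        fd <- if (grepl("_CV$", sc)) folds[[sub("_CV$", "", sc)]] else NULL
        for (vn in names(variants)) {
          cell <- eval_variant_scheme(g, y, variants[[vn]], kern[[vn]], sc,
                                      reference = truth, folds = fd,
                                      top_k = top_k, ...)
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(scheme = sc, variant = vn, prob_qtl = prob,
                       replicate = r), cell)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  summarize_study(results, k = k, reps = reps,
                  by = c("scheme", "variant", "prob_qtl"))
}

summarize_study <- function(results, k, reps, by) {
  split_key <- interaction(results[by], drop = TRUE)
  sm <- lapply(split(results, split_key), function(d) {
    is_cv <- grepl("_CV$", d$scheme[1])
    hw <- if (nrow(d) >= 2)
      accuracy_ci(d$accuracy, folds = if (is_cv) k else 1, reps = reps)$halfwidth
    else NA_real_
    cbind(d[1, by, drop = FALSE],
          data.frame(mean_accuracy = mean(d$accuracy), ci_halfwidth = hw,
                     mean_top_k = mean(d$top_k_overlap), n_reps = nrow(d)))
  })
  summary <- do.call(rbind, sm)
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", nrow(x$results), "evaluations\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Empirical-style model comparison on a synthetic panel
#'
#' Mirrors the six-model comparison run on real breeding data: clone BLUEs
#' are computed from the plot-level trial table, deleterious sites are
#' classified and counted into per-clone hom/het load, functional weights
#' come from the leave-one-chromosome-out conservation classifier (or are
#' supplied), and six GBLUP variants are evaluated under the four schemes:
#'
#' * `Marker_G` — kernels from the sparse genotyping-marker set;
#' * `Imputed_G` — kernels from the dense genome-wide set;
#' * `Nonsyn` — kernels from the nonsynonymous site set;
#' * `Nonsyn+Load` — `Nonsyn` plus hom/het load as fixed covariates;
#' * `Weighted_Nonsyn` — nonsynonymous kernels weighted by functional weight;
#' * `Weighted_Nonsyn+Load` — weighted kernels plus load covariates.
#'
#' Cross-population schemes are deterministic and evaluated once; CV schemes
#' are replicated `reps` times with fold draws shared across variants, so
#' variants whose kernels coincide (e.g. unit weights) return identical rows.
#'
#' @param g a two-population [geno_matrix()].
#' @param ann annotation table for the nonsynonymous sites of `g` (row i
#'   annotates site i).
#' @param trials plot-level trial table for the panel's clones.
#' @param marker_sites,imputed_sites,nonsyn_sites site selectors for the
#'   three marker sets.
#' @param weights optional per-site functional weights for `nonsyn_sites`
#'   (aligned with that subset); trained from `ann` when `NULL`.
#' @param schemes,k,reps,seed,top_k as in [run_simulation_study()].
#' @param n_trees forest size when training weights.
#' @param ... passed to [fit_reml()].
#' @return a `study_result` (see [run_simulation_study()]).
#' @export
run_empirical_style_study <- function(g, ann, trials, marker_sites,
                                      imputed_sites, nonsyn_sites,
                                      weights = NULL,
                                      schemes = study_schemes(g), k = 10,
                                      reps = 30, seed = 1, top_k = 25,
                                      n_trees = 500, ...) {
  stopifnot(nlevels(g$pop) == 2)
  blues <- compute_blues(trials)
  pheno <- setNames(blues$blue, blues$clone_id)[rownames(g$dosages)]
  if (anyNA(pheno)) stop("trial table lacks phenotypes for some clones")
  flags_nonsyn <- classify_deleterious(ann)
  nonsyn_idx <- seq_len(n_sites(g))[nonsyn_sites]
  if (length(flags_nonsyn) != length(nonsyn_idx))
    stop("annotation table must have one row per nonsynonymous site")
  flags <- rep(FALSE, n_sites(g))
  flags[nonsyn_idx[flags_nonsyn]] <- TRUE
  burden <- compute_burden(g, flags)
  load <- as.matrix(burden[, c("hom_load", "het_load")])
  rownames(load) <- burden$clone_id
  if (is.null(weights)) {
    w_tab <- train_functional_weights(ann, n_trees = n_trees, seed = seed)
    weights <- w_tab$weight
  }
  variants <- list(
    Marker_G = model_variant("Marker_G", sites = marker_sites),
    Imputed_G = model_variant("Imputed_G", sites = imputed_sites),
    Nonsyn = model_variant("Nonsyn", sites = nonsyn_sites),
    `Nonsyn+Load` = model_variant("Nonsyn+Load", sites = nonsyn_sites,
                                  load = load),
    Weighted_Nonsyn = model_variant("Weighted_Nonsyn", sites = nonsyn_sites,
                                    weights = weights),
    `Weighted_Nonsyn+Load` = model_variant("Weighted_Nonsyn+Load",
                                           sites = nonsyn_sites,
                                           weights = weights, load = load))
  kern <- lapply(variants, function(v) build_variant_kernels(g, v))
  lv <- levels(g$pop)
  rows <- list()
  for (sc in schemes) {
    if (grepl("->", sc, fixed = TRUE)) {
      for (vn in names(variants)) {
        cell <- eval_variant_scheme(g, pheno, variants[[vn]], kern[[vn]], sc,
                                    reference = pheno, top_k = top_k, ...)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(scheme = sc, variant = vn, replicate = 1L), cell)
      }
    } else {
      population <- sub("_CV$", "", sc)
      n_pop <- sum(g$pop == population)
      set.seed(seed + match(sc, study_schemes(g)))
      fold_draws <- replicate(reps,
                              sample(rep(seq_len(k), length.out = n_pop)),
                              simplify = FALSE)
      for (r in seq_len(reps)) {
        for (vn in names(variants)) {
          cell <- eval_variant_scheme(g, pheno, variants[[vn]], kern[[vn]],
                                      sc, reference = pheno,
                                      folds = fold_draws[[r]],
                                      top_k = top_k, ...)
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(scheme = sc, variant = vn, replicate = r), cell)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  summarize_study(results, k = k, reps = reps, by = c("scheme", "variant"))
}
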