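#' Sample QTL positions
#'
#' Each of the `m` sites becomes a QTL independently with probability
#' `prob_qtl`, so the QTL count is binomial(m, prob_qtl) — the architecture
#' dial that moves a trait from oligogenic (a handful of large-effect loci)
#' to highly polygenic.
#'
#' @param m number of candidate sites.
#' @param prob_qtl per-site QTL probability in `[0, 1]`.
#' @param seed integer seed.
#' @return sorted integer vector of QTL site indices (possibly empty).
#' @export
sample_qtl <- function(m, prob_qtl, seed = 1) {
  if (prob_qtl < 0 || prob_qtl > 1) stop("prob_qtl must lie in [0, 1]")
  set.seed(seed)
  which(runif(m) < prob_qtl)
}

#' Sample additive QTL effects
#'
#' i.i.d. gamma draws (default shape 1, scale 1); the effect is attached to
#' the ancestral allele, so all effects are strictly positive.
#'
#' @param n_qtl number of QTL.
#' @param shape,scale gamma parameters.
#' @param seed integer seed.
#' @return numeric vector of positive effects.
#' @export
sample_effects <- function(n_qtl, shape = 1, scale = 1, seed = 1) {
  if (n_qtl < 0) stop("n_qtl must be >= 0")
  set.seed(seed)
  if (n_qtl == 0) return(numeric(0))
  rgamma(n_qtl, shape = shape, scale = scale)
}

#' Sample per-QTL dominance degrees
#'
#' Normal draws truncated above at `cap` by rejection sampling: draws beyond
#' the cap are redrawn, never clipped (clipping would put a point mass at the
#' cap). With the defaults (mean 2, sd 0.3, cap 2) the distribution is an
#' upper-half truncation at its mean, giving mostly (near-)complete dominance
#' of the ancestral allele — the recessive-deleterious regime.
#'
#' @param n_qtl number of QTL.
#' @param mean,sd normal parameters; `sd = 0` returns `mean` (which must not
#'   exceed `cap`).
#' @param cap upper truncation bound.
#' @param seed integer seed.
#' @return numeric vector, all values `<= cap`.
#' @export
sample_dominance <- function(n_qtl, mean = 2, sd = 0.3, cap = 2, seed = 1) {
  if (n_qtl < 0) stop("n_qtl must be >= 0")
  set.seed(seed)
  if (n_qtl == 0) return(numeric(0))
  if (sd == 0) {
    if (mean > cap) stop("degenerate sampler: mean above cap with sd = 0")
    return(rep(mean, n_qtl))
  }
  out <- numeric(n_qtl)
  todo <- seq_len(n_qtl)
  while (length(todo)) {
    draw <- rnorm(length(todo), mean, sd)
    ok <- draw <= cap
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' QTL architecture container
#'
#' @param qtl_indices site indices of the QTL.
#' @param add_effects positive additive effect of the ancestral allele per QTL.
#' @param dom_degrees dominance degree per QTL (1 = additive, 2 = derived
#'   allele fully recessive); all `<= 2` under the default sampler.
#' @param prob_qtl the binomial probability used to sample the QTL.
#' @return an object of class `qtl_architecture`.
#' @export
qtl_architecture <- function(qtl_indices, add_effects, dom_degrees,
                             prob_qtl = NA_real_) {
  if (length(add_effects) != length(qtl_indices) ||
      length(dom_degrees) != length(qtl_indices))
    stop("effects and dominance degrees must match the number of QTL")
  if (length(add_effects) && any(add_effects <= 0))
    stop("additive effects must be positive (ancestral allele is favourable)")
  if (length(dom_degrees) && any(dom_degrees > 2))
    stop("dominance degrees must be <= 2")
  structure(list(qtl_indices = as.integer(qtl_indices),
                 add_effects = as.numeric(add_effects),
                 dom_degrees = as.numeric(dom_degrees),
                 prob_qtl = prob_qtl),
            class = "qtl_architecture")
}

#' @export
print.qtl_architecture <- function(x, ...) {
  cat(sprintf("qtl_architecture: %d QTL (prob_qtl = %g)\n",
              length(x$qtl_indices), x$prob_qtl))
  invisible(x)
}

#' Clone genetic values under a QTL architecture
#'
#' Per QTL with ancestral-allele dosage `g` in \{0, 1, 2\}, additive effect `a`
#' and dominance degree `d`, the locus value is `a * g` for homozygotes (0 or
#' `2a`) and `a * d` for heterozygotes; the clone's genetic value is the sum
#' over QTL. `d = 1` recovers pure additivity, `d = 2` makes the derived
#' allele fully recessive (the heterozygote equals the ancestral homozygote).
#' `type = "additive"` returns breeding values computed as if every `d` were 1.
#'
#' @param g a [geno_matrix()] with known ancestral orientation at the QTL.
#' @param arch a [qtl_architecture()].
#' @param type `"total"` (additive + dominance, the default) or `"additive"`.
#' @return named numeric vector, one genetic value per clone.
#' @export
genetic_value <- function(g, arch, type = c("total", "additive")) {
  type <- match.arg(type)
  idx <- arch$qtl_indices
  if (length(idx) == 0)
    return(setNames(numeric(n_clones(g)), rownames(g$dosages)))
  if (min(idx) < 1 || max(idx) > n_sites(g))
    stop("QTL index out of range")
  ganc <- 2L - derived_dosage(g, idx)   # ancestral-allele dosage
  a <- arch$add_effects
  d <- if (type == "additive") rep(1, length(a)) else arch$dom_degrees
  # locus value matrix: a*g for hom (g in {0,2}), a*d for het
  val <- sweep(ganc, 2L, a, `*`)
  het <- ganc == 1L
  val[het] <- (rep(a * d, each = nrow(ganc)))[het]
  setNames(rowSums(val), rownames(g$dosages))
}

#' Add residuals to genetic values at a target heritability
#'
#' Residuals are i.i.d. normal with variance
#' `var(genetic_values) * (1 - h2) / h2`, so the realized heritability
#' `var(g) / var(g + e)` converges to `target_h2` across replicates. The
#' scaling targets the realized genetic variance of the panel at hand, not an
#' expected variance, so each simulated trait is calibrated to its own panel.
#'
#' @param genetic_values numeric vector of clone genetic values.
#' @param target_h2 narrow-sense target in (0, 1]; 1 means no residuals.
#' @param seed integer seed.
#' @return an object of class `simulated_trait`: list with `genetic_values`,
#'   `residuals`, `phenotypes` (their sum) and `target_h2`.
#' @export
add_residuals <- function(genetic_values, target_h2 = 0.3, seed = 1) {
  if (!(target_h2 > 0 && target_h2 <= 1)) stop("target_h2 must lie in (0, 1]")
  vg <- var(genetic_values)
  if (target_h2 < 1 && (!is.finite(vg) || vg == 0))
    stop("genetic values are degenerate: cannot scale residuals to h2 < 1")
  set.seed(seed)
  res <- if (target_h2 == 1) rep(0, length(genetic_values))
         else rnorm(length(genetic_values), 0, sqrt(vg * (1 - target_h2) / target_h2))
  structure(list(genetic_values = genetic_values, residuals = res,
                 phenotypes = genetic_values + res, target_h2 = target_h2),
            class = "simulated_trait")
}

#' Simulate a full trait on a genotype panel
#'
#' Convenience wrapper: sample QTL, gamma effects and truncated-normal
#' dominance degrees, compute genetic values, and add residuals at the target
#' heritability. Sub-draws derive their seeds from `seed` by fixed offsets so
#' the whole simulation is bit-reproducible.
#'
#' @param g a [geno_matrix()].
#' @param prob_qtl per-site QTL probability.
#' @param h2 target heritability.
#' @param seed master seed.
#' @param effect_shape,effect_scale gamma effect parameters.
#' @param dom_mean,dom_sd,dom_cap dominance sampler parameters.
#' @param min_qtl architectures with fewer QTL are resampled (with a message);
#'   a trait needs at least one QTL to be non-degenerate.
#' @return list with elements `arch` ([qtl_architecture()]) and `trait`
#'   ([add_residuals()] output).
#' @export
simulate_trait <- function(g, prob_qtl, h2 = 0.3, seed = 1,
                           effect_shape = 1, effect_scale = 1,
                           dom_mean = 2, dom_sd = 0.3, dom_cap = 2,
                           min_qtl = 1) {
  m <- n_sites(g)
  attempt <- 0L
  repeat {
    idx <- sample_qtl(m, prob_qtl, seed = seed + 7L * attempt)
    if (length(idx) >= min_qtl) break
    message("simulate_trait: ", length(idx), " QTL sampled; resampling")
    attempt <- attempt + 1L
    if (attempt > 1000L) stop("could not sample a non-degenerate architecture")
  }
  a <- sample_effects(length(idx), shape = effect_shape, scale = effect_scale,
                      seed = seed + 1L)
  d <- sample_dominance(length(idx), mean = dom_mean, sd = dom_sd,
                        cap = dom_cap, seed = seed + 2L)
  arch <- qtl_architecture(idx, a, d, prob_qtl = prob_qtl)
  gv <- genetic_value(g, arch)
  trait <- add_residuals(gv, target_h2 = h2, seed = seed + 3L)
  list(arch = arch, trait = trait)
}
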