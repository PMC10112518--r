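#' Simulate a two-population diploid genotype panel
#'
#' Balding-Nichols model of population divergence: each site draws an
#' ancestral frequency, then each population draws its own frequency from a
#' Beta distribution with parameters `p(1-fst)/fst` and `(1-p)(1-fst)/fst`
#' (so the between-population variance of allele frequency is
#' `fst * p * (1-p)`), and clones draw binomial(2) dosages. Sites whose pooled
#' minor-allele frequency falls below `maf_min` are redrawn so the panel
#' contains no quasi-monomorphic markers. Each site is assigned an ancestral
#' allele (reference or alternate, a fair coin by default) so derived-allele
#' orientation is always known downstream.
#'
#' The defaults emulate a two-program breeding panel of 1048 clones genotyped
#' at ~66k coding sites with moderate divergence.
#'
#' @param n1,n2 clones in population 1 / population 2 (>= 2).
#' @param m number of biallelic sites.
#' @param fst divergence parameter in (0, 1).
#' @param maf_min pooled minor-allele-frequency floor below which a site is
#'   redrawn.
#' @param seed integer seed; every draw is reproducible given it.
#' @param pop_names labels for the two populations.
#' @param chrom_count chromosomes to spread sites across (round-robin blocks).
#' @param p_anc_range range of the uniform ancestral-frequency draw.
#' @return a [geno_matrix()].
#' @examples
#' g <- simulate_population_pair(n1 = 20, n2 = 20, m = 50, seed = 1)
#' g
#' @export
simulate_population_pair <- function(n1 = 524, n2 = 524, m = 66000,
                                     fst = 0.1, maf_min = 0.01, seed = 1,
                                     pop_names = c("IITA", "NaCRRI"),
                                     chrom_count = 18,
                                     p_anc_range = c(0.05, 0.95)) {
  if (n1 < 2 || n2 < 2) stop("need at least 2 clones per population")
  if (m < 1) stop("m must be >= 1")
  if (!(fst > 0 && fst < 1)) stop("fst must lie strictly in (0, 1)")
  set.seed(seed)
  n <- n1 + n2
  draw_block <- function(k) {
    p <- runif(k, p_anc_range[1], p_anc_range[2])
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    p1 <- rbeta(k, a, b)
    p2 <- rbeta(k, a, b)
    d1 <- matrix(rbinom(n1 * k, 2L, rep(p1, each = n1)), nrow = n1)
    d2 <- matrix(rbinom(n2 * k, 2L, rep(p2, each = n2)), nrow = n2)
    list(d = rbind(d1, d2))
  }
  dos <- matrix(0L, n, m)
  todo <- seq_len(m)
  while (length(todo)) {
    blk <- draw_block(length(todo))
    dos[, todo] <- blk$d
    pooled <- colMeans(dos[, todo, drop = FALSE]) / 2
    ok <- pmin(pooled, 1 - pooled) >= maf_min
    todo <- todo[!ok]
  }
  anc_ref <- runif(m) < 0.5
  chrom <- sprintf("chr%02d", 1L + (seq_len(m) - 1L) %/% ceiling(m / chrom_count))
  pos <- as.integer(ave(seq_len(m), chrom, FUN = seq_along) * 100L)
  rownames(dos) <- sprintf("%s_%04d", rep(pop_names, c(n1, n2)),
                           c(seq_len(n1), seq_len(n2)))
  colnames(dos) <- sprintf("S%06d", seq_len(m))
  geno_matrix(dos, pop = rep(pop_names, c(n1, n2)), chrom = chrom, pos = pos,
              ancestral_is_ref = anc_ref)
}

#' Simulate a per-site annotation table
#'
#' Emulates the annotation features available for coding variants: a
#' per-site evolutionary rate (low = conserved), a protein-impact score in
#' `[0, 1]` (low = damaging) negatively associated with conservation, a
#' minor-allele frequency, and a block of generic numeric predictor columns
#' carrying tunable signal about conservation status. Sites are labelled
#' `conserved` when the rate is below 0.3, `non_conserved` when above 2, and
#' `excluded` otherwise — the labelling used to train conservation
#' classifiers.
#'
#' A fraction `prop_deleterious_like` of sites is drawn from a
#' "deleterious-like" corner (rate < 0.5, impact score < 0.05, MAF < 0.2) so
#' the strict deleterious filter always has positives to find.
#'
#' @param m number of sites.
#' @param chrom_count chromosomes to assign sites to.
#' @param prop_deleterious_like fraction of sites drawn deleterious-like;
#'   default emulates ~2.2k of 66k coding sites.
#' @param n_features number of generic predictor columns.
#' @param feature_signal multiplier on the conservation signal carried by the
#'   predictor columns (0 = pure noise).
#' @param seed integer seed.
#' @param site_id,chrom,maf optional vectors (e.g. from a simulated panel) to
#'   use instead of generated ids, chromosome assignments and frequencies.
#' @return a data.frame with columns `site_id`, `chrom`, `evo_rate`,
#'   `sift_score`, `maf`, `conservation_label` and `feat_*` predictor columns.
#' @export
simulate_annotations <- function(m, chrom_count = 18,
                                 prop_deleterious_like = 0.033,
                                 n_features = 16, feature_signal = 1,
                                 seed = 1, site_id = NULL, chrom = NULL,
                                 maf = NULL) {
  if (m < 1) stop("m must be >= 1")
  set.seed(seed)
  if (is.null(site_id)) site_id <- sprintf("S%06d", seq_len(m))
  if (is.null(chrom))
    chrom <- sprintf("chr%02d", 1L + (seq_len(m) - 1L) %/% ceiling(m / chrom_count))
  del_like <- runif(m) < prop_deleterious_like
  # three-component rate mixture: conserved tail, intermediate, fast-evolving
  comp <- sample.int(3L, m, replace = TRUE, prob = c(0.35, 0.35, 0.30))
  rate <- numeric(m)
  rate[comp == 1L] <- rgamma(sum(comp == 1L), shape = 2, scale = 0.08)
  rate[comp == 2L] <- runif(sum(comp == 2L), 0.3, 2)
  rate[comp == 3L] <- 2 + rgamma(sum(comp == 3L), shape = 1, scale = 1.2)
  sift <- rbeta(m, shape1 = 0.3 + pmin(rate, 3), shape2 = 2)
  if (is.null(maf)) maf <- runif(m, 0, 0.5) else maf <- pmin(maf, 1 - maf)
  rate[del_like] <- runif(sum(del_like), 0.01, 0.45)
  sift[del_like] <- runif(sum(del_like), 0, 0.049)
  maf[del_like] <- runif(sum(del_like), 0.001, 0.19)
  label <- ifelse(rate < 0.3, "conserved",
                  ifelse(rate > 2, "non_conserved", "excluded"))
  # predictors: shared conservation axis plus iid noise
  s <- scale(-log(rate + 1e-6))[, 1L]
  b <- runif(n_features, 0.5, 1.5)
  feats <- sapply(seq_len(n_features), function(j)
    feature_signal * b[j] * s + rnorm(m))
  colnames(feats) <- sprintf("feat_%02d", seq_len(n_features))
  out <- data.frame(site_id = site_id, chrom = chrom, evo_rate = rate,
                    sift_score = sift, maf = maf,
                    conservation_label = label,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(feats))
}

#' Simulate a multi-trial field phenotype table
#'
#' Builds plot-level records under a nested trial / replicate / block design:
#' each trial contains `reps_per_trial` complete replicates, and within each
#' replicate the clones are randomized across `blocks_per_rep` incomplete
#' blocks. The plot phenotype is
#' `mu + g_clone + trial + rep(trial) + block(rep) + slope * (plants - mean) + e`
#' with trial effects fixed draws and rep/block/plot effects independent
#' normals with the standard deviations in `variance_config`.
#'
#' @param clones character vector of clone ids.
#' @param genetic_values named or positional numeric vector of clone genetic
#'   values (same length as `clones`).
#' @param n_trials,reps_per_trial,blocks_per_rep design counts (>= 1).
#' @param variance_config list with elements `trial_sd`, `rep_sd`, `block_sd`,
#'   `resid_sd`, `plants_slope`, `plants_mean`; defaults give moderate field
#'   noise.
#' @param mu overall mean.
#' @param seed integer seed.
#' @return a data.frame with columns `clone_id`, `trial_id`, `rep_id`,
#'   `block_id`, `plants_harvested`, `phenotype`. Replicate and block ids are
#'   globally unique so the nesting is strict by construction.
#' @export
simulate_trials <- function(clones, genetic_values, n_trials = 3,
                            reps_per_trial = 2, blocks_per_rep = 2,
                            variance_config = list(), mu = 0, seed = 1) {
  if (length(genetic_values) != length(clones))
    stop("genetic_values must have one value per clone")
  if (n_trials < 1 || reps_per_trial < 1 || blocks_per_rep < 1)
    stop("design counts must be >= 1")
  vc <- modifyList(list(trial_sd = 1, rep_sd = 0.5, block_sd = 0.5,
                        resid_sd = 1, plants_slope = 0.05, plants_mean = 8),
                   variance_config)
  set.seed(seed)
  nc <- length(clones)
  trial_eff <- rnorm(n_trials, 0, vc$trial_sd)
  rows <- vector("list", n_trials * reps_per_trial)
  ix <- 0L
  for (t in seq_len(n_trials)) {
    for (r in seq_len(reps_per_trial)) {
      ord <- sample.int(nc)
      blk <- rep(seq_len(blocks_per_rep), length.out = nc)[order(ord)]
      rep_id <- sprintf("T%02d_R%d", t, r)
      ix <- ix + 1L
      rows[[ix]] <- data.frame(
        clone_id = clones, trial_id = sprintf("T%02d", t), rep_id = rep_id,
        block_id = sprintf("%s_B%d", rep_id, blk),
        rep_eff = rnorm(1, 0, vc$rep_sd), trial_eff = trial_eff[t],
        g = as.numeric(genetic_values), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  blk_lv <- unique(tab$block_id)
  blk_eff <- setNames(rnorm(length(blk_lv), 0, vc$block_sd), blk_lv)
  tab$plants_harvested <- rpois(nrow(tab), vc$plants_mean) + 1L
  tab$phenotype <- mu + tab$g + tab$trial_eff + tab$rep_eff +
    blk_eff[tab$block_id] +
    vc$plants_slope * (tab$plants_harvested - vc$plants_mean) +
    rnorm(nrow(tab), 0, vc$resid_sd)
  tab[c("clone_id", "trial_id", "rep_id", "block_id",
        "plants_harvested", "phenotype")]
}
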