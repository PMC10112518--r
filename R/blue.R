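#' Clone BLUEs from plot-level trial data
#'
#' First stage of two-stage genomic prediction: collapse plot records to one
#' best linear unbiased estimate per clone. The model treats the overall
#' mean, trial (location-year), plants harvested per plot and germplasm id as
#' fixed, and replicate-in-trial and block-in-replicate as independent random
#' effects:
#' `y = X beta + Z_rep(trial) t + Z_block(rep) b + e`.
#'
#' The returned BLUE for clone `c` is its fixed-effect estimate re-centered
#' to the population mean: intercept + clone effect + the non-clone fixed
#' contributions (trial, covariate) averaged over all plots. In a single
#' trial with a constant covariate this reduces to the clone mean of its
#' plots.
#'
#' @param trials a trial table as produced by [simulate_trials()]: columns
#'   `clone_id`, `trial_id`, `rep_id`, `block_id`, `plants_harvested`,
#'   `phenotype`.
#' @param ... passed to [fit_reml()].
#' @return data.frame with columns `clone_id` and `blue`.
#' @export
compute_blues <- function(trials, ...) {
  req <- c("clone_id", "trial_id", "rep_id", "block_id",
           "plants_harvested", "phenotype")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trial table lacks columns: ",
                         paste(miss, collapse = ", "))
  trials$clone_id <- factor(trials$clone_id)
  trials$trial_id <- factor(trials$trial_id)
  y <- trials$phenotype
  fixed <- "~ clone_id"
  if (nlevels(trials$trial_id) > 1) fixed <- paste(fixed, "+ trial_id")
  if (length(unique(trials$plants_harvested)) > 1)
    fixed <- paste(fixed, "+ plants_harvested")
  X <- model.matrix(stats::as.formula(fixed), data = trials)
  rep_f <- factor(trials$rep_id)
  blk_f <- factor(trials$block_id)
  random <- list()
  if (nlevels(rep_f) > 1)
    random$rep_in_trial <- list(Z = model.matrix(~ 0 + rep_f), K = NULL)
  if (nlevels(blk_f) > 1 && nlevels(blk_f) > nlevels(rep_f))
    random$block_in_rep <- list(Z = model.matrix(~ 0 + blk_f), K = NULL)
  fit <- fit_reml(y, X, random, ...)

  beta <- fit$beta
  beta[is.na(beta)] <- 0
  cn <- colnames(X)
  clone_cols <- grepl("^clone_id", cn)
  lev <- levels(trials$clone_id)
  eff <- setNames(rep(0, length(lev)), lev)   # reference clone absorbed in intercept
  est <- beta[clone_cols]
  est_lev <- sub("^clone_id", "", cn[clone_cols])
  eff[est_lev] <- est
  # non-clone, non-intercept fixed contributions averaged over all plots
  other <- !clone_cols & cn != "(Intercept)"
  base <- beta["(Intercept)"] +
    if (any(other)) mean(X[, other, drop = FALSE] %*% beta[other]) else 0
  data.frame(clone_id = lev, blue = as.numeric(base + eff),
             stringsAsFactors = FALSE)
}
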