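#' Flag putatively deleterious sites
#'
#' A site is deleterious when it is evolutionarily constrained, predicted
#' damaging at the protein level, and rare: evolutionary rate below
#' `rate_max`, impact score below `sift_max` and minor-allele frequency below
#' `maf_max`, all strict inequalities — boundary values fall outside the set.
#' Sites with missing annotation are excluded (flagged `FALSE`) with a
#' message giving the count.
#'
#' @param ann annotation table with columns `evo_rate`, `sift_score`, `maf`
#'   (see [simulate_annotations()]).
#' @param rate_max,sift_max,maf_max strict upper thresholds.
#' @return logical vector, one flag per site.
#' @export
classify_deleterious <- function(ann, rate_max = 0.5, sift_max = 0.05,
                                 maf_max = 0.2) {
  req <- c("evo_rate", "sift_score", "maf")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "))
  cc <- stats::complete.cases(ann[req])
  if (any(!cc))
    message(sum(!cc), " site(s) with missing annotation excluded")
  flag <- cc & ann$evo_rate < rate_max & ann$sift_score < sift_max &
    ann$maf < maf_max
  flag[is.na(flag)] <- FALSE
  flag
}

#' Per-clone deleterious mutation burden
#'
#' Counts, over the flagged sites, how many a clone carries homozygous for
#' the derived allele (`hom_load`) and how many heterozygous (`het_load`).
#' Homozygous burden is the component expected to be expressed when
#' deleterious alleles are recessive; heterozygous burden is masked load.
#'
#' @param g a [geno_matrix()] with known ancestral orientation at the flagged
#'   sites.
#' @param deleterious_flags logical per site (or integer site indices).
#' @return data.frame with columns `clone_id`, `hom_load`, `het_load`.
#' @export
compute_burden <- function(g, deleterious_flags) {
  idx <- if (is.logical(deleterious_flags)) which(deleterious_flags)
         else as.integer(deleterious_flags)
  if (!length(idx))
    return(data.frame(clone_id = rownames(g$dosages),
                      hom_load = 0L, het_load = 0L, stringsAsFactors = FALSE))
  d <- derived_dosage(g, idx)
  data.frame(clone_id = rownames(g$dosages),
             hom_load = as.integer(rowSums(d == 2L)),
             het_load = as.integer(rowSums(d == 1L)),
             stringsAsFactors = FALSE)
}

#' Conservation-classifier functional weights, leave-one-chromosome-out
#'
#' Trains a probability random forest to separate conserved from
#' non-conserved sites (labels from the annotation table; `excluded` sites
#' never enter training) once per chromosome, each time leaving that
#' chromosome out of the training data, and scores every site of the held-out
#' chromosome — labelled or not — with the predicted probability of the
#' conserved class. The probability is the site's functional weight in
#' `[0, 1]`, and the held-out chromosome is recorded per site so the absence
#' of training leakage is auditable.
#'
#' Predictors are the `sift_score` column plus every `feat_*` column, making
#' the classifier agnostic to how many features the table carries.
#'
#' @param ann annotation table (see [simulate_annotations()]).
#' @param n_trees ensemble size.
#' @param seed integer seed for the forest.
#' @return data.frame with columns `site_id`, `weight`, `held_out_chrom`,
#'   in the row order of `ann`.
#' @export
train_functional_weights <- function(ann, n_trees = 500, seed = 1) {
  chroms <- unique(ann$chrom)
  if (length(chroms) < 2) stop("need at least 2 chromosomes for leave-one-out")
  feat_cols <- c("sift_score", grep("^feat_", names(ann), value = TRUE))
  labelled <- ann$conservation_label %in% c("conserved", "non_conserved")
  weight <- rep(NA_real_, nrow(ann))
  held <- rep(NA_character_, nrow(ann))
  for (ch in chroms) {
    test_ix <- ann$chrom == ch
    train_ix <- labelled & !test_ix
    ytr <- factor(ann$conservation_label[train_ix],
                  levels = c("conserved", "non_conserved"))
    if (nlevels(droplevels(ytr)) < 2)
      stop("training split for held-out chromosome ", ch,
           " lacks a conservation class")
    rf <- ranger::ranger(
      x = ann[train_ix, feat_cols, drop = FALSE], y = ytr,
      num.trees = n_trees, probability = TRUE, seed = seed,
      num.threads = 1)
    pr <- stats::predict(rf, data = ann[test_ix, feat_cols, drop = FALSE],
                         num.threads = 1)$predictions
    weight[test_ix] <- pr[, "conserved"]
    held[test_ix] <- ch
  }
  data.frame(site_id = ann$site_id, weight = weight, held_out_chrom = held,
             stringsAsFactors = FALSE)
}
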