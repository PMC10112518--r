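#' Genotype panel container
#'
#' A `geno_matrix` bundles a clones-by-sites dosage matrix with the per-clone
#' and per-site metadata the rest of the package needs: population labels,
#' chromosome/position, ancestral-allele orientation and (optionally
#' precomputed) alternate-allele frequencies.
#'
#' Dosages count copies of the alternate allele (0, 1 or 2) and must be
#' complete: the generators never emit missing calls and the relationship
#' matrix builders assume none.
#'
#' @param dosages integer matrix, clones in rows, sites in columns, values in
#'   \{0, 1, 2\}. Row and column names are used as clone and site ids; defaults
#'   are generated when absent.
#' @param pop character or factor of population labels, one per clone.
#' @param chrom chromosome identifier per site.
#' @param pos 1-based integer position per site.
#' @param ancestral_is_ref logical per site; `TRUE` when the reference allele
#'   (dosage axis 0) is the ancestral state.
#' @param freqs optional alternate-allele frequency per site in `[0, 1]`;
#'   computed from `dosages` when `NULL`.
#' @return An object of class `geno_matrix`.
#' @seealso [simulate_population_pair()], [filter_sites()], [additive_grm()]
#' @export
geno_matrix <- function(dosages, pop, chrom = NULL, pos = NULL,
                        ancestral_is_ref = NULL, freqs = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (anyNA(dosages) || !all(dosages %in% 0:2))
    stop("dosages must be complete and in {0, 1, 2}")
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("clone%04d", seq_len(n))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("site%06d", seq_len(m))
  pop <- as.factor(pop)
  if (length(pop) != n) stop("pop must have one label per clone")
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m)
  if (is.null(ancestral_is_ref)) ancestral_is_ref <- rep(NA, m)
  ancestral_is_ref <- as.logical(ancestral_is_ref)
  if (length(chrom) != m || length(pos) != m || length(ancestral_is_ref) != m)
    stop("per-site metadata must match the number of sites")
  if (is.null(freqs)) {
    freqs <- colMeans(dosages) / 2
  } else {
    if (length(freqs) != m || any(freqs < 0 | freqs > 1))
      stop("freqs must have one value per site in [0, 1]")
  }
  structure(
    list(dosages = dosages, pop = pop, chrom = as.character(chrom),
         pos = as.integer(pos), ancestral_is_ref = ancestral_is_ref,
         freqs = as.numeric(freqs)),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d clones x %d sites\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat("populations:",
      paste(sprintf("%s (%d)", levels(x$pop), tabulate(x$pop)), collapse = ", "),
      "\n")
  cat(sprintf("chromosomes: %d; ancestral orientation %s\n",
              length(unique(x$chrom)),
              if (anyNA(x$ancestral_is_ref)) "partially unknown" else "known"))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Number of clones / sites in a panel
#' @param g a [geno_matrix()].
#' @return integer count.
#' @export
n_clones <- function(g) nrow(g$dosages)

#' @rdname n_clones
#' @export
n_sites <- function(g) ncol(g$dosages)

#' Subset the sites of a panel
#'
#' @param g a [geno_matrix()].
#' @param sites integer, logical or character index into the site axis.
#' @return a `geno_matrix` restricted to `sites`, metadata (including stored
#'   frequencies) subset in step.
#' @export
subset_sites <- function(g, sites) {
  if (is.character(sites)) sites <- match(sites, colnames(g$dosages))
  if (is.logical(sites)) sites <- which(sites)
  if (anyNA(sites) || (length(sites) && (min(sites) < 1 || max(sites) > n_sites(g))))
    stop("site index out of range")
  geno_matrix(g$dosages[, sites, drop = FALSE], g$pop,
              chrom = g$chrom[sites], pos = g$pos[sites],
              ancestral_is_ref = g$ancestral_is_ref[sites],
              freqs = g$freqs[sites])
}

#' Dosages of the derived allele
#'
#' Re-orients the stored alternate-allele dosages onto the derived-allele axis
#' using the per-site ancestral flags.
#'
#' @param g a [geno_matrix()] with known ancestral orientation.
#' @param sites optional site subset.
#' @return integer matrix of derived-allele dosages.
#' @export
derived_dosage <- function(g, sites = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(g))
  if (is.character(sites)) sites <- match(sites, colnames(g$dosages))
  flag <- g$ancestral_is_ref[sites]
  if (anyNA(flag))
    stop("ancestral orientation unknown for sites: ",
         paste(colnames(g$dosages)[sites[is.na(flag)]], collapse = ", "))
  d <- g$dosages[, sites, drop = FALSE]
  # ancestral == ref: alternate IS the derived allele; otherwise flip the axis
  d[, !flag] <- 2L - d[, !flag, drop = FALSE]
  d
}

#' Filter panel sites on segregation and frequency
#'
#' Mirrors the marker filtering applied before building relationship matrices:
#' optionally keep only sites segregating within every population, and
#' optionally drop sites whose pooled minor-allele frequency is at or above a
#' ceiling. Site order is preserved and the operation is idempotent.
#'
#' @param g a [geno_matrix()].
#' @param require_segregating_in_both keep only sites polymorphic within each
#'   population.
#' @param maf_max pooled minor-allele-frequency ceiling (strict `<` retained),
#'   or `NULL` to skip.
#' @return a filtered `geno_matrix`; a warning is raised when no site survives.
#' @export
filter_sites <- function(g, require_segregating_in_both = TRUE, maf_max = NULL) {
  keep <- rep(TRUE, n_sites(g))
  if (require_segregating_in_both) {
    for (lv in levels(g$pop)) {
      d <- g$dosages[g$pop == lv, , drop = FALSE]
      keep <- keep & matrixStats_colVar_nonzero(d)
    }
  }
  if (!is.null(maf_max)) {
    maf <- pmin(g$freqs, 1 - g$freqs)
    keep <- keep & (maf < maf_max)
  }
  if (!any(keep)) warning("filter_sites: no sites retained")
  subset_sites(g, which(keep))
}

# polymorphic within a dosage submatrix, per column
matrixStats_colVar_nonzero <- function(d) {
  rng <- apply(d, 2L, function(x) any(x != x[1L]))
  as.logical(rng)
}

#' Hudson's two-population FST estimator
#'
#' Ratio-of-means estimator with within-population sampling corrections,
#' averaged across sites. Used to check the divergence realized by the
#' Balding-Nichols generator.
#'
#' @param g a two-population [geno_matrix()].
#' @return a single FST estimate.
#' @export
hudson_fst <- function(g) {
  if (nlevels(g$pop) != 2L) stop("hudson_fst expects exactly two populations")
  i1 <- g$pop == levels(g$pop)[1L]
  i2 <- g$pop == levels(g$pop)[2L]
  n1 <- 2 * sum(i1); n2 <- 2 * sum(i2)
  p1 <- colMeans(g$dosages[i1, , drop = FALSE]) / 2
  p2 <- colMeans(g$dosages[i2, , drop = FALSE]) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
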