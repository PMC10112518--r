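#' Genomic relationship matrices
#'
#' Builders for the four marker kernels used by the multi-kernel GBLUP
#' models: additive (VanRaden centering), dominance (zero-mean heterozygosity
#' coding), and their functionally weighted counterparts.
#'
#' Additive: with dosages centered by `2 * p_i` per site into `M`,
#' `G_A = M M' / sum_i 2 p_i (1 - p_i)`.
#'
#' Dominance: per site with alternate-allele frequency `p` (`q = 1 - p`) the
#' coding matrix `D` holds `-2 p^2` for the reference homozygote, `2 p q` for
#' the heterozygote and `-2 q^2` for the alternate homozygote — the zero-mean
#' coding whose column expectation vanishes under Hardy-Weinberg, required
#' for the dominance-variance interpretation of the kernel. Then
#' `G_D = D D' / sum_i (2 p_i q_i)^2`. An alternative convention that assigns
#' `+2 q^2` to the alternate homozygote circulates in some pipelines; it is
#' available via `zero_mean = FALSE` for comparison but is not zero-mean.
#'
#' Weighted forms place nonnegative per-site weights `w_i` (e.g. conservation
#' probabilities) on the sites: `G_AW = M W M' / sum_i 2 p_i q_i w_i` and
#' `G_DW = D W D' / sum_i (2 p_i q_i w_i)^2` with `W = diag(w)`. Unit weights
#' reproduce the unweighted kernels exactly.
#'
#' Monomorphic sites carry no information and break the centering; when
#' frequencies are computed from the data such sites are dropped with a
#' warning (an all-monomorphic panel is an error). Supplied frequencies are
#' trusted as-is provided they lie strictly in (0, 1).
#'
#' @param g a [geno_matrix()].
#' @param freqs optional per-site alternate-allele frequencies used for
#'   centering/coding; defaults to the panel's stored (pooled) frequencies.
#' @param weights nonnegative per-site weights, at least one positive.
#' @param zero_mean use the zero-mean dominance coding (default); see Details.
#' @return a `relationship_matrix`: list with `values` (symmetric n x n),
#'   `kind`, `weighted`, `site_ids`, `freqs_used`, `weights_used`.
#' @name grm
NULL

new_relmat <- function(values, kind, weighted, site_ids, freqs, weights) {
  values <- (values + t(values)) / 2   # enforce exact symmetry
  structure(list(values = values, kind = kind, weighted = weighted,
                 site_ids = site_ids, freqs_used = freqs,
                 weights_used = weights),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix: %s%s, %d clones, %d sites\n",
              if (x$weighted) "weighted " else "", x$kind,
              nrow(x$values), length(x$site_ids)))
  cat(sprintf("mean diagonal %.4f\n", mean(diag(x$values))))
  invisible(x)
}

#' @export
as.matrix.relationship_matrix <- function(x, ...) x$values

# resolve frequencies and the usable (polymorphic) site set
grm_sites <- function(g, freqs) {
  supplied <- !is.null(freqs)
  if (!supplied) freqs <- g$freqs
  if (length(freqs) != n_sites(g)) stop("freqs must have one value per site")
  keep <- freqs > 0 & freqs < 1
  if (!all(keep)) {
    if (supplied) stop("supplied freqs must lie strictly in (0, 1)")
    if (!any(keep)) stop("all sites monomorphic: no relationship information")
    warning(sprintf("dropping %d monomorphic site(s)", sum(!keep)))
  }
  list(idx = which(keep), p = freqs[keep])
}

#' @rdname grm
#' @export
additive_grm <- function(g, freqs = NULL) {
  s <- grm_sites(g, freqs)
  M <- sweep(g$dosages[, s$idx, drop = FALSE], 2L, 2 * s$p, `-`)
  denom <- sum(2 * s$p * (1 - s$p))
  new_relmat(tcrossprod(M, M) / denom, "additive", FALSE,
             colnames(g$dosages)[s$idx], s$p, NULL)
}

# dominance coding matrix for given dosages/frequencies
dominance_coding <- function(dos, p, zero_mean = TRUE) {
  q <- 1 - p
  c0 <- -2 * p^2
  c1 <- 2 * p * q
  c2 <- if (zero_mean) -2 * q^2 else 2 * q^2
  D <- matrix(rep(c0, each = nrow(dos)), nrow(dos))
  het <- dos == 1L; alt <- dos == 2L
  D[het] <- rep(c1, each = nrow(dos))[het]
  D[alt] <- rep(c2, each = nrow(dos))[alt]
  dimnames(D) <- dimnames(dos)
  D
}

#' @rdname grm
#' @export
dominance_grm <- function(g, freqs = NULL, zero_mean = TRUE) {
  s <- grm_sites(g, freqs)
  D <- dominance_coding(g$dosages[, s$idx, drop = FALSE], s$p, zero_mean)
  denom <- sum((2 * s$p * (1 - s$p))^2)
  new_relmat(tcrossprod(D, D) / denom, "dominance", FALSE,
             colnames(g$dosages)[s$idx], s$p, NULL)
}

check_weights <- function(w, m) {
  if (length(w) != m) stop("weights must have one value per site")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (all(w == 0)) stop("at least one weight must be positive")
  as.numeric(w)
}

#' @rdname grm
#' @export
weighted_additive_grm <- function(g, weights, freqs = NULL) {
  w <- check_weights(weights, n_sites(g))
  s <- grm_sites(g, freqs)
  w <- w[s$idx]
  M <- sweep(g$dosages[, s$idx, drop = FALSE], 2L, 2 * s$p, `-`)
  MW <- sweep(M, 2L, w, `*`)
  denom <- sum(2 * s$p * (1 - s$p) * w)
  if (denom <= 0) stop("weights remove all polymorphic sites")
  new_relmat(tcrossprod(MW, M) / denom, "additive", TRUE,
             colnames(g$dosages)[s$idx], s$p, w)
}

#' @rdname grm
#' @export
weighted_dominance_grm <- function(g, weights, freqs = NULL, zero_mean = TRUE) {
  w <- check_weights(weights, n_sites(g))
  s <- grm_sites(g, freqs)
  w <- w[s$idx]
  D <- dominance_coding(g$dosages[, s$idx, drop = FALSE], s$p, zero_mean)
  DW <- sweep(D, 2L, w, `*`)
  denom <- sum((2 * s$p * (1 - s$p) * w)^2)
  if (denom <= 0) stop("weights remove all polymorphic sites")
  new_relmat(tcrossprod(DW, D) / denom, "dominance", TRUE,
             colnames(g$dosages)[s$idx], s$p, w)
}
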