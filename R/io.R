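#' Read and write panel, annotation and trial tables
#'
#' Plain-text interchange for the package's containers. The dosage TSV has
#' clones in rows (first column `clone_id`, then `pop`, then one column per
#' site); per-site metadata travels in a companion sites TSV with columns
#' `site_id`, `chrom`, `pos`, `ancestral_is_ref`, `freq`. The VCF writer
#' emits biallelic records with a `GT` field and an `AA` (ancestral allele)
#' INFO tag, readable by standard VCF tooling.
#'
#' @param g a [geno_matrix()].
#' @param path,dosage_path,sites_path file paths.
#' @return `read_geno_tsv` returns a [geno_matrix()]; the writers return
#'   their path invisibly.
#' @name geno_io
NULL

#' @rdname geno_io
#' @export
write_geno_tsv <- function(g, dosage_path, sites_path) {
  df <- data.frame(clone_id = rownames(g$dosages), pop = as.character(g$pop),
                   g$dosages, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, dosage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sites <- data.frame(site_id = colnames(g$dosages), chrom = g$chrom,
                      pos = g$pos, ancestral_is_ref = g$ancestral_is_ref,
                      freq = g$freqs, stringsAsFactors = FALSE)
  write.table(sites, sites_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dosage_path)
}

#' @rdname geno_io
#' @export
read_geno_tsv <- function(dosage_path, sites_path) {
  df <- read.table(dosage_path, header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  sites <- read.table(sites_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  dos <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(dos) <- df$clone_id
  geno_matrix(dos, pop = df$pop, chrom = sites$chrom, pos = sites$pos,
              ancestral_is_ref = sites$ancestral_is_ref, freqs = sites$freq)
}

#' @rdname geno_io
#' @export
write_geno_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=loadgp",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g$dosages)), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  aa <- ifelse(is.na(g$ancestral_is_ref), ".",
               ifelse(g$ancestral_is_ref, "A", "T"))
  for (j in seq_len(n_sites(g))) {
    gt <- gt_codes[g$dosages[, j] + 1L]
    writeLines(paste(c(g$chrom[j], g$pos[j], colnames(g$dosages)[j], "A", "T",
                       ".", "PASS", paste0("AA=", aa[j]), "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a study result to TSV files
#'
#' @param x a `study_result`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_study_result <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(x$results, file.path(dir, "results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(x$summary, file.path(dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
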