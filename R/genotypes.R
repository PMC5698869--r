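#' Simulate a genotype dosage matrix under Hardy-Weinberg equilibrium
#'
#' Draws, for each SNP of the panel, risk-allele dosages 0/1/2 from the
#' Hardy-Weinberg proportions at the configured risk-allele frequency (by
#' default the minor-allele frequency, i.e. the risk allele is taken to be
#' the minor allele).  Missing calls are injected uniformly at `missing_rate`.
#'
#' @param n_individuals number of individuals.
#' @param panel a `snp_panel` (see [load_snp_panel()]); column order of the
#'   output follows the panel.
#' @param maf per-SNP minor-allele frequency in `(0, 0.5]`; recycled to the
#'   panel length (default 0.3).
#' @param missing_rate probability of a missing call, in `[0, 0.1]`.
#' @param seed optional integer seed.
#' @return A `genotype_matrix`: integer matrix individuals x SNPs with values
#'   0/1/2/NA (copies of the panel risk allele), rsIDs as column names,
#'   individual IDs as row names, and attributes `panel` and `maf`.
#' @export
#' @examples
#' g <- generate_genotypes(50, load_snp_panel(), maf = 0.3, seed = 1)
#' mean(g, na.rm = TRUE) # approx 2 * 0.3
generate_genotypes <- function(n_individuals, panel, maf = 0.3,
                               missing_rate = 0, seed = NULL) {
  stopifnot(is_num1(n_individuals), n_individuals >= 1)
  validate_snp_panel(panel)
  m <- nrow(panel)
  maf <- rep_len(maf, m)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (!is_num1(missing_rate) || missing_rate < 0 || missing_rate > 0.1) {
    stop("missing_rate must lie in [0, 0.1]")
  }
  maybe_seed(seed)
  n <- as.integer(n_individuals)
  dosage <- vapply(seq_len(m), function(j) rbinom(n, 2L, maf[j]),
                   integer(n))
  dosage <- matrix(as.integer(dosage), nrow = n, ncol = m)
  if (missing_rate > 0) {
    dosage[runif(length(dosage)) < missing_rate] <- NA_integer_
  }
  dimnames(dosage) <- list(sprintf("S%03d", seq_len(n)), panel$rsid)
  structure(dosage, panel = panel, maf = maf,
            class = c("genotype_matrix", class(dosage)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype dosage matrix: %d individuals x %d SNPs (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Write / read a dosage matrix as TSV
#'
#' The TSV has individuals in rows (first column `individual_id`) and one
#' column per rsID; missing calls are empty cells.
#' @param genotypes matrix of dosages with dimnames.
#' @param path output file.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  m <- genotypes
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  df <- data.frame(individual_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  class(m) <- c("genotype_matrix", class(m))
  m
}

#' Write genotypes as a minimal VCF
#'
#' Emits a minimal VCFv4.2 with GT fields.  ALT is the panel risk allele
#' where available (so ALT dosage equals risk-allele dosage); REF is an
#' arbitrary other base.  Positions are synthetic placeholders (the panel
#' carries no coordinates).
#'
#' @param genotypes a `genotype_matrix`.
#' @param panel matching `snp_panel`.
#' @param path output `.vcf` (plain text).
#' @export
write_vcf_genotypes <- function(genotypes, panel, path) {
  validate_snp_panel(panel)
  stopifnot(identical(colnames(genotypes), panel$rsid))
  alt <- ifelse(is.na(panel$risk_allele), "A", panel$risk_allele)
  ref <- ifelse(alt == "G", "T", "G")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  gt_of <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  body <- vapply(seq_len(nrow(panel)), function(j) {
    d <- genotypes[, j]
    gt <- ifelse(is.na(d), "./.", gt_of[as.character(d)])
    paste(c("1", as.character(j * 1000L), panel$rsid[j], ref[j], alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF, oriented to the panel risk allele
#'
#' Uses `vcfR` to parse the VCF and returns dosages counted in copies of the
#' panel risk allele (for panel SNPs without a risk allele, copies of ALT).
#' SNPs are returned in panel order; panel SNPs absent from the VCF error.
#'
#' @param path VCF path.
#' @param panel `snp_panel`.
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path, panel) {
  validate_snp_panel(panel)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  if (!all(panel$rsid %in% ids)) {
    stop("VCF is missing panel SNPs: ",
         paste(setdiff(panel$rsid, ids), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  names(alt) <- ids
  count_alt <- function(s) {
    if (is.na(s)) return(NA_integer_)
    sum(strsplit(s, "[/|]")[[1]] == "1")
  }
  dosage <- t(apply(gt[panel$rsid, , drop = FALSE], c(1, 2),
                    function(s) count_alt(s)))
  # orient: if a risk allele is declared and differs from ALT, flip
  flip <- !is.na(panel$risk_allele) & alt[panel$rsid] != panel$risk_allele
  dosage[, flip] <- 2L - dosage[, flip]
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- panel$rsid
  structure(dosage, panel = panel,
            class = c("genotype_matrix", class(dosage)))
}
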