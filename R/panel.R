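#' Load a SNP panel table
#'
#' Reads a panel CSV with columns `rsid`, `gene`, `risk_allele` and `source`
#' (`"dyslexia_candidate"` or `"mmr_candidate"`).  The packaged default panel
#' contains the 25 independent dyslexia-candidate SNPs across 10 genes plus
#' the two SNPs previously reported for the late MMR component (rs11100040,
#' rs4234898).  The rsIDs and gene assignments follow the published candidate
#' lists; the `risk_allele` column of the packaged file holds *synthetic*
#' placeholder alleles (the literature risk-allele table is not distributed
#' with the package), with 5 of the 25 candidates carrying no risk allele so
#' that exactly 20 SNPs enter the unweighted risk score.
#'
#' @param path CSV path; defaults to the packaged panel.
#' @return A data frame of class `snp_panel`.
#' @export
#' @examples
#' panel <- load_snp_panel()
#' table(panel$source)
load_snp_panel <- function(path = system.file("extdata", "snp_panel.csv",
                                              package = "latemmr")) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  validate_snp_panel(p)
  class(p) <- c("snp_panel", "data.frame")
  p
}

#' Validate a SNP panel
#'
#' Checks column presence, rsID uniqueness and allele coding.
#' @param p panel data frame.
#' @return `TRUE`, invisibly.
#' @export
validate_snp_panel <- function(p) {
  need <- c("rsid", "gene", "risk_allele", "source")
  if (!all(need %in% names(p))) {
    stop("panel must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(p$rsid)) stop("duplicated rsIDs in panel")
  ok <- is.na(p$risk_allele) | p$risk_allele %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("risk_allele must be A/C/G/T or NA")
  if (!all(p$source %in% c("dyslexia_candidate", "mmr_candidate"))) {
    stop("source must be dyslexia_candidate or mmr_candidate")
  }
  invisible(TRUE)
}
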