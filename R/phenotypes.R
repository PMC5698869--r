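#' Simulate spelling phenotypes from genotypes
#'
#' Builds a latent spelling score as an optional genetic liability (a linear
#' combination of risk-allele dosages) plus Gaussian noise, converts it to a
#' spelling percentile, and flags poor spellers as the lowest decile
#' (`spelling_percentile <= 10`).  Two percentile conventions are supported:
#'
#' * `"empirical"` (default): within-sample mid-rank percentile
#'   `100 * (rank - 0.5) / n`; flags 10% of the sample (up to rounding).
#' * `"norm"`: percentile against a reference population `N(norm_mean,
#'   norm_sd^2)`, emulating norm-referenced spelling tests where the flagged
#'   fraction of a given sample may deviate from 10%.
#'
#' Attention-deficit-disorder (ADD) status is drawn independently with
#' probability `add_rate`.
#'
#' @param genotypes a `genotype_matrix` (missing dosages are mean-imputed in
#'   the liability).
#' @param spelling_model list with elements `beta` (named per-SNP liability
#'   weights on the spelling score; default none), `noise_sd` (default 1),
#'   `percentile` (`"empirical"` or `"norm"`), `norm_mean`, `norm_sd`,
#'   `add_rate` (default 12/67).
#' @param seed optional integer seed.
#' @return A `phenotype_table` data frame: `individual_id`,
#'   `spelling_percentile`, `poor_speller`, `add_status`.
#' @export
#' @examples
#' g <- generate_genotypes(100, load_snp_panel(), seed = 1)
#' ph <- generate_phenotypes(g, seed = 2)
#' sum(ph$poor_speller) # 10
generate_phenotypes <- function(genotypes,
                                spelling_model = list(),
                                seed = NULL) {
  n <- nrow(genotypes)
  if (n < 10) stop("need at least 10 individuals for the decile rule")
  sm <- modifyList(list(beta = NULL, noise_sd = 1,
                        percentile = "empirical",
                        norm_mean = 0, norm_sd = 1,
                        add_rate = 12 / 67), spelling_model)
  maybe_seed(seed)

  liability <- numeric(n)
  if (!is.null(sm$beta) && length(sm$beta)) {
    if (is.null(names(sm$beta)) ||
        !all(names(sm$beta) %in% colnames(genotypes))) {
      stop("spelling_model$beta must be named with panel rsIDs")
    }
    X <- genotypes[, names(sm$beta), drop = FALSE]
    X <- apply(X, 2, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      col
    })
    liability <- drop(X %*% sm$beta)
  }
  latent <- liability + rnorm(n, 0, sm$noise_sd)

  pct <- switch(sm$percentile,
    empirical = 100 * (rank(latent, ties.method = "first") - 0.5) / n,
    norm = 100 * pnorm(latent, sm$norm_mean, sm$norm_sd),
    stop("percentile must be 'empirical' or 'norm'"))

  out <- data.frame(individual_id = rownames(genotypes) %||%
                      sprintf("S%03d", seq_len(n)),
                    spelling_percentile = pct,
                    poor_speller = pct <= 10,
                    add_status = as.logical(rbinom(n, 1, sm$add_rate)),
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  attr(out, "latent") <- latent
  out
}

#' Write / read a phenotype table as TSV
#' @param phenotypes a `phenotype_table`.
#' @param path file path.
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  utils::write.table(as.data.frame(phenotypes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$poor_speller <- as.logical(df$poor_speller)
  df$add_status <- as.logical(df$add_status)
  class(df) <- c("phenotype_table", "data.frame")
  df
}
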