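default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = "latemmr_run",
    simulate = list(
      enabled = TRUE,
      n_subjects = 67,
      blocks = 2,
      n_total = 600,
      n_deviant = 90,
      min_spacing = 2,
      isi_range_ms = c(1450, 1750),
      fs_hz = 500,
      maf = 0.3,
      missing_rate = 0.01,
      prs_liability = -0.2,
      noise_amplitude_uv = 12,
      artifact_rate = 0.2
    ),
    erp = list(
      lowpass_hz = 30,
      highpass_hz = 0.5,
      resample_hz = 250,
      reject_threshold_uv = 80,
      reject_window_ms = 200,
      reject_criterion = "absolute",
      contrast = "pooled"
    ),
    qc = list(
      hwe_alpha = 0.05,
      snp_call_rate_min = 0.97,
      ind_call_rate_min = 0.90,
      maf_min = 0.05
    ),
    assoc = list(
      covariates = "poor_speller",
      compare_add_adjustment = TRUE
    ),
    predict = list(
      ci_method = "delong"
    ),
    power = list(
      alpha = c(0.05, 0.01, 0.001),
      target_power = 0.8,
      u = 1,
      v = 52,
      method = "normal_approx"
    )
  )
}

# recursive merge with unknown-key rejection
merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (path == "") k else paste0(path, "$", k)
    if (!k %in% names(defaults)) stop("unknown config key: ", full)
    if (is.list(defaults[[k]]) && !is.null(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]), full)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' Nested configuration for the end-to-end run with the study defaults
#' (two 600-trial blocks with 90 deviants, ISI 1450--1750 ms, 500 Hz, 20%
#' artifact trials, 67 subjects, the published QC thresholds and the
#' detectable-effect power preset).  Unknown keys are rejected; values
#' round-trip unchanged through YAML serialization
#' ([write_pipeline_config()]).
#'
#' @param file optional YAML file of overrides.
#' @param ... named overrides (nested lists), applied after the file.
#' @return list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(simulate = list(n_subjects = 8))
pipeline_config <- function(file = NULL, ...) {
  cfg <- default_pipeline_config()
  if (!is.null(file)) cfg <- merge_config(cfg, yaml::read_yaml(file))
  dots <- list(...)
  if (length(dots)) cfg <- merge_config(cfg, dots)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Sequences the stages simulate (optional) -> ERP reduction -> genotype QC
#' -> association -> prediction -> power -> report, writing every stage
#' table as TSV under `config$out_dir` and collecting a run manifest
#' (configuration hash, seed, per-file MD5 digests, timestamps, completed
#' stages).  Any stage error is re-raised prefixed with the stage name;
#' files written before the failure remain on disk and the manifest (also
#' saved as `manifest.yaml`) marks the run incomplete.
#'
#' @param config a [pipeline_config()].
#' @param inputs when `config$simulate$enabled` is `FALSE`, named paths
#'   `mmr`, `genotypes`, `phenotypes` (TSVs in the formats written by the
#'   simulate/ERP stages).
#' @return list of class `run_manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- load_snp_panel()
  stages_done <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(force(expr),
                    error = function(e) stop_stage(name, conditionMessage(e)))
    stages_done <<- c(stages_done, name)
    res
  }
  save_manifest <- function(complete) {
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!grepl("manifest\\.yaml$", files)]
    man <- list(package_version = as.character(utils::packageVersion("latemmr")),
                config_hash = config_hash(config),
                seed = config$seed,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stages = stages_done,
                complete = complete,
                digests = as.list(setNames(unname(tools::md5sum(files)),
                                           basename(files))))
    yaml::write_yaml(man, file.path(out_dir, "manifest.yaml"))
    class(man) <- c("run_manifest", "list")
    man
  }
  on.exit(save_manifest(FALSE))

  sim <- config$simulate
  if (isTRUE(sim$enabled)) {
    simdat <- stage("simulate", {
      genotypes <- generate_genotypes(sim$n_subjects, panel, maf = sim$maf,
                                      missing_rate = sim$missing_rate,
                                      seed = child_seed(config$seed, 1))
      scored <- panel$rsid[!is.na(panel$risk_allele)]
      beta <- setNames(rep(sim$prs_liability, length(scored)), scored)
      phenotypes <- generate_phenotypes(
        genotypes, spelling_model = list(beta = beta),
        seed = child_seed(config$seed, 2))
      template <- erp_template_model(
        noise = list(exponent = 1, amplitude_uv = sim$noise_amplitude_uv,
                     alpha_uv = 3),
        artifact_rate = sim$artifact_rate)
      dataset <- generate_eeg_dataset(
        phenotypes, genotypes, template, blocks = seq_len(sim$blocks),
        fs_hz = sim$fs_hz, seed = child_seed(config$seed, 3),
        n_total = sim$n_total, n_deviant = sim$n_deviant,
        min_spacing = sim$min_spacing, isi_range_ms = sim$isi_range_ms)
      write_dosage_tsv(genotypes, file.path(out_dir, "genotypes.tsv"))
      write_vcf_genotypes(genotypes, panel,
                          file.path(out_dir, "genotypes.vcf"))
      write_phenotype_tsv(phenotypes, file.path(out_dir, "phenotypes.tsv"))
      list(genotypes = genotypes, phenotypes = phenotypes, dataset = dataset)
    })
    erp_cfg <- preprocess_config(
      lowpass_hz = config$erp$lowpass_hz,
      highpass_hz = config$erp$highpass_hz,
      resample_hz = config$erp$resample_hz,
      reject_threshold_uv = config$erp$reject_threshold_uv,
      reject_window_ms = config$erp$reject_window_ms,
      reject_criterion = config$erp$reject_criterion,
      contrast = config$erp$contrast)
    erp <- stage("erp", {
      res <- erp_process_dataset(simdat$dataset, erp_cfg)
      write_tsv(res$mmr_table, file.path(out_dir, "mmr.tsv"))
      res
    })
    genotypes <- simdat$genotypes
    phenotypes <- simdat$phenotypes
    mmr_table <- erp$mmr_table
    diff_waves <- erp$diff_waves
  } else {
    loaded <- stage("load", {
      need <- c("mmr", "genotypes", "phenotypes")
      missing <- setdiff(need, names(inputs %||% list()))
      if (length(missing)) {
        stop("missing input file(s): ", paste(missing, collapse = ", "))
      }
      for (f in unlist(inputs[need])) {
        if (!file.exists(f)) stop("input file not found: ", f)
      }
      list(mmr_table = utils::read.table(inputs$mmr, header = TRUE,
                                         sep = "\t",
                                         stringsAsFactors = FALSE),
           genotypes = read_dosage_tsv(inputs$genotypes),
           phenotypes = read_phenotype_tsv(inputs$phenotypes))
    })
    mmr_table <- loaded$mmr_table
    genotypes <- loaded$genotypes
    attr(genotypes, "panel") <- panel[panel$rsid %in% colnames(genotypes), ]
    phenotypes <- loaded$phenotypes
    diff_waves <- NULL
  }

  qcres <- stage("qc", {
    th <- qc_thresholds(hwe_alpha = config$qc$hwe_alpha,
                        snp_call_rate_min = config$qc$snp_call_rate_min,
                        ind_call_rate_min = config$qc$ind_call_rate_min,
                        maf_min = config$qc$maf_min)
    r <- apply_qc(genotypes, th)
    write_tsv(r$report$snps, file.path(out_dir, "qc_snps.tsv"))
    write_tsv(r$report$individuals, file.path(out_dir, "qc_individuals.tsv"))
    r
  })

  assoc <- stage("assoc", {
    a <- assoc_scan(mmr_table, qcres$genotypes, phenotypes,
                    covariates = config$assoc$covariates)
    out <- a
    if (isTRUE(config$assoc$compare_add_adjustment) &&
        "add_status" %in% names(phenotypes)) {
      a_add <- assoc_scan(mmr_table, qcres$genotypes, phenotypes,
                          covariates = c(config$assoc$covariates,
                                         "add_status"))
      write_tsv(compare_covariate_adjustment(a, a_add),
                file.path(out_dir, "assoc_add_adjustment.tsv"))
    }
    write_tsv(as.data.frame(out), file.path(out_dir, "assoc.tsv"))
    out
  })

  pred <- stage("predict", {
    prs <- compute_prs(qcres$genotypes,
                       attr(qcres$genotypes, "panel") %||% panel)
    ids <- mmr_table$subject_id
    keep <- ids %in% rownames(qcres$genotypes)
    cmp <- compare_models(
      mmr_table$mmr_uv[keep],
      prs[match(ids[keep], rownames(qcres$genotypes))],
      phenotypes$poor_speller[match(ids[keep], phenotypes$individual_id)],
      ci_method = config$predict$ci_method)
    write_tsv(data.frame(
      model = c("mmr", "prs", "mmr_prs"),
      auc = c(cmp$auc_mmr$auc, cmp$auc_prs$auc, cmp$auc_combined$auc),
      ci_lower = c(cmp$auc_mmr$ci[1], cmp$auc_prs$ci[1],
                   cmp$auc_combined$ci[1]),
      ci_upper = c(cmp$auc_mmr$ci[2], cmp$auc_prs$ci[2],
                   cmp$auc_combined$ci[2])),
      file.path(out_dir, "prediction_auc.tsv"))
    jsonlite::write_json(
      list(nri_cont = cmp$nri$nri, nri_p = cmp$nri$p,
           idi = cmp$idi_result$idi, idi_p = cmp$idi_result$p),
      file.path(out_dir, "reclassification.json"),
      auto_unbox = TRUE, digits = NA)
    cmp
  })

  stage("power", {
    rows <- lapply(config$power$alpha, function(a) {
      r <- required_effect_size(a, config$power$target_power,
                                config$power$u, config$power$v,
                                config$power$method)
      data.frame(alpha = a, power = config$power$target_power,
                 r2_explained = r$r2_explained, f2 = r$f2,
                 lambda = r$ncp_lambda)
    })
    write_tsv(do.call(rbind, rows), file.path(out_dir, "power.tsv"))
  })

  stage("report", {
    render_report(out_dir, assoc = assoc, diff_waves = diff_waves,
                  phenotypes = phenotypes, mmr_table = mmr_table,
                  genotypes = qcres$genotypes)
  })

  on.exit()
  man <- save_manifest(TRUE)
  man
}

#' Render figures and tables from pipeline artifacts
#'
#' Emits the report layer: the association table (columns `snp`, `p`,
#' `fdr`, `beta`, `gene`), a QQ plot with the order-statistic envelope, the
#' group difference-wave figure with confidence bands (when waves are
#' available), and per-SNP genotype boxplots for the nominally associated
#' SNPs.  Figures are PDF files under `out_dir`.
#'
#' @param out_dir output directory.
#' @param assoc an `mmr_assoc` table.
#' @param diff_waves optional named list of `difference_wave` per subject.
#' @param phenotypes `phenotype_table` (groups for the wave figure).
#' @param mmr_table per-subject MMR table (boxplots).
#' @param genotypes filtered `genotype_matrix` (boxplots).
#' @return invisible character vector of files written.
#' @export
render_report <- function(out_dir, assoc, diff_waves = NULL,
                          phenotypes = NULL, mmr_table = NULL,
                          genotypes = NULL) {
  written <- character(0)
  cand <- assoc[assoc$family == "candidate" & !assoc$untestable, ]
  tab <- data.frame(snp = cand$snp, p = cand$p, fdr = cand$fdr_q,
                    beta = cand$beta, gene = cand$gene)
  written <- c(written, write_tsv(tab, file.path(out_dir,
                                                 "association_table.tsv")))
  if (nrow(cand) == 0) {
    warning("no testable SNP results; QQ plot skipped")
  } else {
    f <- file.path(out_dir, "qq_plot.pdf")
    pdf(f, width = 5, height = 5)
    plot_qq(cand$p, m = nrow(cand))
    dev.off()
    written <- c(written, f)
  }
  if (!is.null(diff_waves) && !is.null(phenotypes)) {
    poor_ids <- phenotypes$individual_id[phenotypes$poor_speller]
    groups <- list(
      `poor spellers` = diff_waves[names(diff_waves) %in% poor_ids],
      `controls` = diff_waves[!names(diff_waves) %in% poor_ids])
    if (all(lengths(groups) >= 2)) {
      f <- file.path(out_dir, "difference_waves.pdf")
      pdf(f, width = 7, height = 5)
      plot_difference_waves(groups)
      dev.off()
      written <- c(written, f)
    }
  }
  if (!is.null(mmr_table) && !is.null(genotypes) && nrow(cand)) {
    top <- cand$snp[cand$p < 0.05]
    top <- intersect(top, colnames(genotypes))
    if (length(top)) {
      f <- file.path(out_dir, "genotype_boxplots.pdf")
      pdf(f, width = 3 * length(top), height = 4)
      g <- genotypes[match(mmr_table$subject_id, rownames(genotypes)), ,
                     drop = FALSE]
      plot_genotype_boxplots(mmr_table$mmr_uv, g, top)
      dev.off()
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("latemmr run (%s): %s\n", x$timestamp,
              if (isTRUE(x$complete)) "complete" else "INCOMPLETE"))
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat("  config hash:", x$config_hash, "\n")
  cat(sprintf("  %d artifact(s) digested\n", length(x$digests)))
  invisible(x)
}
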