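#' Write a synthetic dataset to disk
#'
#' Emits the generator outputs as plain-text tables: counts TSV (libraries x
#' taxa), sample metadata TSV, glycome CSV, covariates CSV, PRS CSV and the
#' planted truth as YAML.
#'
#' @param dataset a [simulate_dataset] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_synth_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  utils::write.table(data.frame(library_id = rownames(dataset$counts),
                                dataset$counts, check.names = FALSE),
                     fp("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$samples, fp("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(individual_id = rownames(dataset$glycome),
                              dataset$glycome, check.names = FALSE),
                   fp("glycome.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$covariates, fp("covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$prs, fp("prs.csv"), row.names = FALSE, quote = FALSE)
  truth <- dataset$truth
  truth$batch_offsets <- NULL  # large matrix; regenerate from the seed
  yaml::write_yaml(truth, fp("truth.yaml"))
  invisible(vapply(c("counts.tsv", "samples.tsv", "glycome.csv",
                     "covariates.csv", "prs.csv", "truth.yaml"), fp, ""))
}

#' Run the full microbiome-glycome analysis chain
#'
#' Orchestrates: synthetic-data generation (or a supplied dataset),
#' contaminant detection, coverage/abundance filtering, zero imputation, CLR
#' transformation, mixed-model batch correction, per-individual profile
#' averaging, microbial PCA, glycan-peak harmonization and trait
#' computation, alpha/beta diversity analyses, effective-test estimation,
#' the univariate association scan with Sidak correction, and the
#' PRS-instrument regression stage.
#'
#' @param config a [synth_config]; all randomness funnels through
#'   `config$seed`.
#' @param dataset optional pre-built [simulate_dataset] result (otherwise
#'   simulated from `config`).
#' @param out_dir optional directory for CSV/YAML outputs.
#' @param B permutation count for PERMANOVA/Mantel/Procrustes (default 9999).
#' @param do_batch_correct run the mixed-model batch correction (default
#'   TRUE).
#' @param n_pcs microbial/glycan PCs computed (default 10); the first
#'   `pc_covariates` of the microbial PCs enter the association models.
#' @param pc_covariates number of microbial PCs used as covariates
#'   (default 4).
#' @param allowlist gut-taxa allowlist for rules R3/R4; defaults to the
#'   dataset's generated allowlist (or [gut_allowlist] for real data).
#' @return list of class `glycomicrobe_run` with every stage's result and a
#'   machine-readable `summary`.
#' @export
run_pipeline <- function(config = synth_config(), dataset = NULL,
                         out_dir = NULL, B = 9999, do_batch_correct = TRUE,
                         n_pcs = 10L, pc_covariates = 4L, allowlist = NULL) {
  if (is.null(dataset)) dataset <- simulate_dataset(config)
  counts <- dataset$counts
  samples <- dataset$samples
  if (is.null(allowlist))
    allowlist <- dataset$truth$gut_allowlist %||% gut_allowlist()

  ## genera never observed cannot be imputed or classified
  seen <- colSums(counts) > 0
  counts <- counts[, seen, drop = FALSE]

  report <- detect_contaminants(counts, samples, dataset$covariates, allowlist)
  filt <- filter_libraries_and_taxa(counts, samples, report)
  rel <- impute_zeros(filt$counts)
  clrm <- clr_transform(rel)
  if (do_batch_correct) clrm <- batch_correct(clrm, filt$samples)
  avg <- average_profiles(clrm, filt$samples)

  ## per-individual alpha diversity: mean of per-library Shannon indices
  h_lib <- shannon_index(rel)
  h_ind <- tapply(h_lib, filt$samples$individual_id[
    match(names(h_lib), filt$samples$library_id)], mean)

  gp <- harmonize_peaks(total_area_normalize(dataset$glycome))
  traits <- compute_traits(gp)

  ids <- Reduce(intersect, list(rownames(avg), rownames(traits),
                                dataset$covariates$individual_id))
  avg <- avg[ids, , drop = FALSE]
  traits <- traits[ids, , drop = FALSE]
  cov <- dataset$covariates[match(ids, dataset$covariates$individual_id), ]
  h_ind <- h_ind[ids]

  mpca <- microbial_pca(avg, k = n_pcs)
  gpca <- glycan_pca(traits, k = n_pcs)

  m_gly <- effective_tests_galwey(traits, "glycome")
  m_gen <- effective_tests_galwey(avg, "genus")
  m_scan <- combine_effective(m_gly, m_gen, block = "glycome x genus")

  scan <- assoc_scan(avg, traits, cov,
                     mpca$scores[, seq_len(pc_covariates), drop = FALSE],
                     m_eff = m_scan)
  enrich <- enrichment_test(scan)
  alpha <- alpha_association(h_ind, traits, cov, m_gly)
  beta_pc <- beta_pc_association(mpca$scores, traits, cov, m_gly)

  ## PERMANOVA of interindividual variation on library-level distances
  ## (location/amplicon means are absorbed by the batch correction, so the
  ## individual grouping is the meaningful beta-diversity contrast here)
  seed <- config$seed
  ind_lib <- filt$samples$individual_id[
    match(rownames(clrm), filt$samples$library_id)]
  multi <- ind_lib %in% names(which(table(ind_lib) >= 2))
  d_micro_lib <- aitchison_dist(clrm[multi, , drop = FALSE])
  perma <- permanova(d_micro_lib, ind_lib[multi], B = B, seed = seed)
  d_micro <- aitchison_dist(avg)
  d_gly <- stats::dist(traits)
  mant <- mantel_test(d_micro, d_gly, B = B, seed = seed)
  procr <- procrustes_test(mpca$scores, gpca$scores, B = B, seed = seed)

  mr <- NULL
  pe <- dataset$truth$true_effects
  if (!is.null(pe) && nrow(pe) && pe$taxon[1] %in% colnames(avg)) {
    prs <- dataset$prs
    pv <- prs$prs[match(ids, prs$individual_id)]
    mr <- mr_stage(pv, avg[, pe$taxon[1]], cov, taxon = pe$taxon[1],
                   trait_name = prs$trait[1])
  }

  top <- scan[order(scan$p_nominal), ][seq_len(min(5L, nrow(scan))), ]
  summary <- list(
    seed = seed,
    n_libraries_input = nrow(dataset$counts),
    n_taxa_input = ncol(dataset$counts),
    n_contaminants_flagged = sum(report$contaminant),
    n_libraries_after_filter = nrow(filt$counts),
    n_taxa_after_filter = ncol(filt$counts),
    n_individuals = length(ids),
    n_traits = ncol(traits),
    m_eff_glycome = m_gly$m_eff,
    m_eff_genus = m_gen$m_eff,
    m_eff_product = m_scan$m_eff,
    n_pairs_tested = nrow(scan),
    n_nominal_hits = enrich$k,
    enrichment_p = enrich$p_binomial,
    permanova_individual_p = perma$p,
    mantel_r = mant$r, mantel_p = mant$p,
    procrustes_correlation = procr$correlation, procrustes_p = procr$p,
    top_associations = lapply(seq_len(nrow(top)), function(i)
      list(taxon = top$taxon[i], trait = top$trait[i],
           beta = top$beta[i], p_nominal = top$p_nominal[i],
           p_sidak = top$p_sidak[i])),
    mr_beta = if (!is.null(mr)) mr$beta else NA,
    mr_p = if (!is.null(mr)) mr$p_nominal else NA)

  out <- structure(list(report = report, clr = avg, micro_pca = mpca,
                        glycan_pca = gpca, traits = traits, scan = scan,
                        alpha = alpha, beta_pc = beta_pc, permanova = perma,
                        mantel = mant, procrustes = procr, mr = mr,
                        m_eff = list(glycome = m_gly, genus = m_gen,
                                     product = m_scan),
                        enrichment = enrich, summary = summary,
                        samples = filt$samples),
                   class = "glycomicrobe_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "contaminant_report.csv"),
                     row.names = FALSE)
    utils::write.table(data.frame(individual_id = rownames(avg), avg,
                                  check.names = FALSE),
                       file.path(out_dir, "clr_by_individual.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(data.frame(individual_id = rownames(mpca$scores),
                                mpca$scores, check.names = FALSE),
                     file.path(out_dir, "micro_pca_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(scan[c("level", "taxon", "trait", "n", "beta", "se",
                            "p_nominal", "p_sidak")],
                     file.path(out_dir, "associations.csv"),
                     row.names = FALSE)
    yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  }
  out
}

#' @export
print.glycomicrobe_run <- function(x, ...) {
  s <- x$summary
  cat("glycomicrobe run (seed ", s$seed, ")\n",
      "  libraries: ", s$n_libraries_input, " -> ", s$n_libraries_after_filter,
      "; taxa: ", s$n_taxa_input, " -> ", s$n_taxa_after_filter, "\n",
      "  contaminants flagged: ", s$n_contaminants_flagged, "\n",
      "  M_eff glycome x genus: ", s$m_eff_glycome, " x ", s$m_eff_genus,
      " = ", s$m_eff_product, "\n",
      "  pairs tested: ", s$n_pairs_tested, " (", s$n_nominal_hits,
      " nominal hits)\n", sep = "")
  invisible(x)
}
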