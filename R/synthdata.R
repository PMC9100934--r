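#' Configuration for the synthetic multi-omics generator
#'
#' Describes the study design the generator emulates: individuals sampled at
#' three gut locations (ileum, transversum, rectum), each location profiled
#' with three 16S amplicons (V1V2, V3V4, V5V6), libraries spread over
#' sequencing runs with taxon-specific batch offsets, a subset of
#' sample-location combinations sequenced in biological replicate, and three
#' planted contaminant mechanisms:
#' \describe{
#'   \item{depth_inverse}{a fixed absolute read count per library, so relative
#'     abundance falls with coverage depth (reagent contamination);}
#'   \item{replicate_inconsistent}{abundance redrawn independently in every
#'     library, so biological replicates disagree;}
#'   \item{run_specific}{present only in a designated subset of runs.}
#' }
#'
#' @param n_individuals number of individuals (default 200).
#' @param n_taxa number of genera (default 150).
#' @param n_contaminants_per_mechanism planted contaminants per mechanism
#'   (default 5).
#' @param n_replicated_pairs number of (individual, location) combinations
#'   sequenced twice across all amplicons (default 25).
#' @param locations,amplicons design vocabularies.
#' @param n_runs number of sequencing runs (default 9); every library is
#'   assigned a run at random so runs cross location-amplicon strata.
#' @param coverage_range integer range of reads per library
#'   (default 5000-50000).
#' @param batch_effect_sd SD of per-(run, location, amplicon), per-taxon
#'   log-abundance offsets (default 0.5).
#' @param planted_effects data.frame with columns taxon, trait (an original
#'   glycan peak label, e.g. "P10"), beta. The default plants one effect of
#'   beta = 1 of the abundant genus "Genus_003" on peak "P10". Use
#'   `planted_effects = NULL` for a global null.
#' @param seed integer seed; fixed seed reproduces every table bit-for-bit.
#' @param sd_individual,sd_location,sd_amplicon,sd_date,sd_noise SDs of the
#'   log-abundance effect layers (individual, location, amplicon, collection
#'   date, residual library noise).
#' @param n_dates number of collection-date batches (default 20).
#' @param depth_count expected absolute reads of a depth_inverse contaminant
#'   per library (default 80).
#' @param runspec_rel relative abundance of a run_specific contaminant in its
#'   designated runs (default 0.003).
#' @param repinc_rel,repinc_sd median relative abundance and log-SD of a
#'   replicate_inconsistent contaminant (defaults 0.002, 1.5).
#' @param n_peaks number of original glycan peaks (39).
#' @param glycome_sd SD of the per-peak logistic-normal latent noise
#'   (default 0.5).
#' @param prs_r correlation between the polygenic score and its designated
#'   glycan trait (default 0.3).
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_individuals = 200L, n_taxa = 150L,
                         n_contaminants_per_mechanism = 5L,
                         n_replicated_pairs = 25L,
                         locations = c("ileum", "transversum", "rectum"),
                         amplicons = c("V1V2", "V3V4", "V5V6"),
                         n_runs = 9L, coverage_range = c(5000L, 50000L),
                         batch_effect_sd = 0.5,
                         planted_effects = data.frame(
                           taxon = "Genus_003", trait = "P10", beta = 1.0,
                           stringsAsFactors = FALSE),
                         seed = 1L,
                         sd_individual = 1.0, sd_location = 0.5,
                         sd_amplicon = 0.5, sd_date = 0.3, sd_noise = 0.3,
                         n_dates = 20L, depth_count = 80,
                         runspec_rel = 0.003, repinc_rel = 0.002,
                         repinc_sd = 1.5, n_peaks = 39L, glycome_sd = 0.5,
                         prs_r = 0.3) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_taxa = as.integer(n_taxa),
              n_contaminants_per_mechanism = as.integer(n_contaminants_per_mechanism),
              n_replicated_pairs = as.integer(n_replicated_pairs),
              locations = locations, amplicons = amplicons,
              n_runs = as.integer(n_runs),
              coverage_range = as.integer(coverage_range),
              batch_effect_sd = batch_effect_sd,
              planted_effects = planted_effects, seed = as.integer(seed),
              sd_individual = sd_individual, sd_location = sd_location,
              sd_amplicon = sd_amplicon, sd_date = sd_date,
              sd_noise = sd_noise, n_dates = as.integer(n_dates),
              depth_count = depth_count, runspec_rel = runspec_rel,
              repinc_rel = repinc_rel, repinc_sd = repinc_sd,
              n_peaks = as.integer(n_peaks), glycome_sd = glycome_sd,
              prs_r = prs_r)
  n_cont <- 3L * cfg$n_contaminants_per_mechanism
  if (n_cont >= cfg$n_taxa)
    stop("contradictory config: ", n_cont, " contaminants but only ",
         cfg$n_taxa, " taxa")
  if (any(cfg$coverage_range <= 0L) || cfg$coverage_range[1] > cfg$coverage_range[2])
    stop("coverage_range must be a positive increasing interval")
  if (cfg$n_individuals < 2L || cfg$n_runs < 1L)
    stop("need at least 2 individuals and 1 run")
  if (abs(cfg$prs_r) > 1) stop("prs_r must lie in [-1, 1]")
  taxa <- sprintf("Genus_%03d", seq_len(cfg$n_taxa))
  if (!is.null(cfg$planted_effects) && nrow(cfg$planted_effects)) {
    pe <- cfg$planted_effects
    if (!all(c("taxon", "trait", "beta") %in% names(pe)))
      stop("planted_effects needs columns taxon, trait, beta")
    if (!all(pe$taxon %in% taxa))
      stop("planted taxon not among generated taxa: ",
           paste(setdiff(pe$taxon, taxa), collapse = ", "))
    pk <- sprintf("P%d", seq_len(cfg$n_peaks))
    if (!all(pe$trait %in% pk))
      stop("planted trait not among generated peaks: ",
           paste(setdiff(pe$trait, pk), collapse = ", "))
  }
  structure(cfg, class = "synth_config")
}

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

#' Simulate a genus-level 16S count table with planted structure
#'
#' Draws one library per individual x location x amplicon (plus replicate
#' pairs). Per-library clean-taxon compositions follow
#' exp(base + individual + location + amplicon + run-batch + date + noise)
#' renormalized; contaminant taxa are injected by mechanism (see
#' [synth_config]) and clean counts drawn multinomially from the remaining
#' coverage, so every row sums exactly to the library coverage.
#'
#' @param config a [synth_config] object.
#' @return list of class `synth_microbiome` with elements
#'   \describe{
#'     \item{counts}{integer matrix, libraries x taxa;}
#'     \item{samples}{data.frame of library metadata (library_id,
#'       individual_id, location, amplicon, run, collection_date, coverage,
#'       replicate_group, negative_control);}
#'     \item{truth}{list recording contaminant taxa per mechanism, designated
#'       runs, per-cell batch offsets, planted effects, the gut allowlist
#'       (all clean genera) and the seed.}
#'   }
#' @export
simulate_microbiome <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cfg <- config
  taxa <- sprintf("Genus_%03d", seq_len(cfg$n_taxa))
  inds <- sprintf("I%03d", seq_len(cfg$n_individuals))

  ## deterministic rank-abundance baseline (most abundant genus first)
  base <- seq(0, -7, length.out = cfg$n_taxa)
  names(base) <- taxa

  ## contaminants drawn from the rarer two thirds, never a planted taxon
  planted_taxa <- if (is.null(cfg$planted_effects)) character(0) else
    unique(cfg$planted_effects$taxon)
  pool <- setdiff(taxa[-seq_len(ceiling(cfg$n_taxa / 3))], planted_taxa)
  k <- cfg$n_contaminants_per_mechanism
  picked <- if (k > 0L) sample(pool, 3L * k) else character(0)
  contam <- list(depth_inverse = picked[seq_len(k)],
                 replicate_inconsistent = picked[k + seq_len(k)],
                 run_specific = picked[2L * k + seq_len(k)])
  if (k == 0L) contam <- lapply(contam, function(x) character(0))
  clean <- setdiff(taxa, unlist(contam))

  runs <- sprintf("run%02d", seq_len(cfg$n_runs))
  dates <- sprintf("D%02d", seq_len(cfg$n_dates))
  ind_date <- stats::setNames(sample(dates, cfg$n_individuals, replace = TRUE), inds)
  runspec_runs <- lapply(contam$run_specific, function(t)
    sample(runs, max(1L, ceiling(cfg$n_runs / 3))))
  names(runspec_runs) <- contam$run_specific

  ## effect layers (per taxon)
  eff_ind <- matrix(stats::rnorm(cfg$n_individuals * cfg$n_taxa, 0, cfg$sd_individual),
                    cfg$n_individuals, cfg$n_taxa, dimnames = list(inds, taxa))
  eff_loc <- matrix(stats::rnorm(length(cfg$locations) * cfg$n_taxa, 0, cfg$sd_location),
                    length(cfg$locations), cfg$n_taxa,
                    dimnames = list(cfg$locations, taxa))
  eff_amp <- matrix(stats::rnorm(length(cfg$amplicons) * cfg$n_taxa, 0, cfg$sd_amplicon),
                    length(cfg$amplicons), cfg$n_taxa,
                    dimnames = list(cfg$amplicons, taxa))
  eff_date <- matrix(stats::rnorm(cfg$n_dates * cfg$n_taxa, 0, cfg$sd_date),
                     cfg$n_dates, cfg$n_taxa, dimnames = list(dates, taxa))
  cells <- as.vector(outer(outer(runs, cfg$locations, paste, sep = ":"),
                           cfg$amplicons, paste, sep = ":"))
  eff_batch <- matrix(stats::rnorm(length(cells) * cfg$n_taxa, 0, cfg$batch_effect_sd),
                      length(cells), cfg$n_taxa, dimnames = list(cells, taxa))

  ## library layout: full grid + replicated (individual, location) combos
  grid <- expand.grid(individual_id = inds, location = cfg$locations,
                      amplicon = cfg$amplicons, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$replicate <- 1L
  if (cfg$n_replicated_pairs > 0L) {
    combos <- expand.grid(individual_id = inds, location = cfg$locations,
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    sel <- combos[sample(nrow(combos), cfg$n_replicated_pairs), ]
    extra <- merge(sel, data.frame(amplicon = cfg$amplicons), by = NULL)
    extra$replicate <- 2L
    grid <- rbind(grid, extra[names(grid)])
  }
  nl <- nrow(grid)
  grid$library_id <- sprintf("L%04d", seq_len(nl))
  grid$run <- sample(runs, nl, replace = TRUE)
  grid$collection_date <- unname(ind_date[grid$individual_id])
  grid$coverage <- sample(cfg$coverage_range[1]:cfg$coverage_range[2], nl,
                          replace = TRUE)
  key <- paste(grid$individual_id, grid$location, grid$amplicon, sep = ":")
  grid$replicate_group <- ifelse(key %in% key[grid$replicate == 2L], key, NA)
  grid$negative_control <- FALSE

  counts <- matrix(0L, nl, cfg$n_taxa, dimnames = list(grid$library_id, taxa))
  cell_of <- paste(grid$run, grid$location, grid$amplicon, sep = ":")
  dep <- contam$depth_inverse; rs <- contam$run_specific
  ri <- contam$replicate_inconsistent
  for (l in seq_len(nl)) {
    cv <- grid$coverage[l]
    cc <- integer(0)
    if (k > 0L) {
      c_dep <- stats::rpois(length(dep), cfg$depth_count)
      in_run <- vapply(rs, function(t) grid$run[l] %in% runspec_runs[[t]], TRUE)
      c_rs <- ifelse(in_run, stats::rpois(length(rs), cfg$runspec_rel * cv), 0L)
      c_ri <- stats::rpois(length(ri),
                           cfg$repinc_rel * exp(stats::rnorm(length(ri), 0, cfg$repinc_sd)) * cv)
      cc <- c(c_dep, c_rs, c_ri)
      names(cc) <- c(dep, rs, ri)
      tot <- sum(cc)
      if (tot > 0.5 * cv) cc <- floor(cc * (0.5 * cv) / tot)
    }
    z <- base[clean] + eff_ind[grid$individual_id[l], clean] +
      eff_loc[grid$location[l], clean] + eff_amp[grid$amplicon[l], clean] +
      eff_batch[cell_of[l], clean] + eff_date[grid$collection_date[l], clean] +
      stats::rnorm(length(clean), 0, cfg$sd_noise)
    pr <- exp(z - max(z)); pr <- pr / sum(pr)
    counts[l, clean] <- stats::rmultinom(1L, cv - sum(cc), pr)[, 1]
    if (length(cc)) counts[l, names(cc)] <- as.integer(cc)
  }

  truth <- list(contaminant_taxa = contam,
                run_specific_runs = runspec_runs,
                batch_offsets = eff_batch,
                true_effects = cfg$planted_effects,
                gut_allowlist = clean,
                seed = cfg$seed)
  samples <- grid[c("library_id", "individual_id", "location", "amplicon",
                    "run", "collection_date", "coverage", "replicate_group",
                    "negative_control")]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples, truth = truth),
            class = "synth_microbiome")
}

## Per-individual standardized CLR abundance of one taxon, computed from the
## generated count table exactly as the downstream pipeline computes it
## (impute zeros -> CLR -> average over libraries -> standardize).
taxon_clr_by_individual <- function(microbiome, taxon) {
  counts <- microbiome$counts
  keep <- colSums(counts) > 0
  cl <- clr_transform(impute_zeros(counts[, keep, drop = FALSE]))
  avg <- average_profiles(cl, microbiome$samples)
  as.numeric(scale(avg[, taxon]))
}

#' Simulate a 39-peak plasma N-glycome composition
#'
#' Per-individual compositions follow a logistic-normal model around a fixed
#' chromatogram-like mean profile. For every planted (taxon, trait, beta) the
#' latent log-abundance of the trait's peak is shifted by
#' beta * (36/35) * (standardized per-individual CLR abundance of the taxon),
#' calibrated so that beta is exactly the effect on the harmonized 36-GP
#' CLR trait scale recovered downstream.
#'
#' @param config a [synth_config].
#' @param microbiome the [simulate_microbiome] result the planted effects
#'   refer to.
#' @return matrix individuals x peaks (columns P1..P39), rows summing to 1.
#' @export
simulate_glycome <- function(config, microbiome) {
  stopifnot(inherits(config, "synth_config"),
            inherits(microbiome, "synth_microbiome"))
  set.seed(config$seed + 1L)
  inds <- unique(microbiome$samples$individual_id)
  np <- config$n_peaks
  peaks <- sprintf("P%d", seq_len(np))
  i <- seq_len(np)
  prof <- 0.3 + 5 * exp(-(i - 5)^2 / 8) + 7 * exp(-(i - 16)^2 / 18) +
    4 * exp(-(i - 28)^2 / 40)
  mu <- log(prof / sum(prof))
  z <- matrix(stats::rnorm(length(inds) * np, 0, config$glycome_sd),
              length(inds), np, dimnames = list(inds, peaks))
  z <- sweep(z, 2L, mu, "+")
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    for (r in seq_len(nrow(pe))) {
      if (!pe$taxon[r] %in% colnames(microbiome$counts))
        stop("planted taxon absent from microbiome: ", pe$taxon[r])
      x <- taxon_clr_by_individual(microbiome, pe$taxon[r])
      z[, pe$trait[r]] <- z[, pe$trait[r]] + pe$beta[r] * (36 / 35) * x
    }
  }
  softmax_rows(z)
}

#' Simulate covariates and polygenic-score values
#'
#' Age, BMI, sex and smoking are drawn to match the cohort's demographic
#' moments (age 55.66 +/- 13.05 y, BMI 26.37 +/- 4.64, 42.3% male, 23.2%
#' smokers). The polygenic score for the designated glycan trait is
#' r * standardized trait + sqrt(1 - r^2) * noise.
#'
#' @param config a [synth_config]; `config$prs_r` sets r.
#' @param glycome peak composition matrix from [simulate_glycome].
#' @param prs_trait peak label whose CLR value the PRS targets; defaults to
#'   the first planted trait (or "P10" under a null configuration).
#' @return list with `covariates` (individual_id, age, sex, bmi, smoking) and
#'   `prs` (individual_id, trait, prs).
#' @export
simulate_covariates_prs <- function(config, glycome, prs_trait = NULL) {
  stopifnot(inherits(config, "synth_config"))
  r <- config$prs_r
  if (abs(r) > 1) stop("prs_r must lie in [-1, 1]")
  set.seed(config$seed + 2L)
  inds <- rownames(glycome)
  n <- length(inds)
  cov <- data.frame(individual_id = inds,
                    age = stats::rnorm(n, 55.66, 13.05),
                    sex = stats::rbinom(n, 1L, 0.423),
                    bmi = stats::rnorm(n, 26.37, 4.64),
                    smoking = stats::rbinom(n, 1L, 0.232),
                    stringsAsFactors = FALSE)
  if (is.null(prs_trait)) {
    pe <- config$planted_effects
    prs_trait <- if (!is.null(pe) && nrow(pe)) pe$trait[1] else "P10"
  }
  tr <- clr_transform(glycome)[, prs_trait]
  zt <- as.numeric(scale(tr))
  prs_val <- r * zt + sqrt(1 - r^2) * stats::rnorm(n)
  list(covariates = cov,
       prs = data.frame(individual_id = inds, trait = prs_trait,
                        prs = prs_val, stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_microbiome], [simulate_glycome] and
#' [simulate_covariates_prs] under one configuration.
#'
#' @param config a [synth_config].
#' @return list of class `synth_dataset` with counts, samples, truth,
#'   glycome, covariates, prs and the config.
#' @export
simulate_dataset <- function(config = synth_config()) {
  mb <- simulate_microbiome(config)
  gly <- simulate_glycome(config, mb)
  cp <- simulate_covariates_prs(config, gly)
  structure(list(counts = mb$counts, samples = mb$samples, truth = mb$truth,
                 glycome = gly, covariates = cp$covariates, prs = cp$prs,
                 config = config),
            class = "synth_dataset")
}
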