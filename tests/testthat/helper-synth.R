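## Small configurations shared across test files.

tiny_cfg <- function(seed = 1L, ...) {
  args <- list(n_individuals = 30L, n_taxa = 40L,
               n_contaminants_per_mechanism = 2L, n_replicated_pairs = 8L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

## Exactly sample-uncorrelated variables (principal component scores).
uncorrelated_matrix <- function(n, m) {
  stats::prcomp(matrix(stats::rnorm(n * (m + 2)), n, m + 2))$x[, seq_len(m)]
}

## Minimal sample table for hand-built count fixtures.
toy_samples <- function(n, location = "ileum", amplicon = "V1V2",
                        coverage = 20000L) {
  data.frame(library_id = sprintf("L%02d", seq_len(n)),
             individual_id = sprintf("I%02d", seq_len(n)),
             location = rep_len(location, n),
             amplicon = rep_len(amplicon, n),
             run = "run01", collection_date = "D01",
             coverage = rep_len(coverage, n),
             replicate_group = NA_character_, negative_control = FALSE,
             stringsAsFactors = FALSE)
}
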