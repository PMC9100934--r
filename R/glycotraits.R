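#' Shipped harmonization map, derived-trait registry and gut allowlist
#'
#' The package ships a synthetic stand-in harmonization map (39 chromatogram
#' peaks onto 36 harmonized glycan peaks), a synthetic registry of 81 derived
#' glycan traits over those 36 GPs, and a user-editable allowlist of genera
#' characteristic for the human gut. The map and registry are structurally
#' faithful stand-ins (constructed, not transcribed from any cohort's
#' supplementary data — hence the `_synthetic` file names); the trait engine
#' is definition-driven, so an alternative panel (e.g. a 24-peak IgG panel)
#' loads from a user-provided file of the same format.
#'
#' @return `default_harmonization_map()` and `default_trait_registry()`
#'   return file paths; `gut_allowlist()` returns a character vector of
#'   genera.
#' @export
default_harmonization_map <- function() {
  system.file("extdata", "plasma_harmonization_map_synthetic.csv",
              package = "glycomicrobe", mustWork = TRUE)
}

#' @rdname default_harmonization_map
#' @export
default_trait_registry <- function() {
  system.file("extdata", "plasma_derived_traits_synthetic.csv",
              package = "glycomicrobe", mustWork = TRUE)
}

#' @rdname default_harmonization_map
#' @param path optional path to an alternative allowlist file.
#' @export
gut_allowlist <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gut_genera_allowlist.txt",
                        package = "glycomicrobe", mustWork = TRUE)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a peak harmonization map
#'
#' Two-column CSV (`peak`, `gp`) mapping every original chromatogram peak to
#' a harmonized glycan-peak label. The mapping must be total: every original
#' peak mapped exactly once.
#'
#' @param path CSV path; defaults to the shipped plasma map.
#' @return data.frame with columns `peak` and `gp`.
#' @export
read_harmonization_map <- function(path = default_harmonization_map()) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("peak", "gp") %in% names(map)))
    stop("map needs columns peak, gp")
  if (anyDuplicated(map$peak)) stop("peak mapped more than once")
  map
}

#' Sum original peaks into harmonized glycan peaks
#'
#' Each harmonized GP is the sum of the original peaks mapped onto it, so
#' total area is conserved exactly.
#'
#' @param peaks samples x original-peaks matrix of (relative) areas.
#' @param map harmonization map (see [read_harmonization_map]).
#' @return samples x GPs matrix; GP columns ordered by first appearance in
#'   the map.
#' @export
harmonize_peaks <- function(peaks, map = read_harmonization_map()) {
  peaks <- as.matrix(peaks)
  unmapped <- setdiff(colnames(peaks), map$peak)
  if (length(unmapped))
    stop("unmapped input peak(s): ", paste(unmapped, collapse = ", "))
  gps <- unique(map$gp)
  out <- matrix(0, nrow(peaks), length(gps),
                dimnames = list(rownames(peaks), gps))
  for (g in gps) {
    cols <- intersect(map$peak[map$gp == g], colnames(peaks))
    if (length(cols))
      out[, g] <- rowSums(peaks[, cols, drop = FALSE])
  }
  out
}

#' Total-area normalization
#'
#' Divides each glycan peak by the total area of its chromatogram, so every
#' row sums to 1.
#'
#' @param peaks samples x peaks matrix of non-negative areas.
#' @return normalized matrix.
#' @export
total_area_normalize <- function(peaks) {
  peaks <- as.matrix(peaks)
  if (any(peaks < 0)) stop("negative peak area")
  rs <- rowSums(peaks)
  if (any(rs <= 0)) {
    bad <- rownames(peaks)[rs <= 0] %||% which(rs <= 0)
    stop("zero total area for sample(s): ", paste(bad, collapse = ", "))
  }
  peaks / rs
}

#' Read a derived-trait registry
#'
#' CSV with columns `name`, `class` (MERGE_CLR, SUBCOMP_CLR or RATIO_ILR),
#' `numerator`, `repertoire`, `denominator` (semicolon-separated GP labels)
#' and `description`. Validates: unique names, known classes, non-empty
#' numerators, numerator within repertoire (SUBCOMP_CLR), and disjoint
#' numerator/denominator (RATIO_ILR).
#'
#' @param path CSV path; defaults to the shipped 81-trait plasma registry.
#' @return data.frame with list-columns `numerator`, `repertoire`,
#'   `denominator` holding GP label vectors.
#' @export
read_trait_registry <- function(path = default_trait_registry()) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "class", "numerator", "repertoire", "denominator")
  if (!all(need %in% names(reg)))
    stop("registry needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(reg$name)) stop("duplicated trait names")
  if (!all(reg$class %in% c("MERGE_CLR", "SUBCOMP_CLR", "RATIO_ILR")))
    stop("unknown transform class")
  split_gp <- function(s) {
    s <- trimws(strsplit(s %||% "", ";", fixed = TRUE)[[1]] %||% character(0))
    s[nzchar(s)]
  }
  reg$numerator <- lapply(reg$numerator, split_gp)
  reg$repertoire <- lapply(reg$repertoire, split_gp)
  reg$denominator <- lapply(reg$denominator, split_gp)
  for (i in seq_len(nrow(reg))) {
    if (!length(reg$numerator[[i]]))
      stop("empty numerator for trait ", reg$name[i])
    if (reg$class[i] == "SUBCOMP_CLR" &&
        !all(reg$numerator[[i]] %in% reg$repertoire[[i]]))
      stop("numerator not within repertoire for trait ", reg$name[i])
    if (reg$class[i] == "RATIO_ILR") {
      if (!length(reg$denominator[[i]]))
        stop("empty denominator for trait ", reg$name[i])
      if (length(intersect(reg$numerator[[i]], reg$denominator[[i]])))
        stop("numerator and denominator overlap for trait ", reg$name[i])
    }
  }
  reg
}

## CLR value of the merged numerator component within composition `comp`
## (columns = GP labels): log(sum numerator) - mean log over the merged parts.
merge_clr_value <- function(comp, numerator) {
  others <- setdiff(colnames(comp), numerator)
  if (!length(others))
    stop("numerator equals the whole composition; CLR undefined")
  s <- rowSums(comp[, numerator, drop = FALSE])
  lmat <- cbind(log(s), log(comp[, others, drop = FALSE]))
  log(s) - rowMeans(lmat)
}

#' Compute one derived glycan trait
#'
#' Applies the definition's compositional transformation to a strictly
#' positive GP composition:
#' \describe{
#'   \item{MERGE_CLR}{replace the numerator GPs by their sum, keep all other
#'     GPs, CLR the merged composition and return the merged component;}
#'   \item{SUBCOMP_CLR}{restrict to the repertoire, renormalize, then as
#'     MERGE_CLR within the subcomposition;}
#'   \item{RATIO_ILR}{the 1-vs-1 isometric log-ratio balance
#'     (1/sqrt(2)) ln(sum numerator / sum denominator).}
#' }
#'
#' @param gp_rel samples x GPs matrix, strictly positive (zeros handled
#'   upstream by the minimal-fraction rule, see [compute_traits]).
#' @param def one row of a parsed registry (see [read_trait_registry]).
#' @return numeric vector, one value per sample.
#' @export
derive_trait <- function(gp_rel, def) {
  gp_rel <- as.matrix(gp_rel)
  if (any(gp_rel <= 0)) stop("non-positive GP value; impute zeros first")
  num <- def$numerator[[1]]
  missing_gp <- setdiff(c(num, def$repertoire[[1]], def$denominator[[1]]),
                        colnames(gp_rel))
  if (length(missing_gp))
    stop("GP(s) absent from data: ", paste(missing_gp, collapse = ", "))
  if (!length(num)) stop("empty numerator")
  switch(def$class,
    MERGE_CLR = merge_clr_value(gp_rel, num),
    SUBCOMP_CLR = {
      rep_gp <- def$repertoire[[1]]
      sub <- gp_rel[, rep_gp, drop = FALSE]
      sub <- sub / rowSums(sub)
      merge_clr_value(sub, num)
    },
    RATIO_ILR = {
      den <- def$denominator[[1]]
      (1 / sqrt(2)) * log(rowSums(gp_rel[, num, drop = FALSE]) /
                            rowSums(gp_rel[, den, drop = FALSE]))
    },
    stop("unknown class: ", def$class))
}

#' CLR-transformed original glycan traits
#'
#' The 36 harmonized GPs as analysis-ready traits: centered log-ratio values
#' of the (zero-imputed) GP composition.
#'
#' @param gp_rel samples x GPs relative-area matrix.
#' @return matrix of CLR values.
#' @export
original_trait_clr <- function(gp_rel) {
  clr_transform(impute_zeros(gp_rel))
}

#' Full analysis-ready glycan trait matrix
#'
#' Total-area-normalizes, imputes zeros by the minimal-fraction rule, then
#' binds the CLR-transformed original GPs with every derived trait in the
#' registry. With the shipped plasma map and registry this yields
#' 36 + 81 = 117 columns.
#'
#' @param gp samples x GPs matrix (harmonized areas or relative areas).
#' @param registry parsed registry from [read_trait_registry].
#' @return samples x traits matrix with attribute `provenance`
#'   ("original"/"derived" per column).
#' @export
compute_traits <- function(gp, registry = read_trait_registry()) {
  gp <- total_area_normalize(gp)
  gp <- impute_zeros(gp)
  orig <- clr_transform(gp)
  der <- vapply(seq_len(nrow(registry)),
                function(i) derive_trait(gp, registry[i, , drop = FALSE]),
                numeric(nrow(gp)))
  colnames(der) <- registry$name
  out <- cbind(orig, der)
  attr(out, "provenance") <- c(rep("original", ncol(orig)),
                               rep("derived", ncol(der)))
  out
}

#' PCA of the glycan trait matrix
#'
#' Same engine and sign convention as [microbial_pca], defaulting to the
#' first 10 components.
#'
#' @param traits samples x traits matrix.
#' @param k number of components (default 10).
#' @return list with scores, loadings and variance fractions.
#' @export
glycan_pca <- function(traits, k = 10L) microbial_pca(traits, k)
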