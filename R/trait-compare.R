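#' @title Trait table agreement statistics
#' @name trait_compare
#' @description
#' Quantifies agreement between two trait tables over the same plants --
#' typically traits derived from manually proofread landmarks (the reference)
#' versus fully automated predictions (the candidate). Each trait value is
#' standardized by the reference distribution, `z = (mu - x) / sigma`, so the
#' absolute z-score difference `dz = |x_ref - x_cand| / sigma` measures the
#' trait error in units of the trait's intrinsic SD; per-trait Pearson
#' correlation complements the standardized differences.
NULL

align_tables <- function(reference, candidate) {
  stopifnot(names(reference)[1L] == "plant_id",
            names(candidate)[1L] == "plant_id")
  plants <- intersect(reference$plant_id, candidate$plant_id)
  if (!length(plants))
    stop("reference and candidate tables share no plant_id")
  traits <- intersect(names(reference)[-1L], names(candidate)[-1L])
  if (!length(traits))
    stop("reference and candidate tables share no trait columns")
  ref <- as.matrix(reference[match(plants, reference$plant_id), traits,
                             drop = FALSE])
  cand <- as.matrix(candidate[match(plants, candidate$plant_id), traits,
                              drop = FALSE])
  rownames(ref) <- rownames(cand) <- plants
  list(ref = ref, cand = cand, plants = plants, traits = traits)
}

pop_sd <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 1L) return(NaN)
  sqrt(mean((v - mean(v))^2))
}

#' Standardized trait differences between two trait tables
#'
#' For every common (plant, trait) cell, computes the absolute z-score
#' difference `dz = |x_ref - x_cand| / sigma`, where `sigma` is the population
#' SD (divisor n) of the trait in the *reference* table. Traits with
#' `sigma = 0` or all-missing reference values are reported as not comparable
#' (`NaN` dz).
#'
#' @param reference Reference trait table `data.frame` (first column
#'   `plant_id`), e.g. from proofread landmarks; its per-trait mean and SD
#'   define the z scores.
#' @param candidate Candidate trait table to evaluate against the reference.
#' @param threshold Agreement threshold in SD units (default 1).
#'
#' @return Object of class `trait_comparison`: a list with `dz` (plants x
#'   traits matrix of absolute z-score differences), `trait_summary` (a
#'   `data.frame` per trait: reference `mu` and `sigma`, `n_pairs` of finite
#'   pairs, `pearson_r`, `frac_within` = fraction of finite dz at or below the
#'   threshold), `overall_frac_within` (over all finite dz cells), `threshold`,
#'   and `n_values` (number of finite dz cells).
#' @export
zscore_differences <- function(reference, candidate, threshold = 1) {
  al <- align_tables(reference, candidate)
  mu <- apply(al$ref, 2L, function(v) mean(v[is.finite(v)]))
  sigma <- apply(al$ref, 2L, pop_sd)
  comparable <- is.finite(sigma) & sigma > 0
  dz <- abs(al$ref - al$cand)
  dz <- sweep(dz, 2L, sigma, "/")
  dz[, !comparable] <- NaN
  r <- pearson_by_trait(reference, candidate)
  frac_within <- apply(dz, 2L, function(col) {
    fin <- is.finite(col)
    if (!any(fin)) NaN else mean(col[fin] <= threshold)
  })
  n_pairs <- colSums(is.finite(al$ref) & is.finite(al$cand))
  fin <- is.finite(dz)
  structure(list(
    dz = dz,
    trait_summary = data.frame(
      trait = al$traits, mu = mu, sigma = sigma, n_pairs = n_pairs,
      pearson_r = as.numeric(r[al$traits]),
      frac_within = as.numeric(frac_within),
      row.names = NULL),
    overall_frac_within = if (any(fin)) mean(dz[fin] <= threshold) else NaN,
    threshold = threshold,
    n_values = sum(fin)),
    class = "trait_comparison")
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "<trait_comparison: %d plants x %d traits, %.1f%% of %d finite |dz| ",
    "within %g SD>\n"),
    nrow(x$dz), ncol(x$dz), 100 * x$overall_frac_within, x$n_values,
    x$threshold))
  invisible(x)
}

#' Per-trait Pearson correlation between two trait tables
#'
#' For every common trait column, the Pearson correlation over plant-paired
#' values; pairs where either value is missing are dropped, and a correlation
#' is only reported when at least 3 finite pairs remain and neither side is
#' constant (`NaN` otherwise).
#'
#' @inheritParams zscore_differences
#' @return Named numeric vector of correlations, one per common trait.
#' @export
pearson_by_trait <- function(reference, candidate) {
  al <- align_tables(reference, candidate)
  r <- vapply(al$traits, function(tr) {
    a <- al$ref[, tr]; b <- al$cand[, tr]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L) return(NaN)
    a <- a[ok]; b <- b[ok]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NaN)
    stats::cor(a, b)
  }, numeric(1L))
  stats::setNames(r, al$traits)
}

#' Write a trait comparison report to CSV
#'
#' @param comparison A `trait_comparison` from [zscore_differences].
#' @param path Output CSV path (per-trait summary table).
#' @return Invisibly, the path.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "trait_comparison"))
  utils::write.csv(comparison$trait_summary, path, row.names = FALSE)
  invisible(path)
}
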