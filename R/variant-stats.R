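# Per-site summary statistics stored with every variant row.
#
# All statistics are computed per biallelic record (multi-allelic sites are
# split upstream) from the gt_types codes alone. Conventions:
#   * UNKNOWN genotypes are excluded from allele-based statistics.
#   * statistics that are undefined for a site (no calls; monomorphic where
#     heterozygosity-based) are NA here and NULL in the database.

#' Tally genotype type codes at one site
#'
#' @param gt_types Integer vector of codes from [gt_type_codes].
#' @return Named integer vector `num_hom_ref`, `num_het`, `num_hom_alt`,
#'   `num_unknown`; the four always sum to `length(gt_types)`.
#' @export
genotype_counts <- function(gt_types) {
  if (length(gt_types) && (anyNA(gt_types) || any(!gt_types %in% 0:3))) {
    vardb_stop("gt_types codes must be in 0..3", "vardb_validation_error")
  }
  tab <- tabulate(gt_types + 1L, nbins = 4L)
  c(num_hom_ref = tab[1], num_het = tab[2], num_hom_alt = tab[4], num_unknown = tab[3])
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit of the observed genotype counts against the
#' expected proportions (p^2, 2pq, q^2) with the allele frequency estimated
#' from the same counts; 1 degree of freedom, no continuity correction. A
#' monomorphic site fits its expectation exactly, so `chi2 = 0`, `p = 1`.
#'
#' @param num_hom_ref,num_het,num_hom_alt Genotype counts (called samples).
#' @return List with `chi2` and `p` (upper tail); both NA when no samples
#'   are called.
#' @examples
#' hwe_test(50, 30, 20) # chi2 ~ 11.605
#' @export
hwe_test <- function(num_hom_ref, num_het, num_hom_alt) {
  n <- num_hom_ref + num_het + num_hom_alt
  if (n == 0) return(list(chi2 = NA_real_, p = NA_real_))
  p_hat <- (2 * num_hom_ref + num_het) / (2 * n)
  q_hat <- 1 - p_hat
  if (p_hat == 0 || q_hat == 0) return(list(chi2 = 0, p = 1))
  expected <- n * c(p_hat^2, 2 * p_hat * q_hat, q_hat^2)
  observed <- c(num_hom_ref, num_het, num_hom_alt)
  chi2 <- sum((observed - expected)^2 / expected)
  p <- min(max(pchisq(chi2, df = 1, lower.tail = FALSE), 0), 1)
  list(chi2 = chi2, p = p)
}

#' Per-site inbreeding coefficient
#'
#' `F = 1 - Ho/He` where `Ho` is the observed heterozygote fraction and
#' `He = 2*p*q` the expected heterozygosity at the estimated allele
#' frequency. Undefined (NA) at monomorphic sites.
#'
#' @inheritParams hwe_test
#' @export
inbreeding_coefficient <- function(num_hom_ref, num_het, num_hom_alt) {
  n <- num_hom_ref + num_het + num_hom_alt
  if (n == 0) return(NA_real_)
  p_hat <- (2 * num_hom_ref + num_het) / (2 * n)
  he <- 2 * p_hat * (1 - p_hat)
  if (he == 0) return(NA_real_)
  1 - (num_het / n) / he
}

#' Per-site nucleotide diversity
#'
#' The probability that two alleles drawn without replacement differ:
#' `pi = 2*j*(m - j) / (m*(m - 1))` with `j` alternate-allele count among
#' `m = 2n` called alleles (the unbiased per-site heterozygosity).
#'
#' @inheritParams hwe_test
#' @export
nucleotide_diversity <- function(num_hom_ref, num_het, num_hom_alt) {
  n <- num_hom_ref + num_het + num_hom_alt
  m <- 2 * n
  if (m < 2) return(NA_real_)
  j <- num_het + 2 * num_hom_alt
  2 * j * (m - j) / (m * (m - 1))
}

#' All stored site statistics for one variant
#'
#' @param gt_types Integer codes for every sample at the site.
#' @return List with `num_hom_ref`, `num_het`, `num_hom_alt`, `num_unknown`,
#'   `call_rate`, `aaf`, `hwe_chi2`, `hwe` (the p-value, the database
#'   column), `inbreeding_coeff`, `pi`. With zero samples everything past
#'   the counts is NA.
#' @export
site_stats <- function(gt_types) {
  ct <- genotype_counts(gt_types)
  s <- length(gt_types)
  n <- s - ct[["num_unknown"]]
  call_rate <- if (s == 0) NA_real_ else n / s
  aaf <- if (n > 0) {
    (ct[["num_het"]] + 2 * ct[["num_hom_alt"]]) / (2 * n)
  } else NA_real_
  hwe <- hwe_test(ct[["num_hom_ref"]], ct[["num_het"]], ct[["num_hom_alt"]])
  list(
    num_hom_ref = ct[["num_hom_ref"]], num_het = ct[["num_het"]],
    num_hom_alt = ct[["num_hom_alt"]], num_unknown = ct[["num_unknown"]],
    call_rate = call_rate, aaf = aaf,
    hwe_chi2 = hwe$chi2, hwe = hwe$p,
    inbreeding_coeff = inbreeding_coefficient(ct[["num_hom_ref"]], ct[["num_het"]],
                                              ct[["num_hom_alt"]]),
    pi = nucleotide_diversity(ct[["num_hom_ref"]], ct[["num_het"]], ct[["num_hom_alt"]])
  )
}
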