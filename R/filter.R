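#' Candidate de novo variant filter
#'
#' Implements the stringent trio-genotype filter used to call candidate de
#' novo variants from joint-genotyped trios. A candidate passes only when all
#' of the following hold:
#' \itemize{
#'   \item proband: >= 5 reads supporting the alternate allele, alternate
#'     allele fraction >= 20\%, genotype quality (GQ) >= 60;
#'   \item population allele frequency <= 0.1\%;
#'   \item each parent: >= 10 reference reads, alternate allele fraction
#'     strictly < 5\%, GQ >= 30;
#'   \item site metrics (when supplied): Fisher strand FS <= 25, quality by
#'     depth QD >= 2, VQSR tranche <= 99.8 for SNVs / <= 99.0 for indels.
#' }
#' Missing site-level metrics are skipped with a recorded reason rather than
#' causing a failure. The pass decision is monotone: raising proband support
#' or quality, or lowering parental contamination, never flips pass to fail.
#'
#' @param proband_alt_reads integer, reads supporting the alternate allele in
#'   the proband.
#' @param proband_total_reads integer, total proband depth at the site.
#' @param proband_gq phred-scaled genotype quality of the proband call.
#' @param parent_ref_reads numeric vector (one per parent) of reference reads.
#' @param parent_alt_fraction numeric vector (one per parent) of alternate
#'   allele fractions, each in `[0, 1]`.
#' @param parent_gq numeric vector (one per parent) of genotype qualities.
#' @param population_af allele frequency in the reference population.
#' @param is_indel logical; selects the indel VQSR tranche bound.
#' @param fs,qd,vqsr_tranche optional site-level metrics (`NA` to skip).
#' @return a list with elements `pass` (logical), `failed` (character vector
#'   of violated rule codes, empty on pass) and `skipped` (site metrics that
#'   were absent and therefore not evaluated).
#' @examples
#' filter_candidate_denovo(5, 20, 60, c(30, 30), c(0, 0), c(99, 99), 0)$pass
#' @export
filter_candidate_denovo <- function(proband_alt_reads, proband_total_reads,
                                    proband_gq,
                                    parent_ref_reads, parent_alt_fraction,
                                    parent_gq,
                                    population_af,
                                    is_indel = FALSE,
                                    fs = NA_real_, qd = NA_real_,
                                    vqsr_tranche = NA_real_) {
  counts <- c(proband_alt_reads, proband_total_reads, parent_ref_reads)
  if (any(is.na(counts)) || any(counts < 0))
    stopf("read counts must be non-negative and non-missing")
  if (proband_alt_reads > proband_total_reads)
    stopf("proband_alt_reads exceeds proband_total_reads")
  fracs <- c(parent_alt_fraction, population_af)
  if (any(is.na(fracs)) || any(fracs < 0) || any(fracs > 1))
    stopf("allele fractions must lie in [0, 1]")

  failed <- character(0)
  skipped <- character(0)
  alt_frac <- if (proband_total_reads > 0)
    proband_alt_reads / proband_total_reads else 0

  if (proband_alt_reads < 5) failed <- c(failed, "alt_reads")
  if (alt_frac < 0.20) failed <- c(failed, "alt_fraction")
  if (proband_gq < 60) failed <- c(failed, "proband_gq")
  if (population_af > 0.001) failed <- c(failed, "population_af")
  if (any(parent_ref_reads < 10)) failed <- c(failed, "parent_ref_reads")
  if (any(parent_alt_fraction >= 0.05)) failed <- c(failed, "parent_alt_fraction")
  if (any(parent_gq < 30)) failed <- c(failed, "parent_gq")

  if (is.na(fs)) skipped <- c(skipped, "fs")
  else if (fs > 25) failed <- c(failed, "fs")
  if (is.na(qd)) skipped <- c(skipped, "qd")
  else if (qd < 2) failed <- c(failed, "qd")
  if (is.na(vqsr_tranche)) skipped <- c(skipped, "vqsr_tranche")
  else if (vqsr_tranche > (if (is_indel) 99.0 else 99.8))
    failed <- c(failed, "vqsr_tranche")

  list(pass = length(failed) == 0L, failed = failed, skipped = skipped)
}
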