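#' @name mutation-model
#' @title Trinucleotide-context baseline mutation rates
#'
#' @description Per-gene, class-specific de novo mutation rates are obtained
#' by enumerating every possible single-base substitution in the selected
#' transcript's CDS (plus canonical splice-site bases), looking up each
#' substitution's trinucleotide-context rate, and adding it to exactly one
#' functional class. The frameshift-indel rate is fixed at 1.1 times the
#' nonsense rate. Expected cohort counts are `rate x 2N` for autosomes and
#' `rate x (2 n_female + n_male)` for chromosome X non-PAR genes.
NULL

RATE_CLASSES <- c("syn", "mis", "dmis", "non", "splice", "frameshift")

#' Per-gene class-specific mutation rates
#'
#' @param gm a `gene_model`.
#' @param genome named character vector of contig sequences.
#' @param rt a [rate_table()].
#' @param dmis_mask either a scalar in `[0,1]` (the fraction of the missense
#'   rate mass treated as deleterious), or a data.frame with columns
#'   `gene, pos, alt` flagging the individual substitutions predicted
#'   deleterious (per-site mask, the preferred mechanism).
#' @param start_codon_class see [enumerate_sites()].
#' @return one-row data.frame with columns `gene, r_syn, r_mis, r_dmis,
#'   r_non, r_splice, r_frameshift, chrx_nonpar`. `r_non` includes stop-loss
#'   substitutions; `r_splice` carries the splice-site mass;
#'   `r_frameshift = 1.1 * r_non` exactly.
#' @export
gene_class_rates <- function(gm, genome, rt, dmis_mask = 0,
                             start_codon_class = "missense") {
  sites <- enumerate_sites(gm, genome, rate_table = rt,
                           start_codon_class = start_codon_class)
  class_rates_from_sites(sites, gm$gene, dmis_mask,
                         chrx_nonpar = gm$chrx_nonpar)
}

class_rates_from_sites <- function(sites, gene, dmis_mask = 0,
                                   chrx_nonpar = FALSE) {
  r <- function(cls) sum(sites$rate[sites$consequence %in% cls])
  r_syn <- r("synonymous")
  r_mis <- r("missense")
  r_non <- r(c("nonsense", "stop_loss"))
  r_splice <- r("splice_site")
  if (is.data.frame(dmis_mask)) {
    key <- paste(sites$gene, sites$pos, sites$alt)
    mkey <- paste(dmis_mask$gene, dmis_mask$pos, dmis_mask$alt)
    r_dmis <- sum(sites$rate[sites$consequence == "missense" & key %in% mkey])
  } else {
    stopifnot(is.numeric(dmis_mask), length(dmis_mask) == 1L,
              dmis_mask >= 0, dmis_mask <= 1)
    r_dmis <- r_mis * dmis_mask
  }
  data.frame(gene = gene, r_syn = r_syn, r_mis = r_mis, r_dmis = r_dmis,
             r_non = r_non, r_splice = r_splice,
             r_frameshift = 1.1 * r_non,
             chrx_nonpar = chrx_nonpar, stringsAsFactors = FALSE)
}

#' Class rates for a whole set of gene models
#'
#' @param models named list of `gene_model` objects.
#' @param genome,rt,dmis_mask,start_codon_class as in [gene_class_rates()].
#' @return data.frame, one row per gene (a `GeneRates` table).
#' @export
gene_rates_table <- function(models, genome, rt, dmis_mask = 0,
                             start_codon_class = "missense") {
  out <- do.call(rbind, lapply(models, gene_class_rates, genome = genome,
                               rt = rt, dmis_mask = dmis_mask,
                               start_codon_class = start_codon_class))
  rownames(out) <- NULL
  out
}

#' Allele factor converting per-generation rates to cohort expectations
#'
#' Autosomes contribute two new haploid genomes per trio; chromosome X
#' non-PAR genes contribute two per female and `male_scale` per male trio
#' (default 1, i.e. plain X-allele counting).
#'
#' @param cohort a [cohort_spec()].
#' @param chrx_nonpar logical vector.
#' @param male_scale scaling of the male X contribution.
#' @return numeric vector of allele factors.
#' @export
allele_factor <- function(cohort, chrx_nonpar = FALSE, male_scale = 1) {
  ifelse(chrx_nonpar,
         2 * cohort$n_female + male_scale * cohort$n_male,
         2 * cohort$n_trios)
}

#' Expected variant counts for a cohort
#'
#' @param rates data.frame from [gene_rates_table()] (or one row).
#' @param cohort a [cohort_spec()].
#' @param male_scale see [allele_factor()].
#' @return data.frame with per-gene expected counts `e_syn, e_mis, e_dmis,
#'   e_non, e_splice, e_frameshift, e_lgd` (LGD = nonsense + splice +
#'   frameshift). Additive over disjoint gene sets by construction.
#' @export
expected_counts <- function(rates, cohort, male_scale = 1) {
  if (cohort$n_trios < 0) stopf("negative trio count")
  A <- allele_factor(cohort, rates$chrx_nonpar %||% FALSE, male_scale)
  out <- data.frame(gene = rates$gene,
                    e_syn = rates$r_syn * A,
                    e_mis = rates$r_mis * A,
                    e_dmis = rates$r_dmis * A,
                    e_non = rates$r_non * A,
                    e_splice = rates$r_splice * A,
                    e_frameshift = rates$r_frameshift * A,
                    stringsAsFactors = FALSE)
  out$e_lgd <- out$e_non + out$e_splice + out$e_frameshift
  out
}

#' Export per-gene rates as a tidy TSV
#' @param rates data.frame from [gene_rates_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_rates <- function(rates, path) {
  long <- do.call(rbind, lapply(RATE_CLASSES, function(cl)
    data.frame(gene = rates$gene, class = cl,
               rate = rates[[paste0("r_", cl)]], stringsAsFactors = FALSE)))
  utils::write.table(long[order(long$gene, long$class), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
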