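#' @name burden-stats
#' @title One-sided Poisson burden and recurrence tests
#'
#' @description Observed class counts are compared with baseline expectations
#' using the one-sided Poisson test `p = P(X >= O | lambda)` (inclusive of
#' the observed count). Fold enrichment is `O / lambda` with an exact
#' (Garwood) confidence interval obtained from the gamma quantiles of the
#' Poisson count, divided by the expectation. The per-gene recurrence test
#' aggregates LGD and D-mis ("damaging") counts and applies a Bonferroni
#' threshold of `alpha / G` across the coding genome.
NULL

BURDEN_CLASSES <- c("synonymous", "missense", "D-mis", "LGD")

class_expectation_col <- c(synonymous = "e_syn", missense = "e_mis",
                           `D-mis` = "e_dmis", LGD = "e_lgd")

#' One-sided Poisson burden test
#'
#' @param observed observed variant count `O` (>= 0).
#' @param expected expected count `lambda` (> 0).
#' @param n_trios number of trios (for the per-case rate; `NA` allowed).
#' @param conf_level confidence level for the fold-enrichment interval.
#' @return one-row data.frame of class `burden_result`: `observed, expected,
#'   fold, p, ci_lo, ci_hi, rate_per_case`. `fold * expected = observed`
#'   exactly; `p` is in `(0, 1]` and non-increasing in `O` at fixed lambda.
#' @examples
#' poisson_burden(57, 32.9, 362)   # FE 1.73, p 8.6e-5
#' poisson_burden(110, 109.1, 362) # FE 1.01, p 0.48
#' @export
poisson_burden <- function(observed, expected, n_trios = NA_integer_,
                           conf_level = 0.95) {
  if (!is.finite(expected) || expected <= 0)
    stopf("undefined expectation: lambda must be > 0 (got %s)",
          format(expected))
  if (!is.finite(observed) || observed < 0 || observed != round(observed))
    stopf("observed count must be a non-negative integer")
  a <- (1 - conf_level) / 2
  # exact (Garwood) Poisson interval for the count, scaled by the expectation
  ci_lo <- if (observed == 0) 0 else qgamma(a, observed) / expected
  ci_hi <- qgamma(1 - a, observed + 1) / expected
  out <- data.frame(
    observed = observed,
    expected = expected,
    fold = observed / expected,
    p = ppois(observed - 1, expected, lower.tail = FALSE),
    ci_lo = ci_lo,
    ci_hi = ci_hi,
    rate_per_case = observed / n_trios)
  class(out) <- c("burden_result", class(out))
  out
}

# observed class counts for a vector of class labels, excluding unscored
# missense from both missense and D-mis cells (configurable upstream)
count_classes <- function(labels, include_unscored = FALSE) {
  c(synonymous = sum(labels == "synonymous"),
    missense = sum(labels %in% c("missense", "D-mis",
                                 if (include_unscored) "unscored")),
    `D-mis` = sum(labels == "D-mis"),
    LGD = sum(labels == "LGD"))
}

#' Stratified burden table
#'
#' One [poisson_burden()] row per (stratum x gene set x variant class).
#' Expectations are rescaled to each stratum's trio and sex counts. Variants
#' in genes absent from the rate table are excluded from both observed and
#' expected counts and reported in the `reconciliation` attribute, as are
#' unscored missense variants (excluded from the missense and D-mis cells
#' unless `include_unscored`).
#'
#' @param variants de novo variant data.frame (see [read_denovo_table()]).
#' @param cohort a [cohort_spec()] covering all probands.
#' @param gene_sets named list of gene-id vectors. A set named `"all_genes"`
#'   covering every gene with rates is added when absent.
#' @param rates data.frame from [gene_rates_table()].
#' @param rule a [variant_class_rule()].
#' @param strata character vector of phenotype strata; `"all"` plus every
#'   observed `group` label by default.
#' @param classes burden classes to report.
#' @param include_unscored count unscored missense in the missense cell.
#' @param male_scale see [allele_factor()].
#' @return data.frame with columns `stratum, gene_set, class` plus the
#'   `burden_result` columns.
#' @export
stratified_burden <- function(variants, cohort, gene_sets, rates,
                              rule = variant_class_rule(),
                              strata = NULL, classes = BURDEN_CLASSES,
                              include_unscored = FALSE, male_scale = 1) {
  if (is.null(strata)) strata <- c("all", sort(unique(cohort$strata$group)))
  if (!"all_genes" %in% names(gene_sets))
    gene_sets <- c(gene_sets, list(all_genes = rates$gene))
  labels <- classify_variant(variants$consequence, variants$cadd_phred, rule)
  known <- variants$gene %in% rates$gene
  recon <- list(
    n_gene_not_in_rates = sum(!known),
    genes_not_in_rates = sort(unique(variants$gene[!known])),
    n_unscored_missense = sum(labels == "unscored"))
  variants <- variants[known, , drop = FALSE]
  labels <- labels[known]

  rows <- list()
  for (st in strata) {
    sub <- if (identical(st, "all")) cohort else subset_cohort(cohort, st)
    exp_tab <- expected_counts(rates, sub, male_scale)
    in_stratum <- variants$proband %in% sub$strata$proband
    for (gs in names(gene_sets)) {
      set_genes <- intersect(gene_sets[[gs]], rates$gene)
      in_set <- in_stratum & variants$gene %in% set_genes
      obs <- count_classes(labels[in_set], include_unscored)
      erow <- exp_tab[exp_tab$gene %in% set_genes, , drop = FALSE]
      for (cl in classes) {
        lam <- sum(erow[[class_expectation_col[[cl]]]])
        br <- poisson_burden(unname(obs[cl]), lam, sub$n_trios)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(stratum = st, gene_set = gs, class = cl,
                           stringsAsFactors = FALSE), br)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reconciliation") <- recon
  out
}

#' Gene sets defined by a pLI cut
#' @param pli named numeric vector from [read_pli()].
#' @param threshold constraint cutoff (default 0.5).
#' @return list with `constrained` and `other` gene sets.
#' @export
pli_gene_sets <- function(pli, threshold = 0.5) {
  list(constrained = names(pli)[pli >= threshold],
       other = names(pli)[pli < threshold])
}

#' Per-gene recurrence test with genome-wide Bonferroni correction
#'
#' Aggregates damaging variants (LGD plus D-mis by default) per gene and
#' tests the count against the gene's damaging expectation. Significance is
#' declared at `p < alpha / n_genes_genomewide` (default `0.01/20000 = 5e-7`).
#'
#' @param variants,cohort,rates,rule as in [stratified_burden()].
#' @param alpha family-wise error budget (default 0.01).
#' @param n_genes_genomewide Bonferroni denominator (default 20000).
#' @param male_scale see [allele_factor()].
#' @return data.frame, one row per gene with at least one damaging variant or
#'   appearing in `rates`: counts by class, `expected_damaging`, `p`,
#'   `significant`. Genes observed but absent from the rate model get
#'   `p = .Machine$double.xmin` as a zero-adjacent sentinel and raise a
#'   model-coverage warning.
#' @export
per_gene_recurrence_test <- function(variants, cohort, rates,
                                     rule = variant_class_rule(),
                                     alpha = 0.01, n_genes_genomewide = 20000,
                                     male_scale = 1) {
  labels <- classify_variant(variants$consequence, variants$cadd_phred, rule)
  damaging <- labels %in% c("LGD", "D-mis")
  obs <- table(factor(variants$gene[damaging],
                      levels = union(rates$gene,
                                     unique(variants$gene[damaging]))))
  exp_tab <- expected_counts(rates, cohort, male_scale)
  lam <- setNames(exp_tab$e_lgd + exp_tab$e_dmis, exp_tab$gene)
  genes <- names(obs)
  lambda <- unname(lam[genes])
  o <- as.integer(obs)
  p <- rep(1, length(genes))
  covered <- !is.na(lambda) & lambda > 0
  p[covered] <- ppois(o[covered] - 1L, lambda[covered], lower.tail = FALSE)
  uncovered_hit <- !covered & o > 0
  if (any(uncovered_hit)) {
    warnf("%d gene(s) with damaging variants lack a rate-model expectation",
          sum(uncovered_hit))
    p[uncovered_hit] <- .Machine$double.xmin
  }
  thr <- alpha / n_genes_genomewide
  n_lgd <- table(factor(variants$gene[labels == "LGD"], levels = genes))
  n_dmis <- table(factor(variants$gene[labels == "D-mis"], levels = genes))
  out <- data.frame(gene = genes, n_lgd = as.integer(n_lgd),
                    n_dmis = as.integer(n_dmis), n_damaging = o,
                    expected_damaging = lambda, p = p,
                    significant = p < thr, stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out[order(out$p, -out$n_damaging), ]
}

#' Scan for recurrently mutated genes
#'
#' Genes hit by at least `min_hits` qualifying variants (de novo LGD or
#' missense of any deleteriousness by default; synonymous-only recurrences
#' never qualify). When `rates` and `cohort` are given the list is annotated
#' with the per-gene recurrence p and ranked by it; otherwise by hit count.
#'
#' @param variants variant data.frame.
#' @param min_hits minimum number of qualifying variants (default 2).
#' @param qualifying consequence-level classes that count as hits.
#' @param rule a [variant_class_rule()].
#' @param pli optional named pLI vector for annotation.
#' @param rates,cohort optional, for per-gene p annotation.
#' @return data.frame `gene, n_hits, n_lgd, n_missense`, plus `pli` and `p`
#'   when available, ranked most-significant first.
#' @export
recurrent_gene_scan <- function(variants, min_hits = 2,
                                qualifying = c("LGD", "missense", "D-mis",
                                               "unscored"),
                                rule = variant_class_rule(), pli = NULL,
                                rates = NULL, cohort = NULL) {
  labels <- classify_variant(variants$consequence, variants$cadd_phred, rule)
  hit <- labels %in% qualifying
  if (!any(hit))
    return(data.frame(gene = character(0), n_hits = integer(0)))
  tab <- table(variants$gene[hit])
  tab <- tab[tab >= min_hits]
  genes <- names(tab)
  out <- data.frame(
    gene = genes, n_hits = as.integer(tab),
    n_lgd = as.integer(table(factor(variants$gene[hit & labels == "LGD"],
                                    levels = genes))),
    n_missense = as.integer(table(factor(
      variants$gene[hit & labels %in% c("missense", "D-mis", "unscored")],
      levels = genes))),
    stringsAsFactors = FALSE)
  if (!is.null(pli)) out$pli <- unname(pli[out$gene])
  if (!is.null(rates) && !is.null(cohort)) {
    pg <- per_gene_recurrence_test(variants, cohort, rates, rule)
    out$p <- pg$p[match(out$gene, pg$gene)]
    out <- out[order(out$p, -out$n_hits), ]
  } else {
    out <- out[order(-out$n_hits, out$gene), ]
  }
  rownames(out) <- NULL
  out
}
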