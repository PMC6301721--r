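#' @name placement-sim
#' @title Context-preserving variant placement simulation
#'
#' @description Cross-disorder gene-set enrichment is evaluated against a
#' Monte-Carlo null that re-places the observed variants across the coding
#' regions while keeping the number of variants and, for every SNV, its
#' trinucleotide context, functional effect and deleteriousness category
#' exactly as observed (a hard constraint, not a sampling target). Within a
#' placement key, sites are sampled uniformly: conditioned on identical
#' context and substitution the rate model assigns equal rates, so uniform
#' sampling is the model-consistent choice. Indels carry no context and are
#' re-placed across genes proportionally to CDS length within their
#' functional class (frameshift/inframe), a documented approximation.
NULL

DELCAT_LEVELS <- c("syn", "mis", "dmis", "lgd")

delcat_of_consequence <- function(consequence, is_dmis) {
  out <- rep(NA_character_, length(consequence))
  out[consequence == "synonymous"] <- "syn"
  out[consequence == "missense" & !is_dmis] <- "mis"
  out[consequence == "missense" & is_dmis] <- "dmis"
  out[consequence %in% c("nonsense", "splice_site", "stop_loss")] <- "lgd"
  out
}

#' Build the placement site index
#'
#' Enumerates every substitutable site of every gene model, labels it with a
#' placement key `context|alt|deleteriousness-category`, and optionally
#' restricts to a coverage mask (sites outside the mask are dropped, e.g. to
#' mimic WES regions with adequate depth).
#'
#' @param models named list of `gene_model` objects.
#' @param genome named character vector of contig sequences.
#' @param dmis_mask per-site deleteriousness mask: data.frame with columns
#'   `gene, pos, alt` flagging D-mis-capable missense substitutions, or
#'   `NULL` (no missense site is D-mis-capable).
#' @param coverage_mask optional data.frame from [read_bed()]; only sites
#'   inside the mask are indexed.
#' @param start_codon_class see [enumerate_sites()].
#' @return object of class `site_index`: list with `sites` (data.frame),
#'   `by_key` (list of row indices per key), `gene_levels`, and `cds_len`
#'   (named, for indel placement).
#' @export
build_site_index <- function(models, genome, dmis_mask = NULL,
                             coverage_mask = NULL,
                             start_codon_class = "missense") {
  sites <- do.call(rbind, lapply(models, enumerate_sites, genome = genome,
                                 start_codon_class = start_codon_class))
  rownames(sites) <- NULL
  if (!is.null(coverage_mask)) {
    keep <- rep(FALSE, nrow(sites))
    for (i in seq_len(nrow(coverage_mask))) {
      keep <- keep | (sites$chrom == coverage_mask$chrom[i] &
                        sites$pos >= coverage_mask$start[i] &
                        sites$pos <= coverage_mask$end[i])
    }
    sites <- sites[keep, , drop = FALSE]
  }
  if (nrow(sites) == 0L) stopf("site index is empty (mask covers no sites?)")
  # canonical order: results must not depend on how sites were enumerated
  sites <- sites[order(sites$gene, sites$chrom, sites$pos, sites$alt), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  is_dmis <- rep(FALSE, nrow(sites))
  if (!is.null(dmis_mask)) {
    key <- paste(sites$gene, sites$pos, sites$alt)
    is_dmis <- key %in% paste(dmis_mask$gene, dmis_mask$pos, dmis_mask$alt)
  }
  sites$delcat <- delcat_of_consequence(sites$consequence, is_dmis)
  sites$key <- paste(sites$context, sites$alt, sites$delcat, sep = "|")
  gene_levels <- vapply(models, `[[`, character(1), "gene")
  sites$gene_idx <- match(sites$gene, gene_levels)
  structure(list(
    sites = sites,
    by_key = split(seq_len(nrow(sites)), sites$key),
    gene_levels = unname(gene_levels),
    cds_len = setNames(vapply(models, `[[`, integer(1), "cds_len"),
                       gene_levels)
  ), class = "site_index")
}

# placement keys for observed variants; indels keyed by functional class only
observed_placement_keys <- function(variants, rule = variant_class_rule()) {
  labels <- classify_variant(variants$consequence, variants$cadd_phred, rule)
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  if (is.null(variants$context) || anyNA(variants$context[is_snv]))
    stopf("observed SNVs need a trinucleotide context column (derive with variant_context())")
  delcat <- delcat_of_consequence(
    ifelse(variants$consequence == "missense", "missense",
           variants$consequence),
    labels == "D-mis")
  # unscored missense is placed as non-D-mis missense
  delcat[labels == "unscored"] <- "mis"
  key <- ifelse(is_snv,
                paste(variants$context, variants$alt, delcat, sep = "|"),
                paste("indel", variants$consequence, sep = "|"))
  unplaceable <- is_snv & is.na(delcat)
  if (any(unplaceable))
    stopf("variant(s) with no placement category: rows %s",
          paste(head(which(unplaceable)), collapse = ", "))
  key
}

#' Simulate variant placements
#'
#' Each simulation contains exactly as many variants as observed and, for
#' every placement key, exactly the observed number of variants with that
#' key. SNVs are placed uniformly over the key's site list; indels are
#' placed across genes with probability proportional to CDS length.
#'
#' @param variants observed de novo variant data.frame with a `context`
#'   column for SNVs (see [variant_context()]).
#' @param index a [build_site_index()] result.
#' @param n_sims number of simulations.
#' @param seed integer seed (placements are bit-reproducible given the seed
#'   and index).
#' @param rule a [variant_class_rule()].
#' @return object of class `placement_sims`: list with `gene_idx` (integer
#'   matrix, one row per observed variant, one column per simulation),
#'   `site_row` (same shape; `NA` for indels), `key` (per observed variant),
#'   `n_sims`, `seed`.
#' @export
simulate_placements <- function(variants, index, n_sims, seed,
                                rule = variant_class_rule()) {
  stopifnot(inherits(index, "site_index"), n_sims >= 1)
  if (nrow(variants) == 0L) stopf("no observed variants to place")
  keys <- observed_placement_keys(variants, rule)
  n_obs <- length(keys)
  missing_keys <- setdiff(keys[!startsWith(keys, "indel|")],
                          names(index$by_key))
  if (length(missing_keys))
    stopf("unplaceable key(s), absent from the site index: %s",
          paste(unique(missing_keys), collapse = ", "))
  set.seed(seed)
  gene_idx <- matrix(NA_integer_, n_obs, n_sims)
  site_row <- matrix(NA_integer_, n_obs, n_sims)
  for (k in sort(unique(keys))) {           # sorted: order-independent stream
    rows <- which(keys == k)
    m <- length(rows)
    if (startsWith(k, "indel|")) {
      gs <- sample.int(length(index$gene_levels), m * n_sims, replace = TRUE,
                       prob = as.numeric(index$cds_len))
      gene_idx[rows, ] <- gs
    } else {
      pool <- index$by_key[[k]]
      picks <- pool[sample.int(length(pool), m * n_sims, replace = TRUE)]
      site_row[rows, ] <- picks
      gene_idx[rows, ] <- index$sites$gene_idx[picks]
    }
  }
  structure(list(gene_idx = gene_idx, site_row = site_row, key = keys,
                 n_sims = n_sims, seed = seed, gene_levels = index$gene_levels),
            class = "placement_sims")
}

#' Assert key-count conservation of a placement run
#'
#' Verifies, for every simulation, that each placed SNV sits on a site whose
#' key equals the observed variant's key — hence the per-key count histogram
#' of every simulation equals the observed histogram exactly.
#'
#' @param placements a [simulate_placements()] result.
#' @param index the [build_site_index()] used.
#' @return `TRUE` invisibly; errors on any violation.
#' @export
assert_key_conservation <- function(placements, index) {
  snv <- !startsWith(placements$key, "indel|")
  placed_keys <- index$sites$key[placements$site_row[snv, , drop = FALSE]]
  want <- rep(placements$key[snv], times = placements$n_sims)
  if (!identical(placed_keys, want))
    stopf("placement key conservation violated")
  invisible(TRUE)
}

#' Empirical gene-set enrichment from a placement null
#'
#' @param placements a [simulate_placements()] result.
#' @param gene_set character vector of gene ids.
#' @param variants the observed variants (used for the observed statistic).
#' @param statistic `"genes_hit"` (number of distinct set genes hit; default,
#'   mirroring counting "n set genes with de novo variants") or
#'   `"variants_in_set"`.
#' @return object of class `placement_null`: list with `statistic`,
#'   `observed`, `expected` (simulation mean), `fold`
#'   (`observed / expected`; `NA` sentinel when the set is disjoint from the
#'   index), `p` (add-one empirical p, ties counted with the `>=`
#'   convention), `sims` (per-simulation statistic), `n_sims`, `seed`.
#' @export
empirical_enrichment <- function(placements, gene_set, variants,
                                 statistic = c("genes_hit",
                                               "variants_in_set")) {
  statistic <- match.arg(statistic)
  set_idx <- which(placements$gene_levels %in% gene_set)
  obs_genes <- variants$gene[variants$gene %in% gene_set]
  stat_fun <- if (statistic == "genes_hit") {
    function(g) length(unique(g))
  } else length
  observed <- stat_fun(obs_genes)
  in_set <- matrix(placements$gene_idx %in% set_idx,
                   nrow = nrow(placements$gene_idx))
  sims <- if (statistic == "variants_in_set") {
    colSums(in_set)
  } else {
    vapply(seq_len(placements$n_sims), function(j)
      length(unique(placements$gene_idx[in_set[, j], j])), integer(1))
  }
  expected <- mean(sims)
  fold <- if (length(set_idx) == 0L) {
    warnf("gene set shares no genes with the site index; fold undefined")
    NA_real_
  } else observed / expected
  p <- (1 + sum(sims >= observed)) / (1 + placements$n_sims)
  structure(list(statistic = statistic, observed = observed,
                 expected = expected, fold = fold, p = p, sims = sims,
                 n_sims = placements$n_sims, seed = placements$seed),
            class = "placement_null")
}

#' @export
print.placement_null <- function(x, ...) {
  cat(sprintf(
    "placement null (%s): observed %g, expected %.3g, fold %.3g, p %.3g (%d sims)\n",
    x$statistic, x$observed, x$expected, x$fold, x$p, x$n_sims))
  invisible(x)
}

#' Tidy per-set placement enrichment table
#' @param placements a [simulate_placements()] result.
#' @param gene_sets named list of gene sets.
#' @param variants observed variants.
#' @param statistic see [empirical_enrichment()].
#' @return data.frame, one row per gene set.
#' @export
placement_enrichment_table <- function(placements, gene_sets, variants,
                                       statistic = "genes_hit") {
  do.call(rbind, lapply(names(gene_sets), function(nm) {
    e <- empirical_enrichment(placements, gene_sets[[nm]], variants,
                              statistic)
    data.frame(gene_set = nm, statistic = statistic, observed = e$observed,
               expected = e$expected, fold = e$fold, p = e$p,
               n_sims = e$n_sims, seed = e$seed, stringsAsFactors = FALSE)
  }))
}
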