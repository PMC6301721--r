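#' @name synthetic-data
#' @title Seeded synthetic-data generators with ground-truth manifests
#'
#' @description Every input the pipeline consumes can be generated from a
#' seeded configuration: toy exomes (gene models + contigs + per-site
#' deleteriousness mask), trinucleotide rate tables, null and risk-spiked
#' trio cohorts, expression matrices, gene-set catalogs, pLI tables and
#' coverage masks. Each generator is a pure function of (config, seed) and
#' returns a truth manifest recording every injected parameter, so
#' calibration and parameter-recovery tests have an exact oracle. The toy
#' world uses inflated per-context mutation rates so that cohorts of a few
#' hundred trios yield workable variant counts; it does not mimic human
#' base composition, real CADD scores or real pLI values.
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generator configuration
#'
#' @param seed mandatory integer seed.
#' @param n_genes number of genes (default 200).
#' @param cds_len_mean,cds_len_sd CDS length distribution in bp (rounded to
#'   codons; default mean 1200).
#' @param gc GC content of generated coding sequence (default 0.45).
#' @param x_frac fraction of genes flagged chrX non-PAR (default 0.05).
#' @param n_trios,male_frac,complex_frac cohort shape (defaults 500 trios,
#'   58.6\% male, 41.2\% complex — the shape of a realistic CDH trio cohort).
#' @param dmis_frac fraction of missense substitutions flagged deleterious
#'   in the site mask (default 0.37, matching the expected D-mis/missense
#'   rate ratio in exome-scale baselines).
#' @param rate_mean mean per-context per-generation rate for generated rate
#'   tables (default 1e-7; deliberately ~25x human scale so toy cohorts
#'   carry signal).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed, n_genes = 200, cds_len_mean = 1200,
                             cds_len_sd = 400, gc = 0.45, x_frac = 0.05,
                             n_trios = 500, male_frac = 0.586,
                             complex_frac = 0.412, dmis_frac = 0.37,
                             rate_mean = 1e-7) {
  if (missing(seed)) stopf("a seed is mandatory for every generator")
  stopifnot(n_genes > 0, cds_len_mean > 0, gc > 0, gc < 1,
            n_trios >= 0, dmis_frac >= 0, dmis_frac <= 1)
  structure(as.list(environment()), class = "generator_config")
}

base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                             T = (1 - gc) / 2)

random_codons <- function(n, gc) {
  # n sense (non-stop) codons
  p <- base_probs(gc)
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    cod <- paste0(sample(DNA_BASES, length(need), TRUE, p),
                  sample(DNA_BASES, length(need), TRUE, p),
                  sample(DNA_BASES, length(need), TRUE, p))
    ok <- !(cod %in% STOP_CODONS)
    out[need[ok]] <- cod[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a toy exome
#'
#' Each gene gets its own contig: 50 bp flank, two CDS exons separated by a
#' 100 bp intron with canonical GT..AG splice dinucleotides (in transcript
#' sense), 50 bp flank. The CDS starts with ATG, contains no internal stop
#' codon, and ends in a stop codon. Roughly half the genes are placed on the
#' minus strand. A per-site deleteriousness mask flags each missense
#' substitution independently with probability `dmis_frac`.
#'
#' @param cfg a [generator_config()].
#' @return object of class `synthetic_exome`: list with `models` (named list
#'   of `gene_model`), `genome`, `dmis_mask` (data.frame `gene, pos, alt`)
#'   and `cfg`. Deterministic under `cfg$seed`.
#' @export
gen_exome <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n_codons <- pmax(20L, round(rnorm(cfg$n_genes, cfg$cds_len_mean,
                                    cfg$cds_len_sd) / 3))
  if (any(!is.finite(n_codons)))
    stopf("infeasible CDS length distribution")
  x_genes <- sample.int(cfg$n_genes, round(cfg$x_frac * cfg$n_genes))
  flank <- 50L; ilen <- 100L
  p <- base_probs(cfg$gc)
  models <- vector("list", cfg$n_genes)
  genome <- character(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    gene <- sprintf("G%04d", i)
    chrom <- sprintf("ctg%04d", i)
    nc <- n_codons[i]
    cds <- paste0("ATG",
                  paste(random_codons(nc - 2L, cfg$gc), collapse = ""),
                  sample(STOP_CODONS, 1L))
    L <- nchar(cds)
    cut <- 3L * sample.int(nc - 1L, 1L)          # codon-aligned exon split
    e1 <- substr(cds, 1L, cut); e2 <- substr(cds, cut + 1L, L)
    intron <- paste0("GT",
                     paste(sample(DNA_BASES, ilen - 4L, TRUE, p),
                           collapse = ""), "AG")
    strand <- sample(c("+", "-"), 1L)
    f1 <- paste(sample(DNA_BASES, flank, TRUE, p), collapse = "")
    f2 <- paste(sample(DNA_BASES, flank, TRUE, p), collapse = "")
    if (strand == "+") {
      genome[i] <- paste0(f1, e1, intron, e2, f2)
      s1 <- flank + 1L
      iv <- cbind(c(s1, s1 + nchar(e1) + ilen),
                  c(s1 + nchar(e1) - 1L, s1 + nchar(e1) + ilen + nchar(e2) - 1L))
    } else {
      genome[i] <- paste0(f1, revcomp(e2), revcomp(intron), revcomp(e1), f2)
      s1 <- flank + 1L
      iv <- cbind(c(s1, s1 + nchar(e2) + ilen),
                  c(s1 + nchar(e2) - 1L, s1 + nchar(e2) + ilen + nchar(e1) - 1L))
    }
    models[[i]] <- new_gene_model(gene, paste0("T", i), chrom, strand,
                                  iv[, 1], iv[, 2],
                                  chrx_nonpar = i %in% x_genes)
  }
  names(genome) <- vapply(models, `[[`, character(1), "chrom")
  names(models) <- vapply(models, `[[`, character(1), "gene")
  # site-level deleteriousness mask over missense substitutions
  all_sites <- do.call(rbind, lapply(models, enumerate_sites, genome = genome))
  mis <- all_sites[all_sites$consequence == "missense",
                   c("gene", "pos", "alt")]
  mask <- mis[runif(nrow(mis)) < cfg$dmis_frac, , drop = FALSE]
  rownames(mask) <- NULL
  structure(list(models = models, genome = genome, dmis_mask = mask,
                 cfg = cfg), class = "synthetic_exome")
}

#' Generate a trinucleotide rate table
#'
#' All 64 x 3 = 192 context-to-alternate entries. Rates are log-normal
#' around `rate_mean`; the `"cpg"` spectrum additionally multiplies C>T
#' rates at CpG contexts (NCG middle-C) tenfold, mimicking the dominant
#' feature of the human germline spectrum.
#'
#' @param seed integer seed.
#' @param spectrum `"lognormal"`, `"uniform"` or `"cpg"`.
#' @param rate_mean mean rate per entry.
#' @return a [rate_table()] with 192 entries.
#' @export
gen_rate_table <- function(seed, spectrum = c("lognormal", "uniform", "cpg"),
                           rate_mean = 1e-7) {
  spectrum <- match.arg(spectrum)
  set.seed(seed)
  ctx <- as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                         DNA_BASES,
                         function(ab, c) paste0(substr(ab, 1, 1),
                                                substr(ab, 2, 2), c)))
  from <- rep(ctx, each = 3L)
  alt <- unlist(lapply(substr(ctx, 2, 2),
                       function(m) setdiff(DNA_BASES, m)),
                use.names = FALSE)
  to <- paste0(substr(from, 1, 1), alt, substr(from, 3, 3))
  n <- length(from)
  # strand symmetry: a substitution and its reverse complement are the same
  # mutational event, so they share one rate (as in real germline tables)
  key <- paste0(from, ">", to)
  rc_key <- paste0(vapply(from, function(s) revcomp(s), ""), ">",
                   vapply(to, function(s) revcomp(s), ""))
  canon <- pmin(key, rc_key)
  draw <- switch(spectrum,
    uniform = setNames(rep(rate_mean, n), key),
    lognormal = ,
    cpg = setNames(rate_mean * exp(rnorm(n, 0, 0.5)) / exp(0.125), key))
  rate <- unname(draw[canon])
  if (spectrum == "cpg") {
    # CpG transition in either orientation (C>T with 3' G, or G>A with 5' C)
    cpg <- (substr(from, 2, 2) == "C" & substr(from, 3, 3) == "G" &
              alt == "T") |
           (substr(from, 2, 2) == "G" & substr(from, 1, 1) == "C" &
              alt == "A")
    rate[cpg] <- rate[cpg] * 10
  }
  rate_table(from, to, rate)
}

#' Precompute the site/rate catalog of a synthetic exome
#'
#' Enumerates all substitutions with rates once so repeated cohort draws are
#' cheap. Used internally by the cohort generators; exposed because tests
#' and pipelines reuse it.
#'
#' @param exome a [gen_exome()] result.
#' @param rt a [rate_table()].
#' @return list with `sites` (data.frame incl. `rate` and `delcat`) and
#'   `rates` (per-gene class-rate table using the exome's site mask).
#' @export
exome_site_catalog <- function(exome, rt) {
  sites <- do.call(rbind, lapply(exome$models, enumerate_sites,
                                 genome = exome$genome, rate_table = rt))
  rownames(sites) <- NULL
  mkey <- paste(exome$dmis_mask$gene, exome$dmis_mask$pos,
                exome$dmis_mask$alt)
  is_dmis <- paste(sites$gene, sites$pos, sites$alt) %in% mkey
  sites$delcat <- delcat_of_consequence(sites$consequence, is_dmis)
  rates <- do.call(rbind, lapply(split(sites, sites$gene), function(ss) {
    g <- ss$gene[1]
    out <- class_rates_from_sites(ss, g, dmis_mask = 0,
                                  chrx_nonpar = exome$models[[g]]$chrx_nonpar)
    out$r_dmis <- sum(ss$rate[ss$delcat == "dmis"])
    out
  }))
  rates <- rates[match(names(exome$models), rates$gene), ]
  rownames(rates) <- NULL
  list(sites = sites, rates = rates)
}

sample_cadd <- function(delcat) {
  n <- length(delcat)
  out <- numeric(n)
  out[delcat == "syn"] <- runif(sum(delcat == "syn"), 0, 10)
  out[delcat == "mis"] <- runif(sum(delcat == "mis"), 0, 24.9)
  out[delcat == "dmis"] <- runif(sum(delcat == "dmis"), 25, 40)
  out[delcat == "lgd"] <- runif(sum(delcat == "lgd"), 20, 50)
  round(out, 1)
}

#' Generate a trio cohort of de novo variants
#'
#' Per gene and class, variant counts are Poisson with mean
#' `class rate x allele factor x RR` (allele factor `2N`, or
#' `2 n_female + n_male` for chrX non-PAR genes); positions are drawn within
#' the gene proportionally to site rates; deleterious missense status follows
#' the exome's site mask; CADD-like scores are drawn consistently with the
#' class. Frameshift indels (rate `1.1 x nonsense`) are placed uniformly in
#' the CDS as 1 bp insertions. With all relative risks at 1 this is the null
#' generator; [spike_risk()] passes RR > 1 for chosen genes and reproduces
#' the null byte-for-byte when RR = 1 at the same seed.
#'
#' @param exome a [gen_exome()] result.
#' @param rt a [rate_table()].
#' @param seed integer seed for the cohort draw.
#' @param n_trios,male_frac,complex_frac cohort shape; default from
#'   `exome$cfg`.
#' @param rr named list of per-gene relative risks; each element a numeric
#'   vector `c(syn=, mis=, dmis=, lgd=)` or a scalar applied to dmis+lgd.
#' @param catalog optional precomputed [exome_site_catalog()].
#' @return list with `variants` (data.frame in the de novo table dialect,
#'   plus `context`), `cohort` (a [cohort_spec()]), `truth` (manifest:
#'   per-gene class expectations, rr, seed).
#' @export
gen_null_cohort <- function(exome, rt, seed, n_trios = NULL,
                            male_frac = NULL, complex_frac = NULL,
                            rr = list(), catalog = NULL) {
  cfg <- exome$cfg
  n_trios <- n_trios %||% cfg$n_trios
  male_frac <- male_frac %||% cfg$male_frac
  complex_frac <- complex_frac %||% cfg$complex_frac
  if (is.null(catalog)) catalog <- exome_site_catalog(exome, rt)
  sites <- catalog$sites; rates <- catalog$rates

  set.seed(seed)
  n_male <- round(male_frac * n_trios)
  probands <- data.frame(
    proband = sprintf("P%05d", seq_len(n_trios)),
    sex = sample(rep(c("male", "female"),
                     c(n_male, n_trios - n_male))),
    group = sample(rep(c("complex", "isolated"),
                       c(round(complex_frac * n_trios),
                         n_trios - round(complex_frac * n_trios)))),
    stringsAsFactors = FALSE)
  if (n_trios == 0L)
    probands <- data.frame(proband = character(0), sex = character(0),
                           group = character(0))
  cohortsp <- if (n_trios > 0) cohort_spec(probands) else
    structure(list(n_trios = 0L, n_male = 0L, n_female = 0L,
                   strata = probands), class = "cohort_spec")
  pweight <- ifelse(probands$sex == "female", 2, 1)

  by_gene <- split(sites, sites$gene)
  rows <- list(); lam_rows <- list()
  for (g in names(exome$models)) {
    gm <- exome$models[[g]]
    A <- if (gm$chrx_nonpar) 2 * cohortsp$n_female + cohortsp$n_male else
      2 * n_trios
    ss <- by_gene[[g]]
    mass <- c(syn = sum(ss$rate[ss$delcat == "syn"]),
              mis = sum(ss$rate[ss$delcat == "mis"]),
              dmis = sum(ss$rate[ss$delcat == "dmis"]),
              lgd = sum(ss$rate[ss$delcat == "lgd"]))
    fs_mass <- 1.1 * sum(ss$rate[ss$consequence %in% c("nonsense",
                                                       "stop_loss")])
    grr <- c(syn = 1, mis = 1, dmis = 1, lgd = 1)
    if (g %in% names(rr)) {
      v <- rr[[g]]
      if (length(v) == 1L && is.null(names(v)))
        v <- c(dmis = unname(v), lgd = unname(v))
      grr[names(v)] <- v
    }
    lam <- c(mass * grr, fs = fs_mass * unname(grr["lgd"])) * A
    lam_rows[[g]] <- c(gene = g, lam)
    counts <- rpois(5L, lam)
    names(counts) <- c("syn", "mis", "dmis", "lgd", "fs")
    tot_snv <- sum(counts[1:4])
    if (tot_snv > 0) {
      for (cl in c("syn", "mis", "dmis", "lgd")) {
        if (counts[cl] == 0L) next
        pool <- ss[ss$delcat == cl, , drop = FALSE]
        pick <- pool[sample.int(nrow(pool), counts[cl], replace = TRUE,
                                prob = pool$rate), , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = pick$chrom, pos = pick$pos, ref = pick$ref, alt = pick$alt,
          gene = g, consequence = pick$consequence,
          cadd_phred = sample_cadd(rep(cl, counts[cl])),
          context = pick$context, stringsAsFactors = FALSE)
      }
    }
    if (counts["fs"] > 0) {
      cp <- cds_positions(gm)
      at <- sample(cp, counts["fs"], replace = TRUE)
      refb <- substring(exome$genome[[gm$chrom]], at, at)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = gm$chrom, pos = at, ref = refb,
        alt = paste0(refb, sample(DNA_BASES, counts["fs"], TRUE)),
        gene = g, consequence = "frameshift", cadd_phred = NA_real_,
        context = NA_character_, stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gene = character(0),
               consequence = character(0), cadd_phred = numeric(0),
               context = character(0), stringsAsFactors = FALSE)
  if (nrow(variants) && n_trios > 0) {
    xgene <- vapply(exome$models[variants$gene], `[[`, logical(1),
                    "chrx_nonpar")
    pid <- integer(nrow(variants))
    if (any(xgene))
      pid[xgene] <- sample.int(n_trios, sum(xgene), TRUE, prob = pweight)
    if (any(!xgene))
      pid[!xgene] <- sample.int(n_trios, sum(!xgene), TRUE)
    variants$proband <- probands$proband[pid]
    variants$sex <- probands$sex[pid]
    variants$group <- probands$group[pid]
  } else {
    variants$proband <- character(0); variants$sex <- character(0)
    variants$group <- character(0)
  }
  variants$platform <- rep("WGS", nrow(variants))
  variants <- variants[, c(DENOVO_COLUMNS, "context")]
  rownames(variants) <- NULL
  lam_tab <- as.data.frame(do.call(rbind, lam_rows), stringsAsFactors = FALSE)
  for (cl in c("syn", "mis", "dmis", "lgd", "fs"))
    lam_tab[[cl]] <- as.numeric(lam_tab[[cl]])
  truth <- list(seed = seed, n_trios = n_trios,
                rr = rr, lambda = lam_tab,
                dmis_frac = cfg$dmis_frac)
  list(variants = variants, cohort = cohortsp, truth = truth)
}

#' Spike risk genes into a synthetic cohort
#'
#' Multiplies the class rates of chosen risk genes by relative risks before
#' sampling; everything else, including the random stream, matches
#' [gen_null_cohort()], so `rr = 1` reproduces the null cohort exactly at
#' the same seed.
#'
#' @param exome,rt,seed,n_trios,catalog as in [gen_null_cohort()].
#' @param risk_genes character vector, must be exome genes.
#' @param rr_lgd,rr_dmis relative risks applied to the LGD(-side) and D-mis
#'   classes of risk genes.
#' @return as [gen_null_cohort()]; `truth$risk` lists every injected
#'   parameter.
#' @export
spike_risk <- function(exome, rt, seed, risk_genes, rr_lgd = 1, rr_dmis = 1,
                       n_trios = NULL, catalog = NULL) {
  unknown <- setdiff(risk_genes, names(exome$models))
  if (length(unknown)) stopf("unknown risk gene(s): %s",
                             paste(unknown, collapse = ", "))
  rr <- setNames(rep(list(c(dmis = rr_dmis, lgd = rr_lgd)),
                     length(risk_genes)), risk_genes)
  out <- gen_null_cohort(exome, rt, seed, n_trios = n_trios, rr = rr,
                         catalog = catalog)
  out$truth$risk <- list(risk_genes = risk_genes, rr_lgd = rr_lgd,
                         rr_dmis = rr_dmis)
  out
}

#' Generate an expression matrix with a target-set shift in carriers
#'
#' Normalized log2 expression: per-gene baseline `mu_g ~ N(6, 2)` plus
#' `N(0, 1)` noise; target genes in carrier samples are shifted by `delta`
#' noise standard deviations.
#'
#' @param genes character vector of gene ids.
#' @param n_samples number of samples.
#' @param carriers sample indices or names designated carriers (non-empty,
#'   proper subset).
#' @param target_genes subset of `genes`.
#' @param delta shift in carrier samples, in units of the noise sd (any
#'   real; negative = down-shift).
#' @param seed integer seed.
#' @return list with `matrix` (genes x samples, log2 scale) and `truth`
#'   (delta, carriers, targets, seed).
#' @export
gen_expression <- function(genes, n_samples, carriers, target_genes,
                           delta = 0, seed) {
  if (length(genes) == 0L || n_samples < 2L) stopf("degenerate config")
  if (!all(target_genes %in% genes)) stopf("targets must be a subset of genes")
  if (length(carriers) == 0L || length(carriers) >= n_samples)
    stopf("carriers must be a non-empty proper subset of samples")
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  if (is.character(carriers)) carriers <- match(carriers, samples)
  if (anyNA(carriers)) stopf("carrier sample not found")
  mu <- rnorm(length(genes), 6, 2)
  m <- matrix(rnorm(length(genes) * n_samples, 0, 1), length(genes)) + mu
  dimnames(m) <- list(genes, samples)
  m[genes %in% target_genes, carriers] <-
    m[genes %in% target_genes, carriers] + delta
  list(matrix = m,
       truth = list(delta = delta, carriers = samples[carriers],
                    target_genes = target_genes, seed = seed))
}

#' Generate a gene-set catalog
#' @param genes gene universe.
#' @param n_sets number of sets.
#' @param size_range inclusive size bounds.
#' @param seed integer seed.
#' @return list with `sets` (named list, GMT-writable) and `truth`
#'   (manifest of sizes and seed).
#' @export
gen_gene_sets <- function(genes, n_sets = 200, size_range = c(5, 50), seed) {
  set.seed(seed)
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  sizes <- pmin(sizes, length(genes))
  sets <- lapply(sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("SET%04d", seq_len(n_sets))
  list(sets = sets, truth = list(sizes = setNames(sizes, names(sets)),
                                 seed = seed))
}

#' Generate a pLI table
#' @param genes gene ids.
#' @param seed integer seed.
#' @param high_genes genes forced to pLI in `[0.5, 1]` (e.g. spiked risk
#'   genes, which in real cohorts are enriched for constraint).
#' @return named numeric vector of pLI values in `[0, 1]`.
#' @export
gen_pli <- function(genes, seed, high_genes = character(0)) {
  set.seed(seed)
  pli <- setNames(runif(length(genes)), genes)
  pli[names(pli) %in% high_genes] <- runif(sum(names(pli) %in% high_genes),
                                           0.5, 1)
  pli
}

#' Generate a BED coverage mask for a synthetic exome
#' @param exome a [gen_exome()] result.
#' @param exclude_genes genes to leave uncovered entirely.
#' @return data.frame in the [read_bed()] dialect (1-based inclusive).
#' @export
gen_coverage_mask <- function(exome, exclude_genes = character(0)) {
  keep <- setdiff(names(exome$models), exclude_genes)
  do.call(rbind, lapply(exome$models[keep], function(gm)
    data.frame(chrom = gm$chrom, start = 1L,
               end = nchar(exome$genome[[gm$chrom]]),
               stringsAsFactors = FALSE)))
}

#' Write a BED mask
#' @param mask data.frame from [gen_coverage_mask()] / [read_bed()] dialect.
#' @param path output BED path (0-based half-open on disk).
#' @return invisibly, `path`.
#' @export
write_bed <- function(mask, path) {
  utils::write.table(
    data.frame(mask$chrom, mask$start - 1L, mask$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
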