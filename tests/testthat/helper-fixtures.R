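# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the code paths they check.

tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(seed = 101, n_genes = 12, cds_len_mean = 450,
                              cds_len_sd = 90, n_trios = 150, x_frac = 0.15)
      ex <- gen_exome(cfg)
      rt <- gen_rate_table(202, spectrum = "cpg")
      cache <<- list(cfg = cfg, exome = ex, rt = rt,
                     catalog = exome_site_catalog(ex, rt))
    }
    cache
  }
})

two_gene_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(seed = 77, n_genes = 2, cds_len_mean = 300,
                              cds_len_sd = 1, n_trios = 100, x_frac = 0)
      ex <- gen_exome(cfg)
      # inflated rates so a 2-gene exome yields workable variant counts
      rt <- gen_rate_table(78, rate_mean = 5e-6)
      cache <<- list(exome = ex, rt = rt,
                     index = build_site_index(ex$models, ex$genome,
                                              dmis_mask = ex$dmis_mask))
    }
    cache
  }
})

# brute-force class rates: mutate every CDS base, translate the WHOLE protein
# with Biostrings, and compare protein sequences (independent of the codon-
# local logic inside enumerate_sites)
oracle_class_rates <- function(gm, genome, rt) {
  cds <- cds_sequence(gm, genome)
  L <- nchar(cds)
  prot_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  pos_tx <- if (gm$strand == "-") {
    rev(unlist(Map(seq.int, gm$intervals$start, gm$intervals$end)))
  } else unlist(Map(seq.int, gm$intervals$start, gm$intervals$end))
  chars <- strsplit(genome[[gm$chrom]], "")[[1]]
  acc <- c(synonymous = 0, missense = 0, nonsense = 0, stop_loss = 0,
           splice = 0)
  for (i in seq_len(L)) {
    ref_tx <- substr(cds, i, i)
    gpos <- pos_tx[i]
    ctx <- paste0(chars[gpos - 1], chars[gpos], chars[gpos + 1])
    for (b in setdiff(c("A", "C", "G", "T"), ref_tx)) {
      alt_g <- if (gm$strand == "-") chartr("ACGT", "TGCA", b) else b
      r <- rate_lookup(rt, ctx, alt_g)
      mut <- cds
      substr(mut, i, i) <- b
      prot_alt <- as.character(Biostrings::translate(
        Biostrings::DNAString(mut), no.init.codon = TRUE))
      cls <- if (prot_alt == prot_ref) "synonymous"
      else {
        d <- which(strsplit(prot_alt, "")[[1]] != strsplit(prot_ref, "")[[1]])[1]
        aa_new <- substr(prot_alt, d, d); aa_old <- substr(prot_ref, d, d)
        if (aa_new == "*") "nonsense"
        else if (aa_old == "*") "stop_loss"
        else "missense"
      }
      acc[cls] <- acc[cls] + r
    }
  }
  # splice: first/last 2 bases of each intron
  iv <- gm$intervals
  if (nrow(iv) > 1) {
    a <- iv$end[-nrow(iv)] + 1L; b2 <- iv$start[-1L] - 1L
    for (p in unique(c(a, a + 1L, b2 - 1L, b2))) {
      refb <- chars[p]
      ctx <- paste0(chars[p - 1], chars[p], chars[p + 1])
      for (alt in setdiff(c("A", "C", "G", "T"), refb))
        acc["splice"] <- acc["splice"] + rate_lookup(rt, ctx, alt)
    }
  }
  acc
}

# arbitrary-precision-style Poisson upper tail: direct term summation from O
# upward in log space until terms are negligible
oracle_poisson_tail <- function(o, lambda) {
  if (o == 0) return(1)
  k <- o; total <- 0
  repeat {
    term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
    total <- total + term
    if (term < total * 1e-18 && k > lambda + o) break
    k <- k + 1
    if (k > o + 10000) break
  }
  total
}

# two-sample KS statistic by brute-force ECDF max gap
oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# hypergeometric upper tail by direct combinatorial summation
oracle_hypergeom <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

expect_rel_equal <- function(object, expected, tol) {
  testthat::expect_lt(abs(object - expected) / abs(expected), tol)
}
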