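test_that("site index size equals brute-force substitution arithmetic", {
  tw <- two_gene_world()
  # each CDS position admits 3 substitutions; each of the 1-intron genes
  # adds 4 splice positions x 3 alts; flanks guarantee no context is skipped
  want <- sum(vapply(tw$exome$models, function(gm)
    3L * gm$cds_len + 12L, integer(1)))
  expect_equal(nrow(tw$index$sites), want)
  # a site appears once per (pos, alt) key
  expect_false(anyDuplicated(
    tw$index$sites[, c("chrom", "pos", "alt")]) > 0)
})

test_that("coverage masks restrict the index", {
  tw <- two_gene_world()
  g1 <- names(tw$exome$models)[1]
  mask <- gen_coverage_mask(tw$exome, exclude_genes = g1)
  idx <- build_site_index(tw$exome$models, tw$exome$genome,
                          dmis_mask = tw$exome$dmis_mask,
                          coverage_mask = mask)
  expect_false(g1 %in% idx$sites$gene)
  empty_mask <- data.frame(chrom = "nowhere", start = 1L, end = 0L)
  expect_error(build_site_index(tw$exome$models, tw$exome$genome,
                                coverage_mask = empty_mask), "empty")
})

test_that("single-site keys force the placement", {
  tw <- two_gene_world()
  tab <- table(tw$index$sites$key)
  k <- names(tab)[tab == 1][1]
  site <- tw$index$sites[tw$index$sites$key == k, ]
  v <- data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref,
                  alt = site$alt, proband = "P1", sex = "male",
                  group = "isolated", gene = site$gene,
                  consequence = ifelse(site$consequence == "missense",
                                       "missense", site$consequence),
                  cadd_phred = switch(site$delcat, dmis = 30, mis = 10,
                                      NA_real_),
                  platform = "WGS", context = site$context,
                  stringsAsFactors = FALSE)
  pl <- simulate_placements(v, tw$index, n_sims = 25, seed = 5)
  expect_true(all(tw$index$sites$gene[pl$site_row] == site$gene))
  expect_true(all(tw$index$sites$pos[pl$site_row] == site$pos))
})

test_that("every simulation conserves the observed key histogram", {
  tw <- two_gene_world()
  co <- gen_null_cohort(tw$exome, tw$rt, seed = 81, n_trios = 3000)
  expect_gt(nrow(co$variants), 10)
  pl <- simulate_placements(co$variants, tw$index, n_sims = 100, seed = 6)
  expect_true(assert_key_conservation(pl, tw$index))
  # per-sim variant count equals observed
  expect_true(all(colSums(!is.na(pl$gene_idx)) == nrow(co$variants)))
})

test_that("an unplaceable key is reported with the offending key", {
  tw <- two_gene_world()
  v <- data.frame(chrom = "x", pos = 10L, ref = "A", alt = "C",
                  proband = "P1", sex = "male", group = "isolated",
                  gene = "G", consequence = "synonymous", cadd_phred = 3,
                  platform = "WGS", context = "NNN",
                  stringsAsFactors = FALSE)
  expect_error(simulate_placements(v, tw$index, 10, 1), "NNN")
})

test_that("within-key sampling is uniform over sites (binomial oracle)", {
  tw <- two_gene_world()
  sites <- tw$index$sites
  tab <- table(sites$key)
  # pick a key with sites in both genes
  cand <- names(tab)[tab >= 5]
  k <- cand[which.max(vapply(cand, function(kk)
    length(unique(sites$gene[sites$key == kk])), integer(1)))]
  pool <- sites[sites$key == k, ]
  gA <- pool$gene[1]
  pA <- mean(pool$gene == gA)
  expect_gt(pA, 0); expect_lt(pA, 1)
  v <- data.frame(chrom = pool$chrom[1], pos = pool$pos[1],
                  ref = pool$ref[1], alt = pool$alt[1], proband = "P1",
                  sex = "male", group = "isolated", gene = pool$gene[1],
                  consequence = ifelse(pool$consequence[1] == "missense",
                                       "missense", pool$consequence[1]),
                  cadd_phred = switch(pool$delcat[1], dmis = 30, mis = 10,
                                      lgd = 35, 3),
                  platform = "WGS", context = pool$context[1],
                  stringsAsFactors = FALSE)
  n <- 4000
  pl <- simulate_placements(v, tw$index, n_sims = n, seed = 9)
  hit <- mean(tw$index$sites$gene[pl$site_row] == gA)
  expect_lt(abs(hit - pA), 4 * sqrt(pA * (1 - pA) / n))
})

test_that("whole-exome variants_in_set is the identity: fold 1, p 1", {
  tw <- two_gene_world()
  co <- gen_null_cohort(tw$exome, tw$rt, seed = 82, n_trios = 2000)
  pl <- simulate_placements(co$variants, tw$index, n_sims = 50, seed = 7)
  e <- empirical_enrichment(pl, names(tw$exome$models), co$variants,
                            statistic = "variants_in_set")
  expect_equal(e$fold, 1)
  expect_equal(e$p, 1)
  expect_true(all(e$sims == e$observed))
})

test_that("zero observed statistic gives p = 1; disjoint set gives NA fold", {
  tw <- two_gene_world()
  co <- gen_null_cohort(tw$exome, tw$rt, seed = 83, n_trios = 2000)
  pl <- simulate_placements(co$variants, tw$index, n_sims = 50, seed = 8)
  expect_warning(
    e <- empirical_enrichment(pl, "NOT_A_GENE", co$variants),
    "no genes")
  expect_equal(e$observed, 0)
  expect_equal(e$p, 1)
  expect_true(is.na(e$fold))
})

test_that("placements are reproducible and independent of site ordering", {
  tw <- two_gene_world()
  co <- gen_null_cohort(tw$exome, tw$rt, seed = 84, n_trios = 2000)
  a <- simulate_placements(co$variants, tw$index, n_sims = 20, seed = 11)
  b <- simulate_placements(co$variants, tw$index, n_sims = 20, seed = 11)
  expect_identical(a$gene_idx, b$gene_idx)
  expect_identical(a$site_row, b$site_row)
  # reversing the model list order leaves per-key placement sets identical
  idx2 <- build_site_index(rev(tw$exome$models), tw$exome$genome,
                           dmis_mask = tw$exome$dmis_mask)
  c2 <- simulate_placements(co$variants, idx2, n_sims = 20, seed = 11)
  expect_identical(tw$index$sites$pos[a$site_row],
                   idx2$sites$pos[c2$site_row])
  expect_identical(tw$index$sites$gene[a$site_row],
                   idx2$sites$gene[c2$site_row])
})

test_that("empirical p is super-uniform under the matched null", {
  tw <- two_gene_world()
  sites <- tw$index$sites
  set.seed(42)
  gene_set <- names(tw$exome$models)[1]
  R <- 120; n_sims <- 300
  ps <- vapply(seq_len(R), function(r) {
    draw <- sites[sample.int(nrow(sites), 25, replace = TRUE), ]
    v <- data.frame(chrom = draw$chrom, pos = draw$pos, ref = draw$ref,
                    alt = draw$alt, proband = "P1", sex = "male",
                    group = "isolated", gene = draw$gene,
                    consequence = ifelse(draw$consequence == "missense",
                                         "missense", draw$consequence),
                    cadd_phred = ifelse(draw$delcat == "dmis", 30,
                                 ifelse(draw$delcat == "mis", 10, 35)),
                    platform = "WGS", context = draw$context,
                    stringsAsFactors = FALSE)
    pl <- simulate_placements(v, tw$index, n_sims = n_sims, seed = 9000 + r)
    empirical_enrichment(pl, gene_set, v, "variants_in_set")$p
  }, numeric(1))
  expect_gte(min(ps), 1 / (n_sims + 1))
  expect_lte(max(ps), 1)
  for (t in c(0.1, 0.25, 0.5))
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / R))
  expect_gte(mean(ps), 0.42)   # not grossly conservative either
})

test_that("indels are placed by CDS length within their class", {
  tw <- two_gene_world()
  v <- data.frame(chrom = "c", pos = 5L, ref = "A", alt = "AT",
                  proband = "P1", sex = "male", group = "isolated",
                  gene = names(tw$exome$models)[1],
                  consequence = "frameshift", cadd_phred = NA_real_,
                  platform = "WGS", context = NA_character_,
                  stringsAsFactors = FALSE)
  n <- 4000
  pl <- simulate_placements(v, tw$index, n_sims = n, seed = 12)
  lens <- tw$index$cds_len
  pA <- lens[1] / sum(lens)
  hit <- mean(pl$gene_idx == 1L)
  expect_lt(abs(hit - pA), 4 * sqrt(pA * (1 - pA) / n))
})
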