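test_that("expression ranks point the right way and resolve orthologs by max", {
  e <- c(g1 = 10, g2 = 5, g3 = 1)
  r <- expression_rank(e)
  expect_equal(unname(r["g1"]), 1 / 3)   # highest expression, smallest rank
  expect_equal(unname(r["g3"]), 1)
  # many-to-one orthologs: the human gene takes the highest expression
  m <- matrix(c(3, 7.5, 5), ncol = 1,
              dimnames = list(c("mA", "mB", "mC"), "s1"))
  map <- data.frame(query = c("H1", "H1", "H2"),
                    source = c("mA", "mB", "mC"))
  r2 <- expression_rank(m, map)
  expect_equal(unname(r2["H1"]), 0.5)    # uses 7.5, beating mC's 5
  expect_equal(unname(r2["H2"]), 1)
  # unmapped query genes are tallied, not silently kept
  map2 <- rbind(map, data.frame(query = "H3", source = "absent"))
  expect_equal(attr(expression_rank(m, map2), "n_unmapped"), 1L)
})

test_that("ranks are invariant to monotone transforms; ties share a percentile", {
  set.seed(5)
  e <- stats::setNames(rexp(50), paste0("g", 1:50))
  expect_equal(expression_rank(e), expression_rank(log1p(e) * 3 + 1),
               ignore_attr = TRUE)
  tied <- c(a = 2, b = 2, c = 1)
  r <- expression_rank(tied)
  expect_equal(unname(r["a"]), unname(r["b"]))
  # all-equal expression: one shared percentile, quartile falls back low
  allsame <- stats::setNames(rep(3, 8), paste0("g", 1:8))
  ra <- expression_rank(allsame)
  expect_true(all(ra == ra[1]))
  expect_true(all(expression_quartile(ra) ==
                    expression_quartile(ra)[1]))
  # direct-sort oracle on a random vector without ties
  x <- stats::setNames(sample(100, 20), paste0("h", 1:20))
  ro <- expression_rank(x)
  expect_equal(unname(ro[order(-x)]), seq_len(20) / 20)
  # quartile boundaries: ties at 0.25 go to the top quartile
  expect_equal(expression_quartile(c(0.25, 0.2500001, 0.5, 0.75, 1)),
               c(1L, 2L, 2L, 3L, 4L))
})

test_that("quartile burden finds spiked top-quartile signal and keeps unranked cells", {
  w <- tiny_world()
  genes <- names(w$exome$models)
  # expression: the 3 risk genes most expressed -> top quartile
  risk <- genes[1:3]
  expr <- stats::setNames(seq(100, 10, length.out = length(genes)), genes)
  ranks <- expression_rank(expr)
  expect_true(all(expression_quartile(ranks[risk]) == 1L))
  sp <- spike_risk(w$exome, w$rt, seed = 91, risk_genes = risk,
                   rr_lgd = 150, rr_dmis = 150, n_trios = 400,
                   catalog = w$catalog)
  qb <- quartile_burden(sp$variants, sp$cohort, ranks, w$catalog$rates)
  top <- qb[qb$stratum == "all" & qb$gene_set == "Q1" & qb$class == "LGD", ]
  rest <- qb[qb$stratum == "all" & qb$gene_set %in% c("Q2", "Q3", "Q4") &
               qb$class == "LGD", ]
  expect_gt(top$fold, max(rest$fold))
  # unranked genes surface as an explicit fifth cell
  ranks2 <- ranks[-(1:2)]
  qb2 <- quartile_burden(sp$variants, sp$cohort, ranks2, w$catalog$rates)
  expect_true("unranked" %in% qb2$gene_set)
  un <- qb2[qb2$stratum == "all" & qb2$gene_set == "unranked", ]
  expect_true(all(un$expected > 0))
})

test_that("null quartile burden is calibrated near FE 1", {
  w <- tiny_world()
  genes <- names(w$exome$models)
  ranks <- expression_rank(stats::setNames(rexp(length(genes)), genes))
  R <- 150
  folds <- vapply(seq_len(R), function(r) {
    co <- gen_null_cohort(w$exome, w$rt, seed = 40000 + r,
                          catalog = w$catalog)
    qb <- quartile_burden(co$variants, co$cohort, ranks, w$catalog$rates,
                          strata = "all", classes = "missense")
    sum(qb$observed) / sum(qb$expected)
  }, numeric(1))
  se <- stats::sd(folds) / sqrt(R)
  expect_lt(abs(mean(folds) - 1), 4 * se + 0.02)
})

test_that("KS statistic equals the brute-force ECDF max gap", {
  set.seed(9)
  g <- gen_expression(paste0("g", 1:300), n_samples = 20, carriers = 1:3,
                      target_genes = paste0("g", 1:40), delta = -1.5,
                      seed = 10)
  res <- target_shift_test(g$matrix, g$truth$carriers, g$truth$target_genes)
  expect_equal(res$D, oracle_ks_D(res$target_mean_z, res$background_mean_z),
               tolerance = 1e-12)
  expect_gte(res$D, 0); expect_lte(res$D, 1)
})

test_that("target shift test is calibrated under delta = 0", {
  R <- 200
  ps <- vapply(seq_len(R), function(r) {
    g <- gen_expression(paste0("g", 1:150), n_samples = 16, carriers = 1:3,
                        target_genes = paste0("g", sample(150, 25)),
                        delta = 0, seed = 20000 + r)
    target_shift_test(g$matrix, g$truth$carriers,
                      g$truth$target_genes)$p
  }, numeric(1))
  # two-sided KS p under the null: roughly uniform
  for (t in c(0.05, 0.25, 0.5))
    expect_lt(abs(mean(ps <= t) - t), 0.12)
})

test_that("a real down-shift is detected with the right direction", {
  hits <- vapply(1:40, function(r) {
    g <- gen_expression(paste0("g", 1:200), n_samples = 30, carriers = 1:3,
                        target_genes = paste0("g", 1:74), delta = -0.8,
                        seed = 30000 + r)
    res <- target_shift_test(g$matrix, g$truth$carriers,
                             g$truth$target_genes)
    c(res$direction, res$p)
  }, numeric(2))
  expect_gte(mean(hits[1, ] == -1), 0.99)
  expect_gte(mean(hits[2, ] < 0.01), 0.90)
})

test_that("degenerate shift-test inputs are handled explicitly", {
  g <- gen_expression(paste0("g", 1:50), n_samples = 10, carriers = 1:2,
                      target_genes = "g1", delta = -2, seed = 11)
  res <- target_shift_test(g$matrix, g$truth$carriers, "g1")
  expect_equal(res$n_target, 1L)
  m <- g$matrix
  m["g5", ] <- 4  # constant gene: excluded with a tally
  res2 <- target_shift_test(m, g$truth$carriers, c("g1", "g2"))
  expect_equal(res2$n_excluded_constant, 1L)
  expect_error(target_shift_test(g$matrix, g$truth$carriers, "absent"),
               "no target gene")
  expect_error(gen_expression(paste0("g", 1:5), 10, 1:10, "g1", 0, 1),
               "carriers")
  expect_error(gen_expression(paste0("g", 1:5), 10, 1:2, "zz", 0, 1),
               "subset")
})

test_that("set similarity matches hand evaluation and its bounds", {
  A <- paste0("g", 1:4); B <- paste0("g", 3:6)
  # Jaccard 2/6, overlap 2/4 -> mean 0.41667
  expect_equal(set_similarity(A, B), (2 / 6 + 2 / 4) / 2, tolerance = 1e-12)
  expect_equal(round(set_similarity(A, B), 4), 0.4167)
  expect_equal(set_similarity(A, A), 1)
  expect_equal(set_similarity(A, paste0("x", 1:3)), 0)
  set.seed(12)
  for (i in 1:25) {
    a <- sample(letters, sample(3:20, 1))
    b <- sample(letters, sample(3:20, 1))
    s <- set_similarity(a, b)
    ov <- length(intersect(a, b)) / min(length(a), length(b))
    expect_lte(s, ov)             # Jaccard <= overlap always
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("hypergeometric p equals direct combinatorial summation", {
  # query of 10 with 5 hits in a 20-gene set over a 1000-gene universe
  expect_equal(hypergeom_test(5, 10, 20, 1000),
               oracle_hypergeom(5, 10, 20, 1000), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:20) {
    N <- sample(100:2000, 1); K <- sample(5:80, 1)
    n <- sample(5:50, 1); k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_test(k, n, K, N), oracle_hypergeom(k, n, K, N),
                 tolerance = 1e-10)
  }
})

test_that("enrichment map applies the size band, FDR cut and similarity edges", {
  universe <- paste0("u", 1:1000)
  query <- paste0("u", 1:30)
  sets <- list(
    hit1 = paste0("u", 1:40),          # strongly enriched
    hit2 = paste0("u", 5:44),          # strongly enriched, overlaps hit1
    cold = paste0("u", 500:539),       # no overlap with query
    tiny = paste0("u", 1:10),          # below the size band
    huge = paste0("u", 1:800))         # above the size band
  em <- build_enrichment_map(query, sets, universe, fdr = 0.1,
                             sim_cutoff = 0.375)
  expect_setequal(em$nodes$set, c("hit1", "hit2"))
  expect_true(all(em$nodes$size >= 25 & em$nodes$size <= 750))
  expect_true(all(em$nodes$q < 0.1))
  expect_equal(nrow(em$edges), 1L)
  expect_equal(em$edges$similarity,
               set_similarity(sets$hit1, sets$hit2), tolerance = 1e-12)
  # node set invariant to the order annotation sets are supplied
  em2 <- build_enrichment_map(query, rev(sets), universe, fdr = 0.1)
  expect_identical(em$nodes, em2$nodes)
  # query outside the universe is an error listing offenders
  expect_error(build_enrichment_map(c(query, "alien"), sets, universe),
               "alien")
  # graph round-trips to GraphML and a TSV edge list
  gml <- withr::local_tempfile(fileext = ".graphml")
  etsv <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_map(em, gml, etsv)
  expect_true(file.exists(gml))
  back <- utils::read.delim(etsv)
  expect_equal(nrow(back), nrow(em$edges))
})

test_that("map gene selection combines constraint with the allow-list", {
  v <- data.frame(
    chrom = "c", pos = 1:4, ref = "A", alt = "G",
    proband = paste0("P", 1:4), sex = "male", group = "isolated",
    gene = c("K1", "K2", "K3", "K4"),
    consequence = c("nonsense", "missense", "missense", "synonymous"),
    cadd_phred = c(NA, 30, 10, NA), platform = "WGS",
    stringsAsFactors = FALSE)
  pli <- c(K1 = 0.9, K2 = 0.1, K3 = 0.99, K4 = 1)
  got <- select_map_genes(v, pli, allow_list = "K2")
  # K1 damaging+constrained, K2 damaging+allow-listed; K3's missense is not
  # deleterious, K4 is synonymous-only
  expect_setequal(got, c("K1", "K2"))
})
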