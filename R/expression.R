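#' @name convergence-expression
#' @title Expression-stratified burden and the target-gene shift test
#'
#' @description Normalized expression levels are converted to rank
#' percentiles with smaller values corresponding to higher expression; when
#' a gene maps to several orthologs in the expression source, the highest
#' expression level is assigned before ranking. Quartiles are defined on the
#' percentile, ties going to the lower-numbered (more highly expressed)
#' quartile. The target-gene shift test standardizes each gene's expression
#' to a z-score across all samples, averages the z over carrier samples, and
#' compares the per-gene mean-z distribution of a target set against all
#' other genes with a two-sample Kolmogorov-Smirnov test; direction is the
#' sign of the difference in means.
NULL

#' Read an expression matrix (TSV, genes x samples)
#' @param path TSV with gene ids in the first column.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix
#' @param m numeric matrix with gene rownames.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column ortholog map
#' @param path TSV with columns query gene, source (e.g. mouse) gene.
#' @return data.frame `query`, `source`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  if (nrow(df) && df[1, 1] %in% c("query", "human", "gene"))
    df <- df[-1, , drop = FALSE]
  data.frame(query = df[[1]], source = df[[2]], stringsAsFactors = FALSE)
}

#' Expression rank percentiles
#'
#' @param m expression matrix (genes x samples) or a named per-gene summary
#'   vector; matrices are summarized by row means.
#' @param ortholog_map optional data.frame from [read_ortholog_map()]
#'   mapping query gene ids to the matrix's gene ids. Query genes mapping to
#'   several source genes get the maximum expression; query genes absent
#'   from the map (or mapping only to absent source genes) are excluded and
#'   tallied in the `n_unmapped` attribute.
#' @return named numeric vector of percentiles in `(0, 1]`; smaller = more
#'   highly expressed. Ties share a percentile (average rank). Invariant to
#'   monotone transformations of the expression values.
#' @export
expression_rank <- function(m, ortholog_map = NULL) {
  expr <- if (is.matrix(m)) rowMeans(m) else m
  if (is.null(names(expr))) stopf("expression input must carry gene names")
  n_unmapped <- 0L
  if (!is.null(ortholog_map)) {
    om <- ortholog_map[ortholog_map$source %in% names(expr), , drop = FALSE]
    n_unmapped <- length(setdiff(ortholog_map$query, om$query))
    val <- expr[om$source]
    expr <- vapply(split(val, om$query), max, numeric(1))
  }
  pct <- rank(-expr, ties.method = "average") / length(expr)
  attr(pct, "n_unmapped") <- n_unmapped
  pct
}

#' Quartile of an expression percentile
#' @param pct percentile vector from [expression_rank()].
#' @return integer quartile 1 (top expression) to 4; boundaries are
#'   inclusive on the left, so a gene exactly at 0.25 stays in quartile 1.
#' @export
expression_quartile <- function(pct) {
  q <- findInterval(pct, c(0, 0.25, 0.5, 0.75), left.open = TRUE)
  pmax(pmin(q, 4L), 1L)
}

#' Expression-quartile burden
#'
#' One burden cell per (quartile x class x stratum); genes without a rank
#' fall into an explicit `"unranked"` fifth cell rather than being dropped.
#'
#' @param variants,cohort,rates,rule,strata,classes,male_scale as in
#'   [stratified_burden()].
#' @param ranks percentile vector from [expression_rank()].
#' @return data.frame with a `gene_set` column of the form `"Q1".."Q4"` or
#'   `"unranked"`.
#' @export
quartile_burden <- function(variants, cohort, ranks, rates,
                            rule = variant_class_rule(), strata = NULL,
                            classes = c("LGD", "D-mis"), male_scale = 1) {
  q <- expression_quartile(ranks)
  sets <- split(names(ranks), paste0("Q", q))
  unranked <- setdiff(rates$gene, names(ranks))
  sets$unranked <- unranked
  sets <- sets[lengths(sets) > 0]
  stratified_burden(variants, cohort, sets, rates, rule = rule,
                    strata = strata, classes = classes,
                    male_scale = male_scale)
}

#' Target-gene expression shift test
#'
#' @param m expression matrix (genes x samples), e.g. TPM.
#' @param carrier_samples column names (or indices) of the carrier samples.
#' @param target_genes character vector of putative target genes.
#' @param alternative passed to [stats::ks.test()] (default two-sided, with
#'   direction reported separately).
#' @return object of class `shift_test`: list with `target_mean_z` and
#'   `background_mean_z` (per-gene carrier mean z-scores), `D`, `p`,
#'   `direction` (sign of `mean(target) - mean(background)`),
#'   `n_target`, `n_excluded_constant`.
#' @export
target_shift_test <- function(m, carrier_samples, target_genes,
                              alternative = "two.sided") {
  stopifnot(is.matrix(m))
  if (is.character(carrier_samples))
    carrier_samples <- match(carrier_samples, colnames(m))
  if (anyNA(carrier_samples)) stopf("carrier sample(s) not found in matrix")
  if (length(carrier_samples) < 1L) stopf("need at least one carrier sample")
  sds <- apply(m, 1L, stats::sd)
  constant <- !is.finite(sds) | sds == 0
  n_excluded <- sum(constant)
  m <- m[!constant, , drop = FALSE]
  z <- (m - rowMeans(m)) / sds[!constant]
  mean_z <- rowMeans(z[, carrier_samples, drop = FALSE])
  is_target <- rownames(m) %in% target_genes
  if (!any(is_target)) stopf("no target gene present in the matrix")
  tz <- mean_z[is_target]; bz <- mean_z[!is_target]
  ks <- suppressWarnings(stats::ks.test(tz, bz, alternative = alternative))
  structure(list(target_mean_z = tz, background_mean_z = bz,
                 D = unname(ks$statistic), p = ks$p.value,
                 direction = sign(mean(tz) - mean(bz)),
                 n_target = sum(is_target),
                 n_excluded_constant = n_excluded),
            class = "shift_test")
}

#' @export
print.shift_test <- function(x, ...) {
  cat(sprintf(
    "target shift test: %d target genes, D = %.3f, p = %.3g, direction %+d\n",
    x$n_target, x$D, x$p, x$direction))
  invisible(x)
}
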