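#' @name cohort-io
#' @title Reading and writing cohort inputs
#'
#' @description External formats supported: the de novo variant table (TSV,
#' one row per variant, emulating a deposited supplementary variant list),
#' gene sets (GMT or one-gene-per-line), pLI tables (2-column TSV), coverage
#' masks (BED, 0-based half-open), trinucleotide rate tables (3-column
#' whitespace-delimited), and transcript packs (TSV gene models with CDS
#' sequence for fully offline use). Coordinates are 1-based inclusive in all
#' external files except BED; any conversion happens inside the readers.
NULL

DENOVO_COLUMNS <- c("chrom", "pos", "ref", "alt", "proband", "sex", "group",
                    "gene", "consequence", "cadd_phred", "platform")

#' Cohort specification
#'
#' Trio counts by sex and phenotype stratum, used to scale per-generation
#' mutation rates into cohort expectations.
#'
#' @param probands data.frame with columns `proband`, `sex`
#'   (`"male"`/`"female"`) and `group` (`"isolated"`/`"complex"`; other
#'   labels allowed and kept).
#' @return object of class `cohort_spec` with `n_trios`, `n_male`,
#'   `n_female` and the `strata` table.
#' @export
cohort_spec <- function(probands) {
  stopifnot(is.data.frame(probands),
            all(c("proband", "sex", "group") %in% names(probands)))
  probands <- unique(probands[, c("proband", "sex", "group")])
  if (anyDuplicated(probands$proband))
    stopf("conflicting sex/group annotations for a proband")
  bad <- !(probands$sex %in% c("male", "female"))
  if (any(bad)) stopf("sex must be 'male' or 'female' (offenders: %s)",
                      paste(head(probands$proband[bad]), collapse = ", "))
  structure(list(
    n_trios = nrow(probands),
    n_male = sum(probands$sex == "male"),
    n_female = sum(probands$sex == "female"),
    strata = probands
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d trios (%d male, %d female)\n",
              x$n_trios, x$n_male, x$n_female))
  print(table(x$strata$group))
  invisible(x)
}

#' Restrict a cohort to one stratum
#' @param cohort a [cohort_spec()].
#' @param group stratum label, or `"all"`.
#' @param sex optional `"male"`/`"female"` restriction.
#' @return a new `cohort_spec`.
#' @export
subset_cohort <- function(cohort, group = "all", sex = NULL) {
  st <- cohort$strata
  if (!identical(group, "all")) st <- st[st$group == group, , drop = FALSE]
  if (!is.null(sex)) st <- st[st$sex == sex, , drop = FALSE]
  if (nrow(st) == 0L) stopf("stratum '%s' contains zero trios", group)
  cohort_spec(st)
}

validate_denovo_rows <- function(df) {
  reasons <- rep("", nrow(df))
  add <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond] <<- ifelse(reasons[cond] == "", why,
                             paste(reasons[cond], why, sep = ";"))
  }
  add(df$ref == df$alt, "ref==alt")
  add(!grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt),
      "non-ACGT allele")
  add(!is.finite(df$pos) | df$pos < 1 | df$pos != round(df$pos),
      "bad position")
  add(!(df$consequence %in% CONSEQUENCE_LEVELS), "unknown consequence")
  add(!is.na(df$cadd_phred) & df$cadd_phred < 0, "negative CADD")
  is_snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
  add(!is_snv & !is.na(df$cadd_phred) &
        df$consequence %in% c("frameshift", "inframe") & FALSE, "unused")
  reasons
}

#' Read a de novo variant table
#'
#' TSV with mandatory columns `chrom, pos, ref, alt, proband, sex, group,
#' gene, consequence, cadd_phred, platform`; extra columns are kept.
#' Malformed rows (ref==alt, non-ACGT alleles, bad positions, unknown
#' consequences) are rejected with their line numbers. Trinucleotide
#' contexts for SNVs are derived from `genome` when supplied; indels never
#' carry a context.
#'
#' @param path TSV file path.
#' @param genome optional named character vector of contig sequences used to
#'   derive `context` for SNVs.
#' @return list with `variants` (data.frame, plus a `context` column when
#'   derivable), `cohort` (a [cohort_spec()]) and `rejected` (data.frame of
#'   line numbers and reasons; zero rows when clean).
#' @export
read_denovo_table <- function(path, genome = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  # read everything as character first: bare "T"/"F" alleles must not be
  # type-sniffed into logicals
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(DENOVO_COLUMNS, names(df))
  if (length(missing_cols))
    stopf("de novo table %s lacks mandatory column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  df$pos <- as.numeric(df$pos)
  df$cadd_phred <- suppressWarnings(as.numeric(df$cadd_phred))
  reasons <- validate_denovo_rows(df)
  rejected <- data.frame(line = which(reasons != "") + 1L,  # +1 for header
                         reason = reasons[reasons != ""],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warnf("%d malformed row(s) rejected (lines %s)", nrow(rejected),
          paste(head(rejected$line, 10L), collapse = ", "))
  df <- df[reasons == "", , drop = FALSE]
  df$pos <- as.integer(df$pos)
  if (!is.null(genome)) df$context <- variant_context(df, genome)
  cohort <- cohort_spec(data.frame(proband = df$proband, sex = df$sex,
                                   group = df$group,
                                   stringsAsFactors = FALSE))
  list(variants = df, cohort = cohort, rejected = rejected)
}

#' Derive trinucleotide contexts for SNV rows
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param genome named character vector of contig sequences.
#' @return character vector; `NA` for indels or out-of-range positions.
#' @export
variant_context <- function(variants, genome) {
  n <- nrow(variants)
  ctx <- rep(NA_character_, n)
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  for (i in which(is_snv)) {
    chrom <- variants$chrom[i]; pos <- variants$pos[i]
    if (!chrom %in% names(genome)) next
    seq <- genome[[chrom]]
    if (pos < 2 || pos > nchar(seq) - 1L) next
    tri <- substr(seq, pos - 1L, pos + 1L)
    if (substr(tri, 2, 2) != variants$ref[i]) {
      warnf("reference mismatch at %s:%d (table %s, genome %s)",
            chrom, pos, variants$ref[i], substr(tri, 2, 2))
      next
    }
    ctx[i] <- tri
  }
  ctx
}

#' Write a de novo variant table
#' @param variants data.frame as returned in `read_denovo_table()$variants`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_denovo_table <- function(variants, path) {
  cols <- c(DENOVO_COLUMNS, setdiff(names(variants), DENOVO_COLUMNS))
  utils::write.table(variants[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets (GMT or one-gene-per-line)
#'
#' GMT lines are `name<TAB>description<TAB>member...`; membership is
#' deduplicated and empty sets are dropped with a warning.
#'
#' @param path file path.
#' @param format `"GMT"` or `"list"` (one gene per line; the set is named
#'   after the file).
#' @return named list of character vectors (a `GeneSetCollection` in spirit).
#' @export
read_gene_sets <- function(path, format = c("GMT", "list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "list") {
    genes <- unique(trimws(lines))
    out <- list(genes)
    names(out) <- tools::file_path_sans_ext(basename(path))
    if (length(genes) == 0L) warnf("empty gene list in %s", path)
    return(out)
  }
  if (length(lines) == 0L) {
    warnf("empty GMT file %s", path)
    return(setNames(list(), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stopf("unparseable GMT line %d in %s", bad[1], path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warnf("dropping %d empty gene set(s): %s", sum(empty),
          paste(head(names(sets)[empty]), collapse = ", "))
    sets <- sets[!empty]
  }
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of descriptions.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a pLI table
#' @param path 2-column TSV (gene, pLI), header optional.
#' @return named numeric vector of pLI values.
#' @export
read_pli <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  if (suppressWarnings(is.na(as.numeric(df[1, 2])))) df <- df[-1, , drop = FALSE]
  pli <- as.numeric(df[[2]])
  if (any(is.na(pli) | pli < 0 | pli > 1)) stopf("pLI values must be in [0,1]")
  setNames(pli, df[[1]])
}

#' Read a BED coverage mask
#' @param path BED path (0-based half-open).
#' @return data.frame `chrom`, `start` (1-based), `end` (inclusive).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]],
             start = as.integer(df[[2]]) + 1L,   # to 1-based inclusive
             end = as.integer(df[[3]]),
             stringsAsFactors = FALSE)
}

#' Read a trinucleotide mutation-rate table
#'
#' Whitespace-delimited, three columns: reference trinucleotide, alternate
#' trinucleotide (differing at the middle base), per-chromosome
#' per-generation mutation probability. A header line is tolerated. A
#' complete table holds 64 x 3 = 192 entries; strand-complement lookups are
#' resolved by [rate_lookup()].
#'
#' @param path file path.
#' @return object of class `rate_table`: named numeric vector keyed
#'   `"REF>ALT"` on trinucleotides.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stopf("rate table needs 3 columns (from, to, rate)")
  if (suppressWarnings(is.na(as.numeric(df[1, 3])))) df <- df[-1, , drop = FALSE]
  rate_table(df[[1]], df[[2]], as.numeric(df[[3]]))
}

#' Construct a rate table from vectors
#' @param from,to trinucleotide reference and alternate contexts.
#' @param rate per-generation mutation probabilities (> 0).
#' @return a `rate_table`.
#' @export
rate_table <- function(from, to, rate) {
  from <- toupper(from); to <- toupper(to)
  ok <- grepl("^[ACGT]{3}$", from) & grepl("^[ACGT]{3}$", to)
  if (!all(ok)) stopf("contexts must be ACGT trinucleotides")
  if (any(substr(from, 1, 1) != substr(to, 1, 1) |
          substr(from, 3, 3) != substr(to, 3, 3) |
          substr(from, 2, 2) == substr(to, 2, 2)))
    stopf("alternate context must differ from reference exactly at the middle base")
  if (any(!is.finite(rate) | rate <= 0)) stopf("all rates must be > 0")
  structure(setNames(rate, paste0(from, ">", to)), class = "rate_table")
}

#' Write a rate table
#' @param rt a `rate_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_rate_table <- function(rt, path) {
  key <- strsplit(names(rt), ">", fixed = TRUE)
  df <- data.frame(from = vapply(key, `[[`, "", 1L),
                   to = vapply(key, `[[`, "", 2L),
                   rate = as.numeric(rt))
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = c("from", "to", "prob"))
  invisible(path)
}

#' Look up context rates with strand-complement fallback
#' @param rt a `rate_table`.
#' @param context reference trinucleotides.
#' @param alt alternate middle bases.
#' @return numeric vector of rates; errors listing missing contexts.
#' @export
rate_lookup <- function(rt, context, alt) {
  to <- paste0(substr(context, 1, 1), alt, substr(context, 3, 3))
  key <- paste0(context, ">", to)
  r <- unname(rt[key])
  miss <- is.na(r)
  if (any(miss)) {  # strand complement
    key2 <- paste0(revcomp(context[miss]), ">", revcomp(to[miss]))
    r[miss] <- unname(rt[key2])
  }
  if (anyNA(r))
    stopf("rate table is missing context(s): %s",
          paste(unique(key[is.na(r)]), collapse = ", "))
  r
}
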