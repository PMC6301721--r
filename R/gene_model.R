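#' @name gene-models
#' @title Gene models and exhaustive substitution enumeration
#'
#' @description A gene model is one selected transcript per gene: chromosome,
#' strand, ordered CDS intervals (1-based inclusive) and, implicitly through
#' the genome sequence, the spliced CDS. The baseline mutation model and the
#' placement simulation both rest on `enumerate_sites()`, which lists every
#' possible single-base substitution in the CDS (plus the two canonical
#' splice-site bases at each intron end) together with its genomic
#' trinucleotide context and codon-level consequence.
NULL

new_gene_model <- function(gene, transcript, chrom, strand, starts, ends,
                           chrx_nonpar = FALSE) {
  stopifnot(strand %in% c("+", "-"), length(starts) == length(ends),
            all(ends >= starts))
  o <- order(starts)
  starts <- as.integer(starts[o]); ends <- as.integer(ends[o])
  if (length(starts) > 1L && any(starts[-1] <= ends[-length(ends)]))
    stopf("gene %s: overlapping CDS intervals", gene)
  len <- sum(ends - starts + 1L)
  if (len %% 3L != 0L)
    stopf("gene %s: CDS length %d not divisible by 3", gene, len)
  structure(list(gene = gene, transcript = transcript, chrom = chrom,
                 strand = strand,
                 intervals = data.frame(start = starts, end = ends),
                 cds_len = len, chrx_nonpar = isTRUE(chrx_nonpar)),
            class = "gene_model")
}

#' Select the transcript used for rate computation
#'
#' The transcript with the longest CDS is used; ties are broken by the
#' lexicographically smallest transcript identifier (plain string order), so
#' selection is deterministic.
#'
#' @param transcripts list of `gene_model` objects for one gene.
#' @return the selected `gene_model`.
#' @export
select_transcript <- function(transcripts) {
  if (length(transcripts) == 0L) stopf("no transcripts supplied")
  lens <- vapply(transcripts, `[[`, integer(1), "cds_len")
  ids <- vapply(transcripts, `[[`, character(1), "transcript")
  keep <- which(lens == max(lens))
  transcripts[[keep[order(ids[keep])[1L]]]]
}

# genomic CDS positions in transcript (5'->3') order
cds_positions <- function(gm) {
  pos <- unlist(Map(seq.int, gm$intervals$start, gm$intervals$end),
                use.names = FALSE)
  if (gm$strand == "-") rev(pos) else pos
}

#' Spliced CDS sequence of a gene model
#' @param gm a `gene_model`.
#' @param genome named character vector of contig sequences.
#' @return the CDS as a character string in transcript orientation.
#' @export
cds_sequence <- function(gm, genome) {
  chars <- strsplit(genome[[gm$chrom]], "", fixed = TRUE)[[1]]
  b <- chars[cds_positions(gm)]
  if (gm$strand == "-") b <- comp_base(b)
  paste(b, collapse = "")
}

GENETIC_CODE_TBL <- NULL  # populated at load time (Biostrings)

.onLoad <- function(libname, pkgname) {
  GENETIC_CODE_TBL <<- Biostrings::GENETIC_CODE
}

codon_consequence <- function(ref_codon, alt_codon, codon_index,
                              start_codon_class = "missense") {
  aa_ref <- unname(GENETIC_CODE_TBL[ref_codon])
  aa_alt <- unname(GENETIC_CODE_TBL[alt_codon])
  out <- ifelse(aa_ref == aa_alt, "synonymous",
         ifelse(aa_alt == "*", "nonsense",
         ifelse(aa_ref == "*", "stop_loss", "missense")))
  # substitutions destroying the start codon: counted with the configured
  # class (missense by default); synonymous changes at codon 1 stay synonymous
  out[codon_index == 1L & out == "missense"] <- start_codon_class
  out
}

#' Enumerate all single-base substitutions of a gene model
#'
#' Lists every possible SNV in the CDS with its codon-level consequence, plus
#' the two intronic bases at each donor/acceptor (class `splice_site`).
#' Contexts containing `N` or falling off a contig edge are skipped and
#' tallied in the `n_skipped` attribute. Stop-loss substitutions in the
#' terminal stop codon are classed `stop_loss` (counted with the
#' nonsense/LGD rate mass downstream).
#'
#' @param gm a `gene_model`.
#' @param genome named character vector of contig sequences.
#' @param rate_table optional [rate_table()]; adds a `rate` column.
#' @param start_codon_class class assigned to non-synonymous substitutions in
#'   codon 1 (default `"missense"`).
#' @return data.frame with columns `gene, chrom, pos, ref, alt, context,
#'   consequence` (all on the plus strand of the genome) and `rate` when a
#'   rate table is given.
#' @export
enumerate_sites <- function(gm, genome, rate_table = NULL,
                            start_codon_class = "missense") {
  chars <- strsplit(genome[[gm$chrom]], "", fixed = TRUE)[[1]]
  clen <- length(chars)
  pos <- cds_positions(gm)
  refg <- chars[pos]
  reft <- if (gm$strand == "-") comp_base(refg) else refg
  cds <- paste(reft, collapse = "")
  L <- length(pos)
  ci <- (seq_len(L) - 1L) %/% 3L + 1L
  off <- (seq_len(L) - 1L) %% 3L + 1L
  ref_codon <- substring(cds, 3L * (ci - 1L) + 1L, 3L * ci)

  rows <- vector("list", 3L)
  k <- 0L
  for (b in DNA_BASES) {
    idx <- which(reft != b)
    if (!length(idx)) next
    alt_codon <- ref_codon[idx]
    substr(alt_codon, off[idx], off[idx]) <- b
    cons <- codon_consequence(ref_codon[idx], alt_codon, ci[idx],
                              start_codon_class)
    k <- k + 1L
    rows[[k]] <- data.frame(
      pos = pos[idx],
      alt_tx = b,
      consequence = cons,
      stringsAsFactors = FALSE)
  }
  cod <- do.call(rbind, rows[seq_len(k)])
  cod$ref <- chars[cod$pos]
  cod$alt <- if (gm$strand == "-") comp_base(cod$alt_tx) else cod$alt_tx
  cod$alt_tx <- NULL

  # canonical splice dinucleotides: first/last two bases of each intron
  iv <- gm$intervals
  spl <- NULL
  if (nrow(iv) > 1L) {
    a <- iv$end[-nrow(iv)] + 1L
    b2 <- iv$start[-1L] - 1L
    keep <- b2 - a + 1L >= 4L
    sp <- unique(c(a[keep], a[keep] + 1L, b2[keep] - 1L, b2[keep]))
    if (length(sp)) {
      refs <- chars[sp]
      spl <- do.call(rbind, lapply(DNA_BASES, function(bb) {
        j <- which(refs != bb)
        if (!length(j)) return(NULL)
        data.frame(pos = sp[j], consequence = "splice_site", ref = refs[j],
                   alt = bb, stringsAsFactors = FALSE)
      }))
    }
  }
  sites <- rbind(cod[, c("pos", "consequence", "ref", "alt")],
                 spl[, c("pos", "consequence", "ref", "alt")])

  ok_ctx <- sites$pos >= 2L & sites$pos <= clen - 1L
  ctx <- rep(NA_character_, nrow(sites))
  ctx[ok_ctx] <- paste0(chars[sites$pos[ok_ctx] - 1L], chars[sites$pos[ok_ctx]],
                        chars[sites$pos[ok_ctx] + 1L])
  good <- ok_ctx & !grepl("N", ctx, fixed = TRUE) &
    sites$ref %in% DNA_BASES
  n_skipped <- sum(!good)
  sites <- sites[good, , drop = FALSE]
  sites$context <- ctx[good]
  out <- data.frame(gene = gm$gene, chrom = gm$chrom, pos = sites$pos,
                    ref = sites$ref, alt = sites$alt, context = sites$context,
                    consequence = sites$consequence, stringsAsFactors = FALSE)
  if (!is.null(rate_table))
    out$rate <- rate_lookup(rate_table, out$context, out$alt)
  attr(out, "n_skipped") <- n_skipped
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# transcript pack I/O (fully offline gene-model exchange format)

#' Write a transcript pack
#'
#' TSV with one row per selected transcript: gene, transcript, chrom, strand,
#' comma-separated CDS starts and ends (1-based inclusive), chrX non-PAR
#' flag, and the spliced CDS sequence.
#'
#' @param models list of `gene_model` objects.
#' @param genome named character vector of contig sequences.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_transcript_pack <- function(models, genome, path) {
  df <- do.call(rbind, lapply(models, function(gm) data.frame(
    gene = gm$gene, transcript = gm$transcript, chrom = gm$chrom,
    strand = gm$strand,
    cds_starts = paste(gm$intervals$start, collapse = ","),
    cds_ends = paste(gm$intervals$end, collapse = ","),
    chrx_nonpar = as.integer(gm$chrx_nonpar),
    cds_seq = cds_sequence(gm, genome),
    stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript pack
#' @param path TSV written by [write_transcript_pack()].
#' @param genome optional genome; when supplied, stored CDS sequences are
#'   checked against it.
#' @return named list of `gene_model` objects.
#' @export
read_transcript_pack <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "transcript", "chrom", "strand", "cds_starts", "cds_ends")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("transcript pack lacks column(s): %s",
                          paste(miss, collapse = ", "))
  models <- lapply(seq_len(nrow(df)), function(i) {
    gm <- new_gene_model(df$gene[i], df$transcript[i], df$chrom[i],
                         df$strand[i],
                         as.integer(strsplit(df$cds_starts[i], ",")[[1]]),
                         as.integer(strsplit(df$cds_ends[i], ",")[[1]]),
                         isTRUE(df$chrx_nonpar[i] == 1))
    if (!is.null(genome) && "cds_seq" %in% names(df)) {
      got <- cds_sequence(gm, genome)
      if (!identical(got, df$cds_seq[i]))
        stopf("gene %s: stored CDS sequence disagrees with genome", gm$gene)
    }
    gm
  })
  names(models) <- df$gene
  models
}

#' Read gene models from GTF/GFF and a genome FASTA
#'
#' Imports CDS features, groups them into transcripts, and keeps the longest
#' CDS per gene (ties broken by transcript id, see [select_transcript()]).
#' Genes whose CDS length is not a multiple of 3 are skipped with a message.
#' Requires the `rtracklayer` package.
#'
#' @param gtf_path GTF/GFF3 path.
#' @param fasta_path genome FASTA path.
#' @param chrx_nonpar_chroms chromosome names flagged as X non-PAR
#'   (pseudoautosomal regions are not modelled here).
#' @return list with `models` (named list of `gene_model`) and `genome`
#'   (named character vector).
#' @export
read_gene_models_gtf <- function(gtf_path, fasta_path,
                                 chrx_nonpar_chroms = c("X", "chrX")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("read_gene_models_gtf requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(gtf_path))
  gr <- gr[gr$type == "CDS", , drop = FALSE]
  genome <- read_genome_fasta(fasta_path)
  pieces <- split(seq_len(nrow(gr)),
                  paste(gr$gene_id, gr$transcript_id, sep = "\r"))
  tx <- lapply(pieces, function(ix) {
    g <- gr[ix, , drop = FALSE]
    tryCatch(new_gene_model(
      gene = g$gene_id[1], transcript = g$transcript_id[1],
      chrom = as.character(g$seqnames[1]),
      strand = as.character(g$strand[1]),
      starts = g$start, ends = g$end,
      chrx_nonpar = as.character(g$seqnames[1]) %in% chrx_nonpar_chroms),
      error = function(e) { message(conditionMessage(e)); NULL })
  })
  tx <- Filter(Negate(is.null), tx)
  by_gene <- split(tx, vapply(tx, `[[`, character(1), "gene"))
  models <- lapply(by_gene, select_transcript)
  list(models = models, genome = genome)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return named character vector of contig sequences (uppercase).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome FASTA
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
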