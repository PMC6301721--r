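#' @name classify
#' @title Variant functional classification
#'
#' @description Variants arrive annotated with a consequence (the most severe
#' effect on the canonical transcript) and, for missense SNVs, a phred-scaled
#' CADD deleteriousness score. Classification collapses these into the burden
#' classes used throughout the package: synonymous, missense, D-mis
#' (deleterious missense, CADD >= threshold), LGD (likely gene disrupting),
#' inframe and other.
NULL

CONSEQUENCE_LEVELS <- c("synonymous", "missense", "inframe", "frameshift",
                        "nonsense", "splice_site", "stop_loss")

#' Variant classification rule
#'
#' @param dmis_threshold phred-scaled CADD cutoff at or above which a missense
#'   variant is called deleterious (D-mis). Default 25.
#' @param lgd_members consequence values counted as likely gene disrupting.
#'   Stop-loss is included by default: operationally it abolishes the protein
#'   product like a nonsense variant.
#' @return an object of class `variant_class_rule`.
#' @export
variant_class_rule <- function(dmis_threshold = 25,
                               lgd_members = c("frameshift", "nonsense",
                                               "splice_site", "stop_loss")) {
  if (!is.numeric(dmis_threshold) || length(dmis_threshold) != 1L ||
      dmis_threshold <= 0)
    stopf("dmis_threshold must be a single positive number")
  lgd_members <- unique(as.character(lgd_members))
  if (length(lgd_members) == 0L) stopf("lgd_members must be non-empty")
  bad <- setdiff(lgd_members, CONSEQUENCE_LEVELS)
  if (length(bad)) stopf("unknown consequence in lgd_members: %s",
                         paste(bad, collapse = ", "))
  structure(list(dmis_threshold = dmis_threshold, lgd_members = lgd_members),
            class = "variant_class_rule")
}

#' Classify variants into burden classes
#'
#' Deterministic and total over all consequence values. A missense variant
#' with a missing CADD score is labelled `"unscored"` (never silently folded
#' into another class); by default unscored missense is excluded from both
#' the missense and D-mis burden cells downstream.
#'
#' @param consequence character vector of consequence values (see
#'   [variant_class_rule()] for the enum).
#' @param cadd_phred numeric vector of phred-scaled CADD scores (`NA` allowed
#'   for non-missense and indels).
#' @param rule a [variant_class_rule()].
#' @return character vector with values in
#'   `{synonymous, missense, D-mis, LGD, inframe, unscored, other}`.
#'   D-mis is the more specific label for a missense meeting the threshold.
#' @examples
#' rule <- variant_class_rule()
#' classify_variant("missense", 25.9, rule)   # "D-mis"
#' classify_variant("frameshift", NA, rule)   # "LGD"
#' classify_variant("missense", 24.999, rule) # "missense"
#' @export
classify_variant <- function(consequence, cadd_phred = NA_real_,
                             rule = variant_class_rule()) {
  stopifnot(inherits(rule, "variant_class_rule"))
  n <- length(consequence)
  cadd_phred <- rep_len(as.numeric(cadd_phred), n)
  consequence <- as.character(consequence)
  bad <- !is.na(consequence) & !(consequence %in% CONSEQUENCE_LEVELS)
  if (any(bad)) stopf("unknown consequence value(s): %s",
                      paste(unique(consequence[bad]), collapse = ", "))
  out <- rep("other", n)
  out[consequence %in% rule$lgd_members] <- "LGD"
  is_mis <- !is.na(consequence) & consequence == "missense" &
    !(consequence %in% rule$lgd_members)
  out[is_mis & is.na(cadd_phred)] <- "unscored"
  out[is_mis & !is.na(cadd_phred) & cadd_phred >= rule$dmis_threshold] <- "D-mis"
  out[is_mis & !is.na(cadd_phred) & cadd_phred < rule$dmis_threshold] <- "missense"
  out[consequence == "synonymous" & !("synonymous" %in% rule$lgd_members)] <- "synonymous"
  out[consequence == "inframe" & !("inframe" %in% rule$lgd_members)] <- "inframe"
  out
}

#' Transition/transversion ratio of a set of SNVs
#'
#' Transitions are A<->G and C<->T; everything else among single-base
#' substitutions is a transversion. Non-SNV rows are ignored.
#'
#' @param ref,alt character vectors of reference and alternate alleles.
#' @return the Ts/Tv ratio (`NaN` when no transversions are present and no
#'   transitions either; `Inf` when transversions are absent).
#' @export
ts_tv <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  r <- ref[snv]; a <- alt[snv]
  ts <- sum((r == "A" & a == "G") | (r == "G" & a == "A") |
              (r == "C" & a == "T") | (r == "T" & a == "C"))
  tv <- sum(snv) - ts
  ts / tv
}
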