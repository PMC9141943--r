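#' Read a label-free protein quantity table
#'
#' Tab-separated table with columns `accession`, `description`, `peptides`
#' followed by one quantity column per growth condition. Cells reading `ND`
#' (not detected, i.e. below the detection limit) become `NA` and stay a
#' distinct state throughout: they are never imputed as zero or a
#' pseudocount. The S-layer reference table shipped with the package
#' (28 surface-layer-associated proteins quantified under four
#' strain/carbon-source conditions, with the published log2 ratio columns
#' `logR1_printed` and `logR2_printed`) lives at
#' `system.file("extdata", "slayer_table1.tsv", package = "pulascreen")`.
#'
#' @param path TSV file path.
#' @return data.frame; quantity columns numeric with `NA` for ND.
#' @export
read_protein_quant <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("accession", "description", "peptides")
  for (cn in setdiff(names(df), meta)) {
    v <- df[[cn]]
    v[v %in% c("ND", "")] <- NA
    df[[cn]] <- as.numeric(v)
  }
  df
}

#' ND-aware log2 ratio and fold change
#'
#' Both return ND (`NA`) when either input is ND or zero; negative
#' quantities are a domain error. With both inputs detected,
#' `fold_change(a, b) == 2 ^ log2_ratio(a, b)`.
#'
#' @param a,b Numeric vectors of quantities (`NA` = not detected).
#' @return Numeric vector with `NA` for ND results.
#' @examples
#' log2_ratio(2.5e7, 2.8e5) # 6.48: a ~90-fold enrichment
#' @export
log2_ratio <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("quantities must be non-negative", call. = FALSE)
  }
  ifelse(is.na(a) | is.na(b) | a == 0 | b == 0, NA_real_, log2(a / b))
}

#' @rdname log2_ratio
#' @export
fold_change <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("quantities must be non-negative", call. = FALSE)
  }
  ifelse(is.na(a) | is.na(b) | a == 0 | b == 0, NA_real_, a / b)
}

#' Display phrasing for a fold change
#'
#' Fold changes of 50 and above are phrased to the nearest ten ("90-fold"
#' for 89.3); smaller ones to the nearest integer; ND stays "ND".
#'
#' @param fc Numeric vector of fold changes.
#' @return Character vector.
#' @export
fold_phrase <- function(fc) {
  ifelse(is.na(fc), "ND",
         ifelse(fc >= 50,
                paste0(round_half_away(fc / 10) * 10, "-fold"),
                paste0(round_half_away(fc), "-fold")))
}

#' Contrast two conditions across a protein quantity table
#'
#' Computes one log2 ratio and fold change per row for
#' `numerator`/`denominator`, sorted by descending log2 ratio with ND
#' results last. Swapping the contrast negates every detected log2 ratio.
#'
#' @param rows data.frame from [read_protein_quant()].
#' @param numerator,denominator Condition column names.
#' @return data.frame `accession`, `contrast`, `log2_ratio`, `fold_change`.
#' @export
contrast_table <- function(rows, numerator, denominator) {
  for (cn in c(numerator, denominator)) {
    if (!cn %in% names(rows)) {
      stop("unknown condition label: ", cn, call. = FALSE)
    }
  }
  lr <- log2_ratio(rows[[numerator]], rows[[denominator]])
  fc <- fold_change(rows[[numerator]], rows[[denominator]])
  out <- data.frame(accession = rows$accession,
                    contrast = paste0(numerator, "/", denominator),
                    log2_ratio = lr, fold_change = fc,
                    stringsAsFactors = FALSE)
  out <- out[order(is.na(out$log2_ratio), -ifelse(is.na(out$log2_ratio),
                                                  Inf, out$log2_ratio)), ]
  rownames(out) <- NULL
  out
}

#' Fraction of a proteome total contributed by a protein group
#'
#' Sums the detected quantities of the table's rows per condition and
#' divides by a supplied whole-proteome total (ND rows contribute nothing
#' to the group sum).
#'
#' @param rows data.frame from [read_protein_quant()].
#' @param group_total Named numeric vector: whole-proteome total per
#'   condition (must be positive).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
fraction_of_group <- function(rows, group_total) {
  if (any(group_total <= 0)) stop("totals must be positive", call. = FALSE)
  vapply(names(group_total), function(cn) {
    if (!cn %in% names(rows)) stop("unknown condition label: ", cn,
                                   call. = FALSE)
    sum(rows[[cn]], na.rm = TRUE) / group_total[[cn]]
  }, numeric(1))
}
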