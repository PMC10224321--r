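# Cleaning, frequency filtering, pool merging, one-hamming purge, and
# stability (pH/Tm) class construction.

#' Remove sequences with stop codons or invalid characters
#'
#' Keeps only strings composed entirely of the 20 canonical one-letter
#' amino-acid codes, preserving input order. A sequence containing `*`
#' counts as a stop-codon removal; any other non-canonical content
#' (ambiguity codes, lowercase, empty strings) counts as invalid.
#'
#' @param raw character vector of candidate sequences.
#' @return list with `kept` (character vector) and `report` (a
#'   `cleaning_report`: n_input, n_removed_stop, n_removed_invalid, n_kept).
#' @export
clean_sequences <- function(raw) {
  raw <- as.character(raw)
  has_stop <- grepl("*", raw, fixed = TRUE)
  valid <- !has_stop & nchar(raw) > 0 &
    !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), raw)
  report <- structure(list(n_input = length(raw),
                           n_removed_stop = sum(has_stop),
                           n_removed_invalid = sum(!valid & !has_stop),
                           n_kept = sum(valid)),
                      class = "cleaning_report")
  stopifnot(report$n_input ==
              report$n_kept + report$n_removed_stop + report$n_removed_invalid)
  list(kept = raw[valid], report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d in, %d kept, %d stop-codon, %d invalid\n",
              x$n_input, x$n_kept, x$n_removed_stop, x$n_removed_invalid))
  invisible(x)
}

# Pool-specific minimum read counts: reads below these are background.
FREQUENCY_THRESHOLDS <- c(MACS = 10L, FACS = 4L)

#' Drop sub-threshold background reads from a sorted pool
#'
#' Sequences appearing fewer than 10 times (MACS) or 4 times (FACS) are
#' treated as sequencing background and removed; the keep rule is
#' therefore count >= 10 for MACS and count >= 4 for FACS. The naive pool
#' has no threshold and is rejected.
#'
#' @param table a [read_count_table()] with pool `"MACS"` or `"FACS"`.
#' @return character vector of retained sequences (possibly empty).
#' @export
frequency_filter <- function(table) {
  stopifnot(inherits(table, "read_count_table"))
  if (!table$pool %in% names(FREQUENCY_THRESHOLDS))
    stop("frequency_filter supports MACS and FACS pools only, got '",
         table$pool, "'")
  thr <- FREQUENCY_THRESHOLDS[[table$pool]]
  if (length(table$counts) == 0L) return(character(0))
  names(table$counts)[table$counts >= thr]
}

#' Merge pools into a labelled dataset with a one-hamming purge
#'
#' The enriched (positive) class is the union of the filtered MACS and
#' FACS sequences. Negatives are naive-pool sequences that (a) do not
#' appear in the enriched set and (b) lie at hamming distance >= 2 from
#' every enriched sequence; naive records within one substitution of an
#' enriched member are purged as likely deep-sequencing errors. The purge
#' only ever removes naive records -- enriched members are never dropped.
#'
#' @param naive character vector (or set) of naive-pool sequences.
#' @param macs_kept,facs_kept character vectors from [frequency_filter()].
#' @return a [labeled_dataset()] (positives first), with attributes
#'   `purged` (naive sequences removed by the hamming rule) and
#'   `overlap` (naive sequences excluded because they are enriched).
#' @export
build_labeled_dataset <- function(naive, macs_kept, facs_kept = character(0)) {
  naive <- unique(as.character(naive))
  enriched <- unique(c(as.character(macs_kept), as.character(facs_kept)))
  if (length(enriched) == 0L) {
    ds <- labeled_dataset(naive, rep(0L, length(naive)),
                          source = "build_labeled_dataset")
    attr(ds, "purged") <- character(0)
    attr(ds, "overlap") <- character(0)
    return(ds)
  }
  overlap <- intersect(naive, enriched)
  candidates <- setdiff(naive, enriched)
  d <- min_hamming_to_set(candidates, enriched)
  purged <- candidates[d < 2]
  negatives <- candidates[d >= 2]
  ds <- labeled_dataset(c(enriched, negatives),
                        c(rep(1L, length(enriched)), rep(0L, length(negatives))),
                        source = "build_labeled_dataset")
  attr(ds, "purged") <- purged
  attr(ds, "overlap") <- overlap
  ds
}

#' Build stability classes (and a regression table) from Tm records
#'
#' Keeps records measured at the working pH, then labels low-stability
#' (`Tm <= low_max`, class 0) and high-stability (`Tm >= high_min`, class
#' 1); records strictly between the cut-offs are excluded from the
#' classification dataset but retained (all pH-passing records) for the
#' regression task.
#'
#' @param table a `stability_table` (columns sequence, pH, Tm).
#' @param ph working pH (default 7).
#' @param low_max upper Tm bound of the low-stability class (deg C).
#' @param high_min lower Tm bound of the high-stability class (deg C).
#' @return list with `classification` (a [labeled_dataset()]) and
#'   `regression` (data.frame of all pH-passing records).
#' @export
filter_stability <- function(table, ph = 7, low_max = 35, high_min = 60) {
  stopifnot(is.data.frame(table),
            all(c("sequence", "pH", "Tm") %in% names(table)))
  if (low_max >= high_min)
    stop("invalid thresholds: low_max (", low_max,
         ") must be below high_min (", high_min, ")")
  at_ph <- table[table$pH == ph, , drop = FALSE]
  lab <- ifelse(at_ph$Tm <= low_max, 0L,
                ifelse(at_ph$Tm >= high_min, 1L, NA_integer_))
  classed <- at_ph[!is.na(lab), , drop = FALSE]
  list(classification = labeled_dataset(classed$sequence, lab[!is.na(lab)],
                                        source = "filter_stability"),
       regression = at_ph[, c("sequence", "pH", "Tm")])
}
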