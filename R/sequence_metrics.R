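# Per-sequence and per-protein metrics: residue abundance, FG-motif density,
# disorder fraction, FG-Nup candidacy, LCR coverage, ranked LCR statistics
# and lpLCR flagging.

# Fig-style residue ordering: the six most order-promoting residues first,
# the four charged (most disorder-promoting) last.
ORDER_PROMOTING <- c("W", "F", "Y", "I", "L", "V")
CHARGED_RESIDUES <- c("D", "E", "K", "R")

#' Pooled residue abundance of a dataset
#'
#' Abundance of a residue is its count divided by the pooled length of all
#' analysed (disordered) sequences, so the fractions over the full alphabet
#' sum to 1.
#'
#' @param records Record `data.frame`.
#' @param residue_order `"promoting"` (default) lists the order-promoting
#'   residues W, F, Y, I, L, V first and the charged residues D, E, K, R
#'   last, with the remaining letters alphabetical in between;
#'   `"alphabetical"` sorts plainly. A character vector of letters selects
#'   and orders explicitly.
#' @return A `data.frame` with columns `residue`, `count`, `fraction`.
#' @export
residue_abundance <- function(records, residue_order = "promoting") {
  validate_records(records)
  ch <- unlist(strsplit(records$residues, "", fixed = TRUE), use.names = FALSE)
  total <- length(ch)
  if (total == 0L) stop("no residues to pool")
  counts <- table(factor(ch, levels = sort(unique(ch))))
  tab <- data.frame(residue = names(counts),
                    count = as.integer(counts),
                    fraction = as.integer(counts) / total,
                    stringsAsFactors = FALSE)
  if (identical(residue_order, "promoting")) {
    middle <- setdiff(sort(tab$residue), c(ORDER_PROMOTING, CHARGED_RESIDUES))
    ord <- c(intersect(ORDER_PROMOTING, tab$residue), middle,
             intersect(CHARGED_RESIDUES, tab$residue))
  } else if (identical(residue_order, "alphabetical")) {
    ord <- sort(tab$residue)
  } else {
    missing <- setdiff(residue_order, tab$residue)
    if (length(missing)) {
      tab <- rbind(tab, data.frame(residue = missing, count = 0L,
                                   fraction = 0, stringsAsFactors = FALSE))
    }
    ord <- residue_order
  }
  out <- tab[match(ord, tab$residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' FG-motif density (FG dipeptides per residue)
#'
#' Counts occurrences of the exact dipeptide "FG" (F immediately followed by
#' G; occurrences cannot self-overlap) and divides by sequence length.
#'
#' @param record Record `data.frame` or character vector of residue strings.
#' @return Numeric vector of densities, one per sequence.
#' @export
fg_motif_density <- function(record) {
  residues <- if (is.data.frame(record)) record$residues else
    toupper(as.character(record))
  vapply(residues, function(x) {
    hits <- gregexpr("FG", x, fixed = TRUE)[[1L]]
    n <- if (hits[1L] == -1L) 0L else length(hits)
    n / nchar(x)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Fraction of a protein annotated as disordered
#'
#' @param record One-row record `data.frame` holding the full-length protein.
#' @param annotations Annotation `data.frame`; only rows matching the record
#'   id are used. Regions are merged before summing, so overlapping
#'   annotations are not double-counted.
#' @return Fraction in `[0, 1]` of residues covered by disordered regions.
#' @export
disorder_fraction <- function(record, annotations) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  ann <- annotations[annotations$seq_id == record$id, , drop = FALSE]
  if (nrow(ann) == 0L) return(0)
  ann <- region_annotations(ann$seq_id, ann$start, ann$end, ann$evidence)
  validate_annotations(record, ann)
  sum(ann$end - ann$start + 1L) / nchar(record$residues)
}

#' Is a protein an FG-Nup candidate?
#'
#' The selection filter used to assemble FG-Nup datasets: a high disordered
#' fraction and a high FG-motif density, both as strict inequalities.
#'
#' @inheritParams disorder_fraction
#' @param disorder_threshold Strict lower bound on [disorder_fraction()]
#'   (default 0.30).
#' @param fg_threshold Strict lower bound on [fg_motif_density()] (default
#'   0.15 FG/AA).
#' @return `TRUE` iff both thresholds are strictly exceeded.
#' @export
is_fg_nup_candidate <- function(record, annotations,
                                disorder_threshold = 0.30,
                                fg_threshold = 0.15) {
  disorder_fraction(record, annotations) > disorder_threshold &&
    fg_motif_density(record) > fg_threshold
}

#' Percentage of a sequence covered by LCRs of one sign
#'
#' 100 times the summed length of sign-matching LCRs passing the min-length
#' filter, divided by the sequence length. Non-increasing in `min_length`.
#'
#' @param record One-row record `data.frame` or a residue string.
#' @param sign `"POSITIVE"` or `"NEGATIVE"`.
#' @param min_length Strict length filter passed to [filter_lcrs()].
#' @param lcrs Optional precomputed LCR table for the record (avoids
#'   rescanning).
#' @return Percentage in `[0, 100]`.
#' @export
lcr_covered_percentage <- function(record, sign = c("POSITIVE", "NEGATIVE"),
                                   min_length = 2, lcrs = NULL) {
  sign <- match.arg(sign)
  if (!is.data.frame(record)) record <- seq_records("x", record)
  stopifnot(nrow(record) == 1L)
  if (is.null(lcrs)) lcrs <- scan_lcrs(record)
  keep <- filter_lcrs(lcrs[lcrs$sign == sign, , drop = FALSE], min_length)
  100 * sum(keep$length) / nchar(record$residues)
}

#' Top-k LCRs of one sign, ranked by length
#'
#' @param lcrs LCR table (typically one protein's).
#' @param sign `"POSITIVE"` or `"NEGATIVE"`.
#' @param k Maximum number of LCRs to return.
#' @return Up to `k` rows sorted by length descending; ties broken by start
#'   position ascending.
#' @export
top_k_lcrs <- function(lcrs, sign = c("POSITIVE", "NEGATIVE"), k = 3) {
  sign <- match.arg(sign)
  stopifnot(k >= 1)
  sub <- lcrs[lcrs$sign == sign, , drop = FALSE]
  sub <- sub[order(-sub$length, sub$start), , drop = FALSE]
  out <- utils::head(sub, k)
  rownames(out) <- NULL
  out
}

#' Rank gaps and ratios between the longest LCRs
#'
#' Measures how much the longest LCR stands out from the next-longest ones:
#' `gap_12 = length(1st) - length(2nd)`, `ratio_12 = length(1st)/length(2nd)`,
#' and likewise `gap_23`/`ratio_23` for ranks 2 and 3. Fields whose ranks are
#' missing are `NA`.
#'
#' @param ranked LCR table sorted non-increasing by length (e.g. from
#'   [top_k_lcrs()]), or a numeric vector of ranked lengths.
#' @return A list with `gap_12`, `ratio_12`, `gap_23`, `ratio_23`.
#' @export
rank_gap_and_ratio <- function(ranked) {
  len <- if (is.data.frame(ranked)) ranked$length else as.numeric(ranked)
  if (is.unsorted(rev(len))) stop("ranked lengths must be non-increasing")
  g <- function(i, j) if (length(len) >= j) len[i] - len[j] else NA_real_
  r <- function(i, j) if (length(len) >= j) len[i] / len[j] else NA_real_
  list(gap_12 = g(1L, 2L), ratio_12 = r(1L, 2L),
       gap_23 = g(2L, 3L), ratio_23 = r(2L, 3L))
}

#' Flag a protein's lpLCR
#'
#' Two operational notions of the "longest positive LCR" are exposed:
#' `mode = "detect"` flags the longest positive LCR only when it is at least
#' `min_length` residues long (and, when `max_content` is set, no more
#' charge-dense than that bound) — the outlier definition used to call
#' lpLCRs; `mode = "longest"` returns the longest positive LCR
#' unconditionally — the per-protein element removed in exclusion analyses.
#'
#' @param lcrs One protein's LCR table, already filtered with the
#'   conventional `> 2` length filter.
#' @param mode `"detect"` or `"longest"`.
#' @param min_length Detection length threshold (default 200 residues).
#' @param max_content Optional upper bound on charge content for detection.
#' @return A one-row LCR `data.frame`, or `NULL` when nothing qualifies.
#' @export
flag_lplcr <- function(lcrs, mode = c("detect", "longest"),
                       min_length = 200, max_content = NULL) {
  mode <- match.arg(mode)
  top <- top_k_lcrs(lcrs, "POSITIVE", k = 1)
  if (nrow(top) == 0L) return(NULL)
  if (mode == "longest") return(top)
  if (top$length < min_length) return(NULL)
  if (!is.null(max_content) && top$charge_content > max_content) return(NULL)
  top
}

#' Per-protein charge summary
#'
#' Assembles, for one analysed (disordered) sequence, the statistics the
#' dataset-level comparisons are built from: ranked positive/negative LCR
#' lengths, coverage percentages, FG density, disorder fraction and the
#' lpLCR flag.
#'
#' @param record One-row record `data.frame`.
#' @param annotations Optional annotation table for the full protein (used
#'   for `disorder_fraction`; `NA` when absent).
#' @param min_length Strict LCR length filter (default 2) applied before
#'   ranking and coverage.
#' @param lplcr_min_length,lplcr_max_content,lplcr_mode Passed to
#'   [flag_lplcr()].
#' @param lcrs Optional precomputed (unfiltered) LCR table for the record.
#' @return A one-row `data.frame` with columns `seq_id`, `length`,
#'   `longest_pos_len`, `longest_pos_content`, `second_pos_len`,
#'   `third_pos_len`, `longest_neg_len`, `covered_pos_pct`,
#'   `covered_neg_pct`, `fg_density`, `disorder_fraction`, `lplcr_flag`.
#'   Rank columns are `NA` when the protein has no qualifying LCR of that
#'   rank.
#' @export
protein_charge_summary <- function(record, annotations = NULL,
                                   min_length = 2, lplcr_min_length = 200,
                                   lplcr_max_content = NULL,
                                   lplcr_mode = "detect", lcrs = NULL) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  if (is.null(lcrs)) lcrs <- scan_lcrs(record)
  keep <- filter_lcrs(lcrs, min_length)
  pos <- top_k_lcrs(keep, "POSITIVE", k = 3)
  neg <- top_k_lcrs(keep, "NEGATIVE", k = 1)
  flag <- flag_lplcr(keep, mode = lplcr_mode, min_length = lplcr_min_length,
                     max_content = lplcr_max_content)
  nth <- function(df, i, col) if (nrow(df) >= i) df[[col]][i] else NA_real_
  data.frame(
    seq_id = record$id,
    length = nchar(record$residues),
    longest_pos_len = nth(pos, 1L, "length"),
    longest_pos_content = nth(pos, 1L, "charge_content"),
    second_pos_len = nth(pos, 2L, "length"),
    third_pos_len = nth(pos, 3L, "length"),
    longest_neg_len = nth(neg, 1L, "length"),
    covered_pos_pct = lcr_covered_percentage(record, "POSITIVE", min_length,
                                             lcrs = lcrs),
    covered_neg_pct = lcr_covered_percentage(record, "NEGATIVE", min_length,
                                             lcrs = lcrs),
    fg_density = fg_motif_density(record),
    disorder_fraction = if (is.null(annotations)) NA_real_ else
      disorder_fraction(record, annotations),
    lplcr_flag = !is.null(flag),
    stringsAsFactors = FALSE
  )
}

#' Write per-protein summaries to TSV
#' @param summaries Data frame of per-protein summaries.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_table <- function(summaries, path) {
  cols <- c("seq_id", "length", "longest_pos_len", "longest_pos_content",
            "longest_neg_len", "covered_pos_pct", "covered_neg_pct",
            "fg_density", "disorder_fraction", "lplcr_flag")
  utils::write.table(summaries[, intersect(cols, names(summaries))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
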