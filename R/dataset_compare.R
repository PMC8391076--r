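# Dataset-level aggregation and comparison: scatter data, boxplot statistics,
# lpLCR exclusion re-analysis, outlier fractions, coverage histograms.

#' Tukey boxplot statistics
#'
#' Quartiles use linear interpolation ([stats::quantile()] type 7); whiskers
#' reach the most extreme observations within 1.5 IQR of the quartiles;
#' values beyond the whiskers are outliers.
#'
#' @param values Numeric vector, `length >= 1`.
#' @param std_type `"sample"` (default, n-1 denominator) or `"population"`.
#' @return A list of class `"boxplot_stats"`: `n`, `mean`, `std`, `median`,
#'   `q1`, `q3`, `iqr`, `whisker_low`, `whisker_high`, `outlier_values`.
#' @export
boxplot_stats <- function(values, std_type = c("sample", "population")) {
  std_type <- match.arg(std_type)
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop("boxplot_stats needs at least one non-missing value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  std <- if (length(values) == 1L) 0 else stats::sd(values)
  if (std_type == "population")
    std <- sqrt(mean((values - mean(values))^2))
  structure(list(
    n = length(values), mean = mean(values), std = std,
    median = q[2L], q1 = q[1L], q3 = q[3L], iqr = iqr,
    whisker_low = min(inside), whisker_high = max(inside),
    outlier_values = sort(values[values < lo_fence | values > hi_fence])
  ), class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf(
    "n=%d mean=%.3g std=%.3g median=%.3g [q1=%.3g, q3=%.3g] whiskers=[%.3g, %.3g] outliers=%d\n",
    x$n, x$mean, x$std, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
    length(x$outlier_values)))
  invisible(x)
}

#' Fraction of longest-LCR points exceeding a length threshold
#'
#' @param scatter A numeric vector of lengths, or a data frame with a
#'   `length` column (e.g. the `scatter_points` of a dataset summary).
#' @param length_threshold Strict threshold (default 200 residues).
#' @return Fraction in `[0, 1]`, exactly `(count above threshold) / n`.
#' @export
outlier_fraction <- function(scatter, length_threshold = 200) {
  len <- if (is.data.frame(scatter)) scatter$length else as.numeric(scatter)
  if (length(len) == 0L) stop("no scatter points supplied")
  sum(len > length_threshold) / length(len)
}

#' Pool positive LCR lengths with each protein's lpLCR removed
#'
#' Implements the exclusion re-analysis: from a (filtered) positive LCR
#' table spanning many proteins, drop one LCR per protein — its longest
#' positive LCR (`mode = "longest"`, ties broken by earliest start), or only
#' those at least `min_length` long (`mode = "detect"`) — and return the
#' remaining lengths.
#'
#' @param lcrs LCR table (rows of any sign are accepted; only positive rows
#'   are used), already length-filtered as desired.
#' @param mode `"longest"` (default) or `"detect"`.
#' @param min_length Detection threshold for `mode = "detect"`.
#' @return Numeric vector of remaining positive LCR lengths.
#' @export
exclude_lplcrs <- function(lcrs, mode = c("longest", "detect"),
                           min_length = 200) {
  mode <- match.arg(mode)
  pos <- lcrs[lcrs$sign == "POSITIVE", , drop = FALSE]
  if (nrow(pos) == 0L) return(numeric())
  keep <- unlist(lapply(split(seq_len(nrow(pos)), pos$seq_id), function(i) {
    if (mode == "longest") {
      drop <- i[order(-pos$length[i], pos$start[i])][1L]
      setdiff(i, drop)
    } else {
      i[pos$length[i] < min_length]
    }
  }), use.names = FALSE)
  pos$length[sort(keep)]
}

#' Histogram of LCR-covered percentage across proteins
#'
#' Bins per-protein coverage percentages over `[0, 100]` with half-open bins
#' `[lo, hi)`; the last bin is closed so 100% coverage is counted.
#'
#' @param records Record `data.frame`.
#' @param sign `"POSITIVE"` or `"NEGATIVE"`.
#' @param min_lengths Length thresholds to evaluate (default `c(2, 20, 40)`).
#' @param bin_width Bin width in percentage points (default 5).
#' @param lcrs Optional precomputed LCR table for all records.
#' @return A `data.frame` with columns `min_length`, `bin_lo`, `bin_hi`,
#'   `count`. Counts within each `min_length` sum to `nrow(records)`.
#' @export
covered_percentage_histogram <- function(records,
                                         sign = c("POSITIVE", "NEGATIVE"),
                                         min_lengths = c(2, 20, 40),
                                         bin_width = 5, lcrs = NULL) {
  sign <- match.arg(sign)
  validate_records(records)
  if (is.null(lcrs)) lcrs <- scan_lcrs(records)
  edges <- seq(0, 100, by = bin_width)
  if (edges[length(edges)] < 100) edges <- c(edges, 100)
  out <- lapply(min_lengths, function(ml) {
    pct <- vapply(seq_len(nrow(records)), function(i) {
      lcr_covered_percentage(records[i, , drop = FALSE], sign, ml,
                             lcrs = lcrs[lcrs$seq_id == records$id[i], ,
                                         drop = FALSE])
    }, numeric(1))
    idx <- findInterval(pct, edges, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = length(edges) - 1L)
    data.frame(min_length = ml,
               bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
               count = counts)
  })
  do.call(rbind, out)
}

#' Summarise a dataset of (disordered) sequences
#'
#' Runs the full per-protein analysis over a dataset and aggregates it:
#' pooled residue abundance, per-protein summaries, longest-LCR scatter
#' points, pooled LCR length statistics per sign, means of per-protein
#' longest LCR lengths, the outlier fraction above a length threshold, and
#' coverage histograms at several minimum LCR lengths.
#'
#' @param manifest A `dataset_manifest`, or a record `data.frame`.
#' @param min_length Strict LCR length filter (default 2, i.e. keep
#'   length > 2).
#' @param lplcr_min_length,lplcr_mode lpLCR flagging parameters (see
#'   [flag_lplcr()]).
#' @param outlier_threshold Length threshold for [outlier_fraction()]
#'   (default 200).
#' @param covered_min_lengths Thresholds for the coverage histograms.
#' @param bin_width Coverage histogram bin width (percentage points).
#' @return A list of class `"dataset_summary"` holding the aggregates plus
#'   the retained per-protein summaries and filtered LCR table for
#'   drill-down; `params` records every analysis parameter (including the
#'   quartile method) so that comparisons can verify compatibility.
#' @export
summarize_dataset <- function(manifest, min_length = 2,
                              lplcr_min_length = 200, lplcr_mode = "detect",
                              outlier_threshold = 200,
                              covered_min_lengths = c(2, 20, 40),
                              bin_width = 5) {
  if (is.data.frame(manifest))
    manifest <- dataset_manifest("dataset", manifest)
  stopifnot(inherits(manifest, "dataset_manifest"))
  records <- manifest$records
  if (nrow(records) == 0L) stop("empty dataset")
  lcrs <- scan_lcrs(records)
  filtered <- filter_lcrs(lcrs, min_length)
  per_protein <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    protein_charge_summary(rec, annotations = manifest$annotations,
                           min_length = min_length,
                           lplcr_min_length = lplcr_min_length,
                           lplcr_mode = lplcr_mode,
                           lcrs = lcrs[lcrs$seq_id == rec$id, , drop = FALSE])
  }))
  scatter <- do.call(rbind, lapply(c("POSITIVE", "NEGATIVE"), function(sg) {
    top <- do.call(rbind, lapply(split(filtered, filtered$seq_id),
                                 top_k_lcrs, sign = sg, k = 1))
    if (is.null(top) || nrow(top) == 0L) return(NULL)
    data.frame(seq_id = top$seq_id, sign = sg, length = top$length,
               charge_content = top$charge_content,
               dataset_tag = records$dataset_tag[match(top$seq_id,
                                                       records$id)],
               stringsAsFactors = FALSE)
  }))
  if (is.null(scatter))
    scatter <- data.frame(seq_id = character(), sign = character(),
                          length = integer(), charge_content = numeric(),
                          dataset_tag = character(), stringsAsFactors = FALSE)
  rownames(scatter) <- NULL
  pos_scatter <- scatter[scatter$sign == "POSITIVE", , drop = FALSE]
  neg_scatter <- scatter[scatter$sign == "NEGATIVE", , drop = FALSE]
  len_stats <- list(
    POSITIVE = if (any(filtered$sign == "POSITIVE"))
      boxplot_stats(filtered$length[filtered$sign == "POSITIVE"]) else NULL,
    NEGATIVE = if (any(filtered$sign == "NEGATIVE"))
      boxplot_stats(filtered$length[filtered$sign == "NEGATIVE"]) else NULL)
  hists <- lapply(stats::setNames(c("POSITIVE", "NEGATIVE"),
                                  c("POSITIVE", "NEGATIVE")),
                  function(sg) covered_percentage_histogram(
                    records, sg, covered_min_lengths, bin_width, lcrs = lcrs))
  structure(list(
    name = manifest$name,
    dataset_tag = records$dataset_tag[1L],
    n_proteins = nrow(records),
    abundance = residue_abundance(records),
    per_protein = per_protein,
    lcrs = filtered,
    scatter_points = scatter,
    lcr_length_stats = len_stats,
    mean_longest_positive = if (nrow(pos_scatter)) mean(pos_scatter$length)
      else NA_real_,
    mean_longest_negative = if (nrow(neg_scatter)) mean(neg_scatter$length)
      else NA_real_,
    outlier_fraction_positive = if (nrow(pos_scatter))
      outlier_fraction(pos_scatter, outlier_threshold) else NA_real_,
    outlier_fraction_negative = if (nrow(neg_scatter))
      outlier_fraction(neg_scatter, outlier_threshold) else NA_real_,
    n_lplcr_flagged = sum(per_protein$lplcr_flag),
    covered_pct_histograms = hists,
    params = list(min_length = min_length,
                  lplcr_min_length = lplcr_min_length,
                  lplcr_mode = lplcr_mode,
                  outlier_threshold = outlier_threshold,
                  covered_min_lengths = covered_min_lengths,
                  bin_width = bin_width,
                  quartile_method = "linear interpolation (type 7)")
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("Dataset summary '", x$name, "' (", x$n_proteins, " proteins)\n",
      sep = "")
  cat(sprintf("  mean longest positive LCR: %.2f aa\n",
              x$mean_longest_positive))
  cat(sprintf("  mean longest negative LCR: %.2f aa\n",
              x$mean_longest_negative))
  cat(sprintf("  outlier fraction (positive, > %d aa): %.4g\n",
              x$params$outlier_threshold, x$outlier_fraction_positive))
  cat(sprintf("  lpLCR-flagged proteins: %d\n", x$n_lplcr_flagged))
  invisible(x)
}

#' Compare two dataset summaries
#'
#' Produces the descriptive side-by-side contrasts used to oppose FG-Nup-like
#' and generic disordered datasets: abundance deltas, longest-LCR means,
#' pooled length statistics before and after lpLCR exclusion, and outlier
#' fractions. No hypothesis tests are computed; the contrasts are
#' descriptive.
#'
#' @param a,b `dataset_summary` objects computed with identical analysis
#'   parameters (mismatched parameters are an error).
#' @return A list of class `"dataset_comparison"`.
#' @export
compare_datasets <- function(a, b) {
  stopifnot(inherits(a, "dataset_summary"), inherits(b, "dataset_summary"))
  if (!identical(a$params, b$params))
    stop("dataset summaries were computed with different parameters")
  res <- merge(a$abundance, b$abundance, by = "residue", all = TRUE,
               suffixes = c("_a", "_b"), sort = FALSE)
  res[is.na(res)] <- 0
  res$delta <- res$fraction_a - res$fraction_b
  excl <- list(a = exclude_lplcrs(a$lcrs), b = exclude_lplcrs(b$lcrs))
  pooled_pos <- function(s) s$lcrs$length[s$lcrs$sign == "POSITIVE"]
  structure(list(
    names = c(a = a$name, b = b$name),
    params = a$params,
    abundance = res,
    means = data.frame(
      metric = c("mean_longest_positive", "mean_longest_negative",
                 "mean_all_positive", "mean_all_negative",
                 "mean_positive_excl_lplcr"),
      a = c(a$mean_longest_positive, a$mean_longest_negative,
            mean(pooled_pos(a)),
            mean(a$lcrs$length[a$lcrs$sign == "NEGATIVE"]),
            mean(excl$a)),
      b = c(b$mean_longest_positive, b$mean_longest_negative,
            mean(pooled_pos(b)),
            mean(b$lcrs$length[b$lcrs$sign == "NEGATIVE"]),
            mean(excl$b))),
    length_stats = list(a = a$lcr_length_stats, b = b$lcr_length_stats),
    outlier_fraction = data.frame(
      sign = c("POSITIVE", "NEGATIVE"),
      a = c(a$outlier_fraction_positive, a$outlier_fraction_negative),
      b = c(b$outlier_fraction_positive, b$outlier_fraction_negative)),
    lplcr_flagged = c(a = a$n_lplcr_flagged, b = b$n_lplcr_flagged)
  ), class = "dataset_comparison")
}

#' @export
print.dataset_comparison <- function(x, ...) {
  cat("Comparison: ", x$names[["a"]], " vs ", x$names[["b"]], "\n", sep = "")
  print(x$means, row.names = FALSE)
  cat("lpLCR-flagged proteins: ", x$lplcr_flagged[["a"]], " vs ",
      x$lplcr_flagged[["b"]], "\n", sep = "")
  invisible(x)
}
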