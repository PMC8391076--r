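# Independent oracles and random-sequence helpers for the test suite.

# Brute-force LCR enumerator: an explicit position-by-position state machine,
# independent of the package's rle-based scanner. Spans run from the first
# to the last same-sign charged residue of each maximal run.
brute_force_lcrs <- function(residues) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1L]]
  sgn <- function(x) if (x %in% c("K", "R")) 1L else
    if (x %in% c("D", "E")) -1L else 0L
  out <- list()
  cur_sign <- 0L; cur_start <- NA_integer_; cur_end <- NA_integer_
  cur_count <- 0L
  close_run <- function() {
    if (cur_sign != 0L) {
      len <- cur_end - cur_start + 1L
      out[[length(out) + 1L]] <<- data.frame(
        sign = if (cur_sign == 1L) "POSITIVE" else "NEGATIVE",
        start = cur_start, end = cur_end, length = len,
        charge_count = cur_count, charge_content = cur_count / len,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(ch)) {
    s <- sgn(ch[i])
    if (s == 0L) next
    if (s == cur_sign) {
      cur_end <- i; cur_count <- cur_count + 1L
    } else {
      close_run()
      cur_sign <- s; cur_start <- i; cur_end <- i; cur_count <- 1L
    }
  }
  close_run()
  if (!length(out))
    return(data.frame(sign = character(), start = integer(),
                      end = integer(), length = integer(),
                      charge_count = integer(), charge_content = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Random residue string with given positive/negative charge densities.
random_seq <- function(len, p_pos = 0.1, p_neg = 0.1) {
  u <- stats::runif(len)
  ch <- sample(c("A", "G", "S", "T", "N", "Q", "P", "F"), len, replace = TRUE)
  ch[u < p_pos] <- sample(c("K", "R"), sum(u < p_pos), replace = TRUE)
  sel <- u >= p_pos & u < p_pos + p_neg
  ch[sel] <- sample(c("D", "E"), sum(sel), replace = TRUE)
  paste(ch, collapse = "")
}

# Linear-interpolation quantile computed from the definition (independent of
# stats::quantile): h = (n - 1) p + 1, interpolate between floor and ceiling
# order statistics.
interp_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

worked_example <- function() seq_records("ex", "KAKGSKTKGDNADQSDP")
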