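# Core charge classification and like-charge-region (LCR) extraction.
#
# An LCR is a maximal stretch of sequence whose charged residues are all of
# one sign. Positive residues: K, R. Negative residues: D, E. Histidine and
# everything else (including ambiguity codes) are neutral.

POSITIVE_RESIDUES <- c("K", "R")
NEGATIVE_RESIDUES <- c("D", "E")

#' Classify residues by charge sign
#'
#' K and R are `"POSITIVE"`, D and E are `"NEGATIVE"`, every other letter
#' (including histidine and ambiguity codes) is `"NEUTRAL"`.
#'
#' @param residue Character vector of single letters.
#' @return Character vector of `"POSITIVE"`, `"NEGATIVE"` or `"NEUTRAL"`.
#' @examples
#' classify_residue(c("K", "E", "G", "H"))
#' @export
classify_residue <- function(residue) {
  residue <- toupper(as.character(residue))
  if (any(!grepl("^[A-Z]$", residue)))
    stop("classify_residue expects single letters")
  out <- rep("NEUTRAL", length(residue))
  out[residue %in% POSITIVE_RESIDUES] <- "POSITIVE"
  out[residue %in% NEGATIVE_RESIDUES] <- "NEGATIVE"
  out
}

# Integer sign vector for one residue string: +1 pos, -1 neg, 0 neutral.
charge_signs <- function(residues) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1L]]
  s <- integer(length(ch))
  s[ch %in% POSITIVE_RESIDUES] <- 1L
  s[ch %in% NEGATIVE_RESIDUES] <- -1L
  s
}

#' Per-position charge profile of a sequence
#'
#' @param record A one-row record `data.frame` (see [seq_records()]) or a
#'   single residue string.
#' @return A list of class `"charge_profile"`: `seq_id`, `signs` (per-position
#'   `"POSITIVE"`/`"NEGATIVE"`/`"NEUTRAL"`), `n_positive`, `n_negative`,
#'   `f_plus`, `f_minus`.
#' @export
charge_profile <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    seq_id <- record$id
    residues <- record$residues
  } else {
    seq_id <- NA_character_
    residues <- as.character(record)
  }
  s <- charge_signs(residues)
  n <- length(s)
  structure(list(
    seq_id = seq_id,
    signs = c("NEGATIVE", "NEUTRAL", "POSITIVE")[s + 2L],
    n_positive = sum(s == 1L),
    n_negative = sum(s == -1L),
    f_plus = sum(s == 1L) / n,
    f_minus = sum(s == -1L) / n
  ), class = "charge_profile")
}

empty_lcr_table <- function() {
  data.frame(seq_id = character(), sign = character(), start = integer(),
             end = integer(), length = integer(), charge_count = integer(),
             charge_content = numeric(), stringsAsFactors = FALSE)
}

scan_one <- function(seq_id, residues, extend_to_opposite = FALSE) {
  s <- charge_signs(residues)
  charged <- which(s != 0L)
  if (length(charged) == 0L) return(empty_lcr_table())
  runs <- rle(s[charged])
  ends_i <- cumsum(runs$lengths)
  starts_i <- ends_i - runs$lengths + 1L
  start <- charged[starts_i]
  end <- charged[ends_i]
  if (extend_to_opposite) {
    # Methods-wording variant: the region continues until the next
    # opposite-sign charge; the final run extends to the sequence terminus.
    nxt <- c(charged[starts_i[-1L]] - 1L, length(s))
    end <- nxt
  }
  len <- end - start + 1L
  count <- runs$lengths
  data.frame(
    seq_id = seq_id,
    sign = ifelse(runs$values == 1L, "POSITIVE", "NEGATIVE"),
    start = start, end = end, length = len, charge_count = count,
    charge_content = count / len,
    stringsAsFactors = FALSE
  )
}

#' Extract all like-charge regions from sequences
#'
#' Scans each sequence for maximal runs of same-sign charged residues. By
#' default an LCR spans from its first to its last same-sign charged residue,
#' inclusive; neutral residues between the run's last charge and the next
#' opposite charge are not part of the LCR. Setting
#' `extend_to_opposite = TRUE` switches to the alternative convention in
#' which a region continues up to (but excluding) the next opposite-sign
#' charge, with terminal runs extending to the sequence end. The two
#' conventions are never mixed within one scan.
#'
#' Consecutive LCRs of one sequence alternate in sign and their spans are
#' disjoint; sequences without charged residues yield no rows.
#'
#' @param records Record `data.frame`, or a character vector of residue
#'   strings (ids are generated).
#' @param extend_to_opposite Use the extended span convention (default
#'   `FALSE`).
#' @return A `data.frame` with one LCR per row: `seq_id`, `sign`, `start`,
#'   `end` (1-based inclusive), `length`, `charge_count`, `charge_content`
#'   (= `charge_count / length`), ordered by record then `start`.
#' @examples
#' scan_lcrs(seq_records("ex", "KAKGSKTKGDNADQSDP"))
#' @export
scan_lcrs <- function(records, extend_to_opposite = FALSE) {
  if (!is.data.frame(records)) {
    records <- seq_records(paste0("seq", seq_along(records)), records)
  }
  validate_records(records)
  out <- mapply(scan_one, records$id, records$residues,
                MoreArgs = list(extend_to_opposite = extend_to_opposite),
                SIMPLIFY = FALSE, USE.NAMES = FALSE)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter LCRs by minimum length
#'
#' Keeps LCRs strictly longer than `min_length` (the conventional
#' "greater than two amino acids" filter is `min_length = 2`, i.e. length
#' >= 3). Order is preserved.
#'
#' @param lcrs LCR table from [scan_lcrs()].
#' @param min_length Strict lower bound on length (default 2).
#' @return Filtered LCR table.
#' @export
filter_lcrs <- function(lcrs, min_length = 2) {
  stopifnot(min_length >= 1)
  lcrs[lcrs$length > min_length, , drop = FALSE]
}

#' Write an LCR table to TSV
#' @param lcrs LCR table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lcr_table <- function(lcrs, path) {
  utils::write.table(lcrs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
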