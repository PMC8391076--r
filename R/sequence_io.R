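# Sequence and annotation IO: FASTA, region tables, dataset manifests.

VALID_TAGS <- c("FG_NUPS", "DISPROT", "UNIPROT_PRED", "SYNTHETIC", "USER")

#' Construct a table of sequence records
#'
#' Records are plain data frames with one protein (or disordered subsequence)
#' per row: `id`, `description`, `residues` (upper-case amino-acid string) and
#' `dataset_tag`. All analysis functions in the package consume this layout.
#'
#' @param id Character vector of unique identifiers.
#' @param residues Character vector of amino-acid strings (letters only;
#'   ambiguity codes B, J, O, U, X, Z are accepted and treated as uncharged).
#' @param description Optional free-text descriptions.
#' @param dataset_tag Provenance tag, one of `"FG_NUPS"`, `"DISPROT"`,
#'   `"UNIPROT_PRED"`, `"SYNTHETIC"`, `"USER"`.
#' @param strict If `TRUE`, reject ambiguity codes (only the 20 canonical
#'   letters are allowed).
#' @return A `data.frame` with columns `id`, `description`, `residues`,
#'   `dataset_tag`.
#' @examples
#' seq_records("p1", "KAKGSKTKGDNADQSDP")
#' @export
seq_records <- function(id, residues, description = "", dataset_tag = "USER",
                        strict = FALSE) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  dataset_tag <- match.arg(dataset_tag, VALID_TAGS)
  rec <- data.frame(
    id = id,
    description = rep_len(as.character(description), length(id)),
    residues = residues,
    dataset_tag = dataset_tag,
    stringsAsFactors = FALSE
  )
  validate_records(rec, strict = strict)
  rec
}

validate_records <- function(records, strict = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("id", "residues") %in% names(records)))
  if (nrow(records) == 0L) stop("record table is empty")
  if (anyDuplicated(records$id))
    stop("duplicate sequence ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  bad <- !nzchar(records$residues)
  if (any(bad))
    stop("empty sequence for entry: ",
         paste(records$id[bad], collapse = ", "))
  alphabet <- if (strict) "^[ACDEFGHIKLMNPQRSTVWY]+$" else "^[A-Za-z]+$"
  bad <- !grepl(alphabet, records$residues)
  if (any(bad))
    stop("non-letter or disallowed residues in entry: ",
         paste(records$id[bad], collapse = ", "))
  invisible(records)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that returns the
#' package's record layout. The first whitespace-delimited token of each
#' header is the id; the remainder, if any, the description. Residues are
#' upper-cased; entry order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param dataset_tag Provenance tag attached to every record.
#' @inheritParams seq_records
#' @return A record `data.frame` (see [seq_records()]).
#' @export
read_fasta <- function(path, dataset_tag = "USER", strict = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("failed to parse FASTA '", path,
                                          "': ", conditionMessage(e)))
  if (length(aa) == 0L) stop("FASTA file '", path, "' contains no entries")
  headers <- names(aa)
  if (any(!nzchar(headers)))
    stop("malformed FASTA header (empty) at entry ",
         which(!nzchar(headers))[1L], " in '", path, "'")
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  widths <- Biostrings::width(aa)
  if (any(widths == 0L))
    stop("empty sequence for entry '", ids[widths == 0L][1L], "' in '",
         path, "'")
  seq_records(ids, as.character(aa), description = desc,
              dataset_tag = dataset_tag, strict = strict)
}

#' Write sequence records to a FASTA file
#'
#' @param records A record `data.frame`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  validate_records(records)
  aa <- Biostrings::AAStringSet(records$residues)
  names(aa) <- ifelse(nzchar(records$description),
                      paste(records$id, records$description),
                      records$id)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a disordered-region annotation table
#'
#' Reads a TSV with columns `seq_id`, `start`, `end`, `evidence`
#' (1-based inclusive coordinates) and normalises it: rows are validated
#' (`1 <= start <= end`) and overlapping or bookended rows for one `seq_id`
#' are merged into maximal non-overlapping regions via [IRanges::reduce()].
#' Merging is idempotent. Evidence strings of merged rows are joined with
#' `";"`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `seq_id`, `start`, `end`, `evidence`,
#'   sorted by `seq_id` then `start`.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("region table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "start", "end")
  if (!all(need %in% names(tab)))
    stop("region table must have columns seq_id, start, end (and optionally evidence)")
  if (is.null(tab$evidence)) tab$evidence <- ""
  region_annotations(tab$seq_id, tab$start, tab$end, tab$evidence)
}

#' Construct (and normalise) region annotations
#'
#' @param seq_id Character vector of sequence ids.
#' @param start,end 1-based inclusive coordinates.
#' @param evidence Free-text evidence tags (e.g. curated / predicted).
#' @return Merged, validated annotation `data.frame`.
#' @export
region_annotations <- function(seq_id, start, end, evidence = "") {
  n <- length(seq_id)
  start <- as.integer(start)
  end <- as.integer(end)
  evidence <- rep_len(as.character(evidence), n)
  bad <- which(is.na(start) | is.na(end) | start < 1L | start > end)
  if (length(bad))
    stop("invalid region (need 1 <= start <= end) at row ",
         paste(bad, collapse = ", "))
  if (n == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(seq_len(n), seq_id), function(i) {
    ir <- IRanges::IRanges(start = start[i], end = end[i])
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    ev <- vapply(seq_along(red), function(j) {
      src <- S4Vectors::from(ov)[S4Vectors::to(ov) == j]
      paste(unique(evidence[i][src][nzchar(evidence[i][src])]),
            collapse = ";")
    }, character(1))
    data.frame(seq_id = seq_id[i][1L],
               start = IRanges::start(red), end = IRanges::end(red),
               evidence = ev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Write a region annotation table
#' @param annotations Annotation `data.frame`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_region_table <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_annotations <- function(records, annotations) {
  missing <- setdiff(annotations$seq_id, records$id)
  if (length(missing))
    stop("annotations reference unknown sequence ids: ",
         paste(missing, collapse = ", "))
  len <- nchar(records$residues)[match(annotations$seq_id, records$id)]
  bad <- annotations$end > len
  if (any(bad))
    stop("annotation exceeds sequence length for: ",
         paste(unique(annotations$seq_id[bad]), collapse = ", "))
  invisible(annotations)
}

#' Extract annotated (disordered) subsequences
#'
#' Returns one record per annotation, with id suffixed by the region
#' coordinates (`id_start-end`), or one concatenated record per protein when
#' `concatenate = TRUE` (id suffixed `_disordered`). Records with no
#' annotation are omitted.
#'
#' @param records Record `data.frame` of full-length sequences.
#' @param annotations Normalised annotation `data.frame`.
#' @param concatenate Pool multiple regions of one protein into a single
#'   record? Default keeps each region as a separate analysis unit.
#' @return A record `data.frame` of subsequences.
#' @export
extract_regions <- function(records, annotations, concatenate = FALSE) {
  validate_annotations(records, annotations)
  if (nrow(annotations) == 0L) stop("no annotations supplied")
  res <- records$residues[match(annotations$seq_id, records$id)]
  tag <- records$dataset_tag[match(annotations$seq_id, records$id)]
  sub <- substr(res, annotations$start, annotations$end)
  if (concatenate) {
    parts <- split(sub, annotations$seq_id)
    ids <- names(parts)
    out <- data.frame(
      id = paste0(ids, "_disordered"),
      description = "",
      residues = vapply(parts, paste, character(1), collapse = ""),
      dataset_tag = tag[match(ids, annotations$seq_id)],
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      id = paste0(annotations$seq_id, "_", annotations$start, "-",
                  annotations$end),
      description = "",
      residues = sub,
      dataset_tag = tag,
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  validate_records(out)
  out
}

#' Bundle records and annotations into a dataset manifest
#'
#' @param name Dataset name.
#' @param records Record `data.frame`.
#' @param annotations Optional annotation `data.frame` (validated against the
#'   records).
#' @param notes Provenance notes.
#' @return A list of class `"dataset_manifest"`.
#' @export
dataset_manifest <- function(name, records, annotations = NULL, notes = "") {
  validate_records(records)
  if (!is.null(annotations)) validate_annotations(records, annotations)
  structure(list(name = name, records = records, annotations = annotations,
                 notes = notes),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("Dataset manifest '", x$name, "': ", nrow(x$records), " records, ",
      if (is.null(x$annotations)) 0L else nrow(x$annotations),
      " region annotations\n", sep = "")
  invisible(x)
}
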