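## Reference-anchored indel-frequency analysis of a multiple sequence
## alignment, and detection of stretches of residues uninterrupted by
## indels across the whole set of aligned sequences.

.GAP_CHARS <- c("-", ".")

#' Construct a gapped multiple sequence alignment
#'
#' @param ids Unique sequence identifiers.
#' @param seqs Gapped sequences (equal lengths; gaps `-` or `.`; residues
#'   are upper-cased; ambiguity codes X/B/Z count as residues).
#' @return An `alignment` object (list with `ids` and `seqs`).
#' @export
alignment <- function(ids, seqs) {
  if (!length(ids) || length(ids) != length(seqs)) {
    stop_pl("'ids' and 'seqs' must be non-empty and of equal length", "pl_shape_error")
  }
  if (anyDuplicated(ids)) stop_pl("duplicate sequence ids", "pl_id_error")
  seqs <- toupper(as.character(seqs))
  if (length(unique(nchar(seqs))) != 1L) {
    stop_pl("ragged alignment: gapped sequences differ in length", "pl_shape_error")
  }
  structure(list(ids = as.character(ids), seqs = seqs), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d sequences x %d columns\n", length(x$ids), nchar(x$seqs[1])))
  invisible(x)
}

#' @export
as.matrix.alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$ids
  m
}

.n_columns <- function(aln) nchar(aln$seqs[1])

.ref_row <- function(aln, ref_id) {
  i <- match(ref_id, aln$ids)
  if (is.na(i)) stop_pl(sprintf("reference id '%s' not in alignment", ref_id), "pl_id_error")
  i
}

#' Read or write a multiple sequence alignment
#'
#' Reads FASTA or Clustal alignments (via \pkg{seqinr}); gap characters
#' `-` and `.` are both accepted and residues are upper-cased. Writing is
#' FASTA only.
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `read_alignment()` returns an [alignment()];
#'   `write_alignment()` returns `path` invisibly.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_pl(sprintf("no such file: %s", path), "pl_format_error")
  parsed <- tryCatch(
    # oldclustal: seqinr's newer pure-R clustal parser cannot handle
    # single-block alignments; the C parser can.
    seqinr::read.alignment(path, format = format, forceToLower = FALSE,
                           oldclustal = format == "clustal"),
    error = function(e) stop_pl(sprintf("cannot parse %s as %s: %s",
                                        path, format, conditionMessage(e)),
                                "pl_format_error")
  )
  alignment(ids = parsed$nam, seqs = unlist(parsed$seq, use.names = FALSE))
}

#' @rdname read_alignment
#' @param aln An [alignment()].
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(c(paste0(">", aln$ids[i]), aln$seqs[i]), con)
  }
  invisible(path)
}

#' Trim an alignment to a window of reference residues
#'
#' Restricts the alignment to the columns from the one holding the
#' reference's `first_residue`-th residue through the one holding its
#' `last_residue`-th residue, inclusive — e.g. cutting a full alignment down
#' to the mature reference sequence. Insertion columns interior to the
#' window are kept; flanking columns where the reference is gapped are
#' removed.
#'
#' @param aln An [alignment()].
#' @param ref_id Id of the reference row.
#' @param first_residue,last_residue 1-based residue indices on the
#'   ungapped reference sequence.
#' @return A trimmed [alignment()].
#' @export
trim_to_reference <- function(aln, ref_id, first_residue = 1L,
                              last_residue = NULL) {
  stopifnot(inherits(aln, "alignment"))
  ri <- .ref_row(aln, ref_id)
  ref_chars <- strsplit(aln$seqs[ri], "")[[1]]
  is_res <- !(ref_chars %in% .GAP_CHARS)
  n_res <- sum(is_res)
  if (is.null(last_residue)) last_residue <- n_res
  if (!is_count(first_residue, min = 1L) || !is_count(last_residue, min = 1L) ||
      first_residue > last_residue || last_residue > n_res) {
    stop_pl(sprintf("need 1 <= first <= last <= %d reference residues", n_res),
            "pl_range_error")
  }
  res_cols <- which(is_res)
  keep <- res_cols[first_residue]:res_cols[last_residue]
  alignment(aln$ids, substr(aln$seqs, keep[1], keep[length(keep)]))
}

#' Classify alignment columns as deletion, insertion, or indel-free
#'
#' For an alignment of `n` rows, each column is scored by `x`, the number
#' of rows carrying a residue. A full column (`x = n`) carries no indel and
#' gets frequency 0. A column with `x < n` is a *deletion* column when the
#' reference row has a residue there (frequency `(n - x)/n`: the fraction
#' of sequences missing the reference's residue) and an *insertion* column
#' when the reference is gapped (frequency `x/n`: the fraction of sequences
#' carrying a residue the reference lacks). For 72 sequences both
#' frequencies are bounded by 71/72 = 0.986.
#'
#' @inheritParams trim_to_reference
#' @return Data frame with columns `column`, `x`, `kind`
#'   (`none`/`deletion`/`insertion`), and `frequency`.
#' @export
classify_columns <- function(aln, ref_id) {
  stopifnot(inherits(aln, "alignment"))
  ri <- .ref_row(aln, ref_id)
  m <- as.matrix(aln)
  res <- !(m %in% .GAP_CHARS)
  dim(res) <- dim(m)
  x <- colSums(res)
  if (any(x == 0L)) {
    stop_pl("alignment contains all-gap columns; remove them first", "pl_shape_error")
  }
  n <- nrow(m)
  ref_res <- res[ri, ]
  kind <- ifelse(x == n, "none", ifelse(ref_res, "deletion", "insertion"))
  frequency <- ifelse(kind == "none", 0,
                      ifelse(kind == "deletion", (n - x) / n, x / n))
  data.frame(column = seq_along(x), x = as.integer(x), kind = kind,
             frequency = frequency)
}

#' Reference-anchored indel profile and indel-free stretches
#'
#' Maps every alignment column to reference coordinates (1-based on the
#' trimmed reference, plus an optional numbering `offset`, e.g. to report
#' precursor numbering) and extracts the maximal stretches of reference
#' residues uninterrupted by indels anywhere in the set: a reference
#' position is interrupted if its own column is a deletion column, and a
#' stretch breaks between positions `p` and `p + 1` when an insertion
#' column lies between them.
#'
#' @param classifications Output of [classify_columns()] on `aln`.
#' @param aln The (trimmed) [alignment()].
#' @param ref_id Reference row id.
#' @param offset Added to reported reference positions (default 0).
#' @return An `indel_profile`: list with `columns` (the classifications
#'   plus `ref_position`, NA for insertion columns), `stretches`
#'   (`start`, `end`, `length` in reference coordinates), `ref_id`, and
#'   `offset`.
#' @export
indel_profile <- function(classifications, aln, ref_id, offset = 0L) {
  stopifnot(inherits(aln, "alignment"))
  ri <- .ref_row(aln, ref_id)
  if (!is.data.frame(classifications) || nrow(classifications) != .n_columns(aln)) {
    stop_pl("'classifications' does not match the alignment", "pl_shape_error")
  }
  ref_chars <- strsplit(aln$seqs[ri], "")[[1]]
  ref_res <- !(ref_chars %in% .GAP_CHARS)
  ref_pos <- ifelse(ref_res, cumsum(ref_res), NA_integer_)
  cols <- classifications
  cols$ref_position <- ifelse(is.na(ref_pos), NA_integer_,
                              as.integer(ref_pos + offset))

  n_res <- sum(ref_res)
  interrupted <- rep(FALSE, n_res) # own column is a deletion column
  break_after <- rep(FALSE, n_res) # insertion column before the next position
  last_seen <- 0L
  for (j in seq_len(nrow(cols))) {
    if (ref_res[j]) {
      last_seen <- ref_pos[j]
      if (cols$kind[j] == "deletion") interrupted[last_seen] <- TRUE
    } else if (cols$kind[j] == "insertion" && last_seen >= 1L && last_seen < n_res) {
      break_after[last_seen] <- TRUE
    }
  }
  runs <- list()
  start <- NA_integer_
  for (p in seq_len(n_res)) {
    if (interrupted[p]) { start <- NA_integer_; next }
    if (is.na(start)) start <- p
    # The run cannot extend past p if an insertion follows, the next
    # position is itself an indel site, or the reference ends here.
    if (p == n_res || break_after[p] || interrupted[p + 1L]) {
      runs[[length(runs) + 1L]] <- c(start, p)
      start <- NA_integer_
    }
  }
  stretches <- if (length(runs)) {
    s <- do.call(rbind, runs)
    data.frame(start = s[, 1] + offset, end = s[, 2] + offset,
               length = s[, 2] - s[, 1] + 1L)
  } else {
    data.frame(start = integer(0), end = integer(0), length = integer(0))
  }
  structure(
    list(columns = cols, stretches = stretches, ref_id = ref_id,
         offset = as.integer(offset), n_rows = length(aln$ids)),
    class = "indel_profile"
  )
}

#' @export
print.indel_profile <- function(x, ...) {
  n_del <- sum(x$columns$kind == "deletion")
  n_ins <- sum(x$columns$kind == "insertion")
  cat(sprintf("<indel_profile> ref '%s': %d columns (%d deletion, %d insertion), %d indel-free stretch(es), longest %d\n",
              x$ref_id, nrow(x$columns), n_del, n_ins, nrow(x$stretches),
              if (nrow(x$stretches)) max(x$stretches$length) else 0L))
  invisible(x)
}

#' Read a region-annotation table
#'
#' Tab-separated file of labeled reference-coordinate intervals (columns
#' `label`, `start`, `end`, 1-based inclusive), e.g. binding-site loops and
#' transmembrane segments, used to annotate indel-free stretches.
#'
#' @param path File path.
#' @return Data frame with columns `label`, `start`, `end`.
#' @export
read_region_annotations <- function(path) {
  if (!file.exists(path)) stop_pl(sprintf("no such file: %s", path), "pl_format_error")
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("label", "start", "end")
  if (!all(need %in% names(df)) || any(df$start > df$end)) {
    stop_pl("annotation file needs columns label, start, end (start <= end)",
            "pl_format_error")
  }
  df[need]
}

#' Write an indel profile as delimited text
#'
#' Writes the per-column table (`column`, `ref_position`, `x`, `kind`,
#' `frequency`) and the stretches table (`start`, `end`, `length`, plus
#' comma-separated overlapping annotation labels when annotations are
#' given).
#'
#' @param profile An [indel_profile()].
#' @param columns_path,stretches_path Output paths.
#' @param annotations Optional data frame from [read_region_annotations()].
#' @param provenance Optional character vector of `#` header lines.
#' @return Invisibly, a list of the two paths.
#' @export
write_indel_profile <- function(profile, columns_path, stretches_path,
                                annotations = NULL, provenance = NULL) {
  stopifnot(inherits(profile, "indel_profile"))
  cols <- profile$columns[c("column", "ref_position", "x", "kind", "frequency")]
  st <- profile$stretches
  if (!is.null(annotations) && nrow(st)) {
    st$annotations <- vapply(seq_len(nrow(st)), function(i) {
      hit <- annotations$start <= st$end[i] & annotations$end >= st$start[i]
      paste(annotations$label[hit], collapse = ",")
    }, character(1))
  }
  write_one <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_one(cols, columns_path)
  write_one(st, stretches_path)
  invisible(list(columns = columns_path, stretches = stretches_path))
}
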