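#' Construct a set of aligned mitogenome records
#'
#' The central sequence container: an aligned set of mitogenomes stored as
#' a character matrix (one row per record, one column per alignment
#' column) plus per-record metadata. All sequences must have equal
#' aligned length and use the alphabet `A/C/G/T/N/-`; other IUPAC codes
#' are converted to `N` with a warning.
#'
#' @param seqs Named character vector of aligned sequences, or a
#'   character matrix with row names (one base per cell).
#' @param meta Optional `data.frame` with column `id` matching sequence
#'   names and any of `population`, `region`, `btype`
#'   (`"swamp"`, `"river"` or `"outgroup"`), `tip_age` (years before
#'   present, default 0).
#' @return An object of class `mitogenomes`: list with elements `seq`
#'   (character matrix) and `meta` (data.frame).
#' @export
mitogenomes <- function(seqs, meta = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("sequences must have unique names")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(seqs)[lens != stats::median(lens)]
      stop("ragged alignment: records of deviating length: ",
           paste(bad, collapse = ", "))
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- names(seqs)
  }
  mat[] <- toupper(mat)
  ok <- mat %in% c("A", "C", "G", "T", "N", "-")
  if (!all(ok)) {
    n_bad <- sum(!ok)
    warning(n_bad, " non-ACGTN- character(s) converted to N")
    mat[!ok] <- "N"
  }
  meta <- normalize_meta(meta, rownames(mat))
  structure(list(seq = mat, meta = meta), class = "mitogenomes")
}

normalize_meta <- function(meta, ids) {
  if (is.null(meta)) meta <- data.frame(id = ids)
  if (!"id" %in% names(meta)) stop("metadata must have an 'id' column")
  missing_ids <- setdiff(ids, meta$id)
  if (length(missing_ids))
    stop("metadata missing ids: ", paste(missing_ids, collapse = ", "))
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  if (is.null(meta$population)) meta$population <- NA_character_
  if (is.null(meta$region)) meta$region <- NA_character_
  if (is.null(meta$btype)) meta$btype <- "swamp"
  if (!all(meta$btype %in% c("swamp", "river", "outgroup")))
    stop("btype must be one of swamp, river, outgroup")
  if (is.null(meta$tip_age)) meta$tip_age <- 0
  meta$tip_age <- as.numeric(meta$tip_age)
  rownames(meta) <- NULL
  meta
}

#' @export
print.mitogenomes <- function(x, ...) {
  cat("mitogenomes: ", nrow(x$seq), " aligned records x ",
      ncol(x$seq), " columns\n", sep = "")
  tb <- table(x$meta$btype)
  cat("  types: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of records / alignment length
#' @param x A `mitogenomes` object.
#' @return Integer count.
#' @export
n_records <- function(x) nrow(x$seq)

#' Read an aligned FASTA of mitogenomes
#'
#' Sequences are upper-cased and any IUPAC ambiguity code outside
#' `A/C/G/T/N/-` is mapped to `N` (with a warning). A ragged alignment or
#' an empty file is a hard error.
#'
#' @param path FASTA file of pre-aligned sequences.
#' @param metadata Optional metadata `data.frame` (see [mitogenomes()]) or
#'   path to a tab-separated file with an `id` column.
#' @return A [mitogenomes()] object.
#' @export
read_alignment <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L ||
      !any(startsWith(readLines(path, n = 100L), ">")))
    stop("empty FASTA: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA: ", path)
  seqs <- vapply(as.character(dna), function(ch) paste(ch, collapse = ""),
                 character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment in ", path, ": ",
         paste(names(seqs)[lens != stats::median(lens)], collapse = ", "))
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_metadata(metadata)
  mitogenomes(seqs, metadata)
}

#' Write records to FASTA (70-column wrapped)
#'
#' @param x A `mitogenomes` object or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  if (inherits(x, "mitogenomes")) {
    ids <- rownames(x$seq)
    seqs <- apply(x$seq, 1, paste, collapse = "")
  } else {
    ids <- names(x)
    seqs <- x
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a metadata table
#'
#' Tab-separated with header; must contain `id`; recognised optional
#' columns: `population`, `region`, `btype`, `tip_age`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Subset records
#'
#' @param x A `mitogenomes` object.
#' @param ids Character vector of record ids (or logical/integer index).
#' @return A `mitogenomes` object with the selected records.
#' @export
subset_records <- function(x, ids) {
  if (is.character(ids)) {
    miss <- setdiff(ids, rownames(x$seq))
    if (length(miss)) stop("unknown ids: ", paste(miss, collapse = ", "))
    keep <- match(ids, rownames(x$seq))
  } else keep <- ids
  structure(list(seq = x$seq[keep, , drop = FALSE],
                 meta = x$meta[keep, , drop = FALSE]),
            class = "mitogenomes")
}

record_seq <- function(x, id) {
  if (!id %in% rownames(x$seq)) stop("unknown record id: ", id)
  x$seq[id, ]
}
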