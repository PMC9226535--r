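# Alignment container and FASTA IO.
#
# The alignment alphabet is the 20 standard amino acids plus 'X' and the gap
# character '-'. Other ambiguity codes (B, Z, J, U, O) are normalized to 'X'
# on input; '.' gaps are converted to '-'. 'X' counts as a residue for length
# purposes but as indeterminate for classification.

.POLX_AA20 <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")
.POLX_ALPHABET <- c(.POLX_AA20, "X", "-")

.normalize_aligned_seq <- function(x) {
  x <- toupper(x)
  x <- chartr(".", "-", x)
  # rare ambiguity / non-standard codes collapse to X
  chartr("BZJUO", "XXXXX", x)
}

#' Construct a multiple sequence alignment object
#'
#' Builds the package's aligned-protein container from sequence identifiers
#' and aligned strings. Sequences are case-normalized to upper case, '.' gaps
#' become '-', and the ambiguity codes B, Z, J, U, O become 'X'.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of aligned sequences, all the same length.
#' @return An object of class \code{polx_msa}: a list with elements
#'   \code{ids}, \code{seqs} (normalized, upper case) and \code{n_columns}.
#' @examples
#' msa <- polx_msa(c("a", "b"), c("AC-D", "A-CD"))
#' msa$n_columns
#' @export
polx_msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- .normalize_aligned_seq(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have equal length")
  if (length(ids) < 1L)
    stop("alignment must contain at least one record")
  if (anyDuplicated(ids))
    stop("duplicated seq_ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("alignment-shape error: ragged sequence lengths (",
         paste(range(widths), collapse = "-"), ")")
  n_columns <- widths[1L]
  if (n_columns < 1L)
    stop("alignment must have at least one column")
  bad <- grepl(paste0("[^", paste(setdiff(.POLX_ALPHABET, "-"), collapse = ""), "-]"),
               seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- which(!chars %in% .POLX_ALPHABET)[1L]
    stop("alphabet error: illegal character '", chars[pos],
         "' in record '", ids[i], "' at column ", pos)
  }
  structure(list(ids = ids, seqs = seqs, n_columns = n_columns),
            class = "polx_msa")
}

#' @export
print.polx_msa <- function(x, ...) {
  cat("polx_msa: ", length(x$ids), " sequences x ", x$n_columns, " columns\n",
      sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a protein multiple sequence alignment from FASTA, preserving record
#' order. All records must have identical aligned length.
#'
#' @param path path to an aligned FASTA file (gap '-'; '.' accepted).
#' @return A \code{\link{polx_msa}} object.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 1L)
    stop("FASTA contains no records: ", path)
  # FASTA headers: id is the first whitespace-delimited token
  ids <- sub("\\s.*$", "", names(ss))
  polx_msa(ids, as.character(ss))
}

#' Write an aligned FASTA file
#'
#' Writes the alignment with 60-column line wrapping.
#'
#' @param msa a \code{\link{polx_msa}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "polx_msa"))
  ss <- Biostrings::BStringSet(setNames(msa$seqs, msa$ids))
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

#' Count non-gap characters of an aligned sequence
#'
#' @param aligned_seq character vector of aligned sequences.
#' @return integer vector: per sequence, the number of non-'-' characters.
#' @examples
#' ungapped_length(c("A-CD", "----"))
#' @export
ungapped_length <- function(aligned_seq) {
  nchar(gsub("-", "", aligned_seq, fixed = TRUE))
}

# character matrix view of selected 0-based columns; rows follow msa order
.msa_columns <- function(msa, cols0) {
  stopifnot(all(cols0 >= 0L), all(cols0 < msa$n_columns))
  out <- matrix("", nrow = length(msa$ids), ncol = length(cols0))
  for (j in seq_along(cols0)) {
    p <- cols0[j] + 1L
    out[, j] <- substr(msa$seqs, p, p)
  }
  rownames(out) <- msa$ids
  out
}
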