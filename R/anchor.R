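# Reference anchoring: translate reference residue numbering into alignment
# column coordinates. Columns are 0-based internally; user-facing reports
# print 1-based columns.

#' Build a reference anchor
#'
#' Maps reference residue numbers to 0-based alignment columns: residue
#' \code{k} maps to the column holding the reference row's
#' \code{(k - first_residue_number + 1)}-th non-gap character.
#'
#' @param msa a \code{\link{polx_msa}}.
#' @param ref_id identifier of the reference row (must be present).
#' @param first_residue_number residue number of the reference's first
#'   non-gap character (default 1).
#' @return An object of class \code{polx_anchor}: list with \code{ref_id},
#'   \code{first_residue_number}, \code{residues} (integer residue numbers)
#'   and \code{columns} (0-based columns, parallel to \code{residues}).
#' @examples
#' msa <- polx_msa(c("ref", "q"), c("A-CD", "AEC-"))
#' a <- build_anchor(msa, "ref")
#' anchor_column(a, 2)  # residue 2 sits in 0-based column 2
#' @export
build_anchor <- function(msa, ref_id, first_residue_number = 1L) {
  stopifnot(inherits(msa, "polx_msa"))
  i <- match(ref_id, msa$ids)
  if (is.na(i))
    stop("unknown ref_id: '", ref_id, "'")
  chars <- strsplit(msa$seqs[i], "", fixed = TRUE)[[1L]]
  cols0 <- which(chars != "-") - 1L
  if (length(cols0) == 0L)
    stop("reference row '", ref_id, "' is all gaps")
  residues <- seq.int(from = as.integer(first_residue_number),
                      length.out = length(cols0))
  structure(list(ref_id = ref_id,
                 first_residue_number = as.integer(first_residue_number),
                 residues = residues,
                 columns = cols0),
            class = "polx_anchor")
}

#' @export
print.polx_anchor <- function(x, ...) {
  cat("polx_anchor on '", x$ref_id, "': residues ", min(x$residues), "-",
      max(x$residues), " -> ", length(x$columns), " columns\n", sep = "")
  invisible(x)
}

#' Look up alignment columns of reference residues
#'
#' @param anchor a \code{\link{build_anchor}} result.
#' @param residue integer vector of reference residue numbers.
#' @return integer vector of 0-based alignment columns.
#' @export
anchor_column <- function(anchor, residue) {
  stopifnot(inherits(anchor, "polx_anchor"))
  idx <- match(as.integer(residue), anchor$residues)
  if (anyNA(idx))
    stop("range error: residue(s) ",
         paste(residue[is.na(idx)], collapse = ", "),
         " outside reference span ", min(anchor$residues), "-",
         max(anchor$residues))
  anchor$columns[idx]
}

#' Alignment column interval of a reference residue range
#'
#' Returns the inclusive 0-based column interval spanned by a reference
#' residue range. Insertion columns (where the reference is gapped) that lie
#' between the two end residues are inside the interval.
#'
#' @param anchor a \code{\link{build_anchor}} result.
#' @param start_res,end_res reference residue numbers, \code{start_res <=
#'   end_res}, both mapped.
#' @return integer vector \code{c(start = , end = )} of 0-based columns.
#' @export
columns_for_range <- function(anchor, start_res, end_res) {
  if (start_res > end_res)
    stop("start_res must be <= end_res")
  cols <- anchor_column(anchor, c(start_res, end_res))
  c(start = cols[1L], end = cols[2L])
}
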