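#' Standard amino-acid alphabet used for encoding
#'
#' Twenty standard residues plus a final "X" bucket that absorbs any symbol
#' outside the standard alphabet (ambiguity codes such as B, Z, J, U, O).
#'
#' @export
protein_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and a single terminal stop symbol (`*`) is
#' stripped. Duplicate identifiers and empty sequences are rejected.
#' Identifiers are taken up to the first whitespace of the header.
#'
#' @param input path to a FASTA file, or a character vector of FASTA lines.
#' @return data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(input) {
  path <- if (length(input) == 1L && file.exists(input)) input else {
    tf <- tempfile(fileext = ".fa")
    writeLines(as.character(input), tf)
    tf
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- ids[!nzchar(seqs)]
  if (length(empty) > 0L)
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "))
  data.frame(id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param records data.frame with columns `id`, `sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# residue -> alphabet index (unknowns to the last, "unknown", slot)
.residue_index <- function(sequence, alphabet = protein_alphabet) {
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], alphabet)
  idx[is.na(idx)] <- length(alphabet)
  idx
}

#' One-hot encode a batch of protein sequences
#'
#' Each sequence is truncated at `max_len`, residues outside the alphabet
#' map to the trailing unknown bucket, and shorter sequences are right-
#' padded with all-zero position vectors.
#'
#' @param records data.frame with columns `id`, `sequence`.
#' @param max_len number of encoded positions (default 2000).
#' @param alphabet ordered residue symbols; the last symbol is the unknown
#'   bucket (default [protein_alphabet], 21 symbols).
#' @return An `encoded_batch` object: list with `onehot` (array
#'   n x max_len x |alphabet|), `index` (list of integer residue-index
#'   vectors, used internally by the CNN), `ids`, `lengths` (encoded,
#'   i.e. post-truncation, lengths), `alphabet`, `max_len`.
#' @export
encode_batch <- function(records, max_len = 2000L,
                         alphabet = protein_alphabet) {
  stopifnot(max_len >= 1L, length(alphabet) >= 2L)
  n <- nrow(records)
  index <- lapply(records$sequence, function(s)
    head(.residue_index(s, alphabet), max_len))
  onehot <- array(0, dim = c(n, max_len, length(alphabet)),
                  dimnames = list(records$id, NULL, alphabet))
  for (i in seq_len(n)) {
    idx <- index[[i]]
    if (length(idx) > 0L)
      onehot[cbind(i, seq_along(idx), idx)] <- 1
  }
  structure(list(onehot = onehot, index = index, ids = records$id,
                 lengths = lengths(index), alphabet = alphabet,
                 max_len = as.integer(max_len)),
            class = "encoded_batch")
}

#' @export
print.encoded_batch <- function(x, ...) {
  cat("Encoded batch: ", length(x$ids), " sequences x ", x$max_len,
      " positions x ", length(x$alphabet), " symbols\n", sep = "")
  invisible(x)
}
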