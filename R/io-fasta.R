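# Protein FASTA I/O. Sequences are held as Biostrings AAStringSet; readers
# enforce the record invariants (unique ids, non-empty sequences, standard
# alphabet plus X) instead of silently coercing.

.PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                       "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file.
#' @return An \code{\link[Biostrings]{AAStringSet}} with unique names;
#'   sequences are uppercased and whitespace-stripped.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  aa <- Biostrings::AAStringSet(toupper(gsub("\\s", "", as.character(aa))))
  validate_protein_set(aa)
  aa
}

#' Validate a set of protein records
#'
#' Checks id uniqueness, non-empty sequences and the 20-residue alphabet
#' (plus X). Errors name the offending record.
#'
#' @param aa An \code{AAStringSet} or named character vector.
#' @return The input, invisibly, when valid.
#' @export
validate_protein_set <- function(aa) {
  ids <- names(aa)
  if (is.null(ids) || any(is.na(ids)) || any(ids == "")) {
    stop("every protein record needs a non-empty id")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- as.character(aa)
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "", fixed = TRUE)[[1]] %in% .PROTEIN_ALPHABET)
  }, logical(1))
  if (any(bad)) {
    stop("non-standard residues in id(s): ",
         paste(ids[bad], collapse = ", "))
  }
  invisible(aa)
}

#' Write protein records to FASTA
#'
#' @param aa An \code{AAStringSet} or named character vector of sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(aa, path) {
  if (!methods::is(aa, "XStringSet")) {
    aa <- Biostrings::AAStringSet(aa)
  }
  validate_protein_set(aa)
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}
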