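#' Read sequences from a FASTA file
#'
#' Thin wrapper over [ape::read.FASTA()] returning the record data.frame
#' used throughout the package. Sequences are uppercased; gaps and IUPAC
#' ambiguity codes are preserved.
#'
#' @param path FASTA file.
#' @return data.frame with `specimen_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  seqs <- vapply(as.character(bin), function(x)
    toupper(paste(x, collapse = "")), character(1))
  data.frame(specimen_id = names(bin), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records data.frame with `specimen_id`, `sequence`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  lines <- character(2L * nrow(records))
  lines[c(TRUE, FALSE)] <- paste0(">", records$specimen_id)
  lines[c(FALSE, TRUE)] <- records$sequence
  writeLines(lines, path)
  invisible(path)
}

#' Read a taxonomy table
#'
#' @param path TSV with header columns `specimen_id`, `species`, `genus`,
#'   `family`.
#' @return data.frame with those columns.
#' @export
read_taxonomy <- function(path) {
  tax <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
  need <- c("specimen_id", "species", "genus", "family")
  if (!all(need %in% names(tax)))
    stop("taxonomy file must have columns: ", paste(need, collapse = ", "))
  tax[, need]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
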