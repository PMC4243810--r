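#' Read sequences from a FASTA file
#'
#' @param path file path.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path file path.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">", names(seqs)[i]), seqs[[i]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-separated table with a header row
#' @param path file path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a tab-separated table with a header row
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], num_fmt)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square PHYLIP-style distance matrix
#'
#' @param D symmetric numeric matrix with taxon dimnames (or a
#'   `dist_matrix` from [protein_distances()]).
#' @param path file path.
#' @export
write_phylip_dist <- function(D, path) {
  if (inherits(D, "dist_matrix")) D <- D$D
  n <- nrow(D)
  lines <- format(n)
  for (i in seq_len(n)) {
    lines <- c(lines, paste(c(formatC(rownames(D)[i], width = -10),
                              num_fmt(D[i, ])), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}
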