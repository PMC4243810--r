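# Synteny neighborhoods and tandem clusters.  Gene loci are 1-based
# inclusive coordinates; the gap between adjacent loci is
# next.start - prev.end - 1.

#' Read a gene-location table
#'
#' Tab-separated with header: `species`, `scaffold`, `start`, `end`,
#' `strand`, `symbol`; coordinates 1-based inclusive, strand `+`/`-`.
#'
#' @param path file path.
#' @return Validated data.frame.
#' @export
read_loci <- function(path) {
  df <- read_tsv(path)
  validate_loci(df)
}

validate_loci <- function(df) {
  need <- c("species", "scaffold", "start", "end", "strand", "symbol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("loci table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$start > df$end))
    stop_invalid("locus with start > end: ",
                 df$symbol[which(df$start > df$end)[1]])
  if (!all(df$strand %in% c("+", "-")))
    stop_invalid("strand must be '+' or '-'")
  key <- paste(df$species, df$scaffold, df$start)
  if (anyDuplicated(key))
    stop_invalid("duplicate (species, scaffold, start): ",
                 key[anyDuplicated(key)])
  df
}

#' Extract the genomic neighborhood around family genes
#'
#' For each locus whose symbol is in `family_symbols`, the k nearest
#' non-family genes on each side of it on the same scaffold, in
#' coordinate order (fewer if the scaffold ends).
#'
#' @param loci loci data.frame (see [read_loci()]).
#' @param family_symbols symbols of the focal gene family.
#' @param k flank size in genes (>= 1, default 3).
#' @return A named list of neighborhoods, one per focal gene; each has
#'   `focal` (one-row data.frame), `upstream`, `downstream` (symbol
#'   vectors in coordinate order) and `strands`.
#' @export
extract_neighborhood <- function(loci, family_symbols, k = 3) {
  if (k < 1) stop_invalid("k must be >= 1")
  loci <- validate_loci(loci)
  fam <- loci$symbol %in% family_symbols
  if (!any(fam))
    stop_invalid("no locus matches the focal symbols")
  out <- list()
  for (i in which(fam)) {
    same <- loci$species == loci$species[i] &
      loci$scaffold == loci$scaffold[i]
    nb <- loci[same & !(loci$symbol %in% family_symbols), , drop = FALSE]
    nb <- nb[order(nb$start), , drop = FALSE]
    up <- nb[nb$end < loci$start[i], , drop = FALSE]
    down <- nb[nb$start > loci$end[i], , drop = FALSE]
    up <- tail(up, k)
    down <- head(down, k)
    out[[loci$symbol[i]]] <- structure(
      list(focal = loci[i, , drop = FALSE],
           upstream = up$symbol, downstream = down$symbol,
           strands = c(up$strand, loci$strand[i], down$strand)),
      class = "neighborhood")
  }
  out
}

#' Neighborhood conservation score
#'
#' Jaccard index of the two neighborhoods' flanking symbol sets
#' (case-insensitive); symmetric, 1 iff the sets are equal, 0 iff
#' disjoint.
#'
#' @param n1,n2 neighborhoods from [extract_neighborhood()].
#' @return list with `score` in `[0, 1]` and `shared` symbols.
#' @export
conservation_score <- function(n1, n2) {
  s1 <- unique(toupper(c(n1$upstream, n1$downstream)))
  s2 <- unique(toupper(c(n2$upstream, n2$downstream)))
  if (length(s1) == 0 && length(s2) == 0)
    return(list(score = 1, shared = character(0)))
  shared <- intersect(s1, s2)
  list(score = length(shared) / length(union(s1, s2)), shared = shared)
}

#' Detect tandem clusters of family genes
#'
#' Family genes on the same scaffold are chained whenever the gap to the
#' next gene (`next.start - prev.end - 1`) is at most `max_gap`.  The
#' output partitions the family loci; growing `max_gap` only ever merges
#' clusters.
#'
#' @param loci loci data.frame.
#' @param family_symbols symbols of the family.
#' @param max_gap maximal intergenic gap in base pairs (default 200 kb,
#'   which covers the ~30 kb spacing seen in tandem vertebrate pairs
#'   with margin).
#' @return data.frame with one row per cluster: `cluster`, `species`,
#'   `scaffold`, `size`, `span`, `same_strand`, `members`
#'   (comma-separated, in coordinate order).
#' @export
tandem_clusters <- function(loci, family_symbols, max_gap = 200000) {
  if (max_gap <= 0) stop_invalid("max_gap must be > 0")
  loci <- validate_loci(loci)
  fam <- loci[loci$symbol %in% family_symbols, , drop = FALSE]
  rows <- list()
  cl_id <- 0L
  for (key in unique(paste(fam$species, fam$scaffold, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    d <- fam[fam$species == parts[1] & fam$scaffold == parts[2], ,
             drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    gaps <- if (nrow(d) > 1) d$start[-1] - d$end[-nrow(d)] - 1 else numeric(0)
    brk <- c(0, cumsum(gaps > max_gap))
    for (g in unique(brk)) {
      cl_id <- cl_id + 1L
      dd <- d[brk == g, , drop = FALSE]
      rows[[cl_id]] <- data.frame(
        cluster = cl_id, species = parts[1], scaffold = parts[2],
        size = nrow(dd), span = max(dd$end) - min(dd$start) + 1,
        same_strand = length(unique(dd$strand)) == 1,
        members = paste(dd$symbol, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
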