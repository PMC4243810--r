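# Functional scanning: map aligned sequences onto mature reference
# numbering (the mature goose coordinate system, with catalytic sites at
# 73, 86 and 97), classify muramidase and secretion status, and build
# the per-species compensation cross-tab.

#' Map alignment rows onto mature reference numbering
#'
#' The reference row's ungapped positions define the coordinate system;
#' mature position p corresponds to ungapped reference position
#' `p + mature_offset`.  Every other row reports its residue at each
#' mature position, `"gap"` for an internal gap, or `"missing"` where
#' the row has no residues at or beyond/before that region (truncated
#' sequence ends).
#'
#' @param aln an `aligned_set`.
#' @param reference_id row id of the reference sequence.
#' @param mature_offset number of precursor residues preceding mature
#'   position 1 (e.g. the signal peptide length); never guessed.
#' @return A character matrix (rows = sequence ids, columns = mature
#'   positions `1..n`), class `reference_map`.
#' @export
build_reference_map <- function(aln, reference_id, mature_offset = 0) {
  if (!reference_id %in% aln$ids)
    stop_invalid("reference id '", reference_id, "' absent from alignment")
  # positions in the original (pre-trim) reference sequence when the
  # alignment has been trimmed, plain ungapped positions otherwise
  ref_pos <- aln$orig_positions[[reference_id]] %||%
    row_positions(aln, reference_id)
  ref_len <- max(ref_pos, na.rm = TRUE)
  if (mature_offset >= ref_len)
    stop_invalid("mature_offset must be smaller than the reference length")
  mature_cols <- which(!is.na(ref_pos) & ref_pos > mature_offset)
  mature_pos <- ref_pos[mature_cols] - mature_offset
  m <- as.matrix(aln)
  out <- matrix("missing", nrow = length(aln$ids),
                ncol = length(mature_cols),
                dimnames = list(aln$ids, mature_pos))
  for (i in seq_along(aln$ids)) {
    row <- m[i, ]
    res_cols <- which(row != "-")
    first <- min(res_cols); last <- max(res_cols)
    vals <- row[mature_cols]
    vals[vals == "-"] <- "gap"
    vals[mature_cols < first | mature_cols > last] <- "missing"
    out[i, ] <- vals
  }
  structure(out, class = c("reference_map", class(out)),
            reference_id = reference_id, mature_offset = mature_offset)
}

#' Extract site states from a reference map
#' @param refmap a `reference_map`.
#' @param sites mature positions (default the catalytic triple 73/86/97).
#' @return Character matrix rows = ids, columns = sites.
#' @export
site_states <- function(refmap, sites = c(73, 86, 97)) {
  missing_sites <- setdiff(as.character(sites), colnames(refmap))
  if (length(missing_sites)) {
    extra <- matrix("missing", nrow = nrow(refmap),
                    ncol = length(missing_sites),
                    dimnames = list(rownames(refmap), missing_sites))
    refmap <- cbind(unclass(refmap), extra)
  }
  unclass(refmap)[, as.character(sites), drop = FALSE]
}

#' Classify muramidase status from catalytic site states
#'
#' Rules, applied in order on states at mature sites 73 (catalytic
#' glutamate), 86 and 97 (aspartates): E/D/D is `intact`; a
#' non-glutamate at 73 abolishes activity unless it is aspartate, which
#' only reduces it (glutamine is the mutagenesis-verified knockout;
#' lysine, glycine and other replacements are graded as inferred);
#' with glutamate at 73, one replaced aspartate reduces activity and
#' both replaced abolish it.  A gap or missing state at a site required
#' for the verdict yields `unknown`.
#'
#' @param s73,s86,s97 character vectors of site states (single residue
#'   letters, `"gap"`, or `"missing"`).
#' @return data.frame with `site73`, `site86`, `site97`, `muramidase`,
#'   `provenance`.
#' @export
classify_catalytic <- function(s73, s86, s97) {
  n <- length(s73)
  verdict <- character(n)
  prov <- character(n)
  absent <- function(x) x %in% c("gap", "missing")
  for (i in seq_len(n)) {
    a <- s73[i]; b <- s86[i]; c <- s97[i]
    if (absent(a)) {
      verdict[i] <- "unknown"; prov[i] <- "site 73 unobserved"
    } else if (a == "E") {
      if (absent(b) || absent(c)) {
        verdict[i] <- "unknown"; prov[i] <- "aspartate site unobserved"
      } else if (b == "D" && c == "D") {
        verdict[i] <- "intact"; prov[i] <- "wild-type catalytic triple"
      } else if (b != "D" && c != "D") {
        verdict[i] <- "abolished"; prov[i] <- "both aspartates replaced"
      } else {
        verdict[i] <- "reduced"; prov[i] <- "one aspartate replaced"
      }
    } else if (a == "D") {
      verdict[i] <- "reduced"
      prov[i] <- "E73D, mutagenesis-verified reduction"
    } else if (a == "Q") {
      verdict[i] <- "abolished"
      prov[i] <- "E73Q, mutagenesis-verified knockout"
    } else {
      verdict[i] <- "abolished"
      prov[i] <- paste0("E73", a, ", inferred knockout (untested)")
    }
  }
  data.frame(site73 = s73, site86 = s86, site97 = s97,
             muramidase = verdict, provenance = prov,
             stringsAsFactors = FALSE)
}

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Classify secretion status
#'
#' When external predictions are supplied (a signal-peptide yes/no call
#' and a non-classical secretion score), the verdict follows them:
#' `classical` if a signal peptide is predicted, else
#' `nonclassical_possible` when the score reaches `nonclassical_threshold`,
#' else `intracellular`.  Without annotations a crude hydrophobicity
#' fallback is applied - an 8-residue sliding window within positions
#' 1-30 with mean Kyte-Doolittle hydropathy >= 1.6 calls `classical` -
#' and the provenance marks the verdict as heuristic, low confidence.
#'
#' @param sequence amino-acid string (needed for the fallback only).
#' @param annotation optional list or one-row data.frame with
#'   `signal_peptide` (`"yes"`/`"no"`) and `nonclassical_score`.
#' @param nonclassical_threshold score threshold (default 0.5).
#' @return list with `verdict` and `provenance`.
#' @export
classify_secretion <- function(sequence = NULL, annotation = NULL,
                               nonclassical_threshold = 0.5) {
  if (!is.null(annotation)) {
    sp <- annotation$signal_peptide
    if (is.null(sp) || !(sp %in% c("yes", "no")))
      stop_invalid("malformed annotation: signal_peptide must be yes/no",
                   if (!is.null(annotation$id)) paste0(" (", annotation$id, ")"))
    if (sp == "yes")
      return(list(verdict = "classical", provenance = "external prediction"))
    sc <- annotation$nonclassical_score
    if (!is.null(sc) && !is.na(sc) && sc >= nonclassical_threshold)
      return(list(verdict = "nonclassical_possible",
                  provenance = "external prediction"))
    return(list(verdict = "intracellular", provenance = "external prediction"))
  }
  if (is.null(sequence))
    return(list(verdict = "unknown", provenance = "no sequence, no annotation"))
  v <- chars(sequence)
  prefix <- v[seq_len(min(30, length(v)))]
  kd <- unname(KD_SCALE[prefix])
  kd[is.na(kd)] <- 0
  win <- 8
  if (length(kd) >= win) {
    means <- vapply(seq_len(length(kd) - win + 1),
                    function(i) mean(kd[i:(i + win - 1)]), numeric(1))
    if (max(means) >= 1.6)
      return(list(verdict = "classical",
                  provenance = "heuristic, low confidence"))
  }
  list(verdict = "intracellular", provenance = "heuristic, low confidence")
}

#' Per-gene functional status table
#'
#' Combines [build_reference_map()], [classify_catalytic()] and
#' [classify_secretion()] into one table mirroring a per-sequence
#' active-site and secretion survey.
#'
#' @param aln an `aligned_set`.
#' @param reference_id,mature_offset see [build_reference_map()].
#' @param sequences optional named ungapped sequences (for the secretion
#'   fallback); defaults to the de-gapped alignment rows.
#' @param annotations optional data.frame with columns `id`,
#'   `signal_peptide`, `nonclassical_score`.
#' @param sites mature positions of the catalytic sites.
#' @return data.frame with one row per sequence.
#' @export
functional_scan <- function(aln, reference_id, mature_offset = 0,
                            sequences = NULL, annotations = NULL,
                            sites = c(73, 86, 97)) {
  refmap <- build_reference_map(aln, reference_id, mature_offset)
  st <- site_states(refmap, sites)
  res <- classify_catalytic(st[, 1], st[, 2], st[, 3])
  res <- cbind(data.frame(gene = rownames(st), stringsAsFactors = FALSE),
               res)
  if (is.null(sequences)) sequences <- degap(aln)
  sec <- lapply(res$gene, function(g) {
    ann <- NULL
    if (!is.null(annotations) && g %in% annotations$id)
      ann <- annotations[annotations$id == g, , drop = FALSE]
    classify_secretion(sequences[[g]], ann)
  })
  res$secretion <- vapply(sec, function(x) x$verdict, "")
  res$secretion_provenance <- vapply(sec, function(x) x$provenance, "")
  rownames(res) <- NULL
  res
}

#' Copy-number compensation cross-tab
#'
#' Per species: copy number and counts of intact / reduced / abolished /
#' unknown muramidase verdicts.  Globally: counts of replacements at
#' each catalytic site (observed residues only; gap/missing states are
#' excluded from replacement counts and reported separately) and of
#' sequences with both aspartates replaced.  Species carrying at least
#' one non-intact copy and no intact copy are flagged as uncompensated.
#'
#' @param status data.frame from [functional_scan()].
#' @param leaf_map named character vector gene -> species.
#' @return list with `per_species` (data.frame), `global` (named
#'   numeric), `uncompensated` (character vector of species).
#' @export
compensation_table <- function(status, leaf_map) {
  if (nrow(status) < 1) stop_invalid("need at least one gene")
  status$species <- unname(leaf_map[status$gene])
  per <- do.call(rbind, lapply(split(status, status$species), function(d) {
    data.frame(species = d$species[1], n_copies = nrow(d),
               n_intact = sum(d$muramidase == "intact"),
               n_reduced = sum(d$muramidase == "reduced"),
               n_abolished = sum(d$muramidase == "abolished"),
               n_unknown = sum(d$muramidase == "unknown"),
               stringsAsFactors = FALSE)
  }))
  per <- per[order(per$species), , drop = FALSE]
  rownames(per) <- NULL
  observed <- function(x) !(x %in% c("gap", "missing"))
  o73 <- observed(status$site73); o86 <- observed(status$site86)
  o97 <- observed(status$site97)
  glob <- c(
    site73_replaced = sum(o73 & status$site73 != "E"),
    site86_replaced = sum(o86 & status$site86 != "D"),
    site97_replaced = sum(o97 & status$site97 != "D"),
    both_aspartates_replaced = sum(o86 & o97 & status$site86 != "D" &
                                     status$site97 != "D"),
    site73_unobserved = sum(!o73),
    site86_unobserved = sum(!o86),
    site97_unobserved = sum(!o97))
  flagged <- per$species[per$n_intact == 0 &
                           (per$n_reduced + per$n_abolished) > 0]
  list(per_species = per, global = glob, uncompensated = flagged)
}
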