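# End-to-end orchestration: align -> confidence -> trim -> distances ->
# NJ + bootstrap -> outgroup rooting -> reconciliation -> functional
# scan -> synteny.  Intermediate artifacts are plain-text files, the
# contract between stages, and every run is byte-identical under a
# fixed config.

#' Pipeline configuration
#'
#' @param sequences path to a protein FASTA.
#' @param species_tree path to a rooted Newick species tree.
#' @param leaf_map path to a TSV with columns `gene`, `species`.
#' @param loci optional path to a gene-location TSV.
#' @param annotations optional path to a secretion-annotation TSV
#'   (`id`, `signal_peptide`, `nonclassical_score`).
#' @param out_dir output directory.
#' @param trim_cutoff column-confidence retention cutoff (default 0.93).
#' @param bootstrap_reps bootstrap replicates (default 1000).
#' @param n_perturb guide-tree perturbations for column confidence.
#' @param outgroup species names used to root the gene tree; their genes
#'   are dropped before reconciliation.
#' @param reference_id reference sequence id for mature numbering.
#' @param mature_offset precursor residues before mature position 1.
#' @param family_prefix paralog name prefix.
#' @param letter_min_age age tier separating letter-rank duplications
#'   (`NULL`: half the species-tree height).
#' @param synteny_k flank size in genes.
#' @param max_gap tandem-cluster gap limit (bp).
#' @param min_overlap minimum sites for a defined distance.
#' @param seed integer seed governing every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sequences, species_tree, leaf_map,
                            loci = NULL, annotations = NULL,
                            out_dir = "lygfam_out",
                            trim_cutoff = 0.93, bootstrap_reps = 1000,
                            n_perturb = 10, outgroup = character(0),
                            reference_id = NULL, mature_offset = 0,
                            family_prefix = "Lyg", letter_min_age = NULL,
                            synteny_k = 3, max_gap = 200000,
                            min_overlap = 20, seed = 1) {
  cfg <- list(sequences = sequences, species_tree = species_tree,
              leaf_map = leaf_map, loci = loci, annotations = annotations,
              out_dir = out_dir, trim_cutoff = trim_cutoff,
              bootstrap_reps = bootstrap_reps, n_perturb = n_perturb,
              outgroup = outgroup, reference_id = reference_id,
              mature_offset = mature_offset, family_prefix = family_prefix,
              letter_min_age = letter_min_age, synteny_k = synteny_k,
              max_gap = max_gap, min_overlap = min_overlap, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline config (lossless round-trip)
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$outgroup <- as.character(cfg$outgroup %||% character(0))
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% m
  sprintf("%010d", h)
}

#' Validate pipeline inputs
#'
#' Checks that files parse and that ids are cross-consistent: every
#' sequence has a species mapping, mapped species occur in the species
#' tree, and loci coordinates are sane.  Returns diagnostics rather
#' than raising.
#'
#' @param config a `pipeline_config`.
#' @return data.frame with columns `file`, `issue` (zero rows when
#'   everything is consistent).
#' @export
validate_inputs <- function(config) {
  findings <- list()
  note <- function(file, issue)
    findings[[length(findings) + 1L]] <<- data.frame(
      file = file, issue = issue, stringsAsFactors = FALSE)
  seqs <- tryCatch(read_fasta(config$sequences),
                   error = function(e) { note(config$sequences,
                     paste("FASTA parse error:", conditionMessage(e))); NULL })
  st <- tryCatch(ape::read.tree(config$species_tree),
                 error = function(e) { note(config$species_tree,
                   paste("Newick parse error:", conditionMessage(e))); NULL })
  lm <- tryCatch(read_tsv(config$leaf_map),
                 error = function(e) { note(config$leaf_map,
                   paste("TSV parse error:", conditionMessage(e))); NULL })
  if (!is.null(seqs) && !is.null(lm)) {
    for (g in setdiff(names(seqs), lm$gene))
      note(config$leaf_map, paste("sequence without species mapping:", g))
  }
  if (!is.null(lm) && !is.null(st)) {
    for (s in setdiff(unique(lm$species), st$tip.label))
      note(config$species_tree, paste("mapped species absent from tree:", s))
  }
  if (!is.null(config$loci)) {
    loci <- tryCatch(read_tsv(config$loci),
                     error = function(e) { note(config$loci,
                       paste("TSV parse error:", conditionMessage(e))); NULL })
    if (!is.null(loci)) {
      bad <- which(loci$start > loci$end)
      for (b in bad)
        note(config$loci, sprintf("start > end at line %d (%s)", b + 1L,
                                  loci$symbol[b]))
    }
  }
  if (length(findings) == 0)
    return(data.frame(file = character(0), issue = character(0)))
  do.call(rbind, findings)
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Stages run in order with intermediate artifacts persisted under
#' `config$out_dir`; the summary report lists duplication events with
#' age labels, per-branch losses, paralog names, the functional
#' cross-tab with flagged uncompensated species, and synteny scores.
#' Outputs are byte-identical across runs with the same config.
#'
#' @param config a `pipeline_config`.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config) {
  diag <- validate_inputs(config)
  if (nrow(diag))
    stop_invalid("input validation failed: ",
                 paste(diag$issue, collapse = "; "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  seqs <- read_fasta(config$sequences)
  species_tree <- ape::read.tree(config$species_tree)
  lm <- read_tsv(config$leaf_map)
  leaf_map <- setNames(lm$species, lm$gene)

  stage_msg("align", length(seqs), " sequences")
  aln <- column_confidence(seqs, n_perturb = config$n_perturb,
                           seed = config$seed)
  write_fasta(aln$seqs, out("aligned.fasta"))
  write_tsv(data.frame(column = seq_len(aln$width),
                       confidence = aln$confidence),
            out("confidence.tsv"))

  stage_msg("trim", "cutoff ", config$trim_cutoff)
  trimmed <- trim_alignment(aln, config$trim_cutoff)
  if (trimmed$width == 0)
    stop_invalid("trim stage removed every column")
  write_fasta(trimmed$seqs, out("trimmed.fasta"))
  write_tsv(data.frame(removed_column = trimmed$removed %||% integer(0)),
            out("removed_columns.tsv"))
  stage_msg("trim", trimmed$width, " of ", aln$width, " columns kept")

  stage_msg("tree", "NJ + ", config$bootstrap_reps, " bootstrap replicates")
  D <- protein_distances(trimmed, min_overlap = config$min_overlap)
  write_phylip_dist(D, out("distances.phylip"))
  bs <- bootstrap_support(trimmed, n_reps = config$bootstrap_reps,
                          seed = config$seed,
                          min_overlap = config$min_overlap)
  ape::write.tree(bs$tree, out("gene_tree.nwk"))

  og_genes <- names(leaf_map)[leaf_map %in% config$outgroup]
  og_genes <- intersect(og_genes, bs$tree$tip.label)
  if (length(og_genes) == 0)
    stop_invalid("no outgroup genes present; reconciliation needs a ",
                 "rooted gene tree")
  rooted <- root_by_outgroup(bs$tree, og_genes)
  ing <- ape::drop.tip(rooted, og_genes)
  ing_species <- ape::drop.tip(species_tree,
                               intersect(config$outgroup,
                                         species_tree$tip.label))
  ape::write.tree(rooted, out("rooted_tree.nwk"))

  stage_msg("reconcile", length(ing$tip.label), " ingroup genes")
  rec <- lca_reconcile(ing, ing_species, leaf_map)
  dup_labels <- label_duplication_ages(rec)
  losses <- count_losses_per_lineage(rec)
  naming <- assign_names(rec, config$family_prefix,
                         list(letter_min_age = config$letter_min_age))
  write_tsv(dup_labels, out("duplications.tsv"))
  write_tsv(losses, out("losses.tsv"))
  write_tsv(naming, out("names.tsv"))
  stage_msg("reconcile", length(rec$dup_nodes), " duplications, ",
            rec$losses_total, " losses")

  annotations <- if (!is.null(config$annotations))
    read_tsv(config$annotations) else NULL
  reference_id <- config$reference_id %||% trimmed$ids[1]
  stage_msg("scan", "reference ", reference_id, ", mature offset ",
            config$mature_offset)
  status <- functional_scan(trimmed, reference_id, config$mature_offset,
                            sequences = seqs, annotations = annotations)
  status_in <- status[status$gene %in% ing$tip.label, , drop = FALSE]
  comp <- compensation_table(status_in, leaf_map)
  write_tsv(status, out("status.tsv"))
  write_tsv(comp$per_species, out("compensation.tsv"))
  write_tsv(data.frame(species = comp$uncompensated),
            out("uncompensated.tsv"))

  synteny <- NULL
  clusters <- NULL
  if (!is.null(config$loci)) {
    loci <- read_loci(config$loci)
    fam_symbols <- names(leaf_map)
    stage_msg("synteny", "k = ", config$synteny_k, ", max gap ",
              config$max_gap)
    nbhd <- extract_neighborhood(loci, fam_symbols, config$synteny_k)
    ids <- names(nbhd)
    pairs <- if (length(ids) > 1) utils::combn(ids, 2) else
      matrix(character(0), 2, 0)
    synteny <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      cs <- conservation_score(nbhd[[pairs[1, i]]], nbhd[[pairs[2, i]]])
      data.frame(gene1 = pairs[1, i], gene2 = pairs[2, i],
                 score = cs$score,
                 shared = paste(cs$shared, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    clusters <- tandem_clusters(loci, fam_symbols, config$max_gap)
    if (!is.null(synteny)) write_tsv(synteny, out("synteny_scores.tsv"))
    write_tsv(clusters, out("clusters.tsv"))
  }

  report <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_sequences = length(seqs),
    alignment_width = aln$width,
    trimmed_width = trimmed$width,
    n_duplications = length(rec$dup_nodes),
    duplication_labels = if (nrow(dup_labels))
      as.list(setNames(dup_labels$label,
                       paste0("node", dup_labels$node))) else list(),
    total_losses = rec$losses_total,
    uncompensated_species = as.list(comp$uncompensated),
    bootstrap_replicates_used = bs$n_used,
    bootstrap_replicates_skipped = bs$n_skipped)
  yaml::write_yaml(report, out("report.yaml"))
  write_config(config, out("config_used.yaml"))
  stage_msg("report", "written to ", config$out_dir)

  invisible(list(alignment = aln, trimmed = trimmed, tree = bs$tree,
                 rooted = rooted, reconciliation = rec,
                 duplications = dup_labels, losses = losses,
                 naming = naming, status = status, compensation = comp,
                 synteny = synteny, clusters = clusters, report = report))
}
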