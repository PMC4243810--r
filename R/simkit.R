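# Birth-death gene family simulator.  Generates ground-truthed synthetic
# families: a species tree, a gene tree with a full event history
# (duplications, losses, speciations - including events in clades that
# subsequently went extinct), amino-acid sequences with conserved
# catalytic sites, post-duplication functional decay, and clustered gene
# coordinates with conserved flanking markers.

#' Fixed vertebrate-like species tree
#'
#' A 14-species ultrametric rooted tree spanning the major vertebrate
#' classes (mammals, birds, reptiles, an amphibian, a lobe-finned fish,
#' teleosts, and a jawless fish as outgroup), with named internal nodes
#' such as `amniote_ancestor` and `teleost_ancestor`.  Branch lengths are
#' in arbitrary time units with a root depth of 5.
#'
#' @return A rooted binary ultrametric `phylo`.
#' @export
vertebrate_tree <- function() {
  path <- system.file("extdata", "vertebrate_species_tree.nwk",
                      package = "lygfam")
  ape::read.tree(path)
}

#' Simulate a Yule species tree
#'
#' Pure-birth (Yule) simulation conditioned on a number of extant
#' species.  Lineages split at rate `birth_rate` each; after the last
#' split an extra exponential waiting time is drawn and all tips are
#' extended to that horizon, so the tree is ultrametric.
#'
#' @param n_species number of extant species (>= 2).
#' @param birth_rate speciation rate per lineage per time unit (> 0).
#' @param seed integer seed; the operation draws from its own stream.
#' @return A rooted binary ultrametric `phylo` with tips `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1, seed = 1) {
  if (!is.numeric(n_species) || n_species < 2)
    stop_invalid("n_species must be >= 2")
  if (birth_rate <= 0) stop_invalid("birth_rate must be > 0")
  n_species <- as.integer(n_species)
  with_seed(op_seed("simulate_species_tree", seed), {
    # active lineages: birth time of each; children built up as newick text
    frag <- c("L1", "L2")          # placeholders, resolved at the end
    t0 <- c(0, 0)
    sub <- list()                  # resolved subtrees for placeholders
    t <- 0
    k <- 2L
    next_id <- 3L
    while (k < n_species) {
      t <- t + rexp(1, k * birth_rate)
      i <- sample.int(k, 1)
      a <- paste0("L", next_id); b <- paste0("L", next_id + 1L)
      sub[[frag[i]]] <- list(children = c(a, b), t = t)
      frag[i] <- a
      frag <- append(frag, b, after = i)
      t0[i] <- t
      t0 <- append(t0, t, after = i)
      next_id <- next_id + 2L
      k <- k + 1L
    }
    horizon <- t + rexp(1, n_species * birth_rate)
    # assign tip labels in left-to-right order
    labels <- sprintf("sp%02d", seq_len(n_species))
    tipname <- setNames(labels, frag)
    deparse_lineage <- function(id, t_start) {
      if (!is.null(sub[[id]])) {
        s <- sub[[id]]
        kids <- vapply(s$children, deparse_lineage, "", t_start = s$t)
        sprintf("(%s,%s):%s", kids[1], kids[2], num_fmt(s$t - t_start))
      } else {
        sprintf("%s:%s", tipname[[id]], num_fmt(horizon - t_start))
      }
    }
    nwk <- sprintf("(%s,%s);", deparse_lineage("L1", 0),
                   deparse_lineage("L2", 0))
    ape::read.tree(text = nwk)
  })
}

#' Simulate gene duplication and loss along a species tree
#'
#' A linear birth-death process runs independently for every gene lineage
#' along every species-tree branch, starting from a single gene at the
#' species-tree root.  Duplications create a sister lineage at the event
#' time; losses terminate a lineage; at speciation nodes every surviving
#' lineage is copied into both daughter branches.  The returned gene tree
#' contains only lineages with extant descendants (internal nodes with a
#' single surviving child are suppressed), while the event history also
#' records events in fully pruned clades.
#'
#' @param tree rooted binary species tree (`phylo` with branch lengths).
#' @param dup_rate duplication rate per gene lineage per time unit (>= 0).
#' @param loss_rate loss rate per gene lineage per time unit (>= 0).
#' @param seed integer seed.
#' @return A list with elements:
#'   \describe{
#'     \item{gene_tree}{`phylo` (or `NULL` if < 2 genes survive); tips are
#'       `<species>_g<i>`; surviving duplication nodes are labelled
#'       `D<event id>`.}
#'     \item{events}{data.frame of all events: `event_id`, `kind`
#'       (duplication/loss/speciation), `species_branch` (name of the
#'       species node at the bottom of the branch the event occurred on),
#'       `time` (absolute, from the root), `lineage`, `survived` (for
#'       duplications: both daughters left extant descendants).}
#'     \item{leaf_map}{named character vector gene id -> species.}
#'     \item{copy_number}{named integer vector per species (zeros kept).}
#'   }
#' @export
simulate_gene_family <- function(tree, dup_rate, loss_rate, seed = 1) {
  check_rooted_binary(tree, "species tree")
  if (dup_rate < 0 || loss_rate < 0) stop_invalid("rates must be >= 0")
  ntip <- ape::Ntip(tree)
  kids <- node_children(tree)
  times <- node_times(tree)
  tipsets <- descendant_tips(tree)
  branch_name <- vapply(seq_len(ntip + tree$Nnode),
                        function(v) species_node_name(tree, v, tipsets), "")

  env <- new.env()
  env$events <- list()
  env$next_event <- 1L
  env$next_lineage <- 2L
  env$gene_count <- setNames(integer(ntip), tree$tip.label)

  record <- function(kind, branch, time, lineage) {
    id <- env$next_event
    env$next_event <- id + 1L
    env$events[[id]] <- list(event_id = id, kind = kind,
                             species_branch = branch, time = time,
                             lineage = lineage)
    id
  }
  new_lineage <- function() {
    id <- env$next_lineage
    env$next_lineage <- id + 1L
    id
  }

  total <- dup_rate + loss_rate
  # simulate a lineage sitting on the branch that ends at species node v,
  # from absolute time t_now; returns a nested node list or NULL (extinct)
  descend <- function(v, t_now, lineage) {
    t_end <- times[v]
    repeat {
      dt <- if (total > 0) rexp(1, total) else Inf
      if (t_now + dt >= t_end) break
      t_now <- t_now + dt
      if (runif(1) < dup_rate / total) {
        eid <- record("duplication", branch_name[v], t_now, lineage)
        l2 <- new_lineage()
        left <- descend(v, t_now, lineage)
        right <- descend(v, t_now, l2)
        surv <- !is.null(left) && !is.null(right)
        env$events[[eid]]$survived <- surv
        if (is.null(left) && is.null(right)) return(NULL)
        if (is.null(left)) return(right)
        if (is.null(right)) return(left)
        return(list(kind = "duplication", label = paste0("D", eid),
                    time = t_now, children = list(left, right)))
      } else {
        record("loss", branch_name[v], t_now, lineage)
        return(NULL)
      }
    }
    if (v <= ntip) {
      env$gene_count[v] <- env$gene_count[v] + 1L
      g <- sprintf("%s_g%d", tree$tip.label[v], env$gene_count[v])
      return(list(kind = "leaf", label = g, time = t_end, species = v))
    }
    record("speciation", branch_name[v], t_end, lineage)
    left <- descend(kids[[v]][1], t_end, lineage)
    right <- descend(kids[[v]][2], t_end, lineage)
    if (is.null(left) && is.null(right)) return(NULL)
    if (is.null(left)) return(left <- right)
    if (is.null(right)) return(left)
    list(kind = "speciation", label = "", time = t_end,
         children = list(left, right))
  }

  root <- ntip + 1L
  tree_nested <- with_seed(op_seed("simulate_gene_family", seed), {
    eid0 <- record("speciation", branch_name[root], times[root], 1L)
    left <- descend(kids[[root]][1], times[root], 1L)
    right <- descend(kids[[root]][2], times[root], 1L)
    if (is.null(left) && is.null(right)) NULL
    else if (is.null(left)) right
    else if (is.null(right)) left
    else list(kind = "speciation", label = "", time = times[root],
              children = list(left, right))
  })

  events <- do.call(rbind, lapply(env$events, function(e) {
    data.frame(event_id = e$event_id, kind = e$kind,
               species_branch = e$species_branch, time = e$time,
               lineage = e$lineage,
               survived = if (e$kind == "duplication") isTRUE(e$survived)
                          else NA,
               stringsAsFactors = FALSE)
  }))

  leaves <- character(0)
  collect <- function(nd) {
    if (is.null(nd)) return(invisible())
    if (nd$kind == "leaf") leaves <<- c(leaves, nd$label)
    else for (ch in nd$children) collect(ch)
  }
  collect(tree_nested)

  gene_tree <- NULL
  if (!is.null(tree_nested) && length(leaves) >= 2 &&
      !is.null(tree_nested$children)) {
    dep <- function(nd, t_parent) {
      if (nd$kind == "leaf")
        return(sprintf("%s:%s", nd$label, num_fmt(nd$time - t_parent)))
      sprintf("(%s,%s)%s:%s",
              dep(nd$children[[1]], nd$time), dep(nd$children[[2]], nd$time),
              nd$label, num_fmt(nd$time - t_parent))
    }
    nwk <- sprintf("(%s,%s)%s;",
                   dep(tree_nested$children[[1]], tree_nested$time),
                   dep(tree_nested$children[[2]], tree_nested$time),
                   tree_nested$label)
    gene_tree <- ape::read.tree(text = nwk)
  }

  leaf_map <- setNames(sub("_g[0-9]+$", "", leaves), leaves)
  list(gene_tree = gene_tree, events = events, leaf_map = leaf_map,
       copy_number = env$gene_count)
}

#' Evolve amino-acid sequences along a gene tree
#'
#' Independent-site continuous-time substitution under the uniform
#' 20-state exchange model: events arrive at rate `(20/19) * rate` per
#' site per time unit and resample the site uniformly over all 20 amino
#' acids, so the expected number of realized substitutions per site per
#' unit time is `rate` and the proportion of differing sites between two
#' sequences at path length t is `(19/20) (1 - exp(-(20/19) t))`.  Sites
#' in `conserved_sites` evolve at `rate * conserved_rate_factor`.
#'
#' @param gene_tree `phylo` with branch lengths in time units.
#' @param root_sequence amino-acid string at the root.
#' @param rate expected substitutions per site per time unit.
#' @param conserved_sites integer positions (1-based) under conservation.
#' @param conserved_rate_factor multiplier in `[0, 1]` for conserved sites.
#' @param seed integer seed.
#' @return Named character vector of tip sequences.
#' @export
evolve_sequences <- function(gene_tree, root_sequence, rate,
                             conserved_sites = integer(0),
                             conserved_rate_factor = 0, seed = 1) {
  if (!nzchar(root_sequence)) stop_invalid("root_sequence must be non-empty")
  if (conserved_rate_factor < 0 || conserved_rate_factor > 1)
    stop_invalid("conserved_rate_factor must be in [0, 1]")
  L <- nchar(root_sequence)
  if (length(conserved_sites) &&
      (min(conserved_sites) < 1 || max(conserved_sites) > L))
    stop_invalid("conserved_sites out of bounds for root_sequence")
  rootv <- chars(root_sequence)
  if (!all(rootv %in% AA20))
    stop_invalid("root_sequence contains non-amino-acid characters")

  site_rate <- rep(rate, L)
  site_rate[conserved_sites] <- rate * conserved_rate_factor
  event_rate <- (20 / 19) * site_rate

  ntip <- ape::Ntip(gene_tree)
  nnode <- ntip + gene_tree$Nnode
  seqs <- vector("list", nnode)
  seqs[[ntip + 1L]] <- rootv
  po <- ape::reorder.phylo(gene_tree, "cladewise")
  with_seed(op_seed("evolve_sequences", seed), {
    for (i in seq_len(nrow(po$edge))) {
      a <- po$edge[i, 1]; b <- po$edge[i, 2]
      len <- po$edge.length[i]
      s <- seqs[[a]]
      hit <- runif(L) < 1 - exp(-event_rate * len)
      if (any(hit)) s[hit] <- sample(AA20, sum(hit), replace = TRUE)
      seqs[[b]] <- s
    }
  })
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
  setNames(out, gene_tree$tip.label)
}

#' Default root sequence for simulated families
#'
#' A 205-residue precursor: a 20-residue hydrophobic signal peptide
#' followed by a 185-residue mature region with the catalytic glutamate at
#' mature position 73 and aspartates at mature positions 86 and 97
#' (mirroring the mature goose lysozyme g coordinate system).
#'
#' @param signal_len signal peptide length (default 20).
#' @param mature_len mature region length (default 185).
#' @return Character string; attributes `signal_len` and `catalytic`
#'   (absolute positions of the three catalytic sites).
#' @export
default_root_sequence <- function(signal_len = 20, mature_len = 185) {
  signal <- paste(c("M", rep(c("K", "L", "L", "F", "L", "A", "V", "L",
                               "L", "A"), length.out = signal_len - 1)),
                  collapse = "")
  mature <- with_seed(104729L,
                      paste(sample(AA20, mature_len, replace = TRUE),
                            collapse = ""))
  mv <- chars(mature)
  mv[73] <- "E"; mv[86] <- "D"; mv[97] <- "D"
  out <- paste0(signal, paste(mv, collapse = ""))
  attr(out, "signal_len") <- signal_len
  attr(out, "catalytic") <- signal_len + c(73, 86, 97)
  out
}

#' Inject post-duplication functional decay
#'
#' For each surviving duplication in a simulated family, one randomly
#' chosen daughter clade is degraded - catalytic knockouts (glutamine at
#' the site-73 analog, asparagine at the 86/97 analogs) with probability
#' `post_dup_catalytic_loss_prob`, and/or deletion of the signal-peptide
#' prefix with probability `post_dup_signal_loss_prob` - while the sibling
#' clade is left intact.  Catalytic decay emulates the essentiality of
#' the muramidase: a daughter clade is only degraded when every species
#' in it retains an intact copy outside the clade; when the drawn
#' daughter fails that constraint the sibling is tried, and if neither
#' qualifies the knockout is skipped.  The construction therefore
#' guarantees the compensation pattern in which every species carrying a
#' degraded copy also carries an intact one.  Signal-peptide loss is not
#' constrained (whole lineages can lose secretion).  True states are
#' recorded in the truth table.
#'
#' @param family a simulated family, as returned by [simulate_family()].
#' @param post_dup_catalytic_loss_prob probability in `[0, 1]`.
#' @param post_dup_signal_loss_prob probability in `[0, 1]`.
#' @param seed integer seed.
#' @return The family with `sequences` and `truth` updated.
#' @export
inject_functional_decay <- function(family, post_dup_catalytic_loss_prob,
                                    post_dup_signal_loss_prob, seed = 1) {
  p_cat <- post_dup_catalytic_loss_prob
  p_sig <- post_dup_signal_loss_prob
  if (p_cat < 0 || p_cat > 1 || p_sig < 0 || p_sig > 1)
    stop_invalid("probabilities must be in [0, 1]")
  cat_pos <- family$config$catalytic
  sig_len <- family$config$signal_len
  if (is.null(cat_pos) || length(cat_pos) != 3)
    stop_invalid("family lacks designated catalytic sites")
  gt <- family$gene_tree
  if (is.null(gt)) return(family)

  ntip <- ape::Ntip(gt)
  dup_nodes <- which(grepl("^D[0-9]+$", gt$node.label)) + ntip
  dup_nodes <- dup_nodes[order(as.integer(sub("^D", "",
                         gt$node.label[dup_nodes - ntip])))]
  kids <- node_children(gt)
  tipsets <- descendant_tips(gt)

  truth <- family$truth
  seqs <- family$sequences
  draws <- with_seed(op_seed("inject_functional_decay", seed), {
    lapply(dup_nodes, function(v) list(side = sample.int(2, 1),
                                       hit_cat = runif(1) < p_cat,
                                       hit_sig = runif(1) < p_sig))
  })
  species_of <- setNames(family$leaf_map[truth$gene], truth$gene)
  # TRUE iff every species in the clade keeps an intact copy elsewhere
  compensated <- function(clade) {
    outside_ok <- truth$gene[truth$catalytic_intact &
                               !(truth$gene %in% clade)]
    all(unique(species_of[clade]) %in% species_of[outside_ok])
  }
  # the decayed daughter: the drawn side when admissible, else the
  # sibling, else no catalytic decay for this event.  Knockouts are
  # applied immediately (and before any signal-prefix deletion, so the
  # absolute coordinates stay valid) so that later admissibility checks
  # see the updated state.
  sides <- integer(length(dup_nodes))
  for (i in seq_along(dup_nodes)) {
    d <- draws[[i]]
    side_cat <- NA_integer_
    if (d$hit_cat) {
      for (s in c(d$side, 3L - d$side)) {
        if (compensated(tipsets[[kids[[dup_nodes[i]]][s]]])) {
          side_cat <- s
          break
        }
      }
      if (!is.na(side_cat)) {
        for (g in tipsets[[kids[[dup_nodes[i]]][side_cat]]]) {
          if (truth$catalytic_intact[truth$gene == g]) {
            s2 <- chars(seqs[[g]])
            s2[cat_pos[1]] <- "Q"
            s2[cat_pos[2]] <- "N"
            s2[cat_pos[3]] <- "N"
            seqs[[g]] <- paste(s2, collapse = "")
            truth$catalytic_intact[truth$gene == g] <- FALSE
          }
        }
      }
    }
    sides[i] <- if (is.na(side_cat)) d$side else side_cat
  }
  for (i in seq_along(dup_nodes)) {
    if (!draws[[i]]$hit_sig) next
    clade <- tipsets[[kids[[dup_nodes[i]]][sides[i]]]]
    for (g in clade) {
      if (truth$signal_peptide[truth$gene == g]) {
        seqs[[g]] <- substr(seqs[[g]], sig_len + 1, nchar(seqs[[g]]))
        truth$signal_peptide[truth$gene == g] <- FALSE
      }
    }
  }
  family$sequences <- seqs
  family$truth <- truth
  family
}

# clustered gene coordinates: copies within a species on one scaffold,
# same strand, separated by ~30 kb, flanked by conserved marker genes
make_loci <- function(leaf_map, gene_len = 4000, spacing = 30000,
                      flank_up = c("E1F5B", "TXNDC9"),
                      flank_down = c("MRPL30", "MITD1")) {
  rows <- list()
  for (sp in sort(unique(leaf_map))) {
    genes <- sort(names(leaf_map)[leaf_map == sp])
    pos <- 1000000
    for (i in seq_along(flank_up)) {
      j <- length(flank_up) - i + 1L
      start <- pos - j * (gene_len + spacing)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, scaffold = "scaf1", start = start,
        end = start + gene_len - 1, strand = "+",
        symbol = flank_up[i], stringsAsFactors = FALSE)
    }
    for (g in genes) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, scaffold = "scaf1", start = pos,
        end = pos + gene_len - 1, strand = "+", symbol = g,
        stringsAsFactors = FALSE)
      pos <- pos + gene_len + spacing
    }
    for (i in seq_along(flank_down)) {
      start <- pos + (i - 1L) * (gene_len + spacing)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, scaffold = "scaf1", start = start,
        end = start + gene_len - 1, strand = "+",
        symbol = flank_down[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a complete ground-truthed gene family
#'
#' Composes the simulator: gene duplication/loss along the species tree,
#' sequence evolution with conserved catalytic sites, post-duplication
#' functional decay, and clustered gene coordinates.
#'
#' @param species_tree rooted binary species tree; default
#'   [vertebrate_tree()].
#' @param dup_rate,loss_rate birth-death rates per lineage per time unit.
#' @param rate substitutions per site per time unit.
#' @param root_sequence precursor sequence; default
#'   [default_root_sequence()].  Must carry `signal_len` and `catalytic`
#'   attributes.
#' @param conserved_rate_factor rate multiplier at catalytic sites
#'   (default 0: catalytic residues only change through injected decay,
#'   so truth tables are exact).
#' @param p_catalytic_loss,p_signal_loss post-duplication decay
#'   probabilities.
#' @param seed integer seed; sub-operations split their own streams.
#' @return A list of class `simulated_family`: `species_tree`,
#'   `gene_tree`, `events`, `leaf_map`, `copy_number`, `sequences`,
#'   `truth`, `loci`, `config`.
#' @export
simulate_family <- function(species_tree = vertebrate_tree(),
                            dup_rate = 0.2, loss_rate = 0.05, rate = 0.15,
                            root_sequence = default_root_sequence(),
                            conserved_rate_factor = 0,
                            p_catalytic_loss = 0.5, p_signal_loss = 0.5,
                            seed = 1) {
  sim <- simulate_gene_family(species_tree, dup_rate, loss_rate, seed)
  cat_pos <- attr(root_sequence, "catalytic")
  sig_len <- attr(root_sequence, "signal_len")
  fam <- list(species_tree = species_tree, gene_tree = sim$gene_tree,
              events = sim$events, leaf_map = sim$leaf_map,
              copy_number = sim$copy_number,
              config = list(catalytic = cat_pos, signal_len = sig_len,
                            dup_rate = dup_rate, loss_rate = loss_rate,
                            rate = rate, seed = seed))
  class(fam) <- "simulated_family"
  if (is.null(sim$gene_tree)) {
    fam$sequences <- character(0)
    fam$truth <- data.frame(gene = character(0), species = character(0),
                            catalytic_intact = logical(0),
                            signal_peptide = logical(0))
    fam$loci <- make_loci(sim$leaf_map)
    return(fam)
  }
  fam$sequences <- evolve_sequences(sim$gene_tree,
                                    as.character(root_sequence), rate,
                                    conserved_sites = cat_pos,
                                    conserved_rate_factor =
                                      conserved_rate_factor,
                                    seed = seed)
  fam$truth <- data.frame(gene = names(fam$sequences),
                          species = unname(sim$leaf_map[names(fam$sequences)]),
                          catalytic_intact = TRUE, signal_peptide = TRUE,
                          stringsAsFactors = FALSE)
  fam <- inject_functional_decay(fam, p_catalytic_loss, p_signal_loss, seed)
  fam$loci <- make_loci(sim$leaf_map)
  fam
}

#' Write a simulated family to a fixture directory
#'
#' Emits FASTA (sequences), Newick (true gene tree and species tree) and
#' TSV files (leaf map, event history, functional truth, gene loci) that
#' round-trip losslessly through [read_fixture()].
#'
#' @param family a `simulated_family`.
#' @param out_dir directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(family, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(family$sequences, file.path(out_dir, "sequences.fasta"))
  if (!is.null(family$gene_tree))
    ape::write.tree(family$gene_tree, file.path(out_dir, "gene_tree.nwk"))
  ape::write.tree(family$species_tree,
                  file.path(out_dir, "species_tree.nwk"))
  write_tsv(data.frame(gene = names(family$leaf_map),
                       species = unname(family$leaf_map)),
            file.path(out_dir, "leaf_map.tsv"))
  write_tsv(family$events, file.path(out_dir, "events.tsv"))
  write_tsv(family$truth, file.path(out_dir, "truth.tsv"))
  # secretion annotations in the import format used for external
  # signal-peptide predictions, derived from the simulated truth
  write_tsv(data.frame(id = family$truth$gene,
                       signal_peptide = ifelse(family$truth$signal_peptide,
                                               "yes", "no"),
                       nonclassical_score = 0.1),
            file.path(out_dir, "annotations.tsv"))
  write_tsv(family$loci, file.path(out_dir, "loci.tsv"))
  yaml::write_yaml(family$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Read a fixture directory back into a simulated family
#' @param dir directory written by [write_fixture()].
#' @return A `simulated_family` list.
#' @export
read_fixture <- function(dir) {
  lm <- read_tsv(file.path(dir, "leaf_map.tsv"))
  gt_path <- file.path(dir, "gene_tree.nwk")
  ev <- read_tsv(file.path(dir, "events.tsv"))
  ev$survived <- as.logical(ev$survived)
  fam <- list(
    species_tree = ape::read.tree(file.path(dir, "species_tree.nwk")),
    gene_tree = if (file.exists(gt_path)) ape::read.tree(gt_path) else NULL,
    events = ev,
    leaf_map = setNames(lm$species, lm$gene),
    sequences = read_fasta(file.path(dir, "sequences.fasta")),
    truth = read_tsv(file.path(dir, "truth.tsv")),
    loci = read_tsv(file.path(dir, "loci.tsv")),
    config = yaml::read_yaml(file.path(dir, "config.yaml")))
  fam$truth$catalytic_intact <- as.logical(fam$truth$catalytic_intact)
  fam$truth$signal_peptide <- as.logical(fam$truth$signal_peptide)
  fam$copy_number <- vapply(
    fam$species_tree$tip.label,
    function(sp) sum(fam$leaf_map == sp), integer(1))
  class(fam) <- "simulated_family"
  fam
}
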