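# Synthetic gene families with known duplication history, selection
# pressure, intron evolution and expression structure.
#
# The generator emulates the study conditions of a plant gene-family
# survey: family members arise from tandem and WGD/segmental duplications
# placed on multiple chromosomes, coding sequences diverge under a
# specified dN/dS (omega) with a transition/transversion bias (kappa),
# exon-intron structures evolve by intron gain and loss on the true tree,
# and FPKM-like expression tables carry planted treated/control
# contrasts. Every random draw is tied to a master seed through derived
# per-submodule streams, so identical configurations give byte-identical
# outputs.

# A fixed GDSL-like domain consensus (120 aa). Hard-coded so the family
# signal is identical across sessions; the catalytic-block flavour
# (GDSL ... SGNH residues) is decorative, not biological.
GDSL_CONSENSUS <- paste0(
  "GDSLVDTGNNNYLQTLAKANYWPYGIDFPGGKATGRFSNGRLIPDFIAEYAGLPLVPAYLE",
  "PGNHQFAYGANFASAGSTILPETAASWVIDLKTQLDYFKEVEKQLRQKLGDAEAKSLVS")

#' Simulation configuration
#'
#' Collects every knob of the synthetic family generator. The default
#' protein and gene length ranges (266-460 aa; 974-14351 bp) match the
#' observed ranges of the soybean GELP survey that motivates the
#' pipeline.
#'
#' @param seed Master integer seed.
#' @param n_chromosomes Number of chromosomes (>= 2 when
#'   `segmental_events > 0`).
#' @param n_background_genes Non-family genes providing the negative set.
#' @param n_family_ancestors Independent family lineages before
#'   duplication events.
#' @param tandem_events List/vector of tandem set sizes (each >= 2).
#' @param segmental_events Number of segmental duplication events (each
#'   produces a cross-chromosome pair).
#' @param omega Target dN/dS of family coding-sequence evolution outside
#'   the embedded domain.
#' @param omega_domain dN/dS applied to the embedded domain region
#'   (default 0.05): conserved functional cores sit under much stronger
#'   purifying selection than the surrounding sequence, which is what
#'   keeps a family identifiable by profile search.
#' @param kappa Transition/transversion rate ratio.
#' @param branch_length Expected substitutions per codon on each tree
#'   edge.
#' @param intron_gain_rate Expected intron gains per lineage per unit
#'   branch length.
#' @param intron_loss_rate Loss rate per present intron position per unit
#'   branch length.
#' @param n_ancestral_introns Intron positions in the family ancestor
#'   (default 4, the canonical five-exon/four-intron plant structure).
#' @param protein_length_range,gene_length_range Sampling ranges.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 5L,
                       n_background_genes = 40L, n_family_ancestors = 8L,
                       tandem_events = list(2L, 2L), segmental_events = 4L,
                       omega = 0.3, omega_domain = 0.05, kappa = 2,
                       branch_length = 0.1,
                       intron_gain_rate = 0.1, intron_loss_rate = 0.1,
                       n_ancestral_introns = 4L,
                       protein_length_range = c(266L, 460L),
                       gene_length_range = c(974L, 14351L)) {
  tandem_events <- as.list(as.integer(unlist(tandem_events)))
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              n_background_genes = as.integer(n_background_genes),
              n_family_ancestors = as.integer(n_family_ancestors),
              tandem_events = tandem_events,
              segmental_events = as.integer(segmental_events),
              omega = omega, omega_domain = omega_domain, kappa = kappa,
              branch_length = branch_length,
              intron_gain_rate = intron_gain_rate,
              intron_loss_rate = intron_loss_rate,
              n_ancestral_introns = as.integer(n_ancestral_introns),
              protein_length_range = as.integer(protein_length_range),
              gene_length_range = as.integer(gene_length_range))
  stopifnot(cfg$n_chromosomes >= 1L, cfg$n_family_ancestors >= 1L,
            cfg$n_background_genes >= 0L, cfg$segmental_events >= 0L,
            cfg$omega >= 0, cfg$omega_domain >= 0, cfg$kappa > 0,
            cfg$branch_length >= 0, cfg$intron_gain_rate >= 0,
            cfg$intron_loss_rate >= 0)
  if (length(cfg$tandem_events) && any(unlist(cfg$tandem_events) < 2L))
    stop("tandem event set sizes must be >= 2")
  n_events <- length(cfg$tandem_events) + cfg$segmental_events
  if (cfg$n_family_ancestors < n_events)
    stop("need at least ", n_events, " family ancestors for ", n_events,
         " duplication events")
  if (cfg$segmental_events > 0L && cfg$n_chromosomes < 2L)
    stop("segmental events need at least 2 chromosomes")
  structure(cfg, class = "sim_config")
}

# ---- codon evolution ---------------------------------------------------

.evolve_env <- new.env(parent = emptyenv())

# per sense codon: 9 neighbour codons + logicals (transition, synonymous,
# to_stop), cached once
codon_neighbor_tables <- function() {
  if (!is.null(.evolve_env$nb)) return(.evolve_env$nb)
  sense <- sense_codons()
  nb_codon <- matrix("", length(sense), 9L)
  nb_ts <- nb_syn <- nb_stop <- matrix(FALSE, length(sense), 9L)
  for (i in seq_along(sense)) {
    nb <- codon_neighbors(sense[i])
    nb_codon[i, ] <- nb$codon
    nb_ts[i, ] <- nb$transition
    nb_syn[i, ] <- nb$synonymous
    nb_stop[i, ] <- nb$to_stop
  }
  .evolve_env$nb <- list(sense = sense, codon = nb_codon, ts = nb_ts,
                         syn = nb_syn, stop = nb_stop)
  .evolve_env$nb
}

#' Evolve a coding sequence under a simple codon substitution process
#'
#' Single-nucleotide substitution events occur at exponential waiting
#' times; relative rates weight transitions by `kappa` and nonsynonymous
#' changes by `omega`, and proposals creating stop codons are rejected
#' (rate zero). Time is scaled so that `t` is the expected number of
#' substitutions per codon at the starting composition.
#'
#' @param cds Coding sequence, length divisible by 3, no stop codons.
#' @param t Branch length (expected substitutions per codon).
#' @param omega Nonsynonymous relative rate (dN/dS target).
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @return The evolved coding sequence (same length).
#' @export
evolve_codons <- function(cds, t, omega, kappa, seed = 1L) {
  cod <- split_codons(cds)
  if (any(codon_aa(cod) == "*"))
    stop("CDS contains a stop codon; cannot evolve")
  if (t < 0) stop("`t` must be >= 0")
  if (t == 0) return(paste(cod, collapse = ""))
  tab <- codon_neighbor_tables()
  idx <- match(cod, tab$sense)
  wt <- function(i) {
    w <- ifelse(tab$ts[i, ], kappa, 1) * ifelse(tab$syn[i, ], 1, omega)
    w[tab$stop[i, ]] <- 0
    w
  }
  L <- length(cod)
  W <- t(vapply(idx, wt, numeric(9L)))
  row_tot <- rowSums(W)
  scale <- L / sum(row_tot)  # rate L at the starting composition
  set.seed(seed)
  elapsed <- 0
  repeat {
    total <- sum(row_tot)
    if (total <= 0) break
    elapsed <- elapsed + stats::rexp(1L, rate = total * scale)
    if (elapsed > t) break
    i <- sample.int(L, 1L, prob = row_tot)
    j <- sample.int(9L, 1L, prob = W[i, ])
    new_codon <- tab$codon[idx[i], j]
    idx[i] <- match(new_codon, tab$sense)
    W[i, ] <- wt(idx[i])
    row_tot[i] <- sum(W[i, ])
  }
  paste(tab$sense[idx], collapse = "")
}

#' Random stop-free coding sequence
#'
#' @param n_codons Number of codons; the first is ATG.
#' @param seed Integer seed.
#' @return CDS string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, seed = 1L) {
  set.seed(seed)
  sense <- sense_codons()
  cods <- sample(sense, n_codons, replace = TRUE)
  cods[1L] <- "ATG"
  paste(cods, collapse = "")
}

# encode a protein as a CDS by sampling synonymous codons
encode_protein <- function(aa, seed = 1L) {
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  cods <- vapply(strsplit(aa, "")[[1]], function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(cods, collapse = "")
}

#' Synthetic GDSL-like seed domain alignment
#'
#' Generates diverged copies of a fixed 120-aa domain consensus: each
#' position mutates to a random amino acid with probability `divergence`.
#' All copies have the full domain length, so the result is a gap-free
#' alignment usable as a profile seed.
#'
#' @param n_seq Number of seed sequences (default 20).
#' @param divergence Per-site substitution probability (default 0.1).
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences.
#' @export
synthetic_domain_seed <- function(n_seq = 20L, divergence = 0.1, seed = 1L) {
  set.seed(seed)
  cons <- strsplit(GDSL_CONSENSUS, "")[[1]]
  out <- character(n_seq)
  for (i in seq_len(n_seq)) {
    s <- cons
    mut <- stats::runif(length(s)) < divergence
    s[mut] <- sample(AA20, sum(mut), replace = TRUE)
    out[i] <- paste(s, collapse = "")
  }
  stats::setNames(out, paste0("seed_", seq_len(n_seq)))
}

# ---- tree construction -------------------------------------------------

# balanced newick over labelled subtrees, so root-to-leaf depth grows
# logarithmically with family size; within-group edges get `bl`,
# backbone edges `deep`
family_tree_newick <- function(groups, bl, deep) {
  balance <- function(frags, len) {
    n <- length(frags)
    if (n == 1L) return(frags)
    k <- n %/% 2L
    sprintf("(%s:%g,%s:%g)", balance(frags[seq_len(k)], len), len,
            balance(frags[-seq_len(k)], len), len)
  }
  subs <- vapply(groups, function(mem) balance(mem, bl), character(1))
  paste0(balance(subs, deep), ";")
}

#' True family tree over duplication groups
#'
#' Builds a rooted tree in which every duplication group (tandem set,
#' segmental pair, or singleton ancestor) forms a clade; within-group
#' edges have length `branch_length`, the backbone separating ancestors
#' uses `deep_factor * branch_length`.
#'
#' @param groups List of character vectors of gene ids.
#' @param branch_length Within-group edge length.
#' @param deep_factor Backbone multiplier (default 3).
#' @return A `phylo` tree.
#' @export
family_tree <- function(groups, branch_length, deep_factor = 3) {
  txt <- family_tree_newick(groups, branch_length,
                            deep_factor * branch_length)
  ape::read.tree(text = txt)
}

# ---- intron evolution --------------------------------------------------

#' Evolve an intron-position set along a tree
#'
#' Starting from the ancestral position set at the root, each branch
#' loses every present position independently with probability
#' `1 - exp(-loss_rate * len)` and acquires `Poisson(gain_rate * len)`
#' new positions, each with a previously unused codon index and a random
#' phase. Every event is logged with the branch (child node) on which it
#' occurred.
#'
#' @param positions Data frame of ancestral positions with columns
#'   `label`, `codon_index`, `phase` (may have zero rows).
#' @param tree A rooted `phylo` tree with edge lengths.
#' @param gain_rate,loss_rate Non-negative rates per unit branch length
#'   (gains per lineage; losses per present position).
#' @param n_codons Number of codons available for new positions.
#' @param seed Integer seed.
#' @return List with `leaf_sets` (named list of label vectors),
#'   `positions` (all positions ever present) and `events` (data frame
#'   `branch`, `type`, `label`).
#' @export
mutate_intron_set <- function(positions, tree, gain_rate, loss_rate,
                              n_codons, seed = 1L) {
  stopifnot(gain_rate >= 0, loss_rate >= 0)
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  all_pos <- positions
  gain_counter <- 0L
  events <- list()
  node_sets <- list()
  node_sets[[as.character(root)]] <- positions$label
  # preorder over edges
  ord <- order(tree$edge[, 1L])
  for (e in ord) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    cur <- node_sets[[as.character(parent)]]
    if (length(cur) && loss_rate > 0 && len > 0) {
      lostp <- stats::runif(length(cur)) < (1 - exp(-loss_rate * len))
      for (lab in cur[lostp])
        events[[length(events) + 1L]] <- data.frame(
          branch = node_name(tree, child), type = "loss", label = lab,
          stringsAsFactors = FALSE)
      cur <- cur[!lostp]
    }
    n_gain <- if (gain_rate > 0 && len > 0)
      stats::rpois(1L, gain_rate * len) else 0L
    for (k in seq_len(n_gain)) {
      gain_counter <- gain_counter + 1L
      used <- all_pos$codon_index
      free <- setdiff(seq_len(n_codons - 1L), used)
      if (!length(free)) break
      ci <- free[sample.int(length(free), 1L)]
      lab <- paste0("g", gain_counter)
      all_pos <- rbind(all_pos, data.frame(label = lab, codon_index = ci,
                                           phase = sample(0:2, 1L),
                                           stringsAsFactors = FALSE))
      cur <- c(cur, lab)
      events[[length(events) + 1L]] <- data.frame(
        branch = node_name(tree, child), type = "gain", label = lab,
        stringsAsFactors = FALSE)
    }
    node_sets[[as.character(child)]] <- cur
  }
  leaf_sets <- stats::setNames(
    lapply(seq_len(n_tip), function(i) node_sets[[as.character(i)]]),
    tree$tip.label)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(), type = character(), label = character(),
               stringsAsFactors = FALSE)
  list(leaf_sets = leaf_sets, positions = all_pos, events = events)
}

# ---- expression simulation ---------------------------------------------

#' Simulate an FPKM expression matrix with planted responses
#'
#' Baseline per-gene expression is log-normal; for each treatment a
#' chosen number of genes receive a true fold-change (up or down) in the
#' treated replicates. Replicate noise is log-normal. P-values come from
#' Welch t-tests on log2(FPKM + 1) replicate values, mirroring the
#' downstream filtering convention.
#'
#' @param gene_ids Character vector of genes.
#' @param treatments Treatment names (default drought/NaCl/ABA).
#' @param n_up,n_down Planted up-/down-regulated genes per treatment.
#' @param fold_change True fold change magnitude (default 4).
#' @param n_reps Replicates per condition (default 3).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters.
#' @param noise_sdlog Replicate noise (sdlog, default 0.25).
#' @param seed Integer seed.
#' @return List with `fpkm` (genes x samples matrix), `samples`
#'   (metadata data frame), `truth` (data frame `gene`, `treatment`,
#'   `direction`).
#' @export
simulate_expression <- function(gene_ids,
                                treatments = c("drought", "NaCl", "ABA"),
                                n_up = 3L, n_down = 8L, fold_change = 4,
                                n_reps = 3L, baseline_meanlog = 3,
                                baseline_sdlog = 1, noise_sdlog = 0.25,
                                seed = 1L) {
  set.seed(seed)
  n <- length(gene_ids)
  if (n_up + n_down > n) stop("more planted responders than genes")
  base <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
  conds <- c("control", treatments)
  samples <- data.frame(
    sample = paste(rep(conds, each = n_reps), seq_len(n_reps), sep = "_"),
    condition = rep(conds, each = n_reps),
    replicate = rep(seq_len(n_reps), length(conds)),
    stringsAsFactors = FALSE)
  fpkm <- matrix(0, n, nrow(samples),
                 dimnames = list(gene_ids, samples$sample))
  truth <- list()
  effect <- matrix(1, n, length(conds), dimnames = list(gene_ids, conds))
  for (tr in treatments) {
    picked <- sample(gene_ids, n_up + n_down)
    ups <- picked[seq_len(n_up)]
    downs <- setdiff(picked, ups)
    effect[ups, tr] <- fold_change
    effect[downs, tr] <- 1 / fold_change
    truth[[tr]] <- data.frame(
      gene = picked, treatment = tr,
      direction = c(rep("up", n_up), rep("down", n_down)),
      stringsAsFactors = FALSE)
  }
  for (s in seq_len(nrow(samples))) {
    mu <- base * effect[, samples$condition[s]]
    fpkm[, s] <- mu * stats::rlnorm(n, 0, noise_sdlog)
  }
  list(fpkm = fpkm, samples = samples,
       truth = do.call(rbind, truth))
}

# ---- full family simulation --------------------------------------------

#' Simulate a complete synthetic gene family
#'
#' Generates family members by evolving a single ancestral coding
#' sequence (carrying an embedded GDSL-like domain) along a true tree in
#' which tandem sets, segmental pairs and singleton ancestors form
#' clades; places the genes on chromosomes (tandem members consecutive,
#' segmental partners on different chromosomes); evolves the ancestral
#' intron set by gain/loss along the tree; adds domain-free background
#' genes; and simulates an expression matrix with planted stress
#' responses. The full truth record (tree, pair modes, intron events,
#' expression truth) is retained.
#'
#' @param config A [sim_config()].
#' @return Object of class `family_simulation`: list with `gene_models`,
#'   `proteome`, `cds`, `true_tree`, `true_pairs`, `intron_truth`,
#'   `expression`, `gene_order`, `chromosome_lengths`, `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  master <- config$seed
  # --- duplication groups ------------------------------------------------
  n_tand <- length(config$tandem_events)
  sizes <- c(unlist(config$tandem_events),
             rep(2L, config$segmental_events),
             rep(1L, config$n_family_ancestors - n_tand -
                   config$segmental_events))
  types <- c(rep("tandem", n_tand),
             rep("segmental", config$segmental_events),
             rep("singleton", config$n_family_ancestors - n_tand -
                   config$segmental_events))
  n_members <- sum(sizes)
  ids <- sprintf("fam%03d", seq_len(n_members))
  groups <- split(ids, rep(seq_along(sizes), sizes))
  # --- true pairs --------------------------------------------------------
  pair_rows <- list()
  for (g in seq_along(groups)) {
    mem <- groups[[g]]
    if (types[g] == "tandem") {
      cmb <- utils::combn(mem, 2L)
      for (k in seq_len(ncol(cmb)))
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          gene_a = cmb[1L, k], gene_b = cmb[2L, k], mode = "tandem",
          stringsAsFactors = FALSE)
    } else if (types[g] == "segmental") {
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        gene_a = mem[1L], gene_b = mem[2L], mode = "segmental",
        stringsAsFactors = FALSE)
    }
  }
  true_pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(gene_a = character(), gene_b = character(),
               mode = character(), stringsAsFactors = FALSE)
  # --- ancestral CDS with embedded domain --------------------------------
  set.seed(derive_seed(master, "ancestor"))
  prot_len <- sample(seq(config$protein_length_range[1L],
                         config$protein_length_range[2L]), 1L)
  dom_len <- nchar(GDSL_CONSENSUS)
  dom_start <- max(2L, (prot_len - dom_len) %/% 4L)
  flank5 <- substr(random_cds(dom_start - 1L,
                              derive_seed(master, "flank5")), 1L,
                   3L * (dom_start - 1L))
  dom_cds <- encode_protein(GDSL_CONSENSUS, derive_seed(master, "domain"))
  n_flank3 <- prot_len - (dom_start - 1L) - dom_len
  flank3 <- random_cds(max(n_flank3, 1L) + 1L, derive_seed(master, "flank3"))
  flank3 <- substr(flank3, 4L, nchar(flank3))  # drop the leading ATG
  anc_cds <- paste0(flank5, dom_cds, flank3)
  n_codons <- nchar(anc_cds) %/% 3L
  # --- tree + sequence evolution ----------------------------------------
  # the embedded domain evolves under omega_domain (strong purifying
  # selection); the flanks under omega
  tree <- family_tree(groups, config$branch_length)
  seg_bounds <- c(3L * (dom_start - 1L), 3L * (dom_start - 1L + dom_len))
  evolve_gene <- function(cds, t, tag) {
    seg1 <- substr(cds, 1L, seg_bounds[1L])
    seg2 <- substr(cds, seg_bounds[1L] + 1L, seg_bounds[2L])
    seg3 <- substr(cds, seg_bounds[2L] + 1L, nchar(cds))
    paste0(
      evolve_codons(seg1, t, config$omega, config$kappa,
                    seed = derive_seed(master, paste0(tag, "f5"))),
      evolve_codons(seg2, t, config$omega_domain, config$kappa,
                    seed = derive_seed(master, paste0(tag, "dom"))),
      evolve_codons(seg3, t, config$omega, config$kappa,
                    seed = derive_seed(master, paste0(tag, "f3"))))
  }
  node_seq <- list()
  node_seq[[as.character(length(tree$tip.label) + 1L)]] <- anc_cds
  for (e in order(tree$edge[, 1L])) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    node_seq[[as.character(child)]] <- evolve_gene(
      node_seq[[as.character(parent)]], tree$edge.length[e],
      paste0("edge", e))
  }
  cds <- stats::setNames(
    vapply(seq_along(tree$tip.label),
           function(i) node_seq[[as.character(i)]], character(1)),
    tree$tip.label)[ids]
  # --- intron evolution --------------------------------------------------
  set.seed(derive_seed(master, "anc_introns"))
  anc_pos <- sort(sample(seq(5L, n_codons - 5L), config$n_ancestral_introns))
  positions <- data.frame(label = paste0("P", seq_along(anc_pos)),
                          codon_index = anc_pos,
                          phase = sample(0:2, length(anc_pos), replace = TRUE),
                          stringsAsFactors = FALSE)
  introns <- mutate_intron_set(positions, tree, config$intron_gain_rate,
                               config$intron_loss_rate, n_codons,
                               seed = derive_seed(master, "introns"))
  # --- chromosome layout -------------------------------------------------
  set.seed(derive_seed(master, "layout"))
  n_chr <- config$n_chromosomes
  chr_names <- sprintf("chr%02d", seq_len(n_chr))
  slots <- stats::setNames(vector("list", n_chr), chr_names)
  total_genes <- n_members + config$n_background_genes
  capacity <- ceiling(total_genes / n_chr) + max(unlist(config$tandem_events), 0L)
  for (g in seq_along(groups)) {
    mem <- groups[[g]]
    if (types[g] == "tandem") {
      if (length(mem) > capacity)
        stop("tandem set of ", length(mem),
             " genes exceeds chromosome capacity (", capacity, ")")
      chr <- sample(chr_names, 1L)
      slots[[chr]] <- c(slots[[chr]], list(mem))  # kept consecutive
    } else if (types[g] == "segmental") {
      chrs <- sample(chr_names, 2L)
      slots[[chrs[1L]]] <- c(slots[[chrs[1L]]], list(mem[1L]))
      slots[[chrs[2L]]] <- c(slots[[chrs[2L]]], list(mem[2L]))
    } else {
      chr <- sample(chr_names, 1L)
      slots[[chr]] <- c(slots[[chr]], list(mem))
    }
  }
  bg_ids <- if (config$n_background_genes > 0L)
    sprintf("bg%03d", seq_len(config$n_background_genes)) else character()
  for (b in bg_ids) {
    chr <- sample(chr_names, 1L)
    slots[[chr]] <- c(slots[[chr]], list(b))
  }
  # shuffle block order per chromosome, then flatten (tandem blocks stay
  # consecutive)
  gene_order <- lapply(slots, function(blocks) {
    if (!length(blocks)) return(character())
    unlist(blocks[sample.int(length(blocks))])
  })
  # --- gene models -------------------------------------------------------
  set.seed(derive_seed(master, "coords"))
  bg_cds <- stats::setNames(
    lapply(seq_along(bg_ids), function(i)
      random_cds(sample(seq(config$protein_length_range[1L],
                            config$protein_length_range[2L]), 1L),
                 derive_seed(master, paste0("bg", i)))),
    bg_ids)
  models <- list()
  chromosome_lengths <- stats::setNames(integer(n_chr), chr_names)
  for (chr in chr_names) {
    cursor <- 1L
    for (g in gene_order[[chr]]) {
      cursor <- cursor + sample(2000:4000, 1L)  # intergenic gap
      if (g %in% ids) {
        gcds <- cds[[g]]
        labs <- introns$leaf_sets[[g]]
        pos <- introns$positions[introns$positions$label %in% labs, ,
                                 drop = FALSE]
        pos <- pos[order(pos$codon_index, pos$phase), , drop = FALSE]
        offs <- ifelse(pos$phase == 0L, pos$codon_index * 3L,
                       (pos$codon_index - 1L) * 3L + pos$phase)
        offs <- sort(unique(offs))
        exon_len <- diff(c(0L, offs, nchar(gcds)))
        intron_len <- if (length(offs))
          sample(100:400, length(offs), replace = TRUE) else integer()
      } else {
        gcds <- bg_cds[[g]]
        exon_len <- nchar(gcds)
        intron_len <- integer()
      }
      starts <- integer(length(exon_len))
      ends <- integer(length(exon_len))
      pos_cursor <- cursor
      for (k in seq_along(exon_len)) {
        starts[k] <- pos_cursor
        ends[k] <- pos_cursor + exon_len[k] - 1L
        pos_cursor <- ends[k] + 1L
        if (k <= length(intron_len)) pos_cursor <- pos_cursor + intron_len[k]
      }
      models[[g]] <- gene_model(g, chr, "+",
                                cbind(start = starts, end = ends), gcds,
                                subfamily = NULL)
      attr(models[[g]], "intron_lengths") <- intron_len
      cursor <- ends[length(ends)]
    }
    chromosome_lengths[chr] <- cursor + 2000L
  }
  proteome <- stats::setNames(
    vapply(c(cds, lapply(bg_cds, identity)), translate_cds, character(1)),
    c(ids, bg_ids))
  # planted response fractions mirror a mostly-down-regulated stress
  # response: ~5% up, ~15% down per treatment
  expr <- simulate_expression(
    ids, n_up = max(1L, floor(0.05 * n_members)),
    n_down = max(1L, floor(0.15 * n_members)),
    seed = derive_seed(master, "expression"))
  structure(list(gene_models = models, proteome = proteome,
                 cds = c(cds, unlist(bg_cds)),
                 family_ids = ids, background_ids = bg_ids,
                 true_tree = tree, true_pairs = true_pairs,
                 intron_truth = introns, expression = expr,
                 gene_order = gene_order,
                 chromosome_lengths = chromosome_lengths,
                 config = config),
            class = "family_simulation")
}

#' @export
print.family_simulation <- function(x, ...) {
  cat(sprintf(paste0("family_simulation: %d family members (+%d background) ",
                     "on %d chromosomes;\n  %d true pairs, %d intron events\n"),
              length(x$family_ids), length(x$background_ids),
              x$config$n_chromosomes, nrow(x$true_pairs),
              nrow(x$intron_truth$events)))
  invisible(x)
}

# ---- serialization -----------------------------------------------------

#' Write a simulated family to disk
#'
#' Emits genome FASTA (assembled chromosomes with GT..AG introns and
#' random intergenic sequence), protein and CDS FASTA, a GFF3 with
#' gene/mRNA/exon/CDS features (1-based inclusive), truth tables and the
#' expression matrix as TSV. Identical simulations produce byte-identical
#' files.
#'
#' @param sim A `family_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(sim$config$seed, "genome_fill"))
  # assemble chromosome sequences
  chroms <- stats::setNames(vector("character", length(sim$gene_order)),
                            names(sim$gene_order))
  for (chr in names(sim$gene_order)) {
    len <- sim$chromosome_lengths[chr]
    seq <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    for (g in sim$gene_order[[chr]]) {
      m <- sim$gene_models[[g]]
      widths <- m$exons[, "end"] - m$exons[, "start"] + 1L
      offsets <- c(0L, cumsum(widths))
      for (k in seq_len(nrow(m$exons))) {
        piece <- substr(m$cds, offsets[k] + 1L, offsets[k + 1L])
        seq[m$exons[k, "start"]:m$exons[k, "end"]] <- strsplit(piece, "")[[1]]
      }
      if (nrow(m$exons) > 1L) {
        for (k in seq_len(nrow(m$exons) - 1L)) {
          i0 <- m$exons[k, "end"] + 1L; i1 <- m$exons[k + 1L, "start"] - 1L
          seq[i0:(i0 + 1L)] <- c("G", "T")
          seq[(i1 - 1L):i1] <- c("A", "G")
        }
      }
    }
    chroms[chr] <- paste(seq, collapse = "")
  }
  p_genome <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(chroms), p_genome)
  p_prot <- file.path(dir, "proteins.fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$proteome), p_prot)
  p_cds <- file.path(dir, "cds.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$cds), p_cds)
  p_gff <- file.path(dir, "genes.gff3")
  write_gff3(sim$gene_models[unlist(sim$gene_order)], p_gff)
  p_pairs <- file.path(dir, "truth_pairs.tsv")
  utils::write.table(sim$true_pairs, p_pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_events <- file.path(dir, "truth_intron_events.tsv")
  utils::write.table(sim$intron_truth$events, p_events, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p_expr <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(gene = rownames(sim$expression$fpkm),
                                sim$expression$fpkm, check.names = FALSE),
                     p_expr, sep = "\t", quote = FALSE, row.names = FALSE)
  p_samp <- file.path(dir, "samples.tsv")
  utils::write.table(sim$expression$samples, p_samp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p_tree <- file.path(dir, "true_tree.nwk")
  ape::write.tree(sim$true_tree, p_tree)
  invisible(c(p_genome, p_prot, p_cds, p_gff, p_pairs, p_events, p_expr,
              p_samp, p_tree))
}

#' Write gene models as GFF3
#'
#' One `gene`/`mRNA` pair plus `exon` and `CDS` features per model,
#' 1-based inclusive coordinates.
#'
#' @param models List of `gene_model`s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- range(m$exons)
    lines <- c(lines, paste(m$chromosome, "gelpfam", "gene", span[1L],
                            span[2L], ".", m$strand, ".",
                            paste0("ID=", m$gene_id), sep = "\t"))
    lines <- c(lines, paste(m$chromosome, "gelpfam", "mRNA", span[1L],
                            span[2L], ".", m$strand, ".",
                            paste0("ID=", m$gene_id, ".1;Parent=", m$gene_id),
                            sep = "\t"))
    ex <- m$exons[order(m$exons[, "start"]), , drop = FALSE]
    for (k in seq_len(nrow(ex))) {
      for (ft in c("exon", "CDS")) {
        lines <- c(lines, paste(m$chromosome, "gelpfam", ft, ex[k, "start"],
                                ex[k, "end"], ".", m$strand,
                                if (ft == "CDS") "0" else ".",
                                paste0("ID=", m$gene_id, ".1.", ft, k,
                                       ";Parent=", m$gene_id, ".1"),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
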