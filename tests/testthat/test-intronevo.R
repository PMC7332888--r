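# Intron-site extraction, alignment projection, basic forms, gain/loss
# classification (majority and Dollo modes) and the ancestral model.

plus_gene <- function(id = "g1", exon_len = c(100L, 80L, 60L),
                      intron_len = c(50L, 70L), start = 1000L,
                      cds = NULL, subfamily = NULL) {
  starts <- integer(length(exon_len)); ends <- integer(length(exon_len))
  cur <- start
  for (k in seq_along(exon_len)) {
    starts[k] <- cur; ends[k] <- cur + exon_len[k] - 1L
    cur <- ends[k] + 1L + if (k <= length(intron_len)) intron_len[k] else 0L
  }
  if (is.null(cds)) cds <- random_cds(sum(exon_len) %/% 3L, seed = 42)
  gene_model(id, "chr1", "+", cbind(start = starts, end = ends), cds,
             subfamily = subfamily)
}

test_that("intron sites derive from CDS offsets with phase bookkeeping", {
  # single exon: no introns
  g0 <- plus_gene(exon_len = 300L, intron_len = integer())
  expect_equal(nrow(extract_intron_sites(g0)), 0L)
  # intron after 100 CDS nt: codon 34, phase 1; after 180 nt: codon 60, phase 0
  g <- plus_gene(exon_len = c(100L, 80L, 60L))
  sites <- extract_intron_sites(g)
  expect_equal(sites$codon_index, c(34L, 60L))
  expect_equal(sites$phase, c(1L, 0L))
})

test_that("minus-strand mirror genes give identical sites", {
  g <- plus_gene(exon_len = c(100L, 80L, 60L))
  # mirror: same exon lengths walked in transcript order on minus strand
  L <- 5000L
  ex <- g$exons
  mirror <- cbind(start = L - ex[, "end"] + 1L, end = L - ex[, "start"] + 1L)
  gm <- gene_model("g1m", "chr1", "-", mirror, g$cds)
  expect_equal(extract_intron_sites(gm), extract_intron_sites(g))
})

test_that("gene model invariants are enforced", {
  expect_error(gene_model("x", "chr1", "+",
                          cbind(start = c(1, 50), end = c(60, 100)),
                          paste(rep("A", 111), collapse = "")), "overlap")
  expect_error(plus_gene(cds = "ATG"), "match")
})

test_that("projection merges sites by alignment column and phase", {
  sites <- list(g1 = data.frame(codon_index = c(3L, 7L), phase = c(0L, 1L)),
                g2 = data.frame(codon_index = c(3L, 7L), phase = c(0L, 1L)))
  aln <- c(g1 = "MKLVINSEQW", g2 = "MKLVINSEQW")
  m <- project_sites(sites, aln)
  expect_equal(nrow(m$positions), 2L)
  expect_true(all(m$presence == 1L))
  # a gapped row shifts the column but merging still requires identity
  aln2 <- c(g1 = "MKLVINSEQW", g2 = "MK-LVINSEQ")
  m2 <- project_sites(list(g1 = sites$g1,
                           g2 = data.frame(codon_index = 3L, phase = 0L)),
                      aln2)
  # g2 codon 3 is L at column 4; g1 codon 3 is L at column 3: two positions
  expect_equal(nrow(m2$positions), 3L)
  expect_error(project_sites(list(g1 = data.frame(codon_index = 99L,
                                                  phase = 0L)), aln),
               "beyond")
  # same-phase sites within the tolerance window merge when enabled
  m3 <- project_sites(list(g1 = sites$g1,
                           g2 = data.frame(codon_index = 3L, phase = 0L)),
                      aln2, column_tolerance = 1L)
  expect_equal(nrow(m3$positions), 2L)
})

test_that("extract + project round-trips the simulator's intron truth", {
  sim <- simulate_family(sim_config(seed = 23, n_background_genes = 0,
                                    intron_gain_rate = 0.5,
                                    intron_loss_rate = 0.5))
  d <- file.path(tempdir(), "introns_rt")
  write_simulation(sim, d)
  models <- read_gene_models(file.path(d, "genes.gff3"),
                             file.path(d, "cds.fasta"))
  fam <- models[sim$family_ids]
  sites <- lapply(fam, extract_intron_sites)
  m <- project_sites(sites, sim_family_alignment(sim))
  truth <- sim$intron_truth
  for (g in sim$family_ids) {
    want <- truth$positions[truth$positions$label %in% truth$leaf_sets[[g]], ]
    got_cols <- m$positions$column[m$presence[g, ] == 1L]
    expect_setequal(got_cols, want$codon_index)
    # per-gene row sum equals the gene's intron count from the GFF3
    expect_equal(sum(m$presence[g, ]), nrow(fam[[g]]$exons) - 1L)
  }
})

test_that("intron count table appends totals", {
  df <- data.frame(subfamily = c("A", "A", "B", "B", "B"),
                   introns = c(4L, 5L, 4L, 4L, 2L))
  tab <- intron_count_table(df)
  expect_equal(tab["Total", "Total"], 5L)
  expect_equal(tab["B", "4"], 2L)
  expect_equal(tab["Total", "4"], 3L)
  # zero gain/loss simulation: single nonzero intron-count column
  sim <- simulate_family(sim_config(seed = 3, intron_gain_rate = 0,
                                    intron_loss_rate = 0,
                                    n_background_genes = 0))
  counts <- vapply(sim$family_ids, function(g)
    length(sim$intron_truth$leaf_sets[[g]]), integer(1))
  expect_equal(length(unique(counts)), 1L)
})

test_that("basic forms respect the majority threshold monotonically", {
  ws <- gelp_worked_intron_set()
  members <- names(ws$subfamilies)[ws$subfamilies == "I"]
  f50 <- basic_form(ws$matrix, members, 0.5)
  f70 <- basic_form(ws$matrix, members, 0.7)
  f90 <- basic_form(ws$matrix, members, 0.9)
  expect_true(all(f70 %in% f50))
  expect_true(all(f90 %in% f70))
  # all-identical rows: the basic form is each row's set
  ident <- intron_matrix(matrix(1L, 3, 2, dimnames = list(c("a", "b", "c"),
                                                          NULL)),
                         columns = c(5L, 9L), phases = c(0L, 0L))
  expect_equal(basic_form(ident, c("a", "b", "c")), c(1L, 2L))
  expect_error(basic_form(ws$matrix, "GmGELP94"), "2 members")
})

test_that("Dollo event placement matches the brute-force minimum", {
  set.seed(6)
  for (rep in 1:10) {
    tr <- ape::rtree(sample(5:9, 1))
    tips <- tr$tip.label
    carriers <- sample(tips, sample(2:length(tips), 1))
    pres <- matrix(as.integer(tips %in% carriers), ncol = 1,
                   dimnames = list(tips, NULL))
    m <- intron_matrix(pres, columns = 1L, phases = 0L)
    ev <- classify_events(m, tree = tr)
    expect_equal(nrow(ev), oracle_dollo_count(tr, carriers))
    expect_equal(sum(ev$type == "gain"), 1L)
  }
})

test_that("tree-mode classification recovers simulated events", {
  groups <- list(c("a", "b", "c"), c("d", "e"), c("f", "g"))
  tree <- family_tree(groups, 0.25)
  total <- sum(tree$edge.length)
  gain_rate <- 1.5 / total
  loss_rate <- 1.5 / (4 * total)
  anc <- data.frame(label = paste0("P", 1:4),
                    codon_index = c(20L, 60L, 100L, 140L),
                    phase = rep(0L, 4))
  hits <- 0L; total_events <- 0L
  for (i in 1:20) {
    r <- mutate_intron_set(anc, tree, gain_rate, loss_rate, 200, seed = i)
    labels <- unique(c(anc$label, unlist(r$leaf_sets)))
    lookup <- rbind(anc, r$positions[!(r$positions$label %in% anc$label), ])
    lookup <- lookup[lookup$label %in% labels, ]
    lookup <- lookup[order(lookup$codon_index, lookup$phase), ]
    pres <- matrix(0L, length(tree$tip.label), nrow(lookup),
                   dimnames = list(tree$tip.label, lookup$label))
    for (g in tree$tip.label)
      pres[g, intersect(r$leaf_sets[[g]], lookup$label)] <- 1L
    keep <- colSums(pres) > 0
    m <- intron_matrix(pres[, keep, drop = FALSE],
                       columns = lookup$codon_index[keep],
                       phases = lookup$phase[keep],
                       labels = lookup$label[keep])
    bfs <- lapply(groups, function(g) basic_form(m, g, 0.5))
    calls <- classify_events(m, basic_forms = bfs, tree = tree)
    for (j in seq_len(nrow(r$events))) {
      ev <- r$events[j, ]
      total_events <- total_events + 1L
      if (any(calls$type == ev$type &
              as.character(calls$position) == ev$label))
        hits <- hits + 1L
    }
  }
  expect_gt(hits / total_events, 0.85)
})

test_that("ancestral model is the ordered union of basic forms", {
  expect_equal(ancestral_model(list(c(3, 5, 7, 11), c(4, 6, 10, 12))),
               c(3, 4, 5, 6, 7, 10, 11, 12))
  expect_equal(ancestral_model(list(c(1, 2))), c(1, 2))
  expect_length(ancestral_model(list(1:3, 4:7)), 7L)
  expect_error(ancestral_model(list()), "at least one")
})
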