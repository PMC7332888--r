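# Expression transforms, DE filtering, ddCt quantification, promoter
# extraction and cis-element scanning.

test_that("log transform and fold change follow the FPKM+1 convention", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(1), 1)
  expect_equal(log_transform(7), 3)
  expect_error(log_transform(-1), "non-negative")
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(7, 3), 2)
  expect_equal(fold_change(0, 0), 1)
})

test_that("the DE filter applies inclusive thresholds symmetrically", {
  res <- data.frame(gene = paste0("g", 1:5), contrast = "drought",
                    fold_change = c(2.0, 1.9, 0.5, 0.51, 4),
                    p_value = c(0.01, 0.001, 0.01, 0.001, 0.02))
  de <- de_filter(res)
  expect_equal(de$responsive, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(de$direction, c("up", "none", "down", "none", "up"))
  expect_error(de_filter(transform(res, p_value = 2)), "0, 1")
  # idempotence and threshold monotonicity
  de2 <- de_filter(de)
  expect_equal(de2$responsive, de$responsive)
  stricter <- de_filter(res, p_threshold = 0.001)
  expect_true(all(which(stricter$responsive) %in% which(de$responsive)))
})

test_that("regulation summary reports counts and percentages", {
  de <- data.frame(gene = paste0("g", 1:66), contrast = "drought",
                   fold_change = c(rep(4, 7), rep(0.2, 59)),
                   p_value = 0.001)
  s <- regulation_summary(de_filter(de))
  expect_equal(s$n_responsive, 66L)
  expect_equal(s$n_down, 59L)
  expect_equal(s$pct_down, 89.4)
  expect_equal(s$pct_up, 10.6)
  empty <- regulation_summary(de_filter(de[0, ]))
  expect_equal(nrow(empty), 0L)
})

test_that("planted simulated responses are recovered exactly", {
  # well-expressed baseline and low replicate noise so the planted
  # effects dominate and recovery is exact (the property under test is
  # the filter, not the noise floor or the epsilon compression of
  # near-zero FPKM)
  ex <- simulate_expression(sprintf("g%03d", 1:120), treatments = "drought",
                            n_up = 20, n_down = 40, fold_change = 4,
                            baseline_meanlog = 4, baseline_sdlog = 0.8,
                            noise_sdlog = 0.05, seed = 17)
  de <- de_filter(compute_contrasts(ex$fpkm, ex$samples))
  s <- regulation_summary(de)
  truth_up <- ex$truth$gene[ex$truth$direction == "up"]
  truth_down <- ex$truth$gene[ex$truth$direction == "down"]
  got_up <- de$gene[de$responsive & de$direction == "up"]
  got_down <- de$gene[de$responsive & de$direction == "down"]
  expect_setequal(got_up, truth_up)
  expect_setequal(got_down, truth_down)
  expect_equal(s$n_responsive, 60L)
})

test_that("ddct reproduces the textbook identities", {
  ct <- expand.grid(sample = c("T0", "T1"), gene = c("tgt", "ref"),
                    bio_rep = 1:3, tech_rep = 1:3,
                    stringsAsFactors = FALSE)
  ct$ct <- ifelse(ct$gene == "ref", 18,
                  ifelse(ct$sample == "T0", 24, 23))
  r <- ddct(ct, target = "tgt", reference = "ref", calibrator = "T0")
  expect_equal(r$summary$relative_expression[r$summary$sample == "T0"], 1)
  # ddCt = -1 -> doubling
  expect_equal(r$summary$relative_expression[r$summary$sample == "T1"], 2)
  # adding a constant to every Ct leaves relative expression unchanged
  ct2 <- ct; ct2$ct <- ct2$ct + 5
  r2 <- ddct(ct2, "tgt", "ref", "T0")
  expect_equal(r2$summary$relative_expression,
               r$summary$relative_expression)
  # ddCt = 3 -> 0.125
  ct3 <- ct; ct3$ct[ct3$sample == "T1" & ct3$gene == "tgt"] <- 27
  r3 <- ddct(ct3, "tgt", "ref", "T0")
  expect_equal(r3$summary$relative_expression[r3$summary$sample == "T1"],
               0.125)
  expect_error(ddct(ct[ct$gene == "tgt", ], "tgt", "ref", "T0"),
               "reference")
  expect_warning(ddct(ct[ct$tech_rep < 3, ], "tgt", "ref", "T0"),
                 "technical")
})

test_that("promoter extraction is strand-aware and truncates at edges", {
  genome <- c(chr1 = paste(rep(c("A", "C", "G", "T"), 2500), collapse = ""))
  g_plus <- gene_model("p1", "chr1", "+",
                       cbind(start = 3001L, end = 3300L),
                       paste(rep("A", 300), collapse = ""))
  prom <- extract_promoter(g_plus, genome, 2000)
  expect_equal(nchar(prom), 2000L)
  expect_equal(prom, substr(genome[["chr1"]], 1001, 3000))
  # minus-strand mirror: reverse complement of the mirrored window
  g_minus <- gene_model("m1", "chr1", "-",
                        cbind(start = 6701L, end = 7000L),
                        paste(rep("A", 300), collapse = ""))
  promm <- extract_promoter(g_minus, genome, 2000)
  expect_equal(promm, oracle_revcomp(substr(genome[["chr1"]], 7001, 9000)))
  # truncation near the contig start
  g_edge <- gene_model("e1", "chr1", "+", cbind(start = 501L, end = 800L),
                       paste(rep("A", 300), collapse = ""))
  expect_warning(pe <- extract_promoter(g_edge, genome, 2000), "truncated")
  expect_equal(nchar(pe), 500L)
})

test_that("element scanning matches a naive IUPAC oracle on both strands", {
  expect_equal(unname(scan_elements("TTACGTGG", list(ABRE = "ACGTG"))["ABRE"]),
               1L + oracle_motif_count(oracle_revcomp("TTACGTGG"), "ACGTG"))
  expect_equal(unname(scan_elements("", list(x = "ACGT"))["x"]), 0L)
  expect_equal(unname(scan_elements("ACGTG", list(x = "ACGTG"))["x"]), 1L)
  expect_error(scan_elements("ACGT", list(x = "AXGT")), "IUPAC")
  set.seed(12)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    pats <- list(a = "ACGTG", b = "CANNTG", c = "RYRY")
    got <- scan_elements(s, pats)
    want <- vapply(pats, function(p)
      oracle_motif_count(s, p) + oracle_motif_count(oracle_revcomp(s), p),
      integer(1))
    expect_equal(unname(got), unname(want))
  }
})

test_that("element tables append column totals invariant to row order", {
  tab <- element_table(gelp_promoter_elements())
  tot <- tab[tab$gene == "Total", ]
  expect_equal(tot$ABRE, 12)
  expect_equal(tot$MBS, 11)
  expect_equal(tot$LTR, 5)
  perm <- gelp_promoter_elements()[sample(7), ]
  tot2 <- element_table(perm)
  expect_equal(tot2[tot2$gene == "Total", -1], tot[, -1])
  one <- element_table(gelp_promoter_elements()[1, ])
  expect_equal(unlist(one[2, -1]), unlist(one[1, -1]))
})
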