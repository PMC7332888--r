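# Profile construction, calibrated search, domain validation and the
# two-pass iterative identification.

make_proteome <- function(n_family = 10, n_background = 50, divergence = 0.15,
                          seed = 1) {
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  dom <- synthetic_domain_seed(1, divergence = 0, seed = seed)[[1]]
  fam <- vapply(seq_len(n_family), function(i) {
    d <- strsplit(dom, "")[[1]]
    mut <- runif(length(d)) < divergence
    d[mut] <- sample(aas, sum(mut), replace = TRUE)
    paste0(paste(sample(aas, 40, replace = TRUE), collapse = ""),
           paste(d, collapse = ""),
           paste(sample(aas, 60, replace = TRUE), collapse = ""))
  }, character(1))
  bg <- vapply(seq_len(n_background), function(i)
    paste(sample(aas, 250, replace = TRUE), collapse = ""), character(1))
  c(setNames(fam, sprintf("fam%03d", seq_len(n_family))),
    setNames(bg, sprintf("bg%03d", seq_len(n_background))))
}

test_that("profile emissions behave at the consensus and pseudocount limits", {
  aln <- setNames(rep("MKKLLVVNNAAGG", 4), paste0("s", 1:4))
  prof <- build_profile(aln, calibrate = FALSE)
  # consensus residue has the max emission in every column
  cons <- strsplit(aln[[1]], "")[[1]]
  for (k in seq_len(nrow(prof$emissions)))
    expect_equal(names(which.max(prof$emissions[k, ])), cons[k])
  # huge pseudocount: emissions converge to 0 (background)
  prof_inf <- build_profile(aln, pseudocount = 1e9, calibrate = FALSE)
  expect_lt(max(abs(prof_inf$emissions)), 1e-6)
  expect_error(build_profile(aln[1], calibrate = FALSE), "at least 2")
  expect_error(build_profile(setNames(rep("MK-", 3), paste0("s", 1:3)),
                             calibrate = FALSE), "match columns")
})

test_that("low-occupancy columns are dropped", {
  rows <- c(paste0("M", paste(rep("K", 15), collapse = "")),
            paste0("M", paste(rep("K", 15), collapse = "")),
            paste0("-", paste(rep("K", 15), collapse = "")),
            paste0("-", paste(rep("K", 15), collapse = "")))
  # first column 50% occupied -> kept at the 0.5 default (>= rule)
  prof <- build_profile(setNames(rows, paste0("s", 1:4)), calibrate = FALSE)
  expect_equal(nrow(prof$emissions), 16L)
  rows2 <- c(rows[1], rows[3], rows[3], rows[3])
  prof2 <- build_profile(setNames(rows2, paste0("s", 1:4)), calibrate = FALSE)
  expect_equal(nrow(prof2$emissions), 15L)
})

test_that("seed sequences score with tiny E-values against their profile", {
  seed_aln <- synthetic_domain_seed(20, 0.1, seed = 2)
  prof <- build_profile(seed_aln, seed = 3)
  hits <- search_profile(prof, seed_aln, e_threshold = 1e-20)
  expect_equal(sort(hits$gene_id), sort(names(seed_aln)))
  expect_true(all(hits$e_value < 1e-20))
})

test_that("search requires calibration and handles empty input", {
  seed_aln <- synthetic_domain_seed(5, 0.05, seed = 4)
  raw <- build_profile(seed_aln, calibrate = FALSE)
  expect_error(search_profile(raw, seed_aln), "calibrated")
  prof <- build_profile(seed_aln, seed = 4)
  empty <- search_profile(prof, character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("hit set is invariant to proteome order and E decreases in score", {
  proteome <- make_proteome(8, 30, seed = 6)
  prof <- build_profile(synthetic_domain_seed(10, 0.1, seed = 6), seed = 6)
  h1 <- search_profile(prof, proteome)
  h2 <- search_profile(prof, rev(proteome))
  expect_setequal(h1$gene_id, h2$gene_id)
  # E-values grow monotonically as scores shrink
  ord <- order(h1$score, decreasing = TRUE)
  expect_false(is.unsorted(h1$e_value[ord]))
})

test_that("background-only proteomes produce no spurious strong hits", {
  set.seed(7)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bg <- setNames(vapply(1:150, function(i)
    paste(sample(aas, 300, replace = TRUE), collapse = ""), character(1)),
    sprintf("r%03d", 1:150))
  prof <- build_profile(synthetic_domain_seed(10, 0.1, seed = 7), seed = 7)
  hits <- search_profile(prof, bg, e_threshold = 0.1)
  # expected count of E < 0.1 hits is about 0.1; allow a small constant
  expect_lte(nrow(hits), 3L)
})

test_that("domain validation applies the coverage cutoff", {
  expect_true(validate_domain(1.0))
  expect_true(validate_domain(0.6))
  expect_false(validate_domain(0.59))
  hits <- data.frame(coverage = c(0.9, 0.3))
  expect_equal(validate_domain(hits), c(TRUE, FALSE))
})

test_that("half-domain fragments are rejected by coverage validation", {
  proteome <- make_proteome(6, 10, seed = 8)
  dom <- synthetic_domain_seed(1, 0, seed = 8)[[1]]
  frag <- substr(dom, 1, nchar(dom) %/% 2)
  proteome <- c(proteome, frag001 = frag)
  prof <- build_profile(synthetic_domain_seed(10, 0.1, seed = 8), seed = 8)
  hits <- search_profile(prof, proteome, e_threshold = 1e-10)
  frag_row <- hits[hits$gene_id == "frag001", ]
  if (nrow(frag_row)) expect_false(validate_domain(frag_row))
  full <- hits[grepl("^fam", hits$gene_id), ]
  expect_true(all(validate_domain(full)))
})

test_that("two passes are a fixed point when the proteome is the seed set", {
  seed_aln <- synthetic_domain_seed(12, 0.08, seed = 9)
  res <- iterative_search(seed_aln, seed_aln, e_threshold = 1e-20, seed = 9)
  expect_setequal(res$pass1$gene_id, names(seed_aln))
  expect_setequal(res$pass2$gene_id, names(seed_aln))
  expect_setequal(res$members, names(seed_aln))
})

test_that("the species-specific second pass recovers diverged outliers", {
  proteome <- make_proteome(20, 80, divergence = 0.12, seed = 10)
  # three strongly diverged family members
  set.seed(20)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  dom <- synthetic_domain_seed(1, 0, seed = 10)[[1]]
  outliers <- vapply(1:3, function(i) {
    d <- strsplit(dom, "")[[1]]
    mut <- runif(length(d)) < 0.45
    d[mut] <- sample(aas, sum(mut), replace = TRUE)
    paste0(paste(sample(aas, 30, replace = TRUE), collapse = ""),
           paste(d, collapse = ""))
  }, character(1))
  proteome <- c(proteome, setNames(outliers, paste0("out", 1:3)))
  # a deliberately weak generic seed (few, highly diverged sequences) at
  # a strict threshold: the outliers sit below the pass-1 sensitivity
  generic <- synthetic_domain_seed(3, 0.45, seed = 99)
  res <- iterative_search(generic, proteome, e_threshold = 1e-30, seed = 10)
  expect_equal(sum(grepl("^out", res$pass1$gene_id)), 0L)
  expect_true(nrow(res$pass2) >= nrow(res$pass1))
  gained <- setdiff(res$pass2$gene_id, res$pass1$gene_id)
  expect_gte(length(gained), 1L)
  expect_true(all(grepl("^out", gained)))
})

test_that("a pass-1 singleton falls back with a warning", {
  seed_aln <- synthetic_domain_seed(6, 0.1, seed = 11)
  bg <- make_proteome(0, 5, seed = 11)
  expect_warning(res <- iterative_search(seed_aln, bg, seed = 11),
                 "fewer than 2")
  expect_null(res$pass2)
})
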