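# Duplicate-pair classification and Nei-Gojobori (NG86) Ka/Ks estimation.
#
# A pair of family members counts as duplicated when a protein-guided
# CDS alignment covers > 80% of the longer gene and the aligned region
# is > 80% identical at the nucleotide level; pairs are then classified
# as tandem (same chromosome, few intervening genes) or WGD/segmental,
# and per-pair Ka, Ks and omega = Ka/Ks are estimated by codon counting
# with the Jukes-Cantor multiple-hit correction.

#' Align two coding sequences at codon resolution
#'
#' Translates both CDS, aligns the proteins globally (Needleman-Wunsch with
#' BLOSUM62 and affine gaps via [Biostrings::pairwiseAlignment()]) and
#' back-threads the protein alignment onto the codons, so gaps always come
#' in whole-codon units. Coverage is the ungapped-in-both alignment length
#' divided by the longer CDS; identity is the nucleotide identity over
#' columns ungapped in both sequences.
#'
#' @param cds_a,cds_b Coding sequences (character or `DNAString`), lengths
#'   divisible by 3, no internal stop codons. A terminal stop codon is
#'   trimmed before alignment.
#' @param gap_opening,gap_extension Protein-level affine gap penalties.
#' @return An object of class `cds_pair_alignment`: a list with the aligned
#'   codon vectors (`codons_a`, `codons_b`, gap codons are `"---"`),
#'   `coverage`, `identity` and the input lengths.
#' @export
align_cds_pair <- function(cds_a, cds_b, gap_opening = 10, gap_extension = 0.5) {
  cds_a <- strip_terminal_stop(cds_a)
  cds_b <- strip_terminal_stop(cds_b)
  cod_a <- check_cds(cds_a, allow_terminal_stop = FALSE)
  cod_b <- check_cds(cds_b, allow_terminal_stop = FALSE)
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  row_a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  row_b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ai <- bi <- 0L
  n <- length(row_a)
  ca <- cb <- character(n)
  for (i in seq_len(n)) {
    if (row_a[i] == "-") ca[i] <- "---" else { ai <- ai + 1L; ca[i] <- cod_a[ai] }
    if (row_b[i] == "-") cb[i] <- "---" else { bi <- bi + 1L; cb[i] <- cod_b[bi] }
  }
  both <- ca != "---" & cb != "---"
  nt_a <- unlist(strsplit(ca[both], ""))
  nt_b <- unlist(strsplit(cb[both], ""))
  identity <- if (length(nt_a)) mean(nt_a == nt_b) else 0
  coverage <- (3 * sum(both)) / max(nchar(cds_a), nchar(cds_b))
  structure(list(codons_a = ca, codons_b = cb,
                 coverage = coverage, identity = identity,
                 len_a = nchar(cds_a), len_b = nchar(cds_b)),
            class = "cds_pair_alignment")
}

strip_terminal_stop <- function(cds) {
  cds <- chartr("U", "T", toupper(as.character(cds)))
  cod <- split_codons(cds)
  if (length(cod) > 1L && codon_aa(cod[length(cod)]) == "*")
    cds <- substr(cds, 1L, nchar(cds) - 3L)
  cds
}

#' @export
print.cds_pair_alignment <- function(x, ...) {
  cat(sprintf("codon pairwise alignment: %d columns, coverage %.3f, identity %.3f\n",
              length(x$codons_a), x$coverage, x$identity))
  invisible(x)
}

#' Decide whether an aligned pair qualifies as a duplicated gene pair
#'
#' The criterion is strict: alignment coverage of the longer gene must
#' exceed `min_coverage` and nucleotide identity over the aligned region
#' must exceed `min_identity` (defaults 0.80, both exclusive).
#'
#' @param alignment A `cds_pair_alignment`.
#' @param min_coverage,min_identity Exclusive lower bounds.
#' @return `TRUE` or `FALSE`.
#' @export
classify_duplicate <- function(alignment, min_coverage = 0.8, min_identity = 0.8) {
  stopifnot(inherits(alignment, "cds_pair_alignment"))
  alignment$coverage > min_coverage && alignment$identity > min_identity
}

#' Classify a duplicate pair as tandem or segmental
#'
#' Tandem duplicates sit on the same chromosome separated by at most
#' `max_intervening` genes; everything else is treated as a
#' WGD/segmental duplicate. The default of 4 intervening genes follows
#' the convention that tandem cluster members are adjacent or isolated
#' by 1-4 genes.
#'
#' @param gene_a,gene_b Gene identifiers.
#' @param gene_order Named list: chromosome -> character vector of gene ids
#'   in chromosomal order (all annotated genes, not just family members).
#' @param max_intervening Maximum number of intervening genes for a tandem
#'   call (default 4).
#' @return `"tandem"` or `"segmental"`.
#' @export
assign_mode <- function(gene_a, gene_b, gene_order, max_intervening = 4L) {
  loc <- function(g) {
    for (chr in names(gene_order)) {
      i <- match(g, gene_order[[chr]])
      if (!is.na(i)) return(list(chr = chr, idx = i))
    }
    stop("gene not found in gene order: ", g)
  }
  la <- loc(gene_a); lb <- loc(gene_b)
  if (la$chr == lb$chr && abs(la$idx - lb$idx) - 1L <= max_intervening)
    "tandem" else "segmental"
}

# ---- NG86 site and difference counting --------------------------------

#' Synonymous and nonsynonymous site fractions of a codon (NG86)
#'
#' For each of the three codon positions, the synonymous fraction is the
#' number of the three possible single-nucleotide changes that leave the
#' amino acid unchanged, divided by 3; changes creating a stop codon count
#' as nonsynonymous. The two fractions always sum to 3 per codon.
#'
#' @param codon A sense codon (3-letter string).
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @export
ng86_sites <- function(codon) {
  codon <- chartr("U", "T", toupper(codon))
  if (is_stop_codon(codon)) stop("stop codon has no NG86 site decomposition: ", codon)
  key <- paste0("sites_", codon)
  hit <- .codon_env[[key]]
  if (!is.null(hit)) return(hit)
  nb <- codon_neighbors(codon)
  s <- sum(nb$synonymous) / 3
  res <- c(s = s, n = 3 - s)
  assign(key, res, envir = .codon_env)
  res
}

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' Counts are averaged with equal weight over all minimal substitution
#' pathways between the codons; pathways passing through a stop codon are
#' excluded. If every pathway is blocked by stop codons, all pathways are
#' used with stop-creating steps counted as nonsynonymous, and a warning
#' is raised. `Sd + Nd` equals the number of differing positions.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(sd = ..., nd = ...)`.
#' @export
ng86_differences <- function(codon_a, codon_b) {
  codon_a <- chartr("U", "T", toupper(codon_a))
  codon_b <- chartr("U", "T", toupper(codon_b))
  if (is_stop_codon(codon_a) || is_stop_codon(codon_b))
    stop("NG86 differences are defined for sense codons only")
  key <- paste0("diff_", codon_a, "_", codon_b)
  hit <- .codon_env[[key]]
  if (!is.null(hit)) return(hit)
  res <- ng86_diff_compute(codon_a, codon_b)
  assign(key, res, envir = .codon_env)
  res
}

ng86_diff_compute <- function(codon_a, codon_b) {
  nta <- strsplit(codon_a, "")[[1]]
  ntb <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(nta != ntb)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- perms(diff_pos)
  walk <- function(order, count_stops) {
    cur <- nta
    sd <- nd <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- ntb[pos]
      aa0 <- codon_aa(paste(cur, collapse = ""))
      aa1 <- codon_aa(paste(nxt, collapse = ""))
      if (aa1 == "*" && !count_stops) return(NULL)
      if (aa0 == aa1 && aa1 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(paths, walk, count_stops = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    warning("all minimal pathways between ", codon_a, " and ", codon_b,
            " pass through stop codons; counting them as nonsynonymous steps")
    res <- lapply(paths, walk, count_stops = TRUE)
  }
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(perms(x[-i]), function(p) c(x[i], p)))
  out
}

#' Ka, Ks and omega for an aligned codon pair (NG86 + Jukes-Cantor)
#'
#' Gapped codon columns are excluded. Synonymous (S) and nonsynonymous (N)
#' site totals are averaged over the two sequences; proportions
#' `ps = Sd/S` and `pn = Nd/N` are corrected for multiple hits with
#' `d = -(3/4) log(1 - 4p/3)`. `omega = ka/ks` when `ks > 0`, otherwise
#' `NA` with `omega_defined = FALSE`. Proportions `>= 3/4` make the
#' correction undefined; the pair is then flagged `saturated` and the
#' corresponding rate is `NA`.
#'
#' @param alignment A `cds_pair_alignment` (or a list with `codons_a`,
#'   `codons_b`).
#' @return List with `ka`, `ks`, `omega`, `omega_defined`, `saturated`,
#'   and the raw counts `S`, `N`, `Sd`, `Nd`, `n_codons`.
#' @export
kaks <- function(alignment) {
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  keep <- ca != "---" & cb != "---"
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) stop("no ungapped codon columns to compare")
  sites_a <- vapply(ca, ng86_sites, numeric(2))
  sites_b <- vapply(cb, ng86_sites, numeric(2))
  S <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  N <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2
  diffs <- mapply(function(a, b) ng86_differences(a, b), ca, cb)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  saturated <- is.na(ks) || is.na(ka)
  omega_defined <- !saturated && ks > 0
  omega <- if (omega_defined) ka / ks else NA_real_
  list(ka = ka, ks = ks, omega = omega, omega_defined = omega_defined,
       saturated = saturated, S = S, N = N, Sd = Sd, Nd = Nd,
       n_codons = length(ca))
}

#' Analyse all candidate duplicate pairs in a CDS set
#'
#' Aligns every pair (or a supplied pair list), applies the duplicate
#' criterion, classifies mode by chromosomal position when a gene order is
#' given, and estimates Ka/Ks.
#'
#' @param cds Named character vector (or `DNAStringSet`) of coding
#'   sequences.
#' @param pairs Optional two-column matrix/data.frame of gene id pairs to
#'   test; defaults to all pairs.
#' @param gene_order Optional named list chromosome -> ordered gene ids,
#'   for tandem/segmental classification.
#' @param min_coverage,min_identity Duplicate-pair thresholds
#'   (exclusive, default 0.8).
#' @param max_intervening Tandem distance cutoff (default 4).
#' @return Data frame with one row per retained pair: `gene_a`, `gene_b`,
#'   `coverage`, `identity`, `mode`, `ka`, `ks`, `omega`, `saturated`.
#' @export
duplicate_pair_table <- function(cds, pairs = NULL, gene_order = NULL,
                                 min_coverage = 0.8, min_identity = 0.8,
                                 max_intervening = 4L) {
  cds <- as_named_chr(cds)
  if (is.null(names(cds)) || anyDuplicated(names(cds)))
    stop("`cds` must be uniquely named")
  if (is.null(pairs)) {
    ids <- names(cds)
    pairs <- t(utils::combn(ids, 2L))
  }
  pairs <- as.matrix(pairs)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    aln <- align_cds_pair(cds[[a]], cds[[b]])
    if (!classify_duplicate(aln, min_coverage, min_identity)) next
    mode <- if (is.null(gene_order)) NA_character_ else
      assign_mode(a, b, gene_order, max_intervening)
    kk <- kaks(aln)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = a, gene_b = b,
      coverage = aln$coverage, identity = aln$identity, mode = mode,
      ka = kk$ka, ks = kk$ks, omega = kk$omega, saturated = kk$saturated,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      coverage = numeric(), identity = numeric(),
                      mode = character(), ka = numeric(), ks = numeric(),
                      omega = numeric(), saturated = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin pairwise Ka/Ks ratios into a frequency histogram
#'
#' Half-open bins `[k*w, (k+1)*w)`. Pairs with undefined omega (ks = 0 or
#' saturated) are excluded from the bins and reported separately.
#'
#' @param pairs Data frame with an `omega` column (e.g. from
#'   [duplicate_pair_table()]), or a numeric vector of omega values.
#' @param bin_width Positive bin width.
#' @return List with `table` (data.frame: `bin_lo`, `bin_hi`, `count`,
#'   `frequency`) and `n_excluded`.
#' @export
kaks_histogram <- function(pairs, bin_width = 0.1) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  omega <- if (is.data.frame(pairs)) pairs$omega else as.numeric(pairs)
  n_all <- length(omega)
  omega <- omega[is.finite(omega)]
  n_excluded <- n_all - length(omega)
  if (!length(omega))
    return(list(table = data.frame(bin_lo = numeric(), bin_hi = numeric(),
                                   count = integer(), frequency = numeric()),
                n_excluded = n_excluded))
  k <- floor(omega / bin_width)
  tab <- table(k)
  kk <- as.integer(names(tab))
  list(table = data.frame(bin_lo = kk * bin_width,
                          bin_hi = (kk + 1) * bin_width,
                          count = as.integer(tab),
                          frequency = as.integer(tab) / length(omega)),
       n_excluded = n_excluded)
}
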