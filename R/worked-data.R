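# Published summary tables of the soybean GELP survey, encoded as plain
# data so the counting and classification operations can be exercised and
# checked against the printed numbers without the Wm82.a2.v1 genome.

#' Per-gene subfamily/intron-count rows of the published survey
#'
#' Expands the published per-subfamily intron-number table of the 194
#' soybean GELP genes (subfamilies A-K, 1-6 introns) into one row per
#' gene, suitable for [intron_count_table()]. Gene ids are synthetic
#' placeholders (`A_1`, `A_2`, ...) because the summary table does not
#' name individual genes.
#'
#' @return Data frame with columns `gene_id`, `subfamily`, `introns`
#'   (194 rows).
#' @export
gelp_subfamily_introns <- function() {
  # per-subfamily counts of genes with 1..6 introns
  counts <- rbind(
    A = c(2, 3, 1, 29, 3, 0),
    B = c(0, 0, 0, 11, 1, 0),
    C = c(0, 0, 0, 3, 0, 0),
    D = c(0, 0, 0, 18, 2, 0),
    E = c(0, 0, 0, 1, 1, 0),
    F = c(0, 0, 1, 27, 0, 0),
    G = c(0, 0, 0, 11, 0, 0),
    H = c(0, 0, 0, 2, 0, 0),
    I = c(0, 12, 2, 33, 2, 1),
    J = c(4, 0, 4, 2, 0, 0),
    K = c(0, 1, 0, 7, 10, 0))
  rows <- list()
  for (sf in rownames(counts)) {
    k <- 0L
    for (n_intron in 1:6) {
      cnt <- counts[sf, n_intron]
      if (cnt == 0) next
      for (i in seq_len(cnt)) {
        k <- k + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = paste0(sf, "_", k), subfamily = sf,
          introns = n_intron, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Tandemly duplicated gene sets of the published survey
#'
#' The nine tandem clusters reported for the soybean GELP family: seven
#' two-gene sets, one three-gene set and one five-gene set.
#'
#' @return List of character vectors of gene ids.
#' @export
gelp_tandem_sets <- function() {
  list(
    c("GmGELP52", "GmGELP53"),
    c("GmGELP6", "GmGELP66"),
    c("GmGELP96", "GmGELP97"),
    c("GmGELP107", "GmGELP108"),
    c("GmGELP130", "GmGELP131"),
    c("GmGELP140", "GmGELP141"),
    c("GmGELP142", "GmGELP143"),
    c("GmGELP55", "GmGELP56", "GmGELP57"),
    c("GmGELP176", "GmGELP177", "GmGELP178", "GmGELP179", "GmGELP180"))
}

#' Published promoter cis-element counts for seven GELP genes
#'
#' Counts of six abiotic-stress-responsive cis-elements (ABRE, MBS, LTR,
#' CGTCA-motif, TCA-element, TC-rich repeats) in the 2-kb promoters of
#' seven stress-responsive soybean GELP genes, as published.
#'
#' @return Data frame: one row per gene, one column per element, plus a
#'   `gene` column.
#' @export
gelp_promoter_elements <- function() {
  data.frame(
    gene = c("GmGELP25", "GmGELP28", "GmGELP33", "GmGELP74",
             "GmGELP100", "GmGELP123", "GmGELP163"),
    ABRE = c(2, 1, 1, 2, 4, 2, 0),
    MBS = c(4, 1, 0, 2, 1, 1, 2),
    LTR = c(0, 0, 5, 0, 0, 0, 0),
    `CGTCA-motif` = c(2, 3, 1, 0, 1, 1, 2),
    `TCA-element` = c(1, 1, 3, 0, 0, 1, 1),
    `TC-rich repeats` = c(0, 1, 0, 3, 1, 0, 0),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' The 13-gene worked intron-position set
#'
#' Encodes the intron presence/absence matrix of the 13 genes (5 from
#' subfamily K, 8 from subfamily I) used to work through the
#' basic-form/gain/loss analysis. The published account pins down 11 of
#' the 13 numbered positions: subfamily K carries positions 3, 5, 7, 11
#' (position 13 only in GmGELP125); subfamily I carries 4, 6, 10, 12,
#' with 1 and 2 unique to GmGELP112 and positions 4 and 10 lost from
#' GmGELP16 and GmGELP115 (which retain only 2 introns). Positions 8 and
#' 9 of the original 1-13 numbering cannot be attributed to any of the
#' 13 genes from the published statements and are therefore not encoded.
#' Three K-subfamily and four I-subfamily representatives are unnamed in
#' the source and carry placeholder ids. Alignment columns are synthetic
#' (10 x label) and phases are set to 0, preserving the published
#' left-to-right position order, which is all the downstream operations
#' use.
#'
#' @return List with `matrix` (an [intron_matrix()]) and `subfamilies`
#'   (named character vector gene id -> `"K"`/`"I"`).
#' @export
gelp_worked_intron_set <- function() {
  labels <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 10L, 11L, 12L, 13L)
  genes <- c("GmGELP125", "GmGELP164", "K_rep1", "K_rep2", "K_rep3",
             "GmGELP94", "GmGELP112", "GmGELP16", "GmGELP115",
             "I_rep1", "I_rep2", "I_rep3", "I_rep4")
  sets <- list(
    GmGELP125 = c(3, 5, 7, 11, 13),
    GmGELP164 = c(3, 5, 7, 11),
    K_rep1 = c(3, 5, 7, 11),
    K_rep2 = c(3, 5, 7, 11),
    K_rep3 = c(3, 5, 7, 11),
    GmGELP94 = c(4, 6, 10, 12),
    GmGELP112 = c(1, 2, 4, 6, 10, 12),
    GmGELP16 = c(6, 12),
    GmGELP115 = c(6, 12),
    I_rep1 = c(4, 6, 10, 12),
    I_rep2 = c(4, 6, 10, 12),
    I_rep3 = c(4, 6, 10, 12),
    I_rep4 = c(4, 6, 10, 12))
  pres <- matrix(0L, length(genes), length(labels),
                 dimnames = list(genes, as.character(labels)))
  for (g in genes) pres[g, as.character(sets[[g]])] <- 1L
  subfam <- stats::setNames(
    c(rep("K", 5L), rep("I", 8L)), genes)
  list(matrix = intron_matrix(pres, columns = labels * 10L,
                              phases = rep(0L, length(labels)),
                              labels = labels),
       subfamilies = subfam)
}
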