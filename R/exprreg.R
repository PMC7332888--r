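# Expression and promoter-regulatory stages: FPKM transforms,
# stress-response DE filtering and summaries, 2^-ddCt relative
# quantification, promoter extraction and cis-element scanning.

#' log2(FPKM + 1) transform
#'
#' @param x Non-negative numeric matrix/vector of FPKM values.
#' @return Transformed values, same shape.
#' @export
log_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
  log2(x + 1)
}

#' Pseudo-counted fold change
#'
#' `(treated + eps) / (control + eps)`; the default pseudo-count of 1
#' matches the log2(FPKM + 1) convention and keeps zero-FPKM genes
#' finite.
#'
#' @param treated,control Non-negative FPKM values (vectorized).
#' @param eps Pseudo-count (default 1).
#' @return Positive fold changes.
#' @export
fold_change <- function(treated, control, eps = 1) {
  if (any(treated < 0, na.rm = TRUE) || any(control < 0, na.rm = TRUE))
    stop("FPKM values must be non-negative")
  (treated + eps) / (control + eps)
}

#' Stress-response differential-expression filter
#'
#' A gene responds when its fold change is at least `fc_threshold` up
#' (`fc >= 2`) or the reciprocal down (`fc <= 1/2`) and its p-value is at
#' most `p_threshold` (defaults 2 and 0.01, boundaries inclusive).
#'
#' @param results Data frame with columns `gene`, `contrast`,
#'   `fold_change`, `p_value`.
#' @param fc_threshold Fold-change cutoff (default 2).
#' @param p_threshold P-value cutoff (default 0.01).
#' @return The input with `direction` (`up`/`down`/`none`) and
#'   `responsive` columns appended.
#' @export
de_filter <- function(results, fc_threshold = 2, p_threshold = 0.01) {
  stopifnot(all(c("gene", "fold_change", "p_value") %in% names(results)))
  if (any(results$p_value < 0 | results$p_value > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  fc <- results$fold_change
  up <- fc >= fc_threshold
  down <- fc <= 1 / fc_threshold
  results$direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  results$responsive <- (up | down) & results$p_value <= p_threshold
  results
}

#' Per-contrast fold changes and p-values from an FPKM matrix
#'
#' For each treatment condition, the fold change is the pseudo-counted
#' ratio of mean treated to mean control FPKM, and the p-value a Welch
#' t-test on log2(FPKM + 1) replicate values (a stand-in for an external
#' DE engine when only replicate FPKM values are available).
#'
#' @param fpkm Genes x samples matrix.
#' @param samples Data frame with `sample`, `condition` columns;
#'   conditions other than `control` are treated as contrasts.
#' @param eps Fold-change pseudo-count (default 1).
#' @return Data frame `gene`, `contrast`, `fold_change`, `p_value`.
#' @export
compute_contrasts <- function(fpkm, samples, eps = 1) {
  stopifnot(all(colnames(fpkm) == samples$sample))
  ctrl <- samples$condition == "control"
  if (!any(ctrl)) stop("no control samples")
  out <- list()
  for (tr in setdiff(unique(samples$condition), "control")) {
    sel <- samples$condition == tr
    fc <- fold_change(rowMeans(fpkm[, sel, drop = FALSE]),
                      rowMeans(fpkm[, ctrl, drop = FALSE]), eps)
    lg <- log_transform(fpkm)
    p <- vapply(seq_len(nrow(fpkm)), function(i) {
      a <- lg[i, sel]; b <- lg[i, ctrl]
      if (stats::sd(c(a, b)) == 0) return(1)
      stats::t.test(a, b)$p.value
    }, numeric(1))
    out[[tr]] <- data.frame(gene = rownames(fpkm), contrast = tr,
                            fold_change = fc, p_value = p,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Summarize responsive genes per contrast
#'
#' @param de Output of [de_filter()].
#' @return Data frame per contrast: `n_responsive`, `n_up`, `n_down`,
#'   `pct_up`, `pct_down` (percentages of responsive genes, 1 decimal).
#' @export
regulation_summary <- function(de) {
  if (!nrow(de))
    return(data.frame(contrast = character(), n_responsive = integer(),
                      n_up = integer(), n_down = integer(),
                      pct_up = numeric(), pct_down = numeric(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (tr in unique(de$contrast)) {
    d <- de[de$contrast == tr & de$responsive, , drop = FALSE]
    n <- nrow(d)
    n_up <- sum(d$direction == "up")
    n_down <- sum(d$direction == "down")
    out[[tr]] <- data.frame(
      contrast = tr, n_responsive = n, n_up = n_up, n_down = n_down,
      pct_up = if (n) round(100 * n_up / n, 1) else 0,
      pct_down = if (n) round(100 * n_down / n, 1) else 0,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged within each biological replicate;
#' `dCt = Ct_target - Ct_reference` per (sample, biological replicate),
#' `ddCt = dCt - mean(dCt of the calibrator sample)`, and relative
#' expression is `2^-ddCt`, summarized as mean and sd over biological
#' replicates. Three technical by three biological replicates are
#' expected (a warning is raised otherwise).
#'
#' @param records Data frame with columns `sample`, `gene`, `bio_rep`,
#'   `tech_rep`, `ct`.
#' @param target Target gene id.
#' @param reference Reference (housekeeping) gene id.
#' @param calibrator Calibrator sample id.
#' @return List with `per_rep` (per biological replicate relative
#'   expression) and `summary` (per sample: mean `relative_expression`,
#'   `sd`).
#' @export
ddct <- function(records, target, reference, calibrator) {
  need <- c("sample", "gene", "bio_rep", "tech_rep", "ct")
  stopifnot(all(need %in% names(records)))
  if (any(!is.finite(records$ct))) stop("Ct values must be finite")
  if (!any(records$gene == reference))
    stop("no rows for reference gene ", reference)
  if (!any(records$sample == calibrator))
    stop("calibrator sample not present: ", calibrator)
  reps <- stats::aggregate(ct ~ sample + gene + bio_rep, records, mean)
  n_tech <- stats::aggregate(ct ~ sample + gene + bio_rep, records, length)
  if (any(n_tech$ct != 3L))
    warning("expected 3 technical replicates per biological replicate")
  tgt <- reps[reps$gene == target, ]
  ref <- reps[reps$gene == reference, ]
  m <- merge(tgt, ref, by = c("sample", "bio_rep"),
             suffixes = c("_target", "_ref"))
  m$dct <- m$ct_target - m$ct_ref
  cal_mean <- mean(m$dct[m$sample == calibrator])
  m$ddct <- m$dct - cal_mean
  m$relative_expression <- 2^(-m$ddct)
  if (length(unique(table(m$sample))) && any(table(m$sample) != 3L))
    warning("expected 3 biological replicates per sample")
  summ <- do.call(rbind, lapply(split(m, m$sample), function(d)
    data.frame(sample = d$sample[1L],
               relative_expression = mean(d$relative_expression),
               sd = stats::sd(d$relative_expression),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(per_rep = m[, c("sample", "bio_rep", "dct", "ddct",
                       "relative_expression")],
       summary = summ)
}

#' Extract a promoter sequence upstream of the start codon
#'
#' Returns the `length` bases immediately 5' of the annotated CDS start,
#' strand-aware (reverse-complemented on the minus strand), truncated
#' with a warning at the contig edge.
#'
#' @param model A `gene_model`.
#' @param genome Named `DNAStringSet` or character vector of contig
#'   sequences.
#' @param length Promoter length in bp (default 2000).
#' @return Promoter sequence (character).
#' @export
extract_promoter <- function(model, genome, length = 2000L) {
  stopifnot(inherits(model, "gene_model"))
  genome <- as_named_chr(genome)
  if (!model$chromosome %in% names(genome))
    stop("contig not in genome: ", model$chromosome)
  contig <- genome[[model$chromosome]]
  clen <- nchar(contig)
  if (model$strand == "+") {
    cds_start <- model$exons[1L, "start"]
    from <- cds_start - length
    if (from < 1L) {
      warning("promoter truncated at contig start (",
              cds_start - 1L, " bp available)")
      from <- 1L
    }
    if (cds_start == 1L) return("")
    substr(contig, from, cds_start - 1L)
  } else {
    cds_start <- model$exons[1L, "end"]
    to <- cds_start + length
    if (to > clen) {
      warning("promoter truncated at contig end (",
              clen - cds_start, " bp available)")
      to <- clen
    }
    if (cds_start == clen) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(contig, cds_start + 1L, to))))
  }
}

IUPAC_OK <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]

#' Count cis-element motif matches in a promoter
#'
#' Counts all (possibly overlapping) matches of each IUPAC pattern on
#' both strands; an element's count is the sum over its patterns.
#'
#' @param promoter Nucleotide sequence (character).
#' @param motifs Named list: element name -> character vector of IUPAC
#'   patterns.
#' @return Named integer vector of counts per element.
#' @export
scan_elements <- function(promoter, motifs) {
  if (!length(motifs)) stop("`motifs` must be non-empty")
  bad <- vapply(motifs, function(p)
    any(!unlist(strsplit(toupper(p), "")) %in% IUPAC_OK), logical(1))
  if (any(bad))
    stop("invalid IUPAC symbols in patterns for: ",
         paste(names(motifs)[bad], collapse = ", "))
  promoter <- toupper(as.character(promoter))
  out <- stats::setNames(integer(length(motifs)), names(motifs))
  if (!nchar(promoter)) return(out)
  subj <- Biostrings::DNAString(promoter)
  rc <- Biostrings::reverseComplement(subj)
  for (el in names(motifs)) {
    n <- 0L
    for (pat in motifs[[el]]) {
      if (nchar(pat) > nchar(promoter)) next
      n <- n + length(Biostrings::matchPattern(pat, subj, fixed = FALSE)) +
        length(Biostrings::matchPattern(pat, rc, fixed = FALSE))
    }
    out[el] <- n
  }
  out
}

#' Assemble a promoter element count table with totals
#'
#' @param counts Data frame (or matrix) of per-gene element counts with a
#'   `gene` column or row names.
#' @return Data frame with a final `Total` row of column sums.
#' @export
element_table <- function(counts) {
  df <- as.data.frame(counts, check.names = FALSE)
  if (!"gene" %in% names(df)) {
    df <- cbind(gene = rownames(df), df, stringsAsFactors = FALSE)
  }
  num <- df[setdiff(names(df), "gene")]
  if (!all(vapply(num, is.numeric, logical(1))))
    stop("element counts must be numeric")
  tot <- c(gene = "Total", as.list(colSums(num)))
  out <- rbind(df, as.data.frame(tot, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Illustrative cis-element motif dictionary
#'
#' A small set of example IUPAC core motifs for the six stress-responsive
#' elements tracked in the promoter stage (ABRE, MBS, LTR, CGTCA-motif,
#' TCA-element, TC-rich repeats). The patterns are illustrative cores
#' for testing the scanner, not authoritative database definitions.
#'
#' @return Named list of IUPAC pattern vectors.
#' @export
default_motifs <- function() {
  list(
    "ABRE" = "ACGTG",
    "MBS" = "CAACTG",
    "LTR" = "CCGAAA",
    "CGTCA-motif" = "CGTCA",
    "TCA-element" = "CCATCTTTTT",
    "TC-rich repeats" = "ATTTTCTTCA")
}
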