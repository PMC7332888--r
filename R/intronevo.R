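# Intron-position evolution: extraction of intron sites from gene models,
# projection to protein-alignment coordinates, subfamily "basic forms",
# gain/loss classification (majority and Dollo-parsimony modes), and
# reconstruction of the ancestral exon-intron structure.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of 1-based inclusive
#'   genomic `start`,`end` intervals of the CDS exons, given in transcript
#'   (5'->3') order: ascending on the plus strand, descending on the
#'   minus strand.
#' @param cds Spliced coding sequence (5'->3'); its length must equal the
#'   summed exon widths.
#' @param subfamily Optional subfamily letter.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand = "+", exons, cds,
                       subfamily = NULL) {
  exons <- as.matrix(as.data.frame(exons)[, 1:2])
  colnames(exons) <- c("start", "end")
  storage.mode(exons) <- "integer"
  if (any(exons[, "end"] < exons[, "start"]))
    stop("exon end before start")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (nrow(exons) > 1L) {
    starts <- exons[, "start"]
    ok <- if (strand == "+") all(diff(starts) > 0) else all(diff(starts) < 0)
    if (!ok) stop("exons must be in transcript order and non-overlapping")
    gap_ok <- if (strand == "+")
      all(exons[-1L, "start"] > exons[-nrow(exons), "end"])
    else
      all(exons[-1L, "end"] < exons[-nrow(exons), "start"])
    if (!gap_ok) stop("exons overlap")
  }
  widths <- exons[, "end"] - exons[, "start"] + 1L
  cds <- toupper(as.character(cds))
  if (nchar(cds) != sum(widths))
    stop("CDS length (", nchar(cds), ") does not match summed exon widths (",
         sum(widths), ")")
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 exons = exons, cds = cds, subfamily = subfamily),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d exon(s), CDS %d nt%s\n",
              x$gene_id, x$chromosome, x$strand, nrow(x$exons), nchar(x$cds),
              if (is.null(x$subfamily)) "" else paste0(", subfamily ", x$subfamily)))
  invisible(x)
}

#' Extract intron sites from a gene model
#'
#' Each intron is described by the codon it interrupts and its phase: the
#' CDS offset `c` (nucleotides of coding sequence 5' of the intron) gives
#' `phase = c mod 3`; a phase-1/2 intron interrupts codon
#' `floor(c/3) + 1`, and a phase-0 intron is recorded after codon `c/3`.
#' Coordinates are strand-aware because exons are stored in transcript
#' order, so a minus-strand gene yields the same sites as its plus-strand
#' mirror.
#'
#' @param model A `gene_model`.
#' @return Data frame with columns `codon_index` and `phase` (one row per
#'   intron; zero rows for single-exon genes).
#' @export
extract_intron_sites <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  widths <- model$exons[, "end"] - model$exons[, "start"] + 1L
  if (length(widths) < 2L)
    return(data.frame(codon_index = integer(), phase = integer()))
  offsets <- cumsum(widths)[-length(widths)]
  phase <- offsets %% 3L
  codon_index <- ifelse(phase == 0L, offsets %/% 3L, offsets %/% 3L + 1L)
  data.frame(codon_index = as.integer(codon_index), phase = as.integer(phase))
}

#' Build an intron presence/absence matrix in alignment coordinates
#'
#' Projects per-gene intron sites (codon index + phase) through each
#' gene's row of a protein alignment; sites are merged into a single
#' position if and only if they land on the same alignment column with
#' the same phase (optionally within a +/- `column_tolerance` window).
#' Position labels are integers assigned in ascending column order.
#'
#' @param sites_by_gene Named list of data frames with `codon_index`,
#'   `phase` (e.g. from [extract_intron_sites()]).
#' @param alignment Aligned proteins covering every gene in
#'   `sites_by_gene` (named character vector, matrix, or `AAStringSet`).
#' @param column_tolerance Non-negative integer; columns differing by at
#'   most this much (same phase) are merged. Default 0 (exact).
#' @return An `intron_matrix`: list with `genes`, `positions` (data frame
#'   `label`, `column`, `phase`) and binary `presence` matrix.
#' @export
project_sites <- function(sites_by_gene, alignment, column_tolerance = 0L) {
  m <- aln_to_matrix(alignment)
  missing <- setdiff(names(sites_by_gene), rownames(m))
  if (length(missing))
    stop("genes missing from alignment: ", paste(missing, collapse = ", "))
  hits <- list()
  for (g in names(sites_by_gene)) {
    row <- m[g, ]
    res_cols <- which(!(row %in% GAP_CHARS))
    st <- sites_by_gene[[g]]
    for (i in seq_len(nrow(st))) {
      ci <- st$codon_index[i]
      if (ci > length(res_cols))
        stop("codon index ", ci, " beyond ungapped length of ", g)
      hits[[length(hits) + 1L]] <- data.frame(
        gene = g, column = res_cols[ci], phase = st$phase[i],
        stringsAsFactors = FALSE)
    }
  }
  genes <- names(sites_by_gene)
  if (!length(hits)) {
    return(intron_matrix(matrix(0L, length(genes), 0L,
                                dimnames = list(genes, NULL)),
                         columns = integer(), phases = integer()))
  }
  h <- do.call(rbind, hits)
  # cluster (column, phase) pairs, optionally with a tolerance window
  key <- paste(h$column, h$phase)
  uniq <- unique(h[order(h$column, h$phase), c("column", "phase")])
  if (column_tolerance > 0L) {
    merged <- list()
    for (i in seq_len(nrow(uniq))) {
      placed <- FALSE
      for (j in seq_along(merged)) {
        if (uniq$phase[i] == merged[[j]]$phase &&
            abs(uniq$column[i] - merged[[j]]$column) <= column_tolerance) {
          merged[[j]]$members <- c(merged[[j]]$members,
                                   paste(uniq$column[i], uniq$phase[i]))
          placed <- TRUE; break
        }
      }
      if (!placed)
        merged[[length(merged) + 1L]] <- list(column = uniq$column[i],
                                              phase = uniq$phase[i],
                                              members = paste(uniq$column[i], uniq$phase[i]))
    }
    uniq <- data.frame(column = vapply(merged, `[[`, numeric(1), "column"),
                       phase = vapply(merged, `[[`, numeric(1), "phase"))
    member_of <- stats::setNames(rep(seq_along(merged),
                                     vapply(merged, function(x) length(x$members), integer(1))),
                                 unlist(lapply(merged, `[[`, "members")))
    pos_idx <- member_of[key]
  } else {
    pos_idx <- match(key, paste(uniq$column, uniq$phase))
  }
  P <- nrow(uniq)
  pres <- matrix(0L, length(genes), P, dimnames = list(genes, seq_len(P)))
  for (r in seq_len(nrow(h))) pres[h$gene[r], pos_idx[r]] <- 1L
  intron_matrix(pres, columns = as.integer(uniq$column),
                phases = as.integer(uniq$phase))
}

#' Construct an intron presence/absence matrix directly
#'
#' @param presence Binary genes x positions matrix with gene row names.
#' @param columns Alignment column of each position (strictly increasing
#'   together with `phases` as tie-break).
#' @param phases Phase (0/1/2) of each position.
#' @param labels Optional position labels; default `1..P` in column order.
#' @return An object of class `intron_matrix`.
#' @export
intron_matrix <- function(presence, columns, phases, labels = NULL) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "integer"
  P <- ncol(presence)
  if (length(columns) != P || length(phases) != P)
    stop("`columns` and `phases` must have one entry per position")
  ord <- order(columns, phases)
  if (!identical(ord, seq_len(P))) {
    presence <- presence[, ord, drop = FALSE]
    columns <- columns[ord]; phases <- phases[ord]
    if (!is.null(labels)) labels <- labels[ord]
  }
  if (is.null(labels)) labels <- seq_len(P)
  colnames(presence) <- as.character(labels)
  structure(list(genes = rownames(presence),
                 positions = data.frame(label = labels, column = columns,
                                        phase = phases),
                 presence = presence),
            class = "intron_matrix")
}

#' @export
print.intron_matrix <- function(x, ...) {
  cat(sprintf("intron_matrix: %d genes x %d positions\n",
              length(x$genes), nrow(x$positions)))
  print(x$presence)
  invisible(x)
}

#' Per-subfamily intron-count frequency table
#'
#' Cell (s, k) counts the genes of subfamily s carrying exactly k introns;
#' a `Total` row and column are appended.
#'
#' @param x Either a list of `gene_model`s (each with a subfamily set) or
#'   a data frame with columns `subfamily` and `introns`.
#' @return Integer matrix with subfamily rows (plus `Total`) and
#'   intron-count columns (plus `Total`).
#' @export
intron_count_table <- function(x) {
  if (is.data.frame(x)) {
    df <- x
  } else {
    df <- do.call(rbind, lapply(x, function(m) {
      if (is.null(m$subfamily)) stop("gene ", m$gene_id, " has no subfamily")
      data.frame(subfamily = m$subfamily, introns = nrow(m$exons) - 1L,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!all(c("subfamily", "introns") %in% names(df)))
    stop("need `subfamily` and `introns` columns")
  ks <- seq(min(df$introns), max(df$introns))
  tab <- table(factor(df$subfamily), factor(df$introns, levels = ks))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m <- cbind(m, Total = rowSums(m))
  m <- rbind(m, Total = colSums(m))
  m
}

#' Basic form of a subfamily's intron structure
#'
#' The basic form is the set of intron positions present in more than
#' `threshold` (default 0.5) of the subfamily's members.
#'
#' @param matrix An `intron_matrix`.
#' @param members Gene ids of the subfamily (>= 2).
#' @param threshold Majority threshold in \[0, 1); strictly exceeded.
#' @return Sorted vector of position labels.
#' @export
basic_form <- function(matrix, members, threshold = 0.5) {
  stopifnot(inherits(matrix, "intron_matrix"))
  if (length(members) < 2L) stop("a basic form needs at least 2 members")
  missing <- setdiff(members, matrix$genes)
  if (length(missing)) stop("unknown genes: ", paste(missing, collapse = ", "))
  frac <- colMeans(matrix$presence[members, , drop = FALSE])
  labs <- matrix$positions$label[frac > threshold]
  sort(labs)
}

#' Classify intron gain and loss events
#'
#' In majority mode (no tree), a gain is called for every position outside
#' the union of the subfamily basic forms, with the genes possessing it as
#' carriers, and a loss is called for every (gene, position) absence of a
#' basic-form position of the gene's own subfamily. In tree mode, Dollo
#' parsimony is applied per position: a single gain on the branch above
#' the most recent common ancestor of the carriers, plus the minimum set
#' of loss branches explaining absences inside that clade.
#'
#' @param matrix An `intron_matrix`.
#' @param basic_forms Named list: subfamily -> label vector (from
#'   [basic_form()]).
#' @param subfamilies Named character vector gene id -> subfamily letter,
#'   covering every gene in the matrix (majority mode only).
#' @param tree Optional `phylo` tree over the matrix genes; switches to
#'   Dollo mode. When `basic_forms` are also supplied, positions that
#'   belong to a basic form are treated as ancestral: their single gain
#'   is anchored on the root rather than the carriers' MRCA, so losses
#'   of an ancestral intron in a basal clade are reported as losses
#'   instead of being re-interpreted as a later gain.
#' @return Data frame of calls: `position`, `type` (`gain`/`loss`),
#'   `gene` (carrier list for majority-mode gains, the losing gene for
#'   losses) and, in tree mode, `branch` (child node of the event edge).
#' @export
classify_events <- function(matrix, basic_forms = NULL, subfamilies = NULL,
                            tree = NULL) {
  stopifnot(inherits(matrix, "intron_matrix"))
  if (!is.null(tree)) {
    conserved <- if (is.null(basic_forms)) character() else
      as.character(unique(unlist(basic_forms)))
    return(dollo_events(matrix, tree, conserved))
  }
  if (is.null(basic_forms) || is.null(subfamilies))
    stop("majority mode needs `basic_forms` and `subfamilies`")
  lost <- setdiff(matrix$genes, names(subfamilies))
  if (length(lost))
    stop("genes without subfamily: ", paste(lost, collapse = ", "))
  conserved <- sort(unique(unlist(basic_forms)))
  calls <- list()
  for (j in seq_len(nrow(matrix$positions))) {
    lab <- matrix$positions$label[j]
    carriers <- matrix$genes[matrix$presence[, j] == 1L]
    if (!(lab %in% conserved) && length(carriers)) {
      calls[[length(calls) + 1L]] <- data.frame(
        position = lab, type = "gain",
        gene = paste(carriers, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  for (sf in names(basic_forms)) {
    members <- names(subfamilies)[subfamilies == sf]
    for (lab in basic_forms[[sf]]) {
      j <- match(lab, matrix$positions$label)
      losers <- intersect(members, matrix$genes[matrix$presence[, j] == 0L])
      for (g in losers)
        calls[[length(calls) + 1L]] <- data.frame(
          position = lab, type = "loss", gene = g, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(position = integer(), type = character(),
                      gene = character(), stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

# Dollo parsimony: one gain per position (above the carriers' MRCA, or
# on the root for positions declared ancestral), losses on the branches
# leading to maximal carrier-free subtrees.
dollo_events <- function(matrix, tree, conserved = character()) {
  tips <- tree$tip.label
  missing <- setdiff(matrix$genes, tips)
  if (length(missing))
    stop("matrix genes missing from tree: ", paste(missing, collapse = ", "))
  n_tip <- length(tips)
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= n_tip) return(tips[node])
    unlist(lapply(children_of[[as.character(node)]], tips_below))
  }
  calls <- list()
  for (j in seq_len(nrow(matrix$positions))) {
    lab <- matrix$positions$label[j]
    carriers <- intersect(tips, matrix$genes[matrix$presence[, j] == 1L])
    if (!length(carriers)) next
    origin <- if (as.character(lab) %in% conserved) n_tip + 1L
    else if (length(carriers) == 1L) match(carriers, tips)
    else ape::getMRCA(tree, carriers)
    calls[[length(calls) + 1L]] <- data.frame(
      position = lab, type = "gain", gene = paste(carriers, collapse = ","),
      branch = node_name(tree, origin), stringsAsFactors = FALSE)
    # walk the clade below `origin`; a subtree with no carriers = one loss
    recurse <- function(node) {
      below <- tips_below(node)
      if (!any(below %in% carriers)) {
        calls[[length(calls) + 1L]] <<- data.frame(
          position = lab, type = "loss", gene = paste(below, collapse = ","),
          branch = node_name(tree, node), stringsAsFactors = FALSE)
        return(invisible())
      }
      if (node > n_tip)
        for (ch in children_of[[as.character(node)]]) recurse(ch)
    }
    if (origin > n_tip)
      for (ch in children_of[[as.character(origin)]]) recurse(ch)
  }
  if (!length(calls))
    return(data.frame(position = integer(), type = character(),
                      gene = character(), branch = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

node_name <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) tree$tip.label[node] else paste0("node", node)
}

#' Ancestral conserved-intron model
#'
#' The ancestral exon-intron structure is modelled as the union of the
#' subfamily basic forms, ordered by alignment position.
#'
#' @param basic_forms List of label vectors (one per subfamily).
#' @return Sorted vector of conserved position labels.
#' @export
ancestral_model <- function(basic_forms) {
  if (!length(basic_forms)) stop("need at least one basic form")
  sort(unique(unlist(basic_forms)))
}
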