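# Distance phylogeny: Poisson-corrected protein distances with pairwise
# deletion, neighbor joining, bootstrap support, and subfamily labelling
# by reference propagation.

GAP_CHARS <- c("-", ".", "?", "*")
AMBIG_AA <- c("X", "B", "Z", "J", "U", "O")

aln_to_matrix <- function(alignment) {
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "XStringSet"))
    alignment <- as.character(alignment)
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    if (is.null(names(alignment))) stop("alignment rows must be named")
    if (length(unique(nchar(alignment))) != 1L)
      stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
  }
  m
}

#' Poisson-corrected distance between two aligned protein sequences
#'
#' Sites with a gap or ambiguity character in either sequence are excluded
#' (pairwise deletion); `p` is the fraction of mismatches among the
#' remaining sites and the distance is `d = -log(1 - p)`.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (character strings
#'   or character vectors of residues).
#' @return List with `d`, `p`, `compared_sites`, `saturated` (`TRUE` when
#'   `p = 1`, in which case `d = Inf`).
#' @export
poisson_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1]] else toupper(seq_b)
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  bad <- c(GAP_CHARS, AMBIG_AA)
  keep <- !(a %in% bad) & !(b %in% bad)
  n <- sum(keep)
  if (n == 0L) stop("no comparable sites after pairwise deletion")
  p <- mean(a[keep] != b[keep])
  saturated <- p >= 1
  d <- if (saturated) Inf else -log(1 - p)
  list(d = d, p = p, compared_sites = n, saturated = saturated)
}

#' Poisson distance matrix under pairwise deletion
#'
#' @param alignment Named character vector, residue matrix, or
#'   `AAStringSet` of aligned proteins.
#' @return Object of class `poisson_dist`: list with `labels`, symmetric
#'   matrix `d`, and `compared_sites`.
#' @export
poisson_dist_matrix <- function(alignment) {
  m <- aln_to_matrix(alignment)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  cs <- matrix(NA_integer_, n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) {
    cs[i, i] <- sum(!(m[i, ] %in% c(GAP_CHARS, AMBIG_AA)))
    for (j in seq_len(i - 1L)) {
      pd <- poisson_distance(m[i, ], m[j, ])
      d[i, j] <- d[j, i] <- pd$d
      cs[i, j] <- cs[j, i] <- pd$compared_sites
    }
  }
  structure(list(labels = rownames(m), d = d, compared_sites = cs),
            class = "poisson_dist")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]). Negative branch lengths,
#' which NJ can produce on non-additive matrices, are clamped to zero with
#' a warning.
#'
#' @param x A `poisson_dist` object, `dist`, or symmetric numeric matrix
#'   with labels.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(x) {
  d <- if (inherits(x, "poisson_dist")) x$d else as.matrix(x)
  if (any(!is.finite(d))) stop("distance matrix contains non-finite entries")
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for an NJ tree of aligned proteins
#'
#' Alignment columns are resampled with replacement `n_reps` times
#' (default 1000); the Poisson/NJ tree is rebuilt for each replicate and
#' the support of each internal bipartition of the original tree is the
#' fraction of replicates in which it occurs.
#'
#' @param alignment Aligned proteins (named character vector, matrix or
#'   `AAStringSet`).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for column resampling.
#' @return List with `tree` (the original tree, `node.label` set to
#'   supports) and `support` (numeric in \[0,1\], one per internal node;
#'   `NA` for the root node of the internal representation).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L) {
  m <- aln_to_matrix(alignment)
  if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
  if (n_reps < 1L) stop("`n_reps` must be >= 1")
  tree <- nj_tree(poisson_dist_matrix(m))
  set.seed(seed)
  boot <- vector("list", n_reps)
  # saturated pairs (p = 1) in a resampled replicate get a finite cap so
  # NJ stays defined: the distance at one mismatch short of saturation
  cap_saturation <- function(dm) {
    sat <- !is.finite(dm$d)
    if (any(sat)) dm$d[sat] <- log(dm$compared_sites[sat] + 1)
    dm
  }
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boot[[r]] <- suppressWarnings(
      nj_tree(cap_saturation(poisson_dist_matrix(m[, cols, drop = FALSE]))))
  }
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  support <- counts / n_reps
  tree$node.label <- format(round(support, 3))
  list(tree = tree, support = support)
}

#' Propagate subfamily labels from reference leaves
#'
#' Each unlabeled leaf inherits the subfamily of the smallest clade
#' (bipartition side of the unrooted tree) that contains it together with
#' at least one reference leaf, provided the references inside that clade
#' carry a single label; when the smallest such clade mixes labels the
#' leaf is left unassigned with a warning.
#'
#' @param tree A `phylo` tree.
#' @param reference_labels Named character vector: gene id -> subfamily.
#' @return Named character vector over all leaves (references keep their
#'   label; unresolved leaves are `NA`).
#' @export
assign_subfamilies <- function(tree, reference_labels) {
  if (!length(reference_labels)) stop("no reference labels supplied")
  tips <- tree$tip.label
  refs <- reference_labels[names(reference_labels) %in% tips]
  if (!length(refs)) stop("no reference labels match tree leaves")
  n <- length(tips)
  # both sides of every edge are candidate clades
  parts <- ape::prop.part(tree)
  sides <- list()
  for (p in parts) {
    sides[[length(sides) + 1L]] <- tips[p]
    sides[[length(sides) + 1L]] <- tips[-p]
  }
  sides <- Filter(function(s) length(s) >= 2L && length(s) < n, sides)
  sizes <- vapply(sides, length, integer(1))
  ord <- order(sizes)
  out <- stats::setNames(rep(NA_character_, n), tips)
  out[names(refs)] <- refs
  for (leaf in setdiff(tips, names(refs))) {
    assigned <- FALSE
    for (k in ord) {
      s <- sides[[k]]
      if (!(leaf %in% s)) next
      in_refs <- refs[names(refs) %in% s]
      if (!length(in_refs)) next
      labs <- unique(in_refs)
      if (length(labs) == 1L) {
        out[leaf] <- labs
      } else {
        warning("leaf ", leaf, " falls in a clade with mixed reference labels (",
                paste(labs, collapse = ", "), "); left unassigned")
      }
      assigned <- TRUE
      break
    }
    if (!assigned)
      warning("leaf ", leaf, " shares no clade with any reference; left unassigned")
  }
  out
}
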