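# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals.

GC <- Biostrings::GENETIC_CODE

# all 64 codons
oracle_codons <- function() {
  nt <- c("T", "C", "A", "G")
  as.vector(outer(outer(nt, nt, paste0), nt, paste0))
}

oracle_sense_codons <- function() {
  cods <- oracle_codons()
  cods[GC[cods] != "*"]
}

# NG86 site fractions by direct enumeration of the 9 neighbours
oracle_sites <- function(codon) {
  nt <- strsplit(codon, "")[[1]]
  aa0 <- GC[[codon]]
  s <- 0
  for (pos in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), nt[pos])) {
    mut <- nt; mut[pos] <- alt
    aa1 <- GC[[paste(mut, collapse = "")]]
    if (aa1 == aa0 && aa1 != "*") s <- s + 1
  }
  c(s = s / 3, n = 3 - s / 3)
}

# NG86 pathway-averaged differences by explicit permutation enumeration
oracle_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perm_list <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perm_list(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  score_path <- function(ord, allow_stop) {
    cur <- a; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      aa0 <- GC[[paste(cur, collapse = "")]]
      aa1 <- GC[[paste(nxt, collapse = "")]]
      if (aa1 == "*" && !allow_stop) return(NULL)
      if (aa0 == aa1 && aa1 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perm_list(pos), score_path, FALSE))
  if (!length(res))
    res <- lapply(perm_list(pos), score_path, TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# position-by-position IUPAC motif count (forward strand only)
oracle_motif_count <- function(seq, pattern) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
             S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
             H = "ACT", V = "ACG", N = "ACGT")
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  k <- length(p); n <- length(s)
  if (k > n) return(0L)
  cnt <- 0L
  for (i in seq_len(n - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1L] %in% strsplit(iupac[[p[j]]], "")[[1]]) {
        ok <- FALSE; break
      }
    }
    if (ok) cnt <- cnt + 1L
  }
  cnt
}

oracle_revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}

# minimal Dollo event count for one position on a tree: best single-gain
# placement plus the resulting number of maximal carrier-free subtrees
oracle_dollo_count <- function(tree, carriers) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(v) {
    if (v <= n_tip) return(tree$tip.label[v])
    unlist(lapply(kids[[as.character(v)]], tips_below))
  }
  losses_below <- function(v) {
    below <- tips_below(v)
    if (!any(below %in% carriers)) return(1L)  # whole subtree lost
    if (v <= n_tip) return(0L)
    sum(vapply(kids[[as.character(v)]], losses_below, integer(1)))
  }
  best <- Inf
  for (v in seq_len(n_tip + tree$Nnode)) {
    below <- tips_below(v)
    if (!all(carriers %in% below)) next
    best <- min(best, 1L + losses_below(v))
  }
  best
}

# small helper: aligned family proteins of a simulation (equal length,
# ungapped, since the simulator introduces no indels)
sim_family_alignment <- function(sim) {
  sim$proteome[sim$family_ids]
}
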