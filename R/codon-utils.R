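# Shared codon-level machinery used by the Ka/Ks estimator and the
# sequence simulator.

NUCS <- c("T", "C", "A", "G")

# transition partners (A<->G, C<->T)
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

.codon_env <- new.env(parent = emptyenv())

#' All 64 codons in TCAG order
#' @noRd
all_codons <- function() {
  if (is.null(.codon_env$codons)) {
    g <- expand.grid(p3 = NUCS, p2 = NUCS, p1 = NUCS,
                     stringsAsFactors = FALSE)
    .codon_env$codons <- paste0(g$p1, g$p2, g$p3)
  }
  .codon_env$codons
}

#' Translate a codon with the standard genetic code
#' @noRd
codon_aa <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  unname(code[codon])
}

is_stop_codon <- function(codon) codon_aa(codon) == "*"

#' Sense codons (61) under the standard code
#' @noRd
sense_codons <- function() {
  cods <- all_codons()
  cods[codon_aa(cods) != "*"]
}

#' The 9 single-nucleotide neighbours of a codon
#'
#' Returns a data.frame with the mutated codon, the position changed,
#' whether the change is a transition, whether it is synonymous, and
#' whether it creates a stop codon.
#' @noRd
codon_neighbors <- function(codon) {
  key <- paste0("nb_", codon)
  hit <- .codon_env[[key]]
  if (!is.null(hit)) return(hit)
  aa0 <- codon_aa(codon)
  nt <- strsplit(codon, "")[[1]]
  out <- vector("list", 9L)
  k <- 0L
  for (pos in 1:3) {
    for (alt in setdiff(NUCS, nt[pos])) {
      k <- k + 1L
      mut <- nt
      mut[pos] <- alt
      mutc <- paste(mut, collapse = "")
      aa1 <- codon_aa(mutc)
      out[[k]] <- data.frame(
        codon = mutc, pos = pos,
        transition = TRANSITION[[nt[pos]]] == alt,
        synonymous = aa1 == aa0 && aa1 != "*",
        to_stop = aa1 == "*",
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  assign(key, res, envir = .codon_env)
  res
}

#' Split a CDS string into codons
#' @noRd
split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  cds <- chartr("U", "T", cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length (", n, ") is not divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Validate a CDS: divisible by 3, no internal stop codons
#' @noRd
check_cds <- function(cds, allow_terminal_stop = TRUE) {
  cod <- split_codons(cds)
  internal <- if (allow_terminal_stop && length(cod) > 1L)
    cod[-length(cod)] else cod
  if (any(codon_aa(internal) == "*"))
    stop("CDS contains an internal stop codon")
  invisible(cod)
}

#' Translate a CDS string to protein (terminal stop dropped)
#' @noRd
translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(chartr("U", "T", toupper(as.character(cds)))),
    no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

#' Coerce to character while keeping names (XStringSet or vector)
#' @noRd
as_named_chr <- function(x) {
  nm <- names(x)
  y <- as.character(x)
  names(y) <- nm
  y
}

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Keeps every derived seed a valid 32-bit integer so the same master
#' seed always yields the same per-stage streams.
#' @noRd
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(master) * 7919 + h * 104729) %% 2147483587)
}
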