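# End-to-end orchestration: a single validated configuration drives the
# stages (identify -> tree -> duplication/KaKs -> introns -> expression
# -> promoter), writes intermediate TSV artifacts, and emits a run
# report.

PIPELINE_STAGES <- c("identify", "tree", "duplication", "introns",
                     "expression", "promoter")

config_defaults <- function() {
  list(seed = 1L, out_dir = "gelpfam_out",
       stages = stats::setNames(as.list(rep(TRUE, length(PIPELINE_STAGES))),
                                PIPELINE_STAGES),
       inputs = list(proteome = NULL, seed_alignment = NULL, cds = NULL,
                     gff = NULL, alignment = NULL, subfamilies = NULL,
                     expression = NULL, samples = NULL, genome = NULL,
                     motifs = NULL),
       params = list(evalue = 1e-20, coverage = 0.8, identity = 0.8,
                     max_intervening = 4L, bootstrap = 1000L,
                     fc_threshold = 2, p_threshold = 0.01,
                     promoter_length = 2000L, basic_form_threshold = 0.5,
                     min_domain_coverage = 0.6))
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; fills defaults (which
#' mirror the published thresholds: E-value 1e-20, coverage/identity
#' 0.8, 1000 bootstrap replicates, fold-change 2 and p 0.01, 2000-bp
#' promoters), type- and range-checks every parameter, rejects unknown
#' keys, and verifies that every enabled stage has its required inputs.
#' All problems are collected and reported together.
#'
#' @param config Path to a YAML file, or a list with any of the keys
#'   `seed`, `out_dir`, `stages`, `inputs`, `params`.
#' @return A validated configuration of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defs <- config_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    errors <- c(errors, paste0("unknown top-level keys: ",
                               paste(unknown, collapse = ", ")))
  for (blk in c("stages", "inputs", "params")) {
    extra <- setdiff(names(config[[blk]]), names(defs[[blk]]))
    if (length(extra))
      errors <- c(errors, paste0("unknown ", blk, " keys: ",
                                 paste(extra, collapse = ", ")))
    defs[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  if (!is.null(config$seed)) defs$seed <- config$seed
  if (!is.null(config$out_dir)) defs$out_dir <- config$out_dir
  p <- defs$params
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(is.numeric(defs$seed) && defs$seed == round(defs$seed),
      "seed must be an integer")
  chk(is.numeric(p$evalue) && p$evalue > 0, "evalue must be positive")
  chk(is.numeric(p$coverage) && p$coverage >= 0 && p$coverage <= 1,
      "coverage must lie in [0, 1]")
  chk(is.numeric(p$identity) && p$identity >= 0 && p$identity <= 1,
      "identity must lie in [0, 1]")
  chk(is.numeric(p$max_intervening) && p$max_intervening >= 0,
      "max_intervening must be >= 0")
  chk(is.numeric(p$bootstrap) && p$bootstrap >= 1,
      "bootstrap must be >= 1")
  chk(is.numeric(p$fc_threshold) && p$fc_threshold >= 1,
      "fc_threshold must be >= 1")
  chk(is.numeric(p$p_threshold) && p$p_threshold >= 0 && p$p_threshold <= 1,
      "p_threshold must lie in [0, 1]")
  chk(is.numeric(p$promoter_length) && p$promoter_length > 0,
      "promoter_length must be positive")
  chk(is.numeric(p$basic_form_threshold) && p$basic_form_threshold >= 0 &&
        p$basic_form_threshold < 1,
      "basic_form_threshold must lie in [0, 1)")
  for (st in PIPELINE_STAGES)
    chk(is.logical(defs$stages[[st]]) || defs$stages[[st]] %in% c(0, 1),
        paste0("stage toggle ", st, " must be logical"))
  need <- list(identify = c("proteome", "seed_alignment"),
               tree = "alignment", duplication = c("cds", "gff"),
               introns = c("gff", "cds", "alignment", "subfamilies"),
               expression = c("expression", "samples"),
               promoter = c("gff", "cds", "genome"))
  for (st in PIPELINE_STAGES) {
    if (!isTRUE(as.logical(defs$stages[[st]]))) next
    for (inp in need[[st]]) {
      if (is.null(defs$inputs[[inp]]))
        errors <- c(errors, paste0("stage '", st, "' enabled but input '",
                                   inp, "' missing"))
      else if (!file.exists(defs$inputs[[inp]]))
        errors <- c(errors, paste0("input file not found: ",
                                   defs$inputs[[inp]]))
    }
  }
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  structure(defs, class = "run_config")
}

#' Read gene models from a GFF3 file plus a CDS FASTA
#'
#' CDS features are grouped by transcript (Parent attribute or, failing
#' that, the gene ID), ordered in transcript orientation, and combined
#' with the spliced CDS sequence of the same id.
#'
#' @param gff_path GFF3 file.
#' @param cds CDS sequences (named character vector, `DNAStringSet`, or
#'   FASTA path).
#' @param subfamilies Optional named character vector gene id ->
#'   subfamily.
#' @return Named list of `gene_model`s.
#' @export
read_gene_models <- function(gff_path, cds, subfamilies = NULL) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds))
    cds <- Biostrings::readDNAStringSet(cds)
  cds <- as_named_chr(cds)
  names(cds) <- sub("\\s.*$", "", names(cds))
  gff <- utils::read.delim(gff_path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("seqid", "source", "type", "start",
                                         "end", "score", "strand", "phase",
                                         "attributes"))
  cdsf <- gff[gff$type == "CDS", , drop = FALSE]
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]+"), attrs))
    ifelse(lengths(regmatches(attrs, gregexpr(paste0(key, "=[^;]+"), attrs))) > 0,
           sub(paste0(key, "="), "", m), NA_character_)
  }
  parent <- attr_field(cdsf$attributes, "Parent")
  gene_id <- sub("\\.\\d+$", "", parent)
  models <- list()
  for (g in unique(gene_id)) {
    rows <- cdsf[gene_id == g, , drop = FALSE]
    strand <- rows$strand[1L]
    rows <- rows[order(rows$start, decreasing = (strand == "-")), ,
                 drop = FALSE]
    if (!g %in% names(cds))
      stop("no CDS sequence for gene ", g)
    models[[g]] <- gene_model(g, rows$seqid[1L], strand,
                              cbind(start = rows$start, end = rows$end),
                              cds[[g]],
                              subfamily = if (!is.null(subfamilies))
                                unname(subfamilies[g]) else NULL)
  }
  models
}

#' Run the full pipeline from a validated configuration
#'
#' Executes the enabled stages in dependency order, writes per-stage TSV
#' artifacts into the output directory, and returns (and writes) a run
#' report with record counts, the parameter echo and the master seed.
#' A stage failure aborts with the stage name; artifacts of completed
#' stages are retained.
#'
#' @param config A `run_config` (or anything accepted by
#'   [validate_config()]).
#' @return A `run_report` (invisibly written to
#'   `<out_dir>/report.yaml` and `report.txt`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  report <- list(seed = config$seed, parameters = p, stages = list(),
                 warnings = character())
  note <- function(st, ...) report$stages[[st]] <<- list(...)
  run_stage <- function(st, fn) {
    if (!isTRUE(as.logical(config$stages[[st]]))) return(invisible())
    tryCatch(withCallingHandlers(fn(), warning = function(w) {
      report$warnings <<- c(report$warnings,
                            paste0(st, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e)
      stop("stage '", st, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  tsv <- function(x, name) {
    utils::write.table(x, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  members <- NULL

  run_stage("identify", function() {
    proteome <- as.character(Biostrings::readAAStringSet(config$inputs$proteome))
    names(proteome) <- sub("\\s.*$", "", names(proteome))
    seed_aln <- as.character(Biostrings::readAAStringSet(config$inputs$seed_alignment))
    res <- iterative_search(seed_aln, proteome, e_threshold = p$evalue,
                            min_coverage = p$min_domain_coverage,
                            seed = derive_seed(config$seed, "identify"))
    tsv(res$pass2 %||% res$pass1, "family_hits.tsv")
    members <<- res$members
    note("identify", n_members = length(res$members),
         n_pass1 = nrow(res$pass1),
         n_pass2 = if (is.null(res$pass2)) 0L else nrow(res$pass2))
  })

  run_stage("tree", function() {
    aln <- as.character(Biostrings::readAAStringSet(config$inputs$alignment))
    names(aln) <- sub("\\s.*$", "", names(aln))
    bs <- bootstrap_support(aln, n_reps = p$bootstrap,
                            seed = derive_seed(config$seed, "tree"))
    ape::write.tree(bs$tree, file.path(config$out_dir, "family_tree.nwk"))
    note("tree", n_leaves = length(bs$tree$tip.label),
         n_bootstrap = as.integer(p$bootstrap))
  })

  run_stage("duplication", function() {
    cds <- as.character(Biostrings::readDNAStringSet(config$inputs$cds))
    names(cds) <- sub("\\s.*$", "", names(cds))
    if (!is.null(members)) cds <- cds[intersect(members, names(cds))]
    models <- read_gene_models(config$inputs$gff, config$inputs$cds)
    by_chr <- split(vapply(models, `[[`, character(1), "gene_id"),
                    vapply(models, `[[`, character(1), "chromosome"))
    starts <- vapply(models, function(m) min(m$exons), numeric(1))
    gene_order <- lapply(by_chr, function(g) g[order(starts[g])])
    pairs <- duplicate_pair_table(cds, gene_order = gene_order,
                                  min_coverage = p$coverage,
                                  min_identity = p$identity,
                                  max_intervening = p$max_intervening)
    tsv(pairs, "duplicate_pairs.tsv")
    hist <- kaks_histogram(pairs)
    tsv(hist$table, "kaks_histogram.tsv")
    note("duplication", n_pairs = nrow(pairs),
         n_tandem = sum(pairs$mode == "tandem"),
         n_segmental = sum(pairs$mode == "segmental"),
         mean_omega = if (any(is.finite(pairs$omega)))
           mean(pairs$omega[is.finite(pairs$omega)]) else NA)
  })

  run_stage("introns", function() {
    subf <- utils::read.delim(config$inputs$subfamilies,
                              stringsAsFactors = FALSE)
    subfamilies <- stats::setNames(subf$subfamily, subf$gene_id)
    models <- read_gene_models(config$inputs$gff, config$inputs$cds,
                               subfamilies = subfamilies)
    models <- models[names(models) %in% names(subfamilies)]
    aln <- as.character(Biostrings::readAAStringSet(config$inputs$alignment))
    names(aln) <- sub("\\s.*$", "", names(aln))
    sites <- lapply(models, extract_intron_sites)
    mat <- project_sites(sites, aln[names(models)])
    forms <- list()
    for (sf in unique(subfamilies)) {
      mem <- intersect(names(subfamilies)[subfamilies == sf], mat$genes)
      if (length(mem) >= 2L)
        forms[[sf]] <- basic_form(mat, mem, p$basic_form_threshold)
    }
    events <- classify_events(mat, forms, subfamilies[mat$genes])
    anc <- ancestral_model(forms)
    counts <- intron_count_table(data.frame(
      subfamily = unname(subfamilies[names(models)]),
      introns = vapply(models, function(m) nrow(m$exons) - 1L, integer(1))))
    tsv(data.frame(gene = mat$genes, mat$presence, check.names = FALSE),
        "intron_matrix.tsv")
    tsv(events, "intron_events.tsv")
    tsv(data.frame(subfamily = rownames(counts), counts,
                   check.names = FALSE), "intron_counts.tsv")
    note("introns", n_positions = nrow(mat$positions),
         n_events = nrow(events), ancestral_positions = length(anc))
  })

  run_stage("expression", function() {
    fp <- utils::read.delim(config$inputs$expression, check.names = FALSE,
                            stringsAsFactors = FALSE)
    fpkm <- as.matrix(fp[, -1, drop = FALSE])
    rownames(fpkm) <- fp[[1L]]
    samples <- utils::read.delim(config$inputs$samples,
                                 stringsAsFactors = FALSE)
    de <- de_filter(compute_contrasts(fpkm, samples),
                    fc_threshold = p$fc_threshold,
                    p_threshold = p$p_threshold)
    summ <- regulation_summary(de)
    tsv(de, "de_results.tsv")
    tsv(summ, "de_summary.tsv")
    note("expression", n_genes = nrow(fpkm), n_contrasts = nrow(summ),
         n_responsive = sum(summ$n_responsive))
  })

  run_stage("promoter", function() {
    genome <- as.character(Biostrings::readDNAStringSet(config$inputs$genome))
    names(genome) <- sub("\\s.*$", "", names(genome))
    models <- read_gene_models(config$inputs$gff, config$inputs$cds)
    if (!is.null(members)) models <- models[names(models) %in% members]
    motifs <- if (is.null(config$inputs$motifs)) default_motifs() else
      yaml::read_yaml(config$inputs$motifs)
    counts <- t(vapply(models, function(m)
      scan_elements(extract_promoter(m, genome, p$promoter_length), motifs),
      integer(length(motifs))))
    tab <- element_table(as.data.frame(counts, check.names = FALSE))
    tsv(tab, "promoter_elements.tsv")
    note("promoter", n_genes = length(models), n_elements = length(motifs))
  })

  class(report) <- "run_report"
  yaml::write_yaml(unclass(report), file.path(config$out_dir, "report.yaml"))
  writeLines(utils::capture.output(print(report)),
             file.path(config$out_dir, "report.txt"))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("gelpfam run report (seed ", x$seed, ")\n", sep = "")
  for (st in names(x$stages)) {
    rec <- x$stages[[st]]
    cat("  ", st, ": ",
        paste(names(rec), unlist(lapply(rec, format)), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
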