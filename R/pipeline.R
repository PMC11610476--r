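# End-to-end pipeline: scan -> classify -> physicochemical profile, plus
# the genomics, expression and stress stages when their inputs are present.
# Every run writes its resolved configuration and a manifest beside the
# reports; re-running with the same inputs and config reproduces
# byte-identical files.

#' Pipeline configuration
#'
#' Bundles the tunables of every stage with a single seed. The resolved
#' configuration is written beside the outputs of [run_pipeline()].
#'
#' @param seed Integer seed for every source of randomness.
#' @param grammar A [finger_grammar()].
#' @param classify A [classify_config()].
#' @param name_prefix Gene-name prefix for the nomenclature stage.
#' @param expression_threshold FPKM expression filter threshold.
#' @param k_profiles Profile-group count for expression clustering.
#' @param max_intervening,min_identity Tandem-duplication thresholds.
#' @param alpha Significance level for stress statistics.
#' @param p_adjust P-value adjustment for the correlation grid
#'   (`"none"` or a [stats::p.adjust()] method).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, grammar = finger_grammar(),
                            classify = classify_config(),
                            name_prefix = "ZF",
                            expression_threshold = 1, k_profiles = 7,
                            max_intervening = 1, min_identity = 70,
                            alpha = 0.05, p_adjust = "none") {
  structure(list(seed = as.integer(seed), grammar = grammar,
                 classify = classify, name_prefix = name_prefix,
                 expression_threshold = expression_threshold,
                 k_profiles = k_profiles,
                 max_intervening = max_intervening,
                 min_identity = min_identity, alpha = alpha,
                 p_adjust = p_adjust),
            class = "pipeline_config")
}

.config_as_list <- function(config) {
  list(seed = config$seed,
       grammar = unclass(config$grammar),
       classify = unclass(config$classify),
       name_prefix = config$name_prefix,
       expression_threshold = config$expression_threshold,
       k_profiles = config$k_profiles,
       max_intervening = config$max_intervening,
       min_identity = config$min_identity,
       alpha = config$alpha, p_adjust = config$p_adjust)
}

#' Run the full analysis pipeline
#'
#' Minimal input is the protein FASTA: the finger scan, classification and
#' physicochemical profile are always produced. When gene models are given,
#' the nomenclature, chromosome distribution, exon/intron and
#' tandem-duplication stages run; an FPKM matrix adds the expression
#' filter/transform/clustering stage; an enzyme panel adds the stress
#' summaries, letter groups and (with expression) the correlation grid.
#' Missing optional inputs skip their stages with a notice, never an error.
#'
#' @param fasta Path to the protein FASTA.
#' @param outdir Output directory (created if needed).
#' @param gff Optional path to a GFF3 file of gene models.
#' @param fpkm Optional path to a TSV matrix (genes x samples, header row,
#'   first column gene ids).
#' @param panel Optional path to a long-format CSV panel (`treatment`,
#'   `replicate`, `analyte`, `value`).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   of all written reports.
#' @export
run_pipeline <- function(fasta, outdir, gff = NULL, fpkm = NULL,
                         panel = NULL, config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  out <- list(files = character())
  emit <- function(x, name) {
    path <- file.path(outdir, name)
    write_tsv_report(x, path)
    out$files <<- c(out$files, path)
    path
  }
  notice <- function(...) message("[zfx] ", ...)

  proteins <- read_protein_fasta(fasta)
  notice(nrow(proteins), " proteins read")

  fingers <- scan_proteome(proteins, config$grammar)
  emit(fingers[, setdiff(names(fingers), "helix")], "fingers.tsv")
  cls <- classify_proteome(proteins, config$grammar, config$classify)
  emit(cls$records, "classification.tsv")
  jsonlite::write_json(cls$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$files <- c(out$files, file.path(outdir, "summary.json"))
  props <- profile_table(proteins)
  props$mw <- round(props$mw, 2)
  props$pi <- round(props$pi, 2)
  props$instability <- round(props$instability, 2)
  props$gravy <- round(props$gravy, 4)
  emit(props, "props.tsv")
  out$classification <- cls
  out$fingers <- fingers
  out$props <- props

  if (!is.null(gff)) {
    genes <- read_gene_models(gff)
    names_map <- assign_gene_names(genes, config$name_prefix)
    emit(names_map, "names.tsv")
    dist <- chromosome_distribution(genes)
    emit(data.frame(chromosome = names(dist), n_genes = as.integer(dist)),
         "chromosomes.tsv")
    struct <- exon_intron_structure(genes)
    emit(struct$per_gene, "exons.tsv")
    pairs <- detect_tandem_duplicates(genes, proteins,
                                      config$max_intervening,
                                      config$min_identity)
    pairs$identity <- round(pairs$identity, 2)
    emit(pairs, "tandem_pairs.tsv")
    out$genes <- genes; out$names <- names_map; out$tandem_pairs <- pairs
  } else {
    notice("no gene models; genomic stages skipped")
  }

  expr <- NULL
  if (!is.null(fpkm)) {
    raw <- utils::read.delim(fpkm, check.names = FALSE)
    expr <- as.matrix(raw[, -1, drop = FALSE])
    rownames(expr) <- raw[[1]]
    kept <- filter_expressed(expr, config$expression_threshold)
    notice(nrow(kept), " of ", nrow(expr), " genes expressed")
    grouping <- cluster_profiles(log2_transform(kept), config$k_profiles)
    emit(data.frame(gene_id = names(grouping$groups),
                    group = grouping$groups), "profile_groups.tsv")
    out$expressed <- kept; out$grouping <- grouping
  } else {
    notice("no FPKM matrix; expression stage skipped")
  }

  if (!is.null(panel)) {
    pan <- utils::read.csv(panel)
    summ <- summarize_panel(pan)
    summ$mean <- round(summ$mean, 4); summ$sd <- round(summ$sd, 4)
    emit(summ, "panel_summary.tsv")
    letter_rows <- do.call(rbind, lapply(unique(pan$analyte), function(an) {
      sl <- significance_letters(pan, an, config$alpha)
      data.frame(analyte = an, treatment = names(sl$letters),
                 mean = round(unname(sl$means), 4),
                 letters = unname(sl$letters), stringsAsFactors = FALSE)
    }))
    emit(letter_rows, "panel_letters.tsv")
    if (!is.null(expr)) {
      phys <- .panel_to_matrix(pan)
      kept <- filter_expressed(expr, config$expression_threshold)
      corr <- correlate_expression(.expr_to_treatment_means(kept,
                                                            colnames(phys)),
                                   phys, config$alpha, config$p_adjust)
      corr$r <- round(corr$r, 4)
      corr$p <- signif(corr$p, 4)
      emit(corr, "correlations.tsv")
      out$correlations <- corr
    }
    out$panel_summary <- summ; out$panel_letters <- letter_rows
  } else {
    notice("no enzyme panel; stress stage skipped")
  }

  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(.config_as_list(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE)
  inputs <- c(fasta = fasta, gff = gff, fpkm = fpkm, panel = panel)
  manifest <- list(inputs = as.list(inputs),
                   input_md5 = as.list(tools::md5sum(unlist(inputs))),
                   reports = basename(out$files),
                   seed = config$seed)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$files <- c(out$files, cfg_path, file.path(outdir, "manifest.json"))
  invisible(out)
}

# treatment-mean matrix analytes x treatments from a long panel
.panel_to_matrix <- function(panel) {
  ans <- unique(panel$analyte)
  trts <- unique(panel$treatment)
  m <- matrix(NA_real_, length(ans), length(trts),
              dimnames = list(ans, trts))
  for (a in ans) for (t in trts) {
    m[a, t] <- mean(panel$value[panel$analyte == a & panel$treatment == t])
  }
  m
}

# collapse expression columns named like "CK_1"/"CK" to treatment means in
# the given treatment order
.expr_to_treatment_means <- function(expr, treatments) {
  trt_of <- sub("[_.].*$", "", colnames(expr))
  keep <- trt_of %in% treatments
  expr <- expr[, keep, drop = FALSE]
  trt_of <- trt_of[keep]
  m <- vapply(treatments, function(t)
    rowMeans(expr[, trt_of == t, drop = FALSE]), numeric(nrow(expr)))
  m <- matrix(m, nrow = nrow(expr),
              dimnames = list(rownames(expr), treatments))
  m
}
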