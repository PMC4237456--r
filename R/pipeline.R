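#' Configuration of an end-to-end pipeline run
#'
#' Collects input paths, thresholds and flags for [run_all()]. Thresholds
#' default to the analysis' published operating points: feature screen and
#' association at p < 1.0E-03 with OR > 1.0, per-gene differential
#' expression at p < 0.05.
#'
#' @param genes path to gene annotation.
#' @param chrom_sizes path to the chromosome sizes TSV.
#' @param l1 path to the L1 element table.
#' @param expression optional path to the expression TSV.
#' @param l1_genes optional path to a file of L1-hosting gene ids (one per
#'   line); when absent the set is derived from the classification step.
#' @param ortholog_pairs,other_common_set optional paths enabling the
#'   ortholog join: a two-column pair table and the other species' common
#'   gene set (one id per line).
#' @param outdir output directory.
#' @param dialect gene annotation dialect, `"gff3"` or `"bed12"`.
#' @param species label copied into reports.
#' @param alpha_feature,alpha_de,alpha_assoc,or_min thresholds.
#' @param reference reference stage.
#' @param stages optional stage subset for the association screen.
#' @param collapse duplicate-gene handling for [read_expression()].
#' @param correct continuity-correction flag for the chi-square statistics.
#' @param skip_expression run only classification, density and conservation.
#' @return list of class `run_config`.
#' @export
run_config <- function(genes, chrom_sizes, l1, outdir,
                       expression = NULL, l1_genes = NULL,
                       ortholog_pairs = NULL, other_common_set = NULL,
                       dialect = "gff3", species = "synthetic",
                       alpha_feature = 1e-3, alpha_de = 0.05,
                       alpha_assoc = 1e-3, or_min = 1.0,
                       reference = "1-cell", stages = NULL,
                       collapse = "none", correct = FALSE,
                       skip_expression = FALSE) {
  thr <- c(alpha_feature, alpha_de, alpha_assoc)
  if (any(thr <= 0 | thr >= 1)) stop("thresholds must lie in (0, 1)")
  if (or_min < 0) stop("or_min must be >= 0")
  structure(list(genes = genes, chrom_sizes = chrom_sizes, l1 = l1,
                 expression = expression, l1_genes = l1_genes,
                 ortholog_pairs = ortholog_pairs,
                 other_common_set = other_common_set,
                 outdir = outdir, dialect = dialect, species = species,
                 alpha_feature = alpha_feature, alpha_de = alpha_de,
                 alpha_assoc = alpha_assoc, or_min = or_min,
                 reference = reference, stages = stages,
                 collapse = collapse, correct = correct,
                 skip_expression = skip_expression),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes classification, density, the conservation screen, the
#' expression association screen, cross-stage intersections and (when pair
#' inputs are configured) the ortholog join, writing one TSV per stage plus
#' a JSON run manifest (configuration echo, input checksums, package
#' version, decision flags). Outputs contain no timestamps, so a rerun on
#' identical inputs is byte-identical.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @return invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- run_config_from_yaml(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  paths <- character(0)

  genes <- read_gene_annotation(config$genes, config$dialect)
  sizes <- read_chrom_sizes(config$chrom_sizes)
  l1 <- read_l1_table(config$l1)
  spans <- gene_span(genes)

  classified <- classify_location(l1, spans)
  write_l1_table(classified, out("classified.tsv"))
  paths <- c(paths, out("classified.tsv"))

  dens <- compute_densities(classified, spans, sizes, species = config$species)
  write_tsv_file(dens, out("density.tsv"))
  paths <- c(paths, out("density.tsv"))

  summ <- intragenic_summary(classified)
  write_tsv_file(as.data.frame(summ), out("summary.tsv"))
  paths <- c(paths, out("summary.tsv"))

  manifest <- feature_manifest(classified)
  conserve <- run_feature_screen(classified, manifest,
                                 alpha = config$alpha_feature,
                                 correct = config$correct)
  write_tsv_file(conserve, out("conservation.tsv"))
  paths <- c(paths, out("conservation.tsv"))

  screen <- NULL; common <- NULL; ortho <- NULL
  if (!config$skip_expression && !is.null(config$expression)) {
    expr <- read_expression(config$expression, collapse = config$collapse)
    l1_set <- if (!is.null(config$l1_genes)) {
      readLines(config$l1_genes, warn = FALSE)
    } else {
      hosts <- classified$overlapped_gene_ids
      sort(unique(unlist(strsplit(hosts[nzchar(hosts)], ",", fixed = TRUE))))
    }
    screen <- run_stage_screen(expr, l1_set, stages = config$stages,
                               reference = config$reference,
                               alpha_de = config$alpha_de,
                               alpha = config$alpha_assoc,
                               or_min = config$or_min)
    write_tsv_file(screen$assoc, out("assoc.tsv"))
    de_all <- do.call(rbind, screen$de)
    rownames(de_all) <- NULL
    write_tsv_file(de_all, out("de.tsv"))
    paths <- c(paths, out("assoc.tsv"), out("de.tsv"))

    common <- common_regulated_genes(screen, "down")
    writeLines(common$common, out("common_down_genes.txt"))
    write_tsv_file(common$regions, out("venn_regions.tsv"))
    paths <- c(paths, out("common_down_genes.txt"), out("venn_regions.tsv"))

    if (!is.null(config$ortholog_pairs) && !is.null(config$other_common_set)) {
      pairs <- read.delim(config$ortholog_pairs, stringsAsFactors = FALSE)
      other <- readLines(config$other_common_set, warn = FALSE)
      ortho <- map_orthologs(common$common, other, pairs)
      write_tsv_file(ortho$pairs, out("ortholog_pairs_matched.tsv"))
      paths <- c(paths, out("ortholog_pairs_matched.tsv"))
    }
  }

  inputs <- Filter(Negate(is.null),
                   config[c("genes", "chrom_sizes", "l1", "expression",
                            "l1_genes", "ortholog_pairs", "other_common_set")])
  manifest_json <- list(
    tool = "l1census",
    version = as.character(packageVersion("l1census")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    decisions = list(
      overlap_rule = "element counted once, attributed to every overlapped gene",
      continuity_correction = config$correct,
      intragenic = "total or partial overlap (>= 1 bp) with union of gene spans",
      rest_definition = "all tested genes not called in the given direction"
    ))
  jsonlite::write_json(manifest_json, out("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, out("run_manifest.json"))

  invisible(list(classified = classified, densities = dens, summary = summ,
                 conservation = conserve, screen = screen, common = common,
                 orthologs = ortho, paths = paths))
}
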