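# Mouse-shaped default feature panel: 42 categorical structural features
# (promoter motifs, ORF boundaries, conserved residues, splice sites, poly-A
# terminator) and 11 quantitative ones (intactness/GC scores, monomer counts,
# ORF gap/stop/frameshift counts). The counts match the panel sizes of
# full-length-L1 database annotation for mouse.
default_categorical_features <- function() {
  f <- c("UTR5_promoter_motif", "UTR5_antisense_SA154_splice",
         sprintf("ORF1_residue_%02d", 1:12),
         "ORF1_start_codon", "ORF1_stop_codon", "ORF1_leucine_zipper",
         "ORF2_C_domain",
         sprintf("ORF2_residue_%02d", 1:18),
         "ORF2_start_codon", "ORF2_stop_codon",
         "ORF2_EN_domain", "ORF2_RT_domain",
         "UTR3_polyA_signal", "UTR3_G_rich_motif")
  stopifnot(length(f) == 42L)
  f
}

default_quantitative_features <- function() {
  c("intactness_score", "gc_content", "n_monomers", "n_monomer_splice_sites",
    "orf1_gaps", "orf1_stop_codons", "orf1_frameshifts",
    "orf2_gaps", "orf2_stop_codons", "orf2_frameshifts", "cpg_count")
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator with validation. Defaults emulate a
#' desk-scale mouse-like study: 19 autosomes plus X and Y, a genic fraction
#' near 30%, four L1 subfamilies weighted by their genome-wide abundance
#' (F, A, T_F, G_F), 42 categorical plus 11 quantitative structural
#' features, and a six-stage preimplantation expression design (1-cell to
#' blastocyst, 3 replicates) in which genes hosting an intragenic L1 are
#' down-regulated more often than others.
#'
#' Probabilities may be scalars, per-feature named vectors, or
#' feature-by-subfamily matrices; quantitative means may be scalars or
#' per-feature vectors; `p_down_given_l1`/`p_down_given_no_l1` may be
#' scalars or one value per non-reference stage.
#'
#' @param seed single integer driving every stream (one derived stream per
#'   generator sub-step, so generators do not perturb each other).
#' @param n_autosomes number of autosomes (X and Y are always added).
#' @param chrom_length_bp chromosome length in bp; scalar or one value per
#'   chromosome.
#' @param n_genes_per_chrom,gene_span_bp gene count per chromosome and
#'   (min, max) span.
#' @param n_l1_per_chrom,l1_length_bp element count per chromosome and
#'   element length (scalar or (min, max)).
#' @param subfamily_labels,subfamily_weights subfamily panel and sampling
#'   weights.
#' @param feature_names_categorical,feature_names_quantitative feature panel.
#' @param p_conserved_intragenic,p_conserved_intergenic Bernoulli
#'   probabilities of the conserved state per location class.
#' @param quant_means_intragenic,quant_means_intergenic,quant_sd normal
#'   parameters of quantitative features per location class.
#' @param n_genes_expr gene count for stand-alone expression simulation.
#' @param stages ordered stage labels; the first is the reference.
#' @param n_replicates replicates per stage (>= 2).
#' @param baseline_mean,baseline_sd,noise_sd log2-scale baseline and noise.
#' @param planted_down_effect log2 effect added to genes selected down
#'   (negative).
#' @param p_down_given_l1,p_down_given_no_l1 per-stage probabilities that a
#'   gene is selected down, conditional on hosting an L1 or not.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_autosomes = 19L,
                              chrom_length_bp = 10e6,
                              n_genes_per_chrom = 100L,
                              gene_span_bp = c(5000L, 50000L),
                              n_l1_per_chrom = 200L,
                              l1_length_bp = 7000L,
                              subfamily_labels = c("F", "A", "T_F", "G_F"),
                              subfamily_weights = c(2602, 6336, 4940, 1622),
                              feature_names_categorical = default_categorical_features(),
                              feature_names_quantitative = default_quantitative_features(),
                              p_conserved_intragenic = 0.8,
                              p_conserved_intergenic = 0.5,
                              quant_means_intragenic = 1,
                              quant_means_intergenic = 0,
                              quant_sd = 1,
                              n_genes_expr = 2000L,
                              stages = c("1-cell", "2-cell", "4-cell",
                                         "8-cell", "morula", "blastocyst"),
                              n_replicates = 3L,
                              baseline_mean = 8,
                              baseline_sd = 2,
                              noise_sd = 0.25,
                              planted_down_effect = -2,
                              p_down_given_l1 = 0.30,
                              p_down_given_no_l1 = 0.20) {
  cfg <- list(seed = as.integer(seed), n_autosomes = as.integer(n_autosomes),
              chrom_length_bp = chrom_length_bp,
              n_genes_per_chrom = as.integer(n_genes_per_chrom),
              gene_span_bp = as.integer(gene_span_bp),
              n_l1_per_chrom = as.integer(n_l1_per_chrom),
              l1_length_bp = as.integer(l1_length_bp),
              subfamily_labels = subfamily_labels,
              subfamily_weights = subfamily_weights,
              feature_names_categorical = feature_names_categorical,
              feature_names_quantitative = feature_names_quantitative,
              p_conserved_intragenic = p_conserved_intragenic,
              p_conserved_intergenic = p_conserved_intergenic,
              quant_means_intragenic = quant_means_intragenic,
              quant_means_intergenic = quant_means_intergenic,
              quant_sd = quant_sd,
              n_genes_expr = as.integer(n_genes_expr),
              stages = stages, n_replicates = as.integer(n_replicates),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, planted_down_effect = planted_down_effect,
              p_down_given_l1 = p_down_given_l1,
              p_down_given_no_l1 = p_down_given_no_l1)
  probs <- c(cfg$p_conserved_intragenic, cfg$p_conserved_intergenic,
             cfg$p_down_given_l1, cfg$p_down_given_no_l1)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$chrom_length_bp <= 0)) stop("chrom_length_bp must be positive")
  if (length(cfg$gene_span_bp) != 2L || cfg$gene_span_bp[1] > cfg$gene_span_bp[2] ||
      cfg$gene_span_bp[1] < 10L) {
    stop("gene_span_bp must be (min, max) with min >= 10")
  }
  if (length(cfg$subfamily_weights) != length(cfg$subfamily_labels)) {
    stop("subfamily_weights must match subfamily_labels")
  }
  if (anyDuplicated(cfg$stages)) stop("duplicate stage labels")
  if (cfg$noise_sd < 0 || cfg$baseline_sd < 0 || cfg$quant_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  structure(cfg, class = "sim_config")
}

sim_chromosomes <- function(config) {
  chroms <- c(paste0("chr", seq_len(config$n_autosomes)), "chrX", "chrY")
  len <- config$chrom_length_bp
  if (!is.null(names(len))) {
    if (!all(chroms %in% names(len))) stop("chrom_length_bp names must cover all chromosomes")
    len <- len[chroms]
  } else {
    len <- rep_len(len, length(chroms))
  }
  data.frame(chrom = chroms, length = as.numeric(len), stringsAsFactors = FALSE)
}

#' Simulate a genome annotation
#'
#' Places genes uniformly along each chromosome (overlaps between genes are
#' allowed, as in real genomes; downstream logic merges spans). Each gene
#' receives 1-3 transcripts with 1-5 exons, exon boundaries drawn as sorted
#' distinct positions inside the transcript. Chromosome names follow
#' `chr1..chrN, chrX, chrY`.
#'
#' @param config a [simulation_config()].
#' @return list: `genes` (exon table as in [read_gene_annotation()]) and
#'   `chrom_sizes` (data.frame `chrom`, `length`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, "genome"))
  sizes <- sim_chromosomes(config)
  ng <- config$n_genes_per_chrom
  if (ng > 0 && config$gene_span_bp[2] > min(sizes$length)) {
    stop("gene_span_bp max (", config$gene_span_bp[2],
         ") exceeds shortest chromosome (", min(sizes$length), " bp)")
  }
  cols <- list(gene_id = character(0), transcript_id = character(0),
               chrom = character(0), strand = character(0),
               start = integer(0), end = integer(0))
  acc <- list(); k <- 0L
  for (ci in seq_len(nrow(sizes))) {
    if (ng == 0L) next
    chrom <- sizes$chrom[ci]; L <- sizes$length[ci]
    width <- floor(runif(ng, config$gene_span_bp[1], config$gene_span_bp[2] + 1))
    gstart <- floor(runif(ng, 0, L - width))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    for (g in seq_len(ng)) {
      gid <- sprintf("%s_g%04d", chrom, g)
      n_tx <- sample(1:3, 1)
      for (t in seq_len(n_tx)) {
        n_ex <- sample(1:5, 1)
        pos <- sort(sample.int(width[g], 2L * n_ex)) - 1L + gstart[g]
        k <- k + 1L
        acc[[k]] <- list(gene_id = rep(gid, n_ex),
                         transcript_id = rep(sprintf("%s_t%d", gid, t), n_ex),
                         chrom = rep(chrom, n_ex),
                         strand = rep(strand[g], n_ex),
                         start = as.integer(pos[seq(1, 2 * n_ex, 2)]),
                         end = as.integer(pos[seq(2, 2 * n_ex, 2)]))
      }
    }
  }
  genes <- if (k == 0L) as.data.frame(cols, stringsAsFactors = FALSE) else
    data.frame(gene_id = unlist(lapply(acc, `[[`, "gene_id")),
               transcript_id = unlist(lapply(acc, `[[`, "transcript_id")),
               chrom = unlist(lapply(acc, `[[`, "chrom")),
               strand = unlist(lapply(acc, `[[`, "strand")),
               start = unlist(lapply(acc, `[[`, "start")),
               end = unlist(lapply(acc, `[[`, "end")),
               stringsAsFactors = FALSE)
  list(genes = genes, chrom_sizes = sizes)
}

# Resolve a probability/mean spec (scalar, per-feature vector, or
# feature x stratum matrix) to a full feature x stratum matrix.
resolve_param <- function(p, features, strata) {
  if (is.matrix(p)) {
    stopifnot(nrow(p) == length(features), ncol(p) == length(strata))
    m <- p
  } else if (!is.null(names(p))) {
    stopifnot(all(features %in% names(p)))
    m <- matrix(p[features], length(features), length(strata))
  } else {
    m <- matrix(rep_len(p, length(features)), length(features), length(strata))
  }
  dimnames(m) <- list(features, strata)
  m
}

#' Simulate an L1 element table with planted feature structure
#'
#' Drops elements uniformly on each chromosome, assigns subfamilies by the
#' configured weights, computes each element's true location class against
#' the simulated gene spans, and then plants the feature structure: each
#' categorical feature is conserved with probability
#' `p_conserved_intragenic` or `p_conserved_intergenic` according to the
#' true class (optionally per feature and per subfamily stratum), and each
#' quantitative feature is normal with a class-specific mean. With
#' intragenic rate p1 and intergenic rate p0 the planted per-stratum odds
#' ratio is `(p1/(1-p1))/(p0/(1-p0))`; equal rates plant the null.
#'
#' @param config a [simulation_config()].
#' @param genome result of [simulate_genome()].
#' @return list: `elements` (L1 table as from [read_l1_table()], with a
#'   `features` attribute) and `truth` (data.frame `element_id`,
#'   `true_class`, `overlapped_gene_ids`).
#' @export
simulate_l1_table <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, "l1"))
  sizes <- genome$chrom_sizes
  n_per <- config$n_l1_per_chrom
  lw <- config$l1_length_bp
  if (length(lw) == 1L) lw <- c(lw, lw)
  if (lw[2] >= min(sizes$length)) stop("l1_length_bp exceeds shortest chromosome")

  chrom <- rep(sizes$chrom, each = n_per)
  N <- length(chrom)
  catf <- config$feature_names_categorical
  quantf <- config$feature_names_quantitative
  if (N == 0L) {
    el <- data.frame(element_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     strand = character(0), subfamily = character(0),
                     stringsAsFactors = FALSE)
    for (f in catf) el[[f]] <- character(0)
    for (f in quantf) el[[f]] <- numeric(0)
    attr(el, "features") <- data.frame(
      feature = c(catf, quantf),
      kind = rep(c("categorical", "quantitative"),
                 c(length(catf), length(quantf))),
      stringsAsFactors = FALSE)
    return(list(elements = el,
                truth = data.frame(element_id = character(0),
                                   true_class = character(0),
                                   overlapped_gene_ids = character(0),
                                   stringsAsFactors = FALSE)))
  }
  width <- if (lw[1] == lw[2]) rep(lw[1], N) else floor(runif(N, lw[1], lw[2] + 1))
  L <- rep(sizes$length, each = n_per)
  start <- as.integer(floor(runif(N, 0, L - width)))
  end <- as.integer(start + width)
  subfam <- sample(config$subfamily_labels, N, replace = TRUE,
                   prob = config$subfamily_weights / sum(config$subfamily_weights))
  el <- data.frame(element_id = sprintf("L1_%06d", seq_len(N)),
                   chrom = chrom, start = start, end = end,
                   strand = sample(c("+", "-"), N, replace = TRUE),
                   subfamily = subfam, stringsAsFactors = FALSE)

  spans <- gene_span(genome$genes)
  cls <- classify_location(el[, c("chrom", "start", "end")], spans)
  intra <- is_intragenic(cls$location_class)
  sf_idx <- match(subfam, config$subfamily_labels)

  p_in <- resolve_param(config$p_conserved_intragenic, catf, config$subfamily_labels)
  p_out <- resolve_param(config$p_conserved_intergenic, catf, config$subfamily_labels)
  for (fi in seq_along(catf)) {
    p <- ifelse(intra, p_in[fi, sf_idx], p_out[fi, sf_idx])
    el[[catf[fi]]] <- ifelse(rbinom(N, 1, p) == 1, "conserved", "mutated")
  }
  m_in <- resolve_param(config$quant_means_intragenic, quantf, "all")[, 1]
  m_out <- resolve_param(config$quant_means_intergenic, quantf, "all")[, 1]
  for (fi in seq_along(quantf)) {
    mu <- ifelse(intra, m_in[fi], m_out[fi])
    el[[quantf[fi]]] <- rnorm(N, mu, config$quant_sd)
  }
  attr(el, "features") <- data.frame(
    feature = c(catf, quantf),
    kind = rep(c("categorical", "quantitative"),
               c(length(catf), length(quantf))),
    stringsAsFactors = FALSE)
  truth <- data.frame(element_id = el$element_id,
                      true_class = as.character(cls$location_class),
                      overlapped_gene_ids = cls$overlapped_gene_ids,
                      stringsAsFactors = FALSE)
  list(elements = el, truth = truth)
}

#' Simulate a staged expression matrix with planted down-regulation
#'
#' Gene g at stage s, replicate r has value `baseline(g) + effect(g, s) +
#' noise`, all log2 scale. The first configured stage is the reference and
#' carries no effect. At every other stage each gene is independently
#' selected for down-regulation with probability `p_down_given_l1` if it
#' hosts an L1 and `p_down_given_no_l1` otherwise; selected genes get
#' `planted_down_effect` added at that stage. The planted odds ratio of the
#' L1/down association is therefore `(p1/(1-p1))/(p0/(1-p0))`. Replicate
#' index r pairs samples across stages.
#'
#' @param config a [simulation_config()].
#' @param gene_ids genes to simulate (non-empty).
#' @param l1_gene_ids subset of `gene_ids` hosting an intragenic L1.
#' @return list: `expr` (an [expression_matrix()]) and `truth` (data.frame
#'   `gene_id`, `stage`, `planted_down`).
#' @export
simulate_expression <- function(config, gene_ids, l1_gene_ids = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  if (length(gene_ids) == 0L) stop("gene_ids must be non-empty")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (!all(l1_gene_ids %in% gene_ids)) stop("l1_gene_ids must be a subset of gene_ids")
  if (config$n_replicates < 2L) stop("n_replicates must be >= 2 (paired t-test undefined)")
  set.seed(sub_seed(config$seed, "expression"))

  stages <- config$stages
  R <- config$n_replicates
  G <- length(gene_ids)
  inl1 <- gene_ids %in% l1_gene_ids
  pd1 <- rep_len(config$p_down_given_l1, length(stages) - 1L)
  pd0 <- rep_len(config$p_down_given_no_l1, length(stages) - 1L)

  baseline <- rnorm(G, config$baseline_mean, config$baseline_sd)
  vals <- matrix(NA_real_, G, length(stages) * R,
                 dimnames = list(gene_ids, NULL))
  stage_col <- character(length(stages) * R)
  rep_col <- integer(length(stages) * R)
  truth <- vector("list", length(stages) - 1L)
  j <- 0L
  for (si in seq_along(stages)) {
    if (si == 1L) {
      eff <- numeric(G)
    } else {
      p <- ifelse(inl1, pd1[si - 1L], pd0[si - 1L])
      down <- rbinom(G, 1, p) == 1
      eff <- ifelse(down, config$planted_down_effect, 0)
      truth[[si - 1L]] <- data.frame(gene_id = gene_ids, stage = stages[si],
                                     planted_down = down,
                                     stringsAsFactors = FALSE)
    }
    for (r in seq_len(R)) {
      j <- j + 1L
      vals[, j] <- baseline + eff + rnorm(G, 0, config$noise_sd)
      stage_col[j] <- stages[si]
      rep_col[j] <- r
    }
  }
  list(expr = expression_matrix(vals, stage_col, rep_col),
       truth = do.call(rbind, truth))
}

#' Simulate an ortholog pair table between two gene-id universes
#'
#' Draws a one-to-one sample of `n_pairs` pairs (plus an optional fraction
#' of one-to-many duplications on the first species' side).
#'
#' @param gene_ids1,gene_ids2 gene-id universes of the two species.
#' @param n_pairs number of base pairs to draw.
#' @param seed integer seed.
#' @param p_one_to_many fraction of pairs duplicated to a second partner.
#' @return data.frame with columns `gene_id_species1`, `gene_id_species2`.
#' @export
simulate_ortholog_pairs <- function(gene_ids1, gene_ids2, n_pairs,
                                    seed = 1L, p_one_to_many = 0) {
  stopifnot(n_pairs <= length(gene_ids1), n_pairs <= length(gene_ids2))
  set.seed(sub_seed(seed, "orthologs"))
  g1 <- sample(gene_ids1, n_pairs)
  g2 <- sample(gene_ids2, n_pairs)
  out <- data.frame(gene_id_species1 = g1, gene_id_species2 = g2,
                    stringsAsFactors = FALSE)
  if (p_one_to_many > 0 && n_pairs > 0) {
    extra <- which(rbinom(n_pairs, 1, p_one_to_many) == 1)
    if (length(extra)) {
      pool <- setdiff(gene_ids2, g2)
      extra <- extra[seq_len(min(length(extra), length(pool)))]
      if (length(extra)) {
        out <- rbind(out, data.frame(
          gene_id_species1 = g1[extra],
          gene_id_species2 = sample(pool, length(extra)),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate and write a complete input bundle
#'
#' Runs all generators under one configuration and writes the files the
#' pipeline consumes: `genes.gff3`, `chrom_sizes.tsv`, `l1.tsv`,
#' `l1_truth.tsv`, `expression.tsv`, `expression_truth.tsv` and
#' `l1_genes.txt` (the gene ids whose span overlaps at least one simulated
#' element). The expression matrix covers every simulated gene. Identical
#' configurations (including the seed) produce byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the simulated objects and file paths.
#' @export
simulate_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(config)
  l1 <- simulate_l1_table(config, genome)
  hosts <- l1$truth$overlapped_gene_ids
  l1_genes <- sort(unique(unlist(strsplit(hosts[nzchar(hosts)], ",", fixed = TRUE))))
  gene_ids <- unique(genome$genes$gene_id)

  paths <- list(
    genes = file.path(outdir, "genes.gff3"),
    chrom_sizes = file.path(outdir, "chrom_sizes.tsv"),
    l1 = file.path(outdir, "l1.tsv"),
    l1_truth = file.path(outdir, "l1_truth.tsv"),
    l1_genes = file.path(outdir, "l1_genes.txt"),
    expression = file.path(outdir, "expression.tsv"),
    expression_truth = file.path(outdir, "expression_truth.tsv"))
  write_gene_gff3(genome$genes, paths$genes)
  write_chrom_sizes(genome$chrom_sizes, paths$chrom_sizes)
  write_l1_table(l1$elements, paths$l1)
  write_tsv_file(l1$truth, paths$l1_truth)
  writeLines(l1_genes, paths$l1_genes)
  ex <- NULL
  if (length(gene_ids)) {
    ex <- simulate_expression(config, gene_ids, intersect(l1_genes, gene_ids))
    write_expression(ex$expr, paths$expression)
    write_tsv_file(ex$truth, paths$expression_truth)
  }
  invisible(list(genome = genome, l1 = l1, expression = ex,
                 l1_genes = l1_genes, paths = paths))
}
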