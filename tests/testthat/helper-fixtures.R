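# Shared fixtures and independent oracles, all built in code.

# Brute-force classifier: direct enumeration over spans, the independent
# oracle for classify_location().
brute_classify <- function(l1, spans) {
  vapply(seq_len(nrow(l1)), function(i) {
    s <- l1$start[i]; e <- l1$end[i]
    sp <- spans[spans$chrom == l1$chrom[i], , drop = FALSE]
    if (nrow(sp) == 0L) return("intergenic")
    if (any(sp$start <= s & e <= sp$end)) return("intragenic_total")
    if (any(pmax(s, sp$start) < pmin(e, sp$end))) return("intragenic_partial")
    "intergenic"
  }, character(1))
}

# Per-base sweep: union length of spans on one chromosome of length L.
brute_union_length <- function(spans, L) {
  covered <- logical(L)
  for (i in seq_len(nrow(spans))) {
    if (spans$end[i] > spans$start[i]) {
      covered[(spans$start[i] + 1L):spans$end[i]] <- TRUE
    }
  }
  sum(covered)
}

# Minimal exon table builder: one single-exon transcript per row.
simple_genes <- function(gene_id, chrom, start, end, strand = "+") {
  data.frame(gene_id = gene_id, transcript_id = paste0(gene_id, "_t1"),
             chrom = chrom, strand = strand,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

simple_l1 <- function(chrom, start, end, subfamily = "A") {
  n <- length(start)
  data.frame(element_id = sprintf("e%03d", seq_len(n)),
             chrom = rep_len(chrom, n),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len("+", n), subfamily = rep_len(subfamily, n),
             stringsAsFactors = FALSE)
}

# Annotation + element set realizing exactly n_intra intragenic elements of
# n_total: one megabase-long gene hosts the intragenic elements, the rest
# sit beyond it on the same chromosome.
count_fixture <- function(n_total, n_intra) {
  stopifnot(n_intra <= n_total, n_intra < 20000)
  genes <- simple_genes("host_gene", "chr1", 0L, 2000000L)
  intra_start <- (seq_len(n_intra) - 1L) * 100L
  inter_start <- 2000000L + seq_len(n_total - n_intra) * 200L
  start <- c(intra_start, inter_start)
  l1 <- simple_l1("chr1", start, start + 50L)
  sizes <- data.frame(chrom = "chr1", length = max(start) + 10000,
                      stringsAsFactors = FALSE)
  list(genes = genes, l1 = l1, sizes = sizes)
}

# Random small genome + elements for oracle-based property tests.
random_case <- function(n_spans, n_l1, L = 1e5, chroms = c("chr1", "chr2")) {
  sp_chrom <- sample(chroms, n_spans, replace = TRUE)
  sp_start <- sample.int(L - 5000L, n_spans, replace = TRUE) - 1L
  sp_len <- sample.int(5000L, n_spans, replace = TRUE)
  spans <- data.frame(gene_id = sprintf("g%03d", seq_len(n_spans)),
                      chrom = sp_chrom, strand = "+",
                      start = sp_start, end = sp_start + sp_len,
                      stringsAsFactors = FALSE)
  e_chrom <- sample(chroms, n_l1, replace = TRUE)
  e_start <- sample.int(L - 2000L, n_l1, replace = TRUE) - 1L
  e_len <- sample.int(2000L, n_l1, replace = TRUE)
  l1 <- simple_l1(e_chrom, e_start, e_start + e_len)
  list(spans = spans, l1 = l1, L = as.integer(L), chroms = chroms)
}

# Small-but-complete simulation config for fast tests; any argument of
# simulation_config() may be overridden.
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_autosomes = 2L, chrom_length_bp = 1e6,
                   n_genes_per_chrom = 15L, gene_span_bp = c(2000L, 20000L),
                   n_l1_per_chrom = 40L, l1_length_bp = 6000L,
                   n_genes_expr = 200L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# DE table stub for direct assoc_test() checks.
de_stub <- function(universe, called, direction = "down",
                    stage = "2-cell", reference = "1-cell") {
  data.frame(gene_id = universe, stage = stage, reference = reference,
             mean_diff = 0, t = 0, df = 2L, p = 1,
             call = ifelse(universe %in% called, direction, "ns"),
             degenerate = FALSE, stringsAsFactors = FALSE)
}
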