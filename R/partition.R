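#' Derive the genomic span of each gene
#'
#' The gene definition used throughout the package runs from the first to
#' the last exon of the largest transcript isoform, where "largest" means
#' the largest genomic span (last exon end minus first exon start), not the
#' summed exon length. Ties are broken by the lexicographically smallest
#' transcript id so the result is deterministic.
#'
#' @param genes exon table from [read_gene_annotation()].
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open).
#' @export
#' @examples
#' ex <- data.frame(gene_id = "g1", transcript_id = c("t1", "t1", "t2"),
#'                  chrom = "chr1", strand = "+",
#'                  start = c(100L, 300L, 150L), end = c(200L, 400L, 250L))
#' gene_span(ex)  # t1 spans 300 bp > t2's 100 bp, so span is [100, 400)
gene_span <- function(genes) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  stopifnot(all(need %in% names(genes)))
  if (nrow(genes) == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(genes$gene_id, genes$transcript_id, sep = "\r")
  tstart <- tapply(genes$start, key, min)
  tend <- tapply(genes$end, key, max)
  tx <- genes[!duplicated(key), c("gene_id", "transcript_id", "chrom", "strand")]
  k <- paste(tx$gene_id, tx$transcript_id, sep = "\r")
  tx$start <- as.integer(tstart[k])
  tx$end <- as.integer(tend[k])
  tx$span <- tx$end - tx$start
  tx <- tx[order(tx$gene_id, -tx$span, tx$transcript_id), ]
  out <- tx[!duplicated(tx$gene_id), c("gene_id", "chrom", "strand", "start", "end")]
  rownames(out) <- NULL
  out
}

#' Classify L1 elements as intragenic or intergenic
#'
#' An element totally contained in at least one gene span is
#' `intragenic_total`; an element overlapping a span by at least 1 bp but
#' contained in none is `intragenic_partial`; everything else is
#' `intergenic`. Overlap is strand-agnostic. Elements on chromosomes with no
#' annotated gene are intergenic. An element overlapping the spans of
#' several genes is classified once but attributed to every overlapped gene
#' in `overlapped_gene_ids` (comma-separated, sorted), since element counts
#' and host-gene sets serve different downstream uses.
#'
#' @param l1 data.frame with columns `chrom`, `start`, `end` (plus anything
#'   else, carried through).
#' @param gene_spans data.frame from [gene_span()].
#' @return `l1` with added columns `location_class` (factor with levels
#'   `intragenic_total`, `intragenic_partial`, `intergenic`) and
#'   `overlapped_gene_ids`.
#' @export
classify_location <- function(l1, gene_spans) {
  stopifnot(all(c("chrom", "start", "end") %in% names(l1)))
  n <- nrow(l1)
  loc <- rep("intergenic", n)
  hits <- character(n)
  if (n > 0L && nrow(gene_spans) > 0L) {
    lev <- union(unique(as.character(l1$chrom)), unique(as.character(gene_spans$chrom)))
    q <- as_granges0(l1$chrom, l1$start, l1$end, levels = lev)
    s <- as_granges0(gene_spans$chrom, gene_spans$start, gene_spans$end, levels = lev)
    ov <- GenomicRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(ov)
    loc[unique(qh)] <- "intragenic_partial"
    within <- GenomicRanges::findOverlaps(q, s, type = "within")
    loc[unique(S4Vectors::queryHits(within))] <- "intragenic_total"
    if (length(qh)) {
      gid <- tapply(gene_spans$gene_id[S4Vectors::subjectHits(ov)], qh,
                    function(g) paste(sort(unique(g)), collapse = ","))
      hits[as.integer(names(gid))] <- unname(gid)
    }
  }
  l1$location_class <- factor(loc, levels = c("intragenic_total",
                                              "intragenic_partial",
                                              "intergenic"))
  l1$overlapped_gene_ids <- hits
  l1
}

is_intragenic <- function(location_class) {
  location_class %in% c("intragenic_total", "intragenic_partial")
}

#' Chromosome class from chromosome name
#'
#' `chrX`/`X` and `chrY`/`Y` map to the sex-chromosome classes; `chr<digits>`
#' or bare digits map to `autosome`; anything else (mitochondrial contigs,
#' scaffolds) is `NA` and excluded from density reports with a message.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector: `"autosome"`, `"X"`, `"Y"` or `NA`.
#' @export
chromosome_class <- function(chrom) {
  base <- sub("^chr", "", as.character(chrom))
  out <- rep(NA_character_, length(base))
  out[base == "X"] <- "X"
  out[base == "Y"] <- "Y"
  out[grepl("^[0-9]+$", base)] <- "autosome"
  out
}

#' Per-chromosome genic and intergenic region lengths
#'
#' The intragenic length of a chromosome is the length of the union of its
#' gene spans (overlapping genes are merged, so shared bases count once);
#' the intergenic length is the chromosome length minus that union. Their
#' sum is exactly the chromosome length.
#'
#' @param gene_spans data.frame from [gene_span()].
#' @param chrom_sizes data.frame with columns `chrom`, `length`.
#' @return data.frame: `chrom`, `length`, `intragenic_bp`, `intergenic_bp`.
#' @export
region_lengths <- function(gene_spans, chrom_sizes) {
  genic <- setNames(numeric(nrow(chrom_sizes)), chrom_sizes$chrom)
  if (nrow(gene_spans)) {
    sp <- gene_spans[gene_spans$chrom %in% chrom_sizes$chrom, , drop = FALSE]
    if (nrow(sp)) {
      gr <- as_granges0(sp$chrom, sp$start, sp$end, levels = chrom_sizes$chrom)
      red <- GenomicRanges::reduce(gr)
      w <- tapply(BiocGenerics::width(red),
                  as.character(GenomicRanges::seqnames(red)), sum)
      genic[names(w)] <- w
    }
  }
  out <- data.frame(chrom = chrom_sizes$chrom,
                    length = as.numeric(chrom_sizes$length),
                    intragenic_bp = unname(genic), stringsAsFactors = FALSE)
  if (any(out$intragenic_bp > out$length)) {
    stop("gene spans exceed chromosome length on: ",
         out$chrom[which(out$intragenic_bp > out$length)[1]])
  }
  out$intergenic_bp <- out$length - out$intragenic_bp
  out
}

#' L1 density report per chromosome class
#'
#' For each chromosome class (autosome, X, Y) and each region class (`all`,
#' `intragenic`, `intergenic`), reports the element count, the region length
#' in Mbp, and the density in counts per Mbp (cMbp). The denominator of the
#' `intragenic` (`intergenic`) rows is the summed union-of-gene-spans length
#' (its complement); `density_whole_cmbp` additionally gives every count
#' over the whole chromosome-class length, the denominator used for
#' distribution-style bar charts. `pct_of_chromosome` is the percentage of
#' the class length occupied by the region, so the intergenic rows read off
#' the percent-intergenic content directly.
#'
#' @param l1 classified element table from [classify_location()].
#' @param gene_spans data.frame from [gene_span()].
#' @param chrom_sizes data.frame with columns `chrom`, `length`.
#' @param species optional label copied into the report.
#' @return data.frame, three rows per chromosome class.
#' @export
compute_densities <- function(l1, gene_spans, chrom_sizes, species = NA_character_) {
  stopifnot("location_class" %in% names(l1))
  cls <- chromosome_class(chrom_sizes$chrom)
  dropped <- sum(is.na(cls))
  if (dropped) {
    message("excluding ", dropped, " chromosome(s) outside autosome/X/Y classes")
  }
  sizes <- chrom_sizes[!is.na(cls), , drop = FALSE]
  cls <- cls[!is.na(cls)]
  reg <- region_lengths(gene_spans, sizes)

  l1cls <- chromosome_class(l1$chrom)
  keep <- !is.na(l1cls) & l1$chrom %in% sizes$chrom
  l1 <- l1[keep, , drop = FALSE]
  l1cls <- l1cls[keep]
  intra <- is_intragenic(l1$location_class)

  rows <- list()
  for (cc in intersect(c("autosome", "X", "Y"), unique(cls))) {
    all_bp <- sum(reg$length[cls == cc])
    intra_bp <- sum(reg$intragenic_bp[cls == cc])
    inter_bp <- all_bp - intra_bp
    n_all <- sum(l1cls == cc)
    n_intra <- sum(l1cls == cc & intra)
    n_inter <- n_all - n_intra
    lens <- c(all = all_bp, intragenic = intra_bp, intergenic = inter_bp)
    cnts <- c(all = n_all, intragenic = n_intra, intergenic = n_inter)
    for (rc in names(lens)) {
      if (lens[[rc]] == 0 && cnts[[rc]] > 0) {
        stop("zero-length ", rc, " region with ", cnts[[rc]],
             " element(s) on chromosome class ", cc)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = species, chromosome_class = cc, region_class = rc,
        l1_count = cnts[[rc]],
        region_length_mbp = lens[[rc]] / 1e6,
        density_cmbp = if (lens[[rc]] > 0) cnts[[rc]] / (lens[[rc]] / 1e6) else 0,
        density_whole_cmbp = if (all_bp > 0) cnts[[rc]] / (all_bp / 1e6) else 0,
        pct_of_chromosome = if (all_bp > 0) 100 * lens[[rc]] / all_bp else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Headline intragenic summary
#'
#' Counts intragenic elements (total plus partial) and the distinct genes
#' hosting at least one element. The percentage is rounded half-up to two
#' decimals, the convention of printed summaries; with zero elements it is
#' reported as missing.
#'
#' @param l1 classified element table from [classify_location()].
#' @return list: `n_total`, `n_intragenic`, `pct_intragenic`,
#'   `n_genes_with_l1`.
#' @export
intragenic_summary <- function(l1) {
  stopifnot("location_class" %in% names(l1))
  n_total <- nrow(l1)
  n_intra <- sum(is_intragenic(l1$location_class))
  pct <- if (n_total > 0) round_half_up(100 * n_intra / n_total, 2) else NA_real_
  hosts <- l1$overlapped_gene_ids[nzchar(l1$overlapped_gene_ids %||% character(0))]
  genes <- unique(unlist(strsplit(hosts, ",", fixed = TRUE)))
  list(n_total = n_total, n_intragenic = n_intra, pct_intragenic = pct,
       n_genes_with_l1 = length(genes))
}
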