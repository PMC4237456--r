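#' Read gene models from GFF3 or BED12
#'
#' Parses gene annotation into a flat exon table, the package's internal gene
#' model representation: one row per exon with columns `gene_id`,
#' `transcript_id`, `chrom`, `strand`, `start`, `end`. Coordinates are
#' converted at this boundary to the internal 0-based half-open convention
#' (a GFF3 exon printed as start=101, end=200 becomes the interval
#' `[100, 200)`).
#'
#' For GFF3, exons are grouped into transcripts by their `Parent` attribute
#' and transcripts (`mRNA`/`transcript` features) are grouped into genes the
#' same way; a transcript whose `Parent` names no `gene` feature is an error.
#' Genes that end up with zero exons are dropped with a warning. For BED12,
#' each line is one gene with a single transcript whose exons come from the
#' block columns.
#'
#' @param path file to read.
#' @param dialect `"gff3"` or `"bed12"`.
#' @return data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open). Empty input yields an
#'   empty data.frame with the same columns.
#' @seealso [gene_span()] for deriving a single genomic span per gene.
#' @export
read_gene_annotation <- function(path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body) == 0L) return(empty_gene_models())
  nfield <- if (dialect == "gff3") 9L else 12L
  counts <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  if (any(counts != nfield)) {
    i <- body[which(counts != nfield)[1]]
    stop(sprintf("malformed %s line %d: expected %d tab-separated fields, found %d",
                 dialect, i, nfield, counts[which(counts != nfield)[1]]))
  }
  if (dialect == "gff3") read_gff3_genes(path) else read_bed12_genes(path)
}

empty_gene_models <- function() {
  data.frame(gene_id = character(0), transcript_id = character(0),
             chrom = character(0), strand = character(0),
             start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  gene_ids <- ids[type == "gene"]

  first_parent <- function(idx) {
    vapply(as.list(gr$Parent[idx]), function(p) {
      if (length(p) == 0L) NA_character_ else as.character(p[1])
    }, character(1))
  }

  tx_idx <- which(type %in% c("mRNA", "transcript"))
  tx_ids <- ids[tx_idx]
  tx_parent <- first_parent(tx_idx)
  orphan <- which(is.na(tx_parent) | !(tx_parent %in% gene_ids))
  if (length(orphan)) {
    stop("transcript '", tx_ids[orphan[1]], "' references absent gene '",
         tx_parent[orphan[1]], "'")
  }
  tx2gene <- structure(tx_parent, names = tx_ids)

  ex_idx <- which(type == "exon")
  ex_parent <- first_parent(ex_idx)
  bad <- which(is.na(ex_parent) | !(ex_parent %in% tx_ids))
  if (length(bad)) {
    stop("exon at line for '", as.character(GenomicRanges::seqnames(gr)[ex_idx[bad[1]]]),
         "' references absent transcript '", ex_parent[bad[1]], "'")
  }
  out <- data.frame(
    gene_id = unname(tx2gene[ex_parent]),
    transcript_id = ex_parent,
    chrom = as.character(GenomicRanges::seqnames(gr))[ex_idx],
    strand = as.character(BiocGenerics::strand(gr))[ex_idx],
    start = GenomicRanges::start(gr)[ex_idx] - 1L,
    end = GenomicRanges::end(gr)[ex_idx],
    stringsAsFactors = FALSE
  )
  no_exon <- setdiff(gene_ids, out$gene_id)
  if (length(no_exon)) {
    warning("dropping ", length(no_exon), " gene(s) with zero exons: ",
            paste(utils::head(no_exon, 5), collapse = ", "))
  }
  validate_gene_models(out)
}

read_bed12_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) return(empty_gene_models())
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) nm <- paste0("gene_", seq_along(gr))
  bl <- rtracklayer::blocks(gr)  # absolute 1-based exon coordinates
  names(bl) <- nm
  ub <- BiocGenerics::unlist(bl, use.names = TRUE)
  out <- data.frame(
    gene_id = names(ub),
    transcript_id = names(ub),
    chrom = as.character(GenomicRanges::seqnames(ub)),
    strand = rep(as.character(BiocGenerics::strand(gr)), S4Vectors::elementNROWS(bl)),
    start = GenomicRanges::start(ub) - 1L,
    end = GenomicRanges::end(ub),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  validate_gene_models(out)
}

validate_gene_models <- function(genes) {
  stop_if_bad_interval(genes$start, genes$end, "exon")
  # exons of one gene must share its chromosome
  nchrom <- tapply(genes$chrom, genes$gene_id, function(x) length(unique(x)))
  if (any(nchrom > 1)) {
    stop("gene '", names(nchrom)[which(nchrom > 1)[1]], "' has exons on multiple chromosomes")
  }
  # exons within a transcript must not overlap once sorted
  by_tx <- split(seq_len(nrow(genes)), genes$transcript_id)
  for (idx in by_tx) {
    o <- idx[order(genes$start[idx])]
    if (length(o) > 1 && any(genes$start[o][-1] < genes$end[o][-length(o)])) {
      stop("transcript '", genes$transcript_id[idx[1]], "' has overlapping exons")
    }
  }
  rownames(genes) <- NULL
  genes
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA` and `exon` features with `ID`/`Parent` attributes,
#' converting internal 0-based half-open coordinates back to the 1-based
#' inclusive GFF3 convention. Output ordering is deterministic (chromosome,
#' gene start, gene id), so identical inputs give byte-identical files.
#'
#' @param genes exon table as returned by [read_gene_annotation()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  if (nrow(genes)) {
    gstart <- tapply(genes$start, genes$gene_id, min)
    gend <- tapply(genes$end, genes$gene_id, max)
    gmeta <- genes[!duplicated(genes$gene_id), c("gene_id", "chrom", "strand")]
    gmeta$start <- as.integer(gstart[gmeta$gene_id])
    gmeta$end <- as.integer(gend[gmeta$gene_id])
    gmeta <- gmeta[order(gmeta$chrom, gmeta$start, gmeta$gene_id), ]

    feat <- function(chrom, type, s, e, strand, attrs) {
      sprintf("%s\tl1census\t%s\t%d\t%d\t.\t%s\t.\t%s",
              chrom, type, s + 1L, e, strand, attrs)
    }
    out <- vector("list", nrow(gmeta))
    for (i in seq_len(nrow(gmeta))) {
      g <- gmeta$gene_id[i]
      gi <- genes[genes$gene_id == g, ]
      block <- feat(gmeta$chrom[i], "gene", gmeta$start[i], gmeta$end[i],
                    gmeta$strand[i], paste0("ID=", g))
      for (t in sort(unique(gi$transcript_id))) {
        ti <- gi[gi$transcript_id == t, ]
        ti <- ti[order(ti$start), ]
        block <- c(block,
                   feat(ti$chrom[1], "mRNA", min(ti$start), max(ti$end),
                        ti$strand[1], paste0("ID=", t, ";Parent=", g)),
                   feat(ti$chrom, "exon", ti$start, ti$end, ti$strand,
                        paste0("Parent=", t)))
      }
      out[[i]] <- block
    }
    lines <- c(lines, unlist(out))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a chromosome-sizes table
#'
#' Two-column tab-delimited file: `chrom`, `length` (bp).
#'
#' @param path file path.
#' @return `read_chrom_sizes()`: data.frame with columns `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(x))) {
    names(x)[1:2] <- c("chrom", "length")
  }
  x$length <- as.numeric(x$length)
  if (any(is.na(x$length) | x$length <= 0)) stop("chromosome lengths must be positive")
  x[, c("chrom", "length")]
}

#' @rdname read_chrom_sizes
#' @param sizes data.frame with columns `chrom`, `length`.
#' @export
write_chrom_sizes <- function(sizes, path) {
  write_tsv_file(sizes[, c("chrom", "length")], path)
}
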