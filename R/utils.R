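`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moving away from zero,
#' the convention used for printed percentages (base [round()] rounds halves
#' to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# 6 significant digits, "" for NA: the fixed float dialect of all TSV output
fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.6g", x))
}

# One named pseudo-random stream per generator sub-step, derived from the
# single user-facing seed, so adding a generator does not perturb the others.
# Result stays below 2^31 - 1.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  cp <- utf8ToInt(stream)
  h <- sum(cp * seq_along(cp))
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + h) %% 2147483647)
}

# Data frame -> TSV with deterministic formatting (floats at 6 sig. digits,
# NA as empty cell). Used by every writer so reruns are byte-identical.
write_tsv_file <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      out[[j]] <- fmt_num(col)
    } else {
      v <- as.character(col)
      v[is.na(v)] <- ""
      out[[j]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# 0-based half-open (chrom, start, end) -> GRanges (1-based inclusive).
# `levels` fixes a common seqlevel universe so cross-object overlap queries
# do not warn about disjoint sequence levels.
as_granges0 <- function(chrom, start, end, levels = NULL) {
  if (length(chrom) == 0L) {
    return(GenomicRanges::GRanges(seqnames = factor(character(0), levels = levels %||% character(0)),
                                  ranges = IRanges::IRanges()))
  }
  levels <- levels %||% unique(as.character(chrom))
  GenomicRanges::GRanges(
    seqnames = factor(as.character(chrom), levels = levels),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end))
  )
}

stop_if_bad_interval <- function(start, end, where = "interval") {
  bad <- which(!(start >= 0 & end > start))
  if (length(bad)) {
    stop(sprintf("%s %d: invalid interval (start=%s, end=%s); need 0 <= start < end",
                 where, bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}
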