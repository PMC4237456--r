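#' Paired t-test differential expression against a reference stage
#'
#' For each gene, the per-replicate differences `d_r = value(stage, rep r) -
#' value(reference, rep r)` give the paired t statistic `t = dbar /
#' (s_d/sqrt(R))` on `R - 1` degrees of freedom, with a two-sided p-value.
#' Replicates are paired by replicate index. Genes with `p < alpha_de` are
#' called `up` or `down` by the sign of the mean difference; everything else
#' is `ns`. A degenerate gene (zero difference variance) with a non-zero
#' mean difference is forced significant in its sign direction with `p`
#' recorded as 0 and flagged; with zero mean difference it is `ns`.
#'
#' @param expr an [expression_matrix()].
#' @param stage stage to test.
#' @param reference reference stage (default `"1-cell"`).
#' @param alpha_de differential-expression threshold (default 0.05).
#' @return data.frame, one row per gene: `gene_id`, `stage`, `reference`,
#'   `mean_diff`, `t`, `df`, `p`, `call`, `degenerate`.
#' @export
paired_de <- function(expr, stage, reference = "1-cell", alpha_de = 0.05) {
  s <- expr$samples
  i1 <- which(s$stage == stage)
  i0 <- which(s$stage == reference)
  if (!length(i1)) stop("stage not present: ", stage)
  if (!length(i0)) stop("reference stage not present: ", reference)
  if (!identical(sort(s$replicate[i1]), sort(s$replicate[i0]))) {
    stop("replicate indices differ between '", stage, "' and '", reference, "'")
  }
  R <- length(i1)
  if (R < 2) stop("paired t-test needs >= 2 replicates")
  D <- expr$values[, i1[order(s$replicate[i1])], drop = FALSE] -
       expr$values[, i0[order(s$replicate[i0])], drop = FALSE]
  dbar <- rowMeans(D)
  s_d <- sqrt(rowSums((D - dbar)^2) / (R - 1))
  tt <- dbar / (s_d / sqrt(R))
  p <- 2 * pt(-abs(tt), df = R - 1)
  degen <- s_d == 0
  tt[degen & dbar == 0] <- 0
  p[degen & dbar == 0] <- 1
  p[degen & dbar != 0] <- 0
  call <- rep("ns", length(dbar))
  call[p < alpha_de & dbar > 0] <- "up"
  call[p < alpha_de & dbar < 0] <- "down"
  data.frame(gene_id = rownames(expr$values), stage = stage,
             reference = reference, mean_diff = dbar, t = tt, df = R - 1L,
             p = p, call = call, degenerate = degen,
             row.names = NULL, stringsAsFactors = FALSE)
}

woolf_ci <- function(a, b, cc, d, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  lor <- log(a * d / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  exp(lor + c(-1, 1) * z * se)
}

#' Association between L1 presence and a direction of differential expression
#'
#' Builds the 2x2 table with rows L1-present / L1-absent and columns
#' called-in-direction / rest, where "rest" is every tested gene not called
#' in the given direction (non-significant and opposite-direction genes
#' alike), then applies a Pearson chi-square test without continuity
#' correction. The odds ratio is `ad/bc` with a Woolf 95% confidence
#' interval; when any cell is zero the raw OR is still reported (0 or
#' infinity) and the interval is computed with the Haldane-Anscombe +0.5
#' adjustment on all four cells, flagged in `ci_adjusted`. The gene universe
#' is the set of genes in `de`; `l1_genes` is intersected with it first.
#' Significance requires both `p < alpha` and `or > or_min`.
#'
#' @param de differential-expression table from [paired_de()].
#' @param l1_genes character vector of genes hosting intragenic L1s.
#' @param direction `"up"` or `"down"`.
#' @param alpha association significance threshold (default 1.0E-03).
#' @param or_min odds-ratio threshold (default 1.0).
#' @param conf_level confidence level for the interval.
#' @return one-row data.frame: `stage`, `reference`, `direction`, `a`, `b`,
#'   `c`, `d`, `chi2`, `p`, `or`, `ci_low`, `ci_high`, `significant`,
#'   `degenerate`, `ci_adjusted`.
#' @export
assoc_test <- function(de, l1_genes, direction = c("up", "down"),
                       alpha = 1e-3, or_min = 1.0, conf_level = 0.95) {
  direction <- match.arg(direction)
  universe <- de$gene_id
  if (anyDuplicated(universe)) stop("duplicate gene ids in DE table")
  inl1 <- universe %in% l1_genes
  called <- de$call == direction
  a <- sum(inl1 & called); b <- sum(inl1 & !called)
  cc <- sum(!inl1 & called); d <- sum(!inl1 & !called)

  degenerate <- (a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0
  if (degenerate) {
    chi2 <- NA_real_; p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                                      correct = FALSE))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  num <- a * d; den <- b * cc
  or <- if (den > 0) num / den else if (num > 0) Inf else NA_real_
  ci_adjusted <- FALSE
  if (!degenerate && all(c(a, b, cc, d) > 0)) {
    ci <- woolf_ci(a, b, cc, d, conf_level)
  } else if (!degenerate) {
    ci <- woolf_ci(a + 0.5, b + 0.5, cc + 0.5, d + 0.5, conf_level)
    ci_adjusted <- TRUE
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  significant <- isTRUE(!degenerate && p < alpha && !is.na(or) && or > or_min)
  data.frame(stage = de$stage[1], reference = de$reference[1],
             direction = direction, a = a, b = b, c = cc, d = d,
             chi2 = chi2, p = p, or = or, ci_low = ci[1], ci_high = ci[2],
             significant = significant, degenerate = degenerate,
             ci_adjusted = ci_adjusted, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Stage-by-stage association screen
#'
#' For every stage other than the reference and both directions (up, down),
#' calls differential expression by [paired_de()] and tests association
#' with L1 presence by [assoc_test()], mirroring the layout of a
#' per-contrast association table with significance flags. Also collects,
#' per stage and direction, the set of L1-hosting genes called in that
#' direction, the raw material for cross-stage intersections.
#'
#' @param expr an [expression_matrix()].
#' @param l1_genes character vector of L1-hosting gene ids.
#' @param stages stages to contrast against the reference; default all
#'   non-reference stages in sample order.
#' @param reference reference stage.
#' @param alpha_de per-gene differential-expression threshold.
#' @param alpha,or_min association significance thresholds.
#' @return object of class `stage_screen`: list with `assoc` (data.frame,
#'   one row per stage x direction), `sets_up`/`sets_down` (named lists of
#'   gene sets), `de` (named list of per-stage DE tables), `reference`.
#' @export
run_stage_screen <- function(expr, l1_genes, stages = NULL,
                             reference = "1-cell", alpha_de = 0.05,
                             alpha = 1e-3, or_min = 1.0) {
  st_all <- expr_stages(expr)
  if (!reference %in% st_all) stop("reference stage not present: ", reference)
  if (is.null(stages)) stages <- setdiff(st_all, reference)
  rows <- list()
  sets <- list(up = list(), down = list())
  de_list <- list()
  for (st in stages) {
    de <- paired_de(expr, st, reference, alpha_de)
    de_list[[st]] <- de
    l1u <- intersect(l1_genes, de$gene_id)
    for (dir in c("up", "down")) {
      rows[[paste(st, dir)]] <- assoc_test(de, l1u, dir, alpha, or_min)
      sets[[dir]][[st]] <- de$gene_id[de$call == dir & de$gene_id %in% l1u]
    }
  }
  assoc <- do.call(rbind, rows)
  rownames(assoc) <- NULL
  structure(list(assoc = assoc, sets_up = sets$up, sets_down = sets$down,
                 de = de_list, reference = reference),
            class = "stage_screen")
}

#' @export
print.stage_screen <- function(x, ...) {
  cat("stage_screen:", length(x$de), "contrast(s) vs", x$reference, "\n")
  print(x$assoc[, c("stage", "direction", "p", "or", "ci_low", "ci_high",
                    "significant")])
  invisible(x)
}

#' Venn region cardinalities of a list of sets
#'
#' Counts the elements of each non-empty membership pattern
#' (inclusion-exclusion regions). Region counts sum to the size of the
#' union.
#'
#' @param sets named list of character vectors.
#' @return data.frame with columns `region` (set names joined by `&`) and
#'   `count`.
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  elements <- unique(unlist(sets, use.names = FALSE))
  if (length(elements) == 0L) {
    return(data.frame(region = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  memb <- vapply(sets, function(s) elements %in% s,
                 logical(length(elements)))
  memb <- matrix(memb, nrow = length(elements),
                 dimnames = list(NULL, names(sets)))
  region <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  tab <- table(region)
  data.frame(region = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect per-stage gene sets over the significant stages
#'
#' Takes one gene set per stage (L1-hosting genes called in a direction)
#' and intersects the sets of the stages flagged significant, also
#' reporting Venn region counts over those sets. With no significant stage
#' the intersection is empty with an explanatory status.
#'
#' @param sets named list of character vectors, one per stage.
#' @param significant which sets to use: a logical vector aligned with
#'   `sets`, a character vector of names, or `NULL` for all.
#' @return list: `common` (sorted gene vector), `sets_used`, `regions`
#'   (from [venn_counts()]), `status`.
#' @export
intersect_significant_sets <- function(sets, significant = NULL) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  use_names <- if (is.null(significant)) {
    names(sets)
  } else if (is.logical(significant)) {
    stopifnot(length(significant) == length(sets))
    names(sets)[significant]
  } else {
    intersect(as.character(significant), names(sets))
  }
  if (length(use_names) == 0L) {
    return(list(common = character(0), sets_used = character(0),
                regions = venn_counts(sets)[0, ],
                status = "no significant stage gene sets"))
  }
  use <- sets[use_names]
  list(common = sort(Reduce(intersect, use)), sets_used = use_names,
       regions = venn_counts(use), status = "ok")
}

#' Commonly regulated L1-hosting genes across significant stages
#'
#' Convenience wrapper applying [intersect_significant_sets()] to a
#' [run_stage_screen()] result: the stages entering the intersection are
#' exactly those whose association test in the requested direction passed
#' both thresholds, never a hard-coded stage list.
#'
#' @param screen a `stage_screen`.
#' @param direction `"up"` or `"down"`.
#' @return as [intersect_significant_sets()].
#' @export
common_regulated_genes <- function(screen, direction = c("down", "up")) {
  direction <- match.arg(direction)
  sets <- if (direction == "down") screen$sets_down else screen$sets_up
  sig <- screen$assoc$significant[screen$assoc$direction == direction]
  names(sig) <- screen$assoc$stage[screen$assoc$direction == direction]
  intersect_significant_sets(sets, names(sig)[sig])
}

#' Join two species' gene sets through an ortholog pair table
#'
#' Emits every ortholog pair whose first member is in `set1` and second in
#' `set2`; one-to-many relationships yield every qualifying pair.
#' Duplicated rows in the pair table are collapsed first.
#'
#' @param set1,set2 character vectors of gene ids (e.g. mouse and human).
#' @param pairs data.frame whose first two columns are the ortholog pairs
#'   (species-1 id, species-2 id).
#' @return list: `pairs` (matched rows), `unmatched_set1`,
#'   `unmatched_set2` (genes of each set with no matched pair).
#' @export
map_orthologs <- function(set1, set2, pairs) {
  stopifnot(ncol(pairs) >= 2)
  pr <- unique(pairs[, 1:2, drop = FALSE])
  hit <- pr[[1]] %in% set1 & pr[[2]] %in% set2
  matched <- pr[hit, , drop = FALSE]
  rownames(matched) <- NULL
  list(pairs = matched,
       unmatched_set1 = sort(setdiff(set1, matched[[1]])),
       unmatched_set2 = sort(setdiff(set2, matched[[2]])))
}
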