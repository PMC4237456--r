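#' Build per-subfamily 2x2 tables for one categorical feature
#'
#' Cell layout per stratum: `a` = intragenic and condition-positive, `b` =
#' intragenic and condition-negative, `c` = intergenic positive, `d` =
#' intergenic negative, with intragenic meaning total or partial. Elements
#' with a missing state for this feature are excluded from this feature's
#' tables only. Subfamily labels stratify the tables because subfamily is
#' the age proxy that confounds the intragenic/intergenic comparison.
#'
#' @param l1 classified element table with a `subfamily` column.
#' @param feature name of a categorical feature column.
#' @param positive_state state counted as condition-positive.
#' @return data.frame with columns `stratum`, `a`, `b`, `c`, `d`, one row
#'   per subfamily (in order of first appearance).
#' @export
build_feature_tables <- function(l1, feature, positive_state = "conserved") {
  stopifnot("location_class" %in% names(l1), "subfamily" %in% names(l1))
  if (!feature %in% names(l1)) stop("feature absent from table: ", feature)
  state <- as.character(l1[[feature]])
  keep <- !is.na(state) & nzchar(state)
  if (!any(keep)) stop("feature '", feature, "' has no non-missing states")
  intra <- is_intragenic(l1$location_class)[keep]
  pos <- state[keep] == positive_state
  subfam <- as.character(l1$subfamily)[keep]
  out <- do.call(rbind, lapply(unique(subfam), function(s) {
    i <- subfam == s
    data.frame(stratum = s,
               a = sum(intra[i] & pos[i]), b = sum(intra[i] & !pos[i]),
               c = sum(!intra[i] & pos[i]), d = sum(!intra[i] & !pos[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mantel-Haenszel chi-square test and common odds ratio for stratified 2x2 tables
#'
#' Combines per-stratum 2x2 tables into the Cochran-Mantel-Haenszel
#' statistic without continuity correction,
#' \deqn{X^2 = (\sum_i a_i - \sum_i E_i)^2 / \sum_i V_i,}
#' with \eqn{E_i = (a_i+b_i)(a_i+c_i)/n_i} and
#' \eqn{V_i = (a_i+b_i)(c_i+d_i)(a_i+c_i)(b_i+d_i)/(n_i^2(n_i-1))},
#' referred to a chi-square distribution on 1 df. The common odds ratio is
#' the Mantel-Haenszel estimator
#' \eqn{\hat{OR} = \sum_i (a_i d_i/n_i) / \sum_i (b_i c_i/n_i)}, with a 95%
#' confidence interval from the Robins-Breslow-Greenland variance of its
#' logarithm. Strata with any zero row or column margin carry no
#' information and are dropped (counted in `n_strata_used`). For a single
#' stratum the statistic equals \eqn{((n-1)/n)} times the uncorrected
#' Pearson chi-square.
#'
#' @param strata data.frame with columns `a`, `b`, `c`, `d` (one row per
#'   stratum), e.g. from [build_feature_tables()].
#' @param conf_level confidence level for the odds-ratio interval.
#' @param correct apply the Mantel-Haenszel continuity correction
#'   (subtract 0.5 from `|sum(a) - sum(E)|`). Off by default.
#' @return list: `statistic`, `df`, `p`, `neg_log10_p`, `mh_or`, `ci_low`,
#'   `ci_high`, `n_strata_used`, `degenerate_or` (TRUE when the estimator's
#'   numerator or denominator is zero and the CI is undefined).
#' @export
#' @examples
#' mh_test(data.frame(a = 20, b = 10, c = 10, d = 20))  # OR 4, X^2 6.556
mh_test <- function(strata, conf_level = 0.95, correct = FALSE) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(strata)))
  a <- as.numeric(strata$a); b <- as.numeric(strata$b)
  cc <- as.numeric(strata$c); d <- as.numeric(strata$d)
  if (any(c(a, b, cc, d) < 0)) stop("negative cell count")
  n <- a + b + cc + d
  ok <- (a + b) > 0 & (cc + d) > 0 & (a + cc) > 0 & (b + d) > 0
  if (!any(ok)) stop("no informative strata")
  a <- a[ok]; b <- b[ok]; cc <- cc[ok]; d <- d[ok]; n <- n[ok]

  E <- (a + b) * (a + cc) / n
  V <- (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1))
  dev <- abs(sum(a) - sum(E))
  if (correct) dev <- max(0, dev - 0.5)
  statistic <- dev^2 / sum(V)
  p <- pchisq(statistic, df = 1, lower.tail = FALSE)

  R <- a * d / n
  S <- b * cc / n
  sR <- sum(R); sS <- sum(S)
  or <- if (sS > 0) sR / sS else Inf
  degenerate <- !is.finite(or) || or == 0
  if (!degenerate) {
    P <- (a + d) / n
    Q <- (b + cc) / n
    var_log <- sum(P * R) / (2 * sR^2) +
      sum(P * S + Q * R) / (2 * sR * sS) +
      sum(Q * S) / (2 * sS^2)
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(or) + c(-1, 1) * z * sqrt(var_log))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(statistic = statistic, df = 1L, p = p, neg_log10_p = -log10(p),
       mh_or = or, ci_low = ci[1], ci_high = ci[2],
       n_strata_used = length(n), degenerate_or = degenerate)
}

#' Welch unequal-variance t-test between intragenic and intergenic values
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = FALSE`
#' (Welch-Satterthwaite degrees of freedom), after dropping missing values.
#' Each group needs at least two values and at least one group must have
#' non-zero variance.
#'
#' @param values_intragenic,values_intergenic numeric vectors.
#' @return list: `t`, `df`, `p`, `mean_intragenic`, `mean_intergenic`,
#'   `higher_in` (`"intragenic"` or `"intergenic"`).
#' @export
welch_test <- function(values_intragenic, values_intergenic) {
  x <- values_intragenic[is.finite(values_intragenic)]
  y <- values_intergenic[is.finite(values_intergenic)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 non-missing values")
  if (var(x) == 0 && var(y) == 0) stop("zero variance in both groups; t undefined")
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_intragenic = mean(x), mean_intergenic = mean(y),
       higher_in = if (mean(x) >= mean(y)) "intragenic" else "intergenic")
}

#' Feature-by-feature conservation screen
#'
#' Runs, for every feature in the manifest, either a subfamily-stratified
#' Mantel-Haenszel test ([mh_test()], categorical features) or a Welch
#' t-test ([welch_test()], quantitative features) comparing intragenic with
#' intergenic elements. No multiple-testing adjustment is applied; each
#' feature is flagged significant at the fixed `alpha` (default 1.0E-03).
#' For categorical features the direction label reads the odds ratio: OR >=
#' 1 means the positive state is enriched intragenic, OR < 1 means the
#' opposite state is (the same test, read from the other side). A feature
#' whose test errors (e.g. all states missing) yields a row with
#' `status = "failed: <message>"` rather than aborting the screen.
#'
#' @param l1 classified element table.
#' @param manifest data.frame from [feature_manifest()].
#' @param alpha significance threshold.
#' @param correct continuity-correction flag passed to [mh_test()].
#' @return data.frame, one row per manifest feature, in manifest order:
#'   `feature`, `kind`, `statistic`, `df`, `p`, `neg_log10_p`, `or`,
#'   `ci_low`, `ci_high`, `n_strata_used`, `mean_intragenic`,
#'   `mean_intergenic`, `direction`, `significant`, `status`.
#' @export
run_feature_screen <- function(l1, manifest = feature_manifest(l1),
                               alpha = 1e-3, correct = FALSE) {
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- manifest$feature[i]
    kind <- manifest$kind[i]
    row <- data.frame(feature = f, kind = kind, statistic = NA_real_,
                      df = NA_real_, p = NA_real_, neg_log10_p = NA_real_,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      n_strata_used = NA_integer_,
                      mean_intragenic = NA_real_, mean_intergenic = NA_real_,
                      direction = NA_character_, significant = FALSE,
                      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch({
      if (kind == "categorical") {
        tab <- build_feature_tables(l1, f, manifest$positive_state[i])
        mh <- mh_test(tab, correct = correct)
        row$statistic <- mh$statistic; row$df <- mh$df; row$p <- mh$p
        row$neg_log10_p <- mh$neg_log10_p
        row$or <- mh$mh_or; row$ci_low <- mh$ci_low; row$ci_high <- mh$ci_high
        row$n_strata_used <- mh$n_strata_used
        row$direction <- paste0(
          if (is.finite(mh$mh_or) && mh$mh_or < 1) manifest$negative_state[i]
          else manifest$positive_state[i],
          "-enriched-intragenic")
      } else {
        intra <- is_intragenic(l1$location_class)
        v <- as.numeric(l1[[f]])
        wt <- welch_test(v[intra], v[!intra])
        row$statistic <- wt$t; row$df <- wt$df; row$p <- wt$p
        row$neg_log10_p <- -log10(wt$p)
        row$mean_intragenic <- wt$mean_intragenic
        row$mean_intergenic <- wt$mean_intergenic
        row$direction <- paste0("higher-", wt$higher_in)
      }
      row$significant <- isTRUE(row$p < alpha)
      row
    }, error = function(e) {
      row$status <- paste0("failed: ", conditionMessage(e))
      row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
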