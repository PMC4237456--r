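# Default synonym table for categorical feature cells. Keys are lower-cased
# file tokens, values the internal states. Extendable by the caller because
# database exports encode conservation states inconsistently.
default_state_synonyms <- function() {
  c(conserved = "conserved",
    mutated = "mutated",
    intact = "conserved",
    "non-intact" = "mutated",
    "not conserved" = "mutated")
}

#' Read an L1 element table
#'
#' Reads a tab-delimited L1 table in the style of full-length-L1 database
#' exports: six fixed columns (`element_id`, `chrom`, `start`, `end`,
#' `strand`, `subfamily`) followed by one column per structural feature.
#' Feature columns that parse as numbers become quantitative features; all
#' others are categorical conservation states, parsed case-insensitively
#' through a synonym table (defaults map `conserved`/`intact` and
#' `mutated`/`non-intact`). Blank cells become missing values and the element
#' is retained. Coordinates in the file are 0-based half-open, matching the
#' internal convention.
#'
#' The returned data.frame carries a `features` attribute: a data.frame with
#' columns `feature` and `kind` (`"categorical"` or `"quantitative"`), the
#' seed for [feature_manifest()].
#'
#' @param path file to read.
#' @param subfamily_labels optional character vector; when given, any
#'   subfamily outside the set is an error.
#' @param state_synonyms named character vector mapping (lower-cased) file
#'   tokens to `"conserved"`/`"mutated"`.
#' @return data.frame of elements (see Details).
#' @export
read_l1_table <- function(path, subfamily_labels = NULL,
                          state_synonyms = default_state_synonyms()) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  fixed <- c("element_id", "chrom", "start", "end", "strand", "subfamily")
  if (!all(fixed %in% names(x))) {
    stop("L1 table must declare columns: ", paste(fixed, collapse = ", "))
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  bad <- which(is.na(x$start) | is.na(x$end) | x$end <= x$start)
  if (length(bad)) {
    stop(sprintf("L1 table row %d: end (%s) must exceed start (%s)",
                 bad[1], x$end[bad[1]], x$start[bad[1]]))
  }
  if (!is.null(subfamily_labels)) {
    unknown <- setdiff(unique(x$subfamily), subfamily_labels)
    if (length(unknown)) {
      stop("unknown subfamily label(s): ", paste(unknown, collapse = ", "))
    }
  }
  # classification columns written by the pipeline are metadata, not features
  feat_cols <- setdiff(names(x), c(fixed, "location_class", "overlapped_gene_ids"))
  kinds <- character(0)
  for (f in feat_cols) {
    raw <- x[[f]]
    raw[!nzchar(trimws(raw))] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    if (all(is.na(num) == is.na(raw))) {       # every non-blank cell numeric
      x[[f]] <- num
      kinds[f] <- "quantitative"
    } else {
      tok <- tolower(trimws(raw))
      state <- unname(state_synonyms[tok])
      unknown <- which(!is.na(tok) & is.na(state))
      if (length(unknown)) {
        stop(sprintf("column '%s' row %d: unrecognised state '%s'",
                     f, unknown[1], raw[unknown[1]]))
      }
      x[[f]] <- state
      kinds[f] <- "categorical"
    }
  }
  attr(x, "features") <- data.frame(feature = feat_cols,
                                    kind = unname(kinds[feat_cols]),
                                    stringsAsFactors = FALSE)
  x
}

#' Write an L1 element table
#'
#' Inverse of [read_l1_table()]: tab-delimited, quantitative features at six
#' significant digits, missing values as blank cells. Any classification
#' columns present (`location_class`, `overlapped_gene_ids`) are written too.
#'
#' @param l1 element data.frame.
#' @param path output file.
#' @export
write_l1_table <- function(l1, path) {
  write_tsv_file(l1, path)
}

#' Build a feature manifest for the conservation screen
#'
#' A manifest declares, per feature, its `kind` (categorical or quantitative)
#' and for categorical features the condition-positive state (default
#' `"conserved"`) together with the opposite state used to label the
#' direction of enrichment. [run_feature_screen()] processes features in
#' manifest order.
#'
#' @param l1 element table read by [read_l1_table()] (uses its `features`
#'   attribute), or `NULL` when `features`/`kinds` are supplied directly.
#' @param features,kinds explicit feature names and kinds, overriding `l1`.
#' @param positive_state condition-positive categorical state.
#' @param negative_state label for the opposite state.
#' @return data.frame with columns `feature`, `kind`, `positive_state`,
#'   `negative_state`.
#' @export
feature_manifest <- function(l1 = NULL, features = NULL, kinds = NULL,
                             positive_state = "conserved",
                             negative_state = "mutated") {
  if (is.null(features)) {
    fm <- attr(l1, "features")
    if (is.null(fm)) stop("no feature manifest available; supply `features` and `kinds`")
    features <- fm$feature
    kinds <- fm$kind
  }
  stopifnot(length(features) == length(kinds),
            all(kinds %in% c("categorical", "quantitative")))
  data.frame(feature = features, kind = kinds,
             positive_state = positive_state,
             negative_state = negative_state,
             stringsAsFactors = FALSE)
}
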