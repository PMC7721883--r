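#' Named protein (gene-symbol) set
#'
#' Symbols are normalized by trimming whitespace, uppercasing, dropping
#' empties and deduplicating; overlap arithmetic is case-insensitive
#' string equality on the normalized symbols. No ortholog mapping is
#' attempted for cross-species comparisons -- uppercased symbols coincide
#' for most matrisome genes, and mismatches remain visible in the
#' membership listings for audit.
#'
#' @param symbols character vector of gene symbols.
#' @param name set label.
#' @param annotation optional data frame with a `symbol` column plus
#'   matrisome metadata (e.g. division: core | associated; category).
#' @return object of class `protein_list`.
#' @export
protein_list <- function(symbols, name = "", annotation = NULL) {
  stopifnot(is.character(symbols))
  norm <- toupper(trimws(symbols))
  norm <- norm[nzchar(norm) & !is.na(norm)]
  n_dropped <- length(norm) - length(unique(norm))
  norm <- unique(norm)
  if (!is.null(annotation)) {
    stopifnot(is.data.frame(annotation), "symbol" %in% names(annotation))
    annotation$symbol <- toupper(trimws(annotation$symbol))
    annotation <- annotation[!duplicated(annotation$symbol) &
                               annotation$symbol %in% norm, , drop = FALSE]
    annotation <- tibble::as_tibble(annotation)
  }
  structure(list(name = name, symbols = norm, annotation = annotation,
                 n_duplicates_dropped = n_dropped),
            class = "protein_list")
}

#' @export
print.protein_list <- function(x, ...) {
  cat(sprintf("<protein_list> %s: %d symbol(s)\n",
              if (nzchar(x$name)) x$name else "(unnamed)", length(x$symbols)))
  invisible(x)
}

#' @export
length.protein_list <- function(x) length(x$symbols)

#' Load a protein list from a CSV/TSV table
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param symbol_col name of the gene-symbol column.
#' @param name set label (defaults to the file name).
#' @return a [protein_list()]; the number of duplicates dropped during
#'   normalization is reported via `message()`.
#' @export
load_protein_list <- function(path, symbol_col = "symbol", name = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  tab <- read_table_auto(path)
  if (!(symbol_col %in% names(tab))) {
    stop(sprintf("column '%s' not found in %s", symbol_col, path))
  }
  pl <- protein_list(as.character(tab[[symbol_col]]),
                     name = name %||% basename(path))
  if (!length(pl$symbols)) {
    stop("no usable symbols in ", path)
  }
  if (pl$n_duplicates_dropped > 0) {
    message(sprintf("%s: dropped %d duplicate symbol(s) after normalization",
                    pl$name, pl$n_duplicates_dropped))
  }
  pl
}

read_table_auto <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

#' Set overlap (Venn counts) between two protein lists
#'
#' Exact set algebra on normalized symbols; the partition identities
#' `|A inter B| + |A only| = |A|` and `|A inter B| + |B only| = |B|` hold
#' by construction and are asserted.
#'
#' @param a,b [protein_list()] objects (bare character vectors are
#'   normalized on the fly).
#' @return object of class `overlap_result` with the counts and the
#'   membership listings.
#' @export
intersect_counts <- function(a, b) {
  if (!inherits(a, "protein_list")) a <- protein_list(a, name = "A")
  if (!inherits(b, "protein_list")) b <- protein_list(b, name = "B")
  both <- intersect(a$symbols, b$symbols)
  only_a <- setdiff(a$symbols, b$symbols)
  only_b <- setdiff(b$symbols, a$symbols)
  stopifnot(length(both) + length(only_a) == length(a$symbols),
            length(both) + length(only_b) == length(b$symbols))
  structure(
    list(name_a = a$name, name_b = b$name,
         n_a = length(a$symbols), n_b = length(b$symbols),
         n_intersect = length(both),
         n_only_a = length(only_a), n_only_b = length(only_b),
         intersect = sort(both), only_a = sort(only_a),
         only_b = sort(only_b)),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %s (n=%d) vs %s (n=%d): %d shared, %d/%d unique\n",
              x$name_a, x$n_a, x$name_b, x$n_b, x$n_intersect,
              x$n_only_a, x$n_only_b))
  invisible(x)
}

#' Differential-expression filter
#'
#' Keeps proteins whose fold change exceeds the cutoff in either direction
#' (ratio above `fc_cutoff` or below `1/fc_cutoff`, strict) and whose FDR
#' is at most `fdr_cutoff` (inclusive). The printed convention "FC > 1.5;
#' FDR < 0.1" is ambiguous between strict and inclusive at the FDR bound;
#' this implementation fixes FC strict and FDR inclusive.
#'
#' @param de_table data frame with symbol, fold-change (positive ratio)
#'   and FDR columns.
#' @param fc_cutoff fold-change cutoff (default 1.5).
#' @param fdr_cutoff FDR cutoff (default 0.1).
#' @param symbol_col,fc_col,fdr_col column names.
#' @param name label for the resulting list.
#' @return a [protein_list()] of the proteins passing both cutoffs.
#' @export
de_filter <- function(de_table, fc_cutoff = 1.5, fdr_cutoff = 0.1,
                      symbol_col = "symbol", fc_col = "fold_change",
                      fdr_col = "fdr", name = "DE") {
  miss <- setdiff(c(symbol_col, fc_col, fdr_col), names(de_table))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  fc <- de_table[[fc_col]]
  fdr <- de_table[[fdr_col]]
  if (any(fc <= 0, na.rm = TRUE)) {
    stop("fold changes must be positive ratios")
  }
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) {
    stop("FDR values must lie in [0, 1]")
  }
  keep <- !is.na(fc) & !is.na(fdr) &
    (fc > fc_cutoff | fc < 1 / fc_cutoff) & fdr <= fdr_cutoff
  protein_list(as.character(de_table[[symbol_col]][keep]), name = name)
}

#' Step-up (Benjamini-Hochberg) FDR adjustment
#'
#' The standard rank-based step-up procedure; adjusted values are monotone
#' in the raw p-value ranks and never smaller than the raw p.
#'
#' @param p numeric vector of p-values.
#' @return adjusted values of the same length.
#' @export
stepup_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Per-protein two-way ANOVA with step-up FDR (with t-test routing)
#'
#' For a 2 x 2 (or larger) design with at least one replicate per cell,
#' each protein is tested by two-way ANOVA (`value ~ A * B` when residual
#' degrees of freedom allow, else additive `A + B`), and the per-factor
#' p-values are adjusted across proteins by the step-up procedure.
#' Single-factor designs (e.g. a late-timepoint genotype comparison where
#' the second factor has one level) are routed to a per-protein unpaired
#' two-sided Student's t-test on factor A instead. Proteins with zero
#' variance in every cell are flagged and their p-values left undefined.
#'
#' @param values numeric matrix, proteins x samples, with row names as
#'   protein symbols.
#' @param factor_a,factor_b factors of length `ncol(values)`; `factor_a`
#'   must have at least two levels.
#' @return tibble with per-protein p-values and FDRs: columns `symbol`,
#'   `test`, `p_a`, `fdr_a`, `degenerate`, plus `p_b`, `p_ab`, `fdr_b`,
#'   `fdr_ab` for the two-way case.
#' @export
two_way_anova_stepup <- function(values, factor_a, factor_b) {
  stopifnot(is.matrix(values), ncol(values) == length(factor_a),
            ncol(values) == length(factor_b))
  fa <- droplevels(as.factor(factor_a))
  fb <- droplevels(as.factor(factor_b))
  if (nlevels(fa) < 2L) {
    stop("factor_a must have at least two levels")
  }
  symbols <- rownames(values) %||% as.character(seq_len(nrow(values)))
  if (nlevels(fb) < 2L) {
    res <- t(apply(values, 1L, function(v) {
      if (isTRUE(all(tapply(v, fa, stats::sd) == 0))) {
        return(c(NA_real_, 1))
      }
      c(stats::t.test(v ~ fa, var.equal = TRUE)$p.value, 0)
    }))
    out <- tibble::tibble(symbol = symbols, test = "student_t",
                          p_a = unname(res[, 1]),
                          fdr_a = unname(stepup_adjust(res[, 1])),
                          degenerate = unname(res[, 2] == 1))
    return(out)
  }
  cells <- interaction(fa, fb, drop = TRUE)
  if (any(table(cells) < 1L)) {
    stop("every design cell needs at least one observation")
  }
  with_interaction <- length(fa) > nlevels(cells)
  res <- t(apply(values, 1L, function(v) {
    if (all(tapply(v, cells, stats::sd) %in% c(0, NA))) {
      return(c(NA_real_, NA_real_, NA_real_, 1))
    }
    fit <- if (with_interaction) {
      stats::lm(v ~ fa * fb)
    } else {
      stats::lm(v ~ fa + fb)
    }
    a <- stats::anova(fit)
    p <- a[["Pr(>F)"]]
    c(p[1], p[2], if (with_interaction) p[3] else NA_real_, 0)
  }))
  tibble::tibble(symbol = symbols, test = "two_way_anova",
                 p_a = unname(res[, 1]), p_b = unname(res[, 2]),
                 p_ab = unname(res[, 3]),
                 fdr_a = unname(stepup_adjust(res[, 1])),
                 fdr_b = unname(stepup_adjust(res[, 2])),
                 fdr_ab = unname(stepup_adjust(res[, 3])),
                 degenerate = unname(res[, 4] == 1))
}

#' Paired two-sided t-test on abundance vectors
#'
#' Classical paired t on equal-length paired measurements. When every
#' pairwise difference is zero the statistic is defined as t = 0, p = 1;
#' a nonzero constant difference (zero variance) is flagged degenerate
#' with an undefined p.
#'
#' @param x,y paired numeric vectors of equal length `n >= 2` (pairs with
#'   a missing value in either vector are dropped).
#' @return list with `t`, `df`, `p`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_abundance_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 2L) {
    stop("need at least two complete pairs")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0, n = n,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = NA_real_,
                mean_diff = mean(d), n = n, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), n = n, degenerate = FALSE)
}
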