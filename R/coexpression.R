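# Cis/trans co-expression: correlate element expression with candidate
# target genes across samples, restricted to co-expressed sample subsets,
# with Benjamini-Hochberg adjustment across each result table.

#' Samples where two features are co-expressed
#'
#' @param mat Expression matrix (features x samples, TPM).
#' @param a,b Feature ids.
#' @param threshold Both features must be at or above this TPM.
#' @return Character vector of sample ids.
#' @export
coexpressed_subset <- function(mat, a, b, threshold = 1) {
  for (f in c(a, b)) {
    if (!f %in% rownames(mat)) {
      stop("feature '", f, "' absent from matrix", call. = FALSE)
    }
  }
  colnames(mat)[mat[a, ] >= threshold & mat[b, ] >= threshold]
}

#' Correlate two features across samples
#'
#' `method = "pearson-log"` computes Pearson correlation on `log2(TPM + 1)`;
#' `"spearman"` computes the rank correlation on raw TPM. The two-sided
#' p-value comes from the method's standard test ([stats::cor.test()]). When
#' either feature has zero variance on the chosen samples the coefficient is
#' undefined and reported as `NA` with `constant_input = TRUE`.
#'
#' @param mat Expression matrix.
#' @param a,b Feature ids.
#' @param samples Sample ids to use (default: all).
#' @param method `"pearson-log"` or `"spearman"`.
#' @return List with `feature_a`, `feature_b`, `n`, `r`, `p`, `method`,
#'   `constant_input`.
#' @export
correlate_features <- function(mat, a, b, samples = NULL,
                               method = c("pearson-log", "spearman")) {
  method <- match.arg(method)
  for (f in c(a, b)) {
    if (!f %in% rownames(mat)) {
      stop("feature '", f, "' absent from matrix", call. = FALSE)
    }
  }
  if (is.null(samples)) samples <- colnames(mat)
  if (length(samples) < 3L) {
    stop("at least 3 samples required for a correlation", call. = FALSE)
  }
  x <- mat[a, samples]
  y <- mat[b, samples]
  if (method == "pearson-log") {
    x <- log2(x + 1)
    y <- log2(y + 1)
  }
  base <- list(feature_a = a, feature_b = b, n = length(samples),
               method = method)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(base, list(r = NA_real_, p = NA_real_, constant_input = TRUE)))
  }
  ct <- if (method == "pearson-log") {
    stats::cor.test(x, y, method = "pearson")
  } else {
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  }
  c(base, list(r = unname(ct$estimate), p = ct$p.value,
               constant_input = FALSE))
}

#' Cis/trans correlation table for an element against a gene panel
#'
#' One row per gene, each computed on the co-expressed subset of that
#' element/gene pair; Benjamini-Hochberg adjustment across the table; rows
#' sorted by `r` descending (undefined coefficients last).
#'
#' @param mat Expression matrix.
#' @param element Element feature id.
#' @param genes Character vector of gene ids (non-empty).
#' @param threshold Co-expression TPM threshold.
#' @param method Passed to [correlate_features()].
#' @return `data.frame`: `gene`, `n`, `r`, `p`, `q` (BH-adjusted),
#'   `subset_rule`.
#' @export
cis_trans_table <- function(mat, element, genes, threshold = 1,
                            method = c("pearson-log", "spearman")) {
  method <- match.arg(method)
  if (length(genes) == 0L) stop("empty gene list", call. = FALSE)
  rows <- lapply(genes, function(g) {
    samples <- coexpressed_subset(mat, element, g, threshold)
    if (length(samples) < 3L) {
      return(data.frame(gene = g, n = length(samples), r = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    res <- correlate_features(mat, element, g, samples, method)
    data.frame(gene = g, n = res$n, r = res$r, p = res$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$subset_rule <- "co-expressed"
  tab <- tab[order(-tab$r, tab$gene, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Noncoding/coding promoter usage ratio
#'
#' Per-sample `log2((TPM_nc + pseudocount) / (TPM_coding + pseudocount))`,
#' summarised by the median and a two-sided sign test on the non-zero
#' ratios.
#'
#' @param mat Expression matrix.
#' @param noncoding,coding Feature ids.
#' @param pseudocount Added to both numerator and denominator so zero-TPM
#'   samples stay defined.
#' @return List with `ratios` (named per-sample vector), `median` and
#'   `sign_test_p`.
#' @export
promoter_ratio <- function(mat, noncoding, coding, pseudocount = 0.5) {
  for (f in c(noncoding, coding)) {
    if (!f %in% rownames(mat)) {
      stop("feature '", f, "' absent from matrix", call. = FALSE)
    }
  }
  ratios <- log2((mat[noncoding, ] + pseudocount) /
                   (mat[coding, ] + pseudocount))
  nz <- ratios[ratios != 0]
  p <- if (length(nz) == 0L) 1 else
    stats::binom.test(sum(nz > 0), length(nz))$p.value
  list(ratios = ratios, median = stats::median(ratios), sign_test_p = p)
}
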