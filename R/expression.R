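# Paired and unpaired tumor-vs-normal expression comparison.

#' Construct an expression matrix with group labels and optional pairing
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); non-negative.
#' @param groups Character vector (`"tumor"`/`"normal"`), one per sample.
#' @param pairing Optional named character vector mapping tumor sample ids
#'   (names) to their matched normal sample ids (values); must be a
#'   bijection between subsets of the two groups.
#' @return An `expr_matrix` object.
#' @export
expression_matrix <- function(values, groups, pairing = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  if (length(groups) != ncol(values)) {
    stop("one group label per sample required", call. = FALSE)
  }
  if (!all(groups %in% c("tumor", "normal"))) {
    stop("groups must be 'tumor' or 'normal'", call. = FALSE)
  }
  names(groups) <- colnames(values)
  if (!is.null(pairing)) {
    tumor_ids <- names(pairing); normal_ids <- unname(pairing)
    ok <- all(tumor_ids %in% colnames(values)[groups == "tumor"]) &&
      all(normal_ids %in% colnames(values)[groups == "normal"]) &&
      !anyDuplicated(tumor_ids) && !anyDuplicated(normal_ids)
    if (!ok) {
      stop("pairing must be a bijection between tumor and normal subsets",
           call. = FALSE)
    }
  }
  structure(list(values = values, groups = groups, pairing = pairing),
            class = "expr_matrix")
}

.expr_gene <- function(x, gene) {
  if (!gene %in% rownames(x$values)) {
    stop("gene '", gene, "' not in matrix", call. = FALSE)
  }
  x$values[gene, ]
}

#' Paired tumor-vs-normal comparison for one gene
#'
#' Two-sided paired t-test on `log2(x + 1)`-transformed values (the
#' transform is on by default for count-like RNA-seq input). Pairs with a
#' missing member are dropped with a warning. Direction is the sign of the
#' mean tumor-minus-normal difference; identical vectors give statistic 0,
#' p = 1, direction 0.
#'
#' @param x An [expression_matrix()] with pairing defined.
#' @param gene Gene id (row name).
#' @param log2_transform Apply `log2(x + 1)` before testing (default TRUE).
#' @return List with `statistic`, `p_value`, `direction` (-1/0/1), `n_pairs`,
#'   `mean_diff` (on the analysis scale).
#' @export
paired_compare <- function(x, gene, log2_transform = TRUE) {
  if (is.null(x$pairing)) stop("pairing not defined", call. = FALSE)
  v <- .expr_gene(x, gene)
  tumor <- v[names(x$pairing)]
  normal <- v[unname(x$pairing)]
  keep <- !is.na(tumor) & !is.na(normal)
  if (any(!keep)) {
    warning(sum(!keep), " pair(s) dropped: missing member", call. = FALSE)
    tumor <- tumor[keep]; normal <- normal[keep]
  }
  if (length(tumor) < 3) {
    stop("paired comparison needs >= 3 complete pairs", call. = FALSE)
  }
  if (log2_transform) {
    tumor <- log2(tumor + 1); normal <- log2(normal + 1)
  }
  d <- tumor - normal
  if (sd(d) == 0) {
    return(list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                p_value = if (mean(d) == 0) 1 else 0,
                direction = sign(mean(d)), n_pairs = length(d),
                mean_diff = mean(d)))
  }
  tt <- t.test(tumor, normal, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       direction = sign(mean(d)), n_pairs = length(d), mean_diff = mean(d))
}

#' Unpaired (Welch) tumor-vs-normal comparison for one gene
#'
#' Two-sided Welch t-test, which does not assume equal group variances.
#'
#' @inheritParams paired_compare
#' @return List with `statistic`, `p_value`, `direction`, `n_tumor`,
#'   `n_normal`, `mean_diff`.
#' @export
unpaired_compare <- function(x, gene, log2_transform = TRUE) {
  v <- .expr_gene(x, gene)
  tumor <- v[x$groups == "tumor"]; normal <- v[x$groups == "normal"]
  tumor <- tumor[!is.na(tumor)]; normal <- normal[!is.na(normal)]
  if (length(tumor) < 2 || length(normal) < 2) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  if (log2_transform) {
    tumor <- log2(tumor + 1); normal <- log2(normal + 1)
  }
  md <- mean(tumor) - mean(normal)
  if (sd(tumor) == 0 && sd(normal) == 0) {
    if (md == 0) {
      return(list(statistic = 0, p_value = 1, direction = 0,
                  n_tumor = length(tumor), n_normal = length(normal),
                  mean_diff = 0))
    }
    stop("degenerate variance: both groups constant with different means",
         call. = FALSE)
  }
  tt <- t.test(tumor, normal, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       direction = sign(md), n_tumor = length(tumor),
       n_normal = length(normal), mean_diff = md)
}

#' Conventional significance-star labels
#'
#' Maps a p-value to `ns` / `*` (< 0.05) / `**` (< 0.01) / `***` (< 0.001) /
#' `****` (< 0.0001).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("domain error: p must lie in [0, 1]", call. = FALSE)
  }
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"),
      right = FALSE) |> as.character()
}
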