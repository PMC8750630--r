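# Five-stage HCC-specific protein selection cascade.
#
# Stage order (fixed):
#   1. liver_negative      not detected in hepatocytes and bile duct cells
#   2. tumor_expressed     detected in the cancer at any level
#   3. high_multi_sample   high expression in >= min_high patient samples
#   4. pan_normal_negative not detected in any other normal tissue/cell type
#   5. prognostic          high expression associated with poor prognosis

.liver_target_cells <- c("hepatocytes", "bile duct cells")

#' Stage 1: proteins not detected in normal liver parenchyma
#'
#' A gene is retained iff every normal-tissue record for the liver target
#' cell types has level `NotDetected` and at least one such record exists.
#' Genes with no liver measurement at all are excluded (absence of evidence
#' is not evidence of absence) and reported in the `unmeasured` attribute.
#'
#' @param records Expression records ([read_expression_table()]).
#' @param target_cells Cell types that must be negative; defaults to
#'   hepatocytes and bile duct cells.
#' @param tissue Tissue name the target cells belong to.
#' @return Character vector of retained gene ids (sorted), with attribute
#'   `unmeasured` listing genes lacking any target-cell record.
#' @export
stage_liver_negative <- function(records,
                                 target_cells = .liver_target_cells,
                                 tissue = "liver") {
  if (length(target_cells) == 0) {
    stop("configuration error: target_cells must be non-empty", call. = FALSE)
  }
  all_genes <- unique(records$gene_id)
  in_target <- records$tissue == tissue & records$cell_type %in% target_cells
  tgt <- records[in_target, , drop = FALSE]
  measured <- unique(tgt$gene_id)
  positive <- unique(tgt$gene_id[tgt$level != "NotDetected"])
  keep <- sort(setdiff(measured, positive))
  attr(keep, "unmeasured") <- sort(setdiff(all_genes, measured))
  keep
}

#' Stage 2: proteins detected in the tumor at any level
#'
#' Retains genes with at least one patient sample at High, Medium or Low in
#' the named cancer. Genes absent from the pathology table are excluded and
#' reported in the `missing` attribute.
#'
#' @param profiles Pathology profiles ([read_pathology_table()]).
#' @param genes Candidate gene ids.
#' @param cancer Cancer name (default `"liver cancer"`).
#' @return Sorted character vector of retained gene ids.
#' @export
stage_tumor_expressed <- function(profiles, genes, cancer = "liver cancer") {
  if (!cancer %in% profiles$cancer) {
    stop("configuration error: cancer '", cancer,
         "' not present in pathology table", call. = FALSE)
  }
  prof <- profiles[profiles$cancer == cancer & profiles$gene_id %in% genes, ,
                   drop = FALSE]
  detected <- prof$gene_id[prof$n_high + prof$n_medium + prof$n_low >= 1]
  keep <- sort(intersect(genes, detected))
  attr(keep, "missing") <- sort(setdiff(genes, prof$gene_id))
  keep
}

#' Stage 3: high expression in more than one sample
#'
#' @inheritParams stage_tumor_expressed
#' @param min_high Minimum number of High-level patient samples (default 2,
#'   the strict reading of "more than one sample").
#' @return Sorted character vector of retained gene ids.
#' @export
stage_high_multi_sample <- function(profiles, genes, cancer = "liver cancer",
                                    min_high = 2L) {
  if (min_high < 1) {
    stop("configuration error: min_high must be >= 1", call. = FALSE)
  }
  prof <- profiles[profiles$cancer == cancer & profiles$gene_id %in% genes, ,
                   drop = FALSE]
  sort(intersect(genes, prof$gene_id[prof$n_high >= min_high]))
}

#' Stage 4: absent in all other normal tissues
#'
#' Retains genes with no normal-tissue record at a level other than
#' `NotDetected` outside the exempt (already-checked liver) cell types.
#' Optionally restricts the evidence to records at or above a reliability
#' grade.
#'
#' @inheritParams stage_liver_negative
#' @param genes Candidate gene ids.
#' @param exempt_cells Cell types exempt from the check (default: the liver
#'   target cells, which stage 1 already covered).
#' @param exempt_tissue Tissue of the exempt cells.
#' @param min_reliability Optional reliability grade (`"Enhanced"`,
#'   `"Supported"`, `"Approved"`); when set, only records at that grade or
#'   better count as evidence of expression.
#' @return Sorted character vector of retained gene ids.
#' @export
stage_pan_normal_negative <- function(records, genes,
                                      exempt_cells = .liver_target_cells,
                                      exempt_tissue = "liver",
                                      min_reliability = NULL) {
  rec <- records[records$gene_id %in% genes, , drop = FALSE]
  exempt <- rec$tissue == exempt_tissue & rec$cell_type %in% exempt_cells
  rec <- rec[!exempt, , drop = FALSE]
  if (!is.null(min_reliability)) {
    rank <- match(rec$reliability, HPA_RELIABILITY)  # 1 best .. 4 worst
    cutoff <- match(min_reliability, HPA_RELIABILITY)
    if (is.na(cutoff)) {
      stop("configuration error: unknown reliability grade '",
           min_reliability, "'", call. = FALSE)
    }
    rec <- rec[!is.na(rank) & rank <= cutoff, , drop = FALSE]
  }
  expressed <- unique(rec$gene_id[rec$level != "NotDetected"])
  sort(setdiff(genes, expressed))
}

#' Stage 5: high expression associated with poor prognosis
#'
#' Retains genes whose best-expression-cutoff p-value is strictly below
#' `alpha` with the required prognosis direction. Genes lacking prognostic
#' data are excluded and reported in the `missing` attribute.
#'
#' @inheritParams stage_tumor_expressed
#' @param alpha Significance level in (0, 1); strict inequality.
#' @param direction Required prognosis direction (default `"unfavorable"`;
#'   favorable-prognostic significance never passes).
#' @return Sorted character vector of retained gene ids.
#' @export
stage_prognostic <- function(profiles, genes, cancer = "liver cancer",
                             alpha = 0.05, direction = "unfavorable") {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("configuration error: alpha must lie in (0, 1)", call. = FALSE)
  }
  prof <- profiles[profiles$cancer == cancer & profiles$gene_id %in% genes, ,
                   drop = FALSE]
  has_data <- !is.na(prof$prognostic_p) & !is.na(prof$prognosis_direction)
  hit <- has_data & prof$prognostic_p < alpha &
    prof$prognosis_direction == direction
  keep <- sort(intersect(genes, prof$gene_id[hit]))
  attr(keep, "missing") <- sort(intersect(
    genes, c(setdiff(genes, prof$gene_id), prof$gene_id[!has_data])))
  keep
}

#' Run the full five-stage selection cascade
#'
#' Applies the stages in fixed order, each intersected with the survivors of
#' the previous one, so survivor sets are nested and stage counts are
#' non-increasing by construction.
#'
#' @param normal Normal-tissue expression records.
#' @param pathology Pathology profiles.
#' @param cancer Cancer name.
#' @param config Optional overrides: `target_cells`, `tissue`, `min_high`,
#'   `exempt_cells`, `min_reliability`, `alpha`, `direction`.
#' @return A `cascade_result` object: `stage_names`, `stage_survivors`
#'   (list of gene-id sets), `stage_counts`, `dropped` (set difference at
#'   each stage), `config_snapshot`.
#' @export
run_cascade <- function(normal, pathology, cancer = "liver cancer",
                        config = list()) {
  cfg <- utils::modifyList(list(
    target_cells = .liver_target_cells, tissue = "liver",
    min_high = 2L, exempt_cells = .liver_target_cells,
    min_reliability = NULL, alpha = 0.05, direction = "unfavorable",
    cancer = cancer
  ), config)

  s1 <- stage_liver_negative(normal, cfg$target_cells, cfg$tissue)
  s2 <- stage_tumor_expressed(pathology, s1, cfg$cancer)
  s3 <- stage_high_multi_sample(pathology, s2, cfg$cancer, cfg$min_high)
  s4 <- stage_pan_normal_negative(normal, s3, cfg$exempt_cells, cfg$tissue,
                                  cfg$min_reliability)
  s5 <- stage_prognostic(pathology, s4, cfg$cancer, cfg$alpha, cfg$direction)

  survivors <- list(liver_negative = as.character(s1),
                    tumor_expressed = as.character(s2),
                    high_multi_sample = as.character(s3),
                    pan_normal_negative = as.character(s4),
                    prognostic = as.character(s5))
  prev <- c(list(sort(unique(normal$gene_id))), survivors[-length(survivors)])
  dropped <- Map(function(before, after) sort(setdiff(before, after)),
                 prev, survivors)
  structure(list(
    stage_names = names(survivors),
    stage_survivors = survivors,
    stage_counts = vapply(survivors, length, 0L),
    dropped = dropped,
    config_snapshot = cfg
  ), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("HCC-specific protein selection cascade\n")
  n0 <- length(x$dropped[[1]]) + x$stage_counts[[1]]
  cat(sprintf("  %-22s %6d genes\n", "input universe", n0))
  for (i in seq_along(x$stage_names)) {
    cat(sprintf("  %-22s %6d survivors\n", x$stage_names[i],
                x$stage_counts[[i]]))
  }
  final <- x$stage_survivors[[length(x$stage_survivors)]]
  if (length(final) > 0 && length(final) <= 20) {
    cat("  final:", paste(final, collapse = ", "), "\n")
  }
  invisible(x)
}
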