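# Nonamer enumeration and combined affinity/stability strong-binder
# selection over a pluggable MHC class I binding predictor.

#' Enumerate all overlapping nonamers of a protein
#'
#' Slides a 9-residue window with a one-amino-acid lateral shift over the
#' entire sequence, yielding exactly `L - 8` windows for a length-`L`
#' protein.
#'
#' @param protein Either a single-row data frame / list with `protein_id`
#'   and `sequence`, or a multi-row protein data frame ([read_fasta()]), in
#'   which case all proteins are enumerated.
#' @return Data frame with `protein_id`, `start` (1-based), `peptide`.
#'   Sequences shorter than 9 produce no windows and a warning.
#' @export
enumerate_nonamers <- function(protein) {
  if (is.data.frame(protein) && nrow(protein) > 1) {
    out <- lapply(seq_len(nrow(protein)), function(i)
      enumerate_nonamers(protein[i, , drop = FALSE]))
    return(do.call(rbind, out))
  }
  id <- protein$protein_id
  seq <- protein$sequence
  L <- nchar(seq)
  if (L < 9) {
    warning("sequence '", id, "' shorter than 9 residues: no nonamers",
            call. = FALSE)
    return(data.frame(protein_id = character(), start = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  starts <- seq_len(L - 8L)
  data.frame(protein_id = id, start = starts,
             peptide = substring(seq, starts, starts + 8L),
             stringsAsFactors = FALSE)
}

#' Classify a predicted affinity into the reporting bins
#'
#' Bins partition the positive axis: `lt10` (< 10 nM), `10to50`
#' (\[10, 50) nM), `50to100` (\[50, 100) nM), `gt100` (>= 100 nM). The bins
#' are left-closed on 10 and 50 by convention (the boundary values are not
#' defined by strict-inequality phrasing alone).
#'
#' @param affinity_nM Positive numeric vector of predicted affinities in nM.
#' @return Character vector of bin labels.
#' @export
classify_affinity_bin <- function(affinity_nM) {
  if (any(!is.finite(affinity_nM)) || any(affinity_nM <= 0)) {
    stop("domain error: affinity must be positive and finite", call. = FALSE)
  }
  as.character(cut(affinity_nM, breaks = c(0, 10, 50, 100, Inf),
                   labels = c("lt10", "10to50", "50to100", "gt100"),
                   right = FALSE))
}

#' Run a binding predictor over all nonamers of a protein set
#'
#' @param proteins Protein data frame (`protein_id`, `sequence`).
#' @param alleles Character vector of HLA allele names (default
#'   `HLA-A*02:01` and `HLA-A*24:02`).
#' @param predictor A predictor object ([toy_predictor()]) providing
#'   `$affinity(peptide, allele)` and `$stability(peptide, allele)`.
#' @return Data frame with one row per (nonamer, allele): `protein_id`,
#'   `start`, `peptide`, `allele`, `affinity_nM`, `thalf_h`, `binder_class`
#'   (from the affinity predictor), `affinity_bin`.
#' @export
predict_epitopes <- function(proteins,
                             alleles = c("HLA-A*02:01", "HLA-A*24:02"),
                             predictor = toy_predictor()) {
  windows <- enumerate_nonamers(proteins)
  out <- do.call(rbind, lapply(alleles, function(al) {
    aff <- predictor$affinity(windows$peptide, al)
    stab <- predictor$stability(windows$peptide, al)
    data.frame(windows, allele = al,
               affinity_nM = aff$affinity_nM,
               thalf_h = stab$thalf_h,
               binder_class = aff$binder_class,
               stringsAsFactors = FALSE)
  }))
  out$affinity_bin <- classify_affinity_bin(out$affinity_nM)
  out
}

#' Select strong binders below an affinity cap
#'
#' Retains predictions classified `SB` by the affinity predictor with
#' predicted affinity strictly below `max_affinity` (default 100 nM, the
#' concordance cap with ex vivo binding).
#'
#' @param predictions Data frame with `affinity_nM` and `binder_class`.
#' @param max_affinity Affinity cap in nM (strict `<`).
#' @param require_class Binder class required (default `"SB"`).
#' @return The retained subset of `predictions`.
#' @export
select_strong_binders <- function(predictions, max_affinity = 100,
                                  require_class = "SB") {
  keep <- predictions$binder_class == require_class &
    predictions$affinity_nM < max_affinity
  predictions[keep, , drop = FALSE]
}

#' Combine affinity selection with binding-stability predictions
#'
#' Joins stability predictions on (peptide, allele) and retains a peptide
#' iff it passes the affinity criterion ([select_strong_binders()]) and is
#' classified `SB` by the stability predictor; a minimum Thalf can be
#' required on top. Peptides with an affinity call but no stability row are
#' dropped with a warning (count attached as attribute `n_unmatched`).
#'
#' @param predictions Affinity predictions (see [predict_epitopes()]).
#' @param stability_rows Data frame with `peptide`, `allele`, `thalf_h` and
#'   `binder_class` from the stability predictor.
#' @param max_affinity,require_class Affinity criterion, as in
#'   [select_strong_binders()].
#' @param stability_class Stability class required (default `"SB"`).
#' @param min_thalf_h Optional minimum Thalf in hours.
#' @return The retained predictions with columns `thalf_h` (from the
#'   stability predictor) and `stability_class` added.
#' @export
combine_stability <- function(predictions, stability_rows,
                              max_affinity = 100, require_class = "SB",
                              stability_class = "SB", min_thalf_h = NULL) {
  aff <- select_strong_binders(predictions, max_affinity, require_class)
  aff$thalf_h <- NULL
  aff$stability_class <- NULL  # allow re-filtering an already-joined table
  stab <- stability_rows[, c("peptide", "allele", "thalf_h", "binder_class")]
  names(stab)[4] <- "stability_class"
  merged <- merge(aff, stab, by = c("peptide", "allele"), all.x = TRUE,
                  sort = FALSE)
  unmatched <- sum(is.na(merged$stability_class))
  if (unmatched > 0) {
    warning(unmatched, " peptide(s) without stability prediction dropped",
            call. = FALSE)
  }
  keep <- !is.na(merged$stability_class) &
    merged$stability_class == stability_class
  if (!is.null(min_thalf_h)) {
    keep <- keep & merged$thalf_h >= min_thalf_h
  }
  out <- merged[keep, , drop = FALSE]
  out <- out[order(out$allele, out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- unmatched
  out
}

#' Per-protein strong-binder summary
#'
#' @param selected Selected predictions (must carry `protein_id`).
#' @return An `sb_summary` object: `counts` (data frame `protein_id`,
#'   `n_sb`), `n_total`, `mean`, `mean_2dp` (mean rounded to 2 decimals, the
#'   reporting convention), `min`, `max`. An empty selection yields an empty
#'   summary with `mean = NA` and `defined = FALSE`.
#' @export
per_protein_summary <- function(selected) {
  if (NROW(selected) == 0) {
    return(structure(list(
      counts = data.frame(protein_id = character(), n_sb = integer()),
      n_total = 0L, mean = NA_real_, mean_2dp = NA_real_,
      min = NA_integer_, max = NA_integer_, defined = FALSE
    ), class = "sb_summary"))
  }
  tab <- table(selected$protein_id)
  counts <- data.frame(protein_id = names(tab), n_sb = as.integer(tab),
                       stringsAsFactors = FALSE)
  m <- mean(counts$n_sb)
  structure(list(counts = counts, n_total = sum(counts$n_sb),
                 mean = m, mean_2dp = round(m, 2),
                 min = min(counts$n_sb), max = max(counts$n_sb),
                 defined = TRUE), class = "sb_summary")
}

#' @export
print.sb_summary <- function(x, ...) {
  if (!x$defined) {
    cat("Strong-binder summary: empty selection (mean undefined)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Strong-binder summary: %d SBs over %d proteins; mean %.2f (range %d-%d)\n",
    x$n_total, nrow(x$counts), x$mean_2dp, x$min, x$max))
  invisible(x)
}

# Deterministic 31-based string hash folded into [0, 2^31 - 2]; all
# arithmetic stays below 2^53 so the result is exact in doubles.
.toy_hash <- function(s) {
  vapply(s, function(x) {
    h <- 0
    for (k in utf8ToInt(x)) h <- (h * 31 + k) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Allele-specific anchor preference weights (positions 2 and 9).
.toy_anchor_weights <- function(allele) {
  if (grepl("^HLA-A\\*?02", allele)) {
    list(p2 = c(L = 1, M = 0.9, I = 0.7, V = 0.6, A = 0.3, T = 0.2),
         p9 = c(V = 1, L = 0.9, I = 0.8, A = 0.4, M = 0.3))
  } else if (grepl("^HLA-A\\*?24", allele)) {
    list(p2 = c(Y = 1, F = 0.9, W = 0.6, M = 0.3),
         p9 = c(F = 1, I = 0.9, L = 0.8, W = 0.5))
  } else {
    list(p2 = c(L = 0.8, M = 0.7, Y = 0.7, F = 0.6, V = 0.5),
         p9 = c(V = 0.8, L = 0.8, F = 0.7, I = 0.7))
  }
}

#' Deterministic toy MHC binding/stability predictor
#'
#' A stand-in predictor for exercising the pipeline: pseudo-affinity derives
#' from a fixed position-weight scheme over the canonical anchor positions 2
#' and 9 plus a seeded hash perturbation, mapped monotonically to SB/WB/NB
#' classes. It is fully deterministic for fixed inputs and seed. **It is not
#' a scientific predictor** and carries no information about real
#' peptide-MHC binding; real analyses should parse actual tool output via
#' [read_predictor_output()].
#'
#' Anchor-optimal peptides (e.g. Leu at position 2, Val at position 9 for
#' HLA-A*02-like alleles) always score a strictly lower affinity than the
#' same peptide with a broken anchor: the anchor term dominates the hash
#' perturbation by construction.
#'
#' @param seed Integer seed for the hash perturbation.
#' @param sb_affinity Affinity below which the class is `SB` (default 50 nM).
#' @param wb_affinity Affinity below which the class is `WB` (default
#'   500 nM).
#' @param sb_thalf Thalf at or above which the stability class is `SB`
#'   (default 4 h).
#' @param wb_thalf Thalf at or above which the stability class is `WB`
#'   (default 1 h).
#' @return A `toy_predictor` object with vectorized `$affinity(peptide,
#'   allele)` and `$stability(peptide, allele)` closures.
#' @export
toy_predictor <- function(seed = 1L, sb_affinity = 50, wb_affinity = 500,
                          sb_thalf = 4, wb_thalf = 1) {
  seed <- as.integer(seed)
  anchor_score <- function(peptide, allele) {
    w <- .toy_anchor_weights(allele)
    p2 <- substring(peptide, 2, 2); p9 <- substring(peptide, 9, 9)
    s2 <- ifelse(p2 %in% names(w$p2), w$p2[p2], 0)
    s9 <- ifelse(p9 %in% names(w$p9), w$p9[p9], 0)
    (unname(s2) + unname(s9)) / 2
  }
  perturb <- function(peptide, allele, salt) {
    h <- .toy_hash(paste0(peptide, "|", allele, "|", salt, "|", seed))
    ((h * 48271) %% 2147483647) / 2147483646
  }
  affinity_of <- function(peptide, allele) {
    if (any(nchar(peptide) != 9)) {
      stop("toy predictor accepts 9-mers only", call. = FALSE)
    }
    s <- anchor_score(peptide, allele)
    10^(3.8 - 3.4 * s + 0.4 * perturb(peptide, allele, "aff"))
  }
  obj <- list(
    seed = seed,
    thresholds = list(sb_affinity = sb_affinity, wb_affinity = wb_affinity,
                      sb_thalf = sb_thalf, wb_thalf = wb_thalf),
    affinity = function(peptide, allele) {
      a <- affinity_of(peptide, allele)
      cls <- ifelse(a < sb_affinity, "SB",
                    ifelse(a < wb_affinity, "WB", "NB"))
      data.frame(peptide = peptide, allele = allele, affinity_nM = a,
                 binder_class = cls, stringsAsFactors = FALSE)
    },
    stability = function(peptide, allele) {
      a <- affinity_of(peptide, allele)
      th <- 20 * a^(-0.35) *
        10^(0.3 * (perturb(peptide, allele, "stab") - 0.5))
      cls <- ifelse(th >= sb_thalf, "SB",
                    ifelse(th >= wb_thalf, "WB", "NB"))
      data.frame(peptide = peptide, allele = allele, thalf_h = th,
                 binder_class = cls, stringsAsFactors = FALSE)
    }
  )
  class(obj) <- "toy_predictor"
  obj
}
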