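# Exhaustive ungapped 9-mer identity scan of viral proteomes against
# candidate tumor epitopes. Replaces a heuristic BLAST search: at desk scale
# the O(N * L) scan is exact and trivial, and retained pairs are defined by
# position-wise identity, which BLAST only approximates.

#' Position-wise identity between two 9-mers
#'
#' Counts exactly matching residues position by position. The ambiguity
#' code `X` never matches anything, including another `X`.
#'
#' @param a,b Upper-case amino-acid 9-mers.
#' @return List with `identity` (0--9) and `mismatch_positions` (1-based).
#' @examples
#' identity_score("ALLALTSAV", "ALMAFTSAV")  # 7/9, mismatches at 3 and 5
#' @export
identity_score <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) != 9) {
    stop("domain error: both peptides must have length 9", call. = FALSE)
  }
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  x <- utf8ToInt("X")
  match <- ai == bi & ai != x
  list(identity = sum(match),
       mismatch_positions = which(!match))
}

#' Scan a viral proteome for homologs of tumor epitopes
#'
#' Exhaustive ungapped scan: every 9-residue window of every proteome record
#' is compared position-wise against every epitope; windows with identity at
#' or above `min_identity` are reported. Exact matches (identity 9) are
#' flagged as self-matches.
#'
#' @param epitopes Either a character vector of 9-mers or a data frame with
#'   `peptide` and optionally `protein_id` (the tumor source protein).
#' @param proteome Protein data frame (`protein_id`, `sequence`), e.g. from
#'   [read_fasta()].
#' @param min_identity Minimum identical residues, in \[1, 9\] (default 7,
#'   the weakest retained homology grade).
#' @return Data frame with one row per match: `tumor_peptide`,
#'   `tumor_protein`, `viral_accession`, `position` (1-based window start),
#'   `viral_peptide`, `identity`, `mismatch_positions` (comma-separated),
#'   `self_match`. Sorted by (tumor peptide, viral accession, position).
#' @export
scan_viral_proteome <- function(epitopes, proteome, min_identity = 7L) {
  if (min_identity < 1 || min_identity > 9) {
    stop("configuration error: min_identity must lie in [1, 9]",
         call. = FALSE)
  }
  if (is.character(epitopes)) {
    epitopes <- data.frame(peptide = epitopes,
                           protein_id = names(epitopes) %||%
                             rep(NA_character_, length(epitopes)),
                           stringsAsFactors = FALSE)
  }
  if (any(nchar(epitopes$peptide) != 9)) {
    stop("domain error: epitopes must be 9-mers", call. = FALSE)
  }
  empty <- data.frame(
    tumor_peptide = character(), tumor_protein = character(),
    viral_accession = character(), position = integer(),
    viral_peptide = character(), identity = integer(),
    mismatch_positions = character(), self_match = logical(),
    stringsAsFactors = FALSE)
  if (NROW(proteome) == 0) {
    warning("empty proteome: no matches possible", call. = FALSE)
    return(empty)
  }
  xint <- utf8ToInt("X")
  hits <- list()
  for (r in seq_len(nrow(proteome))) {
    seq <- proteome$sequence[r]
    L <- nchar(seq)
    if (L < 9) next
    ints <- utf8ToInt(seq)
    nw <- L - 8L
    # window matrix: nw rows, 9 columns of residue codes
    W <- vapply(0:8, function(j) ints[seq_len(nw) + j], numeric(nw))
    if (nw == 1L) W <- matrix(W, nrow = 1L)
    notx <- W != xint
    for (e in seq_len(nrow(epitopes))) {
      ei <- utf8ToInt(epitopes$peptide[e])
      eq <- (W == matrix(ei, nw, 9, byrow = TRUE)) & notx
      ident <- rowSums(eq)
      sel <- which(ident >= min_identity)
      for (i in sel) {
        hits[[length(hits) + 1L]] <- data.frame(
          tumor_peptide = epitopes$peptide[e],
          tumor_protein = epitopes$protein_id[e],
          viral_accession = proteome$protein_id[r],
          position = i,
          viral_peptide = substring(seq, i, i + 8L),
          identity = as.integer(ident[i]),
          mismatch_positions = paste(which(!eq[i, ]), collapse = ","),
          self_match = ident[i] == 9L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$tumor_peptide, out$viral_accession, out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter mimicry matches by predicted viral-peptide binding
#'
#' Annotates each candidate viral peptide with predicted affinity, stability
#' and binder class for the given allele, and retains pairs whose viral
#' peptide is an allowed binder class with Thalf strictly above the minimum.
#' The default admits weak binders (`allowed_classes = c("SB", "WB")`): the
#' retained published pairs include WB-class viral peptides despite the
#' "strong binder" phrasing of the selection narrative.
#'
#' @param matches Match table from [scan_viral_proteome()].
#' @param predictor Predictor object (see [toy_predictor()]).
#' @param allele HLA allele name.
#' @param min_thalf_h Minimum stability half-life in hours (strict `>`,
#'   default 3).
#' @param allowed_classes Admissible affinity binder classes.
#' @return A `mimicry_pairs` data frame: the match columns plus `allele`,
#'   `viral_affinity_nM`, `viral_thalf_h`, `viral_binder_class`.
#' @export
filter_viral_binders <- function(matches, predictor, allele,
                                 min_thalf_h = 3.0,
                                 allowed_classes = c("SB", "WB")) {
  if (NROW(matches) == 0) {
    out <- cbind(matches[0, , drop = FALSE],
                 data.frame(allele = character(),
                            viral_affinity_nM = numeric(),
                            viral_thalf_h = numeric(),
                            viral_binder_class = character()))
    class(out) <- c("mimicry_pairs", "data.frame")
    return(out)
  }
  peps <- unique(matches$viral_peptide)
  aff <- predictor$affinity(peps, allele)
  stab <- predictor$stability(peps, allele)
  idx <- match(matches$viral_peptide, peps)
  out <- matches
  out$allele <- allele
  out$viral_affinity_nM <- aff$affinity_nM[idx]
  out$viral_thalf_h <- stab$thalf_h[idx]
  out$viral_binder_class <- aff$binder_class[idx]
  keep <- out$viral_binder_class %in% allowed_classes &
    out$viral_thalf_h > min_thalf_h
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mimicry_pairs", "data.frame")
  out
}

#' Ranked mimicry pair report
#'
#' One row per pair, sorted by (allele, tumor protein, descending identity)
#' with a deterministic tie-break on the viral accession.
#'
#' @param pairs A `mimicry_pairs` data frame ([filter_viral_binders()]) or
#'   any match table carrying the same columns.
#' @return The sorted data frame.
#' @export
pair_report <- function(pairs) {
  if (NROW(pairs) == 0) return(pairs)
  al <- if (is.null(pairs$allele)) rep("", nrow(pairs)) else pairs$allele
  ord <- order(al, pairs$tumor_protein, -pairs$identity,
               pairs$viral_accession)
  out <- pairs[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
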