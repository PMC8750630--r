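# Controlled vocabularies of the IHC-based protein-atlas tables.
HPA_LEVELS <- c("NotDetected", "Low", "Medium", "High")
HPA_RELIABILITY <- c("Enhanced", "Supported", "Approved", "Uncertain")

# 20-letter amino-acid alphabet; X is tolerated but flagged as ambiguous.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# On-disk level tokens -> canonical levels.
.level_map <- c(
  "Not detected" = "NotDetected", "NotDetected" = "NotDetected",
  "Low" = "Low", "Medium" = "Medium", "High" = "High"
)

.default_normal_aliases <- list(
  gene_id = c("Gene", "gene", "gene_id"),
  gene_name = c("Gene name", "gene_name"),
  tissue = c("Tissue", "tissue"),
  cell_type = c("Cell type", "cell_type"),
  level = c("Level", "level"),
  reliability = c("Reliability", "reliability")
)

.default_pathology_aliases <- list(
  gene_id = c("Gene", "gene", "gene_id"),
  cancer = c("Cancer", "cancer"),
  n_high = c("High", "n_high"),
  n_medium = c("Medium", "n_medium"),
  n_low = c("Low", "n_low"),
  n_not_detected = c("Not detected", "n_not_detected"),
  prognostic_p = c("prognostic_p", "Best expression cutoff p", "prognostic p"),
  prognosis_direction = c("prognosis_direction", "prognosis")
)

.find_column <- function(header, aliases, field, required = TRUE) {
  hit <- aliases[[field]][aliases[[field]] %in% header]
  if (length(hit) == 0) {
    if (required) {
      stop("schema error: required column '", aliases[[field]][1],
           "' (field ", field, ") not found", call. = FALSE)
    }
    return(NA_character_)
  }
  hit[1]
}

#' Read a normal-tissue protein expression table
#'
#' Parses a tab-separated table in the Human Protein Atlas download dialect
#' (columns `Gene`, `Gene name`, `Tissue`, `Cell type`, `Level`,
#' `Reliability`) into validated expression records. Every level token must
#' belong to the controlled vocabulary (Not detected / Low / Medium / High);
#' unknown tokens are rejected with the offending row number rather than
#' silently coerced.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @param aliases Optional column-alias map overriding the defaults; a named
#'   list whose elements are candidate header names per field.
#' @param na_as_not_detected If `TRUE`, empty or `"N/A"` level cells are read
#'   as `NotDetected`; the default is to reject them, since a missing IHC
#'   call is not evidence of absence.
#' @return A `data.frame` with columns `gene_id`, `gene_name`, `tissue`,
#'   `cell_type`, `level` (factor over the level vocabulary), `reliability`,
#'   in file order.
#' @seealso [write_expression_table()], [read_pathology_table()]
#' @export
read_expression_table <- function(path, aliases = NULL,
                                  na_as_not_detected = FALSE) {
  aliases <- utils::modifyList(.default_normal_aliases, aliases %||% list())
  tab <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL, fileEncoding = "UTF-8")
  header <- names(tab)
  cols <- c("gene_id", "tissue", "cell_type", "level")
  src <- vapply(cols, function(f) .find_column(header, aliases, f), "")
  gene_name_col <- .find_column(header, aliases, "gene_name", required = FALSE)
  rel_col <- .find_column(header, aliases, "reliability", required = FALSE)

  level_raw <- tab[[src[["level"]]]]
  if (na_as_not_detected) {
    level_raw[is.na(level_raw) | level_raw %in% c("", "N/A", "NA")] <-
      "Not detected"
  }
  level <- unname(.level_map[level_raw])
  bad <- which(is.na(level))
  if (length(bad) > 0) {
    stop("validation error: unknown level token '", level_raw[bad[1]],
         "' at row ", bad[1], call. = FALSE)
  }

  reliability <- if (!is.na(rel_col)) tab[[rel_col]] else
    rep(NA_character_, nrow(tab))
  bad_rel <- which(!is.na(reliability) & reliability != "" &
                     !reliability %in% HPA_RELIABILITY)
  if (length(bad_rel) > 0) {
    stop("validation error: unknown reliability token '",
         reliability[bad_rel[1]], "' at row ", bad_rel[1], call. = FALSE)
  }

  out <- data.frame(
    gene_id = tab[[src[["gene_id"]]]],
    gene_name = if (!is.na(gene_name_col)) tab[[gene_name_col]] else
      tab[[src[["gene_id"]]]],
    tissue = tab[[src[["tissue"]]]],
    cell_type = tab[[src[["cell_type"]]]],
    level = factor(level, levels = HPA_LEVELS),
    reliability = reliability,
    stringsAsFactors = FALSE
  )
  key <- paste(out$gene_id, out$tissue, out$cell_type, sep = "\r")
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (gene, tissue, cell type) record at row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  out
}

#' Write expression records back in the protein-atlas dialect
#'
#' @param records A data frame as returned by [read_expression_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(records, path) {
  disk_level <- c(NotDetected = "Not detected", Low = "Low",
                  Medium = "Medium", High = "High")
  out <- data.frame(
    Gene = records$gene_id, `Gene name` = records$gene_name,
    Tissue = records$tissue, `Cell type` = records$cell_type,
    Level = unname(disk_level[as.character(records$level)]),
    Reliability = records$reliability,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pathology (cancer) protein expression table
#'
#' Parses per-gene patient counts at each IHC level for one or more cancers,
#' plus optional prognostic annotation (best-expression-cutoff p-value and
#' prognosis direction). Counts must be non-negative integers; missing
#' prognostic fields become `NA`, never zero.
#'
#' @inheritParams read_expression_table
#' @return A `data.frame` with columns `gene_id`, `cancer`, `n_high`,
#'   `n_medium`, `n_low`, `n_not_detected`, `prognostic_p`,
#'   `prognosis_direction`.
#' @export
read_pathology_table <- function(path, aliases = NULL) {
  aliases <- utils::modifyList(.default_pathology_aliases, aliases %||% list())
  tab <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL, fileEncoding = "UTF-8")
  header <- names(tab)
  need <- c("gene_id", "cancer", "n_high", "n_medium", "n_low",
            "n_not_detected")
  src <- vapply(need, function(f) .find_column(header, aliases, f), "")
  p_col <- .find_column(header, aliases, "prognostic_p", required = FALSE)
  dir_col <- .find_column(header, aliases, "prognosis_direction",
                          required = FALSE)

  parse_count <- function(field) {
    raw <- tab[[src[[field]]]]
    suppress <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(suppress))
    if (length(bad) > 0) {
      stop("parse error: non-numeric count '", raw[bad[1]], "' in column '",
           src[[field]], "' at row ", bad[1], call. = FALSE)
    }
    neg <- which(suppress < 0)
    if (length(neg) > 0) {
      stop("validation error: negative count at row ", neg[1], " in column '",
           src[[field]], "'", call. = FALSE)
    }
    as.integer(round(suppress))
  }

  prognostic_p <- rep(NA_real_, nrow(tab))
  if (!is.na(p_col)) {
    raw <- tab[[p_col]]
    nonempty <- !is.na(raw) & raw != "" & raw != "NA"
    prognostic_p[nonempty] <- as.numeric(raw[nonempty])
    if (any(prognostic_p <= 0 | prognostic_p > 1, na.rm = TRUE)) {
      stop("validation error: prognostic p-value outside (0, 1]",
           call. = FALSE)
    }
  }
  direction <- rep(NA_character_, nrow(tab))
  if (!is.na(dir_col)) {
    raw <- tab[[dir_col]]
    nonempty <- !is.na(raw) & raw != "" & raw != "NA"
    bad <- nonempty & !raw %in% c("unfavorable", "favorable")
    if (any(bad)) {
      stop("validation error: unknown prognosis direction '",
           raw[which(bad)[1]], "' at row ", which(bad)[1], call. = FALSE)
    }
    direction[nonempty] <- raw[nonempty]
  }

  data.frame(
    gene_id = tab[[src[["gene_id"]]]],
    cancer = tab[[src[["cancer"]]]],
    n_high = parse_count("n_high"),
    n_medium = parse_count("n_medium"),
    n_low = parse_count("n_low"),
    n_not_detected = parse_count("n_not_detected"),
    prognostic_p = prognostic_p,
    prognosis_direction = direction,
    stringsAsFactors = FALSE
  )
}

#' Write a pathology table in the protein-atlas dialect
#'
#' @param profiles Data frame as returned by [read_pathology_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathology_table <- function(profiles, path) {
  out <- data.frame(
    Gene = profiles$gene_id, Cancer = profiles$cancer,
    High = profiles$n_high, Medium = profiles$n_medium,
    Low = profiles$n_low, `Not detected` = profiles$n_not_detected,
    prognostic_p = ifelse(is.na(profiles$prognostic_p), "",
                          format(profiles$prognostic_p, digits = 15)),
    prognosis_direction = ifelse(is.na(profiles$prognosis_direction), "",
                                 profiles$prognosis_direction),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and checked against the 20-letter amino-acid
#' alphabet; `X` is permitted but flagged. The record identifier is the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file (multi-line sequences allowed).
#' @return A `data.frame` with columns `protein_id`, `sequence`,
#'   `has_ambiguous` (`TRUE` when the sequence contains `X`).
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  names(seqs) <- NULL
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    stop("validation error: empty sequence for record '", ids[empty[1]], "'",
         call. = FALSE)
  }
  allowed <- c(AA_ALPHABET, "X")
  for (i in seq_along(seqs)) {
    residues <- strsplit(seqs[i], "")[[1]]
    bad <- setdiff(unique(residues), allowed)
    if (length(bad) > 0) {
      stop("validation error: illegal residue '", bad[1], "' in record '",
           ids[i], "'", call. = FALSE)
    }
  }
  data.frame(protein_id = ids, sequence = seqs,
             has_ambiguous = grepl("X", seqs, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param proteins Data frame with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  set <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                          proteins$protein_id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read MHC binding/stability predictor output
#'
#' Parses the tabular text emitted by NetMHCpan-4.1-style affinity predictors
#' and NetMHCstabpan-1.0-style stability predictors, or a plain five-column
#' `simple_tsv` layout (`peptide allele affinity_nM thalf_h binder_class`).
#' Rows whose peptide is not a 9-mer are skipped with a warning; the skip
#' count is attached as attribute `n_skipped`.
#'
#' The two tool dialects are recognised by data lines of the form
#' `pos allele peptide score value [<= SB|WB]`: for `netmhcpan41` the value
#' column is affinity in nM, for `netmhcstabpan10` it is Thalf in hours.
#' Comment lines (`#`), separator lines (`---`) and header lines are ignored.
#'
#' @param path Path to the predictor output file.
#' @param dialect One of `"simple_tsv"`, `"netmhcpan41"`, `"netmhcstabpan10"`.
#' @return A `data.frame` with columns `peptide`, `allele`, `affinity_nM`,
#'   `thalf_h`, `binder_class` (`SB`/`WB`/`NB`); unavailable quantities are
#'   `NA`.
#' @export
read_predictor_output <- function(path,
                                  dialect = c("simple_tsv", "netmhcpan41",
                                              "netmhcstabpan10")) {
  if (length(dialect) != 1 || !dialect %in%
        c("simple_tsv", "netmhcpan41", "netmhcstabpan10")) {
    dialect <- match.arg(dialect)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|-)", lines) & nzchar(trimws(lines))]
  rows <- list()
  n_skipped <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (dialect == "simple_tsv") {
      if (identical(tolower(tok[1]), "peptide")) next  # header
      if (length(tok) < 4) {
        stop("parse error: simple_tsv line with fewer than 4 fields: ", ln,
             call. = FALSE)
      }
      pep <- tok[1]; allele <- tok[2]
      aff <- as.numeric(tok[3])
      thalf <- if (length(tok) >= 5) as.numeric(tok[4]) else NA_real_
      cls <- tok[length(tok)]
    } else {
      # tool layout: pos allele peptide score value [<= SB]
      if (is.na(suppressWarnings(as.integer(tok[1])))) next  # header line
      if (length(tok) < 5) next
      allele <- tok[2]; pep <- tok[3]
      val <- as.numeric(tok[5])
      cls <- if (length(tok) >= 7 && tok[length(tok) - 1] == "<=")
        tok[length(tok)] else "NB"
      if (dialect == "netmhcpan41") {
        aff <- val; thalf <- NA_real_
      } else {
        aff <- NA_real_; thalf <- val
      }
    }
    if (!cls %in% c("SB", "WB", "NB")) {
      stop("validation error: unknown binder class '", cls, "'",
           call. = FALSE)
    }
    if (nchar(pep) != 9) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (!is.na(aff) && aff <= 0) {
      stop("validation error: non-positive affinity for peptide ", pep,
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = pep, allele = allele, affinity_nM = aff, thalf_h = thalf,
      binder_class = cls, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(peptide = character(), allele = character(),
               affinity_nM = numeric(), thalf_h = numeric(),
               binder_class = character(), stringsAsFactors = FALSE)
  if (n_skipped > 0) {
    warning(n_skipped, " row(s) skipped: peptide length != 9", call. = FALSE)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}
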