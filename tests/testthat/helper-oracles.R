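# Independent oracles and small fixture builders shared across tests.

# Naive double-loop mimicry scan: every epitope against every window via
# substring + character comparison. Deliberately independent of the
# package's vectorized scan; X never matches anything.
naive_scan <- function(epitopes, proteome, min_identity) {
  hits <- data.frame(tumor_peptide = character(),
                     viral_accession = character(),
                     position = integer(), identity = integer(),
                     stringsAsFactors = FALSE)
  for (e in epitopes) {
    ec <- strsplit(e, "")[[1]]
    for (r in seq_len(nrow(proteome))) {
      s <- proteome$sequence[r]
      L <- nchar(s)
      if (L < 9) next
      for (i in seq_len(L - 8)) {
        wc <- strsplit(substr(s, i, i + 8), "")[[1]]
        idt <- sum(ec == wc & ec != "X")
        if (idt >= min_identity) {
          hits <- rbind(hits, data.frame(
            tumor_peptide = e, viral_accession = proteome$protein_id[r],
            position = i, identity = idt, stringsAsFactors = FALSE))
        }
      }
    }
  }
  hits[order(hits$tumor_peptide, hits$viral_accession, hits$position), ,
       drop = FALSE]
}

# Canonical match-key representation for comparing scan outputs.
scan_key <- function(m) {
  if (NROW(m) == 0) return(character(0))
  sort(paste(m$tumor_peptide, m$viral_accession, m$position, m$identity,
             sep = "|"))
}

# A fixed-output predictor stub: affinity/stability looked up per peptide.
stub_predictor <- function(table) {
  list(
    affinity = function(peptide, allele) {
      i <- match(peptide, table$peptide)
      data.frame(peptide = peptide, allele = allele,
                 affinity_nM = table$affinity_nM[i],
                 binder_class = table$binder_class[i],
                 stringsAsFactors = FALSE)
    },
    stability = function(peptide, allele) {
      i <- match(peptide, table$peptide)
      data.frame(peptide = peptide, allele = allele,
                 thalf_h = table$thalf_h[i],
                 binder_class = table$stability_class[i],
                 stringsAsFactors = FALSE)
    }
  )
}

# Random amino-acid sequence (test-local; independent of the generators).
rand_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# Event table with exact planted positive counts among gated events.
make_events <- function(n_gated, pos_counts, channels = names(pos_counts)) {
  ev <- data.frame(live = rep(TRUE, n_gated), cd3 = rep(5000, n_gated),
                   cd8 = rep(5000, n_gated))
  for (ch in channels) {
    v <- rep(100, n_gated)
    if (pos_counts[[ch]] > 0) v[seq_len(pos_counts[[ch]])] <- 5000
    ev[[ch]] <- v
  }
  ev
}
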