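# Synthetic-data generators: every input the pipeline consumes can be
# produced with planted, machine-readable ground truth, so all stages run
# and are testable without any download. Background residue frequencies are
# uniform over the 20 amino acids, which keeps false-positive rates of the
# mimicry scan exactly analyzable.

.sample_aa <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

#' Generate synthetic normal-tissue and pathology tables with ground truth
#'
#' Emulates the protein-atlas table pair consumed by the selection cascade.
#' Planted positive genes satisfy all five cascade stages by construction;
#' every distractor gene fails exactly one stage, cycling through the five
#' stages so each is exercised (stage-coverage guarantee).
#'
#' @param config List with `seed` (mandatory), `n_genes` (default 100),
#'   `n_planted` (default 9), `cancer` (default `"liver cancer"`),
#'   `n_patients` (IHC patient count per gene, default 12), and optionally
#'   `tissues` (named list tissue -> cell types; must include the liver
#'   roster).
#' @param dir Optional directory; when given, `normal.tsv`,
#'   `pathology.tsv` and `truth.json` are written there.
#' @return List with `normal` (expression records), `pathology` (profiles),
#'   `truth` (list: `planted`, `fail_stage` named by distractor gene,
#'   `cancer`), and `paths` when `dir` was given.
#' @export
gen_hpa_tables <- function(config, dir = NULL) {
  stopifnot(!is.null(config$seed))
  n_genes <- config$n_genes %||% 100L
  n_planted <- config$n_planted %||% 9L
  cancer <- config$cancer %||% "liver cancer"
  n_patients <- config$n_patients %||% 12L
  if (n_planted > n_genes) {
    stop("configuration error: n_planted > n_genes", call. = FALSE)
  }
  tissues <- config$tissues %||% list(
    liver = c("hepatocytes", "bile duct cells"),
    `cerebral cortex` = c("neuronal cells", "glial cells"),
    kidney = c("cells in tubules"),
    lung = c("pneumocytes", "macrophages"),
    skin = c("keratinocytes")
  )

  with_seed(config$seed, {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    planted <- if (n_planted > 0) sort(sample(genes, n_planted)) else
      character(0)
    distractors <- setdiff(genes, planted)
    fail_stage <- setNames(
      rep(c("liver_negative", "tumor_expressed", "high_multi_sample",
            "pan_normal_negative", "prognostic"),
          length.out = length(distractors)),
      distractors)

    roster <- do.call(rbind, lapply(names(tissues), function(ts)
      data.frame(tissue = ts, cell_type = tissues[[ts]],
                 stringsAsFactors = FALSE)))
    liver_cells <- tissues$liver
    nonliver <- roster[roster$tissue != "liver", , drop = FALSE]

    normal_rows <- vector("list", n_genes)
    path_rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      g <- genes[i]
      stage <- if (g %in% planted) "pass" else fail_stage[[g]]
      lvl <- setNames(rep("NotDetected", nrow(roster)),
                      paste(roster$tissue, roster$cell_type, sep = "|"))
      if (stage == "liver_negative") {
        # expressed in one liver target cell
        bad <- sample(liver_cells, 1)
        lvl[paste("liver", bad, sep = "|")] <-
          sample(c("Low", "Medium", "High"), 1)
      } else if (stage == "pan_normal_negative") {
        # clean in liver, expressed somewhere else
        k <- sample(nrow(nonliver), 1)
        lvl[paste(nonliver$tissue[k], nonliver$cell_type[k], sep = "|")] <-
          sample(c("Low", "Medium", "High"), 1)
      }
      normal_rows[[i]] <- data.frame(
        gene_id = g, gene_name = g, tissue = roster$tissue,
        cell_type = roster$cell_type, level = unname(lvl),
        reliability = sample(HPA_RELIABILITY, nrow(roster), replace = TRUE),
        stringsAsFactors = FALSE)

      # pathology counts
      if (stage == "tumor_expressed") {
        counts <- c(0L, 0L, 0L, n_patients)
      } else if (stage == "high_multi_sample") {
        nh <- sample(0:1, 1)
        nm <- sample(1:3, 1)
        counts <- c(nh, nm, sample(0:2, 1), 0L)
        counts[4] <- n_patients - sum(counts[1:3])
      } else {
        nh <- sample(2:6, 1)
        nm <- sample(0:3, 1); nl <- sample(0:2, 1)
        counts <- c(nh, nm, nl, n_patients - nh - nm - nl)
      }
      if (stage == "prognostic") {
        # significant-but-favorable or non-significant unfavorable
        if (runif(1) < 0.5) {
          p <- runif(1, 1e-4, 0.049); dirn <- "favorable"
        } else {
          p <- runif(1, 0.051, 0.9); dirn <- "unfavorable"
        }
      } else {
        p <- runif(1, 5e-4, 0.049); dirn <- "unfavorable"
      }
      path_rows[[i]] <- data.frame(
        gene_id = g, cancer = cancer,
        n_high = counts[1], n_medium = counts[2], n_low = counts[3],
        n_not_detected = counts[4],
        prognostic_p = p, prognosis_direction = dirn,
        stringsAsFactors = FALSE)
    }
    normal <- do.call(rbind, normal_rows)
    normal$level <- factor(normal$level, levels = HPA_LEVELS)
    pathology <- do.call(rbind, path_rows)
    truth <- list(planted = planted, fail_stage = as.list(fail_stage),
                  cancer = cancer, seed = config$seed)

    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(normal = file.path(dir, "normal.tsv"),
                    pathology = file.path(dir, "pathology.tsv"),
                    truth = file.path(dir, "truth.json"))
      write_expression_table(normal, paths$normal)
      write_pathology_table(pathology, paths$pathology)
      jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                           digits = NA)
    }
    list(normal = normal, pathology = pathology, truth = truth,
         paths = paths)
  })
}

#' Generate a survival cohort calibrated to target 5-year survival rates
#'
#' Event times are exponential with per-group rate
#' `lambda = -log(surv5) / 5`, so the 5-year survival of each group equals
#' its target in expectation. The high-expression group gets expression
#' values centered at 3, the low group at 1, making 2 the planted cutoff.
#' Censoring is off by default so the Kaplan-Meier estimate equals the
#' empirical surviving fraction.
#'
#' @param n_per_group Subjects per expression group.
#' @param surv5_high,surv5_low Target 5-year survival fractions in (0, 1)
#'   for the high- and low-expression groups.
#' @param seed RNG seed.
#' @param censor_time Optional administrative follow-up horizon in years;
#'   when set, times are uniformly censored on (0, censor_time).
#' @return Data frame (`subject_id`, `time`, `event`, `expression`) with
#'   attributes `group` and `cutoff` (the planted dichotomization point).
#' @export
gen_survival_cohort <- function(n_per_group, surv5_high = 0.28,
                                surv5_low = 0.53, seed = 1,
                                censor_time = NULL) {
  for (s in c(surv5_high, surv5_low)) {
    if (!is.finite(s) || s <= 0 || s >= 1) {
      stop("5-year survival targets must lie in (0, 1)", call. = FALSE)
    }
  }
  with_seed(seed, {
    lam <- c(high = -log(surv5_high) / 5, low = -log(surv5_low) / 5)
    grp <- rep(c("high", "low"), each = n_per_group)
    time <- rexp(2 * n_per_group, rate = lam[grp])
    event <- rep(1L, 2 * n_per_group)
    if (!is.null(censor_time)) {
      cens <- runif(2 * n_per_group, 0, censor_time)
      event <- as.integer(time <= cens)
      time <- pmin(time, cens)
    }
    expr <- rnorm(2 * n_per_group,
                  mean = ifelse(grp == "high", 3, 1), sd = 0.25)
    cohort <- data.frame(
      subject_id = sprintf("S%04d", seq_len(2 * n_per_group)),
      time = time, event = event, expression = expr,
      stringsAsFactors = FALSE)
    attr(cohort, "group") <- grp
    attr(cohort, "cutoff") <- 2
    attr(cohort, "targets") <- c(high = surv5_high, low = surv5_low)
    cohort
  })
}

# Mutate `epitope` at `9 - identity` random positions, each to a different
# residue (never X), yielding a homolog with exactly the requested identity.
.mutate_to_identity <- function(epitope, identity) {
  if (identity < 1 || identity > 9) {
    stop("requested identity must lie in [1, 9]", call. = FALSE)
  }
  res <- strsplit(epitope, "")[[1]]
  n_mut <- 9L - identity
  if (n_mut == 0) return(epitope)
  pos <- sample(9L, n_mut)
  for (p in pos) {
    res[p] <- sample(setdiff(AA_ALPHABET, res[p]), 1)
  }
  paste(res, collapse = "")
}

#' Generate synthetic tumor-protein and viral-proteome FASTA with ground truth
#'
#' Tumor proteins are i.i.d. uniform random sequences with optional planted
#' anchor-strong epitopes embedded at recorded positions; the viral proteome
#' carries planted homologs at the requested identity to their target
#' epitopes, at recorded accessions and positions. Verbatim peptides (e.g.
#' published pairs) can be planted directly via `planted_homologs$peptide`.
#'
#' @param config List with `seed` (mandatory) plus optionally:
#'   `n_tumor_proteins` (default 9), `tumor_protein_length` (default 120),
#'   `n_viral_proteins` (default 50), `viral_protein_length` (default 200),
#'   `planted_epitopes` data frame (`protein_id`, `position`, `peptide`)
#'   embedded into the tumor proteins, and `planted_homologs` data frame
#'   (`epitope`, `viral_id`, `position`, and either `identity` or a
#'   verbatim `peptide`).
#' @param dir Optional directory; writes `tumor.fasta`, `viral.fasta`,
#'   `truth.json`.
#' @return List with `tumor`, `viral` (protein data frames), `truth`
#'   (planted coordinates, including the realized homolog peptides and
#'   identities), `paths`.
#' @export
gen_proteomes <- function(config, dir = NULL) {
  stopifnot(!is.null(config$seed))
  n_tum <- config$n_tumor_proteins %||% 9L
  len_tum <- config$tumor_protein_length %||% 120L
  n_vir <- config$n_viral_proteins %||% 50L
  len_vir <- config$viral_protein_length %||% 200L

  with_seed(config$seed, {
    tumor <- data.frame(
      protein_id = sprintf("TUM%03d", seq_len(n_tum)),
      sequence = vapply(seq_len(n_tum), function(i) .sample_aa(len_tum), ""),
      stringsAsFactors = FALSE)
    pe <- config$planted_epitopes
    if (!is.null(pe)) {
      for (i in seq_len(nrow(pe))) {
        r <- match(pe$protein_id[i], tumor$protein_id)
        if (is.na(r)) stop("unknown tumor protein '", pe$protein_id[i], "'",
                           call. = FALSE)
        substr(tumor$sequence[r], pe$position[i], pe$position[i] + 8L) <-
          pe$peptide[i]
      }
    }
    viral <- data.frame(
      protein_id = sprintf("VIR%03d", seq_len(n_vir)),
      sequence = vapply(seq_len(n_vir), function(i) .sample_aa(len_vir), ""),
      stringsAsFactors = FALSE)
    ph <- config$planted_homologs
    realized <- NULL
    if (!is.null(ph)) {
      realized <- ph
      realized$peptide <- realized$peptide %||% rep(NA_character_, nrow(ph))
      for (i in seq_len(nrow(ph))) {
        hom <- if (!is.na(realized$peptide[i])) realized$peptide[i] else
          .mutate_to_identity(ph$epitope[i], ph$identity[i])
        realized$peptide[i] <- hom
        realized$identity[i] <-
          identity_score(ph$epitope[i], hom)$identity
        r <- match(ph$viral_id[i], viral$protein_id)
        if (is.na(r)) stop("unknown viral protein '", ph$viral_id[i], "'",
                           call. = FALSE)
        substr(viral$sequence[r], ph$position[i], ph$position[i] + 8L) <- hom
      }
    }
    truth <- list(planted_epitopes = pe, planted_homologs = realized,
                  seed = config$seed)
    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(tumor = file.path(dir, "tumor.fasta"),
                    viral = file.path(dir, "viral.fasta"),
                    truth = file.path(dir, "truth.json"))
      write_fasta(tumor, paths$tumor)
      write_fasta(viral, paths$viral)
      jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                           digits = NA)
    }
    list(tumor = tumor, viral = viral, truth = truth, paths = paths)
  })
}

#' Default synthetic multimer panel
#'
#' HCC-group marginal channel frequencies and cross-reactive pair
#' frequencies (fractions of gated CD3+CD8+ events) mirroring the published
#' group averages for the three TAA--viral epitope pairs (ISG15 /
#' calicivirus, MDK / HCV, C1QTNF12 / HBV). Healthy-donor levels are not
#' published and default to a uniform low background.
#'
#' @return List with `channels`, `pairs`, `cross`, `healthy_channels`,
#'   `healthy_cross`.
#' @export
default_multimer_panel <- function() {
  list(
    channels = c(ISG15_TAA = 0.0032, MDK_TAA = 0.0088,
                 C1QTNF12_TAA = 0.0055,
                 ISG15_VIRAL = 0.0046, MDK_VIRAL = 0.0016,
                 C1QTNF12_VIRAL = 0.0016),
    pairs = list(ISG15 = c("ISG15_TAA", "ISG15_VIRAL"),
                 MDK = c("MDK_TAA", "MDK_VIRAL"),
                 C1QTNF12 = c("C1QTNF12_TAA", "C1QTNF12_VIRAL")),
    cross = c(ISG15 = 0.00298, MDK = 0.0011, C1QTNF12 = 0.0004),
    healthy_channels = c(ISG15_TAA = 0.001, MDK_TAA = 0.001,
                         C1QTNF12_TAA = 0.001, ISG15_VIRAL = 0.001,
                         MDK_VIRAL = 0.001, C1QTNF12_VIRAL = 0.001),
    healthy_cross = c(ISG15 = 0.0002, MDK = 0.0002, C1QTNF12 = 0.0002)
  )
}

# One donor's event table: n_gated events passing the live/CD3/CD8 gate plus
# a fraction of non-gated events. Clone events carry high intensity in their
# channel(s); channel noise is log-normal, with positive and background
# populations separated by far more than 5 CV so threshold gating at the
# geometric midpoint is unambiguous.
.gen_multimer_events <- function(n_gated, channel_freqs, pairs, cross_freqs,
                                 nongated_fraction = 0.25, sdlog = 0.25,
                                 meanlog_bg = log(100),
                                 meanlog_pos = log(5000)) {
  channels <- names(channel_freqs)
  if (any(channel_freqs < 0 | channel_freqs > 1)) {
    stop("clone frequencies must lie in [0, 1]", call. = FALSE)
  }
  single <- channel_freqs
  cross_freqs <- setNames(
    vapply(names(pairs), function(pn)
      if (pn %in% names(cross_freqs)) cross_freqs[[pn]] else 0, 0),
    names(pairs))
  for (pn in names(pairs)) {
    p <- pairs[[pn]]; cf <- cross_freqs[[pn]]
    if (!all(p %in% channels)) {
      stop("configuration error: pair '", pn,
           "' references an unknown channel", call. = FALSE)
    }
    if (cf > min(channel_freqs[p])) {
      stop("cross frequency of pair '", pn,
           "' exceeds a marginal channel frequency", call. = FALSE)
    }
    single[p] <- single[p] - cf
  }
  cats <- c("background", channels, names(pairs))
  prob <- c(NA, unname(single), unname(cross_freqs[names(pairs)]))
  prob[1] <- 1 - sum(prob[-1])
  if (prob[1] < 0) {
    stop("clone frequencies sum to more than 1", call. = FALSE)
  }
  assign_cat <- sample(cats, n_gated, replace = TRUE, prob = prob)

  n_extra <- round(n_gated * nongated_fraction)
  n <- n_gated + n_extra
  live <- c(rep(TRUE, n_gated), runif(n_extra) < 0.5)
  cd3 <- c(rlnorm(n_gated, meanlog_pos, sdlog),
           rlnorm(n_extra, meanlog_bg, sdlog))
  cd8 <- c(rlnorm(n_gated, meanlog_pos, sdlog),
           rlnorm(n_extra, meanlog_bg, sdlog))
  ev <- data.frame(live = live, cd3 = cd3, cd8 = cd8)
  for (ch in channels) {
    hot <- c(assign_cat == ch |
               assign_cat %in% names(pairs)[vapply(pairs, function(p)
                 ch %in% p, TRUE)],
             rep(FALSE, n_extra))
    ev[[ch]] <- ifelse(hot, rlnorm(n, meanlog_pos, sdlog),
                       rlnorm(n, meanlog_bg, sdlog))
  }
  ev
}

#' Generate synthetic validation-assay data with ground truth
#'
#' Produces the three assay input families: T2 binding dose series
#' (saturating dose-response in FI), BFA decay series (exponential kinetics
#' with configured half-life and optional log-normal noise), and pMHC
#' multimer event tables (mixtures of background events and planted clones
#' at configured frequencies; see [default_multimer_panel()] for the
#' default panel).
#'
#' @param config List with `seed` (mandatory) plus optionally:
#'   `binding` -- data frame (`peptide`, `fmax`, `ec50_uM`, `noise_cv`);
#'   `decay` -- data frame (`peptide`, `halflife_h`, `noise_cv`);
#'   `timepoints_h`; `concentrations_uM`; `mfi_background`; `mfi0`;
#'   `replicates`;
#'   `multimer` -- list with `donors` (data frame `donor_id`, `group`,
#'   `n_gated`), `channels`, `pairs`, `cross` (HCC group),
#'   `healthy_channels`, `healthy_cross`.
#' @return List with `binding` (list of [binding_series()]), `decay` (list
#'   of [decay_series()]), `multimer` (list: `events` per donor, `groups`,
#'   `thresholds`, `pairs`), and `truth` (all planted parameters).
#' @export
gen_assay_data <- function(config) {
  stopifnot(!is.null(config$seed))
  conc <- config$concentrations_uM %||% c(5, 10, 20, 50, 100)
  tps <- config$timepoints_h %||% c(0, 2, 4, 6, 8)
  bg <- config$mfi_background %||% 100
  mfi0 <- config$mfi0 %||% 1000
  reps <- config$replicates %||% 3L

  binding_cfg <- config$binding %||% data.frame(
    peptide = c("MLAGNEFQV", "ALLALTSAV", "LLGPQLVLL", "SIINFEKL_OVA"),
    fmax = c(2.5, 3.0, 3.5, 0), ec50_uM = c(15, 10, 12, 20),
    noise_cv = 0, stringsAsFactors = FALSE)
  decay_cfg <- config$decay %||% data.frame(
    peptide = c("MLAGNEFQV", "LLGPQLVLL", "ALLALTSAV"),
    halflife_h = c(4, 4, 24), noise_cv = 0, stringsAsFactors = FALSE)

  with_seed(config$seed, {
    lnoise <- function(n, cv) {
      if (cv <= 0) return(rep(1, n))
      sdl <- sqrt(log(1 + cv^2))
      rlnorm(n, -sdl^2 / 2, sdl)
    }
    rep_mfi <- function(expected, cv) {
      m <- matrix(rep(expected, reps), ncol = reps)
      m * matrix(lnoise(length(expected) * reps, cv), ncol = reps)
    }

    binding <- lapply(seq_len(nrow(binding_cfg)), function(i) {
      expected <- bg * (1 + binding_cfg$fmax[i] * conc /
                          (conc + binding_cfg$ec50_uM[i]))
      binding_series(binding_cfg$peptide[i], conc,
                     rep_mfi(expected, binding_cfg$noise_cv[i]), bg)
    })
    names(binding) <- binding_cfg$peptide

    decay <- lapply(seq_len(nrow(decay_cfg)), function(i) {
      expected <- mfi0 * 2^(-tps / decay_cfg$halflife_h[i])
      decay_series(decay_cfg$peptide[i], tps,
                   rep_mfi(expected, decay_cfg$noise_cv[i]))
    })
    names(decay) <- decay_cfg$peptide

    mm_cfg <- config$multimer %||% utils::modifyList(
      default_multimer_panel(),
      list(donors = data.frame(
        donor_id = c(sprintf("HCC%d", 1:4), sprintf("HD%d", 1:3)),
        group = c(rep("HCC", 4), rep("healthy", 3)),
        n_gated = 20000L, stringsAsFactors = FALSE)))
    donors <- mm_cfg$donors
    events <- lapply(seq_len(nrow(donors)), function(i) {
      hcc <- donors$group[i] == "HCC"
      .gen_multimer_events(
        donors$n_gated[i],
        if (hcc) mm_cfg$channels else mm_cfg$healthy_channels,
        mm_cfg$pairs,
        if (hcc) mm_cfg$cross else mm_cfg$healthy_cross)
    })
    names(events) <- donors$donor_id
    thresholds <- c(cd3 = 1000, cd8 = 1000,
                    setNames(rep(1000, length(mm_cfg$channels)),
                             names(mm_cfg$channels)))

    list(
      binding = binding, decay = decay,
      multimer = list(events = events, groups = donors$group,
                      donor_ids = donors$donor_id,
                      thresholds = thresholds, pairs = mm_cfg$pairs),
      truth = list(binding = binding_cfg, decay = decay_cfg,
                   multimer = mm_cfg, seed = config$seed)
    )
  })
}
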