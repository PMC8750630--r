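# Nonamer enumeration, affinity bins, strong-binder selection and the toy
# predictor.

test_that("nonamer enumeration yields exactly L - 8 in-order windows", {
  p9 <- list(protein_id = "p", sequence = "MLAGNEFQV")
  expect_equal(nrow(enumerate_nonamers(p9)), 1)
  set.seed(1)
  p20 <- list(protein_id = "p", sequence = rand_seq(20))
  expect_equal(nrow(enumerate_nonamers(p20)), 12)
  expect_warning(
    short <- enumerate_nonamers(list(protein_id = "p", sequence = "MLAG")),
    "shorter than 9")
  expect_equal(nrow(short), 0)
})

test_that("windows reassemble the original sequence with 8-overlap", {
  set.seed(2)
  seq <- rand_seq(200)
  w <- enumerate_nonamers(list(protein_id = "p", sequence = seq))
  expect_equal(w$start, 1:192)
  # consecutive windows agree on their 8-residue overlap
  expect_true(all(substring(w$peptide[-nrow(w)], 2, 9) ==
                    substring(w$peptide[-1], 1, 8)))
  # first residues plus last window reassemble the protein
  expect_equal(paste0(paste(substring(w$peptide, 1, 1), collapse = ""),
                      substring(w$peptide[nrow(w)], 2, 9)), seq)
})

test_that("affinity bins partition the positive axis with stated bounds", {
  expect_equal(classify_affinity_bin(4.35), "lt10")
  expect_equal(classify_affinity_bin(37.45), "10to50")
  expect_equal(classify_affinity_bin(10), "10to50")   # left-closed boundary
  expect_equal(classify_affinity_bin(50), "50to100")
  expect_equal(classify_affinity_bin(100), "gt100")
  expect_error(classify_affinity_bin(0), "domain error")
  set.seed(3)
  a <- 10^runif(200, -1, 4)
  bins <- classify_affinity_bin(a)
  expect_true(all(bins %in% c("lt10", "10to50", "50to100", "gt100")))
  expect_equal(bins == "lt10", a < 10)
  expect_equal(bins == "gt100", a >= 100)
})

test_that("strong-binder selection applies class and strict affinity cap", {
  preds <- data.frame(
    peptide = sprintf("P%d", 1:4), protein_id = "x",
    affinity_nM = c(99.9, 100, 20, 20),
    binder_class = c("SB", "SB", "SB", "WB"))
  sel <- select_strong_binders(preds)
  expect_equal(sel$peptide, c("P1", "P3"))  # 100 nM excluded, WB excluded
})

test_that("selection equals a brute-force filter over a toy-predictor run", {
  pred <- toy_predictor(seed = 6)
  g <- gen_proteomes(list(seed = 6, n_tumor_proteins = 4,
                          tumor_protein_length = 60))
  preds <- predict_epitopes(g$tumor, alleles = "HLA-A*02:01",
                            predictor = pred)
  sel <- select_strong_binders(preds)
  brute <- preds[vapply(seq_len(nrow(preds)), function(i)
    preds$binder_class[i] == "SB" && preds$affinity_nM[i] < 100, TRUE), ]
  expect_equal(sel$peptide, brute$peptide)
})

test_that("combined affinity+stability selection joins and warns", {
  preds <- data.frame(
    protein_id = "x", start = 1:3,
    peptide = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
    allele = "HLA-A*02:01",
    affinity_nM = c(5, 8, 12), binder_class = "SB",
    stringsAsFactors = FALSE)
  stab <- data.frame(
    peptide = c("AAAAAAAAA", "CCCCCCCCC"), allele = "HLA-A*02:01",
    thalf_h = c(6.1, 0.4), binder_class = c("SB", "NB"),
    stringsAsFactors = FALSE)
  expect_warning(out <- combine_stability(preds, stab),
                 "without stability prediction")
  expect_equal(out$peptide, "AAAAAAAAA")     # stability-SB only
  expect_equal(attr(out, "n_unmatched"), 1L)  # DDDDDDDDD had no row
  # optional minimum Thalf on top
  stab$binder_class <- "SB"
  out2 <- suppressWarnings(combine_stability(preds, stab, min_thalf_h = 3))
  expect_equal(out2$peptide, "AAAAAAAAA")
})

test_that("combined selection is order-independent and idempotent", {
  pred <- toy_predictor(seed = 4)
  g <- gen_proteomes(list(seed = 4, n_tumor_proteins = 3,
                          tumor_protein_length = 50))
  preds <- predict_epitopes(g$tumor, alleles = "HLA-A*02:01",
                            predictor = pred)
  stab <- pred$stability(preds$peptide, "HLA-A*02:01")
  out1 <- combine_stability(preds, stab)
  set.seed(9)
  out2 <- combine_stability(preds[sample(nrow(preds)), ],
                            stab[sample(nrow(stab)), ])
  expect_equal(out1$peptide, out2$peptide)
  # idempotent: re-filtering the survivors changes nothing
  out3 <- combine_stability(out1, stab)
  expect_equal(out3$peptide, out1$peptide)
})

test_that("per-protein summary reports count, range and 2-decimal mean", {
  sel <- data.frame(protein_id = rep(paste0("P", 1:9),
                                     c(1, 1, 1, 2, 3, 4, 4, 6, 6)))
  s <- per_protein_summary(sel)
  expect_equal(s$n_total, 28L)
  expect_equal(s$mean_2dp, 3.11)
  expect_equal(s$min, 1L)
  expect_equal(s$max, 6L)

  one <- per_protein_summary(data.frame(protein_id = rep("P1", 5)))
  expect_equal(one$mean_2dp, 5)

  empty <- per_protein_summary(data.frame(protein_id = character()))
  expect_false(empty$defined)
  expect_true(is.na(empty$mean))
})

test_that("toy predictor is deterministic and anchor-monotone", {
  pred <- toy_predictor(seed = 12)
  a1 <- pred$affinity("KLWENPAQV", "HLA-A*02:01")
  a2 <- pred$affinity("KLWENPAQV", "HLA-A*02:01")
  expect_identical(a1, a2)
  s1 <- pred$stability("KLWENPAQV", "HLA-A*02:01")
  expect_identical(s1, pred$stability("KLWENPAQV", "HLA-A*02:01"))

  # anchor-optimal peptide binds strictly tighter than its broken variant
  optimal <- "GLFDAGHEV"   # L at p2, V at p9 (A*02-like anchors)
  broken2 <- "GGFDAGHEV"
  broken9 <- "GLFDAGHEG"
  a_opt <- pred$affinity(optimal, "HLA-A*02:01")$affinity_nM
  expect_lt(a_opt, pred$affinity(broken2, "HLA-A*02:01")$affinity_nM)
  expect_lt(a_opt, pred$affinity(broken9, "HLA-A*02:01")$affinity_nM)
  # A*24-like anchors differ
  expect_lt(pred$affinity("GYFDAGHEF", "HLA-A*24:02")$affinity_nM,
            pred$affinity("GGFDAGHEG", "HLA-A*24:02")$affinity_nM)
  expect_error(pred$affinity("SHORT", "HLA-A*02:01"), "9-mers only")
})

test_that("planted anchor-strong peptides survive the full selection", {
  pred <- toy_predictor(seed = 31)
  pe <- data.frame(protein_id = c("TUM001", "TUM002", "TUM003"),
                   position = c(5, 20, 40),
                   peptide = c("GLFDAGHEV", "KLWENPAQV", "SLDEHTRQV"),
                   stringsAsFactors = FALSE)
  g <- gen_proteomes(list(seed = 31, n_tumor_proteins = 3,
                          tumor_protein_length = 60,
                          planted_epitopes = pe))
  preds <- predict_epitopes(g$tumor, alleles = "HLA-A*02:01",
                            predictor = pred)
  stab <- pred$stability(preds$peptide, "HLA-A*02:01")
  sel <- combine_stability(preds, stab)
  expect_true(all(pe$peptide %in% sel$peptide))
})
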