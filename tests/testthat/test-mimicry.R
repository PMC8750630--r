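# Position-wise identity scoring and the exhaustive viral-proteome scan.

test_that("identity score counts matches position-wise", {
  r <- identity_score("ALLALTSAV", "ALMAFTSAV")
  expect_equal(r$identity, 7)
  expect_equal(r$mismatch_positions, c(3, 5))
  expect_equal(identity_score("LLLTLLALL", "LLLTLLLLL")$identity, 8)
  expect_equal(identity_score("ABCDEFGHI", "ABCDEFGHI")$identity, 9)
  expect_equal(identity_score("ABCDEFGHI", "ABCDEFGHI")$mismatch_positions,
               integer(0))
  expect_error(identity_score("ALLALTSAV", "ALMAFTSA"), "length 9")
})

test_that("identity score is symmetric and X never matches, even X", {
  set.seed(21)
  for (i in 1:20) {
    a <- rand_seq(9); b <- rand_seq(9)
    expect_equal(identity_score(a, b)$identity,
                 identity_score(b, a)$identity)
  }
  expect_equal(identity_score("XLLALTSAV", "XLLALTSAV")$identity, 8)
  expect_true(1 %in% identity_score("XLLALTSAV", "XLLALTSAV")$mismatch_positions)
})

test_that("identity satisfies the 9-mer triangle property", {
  set.seed(22)
  for (i in 1:50) {
    a <- rand_seq(9); b <- rand_seq(9); c <- rand_seq(9)
    expect_gte(identity_score(a, c)$identity,
               identity_score(a, b)$identity +
                 identity_score(b, c)$identity - 9)
  }
})

test_that("scan finds verbatim and degraded planted homologs", {
  g <- gen_proteomes(list(
    seed = 41, n_viral_proteins = 10, viral_protein_length = 100,
    planted_homologs = data.frame(
      epitope = c("ALLALTSAV", "ALLALTSAV"),
      viral_id = c("VIR003", "VIR007"), position = c(30, 55),
      identity = c(9, 7), stringsAsFactors = FALSE)))
  m <- scan_viral_proteome("ALLALTSAV", g$viral, min_identity = 7)
  verb <- m[m$viral_accession == "VIR003" & m$position == 30, ]
  expect_equal(verb$identity, 9)
  expect_true(verb$self_match)            # exact matches flagged
  degr <- m[m$viral_accession == "VIR007" & m$position == 55, ]
  expect_equal(degr$identity, 7)
  expect_false(degr$self_match)
})

test_that("scan equals the naive double-loop oracle on random instances", {
  set.seed(31)
  for (i in 1:20) {
    proteome <- data.frame(
      protein_id = sprintf("V%02d", 1:3),
      sequence = vapply(1:3, function(k) rand_seq(sample(9:60, 1)), ""),
      stringsAsFactors = FALSE)
    epitopes <- vapply(1:2, function(k) rand_seq(9), "")
    min_id <- sample(3:9, 1)
    got <- scan_viral_proteome(epitopes, proteome, min_identity = min_id)
    want <- naive_scan(epitopes, proteome, min_identity = min_id)
    expect_identical(scan_key(got), scan_key(want))
  }
})

test_that("scan handles boundary configurations", {
  set.seed(32)
  proteome <- data.frame(protein_id = "V1", sequence = rand_seq(200))
  expect_equal(nrow(scan_viral_proteome("WWWWWWWWW", proteome,
                                        min_identity = 9)), 0)
  expect_warning(
    empty <- scan_viral_proteome("ALLALTSAV", proteome[0, ], 7),
    "empty proteome")
  expect_equal(nrow(empty), 0)
  expect_error(scan_viral_proteome("ALLALTSAV", proteome, 0),
               "configuration error")
  expect_error(scan_viral_proteome("ALLALTSA", proteome, 7), "9-mers")
})

test_that("scan output is invariant to proteome record order", {
  g <- gen_proteomes(list(seed = 43, n_viral_proteins = 8,
                          viral_protein_length = 120,
                          planted_homologs = data.frame(
                            epitope = "MLAGNEFQV", viral_id = "VIR002",
                            position = 10, identity = 8)))
  m1 <- scan_viral_proteome("MLAGNEFQV", g$viral, 6)
  set.seed(1)
  m2 <- scan_viral_proteome("MLAGNEFQV",
                            g$viral[sample(nrow(g$viral)), ], 6)
  expect_equal(m1, m2)
})

test_that("viral-binder filter applies class and Thalf thresholds", {
  matches <- data.frame(
    tumor_peptide = c("LLGPQLVLL", "VYSACSFTF"),
    tumor_protein = c("C1QTNF12", "CAPN7"),
    viral_accession = c("AUF41974.1", "AFR55693.1"),
    position = c(10, 20),
    viral_peptide = c("LLGPLLVLL", "GSPACTFTF"),
    identity = c(8L, 7L), mismatch_positions = c("5", "1,5,7"),
    self_match = FALSE, stringsAsFactors = FALSE)
  # stub predictor reproducing published-style annotation values
  pred <- stub_predictor(data.frame(
    peptide = c("LLGPLLVLL", "GSPACTFTF"),
    affinity_nM = c(20.91, 658.27), binder_class = c("WB", "WB"),
    thalf_h = c(3.38, 0.65), stability_class = c("WB", "NB"),
    stringsAsFactors = FALSE))
  pairs <- filter_viral_binders(matches, pred, "HLA-A*02:01")
  expect_equal(pairs$viral_peptide, "LLGPLLVLL")  # Thalf 3.38 > 3 retained
  expect_equal(pairs$viral_binder_class, "WB")    # WB admitted by default
  none <- filter_viral_binders(matches, pred, "HLA-A*02:01",
                               allowed_classes = "SB")
  expect_equal(nrow(none), 0)
  empty <- filter_viral_binders(matches[0, ], pred, "HLA-A*02:01")
  expect_equal(nrow(empty), 0)
})

test_that("pair report ranks by identity with deterministic tie-breaks", {
  pairs <- data.frame(
    allele = "HLA-A*02:01", tumor_protein = c("MDK", "MDK", "MDK"),
    tumor_peptide = "ALLALTSAV",
    viral_accession = c("B2", "A1", "C3"),
    viral_peptide = c("x", "y", "z"), identity = c(7L, 8L, 7L),
    stringsAsFactors = FALSE)
  rep <- pair_report(pairs)
  expect_equal(rep$viral_accession, c("A1", "B2", "C3"))  # 8 first, then id
  expect_equal(rep$identity, c(8L, 7L, 7L))
  # duplicate viral window matched by two epitopes keeps two rows
  two <- pairs[c(1, 1), ]; two$tumor_peptide <- c("AAAAAAAAA", "CCCCCCCCC")
  expect_equal(nrow(pair_report(two)), 2)
})

test_that("mimicry pair table round-trips through TSV", {
  g <- gen_proteomes(list(seed = 44, n_viral_proteins = 6,
                          planted_homologs = data.frame(
                            epitope = "GLFDAGHEV", viral_id = "VIR001",
                            position = 3, identity = 8)))
  m <- scan_viral_proteome(c(MDK = "GLFDAGHEV"), g$viral, 7)
  pairs <- filter_viral_binders(m, toy_predictor(1), "HLA-A*02:01",
                                min_thalf_h = 0)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(pairs, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(nrow(back), nrow(pairs))
  expect_equal(back$viral_peptide, pairs$viral_peptide)
  expect_equal(back$identity, pairs$identity)
})
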