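# Parsing and round-trip of the table and sequence formats.

write_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("expression table parsing validates tokens and round-trips", {
  f <- write_lines(c(
    "Gene\tGene name\tTissue\tCell type\tLevel\tReliability",
    "ENSG1\tAAA\tliver\thepatocytes\tNot detected\tEnhanced",
    "ENSG1\tAAA\tliver\tbile duct cells\tHigh\tApproved"))
  rec <- read_expression_table(f)
  expect_equal(nrow(rec), 2)
  expect_equal(as.character(rec$level), c("NotDetected", "High"))
  expect_equal(rec$cell_type, c("hepatocytes", "bile duct cells"))

  out <- tempfile(fileext = ".tsv")
  write_expression_table(rec, out)
  expect_equal(read_expression_table(out), rec)

  bad <- write_lines(c(
    "Gene\tGene name\tTissue\tCell type\tLevel\tReliability",
    "ENSG1\tAAA\tliver\thepatocytes\tAscending\tEnhanced"))
  expect_error(read_expression_table(bad), "Ascending.*row 1")

  nocol <- write_lines(c("Gene\tTissue\tLevel", "ENSG1\tliver\tHigh"))
  expect_error(read_expression_table(nocol), "Cell type")

  dup <- write_lines(c(
    "Gene\tGene name\tTissue\tCell type\tLevel\tReliability",
    "ENSG1\tAAA\tliver\thepatocytes\tHigh\tEnhanced",
    "ENSG1\tAAA\tliver\thepatocytes\tLow\tEnhanced"))
  expect_error(read_expression_table(dup), "duplicate")
})

test_that("missing level cells are rejected unless explicitly mapped", {
  f <- write_lines(c(
    "Gene\tGene name\tTissue\tCell type\tLevel\tReliability",
    "ENSG1\tAAA\tliver\thepatocytes\tN/A\tEnhanced"))
  expect_error(read_expression_table(f), "N/A")
  rec <- read_expression_table(f, na_as_not_detected = TRUE)
  expect_equal(as.character(rec$level), "NotDetected")
})

test_that("pathology table parses counts and optional prognostic fields", {
  f <- write_lines(c(
    "Gene\tCancer\tHigh\tMedium\tLow\tNot detected",
    "ENSG1\tliver cancer\t6\t3\t2\t1"))
  prof <- read_pathology_table(f)
  expect_equal(prof$n_high, 6L)
  expect_equal(prof$n_not_detected, 1L)
  expect_true(is.na(prof$prognostic_p))     # absent, not zero
  expect_true(is.na(prof$prognosis_direction))

  neg <- write_lines(c("Gene\tCancer\tHigh\tMedium\tLow\tNot detected",
                       "ENSG1\tliver cancer\t-1\t0\t0\t12"))
  expect_error(read_pathology_table(neg), "negative count")

  nonnum <- write_lines(c("Gene\tCancer\tHigh\tMedium\tLow\tNot detected",
                          "ENSG1\tliver cancer\tsix\t0\t0\t12"))
  expect_error(read_pathology_table(nonnum), "non-numeric")
})

test_that("generated table pair round-trips identically through disk", {
  dir <- tempfile()
  h <- gen_hpa_tables(list(seed = 5, n_genes = 30, n_planted = 3), dir = dir)
  normal_back <- read_expression_table(h$paths$normal)
  path_back <- read_pathology_table(h$paths$pathology)
  rownames(h$normal) <- NULL
  expect_equal(normal_back, h$normal)
  expect_equal(path_back$gene_id, h$pathology$gene_id)
  expect_equal(path_back$n_high, h$pathology$n_high)
  expect_equal(path_back$prognostic_p, h$pathology$prognostic_p,
               tolerance = 1e-12)
  # re-serialization is byte-identical
  f2 <- tempfile()
  write_expression_table(normal_back, f2)
  expect_identical(readLines(f2), readLines(h$paths$normal))
})

test_that("FASTA parsing handles wrapping, validation and round-trip", {
  f <- write_lines(c(">p1", "MLAGNEFQV"), ext = ".fa")
  p <- read_fasta(f)
  expect_equal(p$protein_id, "p1")
  expect_equal(nchar(p$sequence), 9)

  wrapped <- write_lines(c(">p1 some description", "MLAGNE", "FQV",
                           ">p2", "ALLA", "LTSAV"), ext = ".fa")
  p2 <- read_fasta(wrapped)
  expect_equal(p2$protein_id, c("p1", "p2"))
  expect_equal(p2$sequence, c("MLAGNEFQV", "ALLALTSAV"))

  emptyrec <- write_lines(c(">p1", "", ">p2", "MLAGNEFQV"), ext = ".fa")
  expect_error(read_fasta(emptyrec), "empty sequence")

  bad <- write_lines(c(">p1", "MLAGNBFQV"), ext = ".fa")
  expect_error(read_fasta(bad), "illegal residue 'B'.*p1")

  g <- gen_proteomes(list(seed = 2, n_viral_proteins = 50,
                          viral_protein_length = 80))
  fa <- tempfile(fileext = ".fa")
  write_fasta(g$viral, fa)
  back <- read_fasta(fa)
  expect_equal(back$protein_id, g$viral$protein_id)
  expect_equal(back$sequence, g$viral$sequence)
})

test_that("ambiguous residues are flagged, not rejected", {
  f <- write_lines(c(">p1", "MLAGNXFQV"), ext = ".fa")
  p <- read_fasta(f)
  expect_true(p$has_ambiguous)
})

test_that("predictor output dialects parse affinity, Thalf and classes", {
  f <- write_lines("MLAGNEFQV\tHLA-A*02:01\t4.35\t5.22\tSB")
  rows <- read_predictor_output(f, "simple_tsv")
  expect_equal(rows$affinity_nM, 4.35)
  expect_equal(rows$thalf_h, 5.22)
  expect_equal(rows$binder_class, "SB")

  # a non-9-mer row is skipped with a counted warning
  f8 <- write_lines(c("MLAGNEFQ\tHLA-A*02:01\t4.35\t5.22\tSB"))
  expect_warning(rows8 <- read_predictor_output(f8, "simple_tsv"),
                 "length != 9")
  expect_equal(nrow(rows8), 0)
  expect_equal(attr(rows8, "n_skipped"), 1L)

  expect_error(read_predictor_output(f, "netmhcpan99"), "one of")

  # tool-style dialects
  fp <- write_lines(c(
    "# NetMHCpan-style output",
    " Pos         HLA      Peptide   Score  Aff(nM)  BindLevel",
    "----------------------------------------------------------",
    "   1  HLA-A*02:01  MLAGNEFQV   0.85     4.35   <= SB",
    "   2  HLA-A*02:01  LLGPQLVLL   0.42    37.45   <= WB"))
  rp <- read_predictor_output(fp, "netmhcpan41")
  expect_equal(rp$affinity_nM, c(4.35, 37.45))
  expect_equal(rp$binder_class, c("SB", "WB"))
  fs <- write_lines(c(
    " Pos         HLA      Peptide   Pred  Thalf(h)  BindLevel",
    "   1  HLA-A*02:01  MLAGNEFQV   0.85     5.22   <= SB"))
  rs <- read_predictor_output(fs, "netmhcstabpan10")
  expect_equal(rs$thalf_h, 5.22)
  expect_true(is.na(rs$affinity_nM))
})

test_that("toy-predictor output written as simple_tsv re-reads identically", {
  pred <- toy_predictor(seed = 9)
  peps <- c("KLWENPAQV", "GLFDAGHEV", "AAAAAAAAA")
  aff <- pred$affinity(peps, "HLA-A*02:01")
  stab <- pred$stability(peps, "HLA-A*02:01")
  f <- tempfile()
  writeLines(sprintf("%s\t%s\t%.6f\t%.6f\t%s", aff$peptide, aff$allele,
                     aff$affinity_nM, stab$thalf_h, aff$binder_class), f)
  back <- read_predictor_output(f, "simple_tsv")
  expect_equal(back$peptide, peps)
  expect_equal(back$affinity_nM, aff$affinity_nM, tolerance = 1e-6)
  expect_equal(back$thalf_h, stab$thalf_h, tolerance = 1e-6)
  expect_equal(back$binder_class, aff$binder_class)
})
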