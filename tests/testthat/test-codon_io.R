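test_that("read_fasta parses records, uppercases, and preserves order", {
  path <- write_tmp_fasta(c(">g1 desc", "atgaaa", ">g2", "ATGCCC"))
  seqs <- read_fasta(path)
  expect_named(seqs, c("g1", "g2"))
  expect_equal(seqs$g1, "ATGAAA")
  expect_equal(seqs$g2, "ATGCCC")

  empty <- write_tmp_fasta(character(0))
  expect_length(read_fasta(empty), 0)

  # length-7 record is accepted by the reader, rejected only at validation
  odd <- write_tmp_fasta(c(">g1", "ATGAAAT"))
  seqs <- read_fasta(odd)
  expect_equal(nchar(seqs$g1), 7)
  expect_error(validate_codon_alignment(
    structure(list(gene_id = "g1", seq_a = seqs$g1, seq_b = seqs$g1,
                   lineage = NA_character_), class = "ortholog_pair")),
    "divisible by 3")

  bad <- write_tmp_fasta(c(">g1", "ATGXAA"))
  expect_error(read_fasta(bad), "illegal character 'X'")
})

test_that("FASTA round-trip reproduces sequences exactly", {
  seqs <- list(a = "ATGAAACCC", b = "ATG---CCC", c = "ATGNNNTTT")
  path <- tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})

test_that("build_codon_alignment back-translates under protein guidance", {
  p <- build_codon_alignment("g", "MK", "MK", "ATGAAA", "ATGAAG")
  expect_equal(p$seq_a, "ATGAAA")
  expect_equal(p$seq_b, "ATGAAG")

  # protein gap column becomes ---
  p <- build_codon_alignment("g", "M-K", "MLK", "ATGAAA", "ATGCTGAAG")
  expect_equal(p$seq_a, "ATG---AAA")
  expect_equal(p$seq_b, "ATGCTGAAG")

  # terminal stop on the CDS is stripped before checking
  p <- build_codon_alignment("g", "MK", "MK", "ATGAAATAA", "ATGAAG")
  expect_equal(p$seq_a, "ATGAAA")

  expect_error(
    build_codon_alignment("g", "MK", "MK", "ATGCTG", "ATGAAA"),
    "position 2")
})

test_that("validate_codon_alignment removes gap/ambiguous/stop columns", {
  clean <- ortholog_pair("g", "ATGAAA", "ATGAAG")
  out <- validate_codon_alignment(clean)
  expect_equal(out$seq_a, clean$seq_a)
  expect_equal(nrow(attr(out, "report")), 0)

  # internal stop column removed with reason
  p <- ortholog_pair("g", "ATGTAAAAA", "ATGTAAAAG")
  out <- validate_codon_alignment(p)
  expect_equal(out$seq_a, "ATGAAA")
  expect_equal(attr(out, "report"),
               data.frame(column = 2L, reason = "stop"))

  # gap column removed with reason (gap wins over ambiguity within a column)
  p <- ortholog_pair("g", "ATGA-GAAA", "ATGAAGAAA")
  out <- validate_codon_alignment(p)
  expect_equal(out$seq_a, "ATGAAA")
  expect_equal(attr(out, "report")$reason, "gap")

  # ambiguity codes trigger removal, not imputation
  p <- ortholog_pair("g", "ATGANGAAA", "ATGAAGAAA")
  expect_equal(attr(validate_codon_alignment(p), "report")$reason,
               "ambiguous")

  expect_error(validate_codon_alignment(ortholog_pair("g", "TAA", "TAA")),
               "no analyzable codons")
})

test_that("validation is idempotent and never lengthens an alignment", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    sc <- sense_codons()
    a <- sample(sc, n, replace = TRUE)
    b <- a
    b[3] <- "TAA"                      # internal stop
    a[7] <- "A-A"; b[7] <- "AAA"       # gap column
    a[11] <- "ANA"                     # ambiguity
    p <- ortholog_pair("g", paste(a, collapse = ""), paste(b, collapse = ""))
    once <- validate_codon_alignment(p)
    twice <- validate_codon_alignment(once)
    expect_equal(twice$seq_a, once$seq_a)
    expect_equal(twice$seq_b, once$seq_b)
    expect_equal(nrow(attr(twice, "report")), 0)
    expect_lte(nchar(once$seq_a), nchar(p$seq_a))
    expect_equal(nchar(once$seq_a), nchar(once$seq_b))
  }
})

test_that("ortholog maps are read and joined to sequences", {
  map_path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tseq_id_a\tseq_id_b\tlineage",
               "gA\ts1\ts2\tbuchnera",
               "gB\ts3\ts4\tbuchnera"), map_path)
  map <- read_ortholog_map(map_path)
  expect_equal(nrow(map), 2)
  seqs <- list(s1 = "ATGAAA", s2 = "ATGAAG", s3 = "ATGCCC", s4 = "ATGCCG")
  pairs <- pairs_from_map(map, seqs)
  expect_length(pairs, 2)
  expect_equal(pairs[[1]]$gene_id, "gA")
  expect_error(pairs_from_map(map, seqs[1:3]), "not found")

  dup_path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tseq_id_a\tseq_id_b\tlineage",
               "gA\ts1\ts2\tbuchnera",
               "gA\ts3\ts4\tbuchnera"), dup_path)
  expect_error(read_ortholog_map(dup_path), "duplicated")
})
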