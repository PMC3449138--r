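test_that("genetic code partitions 64 triplets with stable sense order", {
  expect_length(fix_code$codons, 64L)
  expect_length(fix_code$sense_codons, 61L)
  expect_setequal(fix_code$stop_codons, c("TAA", "TAG", "TGA"))
  expect_identical(sort(c(fix_code$sense_codons, fix_code$stop_codons)),
                   sort(fix_code$codons))
  # T < C < A < G lexicographic convention
  expect_identical(fix_code$sense_codons[1:3], c("TTT", "TTC", "TTA"))
  expect_identical(fix_code$codons[1], "TTT")
  expect_identical(fix_code$codons[64], "GGG")
})

test_that("codon alignments parse, validate and report errors by name", {
  f <- write_tmp_fasta(c(a = "ATGAAA", b = "ATGAAG"))
  aln <- read_codon_alignment(f)
  expect_equal(dim(aln$sites), c(2L, 2L))
  expect_identical(fix_code$sense_codons[aln$sites[1, ]], c("ATG", "AAA"))
  expect_identical(fix_code$sense_codons[aln$sites[2, 2]], "AAG")

  expect_error(read_codon_alignment(
    write_tmp_fasta(c(a = "ATGTAAAAA", b = "ATGAAAAAA"))), "stop codon")
  expect_error(read_codon_alignment(
    write_tmp_fasta(c(a = "ATGAAA", b = "ATGAAAAAA"))), "unequal")
  expect_error(read_codon_alignment(
    write_tmp_fasta(c(a = "ATGAA", b = "ATGAA"))), "frame")
  expect_error(read_codon_alignment(
    write_tmp_fasta(c(a = "ATGAAA", a = "ATGAAG"))), "duplicate")

  gap <- read_codon_alignment(write_tmp_fasta(c(a = "AT-AAA", b = "ATGAAA")))
  expect_true(is.na(gap$sites[1, 1]))
  expect_false(anyNA(gap$sites[2, ]))
  amb <- read_codon_alignment(write_tmp_fasta(c(a = "ATNAAA", b = "ATGAAA")))
  expect_true(is.na(amb$sites[1, 1]))
})

test_that("alignment write/read round-trips exactly, missing as ---", {
  aln <- read_codon_alignment(write_tmp_fasta(c(x = "ATG---AAA",
                                                y = "ATGCCCAAG")))
  f <- tempfile(fileext = ".fa")
  write_codon_alignment(aln, f)
  back <- read_codon_alignment(f)
  expect_identical(back$sites, aln$sites)
  expect_identical(back$taxon_names, aln$taxon_names)
})

test_that("newick parsing handles lengths, #1 tags, and bad input", {
  tr <- read_newick(text = "((A:0.1,B:0.1):0.05,C:0.2);")
  expect_s3_class(tr, "phylo")
  expect_false(any(tr$foreground))
  expect_false(attr(tr, "default_branch_lengths"))

  tg <- read_newick(text = "((A:0.1,B:0.1)#1:0.05,C:0.2);")
  expect_equal(sum(tg$foreground), 1L)
  # the flagged edge subtends the (A,B) clade
  ab <- ape::getMRCA(tg, c("A", "B"))
  expect_true(tg$foreground[tg$edge[, 2] == ab])

  tip_tag <- read_newick(text = "((A#1:0.1,B:0.1):0.05,C:0.2);")
  expect_identical(sort(tip_tag$tip.label), c("A", "B", "C"))
  expect_true(tip_tag$foreground[tip_tag$edge[, 2] ==
                                   match("A", tip_tag$tip.label)])

  expect_error(read_newick(text = "((A,B),C;"), "parse")
  nolen <- read_newick(text = "((A,B),C);")
  expect_true(attr(nolen, "default_branch_lengths"))
  expect_true(all(nolen$edge.length == 0.1))
})

test_that("domain annotations validate intervals and sort by start", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tregion\tstart\tend",
               "g1\tLRR\t41\t300", "g1\tLDLa\t1\t40"), f)
  d <- read_domain_annotation(f)
  expect_identical(d$region, c("LDLa", "LRR"))

  expect_error(domain_annotation(data.frame(
    gene = "g1", region = "TM1", start = 10, end = 5)), "end < start")
  expect_error(domain_annotation(data.frame(
    gene = "g1", region = c("LRR", "LDLa"),
    start = c(30, 50), end = c(60, 70))), "overlap")
})

test_that("write_report is validated, manifested and byte-deterministic", {
  tabs <- list(selection_profiles = data.frame(gene = c("a", "b", "c"),
                                               p = c(0.1, 0.2, 0.3)))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  m <- write_report(tabs, d1)
  expect_identical(m$file, "selection_profiles.tsv")
  expect_identical(m$n_rows, 3L)
  write_report(tabs, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, m$file))),
                   unname(tools::md5sum(file.path(d2, m$file))))
  expect_error(write_report(list(), tempdir()), "nonempty")
})
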