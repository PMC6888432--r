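test_that("aligned FASTA reading validates, normalizes and round-trips", {
  p <- writeTempFasta(c(a = "mkt-as", b = "MKTQAS", c = "M.TQAT"))
  aln <- readAlignment(p, "a")
  expect_s4_class(aln, "MultipleAlignment")
  expect_equal(alignmentWidth(aln), 6L)
  expect_equal(unname(sequences(aln)[["a"]]), "MKT-AS")  # uppercased
  expect_equal(unname(sequences(aln)[["c"]]), "M-TQAT")  # '.' -> '-'

  out <- tempfile(fileext = ".fasta")
  writeAlignment(aln, out)
  again <- readAlignment(out, "a")
  expect_identical(sequences(again), sequences(aln))

  ragged <- writeTempFasta(c(a = "MKT", b = "MK"))
  expect_error(readAlignment(ragged, "a"), "ragged")
  expect_error(readAlignment(p, "zz"), "not found")
  empty <- writeTempLines(character(0), ".fasta")
  expect_error(readAlignment(empty, "a"))
})

test_that("Newick reading handles missing lengths and rejects bad trees", {
  p <- writeTempLines("((A:0.1,B:0.2):0.05,C:0.3);", ".nwk")
  tr <- readNewickTree(p)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(nrow(tr$edge), 4L)

  p2 <- writeTempLines("((A,B),C);", ".nwk")
  expect_warning(tr2 <- readNewickTree(p2), "branch lengths")
  expect_true(all(tr2$edge.length == 0))

  p3 <- writeTempLines("((A,B),(A,C));", ".nwk")
  expect_error(readNewickTree(p3), "duplicate")
  p4 <- writeTempLines("((A,B,C;", ".nwk")
  expect_error(readNewickTree(p4))
})

test_that("column map numbers reference residues and round-trips", {
  aln <- multipleAlignment(c(r = "M-KT", o = "MAKT"), "r")
  map <- buildColumnMap(aln)
  expect_equal(columnToResidue(map, 1:4), c(1L, NA, 2L, 3L))
  expect_equal(residueToColumn(map, 1:3), c(1L, 3L, 4L))

  for (seed in 1:5) {
    a <- randomAlignment(6, 40, seed = seed)
    m <- buildColumnMap(a)
    nongap <- which(!is.na(m@columnToResidue))
    expect_identical(residueToColumn(m, columnToResidue(m, nongap)), nongap)
  }
})

test_that("track reading validates coverage and score range", {
  aln <- tinyAlignment()  # human ungapped length 5
  good <- writeTempLines(c("seq_id\tpos\tscore",
                           paste("human", 1:5, c(.1, .2, .9, .8, .5),
                                 sep = "\t")))
  tr <- readTrack(good, aln, "disorder")
  expect_s4_class(tr, "AnnotationTrack")
  expect_equal(length(scores(tr)), 5L)

  bad <- writeTempLines(c("seq_id\tpos\tscore",
                          paste("human", 1:5, c(.1, .2, 1.2, .8, .5),
                                sep = "\t")))
  expect_error(readTrack(bad, aln), "outside")
  short <- writeTempLines(c("seq_id\tpos\tscore",
                            paste("human", 1:4, 0.5, sep = "\t")))
  expect_error(readTrack(short, aln), "cover")
  dup <- writeTempLines(c("seq_id\tpos\tscore",
                          paste("human", c(1, 2, 2, 4, 5), 0.5, sep = "\t")))
  expect_error(readTrack(dup, aln))

  out <- tempfile(fileext = ".tsv")
  writeTrack(tr, out)
  expect_identical(scores(readTrack(out, aln, "disorder")), scores(tr))
})

test_that("variant reading filters by label and reference match", {
  aln <- tinyAlignment()  # human: M K T A S
  rows <- c("protein\tpos\tref\talt\tn_cases\tlabel",
            "p1\t1\tM\tV\t3\tpathogenic",
            "p1\t2\tK\tR\t1\tpathogenic",
            "p1\t3\tT\tA\t2\tpolymorphism",
            "p1\t2\tQ\tR\t1\tpathogenic",   # ref mismatch (K at 2)
            "p1\t99\tS\tC\t1\tpathogenic")  # out of range
  v <- readVariants(writeTempLines(rows), aln)
  expect_equal(nrow(v), 2L)
  rej <- attr(v, "rejected")
  expect_setequal(rej$reason, c("label not in allow-list",
                                "ref residue mismatch",
                                "position out of range"))

  v2 <- readVariants(writeTempLines(rows), aln,
                     allowedLabels = c("pathogenic", "polymorphism"))
  expect_equal(nrow(v2), 3L)

  emptyTab <- writeTempLines("protein\tpos\tref\talt\tn_cases\tlabel")
  expect_equal(nrow(readVariants(emptyTab, aln)), 0L)

  out <- tempfile(fileext = ".tsv")
  writeVariants(v, out)
  expect_equal(readVariants(out, aln)$pos, v$pos)
})

test_that("domain interval files are validated", {
  good <- writeTempLines(c("name\tstart\tend", "MBD\t10\t20", "TRD\t30\t40"))
  d <- readDomains(good)
  expect_equal(d$name, c("MBD", "TRD"))
  dupNames <- writeTempLines(c("name\tstart\tend", "A\t1\t2", "A\t3\t4"))
  expect_error(readDomains(dupNames), "unique")
  badIv <- writeTempLines(c("name\tstart\tend", "A\t5\t2"))
  expect_error(readDomains(badIv))
})

test_that("alignment container enforces its invariants", {
  expect_error(multipleAlignment(c(a = "MK", b = "MKT"), "a"), "ragged")
  expect_error(multipleAlignment(c(a = "MK", b = "RS"), "c"), "reference")
  expect_error(multipleAlignment(c(a = "--", b = "RS"), "a"), "non-gap")
  expect_error(multipleAlignment(c(a = "M1", b = "RS"), "a"), "invalid")
})
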