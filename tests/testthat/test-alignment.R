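# Alignment and partition I/O: round trips, charset semantics, RY recoding,
# region extraction and genome windows.

test_that("FASTA and NEXUS round-trip preserves matrix, taxa and charsets", {
  aln <- tiny_alignment(c(a = "ACGT-RYN?AGT", b = "ACGTTACGTAGT",
                          c = "ACTTTACGAAGT", d = "AAGTTACG-AGT"))
  sch <- partition_scheme(list(pos1 = seq(1, 12, 3), pos2 = seq(2, 12, 3),
                               rest = c(3, 6, 9, 12)))
  fa <- tempfile(fileext = ".fasta"); nx <- tempfile(fileext = ".nxs")
  write_alignment(aln, fa, "fasta")
  write_alignment(aln, nx, "nexus", scheme = sch)
  back_fa <- read_alignment(fa)
  back_nx <- read_alignment(nx)
  expect_identical(back_fa$matrix, aln$matrix)
  expect_identical(back_fa$taxa, aln$taxa)
  expect_identical(back_nx$matrix, aln$matrix)
  sch2 <- attr(back_nx, "scheme")
  expect_identical(sch2$partitions$pos1, as.integer(seq(1, 12, 3)))
  expect_identical(sch2$partitions$rest, c(3L, 6L, 9L, 12L))
})

test_that("charset stride syntax and interleaved matrices parse", {
  nx <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=4 NCHAR=12;",
               "FORMAT DATATYPE=DNA INTERLEAVE MISSING=? GAP=-;",
               "MATRIX",
               "tax1 ACGTAC", "tax2 ACGTAC", "tax3 ACTTAC", "tax4 AGGTAC",
               "", "tax1 GTACGT", "tax2 GTACGT", "tax3 GTACGA", "tax4 GTACGT",
               ";", "END;", "BEGIN SETS;",
               "charset pos1 = 1-12\\3;",
               "charset tail = 11 12;",
               "END;"), nx)
  aln <- read_alignment(nx)
  expect_equal(ncol(aln$matrix), 12)
  expect_identical(unname(aln$matrix[1, ]), strsplit("ACGTACGTACGT", "")[[1]])
  expect_identical(attr(aln, "scheme")$partitions$pos1, c(1L, 4L, 7L, 10L))
  expect_identical(attr(aln, "scheme")$partitions$tail, c(11L, 12L))
})

test_that("malformed alignments are rejected", {
  expect_error(tiny_alignment(c(a = "ACGT", b = "ACG")), "ragged")
  m <- matrix("A", 2, 4, dimnames = list(c("x", "x"), NULL))
  expect_error(alignment(m), "duplicate")
  expect_error(tiny_alignment(c(a = "ACGZ", b = "ACGT")), "alphabet")
})

test_that("partition scheme construction validates and conserves columns", {
  aln <- random_alignment(4, 9)
  ann <- rep(c("codon1", "codon2", "codon3"), 3)
  sch <- build_partition_scheme(aln, ann)
  expect_identical(sch$partitions$codon1, c(1L, 4L, 7L))
  expect_identical(sch$partitions$codon2, c(2L, 5L, 8L))
  expect_identical(sch$partitions$codon3, c(3L, 6L, 9L))
  expect_equal(sum(lengths(sch$partitions)), ncol(aln$matrix))
  # merging stems and loops gives one combined RNA partition
  ann2 <- c(rep("stem", 4), rep("loop", 5))
  sch2 <- build_partition_scheme(aln, ann2, merge = list(rna = c("stem", "loop")))
  expect_named(sch2$partitions, "rna")
  expect_equal(length(sch2$partitions$rna), 9)
  expect_error(build_partition_scheme(aln, ann[-1]), "label")
  expect_error(partition_scheme(list(a = 1:3, b = 3:5)), "overlap")
})

test_that("RY recoding maps purines/pyrimidines, kills other codes, and is
           idempotent", {
  aln <- tiny_alignment(c(a = "AGCTRN-W", b = "GACTYAMC"))
  rec <- ry_recode(aln, 1:8)
  expect_identical(unname(rec$matrix[1, ]),
                   c("R", "R", "Y", "Y", "R", "?", "?", "?"))
  expect_identical(unname(rec$matrix[2, ]),
                   c("R", "R", "Y", "Y", "Y", "R", "?", "Y"))
  expect_identical(ry_recode(rec, 1:8)$matrix, rec$matrix)
  # columns outside the partition untouched
  part <- ry_recode(aln, 1:4)
  expect_identical(part$matrix[, 5:8], aln$matrix[, 5:8])
  expect_equal(ncol(part$matrix), 8)
})

test_that("region extraction concatenates in order and keeps labels", {
  aln <- random_alignment(3, 2000)
  regions <- list(region_spec("cytb", rbind(c(1, 672))),
                  region_spec("coi", rbind(c(700, 1401))),
                  region_spec("dloop", rbind(c(1402, 1979))))
  ext <- extract_regions(aln, regions)
  expect_equal(ncol(ext$matrix), 672 + 702 + 578)
  expect_equal(ncol(ext$matrix), 1952)
  expect_identical(unique(ext$labels), c("cytb", "coi", "dloop"))
  expect_identical(ext$taxa, aln$taxa)
  # empty and identity cases
  expect_equal(ncol(extract_regions(aln, list())$matrix), 0)
  full <- extract_regions(aln, list(region_spec("all", rbind(c(1, 2000)))))
  expect_identical(full$matrix[, ], aln$matrix[, ])
  expect_error(extract_regions(aln, list(region_spec("bad", rbind(c(1, 3000))))),
               "bounds")
  expect_error(region_spec("x", rbind(c(5, 2))), "inverted")
})

test_that("window slicing covers the alignment and flags the partial tail", {
  aln <- random_alignment(3, 14471)
  w <- window_slice(aln, 1000)
  expect_length(w, 15)
  expect_equal(attr(w[[15]], "width"), 471)
  expect_true(attr(w[[15]], "partial"))
  expect_false(any(vapply(w[1:14], attr, TRUE, which = "partial")))
  # concatenation reproduces the input
  rebuilt <- do.call(cbind, lapply(w, function(x) x$matrix))
  expect_identical(unname(rebuilt), unname(aln$matrix))
  # degenerate width
  one <- window_slice(aln, 20000)
  expect_length(one, 1)
  expect_identical(one[[1]]$matrix, aln$matrix)
  expect_error(window_slice(aln, 0), "positive")
})
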