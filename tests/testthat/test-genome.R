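test_that("generated genomes hit their GC target and are seed-reproducible", {
  g <- generate_genome(10000, 0.5, seed = 7)
  expect_gte(g$realized_gc, 0.49)
  expect_lte(g$realized_gc, 0.51)

  # convergence of realized GC across lengths and targets
  for (gc in c(0.25, 0.38, 0.62, 0.75)) {
    for (len in c(10000, 40000)) {
      gi <- generate_genome(len, gc, seed = 11)
      expect_lte(abs(gi$realized_gc - gc), 0.01)
    }
  }

  g1 <- generate_genome(20000, 0.38,
                        cassettes = data.frame(gene_kind = c("terminase",
                                                             "integrase")),
                        seed = 1)
  g2 <- generate_genome(20000, 0.38,
                        cassettes = data.frame(gene_kind = c("terminase",
                                                             "integrase")),
                        seed = 1)
  expect_identical(g1$sequence, g2$sequence)
  g3 <- generate_genome(20000, 0.38, seed = 2)
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("cassette insertion places annotated back-translated copies", {
  db <- hallmark_db()
  plan <- data.frame(gene_kind = c("terminase", "integrase"))
  g <- generate_genome(20000, 0.38, cassettes = plan, seed = 1)
  expect_setequal(g$cassettes$gene_kind, c("terminase", "integrase"))
  expect_true(all(g$cassettes$start >= 0 & g$cassettes$end <= 20000))
  # intervals must not overlap
  ca <- g$cassettes[order(g$cassettes$start), ]
  expect_true(all(ca$start[-1] >= ca$end[-nrow(ca)]))
  # the inserted nucleotides translate back to the query protein
  i <- which(ca$gene_kind == "terminase")
  nt <- substr(g$sequence, ca$start[i] + 1, ca$end[i])
  if (ca$strand[i] == "-") nt <- chartr("ACGT", "TGCA", paste(rev(strsplit(
    nt, "")[[1]]), collapse = ""))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  expect_identical(sub("\\*$", "", aa), db$aa[db$query_id == ca$query_id[i]])
})

test_that("genome generation rejects bad inputs with informative errors", {
  expect_error(generate_genome(1000, 0.5), "length")
  expect_error(generate_genome(10000, 0.1), "gc_target")
  plan <- data.frame(gene_kind = "capsid", start = 9990)
  expect_error(generate_genome(10000, 0.5, cassettes = plan, seed = 1),
               "capsid")
})

test_that("backtranslate respects the GC target deterministically", {
  aa <- "MKLVNNAGITRDNLLMRMKEEEW"
  nt1 <- backtranslate(aa, 0.35)
  nt2 <- backtranslate(aa, 0.35)
  expect_identical(nt1, nt2)
  expect_identical(nchar(nt1), 3L * (nchar(aa) + 1L))
  tr <- as.character(Biostrings::translate(Biostrings::DNAString(nt1)))
  expect_identical(tr, paste0(aa, "*"))
  # codon choice tracks the target: low-GC target gives lower-GC codons
  expect_lt(gc_content(backtranslate(aa, 0.25)),
            gc_content(backtranslate(aa, 0.75)))
})

test_that("virus GC couples to host GC with the configured offset", {
  expect_equal(couple_virus_gc(0.38, -0.017, 0), 0.363, tolerance = 1e-12)
  expect_equal(couple_virus_gc(0.38, 0, 0), 0.38, tolerance = 1e-12)
  # law of large numbers under the normal offset model
  draws <- couple_virus_gc(rep(0.5, 1000), -0.017, 0.01, seed = 3)
  expect_lt(abs(mean(draws) - 0.483), 0.002)
  # clamping
  expect_equal(couple_virus_gc(0.79, 0.2, 0), 0.8)
  expect_equal(couple_virus_gc(0.21, -0.2, 0), 0.2)
})
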