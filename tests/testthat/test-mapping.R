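test_that("k-mer assignment agrees with the brute-force oracle on toys", {
  set.seed(31)
  ctgs <- vapply(1:5, function(i) random_dna(1500, gc = 0.45), "")
  ids <- sprintf("ctg%02d", 1:5)
  contigs <- manual_contigs(ctgs, ids)
  # reads drawn from the contigs (some with substitutions), plus junk
  reads <- character(0)
  for (i in 1:5) {
    st <- sample(1:(1500 - 120), 30)
    rd <- substring(ctgs[i], st, st + 119)
    reads <- c(reads, rd)
  }
  mutate1 <- function(r) { substr(r, 60, 60) <- "A"; r }
  reads <- c(reads, vapply(reads[1:30], mutate1, ""),
             vapply(1:20, function(i) random_dna(120, 0.45), ""))
  lib <- manual_library(unname(reads), truth = rep("x", length(reads)),
                        read_length = 120L)
  m <- map_reads(lib, contigs, k = 21)
  asg <- hybridsip:::kmer_assign_cpp(lib$reads$sequence,
                                     contigs$contigs$sequence, 21L)
  got <- ifelse(is.na(asg$contig), NA_character_, ids[asg$contig])
  expected <- bf_assign_oracle(lib$reads$sequence, ctgs, ids, 21)
  expect_identical(got, expected)
  # per-contig counts agree with the oracle assignment
  expect_equal(unname(m$mapped_read_count),
               unname(as.integer(table(factor(expected, levels = ids)))))
})

test_that("ties break to the lexicographically smallest contig id", {
  s <- random_dna(500, 0.5, seed = 77)
  contigs <- manual_contigs(c(s, s), ids = c("b_ctg", "a_ctg"))
  lib <- manual_library(substring(s, 101, 250), read_length = 150L)
  m <- map_reads(lib, contigs, k = 21)
  expect_identical(m$mapped_read_count[m$contig_id == "a_ctg"], 1L)
  expect_identical(m$mapped_read_count[m$contig_id == "b_ctg"], 0L)
})

test_that("depth and breadth follow the placement arithmetic", {
  ctg <- random_dna(10000, 0.5, seed = 12)
  contigs <- manual_contigs(ctg, "tile")
  # 66 non-overlapping 150 bp reads tiled end to end cover 9,900 bp
  starts <- seq(1, by = 150, length.out = 66)
  lib <- manual_library(substring(ctg, starts, starts + 149),
                        read_length = 150L)
  m <- map_reads(lib, contigs, k = 21)
  expect_identical(m$mapped_read_count, 66L)
  expect_equal(m$breadth, 0.99, tolerance = 1e-12)
  expect_equal(m$mean_depth, 0.99, tolerance = 1e-12)

  # zero-read library maps nothing
  lib0 <- manual_library(character(0), truth = character(0),
                         read_length = 150L)
  lib0$depth <- 0L
  m0 <- map_reads(lib0, contigs, k = 21)
  expect_identical(m0$mapped_read_count, 0L)
  expect_equal(m0$breadth, 0)

  expect_error(map_reads(manual_library("ACGTACGTAC", read_length = 10L),
                         contigs, k = 21), "exceeds")
})

test_that("breadth/depth consistency holds on realistic mappings", {
  cfg <- fast_config(seed = 2, depth = 4000)
  sc <- build_scenario(cfg)
  profs <- hybridsip:::simulate_gradients(sc, cfg)
  libs <- hybridsip:::simulate_libraries(sc, cfg, profs)
  lay <- experiment_layout(cfg)
  lbd <- libs[lay$library_id[lay$pool == "LBD" & lay$treatment == "12C"]]
  ctg <- recover_contigs(lbd, sc$genomes, min_depth = 1, seed = 1)
  for (lib in libs[c(1, 8, 16, 24)]) {
    m <- map_reads(lib, ctg, 21)
    rl <- lib$read_length
    expect_true(all(m$breadth >= 0 & m$breadth <= 1))
    len <- attr(m, "contig_length")[m$contig_id]
    expect_true(all(m$breadth <= pmin(1, m$mapped_read_count * rl / len) +
                      1e-12))
    expect_true(all(m$mean_depth <= m$mapped_read_count * rl / len + 1e-12))
    expect_identical(sum(m$mapped_read_count) + attr(m, "unmapped"),
                     lib$depth)
  }
})

test_that("contig recovery enforces the LBD-only design and depth gate", {
  cfg <- fast_config(seed = 2, depth = 12000)
  sc <- build_scenario(cfg)
  profs <- hybridsip:::simulate_gradients(sc, cfg)
  libs <- hybridsip:::simulate_libraries(sc, cfg, profs)
  lay <- experiment_layout(cfg)
  lbd <- libs[lay$library_id[lay$pool == "LBD" & lay$treatment == "12C"]]
  hbd <- libs[[lay$library_id[lay$pool == "HBD"][1]]]
  expect_error(recover_contigs(c(lbd, list(hbd)), sc$genomes),
               "design violation")

  ctg <- recover_contigs(lbd, sc$genomes, min_depth = 5, seed = 3)
  # populations below the depth gate yield nothing
  absent <- setdiff(names(sc$genomes), ctg$contigs$source_pop_id)
  expect_true(all(ctg$pooled_depth[absent] < 5))
  expect_true(all(ctg$pooled_depth[unique(ctg$contigs$source_pop_id)] >= 5))
  # the unlabeled high-GC background never yields LBD contigs
  bg <- sc$populations$pop_id[sc$populations$guild == "background"]
  expect_length(intersect(bg, ctg$contigs$source_pop_id), 0)
  # abundant unlabeled low-GC AOA is recovered: the design's premise
  aoa <- sc$populations$pop_id[sc$populations$guild == "AOA_host"]
  expect_gt(length(intersect(aoa, ctg$contigs$source_pop_id)), 0)
  # fragments respect the length floor and partition their genome
  expect_true(all(ctg$contigs$length >= 5000))
  for (p in unique(ctg$contigs$source_pop_id)) {
    cc <- ctg$contigs[ctg$contigs$source_pop_id == p, ]
    cc <- cc[order(cc$start), ]
    expect_identical(cc$start[1], 0L)
    expect_identical(cc$end[nrow(cc)], sc$genomes[[p]]$length)
    if (nrow(cc) > 1)
      expect_true(all(cc$start[-1] == cc$end[-nrow(cc)]))
  }

  # recovery is invariant to library order
  ctg_rev <- recover_contigs(rev(lbd), sc$genomes, min_depth = 5, seed = 3)
  expect_identical(ctg$contigs, ctg_rev$contigs)
})

test_that("feature proportions normalize by library depth", {
  ctg <- manual_contigs(random_dna(2000, 0.5, seed = 9), "fA")
  reads <- substring(ctg$contigs$sequence, seq(1, 971, 10),
                     seq(1, 971, 10) + 99)[1:25]
  lib <- manual_library(c(reads, vapply(1:75, function(i)
    random_dna(100, 0.5), "")), read_length = 100L)
  m <- map_reads(lib, ctg, 21)
  p <- feature_proportions(m, c(fA = "featA"))
  expect_equal(unname(p["featA"]), 0.25)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  lib$depth <- 0L
  m0 <- map_reads(lib, ctg, 21)
  attr(m0, "library_depth") <- 0L
  expect_error(feature_proportions(m0, c(fA = "featA")), "zero-depth")
})
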