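db <- hallmark_db()

test_that("the packaged hallmark set is complete and well-formed", {
  expect_true(all(c("capsid", "terminase", "portal", "integrase", "mco1")
                  %in% db$gene_kind))
  expect_true(all(db$length >= 150 & db$length <= 400))
  expect_true(all(grepl("^M", db$aa)))
  expect_true(all(db$guild %in% c("AOA", "AOB", "NOB")))
})

test_that("alignment scores match an independent Gotoh implementation", {
  mat <- blosum62()
  set.seed(14)
  aas <- rownames(mat)[1:20]
  for (i in 1:8) {
    a <- paste(sample(aas, 40, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 50, replace = TRUE), collapse = "")
    got <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(got, sw_oracle(a, b, mat), tolerance = 1e-9)
  }
  # a homologous pair: query with a mutated/deleted copy inside
  q <- db$aa[1]
  mut <- paste0(substr(q, 1, 80), substr(q, 91, nchar(q)))
  got <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(mut), Biostrings::AAString(q), type = "local",
    substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
  expect_equal(got, sw_oracle(mut, q, mat), tolerance = 1e-9)
})

test_that("an exact fixture copy scores its self-alignment score", {
  mat <- blosum62()
  q <- db[db$gene_kind == "terminase", ][1, ]
  orfs <- data.frame(contig_id = "c1", start = 0L,
                     end = 3L * (nchar(q$aa) + 1L), strand = "+", frame = 0L,
                     length_aa = nchar(q$aa), aa = q$aa)
  hits <- hallmark_search(orfs, db, score_threshold = 100)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$query_id, q$query_id)
  self_score <- sum(mat[cbind(strsplit(q$aa, "")[[1]],
                              strsplit(q$aa, "")[[1]])])
  expect_equal(hits$score, self_score, tolerance = 1e-9)
})

test_that("random ORFs essentially never reach the default threshold", {
  set.seed(99)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
           "T","W","Y","V")
  orfs <- data.frame(
    contig_id = sprintf("r%03d", 1:100), start = 0L, end = 603L,
    strand = "+", frame = 0L, length_aa = 200L,
    aa = vapply(1:100, function(i)
      paste(sample(aas, 200, replace = TRUE), collapse = ""), ""))
  hits <- hallmark_search(orfs, db, score_threshold = 100, prescreen = FALSE)
  expect_gte(sum(!orfs$contig_id %in% hits$contig_id), 99L)
})

test_that("the word prescreen changes no reported hit", {
  set.seed(7)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
           "T","W","Y","V")
  q <- db$aa[db$gene_kind == "capsid"][3]
  orfs <- data.frame(
    contig_id = c("real", "junk1", "junk2"), start = 0L,
    end = 3L * (c(nchar(q), 180L, 180L) + 1L), strand = "+", frame = 0L,
    length_aa = c(nchar(q), 180L, 180L),
    aa = c(q, paste(sample(aas, 180, TRUE), collapse = ""),
           paste(sample(aas, 180, TRUE), collapse = "")))
  h1 <- hallmark_search(orfs, db, 100, prescreen = TRUE)
  h2 <- hallmark_search(orfs, db, 100, prescreen = FALSE)
  expect_identical(h1, h2)
  expect_identical(nrow(hallmark_search(orfs[0, ], db, 100)), 0L)
})

test_that("vOTU calling applies the length, hallmark-kind and GC rules", {
  set.seed(21)
  mk_ctg_with <- function(len, kinds, gc = 0.36, id = "c") {
    plan <- data.frame(gene_kind = kinds, query_id = vapply(kinds,
      function(k) db$query_id[db$gene_kind == k & db$guild == "AOA"][1], ""))
    g <- generate_genome(len, gc, cassettes = plan, seed = 5)
    manual_contigs(g$sequence, id, source = "vir_x")
  }
  screen_one <- function(ctg) {
    orfs <- find_orfs(ctg$contigs$sequence[1], 100,
                      ctg$contigs$contig_id[1])
    hits <- hallmark_search(orfs, db, 100)
    lib <- manual_library(substring(ctg$contigs$sequence, 1, 150))
    m <- map_reads(lib, ctg, 21)
    call_votus(ctg, hits, m, guild_gc = c(AOA = 0.38, AOB = 0.55,
                                          NOB = 0.60))
  }
  # 8 kb contig with a capsid hit: rejected by the >= 10 kb rule
  expect_identical(nrow(screen_one(mk_ctg_with(8000, "capsid"))), 0L)
  # 20 kb with terminase + integrase: vOTU, temperate, AOA host guild
  v <- screen_one(mk_ctg_with(20000, c("terminase", "integrase")))
  expect_identical(nrow(v), 1L)
  expect_true(v$temperate_predicted)
  expect_identical(v$host_guild, "AOA")
  expect_match(v$gene_kinds, "integrase")
  # integrase alone never triggers a call (hosts carry integrases)
  expect_identical(nrow(screen_one(mk_ctg_with(20000, "integrase"))), 0L)
  # neither does the host-derived mco1 AMG alone
  expect_identical(nrow(screen_one(mk_ctg_with(20000, "mco1"))), 0L)
  # GC far from the predicted guild's hosts falls back to unknown
  v2 <- screen_one(mk_ctg_with(20000, "portal", gc = 0.55))
  expect_identical(nrow(v2), 1L)
  expect_identical(v2$host_guild, "unknown")
})

test_that("per-library detection flags require both depth and breadth", {
  g <- generate_genome(20000, 0.36,
                       cassettes = data.frame(gene_kind = "terminase"),
                       seed = 6)
  ctg <- manual_contigs(g$sequence, "cV", source = "vir_y")
  orfs <- find_orfs(g$sequence, 100, "cV")
  hits <- hallmark_search(orfs, db, 100)
  # deep, broad library: tile the whole contig 2x
  st <- seq(1, 19851, by = 75)
  deep <- manual_library(substring(g$sequence, st, st + 149), id = "deep")
  # shallow library: 20 reads from one corner (breadth ~0.15%)
  shal <- manual_library(substring(g$sequence, seq(1, 20, 1),
                                   seq(1, 20, 1) + 149), id = "shallow")
  ms <- list(deep = map_reads(deep, ctg, 21),
             shallow = map_reads(shal, ctg, 21))
  v <- call_votus(ctg, hits, ms, guild_gc = c(AOA = 0.38))
  passes <- attr(v, "passes")
  expect_true(passes[1, "deep"])
  expect_false(passes[1, "shallow"])
})
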