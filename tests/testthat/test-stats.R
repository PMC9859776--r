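test_that("Student, Welch and F tests match textbook-formula oracles", {
  set.seed(1234)
  for (i in 1:250) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1, 0.02, 0.005)
    y <- rnorm(n2, 0.02 * sample(c(1, 2), 1), 0.005)
    # F-test p-value drives variance_check
    fo <- f_test_oracle(x, y)
    expect_equal(var.test(x, y)$p.value, fo$p, tolerance = 1e-10)
    expect_identical(variance_check(x, y, 0.05), fo$p >= 0.05)
    # forced Student
    r_s <- enrichment_test(x, y, var_alpha = 1e-12)  # p >= tiny alpha: student
    so <- student_t_oracle(y, x)
    expect_identical(r_s$test_used, "student")
    expect_equal(r_s$t_stat, so$t, tolerance = 1e-10)
    expect_equal(r_s$p_value, so$p, tolerance = 1e-10)
    # Welch arm whenever the F-test is significant at 0.05
    r <- enrichment_test(x, y, var_alpha = 0.05)
    if (!r$variance_homogeneous) {
      wo <- welch_t_oracle(y, x)
      expect_identical(r$test_used, "welch")
      expect_equal(r$t_stat, wo$t, tolerance = 1e-10)
      expect_equal(r$p_value, wo$p, tolerance = 1e-10)
    }
  }
})

test_that("variance homogeneity decisions include the degenerate rules", {
  x <- c(0.01, 0.012, 0.011)
  expect_true(variance_check(x, x))
  set.seed(3)
  a <- rnorm(3, 0, 1); b <- rnorm(3, 0, 0.1)  # 100x variance ratio
  expect_false(variance_check(a, b, 0.05))
  expect_false(variance_check(c(1, 1, 1), c(1, 2, 3)))
  expect_true(variance_check(c(1, 1, 1), c(2, 2, 2)))
  expect_error(variance_check(1, c(1, 2)), ">= 2")
})

test_that("enrichment calls are directional and handle degenerate inputs", {
  x <- c(0.010, 0.012, 0.011)
  r0 <- enrichment_test(x, x)
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$p_value, 1)
  expect_false(r0$enriched)

  y <- c(0.030, 0.028, 0.032)
  r <- enrichment_test(x, y)
  expect_true(r$enriched)
  oracle <- if (r$variance_homogeneous) student_t_oracle(y, x) else
    welch_t_oracle(y, x)
  expect_equal(r$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(r$t_stat, oracle$t, tolerance = 1e-10)

  # significantly LOWER 13C mean must not be called enriched
  r_dec <- enrichment_test(y, x)
  expect_lt(r_dec$p_value, 0.05)
  expect_false(r_dec$enriched)

  # both groups constant: equal -> p 1; different -> p 0 with direction
  r_c <- enrichment_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(r_c$p_value, 1)
  r_d <- enrichment_test(c(0, 0, 0), c(1, 1, 1))
  expect_equal(r_d$p_value, 0)
  expect_true(r_d$enriched)
})

test_that("enriched is antitone in alpha", {
  set.seed(77)
  calls <- vapply(c(0.2, 0.1, 0.05, 0.01, 0.001), function(a) {
    set.seed(12)
    x <- rnorm(3, 0.01, 0.002); y <- rnorm(3, 0.02, 0.002)
    enrichment_test(x, y, alpha = a)$enriched
  }, NA)
  expect_true(all(diff(as.integer(calls)) <= 0))
})

test_that("soil differential labels features by their dominant soil", {
  pa <- matrix(c(0.05, 0.06, 0.055, 0, 0, 0, 0.01, 0.011, 0.012), 3,
               byrow = TRUE,
               dimnames = list(c("fA", "fB", "fC"), NULL))
  pb <- matrix(c(0, 0, 0, 0.04, 0.05, 0.045, 0.01, 0.011, 0.012), 3,
               byrow = TRUE, dimnames = list(c("fA", "fB", "fC"), NULL))
  r <- soil_differential(pa, pb)
  expect_identical(r$label, c("pH4.5", "pH7.5", "ns"))
})

test_that("the heatmap is ln reads-per-kb with masking, never ln(0)", {
  ctgs <- manual_contigs(c(random_dna(10000, 0.4, seed = 1),
                           random_dna(20000, 0.4, seed = 2)),
                         c("v10", "v20"))
  votus <- data.frame(contig_id = c("v10", "v20"),
                      length = c(10000L, 20000L))
  # tile v10 with 100 reads, v20 with 200: equal reads-per-kb
  r1 <- substring(ctgs$contigs$sequence[1], seq(1, 9851, length.out = 100),
                  seq(1, 9851, length.out = 100) + 149)
  r2 <- substring(ctgs$contigs$sequence[2], seq(1, 19851, length.out = 200),
                  seq(1, 19851, length.out = 200) + 149)
  lib <- manual_library(c(r1, r2), id = "L1")
  m <- map_reads(lib, ctgs, 21)
  hm <- heatmap_matrix(list(m), votus)
  expect_equal(unname(hm$values["v10", 1]), log(10), tolerance = 1e-12)
  expect_equal(unname(hm$values["v10", 1]), unname(hm$values["v20", 1]),
               tolerance = 1e-12)
  expect_true(all(is.finite(hm$values[!hm$mask])))
  # a low-breadth library is masked, not imputed
  lib2 <- manual_library(substring(ctgs$contigs$sequence[1],
                                   seq(1, 30), seq(1, 30) + 149), id = "L2")
  m2 <- map_reads(lib2, ctgs, 21)
  hm2 <- heatmap_matrix(list(m2), votus)
  expect_true(all(hm2$mask[, 1]))
  expect_true(all(is.na(hm2$values[hm2$mask])))
})

test_that("BH adjustment is available behind the config switch", {
  set.seed(5)
  p12 <- matrix(rnorm(30, 0.01, 0.002), 10,
                dimnames = list(paste0("f", 1:10), NULL))
  p13 <- p12 + matrix(rnorm(30, 0, 0.002), 10)
  raw <- enrichment_table(p12, p13, p_adjust = "none")
  adj <- enrichment_table(p12, p13, p_adjust = "BH")
  expect_true(all(adj$p_adjusted >= raw$p_value - 1e-12))
  expect_lte(sum(adj$enriched), sum(raw$enriched))
})
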