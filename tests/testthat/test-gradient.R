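test_that("buoyant density follows the linear GC/labeling model", {
  expect_equal(buoyant_density(0.50, 0.011), 1.7090, tolerance = 1e-9)
  # full labeling of a 0.38-GC genome crosses the HBD cut
  expect_equal(buoyant_density(0.38, 1.00), 1.7332, tolerance = 1e-4)
  expect_gt(buoyant_density(0.38, 1.00), 1.719)
  # unlabeled high-GC background sits above the cut too (co-migration)
  expect_equal(buoyant_density(0.67, 0.011), 1.72566, tolerance = 1e-9)
  expect_gt(buoyant_density(0.67, 0.011), 1.719)
  expect_error(buoyant_density(1.2, 0.011), "gc")
  expect_error(buoyant_density(0.5, -0.1), "atom13c")
})

test_that("buoyant density is strictly increasing in GC and atom fraction", {
  set.seed(42)
  gc <- sort(runif(50)); at <- sort(runif(50))
  expect_true(all(diff(buoyant_density(gc, 0.3)) > 0))
  expect_true(all(diff(buoyant_density(0.4, at)) > 0))
})

test_that("band masses conserve input mass and respect symmetry", {
  sch <- fraction_scheme()
  for (bd in c(1.67, 1.7090, 1.733, 1.775)) {
    v <- band_masses(bd, 0.003, 2.5, sch)
    expect_equal(sum(v), 2.5, tolerance = 1e-9)
    expect_true(all(v >= 0))
  }
  # delta limit: vanishing sigma puts all mass into the bin holding the mean
  v <- band_masses(1.7090 + 0.0001, 1e-7, 1, sch)
  bin <- findInterval(1.7090 + 0.0001, sch$edges)
  expect_equal(v[bin], 1, tolerance = 1e-12)
  # symmetry around a bin edge: equal mass on matching bins each side
  v <- band_masses(sch$edges[21], 0.003, 1, sch)
  expect_equal(v[21], v[20], tolerance = 1e-9)
  expect_equal(v[22], v[19], tolerance = 1e-9)
  # far-out band centre warns and piles mass at the edge
  expect_warning(v <- band_masses(1.60, 0.003, 1, sch), "edge")
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("fraction scheme validates its invariants", {
  expect_error(fraction_scheme(c(1.7, 1.66)), "increasing|span")
  expect_error(fraction_scheme(c(1.66, 1.78), 4), "8")
  expect_error(fraction_scheme(c(1.70, 1.78)), "cover")
  sch <- fraction_scheme(c(1.66, 1.78), 40)
  expect_length(sch$midpoints, 40)
  expect_true(all(diff(sch$edges) > 0))
})

cfg <- sip_config(seed = 9)
sc <- build_scenario(cfg)

test_that("gradient profiles conserve each population's mass", {
  prof <- gradient_profile(sc, cfg, "pH4.5", "13C", 1)
  expect_equal(unname(rowSums(prof$mass)),
               unname(sc$populations$abundance[, "pH4.5"]),
               tolerance = 1e-9)
})

test_that("marker profiles reproduce the labeled-AOA rightward shift", {
  prof <- gradient_profile(sc, cfg, "pH4.5", "13C", 1)
  pops <- sc$populations
  aoa <- pops$pop_id[pops$guild == "AOA_host" & pops$active &
                       pops$soil == "pH4.5"]
  bg <- pops$pop_id[pops$guild == "background" & pops$soil == "pH4.5"]
  m_aoa <- marker_profile(prof, aoa)
  m_bg <- marker_profile(prof, bg)
  expect_equal(sum(m_aoa), 1, tolerance = 1e-12)
  expect_equal(sum(m_bg), 1, tolerance = 1e-12)
  mid <- prof$scheme$midpoints
  expect_gt(mid[which.max(m_aoa)], mid[which.max(m_bg)])
  # single-population subset equals that population's normalized band
  one <- marker_profile(prof, aoa[1])
  expect_equal(unname(one),
               unname(prof$mass[aoa[1], ] / sum(prof$mass[aoa[1], ])),
               tolerance = 1e-12)
  expect_error(marker_profile(prof, character(0)), "non-empty")
  expect_error(marker_profile(prof, "nope"), "unknown")
})

test_that("pooling splits labeled and unlabeled low-GC DNA as designed", {
  sch <- fraction_scheme()
  pool_of <- function(gc, atom) {
    bd <- buoyant_density(gc, atom)
    m <- matrix(band_masses(bd, 0.003, 1, sch), nrow = 1,
                dimnames = list("p", NULL))
    prof <- structure(list(scheme = sch, mass = m),
                      class = "sip_gradient_profile")
    c(LBD = unname(pool_fractions(prof, "LBD")),
      HBD = unname(pool_fractions(prof, "HBD")))
  }
  lab_aoa <- pool_of(0.38, 1.0)      # fully labeled AOA
  unlab_aoa <- pool_of(0.38, 0.011)  # unlabeled AOA
  unlab_bg <- pool_of(0.67, 0.011)   # unlabeled high-GC background
  # co-migration: both labeled AOA and unlabeled background pool in HBD
  expect_gt(lab_aoa["HBD"], 0.5)
  expect_gt(unlab_bg["HBD"], 0.5)
  # separation: unlabeled AOA pools in LBD, background does not
  expect_gt(unlab_aoa["LBD"], 0.5)
  expect_lt(unlab_bg["LBD"], unlab_aoa["LBD"])
  # pools are disjoint subsets of the gradient
  for (p in list(lab_aoa, unlab_aoa, unlab_bg))
    expect_lte(p["LBD"] + p["HBD"], 1 + 1e-12)
})
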