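#' Define a CsCl gradient fraction scheme
#'
#' Contiguous half-open buoyant-density bins `[e_i, e_{i+1})` over the
#' fractionated span. The default (40 bins over 1.66-1.78 g/ml, width
#' 0.003 g/ml) places the 1.699 g/ml LBD cut on a bin edge so midpoint-based
#' pooling reproduces the continuous cut exactly.
#'
#' @param span length-2 numeric, fractionated density range (g/ml).
#' @param n_bins number of equal bins (>= 8).
#' @return class `sip_fractions`: list with `edges` (length `n_bins + 1`) and
#'   `midpoints`.
#' @export
fraction_scheme <- function(span = c(1.66, 1.78), n_bins = 40L) {
  stopifnot(length(span) == 2L, span[1] < span[2], n_bins >= 8L)
  if (span[1] > 1.66 + 1e-12 || span[2] < 1.78 - 1e-12)
    stop("fraction scheme span must cover [1.66, 1.78] g/ml")
  edges <- seq(span[1], span[2], length.out = n_bins + 1L)
  structure(list(edges = edges,
                 midpoints = (edges[-1] + edges[-length(edges)]) / 2),
            class = "sip_fractions")
}

#' Buoyant density of DNA in a CsCl gradient
#'
#' DNA bands at the density matching its own buoyant density, which increases
#' linearly with GC content (Schildkraut-type relation) and with excess 13C
#' atom fraction above natural abundance:
#' `BD = 1.660 + 0.098 * GC + 0.036 * (atom13c - 0.011) / (1 - 0.011)`.
#' Fully labeled low-GC (0.38) DNA reaches ~1.733 g/ml and therefore
#' co-migrates with unlabeled high-GC (0.67, ~1.726 g/ml) DNA above the
#' 1.719 g/ml HBD cut — the confounding this package's hybrid LBD/HBD design
#' resolves.
#'
#' @param gc GC fraction in \[0, 1\].
#' @param atom13c 13C atom fraction in \[0, 1\] (natural abundance 0.011).
#' @param intercept,gc_slope,label_shift model constants (g/ml),
#'   config-overridable.
#' @return buoyant density in g/ml; strictly increasing in both arguments.
#' @export
#' @examples
#' buoyant_density(0.50, 0.011)  # 1.709
#' buoyant_density(0.38, 1.00)   # 1.7332: above the 1.719 HBD cut
buoyant_density <- function(gc, atom13c = NATURAL_13C, intercept = 1.660,
                            gc_slope = 0.098, label_shift = 0.036) {
  if (any(gc < 0 | gc > 1)) stop("gc must be in [0, 1]")
  if (any(atom13c < 0 | atom13c > 1)) stop("atom13c must be in [0, 1]")
  intercept + gc_slope * gc +
    label_shift * (atom13c - NATURAL_13C) / (1 - NATURAL_13C)
}

#' Distribute a population's DNA mass across gradient fractions
#'
#' The isopycnic band is a Gaussian centred on the population's buoyant
#' density with diffusion half-width `sigma`; the density is integrated over
#' each bin and renormalized over the scheme's span so the vector sums to
#' `total_mass` exactly (mass outside the span is folded back
#' proportionally).
#'
#' @param bd_mean band centre (g/ml).
#' @param sigma band half-width (g/ml), > 0.
#' @param total_mass DNA mass (arbitrary units).
#' @param scheme a [fraction_scheme()].
#' @return numeric vector of per-fraction mass summing to `total_mass`.
#' @export
band_masses <- function(bd_mean, sigma, total_mass, scheme) {
  stopifnot(inherits(scheme, "sip_fractions"), sigma > 0, total_mass >= 0)
  edges <- scheme$edges
  if (bd_mean < edges[1] - 5 * sigma || bd_mean > edges[length(edges)] + 5 * sigma)
    warning("band centre ", signif(bd_mean, 6),
            " lies > 5 sigma outside the fraction scheme; ",
            "mass piles into the edge bin after renormalization")
  p <- diff(pnorm(edges, mean = bd_mean, sd = sigma))
  tot <- sum(p)
  if (tot <= 0) {  # band entirely outside numerical support: edge bin
    p <- numeric(length(edges) - 1L)
    p[if (bd_mean <= edges[1]) 1L else length(p)] <- 1
    tot <- 1
  }
  p / tot * total_mass
}

#' Simulate one CsCl gradient (one replicate microcosm)
#'
#' Bands every population's DNA mass (its relative abundance in the soil)
#' at the buoyant density implied by its realized GC and its 13C atom
#' fraction under the treatment, with a small replicate-specific jitter of
#' the band centre emulating inter-gradient variation, and bins the mass
#' into fractions.
#'
#' @param scenario a `sip_scenario`.
#' @param config a [sip_config()].
#' @param soil,treatment,replicate which microcosm.
#' @return class `sip_gradient_profile`: list with `scheme`, `mass`
#'   (populations x fractions matrix), `bd_mean` (jittered band centres),
#'   `soil`, `treatment`, `replicate`.
#' @export
gradient_profile <- function(scenario, config, soil, treatment, replicate) {
  stopifnot(soil %in% scenario$soils, treatment %in% c("12C", "13C"))
  g <- config$gradient
  scheme <- fraction_scheme(g$span, g$n_bins)
  pops <- scenario$populations
  gc <- vapply(scenario$genomes[pops$pop_id], `[[`, 0, "realized_gc")
  atom <- atom13c_fraction(scenario, treatment, config$scenario$atom13c_active)
  bd <- buoyant_density(gc, atom[pops$pop_id], g$bd_intercept, g$bd_gc_slope,
                        g$bd_label_shift)
  set.seed(stable_hash(config$seed, "gradient", soil, treatment, replicate))
  bd <- bd + rnorm(length(bd), 0, g$jitter_sd)
  mass <- t(vapply(seq_along(bd), function(i)
    band_masses(bd[i], g$sigma, pops$abundance[i, soil], scheme),
    numeric(length(scheme$midpoints))))
  dimnames(mass) <- list(pops$pop_id, sprintf("F%02d", seq_along(scheme$midpoints)))
  structure(list(scheme = scheme, mass = mass, bd_mean = setNames(bd, pops$pop_id),
                 soil = soil, treatment = treatment, replicate = replicate),
            class = "sip_gradient_profile")
}

#' Marker-gene profile across gradient fractions
#'
#' Sums the mass of a subset of populations per fraction and normalizes to
#' 1 over fractions — the analogue of qPCR-derived 16S rRNA or amoA gene
#' relative-abundance profiles used to locate labeled populations in the
#' gradient.
#'
#' @param profile a `sip_gradient_profile`.
#' @param marker_populations non-empty character vector of population ids.
#' @return named numeric vector over fractions summing to 1.
#' @export
marker_profile <- function(profile, marker_populations) {
  stopifnot(inherits(profile, "sip_gradient_profile"))
  if (length(marker_populations) == 0L)
    stop("marker population subset must be non-empty")
  missing <- setdiff(marker_populations, rownames(profile$mass))
  if (length(missing))
    stop("unknown population(s): ", paste(missing, collapse = ", "))
  v <- colSums(profile$mass[marker_populations, , drop = FALSE])
  tot <- sum(v)
  if (tot <= 0) stop("selected populations carry no mass in this gradient")
  v / tot
}

#' Pool gradient fractions into LBD or HBD DNA
#'
#' Sums each population's mass over the fractions whose midpoint satisfies
#' the pool predicate: HBD = midpoint above `hbd_min` (default
#' 1.719 g/ml), LBD = midpoint below `lbd_max` (default 1.699 g/ml).
#' Populations with zero pooled mass are retained with mass 0.
#'
#' @param profile a `sip_gradient_profile`.
#' @param pool `"LBD"` or `"HBD"`.
#' @param lbd_max,hbd_min pooling cuts (g/ml).
#' @return named numeric vector of pooled mass per population.
#' @export
pool_fractions <- function(profile, pool = c("LBD", "HBD"), lbd_max = 1.699,
                           hbd_min = 1.719) {
  pool <- match.arg(pool)
  stopifnot(lbd_max < hbd_min)
  mid <- profile$scheme$midpoints
  sel <- if (pool == "LBD") mid < lbd_max else mid > hbd_min
  if (!any(sel) && pool == "LBD" && min(mid) >= lbd_max)
    stop("fraction scheme does not cover the LBD range")
  rowSums(profile$mass[, sel, drop = FALSE])
}

#' @export
print.sip_gradient_profile <- function(x, ...) {
  cat(sprintf("<sip_gradient_profile %s/%s rep %d: %d populations x %d fractions>\n",
              x$soil, x$treatment, x$replicate, nrow(x$mass), ncol(x$mass)))
  invisible(x)
}
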