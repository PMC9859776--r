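#' Build the synthetic two-soil SIP scenario
#'
#' Generates the ground-truth community the pipeline is exercised on: two
#' soils (pH 4.5 and pH 7.5) with disjoint populations, each soil holding
#' active low-GC AOA hosts (~0.38 GC) amid a high-GC (0.57-0.70) unlabeled
#' background block that carries most of the DNA, one inactive AOA
#' population, one active high-GC nitrifier (NOB or AOB) that will band in
#' HBD even unlabeled (the design's known blind spot), and AOA-infecting
#' viruses whose GC is coupled to their hosts'. Under the 13C treatment,
#' active populations (and the viruses infecting them) reach
#' `scenario$atom13c_active` 13C atom fraction; everything else stays at
#' natural abundance (0.011). The pH 4.5 soil carries four active AOA host
#' populations and the pH 7.5 soil three.
#'
#' All AOA host genomes carry an integrase cassette (a provirus remnant, as
#' is typical for AOA genomes), so host contigs exercise the rule that an
#' integrase hit alone never triggers a virus call. Temperate viruses carry
#' an integrase cassette plus at least one of capsid/terminase/portal;
#' virulent viruses carry trigger cassettes only. One virus per soil is
#' shorter than 10 kb (rejected by the vOTU length filter) and one carries an
#' mco1 auxiliary metabolic gene cassette.
#'
#' @param config a [sip_config()].
#' @return an object of class `sip_scenario`: list with `populations` (a
#'   data.frame; `abundance` is a populations x soils matrix column),
#'   `genomes` (named list of `sip_genome`), and `guild_gc` (named vector of
#'   mean host GC per guild, used to corroborate virus-host linkage).
#' @export
#' @examples
#' sc <- build_scenario(sip_config(seed = 1))
#' table(sc$populations$guild)
build_scenario <- function(config = sip_config()) {
  sp <- config$scenario
  if (!identical(sp$preset, "two_soil_default"))
    stop("unknown scenario preset: ", sp$preset)
  soils <- config$soils
  set.seed(stable_hash(config$seed, "scenario"))
  db <- hallmark_db()

  pops <- rbind(
    soil_populations("s45", soils[1], n_active_aoa = 4L, sp),
    soil_populations("s75", soils[2], n_active_aoa = 3L, sp)
  )
  ab <- matrix(0, nrow(pops), length(soils),
               dimnames = list(pops$pop_id, soils))
  for (s in soils) {
    home <- pops$soil == s
    tot <- sum(pops$abundance_home[home])
    if (tot <= 0) stop("abundance vector not normalizable for soil ", s)
    ab[home, s] <- pops$abundance_home[home] / tot
  }
  pops$abundance <- ab
  pops$abundance_home <- NULL

  # virus GC coupled to host GC
  is_virus <- pops$guild == "virus"
  if (any(is_virus)) {
    host_gc <- pops$gc_target[match(pops$host_id[is_virus], pops$pop_id)]
    pops$gc_target[is_virus] <- round(couple_virus_gc(
      host_gc, sp$virus_gc_offset_mean, sp$virus_gc_offset_sd), 4)
  }

  genomes <- lapply(seq_len(nrow(pops)), function(i) {
    p <- pops[i, ]
    plan <- cassette_plan(p, db)
    generate_genome(p$genome_length, p$gc_target, plan,
                    seed = stable_hash(config$seed, "genome", p$pop_id),
                    pop_id = p$pop_id, db = db)
  })
  names(genomes) <- pops$pop_id

  guild_gc <- vapply(c(AOA = "AOA", AOB = "AOB", NOB = "NOB"), function(g) {
    sel <- pops$guild == paste0(g, "_host")
    if (any(sel)) mean(pops$gc_target[sel]) else NA_real_
  }, 0)

  sc <- structure(list(populations = pops, genomes = genomes,
                       guild_gc = guild_gc, soils = soils),
                  class = "sip_scenario")
  validate_scenario(sc)
  sc
}

soil_populations <- function(prefix, soil, n_active_aoa, sp) {
  id <- function(...) paste(prefix, ..., sep = "_")
  host_len <- sp$host_genome_length
  bg_len <- sp$background_genome_length
  aoa_gc <- seq(0.370, 0.390, length.out = n_active_aoa)

  rows <- list(
    data.frame(pop_id = id("aoa_h", seq_len(n_active_aoa)), soil = soil,
               guild = "AOA_host", gc_target = round(aoa_gc, 4),
               genome_length = host_len, abundance_home = 0.12 / n_active_aoa,
               active = TRUE, host_id = NA_character_, temperate = NA),
    data.frame(pop_id = id("aoa_i1"), soil = soil, guild = "AOA_host",
               gc_target = 0.380, genome_length = host_len,
               abundance_home = 0.02, active = FALSE,
               host_id = NA_character_, temperate = NA),
    # active high-GC nitrifier: bands in HBD even unlabeled, so it is never
    # recoverable from LBD — the hybrid design's documented blind spot
    data.frame(pop_id = id("hgc_h1"), soil = soil,
               guild = if (prefix == "s45") "NOB_host" else "AOB_host",
               gc_target = if (prefix == "s45") 0.60 else 0.55,
               genome_length = host_len, abundance_home = 0.03, active = TRUE,
               host_id = NA_character_, temperate = NA),
    data.frame(pop_id = id("bg", 1:6), soil = soil, guild = "background",
               gc_target = c(0.57, 0.60, 0.62, 0.64, 0.67, 0.70),
               genome_length = bg_len, abundance_home = 0.125, active = FALSE,
               host_id = NA_character_, temperate = NA)
  )
  if (isTRUE(sp$viruses)) {
    hosts <- c(id("aoa_h", c(1:min(4, n_active_aoa),
                             rep(1, 4 - min(4, n_active_aoa)))))[1:4]
    rows <- c(rows, list(data.frame(
      pop_id = id("vir", 1:6), soil = soil, guild = "virus",
      gc_target = NA_real_,
      genome_length = c(30000L, 20000L, 40000L, 15000L, 25000L, 8000L),
      abundance_home = c(0.015, 0.015, 0.015, 0.015, 0.010, 0.010),
      active = c(rep(TRUE, 4), FALSE, TRUE),
      host_id = c(hosts, id("aoa_i1"), hosts[1]),
      temperate = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
    )))
  }
  do.call(rbind, rows)
}

# hallmark cassette plan per population. Virus cassettes use AOA-guild
# queries (all default-scenario viruses infect AOA) so host-guild prediction
# is testable, and every population carries a distinct query per gene kind —
# disjoint between soils and between hosts and viruses — emulating distinct
# virus populations per soil rather than one shared pan-soil gene pool.
cassette_plan <- function(p, db) {
  soil_idx <- if (startsWith(p$pop_id, "s45")) 1L else 2L
  pick <- function(kind, idx) {
    pool <- sort(db$query_id[db$gene_kind == kind & db$guild == "AOA"])
    if (idx > length(pool))
      stop("hallmark fixture pool for ", kind, " too small")
    pool[idx]
  }
  if (p$guild %in% c("AOA_host", "AOB_host", "NOB_host")) {
    if (p$guild != "AOA_host") return(NULL)  # only AOA carry provirus remnants
    h <- if (grepl("aoa_i", p$pop_id)) 5L else
      as.integer(sub(".*aoa_h_", "", p$pop_id))
    return(data.frame(gene_kind = "integrase",
                      query_id = pick("integrase", (soil_idx - 1L) * 12L +
                                        6L + h)))
  }
  if (p$guild == "virus") {
    v <- as.integer(sub(".*_vir_", "", p$pop_id))
    kinds <- if (isTRUE(p$temperate)) {
      c("capsid", "terminase", "integrase")
    } else {
      c("capsid", "portal")
    }
    if (v == 2L) kinds <- c(kinds, "mco1")
    if (p$genome_length < 15000L) kinds <- setdiff(kinds, "capsid")
    qidx <- function(kind) {
      base <- if (kind == "integrase") (soil_idx - 1L) * 12L else
        if (kind == "mco1") (soil_idx - 1L) * 3L else (soil_idx - 1L) * 6L
      base + v
    }
    return(data.frame(
      gene_kind = kinds,
      query_id = vapply(kinds, function(k) pick(k, qidx(k)), "")))
  }
  NULL
}

validate_scenario <- function(sc) {
  pops <- sc$populations
  for (s in colnames(pops$abundance)) {
    tot <- sum(pops$abundance[, s])
    if (abs(tot - 1) > 1e-9)
      stop("abundances for soil ", s, " sum to ", tot, ", not 1")
  }
  vir <- pops[pops$guild == "virus", ]
  if (nrow(vir)) {
    if (!all(vir$host_id %in% pops$pop_id))
      stop("virus host_id references missing population")
    for (i in seq_len(nrow(vir))) {
      g <- sc$genomes[[vir$pop_id[i]]]
      has_int <- "integrase" %in% g$cassettes$gene_kind
      if (isTRUE(vir$temperate[i]) != has_int)
        stop("temperate flag and integrase cassette disagree for ",
             vir$pop_id[i])
    }
  }
  invisible(sc)
}

#' Effective 13C atom fraction of each population under a treatment
#'
#' Active populations under the 13C treatment carry their achieved labeling
#' atom fraction; everything else (all populations under 12C, inactive
#' populations under 13C) sits at the natural-abundance constant 0.011.
#'
#' @param scenario a `sip_scenario`.
#' @param treatment `"12C"` or `"13C"`.
#' @param atom13c_active atom fraction achieved by active populations.
#' @return named numeric vector over populations.
#' @export
atom13c_fraction <- function(scenario, treatment, atom13c_active = 1.0) {
  pops <- scenario$populations
  out <- rep(NATURAL_13C, nrow(pops))
  if (treatment == "13C") out[pops$active] <- atom13c_active
  setNames(out, pops$pop_id)
}

#' @export
print.sip_scenario <- function(x, ...) {
  cat(sprintf("<sip_scenario: %d populations (%d viruses) across %s>\n",
              nrow(x$populations), sum(x$populations$guild == "virus"),
              paste(x$soils, collapse = ", ")))
  invisible(x)
}
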