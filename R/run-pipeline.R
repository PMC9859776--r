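#' Run the hybrid SIP pipeline, persisting every stage's artifacts
#'
#' Executes the stage chain `simulate -> fractionate -> sequence -> recover
#' -> map -> screen -> test -> report` against a run directory. Every
#' stage's inputs and outputs are plain-text artifacts (FASTA / GFF3 / TSV /
#' YAML), each stage re-reads its persisted inputs, and the manifest records
#' the package version, a hash of the config, and the derived stage seeds —
#' so re-running any stage (or the whole chain under the same master seed)
#' reproduces its outputs byte for byte. A stage failure aborts with the
#' stage name; earlier stages' outputs remain on disk.
#'
#' @param config a [sip_config()].
#' @param out_dir run directory (created if needed).
#' @param stages stages to run, in order; default all.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "fractionate", "sequence",
                                    "recover", "map", "screen", "test",
                                    "report")) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  for (s in stages) {
    pipeline_log(out_dir, "stage ", s, " started")
    tryCatch(run_stage(s, out_dir),
             error = function(e) {
               pipeline_log(out_dir, "stage ", s, " FAILED: ",
                            conditionMessage(e))
               stop("pipeline stage '", s, "' failed: ", conditionMessage(e),
                    " (partial outputs persisted in ", out_dir, ")",
                    call. = FALSE)
             })
    pipeline_log(out_dir, "stage ", s, " done")
  }
  manifest <- list(
    package = "hybridsip",
    version = as.character(utils::packageVersion("hybridsip")),
    config_hash = stable_hash(paste(readLines(
      file.path(out_dir, "config.yaml")), collapse = "\n")),
    seed = config$seed,
    stage_seeds = list(scenario = stable_hash(config$seed, "scenario"),
                       assembly = stable_hash(config$seed, "assembly")),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

pipeline_log <- function(out_dir, ...) {
  msg <- paste0(...)
  message("[hybridsip] ", msg)
  cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

#' Run a single pipeline stage against a run directory
#'
#' Reads `config.yaml` and the stage's persisted inputs from `run_dir` and
#' writes the stage's outputs there. Stages are deterministic functions of
#' those inputs, so re-running one reproduces its artifacts.
#'
#' @param stage one of `"simulate"`, `"fractionate"`, `"sequence"`,
#'   `"recover"`, `"map"`, `"screen"`, `"test"`, `"report"`.
#' @param run_dir run directory containing `config.yaml`.
#' @return invisibly, the stage's main output object.
#' @export
run_stage <- function(stage, run_dir) {
  fun <- switch(stage,
    simulate = stage_simulate, fractionate = stage_fractionate,
    sequence = stage_sequence, recover = stage_recover, map = stage_map,
    screen = stage_screen, test = stage_test, report = stage_report,
    stop("unknown stage: ", stage))
  config <- read_config(file.path(run_dir, "config.yaml"))
  fun(config, run_dir)
}

subdir <- function(run_dir, name) {
  d <- file.path(run_dir, name)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

gradient_keys <- function(config) {
  k <- expand.grid(replicate = seq_len(config$replicates),
                   treatment = config$treatments, soil = config$soils,
                   stringsAsFactors = FALSE)
  k$key <- sprintf("%s_%s_r%d", k$soil, k$treatment, k$replicate)
  k
}

stage_simulate <- function(config, run_dir) {
  d <- subdir(run_dir, "scenario")
  scenario <- build_scenario(config)
  pops <- scenario$populations
  flat <- pops[, setdiff(names(pops), "abundance")]
  for (s in scenario$soils)
    flat[[paste0("abundance_", s)]] <- pops$abundance[, s]
  write_tsv(flat, file.path(d, "populations.tsv"))
  write_genomes_fasta(scenario, file.path(d, "genomes.fasta"))
  write_cassette_gff3(scenario, file.path(d, "cassettes.gff3"))
  yaml::write_yaml(list(guild_gc = as.list(scenario$guild_gc)),
                   file.path(d, "scenario.yaml"))
  invisible(scenario)
}

stage_fractionate <- function(config, run_dir) {
  d <- subdir(run_dir, "gradient")
  scenario <- build_scenario(config)
  keys <- gradient_keys(config)
  aoa <- scenario$populations$pop_id[scenario$populations$guild == "AOA_host"]
  for (i in seq_len(nrow(keys))) {
    prof <- gradient_profile(scenario, config, keys$soil[i],
                             keys$treatment[i], keys$replicate[i])
    write_profile_tsv(prof, file.path(d, paste0("profile_", keys$key[i],
                                                ".tsv")))
    pooled <- data.frame(
      pop_id = rownames(prof$mass),
      LBD = pool_fractions(prof, "LBD", config$pools$lbd_max,
                           config$pools$hbd_min),
      HBD = pool_fractions(prof, "HBD", config$pools$lbd_max,
                           config$pools$hbd_min))
    write_tsv(pooled, file.path(d, paste0("pooled_", keys$key[i], ".tsv")))
    aoa_here <- intersect(aoa, scenario$populations$pop_id[
      scenario$populations$abundance[, keys$soil[i]] > 0])
    markers <- data.frame(
      fraction = colnames(prof$mass), midpoint_bd = prof$scheme$midpoints,
      total = marker_profile(prof, rownames(prof$mass)),
      aoa = if (length(aoa_here)) marker_profile(prof, aoa_here) else NA_real_)
    write_tsv(markers, file.path(d, paste0("markers_", keys$key[i], ".tsv")))
  }
  invisible(NULL)
}

stage_sequence <- function(config, run_dir) {
  d <- subdir(run_dir, "reads")
  scenario <- build_scenario(config)
  layout <- experiment_layout(config)
  for (i in seq_len(nrow(layout))) {
    l <- layout[i, ]
    pooled <- read_tsv(file.path(run_dir, "gradient",
                                 sprintf("pooled_%s_%s_r%d.tsv", l$soil,
                                         l$treatment, l$replicate)))
    mass <- setNames(pooled[[l$pool]], pooled$pop_id)
    lib <- sample_reads(mass, scenario$genomes, config$sequencing$depth,
                        config$sequencing$read_length,
                        config$sequencing$error_rate,
                        seed = stable_hash(config$seed, "reads", l$library_id),
                        library_id = l$library_id, soil = l$soil,
                        treatment = l$treatment, pool = l$pool,
                        replicate = l$replicate)
    write_library_fasta(lib, file.path(d, paste0(l$library_id, ".fasta")))
  }
  invisible(NULL)
}

read_all_libraries <- function(config, run_dir, sel = TRUE) {
  layout <- experiment_layout(config)[sel, , drop = FALSE]
  libs <- lapply(seq_len(nrow(layout)), function(i)
    read_library_fasta(file.path(run_dir, "reads",
                                 paste0(layout$library_id[i], ".fasta")),
                       library_id = layout$library_id[i]))
  names(libs) <- layout$library_id
  libs
}

stage_recover <- function(config, run_dir) {
  d <- subdir(run_dir, "contigs")
  scenario <- build_scenario(config)
  layout <- experiment_layout(config)
  libs <- read_all_libraries(config, run_dir,
                             layout$pool == "LBD" & layout$treatment == "12C")
  asm <- config$assembly
  contigs <- recover_contigs(libs, scenario$genomes, asm$min_depth,
                             asm$min_contig_length, asm$min_fragments,
                             asm$max_fragments, asm$target_fragment_length,
                             seed = stable_hash(config$seed, "assembly"))
  write_contigs(contigs, file.path(d, "contigs.fasta"),
                file.path(d, "contigs.tsv"))
  invisible(contigs)
}

stage_map <- function(config, run_dir) {
  d <- subdir(run_dir, "mapping")
  contigs <- read_contigs(file.path(run_dir, "contigs", "contigs.fasta"),
                          file.path(run_dir, "contigs", "contigs.tsv"))
  layout <- experiment_layout(config)
  libs <- read_all_libraries(config, run_dir)
  ms <- map_libraries(libs, contigs, config$mapping$k)
  rows <- list(); lib_rows <- list()
  for (i in seq_len(nrow(layout))) {
    id <- layout$library_id[i]
    m <- ms[[id]]
    rows[[id]] <- as.data.frame(m)
    lib_rows[[id]] <- data.frame(
      library_id = id, soil = layout$soil[i], treatment = layout$treatment[i],
      pool = layout$pool[i], replicate = layout$replicate[i],
      depth = attr(m, "library_depth"), unmapped = attr(m, "unmapped"))
  }
  mapping <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write_tsv(mapping[, c("library_id", "contig_id", "mapped_read_count",
                        "mean_depth", "breadth")],
            file.path(d, "mapping.tsv"))
  write_tsv(do.call(rbind, c(lib_rows, list(make.row.names = FALSE))),
            file.path(d, "libraries.tsv"))
  # coverage-vs-GC table for LBD/HBD contig-distribution plots
  pools_of <- function(pool, treatment) {
    ids <- layout$library_id[layout$pool == pool &
                             layout$treatment == treatment]
    sub <- mapping[mapping$library_id %in% ids, , drop = FALSE]
    tapply(sub$mean_depth, sub$contig_id, mean)
  }
  ctab <- contigs$contigs[order(contigs$contigs$contig_id),
                          c("contig_id", "length", "gc", "source_pop_id")]
  if (nrow(ctab)) {
    ctab$mean_depth_lbd_12c <- as.numeric(pools_of("LBD", "12C")[ctab$contig_id])
    ctab$mean_depth_hbd_12c <- as.numeric(pools_of("HBD", "12C")[ctab$contig_id])
    ctab$mean_depth_hbd_13c <- as.numeric(pools_of("HBD", "13C")[ctab$contig_id])
  }
  write_tsv(ctab, file.path(d, "coverage_gc.tsv"))
  invisible(mapping)
}

# rebuild the per-library sip_mapping objects from persisted tables
load_mappings <- function(run_dir) {
  mp <- read_tsv(file.path(run_dir, "mapping", "mapping.tsv"))
  ls <- read_tsv(file.path(run_dir, "mapping", "libraries.tsv"))
  ctg <- read_tsv(file.path(run_dir, "contigs", "contigs.tsv"))
  out <- lapply(ls$library_id, function(id) {
    m <- mp[mp$library_id == id, c("contig_id", "library_id",
                                   "mapped_read_count", "mean_depth",
                                   "breadth"), drop = FALSE]
    rownames(m) <- NULL
    structure(m, class = c("sip_mapping", "data.frame"),
              library_depth = ls$depth[ls$library_id == id],
              unmapped = ls$unmapped[ls$library_id == id],
              contig_length = setNames(ctg$length, ctg$contig_id),
              source_pop_id = setNames(ctg$source_pop_id, ctg$contig_id))
  })
  names(out) <- ls$library_id
  out
}

stage_screen <- function(config, run_dir) {
  d <- subdir(run_dir, "screen")
  contigs <- read_contigs(file.path(run_dir, "contigs", "contigs.fasta"),
                          file.path(run_dir, "contigs", "contigs.tsv"))
  mappings <- load_mappings(run_dir)
  gg <- yaml::read_yaml(file.path(run_dir, "scenario", "scenario.yaml"))
  screened <- screen_contigs(contigs, mappings, config,
                             guild_gc = unlist(gg$guild_gc))
  write_tsv(screened$hits, file.path(d, "hits.tsv"))
  write_tsv(as.data.frame(screened$votus), file.path(d, "votus.tsv"))
  passes <- attr(screened$votus, "passes")
  if (length(passes))
    write_tsv(data.frame(contig_id = rownames(passes), passes,
                         check.names = FALSE),
              file.path(d, "votu_passes.tsv"))
  invisible(screened)
}

stage_test <- function(config, run_dir) {
  d <- subdir(run_dir, "stats")
  contigs <- read_contigs(file.path(run_dir, "contigs", "contigs.fasta"),
                          file.path(run_dir, "contigs", "contigs.tsv"))
  mappings <- load_mappings(run_dir)
  layout <- experiment_layout(config)
  pops <- read_tsv(file.path(run_dir, "scenario", "populations.tsv"))
  votus <- read_tsv(file.path(run_dir, "screen", "votus.tsv"))
  out <- activity_analysis(contigs, mappings, layout, votus, pops, config)
  write_tsv(out$host_activity, file.path(d, "host_activity.tsv"))
  write_tsv(out$votu_activity, file.path(d, "votu_activity.tsv"))
  if (!is.null(out$votu_soil_diff))
    write_tsv(out$votu_soil_diff, file.path(d, "votu_soil_diff.tsv"))
  hm <- out$heatmap
  if (length(hm$values)) {
    long <- data.frame(
      contig_id = rep(rownames(hm$values), ncol(hm$values)),
      library_id = rep(colnames(hm$values), each = nrow(hm$values)),
      ln_reads_per_kb = as.vector(hm$values),
      masked = as.vector(hm$mask))
    write_tsv(long, file.path(d, "heatmap.tsv"))
  }
  invisible(out)
}

stage_report <- function(config, run_dir) {
  d <- subdir(run_dir, "report")
  scenario <- build_scenario(config)
  contigs <- read_contigs(file.path(run_dir, "contigs", "contigs.fasta"),
                          file.path(run_dir, "contigs", "contigs.tsv"))
  votus <- read_tsv(file.path(run_dir, "screen", "votus.tsv"))
  stats_out <- list(
    host_activity = read_tsv(file.path(run_dir, "stats",
                                       "host_activity.tsv")),
    votu_activity = read_tsv(file.path(run_dir, "stats",
                                       "votu_activity.tsv")),
    votu_soil_diff = if (file.exists(file.path(run_dir, "stats",
                                               "votu_soil_diff.tsv")))
      read_tsv(file.path(run_dir, "stats", "votu_soil_diff.tsv")))
  truth <- ground_truth_summary(scenario, contigs, votus, stats_out, config)
  summary <- data.frame(
    metric = c("n_contigs", "n_votus", "n_votus_temperate",
               "n_enriched_host_features", "n_enriched_votus",
               names(truth$votu_confusion), names(truth$activity_confusion)),
    value = c(NROW(contigs$contigs), NROW(votus),
              sum(votus$temperate_predicted),
              sum(stats_out$host_activity$enriched),
              sum(stats_out$votu_activity$enriched),
              unname(truth$votu_confusion),
              unname(truth$activity_confusion)))
  write_tsv(summary, file.path(d, "summary.tsv"))
  write_tsv(truth$activity, file.path(d, "activity_truth.tsv"))
  if (!is.null(truth$soil_diff_eval))
    write_tsv(truth$soil_diff_eval, file.path(d, "soil_diff_truth.tsv"))
  invisible(summary)
}
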