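#' Library layout of the SIP experiment
#'
#' The full replicate design: soils x treatments x pools x replicates
#' (24 libraries under the defaults).
#'
#' @param config a [sip_config()].
#' @return data.frame with `library_id`, `soil`, `treatment`, `pool`,
#'   `replicate`.
#' @export
experiment_layout <- function(config) {
  g <- expand.grid(replicate = seq_len(config$replicates),
                   pool = c("LBD", "HBD"), treatment = config$treatments,
                   soil = config$soils, stringsAsFactors = FALSE)
  g <- g[, c("soil", "treatment", "pool", "replicate")]
  g$library_id <- sprintf("%s_%s_%s_r%d", g$soil, g$treatment, g$pool,
                          g$replicate)
  g
}

simulate_gradients <- function(scenario, config) {
  keys <- expand.grid(replicate = seq_len(config$replicates),
                      treatment = config$treatments, soil = config$soils,
                      stringsAsFactors = FALSE)
  profiles <- lapply(seq_len(nrow(keys)), function(i)
    gradient_profile(scenario, config, keys$soil[i], keys$treatment[i],
                     keys$replicate[i]))
  names(profiles) <- sprintf("%s_%s_r%d", keys$soil, keys$treatment,
                             keys$replicate)
  profiles
}

simulate_libraries <- function(scenario, config, profiles, ids = NULL) {
  layout <- experiment_layout(config)
  if (!is.null(ids))
    layout <- layout[layout$library_id %in% ids, , drop = FALSE]
  libs <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    l <- layout[i, ]
    prof <- profiles[[sprintf("%s_%s_r%d", l$soil, l$treatment, l$replicate)]]
    pooled <- pool_fractions(prof, l$pool, config$pools$lbd_max,
                             config$pools$hbd_min)
    libs[[i]] <- sample_reads(
      pooled, scenario$genomes, config$sequencing$depth,
      config$sequencing$read_length, config$sequencing$error_rate,
      seed = stable_hash(config$seed, "reads", l$library_id),
      library_id = l$library_id, soil = l$soil, treatment = l$treatment,
      pool = l$pool, replicate = l$replicate)
  }
  names(libs) <- layout$library_id
  libs
}

# contig -> feature map: MAG-analog grouping (source population) for host and
# background contigs, one feature per contig for virus contigs
feature_map <- function(contigs, populations) {
  ctg <- contigs$contigs
  guild <- populations$guild[match(ctg$source_pop_id, populations$pop_id)]
  setNames(ifelse(guild == "virus", ctg$contig_id, ctg$source_pop_id),
           ctg$contig_id)
}

proportions_matrix <- function(mappings, lib_ids, fmap, feature_ids,
                               denominator = "library") {
  m <- vapply(lib_ids, function(id) {
    p <- feature_proportions(mappings[[id]], fmap, denominator)
    out <- p[feature_ids]
    out[is.na(out)] <- 0
    unname(out)
  }, numeric(length(feature_ids)))
  m <- matrix(m, nrow = length(feature_ids),
              dimnames = list(feature_ids, lib_ids))
  m
}

#' Run the full hybrid SIP experiment in memory
#'
#' Executes the complete chain — scenario generation, gradient
#' fractionation, LBD/HBD pooling, replicate library sampling, LBD contig
#' recovery, read mapping of every library, hallmark-gene virus screening,
#' and the activity / soil-differential statistics — and returns all
#' intermediate and final objects. [run_pipeline()] is the persisted
#' counterpart writing each stage's artifacts to a run directory.
#'
#' @param config a [sip_config()].
#' @return a list with `config`, `scenario`, `layout`, `profiles`,
#'   `libraries`, `contigs`, `mappings`, `orfs`, `hits`, `votus`,
#'   `host_activity`, `votu_activity`, `votu_soil_diff`, `heatmap`, `truth`.
#' @export
run_sip_experiment <- function(config = sip_config()) {
  validate_config(config)
  scenario <- build_scenario(config)
  profiles <- simulate_gradients(scenario, config)
  libraries <- simulate_libraries(scenario, config, profiles)
  layout <- experiment_layout(config)

  asm <- config$assembly
  lbd12 <- libraries[layout$library_id[layout$pool == "LBD" &
                                       layout$treatment == "12C"]]
  contigs <- recover_contigs(lbd12, scenario$genomes, asm$min_depth,
                             asm$min_contig_length, asm$min_fragments,
                             asm$max_fragments, asm$target_fragment_length,
                             seed = stable_hash(config$seed, "assembly"))
  mappings <- map_libraries(libraries, contigs, config$mapping$k)

  screened <- screen_contigs(contigs, mappings, config,
                             guild_gc = scenario$guild_gc)
  stats_out <- activity_analysis(contigs, mappings, layout,
                                 screened$votus, scenario$populations, config)
  truth <- ground_truth_summary(scenario, contigs, screened$votus,
                                stats_out, config)

  c(list(config = config, scenario = scenario, layout = layout,
         profiles = profiles, libraries = libraries, contigs = contigs,
         mappings = mappings, truth = truth), screened, stats_out)
}

empty_activity_table <- function() {
  data.frame(soil = character(), feature_id = character(),
             mean_12C = numeric(), mean_13C = numeric(),
             var_12C = numeric(), var_13C = numeric(),
             variance_homogeneous = logical(), test_used = character(),
             t_stat = numeric(), df = numeric(), p_value = numeric(),
             enriched = logical(), stringsAsFactors = FALSE)
}

screen_contigs <- function(contigs, mappings, config, guild_gc) {
  scr <- config$screen
  ctg <- contigs$contigs
  orf_list <- lapply(seq_len(NROW(ctg)), function(i)
    find_orfs(ctg$sequence[i], scr$min_aa, ctg$contig_id[i]))
  orfs <- if (length(orf_list))
    do.call(rbind, c(orf_list, list(make.row.names = FALSE)))
  else find_orfs("AAAAAA", min_aa = 10L)
  hits <- hallmark_search(orfs, hallmark_db(), scr$score_threshold,
                          scr$prescreen)
  votus <- call_votus(contigs, hits, mappings, scr$min_votu_length,
                      scr$min_depth, scr$min_breadth, guild_gc,
                      scr$gc_window)
  list(orfs = orfs, hits = hits, votus = votus)
}

activity_analysis <- function(contigs, mappings, layout, votus, populations,
                              config) {
  st <- config$stats
  fmap <- feature_map(contigs, populations)
  ctg <- contigs$contigs
  host_pops <- sort(unique(ctg$source_pop_id[
    populations$guild[match(ctg$source_pop_id, populations$pop_id)] != "virus"]))
  votu_ids <- votus$contig_id

  lib_ids <- function(soil, treatment, pool)
    layout$library_id[layout$soil == soil & layout$treatment == treatment &
                      layout$pool == pool]

  host_activity <- list(); votu_activity <- list()
  for (s in unique(layout$soil)) {
    feats_h <- host_pops[populations$soil[match(host_pops,
                                                populations$pop_id)] == s]
    for (set in list(list(ids = feats_h, out = "host"),
                     list(ids = votu_ids, out = "votu"))) {
      if (!length(set$ids)) next
      p12 <- proportions_matrix(mappings, lib_ids(s, "12C", "HBD"), fmap,
                                set$ids, st$denominator)
      p13 <- proportions_matrix(mappings, lib_ids(s, "13C", "HBD"), fmap,
                                set$ids, st$denominator)
      tab <- enrichment_table(p12, p13, st$alpha, st$alternative,
                              st$var_alpha, st$p_adjust)
      tab <- data.frame(soil = s, tab, stringsAsFactors = FALSE)
      if (set$out == "host")
        host_activity[[s]] <- tab
      else
        votu_activity[[s]] <- tab
    }
  }
  host_activity <- rbind_rows(host_activity) %||% empty_activity_table()
  votu_activity <- rbind_rows(votu_activity) %||% empty_activity_table()

  soils <- unique(layout$soil)
  votu_soil_diff <- NULL
  if (length(votu_ids) && length(soils) == 2L) {
    pa <- proportions_matrix(mappings, lib_ids(soils[1], "12C", "LBD"), fmap,
                             votu_ids, st$denominator)
    pb <- proportions_matrix(mappings, lib_ids(soils[2], "12C", "LBD"), fmap,
                             votu_ids, st$denominator)
    votu_soil_diff <- soil_differential(pa, pb, soils[1], soils[2],
                                        st$alpha, st$var_alpha)
  }
  lbd12_ids <- layout$library_id[layout$pool == "LBD" &
                                 layout$treatment == "12C"]
  heatmap <- heatmap_matrix(mappings[lbd12_ids], votus,
                            config$screen$min_depth, config$screen$min_breadth)
  list(host_activity = host_activity, votu_activity = votu_activity,
       votu_soil_diff = votu_soil_diff, heatmap = heatmap)
}

# evaluation against the simulated ground truth (simulation mode only)
ground_truth_summary <- function(scenario, contigs, votus, stats_out,
                                 config) {
  pops <- scenario$populations
  ctg <- contigs$contigs
  guild <- pops$guild[match(ctg$source_pop_id, pops$pop_id)]
  is_virus_contig <- guild == "virus"

  # which virus contigs retain a virus-diagnostic cassette and pass the
  # length filter, i.e. should be called under the package's rules
  expected_call <- vapply(seq_len(NROW(ctg)), function(i) {
    if (!is_virus_contig[i]) return(FALSE)
    if (ctg$length[i] < config$screen$min_votu_length) return(FALSE)
    ca <- scenario$genomes[[ctg$source_pop_id[i]]]$cassettes
    ca <- ca[ca$gene_kind %in% VIRAL_TRIGGER_KINDS, , drop = FALSE]
    any(ca$start >= ctg$start[i] & ca$end <= ctg$end[i])
  }, NA)

  called <- ctg$contig_id %in% votus$contig_id
  votu_confusion <- c(
    expected_and_called = sum(expected_call & called),
    expected_not_called = sum(expected_call & !called),
    called_not_expected = sum(!expected_call & called),
    host_contigs_called = sum(!is_virus_contig & called))

  act <- rbind(
    if (NROW(stats_out$host_activity))
      data.frame(feature_id = stats_out$host_activity$feature_id,
                 soil = stats_out$host_activity$soil,
                 enriched = stats_out$host_activity$enriched),
    if (NROW(stats_out$votu_activity))
      data.frame(feature_id = stats_out$votu_activity$feature_id,
                 soil = stats_out$votu_activity$soil,
                 enriched = stats_out$votu_activity$enriched))
  if (is.null(act))
    act <- data.frame(feature_id = character(), soil = character(),
                      enriched = logical())
  feat_pop <- ifelse(act$feature_id %in% pops$pop_id, act$feature_id,
                     ctg$source_pop_id[match(act$feature_id, ctg$contig_id)])
  act$truth_active <- pops$active[match(feat_pop, pops$pop_id)]
  act$home_soil <- pops$soil[match(feat_pop, pops$pop_id)]
  home <- act[act$soil == act$home_soil, , drop = FALSE]
  activity_confusion <- c(
    true_positive = sum(home$enriched & home$truth_active),
    false_negative = sum(!home$enriched & home$truth_active),
    false_positive = sum(home$enriched & !home$truth_active),
    true_negative = sum(!home$enriched & !home$truth_active))

  soil_diff_eval <- NULL
  if (!is.null(stats_out$votu_soil_diff) && NROW(stats_out$votu_soil_diff)) {
    sd <- stats_out$votu_soil_diff
    truth_soil <- pops$soil[match(ctg$source_pop_id[
      match(sd$feature_id, ctg$contig_id)], pops$pop_id)]
    soil_diff_eval <- data.frame(feature_id = sd$feature_id,
                                 label = sd$label, truth_soil = truth_soil,
                                 stringsAsFactors = FALSE)
  }
  list(votu_confusion = votu_confusion, activity = act,
       activity_confusion = activity_confusion,
       soil_diff_eval = soil_diff_eval, expected_votu_call =
         setNames(expected_call, ctg$contig_id))
}
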