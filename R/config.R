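#' Build a validated pipeline configuration
#'
#' All thresholds the pipeline applies are named, overridable fields: the
#' LBD/HBD pooling cuts (1.699 / 1.719 g/ml), the vOTU filters (>=10 kb
#' length, >=1x mean depth, >=75% breadth), the significance levels, the
#' gradient constants, and the synthetic-scenario parameters. Pass nested
#' lists to override defaults, e.g.
#' `sip_config(sequencing = list(depth = 10000), seed = 42)`.
#'
#' @param ... nested named lists merged over the defaults (unknown names are
#'   an error).
#' @param seed master seed; all stage and library seeds are derived from it
#'   by stable hashing, so a run is reproducible end to end.
#' @return an object of class `sip_config`.
#' @export
#' @examples
#' cfg <- sip_config(seed = 7, sequencing = list(depth = 5000))
#' cfg$pools$hbd_min
sip_config <- function(..., seed = 1L) {
  defaults <- list(
    soils = c("pH4.5", "pH7.5"),
    treatments = c("12C", "13C"),
    replicates = 3L,
    gradient = list(
      bd_intercept = 1.660,    # g/ml at GC 0, unlabeled
      bd_gc_slope = 0.098,     # g/ml per GC fraction (Schildkraut-type)
      bd_label_shift = 0.036,  # g/ml at full 13C labeling
      sigma = 0.003,           # band half-width (g/ml) from diffusion
      jitter_sd = 5e-4,        # replicate-to-replicate band-centre jitter
      span = c(1.66, 1.78),    # fractionated density range (g/ml)
      n_bins = 40L
    ),
    pools = list(lbd_max = 1.699, hbd_min = 1.719),
    sequencing = list(depth = 50000L, read_length = 150L, error_rate = 0.001),
    assembly = list(min_depth = 5, min_contig_length = 5000L,
                    min_fragments = 1L, max_fragments = 8L,
                    target_fragment_length = 20000L),
    mapping = list(k = 21L),
    screen = list(min_aa = 150L, score_threshold = 100,
                  min_votu_length = 10000L, min_depth = 1, min_breadth = 0.75,
                  gc_window = 0.05, prescreen = TRUE),
    stats = list(alpha = 0.05, var_alpha = 0.05, alternative = "two.sided",
                 p_adjust = "none", denominator = "library"),
    scenario = list(preset = "two_soil_default", viruses = TRUE,
                    atom13c_active = 1.0,
                    virus_gc_offset_mean = -0.017, virus_gc_offset_sd = 0.01,
                    host_genome_length = 100000L,
                    background_genome_length = 150000L)
  )
  cfg <- merge_config(defaults, list(...))
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sip_config"
  validate_config(cfg)
  cfg
}

merge_config <- function(base, override) {
  if (length(override) == 0L) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == ""))
    stop("config overrides must be named")
  unknown <- setdiff(nm, names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (k in nm) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks the structural invariants before any stage runs: the LBD cut must
#' lie below the HBD cut, the fraction scheme must cover both cuts, and all
#' thresholds must be positive.
#'
#' @param cfg a `sip_config`.
#' @return the config, invisibly; errors describe the violated invariant.
#' @export
validate_config <- function(cfg) {
  with(cfg, {
    if (pools$lbd_max >= pools$hbd_min)
      stop("invalid pooling thresholds: LBD cut (", pools$lbd_max,
           ") must be below HBD cut (", pools$hbd_min, ")")
    if (gradient$span[1] >= gradient$span[2] || gradient$n_bins < 8L)
      stop("fraction scheme needs an increasing span and >= 8 bins")
    if (pools$lbd_max <= gradient$span[1] || pools$hbd_min >= gradient$span[2])
      stop("fraction scheme span must cover both pooling cuts")
    stopifnot(gradient$sigma > 0, sequencing$depth >= 0,
              sequencing$read_length > 0, sequencing$error_rate >= 0,
              sequencing$error_rate <= 1, assembly$min_depth > 0,
              assembly$min_contig_length > 0, mapping$k > 0,
              screen$min_votu_length > 0, screen$min_breadth >= 0,
              screen$min_breadth <= 1, stats$alpha > 0, stats$alpha < 1,
              replicates >= 2)
  })
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' Round-trip stable: `read_config(write_config(cfg, f))` reproduces `cfg`.
#'
#' @param cfg a `sip_config`.
#' @param path file path.
#' @return `read_config` returns a `sip_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  seed <- x$seed %||% 1L
  x$seed <- NULL
  do.call(sip_config, c(x, list(seed = seed)))
}

#' @export
print.sip_config <- function(x, ...) {
  cat("<sip_config>\n")
  cat(sprintf("  soils %s | treatments %s | %d replicates | seed %d\n",
              paste(x$soils, collapse = "/"),
              paste(x$treatments, collapse = "/"), x$replicates, x$seed))
  cat(sprintf("  pools: LBD < %.3f, HBD > %.3f g/ml; %d fractions over [%.2f, %.2f]\n",
              x$pools$lbd_max, x$pools$hbd_min, x$gradient$n_bins,
              x$gradient$span[1], x$gradient$span[2]))
  cat(sprintf("  sequencing: %d x %d bp reads/library, error %.3g\n",
              x$sequencing$depth, x$sequencing$read_length,
              x$sequencing$error_rate))
  invisible(x)
}
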