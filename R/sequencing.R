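#' Sample a replicate read library from pooled DNA
#'
#' Stands in for Illumina sequencing of a pooled gradient fraction: each
#' read's source population is drawn multinomially with probability
#' proportional to its pooled DNA mass (mass, not genome copy number — the
#' two are deliberately conflated, as DNA mass is what sequencers sample),
#' its start position is uniform on the linear genome (no wraparound), and
#' substitution errors are applied i.i.d. per base. Single-end reads, no
#' quality scores. Deterministic under `seed`.
#'
#' @param pooled_mass named numeric vector of pooled DNA mass per population.
#' @param genomes named list of `sip_genome` covering the populations.
#' @param depth number of reads to draw (>= 0).
#' @param read_length read length in bp.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param library_id,soil,treatment,pool,replicate library metadata tags.
#' @return class `sip_read_library`: list with the metadata, `depth`, and
#'   `reads` — a data.frame of `read_id`, `sequence`, `truth_pop_id` (ground
#'   truth for evaluation; the pipeline's calls never consult it).
#' @export
sample_reads <- function(pooled_mass, genomes, depth, read_length = 150L,
                         error_rate = 0.001, seed = 1L,
                         library_id = "lib", soil = NA, treatment = NA,
                         pool = NA, replicate = NA) {
  stopifnot(depth >= 0, read_length >= 1, error_rate >= 0, error_rate <= 1)
  pooled_mass <- pooled_mass[pooled_mass > 0]
  lib <- structure(list(library_id = library_id, soil = soil,
                        treatment = treatment, pool = pool,
                        replicate = replicate, depth = as.integer(depth),
                        read_length = as.integer(read_length),
                        reads = data.frame(read_id = character(),
                                           sequence = character(),
                                           truth_pop_id = character())),
                   class = "sip_read_library")
  if (depth == 0L) return(lib)
  if (length(pooled_mass) == 0L)
    stop("cannot sample ", depth, " reads from an all-zero mass vector")
  missing <- setdiff(names(pooled_mass), names(genomes))
  if (length(missing))
    stop("no genome for population(s): ", paste(missing, collapse = ", "))
  glen <- vapply(genomes[names(pooled_mass)], `[[`, 0, "length")
  short <- glen < read_length
  if (any(short)) {
    warning("excluding population(s) shorter than the read length: ",
            paste(names(pooled_mass)[short], collapse = ", "))
    pooled_mass <- pooled_mass[!short]
    if (length(pooled_mass) == 0L)
      stop("no population long enough to sample reads from")
  }

  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, depth, pooled_mass))
  names(counts) <- names(pooled_mass)
  seqs <- character(depth)
  truth <- character(depth)
  at <- 0L
  for (p in names(counts)) {
    n <- counts[[p]]
    if (n == 0L) next
    g <- genomes[[p]]
    starts <- sample.int(g$length - read_length + 1L, n, replace = TRUE)
    idx <- at + seq_len(n)
    seqs[idx] <- substring(g$sequence, starts, starts + read_length - 1L)
    truth[idx] <- p
    at <- at + n
  }

  if (error_rate > 0) {
    n_err <- rbinom(1L, depth * read_length, error_rate)
    if (n_err > 0L) {
      pos <- sample.int(depth * read_length, n_err)
      ridx <- (pos - 1L) %/% read_length + 1L
      off <- (pos - 1L) %% read_length + 1L
      # substitute to one of the 3 other bases; vectorized substr<- only
      # touches one position per string, so apply multi-error reads in rounds
      shift <- sample.int(3L, n_err, replace = TRUE)
      while (length(ridx)) {
        first <- !duplicated(ridx)
        i <- ridx[first]; o <- off[first]
        cur <- substr(seqs[i], o, o)  # element-wise: one char per read
        code <- (match(cur, DNA_BASES) - 1L + shift[first]) %% 4L + 1L
        x <- seqs[i]
        substr(x, o, o) <- DNA_BASES[code]
        seqs[i] <- x
        ridx <- ridx[!first]; off <- off[!first]; shift <- shift[!first]
      }
    }
  }

  lib$reads <- data.frame(
    read_id = sprintf("%s_r%06d", library_id, seq_len(depth)),
    sequence = seqs, truth_pop_id = truth, stringsAsFactors = FALSE)
  lib
}

#' @export
print.sip_read_library <- function(x, ...) {
  cat(sprintf("<sip_read_library %s: %s/%s/%s rep %s, %d x %d bp reads>\n",
              x$library_id, x$soil, x$treatment, x$pool,
              as.character(x$replicate), x$depth, x$read_length))
  invisible(x)
}
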