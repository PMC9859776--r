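#' Recover contigs from LBD libraries (assembly surrogate)
#'
#' Stands in for de novo assembly of the 12C LBD libraries. Real assembly is
#' deliberately not implemented; instead, a population's genome is
#' recoverable if and only if its pooled mean depth across the supplied
#' libraries reaches `min_depth` (default 5x), and recoverable genomes are
#' emitted fragmented at uniform random cut points into contigs of at least
#' `min_contig_length`. This preserves the property the hybrid design turns
#' on — only populations that band in LBD yield reference sequences — without
#' an assembler. The surrogate consults the libraries' ground-truth read
#' provenance, which real assembly would not; treat recovered contigs as an
#' idealized assembly.
#'
#' Only 12C LBD libraries are accepted: assembling from HBD (or labeled) DNA
#' would violate the design the pipeline encodes, so passing such a library
#' is an error rather than a warning.
#'
#' @param lbd_libraries list of `sip_read_library`, all with pool `"LBD"` and
#'   treatment `"12C"`.
#' @param genomes named list of `sip_genome`.
#' @param min_depth pooled mean depth (x-fold) required for recovery.
#' @param min_contig_length minimum emitted contig length (bp).
#' @param min_fragments,max_fragments bounds on fragments per genome.
#' @param target_fragment_length expected fragment size (bp); the fragment
#'   count scales with genome length around `length / target`, so short
#'   virus genomes break into few pieces and host-sized genomes into
#'   several, as real assemblies do.
#' @param seed integer seed; output is independent of library order.
#' @return class `sip_contigs`: list with `contigs` (data.frame `contig_id`,
#'   `sequence`, `length`, `gc`, `source_pop_id`, `start`, `end`),
#'   `provenance` (library ids), `pooled_depth` (named vector, all
#'   populations).
#' @export
recover_contigs <- function(lbd_libraries, genomes, min_depth = 5,
                            min_contig_length = 5000L, min_fragments = 1L,
                            max_fragments = 8L,
                            target_fragment_length = 20000L, seed = 1L) {
  for (lib in lbd_libraries) {
    if (!identical(lib$pool, "LBD") || !identical(lib$treatment, "12C"))
      stop("design violation: recover_contigs accepts 12C LBD libraries only, ",
           "got ", lib$pool, "/", lib$treatment, " (", lib$library_id, ")")
  }
  glen <- vapply(genomes, `[[`, 0, "length")
  bases <- setNames(numeric(length(genomes)), names(genomes))
  for (lib in lbd_libraries) {
    n <- table(lib$reads$truth_pop_id)
    bases[names(n)] <- bases[names(n)] + as.numeric(n) * lib$read_length
  }
  pooled_depth <- bases / glen
  recoverable <- sort(names(pooled_depth)[pooled_depth >= min_depth])

  rows <- list()
  for (p in recoverable) {
    g <- genomes[[p]]
    set.seed(stable_hash(seed, "fragment", p))
    cuts <- fragment_cuts(g$length, min_contig_length, min_fragments,
                          max_fragments, target_fragment_length)
    for (i in seq_len(length(cuts) - 1L)) {
      s <- cuts[i]; e <- cuts[i + 1L]
      seqi <- substring(g$sequence, s + 1L, e)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = sprintf("%s_c%d", p, i), sequence = seqi,
        length = e - s, gc = gc_content(seqi), source_pop_id = p,
        start = s, end = e, stringsAsFactors = FALSE)
    }
  }
  contigs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(), sequence = character(),
               length = integer(), gc = numeric(),
               source_pop_id = character(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  structure(list(
    contigs = contigs,
    provenance = vapply(lbd_libraries, `[[`, "", "library_id"),
    pooled_depth = pooled_depth
  ), class = "sip_contigs")
}

# 0-based cut positions (including 0 and len) with every piece >= min_len;
# fragment count scales with genome length around len / target
fragment_cuts <- function(len, min_len, min_frag, max_frag,
                          target = 20000L) {
  max_possible <- max(1L, len %/% min_len)
  hi <- min(max_frag, max_possible)
  lo <- min(min_frag, hi)
  n <- ceiling(len / target) + sample(0:1, 1L)
  n <- min(hi, max(lo, n))
  if (n <= 1L) return(c(0L, len))
  extra <- len - n * min_len
  inner <- sort(runif(n - 1L, 0, extra))
  pieces <- diff(c(0, inner, extra)) + min_len
  cuts <- round(cumsum(pieces))
  cuts[n] <- len
  as.integer(c(0L, cuts))
}

#' Map a read library onto contigs by exact k-mer assignment
#'
#' Alignment-free read assignment: each read goes to the contig sharing the
#' most canonical k-mers with it (default k = 21), ties broken by
#' lexicographically smallest `contig_id`; reads sharing no k-mer with any
#' contig stay unmapped. The read is placed at its modal seed diagonal and
#' contributes its aligned (clipped to the contig) bases to mean depth and
#' breadth. Mean depth is aligned bases divided by contig length; breadth is
#' the fraction of contig positions covered by at least one read.
#'
#' @param library a `sip_read_library`.
#' @param contigs a `sip_contigs`.
#' @param k k-mer size (must not exceed the read length).
#' @return class `sip_mapping`: data.frame with one row per contig
#'   (`contig_id`, `library_id`, `mapped_read_count`, `mean_depth`,
#'   `breadth`) plus attributes `library_depth`, `unmapped`,
#'   `contig_length`, `source_pop_id`.
#' @export
map_reads <- function(library, contigs, k = 21L) {
  ctg <- contigs$contigs[order(contigs$contigs$contig_id), , drop = FALSE]
  asg <- if (nrow(ctg) > 0L && library$depth > 0L)
    kmer_assign_cpp(library$reads$sequence, ctg$sequence, as.integer(k))
  mapping_from_assignment(library, ctg, asg, k)
}

#' Map several libraries onto one contig set
#'
#' Same assignment as [map_reads()], indexing the contigs once for all
#' libraries.
#'
#' @param libraries named list of `sip_read_library`.
#' @param contigs a `sip_contigs`.
#' @param k k-mer size.
#' @return named list of `sip_mapping`.
#' @export
map_libraries <- function(libraries, contigs, k = 21L) {
  ctg <- contigs$contigs[order(contigs$contigs$contig_id), , drop = FALSE]
  nonempty <- vapply(libraries, function(l) l$depth > 0L, NA)
  asgs <- setNames(vector("list", length(libraries)), names(libraries))
  if (nrow(ctg) > 0L && any(nonempty)) {
    asgs[nonempty] <- kmer_assign_multi_cpp(
      lapply(libraries[nonempty], function(l) l$reads$sequence),
      ctg$sequence, as.integer(k))
  }
  out <- lapply(seq_along(libraries), function(i)
    mapping_from_assignment(libraries[[i]], ctg, asgs[[i]], k))
  names(out) <- names(libraries)
  out
}

mapping_from_assignment <- function(library, ctg, asg, k) {
  stopifnot(inherits(library, "sip_read_library"))
  if (k > library$read_length && library$depth > 0)
    stop("k (", k, ") exceeds the read length (", library$read_length, ")")
  nctg <- nrow(ctg)
  res <- data.frame(contig_id = ctg$contig_id,
                    library_id = rep(library$library_id, nctg),
                    mapped_read_count = integer(nctg) + 0L,
                    mean_depth = numeric(nctg), breadth = numeric(nctg),
                    stringsAsFactors = FALSE)
  unmapped <- library$depth
  if (!is.null(asg)) {
    hit <- !is.na(asg$contig)
    unmapped <- sum(!hit)
    rl <- library$read_length
    pos_by_ctg <- split(asg$pos[hit], asg$contig[hit])
    for (nm in names(pos_by_ctg)) {
      ci <- as.integer(nm)
      len <- ctg$length[ci]
      s <- pmax(0L, pos_by_ctg[[nm]])
      e <- pmin(len, pos_by_ctg[[nm]] + rl)
      keep <- e > s
      s <- s[keep]; e <- e[keep]
      tab_s <- tabulate(s + 1L, nbins = len + 1L)
      tab_e <- tabulate(e + 1L, nbins = len + 1L)
      cov <- cumsum(tab_s - tab_e)[seq_len(len)]
      res$mapped_read_count[ci] <- length(pos_by_ctg[[nm]])
      res$mean_depth[ci] <- sum(e - s) / len
      res$breadth[ci] <- mean(cov > 0)
    }
  }
  structure(res, class = c("sip_mapping", "data.frame"),
            library_depth = library$depth, unmapped = unmapped,
            contig_length = setNames(ctg$length, ctg$contig_id),
            source_pop_id = setNames(ctg$source_pop_id, ctg$contig_id))
}

#' Per-feature relative read proportions for one library
#'
#' A feature is a MAG-analog grouping of one population's contigs, or a
#' single virus contig. The proportion is the feature's mapped read count
#' divided by the library's total read count (so proportions across features
#' plus the unmapped remainder sum to 1); set `denominator = "mapped"` to
#' normalize by mapped reads instead.
#'
#' @param mapping a `sip_mapping` for the library.
#' @param features named character vector mapping `contig_id` to feature id.
#' @param denominator `"library"` (default) or `"mapped"`.
#' @return named numeric vector over features, with an `"unmapped"` entry
#'   under the `"library"` denominator.
#' @export
feature_proportions <- function(mapping, features,
                                denominator = c("library", "mapped")) {
  denominator <- match.arg(denominator)
  depth <- attr(mapping, "library_depth")
  if (is.null(depth) || depth == 0L)
    stop("cannot compute proportions for a zero-depth library")
  feat <- features[mapping$contig_id]
  counts <- tapply(mapping$mapped_read_count, feat, sum)
  counts <- counts[!is.na(names(counts))]
  denom <- if (denominator == "library") depth else sum(counts)
  if (denom == 0) return(setNames(rep(0, length(counts)), names(counts)))
  out <- counts / denom
  if (denominator == "library")
    out <- c(out, unmapped = 1 - sum(out))
  out
}
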