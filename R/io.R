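#' @name sip_io
#' @title Plain-text artifact writers and readers
#'
#' @description Every pipeline artifact is a standard text format: FASTA for
#' genomes/contigs/reads (via Biostrings), GFF3 for cassette annotations,
#' TSV for all tables, YAML for config and scenario metadata. Read
#' counterparts exist where a later stage re-loads the artifact, so any
#' stage can be re-run from its persisted inputs (and real, non-simulated
#' FASTA/TSV inputs can enter at the recovery or mapping stage).
NULL

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write scenario genomes as multi-FASTA
#'
#' One record per population, header
#' `pop_id|guild|gc=<realized>|active=<TRUE/FALSE>`.
#'
#' @param scenario a `sip_scenario`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genomes_fasta <- function(scenario, path) {
  pops <- scenario$populations
  seqs <- Biostrings::DNAStringSet(vapply(scenario$genomes, `[[`, "",
                                          "sequence"))
  names(seqs) <- sprintf("%s|%s|gc=%.4f|active=%s", pops$pop_id, pops$guild,
                         vapply(scenario$genomes, `[[`, 0, "realized_gc"),
                         pops$active)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write cassette annotations as GFF3
#'
#' @param scenario a `sip_scenario`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cassette_gff3 <- function(scenario, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in scenario$genomes) {
    ca <- g$cassettes
    if (!NROW(ca)) next
    # GFF3 is 1-based inclusive; internal coordinates are 0-based half-open
    writeLines(sprintf("%s\thybridsip\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_kind=%s;query_id=%s",
                       g$pop_id, ca$start + 1L, ca$end, ca$strand,
                       paste0(g$pop_id, ".", seq_len(nrow(ca))),
                       ca$gene_kind, ca$query_id), con)
  }
  invisible(path)
}

#' Write / read a read library as FASTA
#'
#' Headers carry the library metadata and the ground-truth source population
#' (`read_id|truth=<pop_id>`); the truth tag is for evaluation only and no
#' pipeline call consults it.
#'
#' @param lib a `sip_read_library`.
#' @param path file path.
#' @return `write_library_fasta` the path; `read_library_fasta` a
#'   `sip_read_library`.
#' @export
write_library_fasta <- function(lib, path) {
  if (nrow(lib$reads)) {
    seqs <- Biostrings::DNAStringSet(lib$reads$sequence)
    names(seqs) <- sprintf("%s|truth=%s|%s|%s|%s|r%s", lib$reads$read_id,
                           lib$reads$truth_pop_id, lib$soil, lib$treatment,
                           lib$pool, lib$replicate)
    Biostrings::writeXStringSet(seqs, path)
  } else {
    writeLines(character(0), path)
  }
  invisible(path)
}

#' @rdname write_library_fasta
#' @param library_id id given to the re-loaded library.
#' @export
read_library_fasta <- function(path, library_id = NULL) {
  fa <- Biostrings::readDNAStringSet(path)
  fields <- strsplit(names(fa), "|", fixed = TRUE)
  get <- function(i) vapply(fields, `[`, "", i)
  rid <- get(1)
  lib_id <- library_id %||% sub("_r[0-9]+$", "", rid[1])
  structure(list(
    library_id = lib_id,
    soil = get(3)[1], treatment = get(4)[1], pool = get(5)[1],
    replicate = as.integer(sub("^r", "", get(6)[1])),
    depth = length(fa),
    read_length = if (length(fa)) Biostrings::width(fa)[1] else 0L,
    reads = data.frame(read_id = rid, sequence = as.character(fa),
                       truth_pop_id = sub("^truth=", "", get(2)),
                       stringsAsFactors = FALSE)),
    class = "sip_read_library")
}

#' Write a gradient profile as TSV
#'
#' Rows are fractions (with midpoint buoyant density), columns populations.
#'
#' @param profile a `sip_gradient_profile`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(fraction = colnames(profile$mass),
                   midpoint_bd = profile$scheme$midpoints,
                   t(profile$mass), check.names = FALSE)
  write_tsv(df, path)
}

#' Write / read recovered contigs (FASTA + provenance TSV)
#'
#' @param contigs a `sip_contigs`.
#' @param fasta_path,tsv_path output files.
#' @return paths / a `sip_contigs`.
#' @export
write_contigs <- function(contigs, fasta_path, tsv_path) {
  ctg <- contigs$contigs
  seqs <- Biostrings::DNAStringSet(ctg$sequence)
  names(seqs) <- ctg$contig_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_tsv(ctg[, c("contig_id", "length", "gc", "source_pop_id", "start",
                    "end")], tsv_path)
  invisible(c(fasta_path, tsv_path))
}

#' @rdname write_contigs
#' @export
read_contigs <- function(fasta_path, tsv_path) {
  fa <- Biostrings::readDNAStringSet(fasta_path)
  meta <- read_tsv(tsv_path)
  stopifnot(identical(names(fa), meta$contig_id))
  meta$sequence <- as.character(fa)
  structure(list(contigs = meta[, c("contig_id", "sequence", "length", "gc",
                                    "source_pop_id", "start", "end")],
                 provenance = character(0),
                 pooled_depth = numeric(0)),
            class = "sip_contigs")
}
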