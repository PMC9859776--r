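#' Load the packaged hallmark protein query set
#'
#' The package ships a fixed set of synthetic hallmark proteins (capsid, large
#' terminase, portal, integrase and the MCO1 multicopper-oxidase auxiliary
#' metabolic gene), each annotated with the nitrifier guild (AOA/AOB/NOB) of
#' the provirus it putatively derives from. They stand in for a curated
#' provirus-derived query database: virus (and host provirus-remnant) cassettes
#' in generated genomes are back-translated copies of these sequences, and
#' [hallmark_search()] uses the same set as queries. The sequences are
#' synthetic (fixed random proteins), which is sufficient because downstream
#' logic depends only on detectable homology between cassette and query, not
#' on biological sequence content.
#'
#' @param path optional path to an alternative FASTA of queries with headers
#'   `kind|guild|nn`.
#' @return a data.frame with columns `query_id`, `gene_kind`, `guild`, `aa`
#'   (protein sequence) and `length`.
#' @export
#' @examples
#' db <- hallmark_db()
#' table(db$gene_kind)
hallmark_db <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hallmark_proteins_synthetic.faa",
                        package = "hybridsip", mustWork = TRUE)
  }
  fa <- Biostrings::readAAStringSet(path)
  ids <- sub(" .*$", "", names(fa))
  parts <- strsplit(ids, "|", fixed = TRUE)
  db <- data.frame(
    query_id = ids,
    gene_kind = vapply(parts, `[`, "", 1L),
    guild = vapply(parts, `[`, "", 2L),
    aa = as.character(fa),
    stringsAsFactors = FALSE
  )
  db$length <- nchar(db$aa)
  stopifnot(all(db$gene_kind %in% GENE_KINDS))
  db
}

GENE_KINDS <- c("capsid", "terminase", "portal", "integrase", "mco1")

# kinds whose presence marks a contig as viral; integrase alone never does
# (hosts carry integrases too), nor does the host-derived mco1 AMG
VIRAL_TRIGGER_KINDS <- c("capsid", "terminase", "portal")
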