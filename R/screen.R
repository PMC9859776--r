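#' Search translated ORFs against the hallmark query set
#'
#' Local (Smith-Waterman) alignment of each translated ORF against each
#' hallmark protein under BLOSUM62 with affine gaps (opening 11, extension
#' 1, Biostrings convention: a gap of length L costs 11 + L). Hits scoring at
#' least `score_threshold` are reported, keeping the best hit per (ORF,
#' gene_kind). The default threshold (100) sits far above the empirical null
#' of random-ORF scores (~30-60) and far below exact-cassette self-scores
#' (hundreds to thousands), and is calibrated once by the null-calibration
#' test.
#'
#' With `prescreen = TRUE` (default) only ORF/query pairs sharing at least
#' one exact 6-residue word are aligned. Pairs sharing no 6-mer cannot
#' approach the default threshold, so reported hits are identical to the
#' all-vs-all alignment; the prescreen only removes hopeless pairs.
#'
#' @param orfs data.frame from [find_orfs()] (possibly several contigs
#'   rbind-ed together).
#' @param db hallmark query set from [hallmark_db()].
#' @param score_threshold minimum reported alignment score.
#' @param prescreen require a shared 6-residue word before aligning.
#' @return data.frame of hits: `contig_id`, `gene_kind`, `start`, `end`,
#'   `strand`, `frame`, `score`, `query_id`, `guild`.
#' @export
hallmark_search <- function(orfs, db = hallmark_db(), score_threshold = 100,
                            prescreen = TRUE) {
  empty <- data.frame(contig_id = character(), gene_kind = character(),
                      start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      score = numeric(), query_id = character(),
                      guild = character(), stringsAsFactors = FALSE)
  if (NROW(orfs) == 0L) return(empty)
  stopifnot(NROW(db) > 0L)

  pairs <- if (prescreen) prescreen_pairs(orfs$aa, db$aa, k = 6L) else
    expand.grid(o = seq_len(nrow(orfs)), q = seq_len(nrow(db)))
  if (NROW(pairs) == 0L) return(empty)

  mat <- get_blosum62()
  scores <- numeric(nrow(pairs))
  for (qi in unique(pairs$q)) {
    sel <- pairs$q == qi
    pat <- Biostrings::AAStringSet(orfs$aa[pairs$o[sel]])
    scores[sel] <- Biostrings::pairwiseAlignment(
      pat, Biostrings::AAString(db$aa[qi]), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
  }
  keep <- scores >= score_threshold
  if (!any(keep)) return(empty)
  hits <- data.frame(
    orfs[pairs$o[keep], c("contig_id", "start", "end", "strand", "frame")],
    score = scores[keep],
    query_id = db$query_id[pairs$q[keep]],
    gene_kind = db$gene_kind[pairs$q[keep]],
    guild = db$guild[pairs$q[keep]],
    stringsAsFactors = FALSE)
  # best hit per (orf, gene_kind); deterministic tie-break on query_id
  key <- paste(hits$contig_id, hits$start, hits$end, hits$strand,
               hits$gene_kind)
  o <- order(key, -hits$score, hits$query_id)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(key[o]), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("contig_id", "gene_kind", "start", "end", "strand", "frame",
           "score", "query_id", "guild")]
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# candidate (orf, query) pairs sharing >= 1 exact k-residue word
prescreen_pairs <- function(orf_aa, query_aa, k = 6L) {
  words <- function(x) {
    n <- nchar(x)
    if (n < k) return(character(0))
    unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  qw <- lapply(query_aa, words)
  qdf <- data.frame(word = unlist(qw),
                    q = rep(seq_along(qw), lengths(qw)),
                    stringsAsFactors = FALSE)
  qmap <- split(qdf$q, qdf$word)
  out_o <- integer(0); out_q <- integer(0)
  for (oi in seq_along(orf_aa)) {
    m <- match(words(orf_aa[oi]), names(qmap))
    m <- unique(m[!is.na(m)])
    if (!length(m)) next
    qs <- unique(unlist(qmap[m], use.names = FALSE))
    out_o <- c(out_o, rep.int(oi, length(qs)))
    out_q <- c(out_q, qs)
  }
  data.frame(o = out_o, q = out_q)
}

#' Call viral operational taxonomic units from hallmark hits
#'
#' A contig is called a vOTU if and only if it is at least `min_length`
#' (default 10 kb) long and carries at least one hallmark hit of a
#' virus-diagnostic kind (capsid, terminase or portal). An integrase hit
#' alone never triggers a call — host genomes carry integrases (provirus
#' remnants) — and neither does the host-derived mco1 AMG; both still
#' contribute annotation. Each called contig is one vOTU (no clustering).
#' Lysogeny capability (`temperate_predicted`) is an integrase hit on the
#' contig. The host guild is the guild annotation of the best-scoring
#' virus-diagnostic query, corroborated by GC proximity: if the contig GC is
#' more than `gc_window` from that guild's mean host GC the prediction
#' falls back to `"unknown"`.
#'
#' Per-library detection flags (`passes` attribute) require mean depth >=
#' `min_depth` and breadth >= `min_breadth` (defaults 1x and 0.75).
#'
#' @param contigs a `sip_contigs`.
#' @param hits data.frame from [hallmark_search()].
#' @param mappings list of `sip_mapping` (one per library), or a single one.
#' @param min_length minimum vOTU contig length (bp).
#' @param min_depth,min_breadth per-library detection filters.
#' @param guild_gc named vector of mean host GC per guild (e.g. from a
#'   `sip_scenario`'s `guild_gc`).
#' @param gc_window GC corroboration half-width.
#' @return class `sip_votus`: data.frame `contig_id`, `length`, `gc`,
#'   `gene_kinds`, `temperate_predicted`, `host_guild`, `best_score`, with a
#'   `passes` attribute (vOTU x library logical matrix).
#' @export
call_votus <- function(contigs, hits, mappings, min_length = 10000L,
                       min_depth = 1, min_breadth = 0.75,
                       guild_gc = c(AOA = 0.38, AOB = 0.55, NOB = 0.60),
                       gc_window = 0.05) {
  ctg <- contigs$contigs
  if (inherits(mappings, "sip_mapping")) mappings <- list(mappings)
  empty <- structure(
    data.frame(contig_id = character(), length = integer(), gc = numeric(),
               gene_kinds = character(), temperate_predicted = logical(),
               host_guild = character(), best_score = numeric(),
               stringsAsFactors = FALSE),
    passes = matrix(FALSE, 0, length(mappings)), class = c("sip_votus", "data.frame"))
  if (NROW(hits) == 0L || NROW(ctg) == 0L) return(empty)

  rows <- list()
  for (cid in sort(unique(hits$contig_id))) {
    h <- hits[hits$contig_id == cid, , drop = FALSE]
    i <- match(cid, ctg$contig_id)
    if (is.na(i)) stop("hit on unknown contig ", cid)
    trig <- h[h$gene_kind %in% VIRAL_TRIGGER_KINDS, , drop = FALSE]
    if (nrow(trig) == 0L || ctg$length[i] < min_length) next
    best <- trig[order(-trig$score, trig$query_id)[1L], ]
    guild <- best$guild
    if (!guild %in% names(guild_gc) || is.na(guild_gc[[guild]]) ||
        abs(ctg$gc[i] - guild_gc[[guild]]) > gc_window)
      guild <- "unknown"
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = cid, length = ctg$length[i], gc = ctg$gc[i],
      gene_kinds = paste(sort(unique(h$gene_kind)), collapse = ","),
      temperate_predicted = "integrase" %in% h$gene_kind,
      host_guild = guild, best_score = best$score,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  votus <- do.call(rbind, rows)

  passes <- matrix(FALSE, nrow(votus), length(mappings),
                   dimnames = list(votus$contig_id,
                                   vapply(mappings, function(m)
                                     m$library_id[1] %||% NA_character_, "")))
  for (j in seq_along(mappings)) {
    m <- mappings[[j]]
    idx <- match(votus$contig_id, m$contig_id)
    passes[, j] <- !is.na(idx) & m$mean_depth[idx] >= min_depth &
      m$breadth[idx] >= min_breadth
  }
  structure(votus, passes = passes, class = c("sip_votus", "data.frame"))
}
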