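# Independent oracles used to check the package's implementations. These are
# deliberately written from first principles (textbook formulas, brute-force
# scans, naive dynamic programming) and share no code with the package.

# --- two-sample t-tests from the textbook formulas ------------------------

student_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

welch_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

f_test_oracle <- function(x, y) {
  f <- var(x) / var(y)
  df1 <- length(x) - 1; df2 <- length(y) - 1
  p <- pf(f, df1, df2)
  list(f = f, p = 2 * min(p, 1 - p))
}

# --- naive Gotoh local alignment (affine gaps, Biostrings convention:
# a gap of length L costs open + L * ext) ----------------------------------

sw_oracle <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)      # best ending in match/mismatch or start
  E <- matrix(NEG, n + 1, m + 1)    # gap in B (deletion from a)
  F <- matrix(NEG, n + 1, m + 1)    # gap in A
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - open - ext, E[i - 1, j] - ext)
      F[i, j] <- max(H[i, j - 1] - open - ext, F[i, j - 1] - ext)
      d <- H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]]
      H[i, j] <- max(0, d, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# --- brute-force canonical k-mer read assignment --------------------------

revcomp_chr <- function(s)
  chartr("ACGT", "TGCA", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))

kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

canonical <- function(km) pmin(km, revcomp_chr(km))

bf_assign_oracle <- function(reads, contig_seqs, contig_ids, k) {
  o <- order(contig_ids)
  contig_ids <- contig_ids[o]; contig_seqs <- contig_seqs[o]
  sets <- lapply(contig_seqs, function(s) unique(canonical(kmers_of(s, k))))
  vapply(reads, function(r) {
    rk <- canonical(kmers_of(r, k))
    shared <- vapply(sets, function(s) sum(rk %in% s), 0L)
    if (!length(shared) || max(shared) == 0L) return(NA_character_)
    contig_ids[which.max(shared)]  # first max = lexicographically smallest
  }, "", USE.NAMES = FALSE)
}

# --- independent six-frame ORF scanner ------------------------------------

orf_oracle <- function(seq, min_aa) {
  code <- Biostrings::GENETIC_CODE
  out <- list()
  len <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_chr(seq)
    for (frame in 0:2) {
      i <- frame + 1
      seg_start <- NA  # codon position of first start in current segment
      pos <- i
      while (pos + 2 <= len) {
        codon <- substr(s, pos, pos + 2)
        aa <- code[[codon]]
        if (is.na(seg_start) && codon %in% c("ATG", "GTG", "TTG"))
          seg_start <- pos
        if (!is.null(aa) && aa == "*") {
          if (!is.na(seg_start)) {
            naa <- (pos - seg_start) / 3
            if (naa >= min_aa) {
              st <- seg_start - 1; en <- pos + 2
              if (strand == "-") { tmp <- st; st <- len - en; en <- len - tmp }
              out[[length(out) + 1]] <- data.frame(
                start = st, end = en, strand = strand, length_aa = naa)
            }
          }
          seg_start <- NA
        }
        pos <- pos + 3
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character(),
                                      length_aa = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# --- shared small fixtures -------------------------------------------------

# reduced-depth config for fast end-to-end tests; scenario structure and all
# thresholds stay at the defaults
fast_config <- function(seed = 1L, depth = 6000L, ...)
  sip_config(sequencing = list(depth = as.integer(depth)), seed = seed, ...)

random_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# minimal sip_read_library built by hand for mapping tests
manual_library <- function(seqs, truth = rep("popA", length(seqs)),
                           id = "toy", read_length = nchar(seqs[1]),
                           pool = "LBD", treatment = "12C") {
  structure(list(
    library_id = id, soil = "pH4.5", treatment = treatment, pool = pool,
    replicate = 1L, depth = length(seqs), read_length = read_length,
    reads = data.frame(read_id = sprintf("%s_r%06d", id, seq_along(seqs)),
                       sequence = seqs, truth_pop_id = truth,
                       stringsAsFactors = FALSE)),
    class = "sip_read_library")
}

# minimal sip_contigs built by hand
manual_contigs <- function(seqs, ids = sprintf("ctg%02d", seq_along(seqs)),
                           source = ids) {
  structure(list(
    contigs = data.frame(contig_id = ids, sequence = seqs,
                         length = nchar(seqs),
                         gc = vapply(seqs, gc_content, 0),
                         source_pop_id = source, start = 0L,
                         end = nchar(seqs), stringsAsFactors = FALSE),
    provenance = character(0), pooled_depth = numeric(0)),
    class = "sip_contigs")
}
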