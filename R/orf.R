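#' Find open reading frames in all six frames
#'
#' An ORF spans from the first (5'-most) start codon (ATG/GTG/TTG) of a
#' stop-to-stop segment to the next in-frame stop codon, and is reported only
#' if its translated length reaches `min_aa`. Coordinates are on the forward
#' strand, 0-based half-open, and include the stop codon; `frame` is 0-2 on
#' the ORF's own strand. Segments running off the contig end without a stop
#' yield no ORF.
#'
#' @param sequence nucleotide string.
#' @param min_aa minimum protein length (codons before the stop).
#' @param contig_id id stored on the output rows.
#' @return data.frame with `contig_id`, `start`, `end`, `strand`, `frame`,
#'   `length_aa`, `aa` (translated sequence, no stop).
#' @export
find_orfs <- function(sequence, min_aa = 100L, contig_id = "contig") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  len <- nchar(sequence)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    for (frame in 0:2) {
      orfs <- scan_frame(s, frame, min_aa)
      if (is.null(orfs)) next
      if (strand == "-") {
        tmp <- orfs$start
        orfs$start <- len - orfs$end
        orfs$end <- len - tmp
      }
      orfs$strand <- strand
      orfs$frame <- frame
      out[[length(out) + 1L]] <- orfs
    }
  }
  if (!length(out))
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(), frame = integer(),
                      length_aa = integer(), aa = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- data.frame(contig_id = contig_id, res[c("start", "end", "strand",
                                                 "frame", "length_aa", "aa")],
                    stringsAsFactors = FALSE)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

scan_frame <- function(seq, frame, min_aa) {
  len <- nchar(seq)
  n_codons <- (len - frame) %/% 3L
  if (n_codons < min_aa + 1L) return(NULL)
  starts_nt <- frame + 3L * (seq_len(n_codons) - 1L) + 1L  # 1-based
  codons <- substring(seq, starts_nt, starts_nt + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  is_stop <- aa == "*"
  is_start <- codons %in% c("ATG", "GTG", "TTG")
  stop_idx <- which(is_stop)
  if (!length(stop_idx)) return(NULL)
  start_idx <- which(is_start)
  if (!length(start_idx)) return(NULL)
  lower <- c(1L, head(stop_idx, -1L) + 1L)  # segment lower bounds
  j <- findInterval(lower - 1L, start_idx) + 1L
  ok <- j <= length(start_idx)
  a <- integer(0); s <- integer(0)
  if (any(ok)) {
    a <- start_idx[j[ok]]
    s <- stop_idx[ok]
    keep <- a < s & (s - a) >= min_aa
    a <- a[keep]; s <- s[keep]
  }
  if (!length(a)) return(NULL)
  aa_str <- paste(aa, collapse = "")
  data.frame(
    start = frame + (a - 1L) * 3L,
    end = frame + s * 3L,
    length_aa = s - a,
    aa = substring(aa_str, a, s - 1L),
    stringsAsFactors = FALSE)
}
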