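# IUPAC ambiguity codes -> the set of plain bases each matches.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Mismatch count between a primer (IUPAC allowed) and a same-length window
# of read bases. An N in the read is a mismatch against everything.
.primer_mismatches <- function(primer_chars, window_chars) {
  ok <- mapply(function(p, b) b != "N" && b %in% .IUPAC[[p]],
               primer_chars, window_chars)
  sum(!ok)
}

#' Merge one read pair by its 3' overlap
#'
#' Searches for an overlap between the forward read and the
#' reverse-complemented reverse read of at least `min_overlap` bp with at
#' most `max_overlap_mismatches` mismatches. Among qualifying overlaps the
#' longest is taken (ties broken by fewest mismatches, then by the smallest
#' start offset of the reverse mate). Disagreements inside the overlap are
#' resolved in favour of the base with the higher Phred quality; at equal
#' quality the forward base wins. Before the overlap search each mate must
#' pass the quality check: at least `q30_fraction` of its bases at Phred
#' quality `>= q30_threshold`.
#'
#' @param fwd,rev Forward and reverse read sequences (reverse in sequencing
#'   orientation; it is reverse-complemented internally).
#' @param fwd_qual,rev_qual Integer Phred scores, one per base.
#' @param params A [preprocess_params()] object.
#' @return A list with `status` (`"ok"` or a rejection reason, one of
#'   `"q30"`, `"overlap"`), `sequence` (merged sequence or `NA`),
#'   `overlap_length` and `overlap_mismatches`.
#' @export
merge_pair <- function(fwd, fwd_qual, rev, rev_qual,
                       params = preprocess_params()) {
  if (!nzchar(fwd) || !nzchar(rev)) abort("both mates must be non-empty")
  f <- .chars(fwd)
  r_raw <- .chars(rev)
  if (length(f) != length(fwd_qual) || length(r_raw) != length(rev_qual)) {
    abort("bases and quality scores differ in length")
  }
  rejected <- function(reason) {
    list(status = reason, sequence = NA_character_,
         overlap_length = NA_integer_, overlap_mismatches = NA_integer_)
  }
  if (mean(fwd_qual >= params$q30_threshold) < params$q30_fraction ||
      mean(rev_qual >= params$q30_threshold) < params$q30_fraction) {
    return(rejected("q30"))
  }
  r <- .chars(.revcomp(rev))
  rq <- rev(rev_qual)
  m <- length(f); n <- length(r)
  # Candidate overlap lengths; larger L = smaller start offset of the
  # reverse mate, so longest-first search realises the offset tie-break too.
  cand <- seq.int(min(m, n), params$min_overlap)
  if (length(cand) == 0L || min(m, n) < params$min_overlap) {
    return(rejected("overlap"))
  }
  best <- NULL
  for (L in cand) {
    fi <- (m - L + 1L):m
    mm <- .mismatch(f[fi], r[1:L])
    if (mm <= params$max_overlap_mismatches) { best <- c(L, mm); break }
  }
  if (is.null(best)) return(rejected("overlap"))
  L <- best[1]; mm <- best[2]
  fi <- (m - L + 1L):m
  ov <- f[fi]
  take_rev <- f[fi] != r[1:L] & rq[1:L] > fwd_qual[fi]
  ov[take_rev] <- r[1:L][take_rev]
  merged <- paste(c(if (m > L) f[1:(m - L)], ov, if (n > L) r[(L + 1L):n]),
                  collapse = "")
  list(status = "ok", sequence = merged,
       overlap_length = as.integer(L), overlap_mismatches = as.integer(mm))
}

#' Trim amplification primers from a merged sequence
#'
#' Looks for the forward primer starting within the first 5 nt and the
#' reverse-complemented reverse primer ending within the last 5 nt, each
#' with at most `max_primer_mismatches` mismatches (IUPAC codes in the
#' primers match any compatible base; N in the read never matches). Returns
#' the interior sequence when both primers are found and the trimmed length
#' is at least `min_trimmed_length`.
#'
#' @param seq Merged amplicon sequence.
#' @param params A [preprocess_params()] object with both primers set.
#' @return A list with `status` (`"ok"`, `"primer_fwd"`, `"primer_rev"`, or
#'   `"length"`) and `sequence` (trimmed sequence or `NA`).
#' @export
trim_primers <- function(seq, params) {
  if (!nzchar(seq)) abort("empty sequence")
  if (is.null(params$primer_fwd) || is.null(params$primer_rev)) {
    abort("both primers must be set in `params`")
  }
  s <- .chars(seq)
  n <- length(s)
  pf <- .chars(toupper(params$primer_fwd))
  pr <- .chars(.revcomp(toupper(params$primer_rev)))
  lf <- length(pf); lr <- length(pr)
  rejected <- function(reason) list(status = reason, sequence = NA_character_)

  find_at <- function(primer, starts, plen) {
    hits <- vapply(starts, function(st) {
      if (st < 1L || st + plen - 1L > n) return(NA_integer_)
      .primer_mismatches(primer, s[st:(st + plen - 1L)])
    }, integer(1))
    ok <- which(!is.na(hits) & hits <= params$max_primer_mismatches)
    if (length(ok) == 0L) return(NA_integer_)
    # fewest mismatches, then smallest offset from the sequence end
    starts[ok][order(hits[ok], seq_along(ok))][1]
  }

  f_start <- find_at(pf, 1:6, lf)
  if (is.na(f_start)) return(rejected("primer_fwd"))
  r_start <- find_at(pr, (n - lr + 1L):(n - lr - 4L), lr)
  if (is.na(r_start)) return(rejected("primer_rev"))
  if (f_start + lf > r_start - 1L) return(rejected("length"))
  inner <- s[(f_start + lf):(r_start - 1L)]
  if (length(inner) < params$min_trimmed_length) return(rejected("length"))
  list(status = "ok", sequence = paste(inner, collapse = ""))
}

#' Preprocess a table of read pairs into retained amplicon sequences
#'
#' Applies [merge_pair()] then [trim_primers()] to every row and reports the
#' outcome per read. This is the in-memory work-horse behind
#' [preprocess_sample()].
#'
#' @param pairs A data frame with columns `read_id`, `fwd`, `rev`
#'   (character) and `fwd_qual`, `rev_qual` (list columns of integer Phred
#'   vectors).
#' @param params A [preprocess_params()] object.
#' @return A tibble with columns `read_id`, `status` (`"ok"` or the first
#'   failed rule) and `sequence` (`NA` unless retained).
#' @export
preprocess_pairs <- function(pairs, params = preprocess_params()) {
  out <- purrr::pmap(
    list(pairs$fwd, pairs$fwd_qual, pairs$rev, pairs$rev_qual),
    function(f, fq, r, rq) {
      m <- merge_pair(f, fq, r, rq, params)
      if (m$status != "ok") return(list(status = m$status, sequence = NA_character_))
      t <- trim_primers(m$sequence, params)
      list(status = t$status, sequence = t$sequence)
    })
  tibble(read_id = pairs$read_id,
         status = purrr::map_chr(out, "status"),
         sequence = purrr::map_chr(out, "sequence"))
}

#' Read a pair of FASTQ files into a read-pair table
#'
#' @param fastq_fwd,fastq_rev Paths to the forward and reverse FASTQ files
#'   (Phred+33), with mates in the same order.
#' @return A tibble suitable for [preprocess_pairs()].
#' @export
read_fastq_pairs <- function(fastq_fwd, fastq_rev) {
  # Biostrings warns when it drops the FASTQ mcols; nothing we use is lost
  f <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq_fwd))
  r <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq_rev))
  if (length(f) != length(r)) abort("mate files differ in read count")
  fq <- as(Biostrings::quality(f), "IntegerList")
  rq <- as(Biostrings::quality(r), "IntegerList")
  tibble(read_id = sub("\\s.*$", "", names(f)),
         fwd = as.character(f), fwd_qual = as.list(fq),
         rev = as.character(r), rev_qual = as.list(rq))
}

#' Preprocess one sample from FASTQ to retained amplicons
#'
#' @inheritParams read_fastq_pairs
#' @param params A [preprocess_params()] object.
#' @return A list with `sequences` (tibble of retained `read_id`,
#'   `sequence`) and `log` (tibble of read counts per outcome).
#' @export
preprocess_sample <- function(fastq_fwd, fastq_rev,
                              params = preprocess_params()) {
  res <- preprocess_pairs(read_fastq_pairs(fastq_fwd, fastq_rev), params)
  list(
    sequences = dplyr::filter(res, .data$status == "ok")[c("read_id", "sequence")],
    log = dplyr::count(res, .data$status, name = "reads")
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs A data frame with columns `read_id` (or `otu_id`) and
#'   `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ids <- if ("read_id" %in% names(seqs)) seqs$read_id else seqs$otu_id
  x <- Biostrings::DNAStringSet(setNames(seqs$sequence, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path FASTA path.
#' @return A tibble with columns `read_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(read_id = sub("\\s.*$", "", names(x)), sequence = as.character(x))
}
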