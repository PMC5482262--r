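# Needleman-Wunsch global alignment core shared by clustering and taxonomy.
# The alignment engine is Biostrings::pairwiseAlignment (type = "global",
# affine gaps); identity is computed from the aligned strings excluding
# terminal-gap overhangs.

.subst_matrix <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- params$match
  m["N", ] <- params$mismatch  # N matches nothing, not even N
  m[, "N"] <- params$mismatch
  m
}

.check_dna <- function(x) {
  if (any(grepl("[^ACGTN]", x))) abort("sequences may contain only A, C, G, T, N")
  x
}

# Identity from a pair of aligned (gapped) strings: matching columns over
# the columns spanned by both sequences (terminal-gap overhangs excluded).
.aligned_identity <- function(pat, sub) {
  p <- .chars(pat); s <- .chars(sub)
  both <- which(p != "-" & s != "-")
  span <- both[1]:both[length(both)]
  keep <- p[span]; other <- s[span]
  sum(keep == other & keep != "N") / length(span)
}

# Identity of many sequences against one, in a single alignment call.
.identity_to_one <- function(patterns, subject, params) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject,
    substitutionMatrix = .subst_matrix(params),
    gapOpening = abs(params$gap_open),
    gapExtension = abs(params$gap_extend),
    type = "global")
  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  purrr::map2_dbl(pat, sub, .aligned_identity)
}

# Align one query against many references in a single vectorised call.
# Returns a tibble with score and identity per reference.
.align_many <- function(query, refs, params) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(refs),
    subject = Biostrings::DNAString(query),
    substitutionMatrix = .subst_matrix(params),
    gapOpening = abs(params$gap_open),
    gapExtension = abs(params$gap_extend),
    type = "global")
  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  tibble(score = Biostrings::score(aln),
         identity = purrr::map2_dbl(pat, sub, .aligned_identity),
         aligned_ref = pat, aligned_query = sub)
}

#' Needleman-Wunsch global alignment of two sequences
#'
#' Optimal global alignment under affine gap scoring (a gap of length L
#' costs `|gap_open| + L * |gap_extend|`). Identity is the fraction of
#' matching columns over the alignment columns excluding terminal-gap
#' overhangs, the same definition used by [pairwise_identity()].
#'
#' @param a,b DNA sequences (characters A, C, G, T, N).
#' @param params An [align_params()] object.
#' @return A list with `score`, `identity`, and `alignment` (the two gapped
#'   strings).
#' @export
global_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  .check_dna(c(a, b))
  res <- .align_many(b, a, params)
  list(score = res$score, identity = res$identity,
       alignment = c(res$aligned_ref, res$aligned_query))
}

#' Pairwise identity between two sequences
#'
#' Identity under the package's global alignment: matching columns divided
#' by alignment columns excluding terminal-gap overhangs. Symmetric, and
#' equal to 1 exactly when the sequences are identical (N-free).
#'
#' @inheritParams global_align
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, params = align_params()) {
  # canonical argument order makes the value exactly symmetric even when
  # co-optimal alignments exist
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  global_align(a, b, params)$identity
}
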