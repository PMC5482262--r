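#' Parameters for paired-read merging and primer trimming
#'
#' Bundles the quality-control thresholds applied when turning raw paired
#' reads into amplicon sequences: the merged pair must have an overlap of at
#' least `min_overlap` bp with at most `max_overlap_mismatches` mismatches,
#' each mate must pass a Q30-style check (`q30_fraction` of bases at Phred
#' quality at least `q30_threshold`), both primers must be found with at most
#' `max_primer_mismatches` mismatches, and the trimmed amplicon must be at
#' least `min_trimmed_length` bp.
#'
#' @param min_overlap Minimum overlap between mates, in bp.
#' @param max_overlap_mismatches Maximum mismatches tolerated in the overlap.
#' @param q30_fraction Minimum fraction of bases in each mate at or above
#'   `q30_threshold`.
#' @param q30_threshold Phred score used by the quality check.
#' @param primer_fwd,primer_rev Primer sequences (IUPAC ambiguity codes
#'   allowed). The reverse primer is given in its primer orientation; its
#'   reverse complement is searched at the 3' end of the merged sequence.
#' @param max_primer_mismatches Maximum mismatches tolerated per primer.
#' @param min_trimmed_length Minimum amplicon length after trimming, in bp.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(min_overlap = 150L,
                              max_overlap_mismatches = 3L,
                              q30_fraction = 0.66,
                              q30_threshold = 30L,
                              primer_fwd = NULL,
                              primer_rev = NULL,
                              max_primer_mismatches = 3L,
                              min_trimmed_length = 250L) {
  stopifnot(min_overlap > 0, max_overlap_mismatches >= 0,
            q30_fraction >= 0, q30_fraction <= 1, q30_threshold >= 0,
            max_primer_mismatches >= 0, min_trimmed_length >= 0)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_overlap_mismatches = as.integer(max_overlap_mismatches),
                 q30_fraction = q30_fraction,
                 q30_threshold = as.integer(q30_threshold),
                 primer_fwd = primer_fwd,
                 primer_rev = primer_rev,
                 max_primer_mismatches = as.integer(max_primer_mismatches),
                 min_trimmed_length = as.integer(min_trimmed_length)),
            class = "preprocess_params")
}

#' Parameters for OTU clustering and count filtering
#'
#' @param identity_threshold Identity threshold for greedy clustering
#'   (fraction in (0, 1]; 0.97 gives the conventional 97% OTUs).
#' @param min_otu_count OTUs observed fewer than this many times in total
#'   are removed after clustering.
#' @param min_sample_count Samples with fewer remaining reads than this are
#'   removed after the OTU filter.
#' @param drop_singletons Drop clusters with a total count of 1 at cluster
#'   formation, before the OTU count filter.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 0.97,
                           min_otu_count = 10L,
                           min_sample_count = 200L,
                           drop_singletons = TRUE) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            min_otu_count >= 0, min_sample_count >= 0)
  structure(list(identity_threshold = identity_threshold,
                 min_otu_count = as.integer(min_otu_count),
                 min_sample_count = as.integer(min_sample_count),
                 drop_singletons = isTRUE(drop_singletons)),
            class = "cluster_params")
}

#' Parameters for global alignment and taxonomy assignment
#'
#' Scoring scheme for the Needleman-Wunsch global alignment used both for
#' pairwise identity during clustering and for searching the reference
#' database. A gap of length L costs `|gap_open| + L * |gap_extend|`.
#' Queries whose best reference identity falls below `min_assign_identity`
#' are flagged unassignable.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative). N never matches anything.
#' @param gap_open Gap opening penalty (negative).
#' @param gap_extend Gap extension penalty per base (negative).
#' @param min_assign_identity Minimum identity for a taxonomy assignment.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 5, mismatch = -4,
                         gap_open = -10, gap_extend = -1,
                         min_assign_identity = 0.90) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            min_assign_identity >= 0, min_assign_identity <= 1)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_assign_identity = min_assign_identity),
            class = "align_params")
}

#' Relative-abundance thresholds defining symbiont niches
#'
#' An OTU is "abundant" in an individual at relative abundance above
#' `abundant_min`, "dominant" above `dominant_min`, and in the "background"
#' niche when present below `background_max`. The background-niche summary
#' requires presence below `background_max` in at least
#' `background_min_species` host species; in the background network,
#' symbiont nodes connected to `prune_degree` or fewer host species are
#' removed.
#'
#' @param abundant_min,dominant_min,background_max Relative-abundance
#'   thresholds (fractions).
#' @param background_min_species Minimum number of host species for the
#'   background-niche summary.
#' @param prune_degree Background-network symbiont nodes with degree less
#'   than or equal to this are pruned.
#' @return A list of class `niche_thresholds`.
#' @export
niche_thresholds <- function(abundant_min = 0.01,
                             dominant_min = 0.50,
                             background_max = 0.01,
                             background_min_species = 3L,
                             prune_degree = 2L) {
  stopifnot(abundant_min > 0, abundant_min < dominant_min, dominant_min <= 1,
            background_max > 0, background_min_species >= 1, prune_degree >= 0)
  structure(list(abundant_min = abundant_min,
                 dominant_min = dominant_min,
                 background_max = background_max,
                 background_min_species = as.integer(background_min_species),
                 prune_degree = as.integer(prune_degree)),
            class = "niche_thresholds")
}
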