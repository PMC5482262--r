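#' Dereplicate sequences into a variant table
#'
#' Collapses exactly identical sequences and records multiplicities — the
#' "100% OTUs" of the finest clustering strategy.
#'
#' @param seqs Character vector of DNA sequences, or a data frame with a
#'   `sequence` column (one row per read).
#' @param sample_id Optional sample id recorded in the output.
#' @return A tibble with columns (`sample_id`,) `sequence`, `count`,
#'   ordered by decreasing count then sequence.
#' @export
dereplicate <- function(seqs, sample_id = NULL) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  if (length(seqs) == 0L) {
    out <- tibble(sequence = character(), count = integer())
  } else {
    out <- tibble(sequence = seqs) |>
      dplyr::count(.data$sequence, name = "count") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  }
  if (!is.null(sample_id)) out <- dplyr::mutate(out, sample_id = sample_id,
                                                .before = 1)
  out
}

#' Greedy abundance-sorted centroid clustering
#'
#' Clusters the variants of one sample (or one pooled set) in the style of
#' uclust: variants are processed in decreasing count order (ties broken by
#' lexicographically smaller sequence first); each variant joins the
#' best-matching existing cluster whose centroid identity is at least
#' `identity_threshold` (ties to the earliest-created cluster), otherwise it
#' founds a new cluster. After all assignments each cluster's representative
#' is re-elected as its highest-count member (ties again lexicographic).
#'
#' @param variants A data frame with columns `sequence`, `count`.
#' @param params A [cluster_params()] object.
#' @param align An [align_params()] object used for pairwise identity.
#' @return A tibble with one row per cluster: `cluster` (integer id in
#'   creation order), `representative`, `total_count`, and `members`, a
#'   list column of tibbles (`sequence`, `count`).
#' @export
greedy_cluster <- function(variants, params = cluster_params(),
                           align = align_params()) {
  stopifnot(nrow(variants) > 0)
  v <- dplyr::arrange(variants, dplyr::desc(.data$count), .data$sequence)
  seqs <- v$sequence
  set <- Biostrings::DNAStringSet(seqs)
  n <- length(seqs)
  # Sequential greedy, evaluated centroid-by-centroid: a variant can only
  # join a cluster founded earlier in the processing order, so the running
  # best identity of each variant over the centroids founded so far fully
  # determines both the next founder (first variant still below threshold)
  # and every assignment. One vectorised alignment call per centroid.
  best_id <- rep(-1, n)
  best_cl <- rep(NA_integer_, n)
  is_founder <- logical(n)
  founder_idx <- integer()
  repeat {
    open <- which(!is_founder & best_id < params$identity_threshold)
    if (length(open) == 0L) break
    f <- open[1]
    is_founder[f] <- TRUE
    founder_idx <- c(founder_idx, f)
    after <- which(seq_len(n) > f & !is_founder)
    if (length(after) == 0L) next
    ids <- .identity_to_one(set[after], set[[f]], align)
    upd <- ids > best_id[after]   # strict: ties keep the earlier cluster
    best_id[after[upd]] <- ids[upd]
    best_cl[after[upd]] <- length(founder_idx)
  }
  assignment <- best_cl
  assignment[is_founder] <- match(which(is_founder), founder_idx)
  v |>
    dplyr::mutate(cluster = assignment) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      representative = .data$sequence[order(-.data$count, .data$sequence)][1],
      total_count = sum(.data$count),
      members = list(dplyr::pick("sequence", "count")),
      .groups = "drop") |>
    dplyr::arrange(.data$cluster)
}

# Internal constructor for the samples-by-OTUs result container.
new_otu_table <- function(counts, representatives, mode,
                          metadata = NULL, membership = NULL) {
  structure(list(counts = counts, representatives = representatives,
                 metadata = metadata, membership = membership, mode = mode),
            class = "symotu_table")
}

# Assemble an OTU table from per-sample cluster tibbles keyed by
# representative sequence. Clusters with the same key become one OTU.
.assemble_otus <- function(per_sample, mode, metadata = NULL,
                           drop_singletons = TRUE) {
  memb <- dplyr::bind_rows(per_sample)   # sample_id, representative, members
  if (drop_singletons) {
    totals <- memb |> dplyr::group_by(.data$representative) |>
      dplyr::summarise(total = sum(.data$total_count), .groups = "drop")
    keep <- totals$representative[totals$total > 1L]
    memb <- dplyr::filter(memb, .data$representative %in% keep)
  }
  if (nrow(memb) == 0L) {
    return(new_otu_table(tibble(sample_id = character(), otu_id = character(),
                                count = integer()),
                         tibble(otu_id = character(), sequence = character()),
                         mode, metadata))
  }
  reps <- memb |>
    dplyr::group_by(sequence = .data$representative) |>
    dplyr::summarise(total = sum(.data$total_count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$sequence) |>
    dplyr::mutate(otu_id = sprintf("OTU%04d", dplyr::row_number()))
  memb <- dplyr::left_join(memb, reps[c("sequence", "otu_id")],
                           by = c(representative = "sequence"))
  counts <- memb |>
    dplyr::group_by(.data$sample_id, .data$otu_id) |>
    dplyr::summarise(count = sum(.data$total_count), .groups = "drop")
  membership <- memb |>
    dplyr::select("sample_id", "otu_id", "members") |>
    tidyr::unnest("members")
  new_otu_table(counts, reps[c("otu_id", "sequence")], mode,
                metadata, membership)
}

.split_samples <- function(tables) {
  stopifnot(nrow(tables) > 0, all(c("sample_id", "sequence", "count") %in%
                                    names(tables)))
  split(tables, tables$sample_id)
}

#' Within-sample 97% clustering with merge by identical representative
#'
#' The package's core strategy: sequences from each sample are clustered
#' independently at `identity_threshold`, and clusters from different
#' samples are merged into one OTU only when their representative sequences
#' are exactly identical. Closely related variants co-occurring in one
#' sample (likely intragenomic) collapse, while similar variants that
#' dominate different samples (likely different taxa) stay separate.
#'
#' @param tables A data frame with columns `sample_id`, `sequence`, `count`
#'   (per-sample dereplicated variants, e.g. from [dereplicate()]).
#' @param params A [cluster_params()] object.
#' @param align An [align_params()] object.
#' @param metadata Optional sample metadata tibble with a `sample_id`
#'   column, carried into the result.
#' @return A `symotu_table`: long counts, representative sequences, and the
#'   full membership map.
#' @export
cluster_within_samples <- function(tables, params = cluster_params(),
                                   align = align_params(), metadata = NULL) {
  per_sample <- purrr::imap(.split_samples(tables), function(tab, sid) {
    greedy_cluster(tab[c("sequence", "count")], params, align) |>
      dplyr::transmute(sample_id = sid, representative = .data$representative,
                       total_count = .data$total_count,
                       members = .data$members)
  })
  .assemble_otus(per_sample, "within", metadata, params$drop_singletons)
}

#' Across-sample 97% clustering
#'
#' The conventional strategy: variants from all samples are pooled (counts
#' summed across samples) and clustered together; per-sample OTU counts are
#' recovered from cluster membership.
#'
#' @inheritParams cluster_within_samples
#' @return A `symotu_table`.
#' @export
cluster_across_samples <- function(tables, params = cluster_params(),
                                   align = align_params(), metadata = NULL) {
  stopifnot(nrow(tables) > 0)
  pooled <- tables |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  clusters <- greedy_cluster(pooled, params, align)
  seq2rep <- clusters |>
    dplyr::select("representative", "members") |>
    tidyr::unnest("members") |>
    dplyr::select("sequence", "representative")
  per_sample <- tables |>
    dplyr::left_join(seq2rep, by = "sequence") |>
    dplyr::group_by(.data$sample_id, .data$representative) |>
    dplyr::summarise(total_count = sum(.data$count),
                     members = list(dplyr::pick("sequence", "count")),
                     .groups = "drop")
  .assemble_otus(list(per_sample), "across", metadata, params$drop_singletons)
}

#' 100% identity OTUs (global dereplication)
#'
#' Every distinct sequence is its own OTU; identical sequences merge across
#' samples.
#'
#' @inheritParams cluster_within_samples
#' @return A `symotu_table`.
#' @export
cluster_denovo100 <- function(tables, params = cluster_params(),
                              metadata = NULL) {
  per_sample <- purrr::imap(.split_samples(tables), function(tab, sid) {
    tibble(sample_id = sid, representative = tab$sequence,
           total_count = tab$count,
           members = purrr::map2(tab$sequence, tab$count,
                                 ~tibble(sequence = .x, count = .y)))
  })
  .assemble_otus(per_sample, "denovo100", metadata, params$drop_singletons)
}

#' Filter an OTU table by OTU and sample count thresholds
#'
#' First drops OTUs observed fewer than `min_otu_count` times in total, then
#' drops samples whose remaining read total is below `min_sample_count`.
#'
#' @param x A `symotu_table`.
#' @param params A [cluster_params()] object.
#' @return The filtered `symotu_table`, with attributes `dropped_otus` and
#'   `dropped_samples` listing removed ids. If every sample is removed the
#'   result is an empty table (with a warning).
#' @export
filter_otu_table <- function(x, params = cluster_params()) {
  stopifnot(inherits(x, "symotu_table"))
  otu_totals <- x$counts |> dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  bad_otus <- otu_totals$otu_id[otu_totals$total < params$min_otu_count]
  counts <- dplyr::filter(x$counts, !(.data$otu_id %in% bad_otus))
  sample_totals <- counts |> dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  all_samples <- unique(x$counts$sample_id)
  keep_samples <- sample_totals$sample_id[sample_totals$total >=
                                            params$min_sample_count]
  bad_samples <- setdiff(all_samples, keep_samples)
  counts <- dplyr::filter(counts, .data$sample_id %in% keep_samples)
  # an OTU may lose all its samples; drop empty columns
  live <- unique(counts$otu_id)
  out <- new_otu_table(
    counts,
    dplyr::filter(x$representatives, .data$otu_id %in% live),
    x$mode,
    if (!is.null(x$metadata))
      dplyr::filter(x$metadata, .data$sample_id %in% keep_samples),
    if (!is.null(x$membership))
      dplyr::filter(x$membership, .data$otu_id %in% live,
                    .data$sample_id %in% keep_samples))
  attr(out, "dropped_otus") <- bad_otus
  attr(out, "dropped_samples") <- bad_samples
  if (length(keep_samples) == 0L) {
    warn("all samples were removed by the count filters; result is empty")
  }
  out
}

#' @export
print.symotu_table <- function(x, ...) {
  cat(sprintf("<symotu_table> %d OTUs x %d samples (%s clustering, %d reads)\n",
              nrow(x$representatives), length(unique(x$counts$sample_id)),
              x$mode, sum(x$counts$count)))
  invisible(x)
}

#' Number of OTUs in an OTU table
#' @param x A `symotu_table`.
#' @return Integer count of OTUs.
#' @export
n_otus <- function(x) nrow(x$representatives)

#' Samples-by-OTUs count matrix
#'
#' @param x A `symotu_table`.
#' @return An integer matrix, rows = samples, columns = OTUs.
#' @export
otu_matrix <- function(x) {
  wide <- x$counts |>
    tidyr::pivot_wider(names_from = "otu_id", values_from = "count",
                       values_fill = 0L) |>
    dplyr::arrange(.data$sample_id)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample_id
  ord <- intersect(x$representatives$otu_id, colnames(m))
  m[, ord, drop = FALSE]
}

#' @export
tidy.symotu_table <- function(x, ...) {
  out <- dplyr::left_join(x$counts, x$representatives, by = "otu_id")
  if (!is.null(x$metadata)) out <- dplyr::left_join(out, x$metadata,
                                                    by = "sample_id")
  out
}

#' @export
glance.symotu_table <- function(x, ...) {
  otu_tot <- x$counts |> dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(t = sum(.data$count), .groups = "drop")
  smp_tot <- x$counts |> dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(t = sum(.data$count), .groups = "drop")
  tibble(mode = x$mode, n_otus = nrow(x$representatives),
         n_samples = nrow(smp_tot), total_reads = sum(x$counts$count),
         min_reads_per_otu = min(otu_tot$t), max_reads_per_otu = max(otu_tot$t),
         min_reads_per_sample = min(smp_tot$t),
         max_reads_per_sample = max(smp_tot$t),
         geomean_reads_per_sample = .geom_mean(smp_tot$t),
         gsd_reads_per_sample = .geom_sd(smp_tot$t))
}

#' Write an OTU table to TSV (OTUs as rows, samples as columns)
#'
#' @param x A `symotu_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  wide <- x$counts |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
  out <- dplyr::left_join(x$representatives, wide, by = "otu_id")
  readr::write_tsv(out, path)
  invisible(path)
}
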