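#' Load a reference database of named ITS2 sequences
#'
#' The FASTA header dialect is `>NAME` where the first character of NAME is
#' the clade letter (e.g. `>B1`, `>C3`). Names must be unique.
#'
#' @param path Path to the reference FASTA.
#' @return A tibble with columns `name`, `clade`, `sequence`.
#' @export
read_reference_db <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) abort("reference names must be unique")
  clade <- substr(nm, 1, 1)
  if (!all(grepl("^[A-I]$", clade))) {
    abort("reference names must start with a clade letter A-I")
  }
  tibble(name = nm, clade = clade, sequence = toupper(as.character(x)))
}

#' Assign taxonomy to OTU representatives by global alignment
#'
#' Each representative is aligned against every reference with the
#' Needleman-Wunsch algorithm; the reference(s) attaining the maximal
#' alignment score give the name. An exact match (identity 1) is named by
#' the sorted best reference names joined with "/". A match below 100% but
#' at or above `min_assign_identity` takes the best name plus a unique
#' variant suffix `_v<k>` — distinct representative sequences sharing a best
#' name always receive distinct suffixes, allocated in lexicographic order
#' of the representative sequences. Below `min_assign_identity` the OTU is
#' flagged unassignable. When equally best references span more than one
#' clade the assignment is marked ambiguous and the lexicographically first
#' name is used.
#'
#' @param x A `symotu_table`, or a data frame with columns `otu_id`,
#'   `sequence` (representatives).
#' @param db A reference tibble from [read_reference_db()].
#' @param params An [align_params()] object.
#' @return A tibble with columns `otu_id`, `assigned_name`, `clade`,
#'   `identity`, `score`, `flag` (`exact`, `variant`, `unassignable`),
#'   `best_refs` ("/"-joined) and `ambiguous`.
#' @export
assign_taxonomy <- function(x, db, params = align_params()) {
  reps <- if (inherits(x, "symotu_table")) x$representatives else x
  stopifnot(nrow(db) > 0, all(c("otu_id", "sequence") %in% names(reps)))
  if (any(!nzchar(reps$sequence))) abort("empty representative sequence")
  hits <- purrr::map(reps$sequence, function(s) {
    res <- .align_many(s, setNames(db$sequence, db$name), params)
    best <- which(res$score == max(res$score))
    nms <- sort(db$name[best])
    tibble(best_refs = paste(nms, collapse = "/"),
           first_name = nms[1],
           identity = max(res$identity[best]),
           score = max(res$score),
           n_clades = length(unique(db$clade[best])))
  }) |> dplyr::bind_rows()
  out <- dplyr::bind_cols(reps["otu_id"], sequence = reps$sequence, hits)

  # deterministic suffix allocation: lexicographic order of representatives
  out <- out[order(out$sequence), ]
  counter <- new.env(parent = emptyenv())
  suffixed <- vapply(seq_len(nrow(out)), function(i) {
    if (out$identity[i] >= 1) return(out$best_refs[i])
    if (out$identity[i] < params$min_assign_identity) return("unassigned")
    base <- out$first_name[i]
    k <- (if (is.null(counter[[base]])) 0L else counter[[base]]) + 1L
    counter[[base]] <- k
    paste0(base, "_v", k)
  }, character(1))
  out$assigned_name <- suffixed
  out$flag <- dplyr::case_when(
    out$identity >= 1 ~ "exact",
    out$identity >= params$min_assign_identity ~ "variant",
    .default = "unassignable")
  out$clade <- ifelse(out$flag == "unassignable", "unknown",
                      substr(out$first_name, 1, 1))
  out$ambiguous <- out$n_clades > 1L
  out <- out[match(reps$otu_id, out$otu_id), ]
  dplyr::select(out, "otu_id", "assigned_name", "clade", "identity",
                "score", "flag", "best_refs", "ambiguous")
}

#' Per-clade relative abundance and OTU counts
#'
#' @param x A `symotu_table` (typically the filtered table).
#' @param tax A taxonomy tibble from [assign_taxonomy()].
#' @return A tibble with columns `clade`, `reads`, `rel_abundance`
#'   (fraction of all reads), `n_otus`, sorted by decreasing abundance.
#' @export
summarize_clades <- function(x, tax) {
  stopifnot(inherits(x, "symotu_table"))
  joined <- dplyr::left_join(x$counts, tax[c("otu_id", "clade")],
                             by = "otu_id")
  if (anyNA(joined$clade)) abort("every OTU must have a taxonomy assignment")
  joined |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(reads = sum(.data$count),
                     n_otus = dplyr::n_distinct(.data$otu_id),
                     .groups = "drop") |>
    dplyr::mutate(rel_abundance = .data$reads / sum(.data$reads)) |>
    dplyr::arrange(dplyr::desc(.data$rel_abundance)) |>
    dplyr::select("clade", "reads", "rel_abundance", "n_otus")
}
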