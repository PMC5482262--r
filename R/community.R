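#' Relative abundance per sample
#'
#' @param x A `symotu_table` or a long tibble with columns `sample_id`,
#'   `otu_id`, `count`.
#' @return A tibble `sample_id`, `otu_id`, `count`, `rel_abund`; the
#'   abundances of each sample sum to 1.
#' @export
relative_abundance <- function(x) {
  counts <- if (inherits(x, "symotu_table")) x$counts else x
  totals <- counts |> dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  if (any(totals$total <= 0)) abort("every sample must have a positive total")
  counts |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(rel_abund = .data$count / .data$total) |>
    dplyr::select(-"total")
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i,j) = 1 - 2 * sum(min(x_i, x_j)) / (sum(x_i) + sum(x_j))`, computed
#' by default on square-root transformed counts.
#'
#' @param x A `symotu_table` or a samples-by-OTUs matrix.
#' @param sqrt_transform Square-root transform counts first (default TRUE).
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(x, sqrt_transform = TRUE) {
  m <- if (inherits(x, "symotu_table")) otu_matrix(x) else as.matrix(x)
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(rowSums(m) == 0)) abort("zero-total sample in the table")
  if (sqrt_transform) m <- sqrt(m)
  vegan::vegdist(m, method = "bray")
}

# squared-distance sums within groups, the work-horse shared by the
# observed statistic and its permutations
.ss_within <- function(d2, groups) {
  sum(vapply(split(seq_along(groups), groups), function(idx) {
    if (length(idx) < 2L) return(0)
    sum(d2[idx, idx]) / 2 / length(idx)
  }, numeric(1)))
}

#' One-factor PERMANOVA
#'
#' Partitions the squared dissimilarities among samples into between- and
#' within-group components and tests the pseudo-F statistic against a
#' permutation null obtained by shuffling group labels.
#'
#' @param d A `dist` object (e.g. from [bray_curtis()]).
#' @param groups Group labels, one per sample, in the order of `d`'s
#'   labels.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A `permanova_result` with fields `r2`, `pseudo_f`, `p`,
#'   `n_perm`, `df`, and the sum-of-squares partition. Use [tidy()] or
#'   [glance()] for tabular views.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL) {
  groups <- as.factor(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) abort("one group label per sample is required")
  if (any(table(groups) == 0L) || nlevels(groups) < 2L) {
    abort("at least two non-empty groups are required")
  }
  a <- nlevels(groups)
  d2 <- as.matrix(d)^2
  ss_total <- sum(d2) / 2 / n
  ss_within <- .ss_within(d2, groups)
  ss_between <- ss_total - ss_within
  f_obs <- (ss_between / (a - 1)) / (ss_within / (n - a))
  if (!is.null(seed)) set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    g <- sample(groups)
    sw <- .ss_within(d2, g)
    ((ss_total - sw) / (a - 1)) / (sw / (n - a))
  }, numeric(1))
  structure(list(r2 = ss_between / ss_total, pseudo_f = f_obs,
                 p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
                 n_perm = as.integer(n_perm),
                 df = c(between = a - 1L, within = n - a),
                 ss = c(between = ss_between, within = ss_within,
                        total = ss_total),
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d,%d) = %.3f, R2 = %.3f, p = %.4f (%d permutations)\n",
              x$df[1], x$df[2], x$pseudo_f, x$r2, x$p, x$n_perm))
  invisible(x)
}

#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(term = c("between", "within", "total"),
         df = c(x$df[1], x$df[2], sum(x$df)),
         sum_of_squares = as.numeric(x$ss),
         pseudo_f = c(x$pseudo_f, NA, NA),
         r2 = c(x$r2, 1 - x$r2, 1),
         p_value = c(x$p, NA, NA))
}

#' @export
glance.permanova_result <- function(x, ...) {
  tibble(pseudo_f = x$pseudo_f, r2 = x$r2, p_value = x$p, n_perm = x$n_perm)
}

#' Principal coordinate analysis with signed eigenvalues
#'
#' Gower-centred double-centering eigendecomposition of a distance matrix.
#' Axes with negative eigenvalues (possible for semi-metric dissimilarities
#' such as Bray-Curtis) are retained separately as imaginary axes scaled by
#' `sqrt(-eigenvalue)`.
#'
#' @param d A `dist` object.
#' @return A list of class `pcoa_axes` with `points` (real axes),
#'   `imaginary` (imaginary axes, possibly zero columns), `eigenvalues`,
#'   and `ids`.
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  a <- -0.5 * dm^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                 length(pos))
  img <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]),
                                                 length(neg))
  rownames(pts) <- rownames(img) <- rownames(dm)
  structure(list(points = pts, imaginary = img,
                 eigenvalues = e$values[c(pos, neg)],
                 ids = rownames(dm)),
            class = "pcoa_axes")
}

# distance of each row to its group centroid in one coordinate block
.centroid_dist2 <- function(coords, groups) {
  if (ncol(coords) == 0L) return(numeric(nrow(coords)))
  out <- numeric(nrow(coords))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cen <- colMeans(coords[idx, , drop = FALSE])
    out[idx] <- rowSums(sweep(coords[idx, , drop = FALSE], 2, cen)^2)
  }
  out
}

.anova_f <- function(values, groups) {
  n <- length(values); a <- nlevels(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  (ssb / (a - 1)) / (ssw / (n - a))
}

#' Multivariate dispersion ("symbiotic flexibility")
#'
#' Computes each sample's distance to its group centroid in principal
#' coordinate space, combining real and imaginary axes as
#' `sqrt(max(0, d_real^2 - d_imag^2))`, then compares mean
#' distance-to-centroid among groups by a permutation test on the one-way
#' ANOVA F statistic (distances shuffled among samples). Pairwise group
#' differences are tested the same way and summarised as a compact letter
#' display at `alpha`.
#'
#' @param d A `dist` object.
#' @param groups Group labels (e.g. host species), one per sample.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param alpha Significance level for the letter display.
#' @return A `dispersion_result` with `group_stats` (mean distance, SE,
#'   letters), `distances` (per sample), `overall` (F, p), and
#'   `pairwise_p`.
#' @export
beta_dispersion <- function(d, groups, n_perm = 999L, seed = NULL,
                            alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  n <- attr(d, "Size")
  if (length(groups) != n) abort("one group label per sample is required")
  ax <- pcoa(d)
  d2r <- .centroid_dist2(ax$points, groups)
  d2i <- .centroid_dist2(ax$imaginary, groups)
  dist_c <- sqrt(pmax(0, d2r - d2i))
  singleton <- groups %in% names(which(table(groups) == 1L))

  if (!is.null(seed)) set.seed(seed)
  f_obs <- .anova_f(dist_c, groups)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    .anova_f(sample(dist_c), groups)
  }, numeric(1))
  p_overall <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)

  lev <- levels(groups)
  pw <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    idx <- groups %in% lev[c(i, j)]
    v <- dist_c[idx]; g <- droplevels(groups[idx])
    if (nlevels(g) < 2L || any(table(g) < 2L)) next
    t_obs <- .anova_f(v, g)
    t_perm <- vapply(seq_len(n_perm), function(k) .anova_f(sample(v), g),
                     numeric(1))
    pw[i, j] <- pw[j, i] <- (1 + sum(t_perm >= t_obs)) / (1 + n_perm)
  }

  stats_tbl <- tibble(group = groups, dist = dist_c) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_dist = mean(.data$dist),
                     se = stats::sd(.data$dist) / sqrt(dplyr::n()),
                     .groups = "drop")
  grp_chr <- as.character(stats_tbl$group)
  stats_tbl$letters <- .letter_display(pw[grp_chr, grp_chr, drop = FALSE],
                                       alpha)
  stats_tbl$singleton <- stats_tbl$n == 1L

  structure(list(group_stats = stats_tbl,
                 distances = tibble(id = ax$ids, group = groups,
                                    dist_to_centroid = dist_c,
                                    singleton = singleton),
                 overall = list(f = f_obs, p = p_overall,
                                n_perm = as.integer(n_perm)),
                 pairwise_p = pw, alpha = alpha, seed = seed),
            class = "dispersion_result")
}

# Compact letter display from a pairwise p matrix: two groups share a
# letter exactly when they are not significantly different at alpha, so the
# letters are the maximal cliques of the non-significance graph (untestable
# pairs, NA, count as not different).
.letter_display <- function(pw, alpha = 0.05) {
  k <- nrow(pw)
  if (k == 1L) return("a")
  adj <- is.na(pw) | pw >= alpha
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  out <- character(k)
  for (s in seq_along(cliques)) {
    idx <- as.integer(cliques[[s]])
    out[idx] <- paste0(out[idx], letters[s])
  }
  out
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Multivariate dispersion: F = %.3f, p = %.4f (%d permutations)\n",
              x$overall$f, x$overall$p, x$overall$n_perm))
  print(x$group_stats)
  invisible(x)
}

#' @export
tidy.dispersion_result <- function(x, ...) x$group_stats

#' @export
glance.dispersion_result <- function(x, ...) {
  tibble(f = x$overall$f, p_value = x$overall$p, n_perm = x$overall$n_perm,
         n_groups = nrow(x$group_stats))
}

#' Per-species PERMANOVA summary of shore differences
#'
#' For each host species sampled on both shores, reports the mean overall,
#' within-shore, and between-shore Bray-Curtis dissimilarities together
#' with the PERMANOVA R2 and p-value for a shore effect.
#'
#' @param x A filtered `symotu_table` whose metadata has `species` and
#'   `shore` columns.
#' @param sqrt_transform Square-root transform counts (default TRUE).
#' @param n_perm,seed Permutation settings passed to [permanova()].
#' @return A tibble with one row per species.
#' @export
shore_permanova <- function(x, sqrt_transform = TRUE, n_perm = 999L,
                            seed = NULL) {
  stopifnot(inherits(x, "symotu_table"), !is.null(x$metadata))
  meta <- dplyr::arrange(x$metadata, .data$sample_id)
  m <- otu_matrix(x)
  meta <- meta[match(rownames(m), meta$sample_id), ]
  purrr::map(split(seq_len(nrow(m)), meta$species), function(idx) {
    sp_meta <- meta[idx, ]
    d <- bray_curtis(m[idx, , drop = FALSE], sqrt_transform)
    dm <- as.matrix(d)
    same <- outer(sp_meta$shore, sp_meta$shore, "==")
    ut <- upper.tri(dm)
    row <- tibble(species = sp_meta$species[1], n = length(idx),
                  mean_overall = mean(dm[ut]),
                  mean_within = mean(dm[ut & same]),
                  mean_between = if (any(ut & !same)) mean(dm[ut & !same])
                                 else NA_real_,
                  r2 = NA_real_, p_value = NA_real_)
    shores <- table(sp_meta$shore)
    if (length(shores) >= 2L && all(shores >= 2L)) {
      pa <- permanova(d, sp_meta$shore, n_perm, seed)
      row$r2 <- pa$r2; row$p_value <- pa$p
    }
    row
  }) |> dplyr::bind_rows()
}
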