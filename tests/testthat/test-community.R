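euclid_dist <- function(m) stats::dist(m)

test_that("relative abundance row-normalizes exactly", {
  counts <- dplyr::bind_rows(
    tibble::tibble(sample_id = "s1", otu_id = "a", count = 7L),
    tibble::tibble(sample_id = "s2", otu_id = c("a", "b"), count = c(5L, 5L)))
  rel <- relative_abundance(counts)
  expect_equal(rel$rel_abund[rel$sample_id == "s1"], 1.0)
  expect_equal(rel$rel_abund[rel$sample_id == "s2"], c(0.5, 0.5))
  set.seed(51)
  big <- tidyr::expand_grid(sample_id = paste0("s", 1:6),
                            otu_id = paste0("o", 1:9)) |>
    dplyr::mutate(count = rpois(dplyr::n(), 20) + 1L)
  sums <- relative_abundance(big) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(rel_abund))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("Bray-Curtis agrees with the hand formula and is bounded", {
  m <- rbind(s1 = c(2, 5, 0), s2 = c(2, 5, 0), s3 = c(0, 0, 7))
  d <- bray_curtis(m, sqrt_transform = FALSE)
  dm <- as.matrix(d)
  expect_equal(dm["s1", "s2"], 0)
  expect_equal(dm["s1", "s3"], 1)
  m2 <- rbind(a = c(1, 3), b = c(3, 1))
  expect_equal(as.numeric(bray_curtis(m2, sqrt_transform = FALSE)), 0.5)

  # hand-formula oracle on random tables, with and without the transform
  set.seed(52)
  for (k in 1:5) {
    m <- matrix(rpois(24, 15) + 1, 4, 6,
                dimnames = list(paste0("s", 1:4), NULL))
    for (tr in c(TRUE, FALSE)) {
      d <- as.matrix(bray_curtis(m, sqrt_transform = tr))
      mm <- if (tr) sqrt(m) else m
      for (i in 1:3) for (j in (i + 1):4) {
        bc <- 1 - 2 * sum(pmin(mm[i, ], mm[j, ])) /
          (sum(mm[i, ]) + sum(mm[j, ]))
        expect_equal(d[i, j], bc)
      }
    }
    expect_true(all(as.matrix(bray_curtis(m)) >= 0 &
                      as.matrix(bray_curtis(m)) <= 1))
  }
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 2))), "zero-total")
})

test_that("PERMANOVA separates duplicated groups perfectly and matches adonis2", {
  set.seed(53)
  a <- rnorm(3); b <- rnorm(3) + 10
  m <- rbind(matrix(rep(a, 10), 10, byrow = TRUE),
             matrix(rep(b, 10), 10, byrow = TRUE))
  rownames(m) <- paste0("s", 1:20)
  groups <- rep(c("g1", "g2"), each = 10)
  res <- permanova(euclid_dist(m), groups, n_perm = 199, seed = 54)
  expect_equal(res$r2, 1)
  expect_equal(res$p, 1 / 200)

  # independent cross-check of the SS partition against vegan::adonis2
  for (k in 1:3) {
    m <- matrix(rnorm(12 * 4), 12, 4)
    g <- rep(c("x", "y", "z"), each = 4)
    d <- euclid_dist(m)
    mine <- permanova(d, g, n_perm = 99, seed = 55)
    ad <- vegan::adonis2(d ~ g, permutations = 99)
    expect_equal(mine$r2, ad$R2[1], tolerance = 1e-10)
    expect_equal(mine$pseudo_f, ad$F[1], tolerance = 1e-10)
  }
})

test_that("the 4-sample SS partition equals exhaustive enumeration over labelings", {
  dm <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  vals <- c(1, 2, 3, 4, 5, 6)  # d(1,2), d(1,3), d(1,4), d(2,3), d(2,4), d(3,4)
  dm[lower.tri(dm)] <- vals
  dm <- dm + t(dm)
  d <- stats::as.dist(dm)
  labelings <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1))
  n <- 4
  for (g in labelings) {
    res <- permanova(d, g, n_perm = 9, seed = 56)
    # direct arithmetic on the definition
    ss_total <- sum(dm[upper.tri(dm)]^2) / n
    ss_within <- 0
    for (lv in unique(g)) {
      idx <- which(g == lv)
      pairs <- utils::combn(idx, 2)
      ss_within <- ss_within +
        sum(dm[cbind(pairs[1, ], pairs[2, ])]^2) / length(idx)
    }
    expect_equal(unname(res$ss["total"]), ss_total)
    expect_equal(unname(res$ss["within"]), ss_within)
    expect_equal(unname(res$ss["between"]), ss_total - ss_within)
    expect_equal(res$r2, (ss_total - ss_within) / ss_total)
  }
})

test_that("PERMANOVA is invariant to group renaming and sample order", {
  set.seed(57)
  m <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  g <- rep(c("a", "b"), each = 5)
  d <- euclid_dist(m)
  r1 <- permanova(d, g, n_perm = 99, seed = 58)
  r2 <- permanova(d, ifelse(g == "a", "ZZZ", "AAA"), n_perm = 99, seed = 58)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$r2, r2$r2)
  perm <- sample(10)
  r3 <- permanova(euclid_dist(m[perm, ]), g[perm], n_perm = 99, seed = 58)
  expect_equal(r1$r2, r3$r2)
  expect_equal(r1$pseudo_f, r3$pseudo_f)
})

test_that("PCoA reproduces Euclidean geometry and exposes negative axes", {
  # three equidistant points: two equal positive eigenvalues
  dm <- matrix(1, 3, 3) - diag(3)
  rownames(dm) <- colnames(dm) <- paste0("s", 1:3)
  ax <- pcoa(stats::as.dist(dm))
  pos <- ax$eigenvalues[ax$eigenvalues > 0]
  expect_equal(length(pos), 2L)
  expect_equal(pos[1], pos[2])

  set.seed(59)
  m <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(paste0("s", 1:8), NULL))
  d <- euclid_dist(m)
  ax <- pcoa(d)
  expect_equal(ncol(ax$imaginary), 0L)
  rec <- stats::dist(ax$points)
  expect_lt(max(abs(as.numeric(rec) - as.numeric(d))), 1e-8)

  # two points: a single axis
  d2 <- stats::as.dist(matrix(c(0, 3, 3, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  ax2 <- pcoa(d2)
  expect_equal(ncol(ax2$points), 1L)
  expect_equal(unname(abs(diff(ax2$points[, 1]))), 3)

  # Bray-Curtis typically yields negative eigenvalues; they are retained
  set.seed(60)
  cm <- matrix(rpois(60, 8), 10, 6, dimnames = list(paste0("s", 1:10), NULL))
  axb <- pcoa(bray_curtis(cm))
  expect_true(any(axb$eigenvalues < 0))
})

test_that("dispersion distances equal direct centroid distances on Euclidean data", {
  set.seed(61)
  m <- matrix(rnorm(18 * 4), 18, 4, dimnames = list(paste0("s", 1:18), NULL))
  g <- rep(c("a", "b", "c"), each = 6)
  res <- beta_dispersion(euclid_dist(m), g, n_perm = 99, seed = 62)
  direct <- numeric(18)
  for (lv in unique(g)) {
    idx <- which(g == lv)
    cen <- colMeans(m[idx, ])
    direct[idx] <- sqrt(rowSums(sweep(m[idx, ], 2, cen)^2))
  }
  expect_lt(max(abs(res$distances$dist_to_centroid - direct)), 1e-8)

  # and matches vegan::betadisper with centroid type
  bd <- vegan::betadisper(euclid_dist(m), g, type = "centroid")
  expect_lt(max(abs(res$distances$dist_to_centroid - bd$distances)), 1e-8)
})

test_that("dispersion handles semimetric distances like betadisper", {
  set.seed(63)
  cm <- matrix(rpois(12 * 8, 10), 12, 8,
               dimnames = list(paste0("s", 1:12), NULL))
  g <- rep(c("a", "b"), each = 6)
  d <- bray_curtis(cm)
  res <- beta_dispersion(d, g, n_perm = 99, seed = 64)
  bd <- vegan::betadisper(d, g, type = "centroid")
  expect_lt(max(abs(res$distances$dist_to_centroid - bd$distances)), 1e-8)
})

test_that("identical samples within groups give zero dispersion; squares give half-diagonals", {
  m <- rbind(matrix(rep(c(0, 0), 4), 4, byrow = TRUE),
             matrix(rep(c(9, 9), 4), 4, byrow = TRUE))
  rownames(m) <- paste0("s", 1:8)
  g <- rep(c("a", "b"), each = 4)
  res <- suppressWarnings(beta_dispersion(euclid_dist(m), g, n_perm = 49,
                                          seed = 65))
  expect_lt(max(res$group_stats$mean_dist), 1e-8)

  sq <- function(side, cx) cbind(cx + c(0, side, side, 0),
                                 c(0, 0, side, side))
  m2 <- rbind(sq(2, 0), sq(6, 100))
  rownames(m2) <- paste0("s", 1:8)
  res2 <- beta_dispersion(euclid_dist(m2), g, n_perm = 999, seed = 66)
  half_diag <- c(2, 6) * sqrt(2) / 2
  expect_equal(sort(res2$group_stats$mean_dist), sort(half_diag),
               tolerance = 1e-10)
  # clearly different spreads: significant overall test, distinct letters
  expect_lt(res2$overall$p, 0.05)
  expect_equal(length(unique(res2$group_stats$letters)), 2L)
})

test_that("the compact letter display reflects the pairwise significance graph", {
  pw <- matrix(NA_real_, 3, 3, dimnames = list(c("A", "B", "C"),
                                               c("A", "B", "C")))
  pw["A", "B"] <- pw["B", "A"] <- 0.60
  pw["B", "C"] <- pw["C", "B"] <- 0.30
  pw["A", "C"] <- pw["C", "A"] <- 0.01
  letters3 <- symits2:::.letter_display(pw, alpha = 0.05)
  expect_equal(letters3, c("a", "ab", "b"))
  # no significant differences: everyone shares one letter
  pw[] <- 0.9; diag(pw) <- NA
  expect_equal(unique(symits2:::.letter_display(pw, 0.05)), "a")
})

test_that("permutation results are reproducible under a fixed seed", {
  set.seed(67)
  m <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(paste0("s", 1:12), NULL))
  g <- rep(c("a", "b"), each = 6)
  d <- euclid_dist(m)
  expect_identical(permanova(d, g, 99, seed = 68)$p,
                   permanova(d, g, 99, seed = 68)$p)
  expect_identical(beta_dispersion(d, g, 99, seed = 68)$overall$p,
                   beta_dispersion(d, g, 99, seed = 68)$overall$p)
})
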