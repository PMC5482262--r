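test_that("dereplication counts multiplicities and orders deterministically", {
  out <- dereplicate(c("AAA", "AAA", "AAT"))
  expect_equal(out$sequence, c("AAA", "AAT"))
  expect_equal(out$count, c(2L, 1L))
  expect_equal(nrow(dereplicate(character())), 0L)

  set.seed(21)
  templates <- replicate(10, random_dna(40))
  draws <- sample(templates, 1000, replace = TRUE)
  out <- dereplicate(draws)
  tally <- table(draws)
  expect_equal(setNames(out$count, out$sequence)[names(tally)],
               setNames(as.integer(tally), names(tally)))
  expect_equal(sum(out$count), 1000L)
})

test_that("pairwise identity matches hand values and is symmetric and bounded", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  set.seed(22)
  for (k in 1:20) {
    a <- random_dna(60)
    b <- mutate_seq(a, n_sub = sample(0:10, 1), n_indel = sample(0:2, 1))
    ia <- pairwise_identity(a, b)
    expect_identical(ia, pairwise_identity(b, a))
    expect_gte(ia, 0); expect_lte(ia, 1)
  }
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("alignment score and identity equal the quadratic DP oracle", {
  set.seed(23)
  # affine configuration, arbitrary pairs: the optimal score is unique
  for (k in 1:30) {
    a <- random_dna(sample(30:60, 1))
    b <- if (k %% 2) mutate_seq(a, n_sub = sample(0:6, 1),
                                n_indel = sample(0:2, 1))
         else random_dna(sample(30:60, 1))
    expect_equal(global_align(a, b)$score, oracle_align(a, b)$score)
  }
  # linear-gap configuration (no opening cost)
  lin <- align_params(gap_open = 0, gap_extend = -2)
  for (k in 1:30) {
    a <- random_dna(sample(30:60, 1))
    b <- random_dna(sample(30:60, 1))
    expect_equal(global_align(a, b, lin)$score,
                 oracle_align(a, b, go = 0, ge = 2)$score)
  }
  # identity, on substitution-only pairs where the optimum is unique
  for (k in 1:20) {
    a <- random_dna(sample(250, 1) + 100)
    b <- mutate_seq(a, n_sub = sample(0:12, 1))
    expect_equal(pairwise_identity(a, b), oracle_align(a, b)$identity)
  }
  expect_equal(global_align("ACGT", "ACGT")$score, 4 * 5)
  # single internal deletion: ACGT vs ACT -> identity 3/4
  expect_equal(global_align("ACGT", "ACT")$identity, 0.75)
})

test_that("greedy clustering separates below-threshold variants and absorbs above-threshold ones", {
  set.seed(24)
  x <- random_dna(300)
  far <- mutate_seq(x, n_sub = 30)    # ~90% identity
  out <- greedy_cluster(tibble::tibble(sequence = c(x, far),
                                       count = c(5L, 4L)))
  expect_equal(nrow(out), 2L)

  near <- mutate_seq(x, n_sub = 6)    # 98% identity
  out <- greedy_cluster(tibble::tibble(sequence = c(x, near),
                                       count = c(10L, 3L)))
  expect_equal(nrow(out), 1L)
  expect_equal(out$representative, x)
  expect_equal(out$total_count, 13L)
})

test_that("greedy partitions equal a definition-replay oracle on random variant sets", {
  set.seed(25)
  for (k in 1:8) {
    n_templates <- sample(2:4, 1)
    templates <- replicate(n_templates, random_dna(150))
    n_var <- sample(6:12, 1)
    variants <- tibble::tibble(
      sequence = vapply(seq_len(n_var), function(i) {
        mutate_seq(sample(templates, 1), n_sub = sample(0:8, 1))
      }, character(1)),
      count = sample(1:50, n_var, replace = TRUE))
    variants <- dplyr::distinct(variants, sequence, .keep_all = TRUE)
    got <- greedy_cluster(variants)
    got_parts <- lapply(got$members, function(m) m$sequence)
    want_parts <- oracle_greedy_partition(variants, 0.97)
    expect_equal(canon_partition(got_parts), canon_partition(want_parts))
  }
})

# Two samples dominated by closely related variants: the regime where the
# clustering strategies disagree.
two_sample_xy <- function(seed = 26, identity = 0.98) {
  set.seed(seed)
  x <- random_dna(300)
  y <- mutate_seq(x, n_sub = round((1 - identity) * 300))
  xe <- mutate_seq(x, n_sub = 2)   # minor variant of x
  ye <- mutate_seq(y, n_sub = 2)
  dplyr::bind_rows(
    tibble::tibble(sample_id = "s1", sequence = c(x, xe), count = c(50L, 5L)),
    tibble::tibble(sample_id = "s2", sequence = c(y, ye), count = c(30L, 4L)))
  }

test_that("within-sample clustering keeps distinct dominants; across-sample collapses them", {
  tabs <- two_sample_xy()
  w <- cluster_within_samples(tabs)
  a <- cluster_across_samples(tabs)
  expect_equal(n_otus(w), 2L)
  expect_equal(n_otus(a), 1L)
  # the across-sample OTU is named by the pooled-most-abundant variant (X)
  x <- dplyr::arrange(tabs[tabs$sample_id == "s1", ],
                      dplyr::desc(count))$sequence[1]
  expect_equal(a$representatives$sequence, x)
  # within-sample: each OTU dominant in its own sample
  w_rel <- relative_abundance(w)
  doms <- w_rel[w_rel$rel_abund > 0.5, ]
  expect_equal(sort(doms$sample_id), c("s1", "s2"))
  expect_equal(length(unique(doms$otu_id)), 2L)
})

test_that("strategies coincide on disjoint samples with mutually distant variants", {
  set.seed(27)
  tabs <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(sample_id = paste0("s", i), sequence = random_dna(300),
                   count = 20L + i)
  }))
  w <- cluster_within_samples(tabs)
  a <- cluster_across_samples(tabs)
  expect_equal(n_otus(w), 3L)
  expect_equal(sort(w$representatives$sequence),
               sort(a$representatives$sequence))
})

test_that("count filters drop weak OTUs first, then shallow samples, matching a direct oracle", {
  tabs <- dplyr::bind_rows(
    tibble::tibble(sample_id = "s1",
                   sequence = c(strrep("A", 30), strrep("C", 30)),
                   count = c(195L, 9L)),
    tibble::tibble(sample_id = "s2", sequence = strrep("A", 30),
                   count = 300L))
  x <- cluster_denovo100(tabs, cluster_params(drop_singletons = FALSE))
  f <- filter_otu_table(x)
  # the 9-count OTU goes; s1 then has 195 < 200 reads and goes too
  expect_equal(length(attr(f, "dropped_otus")), 1L)
  expect_equal(attr(f, "dropped_samples"), "s1")
  expect_equal(unique(f$counts$sample_id), "s2")

  set.seed(28)
  for (k in 1:10) {
    n_otu <- sample(4:8, 1); n_smp <- sample(3:5, 1)
    counts <- tidyr::expand_grid(sample_id = paste0("s", seq_len(n_smp)),
                                 otu_id = paste0("OTU", seq_len(n_otu))) |>
      dplyr::mutate(count = rpois(dplyr::n(), 40))
    reps <- tibble::tibble(otu_id = paste0("OTU", seq_len(n_otu)),
                           sequence = replicate(n_otu, random_dna(30)))
    x <- symits2:::new_otu_table(counts, reps, "denovo100")
    p <- cluster_params(min_otu_count = 120, min_sample_count = 250)
    f <- suppressWarnings(filter_otu_table(x, p))
    # direct set-comprehension oracle
    otu_tot <- tapply(counts$count, counts$otu_id, sum)
    keep_otus <- names(otu_tot)[otu_tot >= 120]
    kept <- counts[counts$otu_id %in% keep_otus, ]
    smp_tot <- tapply(kept$count, kept$sample_id, sum)
    keep_smp <- names(smp_tot)[smp_tot >= 250]
    expect_equal(sort(unique(f$counts$otu_id)),
                 sort(intersect(keep_otus, unique(
                   f$counts$otu_id[f$counts$sample_id %in% keep_smp]))))
    expect_equal(sort(unique(f$counts$sample_id)), sort(keep_smp))
  }
})

test_that("read counts are conserved per sample under all three strategies", {
  set.seed(29)
  pool <- make_species_pool(3, seed = 30)
  tabs <- dplyr::bind_rows(lapply(1:3, function(i) {
    sim <- simulate_sample(pool, setNames(c(0.9, 0.1), c(
      sprintf("sp%02d", i), sprintf("sp%02d", i %% 3 + 1))),
      sample_id = paste0("s", i), read_depth = 150, error_rate = 1e-3,
      seed = 30 + i)
    dereplicate(sim$reads, sample_id = paste0("s", i))
  }))
  totals <- tapply(tabs$count, tabs$sample_id, sum)
  p <- cluster_params(drop_singletons = FALSE)
  for (x in list(cluster_within_samples(tabs, p),
                 cluster_across_samples(tabs, p),
                 cluster_denovo100(tabs, p))) {
    got <- tapply(x$counts$count, x$counts$sample_id, sum)
    expect_equal(got[names(totals)], totals)
  }
})

test_that("clustering is deterministic and within-sample OTUs are idempotent at 100%", {
  tabs <- two_sample_xy(seed = 31)
  w1 <- cluster_within_samples(tabs)
  w2 <- cluster_within_samples(tabs)
  expect_identical(w1$counts, w2$counts)
  expect_identical(w1$representatives, w2$representatives)
  # re-clustering the representatives at 100% returns the same OTU set
  rep_tab <- tibble::tibble(sample_id = "all",
                            sequence = w1$representatives$sequence,
                            count = 5L)
  re <- cluster_denovo100(rep_tab, cluster_params(drop_singletons = FALSE))
  expect_equal(sort(re$representatives$sequence),
               sort(w1$representatives$sequence))
})
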