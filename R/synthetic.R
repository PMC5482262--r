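# Synthetic ITS2 metacommunities with known ground truth. Genomes carry one
# numerically dominant ribosomal variant plus minor intragenomic variants
# inside a 97%-similarity radius; species' dominant variants may themselves
# be >97% similar — the regime in which clustering strategy matters.

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute `positions` of `seq` with bases different from the originals
.substitute_at <- function(seq, positions) {
  s <- .chars(seq)
  for (p in positions) {
    s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  }
  paste(s, collapse = "")
}

#' Generate a pool of synthetic Symbiodinium-like genomes
#'
#' Each species carries `n_variants` intragenomic ITS2 variants: one
#' numerically dominant variant and minor variants within an identity
#' radius of it. Dominant variants of species 2..n are derived from species
#' 1's dominant by substitutions at disjoint position sets, realising the
#' identities in `divergence_plan` to within one substitution.
#'
#' @param n_species Number of species in the pool.
#' @param divergence_plan Numeric vector of length `n_species - 1`: target
#'   identity of each later species' dominant variant to species 1's.
#'   Defaults to values evenly spaced from 0.98 down to 0.90.
#' @param n_variants Intragenomic variants per species (default 3).
#' @param variant_freqs Intragenomic frequencies, dominant first (default
#'   0.70, 0.20, 0.10).
#' @param length Amplicon length in nt (default 300).
#' @param radius Minimum identity of minor variants to their dominant
#'   (default 0.97).
#' @param clades Clade letters recycled across species (default
#'   B, C, A, D, G).
#' @param seed Integer seed.
#' @return A tibble with one row per variant: `species_id`, `clade`,
#'   `variant_id`, `sequence`, `freq`, `dominant`.
#' @export
make_species_pool <- function(n_species,
                              divergence_plan = NULL,
                              n_variants = 3L,
                              variant_freqs = c(0.70, 0.20, 0.10),
                              length = 300L,
                              radius = 0.97,
                              clades = c("B", "C", "A", "D", "G"),
                              seed = 1L) {
  stopifnot(n_species >= 1, length(variant_freqs) == n_variants,
            abs(sum(variant_freqs) - 1) < 1e-9,
            which.max(variant_freqs) == 1L)
  if (is.null(divergence_plan)) {
    divergence_plan <- if (n_species > 1)
      seq(0.98, 0.90, length.out = n_species - 1) else numeric()
  }
  stopifnot(length(divergence_plan) == n_species - 1)
  n_subs <- round((1 - divergence_plan) * length)
  if (sum(n_subs) > length) abort("divergence plan not achievable at this length")
  set.seed(seed)
  base <- .random_seq(length)
  # disjoint substitution sets keep every pairwise divergence determined
  pos_pool <- sample(seq_len(length))
  offset <- 0L
  dominants <- character(n_species)
  dominants[1] <- base
  for (i in seq_len(n_species - 1)) {
    k <- n_subs[i]
    pos <- if (k > 0) pos_pool[(offset + 1L):(offset + k)] else integer()
    offset <- offset + k
    dominants[i + 1L] <- .substitute_at(base, pos)
  }
  max_minor_subs <- floor((1 - radius) * length)
  purrr::map(seq_len(n_species), function(i) {
    minor_subs <- pmin(2L * seq_len(n_variants - 1L), max_minor_subs)
    seqs <- c(dominants[i],
              vapply(minor_subs, function(k) {
                .substitute_at(dominants[i], sample(length, k))
              }, character(1)))
    tibble(species_id = sprintf("sp%02d", i),
           clade = clades[(i - 1L) %% base::length(clades) + 1L],
           variant_id = seq_len(n_variants),
           sequence = seqs,
           freq = variant_freqs,
           dominant = seq_len(n_variants) == 1L)
  }) |> dplyr::bind_rows()
}

#' Simulate reads for one sample from a species pool
#'
#' Reads are drawn multinomially over (species, variant) cells with
#' probability `composition[species] * freq[variant]`, then substitution
#' errors are applied independently per base at `error_rate`.
#'
#' @param pool A species pool from [make_species_pool()].
#' @param composition Named numeric vector of species relative abundances
#'   (must sum to 1; names are `species_id`s present in the pool).
#' @param sample_id Sample id recorded on every read.
#' @param read_depth Number of reads to draw.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list with `reads` (tibble `sample_id`, `read_id`, `sequence`,
#'   `species_id`, `variant_id`, `n_errors`) and `truth` (the composition
#'   and the species-to-dominant-variant map).
#' @export
simulate_sample <- function(pool, composition, sample_id = "s1",
                            read_depth = 2000L, error_rate = 1e-3,
                            seed = 1L) {
  stopifnot(abs(sum(composition) - 1) < 1e-9,
            all(names(composition) %in% pool$species_id))
  cells <- pool |>
    dplyr::filter(.data$species_id %in% names(composition)) |>
    dplyr::mutate(p = composition[.data$species_id] * .data$freq)
  set.seed(seed)
  n_cell <- as.integer(rmultinom(1, read_depth, cells$p))
  idx <- rep(seq_len(nrow(cells)), n_cell)
  seqs <- cells$sequence[idx]
  len <- nchar(seqs[1])
  n_err <- rbinom(length(seqs), len, error_rate)
  mutate_i <- which(n_err > 0)
  for (i in mutate_i) {
    seqs[i] <- .substitute_at(seqs[i], sample(len, n_err[i]))
  }
  reads <- tibble(sample_id = sample_id,
                  read_id = sprintf("%s_r%05d", sample_id, seq_along(seqs)),
                  sequence = seqs,
                  species_id = cells$species_id[idx],
                  variant_id = cells$variant_id[idx],
                  n_errors = n_err)
  truth <- list(
    composition = composition,
    dominant_variant = setNames(
      pool$sequence[pool$dominant], pool$species_id[pool$dominant]))
  list(reads = reads, truth = truth)
}

#' A clustering-strategy discrimination scenario
#'
#' Builds a small metacommunity in the regime where clustering strategy
#' decides the outcome: two (or more) host species, each sample dominated
#' by its host's own symbiont species, with the symbionts' dominant ITS2
#' variants at least 97.5% identical to one another, plus intragenomic
#' variants and one distantly related background symbiont shared by all
#' samples at <1% relative abundance. Within-sample clustering should
#' recover one dominant OTU per symbiont species; across-sample clustering
#' collapses them into one.
#'
#' @param seed Integer seed.
#' @param n_hosts Number of host species (default 2).
#' @param samples_per_host Samples per host species (default 3).
#' @param read_depth Reads per sample (default 2000).
#' @param error_rate Per-base substitution probability (default 1e-3).
#' @param target_identity Identity between the dominant variants of
#'   successive symbiont species (default 0.98).
#' @return A list with `reads` (all samples), `variant_tables`
#'   (dereplicated, ready for the clustering functions), `manifest`
#'   (sample metadata), `pool`, and `truth`.
#' @export
scenario_fig2 <- function(seed = 1L, n_hosts = 2L, samples_per_host = 3L,
                          read_depth = 2000L, error_rate = 1e-3,
                          target_identity = 0.98) {
  stopifnot(target_identity >= 0.975)
  # symbiont species sp01..sp<n_hosts> nearly identical; background last,
  # far outside the clustering radius (clade D)
  plan <- c(seq(target_identity, 0.975, length.out = max(1L, n_hosts - 1L))[
              seq_len(n_hosts - 1L)], 0.90)
  pool <- make_species_pool(n_hosts + 1L, divergence_plan = plan,
                            clades = c(rep("B", n_hosts), "D"),
                            seed = seed)
  bg <- sprintf("sp%02d", n_hosts + 1L)
  sym <- sprintf("sp%02d", seq_len(n_hosts))
  samples <- tidyr::expand_grid(host = seq_len(n_hosts),
                                rep = seq_len(samples_per_host)) |>
    dplyr::mutate(sample_id = sprintf("h%02d_s%02d", .data$host, .data$rep),
                  species = sprintf("host%02d", .data$host))
  sims <- purrr::pmap(samples, function(host, rep, sample_id, species) {
    comp <- setNames(c(0.992, 0.008), c(sym[host], bg))
    simulate_sample(pool, comp, sample_id, read_depth, error_rate,
                    seed = seed + 7L * host + 131L * rep)
  })
  reads <- dplyr::bind_rows(purrr::map(sims, "reads"))
  variant_tables <- reads |>
    dplyr::group_by(.data$sample_id, .data$sequence) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$count), .data$sequence)
  manifest <- samples |>
    dplyr::transmute(sample_id = .data$sample_id, species = .data$species,
                     site = "reef1",
                     shore = ifelse(.data$rep %% 2L == 0L, "north", "south"))
  list(reads = reads, variant_tables = variant_tables, manifest = manifest,
       pool = pool,
       truth = list(
         symbiont_species = sym, background_species = bg,
         dominant_variant = setNames(pool$sequence[pool$dominant],
                                     pool$species_id[pool$dominant]),
         host_of_sample = setNames(samples$species, samples$sample_id)))
}

#' Synthetic primer pair used when wrapping amplicons into read pairs
#'
#' Arbitrary fixed 20-mers attached by [as_read_pairs()]; they stand in for
#' the marker-specific primers a real run would configure.
#' @name syn_primers
NULL

#' @rdname syn_primers
#' @export
SYN_PRIMER_FWD <- "GTGACCTATGAACTCAGGAG"

#' @rdname syn_primers
#' @export
SYN_PRIMER_REV <- "CCTCCGCTTACTTATATGCT"

#' Wrap simulated amplicons into overlapping paired reads
#'
#' Attaches the primer pair to each amplicon and splits the construct into
#' forward and reverse mates of `read_length` nt (reverse mate
#' reverse-complemented), giving pairs whose overlap exercises the full
#' preprocessing path. Qualities are constant.
#'
#' @param reads A reads tibble from [simulate_sample()] or
#'   [scenario_fig2()].
#' @param primer_fwd,primer_rev Primer sequences to attach.
#' @param read_length Mate length in nt (default 250, giving a 160 bp
#'   overlap on the default 340 nt primer-wrapped construct).
#' @param quality Constant Phred score for every base (default 40).
#' @return A tibble compatible with [preprocess_pairs()].
#' @export
as_read_pairs <- function(reads, primer_fwd = SYN_PRIMER_FWD,
                          primer_rev = SYN_PRIMER_REV,
                          read_length = 250L, quality = 40L) {
  construct <- paste0(primer_fwd, reads$sequence, .revcomp(primer_rev))
  len <- nchar(construct)
  stopifnot(all(read_length <= len))
  fwd <- substr(construct, 1L, read_length)
  rev_plain <- substr(construct, len - read_length + 1L, len)
  tibble(read_id = reads$read_id,
         fwd = fwd,
         fwd_qual = purrr::map(nchar(fwd), ~rep(as.integer(quality), .x)),
         rev = vapply(rev_plain, .revcomp, character(1), USE.NAMES = FALSE),
         rev_qual = purrr::map(nchar(rev_plain),
                               ~rep(as.integer(quality), .x)))
}

#' Write simulated reads as FASTQ pairs plus a manifest
#'
#' @param scenario A list from [scenario_fig2()].
#' @param dir Output directory (created if needed).
#' @param ... Passed to [as_read_pairs()].
#' @return The manifest tibble (with `fastq_fwd`, `fastq_rev` columns),
#'   invisibly; files are written under `dir`.
#' @export
write_scenario_fastq <- function(scenario, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- scenario$manifest
  manifest$fastq_fwd <- file.path(dir, paste0(manifest$sample_id, "_R1.fastq"))
  manifest$fastq_rev <- file.path(dir, paste0(manifest$sample_id, "_R2.fastq"))
  for (i in seq_len(nrow(manifest))) {
    rd <- scenario$reads[scenario$reads$sample_id == manifest$sample_id[i], ]
    pairs <- as_read_pairs(rd, ...)
    .write_fastq(pairs$read_id, pairs$fwd, pairs$fwd_qual,
                 manifest$fastq_fwd[i])
    .write_fastq(pairs$read_id, pairs$rev, pairs$rev_qual,
                 manifest$fastq_rev[i])
  }
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

.write_fastq <- function(ids, seqs, quals, path) {
  q <- vapply(quals, function(v) paste(rawToChar(as.raw(v + 33L), TRUE),
                                       collapse = ""), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", q), path)
}
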