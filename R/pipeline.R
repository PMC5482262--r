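#' Read a sample manifest
#'
#' @param path TSV with columns `sample_id`, `species`, `site`, `shore`,
#'   and either `fasta` (preprocessed amplicons) or `fastq_fwd` +
#'   `fastq_rev` (raw paired reads).
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "species", "site", "shore")
  if (!all(need %in% names(m))) {
    abort(paste("manifest must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(m) == 0L) abort("manifest is empty")
  if (!("fasta" %in% names(m)) &&
      !all(c("fastq_fwd", "fastq_rev") %in% names(m))) {
    abort("manifest needs a `fasta` column or `fastq_fwd` + `fastq_rev`")
  }
  m
}

#' Assemble a pipeline configuration
#'
#' @param manifest Path to the sample manifest TSV.
#' @param reference_db Optional path to the reference FASTA for taxonomy.
#' @param out_dir Output directory.
#' @param modes Clustering strategies to run (subset of `"within"`,
#'   `"across"`, `"denovo100"`); statistics and networks use the first.
#' @param preprocess,cluster,align,niche Parameter objects (defaults used
#'   when `NULL`).
#' @param chimera_ids Optional character vector of read ids to exclude
#'   (hook for externally produced chimera calls).
#' @param n_perm,seed Permutation settings for the statistics stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest, reference_db = NULL, out_dir = tempfile(),
                       modes = c("within", "across", "denovo100"),
                       preprocess = NULL, cluster = NULL, align = NULL,
                       niche = NULL, chimera_ids = character(),
                       n_perm = 999L, seed = 1L) {
  stopifnot(all(modes %in% c("within", "across", "denovo100")))
  structure(list(manifest = manifest, reference_db = reference_db,
                 out_dir = out_dir, modes = modes,
                 preprocess = preprocess %||% preprocess_params(),
                 cluster = cluster %||% cluster_params(),
                 align = align %||% align_params(),
                 niche = niche %||% niche_thresholds(),
                 chimera_ids = chimera_ids,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the parameter
#' blocks (`preprocess`, `cluster`, `align`, `niche`) are named lists whose
#' entries override the corresponding defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, block) {
    if (is.null(block)) return(NULL)
    do.call(ctor, block)
  }
  run_config(manifest = y$manifest, reference_db = y$reference_db,
             out_dir = y$out_dir %||% tempfile(),
             modes = y$modes %||% c("within", "across", "denovo100"),
             preprocess = build(preprocess_params, y$preprocess),
             cluster = build(cluster_params, y$cluster),
             align = build(align_params, y$align),
             niche = build(niche_thresholds, y$niche),
             chimera_ids = y$chimera_ids %||% character(),
             n_perm = y$n_perm %||% 999L, seed = y$seed %||% 1L)
}

#' Run the full pipeline
#'
#' Executes preprocess (when the manifest points at FASTQ pairs), the
#' configured clustering strategies, count filtering, taxonomy (when a
#' reference database is configured), community statistics (per-species
#' shore PERMANOVA and the multivariate-dispersion flexibility metric),
#' and the three niche networks, writing TSV/FASTA/GraphML outputs under
#' `config$out_dir`. Every output directory carries a `run_info.tsv` stamp
#' with the configuration hash and seed.
#'
#' @param config A `run_config` from [run_config()] or [read_run_config()].
#' @return A run report: list with `tables` (the filtered `symotu_table`
#'   per mode), `summary` (per-mode OTU/read summary), `taxonomy`,
#'   `clades`, `permanova`, `dispersion`, `networks`,
#'   `background_summary`, and `preprocess_log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- read_manifest(config$manifest)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- preprocess / load ----
  logs <- list()
  seqs <- purrr::pmap(manifest, function(...) {
    row <- list(...)
    if (!is.null(row$fasta) && !is.na(row$fasta %||% NA)) {
      tab <- read_fasta(row$fasta)
    } else {
      pp <- preprocess_sample(row$fastq_fwd, row$fastq_rev, config$preprocess)
      logs[[row$sample_id]] <<- dplyr::mutate(pp$log,
                                              sample_id = row$sample_id,
                                              .before = 1)
      tab <- pp$sequences
    }
    if (length(config$chimera_ids)) {
      tab <- dplyr::filter(tab, !(.data$read_id %in% config$chimera_ids))
    }
    dereplicate(tab, sample_id = row$sample_id)
  })
  tables <- dplyr::bind_rows(seqs)
  metadata <- manifest[c("sample_id", "species", "site", "shore")]
  preprocess_log <- if (length(logs)) dplyr::bind_rows(logs) else NULL
  if (!is.null(preprocess_log)) {
    readr::write_tsv(preprocess_log, file.path(config$out_dir,
                                               "preprocess_log.tsv"))
  }

  # ---- cluster + filter ----
  cluster_fun <- list(
    within = function() cluster_within_samples(tables, config$cluster,
                                               config$align, metadata),
    across = function() cluster_across_samples(tables, config$cluster,
                                               config$align, metadata),
    denovo100 = function() cluster_denovo100(tables, config$cluster,
                                             metadata))
  otu_tables <- purrr::map(setNames(config$modes, config$modes),
                           function(mode) {
    filtered <- filter_otu_table(cluster_fun[[mode]](), config$cluster)
    write_otu_table(filtered,
                    file.path(config$out_dir,
                              paste0("otu_table_", mode, ".tsv")))
    if (n_otus(filtered) > 0) {
      write_fasta(filtered$representatives,
                  file.path(config$out_dir, paste0("otus_", mode, ".fasta")))
    }
    filtered
  })
  summary_tbl <- dplyr::bind_rows(purrr::map(otu_tables, glance))

  # ---- downstream on the primary mode ----
  primary <- otu_tables[[config$modes[1]]]
  taxonomy <- clades <- perm <- disp <- networks <- bg <- NULL
  if (n_otus(primary) > 0) {
    if (!is.null(config$reference_db)) {
      db <- read_reference_db(config$reference_db)
      taxonomy <- assign_taxonomy(primary, db, config$align)
      clades <- summarize_clades(primary, taxonomy)
      readr::write_tsv(taxonomy, file.path(config$out_dir, "taxonomy.tsv"))
    }
    perm <- shore_permanova(primary, n_perm = config$n_perm,
                            seed = config$seed)
    readr::write_tsv(perm, file.path(config$out_dir, "shore_permanova.tsv"))
    meta_in <- primary$metadata
    if (min(table(meta_in$species)) >= 2L &&
        length(unique(meta_in$species)) >= 2L) {
      d <- bray_curtis(primary)
      grp <- meta_in$species[match(attr(d, "Labels"), meta_in$sample_id)]
      disp <- beta_dispersion(d, grp, config$n_perm, config$seed)
      readr::write_tsv(disp$group_stats,
                       file.path(config$out_dir, "dispersion.tsv"))
    }
    rel <- relative_abundance(primary)
    networks <- purrr::map(
      setNames(c("abundant", "dominant", "background"),
               c("abundant", "dominant", "background")),
      function(niche) {
        net <- build_niche_network(rel, metadata, niche, taxonomy,
                                   config$niche)
        if (nrow(net$edges) > 0) {
          write_network_graphml(net, file.path(config$out_dir,
                                               paste0("network_", niche,
                                                      ".graphml")))
        }
        net
      })
    bg <- background_niche_summary(rel, metadata, config$niche)
  }

  stamp <- tibble(key = c("config_hash", "seed", "timestamp"),
                  value = c(.config_hash(config), as.character(config$seed),
                            format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  readr::write_tsv(stamp, file.path(config$out_dir, "run_info.tsv"))

  list(tables = otu_tables, summary = summary_tbl, taxonomy = taxonomy,
       clades = clades, permanova = perm, dispersion = disp,
       networks = networks, background_summary = bg,
       preprocess_log = preprocess_log, config = config)
}

# order-stable hash of the configuration (no external digest dependency)
.config_hash <- function(config) {
  x <- config
  x$out_dir <- NULL
  payload <- paste(deparse(x[order(names(x))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(payload) *
                        (seq_along(utf8ToInt(payload)) %% 251 + 1)) %%
            .Machine$integer.max)
}
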