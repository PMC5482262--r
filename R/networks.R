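#' Build a bipartite host-symbiont network for one niche
#'
#' For the `abundant` (>1%) and `dominant` (>50%) niches, an edge connects a
#' host species to an OTU when the OTU exceeds the niche threshold in at
#' least one individual of that species; the edge weight is the proportion
#' of the species' individuals in which it does. For the `background` niche,
#' an unweighted edge exists when the OTU is present below `background_max`
#' (and above zero) in at least one individual; clade-D OTUs are then merged
#' into a single node, and symbiont nodes connected to `prune_degree` or
#' fewer host species are removed.
#'
#' @param relabund A relative-abundance tibble from [relative_abundance()]
#'   (columns `sample_id`, `otu_id`, `rel_abund`).
#' @param metadata Sample metadata with columns `sample_id`, `species`.
#' @param niche One of `"abundant"`, `"dominant"`, `"background"`.
#' @param tax Optional taxonomy tibble ([assign_taxonomy()]); required for
#'   the clade-D merge in the background niche, and used to attach clade
#'   attributes to symbiont nodes.
#' @param th A [niche_thresholds()] object.
#' @return A `symbiont_network`: list with `nodes` (id, type, clade,
#'   n_species), `edges` (host, symbiont, weight), `niche`.
#' @export
build_niche_network <- function(relabund, metadata, niche = "abundant",
                                tax = NULL, th = niche_thresholds()) {
  if (!niche %in% c("abundant", "dominant", "background")) {
    abort("unknown niche label")
  }
  if (any(relabund$rel_abund < 0 | relabund$rel_abund > 1)) {
    abort("relative abundances must lie in [0, 1]")
  }
  x <- dplyr::left_join(relabund, metadata[c("sample_id", "species")],
                        by = "sample_id")
  n_ind <- metadata |>
    dplyr::filter(.data$sample_id %in% unique(relabund$sample_id)) |>
    dplyr::count(.data$species, name = "n_individuals")

  if (niche %in% c("abundant", "dominant")) {
    thr <- if (niche == "dominant") th$dominant_min else th$abundant_min
    edges <- x |>
      dplyr::filter(.data$rel_abund > thr) |>
      dplyr::group_by(.data$species, .data$otu_id) |>
      dplyr::summarise(n_exceed = dplyr::n_distinct(.data$sample_id),
                       .groups = "drop") |>
      dplyr::left_join(n_ind, by = "species") |>
      dplyr::transmute(host = .data$species, symbiont = .data$otu_id,
                       weight = .data$n_exceed / .data$n_individuals)
  } else {
    edges <- x |>
      dplyr::filter(.data$rel_abund > 0,
                    .data$rel_abund < th$background_max) |>
      dplyr::distinct(host = .data$species, symbiont = .data$otu_id) |>
      dplyr::mutate(weight = NA_real_)
    if (!is.null(tax)) {
      clade_d <- tax$otu_id[tax$clade == "D"]
      edges <- edges |>
        dplyr::mutate(symbiont = dplyr::if_else(.data$symbiont %in% clade_d,
                                                "cladeD", .data$symbiont)) |>
        dplyr::distinct(.data$host, .data$symbiont, .keep_all = TRUE)
    }
    degree <- edges |> dplyr::count(.data$symbiont, name = "deg")
    keep <- degree$symbiont[degree$deg > th$prune_degree]
    edges <- dplyr::filter(edges, .data$symbiont %in% keep)
  }

  clade_of <- function(ids) {
    if (is.null(tax)) return(rep(NA_character_, length(ids)))
    out <- tax$clade[match(ids, tax$otu_id)]
    out[ids == "cladeD"] <- "D"
    out
  }
  sym <- edges |> dplyr::count(.data$symbiont, name = "n_species")
  nodes <- dplyr::bind_rows(
    tibble(id = unique(metadata$species), type = "host",
           clade = NA_character_, n_species = NA_integer_),
    tibble(id = sym$symbiont, type = "symbiont",
           clade = clade_of(sym$symbiont), n_species = sym$n_species))
  structure(list(nodes = nodes, edges = edges, niche = niche,
                 thresholds = th),
            class = "symbiont_network")
}

#' @export
print.symbiont_network <- function(x, ...) {
  cat(sprintf("<symbiont_network> niche = %s: %d hosts, %d symbionts, %d edges\n",
              x$niche, sum(x$nodes$type == "host"),
              sum(x$nodes$type == "symbiont"), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.symbiont_network <- function(x, ...) x$edges

#' @export
glance.symbiont_network <- function(x, ...) {
  tibble(niche = x$niche, n_hosts = sum(x$nodes$type == "host"),
         n_symbionts = sum(x$nodes$type == "symbiont"),
         n_edges = nrow(x$edges))
}

#' Convert a symbiont network to an igraph object
#'
#' @param net A `symbiont_network`.
#' @return An igraph graph with vertex attributes `type`, `clade`,
#'   `n_species` and (where defined) edge weights.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "symbiont_network"))
  used <- net$nodes[net$nodes$id %in% c(net$edges$host, net$edges$symbiont), ]
  g <- igraph::graph_from_data_frame(
    net$edges[c("host", "symbiont", "weight")],
    directed = FALSE, vertices = used)
  igraph::V(g)$bipartite <- igraph::V(g)$type == "symbiont"
  g
}

#' Fruchterman-Reingold layout for a symbiont network
#'
#' @param net A `symbiont_network`.
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @return A tibble with columns `id`, `x`, `y`.
#' @export
layout_fr <- function(net, seed = 1L) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0L) return(tibble(id = character(), x = numeric(),
                                             y = numeric()))
  w <- igraph::E(g)$weight
  set.seed(seed)
  xy <- igraph::layout_with_fr(
    g, weights = if (length(w) && !anyNA(w)) w else NULL)
  tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}

#' Write a symbiont network to GraphML
#'
#' @param net A `symbiont_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  if (anyNA(igraph::E(g)$weight)) g <- igraph::delete_edge_attr(g, "weight")
  if (anyNA(igraph::V(g)$clade)) {
    igraph::V(g)$clade <- ifelse(is.na(igraph::V(g)$clade), "",
                                 igraph::V(g)$clade)
  }
  if (anyNA(igraph::V(g)$n_species)) {
    igraph::V(g)$n_species <- ifelse(is.na(igraph::V(g)$n_species), 0L,
                                     igraph::V(g)$n_species)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' OTUs occupying the background niche
#'
#' Background symbionts are OTUs present above zero but below
#' `background_max` relative abundance in at least `background_min_species`
#' host species.
#'
#' @inheritParams build_niche_network
#' @return A tibble with columns `otu_id`, `n_species_background`,
#'   `species` (list column of host species names).
#' @export
background_niche_summary <- function(relabund, metadata,
                                     th = niche_thresholds()) {
  x <- dplyr::left_join(relabund, metadata[c("sample_id", "species")],
                        by = "sample_id")
  x |>
    dplyr::filter(.data$rel_abund > 0,
                  .data$rel_abund < th$background_max) |>
    dplyr::distinct(.data$otu_id, .data$species) |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(n_species_background = dplyr::n(),
                     species = list(sort(.data$species)), .groups = "drop") |>
    dplyr::filter(.data$n_species_background >= th$background_min_species) |>
    dplyr::arrange(dplyr::desc(.data$n_species_background), .data$otu_id)
}
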