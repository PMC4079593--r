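# Reproducible pipeline drivers over the analysis stages. A config (named
# list or YAML file) declares inputs and parameters; every report directory
# carries the config hash so outputs can be traced to their settings.

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

config_hash <- function(config) rlang::hash(config)

#' Run the damage-spectrum stage end to end
#'
#' Reads per-group aligned read FASTAs, builds each group's consensus,
#' computes composition-scaled misincorporation spectra and the pooled
#' type-2/type-1 ratio, and writes per-group spectra, a per-group summary
#' and the pooled ratio into the run directory.
#'
#' Config fields: `read_fastas` (character vector of per-group FASTA paths,
#' or a directory searched for `*.fasta`/`*.fa`), `tie_rule` (optional,
#' default `"ambiguity"`), `out_dir`.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with `spectra`, `summary` (a
#'   [type_ratio()] result), `paths`, `config_hash`. The pooled summary
#'   flags an undefined ratio via `ratio_defined`.
#' @export
run_damage <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required",
                                 call. = FALSE)
  paths <- cfg$read_fastas
  if (is.null(paths)) stop("config error: read_fastas is required",
                           call. = FALSE)
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(fasta|fa)$", full.names = TRUE)
  }
  if (length(paths) == 0L) {
    stop("config error: no read FASTA files found", call. = FALSE)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("config error: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tie_rule <- cfg$tie_rule %||% "ambiguity"
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  spectra <- lapply(paths, function(p) {
    ss <- Biostrings::readBStringSet(p)
    gid <- sub("\\.(fasta|fa)$", "", basename(p))
    grp <- clone_group(stats::setNames(toupper(as.character(ss)),
                                       sub("\\s.*$", "", names(ss))),
                       group_id = gid)
    damage_spectrum(grp, tie_rule = tie_rule)
  })
  summ <- type_ratio(spectra)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  out <- list(
    spectra_tsv = file.path(cfg$out_dir, "spectra.tsv"),
    per_group_tsv = file.path(cfg$out_dir, "type_ratio_per_group.tsv"),
    pooled_json = file.path(cfg$out_dir, "type_ratio_pooled.json")
  )
  write_spectra_tsv(spectra, out$spectra_tsv)
  readr::write_tsv(summ$per_group, out$per_group_tsv)
  jsonlite::write_json(
    c(as.list(summ$pooled), list(config_hash = hash)),
    out$pooled_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!summ$pooled$ratio_defined) {
    warning("pooled type-1 class is zero; type2/type1 ratio undefined",
            call. = FALSE)
  }
  invisible(list(spectra = spectra, summary = summ, paths = out,
                 config_hash = hash))
}

#' Run the haplotype-network stage end to end
#'
#' Reads the aligned haplotype FASTA, restricts to the analysis region,
#' applies the gap policy with the configured exceptions, collapses
#' identical haplotypes, builds the two-pass inverse-frequency-weighted
#' median-joining network, and writes collapse/node/edge/frequency/weight
#' tables, a GraphML export, motif reports for configured haplogroups and a
#' placement report for an optional query haplotype.
#'
#' Config fields: `alignment_fasta`; one of `ref_label` or `colmap_tsv`;
#' optional `region` (list `start`, `end`), `gap_exceptions` (position
#' keys), `epsilon` (default 0), `weight_scale` (default 10), `missing`
#' (`"permissive"`/`"strict"`), `haplogroups` (named list of haplotype
#' label vectors), `query` (label) and `query_against` (label); `out_dir`.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with `clusters`, `network`, `frequencies`,
#'   `weights`, `motifs`, `placement`, `paths`, `config_hash`.
#' @export
run_network <- function(config) {
  cfg <- read_pipeline_config(config)
  for (f in c("alignment_fasta", "out_dir")) {
    if (is.null(cfg[[f]])) stop("config error: ", f, " is required",
                                call. = FALSE)
  }
  if (!file.exists(cfg$alignment_fasta)) {
    stop("config error: missing input file: ", cfg$alignment_fasta,
         call. = FALSE)
  }
  aln <- read_alignment_fasta(cfg$alignment_fasta,
                              ref_label = cfg$ref_label,
                              colmap_path = cfg$colmap_tsv,
                              ref_start = cfg$ref_start %||% 1L,
                              ref_length = cfg$ref_length)
  if (!is.null(cfg$region)) {
    aln <- extract_region(aln, ref_interval(cfg$region$start,
                                            cfg$region$end))
  }
  aln <- apply_gap_policy(aln, exceptions = cfg$gap_exceptions %||%
                            character())
  clusters <- collapse_haplotypes(aln,
                                  missing = cfg$missing %||% "permissive")
  if (nrow(clusters) < 2L) {
    stop("input error: fewer than two distinct haplotypes after collapsing",
         call. = FALSE)
  }
  two <- build_mj_network_weighted(clusters,
                                   epsilon = cfg$epsilon %||% 0L,
                                   scale = cfg$weight_scale %||% 10L)
  net <- two$network
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  paths <- list(
    collapse_tsv = file.path(cfg$out_dir, "clusters.tsv"),
    nodes_tsv = file.path(cfg$out_dir, "nodes.tsv"),
    edges_tsv = file.path(cfg$out_dir, "edges.tsv"),
    frequencies_tsv = file.path(cfg$out_dir, "frequencies.tsv"),
    weights_tsv = file.path(cfg$out_dir, "weights.tsv"),
    dropped_tsv = file.path(cfg$out_dir, "dropped_columns.tsv"),
    graphml = file.path(cfg$out_dir, "network.graphml"),
    run_json = file.path(cfg$out_dir, "run.json")
  )
  readr::write_tsv(dplyr::mutate(
    tibble::as_tibble(clusters),
    members = vapply(.data$members, paste, "", collapse = ",")),
    paths$collapse_tsv)
  write_network_tsv(net, paths$nodes_tsv, paths$edges_tsv)
  write_frequency_tsv(two$frequencies, paths$frequencies_tsv)
  readr::write_tsv(two$weights, paths$weights_tsv)
  write_drop_report(aln, paths$dropped_tsv)
  write_network_graphml(net, paths$graphml)
  motifs <- list()
  if (!is.null(cfg$haplogroups)) {
    label_to_cluster <- label_cluster_lookup(clusters)
    for (hg in names(cfg$haplogroups)) {
      node_ids <- unique(stats::na.omit(
        label_to_cluster[unlist(cfg$haplogroups[[hg]])]))
      motifs[[hg]] <- infer_motif(net, node_ids, ft = two$frequencies,
                                  haplogroup = hg)
      write_motif_tsv(motifs[[hg]],
                      file.path(cfg$out_dir, paste0("motif_", hg, ".tsv")))
    }
  }
  placement <- NULL
  if (!is.null(cfg$query) && !is.null(cfg$query_against)) {
    label_to_cluster <- label_cluster_lookup(clusters)
    placement <- cluster_distance_report(
      net, label_to_cluster[[cfg$query]],
      label_to_cluster[[cfg$query_against]])
    jsonlite::write_json(
      list(from = placement$from, to = placement$to, path = placement$path,
           total_length = placement$total_length,
           n_labels = placement$n_labels,
           labels = lapply(placement$edges$labels, identity),
           config_hash = hash),
      file.path(cfg$out_dir, "placement.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(
    list(config_hash = hash,
         n_input = attr(clusters, "n_input"),
         n_clusters = nrow(clusters),
         n_variable_positions = length(attr(clusters, "positions")),
         n_medians = sum(net$nodes$is_median),
         spanning_length = net$spanning_length,
         hotspots = hotspots(two$frequencies)),
    paths$run_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(clusters = clusters, network = net,
                 frequencies = two$frequencies, weights = two$weights,
                 motifs = motifs, placement = placement, paths = paths,
                 config_hash = hash))
}

# map each haplotype label to the id of the cluster containing it
label_cluster_lookup <- function(clusters) {
  lab <- unlist(clusters$members)
  stats::setNames(rep(clusters$cluster_id, clusters$n), lab)
}
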