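#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: input paths, cohort
#' filter thresholds (>0.30 disorder, >0.15 FG/AA), linker length bounds
#' (10-30), clustering parameters per feature type (epsilon 35/8/2,
#' minimum points 2/2/4), linker-curve binning (width 0.05, 50-sample bin
#' floor, 0.7 charge-density cap), zone count (3), group cutoff (0.5),
#' seed and output directory. Round-trips losslessly through YAML.
#'
#' @param fasta Path to the cohort FASTA file.
#' @param regions Optional region TSV path.
#' @param locations Optional location TSV path.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the stages that sample (control linkers).
#' @param include_gf Count GF dimers as motifs (clustering/linkers).
#' @param disorder_threshold,fg_density_threshold Cohort filter.
#' @param linker_min,linker_max Linker length bounds.
#' @param bin_width,min_bin_samples,max_linker_charge_density Curve binning.
#' @param n_zones,group_cutoff Zonal analysis settings.
#' @param cluster_params Named list of [clustering_params()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, regions = NULL, locations = NULL,
                            out_dir = "fgseq_out", seed = 1L,
                            include_gf = TRUE,
                            disorder_threshold = 0.30,
                            fg_density_threshold = 0.15,
                            linker_min = 10L, linker_max = 30L,
                            bin_width = 0.05, min_bin_samples = 50L,
                            max_linker_charge_density = 0.7,
                            n_zones = 3L, group_cutoff = 0.5,
                            cluster_params = default_cluster_params()) {
  stopifnot(disorder_threshold > 0, disorder_threshold < 1,
            fg_density_threshold > 0, fg_density_threshold < 1,
            linker_min >= 1, linker_max >= linker_min,
            bin_width > 0, bin_width <= max_linker_charge_density,
            n_zones >= 1, group_cutoff >= 0, group_cutoff <= 1)
  structure(
    list(fasta = fasta, regions = regions, locations = locations,
         out_dir = out_dir, seed = as.integer(seed),
         include_gf = include_gf,
         disorder_threshold = disorder_threshold,
         fg_density_threshold = fg_density_threshold,
         linker_min = as.integer(linker_min),
         linker_max = as.integer(linker_max),
         bin_width = bin_width,
         min_bin_samples = as.integer(min_bin_samples),
         max_linker_charge_density = max_linker_charge_density,
         n_zones = as.integer(n_zones), group_cutoff = group_cutoff,
         cluster_params = cluster_params),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` / the restored [pipeline_config()].
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$cluster_params <- lapply(x$cluster_params, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cp <- lapply(x$cluster_params, function(p)
    clustering_params(p$epsilon, p$min_points))
  do.call(pipeline_config, c(
    x[setdiff(names(x), "cluster_params")],
    list(cluster_params = cp)
  ))
}

#' Run the full FG-nucleoporin sequence analysis pipeline
#'
#' Chains every stage: cohort filter, per-protein composition, FG linkers
#' and the polar-vs-charge curve, largest like-charge regions, density
#' clustering of the three feature types, cluster-overlap statistics,
#' three-zone localization and group A/B assignment. Writes one TSV per
#' stage plus a YAML run manifest (config, config file MD5, record counts,
#' seed) to `config$out_dir`; identical inputs and seed give identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the stage data frames.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- read_protein_records(config$fasta, config$regions,
                                  config$locations)
  message(sprintf("read %d records", length(records)))
  keep <- vapply(records, passes_fg_nup_filter, logical(1),
                 disorder_threshold = config$disorder_threshold,
                 fg_density_threshold = config$fg_density_threshold)
  cohort <- records[keep]
  message(sprintf("%d records pass the FG Nup filter", length(cohort)))
  if (length(cohort) == 0L)
    stop("empty cohort: no protein passes the FG Nup filter")
  scheme <- residue_scheme()
  # deterministic ordering by id throughout
  cohort <- cohort[order(vapply(cohort, `[[`, character(1), "id"))]

  compo <- composition_profile(cohort, scheme)
  abund <- abundance_profile(cohort)
  abund_df <- data.frame(residue = names(abund), fraction = unname(abund))

  set.seed(config$seed)
  linkers <- cohort_linkers(cohort, min_len = config$linker_min,
                            max_len = config$linker_max,
                            include_gf = config$include_gf, scheme = scheme)
  message(sprintf("%d FG linkers extracted", nrow(linkers)))
  curve <- if (nrow(linkers) > 0)
    polar_vs_charge_curve(linkers, config$bin_width, config$min_bin_samples,
                          config$max_linker_charge_density)
  else NULL

  lcrs <- lcr_length_content_table(cohort, scheme)
  if (nrow(lcrs) > 0)
    lcrs$lcr_location_class <- classify_location_by_lcr(lcrs$charge_count)

  cluster_rows <- list(); overlap_rows <- list(); zone_rows <- list()
  for (rec in cohort) {
    cl <- cluster_record_features(rec, config$cluster_params, scheme,
                                  config$include_gf)
    cdf <- clusters_to_df(c(cl$fg, cl$charged, cl$polar))
    if (nrow(cdf) > 0)
      cluster_rows[[rec$id]] <- cbind(id = rec$id, cdf,
                                      stringsAsFactors = FALSE)
    zp <- zone_profile(rec, cl, config$n_zones, config$group_cutoff)
    overlap_rows[[rec$id]] <- data.frame(
      id = rec$id,
      fg_polar = cluster_overlap(cl$fg, cl$polar),
      charged_polar = cluster_overlap(cl$charged, cl$polar),
      fg_charged = cluster_overlap(cl$fg, cl$charged),
      group = zp$group, stringsAsFactors = FALSE
    )
    pr <- as.data.frame(zp$proportions)
    zone_rows[[rec$id]] <- cbind(
      id = rec$id, feature_type = rownames(pr), pr,
      stringsAsFactors = FALSE
    )
  }
  clusters <- do.call(rbind, c(cluster_rows, list(make.row.names = FALSE)))
  overlaps <- do.call(rbind, c(overlap_rows, list(make.row.names = FALSE)))
  zones <- do.call(rbind, c(zone_rows, list(make.row.names = FALSE)))
  groups <- group_overlap_comparison(overlaps$fg_polar, overlaps$group)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  coord_note <- "coordinates 1-based inclusive; densities per residue"
  w <- function(d, f) if (!is.null(d))
    write_stage_tsv(d, file.path(config$out_dir, f), coord_note)
  w(compo, "composition.tsv")
  w(abund_df, "abundance.tsv")
  w(linkers, "linkers.tsv")
  w(curve, "linker_curve.tsv")
  w(lcrs, "lcrs.tsv")
  w(clusters, "clusters.tsv")
  w(overlaps, "overlaps.tsv")
  w(zones, "zones.tsv")
  w(groups, "group_overlap.tsv")

  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    package = "fgseq",
    version = as.character(utils::packageVersion("fgseq")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_records_read = length(records),
    n_records_cohort = length(cohort),
    n_linkers = nrow(linkers),
    linker_low_net_charge_fraction =
      if (nrow(linkers) > 0) linker_net_charge_summary(linkers) else NA
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(records = cohort, composition = compo,
                 abundance = abund_df, linkers = linkers, curve = curve,
                 lcrs = lcrs, clusters = clusters, overlaps = overlaps,
                 zones = zones, group_overlap = groups,
                 manifest = manifest))
}
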