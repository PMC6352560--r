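# Ensemble descriptor report: every descriptor with mean +/- sd across
# replicates, mirroring ensemble-averaged error bars.

#' Summarize descriptors over an ensemble of replicates
#'
#' Computes the descriptor suite for each replicate system and aggregates
#' mean and standard deviation across replicates (sd is 0 for a single
#' replicate).
#'
#' @param systems A `particle_system` or list of them (seeded replicates
#'   or frames).
#' @param hbond_d_cut,hbond_angle_cut Hydrogen-bond criteria.
#' @param profile_bin_width Radial-profile bin width (Angstrom).
#' @param rdf_bin_width RDF bin width (Angstrom).
#' @param include_surface Compute accessible surface area (the slowest
#'   descriptor; default `TRUE`).
#' @param surface_points Sphere test points per particle for the surface
#'   area.
#' @return A `descriptor_report`: `per_replicate` (data.frame of scalar
#'   descriptors per replicate), `summary` (mean/sd per descriptor),
#'   `radial_profile`, `rdf_chains`, `rdf_pcl`, `rdf_pla`,
#'   `hbond_tables`, `distances` (per-replicate `distance_stats`),
#'   `n_replicates`.
#' @export
summarize_descriptors <- function(systems,
                                  hbond_d_cut = 3.0, hbond_angle_cut = 30,
                                  profile_bin_width = 5,
                                  rdf_bin_width = 0.5,
                                  include_surface = TRUE,
                                  surface_points = 240L) {
  if (inherits(systems, "particle_system")) systems <- list(systems)
  if (!length(systems)) stop("need at least one replicate", call. = FALSE)
  n_rep <- length(systems)

  per <- vector("list", n_rep)
  hb_tabs <- vector("list", n_rep)
  dists <- vector("list", n_rep)
  rdf_ch <- vector("list", n_rep)
  rdf_pcl <- vector("list", n_rep)
  rdf_pla <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    sys <- systems[[r]]
    shp <- shape_descriptors(sys)
    ee <- tryCatch(end_to_end_distances(sys), error = function(e) NULL)
    dists[[r]] <- ee
    hb <- detect_hbonds(sys, d_cut = hbond_d_cut,
                        angle_cut = hbond_angle_cut)
    cls <- classify_hbonds(hb, sys)
    hb_tabs[[r]] <- cls
    n_chain <- length(unique(sys$particles$chain_id))
    rdf_ch[[r]] <- if (n_chain >= 2L) {
      rdf(chain_centroids(sys), bin_width = rdf_bin_width)
    } else NULL
    rdf_pcl[[r]] <- tryCatch(
      rdf(segment_centroids(sys, "PCL"), bin_width = rdf_bin_width),
      error = function(e) NULL)
    rdf_pla[[r]] <- tryCatch(
      rdf(segment_centroids(sys, "PLA"), bin_width = rdf_bin_width),
      error = function(e) NULL)
    srf <- if (include_surface) {
      surface_area(sys, n_sphere_points = surface_points)
    } else NULL
    per[[r]] <- data.frame(
      replicate = r,
      rg = shp$rg,
      eccentricity = shp$eccentricity,
      surface_area = if (is.null(srf)) NA_real_ else srf$area_measured,
      surface_ratio = if (is.null(srf)) NA_real_ else srf$ratio,
      mean_end_to_end = if (is.null(ee)) NA_real_ else ee$chain_mean,
      mean_seg_pcl = if (is.null(ee) || !"PCL" %in% names(ee$segment_mean))
        NA_real_ else unname(ee$segment_mean["PCL"]),
      mean_seg_pla = if (is.null(ee) || !"PLA" %in% names(ee$segment_mean))
        NA_real_ else unname(ee$segment_mean["PLA"]),
      hbond_total = cls$total,
      hbond_pcl_pcl = unname(cls$by_category["PCL-PCL"]),
      hbond_pla_pla = unname(cls$by_category["PLA-PLA"]),
      hbond_pcl_pla = unname(cls$by_category["PCL-PLA"]),
      hbond_inter = unname(cls$by_scope["intermolecular"]),
      rdf_chain_peak = if (is.null(rdf_ch[[r]])) NA_real_ else
        rdf_ch[[r]]$peak,
      rdf_pla_first_peak = if (is.null(rdf_pla[[r]])) NA_real_ else
        rdf_pla[[r]]$first_peak)
  }
  per_df <- do.call(rbind, per)
  stats_cols <- setdiff(names(per_df), "replicate")
  summary <- data.frame(
    descriptor = stats_cols,
    mean = vapply(stats_cols, function(cn) mean(per_df[[cn]]), numeric(1L)),
    sd = vapply(stats_cols, function(cn) {
      if (n_rep > 1L) stats::sd(per_df[[cn]]) else 0
    }, numeric(1L)),
    row.names = NULL)

  structure(list(per_replicate = per_df,
                 summary = summary,
                 radial_profile = radial_density_profile(
                   systems, bin_width = profile_bin_width),
                 rdf_chains = rdf_ch,
                 rdf_pcl = rdf_pcl,
                 rdf_pla = rdf_pla,
                 hbond_tables = hb_tabs,
                 distances = dists,
                 n_replicates = n_rep),
            class = "descriptor_report")
}

#' @export
print.descriptor_report <- function(x, ...) {
  cat(sprintf("descriptor_report over %d replicate(s)\n", x$n_replicates))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (is.na(s$mean[i])) next
    cat(sprintf("  %-20s %10.3f +/- %.3f\n", s$descriptor[i], s$mean[i],
                s$sd[i]))
  }
  invisible(x)
}

#' Write a descriptor report to JSON and tidy CSV files
#'
#' @param report A `descriptor_report`.
#' @param dir Output directory (created if needed).
#' @param config_hash Optional provenance string recorded in every file.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, config_hash = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = "wdpunano",
               version = as.character(utils::packageVersion("wdpunano")),
               config_hash = config_hash)
  paths <- character(0)
  js <- file.path(dir, "report.json")
  jsonlite::write_json(list(
    meta = meta,
    summary = report$summary,
    per_replicate = report$per_replicate,
    radial_profile = list(bin_mid = report$radial_profile$bin_mid,
                          density = report$radial_profile$density)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, js)
  w <- function(df, name) {
    pth <- file.path(dir, name)
    utils::write.csv(df, pth, row.names = FALSE)
    paths <<- c(paths, pth)
  }
  w(report$summary, "summary.csv")
  w(report$per_replicate, "per_replicate.csv")
  w(data.frame(bin_mid = report$radial_profile$bin_mid,
               density = report$radial_profile$density,
               number_density = report$radial_profile$number_density),
    "radial_profile.csv")
  first_rdf <- Filter(Negate(is.null), report$rdf_chains)
  if (length(first_rdf)) {
    w(data.frame(bin_center = first_rdf[[1]]$bin_centers,
                 g = first_rdf[[1]]$g,
                 raw_counts = first_rdf[[1]]$raw_counts),
      "rdf_chains.csv")
  }
  invisible(paths)
}
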