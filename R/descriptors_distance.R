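# End-to-end / segment-to-segment distances and radial distribution
# functions.

#' End-to-end and segment-to-segment distances
#'
#' Euclidean distances between the junction (nitrogen) markers delimiting
#' each chain and each soft segment, grouped by segment type.
#'
#' @param system A `particle_system` with coordinates and
#'   `segment_markers`.
#' @return A `distance_stats` list: `chains` (data.frame chain_id,
#'   distance, contour), `segments` (data.frame chain_id, segment_type,
#'   distance), `chain_mean`, `chain_sd`, and per-type segment means/sds.
#' @export
end_to_end_distances <- function(system) {
  stopifnot_coords(system)
  mk <- system$segment_markers
  if (is.null(mk) || !nrow(mk)) {
    stop("system has no segment markers; end-to-end distances undefined",
         call. = FALSE)
  }
  chains <- sort(unique(system$particles$chain_id))
  missing <- setdiff(chains, mk$chain_id[mk$scope == "chain"])
  if (length(missing)) {
    stop("missing chain end markers for chain(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  i1 <- match_ids(system, mk$start)
  i2 <- match_ids(system, mk$end)
  d <- row_norms(system$coords[i1, , drop = FALSE] -
                   system$coords[i2, , drop = FALSE])

  # backbone contour per chain, from realized coordinates
  bb <- which(system$particles$backbone)
  bb_chain <- system$particles$chain_id[bb]
  contour <- vapply(chains, function(ch) {
    idx <- bb[bb_chain == ch]
    sum(row_norms(diff(system$coords[idx, , drop = FALSE])))
  }, numeric(1L))
  names(contour) <- as.character(chains)

  is_chain <- mk$scope == "chain"
  chain_df <- data.frame(chain_id = mk$chain_id[is_chain],
                         distance = d[is_chain],
                         contour = contour[as.character(mk$chain_id[is_chain])],
                         row.names = NULL)
  seg_df <- data.frame(chain_id = mk$chain_id[!is_chain],
                       segment_type = mk$segment_type[!is_chain],
                       distance = d[!is_chain], row.names = NULL)
  seg_mean <- tapply(seg_df$distance, seg_df$segment_type, mean)
  seg_sd <- tapply(seg_df$distance, seg_df$segment_type, stats::sd)
  structure(list(chains = chain_df,
                 segments = seg_df,
                 chain_mean = mean(chain_df$distance),
                 chain_sd = stats::sd(chain_df$distance),
                 segment_mean = seg_mean,
                 segment_sd = seg_sd),
            class = "distance_stats")
}

#' Mass-weighted chain centroids
#' @param system A `particle_system` with coordinates.
#' @return Matrix of chain centroids (one row per chain, ordered by
#'   chain id).
#' @export
chain_centroids <- function(system) {
  stopifnot_coords(system)
  p <- system$particles
  chains <- sort(unique(p$chain_id))
  t(vapply(chains, function(ch) {
    sel <- p$chain_id == ch
    colSums(system$coords[sel, , drop = FALSE] * p$mass[sel]) /
      sum(p$mass[sel])
  }, numeric(3L)))
}

#' Mass-weighted soft-segment centroids
#' @param system A `particle_system` with coordinates and segment markers.
#' @param segment_type `"PCL"`, `"PLA"` or `"ALL"` soft segments.
#' @return Matrix of segment centroids (one row per soft segment).
#' @export
segment_centroids <- function(system, segment_type = c("PCL", "PLA", "ALL")) {
  segment_type <- match.arg(segment_type)
  stopifnot_coords(system)
  p <- system$particles
  sel_type <- if (segment_type == "ALL") p$segment_type != "HARD" else
    p$segment_type == segment_type
  if (!any(sel_type)) {
    stop("no particles of segment type ", segment_type, call. = FALSE)
  }
  # group soft-segment particles into contiguous per-chain segments by
  # (chain, type, run): runs of equal (chain_id, segment_type, unit slot)
  mk <- system$segment_markers
  mk <- mk[mk$scope == "segment", , drop = FALSE]
  if (segment_type != "ALL") {
    mk <- mk[mk$segment_type == segment_type, , drop = FALSE]
  }
  if (!nrow(mk)) stop("no segments of type ", segment_type, call. = FALSE)
  out <- matrix(NA_real_, nrow(mk), 3L)
  for (s in seq_len(nrow(mk))) {
    i1 <- match_ids(system, mk$start[s])
    i2 <- match_ids(system, mk$end[s])
    rows <- seq(min(i1, i2), max(i1, i2))
    rows <- rows[p$segment_type[rows] != "HARD"]
    m <- p$mass[rows]
    out[s, ] <- colSums(system$coords[rows, , drop = FALSE] * m) / sum(m)
  }
  out
}

#' Radial distribution function for a finite cluster
#'
#' Pair-distance histogram normalized by shell volume times the mean pair
#' density inside the minimal enclosing sphere of the point sets, so that
#' ideal-gas (uniform) points give g(r) of about 1 well inside the
#' cluster. No periodic images: this is the non-periodic-cluster
#' convention.
#'
#' @param a Point matrix (e.g. [chain_centroids()] or
#'   [segment_centroids()] output), or a `particle_system` whose particle
#'   coordinates are used directly.
#' @param b Optional second point set for a cross RDF; defaults to `a`.
#' @param bin_width Bin width in Angstrom (default 0.5; reported peak
#'   positions then sit at odd multiples of 0.25 Angstrom).
#' @param r_max Histogram range; defaults to the largest pair distance.
#' @param peak_threshold Fraction of the global maximum a local maximum
#'   must exceed to count as `first_peak` (default 0.5).
#' @return An `rdf_result` list: `bin_centers`, `g`, `raw_counts`,
#'   `peak` (global-maximum bin center), `first_peak` (first qualifying
#'   local maximum), `n_pairs`.
#' @export
rdf <- function(a, b = NULL, bin_width = 0.5, r_max = NULL,
                peak_threshold = 0.5) {
  if (inherits(a, "particle_system")) { stopifnot_coords(a); a <- a$coords }
  if (!is.null(b) && inherits(b, "particle_system")) {
    stopifnot_coords(b); b <- b$coords
  }
  a <- as.matrix(a)
  same <- is.null(b)
  if (same) b <- a else b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stop("selections must be non-empty", call. = FALSE)

  if (same) {
    d <- as.numeric(stats::dist(a))
  } else {
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
    d <- as.numeric(sqrt(pmax(d2, 0)))
  }
  if (is.null(r_max)) r_max <- max(d) + bin_width
  if (r_max <= bin_width) stop("r_max must exceed bin_width", call. = FALSE)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  keep <- d > 1e-12 & d <= r_max
  idx <- pmin(pmax(findInterval(d[keep], edges, rightmost.closed = TRUE), 1L),
              nb)
  counts <- tabulate(idx, nb)

  # enclosing-sphere pair density
  all_pts <- rbind(a, if (same) NULL else b)
  ctr <- colMeans(all_pts)
  r_enc <- max(row_norms(sweep(all_pts, 2, ctr)))
  v_enc <- (4 / 3) * pi * max(r_enc, bin_width)^3
  n_pairs_tot <- if (same) nrow(a) * (nrow(a) - 1) / 2 else
    as.numeric(nrow(a)) * nrow(b)
  shell_vol <- (4 / 3) * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  ideal <- n_pairs_tot * shell_vol / v_enc
  g <- ifelse(ideal > 0, counts / ideal, 0)

  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  peak <- centers[which.max(g)]
  first_peak <- NA_real_
  if (nb >= 3L) {
    thr <- peak_threshold * max(g)
    for (i in 2:(nb - 1L)) {
      if (g[i] >= g[i - 1L] && g[i] > g[i + 1L] && g[i] >= thr) {
        first_peak <- centers[i]; break
      }
    }
  }
  structure(list(bin_centers = centers, g = g, raw_counts = counts,
                 peak = peak, first_peak = first_peak,
                 n_pairs = sum(counts), bin_width = bin_width,
                 r_max = r_max),
            class = "rdf_result")
}
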