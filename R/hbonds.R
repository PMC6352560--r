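# Geometric hydrogen-bond detection and three-way classification.
#
# A hydrogen bond is a donor-H-acceptor triple with
#   d(donor, acceptor) <= d_cut          (default 3.0 Angstrom) and
#   deviation of D-H...A from 180 deg <= angle_cut (default 30 deg).
# Donor/acceptor assignment comes from topology labels (urethane-type N-H
# donors, carbonyl/ester oxygen acceptors), never from element inference.
# Detection is cell-list accelerated but returns exactly the exhaustive-
# search result.

# donor heavy atom -> bonded donor hydrogen(s)
donor_hydrogen_map <- function(system) {
  p <- system$particles
  h_idx <- which(p$hbond_role == "donor_hydrogen")
  if (!length(h_idx)) {
    return(list(donor = integer(0), hydrogen = integer(0)))
  }
  b <- system$bonds
  donor <- integer(length(h_idx))
  for (k in seq_along(h_idx)) {
    i <- h_idx[k]
    partner <- c(b[b[, 1L] == i, 2L], b[b[, 2L] == i, 1L])
    partner <- partner[p$hbond_role[partner] == "donor_heavy"]
    if (!length(partner)) {
      stop(sprintf("donor hydrogen (particle id %d) is not bonded to a donor heavy atom",
                   p$id[i]), call. = FALSE)
    }
    donor[k] <- partner[1L]
  }
  list(donor = donor, hydrogen = h_idx)
}

#' Detect hydrogen bonds
#'
#' @param system A `particle_system` with coordinates, hydrogen-bond role
#'   labels and donor-hydrogen bonds.
#' @param d_cut Donor-acceptor distance cutoff in Angstrom (default 3.0).
#' @param angle_cut Maximum deviation of the D-H...A angle from linearity,
#'   in degrees (default 30).
#' @param classify Attach category/scope columns (default `TRUE`).
#' @param min_bond_separation Acceptors within this many covalent bonds of
#'   the donor heavy atom are excluded (default 3, the usual convention
#'   that suppresses trivial intra-residue contacts); 0 disables all
#'   topological exclusion beyond the donor and its hydrogen.
#' @return A data.frame of class `hbond_records` with one row per detected
#'   triple: `donor_id`, `hydrogen_id`, `acceptor_id`, `d_DA` (Angstrom),
#'   `angle` (deviation, degrees) and, if classified, `category`
#'   (`PCL-PCL`, `PLA-PLA`, `PCL-PLA`) and `scope` (`intramolecular`,
#'   `intermolecular`).
#' @export
detect_hbonds <- function(system, d_cut = 3.0, angle_cut = 30,
                          classify = TRUE, min_bond_separation = 3L) {
  stopifnot_coords(system)
  p <- system$particles
  dh <- donor_hydrogen_map(system)
  empty <- data.frame(donor_id = integer(0), hydrogen_id = integer(0),
                      acceptor_id = integer(0), d_DA = numeric(0),
                      angle = numeric(0))
  if (!length(dh$hydrogen)) {
    warning("no donor hydrogens labeled; returning no hydrogen bonds")
    return(structure(empty, class = c("hbond_records", "data.frame")))
  }
  acc <- which(p$hbond_role == "acceptor")
  if (!length(acc)) {
    return(structure(empty, class = c("hbond_records", "data.frame")))
  }
  xyz <- system$coords

  # cell list over acceptors with cell edge d_cut
  origin <- apply(xyz, 2, min)
  cell_of <- function(idx) floor(sweep(xyz[idx, , drop = FALSE], 2, origin) / d_cut)
  enc <- function(k) k[, 1] + 2048 * (k[, 2] + 2048 * k[, 3])
  acc_cells <- enc(cell_of(acc))
  acc_by_cell <- split(acc, acc_cells)
  don_cells <- cell_of(dh$donor)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  adj <- adjacency_list(system$bonds, nrow(p))

  rows <- vector("list", length(dh$donor))
  for (k in seq_along(dh$donor)) {
    i_d <- dh$donor[k]; i_h <- dh$hydrogen[k]
    nb <- enc(sweep(offs, 2, as.numeric(don_cells[k, ]), `+`))
    cand <- unlist(acc_by_cell[as.character(nb)], use.names = FALSE)
    if (!length(cand)) next
    # exclude the donor itself, the hydrogen's neighbours, and anything
    # within min_bond_separation covalent bonds of the donor
    excl <- c(i_d, i_h, bonded_partners(system, i_h),
              graph_neighborhood(adj, i_d, max(min_bond_separation, 1L)))
    cand <- setdiff(cand, excl)
    if (!length(cand)) next
    dvec <- sweep(xyz[cand, , drop = FALSE], 2, xyz[i_d, ])
    d_da <- row_norms(dvec)
    ok <- d_da <= d_cut
    if (!any(ok)) next
    cand <- cand[ok]; d_da <- d_da[ok]
    hd <- xyz[i_d, ] - xyz[i_h, ]
    ha <- sweep(xyz[cand, , drop = FALSE], 2, xyz[i_h, ])
    cosang <- (ha %*% hd) / (row_norms(ha) * vnorm(hd))
    ang_dha <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    dev <- 180 - ang_dha
    ok2 <- dev <= angle_cut
    if (!any(ok2)) next
    rows[[k]] <- data.frame(donor_id = p$id[i_d], hydrogen_id = p$id[i_h],
                            acceptor_id = p$id[cand[ok2]],
                            d_DA = d_da[ok2], angle = dev[ok2])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  out <- structure(out, class = c("hbond_records", "data.frame"))
  if (classify && nrow(out)) out <- add_hbond_labels(out, system)
  out
}

bonded_partners <- function(system, i) {
  b <- system$bonds
  c(b[b[, 1L] == i, 2L], b[b[, 2L] == i, 1L])
}

adjacency_list <- function(bonds, n) {
  adj <- vector("list", n)
  if (!nrow(bonds)) return(adj)
  sp <- split(c(bonds[, 2L], bonds[, 1L]), c(bonds[, 1L], bonds[, 2L]))
  adj[as.integer(names(sp))] <- sp
  adj
}

# all atoms within `depth` bonds of atom i (including i)
graph_neighborhood <- function(adj, i, depth) {
  seen <- i
  frontier <- i
  for (d in seq_len(depth)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  seen
}

add_hbond_labels <- function(records, system) {
  p <- system$particles
  i_d <- match_ids(system, records$donor_id)
  i_a <- match_ids(system, records$acceptor_id)
  cls_d <- p$hb_class[i_d]
  cls_a <- p$hb_class[i_a]
  if (anyNA(cls_d) || anyNA(cls_a)) {
    stop("hydrogen-bond participant lacks a segment class label",
         call. = FALSE)
  }
  records$category <- ifelse(cls_d == cls_a,
                             paste0(cls_d, "-", cls_a),
                             "PCL-PLA")
  records$scope <- ifelse(p$chain_id[i_d] == p$chain_id[i_a],
                          "intramolecular", "intermolecular")
  records
}

#' Classify hydrogen bonds into the three-way partition
#'
#' Partitions detected records into PCL-PCL, PLA-PLA and PCL-PLA
#' categories (by the donor/acceptor segment class labels) crossed with
#' intramolecular/intermolecular scope (by chain id); the three categories
#' always sum to the total.
#'
#' @param records `hbond_records` from [detect_hbonds()].
#' @param system The `particle_system` the records came from.
#' @return A `hbond_counts` list: `by_category` (named counts over the
#'   three categories), `by_scope`, `table` (category x scope), `total`.
#' @export
classify_hbonds <- function(records, system) {
  categories <- c("PCL-PCL", "PLA-PLA", "PCL-PLA")
  scopes <- c("intramolecular", "intermolecular")
  if (nrow(records) && (is.null(records$category) || is.null(records$scope))) {
    records <- add_hbond_labels(records, system)
  }
  tab <- matrix(0L, length(categories), length(scopes),
                dimnames = list(categories, scopes))
  if (nrow(records)) {
    got <- table(factor(records$category, levels = categories),
                 factor(records$scope, levels = scopes))
    tab[] <- as.integer(got)
  }
  structure(list(by_category = as.integer(rowSums(tab)) |>
                   stats::setNames(categories),
                 by_scope = as.integer(colSums(tab)) |>
                   stats::setNames(scopes),
                 table = tab,
                 total = as.integer(sum(tab))),
            class = "hbond_counts")
}

#' @export
print.hbond_counts <- function(x, ...) {
  cat(sprintf("hydrogen bonds: %d total\n", x$total))
  print(x$table)
  invisible(x)
}
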