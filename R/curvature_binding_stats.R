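# Headline statistics: mean-curvature histograms for all lipids and for
# ion-contacted lipids, the enrichment profile p(Km) obtained by dividing
# the two densities, and per-leaflet summaries. Errors come from three
# equal contiguous, non-overlapping parts of the trajectory.

# shared bin edges aligned to multiples of the bin width
.curv_breaks <- function(values, bin_width) {
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  seq(lo, hi + 1e-12, by = bin_width)
}

.bin_sums <- function(values, breaks) {
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  ok <- values >= breaks[1] & values <= breaks[length(breaks)]
  out <- numeric(length(breaks) - 1L)
  if (any(ok)) {
    s <- rowsum(values[ok], idx[ok])
    out[as.integer(rownames(s))] <- s
  }
  out
}

.bin_counts <- function(values, breaks) {
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = FALSE)
  idx[values < breaks[1] | values > breaks[length(breaks)]] <- NA
  tabulate(idx, nbins = length(breaks) - 1L)
}

.as_curv_hist <- function(counts, blocks, breaks, km_sum = NULL) {
  n <- sum(counts)
  dx <- diff(breaks)
  out <- data.frame(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    center = (breaks[-1] + breaks[-length(breaks)]) / 2,
    count = counts,
    density = if (n > 0) counts / (n * dx) else rep(0, length(counts)))
  # occupancy-weighted bin position (mean Km of the samples in the bin)
  out$km_mean <- if (is.null(km_sum)) out$center
                 else ifelse(counts > 0, km_sum / counts, out$center)
  attr(out, "breaks") <- breaks
  attr(out, "n_samples") <- n
  attr(out, "blocks") <- blocks   # counts per trajectory third (matrix)
  class(out) <- c("cb_curv_hist", class(out))
  out
}

#' Mean-curvature histograms of all lipids and of ion-contacted lipids
#'
#' `P_lip` accumulates one sample per lipid per frame at that lipid's
#' mean curvature; `P_Ca` accumulates one sample per (ion, contacted
#' lipid) pair per frame — an ion coordinating three lipids contributes
#' three samples. Both share the same bin edges and are normalized to
#' probability densities. Contacted lipids without a valid curvature are
#' dropped and counted in `attr(P_Ca, "n_dropped")`.
#'
#' @param surface_table a `cb_surface_table` from [compute_surface()].
#' @param maps list of `cb_contact_map`, parallel to the frames of
#'   `surface_table`.
#' @param bin_width bin width, nm^-1 (default 0.05).
#' @param breaks explicit bin edges (overrides `bin_width`).
#' @param lipid_subset restrict both histograms to these lipid ids.
#' @param km_estimate `"frame"` bins each sample at that frame's fitted
#'   curvature (the default; appropriate when the membrane shape evolves).
#'   `"lipid_mean"` bins at the lipid's trajectory-mean curvature, which
#'   suppresses per-frame estimator noise when the underlying geometry is
#'   static (as in the synthetic benchmarks) and would otherwise dilute
#'   curvature-dependence estimates.
#' @return list with elements `P_lip` and `P_Ca` (class `cb_curv_hist`).
#' @export
curvature_histograms <- function(surface_table, maps, bin_width = 0.05,
                                 breaks = NULL, lipid_subset = NULL,
                                 km_estimate = c("frame", "lipid_mean")) {
  km_estimate <- match.arg(km_estimate)
  st <- surface_table[surface_table$ok & !is.na(surface_table$Km), ,
                      drop = FALSE]
  if (!is.null(lipid_subset))
    st <- st[st$lipid_id %in% lipid_subset, , drop = FALSE]
  if (!nrow(st)) stop("no valid curvature samples")
  if (km_estimate == "lipid_mean") {
    mu <- tapply(st$Km, st$lipid_id, mean)
    st$Km <- as.vector(mu[as.character(st$lipid_id)])
  }
  if (is.null(breaks)) breaks <- .curv_breaks(st$Km, bin_width)
  n_frames <- length(maps)
  thirds <- cut(seq_len(n_frames), breaks = 3, labels = FALSE)
  km_lookup <- split(st[, c("lipid_id", "Km")], st$frame)
  lip_counts <- 0; lip_blocks <- matrix(0, length(breaks) - 1L, 3)
  ca_counts <- 0; ca_blocks <- matrix(0, length(breaks) - 1L, 3)
  lip_km_sum <- 0; ca_km_sum <- 0
  dropped <- 0L
  for (k in seq_len(n_frames)) {
    kmf <- km_lookup[[as.character(k)]]
    if (is.null(kmf)) next
    cl <- .bin_counts(kmf$Km, breaks)
    lip_counts <- lip_counts + cl
    lip_km_sum <- lip_km_sum + .bin_sums(kmf$Km, breaks)
    lip_blocks[, thirds[k]] <- lip_blocks[, thirds[k]] + cl
    cc <- maps[[k]]$contacts
    if (!is.null(lipid_subset))
      cc <- cc[cc$lipid_id %in% lipid_subset, , drop = FALSE]
    if (nrow(cc)) {
      km_c <- kmf$Km[match(cc$lipid_id, kmf$lipid_id)]
      dropped <- dropped + sum(is.na(km_c))
      km_c <- km_c[!is.na(km_c)]
      if (length(km_c)) {
        cm <- .bin_counts(km_c, breaks)
        ca_counts <- ca_counts + cm
        ca_km_sum <- ca_km_sum + .bin_sums(km_c, breaks)
        ca_blocks[, thirds[k]] <- ca_blocks[, thirds[k]] + cm
      }
    }
  }
  P_lip <- .as_curv_hist(lip_counts, lip_blocks, breaks, lip_km_sum)
  P_Ca <- .as_curv_hist(ca_counts, ca_blocks, breaks, ca_km_sum)
  attr(P_Ca, "n_dropped") <- dropped
  list(P_lip = P_lip, P_Ca = P_Ca)
}

#' Curvature-enrichment profile p(Km)
#'
#' The enrichment is the ratio of the contacted-lipid curvature density to
#' the all-lipid curvature density per bin: p > 1 marks preferred ion
#' binding at that curvature, p = 1 no preference, p < 1 avoidance. Bins
#' whose all-lipid count is below `n_min` are masked invalid (the density
#' ratio is unstable there). Per-third curves give the error band (SD
#' across the three trajectory thirds).
#'
#' @param P_Ca,P_lip histograms from [curvature_histograms()] on identical
#'   bin edges.
#' @param n_min minimum all-lipid samples per valid bin.
#' @return a `cb_enrichment` data.frame: `center`, `p`, `err`, `valid`,
#'   `n_lip`, `n_ca`; per-third curves in `attr(x, "blocks")`.
#' @export
enrichment <- function(P_Ca, P_lip, n_min = 50) {
  if (!isTRUE(all.equal(attr(P_Ca, "breaks"), attr(P_lip, "breaks"))))
    stop("P_Ca and P_lip must share identical bin edges")
  valid <- P_lip$count >= n_min
  p <- rep(NA_real_, nrow(P_lip))
  p[valid] <- P_Ca$density[valid] / P_lip$density[valid]
  lb <- attr(P_lip, "blocks"); cb <- attr(P_Ca, "blocks")
  dx <- P_lip$bin_hi - P_lip$bin_lo
  blocks <- sapply(1:3, function(bkl) {
    dl <- lb[, bkl] / (sum(lb[, bkl]) * dx)
    dc <- cb[, bkl] / (sum(cb[, bkl]) * dx)
    pb <- rep(NA_real_, length(dl))
    okb <- valid & lb[, bkl] > 0
    pb[okb] <- dc[okb] / dl[okb]
    pb
  })
  err <- apply(blocks, 1, function(v) stats::sd(v))
  out <- data.frame(center = P_lip$center, km_mean = P_lip$km_mean,
                    p = p, err = err, valid = valid,
                    n_lip = P_lip$count, n_ca = P_Ca$count)
  attr(out, "blocks") <- blocks
  attr(out, "n_min") <- n_min
  class(out) <- c("cb_enrichment", class(out))
  out
}

#' Log-linear slope of an enrichment profile
#'
#' Weighted least-squares fit of log p versus curvature over valid bins
#' with p > 0, weighting by the contacted-lipid bin counts. The abscissa
#' is the occupancy-weighted mean curvature of each bin rather than the
#' nominal bin center: curvature densities typically peak near the extreme
#' curvatures, where the within-bin sample mean differs appreciably from
#' the center and using the center would bias the slope. For ions placed
#' with log-linear curvature bias exp(-alpha Km), the slope estimates
#' -alpha.
#'
#' @param profile a `cb_enrichment`.
#' @param weighted weight bins by their contact counts.
#' @param at `"km_mean"` (default) or `"center"` — abscissa choice.
#' @return list with `slope` (nm), `intercept` and `n_bins` used.
#' @export
fit_log_slope <- function(profile, weighted = TRUE,
                          at = c("km_mean", "center")) {
  at <- match.arg(at)
  use <- profile$valid & !is.na(profile$p) & profile$p > 0
  if (sum(use) < 2) stop("fewer than 2 usable bins for the slope fit")
  x <- profile[[at]][use]
  y <- log(profile$p[use])
  w <- if (weighted) profile$n_ca[use] else rep(1, sum(use))
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n_bins = sum(use))
}

# ---- leaflet summaries ------------------------------------------------------

#' Assign each ion to the leaflet of its nearest lipid marker
#'
#' @param frame a `cb_frame` with ions.
#' @param markers marker table from [select_markers()].
#' @param leaflets leaflet table from [assign_leaflets()].
#' @return data.frame `ion_id`, `leaflet`.
#' @export
nearest_leaflet <- function(frame, markers = NULL, leaflets = NULL) {
  if (is.null(markers)) markers <- select_markers(frame)
  if (is.null(leaflets)) leaflets <- assign_leaflets(frame, markers)
  a <- frame$atoms
  ions <- a[a$mol_kind == "ion", , drop = FALSE]
  M <- as.matrix(markers[, c("x", "y", "z")])
  lf <- leaflets$leaflet[match(markers$lipid_id, leaflets$lipid_id)]
  near <- vapply(seq_len(nrow(ions)), function(i) {
    d2 <- .mi_dist2(M, c(ions$x[i], ions$y[i], ions$z[i]),
                    frame$box, frame$periodic)
    lf[which.min(d2)]
  }, character(1))
  data.frame(ion_id = ions$mol_id, leaflet = near, stringsAsFactors = FALSE)
}

#' Per-leaflet binding summary
#'
#' For each leaflet: number of lipids, mean lipid curvature, mean ion
#' coordination number and free-ion fraction (with trajectory-thirds
#' errors). Ions are attributed to leaflets by `ion_leaflets`; coordination
#' and free/bound status count only contacts with that leaflet's lipids.
#'
#' @param surface_table a `cb_surface_table`.
#' @param maps list of `cb_contact_map`.
#' @param ion_leaflets data.frame `ion_id`, `leaflet` (applied to every
#'   frame), or a list of such tables parallel to `maps`.
#' @param lipid_subset optional lipid-id mask (e.g. from
#'   [central_sector_mask()]).
#' @return data.frame, one row per leaflet: `leaflet`, `n_lipids`,
#'   `mean_Km`, `mean_coord`, `mean_coord_err`, `free_fraction`,
#'   `free_fraction_err`.
#' @export
leaflet_summary <- function(surface_table, maps, ion_leaflets,
                            lipid_subset = NULL) {
  st <- surface_table[surface_table$ok, , drop = FALSE]
  if (!is.null(lipid_subset))
    st <- st[st$lipid_id %in% lipid_subset, , drop = FALSE]
  per_frame_ions <- !is.data.frame(ion_leaflets)
  leaves <- sort(unique(st$leaflet))
  thirds <- cut(seq_along(maps), breaks = 3, labels = FALSE)
  rows <- lapply(leaves, function(lf) {
    lip_ids <- unique(st$lipid_id[st$leaflet == lf])
    if (!length(lip_ids)) stop("empty leaflet subset: ", lf)
    coords <- lapply(seq_along(maps), function(k) {
      il <- if (per_frame_ions) ion_leaflets[[k]] else ion_leaflets
      ions <- il$ion_id[il$leaflet == lf]
      cc <- maps[[k]]$contacts
      cc <- cc[cc$lipid_id %in% lip_ids & cc$ion_id %in% ions, ,
               drop = FALSE]
      cnt <- table(factor(cc$ion_id, levels = ions))
      data.frame(third = thirds[k], coord = as.integer(cnt))
    })
    coords <- do.call(rbind, coords)
    by3 <- split(coords$coord, coords$third)
    mc3 <- vapply(by3, mean, numeric(1))
    ff3 <- vapply(by3, function(v) mean(v == 0), numeric(1))
    data.frame(leaflet = lf, n_lipids = length(lip_ids),
               mean_Km = mean(st$Km[st$leaflet == lf], na.rm = TRUE),
               mean_coord = mean(coords$coord),
               mean_coord_err = stats::sd(mc3),
               free_fraction = mean(coords$coord == 0),
               free_fraction_err = stats::sd(ff3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an enrichment profile as TSV
#' @param profile a `cb_enrichment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(profile, path) {
  blocks <- attr(profile, "blocks")
  out <- data.frame(bin_center = profile$center,
                    p = profile$p, err = profile$err,
                    p_lo = profile$p - profile$err,
                    p_hi = profile$p + profile$err,
                    valid = profile$valid,
                    n_lip = profile$n_lip, n_ca = profile$n_ca)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
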