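# Membrane surface reconstruction: per-lipid normals, iteratively
# re-aligned local quadric (Monge patch) fits, principal/mean/Gaussian
# curvatures and Voronoi surface areas in the local tangent planes.
#
# Sign convention: curvature is reported against each leaflet's outward
# (water-side) normal such that a leaflet bending toward its water side —
# concave as seen from the adjacent water — has negative mean curvature.

# ---- leaflet assignment -----------------------------------------------------

#' Split lipids into leaflets
#'
#' Each lipid's outward axis (marker minus mean tail-site position) is
#' compared against a reference orientation: a fixed axis for planar or
#' buckled membranes (labels `upper`/`lower`) or the radial direction from
#' the marker centroid for bent/closed membranes (labels `convex`/`concave`,
#' the concave leaflet facing the center of bending curvature).
#'
#' @param frame a `cb_frame` containing full lipids (tail sites needed).
#' @param markers marker table from [select_markers()]; recomputed when
#'   `NULL`.
#' @param method `"axis"`, `"radial"` or `"auto"`. Auto uses the fixed axis
#'   unless some lipid axes are nearly orthogonal to it (curved geometries).
#' @param axis reference axis for the planar case.
#' @param center bending center for the radial case (default: marker
#'   centroid).
#' @param rule marker selection rule.
#' @return data.frame: `lipid_id`, `leaflet`, and the unit outward axis
#'   (`ox`, `oy`, `oz`).
#' @export
assign_leaflets <- function(frame, markers = NULL,
                            method = c("auto", "axis", "radial"),
                            axis = c(0, 0, 1), center = NULL,
                            rule = marker_rule()) {
  method <- match.arg(method)
  if (is.null(markers)) markers <- select_markers(frame, rule)
  a <- frame$atoms
  lip <- a[a$mol_kind == "lipid", , drop = FALSE]
  # mean tail-site position per lipid (fall back to mean of all sites)
  tails <- lip[lip$group == "tail", , drop = FALSE]
  if (!nrow(tails)) tails <- lip
  tm <- rowsum(as.matrix(tails[, c("x", "y", "z")]), tails$mol_id)
  tm <- tm / as.vector(table(tails$mol_id)[rownames(tm)])
  tm <- tm[match(markers$lipid_id, as.integer(rownames(tm))), , drop = FALSE]
  M <- as.matrix(markers[, c("x", "y", "z")])
  # outward axis via minimum image (lipids may straddle the box boundary)
  O <- -t(vapply(seq_len(nrow(M)), function(i)
    min_image_displacement(M[i, ], tm[i, ], frame$box, frame$periodic),
    numeric(3)))
  len <- sqrt(rowSums(O^2))
  if (any(len < 1e-9))
    stop("degenerate lipid axis (zero length) for lipid(s) ",
         paste(markers$lipid_id[len < 1e-9], collapse = ", "))
  O <- O / len
  if (method == "auto") {
    d <- abs(O %*% axis)
    method <- if (min(d) < 0.2) "radial" else "axis"
  }
  if (method == "axis") {
    up <- as.vector(O %*% axis) > 0
    leaflet <- ifelse(up, "upper", "lower")
  } else {
    if (is.null(center)) {
      # bending center: least-squares intersection of the lipid axes
      # (solve sum_i (I - o_i o_i^T) c = sum_i (I - o_i o_i^T) m_i)
      A <- diag(3) * nrow(O) - crossprod(O)
      b <- colSums(M) - colSums(O * as.vector(rowSums(O * M)))
      center <- tryCatch(solve(A, b), error = function(e) colMeans(M))
    }
    R <- sweep(M, 2, center)
    out <- rowSums(R * O) > 0
    leaflet <- ifelse(out, "convex", "concave")
  }
  data.frame(lipid_id = markers$lipid_id, leaflet = leaflet,
             ox = O[, 1], oy = O[, 2], oz = O[, 3],
             stringsAsFactors = FALSE)
}

# ---- neighborhoods ----------------------------------------------------------

# All displacements of markers (and their periodic images) within `radius`
# of the center marker. In boxes thinner than twice the radius a marker can
# contribute several images to the same neighborhood, which keeps the fit
# design well conditioned; the plain minimum image is a special case.
.neighbor_disps <- function(markers, center, radius, box, periodic) {
  D0 <- sweep(markers, 2L, markers[center, ])
  reps <- ifelse(periodic, pmax(1L, ceiling(radius / box)), 0L)
  sh <- expand.grid(x = -reps[1]:reps[1], y = -reps[2]:reps[2],
                    z = -reps[3]:reps[3])
  sh <- as.matrix(sh) * rep(box, each = nrow(sh))
  D <- NULL; ids <- NULL
  for (s in seq_len(nrow(sh))) {
    Ds <- sweep(D0, 2L, sh[s, ], "+")
    keep <- rowSums(Ds * Ds) <= radius^2
    keep[center] <- keep[center] & any(sh[s, ] != 0)  # drop self at origin
    if (!any(keep)) next
    D <- rbind(D, Ds[keep, , drop = FALSE])
    ids <- c(ids, which(keep))
  }
  # the center itself (origin) is always part of its neighborhood
  list(disp = rbind(rep(0, 3), D), ids = c(center, ids))
}

# ---- normals ----------------------------------------------------------------

# covariance normal from a displacement matrix (center at origin)
.normal_from_disps <- function(Dn, orient) {
  Dc <- sweep(Dn, 2, colMeans(Dn))
  ev <- eigen(crossprod(Dc), symmetric = TRUE)
  n <- ev$vectors[, 3]
  if (sum(n * orient) < 0) n <- -n
  n
}

# iterative re-aligned Monge-patch least squares on a displacement matrix
.fit_quadric_core <- function(Dn, n, max_iter = 10L, tol_deg = 0.5,
                              where = "") {
  n0 <- n
  ang <- Inf
  for (it in seq_len(max_iter)) {
    Fm <- .tangent_frame(n)
    L <- Dn %*% Fm
    X <- cbind(L[, 1]^2, L[, 2]^2, L[, 1] * L[, 2], L[, 1], L[, 2], 1)
    qrX <- qr(X)
    if (qrX$rank < 6L)
      stop("rank-deficient quadric design (collinear neighbors)", where)
    coef <- qr.coef(qrX, L[, 3])
    nl <- c(-coef[4], -coef[5], 1)
    nl <- nl / sqrt(sum(nl^2))
    n_new <- as.vector(Fm %*% nl)
    ang <- acos(min(1, max(-1, sum(n * n_new)))) * 180 / pi
    n <- n_new
    if (ang < tol_deg) break
  }
  Fm <- .tangent_frame(n)
  L <- Dn %*% Fm
  X <- cbind(L[, 1]^2, L[, 2]^2, L[, 1] * L[, 2], L[, 1], L[, 2], 1)
  coef <- qr.coef(qr(X), L[, 3])
  resid <- L[, 3] - as.vector(X %*% coef)
  drift <- acos(min(1, max(-1, sum(n * n0)))) * 180 / pi
  list(frame = Fm, local = L,
       coef = stats::setNames(as.vector(coef),
                              c("a", "b", "c", "d", "e", "f")),
       residual = sqrt(mean(resid^2)),
       converged = ang < tol_deg, normal_drift = drift)
}

#' Initial surface normal from the local marker neighborhood
#'
#' The working normal is the smallest principal axis of the covariance of
#' markers within `radius` of the center (minimum-image distances),
#' oriented along the center lipid's outward axis.
#'
#' @param markers n x 3 matrix of same-leaflet marker positions.
#' @param center row index of the center marker.
#' @param radius neighborhood radius, nm.
#' @param box,periodic box geometry.
#' @param orient outward direction used to fix the sign (length-3).
#' @return unit normal (length-3).
#' @export
initial_normal <- function(markers, center, radius, box,
                           periodic = c(TRUE, TRUE, TRUE),
                           orient = c(0, 0, 1)) {
  nb <- .neighbor_disps(markers, center, radius, box, periodic)
  if (nrow(nb$disp) < 3)
    stop("insufficient neighborhood: ", nrow(nb$disp),
         " markers within ", radius, " nm")
  .normal_from_disps(nb$disp, orient)
}

# ---- quadric fitting --------------------------------------------------------

# orthonormal frame with given z-axis
.tangent_frame <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  cbind(e1, e2, n)
}

#' Fit a local quadric (Monge) patch around one marker
#'
#' Least-squares fit of z = a x^2 + b y^2 + c xy + d x + e y + f to the
#' minimum-image neighborhood in a local frame whose z-axis is the working
#' normal; the frame is re-aligned to the fitted normal at the origin and
#' the fit repeated until the per-iteration normal rotation is below
#' `tol_deg` or `max_iter` is reached. If fewer than `min_pts` markers fall
#' inside `radius`, the radius is grown by 25% up to twice.
#'
#' @param markers n x 3 matrix of same-leaflet marker positions.
#' @param center row index of the center marker.
#' @param normal initial unit normal (outward-oriented).
#' @param radius neighborhood radius, nm.
#' @param box,periodic box geometry.
#' @param max_iter,tol_deg re-alignment controls.
#' @param min_pts minimum markers in the neighborhood (center included).
#' @return a `cb_quadric_patch`: local `frame` (columns e1, e2, normal),
#'   `coef` (a, b, c, d, e, f), neighbor indices, local neighbor
#'   coordinates, rms `residual` and `n_neighbors` (excluding the center).
#' @export
fit_quadric <- function(markers, center, normal, radius, box,
                        periodic = c(TRUE, TRUE, TRUE),
                        max_iter = 10L, tol_deg = 0.5, min_pts = 7L) {
  r <- radius
  for (g in 0:2) {
    nb <- .neighbor_disps(markers, center, r, box, periodic)
    if (nrow(nb$disp) >= min_pts) break
    r <- r * 1.25
  }
  if (nrow(nb$disp) < min_pts)
    stop("insufficient neighborhood for quadric fit: ", nrow(nb$disp),
         " markers within ", signif(r, 3), " nm (need ", min_pts, ")")
  sel <- nb$ids
  fit <- .fit_quadric_core(nb$disp, normal, max_iter, tol_deg,
                           where = paste0(" at marker ", center))
  structure(list(
    center = center, origin = markers[center, ], frame = fit$frame,
    coef = fit$coef,
    neighbors = sel[sel != center], local = fit$local,
    local_ids = sel,
    residual = fit$residual,
    converged = fit$converged, normal_drift = fit$normal_drift,
    n_neighbors = length(sel) - 1L,
    radius = r), class = "cb_quadric_patch")
}

#' Curvatures of a fitted quadric patch at its origin
#'
#' Mean and Gaussian curvature of the Monge patch evaluated at the local
#' origin with gradient (d, e), then sign-flipped so that bending toward
#' the water side (outward normal) is negative: Km < 0 on concave leaflet
#' surfaces. Principal curvatures are recovered from (Km, Kg) and sorted
#' k1 >= k2.
#'
#' @param patch a `cb_quadric_patch`.
#' @return list with `k1`, `k2`, `Km` (nm^-1), `Kg` (nm^-2) and the fitted
#'   unit `normal` in global coordinates (outward).
#' @export
curvature_from_patch <- function(patch) {
  co <- patch$coef
  a <- co[["a"]]; b <- co[["b"]]; cc <- co[["c"]]
  d <- co[["d"]]; e <- co[["e"]]
  w <- 1 + d^2 + e^2
  H <- ((1 + e^2) * 2 * a - 2 * d * e * cc + (1 + d^2) * 2 * b) /
    (2 * w^1.5)
  K <- (4 * a * b - cc^2) / w^2
  # outward-normal sign convention (concave toward water negative)
  H <- -H
  disc <- max(H^2 - K, 0)
  k1 <- H + sqrt(disc)
  k2 <- H - sqrt(disc)
  nl <- c(-d, -e, 1); nl <- nl / sqrt(sum(nl^2))
  list(k1 = k1, k2 = k2, Km = H, Kg = K,
       normal = as.vector(patch$frame %*% nl))
}

# ---- projection -------------------------------------------------------------

# closest point on z = f(x,y) for one local point (Newton on (x,y))
.project_point <- function(co, p, max_steps = 50L, tol = 1e-10) {
  a <- co[["a"]]; b <- co[["b"]]; cc <- co[["c"]]
  d <- co[["d"]]; e <- co[["e"]]; f0 <- co[["f"]]
  fxy <- function(x, y) a * x^2 + b * y^2 + cc * x * y + d * x + e * y + f0
  x <- p[1]; y <- p[2]
  for (s in seq_len(max_steps)) {
    z <- fxy(x, y)
    fx <- 2 * a * x + cc * y + d
    fy <- 2 * b * y + cc * x + e
    dz <- z - p[3]
    g <- c(x - p[1] + dz * fx, y - p[2] + dz * fy)
    Hm <- matrix(c(1 + fx^2 + dz * 2 * a, fx * fy + dz * cc,
                   fx * fy + dz * cc, 1 + fy^2 + dz * 2 * b), 2)
    step <- tryCatch(solve(Hm, g), error = function(err) g)
    x <- x - step[1]; y <- y - step[2]
    if (sum(step^2) < tol^2) break
  }
  if (s == max_steps && sum(step^2) >= tol^2) {
    # fall back to vertical (local-z) projection
    x <- p[1]; y <- p[2]
  }
  c(x, y, fxy(x, y))
}

#' Project neighborhood markers onto the fitted quadric
#'
#' Each marker of the patch neighborhood is mapped to its closest point on
#' the quadric surface by Newton descent on the squared distance; on
#' non-convergence the vertical (local-z) projection is used.
#'
#' @param patch a `cb_quadric_patch`.
#' @return data.frame of foot points in patch-local coordinates (`lx`,
#'   `ly`, `lz`) with the marker row indices in `id`.
#' @export
project_markers <- function(patch) {
  L <- patch$local
  feet <- t(apply(L, 1, function(p) .project_point(patch$coef, p)))
  data.frame(id = patch$local_ids, lx = feet[, 1], ly = feet[, 2],
             lz = feet[, 3])
}

# ---- Voronoi areas ----------------------------------------------------------

# clip convex polygon (matrix of xy rows) by half-plane {q : q.nrm <= off}
.clip_halfplane <- function(poly, nrm, off) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  d <- poly %*% nrm - off
  out <- matrix(0, n + 4, 2)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    in_i <- d[i] <= 0; in_j <- d[j] <= 0
    if (in_i) { m <- m + 1L; out[m, ] <- poly[i, ] }
    if (xor(in_i, in_j)) {
      t <- d[i] / (d[i] - d[j])
      m <- m + 1L
      out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

# Voronoi cell of `site` among candidate sites (xy matrix),
# clipped to a square of half-width r. Returns polygon vertex matrix.
.voronoi_cell <- function(site, others, r) {
  poly <- matrix(c(-r, -r, r, -r, r, r, -r, r), ncol = 2, byrow = TRUE)
  poly <- sweep(poly, 2, site, "+")
  if (nrow(others)) {
    d2 <- rowSums(sweep(others, 2, site)^2)
    ord <- order(d2)
    for (i in ord) {
      if (d2[i] > (2 * r)^2 * 2) break
      mid <- (site + others[i, ]) / 2
      nrm <- others[i, ] - site
      poly <- .clip_halfplane(poly, nrm, sum(nrm * mid))
      if (nrow(poly) < 3) break
    }
  }
  poly
}

# area of the polygon lifted onto the quadric, by fan triangulation
.lifted_area <- function(poly, co) {
  if (nrow(poly) < 3) return(NA_real_)
  a <- co[["a"]]; b <- co[["b"]]; cc <- co[["c"]]
  d <- co[["d"]]; e <- co[["e"]]; f0 <- co[["f"]]
  z <- a * poly[, 1]^2 + b * poly[, 2]^2 + cc * poly[, 1] * poly[, 2] +
    d * poly[, 1] + e * poly[, 2] + f0
  V <- cbind(poly, z)
  tot <- 0
  for (i in 2:(nrow(V) - 1)) {
    u <- V[i, ] - V[1, ]; w <- V[i + 1, ] - V[1, ]
    cr <- c(u[2] * w[3] - u[3] * w[2],
            u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    tot <- tot + 0.5 * sqrt(sum(cr^2))
  }
  tot
}

#' Per-lipid Voronoi surface areas for one leaflet
#'
#' For each lipid, the Voronoi cell of its (projected) marker is built in
#' the tangent plane of its own quadric patch by half-plane clipping
#' against all same-leaflet sites — periodic images included on periodic
#' axes — then clipped to the neighborhood square, lifted onto the quadric
#' and measured by fan triangulation.
#'
#' @param markers n x 3 matrix of same-leaflet marker positions.
#' @param patches list of `cb_quadric_patch`, one per marker row (entries
#'   may be `NULL` for failed fits).
#' @param box,periodic box geometry.
#' @param feet optional list of [project_markers()] results per patch; when
#'   `NULL` the Newton projection is computed here.
#' @param r_clip clipping half-width, nm (default: each patch's radius).
#' @return numeric vector of areas (nm^2), `NA` where the tessellation or
#'   fit failed.
#' @export
voronoi_areas <- function(markers, patches, box,
                          periodic = c(TRUE, TRUE, TRUE),
                          feet = NULL, r_clip = NULL) {
  n <- nrow(markers)
  areas <- rep(NA_real_, n)
  # pre-build periodic image shifts
  shifts <- as.matrix(expand.grid(
    x = if (periodic[1]) -1:1 else 0,
    y = if (periodic[2]) -1:1 else 0,
    z = if (periodic[3]) -1:1 else 0))
  shifts <- sweep(shifts, 2, box, "*")
  for (i in seq_len(n)) {
    patch <- patches[[i]]
    if (is.null(patch)) next
    rc <- if (is.null(r_clip)) patch$radius else r_clip
    Fm <- patch$frame
    # center-site foot point in local xy
    ft <- if (is.null(feet)) project_markers(patch) else feet[[i]]
    c_idx <- which(ft$id == i)  # first entry is the origin; later entries
                                # are periodic images of the center, which
                                # re-enter below as image candidates
    site <- c(ft$lx[c_idx[1]], ft$ly[c_idx[1]])
    # candidate sites: Newton feet for in-patch neighbors, tangent-projected
    # periodic images of every same-leaflet marker for the rest
    nb <- cbind(ft$lx[-c_idx], ft$ly[-c_idx])
    D0 <- sweep(markers, 2, markers[i, ])
    allxy <- NULL
    for (s in seq_len(nrow(shifts))) {
      Ds <- sweep(D0, 2, shifts[s, ], "+")
      keep <- rowSums(Ds * Ds) <= (2.5 * rc)^2
      keep[i] <- keep[i] & any(shifts[s, ] != 0)
      if (!any(keep)) next
      Lx <- Ds[keep, , drop = FALSE] %*% Fm
      allxy <- rbind(allxy, Lx[, 1:2, drop = FALSE])
    }
    # drop image candidates that duplicate the Newton feet (same marker at
    # zero shift); feet are more accurate, so keep feet and distant images
    others <- rbind(nb, allxy)
    # dedupe near-coincident sites
    if (nrow(others) > 1) {
      ord <- order(others[, 1], others[, 2])
      o <- others[ord, , drop = FALSE]
      dup <- c(FALSE, rowSums(abs(diff(o))) < 1e-6)
      others <- o[!dup, , drop = FALSE]
    }
    poly <- .voronoi_cell(site, others, rc)
    if (nrow(poly) >= 3) areas[i] <- .lifted_area(poly, patch$coef)
  }
  areas
}

# ---- full pipeline ----------------------------------------------------------

#' Reconstruct the membrane surface and per-lipid curvatures
#'
#' Runs the full per-frame pipeline: marker selection, leaflet assignment,
#' initial normals, iterative quadric fits, curvature extraction and
#' (optionally) Voronoi surface areas. Lipids whose fit fails are reported
#' with `NA` curvatures and excluded from downstream histograms; a frame
#' with more than 10% failures is flagged.
#'
#' @param frames a `cb_frame` or list of frames.
#' @param patch_radius quadric neighborhood radius, nm.
#' @param compute_areas also compute Voronoi areas (slower).
#' @param rule marker selection rule.
#' @param leaflet_method passed to [assign_leaflets()].
#' @param max_curvature reject fits whose principal curvature magnitude
#'   exceeds this bound (default `2/patch_radius`: radii smaller than half
#'   the patch radius cannot be resolved by the fit and indicate an
#'   unstable frame).
#' @return data.frame of class `cb_surface_table`: one row per lipid per
#'   frame with `frame`, `lipid_id`, `leaflet`, marker position, `k1`,
#'   `k2`, `Km`, `Kg`, `area`, `n_neighbors`, `residual`, `ok`; flagged
#'   frames are listed in `attr(x, "flagged_frames")`.
#' @export
compute_surface <- function(frames, patch_radius = 1.5,
                            compute_areas = TRUE, rule = marker_rule(),
                            leaflet_method = "auto",
                            max_curvature = 2 / patch_radius) {
  if (inherits(frames, "cb_frame")) frames <- list(frames)
  out <- vector("list", length(frames))
  flagged <- integer(0)
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    markers <- select_markers(fr, rule)
    la <- assign_leaflets(fr, markers, method = leaflet_method)
    res <- data.frame(frame = fi, lipid_id = markers$lipid_id,
                      leaflet = la$leaflet,
                      x = markers$x, y = markers$y, z = markers$z,
                      k1 = NA_real_, k2 = NA_real_, Km = NA_real_,
                      Kg = NA_real_, area = NA_real_,
                      n_neighbors = NA_integer_, residual = NA_real_,
                      ok = FALSE, stringsAsFactors = FALSE)
    for (lf in unique(la$leaflet)) {
      idx <- which(la$leaflet == lf)
      M <- as.matrix(markers[idx, c("x", "y", "z")])
      patches <- vector("list", length(idx))
      orient_m <- as.matrix(la[idx, c("ox", "oy", "oz")])
      for (j in seq_along(idx)) {
        cur <- tryCatch({
          r <- patch_radius
          for (g in 0:2) {  # grow the radius by 25% (twice) if short
            nb <- .neighbor_disps(M, j, r, fr$box, fr$periodic)
            if (nrow(nb$disp) >= 7L) break
            r <- r * 1.25
          }
          if (nrow(nb$disp) < 7L)
            stop("insufficient neighborhood")
          n0 <- .normal_from_disps(nb$disp, orient_m[j, ])
          fit <- .fit_quadric_core(nb$disp, n0)
          # robustness guards: a fit whose frame drifted far from the
          # covariance normal, failed to converge, or reports curvature
          # radii below the patch's resolving scale is unreliable
          if (!fit$converged || fit$normal_drift > 45)
            stop("unstable quadric fit")
          patches[[j]] <- structure(list(
            center = j, origin = M[j, ], frame = fit$frame,
            coef = fit$coef, neighbors = nb$ids[nb$ids != j],
            local = fit$local, local_ids = nb$ids,
            residual = fit$residual,
            n_neighbors = length(nb$ids) - 1L,
            radius = r), class = "cb_quadric_patch")
          cv <- curvature_from_patch(patches[[j]])
          if (max(abs(c(cv$k1, cv$k2))) > max_curvature)
            stop("curvature beyond the patch resolving scale")
          cv
        }, error = function(err) NULL)
        if (is.null(cur)) { patches[j] <- list(NULL); next }
        row <- idx[j]
        res$k1[row] <- cur$k1; res$k2[row] <- cur$k2
        res$Km[row] <- cur$Km; res$Kg[row] <- cur$Kg
        res$n_neighbors[row] <- patches[[j]]$n_neighbors
        res$residual[row] <- patches[[j]]$residual
        res$ok[row] <- TRUE
      }
      if (compute_areas) {
        ar <- voronoi_areas(M, patches, fr$box, fr$periodic)
        res$area[idx] <- ar
      }
    }
    if (mean(!res$ok) > 0.1) flagged <- c(flagged, fi)
    out[[fi]] <- res
  }
  tab <- do.call(rbind, out)
  attr(tab, "flagged_frames") <- flagged
  class(tab) <- c("cb_surface_table", class(tab))
  tab
}

#' Write a surface table as TSV
#' @param table a `cb_surface_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
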