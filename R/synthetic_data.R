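# Synthetic curved-bilayer generator.
#
# Produces marker lattices on flat, buckled (single-mode sinusoid),
# cylindrical-sector and spherical surfaces with analytic per-lipid
# curvature ground truth, instantiates coarse collinear lipids around the
# markers, and places ions with a configurable curvature-biased adsorption
# model. All randomness is driven by the spec seed.

#' Parameterization of a synthetic membrane system
#'
#' @param surface_kind one of `"flat"`, `"buckle"`, `"cylinder"`, `"sphere"`.
#' @param n_lipids_per_leaflet lipids per leaflet; `NULL` derives it from the
#'   geometry and `area_per_lipid` (sphere/cylinder).
#' @param area_per_lipid area per lipid in nm^2 on the reference (outer)
#'   leaflet surface.
#' @param leaflet_separation distance between the two leaflets' marker
#'   surfaces, nm.
#' @param n_leaflets 2 for a bilayer, 1 for a bare marker lattice (oracle
#'   geometries).
#' @param buckle_amplitude,buckle_wavelength sinusoid amplitude A and
#'   wavelength lambda (nm) of the buckled midline z = A sin(2 pi x/lambda).
#' @param cylinder_radius radius (nm) of the convex-leaflet lattice; its
#'   reciprocal is the nominal enforced curvature.
#' @param sector_angle angular width (rad) of the cylindrical sector.
#' @param sphere_radius radius (nm) of the convex-leaflet lattice.
#' @param ion_to_lipid_ratio ions per lipid (default 1:2 as in typical
#'   Ca2+ binding setups).
#' @param free_fraction nominal fraction of ions left free in solvent when
#'   the binding bias is zero.
#' @param binding_bias_alpha slope (nm) of the log binding probability vs
#'   mean curvature; positive values favor negative (concave) curvature.
#' @param contact_distance nm, distance at which a bound ion is placed from
#'   its anchoring lipid site (must be below the analysis contact cutoff).
#' @param jitter_sigma Gaussian positional noise per atom, nm.
#' @param n_frames number of independent jitter/ion realizations.
#' @param seed integer RNG seed.
#' @param box optional 3-vector (nm); derived from the geometry when `NULL`.
#' @return a validated `cb_synthetic_spec` object.
#' @export
synthetic_spec <- function(surface_kind = c("flat", "buckle", "cylinder",
                                            "sphere"),
                           n_lipids_per_leaflet = 64,
                           area_per_lipid = 0.65,
                           leaflet_separation = 3.8,
                           n_leaflets = 2,
                           buckle_amplitude = 2,
                           buckle_wavelength = 20.5,
                           cylinder_radius = 5,
                           sector_angle = pi,
                           sphere_radius = 10,
                           ion_to_lipid_ratio = 0.5,
                           free_fraction = 0.2,
                           binding_bias_alpha = 0,
                           contact_distance = 0.25,
                           jitter_sigma = 0.05,
                           n_frames = 1,
                           seed = 1,
                           box = NULL) {
  surface_kind <- match.arg(surface_kind)
  if (is.null(n_lipids_per_leaflet)) {
    area <- switch(surface_kind,
      sphere = 4 * pi * sphere_radius^2,
      cylinder = stop("n_lipids_per_leaflet required for cylinder"),
      stop("n_lipids_per_leaflet required for ", surface_kind))
    n_lipids_per_leaflet <- round(area / area_per_lipid)
  }
  spec <- structure(list(
    surface_kind = surface_kind,
    n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
    area_per_lipid = area_per_lipid,
    leaflet_separation = leaflet_separation,
    n_leaflets = as.integer(n_leaflets),
    buckle_amplitude = buckle_amplitude,
    buckle_wavelength = buckle_wavelength,
    cylinder_radius = cylinder_radius,
    sector_angle = sector_angle,
    sphere_radius = sphere_radius,
    ion_to_lipid_ratio = ion_to_lipid_ratio,
    free_fraction = free_fraction,
    binding_bias_alpha = binding_bias_alpha,
    contact_distance = contact_distance,
    jitter_sigma = jitter_sigma,
    n_frames = as.integer(n_frames),
    seed = as.integer(seed),
    box = box), class = "cb_synthetic_spec")
  validate_synthetic_spec(spec)
}

#' @rdname synthetic_spec
#' @param spec a `cb_synthetic_spec`.
#' @export
validate_synthetic_spec <- function(spec) {
  stopifnot(inherits(spec, "cb_synthetic_spec"))
  with(spec, {
    if (n_lipids_per_leaflet < 4) stop("need at least 4 lipids per leaflet")
    if (area_per_lipid <= 0) stop("area_per_lipid must be positive")
    if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
    if (n_frames < 1) stop("n_frames must be >= 1")
    if (ion_to_lipid_ratio < 0) stop("ion_to_lipid_ratio must be >= 0")
    if (free_fraction < 0 || free_fraction >= 1)
      stop("free_fraction must be in [0, 1)")
    if (!n_leaflets %in% 1:2) stop("n_leaflets must be 1 or 2")
    if (surface_kind == "cylinder") {
      if (cylinder_radius <= 0) stop("cylinder_radius must be positive")
      if (n_leaflets == 2 && leaflet_separation >= cylinder_radius)
        stop("leaflet_separation >= cylinder_radius: geometry infeasible")
      if (sector_angle <= 0 || sector_angle > 2 * pi)
        stop("sector_angle must be in (0, 2*pi]")
    }
    if (surface_kind == "sphere") {
      if (sphere_radius <= 0) stop("sphere_radius must be positive")
      if (n_leaflets == 2 && leaflet_separation >= sphere_radius)
        stop("leaflet_separation >= sphere_radius: geometry infeasible")
      area <- 4 * pi * sphere_radius^2
      if (abs(n_lipids_per_leaflet * area_per_lipid - area) > area_per_lipid)
        stop("n_lipids_per_leaflet * area_per_lipid inconsistent with ",
             "sphere area (off by more than one lipid)")
    }
    if (surface_kind == "buckle") {
      if (buckle_wavelength <= 0) stop("buckle_wavelength must be positive")
      if (buckle_amplitude < 0) stop("buckle_amplitude must be >= 0")
      if (!is.null(box) && abs(box[1] - buckle_wavelength) > 1e-9)
        stop("box x-length must equal buckle_wavelength")
    }
  })
  spec
}

#' Coarse lipid site template
#'
#' Lipids are reduced to labeled heavy-atom sites on a line along the
#' lipid's inward axis: serine-moiety head sites, phosphate sites (the
#' first of which, named `P`, is the surface marker), ester-carbonyl sites
#' and tail sites. Offsets are nm from the head end, strictly increasing
#' toward the tail.
#'
#' @param groups data.frame with columns `group` (`head`, `po4`, `carbo`,
#'   `tail`), `offset` (nm, start of the group) and `n_sites`; sites within
#'   a group are spaced by `site_spacing` along the axis.
#' @param site_spacing nm between consecutive sites of one group.
#' @return a `cb_lipid_template`.
#' @export
lipid_template <- function(groups = data.frame(
                             group = c("head", "po4", "carbo", "tail"),
                             offset = c(0, 0.35, 0.85, 1.35),
                             n_sites = c(3L, 2L, 2L, 4L)),
                           site_spacing = 0.08) {
  stopifnot(all(c("group", "offset", "n_sites") %in% names(groups)))
  if (!all(groups$group %in% c("head", "po4", "carbo", "tail")))
    stop("template groups must be head, po4, carbo, tail")
  if (is.unsorted(groups$offset, strictly = TRUE))
    stop("group offsets must be strictly increasing from head to tail")
  if (!"po4" %in% groups$group || groups$n_sites[groups$group == "po4"] < 1)
    stop("template needs at least one po4 (marker) site")
  # expand to per-site table with atom names
  prefix <- c(head = "SE", po4 = "OP", carbo = "CB", tail = "CT")
  sites <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups$group[i]
    k <- groups$n_sites[i]
    nm <- paste0(prefix[[g]], seq_len(k))
    if (g == "po4") nm[1] <- "P"
    data.frame(group = g, name = nm,
               offset = groups$offset[i] + (seq_len(k) - 1L) * site_spacing,
               stringsAsFactors = FALSE)
  }))
  structure(list(groups = groups, sites = sites), class = "cb_lipid_template")
}

# ---- surface lattices -------------------------------------------------------

# pick grid dimensions n1 x n2 = n with aspect close to L1/L2
.grid_dims <- function(n, L1, L2) {
  divs <- which(n %% seq_len(n) == 0)
  tgt <- sqrt(n * L1 / L2)
  n1 <- divs[which.min(abs(divs - tgt))]
  c(n1, n / n1)
}

# arc length of z = A sin(2 pi x / lambda) from 0 to x (vectorized, dense grid)
.buckle_arclen_fun <- function(A, lambda) {
  xs <- seq(0, lambda, length.out = 4097)
  dz <- A * (2 * pi / lambda) * cos(2 * pi * xs / lambda)
  seg <- sqrt(1 + dz^2)
  # trapezoid cumulative integral
  cum <- c(0, cumsum((seg[-1] + seg[-length(seg)]) / 2 * diff(xs)))
  list(total = cum[length(cum)],
       x_of_s = stats::approxfun(cum, xs, rule = 2),
       s_of_x = stats::approxfun(xs, cum, rule = 2))
}

.surface_flat <- function(spec) {
  n <- spec$n_lipids_per_leaflet
  L <- sqrt(n * spec$area_per_lipid)
  if (!is.null(spec$box)) {
    if (abs(spec$box[1] * spec$box[2] - n * spec$area_per_lipid) >
        spec$area_per_lipid)
      stop("box xy area inconsistent with n_lipids * area_per_lipid")
    Lx <- spec$box[1]; Ly <- spec$box[2]
  } else Lx <- Ly <- L
  margin <- 3
  Lz <- spec$leaflet_separation + 2 * margin
  dims <- .grid_dims(n, Lx, Ly)
  gx <- (seq_len(dims[1]) - 0.5) * Lx / dims[1]
  gy <- (seq_len(dims[2]) - 0.5) * Ly / dims[2]
  g <- expand.grid(x = gx, y = gy)
  z0 <- Lz / 2
  leaf <- function(side) {  # side +1 upper, -1 lower
    data.frame(leaflet = if (side > 0) "upper" else "lower",
               x = g$x, y = g$y,
               z = z0 + side * spec$leaflet_separation / 2,
               nx = 0, ny = 0, nz = side,
               s = g$x, is_cap = FALSE,
               k1 = 0, k2 = 0)
  }
  sides <- if (spec$n_leaflets == 2) c(1, -1) else 1
  list(markers = do.call(rbind, lapply(sides, leaf)),
       box = c(Lx, Ly, Lz), periodic = c(TRUE, TRUE, FALSE))
}

.surface_buckle <- function(spec) {
  A <- spec$buckle_amplitude; lambda <- spec$buckle_wavelength
  n <- spec$n_lipids_per_leaflet
  arc <- .buckle_arclen_fun(A, lambda)
  Ly <- n * spec$area_per_lipid / arc$total
  margin <- 2.5
  Lz <- 2 * (A + spec$leaflet_separation / 2 + margin)
  dims <- .grid_dims(n, arc$total, Ly)
  # equal-arc-length columns so markers cover the surface quasi-uniformly
  sx <- (seq_len(dims[1]) - 0.5) * arc$total / dims[1]
  gx <- arc$x_of_s(sx)
  gy <- (seq_len(dims[2]) - 0.5) * Ly / dims[2]
  g <- expand.grid(ix = seq_len(dims[1]), y = gy)
  x <- gx[g$ix]
  s <- sx[g$ix]
  z0 <- Lz / 2
  q <- 2 * pi / lambda
  zm <- A * sin(q * x)
  zp <- A * q * cos(q * x)
  zpp <- -A * q^2 * sin(q * x)
  kappa <- zpp / (1 + zp^2)^1.5   # signed curvature, upward normal
  nrm <- sqrt(1 + zp^2)
  leaf <- function(side) {
    # vertical leaflet offset keeps each leaflet an exact sinusoid, so the
    # analytic curvature is the midline formula on both leaflets
    data.frame(leaflet = if (side > 0) "upper" else "lower",
               x = x, y = g$y,
               z = z0 + zm + side * spec$leaflet_separation / 2,
               nx = side * (-zp) / nrm, ny = 0, nz = side * 1 / nrm,
               s = s, is_cap = FALSE,
               # outward-normal sign convention: concave toward water < 0
               k1 = pmax(-side * kappa, 0), k2 = pmin(-side * kappa, 0))
  }
  sides <- if (spec$n_leaflets == 2) c(1, -1) else 1
  list(markers = do.call(rbind, lapply(sides, leaf)),
       box = c(lambda, Ly, Lz), periodic = c(TRUE, TRUE, FALSE))
}

.surface_cylinder <- function(spec) {
  R <- spec$cylinder_radius; Th <- spec$sector_angle
  n <- spec$n_lipids_per_leaflet
  Ly <- n * spec$area_per_lipid / (R * Th)
  margin <- 3
  Lx <- 2 * R + 2 * margin
  Lz <- 2 * R + 2 * margin
  cx <- Lx / 2; cz <- Lz / 2
  leaf <- function(r, leaflet, side) {  # side +1: normal outward (radial+)
    dims <- .grid_dims(n, r * Th, Ly)
    th <- -Th / 2 + (seq_len(dims[1]) - 0.5) * Th / dims[1]
    gy <- (seq_len(dims[2]) - 0.5) * Ly / dims[2]
    g <- expand.grid(ith = seq_len(dims[1]), y = gy)
    theta <- th[g$ith]
    nx <- sin(theta); nz <- cos(theta)
    k <- side / r   # signed principal curvature along the bent direction
    edge <- g$ith == 1L | g$ith == dims[1]
    data.frame(leaflet = leaflet,
               x = cx + r * nx, y = g$y, z = cz + r * nz,
               nx = side * nx, ny = 0, nz = side * nz,
               s = r * (theta + Th / 2), is_cap = edge,
               k1 = pmax(k, 0), k2 = pmin(k, 0))
  }
  m <- leaf(R, "convex", +1)
  if (spec$n_leaflets == 2)
    m <- rbind(m, leaf(R - spec$leaflet_separation, "concave", -1))
  list(markers = m, box = c(Lx, Ly, Lz), periodic = c(FALSE, TRUE, FALSE))
}

.surface_sphere <- function(spec) {
  R <- spec$sphere_radius
  n <- spec$n_lipids_per_leaflet
  margin <- 3
  L <- 2 * R + 2 * margin
  c0 <- L / 2
  fib <- function(m) {  # Fibonacci sphere lattice, quasi-uniform
    i <- seq_len(m) - 0.5
    phi <- acos(1 - 2 * i / m)
    th <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  }
  leaf <- function(r, leaflet, side) {
    u <- fib(n)
    k <- side / r
    data.frame(leaflet = leaflet,
               x = c0 + r * u[, 1], y = c0 + r * u[, 2], z = c0 + r * u[, 3],
               nx = side * u[, 1], ny = side * u[, 2], nz = side * u[, 3],
               s = NA_real_, is_cap = FALSE,
               k1 = k, k2 = k)  # umbilic: k1 = k2 = side/r
  }
  m <- leaf(R, "convex", +1)
  if (spec$n_leaflets == 2)
    m <- rbind(m, leaf(R - spec$leaflet_separation, "concave", -1))
  list(markers = m, box = c(L, L, L), periodic = c(FALSE, FALSE, FALSE))
}

#' Generate a marker lattice with analytic curvature ground truth
#'
#' Builds a quasi-uniform lattice of one surface marker per lipid on the
#' requested geometry, two leaflets separated by `leaflet_separation`, with
#' outward (water-side) unit normals and exact principal curvatures under
#' the package sign convention (leaflet bending toward its water side, i.e.
#' concave as seen from the water, has negative mean curvature).
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class `cb_surface` with elements `markers` (data.frame:
#'   `lipid_id`, `leaflet`, position, outward normal, arc coordinate `s`,
#'   `is_cap` edge flag), `truth` (data.frame: `lipid_id`, `leaflet`, `k1`,
#'   `k2`, `Km`, `Kg`), `box`, `periodic` and `spec`.
#' @export
generate_surface <- function(spec) {
  validate_synthetic_spec(spec)
  geo <- switch(spec$surface_kind,
    flat = .surface_flat(spec),
    buckle = .surface_buckle(spec),
    cylinder = .surface_cylinder(spec),
    sphere = .surface_sphere(spec))
  m <- geo$markers
  m$lipid_id <- seq_len(nrow(m))
  k1 <- pmax(m$k1, m$k2); k2 <- pmin(m$k1, m$k2)
  truth <- data.frame(lipid_id = m$lipid_id, leaflet = m$leaflet,
                      k1 = k1, k2 = k2,
                      Km = (k1 + k2) / 2, Kg = k1 * k2)
  m$k1 <- NULL; m$k2 <- NULL
  m <- m[, c("lipid_id", "leaflet", "x", "y", "z", "nx", "ny", "nz",
             "s", "is_cap")]
  structure(list(markers = m, truth = truth, box = geo$box,
                 periodic = geo$periodic, spec = spec),
            class = "cb_surface")
}

# ---- lipid instantiation ----------------------------------------------------

#' Instantiate coarse lipids around surface markers
#'
#' Each lipid receives heavy-atom sites at the template offsets along its
#' inward axis (minus the outward normal), plus isotropic Gaussian jitter
#' of width `spec$jitter_sigma` applied to every site. The site at the
#' template's marker position (atom name `P`) lands on the lattice marker
#' before jitter.
#'
#' @param surface a `cb_surface` from [generate_surface()].
#' @param template a [lipid_template()].
#' @param spec the generating spec (defaults to `surface$spec`).
#' @return a `cb_frame` of lipid atoms.
#' @export
instantiate_lipids <- function(surface, template = lipid_template(),
                               spec = surface$spec) {
  m <- surface$markers
  sites <- template$sites
  marker_off <- sites$offset[sites$name == "P"][1]
  ns <- nrow(sites)
  nl <- nrow(m)
  inward <- -as.matrix(m[, c("nx", "ny", "nz")])
  rel <- sites$offset - marker_off
  pos <- matrix(0, nl * ns, 3)
  idx <- rep(seq_len(nl), each = ns)
  base <- as.matrix(m[, c("x", "y", "z")])[idx, , drop = FALSE]
  pos <- base + inward[idx, , drop = FALSE] * rep(rel, nl)
  if (spec$jitter_sigma > 0)
    pos <- pos + matrix(stats::rnorm(length(pos), 0, spec$jitter_sigma),
                        ncol = 3)
  atoms <- data.frame(
    atom_id = seq_len(nl * ns),
    mol_id = m$lipid_id[idx],
    mol_kind = "lipid",
    species = "SYNT",
    name = rep(sites$name, nl),
    group = rep(sites$group, nl),
    heavy = TRUE,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    stringsAsFactors = FALSE)
  cb_frame(atoms, surface$box, surface$periodic, time = 0)
}

# ---- ion placement ----------------------------------------------------------

# one solvent-region point for the given geometry
.solvent_point <- function(surface) {
  spec <- surface$spec
  box <- surface$box
  m <- surface$markers
  switch(spec$surface_kind,
    flat = ,
    buckle = {
      zmax <- max(m$z); zmin <- min(m$z)
      pad <- 1.8  # beyond lipid tails + 2x contact cutoff
      up <- stats::runif(1) < 0.5
      z <- if (up) stats::runif(1, min(zmax + pad, box[3] - 0.1), box[3] - 0.1)
           else stats::runif(1, 0.1, max(zmin - pad, 0.1))
      c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]), z)
    },
    cylinder = {
      r_out <- spec$cylinder_radius + 2.2
      th <- stats::runif(1, -spec$sector_angle / 2, spec$sector_angle / 2)
      r <- min(r_out, box[1] / 2 - 0.1)
      c(box[1] / 2 + r * sin(th), stats::runif(1, 0, box[2]),
        box[3] / 2 + r * cos(th))
    },
    sphere = {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      r <- min(spec$sphere_radius + 2.2, box[1] / 2 - 0.1)
      box / 2 + r * u
    })
}

#' Place ions with a curvature-biased adsorption model
#'
#' `round(ratio * n_lipids)` ions are appended to the frame. Ions are split
#' evenly between leaflets; each ion then chooses, within its leaflet,
#' between staying free in solvent (weight `n * f/(1 - f)`, where `f` is the
#' nominal free fraction at zero bias) and binding lipid `i` (weight
#' `exp(-alpha * Km_i)` with `Km_i` the analytic ground-truth mean
#' curvature). Bound ions are placed `contact_distance` nm from a randomly
#' chosen head/po4 site of the host lipid; free ions are placed in the
#' solvent region, at least twice the typical contact cutoff from any lipid
#' heavy atom.
#'
#' @param frame lipid `cb_frame` from [instantiate_lipids()].
#' @param surface the generating `cb_surface` (carries ground truth).
#' @param alpha binding bias slope (nm); `NULL` uses the spec value.
#' @param ratio ion-to-lipid ratio; `NULL` uses the spec value.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return the frame with ion atoms appended; the intended placement is
#'   attached as `attr(frame, "ion_placement")` (data.frame: `ion_id`,
#'   `host_lipid_id` (NA when free), `leaflet`).
#' @export
place_ions <- function(frame, surface, alpha = NULL, ratio = NULL,
                       seed = NULL) {
  spec <- surface$spec
  if (is.null(alpha)) alpha <- spec$binding_bias_alpha
  if (is.null(ratio)) ratio <- spec$ion_to_lipid_ratio
  if (!is.null(seed)) set.seed(seed)
  if (ratio < 0) stop("ion_to_lipid_ratio must be >= 0")
  tr <- surface$truth
  n_lip <- nrow(tr)
  n_ion <- round(ratio * n_lip)
  if (n_ion == 0) {
    attr(frame, "ion_placement") <-
      data.frame(ion_id = integer(0), host_lipid_id = integer(0),
                 leaflet = character(0))
    return(frame)
  }
  leaflets <- unique(tr$leaflet)
  ion_leaf <- rep(leaflets, length.out = n_ion)
  f <- spec$free_fraction
  a <- frame$atoms
  heavy_sites <- a[a$group %in% c("head", "po4"), , drop = FALSE]
  site_rows <- split(seq_len(nrow(heavy_sites)), heavy_sites$mol_id)
  lip_heavy <- as.matrix(a[a$mol_kind == "lipid" & a$heavy,
                           c("x", "y", "z")])
  # per-leaflet host tables and adsorption weights, computed once
  leaf_tabs <- lapply(leaflets, function(lf) {
    sub <- tr[tr$leaflet == lf, , drop = FALSE]
    w <- exp(-alpha * sub$Km)
    list(ids = sub$lipid_id,
         prob = c(w, nrow(sub) * f / (1 - f)))
  })
  names(leaf_tabs) <- leaflets
  hosts <- integer(n_ion)
  pos <- matrix(0, n_ion, 3)
  for (i in seq_len(n_ion)) {
    lt <- leaf_tabs[[ion_leaf[i]]]
    pick <- sample.int(length(lt$prob), 1L, prob = lt$prob)
    if (pick > length(lt$ids)) {  # free ion
      hosts[i] <- NA_integer_
      for (try in 1:25) {
        p <- .solvent_point(surface)
        if (min(.mi_dist2(lip_heavy, p, frame$box, frame$periodic)) >=
            0.6^2) break
      }
      pos[i, ] <- p
    } else {
      host <- lt$ids[pick]
      hosts[i] <- host
      rows <- site_rows[[as.character(host)]]
      site <- heavy_sites[rows[sample.int(length(rows), 1L)], ]
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      pos[i, ] <- c(site$x, site$y, site$z) + spec$contact_distance * u
    }
  }
  max_id <- max(a$mol_id)
  ions <- data.frame(
    atom_id = max(a$atom_id) + seq_len(n_ion),
    mol_id = max_id + seq_len(n_ion),
    mol_kind = "ion", species = "CA", name = "CA", group = "none",
    heavy = TRUE, x = pos[, 1], y = pos[, 2], z = pos[, 3],
    stringsAsFactors = FALSE)
  out <- cb_frame(rbind(a, ions), frame$box, frame$periodic, frame$time)
  attr(out, "ion_placement") <- data.frame(
    ion_id = ions$mol_id, host_lipid_id = hosts, leaflet = ion_leaf,
    stringsAsFactors = FALSE)
  out
}

# ---- frame emission ---------------------------------------------------------

#' Generate a frame sequence around one mean geometry
#'
#' Draws `spec$n_frames` independent jitter and ion realizations around the
#' same marker lattice. The whole sequence is reproducible from
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param template a [lipid_template()].
#' @return list with `frames` (list of `cb_frame`, time-stamped 1 ps apart),
#'   `surface` (the shared `cb_surface` ground truth) and `placements`
#'   (per-frame ion placement tables).
#' @export
generate_frames <- function(spec, template = lipid_template()) {
  set.seed(spec$seed)
  surface <- generate_surface(spec)
  frames <- vector("list", spec$n_frames)
  placements <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    fr <- instantiate_lipids(surface, template, spec)
    fr <- place_ions(fr, surface)
    fr$time <- k - 1
    placements[[k]] <- attr(fr, "ion_placement")
    frames[[k]] <- fr
  }
  list(frames = frames, surface = surface, placements = placements)
}

#' Write a generated system to disk
#'
#' Writes the frame sequence (GRO by default, PDB on request), the analytic
#' ground truth as a TSV sidecar (`lipid_id`, `leaflet`, `k1`, `k2`, `Km`,
#' `Kg`) and the generating spec as YAML.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if missing).
#' @param template a [lipid_template()].
#' @param format `"gro"` or `"pdb"`.
#' @return invisibly, the list from [generate_frames()].
#' @export
emit_frames <- function(spec, out_dir, template = lipid_template(),
                        format = "gro") {
  gen <- generate_frames(spec, template)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_frames(gen$frames, file.path(out_dir, paste0("frames.", format)))
  utils::write.table(gen$surface$truth,
                     file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sp <- gen$surface$spec
  yaml::write_yaml(unclass(sp)[!vapply(unclass(sp), is.null, TRUE)],
                   file.path(out_dir, "spec.yaml"))
  invisible(gen)
}

#' Read a synthetic spec back from YAML
#' @param path YAML file written by [emit_frames()].
#' @return a `cb_synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  do.call(synthetic_spec, yaml::read_yaml(path))
}
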