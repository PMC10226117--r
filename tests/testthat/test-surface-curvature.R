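# closed-form oracles: plane, sphere, cylinder, explicit Monge patches

test_that("quadric curvature formulas reproduce closed forms", {
  mk_patch <- function(co) {
    structure(list(frame = diag(3),
                   coef = stats::setNames(unname(co),
                                          c("a", "b", "c", "d", "e", "f"))),
              class = "cb_quadric_patch")
  }
  flat <- curvature_from_patch(mk_patch(c(0, 0, 0, 0, 0, 0)))
  expect_equal(flat$k1, 0); expect_equal(flat$Km, 0); expect_equal(flat$Kg, 0)

  # bowl bending away from the outward normal: sphere-like, positive Km
  # (surface z = -(x^2+y^2)/(2R) under the water-side normal +z)
  sph <- curvature_from_patch(mk_patch(c(-0.05, -0.05, 0, 0, 0, 0)))
  expect_equal(sph$Km, 0.1)
  expect_equal(sph$Kg, 0.01)
  expect_equal(sph$k1, sph$k2)

  # cylinder Monge patch a = -0.1: k1 = 0.2, k2 = 0
  cyl <- curvature_from_patch(mk_patch(c(-0.1, 0, 0, 0, 0, 0)))
  expect_equal(cyl$k1, 0.2); expect_equal(cyl$k2, 0)
  expect_equal(cyl$Km, 0.1); expect_equal(cyl$Kg, 0)

  # tilted-frame gradient terms enter through the full Monge formula
  co <- c(a = 0.03, b = -0.02, c = 0.01, d = 0.2, e = -0.1, f = 0)
  got <- curvature_from_patch(mk_patch(co))
  w <- 1 + co[["d"]]^2 + co[["e"]]^2
  H_ref <- -((1 + co[["e"]]^2) * 2 * co[["a"]] -
             2 * co[["d"]] * co[["e"]] * co[["c"]] +
             (1 + co[["d"]]^2) * 2 * co[["b"]]) / (2 * w^1.5)
  K_ref <- (4 * co[["a"]] * co[["b"]] - co[["c"]]^2) / w^2
  expect_equal(got$Km, H_ref)
  expect_equal(got$Kg, K_ref)
  expect_equal(got$Km, (got$k1 + got$k2) / 2)
  expect_equal(got$Kg, got$k1 * got$k2)
  expect_true(got$k1 >= got$k2)
})

test_that("quadric fit recovers an exact model surface to 1e-10", {
  g <- expand.grid(x = seq(-1, 1, by = 0.25), y = seq(-1, 1, by = 0.25))
  M <- cbind(g$x, g$y, g$x^2)  # z = x^2
  ctr <- which(g$x == 0 & g$y == 0)
  patch <- fit_quadric(M, ctr, c(0, 0, 1), radius = 3, box = c(10, 10, 10),
                       periodic = c(FALSE, FALSE, FALSE))
  expect_equal(unname(patch$coef["a"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(patch$coef[c("b", "c", "d", "e", "f")])), 1e-10)
  expect_lt(patch$residual, 1e-10)

  # flat lattice: all coefficients vanish
  Mf <- cbind(g$x, g$y, 0)
  pf <- fit_quadric(Mf, ctr, c(0, 0, 1), 3, c(10, 10, 10),
                    c(FALSE, FALSE, FALSE))
  expect_lt(max(abs(pf$coef)), 1e-12)

  # collinear neighbors cannot determine a quadric
  Mc <- cbind(seq(-1, 1, by = 0.2), 0, 0)
  expect_error(fit_quadric(Mc, 6, c(0, 0, 1), 3, c(10, 10, 10),
                           c(FALSE, FALSE, FALSE)),
               "rank-deficient")
})

test_that("initial normals align with exact geometry on spheres/cylinders", {
  sph <- generate_surface(synthetic_spec(
    "sphere", n_lipids_per_leaflet = NULL, sphere_radius = 10,
    n_leaflets = 1))
  M <- as.matrix(sph$markers[, c("x", "y", "z")])
  ctr <- colMeans(M)
  deg <- function(u, v) acos(min(1, abs(sum(u * v)))) * 180 / pi
  set.seed(8)
  for (i in sample(nrow(M), 25)) {
    radial <- (M[i, ] - ctr) / sqrt(sum((M[i, ] - ctr)^2))
    n <- initial_normal(M, i, radius = 2.5, box = sph$box,
                        periodic = sph$periodic, orient = radial)
    expect_lt(deg(n, radial), 2)
  }
  cyl <- generate_surface(synthetic_spec(
    "cylinder", n_lipids_per_leaflet = 128, cylinder_radius = 5,
    n_leaflets = 1))
  Mc <- as.matrix(cyl$markers[, c("x", "y", "z")])
  nrm <- as.matrix(cyl$markers[, c("nx", "ny", "nz")])
  interior <- which(!cyl$markers$is_cap)
  for (i in interior[seq(1, length(interior), by = 9)]) {
    n <- initial_normal(Mc, i, 1.5, cyl$box, cyl$periodic, orient = nrm[i, ])
    expect_lt(deg(n, nrm[i, ]), 1)
    expect_lt(abs(n[2]), 0.02)  # orthogonal to the cylinder axis
  }
})

test_that("noiseless sphere fit recovers 1/(2R) quadratic coefficients", {
  sph <- generate_surface(synthetic_spec(
    "sphere", n_lipids_per_leaflet = NULL, sphere_radius = 10,
    n_leaflets = 1))
  M <- as.matrix(sph$markers[, c("x", "y", "z")])
  ctr <- colMeans(M)
  i <- 57
  radial <- (M[i, ] - ctr) / sqrt(sum((M[i, ] - ctr)^2))
  patch <- fit_quadric(M, i, radial, 2.5, sph$box, sph$periodic)
  # surface curves away from the outward normal: a, b ~ -1/(2R)
  expect_equal(unname(patch$coef["a"]), -0.05, tolerance = 0.02)
  expect_equal(unname(patch$coef["b"]), -0.05, tolerance = 0.02)
})

test_that("marker projection lands on the quadric and matches sphere geometry", {
  g <- expand.grid(x = seq(-1, 1, by = 0.25), y = seq(-1, 1, by = 0.25))
  R <- 10
  z <- R - sqrt(R^2 - g$x^2 - g$y^2)   # sphere cap, center at (0,0,R)
  M <- cbind(g$x, g$y, z)
  ctr <- which(g$x == 0 & g$y == 0)
  patch <- fit_quadric(M, ctr, c(0, 0, 1), 3, c(50, 50, 50),
                       periodic = c(FALSE, FALSE, FALSE))
  feet <- project_markers(patch)
  # feet satisfy the quadric equation
  co <- patch$coef
  zq <- co["a"] * feet$lx^2 + co["b"] * feet$ly^2 + co["c"] * feet$lx *
    feet$ly + co["d"] * feet$lx + co["e"] * feet$ly + co["f"]
  expect_equal(feet$lz, unname(zq), tolerance = 1e-9)
  # displacement from each marker is below the fit residual scale
  L <- patch$local
  d <- sqrt((feet$lx - L[, 1])^2 + (feet$ly - L[, 2])^2 +
            (feet$lz - L[, 3])^2)
  expect_lt(max(d), 1e-3)
  # a point already on the quadric projects onto itself
  q0 <- c(0.4, -0.3)
  z0 <- co["a"] * q0[1]^2 + co["b"] * q0[2]^2 + co["c"] * q0[1] * q0[2] +
    co["d"] * q0[1] + co["e"] * q0[2] + co["f"]
  foot0 <- curvbind:::.project_point(co, c(q0, z0))
  expect_equal(unname(foot0), unname(c(q0, z0)), tolerance = 1e-9)
  # flat patch: foot keeps (x, y), lands at z = 0
  co_flat <- stats::setNames(numeric(6), c("a", "b", "c", "d", "e", "f"))
  expect_equal(curvbind:::.project_point(co_flat, c(0.2, 0.7, 0.5)),
               c(0.2, 0.7, 0))
})

test_that("Voronoi areas are exact on a flat lattice and tile the box", {
  sp <- synthetic_spec("flat", n_lipids_per_leaflet = 64, jitter_sigma = 0)
  gen <- generate_frames(sp)
  st <- compute_surface(gen$frames[[1]])
  s2 <- sp$area_per_lipid
  expect_equal(unique(round(st$area, 9)), s2)
  # jittered markers still tile the periodic leaflet exactly
  spj <- synthetic_spec("flat", n_lipids_per_leaflet = 64,
                        jitter_sigma = 0.05, seed = 2)
  stj <- compute_surface(generate_frames(spj)$frames[[1]])
  box_area <- gen$frames[[1]]$box[1] * gen$frames[[1]]$box[2]
  for (lf in c("upper", "lower"))
    expect_equal(sum(stj$area[stj$leaflet == lf]), box_area,
                 tolerance = 0.005)
})

test_that("sphere Voronoi areas total the analytic surface area within 2%", {
  st <- cached("sphere_surface", {
    sp <- synthetic_spec("sphere", n_lipids_per_leaflet = NULL,
                         sphere_radius = 10, n_leaflets = 1,
                         jitter_sigma = 0, ion_to_lipid_ratio = 0)
    compute_surface(generate_frames(sp)$frames[[1]])
  })
  expect_equal(sum(st$area, na.rm = TRUE), 4 * pi * 100, tolerance = 0.02)
})

test_that("estimated curvatures hit closed forms on noiseless lattices", {
  # sphere R = 10: Km = +0.1, Kg = +0.01, within 2%
  st <- cached("sphere_surface", {
    sp <- synthetic_spec("sphere", n_lipids_per_leaflet = NULL,
                         sphere_radius = 10, n_leaflets = 1,
                         jitter_sigma = 0, ion_to_lipid_ratio = 0)
    compute_surface(generate_frames(sp)$frames[[1]])
  })
  expect_true(all(st$ok))
  expect_equal(mean(st$Km), 0.1, tolerance = 0.02)
  expect_lt(max(abs(st$Km - 0.1) / 0.1), 0.02)
  expect_equal(mean(st$Kg), 0.01, tolerance = 0.02)

  # cylinder R = 5: (k1, k2) = (0.2, 0) within 2% away from sector edges
  cy <- cached("cylinder_surface", {
    sp <- synthetic_spec("cylinder", n_lipids_per_leaflet = 128,
                         cylinder_radius = 5, n_leaflets = 1,
                         jitter_sigma = 0, ion_to_lipid_ratio = 0)
    gen <- generate_frames(sp)
    list(st = compute_surface(gen$frames[[1]], compute_areas = FALSE),
         markers = gen$surface$markers)
  })
  interior <- cy$markers$lipid_id[!cy$markers$is_cap]
  sti <- cy$st[cy$st$lipid_id %in% interior, ]
  expect_equal(mean(sti$k1), 0.2, tolerance = 0.02)
  expect_lt(max(abs(sti$k2)), 0.004)
  expect_lt(max(abs(sti$Kg)), 0.002)

  # flat: |Km| below 1e-6 at zero jitter
  fl <- compute_surface(generate_frames(
    synthetic_spec("flat", n_lipids_per_leaflet = 64,
                   jitter_sigma = 0))$frames[[1]], compute_areas = FALSE)
  expect_lt(max(abs(fl$Km)), 1e-6)
})

test_that("buckled-leaflet sign convention and mirror symmetry hold", {
  sp <- synthetic_spec("buckle", n_lipids_per_leaflet = 64, jitter_sigma = 0,
                       ion_to_lipid_ratio = 0)
  gen <- generate_frames(sp)
  st <- compute_surface(gen$frames[[1]], compute_areas = FALSE)
  lam <- sp$buckle_wavelength
  crest <- abs(st$x - lam / 4) < lam / 8
  expect_true(all(st$Km[crest & st$leaflet == "lower"] < 0))
  expect_true(all(st$Km[crest & st$leaflet == "upper"] > 0))
  # mirror: the two leaflets' curvature distributions are reflections
  up <- sort(st$Km[st$leaflet == "upper"])
  lo <- sort(-st$Km[st$leaflet == "lower"])
  expect_equal(up, lo, tolerance = 1e-6)
})

test_that("per-lipid curvature tracks ground truth under noise", {
  gen <- cached("buckle_noisy", {
    sp <- synthetic_spec("buckle", n_lipids_per_leaflet = 64,
                         jitter_sigma = 0.05, ion_to_lipid_ratio = 0,
                         n_frames = 25, seed = 19)
    g <- generate_frames(sp)
    list(st = compute_surface(g$frames, compute_areas = FALSE),
         truth = g$surface$truth)
  })
  km_hat <- tapply(gen$st$Km, gen$st$lipid_id, mean)
  km_true <- gen$truth$Km[match(as.integer(names(km_hat)),
                                gen$truth$lipid_id)]
  expect_gt(stats::cor(km_hat, km_true), 0.95)
})

test_that("curvature error grows monotonically with jitter", {
  rms <- vapply(c(0, 0.02, 0.05, 0.1), function(sig) {
    sp <- synthetic_spec("buckle", n_lipids_per_leaflet = 64,
                         jitter_sigma = sig, ion_to_lipid_ratio = 0,
                         seed = 23)
    gen <- generate_frames(sp)
    st <- compute_surface(gen$frames[[1]], compute_areas = FALSE)
    tr <- gen$surface$truth
    sqrt(mean((st$Km - tr$Km[match(st$lipid_id, tr$lipid_id)])^2))
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("leaflet assignment is exact on all generator geometries", {
  for (kind in c("flat", "buckle")) {
    sp <- synthetic_spec(kind, n_lipids_per_leaflet = 32,
                         jitter_sigma = 0.05, seed = 3)
    gen <- generate_frames(sp)
    la <- assign_leaflets(gen$frames[[1]])
    expect_equal(sort(as.vector(table(la$leaflet))), c(32L, 32L))
    expect_equal(la$leaflet,
                 gen$surface$markers$leaflet[match(la$lipid_id,
                   gen$surface$markers$lipid_id)])
  }
  sp <- synthetic_spec("cylinder", n_lipids_per_leaflet = 96,
                       cylinder_radius = 6.9, jitter_sigma = 0.05, seed = 3)
  gen <- generate_frames(sp)
  la <- assign_leaflets(gen$frames[[1]])
  ref <- gen$surface$markers$leaflet[match(la$lipid_id,
                                           gen$surface$markers$lipid_id)]
  expect_equal(la$leaflet, ref)
})
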