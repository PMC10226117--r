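test_that("contact detection applies a strict heavy-atom cutoff", {
  box <- c(10, 10, 10)
  atoms <- toy_atoms(
    list(mol = 1, name = "P",   group = "po4",  pos = c(5, 5, 5)),
    list(mol = 1, name = "CT1", group = "tail", pos = c(5, 5, 4)),
    list(mol = 2, name = "P",   group = "po4",  pos = c(6.5, 5, 5)),
    list(mol = 3, kind = "ion", pos = c(5.29, 5, 5)),        # 0.29 from P(1)
    list(mol = 4, kind = "ion", pos = c(6.5, 5, 5.31)))      # 0.31 from P(2)
  fr <- cb_frame(atoms, box)
  cm <- detect_contacts(fr, cutoff = 0.3)
  expect_equal(cm$contacts$ion_id, 3)
  expect_equal(cm$contacts$lipid_id, 1)
  expect_equal(cm$contacts$groups, "po4")   # ion 4 at 0.31 nm stays free
  expect_error(detect_contacts(fr, cutoff = 0), "positive")
  # tail-only contact yields an empty group set
  atoms2 <- toy_atoms(
    list(mol = 1, name = "P",   group = "po4",  pos = c(5, 5, 5)),
    list(mol = 1, name = "CT1", group = "tail", pos = c(5, 5, 4)),
    list(mol = 2, kind = "ion", pos = c(5, 5, 4.1)))
  cm2 <- detect_contacts(cb_frame(atoms2, box))
  expect_equal(cm2$contacts$groups, "")
  # hydrogens never count: same position but heavy = FALSE
  atoms3 <- atoms2
  atoms3$heavy[2] <- FALSE
  cm3 <- detect_contacts(cb_frame(atoms3, box))
  expect_equal(nrow(cm3$contacts), 0)
  # minimum image: contact across the periodic boundary
  atoms4 <- toy_atoms(
    list(mol = 1, name = "P", group = "po4", pos = c(0.05, 5, 5)),
    list(mol = 2, kind = "ion", pos = c(9.85, 5, 5)))
  cm4 <- detect_contacts(cb_frame(atoms4, box))
  expect_equal(cm4$contacts$lipid_id, 1)
})

test_that("a multi-lipid contact records one entry per lipid with its groups", {
  box <- c(10, 10, 10)
  atoms <- toy_atoms(
    list(mol = 1, name = "SE1", group = "head", pos = c(5.0, 5.2, 5)),
    list(mol = 2, name = "SE1", group = "head", pos = c(5.0, 4.8, 5)),
    list(mol = 3, name = "P",   group = "po4",  pos = c(5.2, 5.0, 5)),
    list(mol = 4, kind = "ion", pos = c(5, 5, 5)))
  cm <- detect_contacts(cb_frame(atoms, box))
  expect_equal(nrow(cm$contacts), 3)
  expect_equal(classify_pattern(cm$contacts$groups), "head-head-po4")
})

test_that("zero-ion and zero-contact frames give empty maps, not errors", {
  atoms <- toy_atoms(list(mol = 1, name = "P", group = "po4",
                          pos = c(5, 5, 5)))
  cm <- detect_contacts(cb_frame(atoms, c(10, 10, 10)))
  expect_equal(nrow(cm$contacts), 0)
  expect_length(cm$ion_ids, 0)
})

test_that("pattern canonicalization is idempotent and order-independent", {
  expect_equal(classify_pattern(character(0)), "free")
  expect_equal(classify_pattern(c("head", "head", "po4")), "head-head-po4")
  # one lipid touched at head and po4 is distinct from two lipids
  expect_equal(classify_pattern("head,po4"), "head+po4")
  expect_equal(classify_pattern(c("head", "po4")), "head-po4")
  # tail-only contact contributes the token "tail"
  expect_equal(classify_pattern(c("", "po4")), "po4-tail")
  # exhaustive permutation invariance, up to 4 lipids x 3 groups
  pool <- c("head", "po4", "carbo", "head,po4", "carbo,po4",
            "carbo,head,po4", "")
  set.seed(99)
  for (n in 1:4) {
    for (rep in 1:40) {
      g <- sample(pool, n, replace = TRUE)
      ref <- classify_pattern(g)
      for (k in 1:5)
        expect_identical(classify_pattern(sample(g)), ref)
      # idempotent under re-canonicalization of its own tokens
      expect_identical(
        classify_pattern(gsub("\\+", ",", strsplit(ref, "-")[[1]][
          strsplit(ref, "-")[[1]] != "tail"])),
        classify_pattern(g[g != ""]))
    }
  }
})

test_that("pattern flattening reproduces the space-separated multiset form", {
  expect_equal(pattern_flat("head+po4-head"), "head head po4")
  expect_equal(pattern_flat("free"), "free")
  expect_equal(pattern_flat(c("po4-po4", "carbo+po4-po4-po4")),
               c("po4 po4", "carbo po4 po4 po4"))
})

test_that("pattern abundances normalize to 100% and filter at 1%", {
  maps <- make_maps(list(
    rbind(contact_row(10, 1, "head"), contact_row(10, 2, "head"),
          contact_row(10, 3, "po4")),
    contact_row(10, 1, "head,po4"),
    NULL,
    contact_row(10, 2, "")), ions = 10)
  tab <- pattern_abundances(maps, min_fraction = 0.3)
  expect_equal(sum(tab$percent), 100)
  expect_equal(attr(tab, "n_ion_frames"), 4)
  # tail-only ion-frame collapses to free when tail tokens are dropped
  expect_equal(sort(tab$pattern),
               sort(c("head-head-po4", "head+po4", "free")))
  expect_equal(tab$percent[tab$pattern == "free"], 50)
  tab2 <- pattern_abundances(maps, min_fraction = 0.3, drop_tail = FALSE)
  expect_true("tail" %in% tab2$pattern)
  expect_true(all(tab2$abundant == (tab2$percent > 30)))
})

test_that("coordination distribution matches constructed maps and patterns", {
  maps <- make_maps(list(
    rbind(contact_row(7, 1, "head"), contact_row(7, 2, "po4")),
    rbind(contact_row(7, 1, "head"), contact_row(7, 2, "po4")),
    rbind(contact_row(7, 1, "head"), contact_row(7, 2, "po4"))),
    ions = c(7, 8))
  cd <- coordination_distribution(maps)
  expect_equal(cd$p[cd$coord == 2], 0.5)  # ion 7 always binds two lipids
  expect_equal(cd$p[cd$coord == 0], 0.5)  # ion 8 always free
  expect_equal(sum(cd$p), 1)
  blocks <- attr(cd, "blocks")
  expect_equal(colSums(blocks), rep(1, 3))
  expect_equal(cd$err, apply(blocks, 1, sd))
  # all ions free in all frames
  cd0 <- coordination_distribution(make_maps(list(NULL, NULL, NULL), 1:3))
  expect_equal(cd0$p, 1)
  expect_equal(cd0$coord, 0)
  # subset restriction changes the count
  cds <- coordination_distribution(maps, lipid_subset = 1)
  expect_equal(cds$p[cds$coord == 1], 0.5)
  expect_error(coordination_distribution(maps, lipid_subset = integer(0)),
               "empty")
  expect_error(coordination_distribution(maps[1:2]), "at least 3")
  # coordination numbers equal the lipid-token counts of the pattern view
  cc <- maps[[1]]$contacts
  pat <- classify_pattern(cc$groups[cc$ion_id == 7])
  expect_equal(length(strsplit(pat, "-")[[1]]), 2)
})

test_that("residence episodes follow the run/gap definition exactly", {
  flags_to_maps <- function(flags)
    make_maps(lapply(flags, function(b)
      if (b) contact_row(1, 1, "po4") else NULL), ions = 1)
  r1 <- residence_times(flags_to_maps(c(0, 1, 1, 1, 0)), dt = 100)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$duration, 300)
  expect_false(r1$censored)
  r2 <- residence_times(flags_to_maps(c(1, 1, 0, 1, 1)), dt = 100,
                        gap_tolerance = 1)
  expect_equal(r2$duration, 500)
  expect_true(r2$censored)   # touches both trajectory ends
  r3 <- residence_times(flags_to_maps(c(1, 1, 0, 1, 1)), dt = 100,
                        gap_tolerance = 0)
  expect_equal(r3$duration, c(200, 200))
  expect_equal(r3$censored, c(TRUE, TRUE))
  surv <- residence_survival(r3, times = c(100, 200, 300))
  expect_equal(surv$survival, c(1, 1, 0))
})

test_that("two-state chain residence matches the geometric closed form", {
  set.seed(123)
  k_on <- 0.25; k_off <- 0.2
  n <- 120000  # yields >= 1e4 completed episodes
  flags <- integer(n)
  s <- 0L
  for (i in seq_len(n)) {
    s <- if (s == 1L) rbinom(1, 1, 1 - k_off) else rbinom(1, 1, k_on)
    flags[i] <- s
  }
  maps <- make_maps(lapply(flags, function(b)
    if (b) contact_row(1, 1, "po4") else NULL), ions = 1)
  res <- residence_times(maps, dt = 1)
  done <- res[!res$censored, ]
  expect_gt(nrow(done), 1e4)
  expect_equal(mean(done$duration), 1 / k_off, tolerance = 0.1)
})

test_that("central sector mask trims cap margins by arc length", {
  sp <- synthetic_spec("cylinder", n_lipids_per_leaflet = 96,
                       cylinder_radius = 6.9, jitter_sigma = 0,
                       ion_to_lipid_ratio = 0)
  sur <- generate_surface(sp)
  m <- sur$markers
  expect_equal(sort(central_sector_mask(m, 0)), sort(m$lipid_id))
  # margin of one lattice spacing + 1 nm removes exactly the flagged caps
  spacing <- diff(sort(unique(m$s[m$leaflet == "convex"])))[1]
  keep <- central_sector_mask(m, spacing + 1)
  flagged <- m$lipid_id[m$is_cap]
  expect_length(intersect(keep, flagged), 0)
  # margin of a quarter arc per side keeps the interior half
  for (lf in c("convex", "concave")) {
    ml <- m[m$leaflet == lf, ]
    arc <- max(ml$s) - min(ml$s)
    kept <- intersect(central_sector_mask(m, arc / 4), ml$lipid_id)
    expect_equal(length(kept) / nrow(ml), 0.5, tolerance = 0.06)
  }
  expect_error(central_sector_mask(m, 1e4), "empty")
})
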