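# Ion-lipid contact analysis: distance-cutoff contact detection,
# coordination-number distributions with trajectory-thirds errors,
# canonical chemical-group binding patterns and residence times.

# ---- contact detection ------------------------------------------------------

#' Detect ion-lipid contacts in one frame
#'
#' An ion is in contact with a lipid iff any heavy atom of that lipid lies
#' strictly within `cutoff` (minimum-image distance). The contacted group
#' set of a lipid is the set of group labels of all such atoms except
#' `tail`; a lipid touched only at tail atoms is recorded with an empty
#' group set.
#'
#' @param frame a `cb_frame` with ions and heavy-flagged lipid atoms.
#' @param cutoff contact cutoff, nm (default 0.3).
#' @return a `cb_contact_map`: list with `contacts` (data.frame `ion_id`,
#'   `lipid_id`, `groups` — comma-joined sorted labels, `""` for
#'   tail-only), `ion_ids` (all ion molecule ids, bound or free) and
#'   `time`.
#' @export
detect_contacts <- function(frame, cutoff = 0.3) {
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- frame$atoms
  ions <- a[a$mol_kind == "ion", , drop = FALSE]
  H <- a[a$mol_kind == "lipid" & a$heavy, , drop = FALSE]
  HM <- as.matrix(H[, c("x", "y", "z")])
  recs <- vector("list", nrow(ions))
  if (nrow(ions) && nrow(H)) {
    for (i in seq_len(nrow(ions))) {
      d2 <- .mi_dist2(HM, c(ions$x[i], ions$y[i], ions$z[i]),
                      frame$box, frame$periodic)
      hit <- d2 < cutoff^2
      if (!any(hit)) next
      lip <- H$mol_id[hit]
      grp <- H$group[hit]
      gsets <- vapply(split(grp, lip), function(g) {
        g <- sort(unique(g[g != "tail"]))
        paste(g, collapse = ",")
      }, character(1))
      recs[[i]] <- data.frame(ion_id = ions$mol_id[i],
                              lipid_id = as.integer(names(gsets)),
                              groups = unname(gsets),
                              stringsAsFactors = FALSE)
    }
  }
  contacts <- do.call(rbind, recs)
  if (is.null(contacts))
    contacts <- data.frame(ion_id = integer(0), lipid_id = integer(0),
                           groups = character(0), stringsAsFactors = FALSE)
  structure(list(contacts = contacts, ion_ids = ions$mol_id,
                 time = frame$time), class = "cb_contact_map")
}

#' Detect contacts over a frame sequence
#' @param frames list of `cb_frame`.
#' @param cutoff contact cutoff, nm.
#' @return list of `cb_contact_map`, one per frame.
#' @export
contact_maps <- function(frames, cutoff = 0.3) {
  lapply(frames, detect_contacts, cutoff = cutoff)
}

# per-ion-per-frame coordination numbers (restricted to a lipid subset)
.coordination_samples <- function(maps, lipid_subset = NULL,
                                  ion_subset = NULL) {
  do.call(rbind, lapply(seq_along(maps), function(k) {
    cm <- maps[[k]]
    ions <- cm$ion_ids
    if (!is.null(ion_subset)) ions <- intersect(ions, ion_subset)
    if (!length(ions))
      return(data.frame(block_frame = integer(0), ion_id = integer(0),
                        coord = integer(0)))
    cc <- cm$contacts
    if (!is.null(lipid_subset))
      cc <- cc[cc$lipid_id %in% lipid_subset, , drop = FALSE]
    cnt <- table(factor(cc$ion_id, levels = ions))
    data.frame(block_frame = k, ion_id = ions, coord = as.integer(cnt))
  }))
}

#' Coordination-number distribution with trajectory-thirds errors
#'
#' Coordination of one ion in one frame is the number of distinct lipids
#' (within `lipid_subset` when given) it contacts. The distribution is
#' normalized over all ion-frames; errors are the standard deviation of
#' the distributions computed independently for three equal contiguous,
#' non-overlapping parts of the trajectory.
#'
#' @param maps list of `cb_contact_map` (at least 3 frames).
#' @param lipid_subset lipid ids to count, or `NULL` for all.
#' @param ion_subset ion ids to include, or `NULL` for all.
#' @return a `cb_coordination`: data.frame `coord`, `p`, `err`, plus block
#'   curves in `attr(x, "blocks")` and sample count in
#'   `attr(x, "n_samples")`.
#' @export
coordination_distribution <- function(maps, lipid_subset = NULL,
                                      ion_subset = NULL) {
  if (!is.null(lipid_subset) && !length(lipid_subset))
    stop("lipid_subset is empty")
  if (length(maps) < 3)
    stop("need at least 3 frames for thirds-based errors")
  smp <- .coordination_samples(maps, lipid_subset, ion_subset)
  if (!nrow(smp)) stop("no ion-frame samples")
  n_max <- max(smp$coord)
  lv <- 0:n_max
  hist_of <- function(x) as.vector(table(factor(x, levels = lv)) / length(x))
  p <- hist_of(smp$coord)
  thirds <- cut(smp$block_frame, breaks = 3, labels = FALSE)
  blocks <- sapply(1:3, function(b) hist_of(smp$coord[thirds == b]))
  if (is.null(dim(blocks))) blocks <- matrix(blocks, nrow = 1)
  err <- apply(blocks, 1, stats::sd)
  out <- data.frame(coord = lv, p = p, err = err)
  attr(out, "blocks") <- blocks
  attr(out, "n_samples") <- nrow(smp)
  class(out) <- c("cb_coordination", class(out))
  out
}

# ---- binding patterns -------------------------------------------------------

#' Canonical binding pattern of one ion in one frame
#'
#' Each contacted lipid contributes one token: its sorted group labels
#' joined with `+` (e.g. `head+po4` for one lipid touched at both head and
#' phosphate), or `tail` for a tail-only contact. Tokens are sorted and
#' joined with `-`; an ion with no contacts is `"free"`. Canonicalization
#' is idempotent and independent of contact order.
#'
#' @param groups character vector of per-lipid group sets as produced by
#'   [detect_contacts()] (comma-joined labels, `""` for tail-only); one
#'   element per contacted lipid.
#' @return canonical pattern string.
#' @export
classify_pattern <- function(groups) {
  if (!length(groups)) return("free")
  tok <- vapply(strsplit(groups, ","), function(g) {
    g <- sort(g[nzchar(g)])
    if (!length(g)) "tail" else paste(g, collapse = "+")
  }, character(1))
  paste(sort(tok), collapse = "-")
}

#' Flatten a canonical pattern to the space-separated multiset form
#'
#' Lossy export in which per-lipid identity of compound tokens is
#' discarded: every group mention is listed once, sorted, joined by
#' spaces (e.g. `head+po4-head` becomes `"head head po4"`).
#'
#' @param pattern canonical pattern string(s).
#' @return character vector of flattened patterns.
#' @export
pattern_flat <- function(pattern) {
  vapply(strsplit(pattern, "-"), function(tok) {
    if (identical(tok, "free")) return("free")
    g <- sort(unlist(strsplit(tok, "\\+")))
    paste(g, collapse = " ")
  }, character(1))
}

#' Relative abundances of binding patterns
#'
#' Classifies every ion-frame into its canonical pattern and tabulates
#' relative abundances in percent. Tail-only lipid contacts are dropped
#' from the three-group pattern report by default (an ion left with no
#' tokens counts as `free`).
#'
#' @param maps list of `cb_contact_map`.
#' @param min_fraction patterns above this fraction are flagged abundant
#'   (default 0.01, i.e. 1% of all patterns).
#' @param ion_subset ion ids to include, or `NULL` for all.
#' @param drop_tail drop `tail` tokens before tabulating.
#' @return a `cb_pattern_table` data.frame: `pattern`, `pattern_flat`,
#'   `count`, `percent`, `abundant`, sorted by decreasing abundance.
#' @export
pattern_abundances <- function(maps, min_fraction = 0.01,
                               ion_subset = NULL, drop_tail = TRUE) {
  if (!length(maps)) stop("need at least one frame")
  pats <- unlist(lapply(maps, function(cm) {
    ions <- cm$ion_ids
    if (!is.null(ion_subset)) ions <- intersect(ions, ion_subset)
    if (!length(ions)) return(character(0))
    cc <- cm$contacts[cm$contacts$ion_id %in% ions, , drop = FALSE]
    by_ion <- split(cc$groups, factor(cc$ion_id, levels = ions))
    vapply(by_ion, classify_pattern, character(1))
  }))
  if (drop_tail) {
    pats <- vapply(strsplit(pats, "-"), function(tok) {
      tok <- tok[tok != "tail"]
      if (!length(tok)) "free" else paste(tok, collapse = "-")
    }, character(1))
  }
  tab <- sort(table(pats), decreasing = TRUE)
  out <- data.frame(pattern = names(tab),
                    pattern_flat = pattern_flat(names(tab)),
                    count = as.integer(tab),
                    percent = 100 * as.integer(tab) / length(pats),
                    stringsAsFactors = FALSE)
  out$abundant <- out$percent > 100 * min_fraction
  attr(out, "n_ion_frames") <- length(pats)
  class(out) <- c("cb_pattern_table", class(out))
  out
}

# ---- residence times --------------------------------------------------------

# maximal bound episodes of one 0/1 flag vector, bridging gaps <= gap_tol
.episodes_of_flags <- function(flags, gap_tol) {
  n <- length(flags)
  bound <- which(flags > 0)
  if (!length(bound)) return(NULL)
  brk <- which(diff(bound) > gap_tol + 1L)
  starts <- bound[c(1L, brk + 1L)]
  ends <- bound[c(brk, length(bound))]
  data.frame(start = starts, end = ends,
             censored = starts == 1L | ends == n)
}

#' Residence-time distribution of ion-lipid binding episodes
#'
#' An episode is a maximal run of frames in which an ion contacts at least
#' one lipid, allowing interruptions of at most `gap_tolerance` frames.
#' Episode duration is the number of frames in the run times `dt`.
#' Episodes touching either trajectory end are flagged censored.
#'
#' @param maps list of `cb_contact_map` from equally spaced frames.
#' @param dt frame spacing, ps.
#' @param gap_tolerance maximum bridged interruption, frames.
#' @param lipid_subset restrict contacts to these lipid ids.
#' @return a `cb_residence`: data.frame `ion_id`, `start`, `end`,
#'   `duration` (ps), `censored`.
#' @export
residence_times <- function(maps, dt, gap_tolerance = 0L,
                            lipid_subset = NULL) {
  ions <- sort(unique(unlist(lapply(maps, `[[`, "ion_ids"))))
  flags <- sapply(maps, function(cm) {
    cc <- cm$contacts
    if (!is.null(lipid_subset))
      cc <- cc[cc$lipid_id %in% lipid_subset, , drop = FALSE]
    as.integer(ions %in% cc$ion_id)
  })
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = length(ions))
  eps <- lapply(seq_along(ions), function(i) {
    e <- .episodes_of_flags(flags[i, ], gap_tolerance)
    if (is.null(e)) return(NULL)
    cbind(ion_id = ions[i], e)
  })
  eps <- do.call(rbind, eps)
  if (is.null(eps))
    eps <- data.frame(ion_id = integer(0), start = integer(0),
                      end = integer(0), censored = logical(0))
  eps$duration <- (eps$end - eps$start + 1L) * dt
  eps <- eps[, c("ion_id", "start", "end", "duration", "censored")]
  attr(eps, "dt") <- dt
  attr(eps, "gap_tolerance") <- gap_tolerance
  class(eps) <- c("cb_residence", class(eps))
  eps
}

#' Survival histogram of residence episodes
#' @param residence a `cb_residence`.
#' @param times evaluation times, ps (default: observed durations).
#' @return data.frame `t`, `survival` — fraction of episodes with duration
#'   >= t.
#' @export
residence_survival <- function(residence, times = NULL) {
  d <- residence$duration
  if (is.null(times)) times <- sort(unique(d))
  data.frame(t = times,
             survival = vapply(times, function(t0) mean(d >= t0),
                               numeric(1)))
}

# ---- bicelle central sector -------------------------------------------------

#' Central-sector lipid mask for bent bicelle membranes
#'
#' Excludes lipids within `cap_margin` of either membrane edge along the
#' bending direction; edges are located by the extreme arc-length
#' coordinates of the markers, separately per leaflet.
#'
#' @param markers data.frame with columns `lipid_id`, `leaflet` and the
#'   arc-length coordinate `s` (nm), e.g. `surface$markers` from
#'   [generate_surface()].
#' @param cap_margin excluded band width at each edge, nm.
#' @return integer vector of retained lipid ids.
#' @export
central_sector_mask <- function(markers, cap_margin) {
  if (cap_margin < 0) stop("cap_margin must be >= 0")
  if (!all(c("lipid_id", "leaflet", "s") %in% names(markers)))
    stop("markers must carry lipid_id, leaflet and arc coordinate s")
  keep <- unlist(lapply(split(markers, markers$leaflet), function(m) {
    lo <- min(m$s); hi <- max(m$s)
    m$lipid_id[m$s >= lo + cap_margin & m$s <= hi - cap_margin]
  }))
  keep <- sort(as.integer(keep))
  if (!length(keep)) stop("central sector empty at cap_margin = ", cap_margin)
  keep
}
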