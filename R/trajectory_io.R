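# ---- Frame container --------------------------------------------------------

#' Construct a coordinate frame
#'
#' A frame holds one time point of a membrane system: an atom table with
#' chemical metadata, an orthorhombic box and per-axis periodicity flags.
#' Positions are in nm throughout the package (GRO convention).
#'
#' @param atoms data.frame with columns `atom_id`, `mol_id`, `mol_kind`
#'   (one of `"lipid"`, `"ion"`, `"other"`), `species` (residue name),
#'   `name` (atom name), `group` (one of `"head"`, `"po4"`, `"carbo"`,
#'   `"tail"`, `"none"`), `heavy` (logical) and coordinates `x`, `y`, `z`
#'   in nm.
#' @param box numeric length-3, box lengths in nm (must be positive).
#' @param periodic logical length-3, which axes are periodic.
#' @param time time stamp in ps.
#' @param wrap wrap positions into the primary box on periodic axes.
#' @return an object of class `cb_frame`.
#' @export
cb_frame <- function(atoms, box, periodic = c(TRUE, TRUE, TRUE), time = 0,
                     wrap = TRUE) {
  req <- c("atom_id", "mol_id", "mol_kind", "species", "name", "group",
           "heavy", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths (nm)")
  periodic <- as.logical(periodic)
  if (length(periodic) != 3L || any(is.na(periodic)))
    stop("periodic must be three logicals")
  bad <- setdiff(unique(atoms$group),
                 c("head", "po4", "carbo", "tail", "none"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  if (any(atoms$mol_kind == "ion" & atoms$group != "none"))
    stop("ions must carry group label 'none'")
  fr <- structure(list(atoms = atoms, box = box, periodic = periodic,
                       time = as.numeric(time)),
                  class = "cb_frame")
  if (wrap) fr <- wrap_frame(fr)
  fr
}

#' @export
print.cb_frame <- function(x, ...) {
  nl <- length(unique(x$atoms$mol_id[x$atoms$mol_kind == "lipid"]))
  ni <- sum(x$atoms$mol_kind == "ion")
  cat(sprintf(
    "<cb_frame> %d atoms (%d lipids, %d ions), box %.2f x %.2f x %.2f nm, pbc %s, t = %g ps\n",
    nrow(x$atoms), nl, ni, x$box[1], x$box[2], x$box[3],
    paste(ifelse(x$periodic, c("x", "y", "z"), "-"), collapse = ""), x$time))
  invisible(x)
}

#' Wrap atom positions into the primary box on periodic axes
#' @param frame a `cb_frame`.
#' @return the frame with wrapped coordinates.
#' @export
wrap_frame <- function(frame) {
  for (i in 1:3) {
    if (!frame$periodic[i]) next
    cn <- c("x", "y", "z")[i]
    frame$atoms[[cn]] <- frame$atoms[[cn]] %% frame$box[i]
  }
  frame
}

# ---- Minimum image ----------------------------------------------------------

#' Minimum-image displacement between two positions
#'
#' Componentwise minimum-image convention on periodic axes, raw difference
#' on aperiodic axes. Returns the displacement from `a` to `b` (i.e.
#' `b - a` reduced to the nearest periodic image).
#'
#' @param a,b positions, numeric length-3 (nm).
#' @param box box lengths (nm).
#' @param periodic logical length-3.
#' @return numeric length-3 displacement (nm).
#' @export
min_image_displacement <- function(a, b, box, periodic = c(TRUE, TRUE, TRUE)) {
  d <- as.numeric(b) - as.numeric(a)
  w <- which(periodic)
  d[w] <- d[w] - box[w] * round(d[w] / box[w])
  d
}

# Minimum-image displacement of many points relative to one center.
# P: n x 3 matrix, q: length-3. Returns n x 3 matrix of P - q (min-imaged).
.mi_disp_mat <- function(P, q, box, periodic) {
  D <- sweep(P, 2L, as.numeric(q))
  for (i in which(periodic))
    D[, i] <- D[, i] - box[i] * round(D[, i] / box[i])
  D
}

# Squared minimum-image distances of rows of P to point q.
.mi_dist2 <- function(P, q, box, periodic) {
  D <- .mi_disp_mat(P, q, box, periodic)
  rowSums(D * D)
}

# ---- Topology maps ----------------------------------------------------------

#' Default topology map
#'
#' Maps (residue name, atom name) to molecule kind and chemical-group label.
#' Covers the synthetic lipid `SYNT`, the phosphatidylserine and
#' phosphatidylcholine residues `POPS`/`POPC` (head = serine/choline moiety,
#' po4 = phosphate, carbo = ester carbonyls, everything else = tail) and the
#' common monatomic ions. Atom-name patterns are shell globs.
#'
#' @return a topology map (named list) usable by [read_frames()].
#' @export
default_topology_map <- function() {
  list(residues = list(
    SYNT = list(kind = "lipid", atoms = list(
      "SE*" = "head", "P" = "po4", "OP*" = "po4",
      "CB*" = "carbo", "CT*" = "tail")),
    POPS = list(kind = "lipid", atoms = list(
      "N" = "head", "C12" = "head", "C13" = "head",
      "O13A" = "head", "O13B" = "head", "C11" = "head",
      "P" = "po4", "O11" = "po4", "O12" = "po4", "O13" = "po4", "O14" = "po4",
      "C21" = "carbo", "O21" = "carbo", "O22" = "carbo",
      "C31" = "carbo", "O31" = "carbo", "O32" = "carbo",
      "*" = "tail")),
    POPC = list(kind = "lipid", atoms = list(
      "N" = "head", "C11" = "head", "C12" = "head",
      "C13" = "head", "C14" = "head", "C15" = "head",
      "P" = "po4", "O11" = "po4", "O12" = "po4", "O13" = "po4", "O14" = "po4",
      "C21" = "carbo", "O21" = "carbo", "O22" = "carbo",
      "C31" = "carbo", "O31" = "carbo", "O32" = "carbo",
      "*" = "tail")),
    CA  = list(kind = "ion"), CAL = list(kind = "ion"),
    K   = list(kind = "ion"), POT = list(kind = "ion"),
    `NA` = list(kind = "ion"), SOD = list(kind = "ion"),
    CL  = list(kind = "ion"), CLA = list(kind = "ion"),
    SOL = list(kind = "other"), TIP3 = list(kind = "other")
  ))
}

#' Read a topology map from YAML
#'
#' The YAML layout mirrors [default_topology_map()]: a `residues` mapping
#' from residue name to `kind` (`lipid`/`ion`/`other`) and, for lipids, an
#' `atoms` mapping from atom-name glob to group label.
#'
#' @param path YAML file path.
#' @return a topology map list.
#' @export
read_topology_map <- function(path) {
  tm <- yaml::read_yaml(path)
  if (is.null(tm$residues)) stop("topology map must contain a 'residues' key")
  tm
}

# Hydrogen by atom-name convention: strip leading digits, then H/h prefix.
.is_hydrogen_name <- function(name) {
  grepl("^[Hh]", sub("^[0-9]+", "", name))
}

# Resolve kind/group/heavy metadata for raw (species, name) columns.
.resolve_metadata <- function(species, name, topology_map) {
  n <- length(species)
  kind <- rep("other", n)
  group <- rep("none", n)
  res <- topology_map$residues
  unknown <- character(0)
  for (rn in unique(species)) {
    sel <- species == rn
    entry <- res[[rn]]
    if (is.null(entry)) {
      unknown <- c(unknown, rn)
      next
    }
    kind[sel] <- entry$kind
    if (identical(entry$kind, "lipid")) {
      g <- rep(NA_character_, sum(sel))
      nm <- name[sel]
      pats <- names(entry$atoms)
      # literal names first, globs (incl. catch-all "*") after, in map order
      ord <- order(grepl("[*?]", pats))
      for (p in pats[ord]) {
        hit <- is.na(g) & grepl(utils::glob2rx(p), nm)
        g[hit] <- entry$atoms[[p]]
      }
      if (anyNA(g)) {
        warning("unmapped atom names in residue ", rn, ": ",
                paste(unique(nm[is.na(g)]), collapse = ", "),
                " -> group 'none'", call. = FALSE)
        g[is.na(g)] <- "none"
      }
      group[sel] <- g
    }
  }
  if (length(unknown))
    warning("residues not in topology map (kind 'other'): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  list(kind = kind, group = group,
       heavy = !.is_hydrogen_name(name))
}

# ---- GRO reader / writer ----------------------------------------------------

.parse_gro_block <- function(lines, start, topology_map, periodic) {
  title <- lines[start]
  natoms <- suppressWarnings(as.integer(trimws(lines[start + 1L])))
  if (is.na(natoms))
    stop("malformed GRO atom count at line ", start + 1L)
  al <- lines[(start + 2L):(start + 1L + natoms)]
  boxline <- lines[start + 2L + natoms]
  if (is.na(boxline) || !nzchar(trimws(boxline)))
    stop("missing box line at line ", start + 2L + natoms)
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO atom record at line ", start + 1L + bad[1])
  box <- suppressWarnings(as.numeric(strsplit(trimws(boxline), "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3]))
    stop("malformed GRO box at line ", start + 2L + natoms)
  time <- 0
  tm <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
  if (length(tm) == 2) time <- as.numeric(tm[2])
  # renumber molecules sequentially (GRO residue ids wrap at 100000)
  mol_id <- cumsum(c(TRUE, resid[-1] != resid[-natoms] |
                             resname[-1] != resname[-natoms]))
  meta <- .resolve_metadata(resname, name, topology_map)
  atoms <- data.frame(
    atom_id = seq_len(natoms), mol_id = mol_id, mol_kind = meta$kind,
    species = resname, name = name, group = meta$group, heavy = meta$heavy,
    x = x, y = y, z = z, stringsAsFactors = FALSE)
  atoms$group[atoms$mol_kind != "lipid"] <- "none"
  list(frame = cb_frame(atoms, box[1:3], periodic, time, wrap = FALSE),
       next_start = start + 3L + natoms)
}

.read_gro <- function(path, topology_map, periodic) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    blk <- .parse_gro_block(lines, i, topology_map, periodic)
    frames[[length(frames) + 1L]] <- blk$frame
    i <- blk$next_start
  }
  frames
}

.format_gro_block <- function(frame) {
  a <- frame$atoms
  n <- nrow(a)
  hdr <- sprintf("curvbind frame t= %g", frame$time)
  recs <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  a$mol_id %% 100000L, substr(a$species, 1, 5),
                  substr(a$name, 1, 5), a$atom_id %% 100000L,
                  a$x, a$y, a$z)
  c(hdr, sprintf("%5d", n), recs,
    sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3]))
}

# ---- PDB reader / writer ----------------------------------------------------

.read_pdb <- function(path, topology_map, periodic) {
  lines <- readLines(path)
  frames <- list()
  box <- NULL
  cur <- NULL  # accumulating atom lines of the current model
  flush <- function(al) {
    if (!length(al)) return(NULL)
    if (is.null(box)) stop("missing CRYST1 box record in PDB file")
    name <- trimws(substr(al, 13, 16))
    resname <- trimws(substr(al, 18, 21))
    resid <- suppressWarnings(as.integer(substr(al, 23, 26)))
    x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad)) stop("malformed PDB ATOM record: ", al[bad[1]])
    n <- length(al)
    mol_id <- cumsum(c(TRUE, resid[-1] != resid[-n] |
                               resname[-1] != resname[-n]))
    meta <- .resolve_metadata(resname, name, topology_map)
    atoms <- data.frame(
      atom_id = seq_len(n), mol_id = mol_id, mol_kind = meta$kind,
      species = resname, name = name, group = meta$group, heavy = meta$heavy,
      x = x / 10, y = y / 10, z = z / 10, stringsAsFactors = FALSE)
    atoms$group[atoms$mol_kind != "lipid"] <- "none"
    cb_frame(atoms, box, periodic, time = length(frames), wrap = FALSE)
  }
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (rec == "CRYST1") {
      box <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                          substr(ln, 25, 33))) / 10
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      cur <- c(cur, ln)
    } else if (trimws(rec) %in% c("ENDMDL", "END")) {
      fr <- flush(cur)
      if (!is.null(fr)) frames[[length(frames) + 1L]] <- fr
      cur <- NULL
    }
  }
  fr <- flush(cur)
  if (!is.null(fr)) frames[[length(frames) + 1L]] <- fr
  frames
}

.format_pdb_block <- function(frame, model) {
  a <- frame$atoms
  recs <- sprintf(
    "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
    a$atom_id %% 100000L, substr(a$name, 1, 4), substr(a$species, 1, 4),
    a$mol_id %% 10000L, a$x * 10, a$y * 10, a$z * 10)
  c(sprintf("MODEL     %4d", model), recs, "ENDMDL")
}

# ---- Public I/O -------------------------------------------------------------

#' Read coordinate frames from a GRO or PDB file
#'
#' Atom chemical metadata (molecule kind, group label, heavy flag) is
#' resolved from the topology map by (residue name, atom name); unknown
#' atom names map to group `"none"` with a warning. GRO positions are read
#' as nm, PDB positions as Angstrom and converted to nm.
#'
#' @param path file path; format from extension (`.gro` / `.pdb`) unless
#'   `format` is given.
#' @param topology_map a topology map, see [default_topology_map()].
#' @param periodic logical length-3 periodicity flags to attach (file
#'   formats do not store them).
#' @param format `"gro"`, `"pdb"` or `NULL` (auto).
#' @return list of `cb_frame` objects.
#' @export
read_frames <- function(path, topology_map = default_topology_map(),
                        periodic = c(TRUE, TRUE, TRUE), format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
    gro = .read_gro(path, topology_map, periodic),
    pdb = .read_pdb(path, topology_map, periodic),
    stop("unsupported trajectory format: ", format))
}

#' Write coordinate frames to a GRO or PDB file
#'
#' Multiple frames are written as concatenated GRO blocks or PDB MODEL
#' records. GRO keeps nm with 0.001 nm precision; PDB converts to Angstrom.
#'
#' @param frames a `cb_frame` or list of them.
#' @param path output path; format from extension unless `format` given.
#' @param format `"gro"`, `"pdb"` or `NULL` (auto).
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, format = NULL) {
  if (inherits(frames, "cb_frame")) frames <- list(frames)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  out <- switch(format,
    gro = unlist(lapply(frames, .format_gro_block)),
    pdb = {
      b <- frames[[1]]$box * 10
      c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                b[1], b[2], b[3]),
        unlist(lapply(seq_along(frames),
                      function(i) .format_pdb_block(frames[[i]], i))),
        "END")
    },
    stop("unsupported trajectory format: ", format))
  writeLines(out, path)
  invisible(path)
}

# ---- Marker selection -------------------------------------------------------

#' Marker-atom selection rule
#'
#' Selects the single atom per lipid whose positions define the membrane
#' surface. The default is the phosphate phosphorus (`P`), the standard
#' marker choice for lipid surface reconstruction.
#'
#' @param name atom name the marker must match (exact).
#' @param group group label the marker must carry, or `NULL` to ignore.
#' @return a rule object for [select_markers()].
#' @export
marker_rule <- function(name = "P", group = "po4") {
  structure(list(name = name, group = group), class = "cb_marker_rule")
}

#' Select one surface marker per lipid
#'
#' @param frame a `cb_frame`.
#' @param rule a [marker_rule()].
#' @return data.frame with one row per lipid: `lipid_id`, `species`,
#'   `x`, `y`, `z` (nm), ordered by `lipid_id`.
#' @export
select_markers <- function(frame, rule = marker_rule()) {
  a <- frame$atoms
  lip <- a[a$mol_kind == "lipid", , drop = FALSE]
  if (!nrow(lip)) stop("frame contains no lipids")
  sel <- lip$name == rule$name
  if (!is.null(rule$group)) sel <- sel & lip$group == rule$group
  hits <- lip[sel, , drop = FALSE]
  cnt <- table(factor(hits$mol_id, levels = unique(lip$mol_id)))
  if (any(cnt != 1L)) {
    off <- names(cnt)[cnt != 1L]
    stop("marker rule matches ", paste(cnt[cnt != 1L], collapse = "/"),
         " atoms for lipid(s) ", paste(utils::head(off, 5), collapse = ", "),
         " (need exactly 1)")
  }
  out <- data.frame(lipid_id = hits$mol_id, species = hits$species,
                    x = hits$x, y = hits$y, z = hits$z,
                    stringsAsFactors = FALSE)
  out[order(out$lipid_id), , drop = FALSE]
}
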