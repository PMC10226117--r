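# Fixtures are built in code. `toy_atoms()` assembles an atom table row by
# row; `.fixture_cache` memoizes the heavier synthetic systems so several
# test files can share one realization.

toy_atoms <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(atom_id = i,
               mol_id = r$mol %||% i,
               mol_kind = r$kind %||% "lipid",
               species = r$species %||% if ((r$kind %||% "lipid") == "ion")
                 "CA" else "SYNT",
               name = r$name %||% if ((r$kind %||% "lipid") == "ion")
                 "CA" else "P",
               group = r$group %||% if ((r$kind %||% "lipid") == "ion")
                 "none" else "po4",
               heavy = r$heavy %||% TRUE,
               x = r$pos[1], y = r$pos[2], z = r$pos[3],
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# contact maps built directly from a per-frame list of (ion, lipid, groups)
# triples; `ions` fixes the full ion roster so free ions are represented
make_maps <- function(per_frame, ions) {
  lapply(seq_along(per_frame), function(k) {
    cc <- per_frame[[k]]
    if (is.null(cc))
      cc <- data.frame(ion_id = integer(0), lipid_id = integer(0),
                       groups = character(0), stringsAsFactors = FALSE)
    structure(list(contacts = cc, ion_ids = ions, time = k - 1),
              class = "cb_contact_map")
  })
}

contact_row <- function(ion, lipid, groups) {
  data.frame(ion_id = ion, lipid_id = lipid, groups = groups,
             stringsAsFactors = FALSE)
}
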