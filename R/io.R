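# Structure file I/O: SDF (V2000 read/write, V3000 read) and a small-molecule
# CIF dialect (Cartesian atom sites plus an optional bond loop). Readers
# return heavy-atom graphs with coordinates aligned to the canonical atom
# order; explicit hydrogens are folded into n_hydrogens unless asked for.

#' Load molecular structures with 3D coordinates
#'
#' Reads an SDF (V2000 or V3000) or small-molecule CIF file into
#' `(molecular_graph, coordinates)` pairs. Records that cannot be parsed or
#' whose bonding is ambiguous (valence violations, overlapping atoms, failed
#' bond perception) are returned in a `rejects` table with reasons rather
#' than aborting the whole file.
#'
#' @param path file path.
#' @param format `"sdf"` or `"cif"`; default guessed from the extension.
#' @param keep_hydrogens keep explicit H atoms as graph atoms (default FALSE:
#'   fold them into the neighbour's `n_hydrogens` and drop their coordinates).
#' @return A list with `records` (list of `list(graph, coords)`) and
#'   `rejects` (data.frame with `index`, `name`, `reason`). If no record is
#'   valid, a warning of class `moltransfer_empty_result` is signalled.
#' @export
load_structures <- function(path, format = NULL, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "sdf"
  format <- match.arg(format, c("sdf", "cif"))
  raws <- if (format == "sdf") split_sdf_records(path) else split_cif_blocks(path)

  records <- list()
  rejects <- data.frame(index = integer(), name = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (i in seq_along(raws)) {
    parsed <- tryCatch(
      if (format == "sdf") parse_sdf_record(raws[[i]], keep_hydrogens)
      else parse_cif_block(raws[[i]], keep_hydrogens),
      error = function(e) e)
    if (inherits(parsed, "error")) {
      rejects <- rbind(rejects, data.frame(
        index = i, name = raw_record_name(raws[[i]], format),
        reason = conditionMessage(parsed), stringsAsFactors = FALSE))
    } else {
      records[[length(records) + 1L]] <- parsed
    }
  }
  if (!length(records) && length(raws))
    warning(structure(class = c("moltransfer_empty_result", "warning",
                                "condition"),
                      list(message = paste0("no valid records in ", path),
                           call = NULL)))
  list(records = records, rejects = rejects)
}

raw_record_name <- function(raw, format) {
  if (format == "sdf") {
    nm <- trimws(raw[1])
  } else {
    nm <- sub("^data_", "", raw[grepl("^data_", raw)][1])
  }
  if (is.na(nm) || !nzchar(nm)) NA_character_ else nm
}

# ---- SDF -------------------------------------------------------------------

split_sdf_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(list())
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) return(list(lines))
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  # trailing content after the last $$$$ (tolerated if blank)
  tail_lines <- if (max(ends) < length(lines)) lines[(max(ends) + 1L):length(lines)] else character()
  if (any(nzchar(trimws(tail_lines)))) out <- c(out, list(tail_lines))
  out
}

parse_sdf_record <- function(lines, keep_hydrogens) {
  if (length(lines) < 4L) stop("truncated SDF record")
  name <- trimws(lines[1])
  counts <- lines[4]
  if (grepl("V3000", counts)) return(parse_sdf_v3000(lines, name, keep_hydrogens))
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1L) stop("bad counts line")
  if (length(lines) < 4L + na + nb) stop("truncated atom/bond block")
  atom_lines <- lines[5:(4 + na)]
  coords <- matrix(NA_real_, na, 3)
  element <- character(na)
  for (k in seq_len(na)) {
    coords[k, ] <- suppressWarnings(as.numeric(c(substr(atom_lines[k], 1, 10),
                                                 substr(atom_lines[k], 11, 20),
                                                 substr(atom_lines[k], 21, 30))))
    element[k] <- trimws(substr(atom_lines[k], 31, 34))
  }
  if (any(is.na(coords)) || any(!nzchar(element))) stop("bad atom block")
  bonds <- if (nb > 0L) {
    bl <- lines[(5 + na):(4 + na + nb)]
    data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      code = as.integer(substr(bl, 7, 9)),
      stringsAsFactors = FALSE)
  } else data.frame(a1 = integer(), a2 = integer(), code = integer())
  charges <- rep(0L, na)
  for (ln in lines[grepl("^M  CHG", lines)]) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    cnt <- f[1]
    for (j in seq_len(cnt)) charges[f[2 * j]] <- f[2 * j + 1]
  }
  build_structure_record(element, coords, bonds, charges, name, keep_hydrogens)
}

parse_sdf_v3000 <- function(lines, name, keep_hydrogens) {
  v <- trimws(sub("^M  V30 ?", "", lines[grepl("^M  V30", lines)]))
  cl <- v[grepl("^COUNTS", v)][1]
  if (is.na(cl)) stop("V3000 record without COUNTS")
  cnt <- as.integer(strsplit(cl, "\\s+")[[1]][2:3])
  a0 <- which(v == "BEGIN ATOM"); a1 <- which(v == "END ATOM")
  b0 <- which(v == "BEGIN BOND"); b1 <- which(v == "END BOND")
  if (!length(a0) || !length(a1)) stop("V3000 record without atom block")
  atom_rows <- if (a1 - a0 > 1L) v[(a0 + 1L):(a1 - 1L)] else character()
  if (length(atom_rows) != cnt[1]) stop("V3000 atom count mismatch")
  element <- character(cnt[1]); coords <- matrix(NA_real_, cnt[1], 3)
  idx_map <- integer(cnt[1])
  for (k in seq_along(atom_rows)) {
    f <- strsplit(atom_rows[k], "\\s+")[[1]]
    idx_map[k] <- as.integer(f[1])
    element[k] <- f[2]
    coords[k, ] <- as.numeric(f[3:5])
  }
  bonds <- data.frame(a1 = integer(), a2 = integer(), code = integer())
  if (length(b0) && length(b1) && b1 - b0 > 1L) {
    for (row in v[(b0 + 1L):(b1 - 1L)]) {
      f <- as.integer(strsplit(row, "\\s+")[[1]])
      bonds <- rbind(bonds, data.frame(a1 = match(f[3], idx_map),
                                       a2 = match(f[4], idx_map),
                                       code = f[2]))
    }
  }
  build_structure_record(element, coords, bonds, rep(0L, cnt[1]), name,
                         keep_hydrogens)
}

#' Write structures to an SDF (V2000) file
#'
#' @param records list of `list(graph, coords)` pairs.
#' @param path output path.
#' @param explicit_h not supported for writing; heavy atoms only.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(records, path, explicit_h = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  code_of <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
  for (rec in records) {
    g <- rec$graph; xyz <- rec$coords
    writeLines(c(if (!is.null(g$name)) g$name else "", "  moltransfer", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       n_atoms(g), n_bonds(g)), con)
    for (i in seq_len(n_atoms(g)))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         xyz[i, 1], xyz[i, 2], xyz[i, 3], g$atoms$element[i]), con)
    for (k in seq_len(n_bonds(g)))
      writeLines(sprintf("%3d%3d%3d  0", g$bonds$a1[k], g$bonds$a2[k],
                         code_of[[g$bonds$order[k]]]), con)
    chg <- which(g$atoms$formal_charge != 0L)
    if (length(chg))
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, g$atoms$formal_charge[chg]),
                               collapse = "")), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

# ---- CIF -------------------------------------------------------------------

split_cif_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(grepl("^data_", lines))
  if (!length(starts)) stop("no data_ block in CIF file")
  ends <- c(utils::tail(starts, -1) - 1L, length(lines))
  Map(function(s, e) lines[s:e], starts, ends)
}

parse_cif_block <- function(lines, keep_hydrogens) {
  loops <- parse_cif_loops(lines)
  site <- NULL; bond <- NULL
  for (lp in loops) {
    if (any(grepl("^_atom_site_type_symbol$", lp$tags))) site <- lp
    if (any(grepl("^_geom_bond_atom_site_label_1$", lp$tags))) bond <- lp
  }
  if (is.null(site)) stop("CIF block has no _atom_site loop")
  col <- function(lp, tag) {
    j <- match(tag, lp$tags)
    if (is.na(j)) NULL else vapply(lp$rows, `[[`, character(1), j)
  }
  label <- col(site, "_atom_site_label")
  element <- col(site, "_atom_site_type_symbol")
  x <- col(site, "_atom_site_Cartn_x")
  y <- col(site, "_atom_site_Cartn_y")
  z <- col(site, "_atom_site_Cartn_z")
  if (is.null(x)) stop("CIF atom sites lack Cartesian coordinates")
  coords <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))
  if (any(is.na(coords))) stop("non-numeric CIF coordinates")
  charge_col <- col(site, "_atom_site_formal_charge")
  charges <- if (is.null(charge_col)) rep(0L, length(element))
             else as.integer(charge_col)
  name <- sub("^data_", "", lines[grepl("^data_", lines)][1])

  if (!is.null(bond)) {
    l1 <- col(bond, "_geom_bond_atom_site_label_1")
    l2 <- col(bond, "_geom_bond_atom_site_label_2")
    typ <- col(bond, "_geom_bond_type")
    ord_code <- c(sing = 1L, doub = 2L, trip = 3L, arom = 4L)
    code <- if (is.null(typ)) rep(1L, length(l1)) else ord_code[typ]
    if (any(is.na(code))) stop("unknown bond type in CIF bond loop")
    a1 <- match(l1, label); a2 <- match(l2, label)
    if (any(is.na(a1)) || any(is.na(a2))) stop("CIF bond references unknown atom label")
    bonds <- data.frame(a1 = a1, a2 = a2, code = code)
  } else {
    bonds <- perceive_bonds(element, coords)
  }
  build_structure_record(element, coords, bonds, charges, name, keep_hydrogens)
}

# whitespace tokenizer honouring single/double quotes
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1L) return(character())
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

parse_cif_loops <- function(lines) {
  loops <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1L
      }
      rows <- list()
      while (i <= length(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln) || grepl("^(_|loop_|data_|#)", ln)) break
        toks <- cif_tokens(ln)
        if (length(toks) == length(tags)) rows[[length(rows) + 1L]] <- toks
        i <- i + 1L
      }
      loops[[length(loops) + 1L]] <- list(tags = tags, rows = rows)
    } else i <- i + 1L
  }
  loops
}

#' Write structures to a small-molecule CIF file
#'
#' One `data_` block per record: an `_atom_site` loop with Cartesian
#' coordinates plus a `_geom_bond` loop carrying bond orders
#' (`sing`/`doub`/`trip`/`arom`) so graphs round-trip exactly. The dialect is
#' deliberately minimal; unit cells, symmetry and disorder are out of scope.
#'
#' @param records list of `list(graph, coords)` pairs.
#' @param path output path.
#' @param include_bonds write the bond loop (default TRUE; set FALSE to
#'   exercise distance-based bond perception on re-read).
#' @return `path`, invisibly.
#' @export
write_cif <- function(records, path, include_bonds = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  ord_name <- c(single = "sing", double = "doub", triple = "trip",
                aromatic = "arom")
  for (r in seq_along(records)) {
    g <- records[[r]]$graph; xyz <- records[[r]]$coords
    nm <- if (!is.null(g$name)) gsub("\\s", "_", g$name) else sprintf("mol%03d", r)
    label <- paste0(g$atoms$element, seq_len(n_atoms(g)))
    writeLines(c(sprintf("data_%s", nm), "loop_",
                 "_atom_site_label", "_atom_site_type_symbol",
                 "_atom_site_Cartn_x", "_atom_site_Cartn_y",
                 "_atom_site_Cartn_z", "_atom_site_formal_charge"), con)
    writeLines(sprintf("%s %s %.6f %.6f %.6f %d", label, g$atoms$element,
                       xyz[, 1], xyz[, 2], xyz[, 3],
                       g$atoms$formal_charge), con)
    if (include_bonds && n_bonds(g)) {
      writeLines(c("loop_", "_geom_bond_atom_site_label_1",
                   "_geom_bond_atom_site_label_2", "_geom_bond_type"), con)
      writeLines(sprintf("%s %s %s", label[g$bonds$a1], label[g$bonds$a2],
                         ord_name[g$bonds$order]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# ---- shared assembly -------------------------------------------------------

# Distance-based bond perception from covalent radii; flags ambiguity.
perceive_bonds <- function(element, coords) {
  n <- length(element)
  a1 <- integer(); a2 <- integer()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d < 0.4)
      stop(sprintf("ambiguous bonding: atoms %d and %d overlap (%.2f A)", i, j, d))
    if (d < covalent_radius(element[i]) + covalent_radius(element[j]) + 0.45) {
      a1 <- c(a1, i); a2 <- c(a2, j)
    }
  }
  if (!length(a1)) stop("ambiguous bonding: no bonds perceived")
  data.frame(a1 = a1, a2 = a2, code = 1L)
}

# element/coords/bond-code triples -> (canonical graph, aligned coords)
build_structure_record <- function(element, coords, bonds, charges, name,
                                   keep_hydrogens) {
  order_of <- c("single", "double", "triple", "aromatic")
  if (nrow(bonds) && any(!bonds$code %in% 1:4))
    stop("ambiguous bonding: unsupported bond code")
  ord <- if (nrow(bonds)) order_of[bonds$code] else character()
  aromatic <- rep(FALSE, length(element))
  if (nrow(bonds)) {
    ar <- bonds$code == 4L
    aromatic[unique(c(bonds$a1[ar], bonds$a2[ar]))] <- TRUE
  }

  n_h <- rep(0L, length(element))
  keep <- rep(TRUE, length(element))
  if (!keep_hydrogens && any(element == "H")) {
    is_h <- element == "H"
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]
      if (is_h[i] && !is_h[j]) n_h[j] <- n_h[j] + 1L
      if (is_h[j] && !is_h[i]) n_h[i] <- n_h[i] + 1L
    }
    keep <- !is_h
    remap <- cumsum(keep)
    sel <- keep[bonds$a1] & keep[bonds$a2]
    bonds <- data.frame(a1 = remap[bonds$a1[sel]], a2 = remap[bonds$a2[sel]],
                        code = bonds$code[sel])
    ord <- order_of[bonds$code]
    element <- element[keep]; coords <- coords[keep, , drop = FALSE]
    charges <- charges[keep]; aromatic <- aromatic[keep]; n_h <- n_h[keep]
  }
  had_explicit_h <- n_h > 0L

  # valence fill (skip atoms that carried explicit H or a formal charge)
  n <- length(element)
  bsum <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    v <- bond_order_value(ord[k])
    bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + v
    bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + v
  }
  used <- floor(bsum)
  for (i in seq_len(n)) {
    vals <- .STANDARD_VALENCES[[element[i]]]
    if (is.null(vals)) next
    if (charges[i] == 0L && used[i] + n_h[i] > max(vals))
      stop(sprintf("ambiguous bonding: valence violation at atom %d (%s)",
                   i, element[i]))
    if (!had_explicit_h[i] && charges[i] == 0L && !keep_hydrogens) {
      fit <- vals[vals >= used[i]]
      n_h[i] <- as.integer(fit[1] - used[i])
    }
  }

  atoms_df <- data.frame(element = element, formal_charge = charges,
                         aromatic = aromatic, n_hydrogens = n_h,
                         chiral_tag = "none", stringsAsFactors = FALSE)
  bonds_df <- if (nrow(bonds))
    data.frame(a1 = bonds$a1, a2 = bonds$a2, order = ord,
               stringsAsFactors = FALSE) else NULL
  g <- molecular_graph(atoms_df, bonds_df, name = name, canonicalize = FALSE)
  ranks <- canonical_ranks(g)
  g <- permute_graph(g, ranks)
  coords <- coords[order(ranks), , drop = FALSE]
  list(graph = g, coords = unname(coords))
}
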