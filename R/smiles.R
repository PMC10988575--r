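#' Parse a SMILES string into a molecular graph
#'
#' Handles the Daylight organic subset (B, C, N, O, P, S, F, Cl, Br, I and the
#' aromatic forms b, c, n, o, p, s), bracket atoms with isotope, chirality
#' (`@` / `@@`), explicit H counts and charges, branches, ring closures
#' (including `%nn`), explicit bond symbols (`-`, `=`, `#`, `:`; `/` and `\`
#' are accepted and read as single bonds) and dot-separated components.
#' Implicit hydrogens follow the standard valence rules; an unspecified bond
#' between two aromatic atoms is aromatic. Valence violations on
#' organic-subset atoms are a parse error.
#'
#' Chirality is recorded as an atom-level tag (`@` = counterclockwise,
#' `@@` = clockwise); with `include_chirality = FALSE` all tags are `"none"`
#' so enantiomer pairs parse to identical graphs.
#'
#' @param smiles a non-empty SMILES string.
#' @param include_chirality keep chiral tags (default TRUE).
#' @param name optional molecule identifier.
#' @return A [molecular_graph].
#' @export
parse_smiles <- function(smiles, include_chirality = TRUE, name = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a non-empty string")
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  atoms <- list()      # each: list(element, charge, aromatic, h, chiral)
  bonds <- list()      # each: list(a1, a2, order)
  prev <- NA_integer_
  pending_bond <- NA_character_
  stack <- integer()
  ring_open <- list()  # key: ring number -> list(atom, sym)

  fail <- function(msg, at = i)
    stop(sprintf("SMILES parse error in '%s' at position %d: %s",
                 smiles, at, msg), call. = FALSE)

  add_atom <- function(element, aromatic, charge = 0L, h = NA_integer_,
                       chiral = "none") {
    atoms[[length(atoms) + 1L]] <<- list(element = element, charge = charge,
                                         aromatic = aromatic, h = h,
                                         chiral = chiral)
    idx <- length(atoms)
    if (!is.na(prev)) add_bond(prev, idx, pending_bond)
    pending_bond <<- NA_character_
    prev <<- idx
    idx
  }

  add_bond <- function(a1, a2, sym) {
    order <- if (is.na(sym)) {
      if (atoms[[a1]]$aromatic && atoms[[a2]]$aromatic) "aromatic" else "single"
    } else {
      switch(sym, "-" = "single", "=" = "double", "#" = "triple",
             ":" = "aromatic", "/" = "single", "\\" = "single",
             fail(paste0("unknown bond symbol '", sym, "'")))
    }
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, order = order)
  }

  close_ring <- function(num) {
    key <- as.character(num)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = length(atoms), sym = pending_bond)
      pending_bond <<- NA_character_
    } else {
      open <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      sym <- if (!is.na(pending_bond)) pending_bond else open$sym
      if (!is.na(pending_bond) && !is.na(open$sym) &&
          pending_bond != open$sym)
        fail(sprintf("conflicting bond symbols on ring closure %s", key))
      if (open$atom == length(atoms)) fail("ring closure to the same atom")
      add_bond(open$atom, length(atoms), sym)
      pending_bond <<- NA_character_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.na(pending_bond)) fail("two consecutive bond symbols")
      pending_bond <- ch
      i <- i + 1L
    } else if (ch == ".") {
      if (!is.na(pending_bond)) fail("bond symbol before '.'")
      prev <- NA_integer_
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) fail("branch with no preceding atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) fail("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) fail("ring closure with no preceding atom")
      close_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("[0-9]", chars[i + 1]) ||
          !grepl("[0-9]", chars[i + 2]))
        fail("'%' must be followed by two digits")
      close_ring(as.integer(paste0(chars[i + 1], chars[i + 2])))
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unterminated bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, function(m) fail(m, at = i))
      add_atom(at$element, at$aromatic, at$charge, at$h,
               if (include_chirality) at$chiral else "none")
      i <- j + 1L
    } else {
      # organic-subset atom, two-character symbols first
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE); i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        add_atom(ch, FALSE); i <- i + 1L
      } else if (ch %in% .AROMATIC_SYMBOLS) {
        add_atom(toupper(ch), TRUE); i <- i + 1L
      } else {
        fail(sprintf("unexpected character '%s'", ch))
      }
    }
  }
  if (length(stack)) fail("unmatched '('", at = n)
  if (length(ring_open)) fail(sprintf("unclosed ring bond(s): %s",
                                      paste(names(ring_open), collapse = ",")),
                              at = n)
  if (!is.na(pending_bond)) fail("dangling bond symbol", at = n)
  if (!length(atoms)) fail("no atoms", at = n)

  finish_parsed_graph(atoms, bonds, smiles, name)
}

# body of a bracket atom, e.g. "C@@H", "13CH4", "NH3+", "O-", "nH"
parse_bracket_atom <- function(body, fail) {
  m <- regexec(
    "^([0-9]*)([A-Z][a-z]?|[bcnops])(@{1,2})?(?:H([0-9]*))?([+-][0-9]*|\\+{2,}|-{2,})?(?::[0-9]+)?$",
    body, perl = TRUE)
  g <- regmatches(body, m)[[1]]
  if (!length(g)) fail(sprintf("cannot parse bracket atom '[%s]'", body))
  sym <- g[3]
  aromatic <- sym %in% .AROMATIC_SYMBOLS
  element <- if (aromatic) toupper(sym) else sym
  chiral <- if (g[4] == "@@") "clockwise"
            else if (g[4] == "@") "counterclockwise" else "none"
  # group 4 (H-count digits) participates iff 'H' was present: start >= 0
  h <- if (m[[1]][5] == -1L) 0L else if (g[5] == "") 1L else as.integer(g[5])
  charge <- 0L
  cg <- g[6]
  if (nzchar(cg)) {
    if (grepl("^\\+\\+", cg)) charge <- nchar(cg)
    else if (grepl("^--", cg)) charge <- -nchar(cg)
    else {
      mag <- if (nchar(cg) > 1L) as.integer(substring(cg, 2)) else 1L
      charge <- if (substring(cg, 1, 1) == "+") mag else -mag
    }
  }
  list(element = element, aromatic = aromatic, chiral = chiral,
       h = h, charge = charge)
}

# assign implicit hydrogens, check valences, build the canonical graph
finish_parsed_graph <- function(atoms, bonds, smiles, name) {
  n <- length(atoms)
  bsum <- numeric(n)
  for (b in bonds) {
    v <- bond_order_value(b$order)
    bsum[b$a1] <- bsum[b$a1] + v
    bsum[b$a2] <- bsum[b$a2] + v
  }
  used <- floor(bsum)  # aromatic pairs contribute floor(k * 1.5)

  el <- vapply(atoms, function(a) a$element, character(1))
  h <- vapply(atoms, function(a) a$h, integer(1))
  charge <- vapply(atoms, function(a) a$charge, integer(1))
  for (i in seq_len(n)) {
    vals <- .STANDARD_VALENCES[[el[i]]]
    if (is.na(h[i])) {
      # organic-subset atom: fill to the smallest standard valence
      if (is.null(vals))
        stop(sprintf("no valence model for element %s in '%s'", el[i], smiles),
             call. = FALSE)
      fit <- vals[vals >= used[i]]
      if (!length(fit))
        stop(sprintf(
          "valence violation in '%s': atom %d (%s) has bond order sum %g (max %g)",
          smiles, i, el[i], used[i], max(vals)), call. = FALSE)
      h[i] <- as.integer(fit[1] - used[i])
    } else if (charge[i] == 0L && !is.null(vals)) {
      if (used[i] + h[i] > max(vals))
        stop(sprintf(
          "valence violation in '%s': atom %d (%s) exceeds valence %g",
          smiles, i, el[i], max(vals)), call. = FALSE)
    }
  }

  atoms_df <- data.frame(
    element = el,
    formal_charge = charge,
    aromatic = vapply(atoms, function(a) a$aromatic, logical(1)),
    n_hydrogens = h,
    chiral_tag = vapply(atoms, function(a) a$chiral, character(1)),
    stringsAsFactors = FALSE
  )
  bonds_df <- if (length(bonds)) {
    data.frame(a1 = vapply(bonds, `[[`, integer(1), "a1"),
               a2 = vapply(bonds, `[[`, integer(1), "a2"),
               order = vapply(bonds, `[[`, character(1), "order"),
               stringsAsFactors = FALSE)
  } else NULL
  molecular_graph(atoms_df, bonds_df, name = name, source_smiles = smiles)
}
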