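# SMILES <-> molecular graph. Every Molecule is built from an
# OpenBabel-canonical SMILES (see canonicalSmiles); the reader below targets
# that dialect: organic subset + bracket atoms, ring closures (incl. %nn),
# branches, bond symbols - = # : / \ and dot-separated fragments. Stereo
# markers are accepted and ignored (non-goal).

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
# default valences used for implicit hydrogen assignment
.VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
              F = 1, Cl = 1, Br = 1, I = 1)

#' Canonicalize a SMILES string
#'
#' Converts any parsable SMILES to the OpenBabel canonical form. This is the
#' single source of molecular identity in the package: two spellings of the
#' same structure map to one canonical string, and canonicalization is
#' idempotent.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; unparsable entries are
#'   \code{NA} unless \code{strict}.
#' @param strict error on unparsable input (default) instead of returning NA.
#' @export
canonicalSmiles <- function(smiles, strict = TRUE) {
  out <- vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = paste0(s, "\n")),
      error = function(e) "")
    res <- sub("[ \t].*$", "", trimws(res))
    if (!nzchar(res)) NA_character_ else res
  }, character(1), USE.NAMES = FALSE)
  if (strict && anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop("unparsable SMILES: ", paste(utils::head(bad, 3), collapse = ", "),
         call. = FALSE)
  }
  out
}

# tokenize one SMILES string into a graph; internal, expects valid input
.parseSmilesGraph <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  el <- character(0); arom <- logical(0); chg <- integer(0); hct <- integer(0)
  b1 <- integer(0); b2 <- integer(0); bord <- integer(0); barom <- logical(0)
  explicitH <- logical(0)   # TRUE for bracket atoms (H count fixed)
  stack <- integer(0)
  prev <- 0L
  pending <- ""             # pending bond symbol
  rings <- list()           # digit -> list(atom, sym)
  i <- 1L
  add_atom <- function(sym, aromatic, charge, h, expl) {
    el[length(el) + 1L] <<- sym
    arom[length(arom) + 1L] <<- aromatic
    chg[length(chg) + 1L] <<- charge
    hct[length(hct) + 1L] <<- h
    explicitH[length(explicitH) + 1L] <<- expl
    length(el)
  }
  add_bond <- function(a, b, sym) {
    aromBond <- FALSE; ord <- 1L
    if (sym == "=") ord <- 2L
    else if (sym == "#") ord <- 3L
    else if (sym == ":") { aromBond <- TRUE }
    else if (sym %in% c("", "/", "\\")) {
      if (arom[a] && arom[b]) aromBond <- TRUE
    } # "-" stays single even between aromatic atoms
    b1[length(b1) + 1L] <<- a; b2[length(b2) + 1L] <<- b
    bord[length(bord) + 1L] <<- ord
    barom[length(barom) + 1L] <<- aromBond
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", s, call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) stop("unsupported bracket atom [", body, "]",
                                call. = FALSE)
      sym <- m[3]
      aromatic <- sym %in% c(.AROMATIC_ORGANIC, "se", "as")
      if (aromatic) sym <- paste0(toupper(substr(sym, 1, 1)),
                                  substring(sym, 2))
      h <- 0L
      if (nzchar(m[5])) {
        hs <- sub("^H", "", m[5])
        h <- if (nzchar(hs)) as.integer(hs) else 1L
      }
      charge <- 0L
      if (nzchar(m[6])) {
        cs <- m[6]
        if (grepl("^[+-][0-9]+$", cs)) {
          charge <- as.integer(cs)
        } else {
          charge <- nchar(cs) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
        }
      }
      a <- add_atom(sym, aromatic, charge, h, TRUE)
      if (prev > 0L) add_bond(prev, a, pending)
      prev <- a; pending <- ""
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      a <- add_atom(paste0(ch, chars[i + 1L]), FALSE, 0L, NA_integer_, FALSE)
      if (prev > 0L) add_bond(prev, a, pending)
      prev <- a; pending <- ""
      i <- i + 2L
    } else if (ch %in% .ORGANIC) {
      a <- add_atom(ch, FALSE, 0L, NA_integer_, FALSE)
      if (prev > 0L) add_bond(prev, a, pending)
      prev <- a; pending <- ""
      i <- i + 1L
    } else if (ch %in% .AROMATIC_ORGANIC) {
      a <- add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE)
      if (prev > 0L) add_bond(prev, a, pending)
      prev <- a; pending <- ""
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L; pending <- ""
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        key <- paste(chars[(i + 1L):(i + 2L)], collapse = "")
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, sym = pending)
      } else {
        op <- rings[[key]]
        sym <- if (nzchar(pending)) pending else op$sym
        add_bond(op$atom, prev, sym)
        rings[[key]] <- NULL
      }
      pending <- ""
    } else if (ch == "@") {
      i <- i + 1L  # stray stereo marker; ignore
    } else {
      stop("unsupported SMILES token '", ch, "' in: ", s, call. = FALSE)
    }
  }
  if (length(rings) > 0L && any(!vapply(rings, is.null, TRUE)))
    stop("unmatched ring closure in SMILES: ", s, call. = FALSE)
  atoms <- data.frame(element = el, aromatic = arom, charge = chg,
                      hcount = hct, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = b1, a2 = b2, order = bord, aromatic = barom)
  # implicit hydrogens for organic-subset atoms
  for (a in which(!explicitH)) {
    atoms$hcount[a] <- .implicitH(atoms$element[a], atoms$aromatic[a],
                                  bonds, a)
  }
  list(atoms = atoms, bonds = bonds)
}

.implicitH <- function(element, aromatic, bonds, idx) {
  target <- .VALENCE[[element]]
  if (is.null(target)) return(0L)
  sel <- bonds$a1 == idx | bonds$a2 == idx
  ordsum <- sum(ifelse(bonds$aromatic[sel], 1.5, bonds$order[sel]))
  if (aromatic && !any(bonds$aromatic[sel])) ordsum <- ordsum + 0.5
  max(0L, as.integer(target - ceiling(ordsum)))
}

#' Parse a SMILES string into a Molecule
#'
#' Canonicalizes the input (via OpenBabel), then parses the canonical string
#' into an explicit heavy-atom graph with perceived aromaticity. Unparsable
#' input raises an error carrying the offending string; generative loops
#' catch this and assign score 0 instead of crashing.
#'
#' @param smiles a single SMILES string.
#' @param name optional molecule name.
#' @return a [Molecule-class].
#' @examples
#' mol <- parseSmiles("C1=CC=CC=C1")
#' smiles(mol)  # "c1ccccc1"
#' @export
parseSmiles <- function(smiles, name = "") {
  can <- canonicalSmiles(smiles, strict = TRUE)
  g <- .parseSmilesGraph(can)
  new("Molecule", smiles = can, name = as.character(name),
      atoms = g$atoms, bonds = g$bonds)
}

# write a (possibly edited) graph back to a SMILES string. Output is valid
# but not canonical; callers re-canonicalize through OpenBabel, which also
# serves as the valence/aromaticity validity check for GA edits.
.writeSmilesGraph <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (n == 0L) return("")
  nbr <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      nbr[[bonds$a1[k]]] <- c(nbr[[bonds$a1[k]]], k)
      nbr[[bonds$a2[k]]] <- c(nbr[[bonds$a2[k]]], k)
    }
  }
  other <- function(k, a) if (bonds$a1[k] == a) bonds$a2[k] else bonds$a1[k]
  bondSym <- function(k) {
    if (bonds$aromatic[k]) return("")
    if (bonds$order[k] == 2L) return("=")
    if (bonds$order[k] == 3L) return("#")
    if (atoms$aromatic[bonds$a1[k]] && atoms$aromatic[bonds$a2[k]]) return("-")
    ""
  }
  atomStr <- function(a) {
    elem <- atoms$element[a]
    sym <- if (atoms$aromatic[a]) tolower(elem) else elem
    plainOK <- elem %in% .ORGANIC && atoms$charge[a] == 0L
    if (plainOK) {
      impl <- .implicitH(elem, atoms$aromatic[a], bonds, a)
      if (identical(as.integer(impl), as.integer(atoms$hcount[a])))
        return(sym)
    }
    h <- atoms$hcount[a]
    hs <- if (h == 1L) "H" else if (h > 1L) paste0("H", h) else ""
    ch <- atoms$charge[a]
    cs <- if (ch > 0L) paste0("+", if (ch > 1L) ch else "")
          else if (ch < 0L) paste0("-", if (ch < -1L) -ch else "") else ""
    paste0("[", sym, hs, cs, "]")
  }
  # pass 1: DFS to classify bonds into tree edges and ring closures
  visited <- rep(FALSE, n)
  usedBond <- rep(FALSE, max(1L, nrow(bonds)))
  children <- vector("list", n)    # tree bond indices per atom
  ringTok <- vector("list", n)     # ring closure tokens per atom
  ringNum <- 0L
  starts <- integer(0)
  dfs1 <- function(a) {
    visited[a] <<- TRUE
    for (k in nbr[[a]]) {
      if (usedBond[k]) next
      b <- other(k, a)
      if (visited[b]) {
        usedBond[k] <<- TRUE
        ringNum <<- ringNum + 1L
        d <- if (ringNum > 9L) paste0("%", sprintf("%02d", ringNum))
             else as.character(ringNum)
        tok <- paste0(bondSym(k), d)
        ringTok[[b]] <<- c(ringTok[[b]], tok)
        ringTok[[a]] <<- c(ringTok[[a]], tok)
      } else {
        usedBond[k] <<- TRUE
        children[[a]] <<- c(children[[a]], k)
        dfs1(b)
      }
    }
  }
  for (start in seq_len(n)) {
    if (!visited[start]) { starts <- c(starts, start); dfs1(start) }
  }
  # pass 2: emit in the same order
  out <- character(0)
  emit <- function(x) out[length(out) + 1L] <<- x
  dfs2 <- function(a) {
    emit(atomStr(a))
    for (tok in ringTok[[a]]) emit(tok)
    ks <- children[[a]]
    for (idx in seq_along(ks)) {
      k <- ks[idx]
      b <- other(k, a)
      last <- idx == length(ks)
      if (!last) emit("(")
      emit(bondSym(k))
      dfs2(b)
      if (!last) emit(")")
    }
  }
  pieces <- character(0)
  for (start in starts) {
    out <- character(0)
    dfs2(start)
    pieces <- c(pieces, paste(out, collapse = ""))
  }
  paste(pieces, collapse = ".")
}

# rebuild a Molecule from an edited graph; NA on invalid chemistry
.moleculeFromGraph <- function(atoms, bonds, name = "") {
  s <- .writeSmilesGraph(atoms, bonds)
  can <- canonicalSmiles(s, strict = FALSE)
  if (is.na(can)) return(NULL)
  g <- tryCatch(.parseSmilesGraph(can), error = function(e) NULL)
  if (is.null(g)) return(NULL)
  new("Molecule", smiles = can, name = name, atoms = g$atoms, bonds = g$bonds)
}

#' Read molecules from a .smi file
#'
#' One molecule per line, whitespace-separated SMILES and optional name.
#' Unparsable lines are dropped with a warning (their count is reported).
#'
#' @param path file path.
#' @return list of [Molecule-class] objects.
#' @export
readSmiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  bad <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    m <- tryCatch(parseSmiles(parts[1],
                              name = if (length(parts) > 1) parts[2] else ""),
                  error = function(e) NULL)
    if (is.null(m)) bad <- bad + 1L else out[[length(out) + 1L]] <- m
  }
  if (bad > 0L) warning(bad, " unparsable line(s) dropped from ", path)
  out
}

#' Write molecules to a .smi file
#'
#' @param mols list of [Molecule-class] objects.
#' @param path file path.
#' @export
writeSmiles <- function(mols, path) {
  lines <- vapply(mols, function(m) {
    if (nzchar(m@name)) paste(m@smiles, m@name) else m@smiles
  }, character(1))
  writeLines(lines, path)
}

#' Read a molecule table from CSV
#'
#' Requires a \code{smiles} column; all other columns are kept as
#' precomputed properties. SMILES are canonicalized so rows can be joined
#' against package-internal canonical keys.
#'
#' @param path CSV path.
#' @return data.frame with canonical \code{smiles} plus the input columns.
#' @export
readMoleculeCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"smiles" %in% names(df))
    stop("CSV must contain a 'smiles' column: ", path, call. = FALSE)
  df$smiles <- canonicalSmiles(df$smiles, strict = TRUE)
  df
}
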