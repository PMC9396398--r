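## Amino-acid code tables -----------------------------------------------------

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

#' Default van der Waals radii table
#'
#' Protein heavy-atom radii (PISA-comparable defaults: C 1.70, N 1.55,
#' O 1.52, S 1.80 Angstrom) plus hydrogen and a fallback used, with a
#' warning, for unknown elements.
#'
#' @return Named numeric vector of radii in Angstrom; the `"*"` entry is the
#'   fallback for elements not in the table.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, "*" = 1.70)
}

POLAR_ELEMENTS <- c("N", "O", "S", "SE")

## Element inference from PDB atom names when the element column is absent.
## Two-letter elements that occur in protein files must be checked before
## stripping the leading character.
infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  el <- substr(nm, 1L, 1L)
  two <- substr(nm, 1L, 2L)
  el[two == "SE"] <- "SE"
  el[two %in% c("FE", "ZN", "MG", "MN", "CA") & nchar(atom_name) > 3] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "CA") & nchar(atom_name) > 3]
  el
}

new_structure <- function(id, atoms) {
  stopifnot(is.data.frame(atoms))
  atoms$chain <- as.character(atoms$chain)
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "ank_structure")
}

#' @export
print.ank_structure <- function(x, ...) {
  a <- x$atoms
  prot <- a[!a$is_het, , drop = FALSE]
  nres <- nrow(unique(prot[, c("chain", "resno", "ins")]))
  cat(sprintf("<ank_structure> id=%s  %d atoms, %d polymer residues, chains: %s\n",
              x$id, nrow(a), nres,
              paste(unique(prot$chain), collapse = " ")))
  invisible(x)
}

finish_atoms <- function(atoms, radii, keep_hydrogens = TRUE,
                         keep_hetero = FALSE) {
  if (!nrow(atoms)) stop("no atom records parsed")
  ## highest-occupancy alternate conformer only
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom_name)
    ord <- order(key, -atoms$occ)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$ins,
                                     atoms$atom_name)), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  blank <- is.na(atoms$element) | atoms$element == ""
  atoms$element[blank] <- infer_element(atoms$atom_name[blank])
  atoms$element <- toupper(atoms$element)
  unknown <- !(atoms$element %in% names(radii))
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(atoms$element[unknown]),
                                         collapse = ", "),
            ": using fallback radius ", radii[["*"]])
  }
  atoms$vdw <- unname(ifelse(unknown, radii[["*"]], radii[atoms$element]))
  atoms$is_polar <- atoms$element %in% POLAR_ELEMENTS
  atoms$aa <- unname(AA3_TO_1[atoms$resname])
  atoms$aa[is.na(atoms$aa)] <- "X"
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (!keep_hetero) {
    atoms <- atoms[!atoms$is_het | atoms$resname == "MSE", , drop = FALSE]
  }
  atoms
}

#' Parse a macromolecular structure file
#'
#' Reads PDB or mmCIF coordinates into a flat atom table. Author residue
#' numbering is preserved verbatim, so residue identifiers printed in the
#' literature (e.g. F1202) select the same residues here. Waters and hetero
#' groups are excluded by default (selenomethionine is retained as MET-like);
#' hydrogens are kept when present. Only the highest-occupancy alternate
#' conformer is retained.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension, falling back
#'   to content sniffing).
#' @param radii Named van der Waals radii table, Angstrom
#'   (see [default_vdw_radii()]).
#' @param keep_hetero Keep HETATM/non-polymer groups (default `FALSE`).
#' @param keep_hydrogens Keep hydrogen atoms when present (default `TRUE`).
#' @return An object of class `ank_structure`: a list with `id` and `atoms`,
#'   the latter a data frame with one row per atom (chain, resno, ins,
#'   resname, aa, atom_name, element, x, y, z, occ, vdw, is_polar, is_het).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           radii = default_vdw_radii(),
                           keep_hetero = FALSE, keep_hydrogens = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb" else {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (grepl("^data_", first)) "mmcif" else "pdb"
    }
  }
  atoms <- switch(format,
                  pdb = parse_pdb_lines(readLines(path, warn = FALSE)),
                  mmcif = parse_mmcif_lines(readLines(path, warn = FALSE)))
  atoms <- finish_atoms(atoms, radii, keep_hydrogens, keep_hetero)
  new_structure(id = sub("\\.[^.]*$", "", basename(path)), atoms = atoms)
}

parse_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  ## stop at first ENDMDL: single model only
  endmdl <- which(rec == "ENDMDL")
  if (length(endmdl)) sel <- sel[sel < endmdl[1]]
  if (!length(sel)) stop("PDB parse error: no ATOM/HETATM records found")
  ln <- lines[sel]
  x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop("PDB parse error at line ", sel[bad[1]], ": unreadable coordinates in record: ",
         ln[bad[1]])
  }
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  resname <- trimws(substr(ln, 18, 20))
  data.frame(
    serial = seq_along(ln),
    chain = trimws(substr(ln, 22, 22)),
    resno = as.integer(suppressWarnings(as.numeric(substr(ln, 23, 26)))),
    ins = trimws(substr(ln, 27, 27)),
    resname = resname,
    atom_name = trimws(substr(ln, 13, 16)),
    alt = trimws(substr(ln, 17, 17)),
    x = x, y = y, z = z, occ = occ,
    element = trimws(substr(ln, 77, 78)),
    is_het = substr(ln, 1, 6) == "HETATM" | resname == "HOH",
    stringsAsFactors = FALSE
  )
}

## Minimal mmCIF reader: the atom_site loop only. Handles quoted tokens and
## '.'/'?' missing values; author numbering from auth_* items with label_*
## fallback.
parse_mmcif_lines <- function(lines) {
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  if (!length(loop_starts)) stop("mmCIF parse error: no loop_ blocks")
  for (ls in loop_starts) {
    i <- ls + 1L
    fields <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      fields <- c(fields, trimws(lines[i])); i <- i + 1L
    }
    if (any(grepl("^_atom_site\\.", fields))) {
      j <- i
      while (j <= length(lines) && !grepl("^\\s*(loop_|#|_|data_)", lines[j]) &&
             nzchar(trimws(lines[j]))) j <- j + 1L
      return(parse_atom_site(fields, lines[i:(j - 1L)]))
    }
  }
  stop("mmCIF parse error: no _atom_site loop found")
}

cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  tok <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

parse_atom_site <- function(fields, body) {
  fields <- sub("^_atom_site\\.", "", fields)
  toks <- lapply(body, cif_tokens)
  nf <- length(fields)
  okay <- vapply(toks, length, 1L) == nf
  if (!all(okay)) {
    stop("mmCIF parse error: atom_site row with ", length(toks[[which(!okay)[1]]]),
         " tokens, expected ", nf, ": ", body[which(!okay)[1]])
  }
  mat <- do.call(rbind, toks)
  colnames(mat) <- fields
  get <- function(nm, alt = NULL) {
    if (nm %in% fields) mat[, nm]
    else if (!is.null(alt) && alt %in% fields) mat[, alt]
    else rep(NA_character_, nrow(mat))
  }
  miss_to_blank <- function(v) ifelse(v %in% c(".", "?"), "", v)
  grp <- get("group_PDB")
  resname <- miss_to_blank(get("auth_comp_id", "label_comp_id"))
  data.frame(
    serial = seq_len(nrow(mat)),
    chain = miss_to_blank(get("auth_asym_id", "label_asym_id")),
    resno = as.integer(suppressWarnings(as.numeric(get("auth_seq_id", "label_seq_id")))),
    ins = miss_to_blank(get("pdbx_PDB_ins_code")),
    resname = resname,
    atom_name = miss_to_blank(get("auth_atom_id", "label_atom_id")),
    alt = miss_to_blank(get("label_alt_id")),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occ = {
      o <- suppressWarnings(as.numeric(get("occupancy"))); o[is.na(o)] <- 1; o
    },
    element = miss_to_blank(get("type_symbol")),
    is_het = (!is.na(grp) & grp == "HETATM") | resname == "HOH",
    stringsAsFactors = FALSE
  )
}

#' Write a structure as a normalized PDB file
#'
#' @param x An `ank_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  a <- x$atoms
  rec <- ifelse(a$is_het, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$atom_name) < 4 & nchar(a$element) == 1,
                  sprintf(" %-3s", a$atom_name), sprintf("%-4s", a$atom_name))
  lines <- sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)) %% 100000L, name4, "",
                   substr(a$resname, 1, 3), a$chain, a$resno,
                   ifelse(a$ins == "", " ", a$ins),
                   a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select atoms by chain (and optionally residue numbers)
#'
#' @param x An `ank_structure`.
#' @param chains Character vector of chain identifiers.
#' @param resno Optional integer vector of author residue numbers.
#' @return An `ank_structure` restricted to the selection.
#' @export
select_chains <- function(x, chains, resno = NULL) {
  keep <- x$atoms$chain %in% chains
  if (!is.null(resno)) keep <- keep & x$atoms$resno %in% resno
  new_structure(x$id, x$atoms[keep, , drop = FALSE])
}

#' Per-residue summary of a structure
#'
#' @param x An `ank_structure`.
#' @return Data frame with one row per residue: chain, resno, ins, resname, aa.
#' @export
residue_table <- function(x) {
  a <- x$atoms
  key <- !duplicated(paste(a$chain, a$resno, a$ins))
  out <- a[key, c("chain", "resno", "ins", "resname", "aa")]
  rownames(out) <- NULL
  out
}

#' Read FASTA sequences
#'
#' Thin wrapper around [Biostrings::readBStringSet()]: sequences are
#' uppercased, wrapped lines concatenated, non-standard letters preserved.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write FASTA sequences
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
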