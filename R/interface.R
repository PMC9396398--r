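#' Buried surface area of a two-component complex
#'
#' BSA of each component is its SASA computed alone minus its SASA in the
#' complex; `bsa_total` is the sum over both sides and `interface_area`
#' (the PISA-style convention) is half of it.
#'
#' @param x An `ank_structure` holding both components.
#' @param component_a,component_b Character vectors of chain ids; must be
#'   disjoint and non-empty.
#' @param probe_radius,n_points As in [compute_sasa()].
#' @return List of class `interface_areas`: `bsa_component_a`,
#'   `bsa_component_b`, `bsa_total`, `interface_area`, plus per-residue BSA
#'   tables for each component.
#' @export
buried_surface_area <- function(x, component_a, component_b,
                                probe_radius = 1.4, n_points = 960) {
  check_components(x, component_a, component_b)
  both <- select_chains(x, c(component_a, component_b))
  s_ab <- compute_sasa(both, probe_radius, n_points)
  s_a <- compute_sasa(select_chains(x, component_a), probe_radius, n_points)
  s_b <- compute_sasa(select_chains(x, component_b), probe_radius, n_points)
  in_a <- both$atoms$chain %in% component_a
  bsa_a <- s_a$total - sum(s_ab$per_atom[in_a])
  bsa_b <- s_b$total - sum(s_ab$per_atom[!in_a])
  per_res_bsa <- function(alone, complex_atoms, complex_area, keep) {
    key_c <- paste(complex_atoms$chain, complex_atoms$resno, complex_atoms$ins)[keep]
    buried <- tapply(complex_area[keep], key_c, sum)
    tab <- alone$per_residue
    tab$bsa <- tab$area - as.numeric(buried[paste(tab$chain, tab$resno, tab$ins)])
    tab[order(-tab$bsa), c("chain", "resno", "aa", "bsa")]
  }
  structure(list(
    bsa_component_a = bsa_a,
    bsa_component_b = bsa_b,
    bsa_total = bsa_a + bsa_b,
    interface_area = (bsa_a + bsa_b) / 2,
    per_residue_a = per_res_bsa(s_a, both$atoms, s_ab$per_atom, in_a),
    per_residue_b = per_res_bsa(s_b, both$atoms, s_ab$per_atom, !in_a)
  ), class = "interface_areas")
}

#' @export
print.interface_areas <- function(x, ...) {
  cat(sprintf("<interface_areas> BSA a=%.1f b=%.1f total=%.1f A^2 (interface %.1f A^2)\n",
              x$bsa_component_a, x$bsa_component_b, x$bsa_total,
              x$interface_area))
  invisible(x)
}

check_components <- function(x, component_a, component_b) {
  if (!length(component_a) || !length(component_b))
    stop("both components must be non-empty chain sets")
  if (length(intersect(component_a, component_b)))
    stop("components overlap: ", paste(intersect(component_a, component_b),
                                       collapse = ", "))
  present <- unique(x$atoms$chain)
  missing <- setdiff(c(component_a, component_b), present)
  if (length(missing)) stop("chains not in structure: ",
                            paste(missing, collapse = ", "))
  invisible(TRUE)
}

## Donor/acceptor chemistry for the 20 standard residues. Backbone N donates,
## backbone O (and OXT) accepts; hydroxyls and thiols appear on both sides.
SC_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TYR = "OH", TRP = "NE1", CYS = "SG"
)
SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
  MET = "SD", CYS = "SG"
)

hb_role <- function(atoms, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  tab <- if (role == "donor") SC_DONORS else SC_ACCEPTORS
  sc <- mapply(function(rn, an) an %in% (tab[[rn]] %||% character()),
               atoms$resname, atoms$atom_name)
  bb <- if (role == "donor") atoms$atom_name == "N" & atoms$resname != "PRO"
        else atoms$atom_name %in% c("O", "OXT")
  (sc | bb) & atoms$element %in% c("N", "O", "S")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Antecedent of a donor: the nearest heavy atom of the same residue within
## covalent range; used for the no-hydrogen angle criterion.
antecedent_coord <- function(atoms, i) {
  same <- which(atoms$chain == atoms$chain[i] & atoms$resno == atoms$resno[i] &
                atoms$ins == atoms$ins[i] & atoms$element != "H")
  same <- setdiff(same, i)
  if (!length(same)) return(NULL)
  d <- sqrt((atoms$x[same] - atoms$x[i])^2 + (atoms$y[same] - atoms$y[i])^2 +
            (atoms$z[same] - atoms$z[i])^2)
  j <- same[which.min(d)]
  if (min(d) > 1.9) return(NULL)
  c(atoms$x[j], atoms$y[j], atoms$z[j])
}

bonded_hydrogens <- function(atoms, i) {
  same <- which(atoms$chain == atoms$chain[i] & atoms$resno == atoms$resno[i] &
                atoms$ins == atoms$ins[i] & atoms$element == "H")
  if (!length(same)) return(integer())
  d <- sqrt((atoms$x[same] - atoms$x[i])^2 + (atoms$y[same] - atoms$y[i])^2 +
            (atoms$z[same] - atoms$z[i])^2)
  same[d < 1.25]
}

vangle <- function(p, q, r) {
  ## angle at q, degrees
  u <- p - q; v <- r - q
  cosv <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Geometric hydrogen-bond detection across an interface
#'
#' Finds donor-acceptor pairs between two components. Default criteria:
#' donor-acceptor heavy-atom distance <= 3.5 Angstrom; when the model has no
#' hydrogens the antecedent-donor-acceptor angle must be >= 90 degrees, and
#' when a hydrogen is bonded to the donor the D-H...A angle must be
#' >= 120 degrees. Both main-chain and side-chain donors/acceptors are
#' considered.
#'
#' @param x An `ank_structure`.
#' @param component_a,component_b Chain sets (disjoint).
#' @param max_da_distance Donor-acceptor cutoff, Angstrom.
#' @param min_angle Angle threshold, degrees (see above for which angle).
#' @return Data frame of class `hbond_table`, sorted by donor residue number:
#'   donor_chain, donor_resno, donor_aa, donor_atom, acceptor_* likewise,
#'   distance, angle.
#' @export
find_hydrogen_bonds <- function(x, component_a, component_b,
                                max_da_distance = 3.5, min_angle = NULL) {
  check_components(x, component_a, component_b)
  a <- x$atoms
  has_h <- any(a$element == "H")
  if (is.null(min_angle)) min_angle <- if (has_h) 120 else 90
  rows <- list()
  for (dir in 1:2) {
    don_side <- if (dir == 1) component_a else component_b
    acc_side <- if (dir == 1) component_b else component_a
    don <- which(a$chain %in% don_side & hb_role(a, "donor"))
    acc <- which(a$chain %in% acc_side & hb_role(a, "acceptor"))
    if (!length(don) || !length(acc)) next
    for (i in don) {
      dx <- a$x[acc] - a$x[i]; dy <- a$y[acc] - a$y[i]; dz <- a$z[acc] - a$z[i]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      near <- which(d <= max_da_distance & d > 0.5)
      for (k in near) {
        j <- acc[k]
        dcoord <- c(a$x[i], a$y[i], a$z[i])
        acoord <- c(a$x[j], a$y[j], a$z[j])
        hs <- if (has_h) bonded_hydrogens(a, i) else integer()
        if (length(hs)) {
          ang <- max(vapply(hs, function(h)
            vangle(dcoord, c(a$x[h], a$y[h], a$z[h]), acoord), 0))
        } else {
          ante <- antecedent_coord(a, i)
          ang <- if (is.null(ante)) 180 else vangle(ante, dcoord, acoord)
        }
        if (ang >= min_angle) {
          rows[[length(rows) + 1L]] <- data.frame(
            donor_chain = a$chain[i], donor_resno = a$resno[i],
            donor_aa = a$aa[i], donor_atom = a$atom_name[i],
            acceptor_chain = a$chain[j], acceptor_resno = a$resno[j],
            acceptor_aa = a$aa[j], acceptor_atom = a$atom_name[j],
            distance = d[k], angle = ang, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    donor_chain = character(), donor_resno = integer(), donor_aa = character(),
    donor_atom = character(), acceptor_chain = character(),
    acceptor_resno = integer(), acceptor_aa = character(),
    acceptor_atom = character(), distance = numeric(), angle = numeric(),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$donor_resno, out$acceptor_resno, out$distance), ]
  rownames(out) <- NULL
  class(out) <- c("hbond_table", "data.frame")
  out
}

## Apolar heavy atoms: carbons; optionally the Met SD / Cys SG sulfurs.
apolar_mask <- function(atoms, include_sulfur = FALSE) {
  m <- atoms$element == "C"
  if (include_sulfur)
    m <- m | (atoms$element == "S" & atoms$resname %in% c("MET", "CYS"))
  m
}

#' Hydrophobic residue-residue contacts across an interface
#'
#' Residue pairs (one per component) whose apolar heavy atoms (carbons;
#' optionally Met/Cys sulfur) approach within `cutoff`.
#'
#' @param x An `ank_structure`.
#' @param component_a,component_b Chain sets (disjoint).
#' @param cutoff Apolar heavy-atom distance cutoff, Angstrom (default 4.5).
#' @param include_sulfur Count Met SD / Cys SG as apolar (default `FALSE`).
#' @return Data frame of class `contact_table`: chain/resno/aa for both
#'   residues, `min_dist`, `n_atom_pairs`.
#' @export
find_hydrophobic_contacts <- function(x, component_a, component_b,
                                      cutoff = 4.5, include_sulfur = FALSE) {
  check_components(x, component_a, component_b)
  a <- x$atoms
  ia <- which(a$chain %in% component_a & apolar_mask(a, include_sulfur))
  ib <- which(a$chain %in% component_b & apolar_mask(a, include_sulfur))
  empty <- data.frame(chain_a = character(), resno_a = integer(),
                      aa_a = character(), chain_b = character(),
                      resno_b = integer(), aa_b = character(),
                      min_dist = numeric(), n_atom_pairs = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("contact_table", "data.frame")
  if (!length(ia) || !length(ib)) return(empty)
  xa <- as.matrix(a[ia, c("x", "y", "z")])
  xb <- as.matrix(a[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  key_a <- paste(a$chain[ia][hit[, 1]], a$resno[ia][hit[, 1]])
  key_b <- paste(a$chain[ib][hit[, 2]], a$resno[ib][hit[, 2]])
  pair <- paste(key_a, "|", key_b)
  d <- sqrt(pmax(0, d2[hit]))
  first <- !duplicated(pair)
  out <- data.frame(
    chain_a = a$chain[ia][hit[first, 1]], resno_a = a$resno[ia][hit[first, 1]],
    aa_a = a$aa[ia][hit[first, 1]], chain_b = a$chain[ib][hit[first, 2]],
    resno_b = a$resno[ib][hit[first, 2]], aa_b = a$aa[ib][hit[first, 2]],
    min_dist = as.numeric(tapply(d, pair, min)[pair[first]]),
    n_atom_pairs = as.integer(table(pair)[pair[first]]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$resno_a, out$resno_b), ]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Full interface report for a two-component complex
#'
#' Combines [buried_surface_area()], [find_hydrogen_bonds()] and
#' [find_hydrophobic_contacts()] into one object.
#'
#' @inheritParams buried_surface_area
#' @param hb_dist,hb_angle Hydrogen-bond criteria (see
#'   [find_hydrogen_bonds()]).
#' @param contact_dist Hydrophobic contact cutoff, Angstrom.
#' @return List of class `interface_report` with elements `areas`, `hbonds`,
#'   `hydrophobic_contacts`.
#' @export
interface_report <- function(x, component_a, component_b,
                             probe_radius = 1.4, n_points = 960,
                             hb_dist = 3.5, hb_angle = NULL,
                             contact_dist = 4.5) {
  structure(list(
    areas = buried_surface_area(x, component_a, component_b,
                                probe_radius, n_points),
    hbonds = find_hydrogen_bonds(x, component_a, component_b,
                                 hb_dist, hb_angle),
    hydrophobic_contacts = find_hydrophobic_contacts(x, component_a,
                                                     component_b,
                                                     contact_dist)
  ), class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  print(x$areas)
  cat(sprintf("  %d hydrogen bonds, %d hydrophobic contact pairs\n",
              nrow(x$hbonds), nrow(x$hydrophobic_contacts)))
  invisible(x)
}

#' Write an interface report to JSON plus TSV tables
#'
#' @param report An `interface_report`.
#' @param json_path Output JSON path (`NULL` to skip).
#' @param tsv_prefix If non-`NULL`, writes `<prefix>_hbonds.tsv` and
#'   `<prefix>_contacts.tsv`.
#' @return `json_path`, invisibly.
#' @export
write_interface_report <- function(report, json_path = NULL,
                                   tsv_prefix = NULL) {
  if (!is.null(json_path)) {
    payload <- list(
      bsa_component_a = report$areas$bsa_component_a,
      bsa_component_b = report$areas$bsa_component_b,
      bsa_total = report$areas$bsa_total,
      interface_area = report$areas$interface_area,
      hbonds = as.data.frame(report$hbonds),
      hydrophobic_contacts = as.data.frame(report$hydrophobic_contacts)
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_prefix)) {
    utils::write.table(as.data.frame(report$hbonds),
                       paste0(tsv_prefix, "_hbonds.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(report$hydrophobic_contacts),
                       paste0(tsv_prefix, "_contacts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
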