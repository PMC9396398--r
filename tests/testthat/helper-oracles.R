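## Independent oracles and fixture builders used across the suite.

## Minimal hand-written PDB text: one chain, one residue, two atoms.
minimal_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "END")
}

## Minimal mmCIF atom_site writer for cross-dialect fixtures (test-only; the
## package itself only writes PDB).
write_mmcif_fixture <- function(x, path) {
  a <- x$atoms
  lines <- c(
    "data_fixture", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.auth_atom_id", "_atom_site.label_alt_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    sprintf("%s %d %s %s . %s %s %d %s %.3f %.3f %.3f %.2f",
            ifelse(a$is_het, "HETATM", "ATOM"), seq_len(nrow(a)), a$element,
            a$atom_name, a$resname, a$chain, a$resno,
            ifelse(a$ins == "", "?", a$ins), a$x, a$y, a$z, a$occ),
    "#")
  writeLines(lines, path)
  path
}

## Random multi-residue two-chain toy structure for property tests: residues
## are small clusters of N/O/C atoms at random positions.
random_toy_structure <- function(n_res_per_chain = 3, spread = 8, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (ch in c("A", "B")) {
      base_off <- if (ch == "A") 0 else c(4, 0, 0)
      for (r in seq_len(n_res_per_chain)) {
        centre <- stats::runif(3, -spread, spread) + base_off
        names3 <- c("N", "CA", "O")
        els <- c("N", "C", "O")
        for (k in 1:3) {
          rows[[length(rows) + 1L]] <- data.frame(
            serial = NA_integer_, chain = ch,
            resno = r + if (ch == "B") 100L else 0L, ins = "",
            resname = "GLY", atom_name = names3[k], alt = "",
            x = centre[1] + stats::rnorm(1, 0, 0.8),
            y = centre[2] + stats::rnorm(1, 0, 0.8),
            z = centre[3] + stats::rnorm(1, 0, 0.8),
            occ = 1, element = els[k], is_het = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
    atoms <- ankgroove:::finish_atoms(do.call(rbind, rows),
                                      default_vdw_radii())
    ankgroove:::new_structure("toy", atoms)
  })
}

## Brute-force geometric hydrogen-bond scan, written independently of the
## package detector: explicit double loop over every atom pair with its own
## donor/acceptor name tables and its own angle code.
brute_force_hbonds <- function(x, chains_a, chains_b, max_dist = 3.5,
                               min_angle = 90) {
  a <- x$atoms
  donor_names <- list(
    any = "N", ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
    HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
    TYR = "OH", TRP = "NE1", CYS = "SG")
  acceptor_names <- list(
    any = c("O", "OXT"), ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
    ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"), SER = "OG",
    THR = "OG1", TYR = "OH", MET = "SD", CYS = "SG")
  found <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      in_ab <- a$chain[i] %in% chains_a && a$chain[j] %in% chains_b
      in_ba <- a$chain[i] %in% chains_b && a$chain[j] %in% chains_a
      if (!in_ab && !in_ba) next
      don_ok <- (a$atom_name[i] == "N" && a$resname[i] != "PRO") ||
        a$atom_name[i] %in% donor_names[[a$resname[i]]]
      acc_ok <- a$atom_name[j] %in% c("O", "OXT") ||
        a$atom_name[j] %in% acceptor_names[[a$resname[j]]]
      if (!isTRUE(don_ok) || !isTRUE(acc_ok)) next
      if (!(a$element[i] %in% c("N", "O", "S"))) next
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                     c(a$x[j], a$y[j], a$z[j]))^2))
      if (d > max_dist || d < 0.5) next
      ## antecedent: nearest same-residue heavy atom
      same <- which(a$chain == a$chain[i] & a$resno == a$resno[i] &
                    a$element != "H")
      same <- setdiff(same, i)
      ang <- 180
      if (length(same)) {
        dd <- sqrt((a$x[same] - a$x[i])^2 + (a$y[same] - a$y[i])^2 +
                   (a$z[same] - a$z[i])^2)
        if (min(dd) <= 1.9) {
          k <- same[which.min(dd)]
          u <- c(a$x[k], a$y[k], a$z[k]) - c(a$x[i], a$y[i], a$z[i])
          v <- c(a$x[j], a$y[j], a$z[j]) - c(a$x[i], a$y[i], a$z[i])
          ang <- acos(max(-1, min(1, sum(u * v) /
                                    sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        }
      }
      if (ang >= min_angle) {
        found[[length(found) + 1L]] <- data.frame(
          donor_resno = a$resno[i], donor_atom = a$atom_name[i],
          acceptor_resno = a$resno[j], acceptor_atom = a$atom_name[j])
      }
    }
  }
  if (!length(found)) return(data.frame(donor_resno = integer(),
                                        donor_atom = character(),
                                        acceptor_resno = integer(),
                                        acceptor_atom = character()))
  unique(do.call(rbind, found))
}

## Bisection solve of the 1:1 mass-action equilibrium, independent of the
## closed-form quadratic used by the package.
bisect_complex <- function(S, X, Kd, tol = 1e-15) {
  f <- function(C) (S - C) * (X - C) - Kd * C
  lo <- 0; hi <- min(S, X)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## Per-injection heats from first principles, reusing only the package's
## protocol bookkeeping but the bisection equilibrium solver.
bisect_heats <- function(params, protocol) {
  tot <- ankgroove:::cell_totals(protocol)
  V0 <- protocol$cell_volume
  C <- mapply(function(S, X) bisect_complex(S, X, params$Kd),
              params$n * tot$M, tot$X)
  Q <- V0 * params$dH * C * 1e6
  Qprev <- c(0, Q[-length(Q)])
  dv <- protocol$injection_volumes / V0
  Q - Qprev + dv * (Q + Qprev) / 2 + params$baseline
}

## The Fig 4A layer residue lists (inputs printed in the source study).
ankg_layer_lists <- function() {
  list(phi1 = c(277L, 310L, 343L, 376L, 409L, 442L),
       phi2 = c(282L, 315L, 348L, 381L, 414L, 447L),
       rho2 = c(318L, 351L, 384L),
       rho1 = c(308L, 341L, 374L))
}

## Synthetic stand-in for the AnkG R8-R13 span: a sequence carrying the
## printed layer residues at their printed author positions (everything
## else glycine). This encodes printed identities as fixture metadata; it
## is NOT the real AnkG sequence.
ankg_layer_sequence_synthetic <- function() {
  aa_at <- c("277" = "I", "310" = "L", "343" = "L", "376" = "L",
             "409" = "F", "442" = "L",
             "282" = "V", "315" = "C", "348" = "M", "381" = "V",
             "414" = "I", "447" = "V",
             "308" = "D", "341" = "N", "374" = "D",
             "318" = "R", "351" = "Q", "384" = "H")
  start <- 277L; end <- 447L + 31L
  chars <- rep("G", end - start + 1L)
  for (pos in names(aa_at)) chars[as.integer(pos) - start + 1L] <- aa_at[[pos]]
  list(sequence = paste(chars, collapse = ""), numbering_start = start)
}
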