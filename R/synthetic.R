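#' Generate periodic repeat sequences with controlled layer composition
#'
#' Emits ANK-like repeat sequences with known ground truth. At each layer
#' offset the residue is drawn from the layer's target class with the given
#' probability (uniformly within the class set) and otherwise uniformly from
#' the complement of that class; all non-layer positions are uniform over
#' the 20 standard amino acids. Layer classes follow the preference
#' analysis: phi1/phi2 hydrophobic, rho1/rho2 polar.
#'
#' @param n_repeats Repeats per sequence (>= 1).
#' @param n_sequences Number of sequences.
#' @param probs Named numeric vector in `[0, 1]` over
#'   phi1/phi2/rho1/rho2: per-layer in-class probability.
#' @param scheme A `layer_scheme`.
#' @param class_scheme A `residue_class_scheme`.
#' @param seed Integer seed.
#' @return List of class `synthetic_repeats`: `sequences` (named character
#'   vector), `frames` (list of `repeat_frames` per sequence), `truth`
#'   (data frame seq/label/layer/resno/aa/in_class), `probs`, `seed`.
#' @export
make_repeat_sequences <- function(n_repeats = 10L, n_sequences = 1L,
                                  probs = c(phi1 = 0.7, phi2 = 0.7,
                                            rho1 = 0.7, rho2 = 0.7),
                                  scheme = layer_scheme(),
                                  class_scheme = residue_class_scheme(),
                                  seed = 1L) {
  stopifnot(n_repeats >= 1, all(probs >= 0 & probs <= 1),
            all(LAYER_NAMES %in% names(probs)))
  aa20 <- c(class_scheme$hydrophobic, class_scheme$polar,
            class_scheme$neither)
  layer_class <- c(phi1 = "hydrophobic", phi2 = "hydrophobic",
                   rho1 = "polar", rho2 = "polar")
  period <- scheme$period
  res <- withr::with_seed(seed, {
    seqs <- character(n_sequences)
    frames <- vector("list", n_sequences)
    truth <- list()
    for (s in seq_len(n_sequences)) {
      chars <- sample(aa20, n_repeats * period, replace = TRUE)
      starts <- seq(1L, by = period, length.out = n_repeats)
      for (ly in LAYER_NAMES) {
        cls_set <- class_scheme[[layer_class[[ly]]]]
        off_set <- setdiff(aa20, cls_set)
        pos <- starts + scheme$offsets[[ly]]
        in_class <- stats::runif(n_repeats) < probs[[ly]]
        chars[pos] <- ifelse(in_class,
                             sample(cls_set, n_repeats, replace = TRUE),
                             sample(off_set, n_repeats, replace = TRUE))
        truth[[length(truth) + 1L]] <- data.frame(
          seq = paste0("syn", s), label = paste0("R", seq_len(n_repeats)),
          layer = ly, resno = as.integer(pos), aa = chars[pos],
          in_class = in_class, stringsAsFactors = FALSE)
      }
      seqs[s] <- paste(chars, collapse = "")
      frames[[s]] <- assign_frames(seqs[s], starts = starts, period = period)
    }
    list(sequences = stats::setNames(seqs, paste0("syn", seq_len(n_sequences))),
         frames = stats::setNames(frames, paste0("syn", seq_len(n_sequences))),
         truth = do.call(rbind, truth))
  })
  structure(c(res, list(probs = probs, seed = seed)),
            class = "synthetic_repeats")
}

IDEAL_NH <- 1.0    # idealized N-H bond length, Angstrom
IDEAL_CN <- 1.47   # antecedent C-N bond length, Angstrom

#' Construct a minimal two-residue geometry fixture
#'
#' Builds a PDB-writable two-chain structure realizing exactly one requested
#' inter-component geometry: an N-H...O hydrogen bond at a given
#' donor-acceptor distance and antecedent-donor-acceptor angle
#' (`type = "hbond"`), a pair of apolar carbons at a given distance
#' (`type = "hydrophobic"`), or two residues separated far beyond any
#' contact criterion (`type = "none"`).
#'
#' @param type `"hbond"`, `"hydrophobic"`, or `"none"`.
#' @param distance Donor-acceptor (or carbon-carbon) distance, Angstrom.
#' @param angle Antecedent-donor-acceptor angle, degrees (hbond only).
#' @return An `ank_structure` with chains `"A"` and `"B"`.
#' @export
make_geometry_fixture <- function(type = c("hbond", "hydrophobic", "none"),
                                  distance = 2.9, angle = 165) {
  type <- match.arg(type)
  if (distance <= 0) stop("distance must be positive")
  radii <- default_vdw_radii()
  atom_row <- function(chain, resno, resname, name, el, xyz) {
    data.frame(serial = NA_integer_, chain = chain, resno = resno, ins = "",
               resname = resname, atom_name = name, alt = "",
               x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, element = el,
               is_het = FALSE, stringsAsFactors = FALSE)
  }
  if (type == "hbond") {
    if (angle <= 0 || angle > 180) stop("infeasible geometry: angle must be in (0, 180]")
    ## antecedent CA at origin, donor N on +x; acceptor O placed in the xy
    ## plane at the requested antecedent-donor-acceptor angle
    don <- c(IDEAL_CN, 0, 0)
    th <- angle * pi / 180
    acc <- don + distance * c(cos(pi - th), sin(pi - th), 0)
    atoms <- rbind(
      atom_row("A", 1L, "GLY", "CA", "C", c(0, 0, 0)),
      atom_row("A", 1L, "GLY", "N", "N", don),
      atom_row("B", 2L, "GLY", "O", "O", acc),
      atom_row("B", 2L, "GLY", "C", "C", acc + c(1.23, 0, 0))
    )
  } else if (type == "hydrophobic") {
    atoms <- rbind(
      atom_row("A", 1L, "ALA", "CA", "C", c(-1.53, 0, 0)),
      atom_row("A", 1L, "ALA", "CB", "C", c(0, 0, 0)),
      atom_row("B", 2L, "ALA", "CB", "C", c(distance, 0, 0)),
      atom_row("B", 2L, "ALA", "CA", "C", c(distance + 1.53, 0, 0))
    )
  } else {
    d <- max(distance, 10)
    atoms <- rbind(
      atom_row("A", 1L, "ALA", "CB", "C", c(0, 0, 0)),
      atom_row("B", 2L, "ALA", "CB", "C", c(d, 0, 0))
    )
  }
  atoms <- finish_atoms(atoms, radii)
  new_structure(paste0("geom_", type), atoms)
}

#' Two-sphere SASA fixture with analytic reference areas
#'
#' Places two atoms of given van der Waals radii at centre distance `d` and
#' returns, alongside the structure, the exact exposed areas from the
#' two-sphere spherical-cap formula (on the accessible spheres of radius
#' `r + probe`). At `d = 0` with equal radii the limiting convention is
#' used: each sphere exposes half its area (their union is a single
#' sphere).
#'
#' @param r1,r2 van der Waals radii, Angstrom.
#' @param d Centre distance, Angstrom (>= 0).
#' @param probe Probe radius, Angstrom.
#' @return List: `structure` (an `ank_structure` whose two atoms carry the
#'   requested radii), `analytic` (list `area1`, `area2`, `total`).
#' @export
make_two_sphere_fixture <- function(r1 = 1.7, r2 = 1.55, d = 2.0,
                                    probe = 1.4) {
  if (d < 0) stop("d must be >= 0")
  atoms <- data.frame(
    serial = 1:2, chain = c("A", "B"), resno = c(1L, 2L), ins = "",
    resname = "UNK", atom_name = c("X1", "X2"), alt = "",
    x = c(0, d), y = 0, z = 0, occ = 1, element = "C",
    is_het = FALSE, stringsAsFactors = FALSE)
  atoms <- suppressWarnings(finish_atoms(atoms, default_vdw_radii()))
  atoms$vdw <- c(r1, r2)
  list(structure = new_structure("two_sphere", atoms),
       analytic = two_sphere_reference_area(r1, r2, d, probe))
}

#' Analytic exposed areas of two intersecting accessible spheres
#'
#' Closed-form spherical-cap solution used as the independent oracle for
#' [compute_sasa()].
#'
#' @inheritParams make_two_sphere_fixture
#' @return List `area1`, `area2`, `total` (Angstrom^2).
#' @export
two_sphere_reference_area <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  full1 <- 4 * pi * R1^2; full2 <- 4 * pi * R2^2
  if (d == 0 && R1 == R2) {
    ## limiting split convention: the union is one sphere
    return(list(area1 = full1 / 2, area2 = full2 / 2, total = full1))
  }
  if (d >= R1 + R2) return(list(area1 = full1, area2 = full2,
                                total = full1 + full2))
  if (d <= abs(R1 - R2)) {
    ## smaller sphere engulfed
    if (R1 >= R2) return(list(area1 = full1, area2 = 0, total = full1))
    return(list(area1 = 0, area2 = full2, total = full2))
  }
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)   # distance c1 -> intersection plane
  h1 <- R1 - x1                          # cap of sphere 1 inside sphere 2
  h2 <- R2 - (d - x1)
  a1 <- full1 - 2 * pi * R1 * h1
  a2 <- full2 - 2 * pi * R2 * h2
  list(area1 = a1, area2 = a2, total = a1 + a2)
}
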