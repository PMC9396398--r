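#' Deterministic quasi-uniform sphere point set (Fibonacci lattice)
#'
#' @param n Number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe of radius `probe_radius` over the structure: each atom's
#' accessible sphere (radius vdw + probe) is sampled on a deterministic
#' Fibonacci lattice and points strictly inside any neighbour's accessible
#' sphere are buried. No RNG is involved, so results are exactly
#' reproducible for a given `n_points`.
#'
#' @param x An `ank_structure`.
#' @param probe_radius Probe radius, Angstrom (water: 1.4).
#' @param n_points Lattice points per atom (>= 64; default 960).
#' @param selection Optional character vector of chains to restrict to.
#' @return An object of class `sasa_result`: list with `per_atom` (numeric
#'   vector, Angstrom^2, parallel to the atom table), `per_residue` (data
#'   frame chain/resno/ins/aa/area) and `total`.
#' @export
compute_sasa <- function(x, probe_radius = 1.4, n_points = 960,
                         selection = NULL) {
  stopifnot(inherits(x, "ank_structure"))
  if (n_points < 64) stop("n_points must be >= 64")
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  a <- x$atoms
  if (!is.null(selection)) a <- a[a$chain %in% selection, , drop = FALSE]
  if (!nrow(a)) stop("empty atom selection")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- a$vdw + probe_radius
  per_atom <- sasa_engine(xyz, rad, n_points)
  res_key <- paste(a$chain, a$resno, a$ins)
  per_res_area <- tapply(per_atom, res_key, sum)
  first <- !duplicated(res_key)
  per_residue <- data.frame(
    chain = a$chain[first], resno = a$resno[first], ins = a$ins[first],
    aa = a$aa[first], area = as.numeric(per_res_area[res_key[first]]),
    stringsAsFactors = FALSE
  )
  rownames(per_residue) <- NULL
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 total = sum(per_atom), n_points = n_points,
                 probe_radius = probe_radius),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.1f A^2 over %d atoms (%d points, probe %.2f A)\n",
              x$total, length(x$per_atom), x$n_points, x$probe_radius))
  invisible(x)
}

## Core SR loop: per atom, count lattice points outside all neighbouring
## accessible spheres. Neighbour candidates from a coarse pairwise distance
## screen done in blocks to bound memory.
sasa_engine <- function(xyz, rad, n_points) {
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  maxr <- max(rad)
  area <- numeric(n)
  block <- 512L
  nb <- vector("list", n)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    idx <- s:e
    d2 <- outer(rowSums(xyz[idx, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[idx, , drop = FALSE] %*% t(xyz)
    cut2 <- outer(rad[idx], rad, "+")^2
    hits <- d2 < cut2 - 1e-12
    for (k in seq_along(idx)) {
      i <- idx[k]
      cand <- which(hits[k, ])
      nb[[i]] <- cand[cand != i]
    }
  }
  for (i in seq_len(n)) {
    neigh <- nb[[i]]
    if (!length(neigh)) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    sp <- pts * rad[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in neigh) {
      if (!any(free)) break
      dx <- sp[free, 1] - xyz[j, 1]
      dy <- sp[free, 2] - xyz[j, 2]
      dz <- sp[free, 3] - xyz[j, 3]
      inside <- (dx * dx + dy * dy + dz * dz) < rad[j]^2 - 1e-12
      free[which(free)[inside]] <- FALSE
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  area
}
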