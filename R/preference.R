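#' Residue class scheme (hydrophobic / polar / neither)
#'
#' Default sets are the ones used for the inner-groove preference analysis:
#' hydrophobic A/C/F/I/L/M/V/W/Y and polar D/E/H/K/N/Q/R/S/T (note C and Y
#' count as hydrophobic here, unlike in some other schemes); G and P fall in
#' neither class.
#'
#' @param hydrophobic,polar Character vectors of one-letter codes; must be
#'   disjoint.
#' @return List of class `residue_class_scheme` with `hydrophobic`, `polar`
#'   and the derived `neither` complement (over the 20 standard codes).
#' @export
residue_class_scheme <- function(
    hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W", "Y"),
    polar = c("D", "E", "H", "K", "N", "Q", "R", "S", "T")) {
  hydrophobic <- toupper(hydrophobic); polar <- toupper(polar)
  if (length(intersect(hydrophobic, polar)))
    stop("hydrophobic and polar sets must be disjoint")
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  structure(list(hydrophobic = hydrophobic, polar = polar,
                 neither = setdiff(aa20, c(hydrophobic, polar))),
            class = "residue_class_scheme")
}

#' Classify a residue as hydrophobic, polar, or neither
#'
#' @param aa One-letter code(s); vectorised.
#' @param scheme A `residue_class_scheme`.
#' @return Character vector in `{"hydrophobic", "polar", "neither"}`.
#'   Non-standard letters classify as `"neither"` with a warning.
#' @export
classify_residue <- function(aa, scheme = residue_class_scheme()) {
  aa <- toupper(aa)
  if (any(nchar(aa) != 1)) stop("aa must be single letters")
  std <- c(scheme$hydrophobic, scheme$polar, scheme$neither)
  if (any(!(aa %in% std)))
    warning("non-standard letter(s) classified as 'neither': ",
            paste(unique(aa[!(aa %in% std)]), collapse = ", "))
  ifelse(aa %in% scheme$hydrophobic, "hydrophobic",
         ifelse(aa %in% scheme$polar, "polar", "neither"))
}

#' Class fraction at a layer position over pooled assignments
#'
#' @param assignments A `layer_assignment` or list of them (pooled; pooling
#'   is order-independent).
#' @param position One of `"phi1"`, `"phi2"`, `"rho1"`, `"rho2"`.
#' @param target_class `"hydrophobic"`, `"polar"`, or `"neither"`.
#' @param scheme A `residue_class_scheme`.
#' @return List `(k, n, fraction)`; residues marked absent (`NA`) are
#'   excluded from `n`.
#' @export
layer_fraction <- function(assignments, position,
                           target_class = c("hydrophobic", "polar", "neither"),
                           scheme = residue_class_scheme()) {
  target_class <- match.arg(target_class)
  position <- match.arg(position, LAYER_NAMES)
  if (is.data.frame(assignments)) assignments <- list(assignments)
  aa <- unlist(lapply(assignments, function(a) a$aa[a$layer == position]))
  aa <- aa[!is.na(aa)]
  if (!length(aa)) stop("no residues at position ", position)
  cls <- classify_residue(aa, scheme)
  k <- sum(cls == target_class)
  list(k = k, n = length(aa), fraction = k / length(aa))
}

#' Residue-weighted class fraction over whole sequences
#'
#' Natural-abundance background: the fraction of all residues, over all
#' positions of all sequences, falling in `target_class`.
#'
#' @param sequences Named character vector (e.g. from [read_fasta()]).
#' @param target_class,scheme As in [layer_fraction()].
#' @return List `(k, n, fraction)`.
#' @export
proteome_background <- function(sequences,
                                target_class = c("hydrophobic", "polar",
                                                 "neither"),
                                scheme = residue_class_scheme()) {
  target_class <- match.arg(target_class)
  if (!length(sequences)) stop("need at least one sequence")
  aa <- strsplit(toupper(paste(sequences, collapse = "")), "")[[1]]
  cls <- suppressWarnings(classify_residue(aa, scheme))
  k <- sum(cls == target_class)
  list(k = k, n = length(aa), fraction = k / length(aa))
}

#' One-sided exact binomial enrichment test
#'
#' Upper-tail probability P(X >= k) for X ~ Binomial(n, p0): is the observed
#' in-class count at a layer position larger than the background fraction
#' explains?
#'
#' @param k Observed in-class count.
#' @param n Number of residues observed.
#' @param p0 Background in-class fraction, strictly inside (0, 1).
#' @return List of class `enrichment_result`: `k`, `n`, `p0`, `p_value`.
#' @export
enrichment_test <- function(k, n, p0) {
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be strictly inside (0, 1)")
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  structure(list(k = k, n = n, p0 = p0, p_value = p),
            class = "enrichment_result")
}

#' Preference table across cohorts and layer positions
#'
#' Builds the layer-preference summary: for each of phi1/phi2 (hydrophobic
#' class) and rho1/rho2 (polar class), the in-class fraction for each named
#' cohort of layer assignments, plus an optional proteome background row and
#' enrichment p-values against it.
#'
#' @param cohorts Named list; each element a list of `layer_assignment`s.
#' @param proteome Optional named character vector of sequences for the
#'   natural-abundance background.
#' @param scheme A `residue_class_scheme`.
#' @return Data frame: position, cohort, class, k, n, fraction, p_value
#'   (`NA` without a background).
#' @export
preference_table <- function(cohorts, proteome = NULL,
                             scheme = residue_class_scheme()) {
  pos_class <- c(phi1 = "hydrophobic", phi2 = "hydrophobic",
                 rho1 = "polar", rho2 = "polar")
  rows <- list()
  for (pos in names(pos_class)) {
    cls <- pos_class[[pos]]
    bg <- if (!is.null(proteome))
      proteome_background(proteome, cls, scheme) else NULL
    for (coh in names(cohorts)) {
      lf <- layer_fraction(cohorts[[coh]], pos, cls, scheme)
      pv <- if (!is.null(bg) && bg$fraction > 0 && bg$fraction < 1)
        enrichment_test(lf$k, lf$n, bg$fraction)$p_value else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, cohort = coh, class = cls, k = lf$k, n = lf$n,
        fraction = lf$fraction, p_value = pv, stringsAsFactors = FALSE)
    }
    if (!is.null(bg)) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, cohort = "proteome_background", class = cls,
        k = bg$k, n = bg$n, fraction = bg$fraction, p_value = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
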