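LAYER_NAMES <- c("phi1", "phi2", "rho2", "rho1")

#' Construct an inner-groove layer scheme
#'
#' Offsets of the four inner-groove positions relative to the frame origin
#' (anchored at the hairpin hydrophobic position `phi1`). Defaults are the
#' canonical 33-residue ANK repeat values: phi1 0, phi2 +5, rho2 +8,
#' rho1 +31.
#'
#' @param offsets Named integer vector over `phi1`, `phi2`, `rho2`, `rho1`.
#' @param period Repeat period in residues (30-36).
#' @return List of class `layer_scheme`.
#' @export
layer_scheme <- function(offsets = c(phi1 = 0L, phi2 = 5L, rho2 = 8L,
                                     rho1 = 31L),
                         period = 33L) {
  if (period < 30 || period > 36) stop("period must be in [30, 36]")
  if (!all(LAYER_NAMES %in% names(offsets)))
    stop("offsets must name all of: ", paste(LAYER_NAMES, collapse = ", "))
  offsets <- as.integer(offsets[LAYER_NAMES])
  names(offsets) <- LAYER_NAMES
  if (anyDuplicated(offsets)) stop("offsets must be distinct")
  if (any(offsets < 0 | offsets >= period)) stop("offsets must lie in [0, period)")
  structure(list(offsets = offsets, period = as.integer(period)),
            class = "layer_scheme")
}

#' Derive layer offsets and repeat period from per-layer residue lists
#'
#' Given, for each layer, the author residue numbers observed at that
#' position across consecutive repeats, recovers the common repeat period
#' (the shared spacing of each arithmetic series) and each layer's offset
#' modulo the period, anchored so that `phi1` has offset 0.
#'
#' @param residue_lists Named list (`phi1`, `phi2`, `rho2`, `rho1`; `phi1`
#'   required) of increasing integer vectors of residue numbers.
#' @return A `layer_scheme`.
#' @export
derive_layer_offsets <- function(residue_lists) {
  if (!("phi1" %in% names(residue_lists)))
    stop("residue_lists must include 'phi1' (the anchor layer)")
  diffs <- unlist(lapply(residue_lists, function(v) diff(sort(v))))
  if (!length(diffs)) stop("need at least two residues in some layer to fix the period")
  period <- Reduce(gcd2, diffs)
  if (period < 30 || period > 36) {
    bad <- names(residue_lists)[vapply(residue_lists, function(v)
      any(diff(sort(v)) %% period != 0), TRUE)]
    stop("inconsistent spacing: derived period ", period,
         " outside [30,36]; check entries in: ",
         paste(unique(c(bad, "phi1")), collapse = ", "))
  }
  anchor <- min(residue_lists$phi1)
  offs <- vapply(residue_lists, function(v) {
    o <- unique((v - anchor) %% period)
    if (length(o) != 1)
      stop("inconsistent spacing: residues ", paste(v, collapse = ","),
           " are not phase-consistent at period ", period)
    as.integer(o)
  }, integer(1))
  full <- c(phi1 = 0L, phi2 = 5L, rho2 = 8L, rho1 = 31L)
  full[names(offs)] <- offs
  layer_scheme(offsets = full, period = period)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Assign ANK repeat frames on a sequence
#'
#' Frames are defined by the residue number of their origin (the `phi1`
#' hairpin position) and the repeat period. Boundaries are either given
#' explicitly or found by a self-consistent periodicity scan
#' (`motif_scan = TRUE`): the tiling phase maximising sequence identity
#' between consecutive period-length windows is chosen (ties break to the
#' smallest phase).
#'
#' @param sequence Character scalar (one-letter amino-acid sequence).
#' @param starts Increasing integer vector of frame origins, in the
#'   numbering given by `numbering_start` (omit when `motif_scan = TRUE`).
#' @param period Repeat period (default 33).
#' @param labels Optional repeat labels; default `R<first_index>`,
#'   `R<first_index+1>`, ...
#' @param first_index Ordinal of the first frame (default 1), so AnkG R8-16
#'   fragments can carry their paper indices.
#' @param numbering_start Author residue number of the first sequence
#'   position (default 1).
#' @param motif_scan Scan for the frame phase instead of using `starts`.
#' @return Data frame of class `repeat_frames`: label, start (author
#'   numbering), period.
#' @export
assign_frames <- function(sequence, starts = NULL, period = 33L,
                          labels = NULL, first_index = 1L,
                          numbering_start = 1L, motif_scan = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  last_resno <- numbering_start + L - 1L
  if (motif_scan) {
    if (!is.null(starts)) stop("give either starts or motif_scan, not both")
    starts <- scan_repeat_phase(sequence, period) + numbering_start - 1L
  }
  if (is.null(starts) || !length(starts)) stop("no frame starts given or found")
  if (is.unsorted(starts, strictly = TRUE)) stop("starts must be strictly increasing")
  if (any(starts < numbering_start) || any(starts > last_resno))
    stop("frame start outside sequence: ",
         paste(starts[starts < numbering_start | starts > last_resno],
               collapse = ", "))
  if (is.null(labels))
    labels <- paste0("R", seq(first_index, length.out = length(starts)))
  out <- data.frame(label = labels, start = as.integer(starts),
                    period = as.integer(period), stringsAsFactors = FALSE)
  class(out) <- c("repeat_frames", "data.frame")
  out
}

## Best tiling phase by adjacent-window identity; returns 1-based sequence
## positions of frame origins.
scan_repeat_phase <- function(sequence, period) {
  L <- nchar(sequence)
  if (L < 2 * period) stop("sequence too short for motif scan at period ", period)
  chars <- strsplit(sequence, "")[[1]]
  best_phase <- 1L; best_score <- -1
  for (phase in seq_len(period)) {
    starts <- seq(phase, L - period + 1L, by = period)
    if (length(starts) < 2) next
    score <- 0
    for (k in seq_len(length(starts) - 1L)) {
      a <- chars[starts[k]:(starts[k] + period - 1L)]
      b <- chars[starts[k + 1L]:(starts[k + 1L] + period - 1L)]
      score <- score + sum(a == b)
    }
    score <- score / (length(starts) - 1L)
    if (score > best_score + 1e-9) { best_score <- score; best_phase <- phase }
  }
  seq(best_phase, L - period + 1L, by = period)
}

#' Extract inner-groove layer residues for a set of repeat frames
#'
#' For each frame and each layer position, reports the residue number and
#' amino acid found at origin + offset. Positions outside the input
#' (truncated terminal repeats) are reported as absent (`NA`), never
#' guessed.
#'
#' @param frames A `repeat_frames` data frame (see [assign_frames()]).
#' @param scheme A `layer_scheme`.
#' @param x Either a character sequence (with `numbering_start` giving the
#'   author number of its first residue) or an `ank_structure` (residues
#'   selected by author numbering; `chain` required).
#' @param numbering_start For sequence input, author number of position 1.
#' @param chain For structure input, which chain to read.
#' @return Data frame of class `layer_assignment`: label, layer, resno, aa.
#' @export
extract_layers <- function(frames, scheme, x, numbering_start = 1L,
                           chain = NULL) {
  stopifnot(inherits(scheme, "layer_scheme"))
  lookup <- if (inherits(x, "ank_structure")) {
    rt <- residue_table(x)
    if (!is.null(chain)) rt <- rt[rt$chain == chain, , drop = FALSE]
    stats::setNames(rt$aa, rt$resno)
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    aa <- strsplit(toupper(x), "")[[1]]
    stats::setNames(aa, seq_along(aa) + numbering_start - 1L)
  }
  rows <- lapply(seq_len(nrow(frames)), function(i) {
    resno <- frames$start[i] + scheme$offsets
    data.frame(label = frames$label[i], layer = LAYER_NAMES,
               resno = as.integer(resno),
               aa = unname(lookup[as.character(resno)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("layer_assignment", "data.frame")
  out
}

#' Read repeat frames from JSON or TSV
#'
#' JSON shape: `{"protein": "AnkG", "frames": [{"start": 277, "period": 33,
#' "label": "R8"}, ...]}`. TSV shape: 3 columns label/start/period with a
#' header.
#'
#' @param path File path (`.json` or tab-separated text).
#' @return A `repeat_frames` data frame with attribute `protein` when given.
#' @export
read_frames <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    fr <- obj$frames
    out <- data.frame(label = fr$label, start = as.integer(fr$start),
                      period = as.integer(fr$period),
                      stringsAsFactors = FALSE)
    attr(out, "protein") <- obj$protein
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(out) <- tolower(names(out))
    out <- out[, c("label", "start", "period")]
  }
  if (is.unsorted(out$start, strictly = TRUE))
    stop("frame starts must be strictly increasing")
  class(out) <- c("repeat_frames", "data.frame")
  out
}

#' Write a layer assignment as TSV
#'
#' Columns: protein, repeat, layer, resnum, aa.
#'
#' @param assignment A `layer_assignment`.
#' @param path Output path.
#' @param protein Protein identifier column value.
#' @return `path`, invisibly.
#' @export
write_layer_assignment <- function(assignment, path, protein = "protein") {
  out <- data.frame(protein = protein, repeat_label = assignment$label,
                    layer = assignment$layer, resnum = assignment$resno,
                    aa = assignment$aa)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Built-in AnkG R8-14 repeat frames
#'
#' The frames of the ANK repeats resolved in the AnkG/neurofascin complex,
#' anchored at the phi1 hairpin positions (origin of R8 at residue 277,
#' period 33).
#'
#' @return A `repeat_frames` data frame (R8-R13 full frames; R13 is the last
#'   frame whose phi1 anchor lies in the printed series).
#' @export
ankg_r8_frames <- function() {
  out <- data.frame(label = paste0("R", 8:13),
                    start = seq(277L, by = 33L, length.out = 6L),
                    period = 33L, stringsAsFactors = FALSE)
  attr(out, "protein") <- "AnkG"
  class(out) <- c("repeat_frames", "data.frame")
  out
}
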