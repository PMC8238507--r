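# 64-channel 10-10 layout and the derived 112-pair bipolar montage

#' The nine occipito-parietal analysis pairs, grouped
#'
#' Three triads of bipolar pairs over the left parieto-occipital, right
#' parieto-occipital, and occipital midline regions. The block-level artifact
#' rule requires at least one clean pair in each triad.
#' @return named list of three character vectors (`g1`, `g2`, `g3`)
#' @export
analysis_groups <- function() {
  list(
    g1 = c("PO3-P1", "PO3-P3", "POz-PO3"),
    g2 = c("PO4-P2", "PO4-P4", "POz-PO4"),
    g3 = c("Oz-POz", "Oz-O1", "Oz-O2")
  )
}

#' Build the packaged 64-electrode 10-10 scalp layout
#'
#' Reads the versioned layout shipped with the package: 64 uniquely named
#' 10-10 electrodes with schematic scalp coordinates (an azimuthal-equidistant
#' style projection onto the unit disc, used only for scalp-map plotting).
#'
#' @return an object of class `electrode_layout`: a data frame with columns
#'   `electrode`, `x`, `y`
#' @export
build_layout <- function() {
  path <- system.file("extdata", "electrode_layout.tsv", package = "gammacc",
                      mustWork = TRUE)
  layout <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(layout) == 64, !anyDuplicated(layout$electrode),
            all(is.finite(layout$x)), all(is.finite(layout$y)),
            all(abs(layout$x) <= 1), all(abs(layout$y) <= 1))
  class(layout) <- c("electrode_layout", "data.frame")
  layout
}

#' Derive the bipolar montage from the unipolar layout
#'
#' Returns the packaged neighbor-pair list: 112 bipolar derivations between
#' adjacent 10-10 electrodes, named `Anode-Cathode` with the anode the more
#' posterior (between rows) or more medial (within a row) electrode. The nine
#' printed occipito-parietal analysis pairs are pinned and validated.
#'
#' @param layout an `electrode_layout` from [build_layout()]
#' @return an object of class `bipolar_montage`: a list with elements
#'   `pairs` (data frame: `pair_name`, `anode`, `cathode`, `group`),
#'   `analysis_groups` (list of three triads) and `analysis_set`
#'   (character vector of nine pair names)
#' @export
derive_bipolar <- function(layout) {
  stopifnot(inherits(layout, "electrode_layout"), nrow(layout) == 64)
  path <- system.file("extdata", "bipolar_montage.tsv", package = "gammacc",
                      mustWork = TRUE)
  pairs <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(unique(c(pairs$anode, pairs$cathode)), layout$electrode)
  if (length(missing) > 0) {
    stop("montage configuration error: unknown electrode(s) ",
         paste(missing, collapse = ", "))
  }
  groups <- analysis_groups()
  aset <- unname(unlist(groups))
  stopifnot(nrow(pairs) == 112, !anyDuplicated(pairs$pair_name),
            all(aset %in% pairs$pair_name), length(aset) == 9)
  structure(list(pairs = pairs, analysis_groups = groups,
                 analysis_set = aset),
            class = "bipolar_montage")
}

#' Propagate bad unipolar electrodes to bipolar pairs
#'
#' A bipolar pair is discarded if either of its constituent unipolar
#' electrodes is marked bad.
#'
#' @param montage a `bipolar_montage`
#' @param bad_unipolars character vector of bad unipolar electrode names
#' @return character vector of bad pair names (subset of `montage$pairs$pair_name`)
#' @export
propagate_bad <- function(montage, bad_unipolars) {
  stopifnot(inherits(montage, "bipolar_montage"))
  bad_unipolars <- unique(as.character(bad_unipolars))
  known <- unique(c(montage$pairs$anode, montage$pairs$cathode))
  unknown <- setdiff(bad_unipolars, known)
  if (length(unknown) > 0) {
    stop("unknown electrode name(s): ", paste(unknown, collapse = ", "))
  }
  sel <- montage$pairs$anode %in% bad_unipolars |
    montage$pairs$cathode %in% bad_unipolars
  montage$pairs$pair_name[sel]
}

#' Re-reference unipolar data to bipolar pairs
#'
#' Forms each bipolar series as anode minus cathode, sample-aligned.
#'
#' @param data numeric matrix, samples x 64 unipolar channels, with column
#'   names matching the layout electrode names
#' @param montage a `bipolar_montage`
#' @param pair_names pairs to derive (default: the nine-pair analysis set)
#' @return numeric matrix, samples x pairs, columns named by pair
#' @export
bipolar_signals <- function(data, montage,
                            pair_names = montage$analysis_set) {
  stopifnot(inherits(montage, "bipolar_montage"), is.matrix(data),
            !is.null(colnames(data)))
  p <- montage$pairs[match(pair_names, montage$pairs$pair_name), ]
  if (anyNA(p$pair_name)) stop("unknown pair name(s)")
  out <- data[, p$anode, drop = FALSE] - data[, p$cathode, drop = FALSE]
  colnames(out) <- p$pair_name
  out
}
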