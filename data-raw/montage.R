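# Builds the packaged 64-channel 10-10 layout and its 112-pair bipolar montage.
# Run from the package root: Rscript data-raw/montage.R
# The pairing rule (documented in the methods vignette):
#   (a) within-row laterally adjacent electrodes,
#   (b) same-column electrodes in consecutive rows (the midline vertical chain
#       starts at AFz: Fpz-AFz is omitted, the Fp and AF rows being within one
#       10% arc of each other),
#   (c) six posterior diagonals that close the parieto-occipital lattice:
#       PO3-P3, PO4-P4, PO7-P7, PO8-P8, Iz-O1, Iz-O2.
# Anode convention: between rows, the more posterior electrode; within a row,
# the more medial electrode. This yields exactly 112 pairs and contains the
# nine-pair occipito-parietal analysis set verbatim.

rows <- list(
  Fp = list(y = 7, e = c(Fp1 = -1, Fpz = 0, Fp2 = 1)),
  AF = list(y = 6, e = c(AF7 = -3, AF3 = -1, AFz = 0, AF4 = 1, AF8 = 3)),
  F  = list(y = 5, e = c(F7 = -4, F5 = -3, F3 = -2, F1 = -1, Fz = 0,
                         F2 = 1, F4 = 2, F6 = 3, F8 = 4)),
  FC = list(y = 4, e = c(FT7 = -4, FC5 = -3, FC3 = -2, FC1 = -1, FCz = 0,
                         FC2 = 1, FC4 = 2, FC6 = 3, FT8 = 4)),
  C  = list(y = 3, e = c(T7 = -4, C5 = -3, C3 = -2, C1 = -1, Cz = 0,
                         C2 = 1, C4 = 2, C6 = 3, T8 = 4)),
  CP = list(y = 2, e = c(TP7 = -4, CP5 = -3, CP3 = -2, CP1 = -1, CPz = 0,
                         CP2 = 1, CP4 = 2, CP6 = 3, TP8 = 4)),
  P  = list(y = 1, e = c(P9 = -5, P7 = -4, P5 = -3, P3 = -2, P1 = -1, Pz = 0,
                         P2 = 1, P4 = 2, P6 = 3, P8 = 4, P10 = 5)),
  PO = list(y = 0, e = c(PO7 = -3, PO3 = -1, POz = 0, PO4 = 1, PO8 = 3)),
  O  = list(y = -1, e = c(O1 = -1, Oz = 0, O2 = 1)),
  Iz = list(y = -2, e = c(Iz = 0))
)

grid <- do.call(rbind, lapply(names(rows), function(rn) {
  r <- rows[[rn]]
  data.frame(electrode = names(r$e), gx = unname(r$e), gy = r$y, row = rn,
             stringsAsFactors = FALSE)
}))
stopifnot(nrow(grid) == 64, !anyDuplicated(grid$electrode))

# schematic scalp coordinates: elliptical square-to-disc mapping of the grid,
# an azimuthal-equidistant-style projection used only for scalp-map plots
nx <- grid$gx / 5.5
ny <- (grid$gy - 2.5) / 4.8
grid$x <- round(0.92 * nx * sqrt(1 - ny^2 / 2), 4)
grid$y <- round(0.92 * ny * sqrt(1 - nx^2 / 2), 4)

pos <- setNames(lapply(seq_len(nrow(grid)), function(i)
  c(grid$gx[i], grid$gy[i])), grid$electrode)

pair_name <- function(a, b) {
  pa <- pos[[a]]; pb <- pos[[b]]
  if (pa[2] != pb[2]) {            # between rows: anode more posterior
    an <- if (pa[2] < pb[2]) a else b
  } else {                         # within row: anode more medial
    an <- if (abs(pa[1]) < abs(pb[1])) a else b
  }
  ca <- setdiff(c(a, b), an)
  c(anode = an, cathode = ca)
}

pairs <- list()
add_pair <- function(a, b) {
  p <- pair_name(a, b)
  pairs[[length(pairs) + 1]] <<- p
}

# (a) within-row adjacency
for (rn in names(rows)) {
  e <- sort(rows[[rn]]$e)
  nm <- names(e)
  if (length(e) > 1)
    for (i in seq_len(length(e) - 1)) add_pair(nm[i], nm[i + 1])
}

# (b) same-column verticals between consecutive rows (skip Fpz-AFz)
rn <- names(rows)
for (i in seq_len(length(rn) - 1)) {
  ea <- rows[[rn[i]]]$e; eb <- rows[[rn[i + 1]]]$e
  for (x in intersect(ea, eb)) {
    a <- names(ea)[ea == x]; b <- names(eb)[eb == x]
    if (!(a == "Fpz" && b == "AFz")) add_pair(a, b)
  }
}

# (c) posterior diagonals
diagonals <- list(c("PO3", "P3"), c("PO4", "P4"), c("PO7", "P7"),
                  c("PO8", "P8"), c("Iz", "O1"), c("Iz", "O2"))
for (d in diagonals) add_pair(d[1], d[2])

mont <- do.call(rbind, lapply(pairs, function(p)
  data.frame(anode = p[["anode"]], cathode = p[["cathode"]],
             stringsAsFactors = FALSE)))
mont$pair_name <- paste0(mont$anode, "-", mont$cathode)
stopifnot(nrow(mont) == 112, !anyDuplicated(mont$pair_name))

groups <- list(
  g1 = c("PO3-P1", "PO3-P3", "POz-PO3"),
  g2 = c("PO4-P2", "PO4-P4", "POz-PO4"),
  g3 = c("Oz-POz", "Oz-O1", "Oz-O2")
)
stopifnot(all(unlist(groups) %in% mont$pair_name))
mont$group <- "none"
for (g in names(groups)) mont$group[mont$pair_name %in% groups[[g]]] <- g

write.table(grid[, c("electrode", "x", "y")],
            file.path("inst", "extdata", "electrode_layout.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mont[, c("pair_name", "anode", "cathode", "group")],
            file.path("inst", "extdata", "bipolar_montage.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(grid), "electrodes and", nrow(mont), "bipolar pairs\n")
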