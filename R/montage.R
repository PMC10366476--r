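#' Standard 62-channel 10-20 montage
#'
#' Builds the 62-electrode extended 10-20 montage used throughout the
#' package, with approximate Talairach-like 3D positions in millimetres
#' (x right, y anterior, z superior). Positions are computed on a
#' head-shaped ellipsoid from each electrode's sagittal and lateral
#' angles, so left/right homologs (odd/even numeric suffix) are mirror
#' images in x and Cz sits at the vertex.
#'
#' The label set covers every row of the 10-20 scheme (Fp, AF, F, FC,
#' FT, C, T, CP, TP, P, PO, O), which guarantees that the seven-way
#' spatial subnetwork partition of [partition_subnetworks()] has no
#' empty group.
#'
#' @return A `montage` object: a data.frame with columns `label`, `x`,
#'   `y`, `z` (mm), one row per electrode.
#' @export
#' @examples
#' m <- standard_montage_62()
#' nrow(m)  # 62
standard_montage_62 <- function() {
  # Each row of the 10-20 grid gets a sagittal angle (degrees anterior of
  # the vertex; negative = posterior) and its electrodes a lateral angle
  # (degrees right of the midline; negative = left).
  rows <- list(
    Fp = list(ang = 72, labs = c(Fp1 = -18, Fpz = 0, Fp2 = 18)),
    AF = list(ang = 54, labs = c(AF7 = -54, AF3 = -27, AF4 = 27, AF8 = 54)),
    F  = list(ang = 36, labs = c(F7 = -72, F5 = -54, F3 = -36, F1 = -18, Fz = 0,
                                 F2 = 18, F4 = 36, F6 = 54, F8 = 72)),
    FC = list(ang = 18, labs = c(FT7 = -72, FC5 = -54, FC3 = -36, FC1 = -18, FCz = 0,
                                 FC2 = 18, FC4 = 36, FC6 = 54, FT8 = 72)),
    C  = list(ang = 0,  labs = c(T7 = -72, C5 = -54, C3 = -36, C1 = -18, Cz = 0,
                                 C2 = 18, C4 = 36, C6 = 54, T8 = 72)),
    CP = list(ang = -18, labs = c(TP7 = -72, CP5 = -54, CP3 = -36, CP1 = -18, CPz = 0,
                                  CP2 = 18, CP4 = 36, CP6 = 54, TP8 = 72)),
    P  = list(ang = -36, labs = c(P7 = -72, P5 = -54, P3 = -36, P1 = -18, Pz = 0,
                                  P2 = 18, P4 = 36, P6 = 54, P8 = 72)),
    PO = list(ang = -54, labs = c(PO7 = -54, PO5 = -36, PO3 = -18, POz = 0,
                                  PO4 = 18, PO6 = 36, PO8 = 54)),
    O  = list(ang = -72, labs = c(O1 = -18, Oz = 0, O2 = 18))
  )
  semi <- c(x = 72, y = 85, z = 65)  # head semi-axes, mm
  out <- do.call(rbind, lapply(rows, function(r) {
    a <- r$ang * pi / 180
    b <- r$labs * pi / 180
    data.frame(
      label = names(r$labs),
      x = semi["x"] * sin(b),
      y = semi["y"] * cos(b) * sin(a),
      z = semi["z"] * cos(b) * cos(a),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  stopifnot(nrow(out) == 62L, !anyDuplicated(out$label))
  class(out) <- c("montage", "data.frame")
  out
}

#' Look up electrode coordinates in a montage
#'
#' @param montage A montage from [standard_montage_62()].
#' @param labels Character vector of electrode labels.
#' @return Numeric matrix (length(labels) x 3) of positions in mm.
#' @export
montage_coords <- function(montage, labels) {
  idx <- match(labels, montage$label)
  if (anyNA(idx)) {
    stop("unknown electrode label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  }
  m <- as.matrix(montage[idx, c("x", "y", "z")])
  rownames(m) <- labels
  m
}

#' Write / read a montage as TSV
#'
#' @param montage A montage object.
#' @param path File path.
#' @return `write_montage` returns `path` invisibly; `read_montage`
#'   returns a montage object.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(as.data.frame(montage), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y", "z") %in% names(out)))
  class(out) <- c("montage", "data.frame")
  out
}
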