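#' @title Scalp montages of the 10/20 system
#' @description The package works with the 21 electrodes of the standard
#'   10/20 montage (including the A1/A2 ear references) and with a reduced
#'   8-electrode montage (F7, T3, C3, Cz, Fp2, F8, O2, P4) used for the
#'   electrode-count comparison. Electrode positions live on a unit sphere
#'   (head radius 1, Cz at the vertex); 2-D positions are the azimuthal
#'   equidistant projection used for topographic maps.
#' @name montages
NULL

#' Labels of the standard 21-electrode 10/20 montage
#' @export
STANDARD_21 <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
                 "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz", "A1", "A2")

#' Labels of the reduced 8-electrode montage
#' @export
REDUCED_8 <- c("F7", "T3", "C3", "Cz", "Fp2", "F8", "O2", "P4")

.montage_table <- function() {
  path <- system.file("extdata", "montage_1020.tsv", package = "seizr")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "montage_1020.tsv")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build a montage object
#'
#' @param names electrode labels; must be a subset of [STANDARD_21].
#' @return A `montage` object with fields `names`, `positions_3d`
#'   (unit-sphere coordinates, x = right, y = front, z = up) and
#'   `positions_2d` (azimuthal equidistant projection; the 90-degree
#'   inclination ring maps to the unit circle).
#' @export
montage <- function(names = STANDARD_21) {
  tab <- .montage_table()
  unknown <- setdiff(names, tab$label)
  if (length(unknown) > 0L)
    stop("unknown electrode label(s): ", paste(unknown, collapse = ", "))
  tab <- tab[match(names, tab$label), , drop = FALSE]
  incl <- tab$incl_deg * pi / 180
  az <- tab$az_deg * pi / 180
  p3 <- cbind(x = sin(incl) * sin(az), y = sin(incl) * cos(az), z = cos(incl))
  r <- tab$incl_deg / 90
  p2 <- cbind(x = r * sin(az), y = r * cos(az))
  rownames(p3) <- rownames(p2) <- names
  structure(list(names = names, positions_3d = p3, positions_2d = p2),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes: %s\n", length(x$names),
              paste(x$names, collapse = " ")))
  invisible(x)
}

#' Geodesic scalp distance (radians) between electrodes or points
#'
#' @param m a [montage]
#' @param from,to electrode labels
#' @return matrix of great-circle angles in radians
#' @export
scalp_distance <- function(m, from = m$names, to = m$names) {
  a <- m$positions_3d[from, , drop = FALSE]
  b <- m$positions_3d[to, , drop = FALSE]
  d <- tcrossprod(a, b)
  acos(pmax(pmin(d, 1), -1))
}
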