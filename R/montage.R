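# Idealised 64-channel extended 10-20 montage (FCz reference, as on common
# 64-channel active-electrode caps). Positions are built on a unit sphere
# from the classic 10-20 construction: rows every 10% of the nasion-inion
# arc, lateral positions interpolated between the midline and the 10%
# circumferential ring in the azimuthal-equidistant plane. The result is a
# smooth, plausible geometry for adjacency graphs and spatial weighting,
# not a digitised cap.

MONTAGE_ROWS <- c(Fp = 72, AF = 54, F = 36, FC = 18, C = 0,
                  CP = -18, P = -36, PO = -54, O = -72)

montage_channel_table <- function() {
  # name, row label, column code (0 = midline, 1..8 inner-to-ring, 9/10 below ring)
  tab <- rbind(
    c("Fp1", "Fp", 1), c("Fp2", "Fp", 2),
    c("AF7", "AF", 7), c("AF3", "AF", 3), c("AF4", "AF", 4), c("AF8", "AF", 8),
    c("F7", "F", 7), c("F5", "F", 5), c("F3", "F", 3), c("F1", "F", 1),
    c("Fz", "F", 0), c("F2", "F", 2), c("F4", "F", 4), c("F6", "F", 6), c("F8", "F", 8),
    c("FT9", "FC", 9), c("FT7", "FC", 7), c("FC5", "FC", 5), c("FC3", "FC", 3),
    c("FC1", "FC", 1), c("FC2", "FC", 2), c("FC4", "FC", 4), c("FC6", "FC", 6),
    c("FT8", "FC", 8), c("FT10", "FC", 10),
    c("T7", "C", 7), c("C5", "C", 5), c("C3", "C", 3), c("C1", "C", 1),
    c("Cz", "C", 0), c("C2", "C", 2), c("C4", "C", 4), c("C6", "C", 6), c("T8", "C", 8),
    c("TP9", "CP", 9), c("TP7", "CP", 7), c("CP5", "CP", 5), c("CP3", "CP", 3),
    c("CP1", "CP", 1), c("CPz", "CP", 0), c("CP2", "CP", 2), c("CP4", "CP", 4),
    c("CP6", "CP", 6), c("TP8", "CP", 8), c("TP10", "CP", 10),
    c("P7", "P", 7), c("P5", "P", 5), c("P3", "P", 3), c("P1", "P", 1),
    c("Pz", "P", 0), c("P2", "P", 2), c("P4", "P", 4), c("P6", "P", 6), c("P8", "P", 8),
    c("PO9", "PO", 9), c("PO7", "PO", 7), c("PO3", "PO", 3), c("POz", "PO", 0),
    c("PO4", "PO", 4), c("PO8", "PO", 8), c("PO10", "PO", 10),
    c("O1", "O", 1), c("Oz", "O", 0), c("O2", "O", 2)
  )
  data.frame(name = tab[, 1], row = tab[, 2], col = as.integer(tab[, 3]),
             stringsAsFactors = FALSE)
}

#' Standard 64-channel montage
#'
#' Channel names and unit-sphere 3-D positions for a 64-channel extended
#' 10-20 layout with FCz as the (implicit) recording reference.
#'
#' @return A `montage` object: data frame with name, x, y, z (unit sphere;
#'   x right, y anterior, z up) plus a `reference` attribute (`"FCz"`).
#' @export
standard_montage <- function() {
  tab <- montage_channel_table()
  ring_az <- c(Fp = 18, AF = 36, F = 54, FC = 72, C = 90,
               CP = 108, P = 126, PO = 144, O = 162)
  pos <- t(vapply(seq_len(nrow(tab)), function(i) {
    row <- tab$row[i]; col <- tab$col[i]
    a_mid <- MONTAGE_ROWS[[row]]
    side <- if (col %% 2 == 1) -1 else 1 # odd = left
    if (col == 0) {
      pt <- c(0, a_mid)
    } else if (col >= 9) {
      az <- side * ring_az[[row]]
      pt <- 90 * c(sin(az * pi / 180), cos(az * pi / 180))
    } else {
      frac <- if (row %in% c("Fp", "O")) 1 else min(ceiling(col / 2) / 4, 1)
      az <- side * ring_az[[row]]
      ring_pt <- 72 * c(sin(az * pi / 180), cos(az * pi / 180))
      pt <- (1 - frac) * c(0, a_mid) + frac * ring_pt
    }
    theta <- sqrt(sum(pt^2)) * pi / 180
    phi <- atan2(pt[1], pt[2])
    c(sin(theta) * sin(phi), sin(theta) * cos(phi), cos(theta))
  }, numeric(3)))
  out <- data.frame(name = tab$name, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    stringsAsFactors = FALSE)
  stopifnot(!any(duplicated(out$name)), nrow(out) == 64)
  attr(out, "reference") <- "FCz"
  class(out) <- c("montage", "data.frame")
  out
}

#' Great-circle distances between montage channels
#'
#' @param montage A `montage`.
#' @return Symmetric matrix of angular distances in degrees.
#' @export
montage_distances <- function(montage) {
  p <- as.matrix(montage[, c("x", "y", "z")])
  g <- p %*% t(p)
  g <- pmin(pmax(g, -1), 1)
  d <- acos(g) * 180 / pi
  dimnames(d) <- list(montage$name, montage$name)
  d
}

#' Channel adjacency graph from montage geometry
#'
#' Channels are neighbours when their great-circle distance is below a
#' threshold chosen so the median neighbour count is about `target_degree`.
#'
#' @param montage A `montage`.
#' @param target_degree Desired median number of neighbours (default 6).
#' @return Logical adjacency matrix (FALSE diagonal).
#' @export
channel_adjacency <- function(montage, target_degree = 6) {
  d <- montage_distances(montage)
  diag(d) <- Inf
  kth <- apply(d, 1, function(r) sort(r)[target_degree])
  thr <- stats::median(kth) * 1.0001
  adj <- d <= thr
  diag(adj) <- FALSE
  adj | t(adj)
}
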