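#' Sensor montages
#'
#' A montage holds channel names, idealized 3-D positions on a unit sphere
#' (head-centred RAS: x right, y anterior, z superior), a 2-D
#' azimuthal-equidistant projection used for topographies, neighbour search
#' and interpolation, and a Delaunay neighbour graph.
#'
#' The built-in `"study38"` layout is a 38-channel 10-20/10-10 cap. The
#' exact electrode inventory of the recordings this layout emulates is not
#' fully specified beyond the region-of-interest members, so the layout
#' includes all named ROI channels (including the legacy labels `T3`, `T5`
#' and the nonstandard `PO2`, kept verbatim) and fills the remainder with
#' standard 10-10 names; it is an idealized stand-in, not a measured cap.
#'
#' @param source `"study38"` for the built-in layout, or the path to a TSV
#'   file with columns `name`, `x`, `y`, `z`.
#' @param subset optional character vector of channel names to retain.
#' @param max_dist optional planar distance used to prune Delaunay edges.
#' @return An object of class `eeg_montage` with elements `names`, `pos3d`
#'   (n x 3), `pos2d` (n x 2) and `neighbors` (symmetric logical matrix).
#' @examples
#' m <- load_montage("study38")
#' nrow(m$pos3d)
#' @export
load_montage <- function(source = "study38", subset = NULL, max_dist = NULL) {
  if (identical(source, "study38")) {
    lay <- montage_study38_positions()
  } else {
    if (!file.exists(source)) stop("montage file not found: ", source)
    tab <- utils::read.delim(source, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(tab))) stop("montage TSV needs columns name, x, y, z")
    lay <- list(names = as.character(tab$name),
                pos3d = as.matrix(tab[, c("x", "y", "z")]))
  }
  if (anyDuplicated(lay$names)) stop("duplicate channel names in montage")
  if (!is.null(subset)) {
    missing <- setdiff(subset, lay$names)
    if (length(missing))
      stop("unknown channel: ", paste(missing, collapse = ", "))
    keep <- match(subset, lay$names)
    lay$names <- lay$names[keep]
    lay$pos3d <- lay$pos3d[keep, , drop = FALSE]
  }
  if (length(lay$names) < 3) stop("montage needs at least 3 channels")
  pos2d <- project_azimuthal(lay$pos3d)
  m <- structure(list(names = lay$names, pos3d = lay$pos3d, pos2d = pos2d,
                      neighbors = NULL), class = "eeg_montage")
  m$neighbors <- build_neighbors(m, method = "delaunay", max_dist = max_dist)
  m
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$names), " channels, mean degree ",
      round(mean(rowSums(x$neighbors)), 2), "\n", sep = "")
  invisible(x)
}

# Unit-sphere position from inclination (degrees from vertex) and azimuth
# (degrees from anterior midline, positive to the right).
sph_pos <- function(incl, az) {
  i <- incl * pi / 180; a <- az * pi / 180
  c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
}

# Spherical midpoint (slerp at t = 0.5) used to derive 10-10 positions from
# the primary 10-20 sites, the construction idealized caps use.
slerp_mid <- function(p, q) {
  v <- p + q
  v / sqrt(sum(v^2))
}

montage_study38_positions <- function() {
  p <- list()
  p$Cz <- sph_pos(0, 0)
  ring <- list(Fpz = 0, Fp2 = 18, F8 = 54, T4 = 90, T6 = 126, O2 = 162,
               Oz = 180, O1 = -162, T5 = -126, T3 = -90, F7 = -54, Fp1 = -18)
  for (nm in names(ring)) p[[nm]] <- sph_pos(72, ring[[nm]])
  p$Fz <- sph_pos(36, 0);   p$Pz <- sph_pos(36, 180)
  p$C3 <- sph_pos(36, -90); p$C4 <- sph_pos(36, 90)
  p$F3 <- slerp_mid(p$Fz, p$F7); p$F4 <- slerp_mid(p$Fz, p$F8)
  p$P3 <- slerp_mid(p$Pz, p$T5); p$P4 <- slerp_mid(p$Pz, p$T6)
  p$FCz <- slerp_mid(p$Fz, p$Cz); p$CPz <- slerp_mid(p$Cz, p$Pz)
  p$POz <- slerp_mid(p$Pz, p$Oz)
  p$FC3 <- slerp_mid(p$F3, p$C3); p$FC4 <- slerp_mid(p$F4, p$C4)
  p$CP3 <- slerp_mid(p$C3, p$P3); p$CP4 <- slerp_mid(p$C4, p$P4)
  p$FT7 <- slerp_mid(p$F7, p$T3); p$FT8 <- slerp_mid(p$F8, p$T4)
  p$TP7 <- slerp_mid(p$T3, p$T5); p$TP8 <- slerp_mid(p$T4, p$T6)
  p$C5 <- slerp_mid(p$C3, p$T3);  p$C6 <- slerp_mid(p$C4, p$T4)
  p$AF3 <- slerp_mid(p$Fp1, p$F3); p$AF4 <- slerp_mid(p$Fp2, p$F4)
  po3 <- slerp_mid(p$P3, p$O1); po4 <- slerp_mid(p$P4, p$O2)
  p$PO1 <- slerp_mid(p$POz, po3); p$PO2 <- slerp_mid(p$POz, po4)
  nm <- c("Fp1", "Fpz", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
          "FT7", "FC3", "FCz", "FC4", "FT8", "T3", "C5", "C3", "Cz", "C4",
          "C6", "T4", "TP7", "CP3", "CPz", "CP4", "TP8", "T5", "P3", "Pz",
          "P4", "T6", "PO1", "POz", "PO2", "O1", "Oz", "O2")
  stopifnot(length(nm) == 38, all(nm %in% names(p)))
  pos <- t(vapply(nm, function(k) p[[k]], numeric(3)))
  dimnames(pos) <- list(nm, c("x", "y", "z"))
  list(names = nm, pos3d = pos)
}

#' Azimuthal-equidistant projection of sensor positions
#'
#' Projects unit-sphere positions to the plane from the vertex: the planar
#' radius equals the great-circle distance from the vertex (radians), the
#' direction is the horizontal bearing. This is the standard flattening used
#' for sensor topographies and makes planar nearest-neighbour search
#' well-defined.
#'
#' @param pos3d n x 3 matrix of positions.
#' @return n x 2 matrix.
#' @export
project_azimuthal <- function(pos3d) {
  r <- sqrt(rowSums(pos3d^2))
  u <- pos3d / r
  ang <- acos(pmin(1, pmax(-1, u[, 3])))
  h <- sqrt(u[, 1]^2 + u[, 2]^2)
  dx <- ifelse(h > 1e-12, u[, 1] / h, 0)
  dy <- ifelse(h > 1e-12, u[, 2] / h, 0)
  cbind(ang * dx, ang * dy)
}

circumcircle <- function(a, b, c) {
  # returns centre and radius, or NULL when (near) collinear
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  scale <- max(abs(c(a, b, c)), 1e-12)
  if (abs(d) < 1e-12 * scale^2) return(NULL)
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  list(centre = c(ux, uy), r = sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
}

delaunay_adjacency <- function(pos2d) {
  n <- nrow(pos2d)
  if (n < 3) stop("Delaunay triangulation needs at least 3 points")
  adj <- matrix(FALSE, n, n)
  span <- max(apply(pos2d, 2, function(v) diff(range(v))))
  eps <- 1e-9 * max(span, 1)
  found <- FALSE
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circumcircle(pos2d[i, ], pos2d[j, ], pos2d[k, ])
    if (is.null(cc)) next
    d <- sqrt((pos2d[, 1] - cc$centre[1])^2 + (pos2d[, 2] - cc$centre[2])^2)
    d[c(i, j, k)] <- Inf
    if (all(d >= cc$r - eps)) {      # empty circumdisk (boundary allowed)
      adj[i, j] <- adj[j, i] <- TRUE
      adj[j, k] <- adj[k, j] <- TRUE
      adj[i, k] <- adj[k, i] <- TRUE
      found <- TRUE
    }
  }
  if (!found) stop("degenerate (collinear) sensor layout: no valid triangle")
  adj
}

#' Build a channel neighbour graph
#'
#' Delaunay triangulation of the planar sensor projection (the construction
#' consistent with triangulation-based channel interpolation), optionally
#' pruned by a maximum planar distance, or a plain distance criterion.
#'
#' @param montage an `eeg_montage`.
#' @param method `"delaunay"` or `"distance"`.
#' @param max_dist maximum planar edge length; `NULL` for no pruning
#'   (required for `method = "distance"`).
#' @return symmetric, irreflexive logical adjacency matrix with channel
#'   dimnames.
#' @export
build_neighbors <- function(montage, method = c("delaunay", "distance"),
                            max_dist = NULL) {
  method <- match.arg(method)
  pos <- montage$pos2d
  n <- nrow(pos)
  if (method == "delaunay") {
    adj <- delaunay_adjacency(pos)
  } else {
    if (is.null(max_dist)) stop("method 'distance' needs max_dist")
    d <- as.matrix(stats::dist(pos))
    adj <- d <= max_dist & d > 0
  }
  if (!is.null(max_dist)) {
    d <- as.matrix(stats::dist(pos))
    adj <- adj & d <= max_dist
  }
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$names, montage$names)
  adj
}
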