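#' Parameters for Shrake-Rupley surface calculations
#'
#' The default probe radius (0.256 nm) is the coarse-grained particle
#' radius, so the "solvent" probe is a water bead of the same size as the
#' model beads; the default bead radius is 0.26 nm. Sphere points are
#' placed by a deterministic golden-spiral construction, so results carry
#' no randomness.
#'
#' @param probe_radius probe radius, nm (>= 0).
#' @param n_sphere_points test points per bead (>= 32); 960 keeps the
#'   single-sphere quadrature error below 1%.
#' @param default_bead_radius radius used for beads without one, nm.
#' @return An object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 0.256, n_sphere_points = 960,
                        default_bead_radius = 0.26) {
  if (probe_radius < 0) stop("probe_radius must be >= 0", call. = FALSE)
  if (n_sphere_points < 32) {
    stop("n_sphere_points must be >= 32", call. = FALSE)
  }
  if (default_bead_radius <= 0) {
    stop("default_bead_radius must be > 0", call. = FALSE)
  }
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 default_bead_radius = default_bead_radius),
            class = "sasa_params")
}

#' Golden-spiral (Fibonacci) points on the unit sphere
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each selected bead, test points are placed on a sphere of radius
#' (bead radius + probe radius); the accessible fraction is the share of
#' points not inside any other selected bead's expanded sphere, scaled to
#' that sphere's area. Beads outside the selection are ignored entirely
#' (selection-only context), which is what the buried-interface formula
#' requires. Periodic images are not considered; a warning is emitted when
#' the selection spans more than half the box.
#'
#' @param frame a [cg_frame()].
#' @param system a [bead_system()].
#' @param selection bead indices, group name or chain ids
#'   (see [resolve_selection()]).
#' @param params a [sasa_params()].
#' @return An object of class `sasa_result`: list with `per_bead`
#'   (data.frame `index`, `radius`, `area_nm2`), `total` (nm^2) and
#'   `selection` label.
#' @export
sasa <- function(frame, system, selection, params = sasa_params()) {
  label <- if (is.character(selection)) paste(selection, collapse = ",")
  else "indices"
  sel <- resolve_selection(system, selection)
  if (!length(sel)) stop("empty selection", call. = FALSE)
  rows <- match(sel, system$beads$index)
  xyz <- frame$xyz[rows, , drop = FALSE]
  rad <- system$beads$radius[rows]
  rad[is.na(rad)] <- params$default_bead_radius
  R <- rad + params$probe_radius

  if (!is.null(frame$box)) {
    ext <- apply(xyz, 2, function(v) diff(range(v)))
    if (any(ext > frame$box / 2)) {
      warning("selection spans more than half the box; SASA ignores ",
              "periodic images", call. = FALSE)
    }
  }

  pts <- fibonacci_sphere(params$n_sphere_points)
  n <- length(sel)
  area <- numeric(n)
  # neighbour prune: only beads whose expanded spheres can intersect
  D <- min_image_dist(xyz, xyz, NULL)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < R[i] + R & seq_len(n) != i)
    full <- 4 * pi * R[i]^2
    if (!length(nb)) {
      area[i] <- full
      next
    }
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(acc)) break
      d2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- d2 >= R[j]^2
    }
    area[i] <- full * sum(acc) / nrow(p)
  }
  structure(list(
    per_bead = data.frame(index = sel, radius = rad, area_nm2 = area),
    total = sum(area), selection = label
  ), class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result (%s): %d beads, total %.3f nm^2\n",
              x$selection, nrow(x$per_bead), x$total))
  invisible(x)
}

#' Buried interface area between two selections
#'
#' The surface each partner loses on association:
#' `(SASA_A + SASA_B - SASA_AB) / 2`, with each term computed in its own
#' selection context. Symmetric in A and B, non-negative, and exactly zero
#' when the groups are beyond probe-bridging distance.
#'
#' @param frame,system frame and system.
#' @param selA,selB disjoint selections.
#' @param params a [sasa_params()].
#' @return An object of class `interface_result`: list with `area` (nm^2),
#'   `sasa_a`, `sasa_b`, `sasa_ab` (totals) and selection labels.
#' @export
interface_area <- function(frame, system, selA, selB,
                           params = sasa_params()) {
  a <- resolve_selection(system, selA)
  b <- resolve_selection(system, selB)
  if (!length(a) || !length(b)) stop("empty selection", call. = FALSE)
  if (length(intersect(a, b))) {
    stop("selections overlap; interface area requires disjoint groups",
         call. = FALSE)
  }
  sa <- sasa(frame, system, a, params)
  sb <- sasa(frame, system, b, params)
  sab <- sasa(frame, system, c(a, b), params)
  structure(list(
    area = (sa$total + sb$total - sab$total) / 2,
    sasa_a = sa$total, sasa_b = sb$total, sasa_ab = sab$total,
    selection_a = if (is.character(selA)) paste(selA, collapse = ",")
    else "indices",
    selection_b = if (is.character(selB)) paste(selB, collapse = ",")
    else "indices"
  ), class = "interface_result")
}

#' @export
print.interface_result <- function(x, ...) {
  cat(sprintf("interface_result: %s | %s = %.3f nm^2\n",
              x$selection_a, x$selection_b, x$area))
  invisible(x)
}

#' Buried-interface time series over a trajectory
#'
#' @param traj a [cg_trajectory()].
#' @param selA,selB disjoint selections.
#' @param params a [sasa_params()].
#' @param stride evaluate every `stride`-th frame.
#' @return data.frame with columns `time_ps` and `area_nm2`.
#' @export
interface_timeseries <- function(traj, selA, selB, params = sasa_params(),
                                 stride = 1) {
  stopifnot(stride >= 1)
  picks <- seq(1, length(traj$frames), by = stride)
  out <- lapply(picks, function(k) {
    r <- interface_area(traj$frames[[k]], traj$system, selA, selB, params)
    data.frame(time_ps = traj$frames[[k]]$time, area_nm2 = r$area)
  })
  do.call(rbind, out)
}

#' Export per-bead SASA as TSV
#' @param result a [sasa()] result.
#' @param path output file.
#' @export
write_sasa_tsv <- function(result, path) {
  out <- data.frame(index = result$per_bead$index,
                    radius_nm = sprintf("%.4f", result$per_bead$radius),
                    area_nm2 = sprintf("%.6f", result$per_bead$area_nm2))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
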