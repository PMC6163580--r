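#' Parameters for the coarse-grained beta criterion
#'
#' A backbone bead is assigned to beta structure when its local
#' pseudo-dihedral (over four consecutive backbone beads) exceeds
#' `angle_min` (the strand is locally extended) and a pair of
#' bonded-consecutive backbone beads from another strand lies within
#' `contact_dist` (the strand has an inter-strand neighbour). The defaults
#' are the thresholds used for backbone-bead models: 100 degrees and 0.6 nm.
#'
#' @param angle_min minimum unsigned pseudo-dihedral, degrees (0, 180].
#' @param contact_dist contact distance, nm.
#' @param min_seq_sep minimum residue separation (same chain) for a contact
#'   pair to count as "other" backbone; must be >= 2 so that a bead's own
#'   dihedral window can never satisfy the contact criterion.
#' @param min_strand_len minimum residues for a strand segment.
#' @return An object of class `beta_params`.
#' @export
beta_params <- function(angle_min = 100, contact_dist = 0.6,
                        min_seq_sep = 4, min_strand_len = 3) {
  if (!(angle_min > 0 && angle_min <= 180)) {
    stop("angle_min must be in (0, 180]", call. = FALSE)
  }
  if (contact_dist <= 0) stop("contact_dist must be > 0", call. = FALSE)
  if (min_seq_sep < 2) stop("min_seq_sep must be >= 2", call. = FALSE)
  if (min_strand_len < 1) stop("min_strand_len must be >= 1", call. = FALSE)
  structure(list(angle_min = angle_min, contact_dist = contact_dist,
                 min_seq_sep = as.integer(min_seq_sep),
                 min_strand_len = as.integer(min_strand_len)),
            class = "beta_params")
}

#' Unsigned dihedral angle of four points
#'
#' Returns the torsion of p1-p2-p3-p4 as an unsigned angle in [0, 180]
#' degrees (0 = cis/eclipsed, 180 = trans/extended). Invariant under rigid
#' rotation and translation.
#'
#' @param p1,p2,p3,p4 3-vectors (any consistent length unit).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  n1n <- sqrt(sum(n1^2)); n2n <- sqrt(sum(n2^2))
  if (n1n < 1e-12 || n2n < 1e-12) {
    stop("undefined dihedral: three consecutive points are collinear (or ",
         "coincident)", call. = FALSE)
  }
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  abs(atan2(y, x)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Per-chain backbone bookkeeping used by the detector.
backbone_table <- function(system) {
  rows <- lapply(names(system$chains), function(ch) {
    idx <- system$chains[[ch]]
    if (!length(idx)) return(NULL)
    data.frame(index = idx, chain_id = ch, pos = seq_along(idx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign beta structure from backbone-bead geometry
#'
#' Implements the two-part coarse-grained beta criterion. For every backbone
#' bead `i` with a full dihedral window, the unsigned pseudo-dihedral over
#' the consecutive backbone beads (i-1, i, i+1, i+2) of its chain is
#' computed; the bead is "extended" when that angle exceeds
#' `params$angle_min`. The bead is assigned to beta structure when it is
#' extended and there exists a bonded-consecutive backbone pair (j, j+1) --
#' on another chain, or at residue separation of at least
#' `params$min_seq_sep` on the same chain -- with both partners within
#' `params$contact_dist` of bead `i`. Distances use the minimum-image
#' convention when the frame has a box. Chains with fewer than four
#' backbone beads are wholly non-evaluable (not an error).
#'
#' @param frame a [cg_frame()].
#' @param system a [bead_system()].
#' @param params a [beta_params()].
#' @param selection optional selection (see [resolve_selection()]) limiting
#'   the beads evaluated; contacts are still searched over all backbone
#'   beads.
#' @return A data.frame of class `beta_assignment`, one row per backbone
#'   bead: `index`, `chain_id`, `residue_index`, `evaluable`,
#'   `dihedral_deg`, `extended`, `n_contacts`, `beta`, and a list-column
#'   `partners` of contact-pair first-bead indices (non-empty only for beta
#'   beads).
#' @export
assign_beta <- function(frame, system, params = beta_params(),
                        selection = NULL) {
  bb <- backbone_table(system)
  if (is.null(bb) || nrow(bb) == 0) {
    res <- data.frame(index = integer(0), chain_id = character(0),
                      residue_index = integer(0), evaluable = logical(0),
                      dihedral_deg = numeric(0), extended = logical(0),
                      n_contacts = integer(0), beta = logical(0))
    res$partners <- list()
    class(res) <- c("beta_assignment", class(res))
    attr(res, "params") <- params
    return(res)
  }
  keep <- rep(TRUE, nrow(bb))
  if (!is.null(selection)) {
    keep <- bb$index %in% resolve_selection(system, selection)
  }
  row_of <- match(bb$index, system$beads$index)
  xyz <- frame$xyz

  # (a) extendedness: centered dihedral window per chain
  dih <- rep(NA_real_, nrow(bb))
  for (ch in unique(bb$chain_id)) {
    sel <- which(bb$chain_id == ch)
    m <- length(sel)
    if (m < 4) next
    for (k in 2:(m - 2)) {
      r <- row_of[sel[c(k - 1, k, k + 1, k + 2)]]
      dih[sel[k]] <- dihedral(xyz[r[1], ], xyz[r[2], ], xyz[r[3], ],
                              xyz[r[4], ])
    }
  }
  evaluable <- !is.na(dih) & keep
  extended <- evaluable & dih > params$angle_min

  # (b) inter-strand contact: bonded-consecutive backbone pairs (pos, pos+1)
  D <- min_image_dist(xyz[row_of, , drop = FALSE],
                      xyz[row_of, , drop = FALSE], frame$box)
  n_contacts <- integer(nrow(bb))
  partners <- vector("list", nrow(bb))
  # candidate pairs: consecutive backbone positions within each chain
  pair_a <- which(c(diff(bb$pos) == 1, FALSE) &
                    c(bb$chain_id[-nrow(bb)] == bb$chain_id[-1], FALSE))
  pair_b <- pair_a + 1L
  for (i in which(extended)) {
    ok <- D[i, pair_a] <= params$contact_dist &
      D[i, pair_b] <= params$contact_dist
    if (any(ok)) {
      same <- bb$chain_id[pair_a] == bb$chain_id[i]
      sep_ok <- !same |
        (abs(bb$pos[pair_a] - bb$pos[i]) >= params$min_seq_sep &
           abs(bb$pos[pair_b] - bb$pos[i]) >= params$min_seq_sep)
      ok <- ok & sep_ok
    }
    n_contacts[i] <- sum(ok)
    if (n_contacts[i] > 0) partners[[i]] <- bb$index[pair_a[ok]]
  }
  beta <- extended & n_contacts > 0

  res <- data.frame(
    index = bb$index, chain_id = bb$chain_id,
    residue_index = system$beads$residue_index[row_of],
    evaluable = evaluable, dihedral_deg = dih, extended = extended,
    n_contacts = n_contacts, beta = beta, stringsAsFactors = FALSE
  )
  res$partners <- partners
  res$partners[!res$beta] <- list(integer(0))
  class(res) <- c("beta_assignment", class(res))
  attr(res, "params") <- params
  res
}

#' Percentage of backbone beads in beta structure
#'
#' 100 x (beta beads) / (evaluable backbone beads). Terminal beads without a
#' full dihedral window are excluded from the denominator.
#'
#' @param assignment a [assign_beta()] result.
#' @return percentage in [0, 100].
#' @export
beta_fraction <- function(assignment) {
  n_eval <- sum(assignment$evaluable)
  if (n_eval == 0) {
    stop("beta fraction undefined: no evaluable backbone beads", call. = FALSE)
  }
  100 * sum(assignment$beta) / n_eval
}

#' Beta-content time series over a trajectory
#'
#' @param traj a [cg_trajectory()].
#' @param params a [beta_params()].
#' @param stride evaluate every `stride`-th frame (>= 1).
#' @param selection optional selection passed to [assign_beta()].
#' @return data.frame with columns `time_ps` and `beta_percent`.
#' @export
beta_timeseries <- function(traj, params = beta_params(), stride = 1,
                            selection = NULL) {
  stopifnot(stride >= 1)
  picks <- seq(1, length(traj$frames), by = stride)
  out <- lapply(picks, function(k) {
    a <- assign_beta(traj$frames[[k]], traj$system, params, selection)
    data.frame(time_ps = traj$frames[[k]]$time, beta_percent = beta_fraction(a))
  })
  do.call(rbind, out)
}

#' Find maximal beta strand segments
#'
#' Maximal runs of consecutive beta-assigned backbone beads per chain, of
#' length at least `params$min_strand_len`. The segment direction is the
#' unit vector from the first to the last member bead.
#'
#' @param assignment a [assign_beta()] result.
#' @param frame the frame the assignment was computed on.
#' @param system the system.
#' @param params a [beta_params()].
#' @return data.frame of class `strand_segments`: `chain_id`, `start_res`,
#'   `end_res`, `n_res`, `dir_x`, `dir_y`, `dir_z`, plus a list-column
#'   `member_index` of bead indices.
#' @export
find_strands <- function(assignment, frame, system, params = beta_params()) {
  segs <- list()
  for (ch in unique(assignment$chain_id)) {
    a <- assignment[assignment$chain_id == ch, ]
    r <- rle(a$beta)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < params$min_strand_len) next
      rows <- starts[k]:ends[k]
      idx <- a$index[rows]
      p1 <- frame$xyz[match(idx[1], system$beads$index), ]
      p2 <- frame$xyz[match(idx[length(idx)], system$beads$index), ]
      d <- p2 - p1
      d <- d / sqrt(sum(d^2))
      segs[[length(segs) + 1]] <- data.frame(
        chain_id = ch, start_res = a$residue_index[rows[1]],
        end_res = a$residue_index[rows[length(rows)]],
        n_res = length(rows), dir_x = d[1], dir_y = d[2], dir_z = d[3],
        stringsAsFactors = FALSE
      )
      segs[[length(segs)]]$member_index <- list(idx)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else {
    z <- data.frame(chain_id = character(0), start_res = integer(0),
                    end_res = integer(0), n_res = integer(0),
                    dir_x = numeric(0), dir_y = numeric(0),
                    dir_z = numeric(0))
    z$member_index <- list()
    z
  }
  class(out) <- c("strand_segments", class(out))
  out
}

#' Pair beta strands into sheets
#'
#' Two strand segments pair when the mean nearest inter-bead distance
#' between them (averaged over both directions) is at most `pair_dist`.
#' Orientation follows the sign of the direction-vector dot product
#' (`>= 0` parallel, `< 0` antiparallel). The registry shift is the integer
#' bead offset, after aligning the second strand to run along the first
#' strand's direction, that minimises the mean matched-bead distance;
#' the search covers `|shift| <= max_shift` and ties break toward the
#' smaller |shift| (then the smaller signed shift).
#'
#' @param segments a [find_strands()] result.
#' @param frame,system frame and system the segments refer to.
#' @param pair_dist pairing cutoff, nm.
#' @param max_shift registry shift search bound (residues).
#' @return data.frame of class `sheet_pairing`: `segA`, `segB` (row numbers
#'   in `segments`), `chainA`, `chainB`, `orientation`, `registry_shift`,
#'   `mean_dist`.
#' @export
pair_strands <- function(segments, frame, system, pair_dist = 0.6,
                         max_shift = 3) {
  stopifnot(pair_dist > 0)
  empty <- data.frame(segA = integer(0), segB = integer(0),
                      chainA = character(0), chainB = character(0),
                      orientation = character(0), registry_shift = integer(0),
                      mean_dist = numeric(0))
  class(empty) <- c("sheet_pairing", class(empty))
  if (nrow(segments) < 2) return(empty)
  coords <- lapply(segments$member_index, function(idx) {
    frame$xyz[match(idx, system$beads$index), , drop = FALSE]
  })
  out <- list()
  for (a in seq_len(nrow(segments) - 1)) {
    for (b in (a + 1):nrow(segments)) {
      D <- min_image_dist(coords[[a]], coords[[b]], frame$box)
      md <- (mean(apply(D, 1, min)) + mean(apply(D, 2, min))) / 2
      if (md > pair_dist) next
      da <- c(segments$dir_x[a], segments$dir_y[a], segments$dir_z[a])
      db <- c(segments$dir_x[b], segments$dir_y[b], segments$dir_z[b])
      par <- sum(da * db) >= 0
      # Registry is measured between the chains' full backbone bead lists
      # (bead k of A against bead k+s of B, B reversed when antiparallel),
      # so it does not depend on how the beta runs were trimmed. For two
      # segments on one chain (hairpin) the segments themselves are used.
      same_chain <- segments$chain_id[a] == segments$chain_id[b]
      xa <- if (same_chain) coords[[a]] else
        frame$xyz[match(system$chains[[segments$chain_id[a]]],
                        system$beads$index), , drop = FALSE]
      xb <- if (same_chain) coords[[b]] else
        frame$xyz[match(system$chains[[segments$chain_id[b]]],
                        system$beads$index), , drop = FALSE]
      if (!par) xb <- xb[nrow(xb):1, , drop = FALSE]  # align running direction
      best <- NULL
      for (s in -max_shift:max_shift) {
        ia <- seq_len(nrow(xa))
        ib <- ia + s
        ok <- ib >= 1 & ib <= nrow(xb)
        if (sum(ok) < 2) next
        d <- sqrt(rowSums((xa[ok, , drop = FALSE] -
                             xb[ib[ok], , drop = FALSE])^2))
        cost <- mean(d)
        if (is.null(best) || cost < best$cost - 1e-12 ||
            (abs(cost - best$cost) <= 1e-12 &&
               (abs(s) < abs(best$s) ||
                  (abs(s) == abs(best$s) && s < best$s)))) {
          best <- list(cost = cost, s = s)
        }
      }
      out[[length(out) + 1]] <- data.frame(
        segA = a, segB = b, chainA = segments$chain_id[a],
        chainB = segments$chain_id[b],
        orientation = if (par) "parallel" else "antiparallel",
        registry_shift = if (is.null(best)) NA_integer_ else best$s,
        mean_dist = md, stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  class(res) <- c("sheet_pairing", class(res))
  res
}

#' Acute angle between a strand direction and an axis
#'
#' @param segment one row of a [find_strands()] result (or a data.frame
#'   with `dir_x`, `dir_y`, `dir_z`).
#' @param axis non-zero 3-vector.
#' @return angle in degrees in [0, 90].
#' @export
strand_tilt <- function(segment, axis) {
  axis <- as.numeric(axis)
  na <- sqrt(sum(axis^2))
  if (na < 1e-12) stop("axis must be non-zero", call. = FALSE)
  d <- c(segment$dir_x[1], segment$dir_y[1], segment$dir_z[1])
  ct <- abs(sum(d * axis) / (na * sqrt(sum(d^2))))
  acos(pmin(1, ct)) * 180 / pi
}

#' Export a beta assignment as TSV
#'
#' Columns: chain, residue_index, beta_state, dihedral_deg, n_contacts.
#' @param assignment a [assign_beta()] result.
#' @param path output file.
#' @export
write_beta_tsv <- function(assignment, path) {
  out <- data.frame(
    chain = assignment$chain_id,
    residue_index = assignment$residue_index,
    beta_state = as.integer(assignment$beta),
    dihedral_deg = ifelse(is.na(assignment$dihedral_deg), "NA",
                          sprintf("%.3f", assignment$dihedral_deg)),
    n_contacts = assignment$n_contacts
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
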