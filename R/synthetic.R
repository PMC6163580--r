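# Deterministic geometry generators. Geometry constants follow canonical
# beta-sheet dimensions for one-bead-per-residue models: 0.35 nm
# consecutive-bead distance, 0.48 nm inter-strand spacing. These are fixture
# conventions, not force-field claims.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

fixture_beads <- function(xyz, chain_id, residue_index, residue_name,
                          name = "BB", class, radius = 0.26,
                          is_backbone = TRUE) {
  n <- nrow(xyz)
  data.frame(
    index = seq_len(n), name = rep_len(name, n),
    residue_index = as.integer(rep_len(residue_index, n)),
    residue_name = rep_len(residue_name, n),
    chain_id = rep_len(chain_id, n),
    is_backbone = rep_len(is_backbone, n),
    radius = rep_len(radius, n), class = rep_len(class, n),
    stringsAsFactors = FALSE
  )
}

# Extend a chain by one bead with given bond length, bond angle (deg, at the
# last placed bead) and torsion (deg) -- natural extension reference frame.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cbind(bc, cross3(n, bc), n)
  c + as.numeric(m %*% d2)
}

# Regular backbone lattice: constant bond / angle / torsion chain.
strand_lattice <- function(n, bond = 0.35, angle = 125,
                           torsion = 170) {
  xyz <- matrix(0, n, 3)
  xyz[2, ] <- c(bond, 0, 0)
  th <- angle * pi / 180
  xyz[3, ] <- xyz[2, ] + bond * c(-cos(th), sin(th), 0)
  if (n >= 4) {
    for (k in 4:n) {
      xyz[k, ] <- nerf_place(xyz[k - 3, ], xyz[k - 2, ], xyz[k - 1, ],
                             bond, angle, torsion)
    }
  }
  xyz
}

#' Ideal extended beta strand
#'
#' One backbone bead per residue on a regular extended zigzag: constant
#' consecutive-bead distance `rise`, constant interior pseudo-dihedral
#' `zigzag_dihedral`. Residue classes alternate hydrophobic (VAL) and polar
#' (THR), giving the amphipathic pattern of a designed detergent peptide.
#'
#' @param n_res number of residues (>= 4).
#' @param rise consecutive-bead distance, nm.
#' @param zigzag_dihedral interior pseudo-dihedral, degrees.
#' @param chain_id chain identifier.
#' @return list with `system` ([bead_system()]) and `frame` ([cg_frame()]).
#' @export
make_strand <- function(n_res, rise = 0.35, zigzag_dihedral = 170,
                        chain_id = "P1") {
  if (n_res < 4) stop("a strand needs at least 4 residues", call. = FALSE)
  if (rise <= 0) stop("rise must be > 0", call. = FALSE)
  xyz <- strand_lattice(n_res, bond = rise, torsion = zigzag_dihedral)
  classes <- ifelse(seq_len(n_res) %% 2 == 1, "hydrophobic", "polar")
  beads <- fixture_beads(xyz, chain_id, seq_len(n_res),
                         ifelse(classes == "hydrophobic", "VAL", "THR"),
                         class = classes)
  system <- bead_system(beads, groups = list(peptide = beads$index))
  list(system = system, frame = cg_frame(xyz))
}

#' Ideal multi-strand beta sheet
#'
#' Strands are windows of one exactly periodic planar zigzag lattice
#' (consecutive-bead distance `rise`, pleat half-amplitude `pleat`, pure
#' trans pseudo-dihedrals), stacked at exactly `inter_strand`. For
#' `orientation = "antiparallel"` the bead order of every second strand is
#' reversed. A `registry_shift` of `s` offsets each successive strand's
#' window so that [pair_strands()] recovers `s`. Hydrophobic residues share
#' one lattice parity, so one pleat face is entirely hydrophobic.
#'
#' @param n_strands number of strands (>= 2).
#' @param n_res residues per strand.
#' @param inter_strand inter-strand spacing, nm.
#' @param orientation `"antiparallel"` or `"parallel"`.
#' @param registry_shift integer residue offset between adjacent strands.
#' @param rise consecutive-bead distance, nm.
#' @param pleat zigzag half-amplitude, nm.
#' @return list with `system` and `frame`.
#' @export
make_sheet <- function(n_strands = 2, n_res = 8, inter_strand = 0.48,
                       orientation = c("antiparallel", "parallel"),
                       registry_shift = 0, rise = 0.35, pleat = 0.05) {
  if (n_strands < 2) stop("a sheet needs at least 2 strands", call. = FALSE)
  if (inter_strand <= 0) stop("inter_strand must be > 0", call. = FALSE)
  if (2 * pleat >= rise) stop("pleat must be < rise/2", call. = FALSE)
  orientation <- match.arg(orientation)
  registry_shift <- as.integer(registry_shift)

  a <- sqrt(rise^2 - (2 * pleat)^2)  # axial step preserving bond length
  n_extra <- (n_strands - 1) * abs(registry_shift)
  k <- seq_len(n_res + n_extra)
  base <- cbind(k * a, 0, pleat * ifelse(k %% 2 == 0, 1, -1))

  # window offsets chosen so the detected shift of strand s+1 relative to
  # strand s equals registry_shift
  offs <- -(seq_len(n_strands) - 1) * registry_shift
  offs <- offs - min(offs)

  xyz_list <- list()
  bead_rows <- list()
  for (s in seq_len(n_strands)) {
    win <- seq_len(n_res) + offs[s]
    coords <- base[win, , drop = FALSE]
    coords[, 2] <- (s - 1) * inter_strand
    lattice_pos <- win
    if (orientation == "antiparallel" && s %% 2 == 0) {
      coords <- coords[n_res:1, , drop = FALSE]
      lattice_pos <- rev(lattice_pos)
    }
    classes <- ifelse(lattice_pos %% 2 == 1, "hydrophobic", "polar")
    xyz_list[[s]] <- coords
    bead_rows[[s]] <- fixture_beads(
      coords, paste0("P", s), seq_len(n_res),
      ifelse(classes == "hydrophobic", "VAL", "THR"), class = classes
    )
  }
  xyz <- do.call(rbind, xyz_list)
  beads <- do.call(rbind, bead_rows)
  beads$index <- seq_len(nrow(beads))
  system <- bead_system(beads, groups = list(peptide = beads$index))
  list(system = system, frame = cg_frame(xyz))
}

#' Ideal beta barrel
#'
#' Strands run along the barrel (z) axis on a cylinder, radially zigzagged
#' so that hydrophobic residues literally face inward. Adjacent strands sit
#' at `inter_strand` spacing; the radius defaults to the value that
#' achieves this for `n_strands`. Alternate strands are antiparallel.
#'
#' @param n_strands number of strands (>= 4).
#' @param n_res residues per strand.
#' @param radius cylinder radius (nm); NULL to derive from `inter_strand`.
#' @param inter_strand target spacing between adjacent strands, nm.
#' @param bond consecutive-bead distance, nm.
#' @param zigzag radial zigzag half-amplitude, nm.
#' @return list with `system` and `frame`.
#' @export
make_barrel <- function(n_strands = 8, n_res = 8, radius = NULL,
                        inter_strand = 0.48, bond = 0.35, zigzag = 0.05) {
  if (n_strands < 4) stop("a barrel needs at least 4 strands", call. = FALSE)
  if (is.null(radius)) radius <- inter_strand / (2 * sin(pi / n_strands))
  spacing <- 2 * radius * sin(pi / n_strands)
  if (spacing < 0.3 || spacing > 0.8) {
    stop("geometric infeasibility: implied inter-strand spacing ",
         sprintf("%.2f", spacing), " nm is outside [0.3, 0.8]",
         call. = FALSE)
  }
  a <- sqrt(bond^2 - (2 * zigzag)^2)
  xyz_list <- list(); bead_rows <- list()
  for (s in seq_len(n_strands)) {
    alpha <- 2 * pi * (s - 1) / n_strands
    k <- seq_len(n_res)
    r_k <- radius + ifelse(k %% 2 == 0, zigzag, -zigzag)  # odd k inward
    coords <- cbind(r_k * cos(alpha), r_k * sin(alpha), k * a)
    lattice_pos <- k
    if (s %% 2 == 0) {  # antiparallel neighbours
      coords <- coords[n_res:1, , drop = FALSE]
      lattice_pos <- rev(lattice_pos)
    }
    classes <- ifelse(lattice_pos %% 2 == 1, "hydrophobic", "polar")
    xyz_list[[s]] <- coords
    bead_rows[[s]] <- fixture_beads(
      coords, paste0("P", s), seq_len(n_res),
      ifelse(classes == "hydrophobic", "VAL", "THR"), class = classes
    )
  }
  xyz <- do.call(rbind, xyz_list)
  beads <- do.call(rbind, bead_rows)
  beads$index <- seq_len(nrow(beads))
  system <- bead_system(beads, groups = list(peptide = beads$index))
  list(system = system, frame = cg_frame(xyz))
}

#' Self-avoiding random coil
#'
#' A seeded self-avoiding random walk: all bond lengths equal `bond`, all
#' non-bonded bead pairs at least `exclusion` apart. The same seed always
#' produces identical coordinates.
#'
#' @param n_res number of residues (>= 2).
#' @param bond bond length, nm.
#' @param exclusion minimum non-bonded distance, nm.
#' @param seed RNG seed.
#' @param chain_id chain identifier.
#' @param max_restarts walk restarts before giving up.
#' @return list with `system` and `frame`.
#' @export
make_coil <- function(n_res, bond = 0.35, exclusion = 0.4, seed = 1,
                      chain_id = "C1", max_restarts = 100) {
  if (n_res < 2) stop("a coil needs at least 2 residues", call. = FALSE)
  if (exclusion >= 2 * bond) {
    stop("exclusion must be < twice the bond length", call. = FALSE)
  }
  xyz <- with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      pts <- matrix(0, n_res, 3)
      ok <- TRUE
      for (k in 2:n_res) {
        placed <- FALSE
        for (try in 1:50) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- pts[k - 1, ] + bond * u
          if (k > 2) {
            d <- sqrt(colSums((t(pts[1:(k - 2), , drop = FALSE]) - cand)^2))
            if (any(d < exclusion)) next
          }
          pts[k, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) {
      stop("self-avoiding walk placement failed after ", max_restarts,
           " restarts", call. = FALSE)
    }
    pts
  })
  classes <- ifelse(seq_len(n_res) %% 2 == 1, "hydrophobic", "polar")
  beads <- fixture_beads(xyz, chain_id, seq_len(n_res),
                         ifelse(classes == "hydrophobic", "VAL", "THR"),
                         class = classes)
  system <- bead_system(beads, groups = list(peptide = beads$index))
  list(system = system, frame = cg_frame(xyz))
}

#' Helical-bundle membrane-protein mimic
#'
#' A synthetic integral-membrane-protein stand-in: `n_helices` ideal
#' alpha-helical backbone traces (3.6 residues/turn, 0.15 nm rise) arranged
#' on a circle of `bundle_radius`, with a hydrophobic mid-section
#' (transmembrane belt) and polar caps. With `side_beads = TRUE` each
#' residue also gets one outward side bead, approximating the bead density
#' of a MARTINI-style protein model.
#'
#' @param n_helices number of helices.
#' @param n_res_per_helix residues per helix.
#' @param bundle_radius circle radius for helix axes, nm.
#' @param helix_radius backbone helix radius, nm.
#' @param rise_per_res helical rise per residue, nm.
#' @param hydrophobic_fraction central fraction of each helix classed
#'   hydrophobic.
#' @param side_beads add one side bead per residue.
#' @return list with `system` and `frame`; the whole assembly is group
#'   `"protein"`.
#' @export
make_cylinder_protein <- function(n_helices = 7, n_res_per_helix = 25,
                                  bundle_radius = 1.15, helix_radius = 0.25,
                                  rise_per_res = 0.15,
                                  hydrophobic_fraction = 0.6,
                                  side_beads = FALSE) {
  if (n_helices < 1 || n_res_per_helix < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  height <- n_res_per_helix * rise_per_res
  lo <- height * (1 - hydrophobic_fraction) / 2
  hi <- height - lo
  bead_rows <- list(); xyz_list <- list()
  for (h in seq_len(n_helices)) {
    beta <- 2 * pi * (h - 1) / n_helices
    cx <- bundle_radius * cos(beta); cy <- bundle_radius * sin(beta)
    k <- seq_len(n_res_per_helix)
    gamma <- k * 2 * pi / 3.6 + h  # per-helix phase offset
    z <- k * rise_per_res
    bb <- cbind(cx + helix_radius * cos(gamma),
                cy + helix_radius * sin(gamma), z)
    mid <- z > lo & z < hi
    classes <- ifelse(mid, "hydrophobic", "polar")
    resname <- ifelse(mid, "LEU", "SER")
    rows <- fixture_beads(bb, paste0("H", h), k, resname, class = classes)
    coords <- bb
    if (side_beads) {
      u <- cbind(bb[, 1], bb[, 2], 0)
      nu <- sqrt(rowSums(u^2)); u <- u / nu
      sc <- bb + 0.25 * u  # side bead radially outward from the bundle axis
      sc_rows <- fixture_beads(sc, paste0("H", h), k, resname, name = "SC1",
                               class = classes, is_backbone = FALSE)
      # interleave BB/SC per residue to keep residues contiguous
      ord <- order(rep(k, 2), rep(c(1, 2), each = n_res_per_helix))
      rows <- rbind(rows, sc_rows)[ord, ]
      coords <- rbind(bb, sc)[ord, , drop = FALSE]
    }
    bead_rows[[h]] <- rows
    xyz_list[[h]] <- coords
  }
  beads <- do.call(rbind, bead_rows)
  beads$index <- seq_len(nrow(beads))
  xyz <- do.call(rbind, xyz_list)
  system <- bead_system(beads, groups = list(protein = beads$index))
  list(system = system, frame = cg_frame(xyz))
}

#' Synthetic bacteriorhodopsin-scale bundle
#'
#' A labelled-synthetic stand-in for a seven-helix transmembrane protein at
#' coarse-grained resolution: seven ~25-residue helices at ~1 nm packing
#' distance with backbone and side beads. This is a geometric mimic built
#' by [make_cylinder_protein()], not an experimental structure.
#'
#' @return list with `system` and `frame`.
#' @export
bacteriorhodopsin_mimic <- function() {
  make_cylinder_protein(n_helices = 7, n_res_per_helix = 25,
                        bundle_radius = 1.15, side_beads = TRUE)
}

#' Detergent shell around a protein fixture
#'
#' Places single-chain detergent molecules (one polar head bead, several
#' hydrophobic tail beads, tails pointing inward) on a cylindrical shell
#' around a protein fixture. With `n_patches` set, molecules concentrate in
#' that many well-separated angular patches (seeded micelle nuclei);
#' otherwise they spread uniformly. Deterministic per seed.
#'
#' @param protein a `list(system, frame)` protein fixture.
#' @param n_detergent number of detergent molecules (>= 1).
#' @param shell_radius radius (nm) of the innermost tail bead, measured
#'   from the protein axis.
#' @param seed RNG seed.
#' @param n_patches number of angular patches, or NULL for uniform.
#' @param tail_beads tail beads per molecule.
#' @param spacing intra-molecule bead spacing, nm.
#' @param min_sep minimum allowed distance between beads of different
#'   detergent molecules, nm; placement is retried and then fails with an
#'   overcrowded-shell error.
#' @return augmented `list(system, frame)` with groups `protein` and
#'   `detergent`.
#' @export
make_detergent_shell <- function(protein, n_detergent = 30,
                                 shell_radius = 2.0, seed = 1,
                                 n_patches = NULL, tail_beads = 3,
                                 spacing = 0.3, min_sep = 0.15) {
  if (n_detergent < 1) stop("n_detergent must be >= 1", call. = FALSE)
  pxyz <- protein$frame$xyz
  center <- colMeans(pxyz)
  zr <- range(pxyz[, 3])
  zspan <- diff(zr)

  mol_beads <- function(ang, z) {
    u <- c(cos(ang), sin(ang), 0)
    t(vapply(seq_len(tail_beads + 1), function(t) {
      c(center[1], center[2], 0) + u * (shell_radius + (t - 1) * spacing) +
        c(0, 0, z)
    }, numeric(3)))
  }

  beadpos_list <- with_seed(seed, {
    placed <- list()
    for (d in seq_len(n_detergent)) {
      ok <- FALSE
      for (try in 1:200) {
        if (is.null(n_patches)) {
          ang <- runif(1, 0, 2 * pi)
          z <- runif(1, zr[1] + 0.1 * zspan, zr[2] - 0.1 * zspan)
        } else {
          # patch members sit on a tight jittered ladder in z, so every
          # patch stays internally connected at the 0.6 nm contact scale
          p <- ((d - 1) %% n_patches)
          m <- ((d - 1) %/% n_patches)
          n_in <- ceiling((n_detergent - p) / n_patches)
          ang <- 2 * pi * p / n_patches + rnorm(1, 0, 0.05)
          z <- center[3] + (m - (n_in - 1) / 2) * 0.22 + runif(1, -0.04, 0.04)
        }
        cand <- mol_beads(ang, z)
        clash <- FALSE
        for (prev in placed) {
          if (min(min_image_dist(cand, prev, NULL)) < min_sep) {
            clash <- TRUE
            break
          }
        }
        if (!clash) { placed[[d]] <- cand; ok <- TRUE; break }
      }
      if (!ok) {
        stop("overcrowded shell: could not place detergent ", d, " of ",
             n_detergent, " with ", min_sep, " nm separation", call. = FALSE)
      }
    }
    placed
  })

  det_rows <- list()
  for (d in seq_len(n_detergent)) {
    nb <- tail_beads + 1
    # bead 1..tail_beads: hydrophobic tail (innermost first); last: polar head
    classes <- c(rep("hydrophobic", tail_beads), "polar")
    names_ <- c(paste0("C", seq_len(tail_beads)), "PO4")
    det_rows[[d]] <- fixture_beads(beadpos_list[[d]], paste0("D", d),
                                   rep(1L, nb), "DPC", name = names_,
                                   class = classes, is_backbone = FALSE)
  }
  det_beads <- do.call(rbind, det_rows)
  prot_beads <- protein$system$beads
  det_beads$index <- seq_len(nrow(det_beads)) + nrow(prot_beads)
  beads <- rbind(prot_beads, det_beads)
  xyz <- rbind(protein$frame$xyz, do.call(rbind, beadpos_list))
  system <- bead_system(beads, groups = list(
    protein = prot_beads$index, detergent = det_beads$index))
  list(system = system, frame = cg_frame(xyz, box = protein$frame$box))
}

#' Linearly interpolated trajectory between two frames
#'
#' Geometric stand-in for a time series: coordinates interpolate linearly
#' from `start` to `end`, frame times are 0..n_frames-1 ps. No physics is
#' implied.
#'
#' @param start,end [cg_frame()] objects over the same bead system.
#' @param system the [bead_system()].
#' @param n_frames number of frames (>= 2); endpoints are reproduced
#'   exactly.
#' @return a [cg_trajectory()].
#' @export
make_interpolated_trajectory <- function(start, end, system, n_frames) {
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (nrow(start$xyz) != nrow(end$xyz) ||
      nrow(start$xyz) != nrow(system$beads)) {
    stop("start/end frames and system must have matching bead counts",
         call. = FALSE)
  }
  frames <- lapply(seq_len(n_frames), function(k) {
    t <- (k - 1) / (n_frames - 1)
    cg_frame(start$xyz * (1 - t) + end$xyz * t, box = start$box,
             time = k - 1)
  })
  cg_trajectory(frames, system)
}
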