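#' Construct a bead system
#'
#' A `bead_system` is the topology side of a coarse-grained model: the beads
#' (one per coarse-grained particle; for one-bead-per-residue models one per
#' residue), their chain membership and backbone order, bonds, and named
#' index groups (conventionally `protein`, `peptide`, `detergent`).
#'
#' @param beads data.frame with columns `index` (unique positive integers),
#'   `name`, `residue_index`, `residue_name`, `chain_id`, `is_backbone`,
#'   `radius` (nm, > 0), `class` (one of hydrophobic, polar, charged_pos,
#'   charged_neg, other).
#' @param bonds two-column integer matrix of bonded bead index pairs, or
#'   NULL to bond consecutive backbone beads within each chain.
#' @param groups named list of integer bead-index vectors. Groups must be
#'   disjoint unless `allow_overlap = TRUE`.
#' @param allow_overlap allow overlapping groups.
#' @return An object of class `bead_system` with elements `beads`, `bonds`,
#'   `chains` (per-chain ordered backbone bead indices) and `groups`.
#' @export
bead_system <- function(beads, bonds = NULL, groups = list(),
                        allow_overlap = FALSE) {
  required <- c("index", "name", "residue_index", "residue_name", "chain_id",
                "is_backbone", "radius", "class")
  missing_cols <- setdiff(required, names(beads))
  if (length(missing_cols)) {
    stop("beads is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(beads$index)) {
    stop("bead indices must be unique", call. = FALSE)
  }
  if (any(beads$radius <= 0)) stop("bead radii must be > 0", call. = FALSE)
  bad <- setdiff(unique(beads$class), BEAD_CLASSES)
  if (length(bad)) {
    stop("unknown hydropathy class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rownames(beads) <- NULL

  chains <- lapply(split(seq_len(nrow(beads)), beads$chain_id), function(rows) {
    bb <- rows[beads$is_backbone[rows]]
    beads$index[bb]
  })
  chains <- chains[unique(beads$chain_id)]  # preserve file order

  if (is.null(bonds)) {
    bonds <- do.call(rbind, lapply(chains, function(idx) {
      if (length(idx) < 2) return(NULL)
      cbind(idx[-length(idx)], idx[-1])
    }))
    if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && !all(bonds %in% beads$index)) {
    stop("bonds reference bead indices absent from the system", call. = FALSE)
  }

  if (length(groups)) {
    for (g in names(groups)) {
      if (!all(groups[[g]] %in% beads$index)) {
        stop("group '", g, "' references bead indices absent from the system",
             call. = FALSE)
      }
    }
    if (!allow_overlap && length(groups) > 1) {
      all_idx <- unlist(groups, use.names = FALSE)
      if (anyDuplicated(all_idx)) {
        stop("groups overlap; pass allow_overlap = TRUE if intended",
             call. = FALSE)
      }
    }
  }

  structure(
    list(beads = beads, bonds = bonds, chains = chains, groups = groups),
    class = "bead_system"
  )
}

#' @export
print.bead_system <- function(x, ...) {
  cat("bead_system:", nrow(x$beads), "beads,", length(x$chains), "chains,",
      nrow(x$bonds), "bonds\n")
  if (length(x$groups)) {
    cat("  groups:", paste(sprintf("%s (%d)", names(x$groups),
                                   lengths(x$groups)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a coordinate frame
#'
#' @param xyz n x 3 numeric matrix of bead coordinates in nm.
#' @param box lengths (nm) of an orthorhombic periodic box, or NULL for a
#'   non-periodic frame.
#' @param time frame time in ps.
#' @return An object of class `cg_frame`.
#' @export
cg_frame <- function(xyz, box = NULL, time = 0) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive lengths (orthorhombic)", call. = FALSE)
    }
  }
  structure(list(xyz = xyz, box = box, time = as.numeric(time)),
            class = "cg_frame")
}

#' Construct a trajectory
#'
#' @param frames list of [cg_frame()] objects, time-ordered.
#' @param system the [bead_system()] the frames belong to.
#' @return An object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(frames, system) {
  stopifnot(inherits(system, "bead_system"))
  n <- nrow(system$beads)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$xyz) != n) {
      stop("frame ", k, " has ", nrow(frames[[k]]$xyz),
           " beads; system has ", n, call. = FALSE)
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(frames = frames, system = system), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", length(x$frames), "frames x",
      nrow(x$system$beads), "beads\n")
  invisible(x)
}

#' @export
length.cg_trajectory <- function(x) length(x$frames)

# ---------------------------------------------------------------------------
# GRO format (fixed column, nm)

parse_gro_block <- function(lines, offset = 0L) {
  # offset: number of lines preceding this block in the file (for messages)
  if (length(lines) < 3) {
    stop("GRO parse error at line ", offset + 1,
         ": truncated file (need title, atom count, atoms, box)",
         call. = FALSE)
  }
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) {
    stop("GRO parse error at line ", offset + 2,
         ": atom count is not an integer", call. = FALSE)
  }
  if (natoms == 0) {
    stop("empty input: GRO file declares zero beads (line ", offset + 2, ")",
         call. = FALSE)
  }
  if (length(lines) < 3 + natoms) {
    stop("GRO parse error at line ", offset + length(lines),
         ": file ends before ", natoms, " atom records", call. = FALSE)
  }
  atom_lines <- lines[3:(2 + natoms)]
  resnum <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
  resname <- trimws(substr(atom_lines, 6, 10))
  atname <- trimws(substr(atom_lines, 11, 15))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
  bad <- which(is.na(resnum) | is.na(x) | is.na(y) | is.na(z) |
                 nchar(atom_lines) < 44)
  if (length(bad)) {
    stop("GRO parse error at line ", offset + 2 + bad[1],
         ": malformed atom record '", atom_lines[bad[1]], "'", call. = FALSE)
  }
  box_fields <- suppressWarnings(
    as.numeric(strsplit(trimws(lines[3 + natoms]), "\\s+")[[1]])
  )
  box <- NULL
  if (length(box_fields) >= 3 && !any(is.na(box_fields[1:3]))) {
    if (length(box_fields) > 3 && any(abs(box_fields[-(1:3)]) > 1e-9)) {
      stop("triclinic boxes are not supported (GRO box line has off-diagonal ",
           "components)", call. = FALSE)
    }
    if (all(box_fields[1:3] > 0)) box <- box_fields[1:3]
  }
  # time stamp from title, GROMACS convention "... t= <ps>"
  time <- NA_real_
  m <- regmatches(lines[1], regexec("t=\\s*([-0-9.eE+]+)", lines[1]))[[1]]
  if (length(m) == 2) time <- suppressWarnings(as.numeric(m[2]))
  list(resnum = resnum, resname = resname, atname = atname,
       xyz = cbind(x, y, z), box = box, time = time,
       nlines = 3 + natoms)
}

#' Infer chain breaks from residue numbering
#'
#' GRO files carry no chain identifiers; a new chain is opened whenever the
#' residue number fails to be non-decreasing by at most one step.
#' @noRd
infer_chains <- function(resnum) {
  chain <- integer(length(resnum))
  cur <- 1L
  chain[1] <- cur
  for (k in seq_along(resnum)[-1]) {
    if (resnum[k] < resnum[k - 1] || resnum[k] > resnum[k - 1] + 1) {
      cur <- cur + 1L
    }
    chain[k] <- cur
  }
  chain_letters()[((chain - 1) %% length(chain_letters())) + 1]
}

chain_letters <- function() c(LETTERS, letters, as.character(0:9))

build_system_from_records <- function(resnum, resname, atname, chain_id,
                                      class_table, backbone_names) {
  n <- length(resnum)
  look <- lookup_residue(class_table, resname)
  beads <- data.frame(
    index = seq_len(n),
    name = atname,
    residue_index = as.integer(resnum),
    residue_name = resname,
    chain_id = chain_id,
    is_backbone = atname %in% backbone_names,
    radius = look$radius_nm,
    class = look$class,
    stringsAsFactors = FALSE
  )
  beads
}

#' Read a coarse-grained structure file
#'
#' Reads a GRO or PDB file into a ([bead_system()], [cg_frame()]) pair.
#' Coordinates are stored in nm (PDB Angstrom values are divided by 10).
#' Chains are taken from the PDB chain column, or inferred from residue
#' numbering for GRO files (which have none). Hydropathy class and bead
#' radius come from the class table; unknown residue names fall back to the
#' table default.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"gro"` or `"pdb"`.
#' @param class_table a [read_class_table()] object; default shipped table.
#' @param backbone_names bead names treated as backbone; `"BB"` is the
#'   coarse-grained dialect, `"CA"` the C-alpha-trace dialect.
#' @param groups optional named list: group name -> character vector of
#'   chain ids, converted to bead-index groups.
#' @return list with elements `system` and `frame`.
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb"),
                           class_table = default_class_table(),
                           backbone_names = c("BB", "CA"),
                           groups = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "gro") {
    lines <- readLines(path)
    blk <- parse_gro_block(lines)
    chain_id <- infer_chains(blk$resnum)
    beads <- build_system_from_records(blk$resnum, blk$resname, blk$atname,
                                       chain_id, class_table, backbone_names)
    frame <- cg_frame(blk$xyz, box = blk$box,
                      time = if (is.na(blk$time)) 0 else blk$time)
  } else {
    pdb <- read_pdb_records(path)
    beads <- build_system_from_records(pdb$resnum, pdb$resname, pdb$atname,
                                       pdb$chain, class_table, backbone_names)
    frame <- cg_frame(pdb$xyz[[1]] / 10, box = pdb$box, time = 0)
  }
  grp <- list()
  if (!is.null(groups)) grp <- groups_from_chains(beads, groups)
  system <- bead_system(beads, groups = grp)
  list(system = system, frame = frame)
}

groups_from_chains <- function(beads, groups) {
  lapply(groups, function(chs) beads$index[beads$chain_id %in% chs])
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro")) return("gro")
  if (ext %in% c("pdb", "ent")) return("pdb")
  stop("cannot guess format of '", path, "'; pass format explicitly",
       call. = FALSE)
}

# PDB reading: bio3d handles the record grammar (incl. MODEL/ENDMDL);
# CRYST1 is read directly since we only support orthorhombic boxes.
read_pdb_records <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(pdb$atom) == 0) stop("empty input: no atoms in ", path,
                                call. = FALSE)
  nmodel <- nrow(pdb$xyz)
  xyz <- lapply(seq_len(nmodel), function(m) {
    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  })
  chain <- pdb$atom$chain
  chain[is.na(chain) | chain == ""] <- "A"
  box <- NULL
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cr)) {
    abc <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                         substr(cr[1], 16, 24),
                                         substr(cr[1], 25, 33))))
    ang <- suppressWarnings(as.numeric(c(substr(cr[1], 34, 40),
                                         substr(cr[1], 41, 47),
                                         substr(cr[1], 48, 54))))
    if (!any(is.na(abc)) && all(abc > 1)) {
      if (!any(is.na(ang)) && any(abs(ang - 90) > 1e-3)) {
        stop("triclinic boxes are not supported (CRYST1 angles != 90)",
             call. = FALSE)
      }
      box <- abc / 10
    }
  }
  list(resnum = pdb$atom$resno, resname = pdb$atom$resid,
       atname = pdb$atom$elety, chain = chain, xyz = xyz, box = box)
}

#' Read a multi-frame trajectory
#'
#' Reads a concatenated GRO file or a multi-model PDB as a time-ordered
#' trajectory over an existing bead system. Frames missing time stamps are
#' assigned 0, 1, 2, ... ps.
#'
#' @param path input file.
#' @param format `"auto"`, `"multi_gro"` or `"multi_model_pdb"`.
#' @param system the [bead_system()] the frames describe; every frame must
#'   have the system's bead count.
#' @return A [cg_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "multi_gro",
                                             "multi_model_pdb"),
                            system) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (guess_format(path) == "gro") "multi_gro" else
      "multi_model_pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n <- nrow(system$beads)
  frames <- list()
  if (format == "multi_gro") {
    lines <- readLines(path)
    offset <- 0L
    while (offset < length(lines)) {
      if (all(!nzchar(trimws(lines[(offset + 1):length(lines)])))) break
      blk <- parse_gro_block(lines[(offset + 1):length(lines)], offset)
      if (nrow(blk$xyz) != n) {
        stop("trajectory frame ", length(frames) + 1, " has ", nrow(blk$xyz),
             " beads; system has ", n, call. = FALSE)
      }
      frames[[length(frames) + 1]] <-
        cg_frame(blk$xyz, box = blk$box, time = blk$time)
      offset <- offset + blk$nlines
    }
  } else {
    pdb <- read_pdb_records(path)
    for (m in seq_along(pdb$xyz)) {
      if (nrow(pdb$xyz[[m]]) != n) {
        stop("trajectory frame ", m, " has ", nrow(pdb$xyz[[m]]),
             " beads; system has ", n, call. = FALSE)
      }
      frames[[m]] <- cg_frame(pdb$xyz[[m]] / 10, box = pdb$box, time = NA_real_)
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(is.na(times)) || (length(times) > 1 && any(diff(times) <= 0))) {
    for (k in seq_along(frames)) frames[[k]]$time <- k - 1
  }
  cg_trajectory(frames, system)
}

# ---------------------------------------------------------------------------
# Writers

#' Write a system/frame as a GRO file
#'
#' @param system a [bead_system()].
#' @param frame a [cg_frame()] (or list of frames for a concatenated
#'   multi-frame GRO).
#' @param path output file.
#' @param title title line content.
#' @export
write_gro <- function(system, frame, path, title = "cgbeta system") {
  frames <- if (inherits(frame, "cg_frame")) list(frame) else frame
  con <- file(path, "w")
  on.exit(close(con))
  b <- system$beads
  for (f in frames) {
    writeLines(sprintf("%s t= %.5f", title, f$time), con)
    writeLines(sprintf("%5d", nrow(b)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       b$residue_index %% 100000L,
                       substr(b$residue_name, 1, 5),
                       substr(b$name, 1, 5),
                       b$index %% 100000L,
                       f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]), con)
    box <- f$box
    if (is.null(box)) box <- c(0, 0, 0)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

#' Write a system/frame(s) as a (multi-model) PDB file
#'
#' Coordinates are converted to Angstrom. Chain ids longer than one
#' character are remapped to single letters in order of appearance.
#'
#' @inheritParams write_gro
#' @export
write_pdb <- function(system, frame, path) {
  frames <- if (inherits(frame, "cg_frame")) list(frame) else frame
  b <- system$beads
  chains <- unique(b$chain_id)
  letters1 <- chain_letters()
  cmap <- setNames(letters1[((seq_along(chains) - 1) %% length(letters1)) + 1],
                   chains)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  box <- frames[[1]]$box
  if (!is.null(box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90), con)
  }
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]$xyz * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      b$index %% 100000L, substr(b$name, 1, 4),
      substr(b$residue_name, 1, 3), cmap[b$chain_id],
      b$residue_index %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Periodic-boundary geometry

#' Minimum-image displacement
#'
#' Displacement from `a` to `b` wrapped to the nearest periodic image of an
#' orthorhombic box; with `box = NULL` the plain difference is returned.
#' Each returned component has magnitude at most half the box length.
#'
#' @param a,b 3-vectors (nm).
#' @param box box lengths (nm) or NULL.
#' @return 3-vector displacement (nm).
#' @export
min_image_displacement <- function(a, b, box = NULL) {
  d <- as.numeric(b) - as.numeric(a)
  if (!is.null(box)) d <- d - box * round(d / box)
  d
}

#' Minimum-image distance matrix between two coordinate sets
#'
#' @param x,y coordinate matrices (rows are beads, nm).
#' @param box box lengths or NULL.
#' @return matrix of distances, `nrow(x)` x `nrow(y)`.
#' @export
min_image_dist <- function(x, y, box = NULL) {
  x <- matrix(x, ncol = 3)
  y <- matrix(y, ncol = 3)
  d2 <- matrix(0, nrow(x), nrow(y))
  for (k in 1:3) {
    dk <- outer(x[, k], y[, k], `-`)
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Resolve a selection to bead indices
#'
#' Selections may be given as integer bead indices, a group name, or a
#' character vector of chain ids.
#' @param system a [bead_system()].
#' @param selection integer indices, group name, or chain ids.
#' @return integer vector of bead indices.
#' @export
resolve_selection <- function(system, selection) {
  if (is.numeric(selection)) {
    sel <- as.integer(selection)
    if (!all(sel %in% system$beads$index)) {
      stop("selection contains bead indices absent from the system",
           call. = FALSE)
    }
    return(sel)
  }
  if (is.character(selection)) {
    if (length(selection) == 1 && selection %in% names(system$groups)) {
      return(as.integer(system$groups[[selection]]))
    }
    if (all(selection %in% system$beads$chain_id)) {
      return(system$beads$index[system$beads$chain_id %in% selection])
    }
    stop("selection '", paste(selection, collapse = ","),
         "' matches neither a group name nor chain ids", call. = FALSE)
  }
  stop("selection must be numeric indices, a group name or chain ids",
       call. = FALSE)
}
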