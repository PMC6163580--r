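# Independent brute-force oracles. These deliberately re-derive every
# quantity with the most naive algorithm available (explicit loops,
# different trigonometric route) so they share no code path with the
# package implementations they check.

# Unsigned dihedral via plane-normal acos (implementation uses atan2).
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                         a[1]*b[2]-a[2]*b[1])
  n1 <- cr(p2 - p1, p3 - p2)
  n2 <- cr(p3 - p2, p4 - p3)
  ct <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  acos(max(-1, min(1, ct))) * 180 / pi
}

oracle_mi <- function(a, b, box) {
  d <- b - a
  if (!is.null(box)) for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
  d
}

# Naive re-implementation of the beta criterion: all windows, all contact
# pairs, explicit loops.
oracle_assign_beta <- function(frame, system, params = beta_params()) {
  beads <- system$beads
  bb <- list()
  for (ch in names(system$chains)) {
    idx <- system$chains[[ch]]
    if (length(idx)) {
      bb[[length(bb) + 1]] <- data.frame(index = idx, chain = ch,
                                         pos = seq_along(idx))
    }
  }
  bb <- do.call(rbind, bb)
  xyz <- frame$xyz
  n <- nrow(bb)
  beta <- logical(n)
  for (i in seq_len(n)) {
    ch <- bb$chain[i]; pos <- bb$pos[i]
    chain_idx <- system$chains[[ch]]
    m <- length(chain_idx)
    if (pos < 2 || pos > m - 2) next
    r <- match(chain_idx[(pos - 1):(pos + 2)], beads$index)
    ang <- oracle_dihedral(xyz[r[1], ], xyz[r[2], ], xyz[r[3], ], xyz[r[4], ])
    if (ang <= params$angle_min) next
    pi_row <- match(bb$index[i], beads$index)
    found <- FALSE
    for (j in seq_len(n - 1)) {
      if (found) break
      if (bb$chain[j] != bb$chain[j + 1]) next
      if (bb$pos[j + 1] != bb$pos[j] + 1) next
      if (bb$chain[j] == ch &&
          (abs(bb$pos[j] - pos) < params$min_seq_sep ||
             abs(bb$pos[j + 1] - pos) < params$min_seq_sep)) next
      d1 <- sqrt(sum(oracle_mi(xyz[pi_row, ],
                               xyz[match(bb$index[j], beads$index), ],
                               frame$box)^2))
      d2 <- sqrt(sum(oracle_mi(xyz[pi_row, ],
                               xyz[match(bb$index[j + 1], beads$index), ],
                               frame$box)^2))
      if (d1 <= params$contact_dist && d2 <= params$contact_dist) found <- TRUE
    }
    beta[i] <- found
  }
  data.frame(index = bb$index, beta = beta)
}

# Brute-force union-find single-linkage over the full molecule distance
# matrix.
oracle_cluster <- function(frame, system, group, cutoff) {
  sel <- resolve_selection(system, group)
  rows <- match(sel, system$beads$index)
  chain <- system$beads$chain_id[rows]
  chains <- unique(chain)
  parent <- seq_along(chains)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_along(chains)) {
    for (b in seq_along(chains)) {
      if (b <= a) next
      ra <- rows[chain == chains[a]]; rb <- rows[chain == chains[b]]
      touch <- FALSE
      for (i in ra) {
        for (j in rb) {
          d <- sqrt(sum(oracle_mi(frame$xyz[i, ], frame$xyz[j, ],
                                  frame$box)^2))
          if (d <= cutoff) { touch <- TRUE; break }
        }
        if (touch) break
      }
      if (touch) {
        fa <- find(a); fb <- find(b)
        if (fa != fb) parent[max(fa, fb)] <- min(fa, fb)
      }
    }
  }
  labels <- vapply(seq_along(chains), find, integer(1))
  # canonical: label by lowest member index
  vapply(labels, function(l) min(which(labels == l)), integer(1))
}

# Analytic union surface of two intersecting spheres (radii R1, R2,
# centre distance d): each sphere loses a spherical cap.
oracle_two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  (4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)) +
    (4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2))
}

# Small helpers used across test files -------------------------------------

# bare one-chain system from coordinates
toy_system <- function(xyz, class = "hydrophobic", chain = "A",
                       radius = 0.26) {
  n <- nrow(xyz)
  beads <- data.frame(
    index = seq_len(n), name = "BB", residue_index = seq_len(n),
    residue_name = "VAL", chain_id = chain, is_backbone = TRUE,
    radius = radius, class = rep_len(class, n), stringsAsFactors = FALSE
  )
  bead_system(beads)
}

random_rotation <- function() {
  # QR of a random gaussian matrix, det forced to +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# randomized small fixture for detector-oracle sweeps: mixes sheets,
# perturbed sheets, coils and coil pairs, sometimes in a periodic box
random_beta_fixture <- function(seed) {
  set.seed(seed)
  kind <- sample(c("sheet", "noisy_sheet", "coil_pair", "barrel"), 1)
  fx <- switch(kind,
    sheet = make_sheet(n_strands = sample(2:3, 1), n_res = sample(6:10, 1),
                       orientation = sample(c("parallel", "antiparallel"), 1),
                       registry_shift = sample(-1:1, 1)),
    noisy_sheet = {
      f <- make_sheet(2, sample(6:10, 1))
      f$frame$xyz <- f$frame$xyz + matrix(rnorm(length(f$frame$xyz), 0, 0.05),
                                          ncol = 3)
      f
    },
    coil_pair = {
      c1 <- make_coil(sample(8:14, 1), seed = seed * 2 + 1, chain_id = "C1")
      c2 <- make_coil(sample(8:14, 1), seed = seed * 2 + 2, chain_id = "C2")
      b2 <- c2$system$beads
      b2$index <- b2$index + nrow(c1$system$beads)
      beads <- rbind(c1$system$beads, b2)
      beads$index <- seq_len(nrow(beads))
      shift <- runif(3, -1, 1) * 2
      xyz <- rbind(c1$frame$xyz, sweep(c2$frame$xyz, 2, shift, `+`))
      list(system = bead_system(beads), frame = cg_frame(xyz))
    },
    barrel = make_barrel(n_strands = sample(4:8, 1), n_res = sample(6:8, 1))
  )
  if (runif(1) < 0.3) {
    # wrap into a periodic box large enough to hold the assembly
    span <- apply(fx$frame$xyz, 2, function(v) diff(range(v)))
    box <- pmax(span * 2, 4)
    fx$frame <- cg_frame(sweep(fx$frame$xyz, 2,
                               apply(fx$frame$xyz, 2, min) - 0.5, `-`),
                         box = box)
  }
  fx
}
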