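two_blob_fixture <- function(sep = 10, n_per = 5) {
  # two groups of single-bead "molecules" packed within 0.5 nm internally
  xyz <- NULL; chains <- character(0)
  for (blob in 1:2) {
    ctr <- c((blob - 1) * sep, 0, 0)
    for (m in seq_len(n_per)) {
      xyz <- rbind(xyz, ctr + c(0.5 * (m - 1), 0, 0))
      chains <- c(chains, sprintf("B%dM%d", blob, m))
    }
  }
  n <- nrow(xyz)
  beads <- data.frame(index = seq_len(n), name = "BB", residue_index = 1L,
                      residue_name = "DPC", chain_id = chains,
                      is_backbone = FALSE, radius = 0.26,
                      class = "hydrophobic", stringsAsFactors = FALSE)
  sys <- bead_system(beads, groups = list(detergent = seq_len(n)))
  list(system = sys, frame = cg_frame(xyz))
}

test_that("well-separated blobs cluster apart, chained molecules merge", {
  fx <- two_blob_fixture()
  cl <- cluster_molecules(fx$frame, fx$system, "detergent", 0.6)
  expect_equal(cl$n_clusters, 2)
  expect_equal(unname(sort(cl$sizes)), c(5, 5))
  # raise the cutoff beyond the blob separation: single-linkage chains all
  cl2 <- cluster_molecules(fx$frame, fx$system, "detergent", 8.1)
  expect_equal(cl2$n_clusters, 1)
})

test_that("cluster labels match brute-force union-find on randomized scenes", {
  for (seed in 1:10) {
    set.seed(seed)
    nmol <- sample(5:20, 1)
    xyz <- NULL; chains <- character(0)
    for (m in seq_len(nmol)) {
      ctr <- runif(3, 0, 4)
      nb <- sample(1:3, 1)
      xyz <- rbind(xyz, sweep(matrix(rnorm(nb * 3, 0, 0.15), ncol = 3),
                              2, ctr, `+`))
      chains <- c(chains, rep(paste0("M", m), nb))
    }
    beads <- data.frame(index = seq_len(nrow(xyz)), name = "BB",
                        residue_index = 1L, residue_name = "DPC",
                        chain_id = chains, is_backbone = FALSE,
                        radius = 0.26, class = "hydrophobic",
                        stringsAsFactors = FALSE)
    sys <- bead_system(beads, groups = list(mols = seq_len(nrow(xyz))))
    box <- if (seed %% 2) c(5, 5, 5) else NULL
    fr <- cg_frame(xyz, box = box)
    cl <- cluster_molecules(fr, sys, "mols", 0.6)
    expect_equal(cl$molecules$cluster, oracle_cluster(fr, sys, "mols", 0.6),
                 label = paste("scene", seed))
  }
})

test_that("cluster count is non-increasing in the cutoff", {
  fx <- two_blob_fixture(sep = 3, n_per = 4)
  counts <- vapply(c(0.3, 0.6, 1.5, 3.5), function(ct) {
    cluster_molecules(fx$frame, fx$system, "detergent", ct)$n_clusters
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("seeded micelle patches are recovered exactly", {
  prot <- make_cylinder_protein(5, 12, bundle_radius = 0.8)
  for (k in 1:5) {
    fx <- make_detergent_shell(prot, 8 * k, 1.8, seed = 11, n_patches = k)
    cl <- cluster_molecules(fx$frame, fx$system, "detergent", 0.6)
    expect_equal(cl$n_clusters, k)
  }
})

test_that("contact maps list exactly the residue pairs within cutoff", {
  # constructed: one bead of B placed 0.4 nm from one bead of A
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(0.4, 0, 0), c(9, 9, 9))
  beads <- data.frame(index = 1:4, name = "BB", residue_index = c(1, 2, 1, 2),
                      residue_name = "VAL", chain_id = c("A", "A", "B", "B"),
                      is_backbone = TRUE, radius = 0.26,
                      class = "hydrophobic", stringsAsFactors = FALSE)
  sys <- bead_system(beads, groups = list(ga = 1:2, gb = 3:4))
  fr <- cg_frame(xyz)
  cm <- contact_residues(fr, sys, "ga", "gb", 0.6)
  expect_equal(nrow(cm), 1)
  expect_equal(cm$resA, 1); expect_equal(cm$resB, 1)
  expect_equal(cm$min_dist_nm, 0.4, tolerance = 1e-12)
  # distant groups: empty
  fr2 <- cg_frame(xyz + rep(c(0, 0, 100, 100), 3) * 0)  # no-op guard
  far <- cg_frame(rbind(xyz[1:2, ], xyz[3:4, ] + 50))
  expect_equal(nrow(contact_residues(far, sys, "ga", "gb", 0.6)), 0)
})

test_that("contact maps match a brute-force distance scan on a sheet-protein scene", {
  prot <- make_cylinder_protein(4, 8, bundle_radius = 0.7)
  pep <- make_strand(8)
  bp <- pep$system$beads
  bp$index <- bp$index + nrow(prot$system$beads)
  bp$chain_id <- "Z"
  beads <- rbind(prot$system$beads, bp)
  sys <- bead_system(beads, groups = list(protein = prot$system$beads$index,
                                          peptide = bp$index))
  fr <- cg_frame(rbind(prot$frame$xyz,
                       sweep(pep$frame$xyz, 2, c(1.3, 0, 0.4), `+`)))
  cm <- contact_residues(fr, sys, "protein", "peptide", 0.7)
  # oracle: triple loop over residue pairs
  pa <- resolve_selection(sys, "protein"); pb <- resolve_selection(sys, "peptide")
  found <- list()
  for (i in pa) for (j in pb) {
    d <- sqrt(sum((fr$xyz[i, ] - fr$xyz[j, ])^2))
    if (d <= 0.7) {
      key <- paste(sys$beads$chain_id[i], sys$beads$residue_index[i],
                   sys$beads$chain_id[j], sys$beads$residue_index[j])
      if (is.null(found[[key]]) || d < found[[key]]) found[[key]] <- d
    }
  }
  expect_equal(nrow(cm), length(found))
  got_keys <- paste(cm$chainA, cm$resA, cm$chainB, cm$resB)
  expect_setequal(got_keys, names(found))
  expect_equal(cm$min_dist_nm[order(got_keys)],
               unlist(found)[sort(names(found))], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("hydrophobic burial spans its contract range", {
  # isolated bead: zero burial
  one <- list(system = toy_system(matrix(0, 1, 3)),
              frame = cg_frame(matrix(0, 1, 3)))
  expect_equal(hydrophobic_burial(one$frame, one$system, 1), 0)
  # bead caged by 12 icosahedral polar neighbours at tight contact: ~1
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(c(0,1,phi), c(0,-1,phi), c(0,1,-phi), c(0,-1,-phi),
               c(1,phi,0), c(-1,phi,0), c(1,-phi,0), c(-1,-phi,0),
               c(phi,0,1), c(-phi,0,1), c(phi,0,-1), c(-phi,0,-1))
  ico <- ico / sqrt(rowSums(ico^2)) * 0.35
  xyz <- rbind(c(0, 0, 0), ico)
  sys <- toy_system(xyz, class = c("hydrophobic", rep("polar", 12)))
  expect_gt(hydrophobic_burial(cg_frame(xyz), sys, 1:13), 0.95)
  # error when the group has no hydrophobic beads
  sys2 <- toy_system(matrix(0, 1, 3), class = "polar")
  expect_error(hydrophobic_burial(cg_frame(matrix(0, 1, 3)), sys2, 1),
               "no hydrophobic")
})

test_that("sheet sandwiches bury more hydrophobic surface than splayed strands", {
  sandwich <- make_sheet(4, 8)
  splayed <- make_sheet(4, 8, inter_strand = 3)
  p <- sasa_params(n_sphere_points = 320)
  expect_gt(hydrophobic_burial(sandwich$frame, sandwich$system, "peptide", p),
            hydrophobic_burial(splayed$frame, splayed$system, "peptide", p))
  # barrels bury more than the same strands laid flat
  barrel <- make_barrel(8, 8)
  flat <- make_sheet(8, 8)
  expect_gt(hydrophobic_burial(barrel$frame, barrel$system, "peptide", p),
            hydrophobic_burial(flat$frame, flat$system, "peptide", p))
})

test_that("burial ignores distant spectator molecules", {
  fx <- make_sheet(2, 8)
  p <- sasa_params(n_sphere_points = 320)
  base <- hydrophobic_burial(fx$frame, fx$system, "peptide", p)
  spect <- make_coil(10, seed = 4, chain_id = "S1")
  bs <- spect$system$beads
  bs$index <- bs$index + nrow(fx$system$beads)
  beads <- rbind(fx$system$beads, bs)
  sys <- bead_system(beads, groups = list(peptide = fx$system$beads$index,
                                          spectator = bs$index))
  fr <- cg_frame(rbind(fx$frame$xyz, spect$frame$xyz + 8))
  expect_equal(hydrophobic_burial(fr, sys, "peptide", p), base,
               tolerance = 1e-12)
})
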