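# Typed-interaction detectors and network assembly.

crit <- geometric_criteria()
chem <- default_chemistry()

test_that("a constructed salt bridge yields exactly one ionic edge", {
  d <- 0.85 * crit$ionic_max_dist
  st <- make_salt_bridge()$ensemble$states[[1]]
  e <- detect_ionic(st, crit, chem)
  expect_equal(nrow(e), 1)
  expect_equal(e$source, "A:1:LYS")
  expect_equal(e$target, "A:3:GLU")
  expect_equal(e$distance, d, tolerance = 1e-9)

  far <- make_salt_bridge(distance = 2 * crit$ionic_max_dist)
  expect_equal(nrow(detect_ionic(far$ensemble$states[[1]], crit, chem)), 0)
})

test_that("parallel and T-shaped stacks pass, oblique ones fail", {
  on <- make_stacked_rings()$ensemble$states[[1]]
  e <- detect_pipistack(on, crit, chem)
  expect_equal(nrow(e), 1)
  expect_equal(e$type, "PIPISTACK")
  expect_equal(e$angle, 0, tolerance = 1e-6)

  far <- make_stacked_rings(centroid_dist = 10)$ensemble$states[[1]]
  expect_equal(nrow(detect_pipistack(far, crit, chem)), 0)

  tshape <- make_stacked_rings(plane_angle = 90)$ensemble$states[[1]]
  expect_equal(nrow(detect_pipistack(tshape, crit, chem)), 1)

  oblique <- make_stacked_rings(plane_angle = 45)$ensemble$states[[1]]
  expect_equal(nrow(detect_pipistack(oblique, crit, chem)), 0)
})

test_that("pi-cation requires the cation near the ring normal", {
  on <- make_pication_pair()$ensemble$states[[1]]
  e <- detect_pication(on, crit, chem)
  expect_equal(nrow(e), 1)
  expect_equal(e$angle, 0, tolerance = 1e-6)

  side <- make_pication_pair(angle_from_normal = 90)$ensemble$states[[1]]
  expect_equal(nrow(detect_pication(side, crit, chem)), 0)

  just_in <- make_pication_pair(
    angle_from_normal = crit$pication_max_angle - 1)$ensemble$states[[1]]
  expect_equal(nrow(detect_pication(just_in, crit, chem)), 1)
  just_out <- make_pication_pair(
    angle_from_normal = crit$pication_max_angle + 1)$ensemble$states[[1]]
  expect_equal(nrow(detect_pication(just_out, crit, chem)), 0)
})

test_that("hydrogen-bond angle gate rejects bad donor geometry", {
  base <- rinens:::hbond_pair_residues(c(0, 0, 0),
                                       0.85 * crit$hbond_max_da)
  good <- rinens:::fx_state(base)
  e <- detect_hbond(good, crit, chem)
  expect_equal(nrow(e), 1)
  expect_gte(e$angle, crit$hbond_min_angle)

  # put the antecedent on the acceptor side: angle collapses below 90
  bad <- base
  bad[[1]]$atoms$CB <- c(1.4, 0.3, 0)
  st_bad <- rinens:::fx_state(bad)
  expect_equal(nrow(detect_hbond(st_bad, crit, chem)), 0)
})

test_that("helix hydrogen bonds equal the exhaustive rule scan", {
  hx <- make_ideal_helix(18)
  st <- hx$ensemble$states[[1]]
  e <- detect_hbond(st, crit, chem)
  expect_edges_match_oracle(e, oracle_hbond(st, crit, chem))
  # every alpha-helical (i, i+4) pair is present
  pairs <- paste(parse_residue_key(e$source)$number,
                 parse_residue_key(e$target)$number)
  for (k in seq_len(nrow(hx$truth$helical_pairs))) {
    expect_true(paste(hx$truth$helical_pairs[k, 1],
                      hx$truth$helical_pairs[k, 2]) %in% pairs)
  }
  # and the full set matches the fixture's ground truth
  expect_setequal(pairs, paste(hx$truth$hbond_pairs[, 1],
                               hx$truth$hbond_pairs[, 2]))
  # no pi or ionic edges on a backbone-only helix
  net <- detect_interactions(st, crit, chem)
  expect_equal(sum(net$edges$type %in%
                     c("IONIC", "PIPISTACK", "PICATION")), 0)
})

test_that("disulphides are detected and exempt from sequence separation", {
  cys_pair <- function(resno, d) {
    lapply(seq_along(resno), function(k)
      list(chain = "A", resno = resno[k], resname = "CYS", atoms = list(
        CA = c((k - 1) * d, 8, 0),
        CB = c((k - 1) * d, 1.8, 0),
        SG = c((k - 1) * d, 0, 0))))
  }
  st <- rinens:::fx_state(cys_pair(c(1, 2), 0.8 * crit$ssbond_max_ss))
  e <- detect_ssbond(st, crit, chem)
  expect_equal(nrow(e), 1)           # adjacent residues still bond
  expect_equal(e$source_atom, "SG")
  st_far <- rinens:::fx_state(cys_pair(c(1, 2), 2 * crit$ssbond_max_ss))
  expect_equal(nrow(detect_ssbond(st_far, crit, chem)), 0)
})

test_that("van der Waals contacts exclude hydrogen/ionic-explained pairs", {
  sb <- make_salt_bridge()$ensemble$states[[1]]
  net <- detect_interactions(sb, crit, chem)
  vdw_same_pair <- net$edges$type == "VDW" &
    net$edges$source == "A:1:LYS" & net$edges$target == "A:3:GLU"
  expect_equal(sum(vdw_same_pair), 0)
  # standalone detector computes its own exclusions identically
  expect_identical(detect_vdw(sb, crit, chem),
                   detect_vdw(sb, crit, chem, exclude_pairs = "A:1:LYS|A:3:GLU"))
})

test_that("sequence separation suppresses near-in-chain pairs", {
  near <- rinens:::salt_bridge_residues(c(0, 0, 0),
                                        0.85 * crit$ionic_max_dist,
                                        resno = c(1, 2))
  st <- rinens:::fx_state(near)
  expect_equal(nrow(detect_ionic(st, crit, chem)), 0)
  # same geometry across chains is allowed
  cross <- near
  cross[[2]]$chain <- "B"
  cross[[2]]$resno <- 1
  st2 <- rinens:::fx_state(cross)
  expect_equal(nrow(detect_ionic(st2, crit, chem)), 1)
})

test_that("every detector equals its exhaustive oracle on random decoys", {
  for (seed in 1:2) {
    st <- make_decoy_state(100, seed = 100 + seed)
    f <- rinens:::state_features(st, chem)
    of <- oracle_features(st, chem)
    expect_edges_match_oracle(detect_hbond(st, crit, chem, features = f),
                              oracle_hbond(st, crit, chem, of))
    expect_edges_match_oracle(detect_ionic(st, crit, chem, features = f),
                              oracle_ionic(st, crit, chem, of))
    expect_edges_match_oracle(detect_pipistack(st, crit, chem, features = f),
                              oracle_pipistack(st, crit, chem, of))
    expect_edges_match_oracle(detect_pication(st, crit, chem, features = f),
                              oracle_pication(st, crit, chem, of))
    expect_edges_match_oracle(detect_ssbond(st, crit, chem, features = f),
                              oracle_ssbond(st, crit, chem, of))
    expect_edges_match_oracle(detect_vdw(st, crit, chem, features = f),
                              oracle_vdw(st, crit, chem, of))
  }
})

test_that("edges are canonically oriented with no duplicates", {
  st <- make_decoy_state(80, seed = 21)
  e <- detect_interactions(st, crit, chem)$edges
  expect_true(all(rinens:::residue_key_lt(e$source, e$target)))
  expect_equal(anyDuplicated(paste(e$source, e$target, e$type)), 0)
  expect_true(all(e$distance > 0))
})

test_that("detection is invariant to atom input order", {
  st <- make_decoy_state(60, seed = 22)
  e1 <- detect_interactions(st, crit, chem)$edges
  set.seed(1)
  perm <- sample(nrow(st$atoms))
  st2 <- st
  st2$atoms <- st$atoms[perm, ]
  rownames(st2$atoms) <- NULL
  e2 <- detect_interactions(st2, crit, chem)$edges
  expect_identical(edge_set(e1), edge_set(e2))
})

test_that("enlarging a cutoff never removes edges of that type", {
  st <- make_decoy_state(80, seed = 23)
  for (field in c("ionic_max_dist", "pipi_max_centroid",
                  "pication_max_dist", "hbond_max_da")) {
    small <- crit
    big <- crit
    big[[field]] <- big[[field]] * 1.4
    es <- detect_interactions(st, small, chem)$edges
    eb <- detect_interactions(st, big, chem)$edges
    tp <- c(ionic_max_dist = "IONIC", pipi_max_centroid = "PIPISTACK",
            pication_max_dist = "PICATION", hbond_max_da = "HBOND")[[field]]
    id_s <- paste(es$source, es$target)[es$type == tp]
    id_b <- paste(eb$source, eb$target)[eb$type == tp]
    expect_true(all(id_s %in% id_b))
  }
})

test_that("multi-edge mode keeps every geometric instance", {
  # two rings on residue 1 (TRP-like would do); simpler: widen pipi
  # cutoff so both TRP rings of a decoy hit multiple partners
  st <- make_stacked_rings()$ensemble$states[[1]]
  multi <- geometric_criteria(multi_edge = TRUE)
  e1 <- detect_vdw(st, crit, chem)
  e2 <- detect_vdw(st, multi, chem)
  expect_gte(nrow(e2), nrow(e1))
  expect_equal(anyDuplicated(paste(e1$source, e1$target, e1$type)), 0)
})

test_that("filter_network splits scopes into a disjoint partition", {
  # 2-chain fixture: inter-chain ionic + intra-chain helix hydrogen bonds
  helix_res <- lapply(seq_len(8), function(i) {
    bb <- rinens:::build_backbone(8, -57, -47)
    list(chain = "A", resno = i, resname = "ALA", atoms = bb[[i]])
  })
  bridge <- rinens:::salt_bridge_residues(c(40, 0, 0),
                                          0.85 * crit$ionic_max_dist)
  bridge[[1]]$chain <- "A"; bridge[[1]]$resno <- 9
  bridge[[2]]$chain <- "B"; bridge[[2]]$resno <- 1
  st <- rinens:::fx_state(c(helix_res, bridge))
  net <- detect_interactions(st, crit, chem)

  inter <- filter_network(net, "inter_chain")
  intra <- filter_network(net, "intra_chain")
  expect_equal(nrow(inter$edges), 1)
  expect_equal(inter$edges$type, "IONIC")
  expect_equal(nrow(inter$edges) + nrow(intra$edges), nrow(net$edges))
  expect_length(intersect(paste(inter$edges$source, inter$edges$target),
                          paste(intra$edges$source, intra$edges$target)), 0)
  # nodes pruned to endpoints
  expect_setequal(inter$nodes, c(inter$edges$source, inter$edges$target))

  none <- filter_network(net, types = "PIPISTACK")
  expect_equal(nrow(none$edges), 0)
  expect_length(none$nodes, 0)
})

test_that("ensemble detection equals independent per-state detection", {
  sb <- make_salt_bridge(n_states = 3)$ensemble
  # break the bridge in state 2 by moving the glutamate away
  glu <- sb$states[[2]]$atoms$resname == "GLU"
  sb$states[[2]]$atoms$x[glu] <- sb$states[[2]]$atoms$x[glu] + 8
  nets <- network_for_ensemble(sb, crit, chem)
  expect_length(nets, 3)
  ionic_per_state <- vapply(nets, function(n)
    sum(n$edges$type == "IONIC"), integer(1))
  expect_equal(ionic_per_state, c(1L, 0L, 1L))
  for (k in 1:3) {
    solo <- detect_interactions(sb$states[[k]], crit, chem)
    expect_identical(edge_set(nets[[k]]$edges), edge_set(solo$edges))
    expect_equal(nets[[k]]$state_index, k - 1L)
  }
})

test_that("unknown residues warn once and stay vdW-only", {
  st <- make_salt_bridge()$ensemble$states[[1]]
  st$atoms$resname[st$atoms$resname == "LYS"] <- "XYZ"
  st$atoms$polymer_class <- rinens:::polymer_class_of(st$atoms$resname)
  expect_warning(net <- detect_interactions(st, crit, chem,
                                            warn_unknown = TRUE), "XYZ")
  expect_equal(sum(net$edges$type == "IONIC"), 0)
})
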