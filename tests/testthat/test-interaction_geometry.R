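test_that("ring templates find protein aromatic rings", {
  fx <- make_interaction_fixture("pi_pi_parallel")
  rings <- detect_rings(fx$positive$receptor)
  expect_length(rings, 1)
  expect_equal(length(rings[[1]]$members), 6)
  expect_equal(sqrt(sum(rings[[1]]$normal^2)), 1, tolerance = 1e-9)
  expect_lt(rings[[1]]$planarity, 0.3)
})

test_that("cycle perception finds 2 aromatic rings, 3 with the gallate", {
  lig <- make_toy_ligand()
  rings <- detect_rings(lig$structure, connectivity = lig$connectivity)
  expect_length(rings, 2)
  ligg <- make_toy_ligand(gallate = TRUE)
  ringsg <- detect_rings(ligg$structure, connectivity = ligg$connectivity)
  expect_length(ringsg, 3)
  # the annotation route agrees with perception
  ann <- detect_rings(lig$structure, ligand_rings = lig$rings)
  expect_length(ann, 2)
})

test_that("a ring with one atom lifted 1 A fails the planarity tolerance", {
  fx <- make_interaction_fixture("pi_pi_parallel")
  lig <- fx$positive$ligand
  lig$atom$z[3] <- lig$atom$z[3] + 1
  expect_length(detect_rings(lig, ligand_rings = list(1:6)), 0)
  expect_error(detect_rings(lig, ligand_rings = list(c("C1", "C9"))),
               "absent")
})

test_that("each interaction kind is detected by its own classifier only", {
  crit <- interaction_criteria()
  classify_case <- function(case, kind) {
    # apply every classifier to the fixture and collect which fire
    fired <- character(0)
    prings <- detect_rings(case$receptor)
    lrings <- if (!is.null(case$rings))
      detect_rings(case$ligand, ligand_rings = case$rings) else list()
    if (length(prings) == 1 && length(lrings) == 1) {
      rec <- classify_aromatic(prings[[1]], lrings[[1]], crit)
      if (!is.null(rec)) fired <- c(fired, rec$kind)
    }
    if (!is.null(case$x_idx) && length(prings) == 1) {
      rec <- classify_xh_pi(coords(case$ligand)[case$x_idx, ],
                            coords(case$ligand)[case$h_idx, ],
                            case$ligand$atom$element[case$x_idx],
                            prings[[1]], crit)
      if (!is.null(rec)) fired <- c(fired, rec$kind)
    }
    if (!is.null(case$a_idx) && length(prings) == 1) {
      rec <- classify_lonepair_pi(coords(case$ligand)[case$a_idx, ],
                                  case$ligand$atom$element[case$a_idx],
                                  prings[[1]], crit)
      if (!is.null(rec)) fired <- c(fired, rec$kind)
    }
    if (!is.null(case$sites_receptor)) {
      hb <- detect_hbonds(case$receptor, case$ligand, case$sites_receptor,
                          case$sites_ligand, crit)
      if (nrow(hb) > 0) fired <- c(fired, "hbond")
    }
    fired
  }
  kinds <- c("pi_pi_parallel", "pi_pi_tshaped", "xh_pi", "lonepair_pi",
             "hbond")
  for (kind in kinds) {
    fx <- make_interaction_fixture(kind)
    expect_equal(classify_case(fx$positive, kind), kind, info = kind)
    expect_length(classify_case(fx$negative, kind), 0)
  }
})

test_that("aromatic classification thresholds behave geometrically", {
  fx1 <- make_interaction_fixture("pi_pi_parallel")$positive
  r1 <- detect_rings(fx1$receptor)[[1]]
  r2 <- detect_rings(fx1$ligand, ligand_rings = list(1:6))[[1]]
  rec <- classify_aromatic(r1, r2)
  expect_equal(rec$kind, "pi_pi_parallel")
  expect_equal(rec$d, 3.5, tolerance = 1e-6)
  expect_lt(rec$alpha, 1e-6)
  # far apart: nothing
  far <- r2; far$centroid <- r2$centroid + c(0, 0, 4.5)
  expect_null(classify_aromatic(r1, far))
})

test_that("XH-pi projection geometry: lateral displacement rejects", {
  fx <- make_interaction_fixture("xh_pi")$positive
  ring <- detect_rings(fx$receptor)[[1]]
  # H directly above centroid at 2.6 A: fires
  expect_equal(classify_xh_pi(c(0, 0, 3.69), c(0, 0, 2.6), "C", ring)$kind,
               "xh_pi")
  # H displaced laterally: within distance, but the in-plane projection
  # leaves ring radius + slack
  expect_null(classify_xh_pi(c(2, 0, 3.2), c(2, 0, 2.1), "C", ring))
  # and far lateral displacement fails the distance cutoff itself
  expect_null(classify_xh_pi(c(3, 0, 3.1), c(3, 0, 2.0), "C", ring))
  # O-H accepted like C-H; silicon rejected
  expect_equal(classify_xh_pi(c(0, 0, 3.56), c(0, 0, 2.6), "O", ring)$kind,
               "xh_pi")
  expect_error(classify_xh_pi(c(0, 0, 3.56), c(0, 0, 2.6), "Si", ring),
               "must be C, N or O")
})

test_that("lone-pair-pi requires the acceptor near the ring axis", {
  ring <- detect_rings(make_interaction_fixture("lonepair_pi")$positive$receptor)[[1]]
  expect_equal(classify_lonepair_pi(c(0, 0, 3.0), "O", ring)$kind,
               "lonepair_pi")
  expect_null(classify_lonepair_pi(c(0, 0, 4.5), "O", ring))
  # 45 degrees off-axis at the same distance: rejected
  expect_null(classify_lonepair_pi(c(2.12, 0, 2.12), "O", ring))
  # random placements match a brute-force criteria scan
  crit <- interaction_criteria()
  set.seed(77)
  for (i in 1:30) {
    p <- runif(3, -4, 4)
    got <- classify_lonepair_pi(p, "O", ring, crit)
    d <- sqrt(sum((p - ring$centroid)^2))
    ang <- acos(min(1, abs(sum((p - ring$centroid) * ring$normal)) /
                      max(d, 1e-12))) * 180 / pi
    want <- d <= crit$lp_d_max && ang <= crit$lp_axis_max
    expect_equal(!is.null(got), want)
  }
})

test_that("hydrogen bonds obey distance and angle criteria inclusively", {
  fx <- make_interaction_fixture("hbond")
  hb <- detect_hbonds(fx$positive$receptor, fx$positive$ligand,
                      fx$positive$sites_receptor, fx$positive$sites_ligand)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  # boundary case: D...A exactly at d_max is kept
  bd <- fx$positive
  bd$ligand$atom$z <- 3.5
  expect_equal(nrow(detect_hbonds(bd$receptor, bd$ligand, bd$sites_receptor,
                                  bd$sites_ligand)), 1)
  # 3.6 A: rejected
  expect_equal(nrow(detect_hbonds(fx$negative$receptor, fx$negative$ligand,
                                  fx$negative$sites_receptor,
                                  fx$negative$sites_ligand)), 0)
})

test_that("hbond detection matches a brute-force scan on random sites", {
  crit <- interaction_criteria()
  for (seed in 1:50) {
    set.seed(seed)
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    xa <- matrix(runif(3 * (2 * na), -4, 4), ncol = 3)
    xb <- matrix(runif(3 * nb, -4, 4), ncol = 3)
    at_a <- data.frame(serial = seq_len(2 * na),
                       name = paste0("O", seq_len(2 * na)),
                       element = rep(c("O", "H"), na),
                       resid = "SER", resno = rep(seq_len(na), each = 2),
                       ins = " ", chain = "A",
                       x = xa[, 1], y = xa[, 2], z = xa[, 3],
                       stringsAsFactors = FALSE)
    at_b <- data.frame(serial = seq_len(nb), name = paste0("O", seq_len(nb)),
                       element = "O", resid = "LIG", resno = 1L, ins = " ",
                       chain = "L", x = xb[, 1], y = xb[, 2], z = xb[, 3],
                       stringsAsFactors = FALSE)
    sa <- ens_structure(at_a, "a"); sb <- ens_structure(at_b, "b")
    sites_a <- hbond_sites(data.frame(donor = seq(1, 2 * na, 2),
                                      h = seq(2, 2 * na, 2)), integer(0))
    sites_b <- hbond_sites(NULL, seq_len(nb))
    hb <- detect_hbonds(sa, sb, sites_a, sites_b, crit)
    # brute force over donor/acceptor pairs
    want <- 0L
    for (di in seq(1, 2 * na, 2)) for (ai in seq_len(nb)) {
      d <- sqrt(sum((xa[di, ] - xb[ai, ])^2))
      h <- xa[di + 1, ]
      v1 <- xa[di, ] - h; v2 <- xb[ai, ] - h
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (d <= crit$hbond_d_max && d > 1e-6 && ang >= crit$hbond_theta_min)
        want <- want + 1L
    }
    expect_equal(nrow(hb), want, info = paste("seed", seed))
  }
})

test_that("hbond roles are symmetric under molecule swap", {
  fx <- make_interaction_fixture("hbond")$positive
  hb1 <- detect_hbonds(fx$receptor, fx$ligand, fx$sites_receptor,
                       fx$sites_ligand)
  hb2 <- detect_hbonds(fx$ligand, fx$receptor, fx$sites_ligand,
                       fx$sites_receptor)
  expect_equal(nrow(hb1), nrow(hb2))
  expect_equal(hb1$distance, hb2$distance)
  expect_equal(hb1$donor_mol, "a")
  expect_equal(hb2$donor_mol, "b")
})

test_that("a donor without hydrogen errors unless distance-only", {
  fx <- make_interaction_fixture("hbond")$positive
  sites_noH <- hbond_sites(data.frame(donor = 1L, h = NA_integer_),
                           integer(0))
  expect_error(detect_hbonds(fx$receptor, fx$ligand, sites_noH,
                             fx$sites_ligand), "no hydrogen")
  hb <- detect_hbonds(fx$receptor, fx$ligand, sites_noH, fx$sites_ligand,
                      distance_only = TRUE)
  expect_equal(nrow(hb), 1)
  expect_true(is.na(hb$angle))
})

test_that("classification is invariant under rigid motion", {
  set.seed(123)
  kinds <- c("pi_pi_parallel", "pi_pi_tshaped", "lonepair_pi")
  for (kind in kinds) {
    fx <- make_interaction_fixture(kind)$positive
    r1 <- detect_rings(fx$receptor)[[1]]
    geom0 <- if (kind == "lonepair_pi")
      classify_lonepair_pi(coords(fx$ligand)[fx$a_idx, ],
                           "O", r1)
    else classify_aromatic(r1, detect_rings(fx$ligand,
                                            ligand_rings = fx$rings)[[1]])
    for (rep in 1:5) {
      rot <- matrix(c(qr.Q(qr(matrix(rnorm(9), 3)))), 3)
      if (det(rot) < 0) rot[, 1] <- -rot[, 1]
      shift <- runif(3, -20, 20)
      move <- function(s) {
        set_coords(s, sweep(coords(s) %*% t(rot), 2, shift, "+"))
      }
      rr <- detect_rings(move(fx$receptor))[[1]]
      geom <- if (kind == "lonepair_pi") {
        a <- as.numeric(coords(move(fx$ligand))[fx$a_idx, ])
        classify_lonepair_pi(a, "O", rr)
      } else {
        classify_aromatic(rr, detect_rings(move(fx$ligand),
                                           ligand_rings = fx$rings)[[1]])
      }
      expect_equal(geom$kind, geom0$kind)
      expect_equal(geom$d, geom0$d, tolerance = 1e-6)
    }
  }
})

test_that("every emitted record re-satisfies its thresholds (audit)", {
  crit <- interaction_criteria()
  records <- list()
  for (kind in c("pi_pi_parallel", "pi_pi_tshaped", "xh_pi", "lonepair_pi")) {
    fx <- make_interaction_fixture(kind)$positive
    ring <- detect_rings(fx$receptor)[[1]]
    rec <- switch(kind,
      pi_pi_parallel = ,
      pi_pi_tshaped = classify_aromatic(
        ring, detect_rings(fx$ligand, ligand_rings = fx$rings)[[1]], crit),
      xh_pi = classify_xh_pi(coords(fx$ligand)[fx$x_idx, ],
                             coords(fx$ligand)[fx$h_idx, ], "C", ring, crit),
      lonepair_pi = classify_lonepair_pi(coords(fx$ligand)[fx$a_idx, ], "O",
                                         ring, crit))
    records[[length(records) + 1]] <- rec
  }
  fxh <- make_interaction_fixture("hbond")$positive
  hb <- detect_hbonds(fxh$receptor, fxh$ligand, fxh$sites_receptor,
                      fxh$sites_ligand, crit)
  records <- c(records, split(hb, seq_len(nrow(hb))))
  expect_true(all(audit_interactions(records, crit)))
})

test_that("contacts at 5 A are a superset of classified interactions", {
  # cross-module property: wherever a classifier fires, the participating
  # residue is a binding residue at the 5.0 A contact cutoff
  for (kind in c("pi_pi_parallel", "pi_pi_tshaped", "xh_pi", "lonepair_pi",
                 "hbond")) {
    fx <- make_interaction_fixture(kind)$positive
    lig_atoms <- fx$ligand$atom
    br <- binding_residues(fx$receptor, list(atoms = lig_atoms), 5.0)
    expect_gte(length(br), 1)
  }
})
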