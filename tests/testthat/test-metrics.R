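test_that("geometric helicity calibrates to the ideal and extended limits", {
  expect_equal(attr(assign_helicity(build_ideal_helix(10)), "fraction"), 1)
  expect_equal(attr(assign_helicity(build_extended_chain(10)), "fraction"), 0)
  a <- assign_helicity(build_ideal_helix(10))
  expect_equal(sum(a$assignable), 7)          # residues 2..8
  expect_true(all(is.na(a$helical[c(1, 9, 10)])))
})

test_that("helicity flags match a manual evaluation of the two geometric tests", {
  cf <- random_chain(6, seed = 77)
  X <- cf$coords
  a <- assign_helicity(cf)
  for (j in 2:4) {
    dih <- dihedral_oracle(X, j - 1) * 180 / pi
    ok <- dih >= 30 && dih <= 80
    if (j + 3 <= 6) {
      d <- sqrt(sum((X[j, ] - X[j + 3, ])^2))
      ok <- ok && d >= 0.44 && d <= 0.56
    }
    expect_identical(a$helical[j], ok)
  }
})

test_that("helicity-vs-R curve finds the 50% crossing", {
  params <- model_parameters(helix_bias = 3.5, contact_strength = 0.5,
                             n_residues = 10)
  ws <- run_hremd(params, build_windows(12, 0, 0.5, 1000), n_steps = 1500,
                  exchange_interval = 250, seed = 12, record_every = 2)
  hv <- helicity_vs_R(ws)
  # near-monotone decay: allow single-bin noise violations
  h <- hv$mean_helicity[hv$n > 30]
  violations <- sum(diff(h) > 0.02)
  expect_lte(violations, 1)
  cr <- attr(hv, "crossing")
  expect_false(is.na(cr))
  # crossing agrees with a brute-force scan over the binned curve
  below <- which(hv$mean_helicity < 0.5)[1]
  expect_gte(cr, hv$R[below - 1])
  expect_lte(cr, hv$R[below])
})

test_that("crossing detection handles step and degenerate curves", {
  bw <- 0.02
  R <- seq(0.01, 0.39, by = bw)
  # step function: helicity 1 below R = 0.1, 0 above
  h_step <- as.numeric(R < 0.1)
  cr <- helixscan:::crossing_50(R, h_step)
  expect_gte(cr, 0.1 - bw)
  expect_lte(cr, 0.1 + bw)
  # no crossing in range
  expect_true(is.na(helixscan:::crossing_50(R, rep(0.9, length(R)))))
  # crossing equals a brute-force scan on a noisy decaying curve
  set.seed(5)
  h <- pmin(1, pmax(0, 1 - 2.2 * R + rnorm(length(R), 0, 0.02)))
  cr2 <- helixscan:::crossing_50(R, h)
  i <- which(h < 0.5)[1]
  expect_gte(cr2, R[i - 1])
  expect_lte(cr2, R[i])
})

test_that("radius of gyration matches its definition", {
  one <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(sqrt(mean(rowSums(sweep(one, 2, colMeans(one))^2))), 0)
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(sqrt(mean(rowSums(sweep(two, 2, colMeans(two))^2))), 0.5)
  cf <- random_chain(10, seed = 14)
  X <- cf$coords
  oracle <- sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
  expect_equal(radius_of_gyration(cf), oracle, tolerance = 1e-12)
})

test_that("H-bond surrogate counts i,i+4+ contacts inside 0.62 nm", {
  expect_equal(count_hbond_surrogate(build_extended_chain(10)), 0)
  # ideal helix: every i,i+4 pair sits just inside the cutoff -> n - 4
  expect_equal(count_hbond_surrogate(build_ideal_helix(10)), 6)
  X <- build_ideal_helix(10)$coords
  d4 <- sqrt(sum((X[1, ] - X[5, ])^2))
  d5 <- sqrt(sum((X[1, ] - X[6, ])^2))
  expect_lt(d4, 0.62)
  expect_gt(d5, 0.62)
  for (s in 1:3) {
    cf <- random_chain(12, seed = s)
    # double-loop oracle
    cnt <- 0
    for (i in 1:12) for (j in 1:12) {
      if (j >= i + 4 && sqrt(sum((cf$coords[i, ] - cf$coords[j, ])^2)) < 0.62) cnt <- cnt + 1
    }
    expect_equal(count_hbond_surrogate(cf), cnt)
  }
})

test_that("Kabsch RMSD is zero under rigid motion and positive for mirrors", {
  cf <- random_chain(10, seed = 19)
  for (s in 1:4) expect_lt(kabsch_rmsd(cf, rigid_motion(cf, s)), 1e-9)
  mirror <- cf$coords %*% diag(c(-1, 1, 1))
  expect_gt(kabsch_rmsd(cf, chain_conformation(mirror)), 1e-3)
  expect_error(kabsch_rmsd(build_ideal_helix(5), build_ideal_helix(6)),
               class = "helixscan_shape_error")
})

test_that("Kabsch RMSD agrees with a rotation-grid search on 4-point toys", {
  set.seed(23)
  A <- matrix(rnorm(12, sd = 0.3), 4, 3)
  B <- matrix(rnorm(12, sd = 0.3), 4, 3)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rot <- function(a, b, c) {
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
    Rz1 %*% Ry %*% Rz2
  }
  grid <- seq(0, 2 * pi, length.out = 60)
  bgrid <- seq(0, pi, length.out = 30)
  best <- Inf
  for (a in grid) for (b in bgrid) for (c in grid) {
    r <- sqrt(mean(rowSums((Ac %*% rot(a, b, c) - Bc)^2)))
    if (r < best) best <- r
  }
  # the true minimum can only undercut the finite grid's best
  r <- kabsch_rmsd(A, B)
  expect_lte(r, best + 1e-9)
  expect_lt(best - r, 2e-3)
})

test_that("Daura clustering matches exhaustive brute force on small sets", {
  set.seed(31)
  structures <- c(
    lapply(1:10, function(i) jitter_conf(build_ideal_helix(8), 0.01, i)),
    lapply(1:10, function(i) jitter_conf(build_extended_chain(8), 0.01, 100 + i)),
    lapply(1:8, function(i) random_chain(8, seed = 200 + i))
  )
  cl <- daura_cluster(structures, cutoff = 0.1)
  oracle <- daura_oracle(structures, 0.1)
  # same partition up to label permutation
  expect_equal(length(unique(cl$membership$cluster)), length(unique(oracle)))
  tab <- table(cl$membership$cluster, oracle)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  # sizes non-increasing; union covers everything; clusters disjoint
  expect_true(all(diff(cl$clusters$size) <= 0))
  expect_setequal(cl$membership$structure, seq_along(structures))
})

test_that("Daura clustering limits: identical and well-separated bundles", {
  same <- lapply(1:6, function(i) build_ideal_helix(8))
  cl <- daura_cluster(same, cutoff = 0.05)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$size, 6)
  bundles <- c(lapply(1:5, function(i) jitter_conf(build_ideal_helix(8), 0.005, i)),
               lapply(1:5, function(i) jitter_conf(build_extended_chain(8), 0.005, i)))
  cl2 <- daura_cluster(bundles, cutoff = 0.1)
  expect_equal(nrow(cl2$clusters), 2)
  # deterministic and permutation-stable up to the documented tie-break
  cl3 <- daura_cluster(bundles, cutoff = 0.1)
  expect_identical(cl2$membership, cl3$membership)
  # cluster count is non-increasing in cutoff
  counts <- vapply(c(0.02, 0.1, 0.5),
                   function(ct) nrow(daura_cluster(bundles, ct)$clusters),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("dominance analysis applies the 80% / 1% / >100 rules", {
  mk_cluster_set <- function(sizes, labellers) {
    membership <- purrr::map2_dfr(seq_along(sizes), labellers, function(k, lab) {
      tibble::tibble(structure = 0L, cluster = k, is_center = FALSE, label = lab)
    })
    membership$structure <- seq_len(nrow(membership))
    structure(list(membership = membership,
                   clusters = tibble::tibble(cluster = seq_along(sizes),
                                             center = 1L, size = sizes),
                   cutoff = 0.1), class = "cluster_set")
  }
  cs <- mk_cluster_set(
    sizes = c(200, 200, 100),
    labellers = list(c(rep("A", 170), rep("B", 30)),
                     c(rep("A", 99), rep("B", 100), "C"),
                     c(rep("A", 50), rep("B", 50))))
  dom <- dominance_analysis(cs, min_size = 100)
  # cluster 3 has exactly 100 structures: excluded by the strict rule
  expect_setequal(unique(dom$cluster), c(1, 2))
  expect_equal(dom$status[dom$cluster == 1 & dom$variant == "A"], "dominated")  # 85%
  expect_equal(dom$status[dom$cluster == 2 & dom$variant == "C"], "neglected")  # 0.5%
  expect_equal(dom$status[dom$cluster == 1 & dom$variant == "B"], "neutral")
  # shares sum to one within each cluster
  sums <- tapply(dom$share, dom$cluster, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-12)
  expect_error(dominance_analysis(mk_cluster_set(5, list(rep("A", 5)))),
               class = "helixscan_invalid_config")
})
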