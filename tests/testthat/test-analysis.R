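test_that("clustering handles degenerate and well-separated inputs", {
  # all points identical -> one cluster with every strided frame
  fr <- planted_frames(rep(c(1, 2, 3), 30))
  cl <- cluster_frames(fr, stride = 1, cutoff = 5)
  expect_length(cl$clusters, 1L)
  expect_equal(cl$clusters[[1]]$size, 30L)
  # two tight groups 20 A apart -> exactly two clusters, correct members
  pts <- rbind(matrix(rnorm(15, sd = 0.5), 5, 3),
               matrix(rnorm(15, sd = 0.5) + 20, 5, 3))
  fr2 <- planted_frames(pts)
  cl2 <- cluster_frames(fr2, stride = 1, cutoff = 5)
  expect_length(cl2$clusters, 2L)
  got <- lapply(cl2$clusters, function(c0) sort(c0$members))
  expect_setequal(unlist(got[[1]]), if (6 %in% got[[1]]) 6:10 else 1:5)
  expect_equal(sort(unlist(got)), 1:10)
  expect_error(cluster_frames(fr[0, ]), class = "ligmig_domain_error")
})

test_that("striding keeps every nth frame and caps cluster count", {
  fr <- planted_frames(rep(0, 300))   # 100 identical points
  cl <- cluster_frames(fr, stride = 10, cutoff = 5)
  expect_equal(nrow(cl$frames), 10L)
  expect_equal(cl$clusters[[1]]$size, 10L)
  # with an infinite cutoff a single cluster holds everything
  spread <- planted_frames(rnorm(90, sd = 50))
  cl2 <- cluster_frames(spread, stride = 1, cutoff = Inf)
  expect_length(cl2$clusters, 1L)
  expect_equal(cl2$clusters[[1]]$size, 30L)
  # sum of cluster sizes never exceeds the strided frame count
  cl3 <- cluster_frames(spread, stride = 1, cutoff = 5, max_clusters = 3)
  expect_lte(sum(vapply(cl3$clusters, function(c0) c0$size, numeric(1))), 30)
})

test_that("greedy clustering matches the brute-force oracle", {
  set.seed(31)
  for (case in 1:10) {
    pts <- matrix(runif(36, 0, 20), 12, 3)
    fr <- planted_frames(pts)
    cl <- cluster_frames(fr, stride = 1, cutoff = 6, max_clusters = 10)
    want <- oracle_qt_cluster(pts, cutoff = 6, max_clusters = 10)
    got <- integer(12)
    for (i in seq_along(cl$clusters)) got[cl$clusters[[i]]$members] <- i
    # same partition up to rank order (ranks are size-sorted afterwards)
    expect_equal(got > 0, want > 0)
    for (k in unique(want[want > 0]))
      expect_length(unique(got[want == k]), 1L)
  }
})

test_that("clusters are ranked by size with stable tie-breaking", {
  # 3 + 2 + 2 points; the two size-2 clusters tie, first-occurrence first
  pts <- rbind(matrix(0, 3, 3), matrix(30, 2, 3), matrix(60, 2, 3))
  fr <- planted_frames(pts)
  cl <- cluster_frames(fr, stride = 1, cutoff = 3)
  sizes <- vapply(cl$clusters, function(c0) c0$size, numeric(1))
  expect_equal(sizes, c(3, 2, 2))
  expect_lt(min(cl$clusters[[2]]$members), min(cl$clusters[[3]]$members))
})

test_that("cluster assignment picks the nearer receptor with a tie rule", {
  sys <- list(receptor_a = toy_structure(c(0, 0, 0)),
              receptor_b = toy_structure(c(90, 0, 0)))
  class(sys) <- "ligmig_system"
  # pairs of points at each site (singletons never form clusters)
  fr <- planted_frames(c(10, 0, 0, 10, 0, 0, 80, 0, 0, 80, 0, 0,
                         45, 0, 0, 45, 0, 0))
  cl <- cluster_frames(fr, stride = 1, cutoff = 3)
  cl <- assign_clusters(cl, sys)
  assign <- vapply(cl$clusters, function(c0) c0$receptor_assignment,
                   character(1))
  cent <- vapply(cl$clusters, function(c0) c0$centroid[1], numeric(1))
  expect_identical(assign[cent == 10], "a")
  expect_identical(assign[cent == 80], "b")
  expect_identical(assign[cent == 45], "unassigned")  # exactly equidistant
})

test_that("planted two-receptor frames reconstruct their design counts", {
  sys <- list(receptor_a = toy_structure(c(0, 0, 0)),
              receptor_b = toy_structure(c(50, 0, 0)))
  class(sys) <- "ligmig_system"
  # 12 frames near receptor a in two groups, 18 near receptor b in one
  set.seed(4)
  pts <- rbind(matrix(rnorm(21, sd = 0.5), 7, 3),
               sweep(matrix(rnorm(15, sd = 0.5), 5, 3), 2, c(0, 12, 0), "-"),
               sweep(matrix(rnorm(54, sd = 0.5), 18, 3), 2, c(50, 0, 0), "+"))
  fr <- planted_frames(pts)
  cl <- assign_clusters(cluster_frames(fr, stride = 1, cutoff = 5), sys)
  p <- preference(cl)
  expect_equal(p$counts_a, 12)
  expect_equal(p$counts_b, 18)
  expect_equal(p$total, 30)
  expect_equal(p$preference_b_percent, 60)
})

test_that("preference reproduces the published per-cluster arithmetic", {
  # per-protein cluster counts of the four competitive runs
  expect_equal(preference(c(63, 40, 37, 35, 32),
                          c(210, 44, 41, 35, 30))$preference_b_percent, 64)
  expect_equal(preference(c(105, 101, 74, 71),
                          c(210, 181, 131, 117, 68, 68))$preference_b_percent,
               69)
  expect_equal(preference(c(58, 53, 51),
                          c(163, 153, 126, 125, 91, 74, 53))$preference_b_percent,
               83)
  expect_equal(preference(c(126, 77, 71),
                          c(170, 144, 140, 132, 78, 74, 74))$preference_b_percent,
               75)
})

test_that("preference obeys its symmetry and range invariants", {
  expect_equal(preference(numeric(0), c(5, 3))$preference_b_percent, 100)
  expect_equal(preference(c(4, 4), c(4, 4))$preference_b_percent, 50)
  expect_error(preference(numeric(0), numeric(0)),
               class = "ligmig_domain_error")
  set.seed(12)
  for (i in 1:20) {
    a <- sample.int(200, sample.int(5, 1))
    b <- sample.int(200, sample.int(5, 1))
    pab <- preference(a, b)$preference_b_percent
    pba <- preference(b, a)$preference_b_percent
    expect_lte(abs(pab + pba - 100), 1)   # complement up to rounding
    expect_gte(pab, 0); expect_lte(pab, 100)
  }
})

test_that("COM-distance traces track the stored frame order", {
  sys <- standard_fixture(seed = 8)
  tr <- run_chain(sys, 1, mc_config(steps = 120, seed = 3), chain_id = 1)
  expect_equal(com_distance_trace(tr, "a"), tr$frames$dist_a)
  expect_equal(com_distance_trace(tr, "b"), tr$frames$dist_b)
  expect_error(com_distance_trace(tr, "c"), class = "ligmig_domain_error")
  expect_true(all(com_distance_trace(tr, "a") >= 0))
})

test_that("rmsd follows its closed forms with and without superposition", {
  set.seed(6)
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(rmsd_to_reference(x, x), 0)
  shifted <- sweep(x, 2, c(2, 0, 0), "+")
  expect_equal(rmsd_to_reference(shifted, x), 2.0, tolerance = 1e-12)
  expect_equal(rmsd_to_reference(shifted, x, superpose_first = TRUE), 0,
               tolerance = 1e-9)
  expect_error(rmsd_to_reference(x[1:3, ], x), class = "ligmig_domain_error")
})

test_that("scatter export applies the distance and energy cutoffs", {
  fr <- planted_frames(c(0, 0, 0, 1, 0, 0, 2, 0, 0))
  fr$dist_a <- c(20, 150, 30)
  fr$e_interaction <- c(-5, -5, 2)
  f <- withr::local_tempfile(fileext = ".csv")
  out <- export_scatter(fr, "a", f)
  expect_equal(nrow(out), 1L)   # one too far, one at positive energy
  back <- read.csv(f)
  expect_identical(names(back),
                   c("chain", "step", "distance_A", "energy_kcal_mol"))
  expect_equal(nrow(back), nrow(out))
  expect_equal(back$distance_A, 20)
})
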