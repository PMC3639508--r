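test_that("spot classification partitions singles, intermediates and clusters", {
  sp <- tibble::tibble(intensity_au = c(0.9, 1.2, 1.7, 3.2, 5.9))
  cl <- classify_spots(sp)
  expect_equal(cl$singles, 2)
  expect_equal(cl$intermediate, 1)
  expect_equal(cl$clusters, 2)
  expect_equal(cl$clusters_pooled, 3)
  expect_equal(cl$singles + cl$intermediate + cl$clusters, cl$total)
  expect_error(classifier_params(single_max_au = 3, cluster_min_au = 2))

  # partition property on random inputs
  set.seed(31)
  for (r in 1:20) {
    au <- runif(50, 0, 8)
    cc <- classify_spots(tibble::tibble(intensity_au = au))
    expect_equal(cc$singles + cc$intermediate + cc$clusters, 50)
  }
})

test_that("planted multiplicities classify correctly at low noise", {
  p <- make_preset("cluster_WT_20uM",
    overrides = list(n_docked = 150, clustering_efficiency = 150,
                     large_aggregate_rate = 0,
                     optics = list(field_size_px = 256L)))
  m <- render_movie(p, seed = 32)
  gt <- ground_truth(m)
  sp <- normalize_au(detect_spots(m[, , 1], psf_sigma_px = 1.5))
  # match detections to planted truth and compare single-vs-cluster calls
  agree <- 0; matched <- 0
  for (i in seq_len(nrow(sp))) {
    d <- sqrt((gt$x - sp$x[i])^2 + (gt$y - sp$y[i])^2)
    j <- which.min(d)
    if (d[j] < 2) {
      matched <- matched + 1
      call_cluster <- sp$intensity_au[i] >= 1.5
      if (call_cluster == (gt$k[j] >= 2)) agree <- agree + 1
    }
  }
  expect_gte(matched / nrow(gt), 0.98)
  expect_gte(agree / matched, 0.95)
})

test_that("surface homogeneity separates uniform from half-dark fields", {
  expect_equal(surface_homogeneity(matrix(10, 256, 256), 64L)$cv, 0)
  half <- cbind(matrix(0, 256, 128), matrix(10, 256, 128))
  hh <- surface_homogeneity(half, 64L)
  expect_gt(hh$cv, 0.9)
  expect_false(hh$pass)
  expect_error(surface_homogeneity(matrix(1, 32, 32), 64L), "two blocks")

  sat <- render_movie(make_preset("saturated_surface"), seed = 33)
  expect_true(surface_homogeneity(sat[, , 1])$pass)
})

test_that("students_t matches the pooled-variance formula and reference CDF", {
  r <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.02131, tolerance = 1e-3)

  # identical samples: the null case
  r0 <- students_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # symmetry: swapping flips t, keeps p
  rs <- students_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rs$t, -r$t)
  expect_equal(rs$p, r$p)

  # degenerate: zero variance, unequal means
  expect_warning(rd <- students_t(c(1, 1), c(2, 2)), "undefined")
  expect_true(rd$degenerate)

  # agreement with the independent reference implementation over random cases
  set.seed(34)
  for (r_i in 1:25) {
    a <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
    mine <- students_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  }
})

test_that("finite-volume depletion divides the vesicle budget by mean cluster size", {
  expect_equal(depletion_spot_count(1000, c(1, 0, 0)), 1000)
  expect_equal(depletion_spot_count(1000, c(0, 1, 0)), 500)
  # strictly antitone in E[k], scale-equivariant in the budget
  laws <- lapply(c(1.2, 1.8, 2.5), cluster_law_geometric)
  counts <- vapply(laws, function(l) depletion_spot_count(1000, l), numeric(1))
  expect_true(all(diff(counts) < 0))
  expect_true(all(counts < 1000))
  expect_equal(depletion_spot_count(3000, laws[[2]]),
               3 * depletion_spot_count(1000, laws[[2]]))
  expect_error(depletion_spot_count(1000, c(0.5, 0.4)), "sum")
})

test_that("anticorrelation report computes Spearman rho over paired conditions", {
  cl <- tibble::tibble(condition = c("WT", "A30P", "none"), mean = c(30, 15, 5))
  as_ <- tibble::tibble(condition = c("WT", "A30P", "none"), mean = c(10, 20, 30))
  rep1 <- anticorrelation_report(cl, as_)
  expect_equal(rep1$spearman_rho, -1)
  expect_equal(anticorrelation_report(cl, cl)$spearman_rho, 1)
  expect_error(anticorrelation_report(cl, as_[1:2, ]), "condition sets")
})

test_that("flotation percent bound is the top-two fraction share", {
  expect_equal(flotation_percent_bound(c(30, 20, 10, 10, 10, 10, 5, 5)), 50)
  expect_equal(flotation_percent_bound(c(100, 0, 0, 0, 0, 0, 0, 0)), 100)
  expect_equal(flotation_percent_bound(c(0, 0, 10, 10, 10, 10, 10, 10)), 0)
  expect_error(flotation_percent_bound(rep(0, 8)), "zero")
  expect_error(flotation_percent_bound(1:7), "length")
})

test_that("v-/v counting enforces the surface homogeneity precondition", {
  fld <- render_clustering_field(small_surface_preset(),
                                 small_cluster_preset("cluster_noSyn", 40),
                                 seed = 35)
  fc <- count_vv_interactions(list(fld))
  expect_s3_class(fc, "tbl_df")
  # half-dark surface fails by name
  bad <- fld
  bad$DiD[, 1:128, ] <- 0L
  expect_error(count_vv_interactions(list(bad)), "field 1")
})

test_that("the dose-response table is ordinal in concentration", {
  presets <- list(control = small_cluster_preset("cluster_noSyn", 15),
                  low = small_cluster_preset("cluster_WT_2uM", 45),
                  high = small_cluster_preset("cluster_WT_20uM", 90))
  tab <- dose_response_table(presets, concentrations = c(0, 2, 20),
                             n_locations = 4,
                             surface_preset = small_surface_preset(),
                             seed = 36)
  expect_equal(tab$condition, c("control", "low", "high"))
  expect_true(all(diff(tab$mean) > 0))
  expect_true(is.na(tab$t[1]))
  expect_true(all(tab$p[-1] < 0.05))

  # duplicated condition: no significance
  dup <- dose_response_table(list(a = presets$low, b = presets$low),
                             concentrations = c(2, 2), n_locations = 4,
                             surface_preset = small_surface_preset(),
                             seed = 37)
  expect_gt(dup$p[2], 0.05)
})
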