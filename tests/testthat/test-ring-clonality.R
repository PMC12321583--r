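# Ring bins, same-color counting, two-stage averaging, the shuffle null and
# the clonality decision.

test_that("ring bins follow the (0,10], 20-um-step layout", {
  b290 <- make_ring_bins(290)
  expect_equal(b290$n_bins, 15)
  expect_equal(b290$edges[1:3], c(0, 10, 30))
  expect_equal(utils::tail(b290$edges, 2), c(270, 290))
  expect_equal(make_ring_bins(190)$n_bins, 10)
  b10 <- make_ring_bins(10)
  expect_equal(b10$n_bins, 1)
  expect_equal(b10$edges, c(0, 10))
  expect_error(make_ring_bins(300), "20k")
  expect_error(make_ring_bins(5), "20k")
})

test_that("a single labeled cell has zero counts everywhere", {
  cells <- toy_cells(c(10, 40, 70), c(10, 10, 10),
                     color = c("RFP", "none", "none"))
  cnt <- same_color_counts(cells, make_ring_bins(90))
  expect_equal(nrow(cnt), 1)
  expect_true(all(cnt == 0))
})

test_that("xy distance decides the bin; z offsets are ignored", {
  cells <- toy_cells(c(10, 30), c(10, 10), color = "RFP", z = c(0, 48))
  cnt <- same_color_counts(cells, make_ring_bins(90))
  expect_equal(unname(cnt[, 2]), c(1, 1))  # 20 um apart -> (10,30]
  expect_true(all(cnt[, -2] == 0))
  # boundary: exactly 10 um apart falls in (0,10]
  cells2 <- toy_cells(c(10, 20), c(10, 10), color = "YFP", z = c(0, 30))
  cnt2 <- same_color_counts(cells2, make_ring_bins(90))
  expect_equal(unname(cnt2[, 1]), c(1, 1))
})

test_that("counts equal the O(n^2) brute-force recount on random images", {
  set.seed(31)
  bins <- make_ring_bins(150)
  for (trial in 1:20) {
    n <- sample(20:60, 1)
    cells <- toy_cells(runif(n, 0, 250), runif(n, 0, 250),
                       color = sample(c("none", confetti_colors()), n,
                                      replace = TRUE,
                                      prob = c(0.3, rep(0.175, 4))),
                       z = runif(n, 0, 30))
    got <- same_color_counts(cells, bins)
    want <- oracle_ring_counts(cells$x_um, cells$y_um, cells$confetti_color,
                               bins$edges)
    expect_equal(unname(got), unname(want))
  }
})

test_that("subset filtering restricts origins and neighbors alike", {
  cells <- toy_cells(c(10, 25, 40), c(10, 10, 10), color = "RFP",
                     state = c("PAM", "PAM", "nonPAM"))
  bins <- make_ring_bins(90)
  pam <- same_color_counts(cells, bins, subset = "PAM")
  expect_equal(nrow(pam), 2)
  expect_equal(unname(pam[, 2]), c(1, 1))  # only the 15-um PAM-PAM pair
  nonpam <- same_color_counts(cells, bins, subset = "nonPAM")
  expect_true(all(nonpam == 0))
})

test_that("densities follow count / (pi (r2^2 - r1^2) Lz) and scale with
           depth", {
  bins <- make_ring_bins(90)
  cells <- toy_cells(c(10, 30), c(10, 10), color = "RFP", z = c(0, 10))
  meta100 <- image_meta("img1", c(400, 400, 100))
  p <- ring_density_profile(cells, bins, meta100)
  expect_equal(p$density_um3[2], 1 / (pi * 800 * 100))
  expect_equal(p$mean_count[2], 1)
  expect_true(all(p$density_um3[-2] == 0))
  meta200 <- image_meta("img1", c(400, 400, 200))
  p2 <- ring_density_profile(cells, bins, meta200)
  expect_equal(p2$density_um3, p$density_um3 / 2)

  empty <- ring_density_profile(toy_cells(5, 5), bins, meta100)
  expect_true(all(is.na(empty$density_um3)))
  expect_equal(empty$n_origin_cells[1], 0)
})

test_that("group averaging is two-stage (image -> replicate -> group)", {
  bins <- make_ring_bins(10)
  prof <- function(rep, img, d) {
    data.frame(group = "g", replicate_id = rep, image_id = img,
               subset = "all", bin = 1, r_lo = 0, r_hi = 10,
               mean_count = NA, density_um3 = d, n_origin_cells = 5)
  }
  # identical profiles -> mean equals them, zero-width CI
  same <- rbind(prof("r1", "i1", 2), prof("r2", "i2", 2))
  a <- average_profiles(same)
  expect_equal(a$density_mean, 2)
  expect_equal(a$ci_lo, 2)
  expect_equal(a$ci_hi, 2)

  # replicates at d and 3d -> group mean 2d
  ab <- average_profiles(rbind(prof("r1", "i1", 1), prof("r2", "i2", 3)))
  expect_equal(ab$density_mean, 2)

  # unbalanced images per replicate: two-stage mean, not the pooled mean
  unb <- rbind(prof("r1", "i1", 1), prof("r1", "i2", 3), prof("r2", "i3", 8))
  u <- average_profiles(unb)
  expect_equal(u$density_mean, mean(c(mean(c(1, 3)), 8)))  # 5, pooled = 4
  expect_equal(u$n_replicates, 2)

  single <- average_profiles(prof("r1", "i1", 2))
  expect_true(single$single_replicate)
  expect_true(is.na(single$ci_lo))
})

test_that("label shuffling preserves positions and per-color counts", {
  set.seed(32)
  cells <- toy_cells(runif(50, 0, 100), runif(50, 0, 100),
                     color = c(rep("RFP", 3), rep("YFP", 2), rep("none", 45)))
  none <- toy_cells(1:3, 1:3)
  expect_equal(shuffle_labels(none)[order(none$cell_id), ],
               none[order(none$cell_id), ])
  for (i in 1:20) {
    sh <- shuffle_labels(cells)
    expect_equal(sort(paste(sh$x_um, sh$y_um)),
                 sort(paste(cells$x_um, cells$y_um)))
    expect_equal(table(sh$confetti_color), table(cells$confetti_color))
  }
  # uniformity: each position hosts a label with frequency ~ 5/50
  hits <- numeric(50)
  n_shuf <- 4000
  for (i in seq_len(n_shuf)) {
    hits <- hits + (shuffle_labels(cells)$confetti_color != "none")
  }
  p <- hits / n_shuf
  expect_lt(max(abs(p - 0.1)), 4.5 * sqrt(0.1 * 0.9 / n_shuf))
  expect_equal(mean(p), 0.1)
})

test_that("a fully labeled single-color image gives a zero-width envelope
           equal to the observed profile", {
  set.seed(33)
  cells <- toy_cells(runif(30, 0, 100), runif(30, 0, 100), color = "YFP")
  meta <- image_meta("img1", c(100, 100, 20))
  bins <- make_ring_bins(50)
  env <- mc_null_envelope(cells, bins, meta, n_shuffles = 200, seed = 1)
  obs <- ring_density_profile(cells, bins, meta)
  expect_equal(env$envelope$lo, obs$density_um3)
  expect_equal(env$envelope$hi, obs$density_um3)
})

test_that("envelope bounds are the type-7 empirical quantiles across
           shuffles", {
  set.seed(34)
  cells <- toy_cells(runif(60, 0, 150), runif(60, 0, 150),
                     color = sample(c("none", "RFP", "YFP"), 60, TRUE,
                                    prob = c(0.5, 0.25, 0.25)))
  meta <- image_meta("img1", c(150, 150, 20))
  bins <- make_ring_bins(70)
  env <- mc_null_envelope(cells, bins, meta, n_shuffles = 500, seed = 7,
                          keep_shuffles = TRUE)
  st <- env$shuffle_stats
  expect_equal(env$envelope$lo,
               apply(st, 2, quantile, 0.01, type = 7, names = FALSE))
  expect_equal(env$envelope$hi,
               apply(st, 2, quantile, 0.99, type = 7, names = FALSE))
  # identical seed + input -> identical envelope
  env2 <- mc_null_envelope(cells, bins, meta, n_shuffles = 500, seed = 7)
  expect_equal(env$envelope, env2$envelope)
  expect_warning(mc_null_envelope(cells, bins, meta, n_shuffles = 50,
                                  seed = 1), "quantile resolution")
})

test_that("the shuffled statistic matches the R counting path", {
  set.seed(35)
  cells <- toy_cells(runif(80, 0, 200), runif(80, 0, 200),
                     color = sample(c("none", confetti_colors()), 80, TRUE))
  bins <- make_ring_bins(110)
  # row 1 of the kernel output is the observed assignment
  codes <- match(cells$confetti_color, confetti_colors(), nomatch = 0L)
  kern <- microclonality:::ring_shuffle_pair_counts(cells$x_um, cells$y_um,
                                                    codes, bins$edges, 0)
  obs <- same_color_counts(cells, bins)
  expect_equal(as.integer(kern[1, ]), unname(colSums(obs)))
})

test_that("clonality calls require strict interval separation", {
  obs <- data.frame(group = "g", subset = "all", bin = 1:3, r_lo = c(0, 10, 30),
                    r_hi = c(10, 30, 50), density_mean = c(5.5, 2, 1),
                    ci_lo = c(5, 1, 0), ci_hi = c(6, 3, 1.5),
                    n_replicates = 3, single_replicate = FALSE)
  env <- structure(list(envelope = data.frame(
    bin = 1:3, r_lo = c(0, 10, 30), r_hi = c(10, 30, 50),
    lo = c(1, 2, 2), hi = c(2, 4, 3))), class = "null_envelope")
  calls <- clonality_decision(obs, env)
  expect_equal(calls$call, c("excess", "none", "deficit"))

  env_bad <- structure(list(envelope = data.frame(
    bin = 1:2, r_lo = c(0, 10), r_hi = c(10, 30), lo = 0, hi = 1)),
    class = "null_envelope")
  expect_error(clonality_decision(obs, env_bad), "bins do not match")
})

test_that("Confetti+ cells within 30 um are counted per animal", {
  # surface distances 5, 29, 31, 60 from a 1-um-radius plaque -> 2 inside
  pl <- toy_plaques(0, 0, volume = 4 * pi / 3)
  cells <- toy_cells(c(6, 30, 32, 61), c(0, 0, 0, 0), color = "RFP")
  cc <- classify_cells(cells, pl)
  expect_equal(cells_within_30um(cc, pl)$n_cells, 2)

  none <- classify_cells(toy_cells(c(5, 10), c(0, 0), color = "RFP"),
                         no_plaques())
  expect_equal(cells_within_30um(none, no_plaques())$n_cells, 0)

  # random synthetic image equals a direct recount
  set.seed(36)
  g <- simulate_group(sim_config(image_extent = c(400, 400, 40),
                                 background_cell_intensity = 6000,
                                 plaque_intensity = 800, seed = 37))
  cc <- classify_cells(g$cells, g$plaques)
  got <- cells_within_30um(cc, g$plaques)
  d <- distance_to_nearest_plaque(g$cells, g$plaques)
  want <- tapply(g$cells$confetti_color != "none" & d <= 30,
                 g$cells$replicate_id, sum)
  expect_equal(got$n_cells, as.integer(want[got$replicate_id]),
               ignore_attr = TRUE)
})
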