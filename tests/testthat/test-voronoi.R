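# Tessellation geometry, adjacency, clone components, territories and
# clone-to-plaque contacts, each against an independent oracle.

test_that("four symmetric seeds split the box into four equal quarters", {
  meta <- image_meta("img1", c(1, 1, 1))
  cells <- toy_cells(c(0.25, 0.75, 0.25, 0.75), c(0.25, 0.25, 0.75, 0.75))
  tess <- build_tessellation(cells, no_plaques(), meta)
  expect_equal(tess$areas, rep(0.25, 4))
  expect_true(all(tess$touches_border))
  # the two diagonal pairs meet only at the centre point -> not adjacent
  adj <- tess$adjacency
  expect_equal(nrow(adj), 4)
  expect_false(any((adj[, 1] == 1 & adj[, 2] == 4) |
                     (adj[, 1] == 2 & adj[, 2] == 3)))
})

test_that("clipped polygon areas tile the bounding box on random configs", {
  set.seed(41)
  meta <- image_meta("img1", c(300, 200, 10))
  for (trial in 1:20) {
    n <- sample(c(5, 20, 100), 1)
    cells <- toy_cells(runif(n, 0, 300), runif(n, 0, 200))
    tess <- build_tessellation(cells, no_plaques(), meta)
    expect_lt(abs(sum(tess$areas) - 300 * 200) / (300 * 200), 1e-6)
    # areas match an independent shoelace recomputation
    sh <- vapply(tess$polygons, shoelace_area, numeric(1))
    expect_equal(tess$areas, sh, tolerance = 1e-12)
  }
})

test_that("degenerate seed sets are rejected; coincident seeds are split", {
  meta <- image_meta("img1", c(10, 10, 1))
  expect_error(build_tessellation(toy_cells(c(1, 2), c(1, 2)), no_plaques(),
                                  meta), "3 seeds")
  expect_error(build_tessellation(toy_cells(c(1, 2, 3), c(1, 2, 3)),
                                  no_plaques(), meta), "collinear")
  dup <- build_tessellation(toy_cells(c(2, 2, 2, 7), c(3, 3, 3, 8)),
                            no_plaques(), meta)
  expect_equal(length(dup$polygons), 4)
  expect_lt(abs(sum(dup$areas) - 100) / 100, 1e-6)
})

test_that("adjacency matches the exact bisector-interval oracle", {
  set.seed(42)
  meta <- image_meta("img1", c(100, 100, 1))
  for (trial in 1:8) {
    n <- 30
    cells <- toy_cells(runif(n, 0, 100), runif(n, 0, 100))
    tess <- build_tessellation(cells, no_plaques(), meta)
    got <- tess$adjacency[order(tess$adjacency[, 1], tess$adjacency[, 2]), ,
                          drop = FALSE]
    want <- oracle_voronoi_adjacency(cells$x_um, cells$y_um,
                                     c(0, 0, 100, 100))
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
})

test_that("clone calling groups same-color adjacency components", {
  meta <- image_meta("img1", c(10, 10, 1))
  # three mutually adjacent YFP cells -> one clone of 3
  tri <- toy_cells(c(3, 7, 5), c(3, 3, 6), color = "YFP")
  tess <- build_tessellation(tri, no_plaques(), meta)
  cs <- call_clones(tess, tri)
  expect_equal(nrow(cs$clones), 1)
  expect_equal(cs$clones$n_cells, 3)
  expect_equal(cs$clones$color, "YFP")

  # an intervening unlabeled seed splits two RFP cells into singletons
  spl <- toy_cells(c(2, 8, 5, 5, 5), c(5, 5, 5, 1, 9),
                   color = c("RFP", "RFP", "none", "none", "none"))
  tess2 <- build_tessellation(spl, no_plaques(), meta)
  cs2 <- call_clones(tess2, spl)
  expect_equal(nrow(cs2$clones), 2)
  expect_equal(cs2$clones$n_cells, c(1, 1))
  expect_equal(sort(cs2$unassigned), c("c003", "c004", "c005"))
})

test_that("components equal a brute-force union-find on random labelings", {
  set.seed(43)
  meta <- image_meta("img1", c(100, 100, 1))
  for (trial in 1:8) {
    n <- 50
    cells <- toy_cells(runif(n, 0, 100), runif(n, 0, 100),
                       color = sample(c("none", confetti_colors()), n, TRUE,
                                      prob = c(0.4, rep(0.15, 4))))
    tess <- build_tessellation(cells, no_plaques(), meta)
    cs <- call_clones(tess, cells)
    # every labeled cell in exactly one clone
    expect_setequal(cs$members$cell_id,
                    cells$cell_id[cells$confetti_color != "none"])
    expect_equal(sum(cs$clones$n_cells), nrow(cs$members))
    # oracle components over the same-color adjacency list
    lab <- which(cells$confetti_color != "none")
    adj <- tess$adjacency
    keep <- adj[, 1] %in% lab & adj[, 2] %in% lab &
      cells$confetti_color[adj[, 1]] == cells$confetti_color[adj[, 2]]
    comp <- oracle_components(lab, adj[keep, , drop = FALSE])
    want_sizes <- sort(as.integer(table(comp)))
    expect_equal(sort(cs$clones$n_cells), want_sizes)
    # member partitions agree, not just sizes
    got_part <- split(cs$members$cell_id, cs$members$clone_id)
    want_part <- split(cells$cell_id[lab], comp)
    expect_setequal(lapply(got_part, sort) |> unname(),
                    lapply(want_part, sort) |> unname())
    # territory conservation
    expect_lte(sum(cs$clones$territory_um2), 100 * 100 + 1e-6)
  }
})

test_that("clone territory sums member polygon areas; depth converts to
           volume", {
  meta <- image_meta("img1", c(20, 10, 7))
  cells <- toy_cells(c(5, 15, 10), c(5, 5, 8), color = c("RFP", "RFP", "none"))
  tess <- build_tessellation(cells, no_plaques(), meta)
  cs <- call_clones(tess, cells)
  terr <- clone_territory(cs)
  for (cl in names(terr)) {
    seeds <- cs$members$seed[cs$members$clone_id == cl]
    expect_equal(unname(terr[cl]),
                 sum(vapply(tess$polygons[seeds], shoelace_area, numeric(1))))
  }
  vol <- clone_territory(cs, report_volume = TRUE, meta = meta)
  expect_equal(unname(vol), unname(terr) * 7)
  # all seeds in one clone -> territory equals the whole box
  one <- toy_cells(c(4, 9, 16), c(3, 7, 4), color = "mCFP")
  to <- build_tessellation(one, no_plaques(), meta)
  co <- call_clones(to, one)
  expect_equal(sum(clone_territory(co)), 200)
})

test_that("clone-to-plaque contacts come from shared tessellation edges", {
  meta <- image_meta("img1", c(10, 10, 1))
  # a clone ring around a lone plaque seed -> one contact
  ring <- toy_cells(c(3, 7, 5, 5), c(5, 5, 3, 7), color = "YFP")
  pl <- toy_plaques(5, 5, volume = 50)
  tess <- build_tessellation(ring, pl, meta)
  cs <- call_clones(tess, ring)
  ct <- clone_plaque_contacts(cs)
  expect_equal(nrow(cs$clones), 1)
  expect_equal(nrow(ct$pairs), 1)
  expect_equal(ct$clones_per_plaque$n_clones, 1)
  expect_equal(ct$frac_plaques_multiclone, 0)

  # a plaque flanked by an RFP clone and a YFP clone -> two clones contact it
  flank <- toy_cells(c(2, 3.2, 8, 6.8, 5, 5), c(5, 5, 5, 5, 1, 9),
                     color = c("RFP", "RFP", "YFP", "YFP", "none", "none"))
  tess2 <- build_tessellation(flank, pl, meta)
  cs2 <- call_clones(tess2, flank)
  ct2 <- clone_plaque_contacts(cs2)
  expect_equal(nrow(cs2$clones), 2)
  expect_equal(ct2$clones_per_plaque$n_clones, 2)
  expect_equal(ct2$frac_plaques_multiclone, 1)

  # no plaques -> empty contact set
  ct0 <- clone_plaque_contacts(call_clones(build_tessellation(
    ring, no_plaques(), meta), ring))
  expect_equal(nrow(ct0$pairs), 0)
  expect_true(is.na(ct0$frac_plaques_multiclone))
})

test_that("contacts match a brute-force adjacency scan on random configs", {
  set.seed(44)
  meta <- image_meta("img1", c(100, 100, 1))
  for (trial in 1:6) {
    cells <- toy_cells(runif(40, 0, 100), runif(40, 0, 100),
                       color = sample(c("none", confetti_colors()), 40, TRUE))
    pl <- toy_plaques(runif(5, 0, 100), runif(5, 0, 100), volume = 200)
    tess <- build_tessellation(cells, pl, meta)
    cs <- call_clones(tess, cells)
    ct <- clone_plaque_contacts(cs)
    # oracle: exact bisector-interval adjacency between every seed pair
    want_adj <- oracle_voronoi_adjacency(tess$seeds$x, tess$seeds$y,
                                         c(0, 0, 100, 100))
    plq_seed <- tess$seeds$seed[tess$seeds$kind == "plaque"]
    want_pairs <- unique(do.call(rbind, lapply(seq_len(nrow(want_adj)),
                                               function(r) {
      a <- want_adj[r, 1]; b <- want_adj[r, 2]
      if (a %in% plq_seed && b %in% cs$members$seed) {
        data.frame(clone_id = cs$members$clone_id[match(b, cs$members$seed)],
                   plaque_id = tess$seeds$ref_id[a])
      } else if (b %in% plq_seed && a %in% cs$members$seed) {
        data.frame(clone_id = cs$members$clone_id[match(a, cs$members$seed)],
                   plaque_id = tess$seeds$ref_id[b])
      } else NULL
    })))
    got <- ct$pairs[, c("clone_id", "plaque_id")]
    if (is.null(want_pairs)) {
      expect_equal(nrow(got), 0)
    } else {
      want_pairs <- want_pairs[order(want_pairs$clone_id,
                                     want_pairs$plaque_id), ]
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want_pairs)))
    }
  }
})

test_that("founder lineages are recovered 1:1 at sparse labeling and degrade
           as label collisions rise", {
  cfg <- function(p, seed) sim_config(n_images_per_replicate = 2L,
                                      n_replicates_per_group = 1L,
                                      label_prob = p, seed = seed)
  recover <- function(p) {
    g <- simulate_group(cfg(p, 45))
    rates <- vapply(unique(g$cells$image_id), function(img) {
      ci <- g$cells[g$cells$image_id == img, ]
      pi_ <- g$plaques[g$plaques$image_id == img, ]
      cs <- call_clones(build_tessellation(ci, pi_, g$meta), ci)
      founder_recovery(ci, cs)
    }, numeric(1))
    mean(rates, na.rm = TRUE)
  }
  sparse <- recover(0.03)
  expect_gte(sparse, 0.9)
  dense <- recover(0.7)
  expect_gt(sparse, dense)
})
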