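# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# O(n^2) per-origin same-color ring recount on sqrt distances.
oracle_ring_counts <- function(x, y, color, edges) {
  lab <- which(color != "none")
  nb <- length(edges) - 1L
  out <- matrix(0L, length(lab), nb)
  for (a in seq_along(lab)) {
    i <- lab[a]
    for (j in lab) {
      if (j == i || color[j] != color[i]) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      for (k in seq_len(nb)) {
        if (d > edges[k] && d <= edges[k + 1]) {
          out[a, k] <- out[a, k] + 1L
          break
        }
      }
    }
  }
  out
}

# Exact Voronoi adjacency of seeds clipped to a box, by 1D interval
# intersection along each pair's perpendicular bisector: i and j share an
# edge iff some segment of the bisector lies inside the box and closer to
# i (and j) than to every other seed.
oracle_voronoi_adjacency <- function(x, y, box, eps = 1e-9) {
  n <- length(x)
  pairs <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
      ux <- x[j] - x[i]; uy <- y[j] - y[i]
      nrm <- sqrt(ux^2 + uy^2)
      if (nrm < 1e-12) next
      dx <- -uy / nrm; dy <- ux / nrm          # direction along the bisector
      lo <- -Inf; hi <- Inf
      add <- function(b, a) {
        # constraint a + b t <= 0
        if (abs(b) < 1e-14) {
          if (a > 0) return(c(1, -1))          # infeasible
          return(c(lo, hi))
        }
        t0 <- -a / b
        if (b > 0) c(lo, min(hi, t0)) else c(max(lo, t0), hi)
      }
      # inside the box
      for (cons in list(c(-dx, box[1] - mx), c(dx, mx - box[3]),
                        c(-dy, box[2] - my), c(dy, my - box[4]))) {
        v <- add(cons[1], cons[2]); lo <- v[1]; hi <- v[2]
      }
      # closer to i than to every other seed k
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        kx <- x[k] - x[i]; ky <- y[k] - y[i]
        a <- kx * (2 * mx - x[i] - x[k]) + ky * (2 * my - y[i] - y[k])
        b <- 2 * (kx * dx + ky * dy)
        v <- add(b, a); lo <- v[1]; hi <- v[2]
        if (hi - lo <= eps) break
      }
      if (hi - lo > eps) pairs <- rbind(pairs, c(i, j))
    }
  }
  if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs
}

# Hand-rolled union-find over an adjacency list restricted to same-color
# labeled vertices.
oracle_components <- function(vertices, edges) {
  parent <- seq_along(vertices)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ia <- match(edges[r, 1], vertices)
      ib <- match(edges[r, 2], vertices)
      ra <- find(ia); rb <- find(ib)
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_along(vertices), find, integer(1))
}

shoelace_area <- function(poly) {
  k <- nrow(poly)
  if (k < 3) return(0)
  nxt <- c(2:k, 1)
  abs(sum(poly[, 1] * poly[nxt, 2] - poly[nxt, 1] * poly[, 2])) / 2
}

# tiny cell/plaque table constructors for geometric fixtures
toy_cells <- function(x, y, color = "none", z = 0, state = NULL,
                      image_id = "img1") {
  n <- length(x)
  df <- data.frame(
    group = "g1", replicate_id = "r1", image_id = image_id,
    cell_id = sprintf("c%03d", seq_len(n)),
    x_um = x, y_um = y, z_um = rep_len(z, n),
    confetti_color = rep_len(color, n), pu1 = TRUE,
    stringsAsFactors = FALSE
  )
  if (!is.null(state)) df$state <- rep_len(state, n)
  df
}

toy_plaques <- function(x, y, volume = 100, z = 0, image_id = "img1") {
  n <- length(x)
  data.frame(
    group = rep_len("g1", n), replicate_id = rep_len("r1", n),
    image_id = rep_len(image_id, n),
    plaque_id = sprintf("p%03d", seq_len(n)),
    x_um = x, y_um = y, z_um = rep_len(z, n),
    volume_um3 = rep_len(volume, n),
    stringsAsFactors = FALSE
  )
}

no_plaques <- function(image_id = "img1") toy_plaques(numeric(0), numeric(0),
                                                      image_id = image_id)

# map called clones back to true labeled founder lineages and score the
# fraction of lineages recovered 1:1 with Jaccard > 0.8
founder_recovery <- function(cells, clone_set) {
  lab <- cells[cells$confetti_color != "none", , drop = FALSE]
  lineages <- split(lab$cell_id, lab$founder_id)
  called <- split(clone_set$members$cell_id, clone_set$members$clone_id)
  if (!length(lineages)) return(NA_real_)
  hit <- vapply(lineages, function(tr) {
    best <- 0
    for (cl in called) {
      j <- length(intersect(tr, cl)) / length(union(tr, cl))
      if (j > best) best <- j
    }
    best > 0.8
  }, logical(1))
  mean(hit)
}
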