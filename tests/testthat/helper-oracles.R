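# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# Stack-based flood fill connected-component labeling.
flood_fill_label <- function(fg, connectivity = 8) {
  nr <- nrow(fg); nc <- ncol(fg)
  nbr <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!fg[r, c] || labels[r, c] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r, c))
    labels[r, c] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        rr <- p[1] + nbr[k, 1]; cc <- p[2] + nbr[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            fg[rr, cc] && labels[rr, cc] == 0L) {
          labels[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  labels
}

# Per-pixel 4-neighbor boundary check.
boundary_oracle <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  out <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    l <- labels[r, c]
    if (l == 0L) next
    nb <- c(if (r > 1) labels[r - 1, c] else 0L,
            if (r < nr) labels[r + 1, c] else 0L,
            if (c > 1) labels[r, c - 1] else 0L,
            if (c < nc) labels[r, c + 1] else 0L)
    if (r == 1 || r == nr || c == 1 || c == nc || any(nb != l))
      out[[as.character(l)]] <- rbind(out[[as.character(l)]], c(r, c))
  }
  out
}

# All-pairs symmetric mean nearest-neighbor distance, double loop.
allpairs_avg_dist <- function(a, b) {
  nn <- function(p, q) {
    s <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q)))
        best <- min(best, sqrt(sum((p[i, ] - q[j, ])^2)))
      s <- s + best
    }
    s / nrow(p)
  }
  (nn(a, b) + nn(b, a)) / 2
}

# Shoelace polygon area (cross-check for the pixel-fill area path).
shoelace_area <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
}

random_class_mask <- function(nr, nc, p_islet = 0.35) {
  classes <- matrix(sample(0:2, nr * nc, replace = TRUE,
                           prob = c(1 - p_islet - 0.1, 0.1, p_islet)),
                    nr, nc)
  isletscope:::new_label_mask(classes, default_mask_encoding())
}

random_pixel_set <- function(n, lim = 60) {
  unique(cbind(sample.int(lim, n, replace = TRUE),
               sample.int(lim, n, replace = TRUE)))
}

# One mid-size test scene shared across files (built once per test run).
test_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      isl <- data.frame(center_row = c(70, 190, 80),
                        center_col = c(70, 170, 230),
                        eq_diameter_um = c(90, 160, 60),
                        shape = c("disc", "blob", "blob"),
                        irregularity = c(0, 0.12, 0.1),
                        embedded = c(FALSE, FALSE, TRUE))
      cache <<- make_scene(scene_spec(300L, 300L, pixel_size_um = 1,
                                      islets = isl, seed = 7L))
    }
    cache
  }
})
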