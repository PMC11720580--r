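# Independent oracles and small fixture builders used across the suite.

# brute-force Bradley rule: per-pixel double loop over clipped windows
naive_bradley <- function(img, w, s) {
  h <- nrow(img); wd <- ncol(img)
  k <- (w - 1) %/% 2
  out <- matrix(FALSE, h, wd)
  for (i in seq_len(h)) {
    for (j in seq_len(wd)) {
      rs <- max(1, i - k):min(h, i + k)
      cs <- max(1, j - k):min(wd, j + k)
      out[i, j] <- img[i, j] > mean(img[rs, cs]) * (1 - s)
    }
  }
  out
}

# connected-component count oracle via igraph
igraph_n_components <- function(mask, connectivity = 8L) {
  idx <- which(mask > 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0L)
  key <- paste(idx[, 1], idx[, 2])
  offs <- if (connectivity == 8L)
    rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1)) else rbind(c(0, 1), c(1, 0))
  edges <- c()
  for (o in seq_len(nrow(offs))) {
    nb <- paste(idx[, 1] + offs[o, 1], idx[, 2] + offs[o, 2])
    hit <- nb %in% key
    if (any(hit))
      edges <- c(edges, rbind(key[hit], nb[hit]))
  }
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = character(0), to = character(0))
        else data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)]),
    directed = FALSE, vertices = data.frame(name = key))
  as.integer(igraph::count_components(g))
}

# rasterized shapes
draw_disk <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- t(xs)
  ((xs - c0)^2 + (ys - c0)^2 <= r^2) + 0L
}

draw_ellipse <- function(a, b, pad = 4, phi = 0) {
  n <- 2 * (max(a, b) + pad) + 1
  c0 <- max(a, b) + pad + 1
  xs <- matrix(seq_len(n), n, n, byrow = TRUE) - c0
  ys <- t(matrix(seq_len(n), n, n, byrow = TRUE)) - c0
  xr <- cos(phi) * xs + sin(phi) * ys
  yr <- -sin(phi) * xs + cos(phi) * ys
  ((xr / a)^2 + (yr / b)^2 <= 1) + 0L
}

# ten hand-counted skeleton fixtures: list(mask, branches, junctions, length
# or NA when not hand-derived)
skeleton_fixtures <- function() {
  f <- list()
  m <- matrix(0, 16, 20); m[8, 5:15] <- 1
  f$line11 <- list(mask = m, b = 1L, j = 0L, len = 10)
  m <- matrix(0, 17, 17); m[9, 3:15] <- 1; m[3:15, 9] <- 1
  f$plus <- list(mask = m, b = 4L, j = 1L, len = 24)
  m <- matrix(0, 14, 15); m[5, 3:13] <- 1; m[6:10, 8] <- 1
  f$tee <- list(mask = m, b = 3L, j = 1L, len = 15)
  m <- matrix(0, 16, 16)
  m[8, 8] <- 1
  for (d in 1:4) { m[8 - d, 8 - d] <- 1; m[8 - d, 8 + d] <- 1 }
  m[9:12, 8] <- 1
  f$wye <- list(mask = m, b = 3L, j = 1L, len = 8 * sqrt(2) + 4)
  m <- matrix(0, 17, 13); m[3:13, 3] <- 1; m[3:13, 9] <- 1; m[8, 4:8] <- 1
  f$aitch <- list(mask = m, b = 5L, j = 2L, len = 26)
  m <- matrix(0, 14, 14); for (d in 0:7) m[3 + d, 3 + d] <- 1
  f$diag8 <- list(mask = m, b = 1L, j = 0L, len = 7 * sqrt(2))
  m <- matrix(0, 16, 16); m[4, 3:13] <- 1; m[12, 3:13] <- 1
  f$two_lines <- list(mask = m, b = 2L, j = 0L, len = 20)
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  f$dot <- list(mask = m, b = 1L, j = 0L, len = 0)
  m <- matrix(0, 15, 15)
  for (d in 0:4) {
    m[8 - d, 4 + d] <- 1; m[8 - d, 12 - d] <- 1
    m[8 + d, 4 + d] <- 1; m[8 + d, 12 - d] <- 1
  }
  f$diamond <- list(mask = m, b = 1L, j = 0L, len = 16 * sqrt(2))
  m <- matrix(0, 14, 21); m[10, 2:18] <- 1
  for (cc in c(6, 10, 14)) m[7:9, cc] <- 1
  f$comb <- list(mask = m, b = 7L, j = 3L, len = 25)
  f
}
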