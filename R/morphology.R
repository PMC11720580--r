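# Mitochondrial morphology and network-connectivity metrics: per-object
# size/shape descriptors (area, Crofton perimeter, form factor, aspect
# ratio) and skeleton-graph statistics (total branch length, branch count,
# junction count).

# Crofton 4-direction perimeter of a binary mask.
# Cauchy-Crofton: P = (1/2) * Int_0^pi (sum over parallel lines of
# boundary crossings x line spacing) dtheta, discretized at 0/45/90/135 deg
# with spacing 1 for the axis directions and 1/sqrt(2) for the diagonals:
# P ~= (pi/8) * (N0 + N90 + (N45 + N135) / sqrt(2)).
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) + 0L
  H <- nrow(m); W <- ncol(m)
  n_h <- sum(m[, -W] != m[, -1])                       # along rows (0 deg)
  n_v <- sum(m[-H, ] != m[-1, ])                       # along columns (90 deg)
  n_d1 <- sum(m[-H, -W] != m[-1, -1])                  # 45 deg diagonals
  n_d2 <- sum(m[-H, -1] != m[-1, -W])                  # 135 deg diagonals
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

# naive exposed-edge perimeter (biased high on smooth shapes); kept for
# comparison behind the `perimeter` flag
edge_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) + 0L
  H <- nrow(m); W <- ncol(m)
  sum(abs(m[, -W] - m[, -1])) + sum(abs(m[-H, ] - m[-1, ]))
}

#' Per-object morphology metrics
#'
#' For every labeled object: area (pixel count), perimeter (Crofton
#' 4-direction estimator by default), form factor `P^2 / (4 pi A)` (>= 1,
#' circle = 1; its inverse, circularity, is included as a derived column)
#' and aspect ratio (major/minor axis of the second-moment equivalent
#' ellipse, with the 1/12 square-pixel variance correction). Objects under
#' 4 px are flagged (`degenerate`) and get NA form factor / aspect ratio.
#'
#' @param labels integer label mask.
#' @param perimeter "crofton" (default) or "edges" (naive exposed-edge
#'   count).
#' @return data.frame: `label`, `area_px`, `perimeter_px`, `form_factor`,
#'   `circularity`, `aspect_ratio`, `degenerate`.
#' @export
object_metrics <- function(labels, perimeter = c("crofton", "edges")) {
  perimeter <- match.arg(perimeter)
  if (!is.matrix(labels)) stop_fq("`labels` must be a matrix")
  labs <- sort(unique(labels[labels > 0]))
  out <- data.frame(label = labs, area_px = NA_real_, perimeter_px = NA_real_,
                    form_factor = NA_real_, circularity = NA_real_,
                    aspect_ratio = NA_real_, degenerate = FALSE)
  for (i in seq_along(labs)) {
    sel <- labels == labs[i]
    idx <- which(sel, arr.ind = TRUE)
    area <- nrow(idx)
    sub <- sel[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]),
               drop = FALSE]
    P <- if (perimeter == "crofton") crofton_perimeter(sub)
         else edge_perimeter(sub)
    out$area_px[i] <- area
    out$perimeter_px[i] <- P
    if (area < 4) {
      out$degenerate[i] <- TRUE
      next
    }
    out$form_factor[i] <- P^2 / (4 * pi * area)
    out$circularity[i] <- 1 / out$form_factor[i]
    x <- idx[, 2]; y <- idx[, 1]
    # central second moments with the square-pixel (1/12) correction
    mxx <- mean((x - mean(x))^2) + 1 / 12
    myy <- mean((y - mean(y))^2) + 1 / 12
    mxy <- mean((x - mean(x)) * (y - mean(y)))
    tr <- mxx + myy
    disc <- sqrt(max((mxx - myy)^2 + 4 * mxy^2, 0))
    out$aspect_ratio[i] <- sqrt(((tr + disc) / 2) / max((tr - disc) / 2, 1e-12))
  }
  out
}

# zero-padded shift helper for binary morphology
shift0 <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- seq_len(h) - dy; cs <- seq_len(w) - dx
  ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# chessboard dilation of a logical mask by r pixels
dilate_cheb <- function(m, r) {
  out <- m
  for (i in seq_len(r)) {
    acc <- out
    for (dy in -1:1) for (dx in -1:1)
      acc <- acc | shift0(out + 0L, dy, dx) > 0L
    out <- acc
  }
  out
}

#' Topological skeletonization (Guo-Hall thinning)
#'
#' Iterative two-subiteration thinning to a 1-px-wide skeleton; connectivity
#' (component count) is preserved, and - unlike plain Zhang-Suen - thin
#' diagonal structures are not eroded away. A post-pass removes pixels that
#' are redundant within residual 2x2 blocks while keeping their
#' neighborhoods connected.
#'
#' @param mask logical or 0/1 matrix.
#' @param prune remove spurs (endpoint-terminated side branches ending at a
#'   junction) shorter than this length in px; 0 (default) disables pruning.
#'   Isolated segments are never pruned.
#' @return logical skeleton matrix.
#' @export
skeletonize <- function(mask, prune = 0) {
  if (!is.matrix(mask)) stop_fq("`mask` must be a matrix")
  img <- (mask > 0) + 0L
  neigh_offsets <- list(  # P2..P9: N, NE, E, SE, S, SW, W, NW
    c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
    c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors p2..p9 clockwise from north
      P <- lapply(neigh_offsets, function(o) shift0(img, o[1], o[2]))
      p2 <- P[[1]]; p3 <- P[[2]]; p4 <- P[[3]]; p5 <- P[[4]]
      p6 <- P[[5]]; p7 <- P[[6]]; p8 <- P[[7]]; p9 <- P[[8]]
      C <- ((1L - p2) & (p3 | p4)) + ((1L - p4) & (p5 | p6)) +
           ((1L - p6) & (p7 | p8)) + ((1L - p8) & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m <- if (sub == 1L) (p6 | p7 | (1L - p9)) & p8
           else (p2 | p3 | (1L - p5)) & p4
      del <- img == 1L & C == 1L & N >= 2L & N <= 3L & m == 0L
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # clean residual 2x2 blocks: drop a corner whose removal keeps its 3x3
  # neighborhood 8-connected
  repeat {
    blocks <- which(img[-nrow(img), -ncol(img)] & img[-1, -ncol(img)] &
                    img[-nrow(img), -1] & img[-1, -1], arr.ind = TRUE)
    if (nrow(blocks) == 0) break
    removed_any <- FALSE
    for (b in seq_len(nrow(blocks))) {
      corners <- rbind(blocks[b, ], blocks[b, ] + c(1, 0),
                       blocks[b, ] + c(0, 1), blocks[b, ] + c(1, 1))
      for (ci in seq_len(4)) {
        r <- corners[ci, 1]; cc <- corners[ci, 2]
        if (img[r, cc] == 0L) next
        rs <- max(1, r - 1):min(nrow(img), r + 1)
        cs <- max(1, cc - 1):min(ncol(img), cc + 1)
        patch <- img[rs, cs, drop = FALSE]
        Bv <- sum(patch) - 1L
        patch[rs == r, cs == cc] <- 0L
        if (Bv > 1L && max(label_components(patch, 8L)) == 1L) {
          img[r, cc] <- 0L
          removed_any <- TRUE
          break
        }
      }
      if (removed_any) break
    }
    if (!removed_any) break
  }
  sk <- img == 1L
  if (prune > 0) sk <- prune_spurs(sk, prune)
  sk
}

# pixel graph over a skeleton: coordinates, ids, neighbor lists, degrees.
# Diagonal edges that shortcut an existing orthogonal 2-step path (both
# pixels share an orthogonal common neighbor) are dropped - staircase
# corners would otherwise read as spurious degree-3 junctions.
skeleton_graph <- function(sk) {
  pix <- which(sk, arr.ind = TRUE)
  id_of <- matrix(0L, nrow(sk), ncol(sk))
  id_of[pix] <- seq_len(nrow(pix))
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nbs <- lapply(seq_len(nrow(pix)), function(i) {
    rr <- pix[i, 1] + offs[, 1]; ccc <- pix[i, 2] + offs[, 2]
    ok <- rr >= 1 & rr <= nrow(sk) & ccc >= 1 & ccc <= ncol(sk)
    ids <- id_of[cbind(rr[ok], ccc[ok])]
    ids[ids > 0]
  })
  is_diag <- function(i, j) all(abs(pix[i, ] - pix[j, ]) == 1L)
  for (i in seq_along(nbs)) {
    for (j in nbs[[i]]) {
      if (j < i || !is_diag(i, j)) next
      common <- intersect(nbs[[i]], nbs[[j]])
      ortho <- common[vapply(common, function(k)
        sum(abs(pix[k, ] - pix[i, ])) == 1L &&
        sum(abs(pix[k, ] - pix[j, ])) == 1L, TRUE)]
      if (length(ortho) > 0) {
        nbs[[i]] <- setdiff(nbs[[i]], j)
        nbs[[j]] <- setdiff(nbs[[j]], i)
      }
    }
  }
  list(pix = pix, id_of = id_of, nbs = nbs, deg = lengths(nbs))
}

# connected components over an adjacency list; returns component id per node
graph_components <- function(nbs) {
  n <- length(nbs)
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (u in nbs[[v]]) if (comp[u] == 0L) {
        comp[u] <- cid
        queue <- c(queue, u)
      }
    }
  }
  comp
}

# iteratively remove endpoint-terminated spurs shorter than prune_len that
# attach to a junction (degree >= 3 in the reduced graph)
prune_spurs <- function(sk, prune_len) {
  repeat {
    g <- skeleton_graph(sk)
    if (nrow(g$pix) == 0) return(sk)
    drop <- integer(0)
    for (e in which(g$deg == 1L)) {
      path <- e
      prev <- 0L; cur <- e
      len <- 0
      repeat {
        nxt <- setdiff(g$nbs[[cur]], prev)
        if (length(nxt) == 0L) { path <- integer(0); break }
        nxt <- nxt[1]
        len <- len + if (sum(abs(g$pix[cur, ] - g$pix[nxt, ])) == 2L)
          sqrt(2) else 1
        if (g$deg[nxt] >= 3L) break  # reached a junction: path is a spur
        if (g$deg[nxt] == 1L || len >= prune_len) {
          path <- integer(0); break  # isolated segment or long branch
        }
        prev <- cur; cur <- nxt
        path <- c(path, cur)
      }
      if (length(path) > 0 && len < prune_len) drop <- c(drop, path)
    }
    if (length(drop) == 0) return(sk)
    sk[g$pix[unique(drop), , drop = FALSE]] <- FALSE
  }
}

#' Skeleton network metrics
#'
#' Classifies skeleton pixels by their degree in the reduced pixel graph
#' (1 = endpoint, 2 = internal, >= 3 = junction), counts junctions as
#' clusters of junction pixels (thinning can spread one biological node
#' over adjacent pixels; clusters count once), enumerates branches as the
#' connected components of the non-junction pixels (maximal paths, cycles,
#' or isolated pixels), and measures branch length as 1 per orthogonal and
#' sqrt(2) per diagonal step including the connection steps into adjacent
#' junction nodes.
#'
#' @param skeleton logical 1-px skeleton matrix (e.g. from
#'   [skeletonize()]). Any 2x2 solid block is rejected as non-skeletal.
#' @param junction_merge_dist chessboard distance (px) within which junction
#'   pixels are treated as one node. The default 1 is plain 8-adjacency
#'   clustering; 2 additionally merges junction pixels separated by one
#'   bridge pixel, which thinning routinely produces at high-degree nodes
#'   (such bridges are absorbed into the node, not counted as branches).
#' @return list: `branches`, `junctions`, `total_length_px`, and
#'   `per_network` data.frame (one row per connected component: `network`,
#'   `branches`, `junctions`, `total_length_px`, `n_pixels`).
#' @export
network_metrics <- function(skeleton, junction_merge_dist = 1) {
  if (!is.matrix(skeleton)) stop_fq("`skeleton` must be a matrix")
  sk <- skeleton > 0
  if (any(sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
          sk[-nrow(sk), -1] & sk[-1, -1]))
    stop_fq("input is not a 1-px skeleton (contains a solid 2x2 block)")
  comp <- label_components(sk, 8L)
  n_comp <- max(comp)
  per <- data.frame(network = seq_len(n_comp), branches = 0L,
                    junctions = 0L, total_length_px = 0,
                    n_pixels = as.numeric(tabulate(comp[comp > 0], n_comp)))
  if (n_comp == 0)
    return(list(branches = 0L, junctions = 0L, total_length_px = 0,
                per_network = per))

  g <- skeleton_graph(sk)
  pix <- g$pix; nbs <- g$nbs; deg <- g$deg
  is_junc <- deg >= 3L
  jmask <- matrix(FALSE, nrow(sk), ncol(sk))
  jmask[pix[is_junc, , drop = FALSE]] <- TRUE
  jseed <- if (junction_merge_dist > 1)
    dilate_cheb(jmask, junction_merge_dist - 1L) else jmask
  jclust <- label_components(jseed, 8L)
  cluster_of <- rep(0L, nrow(pix))
  cluster_of[is_junc] <- jclust[pix[is_junc, , drop = FALSE]]
  step_len <- function(i, j) {
    if (sum(abs(pix[i, ] - pix[j, ])) == 2L) sqrt(2) else 1
  }
  add_branch <- function(compid, len) {
    per$branches[compid] <<- per$branches[compid] + 1L
    per$total_length_px[compid] <<- per$total_length_px[compid] + len
  }

  # branches = connected components of the non-junction ("slab") pixels in
  # the reduced pixel graph; each is a maximal path (or cycle / isolated px)
  slab_ids <- which(!is_junc)
  remap <- match(seq_along(deg), slab_ids)
  slab_nbs <- lapply(slab_ids, function(i) {
    v <- remap[intersect(nbs[[i]], slab_ids)]
    v[!is.na(v)]
  })
  seg_of <- graph_components(slab_nbs)
  for (seg in unique(seg_of)) {
    members <- slab_ids[seg_of == seg]
    compid <- comp[pix[members[1], 1], pix[members[1], 2]]
    nb_in <- lapply(members, function(i) intersect(nbs[[i]], members))
    sdeg <- lengths(nb_in)
    names(nb_in) <- members
    if (length(members) == 1L) {
      path <- members
    } else if (all(sdeg == 2L)) {
      # pure cycle: one branch, no junction connections
      start <- members[1]
      prev <- start; cur <- nb_in[[1]][1]
      len <- step_len(start, cur)
      while (cur != start) {
        nxt <- setdiff(nb_in[[as.character(cur)]], prev)[1]
        len <- len + step_len(cur, nxt)
        prev <- cur; cur <- nxt
      }
      add_branch(compid, len)
      next
    } else {
      # path: traverse from one slab end
      start <- members[which(sdeg <= 1L)[1]]
      path <- start
      cur <- start
      while (TRUE) {
        nxt <- setdiff(nb_in[[as.character(cur)]], path)
        if (length(nxt) == 0L) break
        if (length(nxt) > 1L) {
          d <- vapply(nxt, function(j) step_len(cur, j), 1)
          nxt <- nxt[order(d)]
        }
        path <- c(path, nxt[1])
        cur <- nxt[1]
      }
    }
    len <- 0
    if (length(path) > 1L)
      for (i in seq_len(length(path) - 1L))
        len <- len + step_len(path[i], path[i + 1L])
    # connection steps from the path ends to adjacent junction nodes
    ends <- unique(c(path[1], path[length(path)]))
    end_clusters <- integer(0)
    n_conn <- 0L
    for (e in ends) {
      jn <- nbs[[e]][cluster_of[nbs[[e]]] > 0L]
      if (length(jn) == 0L) next
      d <- vapply(jn, function(j) step_len(e, j), 1)
      o <- order(d)
      take <- if (length(ends) == 1L) min(2L, length(jn)) else 1L
      for (ix in o[seq_len(take)]) {
        len <- len + d[ix]
        n_conn <- n_conn + 1L
        end_clusters <- c(end_clusters, cluster_of[jn[ix]])
      }
    }
    # a short segment whose both ends land in the same merged junction node
    # is a thinning artifact inside the node, not a branch
    intra_node <- n_conn >= 2L && length(unique(end_clusters)) == 1L &&
      len <= 2 * junction_merge_dist
    if (!intra_node) add_branch(compid, len)
  }
  per$junctions <- vapply(seq_len(n_comp), function(cid) {
    cl <- cluster_of[comp[pix] == cid]
    length(unique(cl[cl > 0]))
  }, 0L)
  list(branches = sum(per$branches), junctions = sum(per$junctions),
       total_length_px = sum(per$total_length_px), per_network = per)
}

#' Per-condition aggregation of morphology and network records
#'
#' Aggregates the per-image metrics of one experimental condition: for each
#' image the object totals (area, perimeter), object means (form factor,
#' aspect ratio) and network totals (branch length, branches, junctions),
#' plus condition-level totals and means across images.
#'
#' @param images list with one entry per image, each a list with elements
#'   `morph` (data.frame from [object_metrics()]) and `network` (list from
#'   [network_metrics()]); either may be NULL.
#' @return list: `per_image` data.frame and `totals` / `means` named
#'   vectors across images.
#' @export
condition_summary <- function(images) {
  if (!is.list(images) || length(images) == 0)
    stop_fq("`images` must be a non-empty list")
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    m <- im$morph; nw <- im$network
    data.frame(
      image = i,
      total_area_px = if (!is.null(m)) sum(m$area_px) else NA_real_,
      total_perimeter_px = if (!is.null(m)) sum(m$perimeter_px) else NA_real_,
      mean_form_factor = if (!is.null(m)) mean(m$form_factor, na.rm = TRUE)
                         else NA_real_,
      mean_aspect_ratio = if (!is.null(m)) mean(m$aspect_ratio, na.rm = TRUE)
                          else NA_real_,
      total_branch_length_px = if (!is.null(nw)) nw$total_length_px
                               else NA_real_,
      branches = if (!is.null(nw)) nw$branches else NA_real_,
      junctions = if (!is.null(nw)) nw$junctions else NA_real_
    )
  })
  per_image <- do.call(rbind, rows)
  metrics <- per_image[, -1, drop = FALSE]
  list(per_image = per_image,
       totals = colSums(as.matrix(metrics)),
       means = colMeans(as.matrix(metrics)))
}
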