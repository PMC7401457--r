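#' Skeletonize a binary perfusion slab
#'
#' Reduces the perfused foreground to a trace one pixel in width by
#' topology-preserving morphological thinning (Guo-Hall two-subiteration
#' scheme, followed by a conservative cleanup pass that removes residual
#' 2 x 2 foreground blocks without changing local connectivity). The result
#' keeps one skeleton pixel for every 8-connected component of the input,
#' including isolated pixels, and erodes free line ends by at most a
#' couple of pixels.
#'
#' @param slab A [binary_slab].
#' @return A [skeleton_slab] on the same grid.
#' @export
skeletonize_slab <- function(slab) {
  stopifnot(inherits(slab, "binary_slab"))
  sk <- thin_guo_hall(slab$pixels)
  # junction blobs the parallel scheme cannot thin further are resolved by
  # simple-point deletions (with an X-crossing rewrite for pinwheel
  # blocks), re-thinning in between, until stable
  for (it in 1:30) {
    if (!any_full_2x2(sk)) break
    sk2 <- prune_2x2_blocks(sk)
    if (identical(sk2, sk)) sk2 <- rewrite_pinwheels(sk2)
    sk2 <- thin_guo_hall(sk2)
    if (identical(sk2, sk)) break
    sk <- sk2
  }
  skeleton_slab(sk, slab$pixel_spacing_mm)
}

# shift matrix by (dr, dc), zero-filling
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighborhood of every pixel, clockwise from north:
# p2=N, p3=NE, p4=E, p5=SE, p6=S, p7=SW, p8=W, p9=NW
neighborhood8 <- function(m) {
  list(p2 = shift_mat(m,  1,  0), p3 = shift_mat(m,  1, -1),
       p4 = shift_mat(m,  0, -1), p5 = shift_mat(m, -1, -1),
       p6 = shift_mat(m, -1,  0), p7 = shift_mat(m, -1,  1),
       p8 = shift_mat(m,  0,  1), p9 = shift_mat(m,  1,  1))
}

# Guo-Hall (1989) two-subiteration thinning, fully vectorized over the grid.
thin_guo_hall <- function(m) {
  m <- m * 1
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- neighborhood8(m)
      C <- (1 - nb$p2) * pmax(nb$p3, nb$p4) + (1 - nb$p4) * pmax(nb$p5, nb$p6) +
        (1 - nb$p6) * pmax(nb$p7, nb$p8) + (1 - nb$p8) * pmax(nb$p9, nb$p2)
      N1 <- pmax(nb$p9, nb$p2) + pmax(nb$p3, nb$p4) +
        pmax(nb$p5, nb$p6) + pmax(nb$p7, nb$p8)
      N2 <- pmax(nb$p2, nb$p3) + pmax(nb$p4, nb$p5) +
        pmax(nb$p6, nb$p7) + pmax(nb$p8, nb$p9)
      N <- pmin(N1, N2)
      o <- if (step == 1) {
        pmax(nb$p6, nb$p7, 1 - nb$p9) * nb$p8
      } else {
        pmax(nb$p2, nb$p3, 1 - nb$p5) * nb$p4
      }
      del <- m == 1 & C == 1 & N >= 2 & N <= 3 & o == 0
      if (any(del)) {
        m[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# 8-simple point test on the padded matrix mp at padded coords (r, c):
# deleting the pixel changes neither foreground 8-connectivity nor
# background 4-connectivity in its neighborhood.
is_simple_8 <- function(mp, r, c, strict = TRUE) {
  patch <- mp[(r - 1):(r + 1), (c - 1):(c + 1)]
  ctr <- patch[2, 2]
  if (ctr != 1) return(FALSE)
  ring_idx <- cbind(c(1, 1, 1, 2, 2, 3, 3, 3), c(1, 2, 3, 1, 3, 1, 2, 3))
  fg <- ring_idx[patch[ring_idx] == 1, , drop = FALSE]
  if (nrow(fg) == 0) return(FALSE)  # isolated pixel: keep
  # foreground 8-components among ring pixels
  n_fg_comp <- patch_components(fg, function(a, b)
    max(abs(a - b)) <= 1)
  if (n_fg_comp != 1) return(FALSE)
  if (!strict) return(TRUE)
  # background 4-components among ring pixels, counted only if 4-adjacent
  # to the center (hole-preservation side of the duality)
  bg <- ring_idx[patch[ring_idx] == 0, , drop = FALSE]
  bg4 <- bg[abs(bg[, 1] - 2) + abs(bg[, 2] - 2) == 1, , drop = FALSE]
  if (nrow(bg4) == 0) return(FALSE)  # interior pixel
  # components of the full background ring under 4-adjacency, then count
  # those containing a 4-neighbor of the center
  if (nrow(bg) == 1) return(TRUE)
  lab <- patch_component_labels(bg, function(a, b) sum(abs(a - b)) == 1)
  length(unique(lab[abs(bg[, 1] - 2) + abs(bg[, 2] - 2) == 1])) == 1
}

patch_component_labels <- function(pts, adj) {
  n <- nrow(pts)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] != lab[j] && adj(pts[i, ], pts[j, ])) {
        lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

patch_components <- function(pts, adj) length(unique(patch_component_labels(pts, adj)))

# Resolve "pinwheel" 2x2 blocks: two 1-px diagonal traces crossing leave a
# 2x2 block with one diagonal arm per corner, which no topology-preserving
# single deletion can reduce. Rewrite the junction: drop the anti-diagonal
# pair and re-attach their arms with one pixel each, keeping the crossing
# connected and 1 px wide. Added pixels border former foreground, so the
# skeleton stays inside the 1-px dilation of its source.
rewrite_pinwheels <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  blk <- m[-nr, -nc] + m[-1, -nc] + m[-nr, -1] + m[-1, -1]
  hits <- which(blk == 4, arr.ind = TRUE)
  for (i in seq_len(nrow(hits))) {
    r <- hits[i, 1]; c <- hits[i, 2]
    if (!(m[r, c] & m[r, c + 1] & m[r + 1, c] & m[r + 1, c + 1])) next
    m[r, c + 1] <- 0      # b: top-right of the block
    m[r + 1, c] <- 0      # c: bottom-left
    ne_arm <- r - 1 >= 1 && c + 2 <= nc && m[r - 1, c + 2] == 1
    sw_arm <- r + 2 <= nr && c - 1 >= 1 && m[r + 2, c - 1] == 1
    if (ne_arm) m[r - 1, c + 1] <- 1
    if (sw_arm) m[r + 2, c] <- 1
  }
  m
}

# Remove pixels of residual all-foreground 2x2 blocks one at a time,
# preferring fully 8-simple deletions (connectivity, holes and endpoints
# all preserved). When a sweep stalls — thick junctions pinched between
# adjacent one-pixel holes admit no hole-preserving deletion — a single
# fallback deletion is made that still preserves foreground connectivity
# but may merge a spurious one-pixel hole with the background.
prune_2x2_blocks <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    blk <- m[-nr, -nc] + m[-1, -nc] + m[-nr, -1] + m[-1, -1]
    hits <- which(blk == 4, arr.ind = TRUE)
    if (nrow(hits) == 0) return(m)
    progress <- FALSE
    for (strict in c(TRUE, FALSE)) {
      for (i in seq_len(nrow(hits))) {
        hit <- hits[i, ]
        mp <- matrix(0, nr + 2, nc + 2)
        mp[2:(nr + 1), 2:(nc + 1)] <- m
        for (off in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
          r <- hit[1] + off[1]; c <- hit[2] + off[2]
          if (m[r, c] == 1 && is_simple_8(mp, r + 1, c + 1, strict = strict)) {
            m[r, c] <- 0
            progress <- TRUE
            break
          }
        }
        if (!strict && progress) break  # one fallback deletion, then re-sweep
      }
      if (progress) break
    }
    if (!progress) return(m)
  }
}
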