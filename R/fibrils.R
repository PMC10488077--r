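#' Nematic-tensor anisotropy of a fibril image
#'
#' Implements the image-gradient nematic tensor: intensity gradients are
#' estimated by central differences (border pixels excluded), each pixel
#' contributes its tangent direction (perpendicular to the gradient)
#' weighted by squared gradient magnitude to a mean 2x2 orientation tensor,
#' and the score is the normalized eigenvalue difference
#' (lambda1 - lambda2) / (lambda1 + lambda2). The magnitude weighting means
#' high-contrast fibril edges dominate and flat background contributes
#' next to nothing. A score of 1 means perfectly parallel texture, 0
#' isotropic texture. The score is exactly invariant to affine intensity
#' rescaling.
#'
#' @param img Numeric matrix of grayscale intensities (rows = y, cols = x),
#'   at least 3 x 3.
#' @param grad_floor Pixels whose squared gradient magnitude is below
#'   `grad_floor` times the image maximum are excluded (default 1e-12).
#' @return An object of class `anisotropy_score`: `score` in [0, 1],
#'   `mean_orientation` (radians, axial, measured from the x/column axis),
#'   `n_pixels` used.
#' @export
anisotropy <- function(img, grad_floor = 1e-12) {
  img <- as.matrix(img)
  if (nrow(img) < 3 || ncol(img) < 3) stop("image must be at least 3 x 3")
  if (!all(is.finite(img))) stop("image must be finite")
  m <- nrow(img); n <- ncol(img)
  ii <- 2:(m - 1); jj <- 2:(n - 1)
  gx <- (img[ii, jj + 1] - img[ii, jj - 1]) / 2
  gy <- (img[ii + 1, jj] - img[ii - 1, jj]) / 2
  g2 <- gx^2 + gy^2
  keep <- g2 > grad_floor * max(g2, 0)
  if (max(g2) == 0 || !any(keep)) {
    stop("zero gradient energy: anisotropy undefined for a constant image")
  }
  # tangent (fibril) direction is the gradient rotated by 90 degrees;
  # contributions carry their squared gradient magnitude as weight
  tx <- gy[keep]
  ty <- -gx[keep]
  nxx <- mean(tx^2); nxy <- mean(tx * ty); nyy <- mean(ty^2)
  score <- sqrt((nxx - nyy)^2 + 4 * nxy^2) / (nxx + nyy)
  theta <- 0.5 * atan2(2 * nxy, nxx - nyy)
  theta <- theta %% pi
  structure(list(score = score, mean_orientation = theta,
                 n_pixels = sum(keep)),
            class = "anisotropy_score")
}

#' @export
print.anisotropy_score <- function(x, ...) {
  cat(sprintf("<anisotropy_score> %.4f, mean orientation %.1f deg (%d px)\n",
              x$score, x$mean_orientation * 180 / pi, x$n_pixels))
  invisible(x)
}

#' Parallel-stripe test pattern
#'
#' Sinusoidal stripes at a fixed orientation: the canonical perfectly
#' anisotropic texture (every gradient shares one direction), useful as the
#' upper-limit fixture for [anisotropy()].
#'
#' @param size Image side in pixels.
#' @param period Stripe period in pixels (default 8).
#' @param theta Stripe normal direction in radians measured from the x axis
#'   (the fibrils run at `theta + pi/2`); default 0.
#' @return A `size` x `size` numeric matrix in [0, 1].
#' @export
stripe_image <- function(size, period = 8, theta = 0) {
  x <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  y <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  0.5 + 0.5 * sin(2 * pi * (x * cos(theta) + y * sin(theta)) / period)
}

#' Segment fibrillar foreground
#'
#' Otsu global thresholding of the (range-normalized) image. With
#' `invert = TRUE` the intensity polarity is flipped before thresholding so
#' dark-fiber images produce the same mask as their bright-fiber
#' counterparts.
#'
#' @param img Numeric grayscale matrix.
#' @param method Thresholding method; only `"otsu"` is implemented.
#' @param invert Logical polarity flag (default `FALSE` = bright fibers).
#' @return Logical matrix of foreground pixels with attributes `threshold`,
#'   `method` and `empty` (flag set when no foreground was found).
#' @export
segment_fibers <- function(img, method = "otsu", invert = FALSE) {
  img <- as.matrix(img)
  method <- match.arg(method, "otsu")
  rng <- range(img)
  if (diff(rng) == 0) {
    mask <- matrix(FALSE, nrow(img), ncol(img))
    attr(mask, "threshold") <- NA_real_
    attr(mask, "method") <- method
    attr(mask, "empty") <- TRUE
    return(mask)
  }
  x <- (img - rng[1]) / diff(rng)
  if (invert) x <- 1 - x
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)
  mask <- x > th
  attr(mask, "threshold") <- th
  attr(mask, "method") <- method
  attr(mask, "empty") <- !any(mask)
  mask
}

# Douglas-Peucker polyline simplification. The tolerance (1.5 px) removes
# both the staircase zigzag of 8-connected chains and the +/-1 px weave the
# thinning pass leaves where a slanted stroke keeps a two-pixel-wide
# staircase, so arc lengths are not systematically inflated by pixelation.
simplify_path <- function(p, tol = 1.5) {
  n <- nrow(p)
  if (n <= 2) return(p)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    a <- p[i, ]; b <- p[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    idx <- (i + 1):(j - 1)
    dx <- p[idx, 1] - a[1]; dy <- p[idx, 2] - a[2]
    d <- if (len2 == 0) {
      sqrt(dx^2 + dy^2)
    } else {
      abs(dx * ab[2] - dy * ab[1]) / sqrt(len2)
    }
    k <- which.max(d)
    if (d[k] > tol) {
      keep[idx[k]] <- TRUE
      stack <- c(stack, list(c(i, idx[k])), list(c(idx[k], j)))
    }
  }
  p[keep, , drop = FALSE]
}

# Zhang-Suen thinning of a logical mask to a 1-px skeleton.
skeletonize <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  img <- matrix(0L, m + 2, n + 2)
  img[2:(m + 1), 2:(n + 1)] <- mask * 1L
  core_i <- 2:(m + 1); core_j <- 2:(n + 1)
  nb <- function(img, di, dj) img[core_i + di, core_j + dj]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- nb(img, -1, 0); p3 <- nb(img, -1, 1); p4 <- nb(img, 0, 1)
      p5 <- nb(img, 1, 1);  p6 <- nb(img, 1, 0);  p7 <- nb(img, 1, -1)
      p8 <- nb(img, 0, -1); p9 <- nb(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      core <- img[core_i, core_j]
      if (step == 1) {
        del <- core == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        del <- core == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(del)) {
        core[del] <- 0L
        img[core_i, core_j] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[core_i, core_j] == 1L
}

#' Trace fibers from a binary mask
#'
#' Defined tracing procedure: the mask is thinned to a 1-pixel skeleton
#' (Zhang-Suen), skeleton junction pixels (crossing number >= 3) are removed
#' so each remaining 8-connected component is a branchless chain, each chain
#' is walked end to end (lexicographic pixel order breaks ties, making runs
#' deterministic), chains are re-joined across junctions by collinearity so
#' fiber crossings do not fragment traces, and each polyline is simplified
#' with a 1.5 px Douglas-Peucker tolerance to remove pixelation zigzag.
#' Per fiber: length is the polyline arc length, width the mean over the
#' path of twice the Euclidean distance transform minus one (the local
#' stroke width), and straightness the endpoint (chord) distance divided by
#' the arc length.
#'
#' @param mask Logical matrix, e.g. from [segment_fibers()].
#' @param min_length Minimum arc length in pixels to keep a trace
#'   (default 10).
#' @return A data frame with columns `fiber_id`, `length_px`, `width_px`,
#'   `straightness` and `n_vertices`; the ordered pixel polylines are
#'   attached as the `paths` attribute (list of two-column matrices,
#'   row/column coordinates).
#' @export
trace_fibers <- function(mask, min_length = 10) {
  mask <- as.matrix(mask) > 0
  empty <- data.frame(fiber_id = integer(0), length_px = numeric(0),
                      width_px = numeric(0), straightness = numeric(0),
                      n_vertices = integer(0))
  attr(empty, "paths") <- list()
  if (!any(mask)) return(empty)
  skel <- skeletonize(mask)
  if (!any(skel)) return(empty)
  dmap <- EBImage::distmap(EBImage::Image(mask * 1))
  dmap <- as.matrix(EBImage::imageData(dmap))
  m <- nrow(skel); n <- ncol(skel)
  pad <- matrix(0L, m + 2, n + 2)
  pad[2:(m + 1), 2:(n + 1)] <- skel * 1L
  nb <- function(di, dj) pad[2:(m + 1) + di, 2:(n + 1) + dj]
  p2 <- nb(-1, 0); p3 <- nb(-1, 1); p4 <- nb(0, 1); p5 <- nb(1, 1)
  p6 <- nb(1, 0); p7 <- nb(1, -1); p8 <- nb(0, -1); p9 <- nb(-1, -1)
  # crossing number: junctions have >= 3 branch transitions around them;
  # staircase pixels of an 8-connected chain do not
  a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  junction <- skel & a >= 3
  # drop junction pixels and their 8-neighbourhood: arm tips around a
  # junction are mutually diagonal-adjacent, so removing the junction pixel
  # alone would leave the arms connected; collinearity bridging re-joins them
  jz <- junction
  if (any(junction)) {
    jpad <- matrix(FALSE, m + 2, n + 2)
    jpad[2:(m + 1), 2:(n + 1)] <- junction
    for (di in -1:1) for (dj in -1:1) {
      jz <- jz | jpad[2:(m + 1) + di, 2:(n + 1) + dj]
    }
  }
  chain <- skel & !jz
  if (!any(chain)) return(empty)
  coords <- which(chain, arr.ind = TRUE)
  # map from pixel to index for O(1) neighbour lookup
  key <- function(i, j) (j - 1) * m + i
  idx_of <- new.env(hash = TRUE, size = nrow(coords))
  for (r in seq_len(nrow(coords))) {
    assign(as.character(key(coords[r, 1], coords[r, 2])), r, envir = idx_of)
  }
  neighbours <- function(i, j) {
    out <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > m || jj < 1 || jj > n) next
      if (chain[ii, jj]) {
        r <- get0(as.character(key(ii, jj)), envir = idx_of)
        if (!is.null(r)) out <- c(out, r)
      }
    }
    out
  }
  nbr <- lapply(seq_len(nrow(coords)),
                function(r) neighbours(coords[r, 1], coords[r, 2]))
  visited <- rep(FALSE, nrow(coords))
  # lexicographic order (row, then column) for deterministic starts
  lex <- order(coords[, 1], coords[, 2])
  traces <- list()
  for (r0 in lex) {
    if (visited[r0]) next
    # collect the connected component by BFS
    comp <- integer(0); queue <- r0; visited[r0] <- TRUE
    while (length(queue)) {
      r <- queue[1]; queue <- queue[-1]
      comp <- c(comp, r)
      for (s in nbr[[r]]) if (!visited[s]) { visited[s] <- TRUE; queue <- c(queue, s) }
    }
    degc <- vapply(comp, function(r) sum(nbr[[r]] %in% comp), integer(1))
    ends <- comp[degc <= 1]
    start <- if (length(ends)) {
      ends[order(coords[ends, 1], coords[ends, 2])][1]
    } else {
      comp[order(coords[comp, 1], coords[comp, 2])][1]  # closed loop
    }
    # walk the chain; prefer orthogonal over diagonal steps so staircase
    # triangles are traversed in order instead of dead-ending mid-chain
    walk_from <- function(start, inpath) {
      path <- start
      inpath[start] <- TRUE
      cur <- start
      repeat {
        nxt <- nbr[[cur]]
        nxt <- nxt[!inpath[nxt]]
        if (!length(nxt)) break
        if (length(nxt) > 1) {
          dd <- abs(coords[nxt, 1] - coords[cur, 1]) +
            abs(coords[nxt, 2] - coords[cur, 2])
          nxt <- nxt[order(dd, coords[nxt, 1], coords[nxt, 2])]
        }
        cur <- nxt[1]
        path <- c(path, cur)
        inpath[cur] <- TRUE
      }
      path
    }
    inpath <- rep(FALSE, nrow(coords))
    path <- walk_from(start, inpath)
    inpath[path] <- TRUE
    traces[[length(traces) + 1]] <- coords[path, , drop = FALSE]
    # safety: trace any component pixels the main walk could not reach
    left <- comp[!inpath[comp]]
    while (length(left)) {
      degl <- vapply(left, function(r) sum(nbr[[r]] %in% left), integer(1))
      s2 <- left[degl <= 1]
      s2 <- if (length(s2)) s2[order(coords[s2, 1], coords[s2, 2])][1] else
        left[order(coords[left, 1], coords[left, 2])][1]
      p2 <- walk_from(s2, inpath)
      inpath[p2] <- TRUE
      if (length(p2) > 1) {
        traces[[length(traces) + 1]] <- coords[p2, , drop = FALSE]
      }
      left <- comp[!inpath[comp]]
    }
  }
  if (any(junction)) {
    traces <- bridge_junctions(traces, which(jz, arr.ind = TRUE))
  }
  rows <- list(); paths <- list()
  fid <- 0L
  for (p0 in traces) {
    if (nrow(p0) < 2) next
    p <- simplify_path(p0)
    d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
    arc <- sum(d)
    if (arc < min_length) next
    chord <- sqrt((p[nrow(p), 1] - p[1, 1])^2 + (p[nrow(p), 2] - p[1, 2])^2)
    width <- max(1, mean(2 * dmap[p0] - 1))
    fid <- fid + 1L
    rows[[fid]] <- data.frame(fiber_id = fid, length_px = arc,
                              width_px = width,
                              straightness = min(1, chord / arc),
                              n_vertices = nrow(p))
    paths[[fid]] <- p
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "paths") <- paths
  out
}

# Re-join skeleton chains across junctions left by crossing fibers: at each
# junction zone (connected component of the carved-out junction
# neighbourhood, passed as `jcoords`), incident chain ends are paired
# greedily by collinearity (traversal directions closest to opposite),
# within a 45-degree deviation gate, and the paired chains are
# concatenated. This mirrors how fiber extraction tools resolve crossings
# so a crossing does not cut one fiber into four stubs.
bridge_junctions <- function(traces, jcoords, max_angle = 45) {
  if (!length(traces) || is.null(nrow(jcoords)) || nrow(jcoords) == 0) {
    return(traces)
  }
  # cluster adjacent junction pixels (chebyshev distance <= 1)
  nj <- nrow(jcoords)
  cl <- integer(nj)
  cur <- 0L
  for (i in seq_len(nj)) {
    if (cl[i] > 0) next
    cur <- cur + 1L
    queue <- i; cl[i] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      near <- which(cl == 0 &
                      abs(jcoords[, 1] - jcoords[q, 1]) <= 1 &
                      abs(jcoords[, 2] - jcoords[q, 2]) <= 1)
      cl[near] <- cur
      queue <- c(queue, near)
    }
  }
  # chain endpoints adjacent to a junction pixel, with inbound direction
  ends <- list()
  for (s in seq_along(traces)) {
    p <- traces[[s]]
    n <- nrow(p)
    for (e in 1:2) {
      pt <- if (e == 1) p[1, ] else p[n, ]
      hit <- which(abs(jcoords[, 1] - pt[1]) <= 1 &
                     abs(jcoords[, 2] - pt[2]) <= 1)
      if (!length(hit)) next
      # local direction from ~8 px back along the chain (pixel-noise robust)
      q <- if (e == 1) p else p[rev(seq_len(n)), , drop = FALSE]
      steps <- sqrt(diff(q[, 1])^2 + diff(q[, 2])^2)
      back <- which(cumsum(steps) >= 8)[1]
      if (is.na(back)) back <- n - 1
      d <- pt - q[back + 1, ]
      nd <- sqrt(sum(d^2))
      if (nd == 0) next
      ends[[length(ends) + 1]] <- list(seg = s, end = e, pt = pt,
                                       cluster = cl[hit[1]], dir = d / nd)
    }
  }
  if (length(ends) < 2) return(traces)
  links <- list()
  used <- rep(FALSE, length(ends))
  for (cc in unique(vapply(ends, `[[`, integer(1), "cluster"))) {
    idx <- which(!used & vapply(ends, `[[`, integer(1), "cluster") == cc)
    while (length(idx) >= 2) {
      gate <- cos(max_angle * pi / 180)
      best <- NULL; best_score <- -Inf
      for (i in seq_along(idx)) {
        for (j in seq_along(idx)) {
          if (j <= i) next
          a <- ends[[idx[i]]]; b <- ends[[idx[j]]]
          if (a$seg == b$seg && a$end == b$end) next
          coll <- -sum(a$dir * b$dir)  # 1 when perfectly collinear
          if (coll <= gate) next
          # the bridge across the junction must continue a's direction and
          # run against b's: rejects pairing two arms on the same side
          gap <- b$pt - a$pt
          ng <- sqrt(sum(gap^2))
          gsc <- if (ng == 0) 1 else
            0.5 * (sum(a$dir * gap) - sum(b$dir * gap)) / ng
          if (gsc < 0.3) next
          score <- coll + gsc
          if (score > best_score) { best <- c(idx[i], idx[j]); best_score <- score }
        }
      }
      if (is.null(best)) break
      links[[length(links) + 1]] <- list(a = ends[[best[1]]],
                                         b = ends[[best[2]]])
      used[best] <- TRUE
      idx <- setdiff(idx, best)
    }
  }
  # second pass: shallow crossings thin to two Y-junctions sharing a middle
  # chain, and the middle can only be linked into one of the two fibers;
  # re-join the leftover arm pair straight across the shared stretch
  # (stricter collinearity, bounded gap)
  free <- which(!used)
  if (length(free) >= 2) {
    gate2 <- cos(25 * pi / 180)
    repeat {
      best <- NULL; best_score <- -Inf
      for (i in seq_along(free)) {
        for (j in seq_along(free)) {
          if (j <= i) next
          a <- ends[[free[i]]]; b <- ends[[free[j]]]
          if (a$seg == b$seg) next
          gap <- b$pt - a$pt
          ng <- sqrt(sum(gap^2))
          if (ng > 40) next
          coll <- -sum(a$dir * b$dir)
          if (coll <= gate2) next
          gsc <- if (ng == 0) 1 else
            0.5 * (sum(a$dir * gap) - sum(b$dir * gap)) / ng
          if (gsc < gate2) next
          score <- coll + gsc - ng / 100
          if (score > best_score) { best <- c(free[i], free[j]); best_score <- score }
        }
      }
      if (is.null(best)) break
      links[[length(links) + 1]] <- list(a = ends[[best[1]]],
                                         b = ends[[best[2]]])
      used[best] <- TRUE
      free <- setdiff(free, best)
      if (length(free) < 2) break
    }
  }
  if (!length(links)) return(traces)
  # each (seg, end) participates in at most one link; follow link chains
  link_of <- vector("list", length(traces))
  for (s in seq_along(traces)) link_of[[s]] <- vector("list", 2)
  for (l in links) {
    link_of[[l$a$seg]][[l$a$end]] <- l$b
    link_of[[l$b$seg]][[l$b$end]] <- l$a
  }
  seg_used <- rep(FALSE, length(traces))
  out <- list()
  # start at segments with a free (unlinked) end first so every merged
  # fiber is walked from its tip; leftovers are closed loops
  has_free <- vapply(seq_along(traces), function(s) {
    is.null(link_of[[s]][[1]]) || is.null(link_of[[s]][[2]])
  }, logical(1))
  for (s0 in c(which(has_free), which(!has_free))) {
    if (seg_used[s0]) next
    start_end <- if (is.null(link_of[[s0]][[1]])) 1L
      else if (is.null(link_of[[s0]][[2]])) 2L else 1L
    path <- NULL
    s <- s0; enter <- start_end
    repeat {
      seg_used[s] <- TRUE
      p <- traces[[s]]
      if (enter == 2) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      path <- if (is.null(path)) p else rbind(path, p)
      exit <- if (enter == 1) 2L else 1L
      nxt <- link_of[[s]][[exit]]
      if (is.null(nxt) || seg_used[nxt$seg]) break
      s <- nxt$seg; enter <- nxt$end
    }
    out[[length(out) + 1]] <- path
  }
  out
}

#' Morphometry of one region-of-interest image
#'
#' Segments, traces and aggregates: per-ROI mean fiber length, width and
#' straightness plus the single nematic-tensor anisotropy score of the whole
#' image. Sub-operation flags (empty segmentation, undefined anisotropy) are
#' propagated in the `flags` field, never dropped.
#'
#' @param img Numeric grayscale matrix.
#' @param region_label Optional label, e.g. `"Sc-ACA"`.
#' @param min_length Passed to [trace_fibers()].
#' @param invert Passed to [segment_fibers()].
#' @return One-row data frame: `region_label`, `n_fibers`, `mean_length`,
#'   `mean_width`, `mean_straightness`, `anisotropy`, `flags`.
#' @export
roi_morphometry <- function(img, region_label = NA_character_,
                            min_length = 10, invert = FALSE) {
  flags <- character(0)
  mask <- segment_fibers(img, invert = invert)
  if (isTRUE(attr(mask, "empty"))) flags <- c(flags, "empty_segmentation")
  tr <- trace_fibers(mask, min_length = min_length)
  ani <- tryCatch(anisotropy(img)$score, error = function(e) {
    flags <<- c(flags, "undefined_anisotropy")
    NA_real_
  })
  nf <- nrow(tr)
  data.frame(region_label = region_label, n_fibers = nf,
             mean_length = if (nf) mean(tr$length_px) else NA_real_,
             mean_width = if (nf) mean(tr$width_px) else NA_real_,
             mean_straightness = if (nf) mean(tr$straightness) else NA_real_,
             anisotropy = ani,
             flags = paste(flags, collapse = ";"))
}
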