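# Ridge tracing on flattened topographies: automatic mode (threshold +
# thinning + chain linking) and seeded live-wire mode (minimal-cost path
# between seed pairs on ridge-like pixels). Segments close to another
# path or to a crossing are flagged excluded.

#' Ridge path container
#'
#' @param points Matrix of subpixel (row, col) coordinates ordered along
#'   the ridge; consecutive points at most 2 px apart.
#' @param excluded Logical vector flagging points inside an
#'   overlap/crossing exclusion zone (default none).
#' @return Object of class `ridge_path`.
#' @export
ridge_path <- function(points, excluded = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    fm_error("ridge path points must be (row, col) pairs", "fm_invalid_spec")
  if (nrow(points) >= 2L) {
    gap <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
    if (any(gap > 2))
      fm_error("consecutive ridge points more than 2 px apart",
               "fm_invalid_spec")
  }
  excluded <- excluded %||% rep(FALSE, nrow(points))
  structure(list(points = points, excluded = as.logical(excluded)),
            class = "ridge_path")
}

#' @export
print.ridge_path <- function(x, ...) {
  cat(sprintf("<ridge_path> %d points (%d excluded)\n",
              nrow(x$points), sum(x$excluded)))
  invisible(x)
}

# Vectorized Zhang-Suen thinning of a logical mask down to a 1-px wide
# 8-connected skeleton.
skeletonize_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  Mp <- matrix(FALSE, nr + 2L, nc + 2L)
  Mp[2:(nr + 1L), 2:(nc + 1L)] <- mask
  shift <- function(M, dr, dc) M[(2L + dr):(nr + 1L + dr),
                                 (2L + dc):(nc + 1L + dc)]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P2 <- shift(Mp, -1L, 0L); P3 <- shift(Mp, -1L, 1L)
      P4 <- shift(Mp, 0L, 1L);  P5 <- shift(Mp, 1L, 1L)
      P6 <- shift(Mp, 1L, 0L);  P7 <- shift(Mp, 1L, -1L)
      P8 <- shift(Mp, 0L, -1L); P9 <- shift(Mp, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      core <- shift(Mp, 0L, 0L)
      cond <- core & B >= 2L & B <= 6L & A == 1L
      if (sub == 1L) {
        cond <- cond & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- cond & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        core[cond] <- FALSE
        Mp[2:(nr + 1L), 2:(nc + 1L)] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  Mp[2:(nr + 1L), 2:(nc + 1L)]
}

# 8-neighbor count for each TRUE pixel of a logical mask.
neighbor_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  Mp <- matrix(0L, nr + 2L, nc + 2L)
  Mp[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out + Mp[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  out
}

# Order the pixels of a degree-<=2 chain component by walking from an
# endpoint. `adj` is an adjacency list of local indices.
walk_chain <- function(adj, deg) {
  start <- which(deg == 1L)[1]
  if (is.na(start)) return(NULL)   # cycle: not a fibril geometry
  n <- length(adj)
  order_out <- integer(n)
  visited <- logical(n)
  cur <- start
  for (k in seq_len(n)) {
    order_out[k] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (!length(nxt)) return(order_out[seq_len(k)])
    cur <- nxt[1]
  }
  order_out
}

# Flag path points lying within `radius` px of another path or of a
# junction pixel, via an owner-matrix neighborhood lookup.
flag_exclusions <- function(paths, junctions, dim, radius) {
  nr <- dim[1]; nc <- dim[2]
  owner <- matrix(0L, nr, nc)
  for (i in seq_along(paths)) {
    p <- round(paths[[i]]$points)
    owner[cbind(pmin(pmax(p[, 1], 1L), nr), pmin(pmax(p[, 2], 1L), nc))] <- i
  }
  if (nrow(junctions))
    owner[junctions] <- -1L
  r_i <- as.integer(ceiling(radius))
  og <- expand.grid(dr = -r_i:r_i, dc = -r_i:r_i)
  og <- og[og$dr^2 + og$dc^2 <= radius^2, , drop = FALSE]
  for (i in seq_along(paths)) {
    p <- round(paths[[i]]$points)
    excl <- rep(FALSE, nrow(p))
    for (k in seq_len(nrow(og))) {
      rr <- p[, 1] + og$dr[k]; cc <- p[, 2] + og$dc[k]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      w <- owner[cbind(rr[ok], cc[ok])]
      hit <- w != 0L & w != i
      if (any(hit)) excl[which(ok)[hit]] <- TRUE
    }
    paths[[i]]$excluded <- paths[[i]]$excluded | excl
  }
  paths
}

#' Trace fibril ridges on a flattened height map
#'
#' Automatic mode (default, `seeds = NULL`): pixels above `threshold`
#' are thinned to a one-pixel skeleton (Zhang-Suen), junction pixels are
#' removed, and the remaining chains are linked into ordered paths.
#' Seeded (live-wire) mode: for each seed pair, the minimal-cost path is
#' found over ridge-like pixels with per-pixel cost
#' `w1 * (max_height - height) + w2 * |gradient|`, so the path follows
#' high, locally flat ridge crests.
#'
#' In both modes, path points within `exclusion_radius` (nm) of a
#' junction or of another path are flagged excluded and later skipped by
#' the profiler, mirroring the exclusion of overlapping and crossing
#' segments.
#'
#' @param map A flattened [height_map()].
#' @param seeds Optional list of seed pairs; each element a 2 x 2 matrix
#'   `rbind(start, end)` of (row, col) pixel coordinates.
#' @param threshold Ridge threshold in nm; default `NULL` picks
#'   `max(5 * mad(heights), 20%% of the maximum height)`.
#' @param min_length Minimum path length in pixels (automatic mode).
#' @param exclusion_radius Crossing-exclusion radius in nm; default 3x
#'   `fibril_half_width`.
#' @param fibril_half_width Expected fibril half-width in nm (default 6).
#' @param w1,w2 Live-wire cost weights (height deficit, gradient).
#' @return List of [ridge_path()] objects (empty, with a warning, if no
#'   ridge pixels are found in automatic mode).
#' @export
trace_ridges <- function(map, seeds = NULL, threshold = NULL,
                         min_length = 10L, exclusion_radius = NULL,
                         fibril_half_width = 6, w1 = 1, w2 = 0.5) {
  stopifnot(inherits(map, "height_map"))
  H <- map$heights
  px <- map$pixel_size
  excl_px <- (exclusion_radius %||% (3 * fibril_half_width)) / px
  # background-driven default: the background dominates the map, so its
  # MAD sets the noise scale; the small max-relative floor only matters
  # for noiseless synthetic maps where the MAD is ~0
  thr <- threshold %||% max(5 * stats::mad(H), 0.05 * max(H))
  mask <- H > thr
  if (!any(mask) || max(H) <= 0) {
    if (is.null(seeds)) {
      fm_warn("no ridge pixels above threshold; returning zero paths")
      return(list())
    }
    fm_error("no ridge-like pixels for live-wire tracing",
             "fm_tracing_error")
  }

  if (is.null(seeds)) {
    skel <- skeletonize_mask(mask)
    deg_all <- neighbor_count(skel)
    junction <- skel & deg_all >= 3L
    skel2 <- skel & !junction
    pix <- which(skel2, arr.ind = TRUE)
    if (!nrow(pix)) {
      fm_warn("skeleton empty after junction removal")
      return(list())
    }
    # chain adjacency among remaining skeleton pixels
    id <- matrix(0L, nrow(H), ncol(H))
    id[pix] <- seq_len(nrow(pix))
    edges <- NULL
    for (off in list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))) {
      rr <- pix[, 1] + off[1]; cc <- pix[, 2] + off[2]
      ok <- rr >= 1L & rr <= nrow(H) & cc >= 1L & cc <= ncol(H)
      nb <- integer(nrow(pix)); nb[ok] <- id[cbind(rr[ok], cc[ok])]
      has <- nb > 0L
      if (any(has))
        edges <- rbind(edges, cbind(which(has), nb[has]))
    }
    adj <- vector("list", nrow(pix))
    if (!is.null(edges)) {
      for (k in seq_len(nrow(edges))) {
        a <- edges[k, 1]; b <- edges[k, 2]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
    deg <- lengths(adj)
    comp <- rep(0L, nrow(pix))
    cid <- 0L
    for (v in seq_len(nrow(pix))) {
      if (comp[v] != 0L) next
      cid <- cid + 1L
      queue <- v
      comp[v] <- cid
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (nb in adj[[cur]]) if (comp[nb] == 0L) {
          comp[nb] <- cid
          queue <- c(queue, nb)
        }
      }
    }
    paths <- list()
    for (ci in seq_len(cid)) {
      members <- which(comp == ci)
      if (length(members) < min_length) next
      local <- match(seq_len(nrow(pix)), members)
      adj_local <- lapply(members, function(v) local[adj[[v]]])
      ord <- walk_chain(adj_local, deg[members])
      if (is.null(ord) || length(ord) < min_length) next
      paths[[length(paths) + 1L]] <-
        ridge_path(pix[members[ord], , drop = FALSE])
    }
    paths <- flag_exclusions(paths, which(junction, arr.ind = TRUE),
                             dim(H), excl_px)
    return(paths)
  }

  # seeded live-wire on candidate ridge pixels
  cand_mask <- H > min(thr, 0.5 * max(H))
  cand <- which(cand_mask, arr.ind = TRUE)
  id <- matrix(0L, nrow(H), ncol(H))
  id[cand] <- seq_len(nrow(cand))
  gr <- row_gradient_mag(H)
  cost <- w1 * (max(H) - H[cand]) + w2 * gr[cand]
  efrom <- integer(0); eto <- integer(0); ew <- numeric(0)
  for (off in list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))) {
    rr <- cand[, 1] + off[1]; cc <- cand[, 2] + off[2]
    ok <- rr >= 1L & rr <= nrow(H) & cc >= 1L & cc <= ncol(H)
    nb <- integer(nrow(cand)); nb[ok] <- id[cbind(rr[ok], cc[ok])]
    has <- nb > 0L
    if (any(has)) {
      step_len <- sqrt(sum(off^2))
      efrom <- c(efrom, which(has))
      eto <- c(eto, nb[has])
      ew <- c(ew, step_len * (cost[has] + cost[nb[has]]) / 2 + 1e-9)
    }
  }
  g <- igraph::graph_from_edgelist(cbind(efrom, eto), directed = FALSE)
  igraph::E(g)$weight <- ew
  paths <- list()
  for (sp in seeds) {
    sp <- as.matrix(sp)
    a <- id[sp[1, 1], sp[1, 2]]
    b <- id[sp[2, 1], sp[2, 2]]
    if (a == 0L || b == 0L)
      fm_error("seed point is not on a ridge-like pixel", "fm_tracing_error")
    res <- suppressWarnings(
      igraph::shortest_paths(g, from = a, to = b, output = "vpath"))
    vp <- res$vpath[[1]]
    if (!length(vp))
      fm_error("no live-wire path between seeds", "fm_tracing_error")
    paths[[length(paths) + 1L]] <-
      ridge_path(cand[as.integer(vp), , drop = FALSE])
  }
  flag_exclusions(paths, matrix(integer(0), 0, 2), dim(H), excl_px)
}

# Central-difference gradient magnitude (nm per pixel).
row_gradient_mag <- function(H) {
  nr <- nrow(H); nc <- ncol(H)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (H[3:nr, ] - H[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (H[, 3:nc] - H[, 1:(nc - 2)]) / 2
  sqrt(gr^2 + gc^2)
}
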