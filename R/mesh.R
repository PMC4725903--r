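#' Particle configuration
#'
#' Positions and orientations of a set of proteins in the membrane plane.
#' Each protein carries its own \code{protein_shape} (so mixtures of
#' oligomers and gating states are a single configuration).
#'
#' @param shapes list of \code{protein_shape}, one per protein. Orientations
#'   are taken from each shape's \code{omega}.
#' @param pos N x 2 matrix of centers, nm.
#' @param box optional c(Lx, Ly) rectangle dimensions, nm.
#' @param pbc logical, periodic boundary conditions in \code{box}.
#' @param rng_seed integer seed recorded with the configuration.
#' @return object of class \code{particle_config}.
#' @export
particle_config <- function(shapes, pos, box = NULL, pbc = FALSE, rng_seed = NA_integer_) {
  pos <- matrix(as.numeric(pos), ncol = 2)
  if (length(shapes) == 1L && nrow(pos) > 1L)
    shapes <- rep(shapes, nrow(pos))
  stopifnot(length(shapes) == nrow(pos))
  if (pbc && is.null(box)) stop("pbc requires a box")
  cfg <- list(shapes = shapes, pos = pos, box = box, pbc = isTRUE(pbc),
              rng_seed = rng_seed)
  class(cfg) <- "particle_config"
  cfg
}

#' @exportS3Method base::print
print.particle_config <- function(x, ...) {
  cat(sprintf("particle_config: %d proteins%s\n", nrow(x$pos),
              if (x$pbc) sprintf(", PBC box %.3g x %.3g nm", x$box[1], x$box[2]) else ""))
  invisible(x)
}

n_proteins <- function(config) nrow(config$pos)

# ---- signed distance helpers -------------------------------------------------

# approximate signed distance to a star-convex contour centered at `center`
# (negative inside); exact zero set.
sd_contour <- function(p, shape, center) {
  dx <- p[, 1] - center[1]; dy <- p[, 2] - center[2]
  sqrt(dx * dx + dy * dy) - contour_radius(shape, atan2(dy, dx))
}

sd_disc <- function(p, center, R) sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2) - R

sd_rect <- function(p, lo, hi) {
  pmax(lo[1] - p[, 1], p[, 1] - hi[1], lo[2] - p[, 2], p[, 2] - hi[2])
}

contour_perimeter <- function(shape, n = 2000L) {
  pts <- contour_points(shape, c(0, 0), n)
  sum(sqrt(rowSums((pts - pts[c(2:n, 1L), ])^2)))
}

# ---- the mesher --------------------------------------------------------------

#' Triangulate the membrane patch around protein footprints
#'
#' Distmesh-style mesh generator (force-equilibrated Delaunay over a
#' signed-distance description of the domain): the membrane patch is the
#' outer shape minus the protein footprints, with target edge length
#' \code{h_near} on the protein contours grading to \code{h_far} in the far
#' field. Contour nodes are placed exactly on the contours and fixed.
#'
#' @param config \code{particle_config} of the protein arrangement.
#' @param outer_shape "disc" (free far-field boundary), "symmetry-cell"
#'   (rectangle whose edges carry the mirror zero-normal-slope condition) or
#'   "rectangle-with-PBC" (opposite edges identified).
#' @param outer_size disc radius, or c(W, H) for rectangular outers, nm.
#'   For "disc" the default places the boundary \code{margin_lambda} decay
#'   lengths beyond the outermost contour.
#' @param h_near target edge length on contours, nm (default: smallest
#'   contour perimeter / 200).
#' @param h_far far-field edge length, nm (default \code{4 * h_near}).
#' @param params \code{bilayer_params}, used for the decay-length clearance
#'   check.
#' @param rect_origin lower-left corner of rectangular outers (default the
#'   origin).
#' @param arc_windows optional list of c(theta0, theta1) visibility windows
#'   per protein (used by symmetry cells whose boundary cuts a contour).
#' @param maxit,dptol mesher iteration controls.
#' @param check_clearance require the outer boundary to clear every contour
#'   by at least five decay lengths (disabled for symmetry cells, whose
#'   boundaries legitimately touch the contours).
#' @return object of class \code{tri_mesh} with fields \code{nodes},
#'   \code{triangles} (counterclockwise), \code{areas}, and \code{tags}
#'   (per-feature node index sets).
#' @export
mesh_patch <- function(config,
                       outer_shape = c("disc", "symmetry-cell", "rectangle-with-PBC"),
                       outer_size = NULL, h_near = NULL, h_far = NULL,
                       params = bilayer_params(), rect_origin = c(0, 0),
                       arc_windows = NULL, maxit = 45L, dptol = 0.01,
                       check_clearance = TRUE) {
  outer_shape <- match.arg(outer_shape)
  shapes <- config$shapes
  pos <- config$pos
  N <- length(shapes)
  lam <- decay_length(params)
  mdef <- mscl_defaults()$mesh

  # steric pre-check: contours must not intersect
  if (N > 1L) {
    for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
      if (contour_gap(shapes[[i]], pos[i, ], shapes[[j]], pos[j, ]) <= 0)
        stop("geometry error: contours ", i, " and ", j, " overlap")
    }
  }

  perims <- vapply(shapes, contour_perimeter, 0)
  if (is.null(h_near)) h_near <- min(perims) / mdef$h_near_fraction
  if (is.null(h_far)) h_far <- mdef$h_far_factor * h_near

  if (outer_shape == "disc") {
    rmax <- vapply(seq_len(N), function(i)
      sqrt(sum(pos[i, ]^2)) + shapes[[i]]$R * (1 + shapes[[i]]$eps), 0)
    if (is.null(outer_size)) outer_size <- max(rmax) + mdef$margin_lambda * lam
    if (check_clearance && outer_size < max(rmax) + 5 * lam)
      stop("domain-too-small error: outer radius must clear contours by >= 5 lambda")
    fd_out <- function(p) sd_disc(p, c(0, 0), outer_size)
    bbox <- rbind(c(-outer_size, -outer_size), c(outer_size, outer_size))
  } else {
    if (is.null(outer_size) || length(outer_size) != 2L)
      stop("rectangular outers need outer_size = c(W, H)")
    lo <- rect_origin; hi <- rect_origin + outer_size
    if (check_clearance && outer_shape == "rectangle-with-PBC") {
      for (i in seq_len(N)) {
        re <- shapes[[i]]$R * (1 + shapes[[i]]$eps)
        if (pos[i, 1] - re < lo[1] + h_far || pos[i, 1] + re > hi[1] - h_far ||
            pos[i, 2] - re < lo[2] + h_far || pos[i, 2] + re > hi[2] - h_far)
          stop("PBC cells need contours clear of the boundary")
      }
    }
    fd_out <- function(p) sd_rect(p, lo, hi)
    bbox <- rbind(lo, hi)
  }

  fd <- function(p) {
    d <- fd_out(p)
    for (i in seq_len(N)) d <- pmax(d, -sd_contour(p, shapes[[i]], pos[i, ]))
    d
  }
  # element-size field: graded with distance from the nearest contour
  fh <- function(p) {
    if (N == 0L) return(rep_len(h_far, nrow(p)))
    dmin <- Inf
    for (i in seq_len(N)) dmin <- pmin(dmin, abs(sd_contour(p, shapes[[i]], pos[i, ])))
    pmin(h_far, h_near + 0.3 * dmin)
  }

  # fixed points: contour samples (within visibility windows), outer boundary
  fixed_pts <- NULL; fixed_tag <- NULL
  for (i in seq_len(N)) {
    w <- if (is.null(arc_windows)) c(0, 2 * pi) else arc_windows[[i]]
    nfull <- max(ceiling(perims[i] / h_near), 40L * max(1L, shapes[[i]]$s))
    narc <- max(8L, ceiling(nfull * (w[2] - w[1]) / (2 * pi)))
    th <- seq(w[1], w[2], length.out = narc + 1L)
    if (abs((w[2] - w[1]) - 2 * pi) < 1e-12) th <- th[-(narc + 1L)]
    r <- contour_radius(shapes[[i]], th)
    cp <- cbind(pos[i, 1] + r * cos(th), pos[i, 2] + r * sin(th))
    keep <- fd_out(cp) <= 1e-9   # clip to the outer shape
    fixed_pts <- rbind(fixed_pts, cp[keep, , drop = FALSE])
    fixed_tag <- c(fixed_tag, rep.int(i, sum(keep)))
  }
  outer_fixed_n <- 0L
  if (outer_shape == "disc") {
    nb <- max(16L, ceiling(2 * pi * outer_size / h_far))
    th <- seq(0, 2 * pi, length.out = nb + 1L)[-(nb + 1L)]
    op <- cbind(outer_size * cos(th), outer_size * sin(th))
  } else {
    op <- rect_edge_points(rect_origin, rect_origin + outer_size, h_far)
    keep <- {  # drop edge points swallowed by a contour hole
      k <- rep(TRUE, nrow(op))
      for (i in seq_len(N)) k <- k & (sd_contour(op, shapes[[i]], pos[i, ]) > 0.4 * h_near)
      k
    }
    op <- op[keep, , drop = FALSE]
  }
  outer_fixed_n <- nrow(op)
  fixed_pts <- rbind(fixed_pts, op)
  fixed_tag <- c(fixed_tag, rep.int(0L, outer_fixed_n))

  # initial interior points: equilateral grid + size-based thinning
  p0 <- init_grid_points(bbox, h_near, fh, fd, fixed_pts)
  pts <- rbind(fixed_pts, p0)
  nfix <- nrow(fixed_pts)

  pts <- distmesh_iterate(pts, nfix, fd, fh, h_near, maxit = maxit, dptol = dptol)

  finalize_mesh(pts, nfix, fixed_tag, fd, fh, h_near,
                shapes, pos, fd_out, outer_shape,
                rect_origin, outer_size, h_near, h_far)
}

rect_edge_points <- function(lo, hi, h) {
  nx <- max(2L, ceiling((hi[1] - lo[1]) / h))
  ny <- max(2L, ceiling((hi[2] - lo[2]) / h))
  xs <- seq(lo[1], hi[1], length.out = nx + 1L)
  ys <- seq(lo[2], hi[2], length.out = ny + 1L)
  unique(rbind(cbind(xs, lo[2]), cbind(xs, hi[2]),
               cbind(lo[1], ys), cbind(hi[1], ys)))
}

init_grid_points <- function(bbox, h0, fh, fd, fixed_pts) {
  dx <- h0; dy <- h0 * sqrt(3) / 2
  xs <- seq(bbox[1, 1], bbox[2, 1], by = dx)
  ys <- seq(bbox[1, 2], bbox[2, 2], by = dy)
  g <- expand.grid(x = xs, y = ys)
  odd <- (match(g$y, ys) %% 2L) == 0L
  g$x <- g$x + ifelse(odd, dx / 2, 0)
  p <- cbind(g$x, g$y)
  # break exact-lattice degeneracy for the Delaunay backend
  jit <- 0.02 * h0
  p <- p + jit * (matrix(halton_seq(2L * nrow(p)), ncol = 2) - 0.5)
  p <- p[fd(p) < -0.3 * h0, , drop = FALSE]   # keep interior, off the boundary
  # thin according to the size field (deterministic low-discrepancy threshold)
  pr <- (h0 / fh(p))^2
  u <- halton_seq(nrow(p))
  p <- p[u < pr, , drop = FALSE]
  # drop grid points crowding the fixed boundary points
  if (nrow(fixed_pts) > 0 && nrow(p) > 0) {
    keep <- min_dist_to_set(p, fixed_pts) > 0.7 * h0
    p <- p[keep, , drop = FALSE]
  }
  p
}

# radical-inverse (van der Corput base 2) sequence: deterministic stand-in for
# uniform rejection sampling
halton_seq <- function(n) {
  if (n == 0L) return(numeric(0))
  i <- seq_len(n)
  u <- numeric(n); f <- 0.5; k <- i
  while (any(k > 0)) { u <- u + f * (k %% 2L); k <- k %/% 2L; f <- f / 2 }
  u
}

min_dist_to_set <- function(p, q) {
  # nearest distance from each row of p to the point set q (chunked)
  out <- numeric(nrow(p))
  step <- max(1L, floor(2e6 / nrow(q)))
  for (s in seq(1L, nrow(p), by = step)) {
    e <- min(nrow(p), s + step - 1L)
    d2 <- outer(p[s:e, 1], q[, 1], "-")^2 + outer(p[s:e, 2], q[, 2], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

delaunay_tris <- function(pts) {
  # the s-hull backend occasionally fails on near-degenerate point sets;
  # retry with a deterministic topology-breaking jitter before falling back
  # to the (slower) deldir triangulation
  scale <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  jbase <- (halton_seq(2L * nrow(pts)) - 0.5)
  for (amp in c(0, 1e-7, 1e-5)) {
    q <- pts + amp * scale * matrix(jbase, ncol = 2)
    tm <- tryCatch({
      tri <- suppressWarnings(interp::tri.mesh(q[, 1], q[, 2], duplicate = "error"))
      interp::triangles(tri)[, 1:3, drop = FALSE]
    }, error = function(e) NULL)
    if (!is.null(tm)) { storage.mode(tm) <- "integer"; return(tm) }
  }
  dd <- deldir::deldir(pts[, 1], pts[, 2], round = FALSE)
  tm <- deldir::triMat(dd)
  storage.mode(tm) <- "integer"
  tm
}

tri_orient_ccw <- function(pts, tm) {
  a2 <- (pts[tm[, 2], 1] - pts[tm[, 1], 1]) * (pts[tm[, 3], 2] - pts[tm[, 1], 2]) -
        (pts[tm[, 3], 1] - pts[tm[, 1], 1]) * (pts[tm[, 2], 2] - pts[tm[, 1], 2])
  flip <- a2 < 0
  if (any(flip)) tm[flip, 2:3] <- tm[flip, 3:2]
  tm
}

tri_areas <- function(pts, tm) {
  0.5 * abs((pts[tm[, 2], 1] - pts[tm[, 1], 1]) * (pts[tm[, 3], 2] - pts[tm[, 1], 2]) -
            (pts[tm[, 3], 1] - pts[tm[, 1], 1]) * (pts[tm[, 2], 2] - pts[tm[, 1], 2]))
}

interior_tris <- function(pts, tm, fd, geps) {
  cen <- (pts[tm[, 1], ] + pts[tm[, 2], ] + pts[tm[, 3], ]) / 3
  tm[fd(cen) < -geps, , drop = FALSE]
}

accum2 <- function(idx, vals, n) {
  out <- matrix(0, n, 2)
  s1 <- rowsum(vals, idx, reorder = FALSE)
  out[as.integer(rownames(s1)), ] <- s1
  out
}

distmesh_iterate <- function(pts, nfix, fd, fh, h0, maxit = 45L, dptol = 0.01,
                             deltat = 0.2, Fscale = 1.2, ttol = 0.15) {
  geps <- 1e-3 * h0
  pold <- pts + Inf
  tm <- NULL; edges <- NULL
  hloc <- fh(pts)
  for (it in seq_len(maxit)) {
    if (max(sqrt(rowSums((pts - pold)^2)) / hloc) > ttol) {
      pold <- pts
      hloc <- fh(pts)
      tm <- interior_tris(pts, delaunay_tris(pts), fd, geps)
      e <- rbind(tm[, 1:2], tm[, 2:3], tm[, c(3, 1)])
      e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
      edges <- e
    }
    ev <- pts[edges[, 2], , drop = FALSE] - pts[edges[, 1], , drop = FALSE]
    L <- sqrt(rowSums(ev^2))
    mid <- (pts[edges[, 1], , drop = FALSE] + pts[edges[, 2], , drop = FALSE]) / 2
    hb <- fh(mid)
    L0 <- hb * Fscale * sqrt(sum(L^2) / sum(hb^2))
    Fm <- pmax(L0 - L, 0) / L
    Fv <- cbind(Fm * ev[, 1], Fm * ev[, 2])
    Ftot <- accum2(edges[, 1], -Fv, nrow(pts)) + accum2(edges[, 2], Fv, nrow(pts))
    if (nfix > 0) Ftot[seq_len(nfix), ] <- 0
    pts <- pts + deltat * Ftot
    # project escaped points back onto the boundary
    d <- fd(pts); out <- d > 0
    if (any(out)) {
      po <- pts[out, , drop = FALSE]
      hgrad <- 1e-6 * h0
      gx <- (fd(cbind(po[, 1] + hgrad, po[, 2])) - d[out]) / hgrad
      gy <- (fd(cbind(po[, 1], po[, 2] + hgrad)) - d[out]) / hgrad
      g2 <- gx^2 + gy^2
      pts[out, ] <- po - cbind(d[out] * gx / g2, d[out] * gy / g2)
    }
    inner <- fd(pts) < -geps
    moved <- sqrt(rowSums((deltat * Ftot)^2)) / hloc
    if (max(moved[inner]) < dptol) break
  }
  pts
}

finalize_mesh <- function(pts, nfix, fixed_tag, fd, fh, h0,
                          shapes, pos, fd_out, outer_shape,
                          rect_origin, outer_size, h_near, h_far) {
  N <- length(shapes)
  # snap near-boundary free nodes exactly onto the boundary
  d <- fd(pts)
  hloc <- fh(pts)
  free <- seq_len(nrow(pts)) > nfix
  snap <- free & (abs(d) < 0.25 * hloc)
  if (any(snap)) {
    ps <- pts[snap, , drop = FALSE]
    for (k in 1:6) {
      dk <- fd(ps)
      hg <- 1e-6 * h0
      gx <- (fd(cbind(ps[, 1] + hg, ps[, 2])) - dk) / hg
      gy <- (fd(cbind(ps[, 1], ps[, 2] + hg)) - dk) / hg
      g2 <- pmax(gx^2 + gy^2, 1e-12)
      ps <- ps - cbind(dk * gx / g2, dk * gy / g2)
    }
    pts[snap, ] <- ps
  }
  # drop free nodes that collapsed onto another node
  dup <- rep(FALSE, nrow(pts))
  if (any(free)) {
    dmin <- min_dist_to_set(pts[free, , drop = FALSE], pts[seq_len(nfix), , drop = FALSE])
    dup[which(free)[dmin < 0.35 * hloc[free]]] <- TRUE
  }
  keep <- !dup
  remap <- cumsum(keep)
  pts <- pts[keep, , drop = FALSE]

  tm <- interior_tris(pts, delaunay_tris(pts), fd, 1e-3 * h0)
  tm <- tri_orient_ccw(pts, tm)
  ar <- tri_areas(pts, tm)
  good <- ar > 1e-12
  tm <- tm[good, , drop = FALSE]; ar <- ar[good]
  # drop nodes unused by any interior triangle
  used <- sort(unique(as.integer(tm)))
  remap2 <- match(seq_len(nrow(pts)), used)
  pts2 <- pts[used, , drop = FALSE]
  tm <- matrix(remap2[tm], ncol = 3)

  # tag nodes by feature
  tol <- 1e-6
  tags <- list(protein = vector("list", N), outer = integer(0),
               sym_x = integer(0), sym_y = integer(0))
  for (i in seq_len(N)) {
    di <- abs(sd_contour(pts2, shapes[[i]], pos[i, ]))
    tags$protein[[i]] <- which(di < 1e-5)
  }
  if (outer_shape == "disc") {
    tags$outer <- which(abs(fd_out(pts2)) < 1e-5)
  } else {
    lo <- rect_origin; hi <- rect_origin + outer_size
    on_lo_x <- abs(pts2[, 1] - lo[1]) < 1e-7; on_hi_x <- abs(pts2[, 1] - hi[1]) < 1e-7
    on_lo_y <- abs(pts2[, 2] - lo[2]) < 1e-7; on_hi_y <- abs(pts2[, 2] - hi[2]) < 1e-7
    if (outer_shape == "symmetry-cell") {
      tags$sym_x <- which(on_lo_x | on_hi_x)   # edge normal along x
      tags$sym_y <- which(on_lo_y | on_hi_y)
    } else {
      tags$outer <- which(on_lo_x | on_hi_x | on_lo_y | on_hi_y)
      tags$pbc <- pbc_pairs(pts2, lo, hi)
    }
  }
  m <- list(nodes = pts2, triangles = tm, areas = ar, tags = tags,
            h_near = h_near, h_far = h_far, outer_shape = outer_shape,
            rect = if (outer_shape == "disc") NULL else rbind(rect_origin, rect_origin + outer_size),
            shapes = shapes, centers = pos)
  class(m) <- "tri_mesh"
  m
}

# match nodes on opposite edges of a periodic rectangle; returns a 2-column
# matrix of (slave, master) node indices
pbc_pairs <- function(pts, lo, hi) {
  tol <- 1e-6
  W <- hi[1] - lo[1]; H <- hi[2] - lo[2]
  onL <- which(abs(pts[, 1] - lo[1]) < tol)
  onR <- which(abs(pts[, 1] - hi[1]) < tol)
  onB <- which(abs(pts[, 2] - lo[2]) < tol)
  onT <- which(abs(pts[, 2] - hi[2]) < tol)
  pair_up <- function(sl, ms, coord) {
    if (length(sl) == 0L) return(NULL)
    i <- ms[match(round(pts[sl, coord], 6), round(pts[ms, coord], 6))]
    ok <- !is.na(i)
    cbind(sl[ok], i[ok])
  }
  rbind(pair_up(onR, onL, 2), pair_up(onT, onB, 1))
}

#' @exportS3Method base::print
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d nodes, %d triangles (%s outer), h = [%.3g, %.3g] nm\n",
              nrow(x$nodes), nrow(x$triangles), x$outer_shape, x$h_near, x$h_far))
  invisible(x)
}

#' Total meshed area
#' @param mesh \code{tri_mesh}.
#' @return area in nm^2.
#' @export
mesh_area <- function(mesh) sum(mesh$areas)
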