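#' Lattice specification
#'
#' Candidate lattice architectures for protein clusters. Honeycomb, square
#' and hexagonal lattices have 3, 4 and 6 nearest neighbours per site;
#' "shifted-square" displaces alternate rows by half a spacing;
#' "distorted-A" is a hexagonal lattice with independent row spacing /
#' row shift and alternate rows oriented oppositely (rotated by pi/s);
#' "distorted-B" tiles a three-protein face-on motif on a triangular
#' superlattice.
#'
#' @param family one of "honeycomb", "square", "shifted-square",
#'   "hexagonal", "distorted-A", "distorted-B".
#' @param d nearest-neighbour spacing, nm (regular families).
#' @param phi area packing fraction (distorted families): protein area times
#'   count over tiled area.
#' @param orientation "face-on", "tip-on", "horizontal", "optimized" or
#'   "alternating-rows".
#' @param L linear cluster size (N = L^2 for square-ish finite clusters).
#' @param N protein count (overrides L).
#' @param infinite logical: infinite-lattice energetics (symmetry cell or
#'   lattice sums) rather than a finite cluster.
#' @param extra named list of family-specific parameters (distorted-A:
#'   \code{ax}, \code{ay}, \code{cx}, \code{omega0}; distorted-B: \code{t},
#'   \code{D}, \code{omegas}).
#' @return object of class \code{lattice_spec}.
#' @export
lattice_spec <- function(family = c("square", "hexagonal", "honeycomb",
                                    "shifted-square", "distorted-A",
                                    "distorted-B"),
                         d = NULL, phi = NULL,
                         orientation = c("face-on", "tip-on", "horizontal",
                                         "optimized", "alternating-rows"),
                         L = 4L, N = NULL, infinite = FALSE, extra = list()) {
  family <- match.arg(family)
  orientation <- match.arg(orientation)
  distorted <- family %in% c("distorted-A", "distorted-B")
  if (distorted && is.null(phi) && length(extra) == 0L)
    stop("distorted families are parameterized by phi (or explicit extra parameters)")
  if (!distorted && is.null(d)) stop("regular families need a spacing d")
  sp <- list(family = family, d = d, phi = phi, orientation = orientation,
             L = as.integer(L), N = if (is.null(N)) NULL else as.integer(N),
             infinite = isTRUE(infinite), extra = extra)
  class(sp) <- "lattice_spec"
  sp
}

#' @exportS3Method base::print
print.lattice_spec <- function(x, ...) {
  cat(sprintf("lattice_spec: %s (%s), %s\n", x$family, x$orientation,
              if (!is.null(x$d)) paste0("d = ", signif(x$d, 5), " nm")
              else paste0("phi = ", signif(x$phi, 5))))
  invisible(x)
}

# orientation angle for a scheme: face-on puts a lobe minimum along +x
scheme_omega <- function(shape, orientation) {
  if (shape$s == 0) return(0)
  switch(orientation,
         "face-on" = pi / shape$s,
         "tip-on" = 0,
         "horizontal" = 0,
         "optimized" = 0,
         "alternating-rows" = 0)
}

# site positions and orientations for a finite cluster
lattice_sites <- function(spec, shape) {
  fam <- spec$family
  L <- spec$L
  w0 <- scheme_omega(shape, spec$orientation)
  s <- shape$s
  alt <- function(j) if (spec$orientation == "alternating-rows" && s > 0)
    w0 + (j %% 2) * pi / s else w0
  if (fam == "square") {
    g <- expand.grid(i = 0:(L - 1), j = 0:(L - 1))
    pos <- cbind(g$i * spec$d, g$j * spec$d)
    om <- vapply(g$j, alt, 0)
  } else if (fam == "shifted-square") {
    g <- expand.grid(i = 0:(L - 1), j = 0:(L - 1))
    pos <- cbind(g$i * spec$d + (g$j %% 2) * spec$d / 2, g$j * spec$d)
    om <- vapply(g$j, alt, 0)
  } else if (fam == "hexagonal") {
    g <- expand.grid(i = 0:(L - 1), j = 0:(L - 1))
    pos <- cbind(g$i * spec$d + (g$j %% 2) * spec$d / 2,
                 g$j * spec$d * sqrt(3) / 2)
    om <- vapply(g$j, alt, 0)
  } else if (fam == "honeycomb") {
    # rectangular cell of 4 sites tiled (3d x sqrt(3) d)
    ncell <- ceiling(sqrt((if (is.null(spec$N)) L^2 else spec$N) / 4))
    g <- expand.grid(cx = 0:(ncell - 1), cy = 0:(ncell - 1), b = 0:3)
    bx <- c(0, spec$d, 1.5 * spec$d, 2.5 * spec$d)
    by <- c(0, 0, sqrt(3) / 2 * spec$d, sqrt(3) / 2 * spec$d)
    pos <- cbind(g$cx * 3 * spec$d + bx[g$b + 1],
                 g$cy * sqrt(3) * spec$d + by[g$b + 1])
    om <- rep(w0, nrow(pos))
  } else if (fam == "distorted-A") {
    pr <- distorted_a_params(spec, shape)
    g <- expand.grid(i = 0:(L - 1), j = 0:(L - 1))
    pos <- cbind(g$i * pr$ax + (g$j %% 2) * pr$cx, g$j * pr$ay)
    om <- pr$omega0 + (g$j %% 2) * (if (s > 0) pi / s else 0)
  } else if (fam == "distorted-B") {
    pr <- spec$extra
    if (is.null(pr$t) || is.null(pr$D) || is.null(pr$omegas))
      stop("distorted-B needs extra = list(t, D, omegas)")
    ncell <- L
    g <- expand.grid(i = 0:(ncell - 1), j = 0:(ncell - 1))
    cen <- cbind(g$i * pr$D + (g$j %% 2) * pr$D / 2, g$j * pr$D * sqrt(3) / 2)
    th <- pi / 2 + c(0, 2 * pi / 3, 4 * pi / 3) # motif vertices around center
    r3 <- pr$t / sqrt(3)
    pos <- NULL; om <- NULL
    for (k in 1:3) {
      pos <- rbind(pos, cbind(cen[, 1] + r3 * cos(th[k]),
                              cen[, 2] + r3 * sin(th[k])))
      om <- c(om, rep(pr$omegas[k], nrow(cen)))
    }
  }
  if (!is.null(spec$N) && nrow(pos) > spec$N) {
    cen <- colMeans(pos)
    keep <- order((pos[, 1] - cen[1])^2 + (pos[, 2] - cen[2])^2)[seq_len(spec$N)]
    keep <- sort(keep)
    pos <- pos[keep, , drop = FALSE]; om <- om[keep]
  }
  list(pos = pos, omega = om)
}

# geometric parameters of the distorted-A family (explicit, or derived from
# phi with a default aspect ratio and shift)
distorted_a_params <- function(spec, shape) {
  e <- spec$extra
  if (!is.null(e$ax) && !is.null(e$ay))
    return(list(ax = e$ax, ay = e$ay,
                cx = if (is.null(e$cx)) e$ax / 2 else e$cx,
                omega0 = if (is.null(e$omega0)) 0 else e$omega0))
  if (is.null(spec$phi)) stop("distorted-A needs phi or explicit extra parameters")
  A <- shape_area(shape)
  cell <- A / spec$phi          # area per protein
  ax <- sqrt(cell / (sqrt(3) / 2)) # hexagonal-like default aspect
  list(ax = ax, ay = cell / ax, cx = ax / 2,
       omega0 = if (is.null(e$omega0)) 0 else e$omega0)
}

#' Build a finite lattice configuration
#'
#' @param spec \code{lattice_spec}.
#' @param shape \code{protein_shape} (one oligomer/state for the whole
#'   lattice).
#' @param check_steric verify that all pairs clear the steric minimum.
#' @param clearance steric edge-to-edge clearance, nm.
#' @return \code{particle_config}.
#' @export
build_lattice <- function(spec, shape, check_steric = TRUE, clearance = NULL) {
  ls <- lattice_sites(spec, shape)
  shapes <- lapply(seq_len(nrow(ls$pos)), function(i) {
    sh <- shape
    if (sh$s > 0) sh$omega <- wrap_angle(ls$omega[i], sector(sh$s))
    sh
  })
  cfg <- particle_config(shapes, ls$pos)
  if (check_steric) {
    if (is.null(clearance)) clearance <- mscl_defaults()$steric$edge_clearance
    np <- neighbor_pairs(cfg, r_cut = 2 * max(vapply(shapes, function(s)
      s$R * (1 + s$eps), 0)) + clearance + 0.5)
    for (r in seq_len(nrow(np))) {
      i <- np[r, 1]; j <- np[r, 2]
      g <- contour_gap(shapes[[i]], ls$pos[i, ], shapes[[j]], ls$pos[j, ])
      # 5e-3 nm tolerance: contact-limited lattices sit exactly at the
      # clearance, and the contour-sampling resolution of the gap is ~1e-3
      if (g < clearance - 5e-3)
        stop("packing error: sites ", i, " and ", j, " closer than the lipid clearance")
    }
  }
  cfg
}

#' Tightest spacing of a lattice family under steric constraints
#'
#' Bisection on the lattice spacing d such that the smallest contour-contour
#' gap in the cluster equals the lipid clearance.
#'
#' @param spec \code{lattice_spec} (d is ignored).
#' @param shape \code{protein_shape}.
#' @param clearance steric clearance, nm.
#' @return minimal d, nm.
#' @export
lattice_min_spacing <- function(spec, shape, clearance = NULL) {
  if (is.null(clearance)) clearance <- mscl_defaults()$steric$edge_clearance
  probe <- spec; probe$L <- 3L; probe$N <- NULL
  re <- shape$R * (1 + shape$eps)
  lo <- 2 * shape$R * (1 - shape$eps); hi <- 2 * re + clearance + 0.5
  min_gap <- function(d) {
    probe$d <- d
    cfg <- build_lattice(probe, shape, check_steric = FALSE)
    np <- neighbor_pairs(cfg, r_cut = 2 * re + clearance + 1)
    min(vapply(seq_len(nrow(np)), function(r)
      contour_gap(cfg$shapes[[np[r, 1]]], cfg$pos[np[r, 1], ],
                  cfg$shapes[[np[r, 2]]], cfg$pos[np[r, 2], ]), 0))
  }
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (min_gap(mid) >= clearance) hi <- mid else lo <- mid
    if (hi - lo < 1e-4) break
  }
  hi + 2e-3  # small pad so contact lattices clear table steric minima
}

# ---- symmetry unit cells -----------------------------------------------------

# numerical mirror-symmetry check of an oriented contour about both axes
check_mirror_symmetry <- function(shape) {
  if (shape$s == 0) return(TRUE)
  th <- seq(0, 2 * pi, length.out = 181L)
  rx <- max(abs(contour_radius(shape, th) - contour_radius(shape, -th)))
  ry <- max(abs(contour_radius(shape, th) - contour_radius(shape, pi - th)))
  rx < 1e-10 && ry < 1e-10
}

#' Symmetry unit cell of an infinite lattice
#'
#' Builds the minimal rectangular mirror cell of the lattice: by symmetry the
#' normal slope of the thickness field vanishes on the cell edges, so an
#' infinite-lattice energy per protein follows from one small solve. The cell
#' contains a protein fraction f (reported); unsupported orientation schemes
#' (those breaking the mirrors, e.g. any uniform pentamer orientation) raise
#' a symmetry-violation error.
#'
#' @param spec \code{lattice_spec} with family in \{square, shifted-square,
#'   hexagonal, honeycomb\}.
#' @param shape \code{protein_shape}.
#' @param params \code{bilayer_params}.
#' @param h_frac mesh resolution (contour edge = perimeter / h_frac).
#' @param maxit mesher iterations.
#' @return list: \code{mesh} (tri_mesh with symmetry-tagged edges),
#'   \code{f} (protein fraction in the cell).
#' @export
build_symmetry_cell <- function(spec, shape, params = bilayer_params(),
                                h_frac = 200, maxit = 45L) {
  d <- spec$d
  stopifnot(!is.null(d))
  w0 <- scheme_omega(shape, spec$orientation)
  sh <- shape
  if (sh$s > 0) sh$omega <- wrap_angle(w0, sector(sh$s))
  if (!check_mirror_symmetry(sh))
    stop("symmetry-violation error: orientation scheme breaks the cell mirrors")
  H <- sqrt(3) * d
  cells <- switch(spec$family,
    "square" = list(W = d, H = d,
      sites = rbind(c(0, 0), c(d, 0), c(0, d), c(d, d)),
      win = list(c(0, pi / 2), c(pi / 2, pi), c(3 * pi / 2, 2 * pi), c(pi, 3 * pi / 2)),
      f = 1),
    "shifted-square" = list(W = d, H = 2 * d,
      sites = rbind(c(0, 0), c(d, 0), c(0, 2 * d), c(d, 2 * d), c(d / 2, d)),
      win = list(c(0, pi / 2), c(pi / 2, pi), c(3 * pi / 2, 2 * pi),
                 c(pi, 3 * pi / 2), c(0, 2 * pi)),
      f = 2),
    "hexagonal" = list(W = d, H = H,
      sites = rbind(c(0, 0), c(d, 0), c(0, H), c(d, H), c(d / 2, H / 2)),
      win = list(c(0, pi / 2), c(pi / 2, pi), c(3 * pi / 2, 2 * pi),
                 c(pi, 3 * pi / 2), c(0, 2 * pi)),
      f = 2),
    "honeycomb" = list(W = 3 * d, H = H,
      sites = rbind(c(d / 2, 0), c(5 * d / 2, 0), c(d / 2, H), c(5 * d / 2, H),
                    c(d, H / 2), c(2 * d, H / 2)),
      win = list(c(0, pi), c(0, pi), c(pi, 2 * pi), c(pi, 2 * pi),
                 c(0, 2 * pi), c(0, 2 * pi)),
      f = 4),
    stop("no symmetry cell for family ", spec$family))
  shapes <- rep(list(sh), nrow(cells$sites))
  cfg <- particle_config(shapes, cells$sites)
  per <- contour_perimeter(sh)
  m <- mesh_patch(cfg, "symmetry-cell", outer_size = c(cells$W, cells$H),
                  h_near = per / h_frac, h_far = 4 * per / h_frac,
                  params = params, arc_windows = cells$win, maxit = maxit,
                  check_clearance = FALSE)
  list(mesh = m, f = cells$f)
}

# ---- lattice energies --------------------------------------------------------

#' Interaction energy per protein of a finite lattice cluster
#'
#' @param spec \code{lattice_spec}.
#' @param shape \code{protein_shape}.
#' @param table \code{pair_table} (pairwise mode).
#' @param params \code{bilayer_params} (multibody-FE mode).
#' @param mode "pairwise" (table lookups over all pairs) or "multibody-FE"
#'   (mesh and solve the full cluster; practical to N of a few tens).
#' @param relax_orientations for \code{orientation = "optimized"}: rotation-only
#'   annealing schedule applied before scoring (pairwise mode).
#' @param seed seed for the orientational relaxation.
#' @param h_frac,maxit mesh controls (multibody-FE mode).
#' @return energy per protein, kBT.
#' @export
lattice_energy_finite <- function(spec, shape, table = NULL, params = NULL,
                                  mode = c("pairwise", "multibody-FE"),
                                  relax_orientations = NULL, seed = 1L,
                                  h_frac = 96, maxit = 25L) {
  mode <- match.arg(mode)
  cfg <- build_lattice(spec, shape)
  N <- n_proteins(cfg)
  if (N == 1L) return(0)
  if (mode == "pairwise") {
    stopifnot(!is.null(table))
    if (spec$orientation == "optimized") {
      sched <- if (is.null(relax_orientations))
        anneal_schedule(n_steps = 4000L, T_start = 0.5, T_end = 0.01)
        else relax_orientations
      cfg <- orientational_relax(cfg, table, sched, seed)$config
    }
    total_energy(cfg, table, clamp = TRUE) / N
  } else {
    stopifnot(!is.null(params))
    per <- contour_perimeter(shape)
    lam <- decay_length(params)
    cen <- colMeans(cfg$pos)
    cfg$pos <- sweep(cfg$pos, 2, cen)
    rext <- max(sqrt(rowSums(cfg$pos^2))) + shape$R * (1 + shape$eps)
    m <- mesh_patch(cfg, "disc", outer_size = rext + 7 * lam,
                    h_near = per / h_frac, h_far = 4 * per / h_frac,
                    params = params, maxit = maxit)
    Efull <- solve_field(m, params)$E_excess
    E1 <- single_protein_energy(shape, params, h_frac, margin_lambda = 7,
                                maxit = maxit)
    (Efull - N * E1) / N
  }
}

#' Interaction energy per protein of an infinite lattice (symmetry cell)
#'
#' Finite-element solve on the minimal mirror cell; the cell energy divided
#' by the protein fraction f gives the per-protein energy of the infinite
#' lattice, and subtracting the isolated-protein energy gives the
#' interaction part.
#'
#' @inheritParams build_symmetry_cell
#' @return interaction energy per protein, kBT.
#' @export
lattice_energy_infinite <- function(spec, shape, params = bilayer_params(),
                                    h_frac = 96, maxit = 30L) {
  cell <- build_symmetry_cell(spec, shape, params, h_frac, maxit)
  Ecell <- solve_field(cell$mesh, params)$E_excess
  E1 <- single_protein_energy(shape, params, h_frac, margin_lambda = NULL,
                              maxit = maxit)
  Ecell / cell$f - E1
}

#' Infinite-lattice energy per protein from pairwise sums
#'
#' Per-protein interaction energy of the infinite lattice in pairwise mode:
#' half the sum of tabulated pair energies from a bulk site to every lattice
#' site within the cutoff (averaged over inequivalent sites).
#'
#' @param spec \code{lattice_spec}.
#' @param shape \code{protein_shape}.
#' @param table \code{pair_table}.
#' @return energy per protein, kBT.
#' @export
infinite_pairwise_energy <- function(spec, shape, table) {
  # build a patch large enough that central sites have full surroundings
  spacing <- if (!is.null(spec$d)) spec$d else {
    pr <- distorted_a_params(spec, shape); min(pr$ax, pr$ay)
  }
  Lneed <- ceiling(2 * table$d_cut / spacing) + 3L
  probe <- spec; probe$L <- Lneed; probe$N <- NULL
  cfg <- build_lattice(probe, shape, check_steric = FALSE)
  cen <- colMeans(cfg$pos)
  d2 <- (cfg$pos[, 1] - cen[1])^2 + (cfg$pos[, 2] - cen[2])^2
  # representative bulk sites: the few closest to the patch center
  core <- order(d2)[1:2]
  e <- vapply(core, function(i) {
    dx <- cfg$pos[, 1] - cfg$pos[i, 1]
    dy <- cfg$pos[, 2] - cfg$pos[i, 2]
    d <- sqrt(dx^2 + dy^2)
    sel <- which(d > 1e-9 & d < table$d_cut)
    sum(vapply(sel, function(j) {
      al <- atan2(dy[j], dx[j])
      pair_lookup(table, d[j], cfg$shapes[[i]]$omega - al,
                  cfg$shapes[[j]]$omega - al, clamp = TRUE)
    }, 0)) / 2
  }, 0)
  mean(e)
}

#' Scan candidate lattices and rank their ground states
#'
#' Evaluates each candidate family over its spacing (or packing-fraction)
#' grid, reports the minimizing point and energy, ranks the candidates, and
#' locates crossover spacings where the energy ordering of two families
#' changes sign.
#'
#' @param shape \code{protein_shape}.
#' @param specs list of \code{lattice_spec}s.
#' @param ranges list of numeric grids (d in nm, or phi), one per spec.
#' @param table \code{pair_table} (pairwise scoring) or NULL.
#' @param params \code{bilayer_params} for symmetry-cell scoring (used when
#'   \code{table} is NULL).
#' @param infinite score infinite lattices (pairwise sums or symmetry cells)
#'   rather than finite clusters.
#' @param h_frac,maxit mesh controls for symmetry-cell scoring.
#' @return list: \code{curves} (long data.frame family/orientation/x/energy),
#'   \code{ranking} (data.frame sorted by minimum energy),
#'   \code{crossovers} (data.frame of sign-change locations).
#' @export
ground_state_scan <- function(shape, specs, ranges, table = NULL,
                              params = NULL, infinite = TRUE,
                              h_frac = 96, maxit = 30L) {
  stopifnot(length(specs) >= 1L, length(specs) == length(ranges))
  curves <- NULL
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    xs <- ranges[[k]]
    es <- vapply(xs, function(x) {
      s2 <- sp
      if (sp$family %in% c("distorted-A", "distorted-B")) s2$phi <- x else s2$d <- x
      if (infinite) {
        if (!is.null(table)) infinite_pairwise_energy(s2, shape, table)
        else lattice_energy_infinite(s2, shape, params, h_frac, maxit)
      } else {
        lattice_energy_finite(s2, shape, table = table, params = params,
                              mode = if (!is.null(table)) "pairwise" else "multibody-FE")
      }
    }, 0)
    curves <- rbind(curves, data.frame(
      family = sp$family, orientation = sp$orientation, x = xs, energy = es,
      stringsAsFactors = FALSE))
  }
  key <- paste(curves$family, curves$orientation)
  ranking <- do.call(rbind, lapply(split(curves, key), function(cc) {
    i <- which.min(cc$energy)
    data.frame(family = cc$family[1], orientation = cc$orientation[1],
               x_min = cc$x[i], energy_min = cc$energy[i],
               stringsAsFactors = FALSE)
  }))
  ranking <- ranking[order(ranking$energy_min), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL

  crossovers <- NULL
  ukey <- unique(key)
  for (a in seq_along(ukey)) for (b in seq_along(ukey)) {
    if (a >= b) next
    ca <- curves[key == ukey[a], ]; cb <- curves[key == ukey[b], ]
    common <- intersect(ca$x, cb$x)
    if (length(common) < 2L) next
    da <- ca$energy[match(common, ca$x)] - cb$energy[match(common, cb$x)]
    sgn <- sign(da)
    flips <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
    for (fidx in flips) {
      x0 <- common[fidx]; x1 <- common[fidx + 1]
      y0 <- da[fidx]; y1 <- da[fidx + 1]
      crossovers <- rbind(crossovers, data.frame(
        family_a = ukey[a], family_b = ukey[b],
        x_cross = x0 - y0 * (x1 - x0) / (y1 - y0), stringsAsFactors = FALSE))
    }
  }
  list(curves = curves, ranking = ranking, crossovers = crossovers)
}

#' Boundary-effect scaling of finite-cluster energy differences
#'
#' Per-protein energy difference between two lattice families as a function
#' of the linear cluster size L, with a power-law fit of its decay toward
#' the infinite-lattice difference.
#'
#' @param spec_a,spec_b \code{lattice_spec}s (finite; L is varied).
#' @param shape \code{protein_shape}.
#' @param table \code{pair_table}.
#' @param L_range integer vector of cluster sizes (>= 3 values).
#' @return list: \code{data} (L, dE), \code{dE_inf} (infinite-lattice
#'   difference), \code{exponent} (fitted decay power), \code{fit} (lm).
#' @export
boundary_scaling <- function(spec_a, spec_b, shape, table, L_range = 3:7) {
  stopifnot(length(L_range) >= 3L)
  dE <- vapply(L_range, function(L) {
    sa <- spec_a; sa$L <- as.integer(L); sa$N <- NULL
    sb <- spec_b; sb$L <- as.integer(L); sb$N <- NULL
    lattice_energy_finite(sa, shape, table = table) -
      lattice_energy_finite(sb, shape, table = table)
  }, 0)
  dE_inf <- infinite_pairwise_energy(spec_a, shape, table) -
    infinite_pairwise_energy(spec_b, shape, table)
  y <- abs(dE - dE_inf)
  ok <- y > 1e-12
  if (sum(ok) >= 2L) {
    fit <- lm(log(y[ok]) ~ log(L_range[ok]))
    expo <- -unname(coef(fit)[2])
  } else {
    fit <- NULL; expo <- NA_real_   # degenerate: no boundary effect to fit
  }
  list(data = data.frame(L = L_range, dE = dE), dE_inf = dE_inf,
       exponent = expo, fit = fit)
}

# ---- distorted pentamer packings --------------------------------------------

# steric feasibility of a distorted-A unit (exact contour geometry; coarser
# contour sampling than the default -- the packing search only needs ~1e-3 nm)
distorted_a_feasible <- function(shape, ax, ay, cx, omega0, clearance, n = 144L) {
  s <- shape$s
  sh1 <- shape; sh1$omega <- wrap_angle(omega0, sector(s))
  sh2 <- shape; sh2$omega <- wrap_angle(omega0 + pi / s, sector(s))
  # within-row neighbours and the four nearest cross-row neighbours
  if (contour_gap(sh1, c(0, 0), sh1, c(ax, 0), n) < clearance) return(FALSE)
  if (contour_gap(sh2, c(0, 0), sh2, c(ax, 0), n) < clearance) return(FALSE)
  for (k in -1:2) {
    if (contour_gap(sh1, c(0, 0), sh2, c(cx + (k - 1) * ax, ay), n) < clearance)
      return(FALSE)
    # row 1 -> row 2 sees the opposite shift (k ax - cx) with the roles of
    # the two orientations swapped; the pair is not mirror symmetric in y
    if (contour_gap(sh2, c(0, 0), sh1, c(k * ax - cx, ay), n) < clearance)
      return(FALSE)
  }
  # second row (same orientation, offset 2 ay)
  if (2 * ay < 2 * shape$R * (1 + shape$eps) + clearance) {
    for (k in -1:1) {
      if (contour_gap(sh1, c(0, 0), sh1, c(k * ax, 2 * ay), n) < clearance)
        return(FALSE)
    }
  }
  TRUE
}

#' Densest distorted-A packing of a protein shape
#'
#' Maximizes the area packing fraction of the alternating-row (distorted-A)
#' family over row spacing, row shift and base orientation, under the exact
#' contour steric constraint; the reported optimum has at least one contact
#' pair exactly at the lipid clearance.
#'
#' @param shape \code{protein_shape}.
#' @param clearance steric clearance, nm.
#' @param n_starts deterministic multi-start count.
#' @return list: \code{phi}, \code{ax}, \code{ay}, \code{cx}, \code{omega0},
#'   and the \code{spec} (a ready-to-use \code{lattice_spec}).
#' @export
max_packing_distorted_a <- function(shape, clearance = NULL, n_starts = 6L) {
  if (is.null(clearance)) clearance <- mscl_defaults()$steric$edge_clearance
  A <- shape_area(shape)
  s <- shape$s
  re <- shape$R * (1 + shape$eps)
  min_ay <- function(ax, cx, omega0) {
    lo <- shape$R * (1 - shape$eps); hi <- 2 * re + clearance
    for (it in 1:22) {
      mid <- (lo + hi) / 2
      if (distorted_a_feasible(shape, ax, mid, cx, omega0, clearance)) hi <- mid
      else lo <- mid
      if (hi - lo < 1e-3) break
    }
    hi
  }
  obj <- function(p) {
    ax <- p[1]; cx <- p[2]; omega0 <- p[3]
    if (ax < 2 * shape$R * (1 - shape$eps) || ax > 2 * re + clearance + 1)
      return(1e6)
    if (!distorted_a_feasible(shape, ax, 2 * re + clearance, cx, omega0, clearance))
      return(1e6)
    ay <- min_ay(ax, cx, omega0)
    -A / (ax * ay)
  }
  ax_row <- min_distance(shape, shape, pi / max(s, 1), pi / max(s, 1), clearance)
  starts <- list(c(ax_row, ax_row / 2, 0),
                 c(ax_row, ax_row / 2, pi / (2 * max(s, 1))),
                 c(ax_row * 1.1, ax_row / 3, 0))
  extra <- max(0L, n_starts - length(starts))
  if (extra > 0) {
    hs <- matrix(halton_seq(3L * extra), ncol = 3)
    for (i in seq_len(extra))
      starts[[length(starts) + 1L]] <-
        c(ax_row * (0.95 + 0.3 * hs[i, 1]), ax_row * hs[i, 2],
          hs[i, 3] * sector(max(s, 1)) / 2)
  }
  best <- NULL
  for (st in starts) {
    o <- optim(st, obj, method = "Nelder-Mead",
               control = list(maxit = 120, reltol = 1e-6))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ax <- best$par[1]; cx <- best$par[2]; omega0 <- best$par[3]
  # pad beyond the bisection tolerance and the coarser contour sampling of
  # the feasibility check, so built lattices clear the exact-geometry check
  ax <- ax + 5e-3
  ay <- min_ay(ax, cx, omega0) + 1e-2
  phi <- A / (ax * ay)
  spec <- lattice_spec("distorted-A", phi = phi,
                       orientation = "alternating-rows",
                       extra = list(ax = ax, ay = ay, cx = cx, omega0 = omega0))
  list(phi = phi, ax = ax, ay = ay, cx = cx, omega0 = omega0, spec = spec)
}

#' Face-on trimer (distorted-B) packing parameters
#'
#' Builds the three-protein face-on motif: three proteins on an equilateral
#' triangle of side t with orientations minimizing the tabulated three-pair
#' energy, tiled at packing fraction phi.
#'
#' @param shape \code{protein_shape}.
#' @param table \code{pair_table} used to optimize the motif orientations.
#' @param phi area packing fraction of the tiling.
#' @param t triangle side, nm (default: the face-on contact distance).
#' @return \code{lattice_spec} for the distorted-B family.
#' @export
distorted_b_spec <- function(shape, table, phi, t = NULL) {
  s <- shape$s
  if (is.null(t)) t <- min_distance(shape, shape, pi / s, pi / s,
                                    table$clearance)
  th <- pi / 2 + c(0, 2 * pi / 3, 4 * pi / 3)
  r3 <- t / sqrt(3)
  pos <- cbind(r3 * cos(th), r3 * sin(th))
  motif_energy <- function(om) {
    e <- 0
    for (i in 1:2) for (j in (i + 1):3) {
      dx <- pos[j, ] - pos[i, ]
      d <- sqrt(sum(dx^2)); al <- atan2(dx[2], dx[1])
      e <- e + tryCatch(pair_lookup(table, d, om[i] - al, om[j] - al),
                        error = function(e) 1e6)
    }
    e
  }
  best <- NULL
  sec <- sector(s)
  for (o1 in seq(0, sec, length.out = 5L)[-5]) {
    o <- optim(rep(o1, 3), motif_energy, method = "Nelder-Mead",
               control = list(maxit = 200))
    if (is.null(best) || o$value < best$value) best <- o
  }
  A <- shape_area(shape)
  D <- sqrt(3 * A / (phi * sqrt(3) / 2))
  lattice_spec("distorted-B", phi = phi, orientation = "face-on",
               extra = list(t = t, D = D, omegas = best$par))
}
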