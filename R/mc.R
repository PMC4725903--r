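#' Annealing schedule
#'
#' Linear-cooling Metropolis schedule. Temperatures are in units of room
#' temperature; pair energies are in kBT at room temperature, so the
#' acceptance rule uses exp(-dE / T).
#'
#' @param n_steps Monte Carlo steps (one step = one displacement and one
#'   rotation trial per protein on average).
#' @param T_start,T_end temperatures in units of room temperature.
#' @param unit_displacement trial displacement amplitude, nm.
#' @param unit_rotation trial rotation amplitude, radians.
#' @param trace_stride record the energy every this many steps.
#' @return object of class \code{anneal_schedule}.
#' @export
anneal_schedule <- function(n_steps = NULL, T_start = NULL, T_end = NULL,
                            unit_displacement = NULL, unit_rotation = NULL,
                            trace_stride = 100L) {
  def <- mscl_defaults()$mc
  s <- list(
    n_steps = as.integer(if (is.null(n_steps)) def$n_steps else n_steps),
    T_start = if (is.null(T_start)) def$T_start else T_start,
    T_end = if (is.null(T_end)) def$T_end else T_end,
    unit_displacement = if (is.null(unit_displacement)) def$unit_displacement else unit_displacement,
    unit_rotation = if (is.null(unit_rotation)) def$unit_rotation else unit_rotation,
    trace_stride = as.integer(trace_stride))
  stopifnot(s$T_start >= s$T_end, s$T_end > 0, s$n_steps >= 1)
  class(s) <- "anneal_schedule"
  s
}

# build the S x S ordered table list the C++ kernel expects.
# `tables` is a named list keyed "i:j" (1-based species indices) holding
# pair_table objects for i <= j; missing (j, i) entries are derived by the
# bond-reversal symmetry.
species_table_set <- function(tables, n_species) {
  out <- vector("list", n_species * n_species)
  for (i in seq_len(n_species)) for (j in seq_len(n_species)) {
    key <- paste0(i, ":", j); rkey <- paste0(j, ":", i)
    tb <- tables[[key]]
    if (is.null(tb) && !is.null(tables[[rkey]])) tb <- swap_pair_table(tables[[rkey]])
    if (is.null(tb)) stop("missing pair table for species pair ", key)
    out[[(i - 1L) * n_species + j]] <- table_to_cpp(tb)
  }
  out
}

# map a particle_config onto species indices + the table list; species are
# identified by shape label
config_species <- function(config, tables) {
  labels <- vapply(config$shapes, function(s) s$label, "")
  species <- sort(unique(labels))
  sp <- match(labels, species) - 1L
  list(species = species, sp = sp)
}

# normalize the `tables` argument: a single pair_table (one species) or a
# named list keyed by "labelA|labelB"
resolve_tables <- function(config, tables) {
  cs <- config_species(config, tables)
  S <- length(cs$species)
  if (inherits(tables, "pair_table")) {
    if (S != 1L) stop("a single pair table needs a single-species configuration")
    tl <- list("1:1" = tables)
  } else {
    tl <- list()
    for (i in seq_len(S)) for (j in i:S) {
      key1 <- paste0(cs$species[i], "|", cs$species[j])
      key2 <- paste0(cs$species[j], "|", cs$species[i])
      tb <- tables[[key1]]
      swapped <- FALSE
      if (is.null(tb) && !is.null(tables[[key2]])) { tb <- tables[[key2]]; swapped <- TRUE }
      if (is.null(tb)) stop("missing pair table ", key1)
      # orient the table as (species i, species j)
      if (swapped) tb <- swap_pair_table(tb)
      tl[[paste0(i, ":", j)]] <- tb
    }
  }
  list(sp = cs$sp, species = cs$species, S = S,
       cpp = species_table_set(tl, S))
}

#' Total tabulated interaction energy of a configuration
#'
#' Sum of pair-table lookups over all pairs within the cutoff, evaluated with
#' a cell list (cell edge >= d_cut) when periodic; identical to the direct
#' O(N^2) double sum.
#'
#' @param config \code{particle_config}.
#' @param tables a \code{pair_table} (single species) or a named list keyed
#'   \code{"labelA|labelB"} covering every species pair.
#' @param use_cells use the cell list (default) or force the direct sum.
#' @param clamp clamp sub-steric-minimum distances to the contact row rather
#'   than raising an overlap error (for scoring contact lattices whose exact
#'   contours are valid).
#' @return energy in kBT.
#' @export
total_energy <- function(config, tables, use_cells = TRUE, clamp = FALSE) {
  N <- n_proteins(config)
  if (N < 2L) return(0)
  rt <- resolve_tables(config, tables)
  w <- vapply(config$shapes, function(s) s$omega, 0)
  if (config$pbc) {
    .mc_total_energy(config$pos[, 1], config$pos[, 2], w, rt$sp, rt$S,
                     rt$cpp, config$box[1], config$box[2], TRUE, use_cells, clamp)
  } else {
    ext <- apply(config$pos, 2, range)
    box <- pmax(c(diff(ext[, 1]), diff(ext[, 2])), 1) + 1
    .mc_total_energy(config$pos[, 1], config$pos[, 2], w, rt$sp, rt$S,
                     rt$cpp, box[1], box[2], FALSE, use_cells, clamp)
  }
}

# shared driver for anneal() / orientational_relax()
run_mc <- function(config, tables, schedule, seed, rotational_only) {
  N <- n_proteins(config)
  if (N <= 1L) {
    return(list(config = config,
                trace = numeric(0), energy = 0,
                acceptance = c(disp = NA_real_, rot = NA_real_)))
  }
  rt <- resolve_tables(config, tables)
  if (config$pbc) {
    box <- config$box; off <- c(0, 0)
  } else {
    ext <- apply(config$pos, 2, range)
    pad <- 2 * max(vapply(config$shapes, function(s) s$R * (1 + s$eps), 0)) + 2
    off <- ext[1, ] - pad
    box <- c(diff(ext[, 1]), diff(ext[, 2])) + 2 * pad
  }
  w <- vapply(config$shapes, function(s) s$omega, 0)
  res <- .mc_run(config$pos[, 1] - off[1], config$pos[, 2] - off[2], w,
                 rt$sp, rt$S, rt$cpp, box[1], box[2], config$pbc,
                 schedule$n_steps, schedule$T_start, schedule$T_end,
                 schedule$unit_displacement, schedule$unit_rotation,
                 rotational_only, schedule$trace_stride, as.numeric(seed))
  out <- config
  # rotation-only runs never move particles; keep the input positions exactly
  # rather than round-tripping them through the internal box offset
  out$pos <- if (rotational_only) config$pos else cbind(res$x + off[1], res$y + off[2])
  for (i in seq_len(N)) {
    s <- out$shapes[[i]]
    out$shapes[[i]]$omega <- if (s$s == 0) 0 else wrap_angle(res$w[i], sector(s$s))
  }
  out$rng_seed <- seed
  # keep raw (unwrapped to sector) orientations for diagnostics
  attr(out, "omega_raw") <- res$w
  list(config = out, trace = res$trace, energy = res$energy,
       acceptance = c(disp = res$acc_disp / max(res$tot_disp, 1),
                      rot = res$acc_rot / max(res$tot_rot, 1)))
}

#' Simulated annealing of a protein configuration
#'
#' Metropolis Monte Carlo of translational and rotational diffusion with the
#' temperature lowered linearly from \code{T_start} to \code{T_end}. Each
#' step performs one displacement and one rotation trial per protein on
#' average, in randomized order; trials violating the steric minimum
#' distance are rejected outright. Deterministic for a given seed.
#'
#' @param config \code{particle_config} (use a periodic box for bulk
#'   assembly studies).
#' @param tables pair table(s), see \code{\link{total_energy}}.
#' @param schedule \code{anneal_schedule}.
#' @param seed integer RNG seed (recorded in the result).
#' @return list: \code{config} (final), \code{trace} (energy trace, kBT),
#'   \code{energy} (final total energy), \code{acceptance} (move-type
#'   acceptance fractions).
#' @export
anneal <- function(config, tables, schedule = anneal_schedule(), seed = 1L) {
  run_mc(config, tables, schedule, seed, rotational_only = FALSE)
}

#' Rotation-only relaxation at fixed positions
#'
#' Anneals only the orientational degrees of freedom; positions are returned
#' bit-identical. Used to optimize lattice orientations at fixed spacing.
#'
#' @inheritParams anneal
#' @return as \code{\link{anneal}}.
#' @export
orientational_relax <- function(config, tables, schedule = anneal_schedule(),
                                seed = 1L) {
  pos0 <- config$pos
  res <- run_mc(config, tables, schedule, seed, rotational_only = TRUE)
  stopifnot(identical(res$config$pos, pos0))
  res
}

# ---- order parameters --------------------------------------------------------

neighbor_pairs <- function(config, r_cut = NULL) {
  N <- n_proteins(config)
  if (N < 2L) return(cbind(integer(0), integer(0), numeric(0)))
  dx <- outer(config$pos[, 1], config$pos[, 1], "-")
  dy <- outer(config$pos[, 2], config$pos[, 2], "-")
  if (config$pbc) {
    dx <- dx - config$box[1] * round(dx / config$box[1])
    dy <- dy - config$box[2] * round(dy / config$box[2])
  }
  dmat <- sqrt(dx^2 + dy^2)
  diag(dmat) <- Inf
  if (is.null(r_cut)) {
    nn <- apply(dmat, 1, min)
    r_cut <- 1.35 * median(nn)
  }
  idx <- which(dmat < r_cut & upper.tri(dmat), arr.ind = TRUE)
  cbind(idx, d = dmat[idx])
}

#' Bond-orientational and orientational order parameters
#'
#' Computes the global bond-orientational moduli psi4 and psi6 (modulus of
#' the site-averaged mean k-fold bond-angle phase factor over nearest
#' neighbours), the nearest-neighbour distance histogram, and the
#' row-alternation statistic: the mean of cos(s (omega_i - omega_j)) over
#' neighbour pairs, which is +1 for aligned and -1 for anti-aligned
#' neighbour orientations.
#'
#' @param config \code{particle_config}.
#' @param r_cut neighbour cutoff, nm (default 1.35 x median nearest-neighbour
#'   distance).
#' @param subset optional protein indices to restrict to (e.g. the largest
#'   cluster, or one species).
#' @return list: \code{psi4}, \code{psi6}, \code{psi4_local}, \code{psi6_local}
#'   (mean per-site moduli), \code{nn_hist}, \code{row_alternation},
#'   \code{n_neighbors}.
#' @export
order_parameters <- function(config, r_cut = NULL, subset = NULL) {
  N <- n_proteins(config)
  stopifnot(N >= 2)
  if (!is.null(subset)) {
    config <- particle_config(config$shapes[subset],
                              config$pos[subset, , drop = FALSE],
                              box = config$box, pbc = config$pbc)
    N <- n_proteins(config)
    if (N < 2) stop("subset too small")
  }
  np <- neighbor_pairs(config, r_cut)
  if (nrow(np) == 0L)
    return(list(psi4 = 0, psi6 = 0, psi4_local = 0, psi6_local = 0,
                nn_hist = numeric(0), row_alternation = NA_real_,
                n_neighbors = 0))
  dx <- config$pos[np[, 2], 1] - config$pos[np[, 1], 1]
  dy <- config$pos[np[, 2], 2] - config$pos[np[, 1], 2]
  if (config$pbc) {
    dx <- dx - config$box[1] * round(dx / config$box[1])
    dy <- dy - config$box[2] * round(dy / config$box[2])
  }
  th <- atan2(dy, dx)
  psi_k <- function(k) {
    ph <- exp(1i * k * th)
    num <- rep(0 + 0i, N); cnt <- numeric(N)
    for (r in seq_len(nrow(np))) {
      i <- np[r, 1]; j <- np[r, 2]
      num[i] <- num[i] + ph[r]; num[j] <- num[j] + ph[r] # bond angle k-fold:
      cnt[i] <- cnt[i] + 1; cnt[j] <- cnt[j] + 1         # +pi invariant for even k
    }
    ok <- cnt > 0
    psi_i <- num[ok] / cnt[ok]
    list(global = Mod(mean(psi_i)), local = mean(Mod(psi_i)))
  }
  p4 <- psi_k(4); p6 <- psi_k(6)
  s_i <- vapply(config$shapes[np[, 1]], function(s) s$s, 0L)
  wi <- vapply(config$shapes[np[, 1]], function(s) s$omega, 0)
  wj <- vapply(config$shapes[np[, 2]], function(s) s$omega, 0)
  same <- s_i == vapply(config$shapes[np[, 2]], function(s) s$s, 0L) & s_i > 0
  row_alt <- if (any(same)) mean(cos(s_i[same] * (wi[same] - wj[same]))) else NA_real_
  list(psi4 = p4$global, psi6 = p6$global,
       psi4_local = p4$local, psi6_local = p6$local,
       nn_hist = np[, 3], row_alternation = row_alt,
       n_neighbors = 2 * nrow(np) / N)
}

#' Largest connected cluster of a configuration
#'
#' Connected components of the neighbour graph (pairs closer than
#' \code{r_cut}); returns the member indices of the largest component.
#'
#' @inheritParams order_parameters
#' @return integer vector of protein indices.
#' @export
largest_cluster <- function(config, r_cut = NULL) {
  N <- n_proteins(config)
  np <- neighbor_pairs(config, r_cut)
  comp <- seq_len(N)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(np))) {
      i <- np[r, 1]; j <- np[r, 2]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) { comp[i] <- m; comp[j] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  tab <- table(comp)
  which(comp == as.integer(names(tab)[which.max(tab)]))
}

# restore RNG state after using a local seed
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random non-overlapping protein gas
#'
#' Sequential random insertion of N proteins with random orientations into a
#' periodic box, rejecting placements that violate the steric minimum
#' distance (plus a safety margin). Deterministic given the seed.
#'
#' @param shapes a \code{protein_shape} or list of them (recycled to N).
#' @param N protein count.
#' @param box c(Lx, Ly), nm.
#' @param seed integer seed.
#' @param clearance steric edge-to-edge clearance, nm.
#' @param margin extra spacing added to the steric minimum during insertion.
#' @param max_tries insertion attempts per protein before giving up.
#' @return \code{particle_config} with \code{pbc = TRUE}.
#' @export
random_gas <- function(shapes, N, box, seed = 1L, clearance = NULL,
                       margin = 0.3, max_tries = 2000L) {
  if (inherits(shapes, "protein_shape")) shapes <- list(shapes)
  shapes <- rep(shapes, length.out = N)
  # conservative circumscribed steric bound per pair
  rmax <- vapply(shapes, function(s) s$R * (1 + s$eps), 0)
  if (is.null(clearance)) clearance <- mscl_defaults()$steric$edge_clearance
  with_seed(seed, {
    pos <- matrix(NA_real_, N, 2)
    for (i in seq_len(N)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- runif(2) * box
        ok <- TRUE
        if (i > 1L) {
          dx <- pos[seq_len(i - 1L), 1] - cand[1]
          dy <- pos[seq_len(i - 1L), 2] - cand[2]
          dx <- dx - box[1] * round(dx / box[1])
          dy <- dy - box[2] * round(dy / box[2])
          dmin_i <- rmax[i] + rmax[seq_len(i - 1L)] + clearance + margin
          ok <- all(dx^2 + dy^2 >= dmin_i^2)
        }
        if (ok) { pos[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) stop("placement error: could not insert protein ", i,
                        " after ", max_tries, " tries")
    }
    for (i in seq_len(N)) {
      s <- shapes[[i]]
      if (s$s > 0) shapes[[i]]$omega <- runif(1) * sector(s$s)
    }
    particle_config(shapes, pos, box = box, pbc = TRUE, rng_seed = seed)
  })
}
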