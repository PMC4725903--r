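# pair lookup with a smooth steric penalty instead of an error; used by the
# local rearrangement minimizer
lookup_penalized <- function(table, d, w1, w2, stiff = 200) {
  nw1 <- length(table$w1_grid); nw2 <- length(table$w2_grid)
  sec1 <- sector(table$shapeA$s); sec2 <- sector(table$shapeB$s)
  i <- (round(wrap_angle(w1, sec1) / (sec1 / nw1)) %% nw1) + 1L
  j <- (round(wrap_angle(w2, sec2) / (sec2 / nw2)) %% nw2) + 1L
  dm <- table$dmin[i, j]
  if (d < dm) return(stiff * (dm - d) + stiff * (dm - d)^2)
  pair_lookup(table, d, w1, w2)
}

# interaction energy between protein a (possibly displaced state xa, ya, wa)
# and protein b of a configuration, via the right species table
mixed_pair_e <- function(tabs, sa, sb, xa, ya, wa, xb, yb, wb, penal = TRUE) {
  dx <- xb - xa; dy <- yb - ya
  d <- sqrt(dx^2 + dy^2)
  tb <- tabs[[paste0(sa, "|", sb)]]
  swapped <- FALSE
  if (is.null(tb)) { tb <- tabs[[paste0(sb, "|", sa)]]; swapped <- TRUE }
  if (is.null(tb)) stop("missing table for ", sa, "|", sb)
  if (d >= tb$d_cut) return(0)
  al <- atan2(dy, dx)
  if (swapped) {
    w1 <- wb - (al + pi); w2 <- wa - (al + pi)
  } else {
    w1 <- wa - al; w2 <- wb - al
  }
  if (penal) lookup_penalized(tb, d, w1, w2)
  else pair_lookup(tb, d, w1, w2, clamp = TRUE)
}

# residual steric violation (nm) of one pair: how far below the tabulated
# minimum distance the pair sits
pair_violation <- function(tabs, sa, sb, xa, ya, wa, xb, yb, wb) {
  dx <- xb - xa; dy <- yb - ya
  d <- sqrt(dx^2 + dy^2)
  tb <- tabs[[paste0(sa, "|", sb)]]
  swapped <- FALSE
  if (is.null(tb)) { tb <- tabs[[paste0(sb, "|", sa)]]; swapped <- TRUE }
  if (d >= tb$d_cut) return(0)
  al <- atan2(dy, dx)
  if (swapped) { w1 <- wb - (al + pi); w2 <- wa - (al + pi) }
  else { w1 <- wa - al; w2 <- wb - al }
  nw1 <- length(tb$w1_grid); nw2 <- length(tb$w2_grid)
  sec1 <- sector(tb$shapeA$s); sec2 <- sector(tb$shapeB$s)
  i <- (round(wrap_angle(w1, sec1) / (sec1 / nw1)) %% nw1) + 1L
  j <- (round(wrap_angle(w2, sec2) / (sec2 / nw2)) %% nw2) + 1L
  max(0, tb$dmin[i, j] - d)
}

#' Lattice activation barrier for gating at a cluster perimeter site
#'
#' Interaction-energy cost of switching one perimeter protein of a
#' ground-state closed-state cluster into its (larger) open-state footprint,
#' allowing the site and its neighbour shell to rearrange locally: the
#' barrier is the minimized mixed-cluster interaction energy minus the
#' all-closed ground-state interaction energy. The isolated-protein gating
#' energy cancels by construction (interaction energies only).
#'
#' @param spec ground-state \code{lattice_spec} for the closed oligomer
#'   (face-on square for tetramers, distorted-A for pentamers).
#' @param shape_closed,shape_open \code{protein_shape}s of the two states.
#' @param table_cc closed-closed \code{pair_table} (at the tension of
#'   interest; the potential itself depends on tension).
#' @param table_co closed-open \code{pair_table} oriented (closed, open).
#' @param site "corner" or "edge" perimeter site.
#' @param L linear cluster size.
#' @param n_restarts randomized restarts added to the deterministic starts.
#' @param shell_depth neighbour shell radius in units of the lattice spacing
#'   (1.6 covers nearest and next-nearest neighbours).
#' @return data.frame (class \code{barrier_result}): tau, site, oligomer,
#'   dG (kBT), steric_violation (nm; residual sub-steric overlap at the
#'   minimizer -- values above ~0.05 mean the site is sterically blocked and
#'   dG is penalty-dominated), and bookkeeping columns.
#' @export
activation_barrier <- function(spec, shape_closed, shape_open,
                               table_cc, table_co,
                               site = c("corner", "edge"), L = 5L,
                               n_restarts = 5L, shell_depth = 1.6) {
  site <- match.arg(site)
  spec$L <- as.integer(L); spec$N <- NULL
  cfg <- build_lattice(spec, shape_closed)
  N <- n_proteins(cfg)
  pos <- cfg$pos
  om <- vapply(cfg$shapes, function(s) s$omega, 0)

  # perimeter site selection
  xr <- range(pos[, 1]); yr <- range(pos[, 2])
  if (site == "corner") {
    isite <- which.min((pos[, 1] - xr[1])^2 + (pos[, 2] - yr[1])^2)
  } else {
    onedge <- abs(pos[, 2] - yr[1]) < 1e-6
    cand <- which(onedge)
    isite <- cand[which.min(abs(pos[cand, 1] - mean(xr)))]
  }

  spacing <- if (!is.null(spec$d)) spec$d else {
    pr <- distorted_a_params(spec, shape_closed); min(pr$ax, pr$ay)
  }
  d2 <- (pos[, 1] - pos[isite, 1])^2 + (pos[, 2] - pos[isite, 2])^2
  shell <- setdiff(which(d2 < (shell_depth * spacing)^2), isite)
  free <- c(isite, shell)
  nfree <- length(free)

  tabs_closed <- list("c|c" = table_cc)
  tabs_mixed <- list("c|c" = table_cc, "c|o" = table_co)
  sp_lab <- rep("c", N)

  pair_sum <- function(positions, omegas, labels, tabs, ii, jj, penal) {
    e <- 0
    for (a in ii) for (b in jj) {
      if (a >= b && b %in% ii) next  # count each free-free pair once
      if (a == b) next
      e <- e + mixed_pair_e(tabs, labels[a], labels[b],
                            positions[a, 1], positions[a, 2], omegas[a],
                            positions[b, 1], positions[b, 2], omegas[b],
                            penal)
    }
    e
  }

  fixed <- setdiff(seq_len(N), free)
  E0_total <- total_energy(cfg, table_cc, clamp = TRUE)

  # energy of pairs touching the free set, all-closed reference
  E0_free <- pair_sum(pos, om, sp_lab, tabs_closed, free, seq_len(N), penal = FALSE)

  lab_mix <- sp_lab; lab_mix[isite] <- "o"
  outward <- pos[isite, ] - c(mean(xr), mean(yr))
  outward <- outward / max(sqrt(sum(outward^2)), 1e-9)
  dR <- shape_open$R * (1 + shape_open$eps) - shape_closed$R * (1 + shape_closed$eps)

  mix_energy <- function(p) {
    po <- pos; oo <- om
    po[free, 1] <- p[seq_len(nfree) * 3 - 2]
    po[free, 2] <- p[seq_len(nfree) * 3 - 1]
    oo[free] <- p[seq_len(nfree) * 3]
    pair_sum(po, oo, lab_mix, tabs_mixed, free, seq_len(N), penal = TRUE)
  }
  base_par <- as.vector(t(cbind(pos[free, , drop = FALSE], om[free])))

  # outward unit vector per free particle (the shell must also give way to
  # accommodate the larger open footprint, so it is pushed at reduced weight)
  cen <- c(mean(xr), mean(yr))
  out_f <- pos[free, , drop = FALSE] - rep(cen, each = nfree)
  nrm <- pmax(sqrt(rowSums(out_f^2)), 1e-9)
  out_f <- out_f / nrm
  starts <- list()
  for (push in c(0.6, 1.0, 1.4) * dR) {
    p <- base_par
    wgt <- c(1, rep(0.4, nfree - 1L))
    p[seq_len(nfree) * 3 - 2] <- pos[free, 1] + push * wgt * out_f[, 1]
    p[seq_len(nfree) * 3 - 1] <- pos[free, 2] + push * wgt * out_f[, 2]
    starts[[length(starts) + 1L]] <- p
  }
  if (n_restarts > 0) {
    hs <- matrix(halton_seq(n_restarts * length(base_par)), ncol = length(base_par))
    for (r in seq_len(n_restarts)) {
      p <- starts[[2]]
      p <- p + (hs[r, ] - 0.5) * rep(c(0.6, 0.6, 0.3), nfree)
      starts[[length(starts) + 1L]] <- p
    }
  }
  best <- NULL
  maxit1 <- max(1200L, 150L * 3L * nfree)  # scale with dimension
  for (st in starts) {
    o <- optim(st, mix_energy, method = "Nelder-Mead",
               control = list(maxit = maxit1, reltol = 1e-7))
    o <- optim(o$par, mix_energy, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-8))
    if (is.null(best) || o$value < best$value) best <- o
  }

  E_mix_total <- E0_total - E0_free + best$value
  dG <- E_mix_total - E0_total

  # residual steric violation at the minimizer: > ~0.05 nm means the open
  # footprint cannot be accommodated by local rearrangement and dG is
  # penalty-dominated (site effectively sterically blocked)
  po <- pos; oo <- om
  po[free, 1] <- best$par[seq_len(nfree) * 3 - 2]
  po[free, 2] <- best$par[seq_len(nfree) * 3 - 1]
  oo[free] <- best$par[seq_len(nfree) * 3]
  viol <- 0
  for (a in free) for (b in seq_len(N)) {
    if (a == b) next
    viol <- max(viol, pair_violation(tabs_mixed, lab_mix[a], lab_mix[b],
                                     po[a, 1], po[a, 2], oo[a],
                                     po[b, 1], po[b, 2], oo[b]))
  }
  out <- data.frame(tau = table_cc$params$tau, site = site,
                    oligomer = shape_closed$label, dG = dG,
                    steric_violation = viol,
                    E_ground = E0_total, L = L, N = N,
                    stringsAsFactors = FALSE)
  class(out) <- c("barrier_result", "data.frame")
  out
}

#' Activation barrier versus membrane tension with a linear fit
#'
#' @param spec ground-state \code{lattice_spec}.
#' @param shape_closed,shape_open state shapes.
#' @param tables_by_tau list (one per tension) of lists with elements
#'   \code{cc} and \code{co}: pair tables tabulated at that tension (the
#'   potential, not just the Boltzmann factor, depends on tension).
#' @param site "corner" or "edge".
#' @param L cluster size.
#' @return list: \code{data} (barrier_result rows), \code{fit} (lm),
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{flat} (TRUE when
#'   the fitted slope is indistinguishable from zero).
#' @export
barrier_vs_tension <- function(spec, shape_closed, shape_open, tables_by_tau,
                               site = "corner", L = 5L) {
  taus <- vapply(tables_by_tau, function(t) t$cc$params$tau, 0)
  if (length(taus) < 3L) stop("need at least 3 tension values")
  if (diff(range(taus)) < 1e-12)
    stop("degenerate-fit error: all tension values identical")
  rows <- do.call(rbind, lapply(tables_by_tau, function(tt)
    activation_barrier(spec, shape_closed, shape_open, tt$cc, tt$co,
                       site = site, L = L)))
  fit <- lm(dG ~ tau, data = rows)
  ss <- summary(fit)
  list(data = rows, fit = fit,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = ss$r.squared,
       flat = abs(unname(coef(fit)[2])) * diff(range(taus)) <
         0.02 * max(abs(rows$dG), 1e-9))
}

#' Arrhenius activation-rate ratio
#'
#' Factor by which a lattice with barrier \code{dG_b} activates faster than
#' one with barrier \code{dG_a}, assuming an Arrhenius form for the
#' reorganization rate: \code{exp((dG_a - dG_b) / T)}.
#'
#' @param dG_a,dG_b activation barriers, kBT.
#' @param T temperature in units of room temperature.
#' @return dimensionless rate ratio.
#' @export
arrhenius_ratio <- function(dG_a, dG_b, T = 1) {
  stopifnot(T > 0)
  exp((dG_a - dG_b) / T)
}

#' Annealing of mixed closed/open clusters with a segregation report
#'
#' Simulated annealing of a closed/open protein mixture followed by
#' structural analysis: the segregation index (mean over sites of the
#' fraction of nearest neighbours sharing the site's state) against its
#' random-mixing expectation, the modal closed-open neighbour distance,
#' per-state sub-cluster order parameters, and whether the final state is a
#' single composite cluster.
#'
#' @param n_closed,n_open protein counts per state.
#' @param shape_closed,shape_open \code{protein_shape}s (same oligomer).
#' @param tables named list with entries \code{"closed|closed"},
#'   \code{"closed|open"}, \code{"open|open"} holding pair tables; names are
#'   matched against the shape labels.
#' @param schedule \code{anneal_schedule}.
#' @param box periodic box c(Lx, Ly), nm (default: area fraction ~ 0.35).
#' @param seed RNG seed.
#' @return list: \code{config}, \code{segregation_index}, \code{baseline},
#'   \code{modal_co_distance}, \code{order_closed}, \code{order_open},
#'   \code{composite} (largest cluster holds both states),
#'   \code{largest_cluster_fraction}, \code{trace}.
#' @export
mixed_state_anneal <- function(n_closed, n_open, shape_closed, shape_open,
                               tables, schedule = anneal_schedule(),
                               box = NULL, seed = 1L) {
  shapes <- c(rep(list(shape_closed), n_closed), rep(list(shape_open), n_open))
  if (is.null(box)) {
    # area fraction 0.2 keeps sequential random insertion below its jamming
    # limit once the steric clearance is added to each footprint
    Atot <- sum(vapply(shapes, shape_area, 0))
    box <- rep(sqrt(Atot / 0.2), 2L)
  }
  names(tables) <- vapply(strsplit(names(tables), "|", fixed = TRUE),
                          function(pr) paste(sub("closed", shape_closed$label,
                                             sub("open", shape_open$label, pr)),
                                             collapse = "|"), "")
  cfg0 <- random_gas(shapes, n_closed + n_open, box, seed = seed)
  res <- anneal(cfg0, tables, schedule, seed = seed)
  cfg <- res$config

  labs <- vapply(cfg$shapes, function(s) s$label, "")
  is_closed <- labs == shape_closed$label
  np <- neighbor_pairs(cfg)
  same <- numeric(n_proteins(cfg)); tot <- numeric(n_proteins(cfg))
  co_d <- numeric(0)
  for (r in seq_len(nrow(np))) {
    i <- np[r, 1]; j <- np[r, 2]
    sm <- is_closed[i] == is_closed[j]
    same[i] <- same[i] + sm; same[j] <- same[j] + sm
    tot[i] <- tot[i] + 1; tot[j] <- tot[j] + 1
    if (!sm) co_d <- c(co_d, np[r, 3])
  }
  ok <- tot > 0
  seg <- mean(same[ok] / tot[ok])
  N <- n_closed + n_open
  baseline <- (n_closed * (n_closed - 1) + n_open * (n_open - 1)) / (N * (N - 1))
  modal <- if (length(co_d)) {
    br <- seq(floor(min(co_d) * 10) / 10, ceiling(max(co_d) * 10) / 10 + 0.1, by = 0.1)
    h <- hist(co_d, breaks = br, plot = FALSE)
    h$mids[which.max(h$counts)]
  } else NA_real_
  lc <- largest_cluster(cfg)
  ordc <- if (sum(is_closed) >= 2)
    order_parameters(cfg, subset = which(is_closed)) else NULL
  ordo <- if (sum(!is_closed) >= 2)
    order_parameters(cfg, subset = which(!is_closed)) else NULL
  list(config = cfg, segregation_index = seg, baseline = baseline,
       modal_co_distance = modal, order_closed = ordc, order_open = ordo,
       composite = any(is_closed[lc]) && any(!is_closed[lc]),
       largest_cluster_fraction = length(lc) / N,
       trace = res$trace, seed = seed)
}
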