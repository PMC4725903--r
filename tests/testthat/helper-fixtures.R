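# Shared fixtures, built lazily and cached for the whole test run.
# Pair tables use coarse "test-grade" grids (documented in the methods
# vignette): dd = 0.5-0.9 nm, 3-8 orientations per symmetry sector, mesh
# edge ~ perimeter/48-64. These resolve the sign structure and energy
# orderings the tests assert while keeping the full suite within a desk-scale
# budget.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_params <- function(tau = 0) bilayer_params(tau = tau)

fx_tab_cyl <- function() fixture("tab_cyl", function() {
  cyl <- mscl_shape("cylinder", "closed")
  build_pair_table(cyl, cyl, fx_params(), dd = 0.5,
                   h_frac = 64, margin_lambda = 6, maxit = 12L)
})

fx_tab_tet <- function() fixture("tab_tet", function() {
  tet <- mscl_shape("tetramer", "closed")
  build_pair_table(tet, tet, fx_params(), dd = 0.5, nw1 = 4L, nw2 = 4L,
                   h_frac = 64, margin_lambda = 6, maxit = 12L)
})

fx_tab_pent <- function() fixture("tab_pent", function() {
  pent <- mscl_shape("pentamer", "closed")
  build_pair_table(pent, pent, fx_params(), dd = 0.5, nw1 = 4L, nw2 = 4L,
                   h_frac = 64, margin_lambda = 6, maxit = 12L)
})

# near-contact tetramer table with fine orientation resolution, for
# orientational-relaxation checks
fx_tab_tet_fine <- function() fixture("tab_tet_fine", function() {
  tet <- mscl_shape("tetramer", "closed")
  build_pair_table(tet, tet, fx_params(), dd = 0.5, nw1 = 8L, nw2 = 8L,
                   d_cut = 7.2, h_frac = 56, margin_lambda = 6, maxit = 10L)
})

# mixed-state tables use even orientation grids (4 per sector): the MC engine
# derives the reversed-species table by a pi shift, which odd grids cannot
# represent
fx_tab_pent_co <- function() fixture("tab_pent_co", function() {
  build_pair_table(mscl_shape("pentamer", "closed"),
                   mscl_shape("pentamer", "open"), fx_params(),
                   dd = 0.6, nw1 = 4L, nw2 = 4L,
                   h_frac = 56, margin_lambda = 6, maxit = 10L)
})

fx_tab_pent_oo <- function() fixture("tab_pent_oo", function() {
  po <- mscl_shape("pentamer", "open")
  build_pair_table(po, po, fx_params(), dd = 0.6, nw1 = 4L, nw2 = 4L,
                   h_frac = 56, margin_lambda = 6, maxit = 10L)
})

# gating tables: cc and co at one tension, coarse grids
fx_gating_tabs <- function(oligomer, tau) {
  key <- paste0("gate_", oligomer, "_", tau)
  fixture(key, function() {
    p <- bilayer_params(tau = tau)
    shc <- mscl_shape(oligomer, "closed")
    sho <- mscl_shape(oligomer, "open")
    list(cc = build_pair_table(shc, shc, p, dd = 0.9, nw1 = 3L, nw2 = 3L,
                               h_frac = 48, margin_lambda = 5.5, maxit = 10L),
         co = build_pair_table(shc, sho, p, dd = 0.9, nw1 = 3L, nw2 = 3L,
                               h_frac = 48, margin_lambda = 5.5, maxit = 10L))
  })
}

fx_ground_spec <- function(oligomer) {
  key <- paste0("gspec_", oligomer)
  fixture(key, function() {
    shc <- mscl_shape(oligomer, "closed")
    if (oligomer == "tetramer") {
      sp <- lattice_spec("square", d = 6, orientation = "face-on")
      sp$d <- lattice_min_spacing(sp, shc)
      sp
    } else {
      max_packing_distorted_a(shc, n_starts = 4L)$spec
    }
  })
}

fx_max_packing_pent <- function() fixture("mp_pent", function()
  max_packing_distorted_a(mscl_shape("pentamer", "closed"), n_starts = 4L))

# ---- shared heavy fixtures for the acceptance suite --------------------------

# annealing study: 5 seeds, N = 100 proteins, 1e5 MC steps, box at area
# fraction 0.2, move sizes sqrt(10)-scaled so the total random-walk length
# matches the full 1e6-step protocol; returns one row of order parameters
# per seed
fx_anneal_stats <- function(oligomer) {
  key <- paste0("anneal_", oligomer)
  fixture(key, function() {
    shape <- mscl_shape(oligomer, "closed")
    tb <- if (oligomer == "tetramer") fx_tab_tet() else fx_tab_pent()
    box <- rep(sqrt(100 * shape_area(shape) / 0.2), 2)
    sched <- anneal_schedule(n_steps = 1e5, unit_displacement = 0.3,
                             unit_rotation = 0.15, trace_stride = 0)
    t(vapply(1:5, function(k) {
      gas <- random_gas(shape, 100, box, seed = k)
      r <- anneal(gas, tb, sched, seed = k)
      lc <- largest_cluster(r$config)
      op <- order_parameters(r$config, subset = lc)
      c(psi4 = op$psi4, psi6 = op$psi6, rowalt = op$row_alternation,
        ncl = length(lc))
    }, c(psi4 = 0, psi6 = 0, rowalt = 0, ncl = 0)))
  })
}

# perimeter-site activation barrier at one tension, cached across tests
fx_barrier <- function(oligomer, tau, site) {
  key <- paste0("barrier_", oligomer, "_", tau, "_", site)
  fixture(key, function() {
    shc <- mscl_shape(oligomer, "closed")
    sho <- mscl_shape(oligomer, "open")
    tt <- fx_gating_tabs(oligomer, tau)
    activation_barrier(fx_ground_spec(oligomer), shc, sho, tt$cc, tt$co,
                       site = site, L = 4L, n_restarts = 2L)
  })
}

# converged-resolution tail energies at the interaction cutoff, shared by the
# pair and acceptance suites
fx_tail_energies <- function() fixture("tail_energies", function() {
  dcut <- mscl_defaults()$steric$d_cut
  tet <- mscl_shape("tetramer", "closed")
  pent <- mscl_shape("pentamer", "closed")
  c(tet_tip = pair_energy(tet, tet, dcut, 0, 0,
                          h_frac = 160, margin_lambda = 8, maxit = 25L),
    tet_face = pair_energy(tet, tet, dcut, pi / 4, pi / 4,
                           h_frac = 160, margin_lambda = 8, maxit = 25L),
    pent_tip = pair_energy(pent, pent, dcut, 0, 0,
                           h_frac = 160, margin_lambda = 8, maxit = 25L))
})
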