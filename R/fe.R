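#' Element stiffness and internal-tension load for one triangle
#'
#' Exposes the mixed DKT / linear-triangle element used by the solver: a
#' 9x9 symmetric stiffness block over the nodal degrees of freedom
#' (u, du/dx, du/dy) per vertex, and the element load vector produced by the
#' tension-thickness coupling ("internal tension").
#'
#' @param coords 3 x 2 matrix of vertex coordinates (counterclockwise), nm.
#' @param params \code{bilayer_params}.
#' @return list with \code{K} (9 x 9), \code{f} (length 9), \code{area}.
#' @export
element_matrices <- function(coords, params = bilayer_params()) {
  .dkt_element(coords, params$kappa_b, params$K_t / params$a^2,
               params$tau, params$tau / params$a, params$tau_u_coupling)
}

# bulk energy density of the uniformly relaxed membrane (tension only);
# subtracting area * e0 yields the excess (deformation) energy
bulk_energy_density <- function(params) {
  if (params$tau_u_coupling) -params$tau^2 / (2 * params$K_t) else 0
}

#' Minimize the thickness-deformation energy on a mesh
#'
#' Assembles the mixed-element quadratic form and solves the constrained
#' minimization. Dirichlet values (u = U with zero slope) are imposed on
#' every protein contour by DOF elimination; symmetry-cell edges constrain
#' the normal gradient component; periodic meshes tie matched boundary nodes.
#' The functional is quadratic, so the primary path is a direct sparse
#' Cholesky solve; \code{method = "lbfgs"} re-minimizes iteratively as a
#' cross-check.
#'
#' @param mesh \code{tri_mesh}.
#' @param params \code{bilayer_params}.
#' @param bcs optional numeric vector of Dirichlet boundary values per
#'   protein (defaults to each shape's stored mismatch U).
#' @param method "cholesky" or "lbfgs".
#' @return object of class \code{nodal_field}: per-node \code{u} and gradient,
#'   total energy \code{E} (kBT), deformation excess energy \code{E_excess}
#'   (bulk tension contribution removed), and the meshed \code{area}.
#' @export
solve_field <- function(mesh, params = bilayer_params(), bcs = NULL,
                        method = c("cholesky", "lbfgs")) {
  method <- match.arg(method)
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  asm <- .dkt_assemble(mesh$nodes, mesh$triangles, params$kappa_b,
                       params$K_t / params$a^2, params$tau,
                       params$tau / params$a, params$tau_u_coupling)
  K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$v, dims = c(ndof, ndof))
  f <- asm$f

  if (is.null(bcs)) bcs <- vapply(mesh$shapes, function(s) s$U, 0)
  if (length(bcs) != length(mesh$tags$protein))
    stop("bcs must cover every protein boundary")

  fixval <- rep(NA_real_, ndof)
  for (k in seq_along(mesh$tags$protein)) {
    idx <- mesh$tags$protein[[k]]
    fixval[3 * (idx - 1) + 1] <- bcs[[k]]
    fixval[3 * (idx - 1) + 2] <- 0
    fixval[3 * (idx - 1) + 3] <- 0
  }
  if (length(mesh$tags$sym_x)) fixval[3 * (mesh$tags$sym_x - 1) + 2] <- 0
  if (length(mesh$tags$sym_y)) fixval[3 * (mesh$tags$sym_y - 1) + 3] <- 0

  # periodic ties: slave DOFs replaced by their masters
  master <- seq_len(ndof)
  if (!is.null(mesh$tags$pbc) && nrow(mesh$tags$pbc) > 0) {
    pr <- mesh$tags$pbc
    for (c in 0:2) master[3 * (pr[, 1] - 1) + 1 + c] <- 3 * (pr[, 2] - 1) + 1 + c
    while (any(master[master] != master)) master <- master[master]
    tied <- master != seq_len(ndof)
    P <- Matrix::sparseMatrix(i = seq_len(ndof), j = master, x = 1,
                              dims = c(ndof, ndof))
    keepcols <- which(!tied)
    P <- P[, keepcols, drop = FALSE]
    K2 <- Matrix::t(P) %*% K %*% P
    f2 <- as.numeric(Matrix::t(P) %*% f)
    fix2 <- fixval[keepcols]
  } else {
    P <- NULL; K2 <- K; f2 <- f; fix2 <- fixval; keepcols <- seq_len(ndof)
  }

  fixed <- !is.na(fix2)
  if (!any(fixed) && params$tau == 0 && params$K_t == 0)
    stop("singular-system error: unconstrained floating domain")
  free <- which(!fixed)
  ufix <- ifelse(fixed, fix2, 0)

  Kff <- K2[free, free, drop = FALSE]
  rhs <- -(f2[free] + as.numeric(K2[free, which(fixed), drop = FALSE] %*% fix2[fixed]))
  ured <- numeric(length(fix2))
  ured[fixed] <- fix2[fixed]
  if (method == "cholesky") {
    ured[free] <- as.numeric(Matrix::solve(Matrix::forceSymmetric(Kff), rhs))
  } else {
    fn <- function(v) 0.5 * sum(v * as.numeric(Kff %*% v)) - sum(rhs * v)
    gr <- function(v) as.numeric(Kff %*% v) - rhs
    st <- optim(numeric(length(free)), fn, gr, method = "L-BFGS-B",
                control = list(maxit = 5000, factr = 10))
    ured[free] <- st$par
  }

  if (is.null(P)) {
    U <- ured
  } else {
    tmp <- numeric(ndof); tmp[keepcols] <- ured; U <- tmp[master]
  }
  E <- 0.5 * sum(U * as.numeric(K %*% U)) + sum(f * U)
  e0 <- bulk_energy_density(params)
  fld <- list(u = U[3 * (1:n) - 2], ux = U[3 * (1:n) - 1], uy = U[3 * (1:n)],
              dofs = U, E = E, E_excess = E - e0 * asm$area,
              area = asm$area, params = params, mesh = mesh, method = method)
  class(fld) <- "nodal_field"
  fld
}

#' @exportS3Method base::print
print.nodal_field <- function(x, ...) {
  cat(sprintf("nodal_field: %d nodes, E = %.6g kBT (excess %.6g kBT)\n",
              length(x$u), x$E, x$E_excess))
  invisible(x)
}

#' Energy recomputed by direct quadrature over the solved field
#'
#' Integrates the energy density of the solved interpolant element by element
#' with the same quadrature rule used in assembly; used as a consistency
#' check against the assembled quadratic form.
#'
#' @param field \code{nodal_field}.
#' @return list with the curvature / stretch / tension parts and their total.
#' @export
energy_quadrature <- function(field) {
  p <- field$params
  .dkt_energy_parts(field$mesh$nodes, field$mesh$triangles, field$dofs,
                    p$kappa_b, p$K_t / p$a^2, p$tau, p$tau / p$a,
                    p$tau_u_coupling)
}

#' Validity check for the leading-order (small-gradient) model
#'
#' @param field \code{nodal_field}.
#' @param threshold small-gradient threshold on |grad u| (default 0.5).
#' @return list: \code{max_grad}, \code{frac_exceed} (fraction of elements
#'   whose maximal |grad u| exceeds the threshold).
#' @export
gradient_validity_check <- function(field, threshold = 0.5) {
  parts <- energy_quadrature(field)
  g <- parts$grad_max
  list(max_grad = max(g), frac_exceed = mean(g > threshold),
       threshold = threshold)
}

# ---- analytic single-cylinder oracle ----------------------------------------

# modified Bessel K_nu (nu = 0, 1) for complex argument with Re(z) > 0, from
# the integral representation K_nu(z) = int_0^inf exp(-z cosh t) cosh(nu t) dt
complex_besselK <- function(nu, z) {
  vapply(z, function(zz) {
    if (Re(zz) <= 0) stop("complex_besselK requires Re(z) > 0")
    upper <- acosh(max(2, 745 / Re(zz))) + 1
    fre <- function(t) Re(exp(-zz * cosh(t)) * cosh(nu * t))
    fim <- function(t) Im(exp(-zz * cosh(t)) * cosh(nu * t))
    re <- integrate(fre, 0, upper, rel.tol = 1e-12, abs.tol = 1e-14,
                    subdivisions = 400L)$value
    im <- integrate(fim, 0, upper, rel.tol = 1e-12, abs.tol = 1e-14,
                    subdivisions = 400L)$value
    complex(real = re, imaginary = im)
  }, complex(1))
}

#' Exact thickness deformation around a single cylindrical inclusion
#'
#' Closed-form minimizer of the thickness-deformation energy outside a
#' circular inclusion of radius \code{R0} with boundary conditions
#' \code{u(R0) = U}, \code{u'(R0) = 0} and decay at infinity. The radial
#' profile is a real combination of modified Bessel functions
#' \code{K0(k r)} where \code{k^2} are the roots of
#' \code{kappa_b k^4 - tau k^2 + K_t/a^2 = 0}; under tension the far field
#' relaxes to \code{u0 = -a tau / K_t} and the boundary condition acts on
#' \code{U - u0}. The energy is the boundary-flux closed form obtained by
#' integrating the energy density by parts.
#'
#' @param params \code{bilayer_params}.
#' @param R0 inclusion radius, nm (> 0).
#' @param U boundary mismatch u(R0), nm.
#' @return list: \code{profile} (vectorized function of r), \code{energy}
#'   (excess deformation energy, kBT), \code{u0}, \code{k} (complex roots).
#' @export
analytic_cylinder <- function(params, R0, U) {
  if (R0 <= 0) stop("R0 must be positive")
  kb <- params$kappa_b; Kt <- params$K_t; a <- params$a; tau <- params$tau
  u0 <- if (params$tau_u_coupling) -a * tau / Kt else 0
  Ueff <- U - u0
  disc <- as.complex(tau^2 - 4 * kb * Kt / a^2)
  k2 <- (tau + c(1, -1) * sqrt(disc)) / (2 * kb)
  k <- sqrt(k2)                       # principal roots, Re(k) > 0
  underdamped <- Re(disc) < 0

  if (underdamped) {
    kk <- k[1]
    A0 <- complex_besselK(0, kk * R0)
    A1 <- kk * complex_besselK(1, kk * R0)
    # v(r) = 2 Re[c K0(k r)];  v(R0) = Ueff, v'(R0) = 0
    M <- rbind(c(2 * Re(A0), -2 * Im(A0)),
               c(2 * Re(A1), -2 * Im(A1)))
    cc <- solve(M, c(Ueff, 0))
    cco <- complex(real = cc[1], imaginary = cc[2])
    profile_v <- function(r) 2 * Re(cco * complex_besselK(0, kk * r))
    dflux <- -2 * Re(cco * kk^3 * complex_besselK(1, kk * R0))
  } else {
    k1 <- Re(k[1]); k2r <- Re(k[2])
    B <- rbind(c(besselK(k1 * R0, 0), besselK(k2r * R0, 0)),
               c(-k1 * besselK(k1 * R0, 1), -k2r * besselK(k2r * R0, 1)))
    cc <- solve(B, c(Ueff, 0))
    profile_v <- function(r) cc[1] * besselK(k1 * r, 0) + cc[2] * besselK(k2r * r, 0)
    dflux <- cc[1] * (-k1^3 * besselK(k1 * R0, 1)) +
             cc[2] * (-k2r^3 * besselK(k2r * R0, 1))
  }
  # E = 1/2 * oint (-kb v d(lap v)/dn) ds with inward normal, v'(R0) = 0
  energy <- pi * R0 * kb * Ueff * dflux
  list(profile = function(r) u0 + profile_v(r), energy = energy,
       u0 = u0, k = k, Ueff = Ueff)
}
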