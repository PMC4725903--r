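#' Model defaults for MscL calculations
#'
#' Reads the versioned defaults file shipped with the package. All numeric
#' model parameters (bilayer elastic constants, contour parameters per
#' oligomer and state, hydrophobic thicknesses, steric clearances, grid
#' resolutions, annealing schedules) live in this file; code never hard-codes
#' them inline.
#'
#' @param path optional path to an alternative defaults file.
#' @return nested list of defaults.
#' @export
mscl_defaults <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.msl$defaults)) return(.msl$defaults)
    path <- system.file("extdata", "mscl_defaults.json", package = "msclattice")
  }
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(d$bilayer)) stop("invalid defaults file: ", path)
  .msl$defaults <- d
  d
}

#' Bilayer elastic parameters
#'
#' Container for the elastic constants of the lipid bilayer entering the
#' thickness-deformation energy: bending rigidity \code{kappa_b} (kBT),
#' thickness deformation modulus \code{K_t} (kBT/nm^2), unperturbed
#' hydrophobic half-thickness \code{a} (nm) and membrane tension \code{tau}
#' (kBT/nm^2). The tension couples both to the local thickness change
#' (through \code{u/a}) and to the leaflet area tilt (through
#' \code{|grad u|^2/2}); set \code{tau_u_coupling = FALSE} for the
#' gradient-only variant.
#'
#' @param kappa_b bending rigidity, kBT. Positive.
#' @param K_t thickness deformation modulus, kBT/nm^2. Positive.
#' @param a unperturbed bilayer hydrophobic half-thickness, nm. Positive.
#' @param tau membrane tension, kBT/nm^2. Non-negative.
#' @param tau_u_coupling logical; couple tension to u as well as to area tilt.
#' @return object of class \code{bilayer_params}.
#' @export
bilayer_params <- function(kappa_b = NULL, K_t = NULL, a = NULL, tau = NULL,
                           tau_u_coupling = TRUE) {
  def <- mscl_defaults()$bilayer
  p <- list(
    kappa_b = if (is.null(kappa_b)) def$kappa_b else kappa_b,
    K_t     = if (is.null(K_t)) def$K_t else K_t,
    a       = if (is.null(a)) def$a else a,
    tau     = if (is.null(tau)) def$tau else tau,
    tau_u_coupling = isTRUE(tau_u_coupling)
  )
  stopifnot(p$kappa_b > 0, p$K_t > 0, p$a > 0, p$tau >= 0)
  class(p) <- "bilayer_params"
  p
}

#' Elastic decay length of thickness deformations
#'
#' \eqn{\lambda = (\kappa_b a^2 / K_t)^{1/4}}; protein-induced thickness
#' deformations decay exponentially on this scale.
#'
#' @param params \code{bilayer_params}.
#' @return length in nm.
#' @export
decay_length <- function(params) (params$kappa_b * params$a^2 / params$K_t)^0.25

#' Protein footprint shape
#'
#' Clover-leaf / tetragonal contour \eqn{r(\theta) = R[1 + \epsilon
#' \cos(s(\theta-\omega))]} describing the transmembrane cross section of an
#' s-fold symmetric protein. \code{s = 0} denotes the cylinder model
#' (\code{eps} forced to 0, orientation ignored). \code{U} is the boundary
#' value of the thickness deformation field at the protein edge: one-half the
#' protein hydrophobic thickness minus the bilayer half-thickness.
#'
#' @param s symmetry order, one of 0 (cylinder), 4, 5.
#' @param R mean contour radius, nm.
#' @param eps undulation amplitude, dimensionless, must satisfy \code{eps < 1}.
#' @param omega orientation, radians counterclockwise from the x-axis;
#'   stored wrapped into the canonical sector \code{[0, 2*pi/s)}.
#' @param U boundary hydrophobic half-mismatch, nm.
#' @param state gating state label, \code{"closed"} or \code{"open"}.
#' @param label optional species label (used in trajectories/tables).
#' @return object of class \code{protein_shape}.
#' @export
protein_shape <- function(s, R, eps = 0, omega = 0, U = 0,
                          state = c("closed", "open"), label = NULL) {
  state <- match.arg(state)
  if (!s %in% c(0, 4, 5)) stop("symmetry order s must be 0, 4 or 5")
  if (eps < 0 || eps >= 1) stop("invalid shape: undulation amplitude must satisfy 0 <= eps < 1")
  if (R <= 0) stop("invalid shape: R must be positive")
  if (s == 0) { eps <- 0; omega <- 0 } else omega <- wrap_angle(omega, sector(s))
  sh <- list(s = as.integer(s), R = R, eps = eps, omega = omega, U = U,
             state = state,
             label = if (is.null(label)) paste0("s", s, "_", state) else label)
  class(sh) <- "protein_shape"
  sh
}

#' @exportS3Method base::print
print.protein_shape <- function(x, ...) {
  cat(sprintf("protein_shape: s=%d R=%.4g nm eps=%.3g omega=%.4g rad U=%+.3g nm (%s)\n",
              x$s, x$R, x$eps, x$omega, x$U, x$state))
  invisible(x)
}

# symmetry sector width; full turn for a cylinder
sector <- function(s) if (s == 0) 2 * pi else 2 * pi / s

wrap_angle <- function(x, period) {
  y <- x %% period
  ifelse(y < 0, y + period, y)
}

#' Build an MscL shape from the packaged defaults
#'
#' Convenience constructor for the tetrameric, pentameric, and cylindrical
#' MscL models in the closed and open states. Tetramer radii follow the
#' matched-area policy (equal transmembrane cross section as the pentamer in
#' the same state); the cylinder is the matched-area circle. The boundary
#' mismatch is \code{U = W/2 - a} with \code{W} the state's hydrophobic
#' thickness.
#'
#' @param oligomer "pentamer", "tetramer" or "cylinder".
#' @param state "closed" or "open".
#' @param bilayer \code{bilayer_params} supplying the half-thickness \code{a}.
#' @return \code{protein_shape}.
#' @export
mscl_shape <- function(oligomer = c("pentamer", "tetramer", "cylinder"),
                       state = c("closed", "open"),
                       bilayer = bilayer_params()) {
  oligomer <- match.arg(oligomer)
  state <- match.arg(state)
  def <- mscl_defaults()
  U <- def$hydrophobic_thickness[[state]] / 2 - bilayer$a
  pent <- def$pentamer[[state]]
  ref <- protein_shape(5, pent$R, pent$eps, U = U, state = state,
                       label = paste0("pentamer_", state))
  switch(oligomer,
    pentamer = ref,
    tetramer = {
      eps4 <- def$tetramer[[state]]$eps
      R4 <- matched_area_radius(ref, 4L, eps4)
      protein_shape(4, R4, eps4, U = U, state = state,
                    label = paste0("tetramer_", state))
    },
    cylinder = {
      R0 <- matched_area_radius(ref, 0L, 0)
      protein_shape(0, R0, 0, U = U, state = state,
                    label = paste0("cylinder_", state))
    })
}

#' Contour radius of a protein footprint
#'
#' @param shape \code{protein_shape}.
#' @param theta polar angle(s), radians.
#' @return radius r(theta), nm; periodic in theta with period \code{2*pi/s}.
#' @export
contour_radius <- function(shape, theta) {
  if (shape$eps >= 1) stop("invalid shape: eps must be < 1")
  if (shape$s == 0) return(rep_len(shape$R, length(theta)))
  shape$R * (1 + shape$eps * cos(shape$s * (theta - shape$omega)))
}

#' Enclosed area of a footprint contour
#'
#' Closed form \eqn{\pi R^2 (1 + \epsilon^2/2)}, independent of the symmetry
#' order; equals the quadrature \eqn{\frac12 \int_0^{2\pi} r(\theta)^2
#' d\theta}.
#'
#' @param shape \code{protein_shape}.
#' @return area, nm^2.
#' @export
shape_area <- function(shape) pi * shape$R^2 * (1 + shape$eps^2 / 2)

#' Radius matching the enclosed area of a reference shape
#'
#' Returns the mean radius R such that a contour with symmetry order
#' \code{target_s} and amplitude \code{target_eps} encloses the same area as
#' \code{reference}.
#'
#' @param reference \code{protein_shape} whose area is matched.
#' @param target_s symmetry order of the target shape.
#' @param target_eps undulation amplitude of the target shape.
#' @return radius, nm.
#' @export
matched_area_radius <- function(reference, target_s, target_eps) {
  A <- shape_area(reference)
  sqrt(A / (pi * (1 + target_eps^2 / 2)))
}

#' Boundary conditions induced by a protein on the thickness field
#'
#' Dirichlet value \code{u = U} along the bilayer-protein interface together
#' with the zero-slope condition \code{du/dn = 0} on the same contour.
#'
#' @param shape \code{protein_shape}.
#' @param bilayer \code{bilayer_params} (kept for signature symmetry; the
#'   mismatch is stored in the shape).
#' @return list with elements \code{u} (Dirichlet value, nm) and
#'   \code{zero_slope} (logical, always TRUE).
#' @export
boundary_conditions <- function(shape, bilayer = bilayer_params()) {
  list(u = shape$U, zero_slope = TRUE)
}

#' Sample points along a footprint contour
#'
#' Used by the mesher; at least \code{40 * max(1, s)} points per full turn by
#' default so that lobe curvature is resolved.
#'
#' @param shape \code{protein_shape}.
#' @param center 2-vector, contour center, nm.
#' @param n number of samples (default per the meshing design rule).
#' @return n x 2 matrix of coordinates.
#' @export
contour_points <- function(shape, center = c(0, 0), n = NULL) {
  if (is.null(n)) n <- 40L * max(1L, shape$s)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- contour_radius(shape, th)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

#' Serialize / deserialize shapes
#'
#' Flat key-value (JSON-compatible) representation; round-trip exact.
#'
#' @param shape \code{protein_shape}.
#' @return \code{shape_to_list}: named list; \code{shape_from_list}: shape.
#' @export
shape_to_list <- function(shape) {
  list(s = shape$s, R = shape$R, eps = shape$eps, omega = shape$omega,
       U = shape$U, state = shape$state, label = shape$label)
}

#' @rdname shape_to_list
#' @param x named list as produced by \code{shape_to_list}.
#' @export
shape_from_list <- function(x) {
  protein_shape(x$s, x$R, x$eps, x$omega, x$U, x$state, x$label)
}
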