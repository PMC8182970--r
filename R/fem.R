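#' Material parameters for the layered fold
#'
#' Young's moduli are per layer; Poisson ratio, density, and the
#' Kelvin-Voigt viscosity are shared across layers.  Defaults are the
#' silicone analogue values measured by uniaxial elongation (moduli), a
#' fixed nearly incompressible Poisson ratio, and representative silicone
#' density and damping.
#'
#' The default viscosity is deliberately small: it is the effective damping
#' at which the two-dimensional linear model sustains flow-induced
#' oscillation with phonatory collision, the regime the silicone experiments
#' operate in (see the methods vignette for the reasoning).
#'
#' @param E_body,E_slp,E_lig,E_epi Young's moduli in kPa.
#' @param nu Poisson ratio (0 < nu < 0.5).
#' @param rho_b Density in kg/m^3.
#' @param eta Kelvin-Voigt viscosity in Pa*s.
#' @return An object of class `vf_material`.
#' @export
material_params <- function(E_body = 11.8, E_slp = 0.6, E_lig = 2.0,
                            E_epi = 45.0, nu = 0.4995, rho_b = 1070,
                            eta = 0.002) {
  stopifnot(E_body > 0, E_slp > 0, E_lig > 0, E_epi > 0,
            nu > 0, nu < 0.5, rho_b > 0, eta >= 0)
  structure(list(E_body = E_body, E_slp = E_slp, E_lig = E_lig,
                 E_epi = E_epi, nu = nu, rho_b = rho_b, eta = eta),
            class = "vf_material")
}

layer_modulus <- function(mat, layer) {
  E <- c(body = mat$E_body, slp = mat$E_slp, ligament = mat$E_lig,
         epithelium = mat$E_epi)
  unname(E[as.character(layer)])
}

#' Plane-strain constitutive matrix
#'
#' The isotropic plane-strain operator written in terms of the shear
#' modulus mu = E / (2 (1 + nu)), acting on the engineering strain vector
#' (du_x/dx, du_z/dz, du_z/dx + du_x/dz).
#'
#' @param E Young's modulus (kPa).
#' @param nu Poisson ratio.
#' @return 3 x 3 matrix in kPa.
#' @export
plane_strain_C <- function(E, nu) {
  if (nu >= 0.5) stop("locking/singular C error: nu must be < 0.5", call. = FALSE)
  mu <- E / (2 * (1 + nu))
  mu * matrix(c(2 * (1 - nu) / (1 - 2 * nu), 2 * nu / (1 - 2 * nu), 0,
                2 * nu / (1 - 2 * nu), 2 * (1 - nu) / (1 - 2 * nu), 0,
                0, 0, 1), 3, 3)
}

#' @rdname plane_strain_C
#' @export
shear_modulus <- function(E, nu) E / (2 * (1 + nu))

# Strain-displacement matrix of a 3-node linear triangle (constant strain).
# Dof order (ux1, uz1, ux2, uz2, ux3, uz3).
tri_B <- function(p) {
  x <- p[, 1]; z <- p[, 2]
  det2A <- (x[2] - x[1]) * (z[3] - z[1]) - (x[3] - x[1]) * (z[2] - z[1])
  b <- c(z[2] - z[3], z[3] - z[1], z[1] - z[2]) / det2A
  c_ <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1]) / det2A
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- b
  B[2, c(2, 4, 6)] <- c_
  B[3, c(1, 3, 5)] <- c_
  B[3, c(2, 4, 6)] <- b
  list(B = B, area = det2A / 2)
}

#' Assemble the finite-element system
#'
#' Builds the consistent mass, Kelvin-Voigt damping, and plane-strain
#' stiffness matrices on the full displacement-coefficient space from
#' 3-node linear triangles.  The element damping matrix is the element
#' stiffness with the shear modulus replaced by the viscosity,
#' `D_e = (eta / mu_e) K_e`.  Matrices carry the anterior-posterior depth as
#' out-of-plane thickness, so forces are in mN.  Fixed-boundary constraints
#' are recorded as the index set of eliminated coefficients.
#'
#' @param mesh A `vf_mesh` (invariants assumed to hold).
#' @param mat A `vf_material`.
#' @return An object of class `vf_system` with sparse `M`, `D`, `K` on the
#'   full dof space, the `free` and `fixed` dof index vectors, and the
#'   inputs.
#' @export
assemble <- function(mesh, mat) {
  if (mat$nu >= 0.5) stop("locking/singular C error: nu must be < 0.5", call. = FALSE)
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$triangles)
  t_depth <- mesh$depth
  rho <- mat$rho_b * KG_M3_TO_INTERNAL       # mg/mm^3
  eta <- mat$eta * PA_S_TO_INTERNAL          # kPa*ms

  Emod <- layer_modulus(mat, mesh$layer)
  mu <- shear_modulus(Emod, mat$nu)

  ii <- integer(36 * ne); jj <- integer(36 * ne)
  kk <- numeric(36 * ne); dd <- numeric(36 * ne); mm <- numeric(36 * ne)
  Mref <- matrix(c(2, 0, 1, 0, 1, 0,
                   0, 2, 0, 1, 0, 1,
                   1, 0, 2, 0, 1, 0,
                   0, 1, 0, 2, 0, 1,
                   1, 0, 1, 0, 2, 0,
                   0, 1, 0, 1, 0, 2), 6, 6) / 12
  pos <- 0L
  for (e in seq_len(ne)) {
    nd <- mesh$triangles[e, ]
    bb <- tri_B(mesh$nodes[nd, ])
    if (bb$area <= 0) stop("assembly error: non-positive element area", call. = FALSE)
    C <- plane_strain_C(Emod[e], mat$nu)
    Ke <- bb$area * t_depth * crossprod(bb$B, C %*% bb$B)
    De <- (eta / mu[e]) * Ke
    Me <- rho * t_depth * bb$area * Mref
    dofs <- as.vector(rbind(2L * nd - 1L, 2L * nd))
    idx <- pos + seq_len(36)
    ii[idx] <- rep(dofs, times = 6)
    jj[idx] <- rep(dofs, each = 6)
    kk[idx] <- as.vector(Ke)
    dd[idx] <- as.vector(De)
    mm[idx] <- as.vector(Me)
    pos <- pos + 36L
  }
  dim2 <- c(2L * nn, 2L * nn)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = dim2)
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = dd, dims = dim2)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = dim2)

  fixed <- sort(c(2L * mesh$gamma_fixed - 1L, 2L * mesh$gamma_fixed))
  free <- setdiff(seq_len(2L * nn), fixed)
  structure(list(M = M, D = D, K = K, free = free, fixed = fixed,
                 mesh = mesh, mat = mat), class = "vf_system")
}

#' Natural frequencies of the constrained system
#'
#' Solves the generalized eigenproblem K phi = omega^2 M phi on the free
#' coefficients and returns the lowest natural frequencies in Hz.
#'
#' @param sys A `vf_system`.
#' @param n Number of frequencies to return.
#' @param return_modes If `TRUE`, also return mode shapes (full dof space).
#' @export
natural_frequencies <- function(sys, n = 6, return_modes = FALSE) {
  Kf <- as.matrix(sys$K[sys$free, sys$free])
  Mf <- as.matrix(sys$M[sys$free, sys$free])
  L <- t(chol(Mf))
  A <- forwardsolve(L, t(forwardsolve(L, Kf)))
  A <- (A + t(A)) / 2
  ee <- eigen(A, symmetric = TRUE)
  ord <- order(ee$values)
  lam <- ee$values[ord][seq_len(n)]
  freq <- sqrt(pmax(lam, 0)) / (2 * pi) * 1000   # rad/ms -> Hz
  if (!return_modes) return(freq)
  modes <- matrix(0, nrow(sys$K), n)
  vec <- backsolve(t(L), ee$vectors[, ord[seq_len(n)], drop = FALSE],
                   transpose = FALSE)
  modes[sys$free, ] <- vec
  list(freq_hz = freq, modes = modes)
}

#' Static solve with prescribed displacements
#'
#' Solves `K u = f` with the fixed boundary at zero and optional extra
#' prescribed dofs; internal workhorse for precompression.
#' @keywords internal
static_solve <- function(sys, f = NULL, prescribed_dofs = integer(0),
                         prescribed_vals = numeric(0)) {
  ndof <- nrow(sys$K)
  f <- f %||% numeric(ndof)
  u <- numeric(ndof)
  u[prescribed_dofs] <- prescribed_vals
  solve_dofs <- setdiff(sys$free, prescribed_dofs)
  rhs <- f[solve_dofs] - as.vector(sys$K[solve_dofs, prescribed_dofs, drop = FALSE] %*%
                                     prescribed_vals)
  u[solve_dofs] <- as.vector(Matrix::solve(sys$K[solve_dofs, solve_dofs, drop = FALSE],
                                           rhs))
  u
}

#' Medial-compression pre-stress
#'
#' Computes the static pre-phonatory state after the fold mount is advanced
#' a total of `m` mm toward the contact plane.  The rigid relocation of the
#' mount is stress free and is baked into the returned reference mesh; the
#' elastic response comes entirely from unilateral contact with the plane.
#' Two solvers are available: `"active_set"` solves the contact
#' complementarity problem directly (prescribing crossing nodes onto the
#' plane and releasing nodes with adhesive reactions until the set is
#' stable); `"incremental"` follows the literal loading path, advancing the
#' mount in increments of `step` mm and applying a fixed `penalty_force` to
#' every plane-crossing node before a final active-set polish.  Both give
#' the same equilibrium for this linear-elastic system.
#'
#' @param mesh A `vf_mesh`.
#' @param mat A `vf_material`.
#' @param m Medial compression in mm (>= 0).
#' @param method `"active_set"` (default) or `"incremental"`.
#' @param tol Relative residual tolerance for the static solve.
#' @param step Mount increment in mm for the incremental method.
#' @param penalty_force Penalty force per crossing node in N for the
#'   incremental method.
#' @param max_iter Active-set iteration cap.
#' @return An object of class `vf_precompress`: the shifted reference
#'   `mesh`, the equilibrium `state` (class `vf_state`, zero velocity and
#'   acceleration), the assembled `system` on the shifted mesh, the contact
#'   node set, and the final static residual.
#' @export
precompress <- function(mesh, mat, m, method = c("active_set", "incremental"),
                        tol = 1e-8, step = 1e-4, penalty_force = 1e-4,
                        max_iter = 200) {
  stopifnot(m >= 0)
  method <- match.arg(method)
  smesh <- mesh
  smesh$nodes[, 1] <- smesh$nodes[, 1] + m
  sys <- assemble(smesh, mat)
  plane <- mesh$contact_plane_x
  xdof <- function(nodes) 2L * nodes - 1L
  candidates <- setdiff(seq_len(nrow(smesh$nodes)), smesh$gamma_fixed)

  u <- numeric(nrow(sys$K))
  if (method == "incremental" && m > 0) {
    # literal loading path: mount advances in `step` increments, a fixed
    # penalty force pushes crossing nodes back each iteration
    pen <- penalty_force * 1e3                      # N -> mN
    n_inc <- max(1L, round(m / step))
    Kff <- sys$K[sys$free, sys$free]
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
    base_x <- mesh$nodes[candidates, 1]
    for (k in seq_len(n_inc)) {
      shift_k <- m * k / n_inc
      f <- numeric(nrow(sys$K))
      defx <- base_x + shift_k + u[xdof(candidates)]
      crossing <- candidates[defx > plane + 1e-12]
      if (length(crossing)) f[xdof(crossing)] <- -pen
      u[sys$free] <- as.vector(Matrix::solve(ch, f[sys$free]))
    }
  }

  # active-set contact solve (also polishes the incremental path)
  contact <- integer(0)
  for (it in seq_len(max_iter)) {
    pdof <- xdof(contact)
    pval <- plane - smesh$nodes[contact, 1]
    u <- static_solve(sys, prescribed_dofs = pdof, prescribed_vals = pval)
    defx <- smesh$nodes[candidates, 1] + u[xdof(candidates)]
    crossing <- candidates[defx > plane + 1e-12]
    reactions <- as.vector(sys$K[pdof, , drop = FALSE] %*% u)
    releasing <- contact[reactions > 1e-12]          # wall can only push (-x)
    new_contact <- sort(union(setdiff(contact, releasing), crossing))
    if (identical(new_contact, contact)) break
    contact <- new_contact
    if (it == max_iter) {
      stop("precompression error: active set did not converge; last residual ",
           format(max(abs(reactions))), call. = FALSE)
    }
  }

  res <- as.vector(sys$K %*% u)
  res_free <- res[setdiff(sys$free, xdof(contact))]
  scale <- max(1, max(abs(res)))
  if (max(abs(res_free)) / scale > tol) {
    stop("precompression error: static residual ",
         format(max(abs(res_free)) / scale), " exceeds tolerance ", tol,
         call. = FALSE)
  }
  structure(list(mesh = smesh, state = sim_state(smesh, u = u),
                 system = sys, m = m, contact_nodes = contact,
                 residual = max(abs(res_free)) / scale),
            class = "vf_precompress")
}

#' One implicit Newmark step
#'
#' Average-acceleration Newmark integration (gamma = 1/2, beta = 1/4) of
#' `M a + D v + K u = F` on the free coefficients; unconditionally stable
#' for this linear system and exact at a constant-force equilibrium.
#'
#' @param sys A `vf_system`.
#' @param state A `vf_state`.
#' @param force Nodal force vector (full dof space, mN).
#' @param dt Time step in ms.
#' @param cache Optional factorization from [newmark_cache()].
#' @param beta,gamma Newmark parameters.
#' @return Updated `vf_state` at `t + dt`.
#' @export
newmark_step <- function(sys, state, force, dt, cache = NULL,
                         beta = 0.25, gamma = 0.5) {
  stopifnot(dt > 0)
  if (is.null(cache)) cache <- newmark_cache(sys, dt, beta, gamma)
  fr <- sys$free
  u <- state$u[fr]; v <- state$v[fr]; a <- state$a[fr]
  a1 <- 1 / (beta * dt^2); a2 <- 1 / (beta * dt); a3 <- (1 - 2 * beta) / (2 * beta)
  c1 <- gamma / (beta * dt); c2 <- gamma / beta - 1; c3 <- dt * (gamma / (2 * beta) - 1)
  rhs <- force[fr] +
    as.vector(cache$Mf %*% (a1 * u + a2 * v + a3 * a)) +
    as.vector(cache$Df %*% (c1 * u + c2 * v + c3 * a))
  unew <- as.vector(Matrix::solve(cache$chol, rhs))
  anew <- a1 * (unew - u) - a2 * v - a3 * a
  vnew <- v + dt * ((1 - gamma) * a + gamma * anew)
  out <- state
  out$t <- state$t + dt
  out$u[fr] <- unew; out$v[fr] <- vnew; out$a[fr] <- anew
  out
}

#' @rdname newmark_step
#' @export
newmark_cache <- function(sys, dt, beta = 0.25, gamma = 0.5) {
  fr <- sys$free
  Mf <- sys$M[fr, fr, drop = FALSE]
  Df <- sys$D[fr, fr, drop = FALSE]
  Kf <- sys$K[fr, fr, drop = FALSE]
  Keff <- Kf + (gamma / (beta * dt)) * Df + (1 / (beta * dt^2)) * Mf
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Keff), LDL = FALSE),
                 error = function(e) stop("integration error: singular effective operator",
                                          call. = FALSE))
  list(chol = ch, Mf = Mf, Df = Df, Kf = Kf, dt = dt, beta = beta, gamma = gamma)
}

#' Contact-plane enforcement
#'
#' Projects any node whose deformed x-coordinate exceeds the contact plane
#' back onto the plane, zeroing the x-velocity and x-acceleration of the
#' projected node (perfectly inelastic wall).  Idempotent.
#'
#' @param mesh A `vf_mesh` (the reference configuration of `state`).
#' @param state A `vf_state`.
#' @return The projected `vf_state`.
#' @export
enforce_contact <- function(mesh, state) {
  xd <- 2L * seq_len(nrow(mesh$nodes)) - 1L
  defx <- mesh$nodes[, 1] + state$u[xd]
  over <- which(defx > mesh$contact_plane_x)
  if (length(over)) {
    d <- xd[over]
    state$u[d] <- mesh$contact_plane_x - mesh$nodes[over, 1]
    state$v[d] <- 0
    state$a[d] <- 0
  }
  state
}

#' Mechanical energy of a state
#'
#' Strain plus kinetic energy, in microjoules (mN * mm).
#' @param sys A `vf_system`.
#' @param state A `vf_state`.
#' @export
mechanical_energy <- function(sys, state) {
  0.5 * sum(state$u * as.vector(sys$K %*% state$u)) +
    0.5 * sum(state$v * as.vector(sys$M %*% state$v))
}
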