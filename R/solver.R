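#' Steady rigid-wall Navier-Stokes solve of the stenotic phantom
#'
#' Solves steady incompressible flow through the phantom lumen in a
#' stream-function-vorticity formulation on a wall-fitted grid
#' \eqn{(\xi = x,\ \eta = r/h(x))}, so that continuity is satisfied
#' identically and the integrated flux through every cross-section equals the
#' prescribed inflow by construction.  The default axisymmetric mode uses the
#' Stokes stream function; a planar (2-D channel) mode is available and
#' matches the axisymmetric mean inlet velocity.  Convection is discretised
#' with first-order upwinding, diffusion with central differences; wall
#' vorticity follows a Thom-type condition generalised to the mapped grid.
#' The nonlinear system is iterated by under-relaxed Picard steps, each step
#' solving the two linear systems by sparse LU.
#'
#' Boundary conditions: fully developed (parabolic) inflow, zero-gradient
#' outflow, symmetry on the axis / centreline and no slip on the wall.  The
#' grid velocity and body force of the general moving-mesh momentum balance
#' are identically zero (rigid wall).
#'
#' @param problem a \code{\link{NavierStokesProblem}} with a symmetric-bump
#'   phantom.
#' @param time phase stamp attached to the returned field, s.
#' @param outGrid \code{c(nx, ny)} resolution of the regular output grid
#'   (defaults to \code{c(nAxial, 2 * nRadial - 1)}).
#' @return a \code{\link{VelocityField}} (cm/s on a regular mm grid) with a
#'   \code{"solver"} attribute carrying provenance: iterations, residual
#'   history, inlet Reynolds number, warnings, and the mapped-grid solution
#'   (stream function, vorticity, wall half-widths) for exact flux queries.
#' @seealso \code{\link{sectionFlux}}, \code{\link{quasiSteadyCycle}}
#' @export
solveStenoticSteady <- function(problem, time = 0, outGrid = NULL) {
  stopifnot(is(problem, "NavierStokesProblem"))
  ph <- problem@phantom
  if (ph@bumpSide != "symmetric")
    stop("the solver requires a symmetric-bump phantom")
  alpha <- if (problem@mode == "axisymmetric") 1 else 0
  nx <- problem@nAxial; ny <- problem@nRadial
  if (is.null(outGrid)) outGrid <- c(nx, 2L * ny - 1L)

  ## geometry in SI (m)
  xi <- seq(-ph@domainLength / 2, ph@domainLength / 2, length.out = nx) * 1e-3
  x_mm <- xi * 1e3
  h  <- lumenHalfwidth(x_mm, ph) * 1e-3
  hp <- .halfwidth_d1(x_mm, ph)              # dimensionless dh/dx
  hpp <- .halfwidth_d2(x_mm, ph) * 1e3       # 1/m
  eta <- seq(0, 1, length.out = ny)
  dxi <- xi[2] - xi[1]; deta <- eta[2] - eta[1]

  rho <- problem@fluid@density; mu <- problem@fluid@viscosity
  nu <- mu / rho
  Q <- problem@flowRate
  R0 <- ph@inletRadius * 1e-3
  vbar <- Q / (pi * R0^2)                    # mean inlet velocity, m/s
  Re <- rho * vbar * 2 * R0 / mu
  prov <- list(mode = problem@mode, Re = Re, warnings = character())
  if (Re > 500) {
    prov$warnings <- c(prov$warnings,
      sprintf("inlet Re = %.0f exceeds the validated range (<= 500)", Re))
    warning("inlet Re = ", round(Re), " exceeds the solver's validated range")
  }

  psi_w <- if (alpha == 1) Q / (2 * pi) else vbar * R0
  mkfield <- function(prov) {
    out <- .solver_output(ph, xi, eta, h, psi = NULL, u = NULL, v = NULL,
                          outGrid = outGrid, time = time, zero = TRUE)
    attr(out, "solver") <- prov
    out
  }
  if (Q <= 0) {                              # trivial zero-flow solution
    prov$iterations <- 0L; prov$residuals <- numeric(); prov$converged <- TRUE
    prov$psi <- matrix(0, nx, ny); prov$h_m <- h; prov$eta <- eta; prov$x_m <- xi
    prov$psi_wall <- 0; prov$alpha <- alpha
    return(mkfield(prov))
  }

  ## mapped-grid profile of the fully developed inflow (independent of h)
  psi_prof <- if (alpha == 1) psi_w * (2 * eta^2 - eta^4)
              else psi_w * (3 * eta - eta^3) / 2
  psi <- matrix(psi_prof, nx, ny, byrow = TRUE)
  vb_loc <- if (alpha == 1) Q / (pi * h^2) else psi_w / h
  omega <- if (alpha == 1) outer(4 * vb_loc / h, eta)
           else outer(3 * vb_loc / h, eta)

  idx <- function(i, j) (j - 1L) * nx + i
  N <- nx * ny

  ## mapped-operator coefficient fields (interior nodes)
  ii <- rep(2:(nx - 1), times = ny - 2)
  jj <- rep(2:(ny - 1), each = nx - 2)
  H <- h[ii]; HP <- hp[ii]; HPP <- hpp[ii]; ETA <- eta[jj]
  r <- ETA * H
  Axe <- -2 * ETA * HP / H                       # mixed-derivative coeff
  Aee <- ETA^2 * (HP / H)^2 + 1 / H^2
  Bgeo <- ETA * (2 * HP^2 / H^2 - HPP / H)       # first-order from the mapping
  ra <- r^alpha

  ## --- stream-function system (constant across Picard iterations) ---------
  Ae_psi <- Bgeo - alpha / (ETA * H^2)
  trip_i <- c(); trip_j <- c(); trip_x <- c()
  add <- function(rows, cols, vals) {
    trip_i <<- c(trip_i, rows); trip_j <<- c(trip_j, cols)
    trip_x <<- c(trip_x, vals)
  }
  ctr <- idx(ii, jj)
  add(ctr, ctr, -2 / dxi^2 - 2 * Aee / deta^2)
  add(ctr, idx(ii + 1, jj), rep(1 / dxi^2, length(ctr)))
  add(ctr, idx(ii - 1, jj), rep(1 / dxi^2, length(ctr)))
  add(ctr, idx(ii, jj + 1), Aee / deta^2 + Ae_psi / (2 * deta))
  add(ctr, idx(ii, jj - 1), Aee / deta^2 - Ae_psi / (2 * deta))
  cxe <- Axe / (4 * dxi * deta)
  add(ctr, idx(ii + 1, jj + 1), cxe)
  add(ctr, idx(ii - 1, jj - 1), cxe)
  add(ctr, idx(ii + 1, jj - 1), -cxe)
  add(ctr, idx(ii - 1, jj + 1), -cxe)
  ## boundary rows
  bpsi_fix <- numeric(N)                      # Dirichlet values
  is_interior <- matrix(FALSE, nx, ny); is_interior[cbind(ii, jj)] <- TRUE
  bnodes <- which(!is_interior)
  bi <- ((bnodes - 1L) %% nx) + 1L
  bj <- ((bnodes - 1L) %/% nx) + 1L
  type <- ifelse(bj == 1L, "axis",
          ifelse(bj == ny, "wall",
          ifelse(bi == 1L, "inlet", "outlet")))
  add(bnodes, bnodes, rep(1, length(bnodes)))
  out_sel <- type == "outlet"
  add(bnodes[out_sel], idx(bi[out_sel] - 1L, bj[out_sel]),
      rep(-1, sum(out_sel)))
  bpsi_fix[bnodes[type == "axis"]] <- 0
  bpsi_fix[bnodes[type == "wall"]] <- psi_w
  bpsi_fix[bnodes[type == "inlet"]] <- psi_prof[bj[type == "inlet"]]
  A_psi <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                dims = c(N, N))

  ## helpers -----------------------------------------------------------------
  velocities <- function(psi) {
    u <- matrix(0, nx, ny); v <- matrix(0, nx, ny)
    j_int <- 2:(ny - 1)
    Feta <- (psi[, j_int + 1] - psi[, j_int - 1]) / (2 * deta)
    Fxi <- matrix(0, nx, ny - 2)
    Fxi[2:(nx - 1), ] <- (psi[3:nx, j_int] - psi[1:(nx - 2), j_int]) / (2 * dxi)
    Fxi[1, ] <- (psi[2, j_int] - psi[1, j_int]) / dxi
    Fxi[nx, ] <- (psi[nx, j_int] - psi[nx - 1, j_int]) / dxi
    Hm <- matrix(h, nx, ny - 2)
    Em <- matrix(eta[j_int], nx, ny - 2, byrow = TRUE)
    Ra <- (Em * Hm)^alpha
    u[, j_int] <- Feta / (Hm * Ra)
    # f_x = F_xi - eta (h'/h) F_eta; v = -f_x / r^alpha
    v[, j_int] <- -(Fxi - Em * matrix(hp / h, nx, ny - 2) * Feta) / Ra
    if (alpha == 1) u[, 1] <- 2 * psi[, 2] / (deta * h)^2
    else u[, 1] <- psi[, 2] / (deta * h)
    v[, 1] <- 0
    u[, ny] <- 0; v[, ny] <- 0
    list(u = u, v = v)
  }
  thom_wall <- function(psi)
    -(1 + hp^2) / h^2 * 2 * (psi[, ny - 1] - psi_w) / deta^2 / h^alpha

  ## --- Picard loop ---------------------------------------------------------
  vel <- velocities(psi)
  omega[, ny] <- thom_wall(psi)
  residuals <- numeric(0)
  converged <- FALSE
  Be_diff <- Bgeo + alpha / (ETA * H^2)
  # adaptive under-relaxation: when the residual stalls in a limit cycle
  # (common on finer grids), damp the iteration further and continue
  relax_cur <- problem@relax
  bestRes <- Inf; bestIter <- 0L
  for (iter in seq_len(problem@maxIter)) {
    U <- vel$u[cbind(ii, jj)]; V <- vel$v[cbind(ii, jj)]
    c_xi <- U
    c_eta <- V / H - U * ETA * HP / H
    react <- -alpha * V / (ETA * H) + nu * alpha / (ETA * H)^2

    ti <- c(); tj <- c(); tx <- c()
    addw <- function(rows, cols, vals) {
      ti <<- c(ti, rows); tj <<- c(tj, cols); tx <<- c(tx, vals)
    }
    ctrv <- -nu * (-2 / dxi^2 - 2 * Aee / deta^2) +
      abs(c_xi) / dxi + abs(c_eta) / deta + react
    addw(ctr, ctr, ctrv)
    addw(ctr, idx(ii + 1, jj), -nu / dxi^2 + pmin(c_xi, 0) / dxi)
    addw(ctr, idx(ii - 1, jj), -nu / dxi^2 - pmax(c_xi, 0) / dxi)
    addw(ctr, idx(ii, jj + 1),
         -nu * Aee / deta^2 - nu * Be_diff / (2 * deta) + pmin(c_eta, 0) / deta)
    addw(ctr, idx(ii, jj - 1),
         -nu * Aee / deta^2 + nu * Be_diff / (2 * deta) - pmax(c_eta, 0) / deta)
    cxw <- -nu * Axe / (4 * dxi * deta)
    addw(ctr, idx(ii + 1, jj + 1), cxw)
    addw(ctr, idx(ii - 1, jj - 1), cxw)
    addw(ctr, idx(ii + 1, jj - 1), -cxw)
    addw(ctr, idx(ii - 1, jj + 1), -cxw)
    addw(bnodes, bnodes, rep(1, length(bnodes)))
    addw(bnodes[out_sel], idx(bi[out_sel] - 1L, bj[out_sel]),
         rep(-1, sum(out_sel)))
    A_om <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(N, N))
    b_om <- numeric(N)
    ## wall Dirichlet values: current (relaxed) wall vorticity
    wall_nodes <- bnodes[type == "wall"]
    b_om[wall_nodes] <- omega[cbind(((wall_nodes - 1L) %% nx) + 1L, ny)]
    inlet_nodes <- bnodes[type == "inlet"]
    b_om[inlet_nodes] <- omega[cbind(1L, bj[type == "inlet"])]
    om_new <- matrix(as.numeric(Matrix::solve(A_om, b_om)), nx, ny)

    # wall vorticity needs stronger damping than the interior: the
    # Thom-condition feedback loop is the stiffest mode of the iteration
    relax_wall <- 0.4 * relax_cur
    om_relaxed <- omega + relax_cur * (om_new - omega)
    res <- max(abs(om_relaxed - omega)) / (max(abs(om_relaxed)) + 1e-300)
    residuals <- c(residuals, res)
    omega <- om_relaxed

    b_psi <- bpsi_fix
    b_psi[ctr] <- -ra * omega[cbind(ii, jj)]
    psi <- matrix(as.numeric(Matrix::solve(A_psi, b_psi)), nx, ny)
    vel <- velocities(psi)
    ww_new <- thom_wall(psi)
    omega[, ny] <- omega[, ny] + relax_wall * (ww_new - omega[, ny])

    if (res < problem@tol) { converged <- TRUE; break }
    if (res < bestRes * 0.999) { bestRes <- res; bestIter <- iter }
    if (iter - bestIter >= 150L && relax_cur > 0.02) {
      relax_cur <- relax_cur / 2
      bestIter <- iter
    }
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "solver did not converge in %d iterations (last residual %.3e)",
      problem@maxIter, utils::tail(residuals, 1)))
    cond$residuals <- residuals
    stop(cond)
  }

  prov$iterations <- length(residuals)
  prov$residuals <- residuals
  prov$converged <- TRUE
  prov$psi <- psi; prov$omega <- omega
  prov$h_m <- h; prov$eta <- eta; prov$x_m <- xi
  prov$psi_wall <- psi_w; prov$alpha <- alpha
  out <- .solver_output(ph, xi, eta, h, psi, vel$u, vel$v,
                        outGrid = outGrid, time = time)
  attr(out, "solver") <- prov
  out
}

# Interpolate the mapped-grid solution onto a regular (x, y) grid in mm/cm/s.
.solver_output <- function(ph, xi, eta, h, psi, u, v, outGrid, time,
                           zero = FALSE) {
  nx_o <- outGrid[1]; ny_o <- outGrid[2]
  ax <- .phantom_axes(ph, nx_o, ny_o)
  mask <- lumenMask(ph, ax$x, ax$y)
  if (zero)
    return(VelocityField(ax$x, ax$y, matrix(0, nx_o, ny_o), time = time,
                         mask = mask))
  pts <- expand.grid(ix = seq_len(nx_o), iy = seq_len(ny_o))
  x_mm <- ax$x[pts$ix]
  y_mm <- ax$y[pts$iy]
  h_loc <- lumenHalfwidth(x_mm, ph)            # mm
  eta_pt <- abs(y_mm) / h_loc
  xm <- x_mm * 1e-3
  deta <- eta[2] - eta[1]; dxi <- xi[2] - xi[1]
  i_f <- (xm - xi[1]) / dxi + 1
  j_f <- eta_pt / deta + 1
  uu <- .bilinear_idx(u, i_f, j_f, fill = 0)
  vv <- .bilinear_idx(v, i_f, j_f, fill = 0) * sign(y_mm)
  uu[eta_pt >= 1] <- 0; vv[eta_pt >= 1] <- 0
  um <- matrix(uu * 100, nx_o, ny_o)           # m/s -> cm/s
  vm <- matrix(vv * 100, nx_o, ny_o)
  VelocityField(ax$x, ax$y, um, vm, time = time, mask = mask)
}

#' Solver provenance of a computed field
#'
#' @param field a \code{\link{VelocityField}} returned by
#'   \code{\link{solveStenoticSteady}}.
#' @return provenance list (iterations, residual history, Re, mapped-grid
#'   solution) or \code{NULL} for fields from other sources.
#' @export
solverProvenance <- function(field) attr(field, "solver")

#' Cross-sectional volumetric flux
#'
#' Integrates the axial velocity over the cross-section at each requested
#' axial station.  With \code{method = "stream"} (available for solver fields)
#' the flux is read off the mapped-grid stream function, for which
#' conservation is exact by construction; \code{method = "quadrature"}
#' integrates the gridded field by the trapezoidal rule (axisymmetric
#' weighting when the field came from the axisymmetric solver or an analytic
#' axisymmetric reference).
#'
#' @param field a \code{\link{VelocityField}}.
#' @param phantom the \code{\link{StenosisPhantom}} the field lives on.
#' @param stations axial stations, mm.
#' @param method \code{"quadrature"} or \code{"stream"}.
#' @param axisymmetric logical; integrate with \eqn{2\pi r\,dr} weighting.
#' @return numeric vector of fluxes, m^3/s.
#' @export
sectionFlux <- function(field, phantom, stations = NULL,
                        method = c("quadrature", "stream"),
                        axisymmetric = TRUE) {
  method <- match.arg(method)
  if (is.null(stations))
    stations <- seq(-0.4, 0.4, length.out = 10) * phantom@domainLength
  if (method == "stream") {
    prov <- solverProvenance(field)
    if (is.null(prov)) stop("no solver provenance attached to this field")
    xs <- stations * 1e-3
    psi_span <- prov$psi[, ncol(prov$psi)] - prov$psi[, 1]
    sp <- stats::approx(prov$x_m, psi_span, xout = xs, rule = 2)$y
    # axisymmetric: Q = 2*pi*(psi_wall - psi_axis); planar: flux per unit
    # depth over the full channel = 2 * half-channel stream-function span
    return(if (prov$alpha == 1) 2 * pi * sp else 2 * sp)
  }
  y <- field@y * 1e-3                          # m
  vapply(stations, function(xs) {
    up <- .sample_field(field, rep(xs, length(y)), field@y)$u / 100  # m/s
    if (axisymmetric) {
      # average the two half-profiles, integrate 2*pi*r*u dr
      r <- abs(y)
      ord <- order(r)
      rr <- r[ord]; uu <- up[ord]
      agg <- tapply(uu, rr, mean)
      rs <- as.numeric(names(agg))
      integrand <- 2 * pi * rs * as.numeric(agg)
      sum(diff(rs) * (integrand[-1] + integrand[-length(integrand)]) / 2)
    } else {
      sum(diff(y) * (up[-1] + up[-length(up)]) / 2) * 1
    }
  }, numeric(1))
}
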