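# Finite-volume transient advection-diffusion of the AI scalar.
# Fluxes: first-order upwind advection + central-difference diffusion on
# cell faces. Open boundaries: upwind outflow, zero-concentration inflow,
# no diffusive exchange with the exterior. Schemes: explicit Euler (with a
# CFL guard) or backward-Euler implicit with the same fluxes (matrix
# factorized once; the velocity field is steady).

#' Transport solver parameters
#'
#' @param eddy_diffusivity effective turbulent diffusivity of the scalar,
#'   m^2/s (> 0); default 0.05
#' @param dt_s time step, s (> 0)
#' @param scheme "implicit_upwind" (backward Euler, default) or
#'   "explicit_upwind"
#' @param cfl_limit stability bound for the explicit scheme (advective +
#'   diffusive CFL number must not exceed it)
#' @param snapshot_every_s snapshot interval, s (Inf = final snapshot only)
#' @param boundary "open" or "closed" domain boundaries
#' @return object of class `sr_transport_params`
#' @export
transport_params <- function(eddy_diffusivity = 0.05, dt_s,
                             scheme = c("implicit_upwind", "explicit_upwind"),
                             cfl_limit = 0.9, snapshot_every_s = Inf,
                             boundary = c("open", "closed")) {
  scheme <- match.arg(scheme)
  boundary <- match.arg(boundary)
  if (eddy_diffusivity <= 0) stop("invalid transport params: eddy_diffusivity")
  if (dt_s <= 0) stop("invalid transport params: dt_s")
  structure(list(eddy_diffusivity = eddy_diffusivity, dt_s = dt_s,
                 scheme = scheme, cfl_limit = cfl_limit,
                 snapshot_every_s = snapshot_every_s, boundary = boundary),
            class = "sr_transport_params")
}

# face-coefficient arrays: velocities with boundary policy applied, and
# diffusive conductances (zero through solids and domain boundaries)
face_coefficients <- function(grid, vel, D, boundary) {
  n <- grid$shape
  U <- vel$U; V <- vel$V; W <- vel$W
  if (boundary == "closed") {
    U[c(1, n[1] + 1L), , ] <- 0
    V[, c(1, n[2] + 1L), ] <- 0
    W[, , c(1, n[3] + 1L)] <- 0
  }
  if (grid$ground) W[, , 1] <- 0
  s <- grid$solid
  Gx <- array(D, dim = dim(U)); Gy <- array(D, dim = dim(V))
  Gz <- array(D, dim = dim(W))
  Gx[c(1, n[1] + 1L), , ] <- 0; Gy[, c(1, n[2] + 1L), ] <- 0
  Gz[, , c(1, n[3] + 1L)] <- 0
  padx <- array(FALSE, dim = c(n[1] + 2L, n[2], n[3])); padx[2:(n[1] + 1L), , ] <- s
  Gx[padx[1:(n[1] + 1L), , , drop = FALSE] |
     padx[2:(n[1] + 2L), , , drop = FALSE]] <- 0
  pady <- array(FALSE, dim = c(n[1], n[2] + 2L, n[3])); pady[, 2:(n[2] + 1L), ] <- s
  Gy[pady[, 1:(n[2] + 1L), , drop = FALSE] |
     pady[, 2:(n[2] + 2L), , drop = FALSE]] <- 0
  padz <- array(FALSE, dim = c(n[1], n[2], n[3] + 2L)); padz[, , 2:(n[3] + 1L)] <- s
  Gz[padz[, , 1:(n[3] + 1L), drop = FALSE] |
     padz[, , 2:(n[3] + 2L), drop = FALSE]] <- 0
  # upwind-split face velocities, precomputed once (the flow is steady)
  list(U = U, V = V, W = W, Gx = Gx, Gy = Gy, Gz = Gz,
       Uxp = pmax(U, 0), Uxn = pmin(U, 0),
       Vyp = pmax(V, 0), Vyn = pmin(V, 0),
       Wzp = pmax(W, 0), Wzn = pmin(W, 0))
}

# net flux divergence (mg/s per cell volume) for the explicit scheme
explicit_rhs <- function(grid, fc, cc) {
  n <- grid$shape; dx <- grid$dx
  a <- dx^2
  pad <- array(0, dim = c(n[1] + 2L, n[2], n[3])); pad[2:(n[1] + 1L), , ] <- cc
  cL <- pad[1:(n[1] + 1L), , , drop = FALSE]; cR <- pad[2:(n[1] + 2L), , , drop = FALSE]
  Fx <- a * (fc$Uxp * cL + fc$Uxn * cR - fc$Gx * (cR - cL) / dx)
  pad <- array(0, dim = c(n[1], n[2] + 2L, n[3])); pad[, 2:(n[2] + 1L), ] <- cc
  cL <- pad[, 1:(n[2] + 1L), , drop = FALSE]; cR <- pad[, 2:(n[2] + 2L), , drop = FALSE]
  Fy <- a * (fc$Vyp * cL + fc$Vyn * cR - fc$Gy * (cR - cL) / dx)
  pad <- array(0, dim = c(n[1], n[2], n[3] + 2L)); pad[, , 2:(n[3] + 1L)] <- cc
  cL <- pad[, , 1:(n[3] + 1L), drop = FALSE]; cR <- pad[, , 2:(n[3] + 2L), drop = FALSE]
  Fz <- a * (fc$Wzp * cL + fc$Wzn * cR - fc$Gz * (cR - cL) / dx)
  net <- (Fx[1:n[1], , , drop = FALSE] - Fx[2:(n[1] + 1L), , , drop = FALSE] +
          Fy[, 1:n[2], , drop = FALSE] - Fy[, 2:(n[2] + 1L), , drop = FALSE] +
          Fz[, , 1:n[3], drop = FALSE] - Fz[, , 2:(n[3] + 1L), drop = FALSE])
  # outflow rate through the domain boundary, mg/s
  out <- a * (sum(fc$Uxp[n[1] + 1L, , ] * cc[n[1], , ]) -
              sum(fc$Uxn[1, , ] * cc[1, , ]) +
              sum(fc$Vyp[, n[2] + 1L, ] * cc[, n[2], ]) -
              sum(fc$Vyn[, 1, ] * cc[, 1, ]) +
              sum(fc$Wzp[, , n[3] + 1L] * cc[, , n[3]]) -
              sum(fc$Wzn[, , 1] * cc[, , 1]))
  list(net = net, outflow_rate = out)
}

# assemble dC/dt = L C (1/s) over fluid cells for the implicit scheme,
# plus the boundary-outflow extraction vector
assemble_operator <- function(grid, fc) {
  n <- grid$shape; dx <- grid$dx
  fluid <- !grid$solid
  nfl <- sum(fluid)
  id <- array(0L, dim = n); id[fluid] <- seq_len(nfl)
  a_over_v <- 1 / dx  # face area / cell volume
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_v <- numeric(nfl)
  out_i <- integer(0); out_c <- numeric(0)

  slice_face <- function(A, axis, m) {
    if (axis == 1) A[m, , , drop = FALSE]
    else if (axis == 2) A[, m, , drop = FALSE]
    else A[, , m, drop = FALSE]
  }
  for (axis in 1:3) {
    Uf <- switch(axis, fc$U, fc$V, fc$W)
    Gf <- switch(axis, fc$Gx, fc$Gy, fc$Gz)
    np <- n[axis]
    for (m in seq_len(np + 1L)) {
      u <- as.vector(slice_face(Uf, axis, m))
      g <- as.vector(slice_face(Gf, axis, m))
      idL <- if (m > 1L) as.vector(slice_face(id, axis, m - 1L)) else
        integer(length(u))
      idR <- if (m <= np) as.vector(slice_face(id, axis, m)) else
        integer(length(u))
      up <- pmax(u, 0); un <- pmin(u, 0)
      both <- which(idL > 0L & idR > 0L)
      if (length(both)) {
        l <- idL[both]; r <- idR[both]
        cl <- (up[both] + g[both] / dx) * a_over_v   # coefficient on c_L
        cr <- (-un[both] + g[both] / dx) * a_over_v  # coefficient on c_R
        # dcL/dt -= flux/vol ; dcR/dt += flux/vol
        diag_v[l] <- diag_v[l] - cl
        diag_v[r] <- diag_v[r] - cr
        ii <- c(ii, l, r); jj <- c(jj, r, l)
        xx <- c(xx, cr, cl)
      }
      # boundary faces: ghost c = 0, advective outflow only
      bl <- which(idL > 0L & idR == 0L & m == np + 1L)
      if (length(bl)) {
        l <- idL[bl]
        diag_v[l] <- diag_v[l] - up[bl] * a_over_v
        out_i <- c(out_i, l); out_c <- c(out_c, up[bl] * dx^2)
      }
      br <- which(idR > 0L & idL == 0L & m == 1L)
      if (length(br)) {
        r <- idR[br]
        diag_v[r] <- diag_v[r] - (-un[br]) * a_over_v
        out_i <- c(out_i, r); out_c <- c(out_c, -un[br] * dx^2)
      }
    }
  }
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(nfl)), j = c(jj, seq_len(nfl)),
                            x = c(xx, diag_v), dims = c(nfl, nfl))
  list(L = L, id = id, nfl = nfl, out_i = out_i, out_c = out_c)
}

#' Solve transient scalar transport
#'
#' Integrates the AI concentration field under the composed velocity field,
#' injecting each device's scheduled emission into its containing cell
#' (point-source deposition). Returns snapshots, the time-average over
#' `avg_window_s`, the cumulative outflow mass and a global mass-balance
#' record.
#'
#' @param grid an `sr_grid`
#' @param vel an `sr_velocity` from [compose_velocity_field()]
#' @param params an [transport_params()]
#' @param sources list of [device_source()] objects (positions must fall in
#'   fluid cells)
#' @param duration_h simulated duration, h
#' @param avg_window_s length-2 vector (start, end) in seconds of the
#'   time-averaging window; default the whole run
#' @param conversion list(temperature_K, pressure_Pa, molar_mass) used when
#'   the field is expressed in ppm; defaults to the standard air state and
#'   metofluthrin
#' @return object of class `sr_conc_field`
#' @export
solve_transport <- function(grid, vel, params, sources, duration_h,
                            avg_window_s = NULL, conversion = NULL) {
  stopifnot(inherits(grid, "sr_grid"), inherits(vel, "sr_velocity"),
            inherits(params, "sr_transport_params"))
  n <- grid$shape; dx <- grid$dx; volcell <- dx^3
  D <- params$eddy_diffusivity
  duration_s <- duration_h * 3600
  if (is.null(avg_window_s)) avg_window_s <- c(0, duration_s)
  fc <- face_coefficients(grid, vel, D, params$boundary)

  # source cells and their schedules
  src_cells <- matrix(0L, nrow = length(sources), ncol = 3)
  for (i in seq_along(sources)) {
    d <- sources[[i]]
    pos <- if (inherits(d, "sr_device")) d$position_m else d$position
    idx <- cell_of(grid, pos)
    if (grid$solid[idx[1], idx[2], idx[3]]) stop("source inside wall")
    src_cells[i, ] <- idx
  }
  src_lin <- src_cells[, 1] + n[1] * (src_cells[, 2] - 1L) +
    n[1] * n[2] * (src_cells[, 3] - 1L)

  nstep <- max(1L, as.integer(ceiling(duration_s / params$dt_s)))
  dt <- duration_s / nstep

  if (params$scheme == "explicit_upwind") {
    umax <- max(abs(fc$U)) / dx + max(abs(fc$V)) / dx + max(abs(fc$W)) / dx
    cfl <- dt * (umax + 6 * D / dx^2)
    if (cfl > params$cfl_limit + 1e-12) {
      stop(sprintf("unstable step size: CFL %.3f exceeds limit %.3f",
                   cfl, params$cfl_limit))
    }
  }

  cc <- array(0, dim = n)
  fluid <- !grid$solid
  injected <- 0; outflow <- 0
  avg_acc <- array(0, dim = n); avg_time <- 0
  snapshots <- list()
  next_snap <- params$snapshot_every_s
  max_balance_err <- 0

  implicit <- params$scheme == "implicit_upwind"
  if (implicit) {
    op <- assemble_operator(grid, fc)
    M <- Matrix::Diagonal(op$nfl) - dt * op$L
    fac <- Matrix::lu(M)
    cvec <- numeric(op$nfl)
    id_lin <- op$id
    src_row <- id_lin[src_lin]
    if (any(src_row == 0L)) stop("source inside wall")
  }

  t_now <- 0
  for (stp in seq_len(nstep)) {
    rates <- vapply(sources, function(d) {
      sch <- if (inherits(d, "sr_device")) d$schedule else d
      schedule_rate_at(sch, t_now / 3600)
    }, numeric(1))
    if (implicit) {
      rhs <- cvec
      if (length(src_row)) {
        add <- dt * rates / volcell
        for (k in seq_along(src_row)) rhs[src_row[k]] <- rhs[src_row[k]] + add[k]
      }
      cnew <- as.numeric(Matrix::solve(fac, rhs))
      step_out <- sum(op$out_c * cnew[op$out_i]) * dt
      cvec <- cnew
      cc[fluid] <- cvec
    } else {
      r <- explicit_rhs(grid, fc, cc)
      cc <- cc + dt * r$net / volcell
      if (length(src_lin)) cc[src_lin] <- cc[src_lin] + dt * rates / volcell
      step_out <- r$outflow_rate * dt
    }
    outflow <- outflow + step_out
    injected <- injected + sum(rates) * dt
    t_now <- t_now + dt

    in_domain <- sum(cc) * volcell
    denom <- max(injected, 1e-30)
    max_balance_err <- max(max_balance_err,
                           abs(injected - in_domain - outflow) / denom)

    w_lo <- max(t_now - dt, avg_window_s[1]); w_hi <- min(t_now, avg_window_s[2])
    if (w_hi > w_lo) {
      avg_acc <- avg_acc + cc * (w_hi - w_lo)
      avg_time <- avg_time + (w_hi - w_lo)
    }
    if (t_now >= next_snap - 1e-9) {
      snapshots[[length(snapshots) + 1L]] <- list(time_s = t_now, values = cc)
      next_snap <- next_snap + params$snapshot_every_s
    }
  }
  if (!length(snapshots) || snapshots[[length(snapshots)]]$time_s < t_now - 1e-9) {
    snapshots[[length(snapshots) + 1L]] <- list(time_s = t_now, values = cc)
  }
  if (is.null(conversion)) {
    conversion <- list(temperature_K = DEFAULT_AIR_TEMPERATURE_K,
                       pressure_Pa = DEFAULT_AIR_PRESSURE_PA,
                       molar_mass = MW_METOFLUTHRIN)
  }
  structure(list(
    grid = grid,
    snapshots = snapshots,
    time_average = if (avg_time > 0) avg_acc / avg_time else cc,
    avg_window_s = avg_window_s,
    outflow_mass_mg = outflow,
    injected_mass_mg = injected,
    mass_balance_rel_error = max_balance_err,
    source_cells = src_cells,
    conversion = conversion
  ), class = "sr_conc_field")
}

#' Time-averaged field in ppm (by volume)
#'
#' @param field an `sr_conc_field`
#' @return array of the time-average converted from mg/m^3 to ppmv with the
#'   field's stored air state and molar mass
#' @export
field_time_average_ppm <- function(field) {
  cv <- field$conversion
  mass_conc_to_ppmv(field$time_average, cv$molar_mass, cv$temperature_K,
                    cv$pressure_Pa)
}

#' Sample a concentration field at arbitrary points
#'
#' Trilinear interpolation of the cell-centered field. Stencil corners that
#' fall in solid cells are dropped and the weights renormalized over the
#' fluid corners; a point inside a solid cell or outside the domain is an
#' error.
#'
#' @param field an `sr_conc_field`
#' @param points numeric matrix (n x 3) of positions, m
#' @param stat "time_average" (default) or a snapshot index
#' @param units "mg_m3" or "ppmv"
#' @return numeric vector of sampled concentrations
#' @export
sample_at_points <- function(field, points, stat = "time_average",
                             units = c("mg_m3", "ppmv")) {
  units <- match.arg(units)
  grid <- field$grid
  vals <- if (identical(stat, "time_average")) field$time_average
          else field$snapshots[[stat]]$values
  if (units == "ppmv") {
    cv <- field$conversion
    vals <- mass_conc_to_ppmv(vals, cv$molar_mass, cv$temperature_K,
                              cv$pressure_Pa)
  }
  points <- matrix(as.numeric(points), ncol = 3)
  n <- grid$shape; dx <- grid$dx
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    pos <- points[p, ]
    if (any(pos < 0) || any(pos > n * dx)) stop("unsampleable point: outside domain")
    host <- pmin(pmax(as.integer(floor(pos / dx)) + 1L, 1L), n)
    if (grid$solid[host[1], host[2], host[3]]) {
      # a point exactly on a cell face belongs to both cells; prefer fluid
      on_face <- abs(pos / dx - round(pos / dx)) < 1e-9 & host > 1L
      fixed <- FALSE
      if (any(on_face)) {
        for (mx in 1:7) {
          alt <- host - c(mx %% 2, (mx %/% 2) %% 2, mx %/% 4) * on_face
          if (all(alt >= 1L) && !grid$solid[alt[1], alt[2], alt[3]]) {
            fixed <- TRUE; break
          }
        }
      }
      if (!fixed) stop("unsampleable point: inside wall")
    }
    g <- pos / dx - 0.5
    i0 <- as.integer(floor(g)) + 1L
    fr <- g - floor(g)
    for (d in 1:3) {
      if (i0[d] < 1L) { i0[d] <- 1L; fr[d] <- 0 }
      if (i0[d] >= n[d]) { i0[d] <- n[d] - 1L; fr[d] <- 1 }
    }
    acc <- 0; wsum <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) fr[1] else 1 - fr[1]) *
           (if (cy) fr[2] else 1 - fr[2]) *
           (if (cz) fr[3] else 1 - fr[3])
      if (w == 0) next
      i <- i0 + c(cx, cy, cz)
      if (grid$solid[i[1], i[2], i[3]]) next
      acc <- acc + w * vals[i[1], i[2], i[3]]
      wsum <- wsum + w
    }
    if (wsum == 0) stop("unsampleable point: no fluid stencil")
    out[p] <- acc / wsum
  }
  out
}

#' @exportS3Method base::print
print.sr_conc_field <- function(x, ...) {
  cat(sprintf(paste0("<sr_conc_field> %d x %d x %d cells; %d snapshot(s); ",
                     "avg window [%g, %g] s\n"),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              length(x$snapshots), x$avg_window_s[1], x$avg_window_s[2]))
  cat(sprintf("  injected %.4g mg, outflow %.4g mg, max balance error %.2e\n",
              x$injected_mass_mg, x$outflow_mass_mg, x$mass_balance_rel_error))
  invisible(x)
}
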