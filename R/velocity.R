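# Prescribed divergence-free flow: ambient wind everywhere, fan patches as
# internal fixed-velocity ("speed jump") faces, zero velocity on solid
# faces, then a pressure-Poisson projection of the free faces so that every
# fluid cell is discretely divergence-free. This stands in for the paper's
# RANS flow solution; turbulent mixing enters the scalar equation through a
# single eddy diffusivity.

#' Compose the prescribed velocity field of a scene
#'
#' Builds face-normal velocities on the staggered grid: initialized to the
#' ambient wind, fan footprints overwritten with the fan speed along the fan
#' normal (held fixed), zeroed on faces of solid cells and on closed
#' boundaries, then projected to discrete divergence-freeness by solving a
#' Poisson equation for a potential correction on all unconstrained faces.
#' Open domain boundaries use a zero-potential ghost (free in/outflow).
#'
#' @param sc a validated `sr_scene`
#' @param grid an `sr_grid` built from the scene
#' @param boundary "open" (free in/outflow at domain edges) or "closed"
#'   (sealed box; ambient wind must be zero)
#' @param div_tol acceptable maximum discrete divergence, expressed as a
#'   fraction of `max(|u|)/dx`
#' @return object of class `sr_velocity` with face arrays `U`, `V`, `W`
#' @export
compose_velocity_field <- function(sc, grid, boundary = c("open", "closed"),
                                   div_tol = 1e-8) {
  boundary <- match.arg(boundary)
  n <- grid$shape; dx <- grid$dx
  wind <- sc$ambient_wind_mps
  if (boundary == "closed" && any(wind != 0)) {
    stop("invalid scene: ambient wind in a closed domain")
  }
  U <- array(wind[1], dim = c(n[1] + 1L, n[2], n[3]))
  V <- array(wind[2], dim = c(n[1], n[2] + 1L, n[3]))
  W <- array(wind[3], dim = c(n[1], n[2], n[3] + 1L))
  FU <- array(FALSE, dim = dim(U))
  FV <- array(FALSE, dim = dim(V))
  FW <- array(FALSE, dim = dim(W))

  if (boundary == "closed") {
    U[c(1, n[1] + 1L), , ] <- 0; FU[c(1, n[1] + 1L), , ] <- TRUE
    V[, c(1, n[2] + 1L), ] <- 0; FV[, c(1, n[2] + 1L), ] <- TRUE
    W[, , c(1, n[3] + 1L)] <- 0; FW[, , c(1, n[3] + 1L)] <- TRUE
  } else if (grid$ground) {
    W[, , 1] <- 0; FW[, , 1] <- TRUE
  }

  # fan patches: prescribed face-normal velocity, held fixed
  for (f in sc$fans) {
    ax <- which(abs(f$normal) > 1e-12)
    sgn <- sign(f$normal[ax])
    p <- as.integer(round(f$center_m[ax] / dx)) + 1L
    p <- max(2L, min(p, n[ax]))  # interior face plane
    ip <- setdiff(1:3, ax)
    half <- c(f$face_width_m, f$face_height_m) / 2
    sel <- lapply(1:2, function(d) {
      a <- ip[d]
      centers <- (seq_len(n[a]) - 0.5) * dx
      which(centers > f$center_m[a] - half[d] - 1e-12 &
            centers < f$center_m[a] + half[d] + 1e-12)
    })
    if (!length(sel[[1]]) || !length(sel[[2]])) {
      stop("resolution too coarse: fan footprint has no faces")
    }
    if (ax == 1) { U[p, sel[[1]], sel[[2]]] <- sgn * f$speed_mps
                   FU[p, sel[[1]], sel[[2]]] <- TRUE }
    if (ax == 2) { V[sel[[1]], p, sel[[2]]] <- sgn * f$speed_mps
                   FV[sel[[1]], p, sel[[2]]] <- TRUE }
    if (ax == 3) { W[sel[[1]], sel[[2]], p] <- sgn * f$speed_mps
                   FW[sel[[1]], sel[[2]], p] <- TRUE }
  }

  # zero and fix every face touching a solid cell
  s <- grid$solid
  padx <- array(FALSE, dim = c(n[1] + 2L, n[2], n[3])); padx[2:(n[1] + 1L), , ] <- s
  sx <- padx[1:(n[1] + 1L), , , drop = FALSE] | padx[2:(n[1] + 2L), , , drop = FALSE]
  U[sx] <- 0; FU[sx] <- TRUE
  pady <- array(FALSE, dim = c(n[1], n[2] + 2L, n[3])); pady[, 2:(n[2] + 1L), ] <- s
  sy <- pady[, 1:(n[2] + 1L), , drop = FALSE] | pady[, 2:(n[2] + 2L), , drop = FALSE]
  V[sy] <- 0; FV[sy] <- TRUE
  padz <- array(FALSE, dim = c(n[1], n[2], n[3] + 2L)); padz[, , 2:(n[3] + 1L)] <- s
  sz <- padz[, , 1:(n[3] + 1L), drop = FALSE] | padz[, , 2:(n[3] + 2L), drop = FALSE]
  W[sz] <- 0; FW[sz] <- TRUE

  vel <- project_divergence_free(grid, U, V, W, FU, FV, FW)
  umax <- max(abs(vel$U), abs(vel$V), abs(vel$W), 1e-30)
  tol <- div_tol * umax / dx + 1e-13
  if (vel$max_div > tol) {
    stop(sprintf("projection failed: max divergence %.3e exceeds %.3e",
                 vel$max_div, tol))
  }
  vel
}

divergence <- function(grid, U, V, W) {
  n <- grid$shape
  (U[2:(n[1] + 1L), , , drop = FALSE] - U[1:n[1], , , drop = FALSE] +
   V[, 2:(n[2] + 1L), , drop = FALSE] - V[, 1:n[2], , drop = FALSE] +
   W[, , 2:(n[3] + 1L), drop = FALSE] - W[, , 1:n[3], drop = FALSE]) / grid$dx
}

project_divergence_free <- function(grid, U, V, W, FU, FV, FW) {
  n <- grid$shape; dx <- grid$dx
  fluid <- !grid$solid
  nf <- sum(fluid)
  id <- array(0L, dim = n)
  id[fluid] <- seq_len(nf)

  div <- divergence(grid, U, V, W)
  b <- -div[fluid] * dx^2          # M phi = -div * dx^2, M = -dx^2 * Laplacian

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_v <- numeric(nf)
  has_dirichlet <- FALSE

  add_axis <- function(axis) {
    # faces on `axis`; couple cell pairs across each free face
    Fm <- switch(axis, FU, FV, FW)
    np <- n[axis]
    # interior faces: between cell index m and m+1 along axis
    for (m in seq_len(np - 1L)) {
      idxL <- switch(axis,
        id[m, , , drop = FALSE], id[, m, , drop = FALSE], id[, , m, drop = FALSE])
      idxR <- switch(axis,
        id[m + 1L, , , drop = FALSE], id[, m + 1L, , drop = FALSE],
        id[, , m + 1L, drop = FALSE])
      free <- switch(axis,
        !Fm[m + 1L, , , drop = FALSE], !Fm[, m + 1L, , drop = FALSE],
        !Fm[, , m + 1L, drop = FALSE])
      sel <- which(free & idxL > 0L & idxR > 0L)
      if (length(sel)) {
        l <- idxL[sel]; r <- idxR[sel]
        ii <<- c(ii, l, r); jj <<- c(jj, r, l); xx <<- c(xx, rep(-1, 2 * length(sel)))
        diag_v[l] <<- diag_v[l] + 1; diag_v[r] <<- diag_v[r] + 1
      }
    }
    # boundary faces (ghost phi = 0): free boundary faces add to the diagonal
    lowF <- switch(axis,
      !Fm[1, , , drop = FALSE], !Fm[, 1, , drop = FALSE], !Fm[, , 1, drop = FALSE])
    lowId <- switch(axis,
      id[1, , , drop = FALSE], id[, 1, , drop = FALSE], id[, , 1, drop = FALSE])
    sel <- which(lowF & lowId > 0L)
    if (length(sel)) {
      diag_v[lowId[sel]] <<- diag_v[lowId[sel]] + 1
      has_dirichlet <<- TRUE
    }
    hiF <- switch(axis,
      !Fm[np + 1L, , , drop = FALSE], !Fm[, np + 1L, , drop = FALSE],
      !Fm[, , np + 1L, drop = FALSE])
    hiId <- switch(axis,
      id[np, , , drop = FALSE], id[, np, , drop = FALSE], id[, , np, drop = FALSE])
    sel <- which(hiF & hiId > 0L)
    if (length(sel)) {
      diag_v[hiId[sel]] <<- diag_v[hiId[sel]] + 1
      has_dirichlet <<- TRUE
    }
  }
  add_axis(1); add_axis(2); add_axis(3)

  if (all(b == 0)) {
    # already discretely divergence-free; no correction needed
    phi <- numeric(nf)
  } else {
    isolated <- diag_v == 0
    diag_v[isolated] <- 1  # identity rows for fully constrained cells
    b[isolated] <- 0
    M <- Matrix::sparseMatrix(i = c(ii, seq_len(nf)), j = c(jj, seq_len(nf)),
                              x = c(xx, diag_v), dims = c(nf, nf),
                              symmetric = FALSE)
    if (!has_dirichlet) {
      # pure-Neumann system: remove the constant nullspace
      M <- M + Matrix::Diagonal(nf, 1e-10 * max(diag_v))
      b <- b - mean(b)
    }
    # M is symmetric positive definite: use a sparse Cholesky factorization
    phi <- tryCatch({
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), perm = TRUE)
      as.numeric(Matrix::solve(ch, b))
    }, error = function(e) stop("projection failed: ", conditionMessage(e)))
  }

  Phi <- array(0, dim = n); Phi[fluid] <- phi
  # corrected face velocity u' = u - (phi_R - phi_L) / dx, ghost phi = 0
  padPhi <- function(axis) {
    dpad <- n; dpad[axis] <- n[axis] + 2L
    P <- array(0, dim = dpad)
    if (axis == 1) P[2:(n[1] + 1L), , ] <- Phi
    if (axis == 2) P[, 2:(n[2] + 1L), ] <- Phi
    if (axis == 3) P[, , 2:(n[3] + 1L)] <- Phi
    P
  }
  P <- padPhi(1)
  gU <- (P[2:(n[1] + 2L), , , drop = FALSE] - P[1:(n[1] + 1L), , , drop = FALSE]) / dx
  U[!FU] <- U[!FU] - gU[!FU]
  P <- padPhi(2)
  gV <- (P[, 2:(n[2] + 2L), , drop = FALSE] - P[, 1:(n[2] + 1L), , drop = FALSE]) / dx
  V[!FV] <- V[!FV] - gV[!FV]
  P <- padPhi(3)
  gW <- (P[, , 2:(n[3] + 2L), drop = FALSE] - P[, , 1:(n[3] + 1L), drop = FALSE]) / dx
  W[!FW] <- W[!FW] - gW[!FW]

  div <- divergence(grid, U, V, W)
  structure(list(U = U, V = V, W = W, grid = grid,
                 max_div = max(abs(div[fluid]), 0)),
            class = "sr_velocity")
}

#' @exportS3Method base::print
print.sr_velocity <- function(x, ...) {
  cat(sprintf("<sr_velocity> max |u| = %.3g m/s, max |div| = %.3e 1/s\n",
              max(abs(x$U), abs(x$V), abs(x$W)), x$max_div))
  invisible(x)
}
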