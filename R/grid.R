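# Structured uniform grid with solid (wall) cells. Cell (i, j, k) spans
# [(i-1) dx, i dx) x ... ; cell centers sit at (i - 1/2) dx. The domain
# z- boundary is treated as solid ground (no-flux) by default, so a tent
# enclosure may stand on it; all other boundaries are open unless the
# transport run is configured as closed.

#' Discretize a scene onto a uniform structured grid
#'
#' @param sc a validated `sr_scene`
#' @param dx uniform cell size, m; must divide the domain extents to within
#'   half a cell and be no larger than the smallest enclosure opening
#' @param ground logical; treat the z- domain boundary as solid ground
#' @return object of class `sr_grid`: origin, spacing `dx`, `shape`
#'   (nx, ny, nz) and a logical `solid` array marking wall cells
#' @export
build_grid <- function(sc, dx, ground = TRUE) {
  if (dx <= 0) stop("invalid grid: dx must be > 0")
  L <- sc$domain_box_m
  shape <- as.integer(round(L / dx))
  if (any(shape < 2)) stop("invalid grid: fewer than 2 cells on an axis")
  if (any(abs(L - shape * dx) > dx / 2 + 1e-12)) {
    stop("invalid grid: dx does not divide domain extents")
  }
  solid <- array(FALSE, dim = shape)
  if (!is.null(sc$enclosure)) {
    enc <- sc$enclosure
    if (length(enc$openings)) {
      odims <- unlist(lapply(enc$openings, function(o) c(o$width_m, o$height_m)))
      if (dx > min(odims) + 1e-12) {
        stop("resolution too coarse: dx exceeds smallest opening dimension")
      }
    }
    i0 <- as.integer(round(enc$box_min_m / dx)) + 1L
    i1 <- as.integer(round(enc$box_max_m / dx))
    flush_lo <- i0 <= 1L
    flush_hi <- i1 >= shape
    if (ground) flush_lo[3] <- FALSE  # tent may stand on the ground
    if (any(flush_lo) || any(flush_hi)) {
      stop("invalid scene: enclosure flush with domain (exterior volume required)")
    }
    if (any(i1 - i0 + 1L <= 2L * enc$wall_thickness_cells)) {
      stop("resolution too coarse: enclosure interior vanishes")
    }
    w <- enc$wall_thickness_cells
    shell <- array(FALSE, dim = shape)
    shell[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- TRUE
    inner <- c(i0 + w, i1 - w)
    shell[(i0[1] + w):(i1[1] - w), (i0[2] + w):(i1[2] - w),
          (i0[3] + w):(i1[3] - w)] <- FALSE
    if (ground && i0[3] == 1L) {
      # open-bottom tent standing on the ground: no floor wall
      shell[(i0[1] + w):(i1[1] - w), (i0[2] + w):(i1[2] - w),
            i0[3]:min(w, i1[3])] <- FALSE
    }
    # carve door openings through the full wall thickness
    for (op in enc$openings) {
      ax <- opening_axes(op$face)
      lo2 <- op$center_m - c(op$width_m, op$height_m) / 2
      hi2 <- op$center_m + c(op$width_m, op$height_m) / 2
      rng <- vector("list", 3)
      if (ax$side < 0) rng[[ax$axis]] <- i0[ax$axis]:(i0[ax$axis] + w - 1L)
      else rng[[ax$axis]] <- (i1[ax$axis] - w + 1L):i1[ax$axis]
      for (d in 1:2) {
        a <- ax$inplane[d]
        cells <- seq_len(shape[a])
        centers <- (cells - 0.5) * dx
        keep <- cells[centers > lo2[d] & centers < hi2[d]]
        if (!length(keep)) stop("resolution too coarse: opening has no cells")
        rng[[a]] <- keep
      }
      shell[rng[[1]], rng[[2]], rng[[3]]] <- FALSE
    }
    solid <- solid | shell
  }
  structure(list(origin = c(0, 0, 0), dx = dx, shape = shape,
                 solid = solid, ground = ground),
            class = "sr_grid")
}

#' Containing cell of a position (half-open cells)
#'
#' @param grid an `sr_grid`
#' @param p position, m (3-vector)
#' @return integer 3-vector of 1-based cell indices
#' @keywords internal
cell_of <- function(grid, p) {
  idx <- as.integer(floor(p / grid$dx)) + 1L
  if (any(idx < 1L) || any(idx > grid$shape)) stop("position outside domain")
  idx
}

#' @exportS3Method base::print
print.sr_grid <- function(x, ...) {
  cat(sprintf("<sr_grid> %d x %d x %d cells, dx = %g m, %d solid cell(s)\n",
              x$shape[1], x$shape[2], x$shape[3], x$dx, sum(x$solid)))
  invisible(x)
}
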