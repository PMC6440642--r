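# The "protection bubble": the region where the time-averaged AI
# concentration meets or exceeds the threshold associated with a target
# mortality. The primary volume statistic is the voxel superlevel volume
# (robust and monotone in the threshold); a triangulated iso-surface built
# by marching tetrahedra provides the mesh and a divergence-theorem volume
# for reporting and export.

#' Voxel superlevel-set volume
#'
#' Sum of fluid-cell volumes whose time-averaged concentration (in ppm) is
#' `>= threshold` (ties count as inside). With
#' `connectivity = "source_component"`, the count is restricted to the
#' 6-connected component(s) containing a device source cell.
#'
#' @param field an `sr_conc_field`
#' @param threshold_ppm threshold concentration, ppm (> 0)
#' @param connectivity "all" or "source_component"
#' @return protective volume, m^3 (0 for an empty superlevel set)
#' @export
superlevel_volume <- function(field, threshold_ppm,
                              connectivity = c("all", "source_component")) {
  connectivity <- match.arg(connectivity)
  if (threshold_ppm <= 0) stop("threshold must be > 0")
  ppm <- field_time_average_ppm(field)
  inside <- (ppm >= threshold_ppm) & !field$grid$solid
  if (connectivity == "source_component") {
    inside <- flood_from_sources(inside, field$grid$shape, field$source_cells)
  }
  sum(inside) * field$grid$dx^3
}

# 6-connected flood fill of `inside` starting from the source cells
flood_from_sources <- function(inside, n, src_cells) {
  keep <- array(FALSE, dim = n)
  if (is.null(src_cells) || nrow(src_cells) == 0) return(keep)
  lin <- function(i, j, k) i + n[1] * (j - 1L) + n[1] * n[2] * (k - 1L)
  queue <- integer(0)
  for (s in seq_len(nrow(src_cells))) {
    i <- src_cells[s, ]
    if (inside[i[1], i[2], i[3]] && !keep[i[1], i[2], i[3]]) {
      keep[i[1], i[2], i[3]] <- TRUE
      queue <- c(queue, lin(i[1], i[2], i[3]))
    }
  }
  nxny <- n[1] * n[2]
  while (length(queue)) {
    cur <- queue[length(queue)]; queue <- queue[-length(queue)]
    k <- (cur - 1L) %/% nxny + 1L
    rem <- (cur - 1L) %% nxny
    j <- rem %/% n[1] + 1L
    i <- rem %% n[1] + 1L
    for (d in 1:6) {
      ni <- i + c(-1L, 1L, 0L, 0L, 0L, 0L)[d]
      nj <- j + c(0L, 0L, -1L, 1L, 0L, 0L)[d]
      nk <- k + c(0L, 0L, 0L, 0L, -1L, 1L)[d]
      if (ni < 1L || ni > n[1] || nj < 1L || nj > n[2] ||
          nk < 1L || nk > n[3]) next
      if (inside[ni, nj, nk] && !keep[ni, nj, nk]) {
        keep[ni, nj, nk] <- TRUE
        queue <- c(queue, lin(ni, nj, nk))
      }
    }
  }
  keep
}

# 6-tetrahedra decomposition of the unit cube around the 0-7 diagonal.
# cube corners are numbered by bits (x, y, z): c0 = (0,0,0) ... c7 = (1,1,1)
TET_DECOMP <- matrix(c(0, 1, 3, 7,
                       0, 3, 2, 7,
                       0, 2, 6, 7,
                       0, 6, 4, 7,
                       0, 4, 5, 7,
                       0, 5, 1, 7) + 1L, ncol = 4, byrow = TRUE)
CUBE_OFFSETS <- cbind(x = bitwAnd(0:7, 1L),
                      y = bitwAnd(0:7, 2L) %/% 2L,
                      z = bitwAnd(0:7, 4L) %/% 4L)

#' Extract the threshold iso-surface as a triangle mesh
#'
#' Marching tetrahedra over the lattice of cell centers of the
#' time-averaged field (in ppm): each lattice cube is split into six
#' tetrahedra, and surface vertices are placed on tetrahedron edges by
#' linear interpolation. Triangles are oriented with outward normals
#' (pointing from the superlevel region toward lower concentration), so
#' the divergence-theorem volume of a closed mesh is positive. Solid cells
#' take the value 0 so the surface wraps around walls.
#'
#' @param field an `sr_conc_field`
#' @param threshold_ppm iso-value, ppm; must cross the field range
#' @return object of class `sr_mesh`: `vertices` (n x 3, m),
#'   `faces` (m x 3 vertex indices), `n_boundary_edges` (0 for a closed
#'   mesh) and `volume_m3` (divergence-theorem enclosed volume)
#' @export
extract_isosurface <- function(field, threshold_ppm) {
  grid <- field$grid
  vals <- field_time_average_ppm(field)
  vals[grid$solid] <- 0
  if (threshold_ppm <= min(vals) || threshold_ppm > max(vals)) {
    stop("no crossing: threshold outside field range")
  }
  n <- grid$shape; dx <- grid$dx
  inside <- vals >= threshold_ppm
  # lattice cubes with mixed corners
  cnt <- array(0L, dim = n - 1L)
  for (c8 in 1:8) {
    off <- CUBE_OFFSETS[c8, ]
    cnt <- cnt + inside[(1 + off[1]):(n[1] - 1 + off[1]),
                        (1 + off[2]):(n[2] - 1 + off[2]),
                        (1 + off[3]):(n[3] - 1 + off[3]), drop = FALSE]
  }
  mixed <- which(cnt > 0L & cnt < 8L, arr.ind = TRUE)

  vkey <- new.env(hash = TRUE, parent = emptyenv())
  verts <- matrix(numeric(0), ncol = 3)
  nvert <- 0L
  vlist <- vector("list", 4096); vn <- 0L
  faces <- vector("list", 4096); fn <- 0L

  node_pos <- function(idx) (idx - 0.5) * dx
  lin_node <- function(idx) idx[1] + n[1] * (idx[2] - 1L) + n[1] * n[2] * (idx[3] - 1L)

  edge_vertex <- function(ia, ib, va, vb) {
    # ia inside (va >= th), ib outside (vb < th)
    la <- lin_node(ia); lb <- lin_node(ib)
    key <- if (la < lb) paste0(la, "_", lb) else paste0(lb, "_", la)
    hit <- vkey[[key]]
    if (!is.null(hit)) return(hit)
    t <- (threshold_ppm - va) / (vb - va)
    p <- node_pos(ia) + t * (node_pos(ib) - node_pos(ia))
    vn <<- vn + 1L
    if (vn > length(vlist)) length(vlist) <<- 2L * vn
    vlist[[vn]] <<- p
    vkey[[key]] <- vn
    vn
  }
  push_face <- function(tri, inside_centroid) {
    p1 <- vlist[[tri[1]]]; p2 <- vlist[[tri[2]]]; p3 <- vlist[[tri[3]]]
    e1 <- p2 - p1; e2 <- p3 - p1
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    ref <- inside_centroid - (p1 + p2 + p3) / 3
    if (sum(nrm * ref) > 0) tri <- tri[c(1, 3, 2)]
    fn <<- fn + 1L
    if (fn > length(faces)) length(faces) <<- 2L * fn
    faces[[fn]] <<- tri
  }

  for (r in seq_len(nrow(mixed))) {
    base <- as.integer(mixed[r, ])
    corner_idx <- sweep(CUBE_OFFSETS, 2, base, "+")  # 8 x 3 node indices
    cv <- vals[cbind(corner_idx[, 1], corner_idx[, 2], corner_idx[, 3])]
    cin <- cv >= threshold_ppm
    for (tt in seq_len(nrow(TET_DECOMP))) {
      tet <- TET_DECOMP[tt, ]
      tin <- cin[tet]
      ni <- sum(tin)
      if (ni == 0L || ni == 4L) next
      ins <- tet[tin]; outs <- tet[!tin]
      icent <- colMeans(corner_idx[ins, , drop = FALSE] - 0.5) * dx
      if (ni == 1L) {
        a <- ins[1]
        tri <- c(edge_vertex(corner_idx[a, ], corner_idx[outs[1], ], cv[a], cv[outs[1]]),
                 edge_vertex(corner_idx[a, ], corner_idx[outs[2], ], cv[a], cv[outs[2]]),
                 edge_vertex(corner_idx[a, ], corner_idx[outs[3], ], cv[a], cv[outs[3]]))
        if (!anyDuplicated(tri)) push_face(tri, icent)
      } else if (ni == 3L) {
        b <- outs[1]
        tri <- c(edge_vertex(corner_idx[ins[1], ], corner_idx[b, ], cv[ins[1]], cv[b]),
                 edge_vertex(corner_idx[ins[2], ], corner_idx[b, ], cv[ins[2]], cv[b]),
                 edge_vertex(corner_idx[ins[3], ], corner_idx[b, ], cv[ins[3]], cv[b]))
        if (!anyDuplicated(tri)) push_face(tri, icent)
      } else {
        a <- ins[1]; b <- ins[2]; cc <- outs[1]; dd <- outs[2]
        q1 <- edge_vertex(corner_idx[a, ], corner_idx[cc, ], cv[a], cv[cc])
        q2 <- edge_vertex(corner_idx[a, ], corner_idx[dd, ], cv[a], cv[dd])
        q3 <- edge_vertex(corner_idx[b, ], corner_idx[dd, ], cv[b], cv[dd])
        q4 <- edge_vertex(corner_idx[b, ], corner_idx[cc, ], cv[b], cv[cc])
        if (!anyDuplicated(c(q1, q2, q3))) push_face(c(q1, q2, q3), icent)
        if (!anyDuplicated(c(q1, q3, q4))) push_face(c(q1, q3, q4), icent)
      }
    }
  }
  if (fn == 0L) stop("no crossing: empty surface")
  vertices <- do.call(rbind, vlist[seq_len(vn)])
  face_mat <- do.call(rbind, faces[seq_len(fn)])

  edges <- rbind(face_mat[, c(1, 2)], face_mat[, c(2, 3)], face_mat[, c(3, 1)])
  ekey <- paste0(pmin(edges[, 1], edges[, 2]), "_", pmax(edges[, 1], edges[, 2]))
  n_boundary <- sum(table(ekey) == 1L)

  v1 <- vertices[face_mat[, 1], , drop = FALSE]
  v2 <- vertices[face_mat[, 2], , drop = FALSE]
  v3 <- vertices[face_mat[, 3], , drop = FALSE]
  cr <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
              v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
              v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  vol <- sum(v1 * cr) / 6
  structure(list(vertices = vertices, faces = face_mat,
                 n_boundary_edges = n_boundary, volume_m3 = abs(vol),
                 signed_volume_m3 = vol, threshold_ppm = threshold_ppm),
            class = "sr_mesh")
}

#' Protection-bubble report
#'
#' Combines a concentration field with an inverted dose-response fit: the
#' threshold is the fit's `c_target`, and both the voxel superlevel volume
#' and (when the threshold crosses the field) the iso-surface mesh volume
#' are computed, together with whether every non-control pouch lies inside
#' the bubble.
#'
#' @param field an `sr_conc_field`
#' @param fit an `sr_dose_fit` with `c_target` set (see
#'   [concentration_for_mortality()])
#' @param sc the scene (for pouch positions); may be NULL
#' @param connectivity passed to [superlevel_volume()]
#' @return object of class `sr_bubble`: threshold_ppm, voxel_volume_m3,
#'   mesh (or NULL), mesh_volume_m3, pouches_inside, connected_to_sources,
#'   bounding_box_m, warnings
#' @export
bubble_report <- function(field, fit, sc = NULL,
                          connectivity = c("all", "source_component")) {
  connectivity <- match.arg(connectivity)
  if (is.na(fit$c_target)) stop("fit has no c_target; invert it first")
  threshold <- fit$c_target
  if (threshold <= 0) stop("threshold must be > 0")
  warnings <- character(0)
  vol <- superlevel_volume(field, threshold, connectivity)
  ppm <- field_time_average_ppm(field)
  ppm[field$grid$solid] <- 0
  mesh <- NULL; mesh_vol <- 0
  if (vol == 0) {
    warnings <- c(warnings, "no protective volume: threshold exceeds field maximum")
  } else if (threshold > min(ppm)) {
    mesh <- extract_isosurface(field, threshold)
    mesh_vol <- mesh$volume_m3
  } else {
    # whole fluid domain above threshold: no interior crossing
    mesh_vol <- vol
    warnings <- c(warnings, "entire domain above threshold; mesh omitted")
  }
  inside <- (ppm >= threshold) & !field$grid$solid
  bbox <- NULL
  if (any(inside)) {
    w <- which(inside, arr.ind = TRUE)
    dx <- field$grid$dx
    bbox <- rbind(min_m = (apply(w, 2, min) - 1) * dx,
                  max_m = apply(w, 2, max) * dx)
    colnames(bbox) <- c("x", "y", "z")
  }
  connected <- FALSE
  if (!is.null(field$source_cells) && nrow(field$source_cells)) {
    sc_in <- apply(field$source_cells, 1, function(i) inside[i[1], i[2], i[3]])
    connected <- any(sc_in)
  }
  pouches_inside <- NA
  if (!is.null(sc) && length(sc$pouches)) {
    act <- Filter(function(p) !p$control, sc$pouches)
    if (length(act)) {
      pts <- do.call(rbind, lapply(act, function(p) p$position_m))
      cell_in <- vapply(seq_len(nrow(pts)), function(r) {
        i <- cell_of(field$grid, pts[r, ])
        inside[i[1], i[2], i[3]]
      }, logical(1))
      pouches_inside <- all(cell_in)
    }
  }
  structure(list(threshold_ppm = threshold,
                 target_mortality = fit$target_mortality,
                 voxel_volume_m3 = vol, mesh = mesh,
                 mesh_volume_m3 = mesh_vol,
                 pouches_inside = pouches_inside,
                 connected_to_sources = connected,
                 bounding_box_m = bbox, warnings = warnings),
            class = "sr_bubble")
}

#' @exportS3Method base::print
print.sr_bubble <- function(x, ...) {
  cat(sprintf("<sr_bubble> threshold %.4g ppm (target mortality %.0f%%)\n",
              x$threshold_ppm, 100 * x$target_mortality))
  cat(sprintf("  voxel volume %.4g m^3, mesh volume %.4g m^3\n",
              x$voxel_volume_m3, x$mesh_volume_m3))
  if (!is.na(x$pouches_inside)) {
    cat(sprintf("  all pouches inside: %s\n", x$pouches_inside))
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
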