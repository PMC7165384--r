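#' Structured triangulation of the extended observation window
#'
#' Builds a regular lattice of nodes covering the window's bounding box
#' extended by a buffer on every side, split into right triangles (two
#' per lattice square). The piecewise-linear finite-element basis
#' \eqn{\psi_i} — value 1 at node i, 0 elsewhere — is implied by the
#' node/triangle structure. The buffer moves the mesh boundary away from
#' the window so the boundary-condition variance inflation of the SPDE
#' field does not reach the cells of interest; the default is 1.5 times
#' the prior median range.
#'
#' The lumped mass matrix \code{C} (diagonal) and stiffness matrix
#' \code{G} of the triangulation are assembled once and stored on the
#' mesh.
#'
#' @param grid a [make_grid()] object (or a list with a \code{window}
#'   ring matrix).
#' @param node_spacing lattice spacing in km.
#' @param buffer extension beyond the window on each side, km (>= 0).
#' @return an object of class \code{spde_mesh}: nodes (M x 2 matrix),
#'   triangles (T x 3 integer matrix), nx, ny, spacing, buffer, origin,
#'   fem (list C, G sparse Matrices).
#' @export
build_mesh <- function(grid, node_spacing, buffer = 1.5 * 60) {
  stopifnot(node_spacing > 0, buffer >= 0)
  win <- grid$window
  xr <- range(win[, 1]) + c(-buffer, buffer)
  yr <- range(win[, 2]) + c(-buffer, buffer)
  if (node_spacing > diff(xr) || node_spacing > diff(yr))
    stop("node_spacing exceeds the extent of the (buffered) window",
         call. = FALSE)
  h <- node_spacing
  nx <- as.integer(ceiling(diff(xr) / h - 1e-9)) + 1L
  ny <- as.integer(ceiling(diff(yr) / h - 1e-9)) + 1L
  # centre the lattice on the extended bounding box
  x0 <- mean(xr) - (nx - 1) * h / 2
  y0 <- mean(yr) - (ny - 1) * h / 2
  xs <- x0 + (0:(nx - 1)) * h
  ys <- y0 + (0:(ny - 1)) * h
  nodes <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
  # two triangles per lattice square; node id = iy*nx + ix + 1
  ix <- rep(0:(nx - 2), times = ny - 1)
  iy <- rep(0:(ny - 2), each = nx - 1)
  v00 <- iy * nx + ix + 1L
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  triangles <- rbind(cbind(v00, v10, v11),   # lower: local x >= y
                     cbind(v00, v11, v01))   # upper
  mesh <- structure(list(nodes = nodes, triangles = triangles,
                         nx = nx, ny = ny, spacing = h, buffer = buffer,
                         origin = c(x0, y0)),
                    class = "spde_mesh")
  mesh$fem <- fem_matrices(mesh)
  mesh
}

#' @export
print.spde_mesh <- function(x, ...) {
  cat(sprintf("spde_mesh: M = %d nodes (%d x %d, spacing %.3g km, buffer %.3g km), %d triangles\n",
              nrow(x$nodes), x$nx, x$ny, x$spacing, x$buffer, nrow(x$triangles)))
  invisible(x)
}

# lumped mass matrix C (diagonal) and stiffness matrix G for
# piecewise-linear elements, assembled over all triangles at once
fem_matrices <- function(mesh) {
  tri <- mesh$triangles
  p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  # opposite-edge vectors
  e1 <- p3 - p2
  e2 <- p1 - p3
  e3 <- p2 - p1
  area <- 0.5 * abs(e3[, 1] * (-e2[, 2]) - e3[, 2] * (-e2[, 1]))
  if (any(area <= 0)) stop("degenerate triangle in mesh", call. = FALSE)
  M <- nrow(mesh$nodes)
  # stiffness: G_lm^T = (e_l . e_m) / (4 |T|)
  E <- list(e1, e2, e3)
  ii <- jj <- xx <- vector("list", 9L)
  idx <- 1L
  for (l in 1:3) for (m in 1:3) {
    ii[[idx]] <- tri[, l]
    jj[[idx]] <- tri[, m]
    xx[[idx]] <- rowSums(E[[l]] * E[[m]]) / (4 * area)
    idx <- idx + 1L
  }
  G <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(M, M))
  G <- Matrix::forceSymmetric((G + Matrix::t(G)) / 2)
  cdiag <- numeric(M)
  for (l in 1:3) {
    tab <- tapply(area / 3, tri[, l], sum)
    cdiag[as.integer(names(tab))] <- cdiag[as.integer(names(tab))] + as.numeric(tab)
  }
  C <- Matrix::Diagonal(M, cdiag)
  list(C = C, G = G)
}

#' Projector from mesh nodes to evaluation points
#'
#' Sparse matrix A whose row r holds the barycentric weights of point r
#' within its containing triangle, so that \code{A \%*\% Z} evaluates the
#' piecewise-linear field \eqn{\sum_i \psi_i(s) Z_i} at the points. Rows
#' sum to 1 and have at most 3 non-zeros; a field linear in (x, y) is
#' reproduced exactly.
#'
#' @param mesh a [build_mesh()] object.
#' @param points 2-column matrix (or data.frame with columns x, y) of
#'   planar coordinates, km.
#' @return a sparse Matrix, rows = points, columns = mesh nodes.
#' @export
make_projector <- function(mesh, points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- matrix(as.numeric(points), ncol = 2)
  h <- mesh$spacing
  lx <- (points[, 1] - mesh$origin[1]) / h
  ly <- (points[, 2] - mesh$origin[2]) / h
  eps <- 1e-9
  out <- lx < -eps | ly < -eps | lx > mesh$nx - 1 + eps | ly > mesh$ny - 1 + eps
  if (any(out)) {
    bad <- which(out)[1]
    stop(sprintf("point (%.3f, %.3f) lies outside the mesh",
                 points[bad, 1], points[bad, 2]), call. = FALSE)
  }
  ix <- pmin(pmax(floor(lx), 0), mesh$nx - 2)
  iy <- pmin(pmax(floor(ly), 0), mesh$ny - 2)
  fx <- lx - ix
  fy <- ly - iy
  v00 <- iy * mesh$nx + ix + 1
  v10 <- v00 + 1
  v01 <- v00 + mesh$nx
  v11 <- v01 + 1
  lower <- fx >= fy
  # lower triangle (v00, v10, v11): w = (1 - fx, fx - fy, fy)
  # upper triangle (v00, v11, v01): w = (1 - fy, fx, fy - fx)
  n <- length(fx)
  i <- rep(seq_len(n), 3L)
  j <- c(ifelse(lower, v00, v00),
         ifelse(lower, v10, v11),
         ifelse(lower, v11, v01))
  w <- c(ifelse(lower, 1 - fx, 1 - fy),
         ifelse(lower, fx - fy, fx),
         ifelse(lower, fy, fy - fx))
  A <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(n, nrow(mesh$nodes)))
  Matrix::drop0(A, tol = 1e-14)
}
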