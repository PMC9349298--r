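#' Triangulated inner/outer mesh for the SPDE approximation
#'
#' Builds a conforming triangulation of the boundary polygon plus an outer
#' extension. Boundary effects of the SPDE are pushed away from the study
#' area by extending the mesh `extension` degrees beyond the polygon's
#' bounding box, with coarser triangles allowed outside the polygon. The
#' generator lays down a structured right-triangle grid whose edges satisfy
#' the outer limit and then refines triangles that intersect the study
#' polygon by Rivara longest-edge bisection until their longest edge is at
#' most `inner_max_edge`. Bisection keeps the mesh conforming (no hanging
#' nodes) and bounds the aspect ratio of descendants.
#'
#' @param boundary two-column matrix of polygon vertices (lon/lat degrees).
#' @param inner_max_edge maximum edge length (degrees) for triangles
#'   intersecting the polygon; default 0.3.
#' @param outer_max_edge maximum edge length (degrees) for the extension;
#'   default 0.6.
#' @param extension width (degrees) of the outer belt; default 1.
#' @return an object of class `herd_mesh`: list with `vertices` (n x 2),
#'   `triangles` (m x 3, counter-clockwise), `inner` (logical per triangle),
#'   `boundary`, and the settings.
#' @export
build_mesh <- function(boundary, inner_max_edge = 0.3, outer_max_edge = 0.6,
                       extension = 1) {
  poly <- check_boundary(boundary)
  if (!(inner_max_edge > 0 && outer_max_edge > inner_max_edge))
    abort("need 0 < inner_max_edge < outer_max_edge")
  if (!(extension > 0)) abort("extension must be > 0")

  bb <- bbox_of(poly)
  x0 <- bb["xmin"] - extension; x1 <- bb["xmax"] + extension
  y0 <- bb["ymin"] - extension; y1 <- bb["ymax"] + extension
  # structured base grid: square cells split along one diagonal; the diagonal
  # is the longest edge, so spacing outer_max_edge/sqrt(2) meets the limit
  h <- outer_max_edge / sqrt(2)
  nx <- max(2L, ceiling((x1 - x0) / h)); ny <- max(2L, ceiling((y1 - y0) / h))
  hx <- (x1 - x0) / nx; hy <- (y1 - y0) / ny
  xs <- x0 + (0:nx) * hx; ys <- y0 + (0:ny) * hy
  nvx <- nx + 1L
  vid <- function(ix, iy) iy * nvx + ix + 1L

  nv_max <- 8L * (nx + 1L) * (ny + 1L) * 8L
  env <- new.env(parent = emptyenv())
  env$V <- matrix(NA_real_, nrow = (nx + 1L) * (ny + 1L), ncol = 2L)
  for (iy in 0:ny) for (ix in 0:nx) env$V[vid(ix, iy), ] <- c(xs[ix + 1L], ys[iy + 1L])
  env$nv <- nrow(env$V)
  env$Tm <- matrix(NA_integer_, nrow = 4L * nx * ny, ncol = 3L)
  env$alive <- logical(nrow(env$Tm))
  env$nt <- 0L
  env$edges <- new.env(hash = TRUE, parent = emptyenv())

  ekey <- function(a, b) if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
  edge_add <- function(a, b, t) {
    k <- ekey(a, b)
    cur <- env$edges[[k]]
    env$edges[[k]] <- c(cur, t)
  }
  edge_rm <- function(a, b, t) {
    k <- ekey(a, b)
    cur <- env$edges[[k]]
    cur <- cur[cur != t]
    if (length(cur)) env$edges[[k]] <- cur else rm(list = k, envir = env$edges)
  }
  add_vertex <- function(xy) {
    if (env$nv == nrow(env$V)) env$V <- rbind(env$V, matrix(NA_real_, nrow(env$V), 2L))
    env$nv <- env$nv + 1L
    env$V[env$nv, ] <- xy
    env$nv
  }
  add_triangle <- function(a, b, c) {
    p <- env$V[c(a, b, c), ]
    s <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
         (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1])
    if (s == 0) abort("degenerate (zero-area) triangle produced by mesh generator")
    if (s < 0) { tmp <- b; b <- c; c <- tmp }
    if (env$nt == nrow(env$Tm)) {
      env$Tm <- rbind(env$Tm, matrix(NA_integer_, nrow(env$Tm), 3L))
      env$alive <- c(env$alive, logical(nrow(env$Tm) - length(env$alive)))
    }
    env$nt <- env$nt + 1L
    env$Tm[env$nt, ] <- c(a, b, c)
    env$alive[env$nt] <- TRUE
    edge_add(a, b, env$nt); edge_add(b, c, env$nt); edge_add(c, a, env$nt)
    env$nt
  }
  kill_triangle <- function(t) {
    v <- env$Tm[t, ]
    env$alive[t] <- FALSE
    edge_rm(v[1], v[2], t); edge_rm(v[2], v[3], t); edge_rm(v[3], v[1], t)
  }
  longest_edge <- function(t) {
    v <- env$Tm[t, ]
    p <- env$V[v, ]
    d <- c(sum((p[1, ] - p[2, ])^2), sum((p[2, ] - p[3, ])^2), sum((p[3, ] - p[1, ])^2))
    w <- which.max(d)
    pair <- rbind(c(v[1], v[2]), c(v[2], v[3]), c(v[3], v[1]))[w, ]
    list(a = pair[1], b = pair[2], len2 = d[w])
  }
  max_edge_len <- function(t) sqrt(longest_edge(t)$len2)
  neighbor_across <- function(t, a, b) {
    cand <- env$edges[[ekey(a, b)]]
    cand <- cand[cand != t & env$alive[cand]]
    if (length(cand)) cand[1] else NA_integer_
  }
  # split t (and the conforming neighbor) through the midpoint of edge (a,b)
  split_pair <- function(t, a, b) {
    mid <- add_vertex((env$V[a, ] + env$V[b, ]) / 2)
    for (tt in c(t, neighbor_across(t, a, b))) {
      if (is.na(tt)) next
      v <- env$Tm[tt, ]
      opp <- setdiff(v, c(a, b))
      kill_triangle(tt)
      add_triangle(a, mid, opp)
      add_triangle(mid, b, opp)
    }
    invisible(mid)
  }
  bisect <- function(t) {
    # Rivara LEPP: walk to a terminal pair, split, repeat until t is gone
    while (env$alive[t]) {
      t0 <- t
      repeat {
        e <- longest_edge(t0)
        nb <- neighbor_across(t0, e$a, e$b)
        if (is.na(nb)) { split_pair(t0, e$a, e$b); break }
        en <- longest_edge(nb)
        if (ekey(en$a, en$b) == ekey(e$a, e$b)) { split_pair(t0, e$a, e$b); break }
        t0 <- nb
      }
    }
  }

  for (iy in 0:(ny - 1L)) for (ix in 0:(nx - 1L)) {
    v00 <- vid(ix, iy); v10 <- vid(ix + 1L, iy)
    v01 <- vid(ix, iy + 1L); v11 <- vid(ix + 1L, iy + 1L)
    add_triangle(v00, v10, v11)
    add_triangle(v00, v11, v01)
  }

  pvx <- poly[, 1L]; pvy <- poly[, 2L]
  touches_inner <- function(t) {
    v <- env$Tm[t, ]
    p <- env$V[v, ]
    probes <- rbind(p, (p[c(1, 2, 3), ] + p[c(2, 3, 1), ]) / 2, colMeans(p))
    if (any(point_in_polygon(probes[, 1], probes[, 2], poly))) return(TRUE)
    # polygon vertex inside triangle (triangle larger than polygon features)
    inb <- pvx >= min(p[, 1]) & pvx <= max(p[, 1]) & pvy >= min(p[, 2]) & pvy <= max(p[, 2])
    if (any(inb)) {
      A <- barycentric_weights(p, cbind(pvx[inb], pvy[inb]))
      if (any(apply(A, 1L, function(w) all(w > -1e-12)))) return(TRUE)
    }
    FALSE
  }

  repeat {
    todo <- which(env$alive)
    todo <- todo[vapply(todo, function(t)
      max_edge_len(t) > inner_max_edge + 1e-12 && touches_inner(t), logical(1))]
    if (!length(todo)) break
    for (t in todo) if (env$alive[t]) bisect(t)
  }

  keep <- which(env$alive)
  tri <- env$Tm[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  remap <- integer(env$nv); remap[used] <- seq_along(used)
  tri <- matrix(remap[tri], ncol = 3L)
  V <- env$V[used, , drop = FALSE]
  colnames(V) <- c("lon", "lat")
  inner <- vapply(seq_len(nrow(tri)), function(i) {
    p <- V[tri[i, ], ]
    probes <- rbind(p, (p[c(1, 2, 3), ] + p[c(2, 3, 1), ]) / 2, colMeans(p))
    any(point_in_polygon(probes[, 1], probes[, 2], poly))
  }, logical(1))

  structure(list(vertices = V, triangles = tri, inner = inner, boundary = poly,
                 inner_max_edge = inner_max_edge, outer_max_edge = outer_max_edge,
                 extension = extension),
            class = "herd_mesh")
}

#' @export
print.herd_mesh <- function(x, ...) {
  cat("<herd_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$triangles),
      " triangles (", sum(x$inner), " inner)\n", sep = "")
  cat("  max edge: inner ", x$inner_max_edge, ", outer ", x$outer_max_edge,
      ", extension ", x$extension, " deg\n", sep = "")
  invisible(x)
}

#' Edge lengths of every triangle
#' @param mesh a `herd_mesh`.
#' @return m x 3 matrix of edge lengths.
#' @export
triangle_edge_lengths <- function(mesh) {
  V <- mesh$vertices; Tr <- mesh$triangles
  e1 <- sqrt(rowSums((V[Tr[, 1], , drop = FALSE] - V[Tr[, 2], , drop = FALSE])^2))
  e2 <- sqrt(rowSums((V[Tr[, 2], , drop = FALSE] - V[Tr[, 3], , drop = FALSE])^2))
  e3 <- sqrt(rowSums((V[Tr[, 3], , drop = FALSE] - V[Tr[, 1], , drop = FALSE])^2))
  cbind(e1, e2, e3)
}

triangle_areas <- function(V, Tr) {
  p1 <- V[Tr[, 1], , drop = FALSE]; p2 <- V[Tr[, 2], , drop = FALSE]
  p3 <- V[Tr[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
   (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])) / 2
}

#' Finite-element mass and stiffness matrices
#'
#' Assembles the piecewise-linear (P1) consistent mass matrix `C`, its
#' lumped (row-sum diagonal) version `C_lumped`, and the stiffness matrix
#' `G` over the mesh. The element mass matrix is `area/12 * [[2,1,1],[1,2,1],
#' [1,1,2]]`; the element stiffness is the integral of gradient inner
#' products, constant per triangle for P1 bases.
#'
#' @param mesh a `herd_mesh` (or a list with `vertices` and `triangles`).
#' @return list of class `herd_fem` with sparse symmetric `C`, `C_lumped`,
#'   `G`, and the vertex count `n`.
#' @export
fem_matrices <- function(mesh) {
  V <- mesh$vertices; Tr <- mesh$triangles
  area <- triangle_areas(V, Tr)
  if (any(area <= 0)) {
    bad <- which(area <= 0)[1]
    abort(paste0("degenerate (zero-area) triangle ", bad, " in mesh"))
  }
  m <- nrow(Tr)
  ii <- integer(9L * m); jj <- integer(9L * m)
  cc <- numeric(9L * m); gg <- numeric(9L * m)
  pos <- 0L
  for (t in seq_len(m)) {
    v <- Tr[t, ]
    p <- V[v, , drop = FALSE]
    A <- area[t]
    # gradient coefficients of the three barycentric bases
    bx <- c(p[2, 2] - p[3, 2], p[3, 2] - p[1, 2], p[1, 2] - p[2, 2]) / (2 * A)
    by <- c(p[3, 1] - p[2, 1], p[1, 1] - p[3, 1], p[2, 1] - p[1, 1]) / (2 * A)
    Ke <- A * (outer(bx, bx) + outer(by, by))
    Me <- (A / 12) * matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3)
    idx <- pos + 1:9
    ii[idx] <- rep(v, each = 3L)
    jj[idx] <- rep(v, times = 3L)
    cc[idx] <- as.vector(Me)
    gg[idx] <- as.vector(Ke)
    pos <- pos + 9L
  }
  n <- nrow(V)
  C <- forceSymmetric(sparseMatrix(i = ii, j = jj, x = cc, dims = c(n, n)))
  G <- forceSymmetric(sparseMatrix(i = ii, j = jj, x = gg, dims = c(n, n)))
  structure(list(C = C, C_lumped = Diagonal(n, x = Matrix::rowSums(C)),
                 G = G, n = n),
            class = "herd_fem")
}

#' Sparse Matern (nu = 1) precision via the SPDE discretization
#'
#' With smoothness fixed at nu = 1 in two dimensions, the SPDE parameters
#' are kappa = sqrt(8)/rho_s and tau with marginal variance
#' sigma_s^2 = 1/(4 pi kappa^2 tau^2). Using the lumped mass matrix the
#' precision over mesh weights is
#' `Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^{-1} G)`,
#' whose sparsity is the second-order vertex neighbourhood.
#'
#' @param fem a `herd_fem` from [fem_matrices()].
#' @param rho_s spatial range (degrees): distance at which correlation has
#'   fallen to about 0.14.
#' @param sigma_s marginal standard deviation.
#' @return object of class `herd_matern`: list with `Q` (sparse, SPD),
#'   `rho_s`, `sigma_s`, `kappa`, `tau`, and cached part matrices for fast
#'   reassembly at new parameters.
#' @export
spde_precision <- function(fem, rho_s, sigma_s) {
  if (!is.finite(rho_s) || !is.finite(sigma_s) || rho_s <= 0 || sigma_s <= 0)
    abort("rho_s and sigma_s must be finite and > 0")
  parts <- spde_parts(fem)
  Q <- spde_assemble(parts, rho_s, sigma_s)
  structure(list(Q = Q, rho_s = rho_s, sigma_s = sigma_s,
                 kappa = sqrt(8) / rho_s,
                 tau = 1 / (sqrt(4 * pi) * (sqrt(8) / rho_s) * sigma_s),
                 parts = parts, nu = 1),
            class = "herd_matern")
}

spde_parts <- function(fem) {
  Ci <- Diagonal(fem$n, x = 1 / Matrix::diag(fem$C_lumped))
  list(C = fem$C_lumped, G = fem$G,
       GCG = forceSymmetric(fem$G %*% Ci %*% fem$G), n = fem$n)
}

spde_assemble <- function(parts, rho_s, sigma_s) {
  kappa <- sqrt(8) / rho_s
  tau2 <- 1 / (4 * pi * kappa^2 * sigma_s^2)
  forceSymmetric(tau2 * (kappa^4 * parts$C + 2 * kappa^2 * parts$G + parts$GCG))
}

barycentric_weights <- function(tri_coords, pts) {
  # rows of pts -> barycentric coordinates w.r.t. the 3x2 matrix tri_coords
  x1 <- tri_coords[1, 1]; y1 <- tri_coords[1, 2]
  x2 <- tri_coords[2, 1]; y2 <- tri_coords[2, 2]
  x3 <- tri_coords[3, 1]; y3 <- tri_coords[3, 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  l1 <- ((y2 - y3) * (pts[, 1] - x3) + (x3 - x2) * (pts[, 2] - y3)) / det
  l2 <- ((y3 - y1) * (pts[, 1] - x3) + (x1 - x3) * (pts[, 2] - y3)) / det
  cbind(l1, l2, 1 - l1 - l2)
}

#' Projection matrix from mesh vertices to arbitrary points
#'
#' Each row holds the barycentric weights of the point within its containing
#' triangle: at most three non-negative entries summing to one.
#'
#' @param mesh a `herd_mesh`.
#' @param points two-column matrix (lon, lat).
#' @return sparse matrix (n_points x n_vertices).
#' @export
project_points <- function(mesh, points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) abort("points must have two columns (lon, lat)")
  np <- nrow(points)
  V <- mesh$vertices; Tr <- mesh$triangles
  tri_id <- rep(NA_integer_, np)
  W <- matrix(NA_real_, np, 3L)
  unassigned <- seq_len(np)
  for (t in seq_len(nrow(Tr))) {
    if (!length(unassigned)) break
    p <- V[Tr[t, ], , drop = FALSE]
    inb <- points[unassigned, 1] >= min(p[, 1]) - 1e-12 &
           points[unassigned, 1] <= max(p[, 1]) + 1e-12 &
           points[unassigned, 2] >= min(p[, 2]) - 1e-12 &
           points[unassigned, 2] <= max(p[, 2]) + 1e-12
    cand <- unassigned[inb]
    if (!length(cand)) next
    Wc <- barycentric_weights(p, points[cand, , drop = FALSE])
    hit <- apply(Wc, 1L, function(w) all(w >= -1e-9))
    if (any(hit)) {
      got <- cand[hit]
      tri_id[got] <- t
      W[got, ] <- pmax(Wc[hit, , drop = FALSE], 0)
      unassigned <- setdiff(unassigned, got)
    }
  }
  if (length(unassigned)) {
    ex <- paste(apply(points[head(unassigned, 5L), , drop = FALSE], 1L,
                      function(r) sprintf("(%.4f, %.4f)", r[1], r[2])),
                collapse = ", ")
    abort(paste0(length(unassigned), " point(s) outside mesh, e.g. ", ex))
  }
  W <- W / rowSums(W)
  sparseMatrix(i = rep(seq_len(np), 3L),
               j = as.vector(Tr[tri_id, ]),
               x = as.vector(W),
               dims = c(np, nrow(V)))
}

#' Draw samples from a Gaussian Markov random field
#'
#' Samples `x ~ N(0, Q^{-1})` through the sparse Cholesky factorization of
#' the precision matrix.
#'
#' @param Q sparse symmetric positive-definite precision matrix.
#' @param n number of draws.
#' @return matrix (dim(Q) x n).
#' @export
gmrf_sample <- function(Q, n = 1L) {
  ch <- Matrix::Cholesky(forceSymmetric(Q), LDL = FALSE, perm = TRUE)
  z <- matrix(rnorm(nrow(Q) * n), nrow(Q), n)
  y <- solve(ch, z, system = "Lt")
  as.matrix(solve(ch, y, system = "Pt"))
}

#' Serialize a mesh to a plain-text container
#'
#' Writes vertices, triangles and flags as JSON so meshes can be cached and
#' shared across pipeline stages.
#' @param mesh a `herd_mesh`.
#' @param path file path.
#' @export
write_mesh <- function(mesh, path) {
  obj <- list(vertices = unname(mesh$vertices), triangles = mesh$triangles,
              inner = mesh$inner, boundary = unname(mesh$boundary),
              inner_max_edge = mesh$inner_max_edge,
              outer_max_edge = mesh$outer_max_edge, extension = mesh$extension)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  V <- as.matrix(o$vertices); colnames(V) <- c("lon", "lat")
  structure(list(vertices = V, triangles = as.matrix(o$triangles),
                 inner = as.logical(o$inner), boundary = as.matrix(o$boundary),
                 inner_max_edge = o$inner_max_edge,
                 outer_max_edge = o$outer_max_edge, extension = o$extension),
            class = "herd_mesh")
}
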