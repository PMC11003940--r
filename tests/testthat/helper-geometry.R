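# Geometric fixtures built in code: icosphere, planar grids, tiny meshes.

make_icosphere <- function(subdivisions = 4, radius = 50) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    nf <- vector("list", nrow(f))
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[k]])) return(mid[[k]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c2 <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, c2); ca <- getmid(c2, a)
      nf[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c2, ca, bc),
                       c(ab, bc, ca))
    }
    f <- do.call(rbind, nf)
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  SurfaceMesh(v, f)
}

# planar grid over [0,w] x [0,h], alternating diagonals, optional height fn
make_grid_mesh <- function(nx = 41, ny = 41, w = 100, h = 100, zfun = NULL) {
  g <- expand.grid(x = seq(0, w, length.out = nx),
                   y = seq(0, h, length.out = ny))
  z <- if (is.null(zfun)) rep(0, nrow(g)) else zfun(g$x, g$y)
  idx <- matrix(seq_len(nx * ny), nx, ny)
  f <- vector("list", 0)
  for (iy in seq_len(ny - 1)) for (ix in seq_len(nx - 1)) {
    a <- idx[ix, iy]; b <- idx[ix + 1, iy]
    c2 <- idx[ix, iy + 1]; d2 <- idx[ix + 1, iy + 1]
    f[[length(f) + 1]] <- if ((ix + iy) %% 2 == 0)
      rbind(c(a, b, d2), c(a, d2, c2)) else rbind(c(a, b, c2), c(b, d2, c2))
  }
  list(mesh = SurfaceMesh(cbind(g$x, g$y, z), do.call(rbind, f)), index = idx)
}

make_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  SurfaceMesh(v, f)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

small_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- buildTemplate(41)
    tpl
  }
})

default_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- buildTemplate()
    tpl
  }
})
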