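## Template LV surface: a truncated prolate spheroid (short semi-axes a,
## long semi-axis c) with a flat basal cap.  Apex at z = 0, base plane at
## z = c.  The septal sector is centered at azimuth 0.

faceAreas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

## triangulate the annulus between two rings of (possibly different) sizes
## by an azimuth-sweep two-pointer walk; returns faces as index triples into
## the global vertex array.  idx1/phi1 is the lower ring (closer to apex).
stripFaces <- function(idx1, phi1, idx2, phi2) {
  n1 <- length(idx1); n2 <- length(idx2)
  faces <- matrix(0L, n1 + n2, 3L)
  i <- 1L; j <- 1L; f <- 0L
  nxt <- function(phi, k, n) phi[(k %% n) + 1L] + ifelse(k == n, 2 * pi, 0)
  while (i <= n1 || j <= n2) {
    adv1 <- if (i <= n1) nxt(phi1, i, n1) else Inf
    adv2 <- if (j <= n2) nxt(phi2, j, n2) else Inf
    f <- f + 1L
    if (adv1 <= adv2) {   # advance along lower ring
      faces[f, ] <- c(idx1[(i - 1L) %% n1 + 1L], idx1[i %% n1 + 1L],
                      idx2[(j - 1L) %% n2 + 1L])
      i <- i + 1L
    } else {              # advance along upper ring
      faces[f, ] <- c(idx1[(i - 1L) %% n1 + 1L], idx2[j %% n2 + 1L],
                      idx2[(j - 1L) %% n2 + 1L])
      j <- j + 1L
    }
  }
  faces[seq_len(f), , drop = FALSE]
}

#' Build the left-ventricular template mesh
#'
#' Constructs a closed, manifold triangulated surrogate for the LV
#' epicardial atlas: a truncated prolate spheroid (default short semi-axes
#' 25 mm, long semi-axis 70 mm) closed by a flat basal cap.  Vertices are
#' laid out on latitude rings with counts proportional to ring
#' circumference so the requested vertex budget is met exactly.  Each vertex
#' carries a region label from the 12-region scheme (z-tertile level
#' basal/mid/apical crossed with azimuth-quadrant sector
#' septal/anterior/lateral/inferior, septal centered at azimuth 0), a
#' one-third-incident-face-area weight and an outward unit normal.
#'
#' The construction is fully deterministic; \code{seed} is accepted for
#' interface symmetry with the cohort generator but does not influence the
#' geometry.
#'
#' @param nVertices total number of vertices (>= 100).
#' @param seed integer, unused (geometry is deterministic).
#' @param a short semi-axes in mm.
#' @param c long semi-axis in mm.
#' @return a \linkS4class{TemplateMesh}.
#' @examples
#' tpl <- buildTemplateMesh(500)
#' table(tpl@region)
#' @export
buildTemplateMesh <- function(nVertices, seed = 0L, a = 25, c = 70) {
  if (!is.numeric(nVertices) || nVertices < 100)
    stop("invalid config: nVertices must be >= 100")
  nVertices <- as.integer(nVertices)
  m <- nVertices - 2L                       # ring vertices (apex + cap center)
  nRings <- max(4L, round(sqrt(m / 3)))
  theta <- seq_len(nRings) / nRings * (pi / 2)
  rad <- a * sin(theta)
  cnt <- pmax(3L, round(m * rad / sum(rad)))
  while (sum(cnt) != m) {                   # absorb rounding drift
    k <- which.max(cnt)
    cnt[k] <- cnt[k] + sign(m - sum(cnt))
  }
  verts <- matrix(0, nVertices, 3L)
  verts[1L, ] <- c(0, 0, 0)                 # apex
  ringIdx <- vector("list", nRings)
  ringPhi <- vector("list", nRings)
  pos <- 1L
  for (i in seq_len(nRings)) {
    phi <- 2 * pi * (seq_len(cnt[i]) - 1L) / cnt[i]
    idx <- pos + seq_len(cnt[i])
    verts[idx, ] <- cbind(rad[i] * cos(phi), rad[i] * sin(phi),
                          c * (1 - cos(theta[i])))
    ringIdx[[i]] <- idx
    ringPhi[[i]] <- phi
    pos <- pos + cnt[i]
  }
  capC <- nVertices                          # cap center at (0,0,c)
  verts[capC, ] <- c(0, 0, c)

  faces <- list()
  ## apex fan
  i1 <- ringIdx[[1L]]
  n1 <- length(i1)
  faces[[1L]] <- cbind(1L, i1[c(2:n1, 1L)], i1)
  for (i in seq_len(nRings - 1L))
    faces[[i + 1L]] <- stripFaces(ringIdx[[i]], ringPhi[[i]],
                                  ringIdx[[i + 1L]], ringPhi[[i + 1L]])
  ib <- ringIdx[[nRings]]
  nb <- length(ib)
  faces[[nRings + 1L]] <- cbind(capC, ib, ib[c(2:nb, 1L)])  # cap fan, +z out
  faces <- do.call(rbind, faces)
  storage.mode(faces) <- "integer"

  fa <- faceAreas(verts, faces)
  va <- numeric(nVertices)
  for (k in 1:3) {
    s <- tapply(fa, faces[, k], sum)
    va[as.integer(names(s))] <- va[as.integer(names(s))] + s
  }
  va <- va / 3

  nrm <- vertexNormals(verts, faces, fa)
  region <- regionLabels(verts, cTotal = c)
  new("TemplateMesh", vertices = verts, faces = faces, region = region,
      vertexArea = va, normals = nrm)
}

vertexNormals <- function(vertices, faces, fa = faceAreas(vertices, faces)) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  fn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])  # area-weighted already
  nrm <- matrix(0, nrow(vertices), 3L)
  for (k in 1:3)
    for (d in 1:3) {
      s <- tapply(fn[, d], faces[, k], sum)
      nrm[as.integer(names(s)), d] <- nrm[as.integer(names(s)), d] + s
    }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

## 12-region labelling: z-tertile x azimuth quadrant (septal centered at 0)
regionLabels <- function(vertices, cTotal) {
  zrel <- vertices[, 3] / cTotal
  lvl <- cut(zrel, c(-Inf, 1 / 3, 2 / 3, Inf),
             labels = c("apical", "mid", "basal"))
  phi <- atan2(vertices[, 2], vertices[, 1]) %% (2 * pi)
  sec <- cut(((phi + pi / 4) %% (2 * pi)), c(-Inf, pi / 2, pi, 3 * pi / 2, Inf),
             labels = c("septal", "anterior", "lateral", "inferior"))
  factor(paste(lvl, sec, sep = "-"),
         levels = as.vector(outer(c("basal", "mid", "apical"),
                                  c("septal", "anterior", "lateral", "inferior"),
                                  paste, sep = "-")))
}

#' Enclosed volume of a closed oriented surface
#'
#' Signed-tetrahedron (divergence theorem) sum over faces, returned as an
#' absolute volume in millilitres.
#'
#' @param vertices n x 3 coordinate matrix (mm).
#' @param faces m x 3 face index matrix (1-based, consistently oriented).
#' @return volume in mL.
#' @export
enclosedVolume <- function(vertices, faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (any(table(key) != 2L))
    stop("topology error: surface is not closed")
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  v6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
        a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(v6) / 6) / 1000
}

## undirected edge list (2-col matrix, i < j, unique)
meshEdges <- function(mesh) {
  e <- rbind(mesh@faces[, c(1, 2)], mesh@faces[, c(2, 3)], mesh@faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

## sparse row-stochastic smoothing operator: average of self + neighbours
smoothingOperator <- function(mesh) {
  e <- meshEdges(mesh)
  n <- nrow(mesh@vertices)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2], seq_len(n)),
                            j = c(e[, 2], e[, 1], seq_len(n)),
                            x = 1, dims = c(n, n))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(A)) %*% A
}
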