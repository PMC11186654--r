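#' Read a surface mesh from an STL file
#'
#' Supports both ASCII and binary STL.  Coordinates in the file are
#' interpreted in millimeters (the convention of segmentation exports)
#' and converted to meters unless `units = "m"`.  Vertices are merged by
#' exact coordinate equality so shared edges are recovered.
#'
#' @param path file path.
#' @param units `"mm"` (default) or `"m"`.
#' @return a [MeshSurface-class].
#' @export
readSTL <- function(path, units = c("mm", "m")) {
  units <- match.arg(units)
  if (!file.exists(path)) stopf("STL file not found: %s", path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", 5)
  close(con)
  tri <- if (identical(rawToChar(head), "solid") && isAsciiSTL(path))
    readSTLascii(path) else readSTLbinary(path)
  if (nrow(tri) == 0L) stopf("STL file contains no triangles: %s", path)
  scale <- if (units == "mm") 1e-3 else 1
  verts <- tri * scale
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- !duplicated(key)
  vid <- match(key, key[uid])
  V <- verts[uid, , drop = FALSE]
  F <- matrix(vid, ncol = 3, byrow = TRUE)
  new("MeshSurface", vertices = V, faces = F)
}

isAsciiSTL <- function(path) {
  ## binary STLs may also start with "solid": verify the facet count
  sz <- file.size(path)
  if (sz < 84) return(TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz != 84 + 50 * as.double(n)
}

readSTLascii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", ln, value = TRUE)
  if (length(vl) %% 3L != 0L) stopf("malformed ASCII STL: %s", path)
  nums <- vapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4]), numeric(3))
  t(nums)
}

readSTLbinary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(n) || is.na(n) || n < 0) stopf("malformed binary STL: %s", path)
  out <- matrix(NA_real_, nrow = 3 * n, ncol = 3)
  for (t in seq_len(n)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12) stopf("truncated binary STL: %s", path)
    out[(3 * t - 2):(3 * t), ] <- matrix(rec[4:12], ncol = 3, byrow = TRUE)
    readBin(con, "raw", 2)
  }
  out
}

#' Write a surface mesh to an ASCII STL file
#'
#' @param mesh a [MeshSurface-class].
#' @param path output file path.
#' @param units `"mm"` (default) or `"m"` for the coordinates written.
#' @return `path`, invisibly.
#' @export
writeSTL <- function(mesh, path, units = c("mm", "m")) {
  units <- match.arg(units)
  scale <- if (units == "mm") 1e3 else 1
  V <- mesh@vertices * scale
  F <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid iustherm", con)
  for (t in seq_len(nrow(F))) {
    p <- V[F[t, ], , drop = FALSE]
    n <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) - (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
           (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) - (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
           (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) - (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(sprintf("facet normal %g %g %g", n[1], n[2], n[3]), con)
    writeLines(" outer loop", con)
    for (vv in 1:3)
      writeLines(sprintf("  vertex %.9g %.9g %.9g", p[vv, 1], p[vv, 2], p[vv, 3]), con)
    writeLines(" endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid iustherm", con)
  invisible(path)
}

#' Icosphere test mesh
#'
#' Closed triangulated sphere obtained by subdividing an icosahedron;
#' used for voxelization tests and synthetic scenes.
#'
#' @param radius sphere radius, m.
#' @param center center, m.
#' @param subdiv subdivision level (3 gives 1280 faces, max radius error
#'   ~0.6%).
#' @return a [MeshSurface-class].
#' @export
icosphereMesh <- function(radius = 5e-3, center = c(0, 0, 0), subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    getMid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      m <- V[a, ] + V[b, ]
      m <- m / sqrt(sum(m^2))
      V <<- rbind(V, m)
      id <- nrow(V)
      assign(key, id, envir = mid)
      id
    }
    Fn <- matrix(0L, nrow = 4 * nrow(F), ncol = 3)
    for (t in seq_len(nrow(F))) {
      a <- F[t, 1]; b <- F[t, 2]; c0 <- F[t, 3]
      ab <- getMid(a, b); bc <- getMid(b, c0); ca <- getMid(c0, a)
      Fn[(4 * t - 3):(4 * t), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c0, ca, bc), c(ab, bc, ca))
    }
    F <- Fn
  }
  new("MeshSurface",
      vertices = sweep(V * radius, 2, center, `+`),
      faces = F)
}

#' Axis-aligned box test mesh
#'
#' @param lo,hi opposite corners, m.
#' @return a closed [MeshSurface-class] of 12 triangles.
#' @export
boxMesh <- function(lo = c(0, 0, 0), hi = c(0.01, 0.01, 0.01)) {
  V <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  ## vertex order: 1:(000) 2:(100) 3:(010) 4:(110) 5:(001) 6:(101) 7:(011) 8:(111)
  F <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = lo
             c(5, 6, 7), c(6, 8, 7),   # z = hi
             c(1, 2, 5), c(2, 6, 5),   # y = lo
             c(3, 7, 4), c(4, 7, 8),   # y = hi
             c(1, 5, 3), c(3, 5, 7),   # x = lo
             c(2, 4, 6), c(4, 8, 6))   # x = hi
  new("MeshSurface", vertices = V, faces = F)
}
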