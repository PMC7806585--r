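#' Export the airway surface as a triangle mesh
#'
#' Writes a triangulated surface of the model: elliptical tubes for the
#' upper-airway sections, a C-shaped extrusion with ring bumps for the
#' trachea (when rings are annotated), and circular tubes for the bronchi.
#' Each conduit is a closed (capped) tube; caps share their centre vertex
#' with the adjoining conduit's cap, so the welded mesh of a connected tree
#' is one connected component. The solid header records the branch count
#' and total centerline length so they are recoverable from the file.
#'
#' ASCII STL (default) or OBJ; both are plain text.
#'
#' @param tree An `airway_tree`.
#' @param path Output file path.
#' @param format `"stl"` or `"obj"`.
#' @param n_theta Vertices per cross-section polygon. Default 16.
#' @param include_upper Mesh the upper-airway sections too (when present).
#' @return `path`, invisibly.
#' @export
#' @examples
#' tree <- build_tree(make_weibel_table(tree_recipe(max_generation = 1)))
#' f <- tempfile(fileext = ".stl")
#' export_surface(tree, f)
export_surface <- function(tree, path, format = c("stl", "obj"),
                           n_theta = 16, include_upper = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "airway_tree"), n_theta >= 8)
  tris <- list()

  # cheap loft-sanity heuristic: a daughter much shorter than the parent
  # radius cannot be lofted without overlapping the junction
  b <- tree$branches
  idx <- stats::setNames(seq_len(nrow(b)), b$id)
  has_par <- !is.na(b$parent_id)
  short <- has_par &
    b$length_cm < b$diameter_cm[idx[ifelse(has_par, b$parent_id, b$id)]] / 2
  if (any(short)) {
    warning("possible self-intersecting loft at branch(es): ",
            paste(b$id[short], collapse = ", "))
  }

  if (include_upper && !is.null(tree$upper_airway)) {
    z_top <- sum(vapply(tree$upper_airway, `[[`, 0, "length"))
    z <- z_top
    for (s in tree$upper_airway) {
      tris <- c(tris, tube_mesh(
        p0 = c(0, 0, z), p1 = c(0, 0, z - s$length),
        section = ellipse_section(s$semi_axis_a, s$semi_axis_b, n_theta)))
      z <- z - s$length
    }
  }

  for (i in seq_len(nrow(b))) {
    p0 <- c(b$x0[i], b$y0[i], b$z0[i])
    p1 <- c(b$x1[i], b$y1[i], b$z1[i])
    if (b$generation[i] == 0L && !is.null(tree$trachea)) {
      sec <- c_shape_section(tree$trachea, n_theta)
      stations <- trachea_stations(tree, b$length_cm[i])
      tris <- c(tris, tube_mesh(p0, p1, sec, stations = stations))
    } else {
      tris <- c(tris, tube_mesh(p0, p1,
                                circle_section(b$diameter_cm[i] / 2, n_theta)))
    }
  }
  tri <- do.call(rbind, tris)
  meta <- sprintf("airway branches=%d centerline_cm=%.6f",
                  nrow(b), sum(b$length_cm))
  if (format == "stl") write_stl_ascii(tri, path, meta)
  else write_obj(tri, path, meta)
  invisible(path)
}

# 2D section generators: matrix of (xi, eta) vertices, counter-clockwise
circle_section <- function(r, n) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

ellipse_section <- function(a, b, n) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

c_shape_section <- function(trachea, n) {
  r <- trachea$diameter / 2
  h <- trachea$posterior_cut_offset
  if (h >= r) return(circle_section(r, n))
  alpha <- asin(h / r)
  # kept arc runs from (pi - alpha) through the bottom to (2 pi + alpha)
  th <- seq(pi - alpha, 2 * pi + alpha, length.out = n - 1)
  arc <- cbind(r * cos(th), r * sin(th))
  rbind(arc, c(0, h))  # midpoint of the posterior chord closes the C
}

# axial stations (fractions of length, radial scale) for the ringed trachea
trachea_stations <- function(tree, len_cm) {
  if (is.null(tree$rings) || !tree$rings$enabled) {
    return(data.frame(s = c(0, 1), scale = c(1, 1)))
  }
  rg <- tree$rings
  step <- rg$step_p / 10
  wid <- rg$width_L / 10
  bump <- 1 + (rg$depth_d / 10) / (tree$trachea$diameter / 2)
  centres <- step * (seq_len(floor(len_cm / step)) - 0.5)
  s <- c(0)
  scale <- c(1)
  for (cc in centres) {
    e0 <- max(0, (cc - wid / 2) / len_cm)
    e1 <- min(1, (cc + wid / 2) / len_cm)
    s <- c(s, e0, e0 + 1e-4, e1 - 1e-4, e1)
    scale <- c(scale, 1, bump, bump, 1)
  }
  s <- c(s, 1); scale <- c(scale, 1)
  keep <- !duplicated(round(s, 6))
  data.frame(s = s[keep], scale = scale[keep])
}

# closed capped tube between p0 and p1 with the given 2D section, optionally
# radially scaled at intermediate stations; returns list of 3x3 matrices
tube_mesh <- function(p0, p1, section, stations = data.frame(s = c(0, 1),
                                                             scale = c(1, 1))) {
  u <- p1 - p0
  len <- sqrt(sum(u^2))
  u <- u / len
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  n <- nrow(section)
  ring_at <- function(s, scale) {
    ctr <- p0 + s * len * u
    t(vapply(seq_len(n), function(k) {
      ctr + scale * (section[k, 1] * e1 + section[k, 2] * e2)
    }, numeric(3)))
  }
  rings <- lapply(seq_len(nrow(stations)),
                  function(i) ring_at(stations$s[i], stations$scale[i]))
  tris <- list()
  for (i in seq_len(length(rings) - 1)) {
    a <- rings[[i]]; bb <- rings[[i + 1]]
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      tris[[length(tris) + 1L]] <- rbind(a[k, ], bb[k, ], bb[k2, ])
      tris[[length(tris) + 1L]] <- rbind(a[k, ], bb[k2, ], a[k2, ])
    }
  }
  # caps: fans to the tube end centres (shared with adjoining conduits)
  first <- rings[[1]]; last <- rings[[length(rings)]]
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    tris[[length(tris) + 1L]] <- rbind(p0, first[k2, ], first[k, ])
    tris[[length(tris) + 1L]] <- rbind(p1, last[k, ], last[k2, ])
  }
  tris
}

write_stl_ascii <- function(tri, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", meta), con)
  for (i in seq_len(nrow(tri) / 3)) {
    v <- tri[(3 * i - 2):(3 * i), , drop = FALSE]
    nrm <- tri_normal(v)
    writeLines(c(
      sprintf("  facet normal %.6e %.6e %.6e", nrm[1], nrm[2], nrm[3]),
      "    outer loop",
      sprintf("      vertex %.6e %.6e %.6e", v[, 1], v[, 2], v[, 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines(paste("endsolid", meta), con)
}

write_obj <- function(tri, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", meta), con)
  writeLines(sprintf("v %.6e %.6e %.6e", tri[, 1], tri[, 2], tri[, 3]), con)
  nf <- nrow(tri) / 3
  writeLines(sprintf("f %d %d %d", 3 * seq_len(nf) - 2, 3 * seq_len(nf) - 1,
                     3 * seq_len(nf)), con)
}

tri_normal <- function(v) {
  a <- v[2, ] - v[1, ]; b <- v[3, ] - v[1, ]
  n <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  l <- sqrt(sum(n^2))
  if (l == 0) c(0, 0, 1) else n / l
}

#' Read an exported surface back for inspection
#'
#' Parses an ASCII STL written by [export_surface()], welds coincident
#' vertices, and returns the mesh with the metadata recorded in the solid
#' header.
#'
#' @param path STL file path.
#' @return List: `vertices` (matrix), `faces` (index matrix), `metadata`
#'   (named list with `branches` and `centerline_cm`).
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  meta <- list()
  m <- regmatches(header, regexec("branches=([0-9]+)", header))[[1]]
  if (length(m) == 2) meta$branches <- as.integer(m[2])
  m <- regmatches(header, regexec("centerline_cm=([0-9.eE+-]+)", header))[[1]]
  if (length(m) == 2) meta$centerline_cm <- as.numeric(m[2])
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(round(xyz, 6), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- xyz[uk, , drop = FALSE]
  vid <- match(key, key[uk])
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces, metadata = meta)
}

#' Mesh diagnostics: area, Euler characteristic, components
#'
#' `mesh_area` sums the triangle areas. `mesh_components` labels the
#' connected components of the welded mesh. `mesh_euler` returns
#' V - E + F per component (2 for each closed genus-0 tube).
#'
#' @param mesh A mesh list from [read_surface()].
#' @return Area; integer component labels per face; named Euler numbers.
#' @export
mesh_area <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname mesh_area
#' @export
mesh_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[r, ]
    a <- find(f[1])
    parent[find(f[2])] <- a
    parent[find(f[3])] <- a
  }
  roots <- vapply(seq_len(nv), find, 0L)
  comp_of_vertex <- match(roots, unique(roots))
  comp_of_vertex[mesh$faces[, 1]]
}

#' @rdname mesh_area
#' @export
mesh_euler <- function(mesh) {
  comp_face <- mesh_components(mesh)
  out <- integer(0)
  for (cmp in sort(unique(comp_face))) {
    f <- mesh$faces[comp_face == cmp, , drop = FALSE]
    vids <- unique(as.vector(f))
    e <- unique(rbind(
      t(apply(f[, c(1, 2), drop = FALSE], 1, sort)),
      t(apply(f[, c(2, 3), drop = FALSE], 1, sort)),
      t(apply(f[, c(1, 3), drop = FALSE], 1, sort))))
    out[as.character(cmp)] <- length(vids) - nrow(e) + nrow(f)
  }
  out
}
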