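#' @title Airway tree construction from a morphometry table
#' @description Build the centerline-and-calibre representation of the
#'   conducting airways (trachea = generation 0 downward) from a per-branch
#'   morphometry table, validating the branching structure and reporting the
#'   diameter-law residual at every bifurcation.
#' @name build_tree
NULL

LOBES <- c("RUL", "RML", "RLL", "LUL", "LLL")
REGIONS <- c("oral", "pharynx", "larynx", "trachea",
             "bif1", "bif2", "bif3", "peripheral")

region_for_generation <- function(g) {
  ifelse(g == 0, "trachea",
         ifelse(g == 1, "bif1",
                ifelse(g == 2, "bif2",
                       ifelse(g == 3, "bif3", "peripheral"))))
}

#' Build an airway tree
#'
#' Validates a morphometry table (one row per branch) and assembles an
#' `airway_tree`: branch coordinates are propagated from the root (trachea
#' inlet at the origin, axis along the table's direction vectors, gravity
#' along -z), children are inferred from `parent_id`, branching and gravity
#' angles are computed, and the diameter-law residual
#' \eqn{|d_P^{x} - d_A^{x} - d_B^{x}| / d_P^{x}} is reported per bifurcation
#' as a diagnostic.
#'
#' @param morphometry Data frame in the morphometry dialect: columns
#'   `id, parent_id, generation, length_cm, diameter_cm, dx, dy, dz, lobe,
#'   region`. `parent_id` empty/NA marks the root; direction vectors are
#'   normalized internally; missing `region` entries are inferred from the
#'   generation (0 trachea, 1-3 bifurcation zones, >= 4 peripheral).
#' @param bif_spec A [bifurcation_spec()].
#' @param trachea A [trachea_spec()]; its length/diameter are taken from the
#'   generation-0 row when that row is present.
#' @param upper_airway Optional list of upper-airway sections from
#'   [build_upper_airway()], mounted above the trachea.
#' @param rings Optional [ring_spec()]; see [add_rings()].
#' @return An object of class `airway_tree`.
#' @export
#' @examples
#' tab <- make_weibel_table(tree_recipe(max_generation = 2))
#' tree <- build_tree(tab)
#' summary(tree)
build_tree <- function(morphometry, bif_spec = bifurcation_spec(),
                       trachea = NULL, upper_airway = NULL, rings = NULL) {
  m <- as.data.frame(morphometry, stringsAsFactors = FALSE)
  need <- c("id", "parent_id", "generation", "length_cm", "diameter_cm",
            "dx", "dy", "dz", "lobe")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("morphometry table lacks columns: ",
                         paste(miss, collapse = ", "))
  m$id <- as.character(m$id)
  m$parent_id <- as.character(m$parent_id)
  m$parent_id[m$parent_id %in% c("", "NA", "none")] <- NA_character_
  if (anyDuplicated(m$id)) stop("duplicate branch ids")
  if (any(m$length_cm <= 0) || any(m$diameter_cm <= 0)) {
    stop("branch lengths and diameters must be > 0")
  }

  root <- which(is.na(m$parent_id))
  if (length(root) != 1L) stop("tree must have exactly one root branch")
  known <- m$parent_id[!is.na(m$parent_id)]
  if (!all(known %in% m$id)) {
    stop("orphan branch: parent id not present: ",
         paste(setdiff(unique(known), m$id), collapse = ", "))
  }

  children <- split(m$id, factor(m$parent_id, levels = m$id))
  nchild <- lengths(children)[m$id]
  names(nchild) <- m$id
  if (any(!nchild %in% c(0L, 2L))) {
    bad <- names(nchild)[!nchild %in% c(0L, 2L)]
    stop("branch with 1 or >2 children: ", paste(bad, collapse = ", "))
  }

  # generations: root must be 0 and child = parent + 1, contiguous
  if (m$generation[root] != 0L) stop("root branch must be generation 0")
  idx <- stats::setNames(seq_len(nrow(m)), m$id)
  pg <- m$generation[idx[m$parent_id[!is.na(m$parent_id)]]]
  if (!all(m$generation[!is.na(m$parent_id)] == pg + 1L)) {
    stop("child generation must equal parent generation + 1")
  }
  gens <- sort(unique(m$generation))
  if (!identical(gens, seq(0L, max(gens)))) stop("generations not contiguous from 0")

  # acyclicity is implied: every non-root has a parent of lower generation

  # normalize directions, propagate coordinates from root (start at origin)
  nrm <- sqrt(m$dx^2 + m$dy^2 + m$dz^2)
  if (any(nrm == 0)) stop("zero direction vector")
  m$dx <- m$dx / nrm; m$dy <- m$dy / nrm; m$dz <- m$dz / nrm
  ord <- order(m$generation)
  m$x0 <- m$y0 <- m$z0 <- m$x1 <- m$y1 <- m$z1 <- NA_real_
  for (i in ord) {
    if (is.na(m$parent_id[i])) {
      m$x0[i] <- m$y0[i] <- m$z0[i] <- 0
    } else {
      p <- idx[m$parent_id[i]]
      m$x0[i] <- m$x1[p]; m$y0[i] <- m$y1[p]; m$z0[i] <- m$z1[p]
    }
    m$x1[i] <- m$x0[i] + m$dx[i] * m$length_cm[i]
    m$y1[i] <- m$y0[i] + m$dy[i] * m$length_cm[i]
    m$z1[i] <- m$z0[i] + m$dz[i] * m$length_cm[i]
  }

  # angles
  m$gravity_angle <- acos(pmin(1, pmax(-1, -m$dz))) * 180 / pi
  m$branching_angle <- NA_real_
  has_par <- !is.na(m$parent_id)
  p <- idx[m$parent_id[has_par]]
  dot <- m$dx[has_par] * m$dx[p] + m$dy[has_par] * m$dy[p] +
    m$dz[has_par] * m$dz[p]
  m$branching_angle[has_par] <- acos(pmin(1, pmax(-1, dot))) * 180 / pi

  # region labels
  if (is.null(m$region)) m$region <- NA_character_
  m$region <- as.character(m$region)
  fill <- is.na(m$region) | m$region == ""
  m$region[fill] <- region_for_generation(m$generation[fill])
  if (!all(m$region %in% REGIONS[-(1:3)])) {
    stop("invalid branch region label")
  }

  # lobe labels: every terminal branch of generation >= 1 needs one
  m$lobe <- as.character(m$lobe)
  m$lobe[is.na(m$lobe) | m$lobe == ""] <- "none"
  term <- nchild[m$id] == 0L
  bad_lobe <- term & m$generation >= 1L & !(m$lobe %in% LOBES)
  if (any(bad_lobe)) {
    stop("terminal branches without a lobe label: ",
         paste(m$id[bad_lobe], collapse = ", "))
  }

  # diameter-law residual at each bifurcation (diagnostic)
  xn <- bif_spec$x_n
  m$diameter_law_residual <- NA_real_
  for (id in names(children)[lengths(children) == 2L]) {
    i <- idx[id]
    kk <- idx[children[[id]]]
    dp <- m$diameter_cm[i]^xn
    m$diameter_law_residual[i] <-
      abs(dp - sum(m$diameter_cm[kk]^xn)) / dp
  }

  max_gen <- max(m$generation)
  if (is.null(trachea)) {
    trachea <- trachea_spec(diameter = m$diameter_cm[root],
                            length = m$length_cm[root])
  }

  tree <- structure(list(
    branches = m[order(m$generation, m$id), , drop = FALSE],
    children = children,
    bif = bif_spec,
    trachea = trachea,
    upper_airway = upper_airway,
    rings = NULL,
    ring_annotations = NULL,
    max_generation = max_gen
  ), class = "airway_tree")
  rownames(tree$branches) <- tree$branches$id

  n_term <- sum(term)
  if (max_gen >= 4 && 2^max_gen == n_term &&
      !all(LOBES %in% tree$branches$lobe)) {
    stop("complete tree to generation >= 4 must carry all five lobe labels")
  }
  if (!is.null(rings)) tree <- add_rings(tree, rings)
  tree
}

#' Terminal (peripheral outlet) branches of a tree
#'
#' @param tree An `airway_tree`.
#' @return Data frame of branches with no children.
#' @export
terminal_branches <- function(tree) {
  ch <- lengths(tree$children)[tree$branches$id]
  ch[is.na(ch)] <- 0L
  tree$branches[ch == 0L, , drop = FALSE]
}

#' @export
print.airway_tree <- function(x, ...) {
  nt <- nrow(terminal_branches(x))
  cat("airway_tree:", nrow(x$branches), "branches to generation",
      x$max_generation, "|", nt, "terminal outlets\n")
  if (!is.null(x$upper_airway)) {
    cat("  upper airway:", paste(vapply(x$upper_airway, `[[`, "", "name"),
                                 collapse = " > "), "\n")
  }
  if (!is.null(x$rings)) {
    cat("  cartilaginous rings:", nrow(x$ring_annotations), "annotated\n")
  }
  invisible(x)
}

#' @export
summary.airway_tree <- function(object, ...) {
  b <- object$branches
  term <- terminal_branches(object)
  res <- list(
    n_branches = nrow(b),
    max_generation = object$max_generation,
    n_terminal = nrow(term),
    terminal_per_lobe = table(factor(term$lobe, levels = c(LOBES, "none"))),
    total_centerline_cm = sum(b$length_cm),
    max_diameter_law_residual = suppressWarnings(
      max(b$diameter_law_residual, na.rm = TRUE))
  )
  class(res) <- "summary.airway_tree"
  res
}

#' @export
print.summary.airway_tree <- function(x, ...) {
  cat("branches:", x$n_branches, " generations: 0..", x$max_generation,
      " terminals:", x$n_terminal, "\n", sep = "")
  cat("terminals per lobe:\n")
  print(x$terminal_per_lobe)
  cat(sprintf("total centerline: %.2f cm\n", x$total_centerline_cm))
  if (is.finite(x$max_diameter_law_residual)) {
    cat(sprintf("max diameter-law residual: %.3g\n",
                x$max_diameter_law_residual))
  }
  invisible(x)
}

#' Annotate cartilaginous rings on trachea and main bronchi
#'
#' Places ring annotations perpendicular to the branch axis at a regular step
#' along the trachea and the two main bronchi (generation 1) only. The ring
#' count per branch is `floor(branch length / step)`. Rings are geometric
#' annotations: flow and deposition are unaffected unless the optional
#' effective-roughness mode is enabled, which subtracts the ring depth from
#' the effective tracheal diameter.
#'
#' @param tree An `airway_tree`.
#' @param rings A [ring_spec()]; when `enabled = FALSE` the tree is returned
#'   unchanged.
#' @param effective_roughness Logical; default `FALSE`.
#' @return The annotated `airway_tree`.
#' @export
add_rings <- function(tree, rings, effective_roughness = FALSE) {
  stopifnot(inherits(tree, "airway_tree"), inherits(rings, "ring_spec"))
  if (!rings$enabled) return(tree)
  b <- tree$branches
  target <- b$generation <= 1L
  step_cm <- rings$step_p / 10
  ann <- do.call(rbind, lapply(which(target), function(i) {
    n <- floor(b$length_cm[i] / step_cm)
    if (n < 1) return(NULL)
    data.frame(branch_id = b$id[i],
               position_cm = step_cm * (seq_len(n) - 0.5),
               stringsAsFactors = FALSE)
  }))
  tree$rings <- rings
  tree$ring_annotations <- ann
  tree$ring_effective_roughness <- isTRUE(effective_roughness)
  tree
}

#' Count annotated rings on a branch
#' @param tree An `airway_tree` with rings annotated.
#' @param branch_id Branch id.
#' @return Integer ring count (0 when rings are absent).
#' @export
ring_count <- function(tree, branch_id) {
  if (is.null(tree$ring_annotations)) return(0L)
  sum(tree$ring_annotations$branch_id == branch_id)
}

#' Read / write the morphometry CSV dialect
#'
#' Header columns: `id,parent_id,generation,length_cm,diameter_cm,dx,dy,dz,
#' lobe,region`. Empty `parent_id` marks the root; direction vectors are
#' normalized on read by [build_tree()].
#'
#' @param path File path.
#' @return `read_morphometry` returns the table as a data frame.
#' @export
read_morphometry <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character",
                                      parent_id = "character"))
  m
}

#' @rdname read_morphometry
#' @param table Morphometry data frame.
#' @export
write_morphometry <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
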