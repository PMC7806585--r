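#' Recipe for generated airway morphometry tables
#'
#' Defines the study geometry that the generators emulate: a symmetric
#' (Weibel-style) binary tree, or the characteristic asymmetric tree to
#' generation 6 with five lobar subtrees and a right-favouring conductance
#' asymmetry whose equal-pressure flow split lands on the published lobar
#' ventilation fractions.
#'
#' The characteristic mode is deterministic: the main-branch dimensions are
#' fixed anatomical anchors (right main bronchus 1.30 cm diameter / 2.2 cm
#' long, left main bronchus 1.17 / 5.0, bronchus intermedius 1.00 / 2.5,
#' right-lower-lobe root 0.90 cm) and the remaining lobar-root diameters are
#' derived in closed form so the Poiseuille network reproduces the target
#' split. Within each lobar subtree branches follow the diameter law with
#' the recipe exponent and a length/diameter ratio of 3.
#'
#' @param max_generation Deepest generation (trachea = 0). Default 6.
#' @param mode `"weibel_symmetric"` or `"characteristic_asymmetric"`.
#' @param x_n Diameter-law exponent. Default 3.
#' @param trachea A [trachea_spec()].
#' @param lobar_fractions Target ventilation partition for the
#'   characteristic mode; default [reference_lobar_fractions()].
#' @param branching_angle Daughter half-angle from the parent axis, degrees.
#' @param length_diameter_ratio Branch length / diameter below the named
#'   central airways. Default 3.
#' @param seed Integer seed recorded with the recipe (the generators are
#'   deterministic; the seed matters for [make_injection()] and
#'   [perturb_morphometry()]).
#' @return Object of class `tree_recipe`.
#' @export
tree_recipe <- function(max_generation = 6,
                        mode = c("characteristic_asymmetric",
                                 "weibel_symmetric"),
                        x_n = 3,
                        trachea = trachea_spec(),
                        lobar_fractions = reference_lobar_fractions(),
                        branching_angle = 35,
                        length_diameter_ratio = 3,
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(max_generation >= 0, x_n > 0, length_diameter_ratio > 0)
  if (abs(sum(lobar_fractions) - 1) > 1e-9) {
    stop("lobar fractions must sum to 1")
  }
  structure(list(max_generation = max_generation, mode = mode, x_n = x_n,
                 trachea = trachea, lobar_fractions = lobar_fractions,
                 branching_angle = branching_angle,
                 length_diameter_ratio = length_diameter_ratio,
                 seed = as.integer(seed)),
            class = "tree_recipe")
}

# Rodrigues rotation of v about unit axis n by ang (radians)
rotate3 <- function(v, n, ang) {
  v * cos(ang) +
    c(n[2] * v[3] - n[3] * v[2],
      n[3] * v[1] - n[1] * v[3],
      n[1] * v[2] - n[2] * v[1]) * sin(ang) +
    n * sum(n * v) * (1 - cos(ang))
}

# two daughter directions at +-theta about an axis alternating with parity
bifurcate_dir <- function(u, generation, theta_deg) {
  a <- if (generation %% 2 == 0) c(0, 1, 0) else c(1, 0, 0)
  n <- c(u[2] * a[3] - u[3] * a[2],
         u[3] * a[1] - u[1] * a[3],
         u[1] * a[2] - u[2] * a[1])
  if (sqrt(sum(n^2)) < 1e-8) {
    a <- if (generation %% 2 == 0) c(1, 0, 0) else c(0, 1, 0)
    n <- c(u[2] * a[3] - u[3] * a[2],
           u[3] * a[1] - u[1] * a[3],
           u[1] * a[2] - u[2] * a[1])
  }
  n <- n / sqrt(sum(n^2))
  th <- theta_deg * pi / 180
  list(rotate3(u, n, th), rotate3(u, n, -th))
}

empty_morpho <- function() {
  data.frame(id = character(), parent_id = character(),
             generation = integer(), length_cm = numeric(),
             diameter_cm = numeric(), dx = numeric(), dy = numeric(),
             dz = numeric(), lobe = character(), region = character(),
             stringsAsFactors = FALSE)
}

morpho_row <- function(id, parent, gen, len, dia, dir, lobe) {
  data.frame(id = id, parent_id = if (is.na(parent)) "" else parent,
             generation = as.integer(gen), length_cm = len,
             diameter_cm = dia, dx = dir[1], dy = dir[2], dz = dir[3],
             lobe = lobe, region = region_for_generation(gen),
             stringsAsFactors = FALSE)
}

# expand a symmetric subtree below a root row down to max_gen
expand_symmetric <- function(id, gen, dia, dir, lobe, recipe, ratio_fun) {
  rows <- empty_morpho()
  if (gen >= recipe$max_generation) return(rows)
  dirs <- bifurcate_dir(dir, gen, recipe$branching_angle)
  d_child <- dia * 2^(-1 / recipe$x_n)
  for (k in 1:2) {
    cid <- paste0(id, c("R", "L")[k])
    clobe <- ratio_fun(cid, gen + 1L, lobe)
    rows <- rbind(rows,
                  morpho_row(cid, id, gen + 1L,
                             recipe$length_diameter_ratio * d_child,
                             d_child, dirs[[k]], clobe),
                  expand_symmetric(cid, gen + 1L, d_child, dirs[[k]],
                                   clobe, recipe, ratio_fun))
  }
  rows
}

weibel_lobe <- function(path) {
  # path = string of R/L letters from the trachea
  n <- nchar(path)
  if (n == 0L) return("none")
  s <- strsplit(path, "")[[1]]
  if (s[1] == "R") {
    if (n >= 2 && s[2] == "R") return("RUL")
    if (n >= 3 && s[3] == "R") return("RML")
    return("RLL")
  }
  if (n >= 2 && s[2] == "R") return("LUL")
  "LLL"
}

#' Generate a symmetric (Weibel-style) morphometry table
#'
#' A complete symmetric binary tree: diameters follow the diameter law with
#' the recipe exponent exactly (each daughter is \eqn{2^{-1/x_n}} of its
#' parent), lengths are `length_diameter_ratio` times the diameter, and the
#' trachea takes its dimensions from the recipe's [trachea_spec()]. The
#' generator is fully deterministic. Terminal branches are labelled with the
#' five lobes by their ancestry (right subtree: RUL / RML / RLL; left: LUL /
#' LLL) so left and right halves stay geometrically mirrored.
#'
#' @param recipe A [tree_recipe()] (its `mode` is ignored here).
#' @return Morphometry data frame in the CSV dialect of [build_tree()].
#' @export
#' @examples
#' nrow(make_weibel_table(tree_recipe(max_generation = 6))) # 127
make_weibel_table <- function(recipe = tree_recipe(mode = "weibel_symmetric")) {
  tr <- recipe$trachea
  root_dir <- c(0, 0, -1)
  lobe_fun <- function(cid, gen, parent_lobe) {
    if (gen == recipe$max_generation) weibel_lobe(sub("^g0", "", cid))
    else "none"
  }
  root_lobe <- if (recipe$max_generation == 0L) "none" else "none"
  rows <- rbind(
    morpho_row("g0", NA, 0L, tr$length, tr$diameter, root_dir, root_lobe),
    expand_symmetric("g0", 0L, tr$diameter, root_dir, "none", recipe,
                     lobe_fun)
  )
  rownames(rows) <- NULL
  rows
}

# closed-form lobar-root diameters reproducing the target equal-pressure
# split on the Poiseuille network (resistances in proportional units L/d^4;
# a lobar subtree rooted at generation k with L = 3d and the x_n = 3 halving
# law has effective resistance (7-k) * 3/d^3, i.e. conductance d^3/(3(7-k)))
characteristic_dimensions <- function(f = reference_lobar_fractions(),
                                      d_RMB = 1.30, L_RMB = 2.2,
                                      d_LMB = 1.17, L_LMB = 5.0,
                                      d_BI = 1.00, L_BI = 2.5,
                                      d_RLL = 0.90) {
  R_RMB <- L_RMB / d_RMB^4
  R_LMB <- L_LMB / d_LMB^4
  R_BI <- L_BI / d_BI^4
  fR <- f[["RUL"]] + f[["RML"]] + f[["RLL"]]
  fL <- f[["LUL"]] + f[["LLL"]]

  G_RLL <- d_RLL^3 / 12                        # root at generation 3
  G_RML <- (f[["RML"]] / f[["RLL"]]) * G_RLL
  d_RML <- (12 * G_RML)^(1 / 3)
  G_bib <- 1 / (R_BI + 1 / (G_RML + G_RLL))    # BI + its two lobes
  G_RUL <- (f[["RUL"]] / (f[["RML"]] + f[["RLL"]])) * G_bib
  d_RUL <- (15 * G_RUL)^(1 / 3)                # root at generation 2
  R_right <- R_RMB + 1 / (G_RUL + G_bib)
  R_left <- R_right * fR / fL
  if (R_left <= R_LMB) stop("left main bronchus too resistive for target split")
  G_leftpar <- 1 / (R_left - R_LMB)
  G_LUL <- (f[["LUL"]] / fL) * G_leftpar
  G_LLL <- (f[["LLL"]] / fL) * G_leftpar
  list(d_RMB = d_RMB, L_RMB = L_RMB, d_LMB = d_LMB, L_LMB = L_LMB,
       d_BI = d_BI, L_BI = L_BI,
       d_RUL = d_RUL, d_RML = d_RML, d_RLL = d_RLL,
       d_LUL = (15 * G_LUL)^(1 / 3), d_LLL = (15 * G_LLL)^(1 / 3))
}

#' Generate the characteristic asymmetric morphometry table
#'
#' The packaged stand-in for a cast-derived tracheobronchial geometry: an
#' asymmetric tree to generation 6 whose 64 peripheral outlets carry the
#' five lobe labels (RUL and LUL/LLL roots at generation 2, RML and RLL at
#' generation 3 below the bronchus intermedius). The named central airways
#' use fixed anatomical dimensions; the five lobar-root diameters are
#' derived in closed form from the recipe's target lobar fractions, so the
#' equal-pressure Poiseuille split reproduces them by construction (the
#' right lung receiving 57% of ventilation). Deterministic for any seed.
#'
#' @param recipe A [tree_recipe()] in `characteristic_asymmetric` mode.
#' @return Morphometry data frame in the CSV dialect of [build_tree()].
#' @export
#' @examples
#' tab <- make_characteristic_table()
#' sum(!tab$id %in% tab$parent_id) # 64 terminals
make_characteristic_table <- function(recipe = tree_recipe()) {
  if (recipe$mode != "characteristic_asymmetric") {
    stop("recipe mode must be characteristic_asymmetric")
  }
  if (recipe$max_generation != 6L) {
    stop("the characteristic table is defined to generation 6")
  }
  dims <- characteristic_dimensions(recipe$lobar_fractions)
  tr <- recipe$trachea
  deg <- pi / 180
  dir_T <- c(0, 0, -1)
  dir_RMB <- c(sin(35 * deg), 0, -cos(35 * deg))
  dir_LMB <- c(-sin(50 * deg), 0, -cos(50 * deg))

  lobe_const <- function(lobe) function(cid, gen, parent_lobe) lobe

  sub_lobe <- function(id, gen, dia, dir, lobe, recipe) {
    rbind(morpho_row(id, NA, gen, recipe$length_diameter_ratio * dia, dia,
                     dir, lobe),
          expand_symmetric(id, gen, dia, dir, lobe, recipe,
                           lobe_const(lobe)))
  }
  fix_parent <- function(rows, root_id, parent) {
    rows$parent_id[rows$id == root_id] <- parent
    rows
  }

  d2 <- bifurcate_dir(dir_RMB, 1L, recipe$branching_angle)
  d2L <- bifurcate_dir(dir_LMB, 1L, recipe$branching_angle)
  d3 <- bifurcate_dir(d2[[2]], 2L, recipe$branching_angle)

  rows <- rbind(
    morpho_row("T", NA, 0L, tr$length, tr$diameter, dir_T, "none"),
    morpho_row("RMB", "T", 1L, dims$L_RMB, dims$d_RMB, dir_RMB, "none"),
    morpho_row("LMB", "T", 1L, dims$L_LMB, dims$d_LMB, dir_LMB, "none"),
    morpho_row("BI", "RMB", 2L, dims$L_BI, dims$d_BI, d2[[2]], "none"),
    fix_parent(sub_lobe("RULr", 2L, dims$d_RUL, d2[[1]], "RUL", recipe),
               "RULr", "RMB"),
    fix_parent(sub_lobe("RMLr", 3L, dims$d_RML, d3[[1]], "RML", recipe),
               "RMLr", "BI"),
    fix_parent(sub_lobe("RLLr", 3L, dims$d_RLL, d3[[2]], "RLL", recipe),
               "RLLr", "BI"),
    fix_parent(sub_lobe("LULr", 2L, dims$d_LUL, d2L[[1]], "LUL", recipe),
               "LULr", "LMB"),
    fix_parent(sub_lobe("LLLr", 2L, dims$d_LLL, d2L[[2]], "LLL", recipe),
               "LLLr", "LMB")
  )
  # lobe labels are carried by every branch of a lobar subtree; the central
  # airways (trachea, main bronchi, bronchus intermedius) stay "none"
  rownames(rows) <- NULL
  rows
}

#' The packaged characteristic airway model
#'
#' Convenience constructor: the characteristic morphometry table (from the
#' packaged fixture when installed, else regenerated — the two are
#' byte-identical), the scaled upper airway and the ringed trachea,
#' assembled into one `airway_tree`.
#'
#' @param recipe A [tree_recipe()].
#' @param upper Attach the scaled upper airway. Default `TRUE`.
#' @param rings Annotate cartilaginous rings. Default `TRUE`.
#' @return An `airway_tree` with 64 peripheral outlets.
#' @export
#' @examples
#' tree <- characteristic_tree()
#' nrow(terminal_branches(tree)) # 64
characteristic_tree <- function(recipe = tree_recipe(), upper = TRUE,
                                rings = TRUE) {
  fixture <- system.file("extdata", "characteristic_tree.csv",
                         package = "airwaydep")
  tab <- if (nzchar(fixture) && identical(recipe, tree_recipe())) {
    read_morphometry(fixture)
  } else {
    make_characteristic_table(recipe)
  }
  ua <- if (upper) build_upper_airway(cheng_section_table(), recipe$trachea)
  build_tree(tab,
             bif_spec = bifurcation_spec(x_n = recipe$x_n),
             trachea = recipe$trachea,
             upper_airway = ua,
             rings = if (rings) ring_spec())
}

#' Timed aerosol bolus injected at the mouth
#'
#' `n_particles` starting positions uniformly distributed on the oral disk,
#' drawn by seeded inverse-transform sampling (radius proportional to the
#' square root of a uniform variate), reproducible per seed.
#'
#' @param n_particles Count, default 2720.
#' @param disk_diameter Disk diameter at the oral inlet, cm. Default 2.16.
#' @param t_inj Injection time within the inhalation phase, s.
#' @param seed Integer seed.
#' @return Object of class `injection_set` with a positions data frame
#'   (`x_cm`, `y_cm`).
#' @export
make_injection <- function(n_particles = 2720, disk_diameter = 2.16,
                           t_inj = 0, seed = 1L) {
  stopifnot(n_particles > 0, disk_diameter > 0, t_inj >= 0)
  R <- disk_diameter / 2
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  r <- R * sqrt(stats::runif(n_particles))
  th <- 2 * pi * stats::runif(n_particles)
  structure(list(n_particles = as.integer(n_particles),
                 disk_diameter = disk_diameter,
                 t_inj = t_inj, seed = as.integer(seed),
                 positions = data.frame(x_cm = r * cos(th),
                                        y_cm = r * sin(th))),
            class = "injection_set")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Perturb a morphometry table with multiplicative lognormal noise
#'
#' Robustness fixture generator: diameters and lengths are multiplied by
#' unit-mean lognormal factors with coefficient of variation `cv`
#' (positivity is preserved by construction); the branching structure is
#' untouched. Seeded and reproducible.
#'
#' @param table Morphometry data frame.
#' @param cv Coefficient of variation, >= 0. `cv = 0` is the identity.
#' @param seed Integer seed.
#' @return Perturbed morphometry data frame.
#' @export
perturb_morphometry <- function(table, cv, seed = 1L) {
  stopifnot(cv >= 0)
  if (cv == 0) return(table)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  n <- nrow(table)
  table$diameter_cm <- table$diameter_cm *
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  table$length_cm <- table$length_cm *
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  table
}
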