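#' Air properties
#'
#' Constant-property incompressible air used throughout the flow and
#' transport computations.
#'
#' @param density kg/m^3, default 1.225.
#' @param viscosity kg/(m s), default 1.7894e-5.
#' @return Object of class `gas_properties`.
#' @export
gas_properties <- function(density = 1.225, viscosity = 1.7894e-5) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "gas_properties")
}

#' Sedentary sinusoidal breathing cycle
#'
#' A 4 s cycle with equal inhalation and exhalation phases; the signed inlet
#' flow is `peak_flow * sin(2 pi t / period)`, positive during inhalation
#' `[0, T/2]`. For a half-sine, the peak is pi/2 times the mean inspiratory
#' flow: 6 L/min mean gives 9.42 L/min peak.
#'
#' @param period_T Cycle period, s. Default 4.
#' @param mean_inspiratory_flow Mean inhalation flow, L/min. Default 6.
#' @return Object of class `breathing_cycle` with the derived `peak_flow`.
#' @export
#' @examples
#' signif(breathing_cycle()$peak_flow, 3) # 9.42
breathing_cycle <- function(period_T = 4, mean_inspiratory_flow = 6) {
  stopifnot(period_T > 0, mean_inspiratory_flow >= 0)
  structure(list(period_T = period_T,
                 mean_inspiratory_flow = mean_inspiratory_flow,
                 peak_flow = mean_inspiratory_flow * pi / 2),
            class = "breathing_cycle")
}

#' Instantaneous inlet flow of the breathing waveform
#'
#' @param cycle A [breathing_cycle()].
#' @param t Time(s) in seconds, >= 0.
#' @return Signed flow in L/min (+ inspiratory).
#' @export
#' @examples
#' waveform_flow(breathing_cycle(), 1) # inspiratory peak
waveform_flow <- function(cycle, t) {
  stopifnot(all(t >= 0))
  cycle$peak_flow * sin(2 * pi * t / cycle$period_T)
}

#' Poiseuille resistance of a circular tube
#'
#' \eqn{R = 128 \mu L / (\pi d^4)} in SI units.
#'
#' @param length Tube length, m.
#' @param diameter Tube diameter, m.
#' @param gas [gas_properties()].
#' @return Resistance in Pa s / m^3.
#' @export
poiseuille_resistance <- function(length, diameter, gas = gas_properties()) {
  if (any(length <= 0)) stop("length must be > 0")
  if (any(diameter <= 0)) stop("diameter must be > 0")
  128 * gas$viscosity * length / (pi * diameter^4)
}

#' Poiseuille resistance of an elliptical tube
#'
#' Exact laminar solution: \eqn{R = 4 \mu L (a^2+b^2) / (\pi a^3 b^3)}.
#'
#' @param a,b Semi-axes, m.
#' @param length Length, m.
#' @param gas [gas_properties()].
#' @return Resistance in Pa s / m^3.
#' @export
ellipse_resistance <- function(a, b, length, gas = gas_properties()) {
  stopifnot(a > 0, b > 0, length > 0)
  4 * gas$viscosity * length * (a^2 + b^2) / (pi * a^3 * b^3)
}

#' Minor-loss and entrance-effect configuration
#'
#' Pure Poiseuille resistance undershoots the pressure drop of a branching
#' network at physiological Reynolds numbers, because entrance lengths are
#' comparable to branch lengths and bifurcations dissipate extra energy.
#' Two documented corrections are provided: the Pedley entrance-flow factor
#' \eqn{Z = \max(1, (C/(4\sqrt 2))\sqrt{Re\, d/L})} multiplying the viscous
#' drop of each branch, and dynamic-head junction losses
#' \eqn{K \rho U |U| / 2} applied at each bifurcation entry and at the
#' larynx (glottal jet).
#'
#' @param pedley Apply the Pedley factor to branches. Default `TRUE`.
#' @param pedley_C Pedley constant, default 1.85.
#' @param K_bifurcation Junction loss coefficient per bifurcation entry.
#'   The default 2.2 is the calibrated value: together with the Pedley
#'   factor it reproduces the reference tracheal-inlet to generation-6
#'   static pressure drop (about 4.5 Pa) at the sedentary inspiratory peak
#'   on the characteristic tree.
#' @param K_larynx Glottal jet loss coefficient, default 1.0.
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(pedley = TRUE, pedley_C = 1.85,
                        K_bifurcation = 2.2, K_larynx = 1.0) {
  stopifnot(pedley_C >= 0, K_bifurcation >= 0, K_larynx >= 0)
  structure(list(pedley = isTRUE(pedley), pedley_C = pedley_C,
                 K_bifurcation = K_bifurcation, K_larynx = K_larynx),
            class = "loss_config")
}

#' Outlet boundary condition for the network solve
#'
#' `equal_pressure`: all 2^g peripheral outlets share one pressure and the
#' flow split emerges from the network resistances. `lobar_fractions`: the
#' terminal flows are pinned to a prescribed per-lobe partition, distributed
#' equally among the terminals of each lobe.
#'
#' @param mode `"equal_pressure"` or `"lobar_fractions"`.
#' @param fractions Named numeric (RUL, RML, RLL, LUL, LLL) summing to 1;
#'   required in `lobar_fractions` mode.
#' @return Object of class `outlet_bc`.
#' @export
outlet_bc <- function(mode = c("equal_pressure", "lobar_fractions"),
                      fractions = NULL) {
  mode <- match.arg(mode)
  if (mode == "lobar_fractions") {
    if (is.null(fractions) || is.null(names(fractions))) {
      stop("lobar_fractions mode needs a named fractions vector")
    }
    if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  }
  structure(list(mode = mode, fractions = fractions), class = "outlet_bc")
}

#' Published lobar ventilation fractions
#'
#' The reference per-lobe ventilation partition (RUL 19, RML 9, RLL 29,
#' LUL 26, LLL 17 percent) used both as the target of the characteristic
#' geometry and as the prescribed split in `lobar_fractions` mode.
#'
#' @return Named numeric fractions summing to 1.
#' @export
reference_lobar_fractions <- function() {
  c(RUL = 0.19, RML = 0.09, RLL = 0.29, LUL = 0.26, LLL = 0.17)
}

#' Reynolds number of a duct section
#'
#' \eqn{Re = \rho U D_h / \mu} with mean velocity `U = Q / CSA`.
#'
#' @param Q_lpm Volumetric flow, L/min (sign ignored).
#' @param csa_cm2 Cross-sectional area, cm^2.
#' @param dh_cm Hydraulic diameter, cm.
#' @param gas [gas_properties()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(Q_lpm, csa_cm2, dh_cm, gas = gas_properties()) {
  stopifnot(all(csa_cm2 > 0), all(dh_cm > 0))
  U <- abs(Q_lpm) / 60000 / (csa_cm2 * 1e-4)
  gas$density * U * (dh_cm / 100) / gas$viscosity
}

# ---- internal: branch hydraulics -------------------------------------------

branch_csa_cm2 <- function(tree) {
  b <- tree$branches
  csa <- pi * (b$diameter_cm / 2)^2
  # trachea: effective C-shape area
  csa[b$generation == 0L] <- tree$trachea$csa_effective
  csa
}

branch_dh_cm <- function(tree) {
  b <- tree$branches
  dh <- b$diameter_cm
  tr <- b$generation == 0L
  dh[tr] <- 4 * tree$trachea$csa_effective / c_shape_perimeter(tree$trachea)
  dh
}

branch_resistance <- function(tree, gas) {
  b <- tree$branches
  d <- b$diameter_cm
  if (isTRUE(tree$ring_effective_roughness) && !is.null(tree$rings)) {
    tgt <- b$generation <= 1L
    d[tgt] <- d[tgt] - 2 * tree$rings$depth_d / 10
  }
  poiseuille_resistance(b$length_cm / 100, d / 100, gas)
}

#' Per-branch flow fractions of the inlet flow
#'
#' In `equal_pressure` mode the split is computed from the linear Poiseuille
#' network by recursive effective resistance (daughter flows inversely
#' proportional to daughter subtree resistance); in `lobar_fractions` mode
#' terminal fractions are pinned and aggregated upward. The fractions are
#' flow-independent, which is what makes the quasi-steady cycle a scaling of
#' one solve.
#'
#' @param tree An `airway_tree`.
#' @param bc An [outlet_bc()].
#' @param gas [gas_properties()].
#' @return Named numeric: fraction of the inlet flow carried by each branch.
#' @export
flow_split <- function(tree, bc = outlet_bc(), gas = gas_properties()) {
  b <- tree$branches
  ids <- b$id
  R <- stats::setNames(branch_resistance(tree, gas), ids)
  kids <- tree$children
  frac <- stats::setNames(rep(NA_real_, nrow(b)), ids)
  root <- ids[is.na(b$parent_id)]

  if (bc$mode == "equal_pressure") {
    Reff <- stats::setNames(rep(NA_real_, nrow(b)), ids)
    for (i in order(b$generation, decreasing = TRUE)) {
      id <- b$id[i]
      ck <- kids[[id]]
      Reff[id] <- if (is.null(ck) || !length(ck)) R[id]
      else R[id] + 1 / sum(1 / Reff[ck])
    }
    frac[root] <- 1
    for (i in order(b$generation)) {
      id <- b$id[i]
      ck <- kids[[id]]
      if (!is.null(ck) && length(ck)) {
        g <- 1 / Reff[ck]
        frac[ck] <- frac[id] * g / sum(g)
      }
    }
  } else {
    term <- terminal_branches(tree)
    if (!all(term$lobe %in% names(bc$fractions))) {
      stop("lobar_fractions must cover every terminal lobe")
    }
    n_lobe <- table(term$lobe)
    frac[term$id] <- bc$fractions[term$lobe] / as.numeric(n_lobe[term$lobe])
    for (i in order(b$generation, decreasing = TRUE)) {
      id <- b$id[i]
      ck <- kids[[id]]
      if (!is.null(ck) && length(ck)) frac[id] <- sum(frac[ck])
    }
  }
  frac
}

pedley_factor <- function(Re, d_m, L_m, losses) {
  if (!losses$pedley) return(rep(1, length(Re)))
  pmax(1, losses$pedley_C / (4 * sqrt(2)) * sqrt(Re * d_m / L_m))
}

#' Steady laminar network solve
#'
#' Solves the quasi-steady flow distribution on the airway network at a
#' given inlet flow. Branch flows follow [flow_split()]; node static
#' pressures (Pa, mouth = 0) accumulate the elliptical-Poiseuille drop of
#' the upper-airway sections, the Pedley-corrected Poiseuille drop of every
#' branch, and the configured minor losses. Mass is conserved exactly at
#' every interior node by construction.
#'
#' @param tree An `airway_tree` (optionally carrying an upper airway).
#' @param Q_in Inlet flow, L/min; signed (+ inspiratory).
#' @param bc [outlet_bc()].
#' @param gas [gas_properties()].
#' @param losses [loss_config()].
#' @param time Time stamp carried by the snapshot, s.
#' @return Object of class `flow_solution`: per-branch flow (L/min),
#'   velocity (m/s), Reynolds number; per-section upper-airway rows; named
#'   `node_pressure` vector (`mouth`, section ends, `trachea_inlet`,
#'   `node_<id>` at each branch distal end).
#' @export
#' @examples
#' tree <- characteristic_tree()
#' sol <- solve_steady(tree, 6)
#' lobar_ventilation(sol)
solve_steady <- function(tree, Q_in, bc = outlet_bc(),
                         gas = gas_properties(), losses = loss_config(),
                         time = NA_real_) {
  stopifnot(inherits(tree, "airway_tree"))
  b <- tree$branches
  frac <- flow_split(tree, bc, gas)
  Q_b <- frac * Q_in                         # L/min, signed
  csa <- branch_csa_cm2(tree)
  dh <- branch_dh_cm(tree)
  U <- Q_b / 60000 / (csa * 1e-4)            # m/s signed
  Re <- gas$density * abs(U) * (dh / 100) / gas$viscosity

  R <- branch_resistance(tree, gas)
  Z <- pedley_factor(Re, b$diameter_cm / 100, b$length_cm / 100, losses)
  Q_si <- Q_b / 60000
  dP_visc <- Z * R * Q_si
  dP_minor <- ifelse(b$generation >= 1L,
                     losses$K_bifurcation * gas$density * U * abs(U) / 2, 0)

  node_pressure <- c(mouth = 0)
  P_cursor <- 0
  upper <- NULL
  if (!is.null(tree$upper_airway)) {
    rows <- lapply(tree$upper_airway, function(s) {
      Rs <- ellipse_resistance(s$semi_axis_a / 100, s$semi_axis_b / 100,
                               s$length / 100, gas)
      Us <- Q_in / 60000 / (s$csa * 1e-4)
      dP <- Rs * Q_in / 60000
      if (s$name == "larynx") dP <- dP + losses$K_larynx * gas$density * Us * abs(Us) / 2
      list(name = s$name, flow_lpm = Q_in, velocity_mps = Us,
           reynolds = gas$density * abs(Us) * (s$hydraulic_diameter / 100) /
             gas$viscosity,
           dP = dP)
    })
    for (r in rows) {
      P_cursor <- P_cursor - r$dP
      node_pressure[paste0(r$name, "_end")] <- P_cursor
    }
    upper <- do.call(rbind, lapply(rows, function(r)
      data.frame(name = r$name, flow_lpm = r$flow_lpm,
                 velocity_mps = r$velocity_mps, reynolds = r$reynolds)))
  }
  node_pressure["trachea_inlet"] <- P_cursor

  idx <- stats::setNames(seq_len(nrow(b)), b$id)
  P_end <- stats::setNames(rep(NA_real_, nrow(b)), b$id)
  for (i in order(b$generation)) {
    p0 <- if (is.na(b$parent_id[i])) P_cursor else P_end[b$parent_id[i]]
    P_end[i] <- p0 - dP_visc[i] - dP_minor[i]
  }
  node_pressure <- c(node_pressure,
                     stats::setNames(P_end, paste0("node_", b$id)))

  structure(list(
    time = time,
    Q_in_lpm = Q_in,
    branches = data.frame(id = b$id, generation = b$generation,
                          lobe = b$lobe, region = b$region,
                          flow_lpm = unname(Q_b),
                          velocity_mps = unname(U),
                          reynolds = unname(Re),
                          stringsAsFactors = FALSE),
    upper = upper,
    node_pressure = node_pressure,
    fractions = frac,
    parents = unique(b$parent_id[!is.na(b$parent_id)]),
    bc = bc$mode
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow_solution: Q_in = %.3f L/min%s, %d branches\n",
              x$Q_in_lpm,
              if (!is.na(x$time)) sprintf(" at t = %.2f s", x$time) else "",
              nrow(x$branches)))
  invisible(x)
}

#' Quasi-steady transient solve over the breathing cycle
#'
#' Each snapshot is [solve_steady()] at the instantaneous waveform flow;
#' exhalation reverses every branch flow. `dt` must divide the half-period
#' evenly so the inspiratory peak and the zero crossings are sampled.
#'
#' @param tree An `airway_tree`.
#' @param cycle [breathing_cycle()].
#' @param bc,gas,losses As in [solve_steady()].
#' @param dt Time step, s. Default 0.01.
#' @return Object of class `flow_series`: `times` and list `solutions`.
#' @export
solve_transient <- function(tree, cycle = breathing_cycle(),
                            bc = outlet_bc(), gas = gas_properties(),
                            losses = loss_config(), dt = 0.01) {
  if (dt <= 0) stop("dt must be > 0")
  half <- cycle$period_T / 2
  n <- half / dt
  if (abs(n - round(n)) > 1e-9) stop("dt must divide T/2 evenly")
  times <- seq(0, cycle$period_T, by = dt)
  sols <- lapply(times, function(t)
    solve_steady(tree, waveform_flow(cycle, t), bc, gas, losses, time = t))
  structure(list(times = times, solutions = sols, cycle = cycle),
            class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("flow_series: %d snapshots over %.1f s cycle\n",
              length(x$times), x$cycle$period_T))
  invisible(x)
}

#' Static pressure difference between two nodes
#'
#' @param sol A `flow_solution`.
#' @param node_a,node_b Node names as in `sol$node_pressure` (e.g. `"mouth"`,
#'   `"trachea_inlet"`, `"node_<branch id>"`).
#' @return `pressure(node_a) - pressure(node_b)` in Pa.
#' @export
pressure_drop <- function(sol, node_a, node_b) {
  p <- sol$node_pressure
  if (!node_a %in% names(p)) stop("unknown node: ", node_a)
  if (!node_b %in% names(p)) stop("unknown node: ", node_b)
  unname(p[node_a] - p[node_b])
}

#' Mean static pressure at the peripheral outlets
#'
#' @param sol A `flow_solution`.
#' @param tree The `airway_tree` it was solved on.
#' @return Mean node pressure (Pa) over the terminal branch distal ends.
#' @export
mean_outlet_pressure <- function(sol, tree) {
  term <- terminal_branches(tree)
  mean(sol$node_pressure[paste0("node_", term$id)])
}

#' Lobar ventilation of a flow solution
#'
#' Partition of the outlet flow among the five lobes, plus the left/right
#' totals, as fractions of the total outflow.
#'
#' @param sol A `flow_solution`.
#' @return List with `lobes` (named fractions) and `right`, `left`.
#' @export
lobar_ventilation <- function(sol) {
  br <- sol$branches
  # terminal = branches that are nobody's parent; they carry the lobe labels
  term <- br[br$lobe %in% LOBES & !(br$id %in% sol$parents), , drop = FALSE]
  tot <- sum(term$flow_lpm)
  lob <- tapply(term$flow_lpm, factor(term$lobe, levels = LOBES), sum,
                default = 0) / tot
  lob <- stats::setNames(as.numeric(lob), LOBES)
  list(lobes = lob,
       right = sum(lob[c("RUL", "RML", "RLL")]),
       left = sum(lob[c("LUL", "LLL")]))
}

#' Mass-conservation residual of a flow solution
#'
#' Maximum relative flow imbalance over the interior nodes (parent flow vs
#' summed daughter flows).
#'
#' @param sol A `flow_solution`.
#' @param tree The `airway_tree` it was solved on.
#' @return Largest `|Q_parent - sum(Q_children)| / max(|Q_parent|, tiny)`.
#' @export
flow_residuals <- function(sol, tree) {
  q <- stats::setNames(sol$branches$flow_lpm, sol$branches$id)
  res <- 0
  for (id in names(tree$children)) {
    ck <- tree$children[[id]]
    if (!length(ck)) next
    num <- abs(q[id] - sum(q[ck]))
    den <- max(abs(q[id]), 1e-300)
    res <- max(res, num / den)
  }
  res
}
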