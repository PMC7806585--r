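#' Aerosol particle specification
#'
#' Inert spherical particles with water-like density; the Cunningham slip
#' correction is ~1 for the micrometre sizes studied (3-25 um).
#'
#' @param diameter_um Particle diameter, micrometres (> 0).
#' @param density Particle density, kg/m^3. Default 998.2 (water).
#' @param cunningham Cunningham slip correction factor, >= 1. Default 1.
#' @return Object of class `particle_spec`.
#' @export
#' @examples
#' particle_spec(7)
particle_spec <- function(diameter_um, density = 998.2, cunningham = 1) {
  stopifnot(diameter_um > 0, density > 0)
  if (cunningham < 1) stop("Cunningham factor must be >= 1")
  structure(list(diameter_um = diameter_um, density = density,
                 cunningham = cunningham), class = "particle_spec")
}

#' Particle Stokes number
#'
#' \eqn{St = \rho_p d_p^2 U C_c / (36 \mu R_0)} with the mean velocity `U`
#' and average radius `R_0` of the parent airway, all in SI units. St
#' measures the ratio of the particle stopping distance to the airway
#' scale: large St particles deviate from streamlines and impact.
#'
#' @param particle A [particle_spec()].
#' @param U Mean airflow velocity in the parent branch, m/s (>= 0).
#' @param R0 Average parent-branch radius, m (> 0).
#' @param gas [gas_properties()].
#' @return Dimensionless Stokes number.
#' @export
stokes_number <- function(particle, U, R0, gas = gas_properties()) {
  if (any(U < 0)) stop("U must be >= 0")
  if (any(R0 <= 0)) stop("R0 must be > 0")
  dp <- particle$diameter_um * 1e-6
  particle$density * dp^2 * U * particle$cunningham /
    (36 * gas$viscosity * R0)
}

#' Impaction parameter
#'
#' \eqn{IP = \rho d_p^2 Q} in the conventional aerosol units: density in
#' g/cm^3, diameter in um, flow in L/min.
#'
#' @param particle A [particle_spec()].
#' @param Q_lpm Flow rate, L/min (>= 0).
#' @return IP in g um^2 L / (cm^3 min).
#' @export
#' @examples
#' impaction_parameter(particle_spec(7), 6) # ~293.5
impaction_parameter <- function(particle, Q_lpm) {
  if (any(Q_lpm < 0)) stop("Q must be >= 0")
  (particle$density / 1000) * particle$diameter_um^2 * Q_lpm
}

#' Deposition-efficiency correlation for one region
#'
#' Empirical single-region deposition efficiency, either
#' `stokes_exp`: \eqn{DE = 1 - \exp(-a\,St^b)} (tracheobronchial regions) or
#' `ip_exp`: \eqn{DE = 1 - \exp(-a\,IP)} (upper airway). The constants `a`,
#' `b` differ by airway region and ship in a documented configuration file
#' ([default_correlations()]); none are hard-coded.
#'
#' @param region Region label the correlation applies to.
#' @param form `"stokes_exp"` or `"ip_exp"`.
#' @param a Dimensionless constant, >= 0.
#' @param b Exponent, > 0; required for `stokes_exp`.
#' @param source Free-text provenance note.
#' @return Object of class `de_correlation`.
#' @export
de_correlation <- function(region, form = c("stokes_exp", "ip_exp"),
                           a, b = NA_real_, source = "") {
  form <- match.arg(form)
  if (a < 0) stop("a must be >= 0")
  if (form == "stokes_exp" && (is.na(b) || b <= 0)) {
    stop("stokes_exp needs b > 0")
  }
  structure(list(region = region, form = form, a = a, b = b,
                 source = source), class = "de_correlation")
}

#' @rdname de_correlation
#' @param path Optional YAML file with a `deposition:` block; defaults to
#'   the configuration shipped with the package.
#' @return `default_correlations` returns a named list of `de_correlation`
#'   objects covering every airway region.
#' @export
default_correlations <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "deposition_correlations.yaml",
                        package = "airwaydep")
  }
  cfg <- yaml::read_yaml(path)
  block <- if (!is.null(cfg$deposition)) cfg$deposition else cfg
  out <- lapply(names(block), function(r) {
    e <- block[[r]]
    de_correlation(r, e$form, e$a, if (is.null(e$b)) NA_real_ else e$b,
                   if (is.null(e$source)) "" else e$source)
  })
  stats::setNames(out, names(block))
}

#' Evaluate the deposition-efficiency correlations
#'
#' @param St Stokes number(s), >= 0.
#' @param IP Impaction parameter(s), >= 0.
#' @param corr A [de_correlation()] of the matching form.
#' @return Deposition efficiency in [0, 1), monotone non-decreasing in the
#'   predictor.
#' @export
#' @examples
#' de_stokes(log(2), de_correlation("x", "stokes_exp", a = 1, b = 1)) # 0.5
de_stokes <- function(St, corr) {
  if (corr$form != "stokes_exp") stop("correlation form is not stokes_exp")
  if (any(St < 0)) stop("St must be >= 0")
  1 - exp(-corr$a * St^corr$b)
}

#' @rdname de_stokes
#' @export
de_ip <- function(IP, corr) {
  if (corr$form != "ip_exp") stop("correlation form is not ip_exp")
  if (any(IP < 0)) stop("IP must be >= 0")
  1 - exp(-corr$a * IP)
}

# ---- internal: unified conduit network for transport -----------------------

# sections (oral > pharynx > larynx) chained ahead of the branch tree; all
# lengths/areas in SI; `frac` is the constant share of the inlet flow
transport_conduits <- function(tree, bc, gas) {
  frac_b <- flow_split(tree, bc, gas)
  b <- tree$branches
  csa_b <- branch_csa_cm2(tree)
  dh_b <- branch_dh_cm(tree)
  ns <- 0L
  name <- region <- lobe <- character(0)
  len <- csa <- R0 <- frac <- grav <- numeric(0)
  if (!is.null(tree$upper_airway)) {
    for (s in tree$upper_airway) {
      ns <- ns + 1L
      name <- c(name, s$name)
      region <- c(region, switch(s$name, oral_cavity = "oral",
                                 pharynx = "pharynx", larynx = "larynx"))
      lobe <- c(lobe, "none")
      len <- c(len, s$length / 100)
      csa <- c(csa, s$csa * 1e-4)
      R0 <- c(R0, s$hydraulic_diameter / 2 / 100)
      frac <- c(frac, 1)
      grav <- c(grav, 0)    # sections stacked along the gravity axis
    }
  }
  name <- c(name, b$id)
  region <- c(region, b$region)
  lobe <- c(lobe, b$lobe)
  len <- c(len, b$length_cm / 100)
  csa <- c(csa, csa_b * 1e-4)
  R0 <- c(R0, ifelse(b$generation == 0L, dh_b, b$diameter_cm) / 2 / 100)
  frac <- c(frac, unname(frac_b[b$id]))
  grav <- c(grav, b$gravity_angle)

  n <- length(name)
  idx <- stats::setNames(seq_len(n), name)
  parent <- rep(NA_integer_, n)
  kids <- vector("list", n)
  if (ns > 0) {
    for (i in seq_len(ns - 1L)) {
      parent[i + 1L] <- i
      kids[[i]] <- i + 1L
    }
  }
  root_row <- which(is.na(b$parent_id)) + ns
  if (ns > 0) {
    parent[root_row] <- ns
    kids[[ns]] <- root_row
  }
  for (j in seq_len(nrow(b))) {
    if (!is.na(b$parent_id[j])) parent[ns + j] <- idx[b$parent_id[j]]
  }
  for (id in names(tree$children)) {
    ck <- tree$children[[id]]
    if (length(ck)) kids[[idx[id]]] <- unname(idx[ck])
  }
  list(n = n, name = name, region = region, lobe = lobe, len = len,
       csa = csa, R0 = R0, frac = frac, grav = grav,
       parent = parent, kids = kids, first = 1L,
       regions = unique(region))
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Transport an injected bolus through the airway model
#'
#' One-dimensional Lagrangian bolus advection under the quasi-steady flow:
#' the bolus moves along each conduit at the local instantaneous mean
#' velocity (constant flow split times the sinusoidal waveform), splits at
#' every bifurcation in proportion to the daughter flows, and on entering a
#' new airway region deposits the fraction given by that region's
#' correlation — `stokes_exp` regions use the Stokes number of the parent
#' conduit at the crossing instant, `ip_exp` (upper-airway) regions the
#' instantaneous impaction parameter. Crossing times are found in closed
#' form from the integrated sinusoid, so the advection is exact (no time
#' step). Reaching a peripheral outlet during inhalation scores the bolus
#' as escaped to that branch's lobe; after flow reversal at T/2 suspended
#' boluses advect backward, may deposit again on region re-entry, and can
#' exit the mouth (recorded as exhaled, folded into the suspended bucket of
#' the conservation ledger); whatever remains in the domain at T is
#' suspended.
#'
#' In `deterministic` mode the bolus is split fractionally (reproducible,
#' variance-free); in `monte_carlo` mode each particle of the injection set
#' samples its route and fate with the same probabilities under the given
#' seed, and per-particle fates are returned for position-fate maps.
#'
#' @param tree An `airway_tree` (usually [characteristic_tree()]).
#' @param flow A [breathing_cycle()] (quasi-steady transient), a single
#'   flow in L/min (steady), or a `flow_series` (its cycle is used).
#' @param injection An [make_injection()] bolus.
#' @param particle A [particle_spec()].
#' @param correlations Named list of [de_correlation()] covering every
#'   region (default [default_correlations()]).
#' @param mode `"deterministic"` or `"monte_carlo"`.
#' @param bc [outlet_bc()] fixing the flow split.
#' @param gas [gas_properties()].
#' @param sedimentation Add gravitational sedimentation (exponential
#'   inclined-tube formula per conduit transit). Default `FALSE`; the sizes
#'   studied are impaction-dominated.
#' @param seed Seed for `monte_carlo` mode; defaults to the injection seed.
#' @param max_time Horizon for steady runs, s.
#' @return Object of class `deposition_record`: named `deposited` (by
#'   region), `escaped` (by lobe), `entering` (by region), `exhaled`,
#'   `suspended` (in-domain + exhaled), and bookkeeping fields. In MC mode
#'   also `fates`, a per-particle data frame with the initial disk position.
#' @export
#' @examples
#' tree <- characteristic_tree()
#' rec <- transport(tree, breathing_cycle(), make_injection(t_inj = 0.8),
#'                  particle_spec(7))
#' total_de(rec)
transport <- function(tree, flow, injection = make_injection(),
                      particle, correlations = default_correlations(),
                      mode = c("deterministic", "monte_carlo"),
                      bc = outlet_bc(), gas = gas_properties(),
                      sedimentation = FALSE, seed = injection$seed,
                      max_time = 300) {
  mode <- match.arg(mode)
  stopifnot(inherits(particle, "particle_spec"))
  net <- transport_conduits(tree, bc, gas)
  missing_corr <- setdiff(net$regions, names(correlations))
  if (length(missing_corr)) {
    stop("no deposition correlation configured for region(s): ",
         paste(missing_corr, collapse = ", "))
  }

  steady <- is.numeric(flow)
  if (inherits(flow, "flow_series")) flow <- flow$cycle
  if (steady) {
    Qpk <- flow
    if (Qpk < 0) stop("steady flow must be >= 0")
    Tcyc <- Inf
  } else {
    stopifnot(inherits(flow, "breathing_cycle"))
    Qpk <- flow$peak_flow
    Tcyc <- flow$period_T
  }
  omega <- if (steady) NA_real_ else 2 * pi / Tcyc
  t0 <- injection$t_inj
  if (!steady && t0 >= Tcyc / 2) {
    stop("injection during exhalation is not modelled (t_inj must be < T/2)")
  }
  A <- net$frac * Qpk / 60000 / net$csa      # velocity amplitude, m/s

  Qt <- function(t) if (steady) Qpk else Qpk * sin(omega * t)
  Ut <- function(ci, t) if (steady) A[ci] else abs(A[ci] * sin(omega * t))

  deposited <- stats::setNames(numeric(length(net$regions)), net$regions)
  entering <- deposited
  escaped <- stats::setNames(numeric(length(LOBES) + 1L), c(LOBES, "none"))
  exhaled <- 0
  suspended_in <- 0
  fates <- NULL
  vs <- particle$density * (particle$diameter_um * 1e-6)^2 * 9.81 *
    particle$cunningham / (18 * gas$viscosity)   # settling velocity, m/s

  entry_de <- function(region_new, ci_ref, frac_new, t) {
    corr <- correlations[[region_new]]
    if (corr$form == "ip_exp") {
      de_ip(impaction_parameter(particle, frac_new * abs(Qt(t))), corr)
    } else {
      de_stokes(stokes_number(particle, Ut(ci_ref, t), net$R0[ci_ref], gas),
                corr)
    }
  }
  sed_de <- function(ci, t_entry, t_exit) {
    if (!sedimentation) return(0)
    d <- 2 * net$R0[ci]
    1 - exp(-(4 / pi) * vs * (t_exit - t_entry) *
              abs(sin(net$grav[ci] * pi / 180)) / d)
  }

  mc <- mode == "monte_carlo"
  if (mc) {
    old <- .Random.seed_exists()
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }

  # advance one bolus to its fate; deterministic splits push siblings on a
  # stack; monte-carlo routes are sampled, weight is never split
  run_bolus <- function(ci, x, t, w, t_entry) {
    stack <- list(list(ci = ci, x = x, t = t, w = w, te = t_entry))
    fate <- NULL
    while (length(stack)) {
      s <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ci <- s$ci; x <- s$x; t <- s$t; w <- s$w; te <- s$te
      fate <- NULL
      for (ev in 1:10000) {
        if (steady) {
          u <- A[ci]
          if (u <= 0 || t > max_time) {
            suspended_in <<- suspended_in + w; fate <- "suspended"; break
          }
          tc <- t + (net$len[ci] - x) / u
          if (tc > max_time) {
            suspended_in <<- suspended_in + w; fate <- "suspended"; break
          }
          forward <- TRUE
        } else {
          if (t >= Tcyc * (1 - 1e-12) || A[ci] <= 0) {
            suspended_in <<- suspended_in + w; fate <- "suspended"; break
          }
          if (t < Tcyc / 2) {
            cstar <- cos(omega * t) - omega * (net$len[ci] - x) / A[ci]
            if (cstar >= -1) {
              tc <- max(t, acos(clamp1(cstar)) / omega)
              forward <- TRUE
            } else {   # stalls at the turnaround, then advects backward
              x <- x + (A[ci] / omega) * (cos(omega * t) + 1)
              t <- Tcyc / 2
              next
            }
          } else {
            cstar <- cos(omega * t) + omega * x / A[ci]
            if (cstar <= 1) {
              tc <- max(t, (2 * pi - acos(clamp1(cstar))) / omega)
              forward <- FALSE
            } else {
              suspended_in <<- suspended_in + w; fate <- "suspended"; break
            }
          }
        }

        if (forward) {
          ck <- net$kids[[ci]]
          if (is.null(ck) || !length(ck)) {   # peripheral outlet
            escaped[net$lobe[ci]] <<- escaped[net$lobe[ci]] + w
            fate <- paste0("escaped:", net$lobe[ci]); break
          }
          # sedimentation in the conduit just traversed
          ps <- sed_de(ci, te, tc)
          if (ps > 0) {
            if (mc) {
              if (stats::runif(1) < ps) {
                deposited[net$region[ci]] <<- deposited[net$region[ci]] + w
                fate <- paste0("deposited:", net$region[ci]); break
              }
            } else {
              deposited[net$region[ci]] <<- deposited[net$region[ci]] + w * ps
              w <- w * (1 - ps)
            }
          }
          rnew <- net$region[ck[1]]
          if (rnew != net$region[ci]) {
            fnew <- sum(net$frac[ck])
            de <- entry_de(rnew, ci, fnew, tc)
            entering[rnew] <<- entering[rnew] + w
            if (mc) {
              if (stats::runif(1) < de) {
                deposited[rnew] <<- deposited[rnew] + w
                fate <- paste0("deposited:", rnew); break
              }
            } else {
              deposited[rnew] <<- deposited[rnew] + w * de
              w <- w * (1 - de)
            }
          }
          if (length(ck) == 1L) {
            ci <- ck; x <- 0; t <- tc; te <- tc
          } else {
            s1 <- net$frac[ck[1]] / (net$frac[ck[1]] + net$frac[ck[2]])
            if (mc) {
              ci <- if (stats::runif(1) < s1) ck[1] else ck[2]
              x <- 0; t <- tc; te <- tc
            } else {
              stack[[length(stack) + 1L]] <-
                list(ci = ck[2], x = 0, t = tc, w = w * (1 - s1), te = tc)
              ci <- ck[1]; x <- 0; t <- tc; w <- w * s1; te <- tc
            }
          }
        } else {                               # backward, x reached 0
          pa <- net$parent[ci]
          if (is.na(pa)) {
            exhaled <<- exhaled + w; fate <- "exhaled"; break
          }
          ps <- sed_de(ci, te, tc)
          if (ps > 0) {
            if (mc) {
              if (stats::runif(1) < ps) {
                deposited[net$region[ci]] <<- deposited[net$region[ci]] + w
                fate <- paste0("deposited:", net$region[ci]); break
              }
            } else {
              deposited[net$region[ci]] <<- deposited[net$region[ci]] + w * ps
              w <- w * (1 - ps)
            }
          }
          rnew <- net$region[pa]
          if (rnew != net$region[ci]) {
            de <- entry_de(rnew, ci, net$frac[pa], tc)
            entering[rnew] <<- entering[rnew] + w
            if (mc) {
              if (stats::runif(1) < de) {
                deposited[rnew] <<- deposited[rnew] + w
                fate <- paste0("deposited:", rnew); break
              }
            } else {
              deposited[rnew] <<- deposited[rnew] + w * de
              w <- w * (1 - de)
            }
          }
          ci <- pa; x <- net$len[pa]; t <- tc; te <- tc
        }
      }
      if (is.null(fate)) stop("transport did not terminate (internal error)")
    }
    fate
  }

  inject_one <- function(w) {
    r1 <- net$region[net$first]
    entering[r1] <<- entering[r1] + w
    de <- entry_de(r1, net$first, net$frac[net$first], t0)
    if (mc) {
      if (stats::runif(1) < de) {
        deposited[r1] <<- deposited[r1] + w
        return(paste0("deposited:", r1))
      }
      run_bolus(net$first, 0, t0, w, t0)
    } else {
      deposited[r1] <<- deposited[r1] + w * de
      run_bolus(net$first, 0, t0, w * (1 - de), t0)
    }
  }

  if (mc) {
    n <- injection$n_particles
    f <- character(n)
    for (i in seq_len(n)) f[i] <- inject_one(1 / n)
    fates <- cbind(injection$positions, fate = f, stringsAsFactors = FALSE)
  } else {
    inject_one(1)
  }

  structure(list(
    deposited = deposited,
    escaped = escaped,
    entering = entering,
    exhaled = exhaled,
    suspended = suspended_in + exhaled,
    suspended_in_domain = suspended_in,
    t_inj = t0,
    particle = particle,
    mode = mode,
    steady = steady,
    seed = if (mc) as.integer(seed) else NA_integer_,
    n_particles = injection$n_particles,
    fates = fates
  ), class = "deposition_record")
}

#' @export
print.deposition_record <- function(x, ...) {
  cat(sprintf(
    "deposition_record (%s, %s): total DE %.2f%%, escaped %.2f%%, suspended %.2f%%\n",
    x$mode, if (x$steady) "steady" else sprintf("t_inj = %.1f s", x$t_inj),
    100 * sum(x$deposited), 100 * sum(x$escaped), 100 * x$suspended))
  invisible(x)
}

#' Regional and total deposition efficiency
#'
#' Regional DE is the fraction deposited in a region over the fraction that
#' entered it; a region never entered has no defined DE and returns `NA`.
#' Total DE is the whole-model deposited fraction of the injected bolus.
#'
#' @param record A `deposition_record`.
#' @param region Region label.
#' @return A fraction in [0, 1], or `NA` for an unvisited region.
#' @export
regional_de <- function(record, region) {
  if (!region %in% names(record$entering)) stop("unknown region: ", region)
  ent <- record$entering[[region]]
  if (ent <= 0) return(NA_real_)
  record$deposited[[region]] / ent
}

#' @rdname regional_de
#' @export
total_de <- function(record) sum(record$deposited)

#' Conservation residual of a deposition record
#'
#' @param record A `deposition_record`.
#' @return `|deposited + escaped + suspended - 1|`.
#' @export
deposition_residual <- function(record) {
  abs(sum(record$deposited) + sum(record$escaped) + record$suspended - 1)
}

#' Injection-time sweep over the inhalation phase
#'
#' Runs [transport()] once per injection time (default every 0.2 s over
#' 0-1.8 s) and tabulates total DE, per-region DE, the suspended fraction
#' and the per-lobe escape fractions.
#'
#' @param tree An `airway_tree`.
#' @param cycle [breathing_cycle()].
#' @param particle [particle_spec()].
#' @param times Injection times, s, all within `[0, T/2)`.
#' @param correlations,bc,gas,mode,sedimentation Passed to [transport()].
#' @param injection Injection template (its `t_inj` is replaced).
#' @return List with `table` (one row per injection time) and `records`.
#' @export
injection_sweep <- function(tree, cycle = breathing_cycle(),
                            particle = particle_spec(7),
                            times = seq(0, 1.8, by = 0.2),
                            correlations = default_correlations(),
                            bc = outlet_bc(), gas = gas_properties(),
                            mode = "deterministic", sedimentation = FALSE,
                            injection = make_injection()) {
  if (any(times < 0) || any(times >= cycle$period_T / 2)) {
    stop("injection times must lie in [0, T/2)")
  }
  records <- lapply(times, function(ti) {
    inj <- injection
    inj$t_inj <- ti
    transport(tree, cycle, inj, particle, correlations, mode, bc, gas,
              sedimentation)
  })
  regions <- names(records[[1]]$deposited)
  tab <- do.call(rbind, lapply(seq_along(times), function(i) {
    r <- records[[i]]
    row <- data.frame(t_inj = times[i], total_DE = total_de(r),
                      suspended = r$suspended, exhaled = r$exhaled)
    for (rg in regions) row[[paste0("DE_", rg)]] <- regional_de(r, rg)
    for (lb in names(r$escaped)) {
      row[[paste0("escaped_", lb)]] <- r$escaped[[lb]]
    }
    row
  }))
  list(table = tab, records = records)
}

#' Steady versus transient deposition comparison
#'
#' Total and per-region DE under constant mean flow against the
#' cycle-averaged transient result (mean over the injection-time sweep) and
#' the best single injection time.
#'
#' @inheritParams injection_sweep
#' @param times Sweep grid for the transient runs.
#' @return List: `steady` and `sweep` records, `best_t_inj`, and `table`
#'   with columns `region, steady_DE, transient_mean_DE, transient_best_DE`
#'   plus a `total` row.
#' @export
steady_vs_transient <- function(tree, cycle = breathing_cycle(),
                                particle = particle_spec(7),
                                correlations = default_correlations(),
                                times = seq(0, 1.8, by = 0.2),
                                bc = outlet_bc(), gas = gas_properties(),
                                injection = make_injection()) {
  st <- transport(tree, cycle$mean_inspiratory_flow, injection, particle,
                  correlations, "deterministic", bc, gas)
  sw <- injection_sweep(tree, cycle, particle, times, correlations, bc, gas,
                        injection = injection)
  totals <- vapply(sw$records, total_de, 0)
  best <- which.max(totals)
  regions <- names(st$deposited)
  tab <- do.call(rbind, lapply(regions, function(rg) {
    data.frame(region = rg,
               steady_DE = regional_de(st, rg),
               transient_mean_DE = mean(vapply(sw$records, regional_de, 0,
                                               region = rg), na.rm = TRUE),
               transient_best_DE = regional_de(sw$records[[best]], rg),
               stringsAsFactors = FALSE)
  }))
  tab <- rbind(tab, data.frame(region = "total",
                               steady_DE = total_de(st),
                               transient_mean_DE = mean(totals),
                               transient_best_DE = totals[best],
                               stringsAsFactors = FALSE))
  list(steady = st, sweep = sw, best_t_inj = times[best], table = tab)
}
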