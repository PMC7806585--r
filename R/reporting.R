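#' Load a run configuration
#'
#' Reads the packaged default YAML configuration (geometry, flow, particles
#' and deposition blocks) and merges a user file over it, recursively:
#' user keys override defaults, untouched defaults remain.
#'
#' @param path Optional user YAML file.
#' @return Named list with the merged configuration and attributes
#'   `config_hash` (md5 of the merged canonical YAML) recorded in every
#'   report written from it.
#' @export
load_run_config <- function(path = NULL) {
  def_path <- system.file("extdata", "default_config.yaml",
                          package = "airwaydep")
  cfg <- yaml::read_yaml(def_path)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

merge_config <- function(base, over) {
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' @rdname load_run_config
#' @param cfg A configuration list.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  attributes(cfg) <- attributes(cfg)["names"]
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

#' Assemble model objects from a configuration
#'
#' Builds the breathing cycle, gas, loss configuration and deposition
#' correlations described by a [load_run_config()] list.
#'
#' @param cfg Configuration list.
#' @return List with `cycle`, `gas`, `losses`, `correlations`, `recipe`.
#' @export
config_objects <- function(cfg) {
  g <- cfg$flow$gas
  cy <- cfg$flow$cycle
  lo <- cfg$flow$losses
  ge <- cfg$geometry
  corr <- lapply(names(cfg$deposition), function(r) {
    e <- cfg$deposition[[r]]
    de_correlation(r, e$form, e$a, if (is.null(e$b)) NA_real_ else e$b,
                   if (is.null(e$source)) "" else e$source)
  })
  names(corr) <- names(cfg$deposition)
  list(
    cycle = breathing_cycle(cy$period_s, cy$mean_inspiratory_lpm),
    gas = gas_properties(g$density_kg_m3, g$viscosity_kg_ms),
    losses = loss_config(lo$pedley, lo$pedley_C, lo$K_bifurcation,
                         lo$K_larynx),
    correlations = corr,
    recipe = tree_recipe(
      trachea = trachea_spec(ge$trachea$diameter_cm,
                             ge$trachea$posterior_cut_cm,
                             ge$trachea$length_cm),
      x_n = ge$bifurcation$x_n)
  )
}

provenance_lines <- function(seed = NA, cfg_hash = NA) {
  c(sprintf("# airwaydep %s", as.character(utils::packageVersion("airwaydep"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", cfg_hash))
}

#' Write flow reports
#'
#' Per-snapshot branch table (`time_s, branch_id, flow_lpm, velocity_mps,
#' reynolds`) and a companion node-pressure table, as CSV with a provenance
#' header.
#'
#' @param series A `flow_series` or single `flow_solution`.
#' @param prefix Output path prefix; writes `<prefix>_branches.csv` and
#'   `<prefix>_pressure.csv`.
#' @param seed,cfg_hash Recorded in the header.
#' @return The two paths, invisibly.
#' @export
write_flow_report <- function(series, prefix, seed = NA, cfg_hash = NA) {
  sols <- if (inherits(series, "flow_series")) series$solutions
  else list(series)
  btab <- do.call(rbind, lapply(sols, function(s)
    cbind(time_s = s$time, s$branches[, c("id", "flow_lpm", "velocity_mps",
                                          "reynolds")])))
  names(btab)[names(btab) == "id"] <- "branch_id"
  ptab <- do.call(rbind, lapply(sols, function(s)
    data.frame(time_s = s$time, node = names(s$node_pressure),
               pressure_pa = unname(s$node_pressure))))
  p1 <- paste0(prefix, "_branches.csv")
  p2 <- paste0(prefix, "_pressure.csv")
  for (pp in list(list(p1, btab), list(p2, ptab))) {
    writeLines(provenance_lines(seed, cfg_hash), pp[[1]])
    suppressWarnings(utils::write.table(pp[[2]], pp[[1]], sep = ",",
                                        row.names = FALSE, append = TRUE,
                                        quote = FALSE))
  }
  invisible(c(p1, p2))
}

#' Write deposition reports
#'
#' Region CSV (`region, entering_fraction, deposited_fraction, DE,
#' DE_percent`), lobe-escape CSV, and a JSON summary carrying the full
#' record, the seed and the config hash. Fractions are reported both as
#' fractions and percentages.
#'
#' @param record A `deposition_record`.
#' @param prefix Output path prefix.
#' @param seed,cfg_hash Recorded in the outputs.
#' @return The three paths, invisibly.
#' @export
write_deposition_report <- function(record, prefix, seed = NA,
                                    cfg_hash = NA) {
  regions <- names(record$deposited)
  rtab <- data.frame(
    region = regions,
    entering_fraction = unname(record$entering[regions]),
    deposited_fraction = unname(record$deposited[regions]),
    DE = vapply(regions, function(r) regional_de(record, r), 0),
    stringsAsFactors = FALSE)
  rtab$DE_percent <- 100 * rtab$DE
  ltab <- data.frame(lobe = names(record$escaped),
                     escaped_fraction = unname(record$escaped),
                     escaped_percent = 100 * unname(record$escaped))
  p1 <- paste0(prefix, "_regions.csv")
  p2 <- paste0(prefix, "_lobes.csv")
  p3 <- paste0(prefix, "_summary.json")
  for (pp in list(list(p1, rtab), list(p2, ltab))) {
    writeLines(provenance_lines(seed, cfg_hash), pp[[1]])
    suppressWarnings(utils::write.table(pp[[2]], pp[[1]], sep = ",",
                                        row.names = FALSE, append = TRUE,
                                        quote = FALSE))
  }
  summ <- list(
    seed = seed, config_hash = cfg_hash,
    particle_um = record$particle$diameter_um,
    mode = record$mode,
    t_inj = record$t_inj,
    total_DE = total_de(record),
    total_DE_percent = 100 * total_de(record),
    deposited = as.list(record$deposited),
    escaped = as.list(record$escaped),
    entering = as.list(record$entering),
    exhaled = record$exhaled,
    suspended = record$suspended,
    conservation_residual = deposition_residual(record))
  jsonlite::write_json(summ, p3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p1, p2, p3))
}

#' Deposition-by-size table (regional DE per particle size)
#'
#' Steady-flow regional and total DE for a set of particle sizes, with the
#' per-region predictor (Stokes number or impaction parameter) alongside,
#' one row per (size, region).
#'
#' @param tree An `airway_tree`.
#' @param sizes_um Particle diameters, um. Default `c(3, 7, 10, 25)`.
#' @param Q_lpm Steady flow, L/min. Default 6.
#' @param correlations,bc,gas Passed to [transport()].
#' @param injection Injection template.
#' @return Data frame: `size_um, region, entering_fraction,
#'   deposited_fraction, DE, DE_percent`, plus `total_DE` per size.
#' @export
de_by_size_table <- function(tree, sizes_um = c(3, 7, 10, 25), Q_lpm = 6,
                             correlations = default_correlations(),
                             bc = outlet_bc(), gas = gas_properties(),
                             injection = make_injection()) {
  do.call(rbind, lapply(sizes_um, function(dp) {
    rec <- transport(tree, Q_lpm, injection, particle_spec(dp),
                     correlations, "deterministic", bc, gas)
    regions <- names(rec$deposited)
    data.frame(size_um = dp, region = regions,
               entering_fraction = unname(rec$entering[regions]),
               deposited_fraction = unname(rec$deposited[regions]),
               DE = vapply(regions, function(r) regional_de(rec, r), 0),
               DE_percent = 100 * vapply(regions, function(r)
                 regional_de(rec, r), 0),
               total_DE = total_de(rec),
               stringsAsFactors = FALSE)
  }))
}

#' DE-versus-predictor table
#'
#' For each region and particle size at a steady flow, the deposition
#' efficiency of the configured correlation against its predictor (St for
#' tracheobronchial regions, IP for the upper airway), the tabular
#' equivalent of a DE-correlation validation figure.
#'
#' @inheritParams de_by_size_table
#' @return Data frame: `region, size_um, predictor, value, DE`.
#' @export
de_vs_predictor_table <- function(tree, sizes_um = c(3, 7, 10, 25),
                                  Q_lpm = 6,
                                  correlations = default_correlations(),
                                  bc = outlet_bc(), gas = gas_properties()) {
  net <- transport_conduits(tree, bc, gas)
  # representative parent conduit per region: the first conduit whose
  # children lie in that region
  rows <- list()
  for (rg in net$regions) {
    parents <- which(vapply(seq_len(net$n), function(i) {
      ck <- net$kids[[i]]
      !is.null(ck) && length(ck) && net$region[ck[1]] == rg &&
        net$region[i] != rg
    }, TRUE))
    ci <- if (length(parents)) parents[1] else net$first
    corr <- correlations[[rg]]
    for (dp in sizes_um) {
      p <- particle_spec(dp)
      if (corr$form == "ip_exp") {
        val <- impaction_parameter(p, Q_lpm)
        de <- de_ip(val, corr)
        pred <- "IP"
      } else {
        U <- net$frac[ci] * Q_lpm / 60000 / net$csa[ci]
        val <- stokes_number(p, U, net$R0[ci], gas)
        de <- de_stokes(val, corr)
        pred <- "St"
      }
      rows[[length(rows) + 1L]] <-
        data.frame(region = rg, size_um = dp, predictor = pred,
                   value = val, DE = de, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
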