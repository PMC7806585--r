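# shared fixtures: built once per test run

weibel_tree <- function(g = 6) {
  build_tree(make_weibel_table(tree_recipe(max_generation = g,
                                           mode = "weibel_symmetric")))
}

char_tree_cache <- local({
  tree <- NULL
  function() {
    if (is.null(tree)) tree <<- characteristic_tree()
    tree
  }
})

# uniform deposition constants for configurable toy runs
flat_correlations <- function(a_ip = 0, a_st = 0, b_st = 1) {
  regions <- c("oral", "pharynx", "larynx", "trachea",
               "bif1", "bif2", "bif3", "peripheral")
  out <- lapply(regions, function(r) {
    if (r %in% c("oral", "pharynx", "larynx")) {
      de_correlation(r, "ip_exp", a_ip)
    } else {
      de_correlation(r, "stokes_exp", a_st, b_st)
    }
  })
  stats::setNames(out, regions)
}

# dense linear-system oracle for node pressures on a small tree:
# unknowns are the distal-end pressures of every branch plus the common
# outlet pressure; Kirchhoff balance at interior ends, total-flow closure
# at the outlets; pure Poiseuille, inlet pressure 0
dense_pressure_oracle <- function(tree, Q_in_lpm, gas = gas_properties()) {
  b <- tree$branches
  n <- nrow(b)
  ids <- b$id
  idx <- stats::setNames(seq_len(n), ids)
  g <- 1 / poiseuille_resistance(b$length_cm / 100, b$diameter_cm / 100, gas)
  kids <- lapply(ids, function(id) {
    ck <- tree$children[[id]]
    if (is.null(ck)) character(0) else ck
  })
  names(kids) <- ids
  terminal <- lengths(kids) == 0
  Q_si <- Q_in_lpm / 60000

  interior <- ids[!terminal]
  unknowns <- c(interior, "P_out")
  m <- length(unknowns)
  A <- matrix(0, m, m, dimnames = list(NULL, unknowns))
  rhs <- numeric(m)
  p_of <- function(id) {
    # symbolic pressure of a branch end: column name or fixed outlet
    if (terminal[idx[id]]) "P_out" else id
  }
  row <- 0
  for (id in interior) {
    row <- row + 1
    # inflow from parent (or inlet at pressure 0)
    pid <- b$parent_id[idx[id]]
    gi <- g[idx[id]]
    if (is.na(pid)) {
      A[row, p_of(id)] <- A[row, p_of(id)] - gi     # g*(0 - P_id)
    } else {
      A[row, p_of(pid)] <- A[row, p_of(pid)] + gi
      A[row, p_of(id)] <- A[row, p_of(id)] - gi
    }
    for (cid in kids[[id]]) {
      gc_ <- g[idx[cid]]
      A[row, p_of(id)] <- A[row, p_of(id)] - gc_
      A[row, p_of(cid)] <- A[row, p_of(cid)] + gc_
    }
  }
  # closure: total outlet flow equals Q_in
  row <- row + 1
  for (id in ids[terminal]) {
    pid <- b$parent_id[idx[id]]
    gi <- g[idx[id]]
    if (is.na(pid)) {
      A[row, "P_out"] <- A[row, "P_out"] - gi
    } else {
      A[row, p_of(pid)] <- A[row, p_of(pid)] + gi
      A[row, "P_out"] <- A[row, "P_out"] - gi
    }
  }
  rhs[row] <- Q_si
  x <- solve(A, rhs)
  p_end <- vapply(ids, function(id)
    if (terminal[idx[id]]) x["P_out"] else x[id], 0)
  names(p_end) <- ids
  p_end
}

# 2D numerical-integration oracle for the area of a cut disk
cut_disk_area_numeric <- function(d, offset, n = 2000) {
  r <- d / 2
  xs <- seq(-r, r, length.out = n)
  dx <- xs[2] - xs[1]
  half_width <- sqrt(pmax(0, r^2 - xs^2))
  # keep y <= offset: column height = min(offset, hw) - (-hw)
  sum(pmin(offset, half_width) + half_width) * dx
}
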