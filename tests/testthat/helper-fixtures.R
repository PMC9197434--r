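# shared fixtures built in code

# straight branch along `dir` starting at `from`
straight_branch <- function(id, parent, from, dir, len, diameter = 3e-3,
                            outlet_id = NA, npts = 3) {
  dir <- dir / sqrt(sum(dir^2))
  s <- seq(0, len, length.out = npts)
  vessel_branch(id, parent, matrix(from, npts, 3, byrow = TRUE) + s %o% dir,
                diameter, outlet_id = outlet_id)
}

# root + single bifurcation into two outlet branches
two_outlet_tree <- function(leaf_len = 10e-3, root_len = 20e-3,
                            diameter = 4e-3) {
  root_end <- c(root_len, 0, 0)
  vessel_tree(list(
    straight_branch(1, NA, c(0, 0, 0), c(1, 0, 0), root_len, diameter),
    straight_branch(2, 1, root_end, c(1, 1, 0), leaf_len, diameter * 0.79,
                    outlet_id = 1),
    straight_branch(3, 1, root_end, c(1, -1, 0), leaf_len, diameter * 0.79,
                    outlet_id = 2)), root = 1)
}

# symmetric two-level binary tree: 4 outlets
four_outlet_tree <- function(lens = c(20e-3, 12e-3, 8e-3)) {
  p1 <- c(lens[1], 0, 0)
  p2a <- p1 + lens[2] * c(1, 1, 0) / sqrt(2)
  p2b <- p1 + lens[2] * c(1, -1, 0) / sqrt(2)
  vessel_tree(list(
    straight_branch(1, NA, c(0, 0, 0), c(1, 0, 0), lens[1], 5e-3),
    straight_branch(2, 1, p1, c(1, 1, 0), lens[2], 4e-3),
    straight_branch(3, 1, p1, c(1, -1, 0), lens[2], 4e-3),
    straight_branch(4, 2, p2a, c(1, 2, 0), lens[3], 3e-3, outlet_id = 1),
    straight_branch(5, 2, p2a, c(2, 1, 0), lens[3], 3e-3, outlet_id = 2),
    straight_branch(6, 3, p2b, c(2, -1, 0), lens[3], 3e-3, outlet_id = 3),
    straight_branch(7, 3, p2b, c(1, -2, 0), lens[3], 3e-3, outlet_id = 4)),
    root = 1)
}

# perfusion map from raw TPP percentages
tpp_map <- function(tpp, vol = 310) {
  perfusion_map_from_tpp(setNames(tpp, seq_along(tpp)), vol)
}

# flow_bc with equal healthy flow per outlet and tumoral flow by tpp
simple_bc <- function(outlets, qh = 10, tpp = NULL, vt = 310, kc = 0.415) {
  qh_v <- setNames(rep(qh, length(outlets)), outlets)
  qt_v <- if (is.null(tpp)) setNames(rep(0, length(outlets)), outlets)
          else setNames(vt * kc * tpp / 100, outlets)
  assemble_bc(qh_v, qt_v)
}

# PRG via the package path: build a PRM and rasterize it. `fates` is a list
# (by cell, column-major over an n x n grid, n even) of integer fate vectors
# (outlet ids, NA = stuck); NULL cells are empty
mk_prg <- function(fates, n, tissue, h = 1e-4, timing = 0) {
  prm <- do.call(rbind, lapply(seq_along(fates), function(k) {
    f <- fates[[k]]
    if (is.null(f)) return(NULL)
    i <- (k - 1) %% n; j <- (k - 1) %/% n
    data.frame(x = (i + 0.5 - n / 2) * h, y = (j + 0.5 - n / 2) * h,
               outlet = f)
  }))
  attr(prm, "timing") <- timing
  class(prm) <- c("prm", "data.frame")
  rasterize_prg(prm, tissue, h = h, lumen_radius = n / 2 * h)
}

# PRG constructed directly (independent of rasterize_prg): classification
# recomputed from first principles, used as input fixture for CPRG / CF tests
mk_prg_direct <- function(fates, n, tissue, h = 1e-4, timing = 0) {
  state <- matrix("no_value", n, n)
  cell_outlet <- matrix(NA_integer_, n, n)
  n_particles <- matrix(0L, n, n)
  for (k in seq_along(fates)) {
    f <- fates[[k]]
    if (is.null(f)) next
    n_particles[k] <- length(f)
    ex <- f[!is.na(f)]
    if (!length(ex)) { state[k] <- "no_exit"; cell_outlet[k] <- 0L; next }
    if (any(is.na(f))) { state[k] <- "spatially_uncertain"; next }
    tis <- tissue[as.character(ex)]
    state[k] <- if (all(tis == "tumor")) "tumor"
                else if (all(tis == "healthy")) "healthy"
                else "spatially_uncertain"
    if (length(unique(ex)) == 1L) cell_outlet[k] <- ex[1]
  }
  structure(list(h = h, half_n = n %/% 2L, dim = c(n, n), state = state,
                 cell_outlet = cell_outlet, n_particles = n_particles,
                 timing = timing), class = "prg")
}
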