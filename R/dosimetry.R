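## Monte Carlo tumor-dose distribution: the catheter-associated grid section
## (a (2w+1)^2 square of release-grid cells) is shifted uniformly at random
## across the admissible part of the injection plane; each placement yields
## a tumor dose, the flow-weighted sum of the section's cell fractions.

#' Admissible catheter-section center cells
#'
#' A cell is admissible when the full square of half-width `half_width`
#' around it contains no `no_value` cell, i.e. the catheter-associated
#' section fits inside the valued region of the plane.
#'
#' @param grid a `prg` or `cprg` (its `state` matrix is used), or a list of
#'   PRGs, in which case a cell is `no_value` only if empty at every timing.
#' @param half_width section half-width in cells (default 3, a 7x7 square).
#' @return 2-column integer matrix of 1-based admissible cell indices.
#' @export
admissible_cells <- function(grid, half_width = 3L) {
  if (inherits(grid, "prg") || inherits(grid, "cprg")) {
    empty <- grid$state == "no_value"
    dm <- grid$dim
  } else {
    .check_same_grid(grid)
    empty <- Reduce(`&`, lapply(grid, function(p) p$state == "no_value"))
    dm <- grid[[1L]]$dim
  }
  w <- as.integer(half_width)
  ok <- matrix(FALSE, dm[1L], dm[2L])
  for (i in seq((1L + w), (dm[1L] - w))) for (j in seq((1L + w), (dm[2L] - w))) {
    ok[i, j] <- !any(empty[(i - w):(i + w), (j - w):(j + w)])
  }
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) stop("no admissible section centers on this grid")
  colnames(idx) <- c("i", "j")
  idx
}

#' Tumor dose of a grid-section distribution
#'
#' TD = sum over outlets of (T)CF_x * Q_t,x / (Q_t,x + Q_h,x), in percent:
#' the flow-weighted share of section particles reaching tumor tissue.
#'
#' @param dist a `distribution_result` (CF over a grid section, or any
#'   outlet distribution).
#' @param bc a `flow_bc` covering the distribution's outlets.
#' @return tumor dose in percent.
#' @export
tumor_dose <- function(dist, bc) {
  keys <- names(dist$fractions)
  qt <- bc$Q_t[keys]; qh <- bc$Q_h[keys]
  if (anyNA(qt) || anyNA(qh))
    stop("flow_bc lacks outlet(s): ",
         paste(keys[is.na(qt) | is.na(qh)], collapse = ", "))
  tot <- qt + qh
  if (any(tot <= 0)) stop("outlet with zero total flow: ",
                          paste(keys[tot <= 0], collapse = ", "))
  100 * sum(dist$fractions * qt / tot)
}

#' Monte Carlo tumor-dose distribution over catheter tip locations
#'
#' Samples section centers uniformly from the admissible cells (without
#' replacement by default), computes the section cell fractions from the
#' pooled timing PRGs and the tumor dose of each placement.
#'
#' @param prgs list of `prg` objects (all burst timings, identical grid).
#' @param bc a `flow_bc` on the simulated outlet set.
#' @param ff optional flow-fraction map: when given, section CFs are first
#'   redistributed to the full outlet set (hybrid TCF) and `bc_full` must
#'   then supply the full-tree flows.
#' @param bc_full `flow_bc` on the full outlet set (required with `ff`).
#' @param n_samples number of sampled catheter locations (default 50).
#' @param half_width section half-width in cells (default 3).
#' @param seed RNG seed for the sampling.
#' @param replace sample with replacement (default `FALSE`).
#' @return object of class `td_result`: list with `td` (percent, one per
#'   sample), `cells` (sampled centers), `min`, `median`, `max`, `spread`,
#'   `seed`.
#' @export
td_distribution <- function(prgs, bc, ff = NULL, bc_full = NULL,
                            n_samples = 50L, half_width = 3L, seed = 1L,
                            replace = FALSE) {
  adm <- admissible_cells(prgs, half_width)
  if (!replace && n_samples > nrow(adm))
    stop("n_samples (", n_samples, ") exceeds the ", nrow(adm),
         " admissible cells; sample with replacement or reduce n")
  set.seed(seed)
  pick <- sample(nrow(adm), n_samples, replace = replace)
  w <- as.integer(half_width)
  td <- numeric(n_samples)
  for (k in seq_len(n_samples)) {
    ci <- adm[pick[k], 1L]; cj <- adm[pick[k], 2L]
    cells <- as.matrix(expand.grid(i = (ci - w):(ci + w),
                                   j = (cj - w):(cj + w)))
    cf <- compute_cf(prgs, cells = cells)
    if (!is.null(ff)) {
      cf <- hybrid_redistribute(cf, ff)
      td[k] <- tumor_dose(cf, bc_full)
    } else {
      td[k] <- tumor_dose(cf, bc)
    }
  }
  structure(list(td = td, cells = adm[pick, , drop = FALSE],
                 min = min(td), median = median(td), max = max(td),
                 spread = max(td) - min(td), seed = seed),
            class = "td_result")
}

#' @export
print.td_result <- function(x, ...) {
  cat("td_result:", length(x$td), "samples; TD min/median/max =",
      sprintf("%.1f/%.1f/%.1f%%", x$min, x$median, x$max),
      "(spread", sprintf("%.1f)", x$spread), "\n")
  invisible(x)
}

#' Write tumor-dose samples as CSV
#' @param td a `td_result`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_td_csv <- function(td, path) {
  write.csv(data.frame(sample_id = seq_along(td$td),
                       cell_i = td$cells[, 1L], cell_j = td$cells[, 2L],
                       td_percent = td$td), path, row.names = FALSE)
  invisible(path)
}
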