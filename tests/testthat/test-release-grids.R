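tissue2 <- c(`1` = "tumor", `2` = "healthy")

test_that("PRG cells follow the five classification rules", {
  # 2x2 grid; cell contents: 4 tumor-exits | tumor+healthy mix | all stuck |
  # empty
  prg <- mk_prg(list(rep(1L, 4), c(1L, 2L), c(NA_integer_, NA_integer_), NULL),
                n = 2, tissue = tissue2)
  expect_equal(prg$state[1, 1], "tumor")
  expect_equal(prg$state[2, 1], "spatially_uncertain")
  expect_equal(prg$state[1, 2], "no_exit")
  expect_equal(prg$state[2, 2], "no_value")
  # exit + stuck mixture is also spatially uncertain
  prg2 <- mk_prg(list(c(1L, NA_integer_), 2L, NULL, NULL), n = 2,
                 tissue = tissue2)
  expect_equal(prg2$state[1, 1], "spatially_uncertain")
  expect_equal(prg2$state[2, 1], "healthy")
  # two different tumor outlets: tumor cell but no outlet unanimity
  prg3 <- mk_prg(list(c(1L, 3L), NULL, NULL, NULL), n = 2,
                 tissue = c(`1` = "tumor", `3` = "tumor"))
  expect_equal(prg3$state[1, 1], "tumor")
  expect_true(is.na(prg3$cell_outlet[1, 1]))
  # unknown outlet in fates is rejected
  expect_error(mk_prg(list(5L, NULL, NULL, NULL), n = 2, tissue = tissue2),
               "without tissue label")
})

test_that("CPRG composition applies the strict ordered thresholds", {
  states <- function(...) {
    # build 8 single-cell PRGs with the given states via crafted fates
    fmap <- list(tumor = 1L, healthy = 2L, no_exit = NA_integer_,
                 spatially_uncertain = c(1L, 2L), no_value = NULL)
    lapply(list(...), function(s) mk_prg_direct(list(fmap[[s]]), n = 1,
                                                tissue = tissue2))
  }
  cell <- function(cprg) cprg$state[1, 1]
  # 7/8 tumor (87.5% > 75%) -> constant
  expect_equal(cell(compose_cprg(states("tumor", "tumor", "tumor", "tumor",
                                        "tumor", "tumor", "tumor", "healthy"))),
               "tumor_constant")
  # 6/8 tumor = 75% is NOT > 75% -> mostly
  expect_equal(cell(compose_cprg(states("tumor", "tumor", "tumor", "tumor",
                                        "tumor", "tumor", "healthy", "healthy"))),
               "tumor_mostly")
  # 5/8 tumor (62.5%) -> mostly
  expect_equal(cell(compose_cprg(states("tumor", "tumor", "tumor", "tumor",
                                        "tumor", "healthy", "healthy",
                                        "healthy"))),
               "tumor_mostly")
  # 4/8 tumor = 50% is NOT > 50%; 3/8 no_value = 37.5% NOT > 37.5% ->
  # temporally uncertain
  expect_equal(cell(compose_cprg(states("tumor", "tumor", "tumor", "tumor",
                                        "healthy", "no_value", "no_value",
                                        "no_value"))),
               "temporally_uncertain")
  # 4/8 no_value (50% > 37.5%) -> no_value
  expect_equal(cell(compose_cprg(states("tumor", "tumor", "healthy", "no_exit",
                                        "no_value", "no_value", "no_value",
                                        "no_value"))),
               "no_value")
  # tie 4/8 no_value + 4/8 spatially_uncertain -> no_value wins (rule order)
  expect_equal(cell(compose_cprg(states("spatially_uncertain",
                                        "spatially_uncertain",
                                        "spatially_uncertain",
                                        "spatially_uncertain", "no_value",
                                        "no_value", "no_value", "no_value"))),
               "no_value")
  # 7/8 no_exit -> no_exit_constant
  expect_equal(cell(compose_cprg(states("no_exit", "no_exit", "no_exit",
                                        "no_exit", "no_exit", "no_exit",
                                        "no_exit", "tumor"))),
               "no_exit_constant")
  expect_error(compose_cprg(states("tumor")), "at least 2")
})

test_that("CPRG rules agree with exhaustive enumeration of 8-timing mixes", {
  # independent oracle straight from the counts
  oracle <- function(cnt) {
    f <- cnt / 8
    if (f[["tumor"]] > 0.75) "tumor_constant"
    else if (f[["healthy"]] > 0.75) "healthy_constant"
    else if (f[["no_exit"]] > 0.75) "no_exit_constant"
    else if (f[["tumor"]] > 0.5) "tumor_mostly"
    else if (f[["healthy"]] > 0.5) "healthy_mostly"
    else if (f[["no_value"]] > 0.375) "no_value"
    else if (f[["spatially_uncertain"]] > 0.375) "spatially_uncertain"
    else "temporally_uncertain"
  }
  fmap <- list(tumor = 1L, healthy = 2L, no_exit = NA_integer_,
               spatially_uncertain = c(1L, 2L), no_value = NULL)
  sts <- names(fmap)
  # all multisets of 8 timings over the 5 states
  combos <- expand.grid(a = 0:8, b = 0:8, c = 0:8, d = 0:8)
  combos <- combos[rowSums(combos) <= 8, ]
  # CPRG composition is permutation invariant, checked on a spot-case below,
  # so enumerating multisets covers all boundary combinations
  for (k in seq_len(nrow(combos))) {
    cnt <- c(unlist(combos[k, ]), 8 - sum(combos[k, ]))
    names(cnt) <- sts
    seq_states <- rep(sts, times = cnt)
    prgs <- lapply(seq_states, function(s) mk_prg_direct(list(fmap[[s]]), n = 1,
                                                         tissue = tissue2))
    expect_identical(compose_cprg(prgs)$state[1, 1], oracle(cnt))
  }
  # permutation invariance spot check
  seq1 <- c("tumor", "no_value", "tumor", "healthy", "no_value", "tumor",
            "no_exit", "tumor")
  p1 <- lapply(seq1, function(s) mk_prg_direct(list(fmap[[s]]), n = 1,
                                               tissue = tissue2))
  expect_identical(compose_cprg(p1)$state, compose_cprg(rev(p1))$state)
})

test_that("cell fractions follow the hand count and exclude uncertain cells", {
  # one timing: 6 cells outlet 1 + 2 no-exit + 1 uncertain + 1 empty ->
  # CF_1 = 6/8
  fates <- c(lapply(1:6, function(i) 1L),
             list(NA_integer_, NA_integer_, c(1L, 2L), NULL),
             rep(list(NULL), 6))
  prg <- mk_prg(fates, n = 4, tissue = tissue2)
  cf <- compute_cf(list(prg))
  expect_equal(unname(cf$fractions[["1"]]), 6 / 8)
  expect_equal(cf$no_exit_fraction, 2 / 8)
  # all cells one outlet -> CF 1, no_exit 0
  prg_all <- mk_prg(lapply(1:16, function(i) 1L), n = 4, tissue = tissue2)
  cf_all <- compute_cf(list(prg_all))
  expect_equal(unname(cf_all$fractions[["1"]]), 1)
  expect_equal(cf_all$no_exit_fraction, 0)
  # aggregation over timings counts cell-timing pairs: (6 + 16) / (8 + 16)
  cf2 <- compute_cf(list(prg, prg_all))
  expect_equal(unname(cf2$fractions[["1"]]), 22 / 24)
  # restriction to a sub-grid section
  cf_sec <- compute_cf(list(prg), cells = cbind(1:2, c(1L, 1L)))
  expect_equal(unname(cf_sec$fractions[["1"]]), 1)
  expect_error(compute_cf(list(mk_prg_direct(list(NULL, NULL, NULL, NULL),
                                             n = 2, tissue = tissue2))),
               "denominator")
})

test_that("hybrid redistribution conserves parent fractions exactly", {
  # CF* = 0.3 on an equal trifurcation -> 0.1 each
  dist <- structure(list(fractions = c(`1` = 0.3, `4` = 0.7),
                         no_exit_fraction = 0, kind = "CF", geometry = "g2"),
                    class = "distribution_result")
  ff <- list(`1` = setNames(rep(1 / 3, 3), 1:3), `4` = c(`4` = 1))
  out <- hybrid_redistribute(dist, ff)
  expect_equal(unname(out$fractions[as.character(1:3)]), rep(0.1, 3))
  expect_equal(unname(out$fractions[["4"]]), 0.7)
  expect_equal(out$kind, "TCF")
  # identity truncation passes through
  id_ff <- list(`1` = c(`1` = 1), `4` = c(`4` = 1))
  expect_equal(hybrid_redistribute(dist, id_ff)$fractions, dist$fractions)
  # random FF maps: member sums equal the parent value
  set.seed(12)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    w <- runif(k); w <- w / sum(w)
    ffr <- list(`1` = setNames(w, seq_len(k)))
    d <- structure(list(fractions = c(`1` = runif(1)), no_exit_fraction = 0,
                        kind = "CF", geometry = ""),
                   class = "distribution_result")
    out <- hybrid_redistribute(d, ffr)
    expect_equal(sum(out$fractions), d$fractions[["1"]], tolerance = 1e-12)
  }
  expect_error(hybrid_redistribute(dist, list(`4` = c(`4` = 1))),
               "no flow fractions")
})

test_that("exit fractions and distribution comparison match brute counts", {
  ex <- data.frame(particle_id = 1:10, t_inject_s = 0, x_m = 0, y_m = 0,
                   outlet = c(rep(1L, 6), rep(2L, 4)),
                   exit_time_s = 1)
  class(ex) <- c("exit_record_set", "data.frame")
  ef <- compute_ef(ex)
  expect_equal(unname(ef$fractions), c(0.6, 0.4))
  ex$outlet[1:2] <- NA
  ef2 <- compute_ef(ex)
  expect_equal(unname(ef2$fractions), c(0.5, 0.5))
  expect_equal(ef2$no_exit_fraction, 0.2)

  # comparison summaries equal order-statistics on |a - b|
  set.seed(3)
  fa <- runif(12); fa <- fa / sum(fa)
  fb <- runif(12); fb <- fb / sum(fb)
  a <- structure(list(fractions = setNames(fa, 1:12), no_exit_fraction = 0,
                      kind = "EF", geometry = "a"),
                 class = "distribution_result")
  cmp <- compare_distributions(a, setNames(fb, 1:12))
  d <- abs(fa - fb) * 100
  expect_equal(cmp$median, median(d))
  expect_equal(cmp$max, max(d))
  expect_equal(cmp$min, min(d))
  expect_equal(cmp$iqr, unname(diff(quantile(d, c(0.25, 0.75)))))
  expect_equal(cmp$argmax, which.max(d))
  # identical inputs -> all-zero summary
  cmp0 <- compare_distributions(a, a)
  expect_equal(cmp0$max, 0)
})
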