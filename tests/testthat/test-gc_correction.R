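# GC-bias model: windowed GC fractions, bin table, quadratic fit, correction

test_that("windowed GC fractions match direct hand counting", {
  s <- "GCGCGCGCGCATATATATATA"
  # independent direct count at every offset
  direct <- vapply(seq_len(nchar(s)), function(i) {
    win <- substring(s, max(1, i - 10), min(nchar(s), i + 10))
    b <- strsplit(win, "")[[1]]
    sum(b %in% c("G", "C")) / length(b)
  }, numeric(1))
  expect_equal(gc_fraction_profile(s, 10), direct, tolerance = 1e-12)
  expect_equal(gc_fraction_window(s, 3, 10), direct[3])
  expect_equal(gc_fraction_window(strrep("G", 21), 11), 1.0)
  expect_equal(gc_fraction_window(strrep("A", 21), 11), 0.0)
})

test_that("ambiguous bases are excluded; all-N windows fall back to 0.5", {
  # N in the window drops out of numerator and denominator
  expect_equal(gc_fraction_window("GANNT", 3, 2), 1 / 3)
  expect_warning(v <- gc_fraction_profile("NNNNN", 2), "ambiguous")
  expect_equal(v, rep(0.5, 5))
})

test_that("bin table tiles complete 20 bp bins and drops partials", {
  seqs <- c(regA = random_sequence(40))
  tr <- normalize_track(constant_track(2, 40))
  tab <- build_bin_table(tr, seqs)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$S, c(1, 1))   # normalized constant track
  expect_equal(attr(tab, "n_dropped_partial"), 0L)
  seqs39 <- c(regA = random_sequence(39))
  tr39 <- normalize_track(constant_track(2, 39))
  tab39 <- build_bin_table(tr39, seqs39)
  expect_equal(nrow(tab39), 1)
  expect_equal(attr(tab39, "n_dropped_partial"), 1L)
  # bin GC matches a direct count of its 20 bases
  b <- strsplit(seqs[[1]], "")[[1]][21:40]
  expect_equal(tab$gc[2], sum(b %in% c("G", "C")) / 20)
})

test_that("quadratic fit recovers planted coefficients at zero noise", {
  gc <- seq(0.2, 0.8, length.out = 60)
  tab <- data.frame(region = "r", bin_start = 0, gc = gc,
                    S = exp(2 * gc^2 - 1 * gc + 0.3))
  m <- fit_gc_model(tab)
  expect_equal(m$a, 2, tolerance = 1e-6)
  expect_equal(m$b, -1, tolerance = 1e-6)
  expect_equal(m$c, 0.3, tolerance = 1e-6)
  expect_equal(m$n_bins_fit, 60L)
  # flat response: a = b = 0, c = log(S)
  tabf <- data.frame(gc = gc, S = 3)
  mf <- fit_gc_model(tabf)
  expect_equal(mf$a, 0, tolerance = 1e-8)
  expect_equal(mf$b, 0, tolerance = 1e-8)
  expect_equal(mf$c, log(3), tolerance = 1e-8)
  # zero-score bins are excluded and counted, no pseudocount
  tab0 <- rbind(tab, data.frame(region = "r", bin_start = 0,
                                gc = c(0.1, 0.9), S = 0))
  m0 <- fit_gc_model(tab0)
  expect_equal(m0$n_excluded, 2L)
  expect_equal(m0$n_bins_fit, 60L)
  expect_equal(m0$a, m$a, tolerance = 1e-9)
  expect_error(fit_gc_model(data.frame(gc = c(.1, .2), S = c(1, 1))),
               ">= 3 bins")
})

test_that("correction divides by exp(F(GC)) and floors at 0.01", {
  n <- 200
  set.seed(104)
  seqs <- c(regA = random_sequence(n))
  reg <- one_region(n)
  v <- runif(n, 0, 2)
  tr <- occupancy_track(reg, list(regA = v / mean(v)), stage = "normalized")
  # F == 0: identity up to the floor
  m0 <- structure(list(a = 0, b = 0, c = 0, bin_size = 20,
                       window_halfwidth = 10), class = "gc_model")
  expect_equal(track_values(apply_gc_correction(tr, seqs, m0)),
               pmax(v / mean(v), 0.01))
  # F == log 2 everywhere: halves the signal
  mlog2 <- structure(list(a = 0, b = 0, c = log(2), bin_size = 20,
                          window_halfwidth = 10), class = "gc_model")
  out <- track_values(apply_gc_correction(tr, seqs, mlog2))
  expect_equal(out, pmax(v / mean(v) / 2, 0.01))
  expect_true(all(out >= 0.01))
  # correction is multiplicative above the floor
  tr2 <- occupancy_track(reg, list(regA = 2 * v / mean(v)),
                         stage = "normalized")
  m <- structure(list(a = 1.2, b = -0.5, c = 0.1, bin_size = 20,
                      window_halfwidth = 10), class = "gc_model")
  o1 <- track_values(apply_gc_correction(tr, seqs, m))
  o2 <- track_values(apply_gc_correction(tr2, seqs, m))
  above <- o1 > 0.011
  expect_equal(o2[above], 2 * o1[above], tolerance = 1e-12)
  # missing sequence fails before any value is written
  expect_error(apply_gc_correction(tr, c(other = "ACGT"), m),
               "missing sequence")
})

test_that("model fit on a track's own bins removes its GC trend", {
  # build a track whose only structure is a quadratic GC response; the GC
  # landscape must vary smoothly (as in real genomes) — GC fluctuation
  # below the bin/window scale is not representable by the model and
  # leaves a residual trend by design (see methods vignette)
  set.seed(105)
  n <- 4000
  gcl <- 0.5 + 0.3 * sin(2 * pi * seq_len(n) / 500)
  isgc <- runif(n) < gcl
  pick <- runif(n) < 0.5
  seqs <- c(regA = paste(ifelse(isgc, ifelse(pick, "G", "C"),
                                ifelse(pick, "A", "T")), collapse = ""))
  gcp <- gc_fraction_profile(seqs[[1]], 10)
  v <- exp(1.5 * gcp^2 - 0.8 * gcp + 0.2)
  reg <- one_region(n)
  tr <- normalize_track(occupancy_track(reg, list(regA = v)))
  model <- fit_gc_model(build_bin_table(tr, seqs))
  adj <- apply_gc_correction(tr, seqs, model)
  tab <- build_bin_table(
    occupancy_track(reg, list(regA = track_values(adj) /
                                mean(track_values(adj))),
                    stage = "normalized"), seqs)
  slope <- coef(lm(log(S) ~ gc, data = tab[tab$S > 0, ]))["gc"]
  expect_lt(abs(slope), 0.1)  # residual trend is negligible
})

test_that("gc_model JSON serialization round trips", {
  gc <- seq(0.1, 0.9, length.out = 20)
  m <- fit_gc_model(data.frame(gc = gc, S = exp(0.5 * gc + 0.1)))
  tmp <- tempfile(fileext = ".json")
  write_gc_model(m, tmp)
  back <- read_gc_model(tmp)
  expect_equal(back$a, m$a)
  expect_equal(back$b, m$b)
  expect_equal(back$c, m$c)
  expect_equal(back$n_bins_fit, m$n_bins_fit)
})
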