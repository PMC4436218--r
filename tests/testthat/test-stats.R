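# group statistics, z-test, Spearman, enrichment and on-target QC

fake_summaries <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    gene_class = sample(c("class1_active", "class2_poised"), n, TRUE),
    functional = sample(c(TRUE, FALSE), n, TRUE),
    invivo_avg = runif(n, 0.05, 3),
    invitro_avg = runif(n, 0.05, 3),
    log2_fold = rnorm(n))
}

test_that("group summaries match direct mean/SEM/median recomputation", {
  s <- fake_summaries(60, seed = 111)
  g <- summarize_groups(s)
  for (i in seq_len(nrow(g))) {
    sel <- s$gene_class == g$gene_class[i] & s$functional == g$functional[i]
    x <- s$invivo_avg[sel]
    expect_equal(g$n[i], sum(sel))
    expect_equal(g$mean_occupancy[i], mean(x))
    expect_equal(g$sem[i], sd(x) / sqrt(length(x)))
    expect_equal(g$median_log2_fold[i], median(s$log2_fold[sel]))
  }
  # in vitro flavour uses the other per-site average
  g2 <- summarize_groups(s, "invitro")
  sel <- s$gene_class == g2$gene_class[1] & s$functional == g2$functional[1]
  expect_equal(g2$mean_occupancy[1], mean(s$invitro_avg[sel]))
})

test_that("degenerate groups are reported, not dropped", {
  s <- fake_summaries(1, seed = 112)
  g <- summarize_groups(s)
  expect_equal(g$n, 1L)
  expect_equal(g$sem, 0)
  expect_false(g$sem_defined)
  s3 <- fake_summaries(3, seed = 113)
  s3$gene_class <- "c"; s3$functional <- TRUE
  s3$log2_fold <- c(-2, 0, 2)
  expect_equal(summarize_groups(s3)$median_log2_fold, 0)
  expect_equal(nrow(summarize_groups(fake_summaries(0))), 0)
})

test_that("two-group z-test has the documented closed form", {
  x <- c(1, 2, 3, 4)
  expect_equal(two_group_z(x, x)$z, 0)
  expect_equal(two_group_z(x, x)$p, 1)
  # shift one group by exactly the combined SEM: z = 1, p = 2*pnorm(-1)
  se <- sqrt(2 * (sd(x) / sqrt(4))^2)
  r <- two_group_z(x + se, x)
  expect_equal(r$z, 1, tolerance = 1e-12)
  expect_equal(r$p, 2 * pnorm(-1), tolerance = 1e-12)
  expect_equal(r$p, 0.3173, tolerance = 1e-4)
  # antisymmetry
  set.seed(114)
  a <- rnorm(10); b <- rnorm(15, 1)
  expect_equal(two_group_z(a, b)$z, -two_group_z(b, a)$z)
  expect_equal(two_group_z(a, b)$p, two_group_z(b, a)$p)
  expect_error(two_group_z(1, b), "n >= 2")
})

test_that("null type-I error is near nominal (calibration simulation)", {
  set.seed(115)
  rej <- mean(replicate(500, two_group_z(rnorm(30), rnorm(30))$p < 0.05))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("Spearman between tracks is rank-based and monotone invariant", {
  set.seed(116)
  reg <- one_region(400)
  va <- runif(400); vb <- runif(400)
  ta <- occupancy_track(reg, list(regA = va))
  tb <- occupancy_track(reg, list(regA = vb))
  expect_equal(spearman_tracks(ta, ta)$rho, 1.0)
  # a rank-reversing transform gives -1
  trev <- occupancy_track(reg, list(regA = max(va) + 1 - va))
  expect_equal(spearman_tracks(ta, trev)$rho, -1.0)
  # matches rank-then-Pearson by hand
  expect_equal(spearman_tracks(ta, tb)$rho,
               cor(rank(va), rank(vb)), tolerance = 1e-12)
  # invariant under strictly monotone transforms
  tmono <- occupancy_track(reg, list(regA = exp(3 * vb)))
  expect_equal(spearman_tracks(ta, tmono)$rho,
               spearman_tracks(ta, tb)$rho, tolerance = 1e-12)
  # mismatched regions error
  reg2 <- one_region(300)
  tc <- occupancy_track(reg2, list(regA = runif(300)))
  expect_error(spearman_tracks(ta, tc), "identical regions")
})

test_that("enrichment fold is the probability ratio, scale invariant in clones", {
  r <- enrichment_fold(64, 100, 150424, 3.0e9)
  expect_equal(r$p_enriched, 0.64)
  expect_equal(r$fold, 0.64 / (150424 / 3.0e9), tolerance = 1e-12)
  expect_equal(r$fold, 12764, tolerance = 1e-4)
  # multiplying both clone counts leaves the fold unchanged
  r2 <- enrichment_fold(640, 1000, 150424, 3.0e9)
  expect_equal(r2$fold, r$fold)
  # no enrichment possible when region == genome, all reads on target
  expect_equal(enrichment_fold(50, 50, 1e6, 1e6)$fold, 1)
  expect_error(enrichment_fold(10, 0, 1, 1), "positive")
  expect_error(enrichment_fold(11, 10, 1, 10), "exceed")
})

test_that("on-target report distributes expectation by region length", {
  reg <- rbind(one_region(1000, "r1", "c1"), one_region(3000, "r2", "c2"))
  # reads proportional to length: every ratio 1
  rep1 <- on_target_report(c(r1 = 250, r2 = 750), reg, 1000)
  expect_equal(rep1$ratio, c(1, 1))
  expect_equal(attr(rep1, "on_target_fraction"), 1)
  # all reads on one of two equal-length regions
  rege <- rbind(one_region(1000, "r1", "c1"), one_region(1000, "r2", "c2"))
  rep2 <- on_target_report(c(r1 = 500, r2 = 0), rege, 500)
  expect_equal(rep2$ratio, c(2, 0))
  # random allocation matches direct arithmetic; expectations sum to total
  set.seed(117)
  cnt <- c(r1 = 321, r2 = 123)
  rep3 <- on_target_report(cnt, reg, 600)
  expect_equal(rep3$expected, 600 * c(1000, 3000) / 4000)
  expect_equal(sum(rep3$expected), 600)
  expect_equal(rep3$ratio, as.numeric(cnt) / rep3$expected)
  expect_equal(attr(rep3, "on_target_fraction"), 444 / 600)
  expect_error(on_target_report(c(r1 = 700, r2 = 0), rege, 600), "smaller")
})
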