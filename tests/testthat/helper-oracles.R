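# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, direct formulas) and share no code with
# the implementation they check.

# per-bp occupancy by looping over (fragment, position) pairs
naive_occupancy <- function(fragments, region, sigma = 20, trunc = 73) {
  n <- region$end - region$start
  occ <- numeric(n)
  for (f in seq_len(nrow(fragments))) {
    if (fragments$chrom[f] != region$chrom) next
    s <- fragments$start[f]; e <- fragments$end[f]
    len <- e - s
    if (len %% 2 == 1) {
      centers <- s + (len - 1) / 2; mass <- 1
    } else {
      centers <- c(s + len / 2 - 1, s + len / 2); mass <- 0.5
    }
    for (p in seq_len(n)) {
      pos <- region$start + p - 1
      for (c0 in centers) {
        d <- abs(pos - c0)
        if (d <= trunc) occ[p] <- occ[p] + mass * exp(-0.5 * (d / sigma)^2)
      }
    }
  }
  occ
}

# position-by-position PWM scorer over both strands
naive_scan <- function(sequence, motif, threshold, pseudocount = 0.01) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  w <- motif$width
  cnt <- motif$counts + pseudocount
  p <- sweep(cnt, 2, colSums(cnt), "/")
  lom <- log2(sweep(p, 1, motif$background[rownames(p)], "/"))
  smin <- sum(apply(lom, 2, min)); smax <- sum(apply(lom, 2, max))
  score1 <- function(win) {
    if (!all(win %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(w), function(j) lom[win[j], j], numeric(1)))
  }
  hits <- list()
  for (i in seq_len(max(0, length(bases) - w + 1))) {
    win <- bases[i:(i + w - 1)]
    sf <- score1(win)
    sr <- score1(rev(unname(comp[win])))
    rf <- (sf - smin) / (smax - smin)
    rr <- (sr - smin) / (smax - smin)
    pass_f <- !is.na(rf) && rf >= threshold - 1e-9
    pass_r <- !is.na(rr) && rr >= threshold - 1e-9
    if (pass_f || pass_r) {
      use_r <- !is.na(sr) && (is.na(sf) || sr > sf)
      hits[[length(hits) + 1]] <- data.frame(
        start = i - 1L, strand = if (use_r) "-" else "+",
        score = if (use_r) sr else sf,
        rel_score = if (use_r) rr else rf)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(),
                                       strand = character(),
                                       score = numeric(),
                                       rel_score = numeric()))
  do.call(rbind, hits)
}

# uniform random fragment set over a region
random_fragments <- function(n, region, len_range = c(120, 170)) {
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  start <- sample(seq(region$start - 50, region$end + 50 - max(len)),
                  n, replace = TRUE)
  data.frame(chrom = region$chrom, start = start, end = start + len,
             length = len, stringsAsFactors = FALSE)
}

one_region <- function(n = 2000, name = "regA", chrom = "chrA",
                       start = 0) {
  data.frame(name = name, chrom = chrom, start = start, end = start + n,
             length = n, stringsAsFactors = FALSE)
}

random_sequence <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

constant_track <- function(value, n = 100, stage = "raw") {
  r <- one_region(n)
  occupancy_track(r, list(regA = rep(value, n)), stage = stage)
}

test_motif <- function() {
  read_motif(system.file("extdata", "oct4_sox2_synthetic.pfm",
                         package = "nucleotrack"))
}

# small, fast world for unit tests
small_world_config <- function(seed = 11, ...) {
  plan <- data.frame(
    region = c("Act", "Poi"),
    gene_class = c("class1_active", "class2_poised"),
    n_functional = c(2L, 2L), n_nonfunctional = c(3L, 3L),
    stringsAsFactors = FALSE)
  world_config(seed = seed, region_length = 3000L, depth = 2e4,
               site_plan = plan, ...)
}
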