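# Synthetic mononucleosome worlds: sequences with a controllable GC
# landscape, a smooth intrinsic nucleosome-preference landscape lambda(i)
# with planted positioning elements, planted motif instances (functional
# and nonfunctional), a displacement factor delta applied in vivo over the
# nucleosome footprint around functional motifs, and a GC-dependent
# multiplicative bias for the naked-DNA control. Everything is reproducible
# from one seed.

#' Default simulation configuration
#'
#' The default world mirrors the targeted-enrichment study design it
#' emulates: six 5 kb regions named after the six targeted gene loci, in
#' three regulatory classes (active, poised, bivalent-unregulated), with
#' planted composite-motif instances in the published per-class counts
#' (functional/nonfunctional 10/12, 4/13 and 0/19; 58 sites, 14
#' functional). Fragments are 147 bp with +/-20 bp uniform jitter; the
#' displacement factor at functional sites is 0.25; the naked-DNA GC bias
#' is a moderate quadratic on the log scale.
#'
#' @param seed RNG seed (integer).
#' @param region_length length of every region in bp.
#' @param depth fragments per library.
#' @param delta in vivo displacement factor in (0, 1] applied to the
#'   preference landscape over a 147 bp window centered on each functional
#'   motif.
#' @param gc_bias named vector `c(a, b, c)` of the naked-control bias
#'   `exp(a*GC^2 + b*GC + c)`; all zero means an unbiased (uniform)
#'   control.
#' @param fragment_length mean fragment length in bp.
#' @param length_jitter uniform length jitter half-range in bp.
#' @param edge_margin bp at each region edge excluded from center sampling
#'   so fragments stay inside their region.
#' @param motif `motif_matrix` whose consensus is planted; default the
#'   shipped synthetic Oct4/Sox2 composite PFM.
#' @param site_plan data.frame with `region`, `gene_class`, `n_functional`,
#'   `n_nonfunctional`.
#' @return Config list for [make_world()].
#' @export
world_config <- function(seed = 1L,
                         region_length = 5000L,
                         depth = 1e5,
                         delta = 0.25,
                         gc_bias = c(a = 2, b = -1, c = -0.2),
                         fragment_length = 147L,
                         length_jitter = 20L,
                         edge_margin = 100L,
                         motif = NULL,
                         site_plan = NULL) {
  if (is.null(motif))
    motif <- read_motif(system.file("extdata", "oct4_sox2_synthetic.pfm",
                                    package = "nucleotrack"))
  if (is.null(site_plan))
    site_plan <- data.frame(
      region = c("Pou5f1", "Sox2", "Nes", "Pax6", "Sox1", "Olig2"),
      gene_class = c("class1_active", "class1_active",
                     "class2_poised", "class2_poised",
                     "class3_bivalent_unregulated",
                     "class3_bivalent_unregulated"),
      n_functional = c(5L, 5L, 2L, 2L, 0L, 0L),
      n_nonfunctional = c(6L, 6L, 7L, 6L, 10L, 9L),
      stringsAsFactors = FALSE)
  stopifnot(delta > 0, delta <= 1, depth >= 0,
            region_length >= 1000L,
            length(gc_bias) == 3L)
  names(gc_bias) <- c("a", "b", "c")
  list(seed = as.integer(seed), region_length = as.integer(region_length),
       depth = depth, delta = delta, gc_bias = gc_bias,
       fragment_length = as.integer(fragment_length),
       length_jitter = as.integer(length_jitter),
       edge_margin = as.integer(edge_margin),
       motif = motif, site_plan = site_plan,
       # ChIP score generators: separated so a cutoff of 20 classifies
       # planted sites perfectly by construction
       chip_functional = c(25, 60), chip_nonfunctional = c(0, 15),
       gc_amplitude = 0.15, gc_period = 1000,
       lambda_amplitude = 0.4, lambda_period = 600,
       element_spacing = 800, element_height = 3, element_sd = 25)
}

# sinusoidal GC landscape, region-specific phase
gc_landscape <- function(cfg, region_index, n) {
  i <- seq_len(n)
  0.5 + cfg$gc_amplitude *
    sin(2 * pi * i / cfg$gc_period + 2 * pi * (region_index - 1) / 6)
}

# smooth positive preference landscape with planted positioning elements
lambda_landscape <- function(cfg, region_index, n) {
  i <- seq_len(n)
  lam <- 1 + cfg$lambda_amplitude *
    sin(2 * pi * i / cfg$lambda_period + pi * (region_index - 1) / 3)
  centers <- seq(cfg$element_spacing / 2, n, by = cfg$element_spacing)
  for (c0 in centers)
    lam <- lam + cfg$element_height * exp(-0.5 * ((i - c0) / cfg$element_sd)^2)
  lam
}

#' Realize a synthetic world
#'
#' Draws region sequences from the GC landscape, overwrites planted motif
#' instances with the motif consensus (or its reverse complement on the
#' minus strand), assigns functional flags and ChIP scores, and stores the
#' preference landscape and bias coefficients as ground truth. Identical
#' seeds produce byte-identical worlds.
#'
#' @param config list from [world_config()].
#' @return Object of class `synthetic_world`: `config`, `regions` (with
#'   `gene_class`), `seqs`, `lambda` (per-region numeric list), `motifs`
#'   (planted-site truth table with ChIP scores), `classes`.
#' @export
make_world <- function(config = world_config()) {
  cfg <- config
  set.seed(cfg$seed)
  width <- cfg$motif$width
  consensus <- motif_consensus(cfg$motif)
  cons_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
  n <- cfg$region_length
  plan <- cfg$site_plan
  regions <- data.frame(name = plan$region, chrom = plan$region,
                        start = 0, end = n, length = n,
                        gene_class = plan$gene_class,
                        stringsAsFactors = FALSE)
  seqs <- character(nrow(plan))
  lambdas <- vector("list", nrow(plan))
  motifs <- list()
  for (r in seq_len(nrow(plan))) {
    gc <- gc_landscape(cfg, r, n)
    is_gc <- stats::runif(n) < gc
    pick <- stats::runif(n) < 0.5
    bases <- ifelse(is_gc, ifelse(pick, "G", "C"),
                    ifelse(pick, "A", "T"))
    ns <- plan$n_functional[r] + plan$n_nonfunctional[r]
    sites <- NULL
    if (ns > 0) {
      margin <- cfg$edge_margin + 147  # keep displacement windows interior
      pos <- round(seq(margin, n - margin - width, length.out = ns))
      pos <- pos + round(stats::runif(ns, -40, 40))
      pos <- sort(pos)
      if (any(diff(pos) < width))
        stop("config error: planted motifs overlap in region ",
             plan$region[r])
      strand <- sample(c("+", "-"), ns, replace = TRUE)
      functional <- sample(rep(c(TRUE, FALSE),
                               c(plan$n_functional[r],
                                 plan$n_nonfunctional[r])))
      for (k in seq_len(ns)) {
        ins <- if (strand[k] == "+") consensus else cons_rc
        bases[(pos[k] + 1):(pos[k] + width)] <- strsplit(ins, "")[[1]]
      }
      chip1 <- ifelse(functional,
                      stats::runif(ns, cfg$chip_functional[1],
                                   cfg$chip_functional[2]),
                      stats::runif(ns, cfg$chip_nonfunctional[1],
                                   cfg$chip_nonfunctional[2]))
      chip2 <- ifelse(functional,
                      stats::runif(ns, cfg$chip_functional[1],
                                   cfg$chip_functional[2]),
                      stats::runif(ns, cfg$chip_nonfunctional[1],
                                   cfg$chip_nonfunctional[2]))
      sites <- data.frame(
        site_id = paste0(plan$region[r], ":", pos, ":", strand),
        region = plan$region[r], start = pos, end = pos + width,
        strand = strand, functional = functional,
        gene_class = plan$gene_class[r],
        chip_oct4 = chip1, chip_sox2 = chip2,
        stringsAsFactors = FALSE)
    }
    seqs[r] <- paste(bases, collapse = "")
    lambdas[[r]] <- lambda_landscape(cfg, r, n)
    if (!is.null(sites)) motifs[[length(motifs) + 1L]] <- sites
  }
  names(seqs) <- plan$region
  names(lambdas) <- plan$region
  motifs <- if (length(motifs)) do.call(rbind, motifs) else NULL
  if (!is.null(motifs)) rownames(motifs) <- NULL
  structure(list(config = cfg, regions = regions, seqs = seqs,
                 lambda = lambdas, motifs = motifs,
                 classes = data.frame(region = plan$region,
                                      gene_class = plan$gene_class,
                                      stringsAsFactors = FALSE)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world: %d regions x %d bp, %d planted sites (%d functional), delta = %g\n",
    nrow(x$regions), x$config$region_length,
    if (is.null(x$motifs)) 0L else nrow(x$motifs),
    if (is.null(x$motifs)) 0L else sum(x$motifs$functional),
    x$config$delta))
  invisible(x)
}

# per-region center-sampling weights for one library kind
library_weights <- function(world, kind) {
  cfg <- world$config
  n <- cfg$region_length
  lapply(seq_len(nrow(world$regions)), function(r) {
    nm <- world$regions$name[r]
    wt <- switch(kind,
      invitro = world$lambda[[nm]],
      invivo = {
        lam <- world$lambda[[nm]]
        mot <- if (is.null(world$motifs)) NULL else
          world$motifs[world$motifs$region == nm &
                         world$motifs$functional, , drop = FALSE]
        if (!is.null(mot) && nrow(mot)) {
          for (k in seq_len(nrow(mot))) {
            ctr <- mot$start[k] + (cfg$motif$width - 1) / 2
            win <- which(abs(seq_len(n) - 1 - ctr) <= 73)
            lam[win] <- lam[win] * cfg$delta
          }
        }
        lam
      },
      naked = {
        gcp <- gc_fraction_profile(world$seqs[[nm]], 10)
        exp(cfg$gc_bias["a"] * gcp^2 + cfg$gc_bias["b"] * gcp +
              cfg$gc_bias["c"])
      },
      stop("unknown library kind: ", kind))
    m <- cfg$edge_margin
    wt[seq_len(m)] <- 0
    wt[(n - m + 1):n] <- 0
    wt
  })
}

#' Sample a fragment library from a world
#'
#' Fragment centers are drawn (multinomially, with replacement) from the
#' per-bp landscape of the requested library kind: in vitro proportional
#' to the intrinsic preference lambda; in vivo the same landscape with the
#' displacement factor delta applied over a 147 bp window centered on each
#' functional motif; naked proportional to `exp(F*(GC_i))` (uniform when
#' the bias coefficients are zero). Lengths are `fragment_length` +/-
#' uniform jitter; even-length fragments place the sampled center on one
#' of the two central basepairs at random, so center sampling is unbiased
#' for both parities.
#'
#' @param world a `synthetic_world`.
#' @param kind `"invitro"`, `"invivo"` or `"naked"`.
#' @param depth number of fragments (default from the config).
#' @param seed RNG seed; default derives a per-kind seed from the world
#'   seed so the three libraries are independent but reproducible.
#' @return Fragment data.frame (`chrom`, `start`, `end`, `length`).
#' @export
sample_library <- function(world, kind = c("invitro", "invivo", "naked"),
                           depth = NULL, seed = NULL) {
  kind <- match.arg(kind)
  cfg <- world$config
  if (is.null(depth)) depth <- cfg$depth
  if (is.null(seed))
    seed <- cfg$seed + match(kind, c("invitro", "invivo", "naked"))
  set.seed(seed)
  if (depth == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric()))
  wts <- library_weights(world, kind)
  totals <- vapply(wts, sum, numeric(1))
  per_region <- as.vector(stats::rmultinom(1, depth, totals))
  out <- vector("list", length(wts))
  for (r in seq_along(wts)) {
    k <- per_region[r]
    if (k == 0) next
    centers <- sample.int(cfg$region_length, k, replace = TRUE,
                          prob = wts[[r]]) - 1L   # 0-based center positions
    len <- cfg$fragment_length +
      sample.int(2L * cfg$length_jitter + 1L, k, replace = TRUE) -
      cfg$length_jitter - 1L
    odd <- len %% 2L == 1L
    half <- integer(k)
    half[odd] <- (len[odd] - 1L) %/% 2L
    half[!odd] <- len[!odd] %/% 2L -
      sample(c(0L, 1L), sum(!odd), replace = TRUE)
    start <- centers - half
    out[[r]] <- data.frame(chrom = world$regions$name[r], start = start,
                           end = start + len, length = len,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Write ground-truth tables for a world
#'
#' Emits everything the pipeline needs as inputs plus everything needed to
#' score recovery: `regions.tsv` (1-based inclusive), `regions.fa`,
#' `motifs.tsv` (planted-site truth), `chip.tsv` (site_id, oct4, sox2 —
#' functional sites score above the cutoff by construction),
#' `classes.tsv`, `lambda.tsv` (per-bp preference landscape) and
#' `gc_bias.json`.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  reg <- world$regions
  out <- data.frame(name = reg$name, chrom = reg$chrom,
                    start = reg$start + 1, end = reg$end,
                    length = reg$end - reg$start,
                    gene_class = reg$gene_class)
  utils::write.table(out, p("regions.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_region_sequences(world$seqs, p("regions.fa"))
  utils::write.table(world$motifs, p("motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(site_id = world$motifs$site_id,
               oct4 = world$motifs$chip_oct4,
               sox2 = world$motifs$chip_sox2),
    p("chip.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$classes, p("classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lam <- do.call(rbind, lapply(names(world$lambda), function(nm)
    data.frame(region = nm, pos = seq_along(world$lambda[[nm]]) - 1L,
               lambda = world$lambda[[nm]])))
  utils::write.table(lam, p("lambda.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(as.list(world$config$gc_bias), p("gc_bias.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a world and write all pipeline inputs to a directory
#'
#' Convenience wrapper: realizes the world, writes the truth tables and
#' the three fragment libraries (`invitro.bed`, `invivo.bed`,
#' `naked.bed`).
#'
#' @param config list from [world_config()].
#' @param outdir output directory.
#' @return The `synthetic_world`, invisibly.
#' @export
simulate_to_dir <- function(config = world_config(), outdir) {
  world <- make_world(config)
  write_truth(world, outdir)
  for (kind in c("invitro", "invivo", "naked"))
    write_fragments(sample_library(world, kind),
                    file.path(outdir, paste0(kind, ".bed")))
  invisible(world)
}
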