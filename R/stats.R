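# Comparative statistics: group means/SEM, median fold change, two-group
# z-test on group means, Spearman correlation between tracks, targeted-
# enrichment fold and on-target read QC.

sem <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x) / sqrt(length(x))
}

#' Group summaries of per-site occupancy and fold change
#'
#' One row per non-empty (gene_class, functional) cell: site count, mean
#' and standard error (n-1 sample SD / sqrt(n)) of the per-site occupancy
#' averages, and the median per-site log2 fold change (the median, not the
#' mean, because small in vitro averages produce extreme ratios that
#' dominate a mean).
#'
#' @param summaries data.frame from [site_occupancy_summary()] carrying
#'   `gene_class`, `functional`, `invivo_avg`, `invitro_avg`, `log2_fold`.
#' @param occupancy which per-site average to summarize: `"invivo"` or
#'   `"invitro"`.
#' @return data.frame with `gene_class`, `functional`, `n`,
#'   `mean_occupancy`, `sem`, `sem_defined` (FALSE when n = 1),
#'   `median_log2_fold`.
#' @export
summarize_groups <- function(summaries, occupancy = c("invivo", "invitro")) {
  occupancy <- match.arg(occupancy)
  col <- paste0(occupancy, "_avg")
  need <- c("gene_class", "functional", col, "log2_fold")
  stopifnot(all(need %in% names(summaries)))
  if (nrow(summaries) == 0L)
    return(data.frame(gene_class = character(), functional = logical(),
                      n = integer(), mean_occupancy = numeric(),
                      sem = numeric(), sem_defined = logical(),
                      median_log2_fold = numeric()))
  key <- interaction(summaries$gene_class, summaries$functional,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(summaries, key), function(g) {
    data.frame(gene_class = g$gene_class[1], functional = g$functional[1],
               n = nrow(g), mean_occupancy = mean(g[[col]]),
               sem = sem(g[[col]]), sem_defined = nrow(g) > 1L,
               median_log2_fold = stats::median(g$log2_fold),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_class, !out$functional), , drop = FALSE]
}

#' Two-group z-test on group means
#'
#' Compares the means of two groups of per-site values using
#' `z = (mean_a - mean_b) / sqrt(sem_a^2 + sem_b^2)` with a two-sided
#' p-value from the standard normal. The groups are unpaired (site sets of
#' different sizes have no natural pairing).
#'
#' @param a,b numeric vectors of per-site values, each of length >= 2.
#' @return List of class `group_comparison` with `z`, `p`, `mean_a`,
#'   `mean_b`, `sem_a`, `sem_b`, `n_a`, `n_b`.
#' @export
two_group_z <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("two_group_z needs n >= 2 in each group")
  se <- sqrt(sem(a)^2 + sem(b)^2)
  if (se == 0) {
    z <- 0
  } else {
    z <- (mean(a) - mean(b)) / se
  }
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)),
                 mean_a = mean(a), mean_b = mean(b),
                 sem_a = sem(a), sem_b = sem(b),
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("two-group z: z = %.3f, p = %.4g (n = %d vs %d)\n",
              x$z, x$p, x$n_a, x$n_b))
  invisible(x)
}

#' Spearman rank correlation between two tracks
#'
#' Rank correlation over all basepairs of two tracks covering identical
#' region sets (average ranks for ties). The p-value uses the large-sample
#' t approximation and is informational.
#'
#' @param track_a,track_b [occupancy_track()]s with identical regions.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_tracks <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "occupancy_track"),
            inherits(track_b, "occupancy_track"))
  if (!identical(track_a$regions[, c("name", "chrom", "start", "end")],
                 track_b$regions[, c("name", "chrom", "start", "end")]))
    stop("tracks must cover identical regions")
  va <- track_values(track_a)
  vb <- track_values(track_b)
  if (length(va) != length(vb)) stop("track length mismatch")
  rho <- stats::cor(va, vb, method = "spearman")
  n <- length(va)
  p <- if (abs(rho) >= 1 || n < 3) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Targeted-enrichment fold from clone counts and region size
#'
#' The probability of drawing an on-target molecule from an unenriched
#' pool is region bp over genome bp; from the enriched pool it is the
#' fraction of sequenced clones hitting the target. The ratio of the two
#' probabilities is the fold enrichment.
#'
#' @param on_target_clones,total_clones clone counts (on_target <= total).
#' @param region_bp,genome_bp target and genome sizes in bp.
#' @return List with `p_unenriched`, `p_enriched`, `fold`.
#' @export
enrichment_fold <- function(on_target_clones, total_clones,
                            region_bp, genome_bp) {
  if (total_clones <= 0 || genome_bp <= 0 || region_bp <= 0)
    stop("counts and sizes must be positive")
  if (on_target_clones > total_clones)
    stop("on-target clones exceed total clones")
  enrichment_fold_probs(on_target_clones / total_clones,
                        region_bp / genome_bp)
}

#' Enrichment fold from probabilities
#' @param p_enriched on-target probability in the enriched pool.
#' @param p_unenriched on-target probability in an unenriched pool.
#' @return List with `p_unenriched`, `p_enriched`, `fold`.
#' @export
enrichment_fold_probs <- function(p_enriched, p_unenriched) {
  stopifnot(p_unenriched > 0, p_unenriched <= 1,
            p_enriched >= 0, p_enriched <= 1)
  list(p_unenriched = p_unenriched, p_enriched = p_enriched,
       fold = p_enriched / p_unenriched)
}

#' Per-region on-target read ratios
#'
#' For each region, the expected read count distributes the total
#' sequencing reads proportionally to region length; the report gives
#' actual/expected per region plus the overall on-target fraction.
#'
#' @param read_counts named numeric vector of on-target reads per region
#'   (names matching `regions$name`) or unnamed in region-table order.
#' @param regions region data.frame.
#' @param total_reads total sequenced reads (>= sum of per-region counts).
#' @return data.frame with `name`, `length`, `actual`, `expected`,
#'   `ratio`; attribute `on_target_fraction`.
#' @export
on_target_report <- function(read_counts, regions, total_reads) {
  lens <- regions$end - regions$start
  if (sum(lens) <= 0) stop("region lengths sum to zero")
  if (!is.null(names(read_counts)))
    read_counts <- read_counts[regions$name]
  if (length(read_counts) != nrow(regions))
    stop("one read count per region required")
  if (total_reads < sum(read_counts))
    stop("total_reads smaller than the sum of per-region counts")
  expected <- total_reads * lens / sum(lens)
  out <- data.frame(name = regions$name, length = lens,
                    actual = as.numeric(read_counts), expected = expected,
                    ratio = as.numeric(read_counts) / expected,
                    stringsAsFactors = FALSE)
  attr(out, "on_target_fraction") <- sum(read_counts) / total_reads
  out
}
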