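# PWM scanning for composite Oct4/Sox2 sites, functional classification by
# ChIP occupancy, and per-site in vivo / in vitro occupancy comparison.

# log2-odds matrix from counts: per-cell pseudocount, column-normalized,
# against the motif background.
pwm_log_odds <- function(motif, pseudocount = 0.01) {
  cnt <- motif$counts + pseudocount
  p <- sweep(cnt, 2, colSums(cnt), "/")
  log2(sweep(p, 1, motif$background[rownames(p)], "/"))
}

# score every window start on one strand; windows containing non-ACGT get NA
pwm_window_scores <- function(codes, lom) {
  w <- ncol(lom)
  n <- length(codes)
  if (n < w) return(numeric(0))
  ns <- n - w + 1L
  acc <- numeric(ns)
  for (j in seq_len(w)) {
    sc <- lom[, j][codes[j:(ns + j - 1L)]]
    acc <- acc + sc  # NA codes propagate
  }
  acc
}

#' Scan a sequence for motif matches on both strands
#'
#' Scores every window of `motif$width` bp with a log2-odds matrix built
#' from the PFM counts (+ `pseudocount` per cell) against the motif
#' background. A window is reported when its relative score
#' `(score - min) / (max - min)` reaches `threshold` on either strand,
#' where min/max are the lowest/highest achievable log-odds scores. When
#' both strands pass at one position, the higher-scoring strand is
#' reported (tie: forward). Windows containing ambiguous bases are never
#' reported. Overlapping hits are all kept.
#'
#' @param sequence region nucleotide string.
#' @param motif a `motif_matrix` from [read_motif()].
#' @param threshold relative score cutoff in [0, 1] (default 0.8).
#' @param region region name stamped on the hits.
#' @param pseudocount per-cell pseudocount for the log-odds construction.
#' @return data.frame of predicted sites: `site_id`, `region`, `start`
#'   (0-based), `end`, `strand`, `score` (log2-odds), `rel_score`.
#' @export
scan_pwm <- function(sequence, motif, threshold = 0.8, region = "region",
                     pseudocount = 0.01) {
  w <- motif$width
  sequence <- toupper(sequence)
  if (nchar(sequence) < w)
    return(empty_sites())
  lom <- pwm_log_odds(motif, pseudocount)
  # minus strand: score of the window's reverse complement under lom ==
  # score of the window under the reverse-complemented matrix
  lom_rc <- lom[c("T", "G", "C", "A"), rev(seq_len(w)), drop = FALSE]
  rownames(lom_rc) <- c("A", "C", "G", "T")
  smin <- sum(apply(lom, 2, min))
  smax <- sum(apply(lom, 2, max))
  codes <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T"))
  fwd <- pwm_window_scores(codes, lom)
  rev_ <- pwm_window_scores(codes, lom_rc)
  rel_f <- (fwd - smin) / (smax - smin)
  rel_r <- (rev_ - smin) / (smax - smin)
  # numeric tolerance so a consensus window passes threshold 1.0 exactly
  eps <- 1e-9
  hit <- (!is.na(rel_f) & rel_f >= threshold - eps) |
    (!is.na(rel_r) & rel_r >= threshold - eps)
  hit[is.na(hit)] <- FALSE
  idx <- which(hit)
  if (!length(idx)) return(empty_sites())
  take_rev <- !is.na(rev_[idx]) &
    (is.na(fwd[idx]) | rev_[idx] > fwd[idx])      # tie -> forward
  strand <- ifelse(take_rev, "-", "+")
  score <- ifelse(take_rev, rev_[idx], fwd[idx])
  rel <- ifelse(take_rev, rel_r[idx], rel_f[idx])
  start0 <- idx - 1L
  data.frame(site_id = paste0(region, ":", start0, ":", strand),
             region = region, start = start0, end = start0 + w,
             strand = strand, score = score, rel_score = rel,
             stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(site_id = character(), region = character(),
             start = integer(), end = integer(), strand = character(),
             score = numeric(), rel_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Scan several region sequences at once
#' @param seqs named character vector of sequences.
#' @param motif a `motif_matrix`.
#' @param threshold relative score cutoff.
#' @param pseudocount per-cell pseudocount.
#' @return Row-bound site data.frame across regions.
#' @export
scan_pwm_regions <- function(seqs, motif, threshold = 0.8,
                             pseudocount = 0.01) {
  out <- lapply(names(seqs), function(nm)
    scan_pwm(seqs[[nm]], motif, threshold, region = nm,
             pseudocount = pseudocount))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify predicted sites as functional from ChIP occupancy
#'
#' Attaches Oct4 and Sox2 ChIP occupancy scores by `site_id`, averages
#' them, and flags a site functional when the mean reaches `cutoff`
#' (boundary included: mean == cutoff is functional). Sites without a ChIP
#' entry are scored 0 with a warning. A `gene_class` label is attached from
#' the declarative region-to-class map when given.
#'
#' @param sites site data.frame from [scan_pwm_regions()].
#' @param chip_table data.frame with columns `site_id`, `oct4`, `sox2`
#'   (non-negative occupancy scores).
#' @param cutoff functional threshold on the Oct4/Sox2 mean (default 20).
#' @param classes optional data.frame with `region`, `gene_class`.
#' @return `sites` with added `chip_oct4`, `chip_sox2`, `chip_mean`,
#'   `functional`, and (if `classes` given) `gene_class`.
#' @export
classify_sites <- function(sites, chip_table, cutoff = 20, classes = NULL) {
  stopifnot(all(c("site_id", "oct4", "sox2") %in% names(chip_table)))
  if (any(chip_table$oct4 < 0 | chip_table$sox2 < 0))
    stop("ChIP occupancy scores must be non-negative")
  m <- match(sites$site_id, chip_table$site_id)
  if (anyNA(m) && nrow(sites))
    warning(sum(is.na(m)), " site(s) without ChIP entry; scored 0")
  sites$chip_oct4 <- ifelse(is.na(m), 0, chip_table$oct4[m])
  sites$chip_sox2 <- ifelse(is.na(m), 0, chip_table$sox2[m])
  sites$chip_mean <- (sites$chip_oct4 + sites$chip_sox2) / 2
  sites$functional <- sites$chip_mean >= cutoff
  if (!is.null(classes)) {
    cm <- match(sites$region, classes$region)
    sites$gene_class <- classes$gene_class[cm]
  }
  sites
}

#' Mean adjusted occupancy over one site
#'
#' @param track GC-adjusted [occupancy_track()].
#' @param region region name.
#' @param start 0-based region-local start of the site.
#' @param width site width in bp (motif width, default 15).
#' @return Arithmetic mean of the `width` per-bp values.
#' @export
site_occupancy <- function(track, region, start, width = 15) {
  stopifnot(inherits(track, "occupancy_track"))
  v <- track$values[[region]]
  if (is.null(v)) stop("region not in track: ", region)
  if (start < 0 || start + width > length(v))
    stop(sprintf("site [%d, %d) extends past region '%s' (%d bp)",
                 start, start + width, region, length(v)))
  mean(v[(start + 1):(start + width)])
}

#' log2 in vivo / in vitro occupancy fold change
#'
#' Negative values mean the site carries fewer nucleosomes in vivo than
#' the sequence preference alone would place there (displacement).
#'
#' @param invivo_avg,invitro_avg per-site mean occupancies, both > 0
#'   (guaranteed upstream by the 0.01 GC-correction floor).
#' @return `log2(invivo_avg / invitro_avg)`.
#' @export
fold_change <- function(invivo_avg, invitro_avg) {
  if (any(invivo_avg <= 0) || any(invitro_avg <= 0))
    stop("fold_change requires positive occupancy averages")
  log2(invivo_avg / invitro_avg)
}

#' Per-site in vivo / in vitro occupancy summary
#'
#' For each classified site, averages the GC-adjusted occupancy over the
#' site's span in both tracks and takes the log2 ratio.
#'
#' @param sites classified site data.frame ([classify_sites()]).
#' @param invivo,invitro GC-adjusted [occupancy_track()]s over the same
#'   regions.
#' @return `sites` with added `invivo_avg`, `invitro_avg`, `log2_fold`.
#' @export
site_occupancy_summary <- function(sites, invivo, invitro) {
  wdt <- sites$end - sites$start
  sites$invivo_avg <- vapply(seq_len(nrow(sites)), function(i)
    site_occupancy(invivo, sites$region[i], sites$start[i], wdt[i]),
    numeric(1))
  sites$invitro_avg <- vapply(seq_len(nrow(sites)), function(i)
    site_occupancy(invitro, sites$region[i], sites$start[i], wdt[i]),
    numeric(1))
  sites$log2_fold <- fold_change(sites$invivo_avg, sites$invitro_avg)
  sites
}
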