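# Center-weighted occupancy: each fragment deposits a truncated Gaussian
# at its center. Odd-length fragments have one center; for even lengths the
# two central basepairs act as center in turn and the two profiles are
# averaged, so per-fragment mass is independent of length parity.

fragment_center_mass <- function(start, end) {
  len <- end - start
  if (len %% 2 == 1) {
    list(centers = start + (len - 1) / 2, mass = 1)
  } else {
    list(centers = c(start + len / 2 - 1, start + len / 2), mass = 0.5)
  }
}

#' Per-bp weight profile of one fragment
#'
#' @param start,end fragment interval, 0-based half-open.
#' @param kernel a [center_kernel()].
#' @return data.frame with `pos` (0-based genomic positions in the kernel
#'   support) and `weight`. For even-length fragments the two single-center
#'   profiles are averaged.
#' @export
fragment_weights <- function(start, end, kernel = center_kernel()) {
  stopifnot(end - start >= 1)
  cm <- fragment_center_mass(start, end)
  prof <- NULL
  for (c0 in cm$centers) {
    p <- data.frame(pos = c0 + kernel$offsets,
                    weight = cm$mass * kernel$weights)
    prof <- if (is.null(prof)) p else {
      m <- merge(prof, p, by = "pos", all = TRUE)
      m[is.na(m)] <- 0
      data.frame(pos = m$pos, weight = m$weight.x + m$weight.y)
    }
  }
  prof[order(prof$pos), , drop = FALSE]
}

#' Build a raw center-weighted occupancy track
#'
#' Accumulates fragment-center mass per genomic position (half mass at each
#' of the two central positions for even-length fragments), then convolves
#' with the truncated Gaussian kernel. Fragments whose kernel support
#' overlaps a region contribute their in-region weights even when the
#' center itself lies outside; weights falling outside every region are
#' discarded (no edge renormalization).
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_fragments()].
#' @param regions region data.frame from [read_regions()].
#' @param kernel a [center_kernel()].
#' @param dataset_label label stored on the track.
#' @return An [occupancy_track()] at stage `"raw"`.
#' @export
build_occupancy <- function(fragments, regions, kernel = center_kernel(),
                            dataset_label = "") {
  if (nrow(fragments) == 0L)
    warning("empty fragment stream: returning all-zero track")
  Tt <- kernel$truncation
  w <- kernel$weights
  values <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    n <- r$end - r$start
    fr <- fragments[fragments$chrom == r$chrom, , drop = FALSE]
    # center mass over the region extended by the kernel support
    ext <- numeric(n + 2L * Tt)      # index 1 <=> genomic pos r$start - Tt
    if (nrow(fr)) {
      len <- fr$end - fr$start
      odd <- len %% 2 == 1
      ctr <- c(fr$start[odd] + (len[odd] - 1) / 2,
               fr$start[!odd] + len[!odd] / 2 - 1,
               fr$start[!odd] + len[!odd] / 2)
      mss <- c(rep(1, sum(odd)), rep(0.5, 2L * sum(!odd)))
      idx <- ctr - (r$start - Tt) + 1
      inb <- idx >= 1 & idx <= length(ext)
      if (any(inb)) {
        tab <- rowsum(mss[inb], idx[inb])
        ext[as.numeric(rownames(tab))] <- ext[as.numeric(rownames(tab))] +
          tab[, 1]
      }
    }
    # occ[j] = sum_k w[k] * ext[j + 2T + 1 - k], exact (no FFT)
    occ <- numeric(n)
    for (k in seq_along(w)) {
      sl <- ext[(2L * Tt + 2L - k):(2L * Tt + 1L - k + n)]
      occ <- occ + w[k] * sl
    }
    values[[i]] <- occ
  }
  names(values) <- regions$name
  occupancy_track(regions, values, stage = "raw",
                  dataset_label = dataset_label)
}

#' Normalize a track by its dataset average
#'
#' Divides every per-bp score by the grand mean over all covered basepairs
#' of all regions in the track, so the normalized dataset average is
#' exactly 1.
#'
#' @param track raw [occupancy_track()].
#' @return Track at stage `"normalized"`.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "occupancy_track"))
  if (track$stage != "raw")
    stop("normalize_track expects a raw track, got stage ", track$stage)
  m <- track_mean(track)
  if (m <= 0) stop("normalization undefined: track mean is zero")
  occupancy_track(track$regions, lapply(track$values, function(v) v / m),
                  stage = "normalized", dataset_label = track$dataset_label)
}
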