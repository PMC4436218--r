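#' Per-basepair occupancy track over named genomic regions
#'
#' An `occupancy_track` holds one numeric vector of per-bp scores for each
#' targeted region, together with the region table and a processing stage.
#' Tracks move through three stages: `"raw"` (summed fragment-center
#' weights), `"normalized"` (divided by the grand mean so the dataset
#' average is 1), and `"gc_adjusted"` (divided by the fitted GC-bias factor
#' and floored at 0.01).
#'
#' @param regions data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open internal convention, see [read_regions()]).
#' @param values named list of numeric vectors, one per region, each of
#'   length `end - start`.
#' @param stage one of `"raw"`, `"normalized"`, `"gc_adjusted"`.
#' @param dataset_label free-text label (e.g. `"invivo"`).
#' @return An object of class `occupancy_track`.
#' @export
occupancy_track <- function(regions, values, stage = "raw",
                            dataset_label = "") {
  stage <- match.arg(stage, c("raw", "normalized", "gc_adjusted"))
  stopifnot(is.data.frame(regions),
            all(c("name", "chrom", "start", "end") %in% names(regions)),
            is.list(values))
  if (!setequal(names(values), regions$name))
    stop("values must be a named list matching regions$name")
  values <- values[regions$name]
  widths <- regions$end - regions$start
  ok <- vapply(seq_along(widths),
               function(i) length(values[[i]]) == widths[i], logical(1))
  if (!all(ok))
    stop("value vector length must equal region length for: ",
         paste(regions$name[!ok], collapse = ", "))
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("occupancy values must be non-negative")
  structure(list(regions = regions, values = values, stage = stage,
                 dataset_label = dataset_label),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  nbp <- sum(lengths(x$values))
  cat(sprintf("occupancy_track [%s] stage=%s: %d region(s), %s bp\n",
              x$dataset_label, x$stage, nrow(x$regions),
              format(nbp, big.mark = ",")))
  invisible(x)
}

#' Grand mean of a track over all covered basepairs
#' @param track an [occupancy_track()].
#' @return Scalar mean over every bp of every region.
#' @export
track_mean <- function(track) {
  stopifnot(inherits(track, "occupancy_track"))
  v <- unlist(track$values, use.names = FALSE)
  if (length(v) == 0L) stop("track covers zero basepairs")
  mean(v)
}

#' Concatenated per-bp values of a track
#' @param track an [occupancy_track()].
#' @return Numeric vector, regions in table order.
#' @export
track_values <- function(track) {
  unlist(track$values, use.names = FALSE)
}

#' Gaussian fragment-center weighting kernel
#'
#' The kernel assigns weight `exp(-0.5 * (d / sigma)^2)` to a position
#' `d` bp away from a fragment center, truncated to `|d| <= truncation`.
#' Defaults (`sigma = 20`, `truncation = 73`) give a weight of 1 at the
#' center, ~0.607 at 20 bp, and 0 beyond 73 bp, so a 147 bp mononucleosome
#' fragment is covered exactly by the support.
#'
#' @param sigma Gaussian width in bp.
#' @param truncation maximum |d| in bp with non-zero weight.
#' @return An object of class `center_kernel` with integer `offsets`
#'   (-truncation..truncation) and matching `weights`.
#' @export
center_kernel <- function(sigma = 20, truncation = 73) {
  stopifnot(sigma > 0, truncation >= 0, truncation == round(truncation))
  offsets <- seq.int(-truncation, truncation)
  structure(list(sigma = sigma, truncation = as.integer(truncation),
                 offsets = offsets,
                 weights = exp(-0.5 * (offsets / sigma)^2)),
            class = "center_kernel")
}

#' Total mass of a center kernel
#'
#' Sum of the truncated Gaussian weights; every fragment fully interior to
#' a region deposits exactly this mass regardless of its length parity.
#' @param kernel a [center_kernel()].
#' @return Scalar sum of weights.
#' @export
kernel_mass <- function(kernel) {
  stopifnot(inherits(kernel, "center_kernel"))
  sum(kernel$weights)
}
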