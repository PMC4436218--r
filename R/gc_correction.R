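# GC sequence-bias correction. MNase digestion and library preparation
# enrich GC-rich sequence; a naked-DNA MNase control carries that bias
# without nucleosome signal. The relation between log bin score and GC
# fraction is modelled as a quadratic F(GC) fit by OLS on 20 bp bins; per-bp
# correction divides the normalized score by exp(F(GC_i)) with GC_i taken
# over a +/-10 bp window, flooring the result at 0.01.

#' GC fraction profile of a sequence
#'
#' For every position i, the G/C fraction of the window
#' `[i - halfwidth, i + halfwidth]`, shrunk at the region edges to the
#' available bases. Ambiguous bases (anything other than A/C/G/T) are
#' excluded from both numerator and denominator; a window with no
#' unambiguous bases gets 0.5 with a warning.
#'
#' @param sequence nucleotide string (case-insensitive).
#' @param halfwidth window half-width in bp (default 10).
#' @return Numeric vector of length `nchar(sequence)`, values in [0, 1].
#' @export
gc_fraction_profile <- function(sequence, halfwidth = 10) {
  b <- strsplit(toupper(sequence), "")[[1]]
  n <- length(b)
  is_gc <- as.numeric(b %in% c("G", "C"))
  is_ok <- as.numeric(b %in% c("A", "C", "G", "T"))
  cg <- c(0, cumsum(is_gc))
  co <- c(0, cumsum(is_ok))
  i <- seq_len(n)
  lo <- pmax(i - halfwidth, 1L)
  hi <- pmin(i + halfwidth, n)
  num <- cg[hi + 1L] - cg[lo]
  den <- co[hi + 1L] - co[lo]
  out <- ifelse(den > 0, num / den, 0.5)
  if (any(den == 0))
    warning(sum(den == 0), " window(s) contained only ambiguous bases; ",
            "GC set to 0.5")
  out
}

#' GC fraction at a single position
#' @param sequence nucleotide string.
#' @param i 1-based position within the sequence.
#' @param halfwidth window half-width in bp.
#' @return GC fraction in [0, 1].
#' @export
gc_fraction_window <- function(sequence, i, halfwidth = 10) {
  stopifnot(i >= 1, i <= nchar(sequence))
  gc_fraction_profile(sequence, halfwidth)[i]
}

#' Bin a normalized control track into (S, GC) pairs
#'
#' Tiles each region in `bin_size` bp steps; each complete bin yields its
#' mean normalized score S and the G/C fraction of its bases. Trailing
#' partial bins are dropped and counted.
#'
#' @param track normalized [occupancy_track()] of the naked-DNA control.
#' @param seqs named character vector of region sequences (names matching
#'   `track$regions$name`).
#' @param bin_size bin width in bp (default 20).
#' @return data.frame with `region`, `bin_start` (0-based, region-local),
#'   `gc`, `S`; attribute `n_dropped_partial`.
#' @export
build_bin_table <- function(track, seqs, bin_size = 20) {
  stopifnot(inherits(track, "occupancy_track"))
  if (track$stage != "normalized")
    stop("build_bin_table expects a normalized track")
  missing <- setdiff(track$regions$name, names(seqs))
  if (length(missing))
    stop("missing sequence for region(s): ", paste(missing, collapse = ", "))
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(track$regions))) {
    r <- track$regions[i, ]
    v <- track$values[[r$name]]
    sq <- toupper(seqs[[r$name]])
    if (nchar(sq) != length(v))
      stop("sequence length mismatch for region ", r$name)
    nb <- length(v) %/% bin_size
    if (length(v) %% bin_size > 0) dropped <- dropped + 1L
    if (nb == 0L) next
    idx <- seq_len(nb * bin_size)
    grp <- rep(seq_len(nb), each = bin_size)
    S <- as.numeric(tapply(v[idx], grp, mean))
    bases <- strsplit(sq, "")[[1]][idx]
    gcn <- tapply(bases %in% c("G", "C"), grp, sum)
    okn <- tapply(bases %in% c("A", "C", "G", "T"), grp, sum)
    gc <- ifelse(okn > 0, as.numeric(gcn) / as.numeric(okn), 0.5)
    rows[[length(rows) + 1L]] <- data.frame(
      region = r$name, bin_start = (seq_len(nb) - 1L) * bin_size,
      gc = gc, S = S, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(), bin_start = integer(),
               gc = numeric(), S = numeric())
  rownames(out) <- NULL
  attr(out, "n_dropped_partial") <- dropped
  out
}

#' Fit the log-quadratic GC-bias model
#'
#' Ordinary least squares of `log(S)` on GC fraction and its square over
#' the bins of a naked-DNA control. Bins with S = 0 (log undefined) are
#' excluded without pseudocount and counted.
#'
#' @param bin_table data.frame from [build_bin_table()].
#' @param bin_size,window_halfwidth metadata stored on the model (bin width
#'   used for fitting; window half-width to use at application time).
#' @return Object of class `gc_model`: coefficients `a` (GC^2), `b` (GC),
#'   `c` (intercept) of `F(GC) = a*GC^2 + b*GC + c`, plus `n_bins_fit`,
#'   `n_excluded`, `bin_size`, `window_halfwidth`.
#' @export
fit_gc_model <- function(bin_table, bin_size = 20, window_halfwidth = 10) {
  use <- bin_table$S > 0
  n_excluded <- sum(!use)
  tab <- bin_table[use, , drop = FALSE]
  if (nrow(tab) < 3L)
    stop("GC model fit needs >= 3 bins with S > 0, got ", nrow(tab))
  fit <- stats::lm(log(S) ~ gc + I(gc^2), data = tab)
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["I(gc^2)"]), b = unname(cf["gc"]),
                 c = unname(cf["(Intercept)"]),
                 bin_size = bin_size, window_halfwidth = window_halfwidth,
                 n_bins_fit = nrow(tab), n_excluded = n_excluded),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat(sprintf(
    "gc_model: F(GC) = %.4g*GC^2 + %.4g*GC + %.4g  (fit on %d bins, %d excluded)\n",
    x$a, x$b, x$c, x$n_bins_fit, x$n_excluded))
  invisible(x)
}

#' Evaluate F(GC) for a fitted model
#' @param model a `gc_model`.
#' @param gc GC fractions in [0, 1].
#' @return `a*gc^2 + b*gc + c`.
#' @export
predict_gc_bias <- function(model, gc) {
  model$a * gc^2 + model$b * gc + model$c
}

#' Apply the GC-bias correction to a normalized track
#'
#' Divides each per-bp score S_i by `exp(F(GC_i))`, where GC_i is the G/C
#' fraction of the +/- `window_halfwidth` bp window around i, then floors
#' the result at `floor` (default 0.01). All region sequences are checked
#' before any value is written.
#'
#' @param track normalized [occupancy_track()].
#' @param seqs named character vector of region sequences.
#' @param model fitted [fit_gc_model()] object.
#' @param floor lower bound applied after division.
#' @return Track at stage `"gc_adjusted"` with all values `>= floor`.
#' @export
apply_gc_correction <- function(track, seqs, model, floor = 0.01) {
  stopifnot(inherits(track, "occupancy_track"), inherits(model, "gc_model"))
  if (track$stage != "normalized")
    stop("apply_gc_correction expects a normalized track")
  missing <- setdiff(track$regions$name, names(seqs))
  if (length(missing))
    stop("missing sequence for region(s): ", paste(missing, collapse = ", "))
  for (nm in track$regions$name)
    if (nchar(seqs[[nm]]) != length(track$values[[nm]]))
      stop("sequence length mismatch for region ", nm)
  values <- lapply(track$regions$name, function(nm) {
    gc <- gc_fraction_profile(seqs[[nm]], model$window_halfwidth)
    pmax(track$values[[nm]] / exp(predict_gc_bias(model, gc)), floor)
  })
  names(values) <- track$regions$name
  occupancy_track(track$regions, values, stage = "gc_adjusted",
                  dataset_label = track$dataset_label)
}

#' Serialize a GC model to JSON
#' @param model a `gc_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gc_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GC model from JSON
#' @param path JSON file written by [write_gc_model()].
#' @return A `gc_model`.
#' @export
read_gc_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("a", "b", "c", "bin_size", "window_halfwidth",
                "n_bins_fit", "n_excluded")], class = "gc_model")
}
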