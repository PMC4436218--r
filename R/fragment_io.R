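# I/O for region tables, fragment BED, JASPAR PFM, FASTA and bedGraph.
# Internal coordinates are 0-based half-open everywhere; 1-based inclusive
# conventions exist only at the region-table boundary.

#' Read a targeted-region table
#'
#' Reads a tab-separated table of enrichment regions (e.g. BAC target
#' regions) with 1-based inclusive coordinates, as printed in genome-browser
#' style tables, and converts to the package-internal 0-based half-open
#' convention. The reported `length` column equals the 1-based inclusive
#' span (`end - start + 1` on input coordinates) and is recomputed, never
#' trusted from the file.
#'
#' @param path tab-separated file with a header containing at least
#'   `name`, `chrom`, `start`, `end` (extra columns such as `gene` or
#'   `length` are carried along / ignored).
#' @return data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open), `length`, plus any extra input columns.
#' @export
read_regions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "chrom", "start", "end")
  if (!all(need %in% names(tab)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    s <- suppressWarnings(as.numeric(tab$start[i]))
    e <- suppressWarnings(as.numeric(tab$end[i]))
    if (is.na(s) || is.na(e))
      stop(sprintf("malformed region row at line %d of %s", i + 1L, path))
    if (s >= e)
      stop(sprintf("invalid region '%s' (line %d): start >= end",
                   tab$name[i], i + 1L))
  }
  if (anyDuplicated(tab$name))
    stop("duplicated region names in ", path)
  out <- tab
  out$start <- as.numeric(tab$start) - 1   # to 0-based half-open
  out$end <- as.numeric(tab$end)
  out$length <- out$end - out$start        # equals 1-based inclusive span
  out
}

#' Write a region table in 1-based inclusive coordinates
#' @param regions internal region data.frame (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  out <- regions[, c("name", "chrom", "start", "end")]
  out$start <- regions$start + 1
  out$length <- regions$end - regions$start
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read mononucleosome fragments from BED3
#'
#' Parses a BED file of aligned fragment intervals (0-based half-open).
#' Malformed lines — too few fields, non-numeric coordinates, inverted or
#' empty intervals, lengths above `length_cap` — are rejected and counted,
#' never silently dropped: `n_parsed + n_rejected (+ n_skipped)` equals the
#' number of non-comment, non-blank input lines. When `regions` is given,
#' records on chromosomes absent from the region table are skipped (counted
#' separately), not treated as errors.
#'
#' @param path BED3 file (chrom, start, end; extra columns ignored).
#' @param regions optional region data.frame acting as a chromosome filter.
#' @param length_cap maximum accepted fragment length in bp (default 500),
#'   rejecting malformed records.
#' @return data.frame with columns `chrom`, `start`, `end`, `length` and
#'   attributes `n_parsed`, `n_rejected`, `n_skipped`.
#' @export
read_fragments <- function(path, regions = NULL, length_cap = 500) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lines <- lines[keep]
  n <- length(lines)
  if (n == 0L) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric())
    attr(out, "n_parsed") <- 0L
    attr(out, "n_rejected") <- 0L
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  chrom <- vapply(fields, function(f) f[1], character(1))
  start <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 2) f[2] else NA_character_, character(1))))
  end <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 3) f[3] else NA_character_, character(1))))
  len <- end - start
  bad <- nf < 3L | is.na(start) | is.na(end) | start < 0 |
    len < 1 | len > length_cap
  skip <- rep(FALSE, n)
  if (!is.null(regions))
    skip <- !bad & !(chrom %in% regions$chrom)
  ok <- !bad & !skip
  out <- data.frame(chrom = chrom[ok], start = start[ok], end = end[ok],
                    length = len[ok], stringsAsFactors = FALSE)
  attr(out, "n_parsed") <- sum(ok)
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "n_skipped") <- sum(skip)
  out
}

#' Write fragments as BED3
#' @param fragments data.frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(
    data.frame(fragments$chrom,
               format(fragments$start, scientific = FALSE, trim = TRUE),
               format(fragments$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a position frequency matrix in JASPAR PFM text format
#'
#' Accepts the JASPAR flat format: an optional `>` header line followed by
#' four base rows, either bare numbers or `A [ 1 2 3 ]` style. All four
#' rows must have the same number of columns and every position must have
#' at least one positive count.
#'
#' @param path PFM text file.
#' @param background length-4 base frequencies (A, C, G, T) summing to 1;
#'   default uniform.
#' @return An object of class `motif_matrix`: list with `counts`
#'   (4 x width matrix, rows A/C/G/T), `width`, `background`, `name`.
#' @export
read_motif <- function(path, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- ""
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) != 4L)
    stop("PFM must have exactly 4 base rows, found ", length(lines))
  bases <- toupper(sub("^\\s*([ACGTacgt]).*", "\\1", lines))
  if (!all(grepl("^[ACGT]\\b|^[ACGT]\\s*\\[", lines, ignore.case = TRUE)))
    bases <- c("A", "C", "G", "T")  # bare-number variant, JASPAR row order
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  w <- lengths(rows)
  if (length(unique(w)) != 1L)
    stop("PFM format error: unequal row lengths (",
         paste(w, collapse = ","), ")")
  counts <- do.call(rbind, rows)
  rownames(counts) <- bases
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  motif_matrix(counts, background = background, name = name)
}

#' Construct a motif matrix from a count matrix
#' @param counts 4 x width non-negative matrix with rownames A, C, G, T.
#' @param background length-4 base frequencies summing to 1.
#' @param name optional motif label.
#' @return `motif_matrix` object.
#' @export
motif_matrix <- function(counts, background = rep(0.25, 4), name = "") {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  if (any(is.na(counts)) || any(counts < 0))
    stop("PFM counts must be non-negative numbers")
  if (ncol(counts) < 1L) stop("motif width must be >= 1")
  if (any(colSums(counts) <= 0))
    stop("every motif position needs at least one positive count")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1")
  structure(list(counts = counts, width = ncol(counts),
                 background = stats::setNames(background,
                                              c("A", "C", "G", "T")),
                 name = name),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix '%s': width %d, consensus %s\n",
              x$name, x$width, motif_consensus(x)))
  invisible(x)
}

#' Consensus string of a motif (highest count per position, ties -> first)
#' @param motif a `motif_matrix`.
#' @return Character string of length `motif$width`.
#' @export
motif_consensus <- function(motif) {
  paste(rownames(motif$counts)[apply(motif$counts, 2, which.max)],
        collapse = "")
}

#' Read region sequences from FASTA
#'
#' @param path FASTA file whose record names are region names.
#' @return Named character vector of upper-case sequences.
#' @export
read_region_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)),
                  sub("\\s.*$", "", names(ss)))
}

#' Write region sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Write an occupancy track as bedGraph
#'
#' Runs of equal value are collapsed to one bedGraph interval. Coordinates
#' are genomic (region chrom + offset), 0-based half-open as bedGraph
#' requires. A round trip through [read_track()] reproduces per-bp values
#' to within text-representation precision (< 1e-6).
#'
#' @param track an [occupancy_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "occupancy_track"))
  runs <- lapply(seq_len(nrow(track$regions)), function(i) {
    r <- track$regions[i, ]
    v <- track$values[[r$name]]
    if (length(v) == 0L) return(NULL)
    rle <- S4Vectors::Rle(v)
    list(chrom = rep(r$chrom, S4Vectors::nrun(rle)),
         start = r$start + S4Vectors::start(rle),  # 1-based GRanges
         width = S4Vectors::runLength(rle),
         score = S4Vectors::runValue(rle))
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  gr <- if (length(runs)) {
    GenomicRanges::GRanges(
      seqnames = unlist(lapply(runs, `[[`, "chrom")),
      ranges = IRanges::IRanges(
        start = unlist(lapply(runs, `[[`, "start")),
        width = unlist(lapply(runs, `[[`, "width"))),
      score = unlist(lapply(runs, `[[`, "score")))
  } else GenomicRanges::GRanges(score = numeric(0))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file back into an occupancy track
#'
#' @param path bedGraph file.
#' @param regions region data.frame giving the target layout; positions
#'   without a bedGraph interval get value 0.
#' @param stage stage label to stamp on the result.
#' @param dataset_label dataset label.
#' @return An [occupancy_track()].
#' @export
read_track <- function(path, regions, stage = "raw", dataset_label = "") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    v <- numeric(r$end - r$start)
    hit <- gr[as.character(GenomicRanges::seqnames(gr)) == r$chrom]
    if (length(hit)) {
      s0 <- GenomicRanges::start(hit) - 1  # back to 0-based
      e0 <- GenomicRanges::end(hit)
      for (j in seq_along(hit)) {
        a <- max(s0[j], r$start); b <- min(e0[j], r$end)
        if (a < b)
          v[(a - r$start + 1):(b - r$start)] <- hit$score[j]
      }
    }
    v
  })
  names(values) <- regions$name
  # a bedGraph holds finite stage information only by convention; caller says
  occupancy_track(regions, values, stage = stage,
                  dataset_label = dataset_label)
}
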