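#' @include AllClasses.R utils.R
NULL

.NARROWPEAK_EXTRA <- c(signalValue = "numeric", pValue = "numeric",
                       qValue = "numeric", peak = "integer")

# Light pre-validation of a BED-like file so malformed lines are reported
# with their line number; parsing itself is delegated to rtracklayer.
.validateBedLines <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    for (i in which(keep)) {
        fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(fields) < 3L)
            stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
        s <- suppressWarnings(as.numeric(fields[2L]))
        e <- suppressWarnings(as.numeric(fields[3L]))
        if (is.na(s) || is.na(e))
            stop(sprintf("malformed BED line %d: non-numeric coordinates",
                         i))
        if (s >= e)
            stop(sprintf("malformed BED line %d: start >= end", i))
    }
    sum(keep)
}

#' Read genomic intervals from BED or narrowPeak
#'
#' Reads BED3+ (and the 10-column MACS2 narrowPeak dialect, whose extra
#' columns are retained as metadata) into a `GRanges`. File coordinates are
#' 0-based half-open; the returned `GRanges` uses the usual 1-based closed
#' convention. Malformed lines raise an error naming the line number.
#'
#' @param path BED/narrowPeak file path.
#' @return a `GRanges`; empty files give an empty `GRanges`.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    n <- .validateBedLines(path)
    if (n == 0L) return(GenomicRanges::GRanges())
    firstData <- grep("^(#|track|browser)", readLines(path), invert = TRUE,
                      value = TRUE)[1L]
    nFields <- length(strsplit(firstData, "\t", fixed = TRUE)[[1]])
    if (nFields == 10L)
        rtracklayer::import(path, format = "BED",
                            extraCols = .NARROWPEAK_EXTRA)
    else
        rtracklayer::import(path, format = "BED")
}

#' Write genomic intervals as BED
#'
#' Writes BED3 by default (metadata columns dropped, so a
#' `readBed`/`writeBed` roundtrip is lossless for BED3); with
#' `keepExtras = TRUE` name/score/extra columns are written too.
#'
#' @param intervals a `GRanges`.
#' @param path output path.
#' @param keepExtras keep metadata columns.
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path, keepExtras = FALSE) {
    if (keepExtras) {
        rtracklayer::export(intervals, path, format = "BED")
    } else {
        # plain three-column BED (rtracklayer pads name/score/strand)
        df <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(intervals)),
            start = GenomicRanges::start(intervals) - 1L,
            end = GenomicRanges::end(intervals))
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Flatten intervals to their coverage union
#'
#' Merges overlapping and book-ended intervals (coverage-union semantics:
#' half-open intervals (0,10) and (10,20) merge to (0,20)).
#'
#' @param intervals a `GRanges`.
#' @return disjoint sorted `GRanges` with the same total coverage.
#' @export
flattenIntervals <- function(intervals) {
    GenomicRanges::reduce(intervals, ignore.strand = TRUE)
}

#' Fraction of reads in peaks (FRiP)
#'
#' Counts a read as in-peak when it shares at least 1 bp with the flattened
#' peak set, and divides by the number of retained reads. Reads overlapping
#' the optional exclusion set (e.g. a blacklist) are removed from numerator
#' and denominator first.
#'
#' @param reads,peaks `GRanges` of read (or fragment) and peak intervals.
#' @param exclude optional `GRanges` of regions to mask.
#' @param details return a list with `frip`, `n_reads`, `n_in_peaks`
#'   instead of the bare fraction.
#' @return fraction in \[0, 1\] (or the detail list).
#' @export
frip <- function(reads, peaks, exclude = NULL, details = FALSE) {
    if (!is.null(exclude) && length(exclude) > 0L) {
        hit <- GenomicRanges::countOverlaps(reads, exclude,
                                            ignore.strand = TRUE) > 0L
        reads <- reads[!hit]
    }
    n <- length(reads)
    if (n == 0L) stop("no reads retained after exclusion")
    flat <- flattenIntervals(peaks)
    inPeak <- GenomicRanges::countOverlaps(reads, flat, minoverlap = 1L,
                                           ignore.strand = TRUE) > 0L
    k <- sum(inPeak)
    if (details) list(frip = k / n, n_reads = n, n_in_peaks = k)
    else k / n
}

#' Genome fraction covered by peaks (rho)
#'
#' Flattened peak basepairs divided by total genome basepairs; the
#' expected in-peak fraction for uniformly distributed background reads.
#'
#' @param peaks a `GRanges`.
#' @param genome named numeric vector of chromosome lengths (bp), as from
#'   [readChromSizes()] or [genGenome()].
#' @return fraction in \[0, 1\].
#' @export
peakGenomeFraction <- function(peaks, genome) {
    if (is.null(names(genome)) || any(genome <= 0))
        stop("genome must be a named vector of positive lengths")
    if (length(peaks) == 0L) return(0)
    chr <- as.character(GenomicRanges::seqnames(peaks))
    if (!all(chr %in% names(genome)))
        stop("peak chromosome absent from genome table: ",
             paste(setdiff(unique(chr), names(genome)), collapse = ", "))
    if (any(GenomicRanges::end(peaks) > genome[chr]))
        stop("peak interval extends beyond chromosome end")
    sum(GenomicRanges::width(flattenIntervals(peaks))) / sum(genome)
}

#' Ratio of perturbed to unperturbed FRiP
#'
#' When several unperturbed FRiPs are supplied their median is used as the
#' reference.
#'
#' @param fripPerturbed FRiP of the perturbed sample.
#' @param fripUnperturbed FRiP (or vector of FRiPs) of unperturbed
#'   samples; must have positive (median) value.
#' @return the ratio.
#' @examples
#' fripRatio(0.1, c(0.2, 0.4, 0.3))  # 1/3
#' @export
fripRatio <- function(fripPerturbed, fripUnperturbed) {
    .assertNumber(fripPerturbed, "fripPerturbed", 0)
    ref <- median(fripUnperturbed)
    if (!is.finite(ref) || ref <= 0)
        stop("unperturbed reference FRiP must be positive")
    fripPerturbed / ref
}

#' Read/write chromosome sizes (UCSC chrom.sizes dialect)
#'
#' Two tab-separated columns: chromosome name and length in bp, no header.
#'
#' @param path file path.
#' @param genome named numeric vector of lengths.
#' @return `readChromSizes`: named numeric vector; `writeChromSizes`:
#'   `path` invisibly.
#' @export
readChromSizes <- function(path) {
    df <- read.table(path, header = FALSE, sep = "\t",
                     col.names = c("chrom", "length"),
                     stringsAsFactors = FALSE)
    if (any(df$length <= 0)) stop("chromosome lengths must be positive")
    setNames(as.numeric(df$length), df$chrom)
}

#' @rdname readChromSizes
#' @export
writeChromSizes <- function(genome, path) {
    write.table(data.frame(names(genome), as.numeric(genome)), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
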