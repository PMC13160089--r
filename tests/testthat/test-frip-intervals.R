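writeLinesTo <- function(lines) {
    path <- withr::local_tempfile(fileext = ".bed",
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

test_that("BED reading handles BED3, narrowPeak and malformed input", {
    path <- writeLinesTo(c("chr1\t0\t100", "chr2\t50\t80"))
    gr <- readBed(path)
    expect_equal(length(gr), 2L)
    expect_equal(GenomicRanges::start(gr), c(1L, 51L))  # 1-based internal
    expect_equal(GenomicRanges::end(gr), c(100L, 80L))

    empty <- writeLinesTo(character(0))
    expect_equal(length(readBed(empty)), 0L)

    np <- writeLinesTo(paste("chr1", 100, 400, "peak_1", 960, ".",
                             13.2, 45.1, 40.2, 150, sep = "\t"))
    grNp <- readBed(np)
    expect_equal(length(grNp), 1L)
    expect_equal(grNp$signalValue, 13.2)
    expect_equal(grNp$peak, 150L)

    bad <- writeLinesTo(c("chr1\t0\t100", "chr1\t200\t100"))
    expect_error(readBed(bad), "line 2")
    bad2 <- writeLinesTo("chr1\tx\t100")
    expect_error(readBed(bad2), "line 1")
})

test_that("BED3 writing roundtrips losslessly", {
    gr <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                 IRanges::IRanges(c(1, 51), c(100, 80)))
    path <- withr::local_tempfile(fileext = ".bed")
    writeBed(gr, path)
    back <- readBed(path)
    expect_equal(as.character(GenomicRanges::seqnames(back)),
                 c("chr1", "chr2"))
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
    expect_equal(readLines(path), c("chr1\t0\t100", "chr2\t50\t80"))
})

test_that("flattening merges overlapping and book-ended intervals", {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(1, 6, 11), end = c(10, 15, 20)))
    flat <- flattenIntervals(gr)
    expect_equal(length(flat), 1L)
    expect_equal(GenomicRanges::width(flat), 20L)
    disjoint <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(1, 50), end = c(10, 60)))
    expect_equal(length(flattenIntervals(disjoint)), 2L)
})

test_that("FRiP counts >=1 bp overlaps and honours exclusion", {
    peaks <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(101, 301), end = c(200, 400)))
    inside <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(110, 350, 390), width = 10))
    outside <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(1, 210, 500), width = 10))
    expect_equal(frip(inside, peaks), 1)
    expect_equal(frip(outside, peaks), 0)
    both <- c(inside, outside)
    expect_equal(frip(both, peaks), 0.5)
    st <- frip(both, peaks, details = TRUE)
    expect_equal(st$n_reads, 6L)
    expect_equal(st$n_in_peaks, 3L)

    # excluded reads leave numerator and denominator
    excl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50))
    expect_equal(frip(both, peaks, exclude = excl), 3 / 5)
    expect_error(frip(outside[1], peaks, exclude = excl), "no reads")

    # invariant under peak permutation and splitting into adjacent pieces
    shuffled <- peaks[c(2, 1)]
    split1 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(101, 151, 301), end = c(150, 200, 400)))
    expect_equal(frip(both, shuffled), frip(both, peaks))
    expect_equal(frip(both, split1), frip(both, peaks))
})

test_that("interval FRiP agrees exactly with the brute-force oracle", {
    for (seed in 1:40) {
        fx <- randomIntervalFixture(seed)
        expect_equal(frip(fx$reads, fx$peaks),
                     bruteForceFrip(fx$reads, fx$peaks))
    }
})

test_that("peak genome fraction is flattened bp over genome bp", {
    genome <- c(chr1 = 1000, chr2 = 2000)
    peaks <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
        IRanges::IRanges(start = c(1, 51, 101), end = c(100, 120, 400)))
    expect_equal(peakGenomeFraction(peaks, genome), 420 / 3000)
    expect_equal(peakGenomeFraction(GenomicRanges::GRanges(), genome), 0)
    whole <- GenomicRanges::GRanges(c("chr1", "chr2"),
        IRanges::IRanges(c(1, 1), c(1000, 2000)))
    expect_equal(peakGenomeFraction(whole, genome), 1)
    # the ~0.8% scale of CTCF peaks on a mammalian genome
    g3 <- c(chr1 = 3e9)
    p24 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 24e6))
    expect_equal(peakGenomeFraction(p24, g3), 0.008)
    beyond <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1100))
    expect_error(peakGenomeFraction(beyond, genome), "beyond")
    expect_error(peakGenomeFraction(p24, c(chrX = 100)), "absent")
})

test_that("FRiP ratio uses the median unperturbed reference", {
    expect_equal(fripRatio(0.2, 0.2), 1)
    expect_equal(fripRatio(0.2, 0.1), 2)
    expect_equal(fripRatio(0.1, c(0.2, 0.4, 0.3)), 1 / 3)
    expect_error(fripRatio(0.1, 0), "positive")
})

test_that("chrom.sizes tables roundtrip", {
    genome <- c(chr1 = 5000, chr2 = 2500)
    path <- withr::local_tempfile(fileext = ".chrom.sizes")
    writeChromSizes(genome, path)
    expect_equal(readChromSizes(path), genome)
})
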