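library(GenomicRanges)

annotDF <- function(probe_id, chrom, pos, genes) {
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos, genes = genes,
             stringsAsFactors = FALSE)
}

test_that("probes within the gap threshold form one region", {
  a <- annotDF(c("cg1", "cg2", "cg3"), "chr1", c(1000, 1100, 1250), "G1")
  rs <- buildRegions(a, verbose = FALSE)
  expect_equal(length(rs), 1L)
  expect_identical(regionProbes(rs)[[1L]], c("cg1", "cg2", "cg3"))
  expect_equal(start(regionRanges(rs)), 1000L)
  expect_equal(end(regionRanges(rs)), 1250L)
  expect_identical(mcols(regionRanges(rs))$context, "genic")
})

test_that("a gap beyond the threshold splits and small clusters are dropped", {
  a <- annotDF(c("cg1", "cg2", "cg3"), "chr1", c(1000, 1300, 1400), "G1")
  expect_equal(length(buildRegions(a, verbose = FALSE)), 0L)
  # a gap of exactly maxGap does not split (threshold inclusive)
  b <- annotDF(c("cg1", "cg2", "cg3"), "chr1", c(1000, 1200, 1400), "G1")
  expect_equal(length(buildRegions(b, verbose = FALSE)), 1L)
})

test_that("genic and intergenic probes never share a stratum", {
  a <- annotDF(c("A", "B", "C"), "chr1", c(100, 200, 300),
               c("X", "", "X"))
  # genic stratum {A, C} has gap 200 but only 2 probes; intergenic {B} has 1
  expect_equal(length(buildRegions(a, verbose = FALSE)), 0L)
  # with minProbes = 2 the genic pair is kept and B still is not
  rs <- buildRegions(a, minProbes = 2, verbose = FALSE)
  expect_equal(length(rs), 1L)
  expect_identical(regionProbes(rs)[[1L]], c("A", "C"))
})

test_that("a multi-gene probe can seed a region in each gene stratum", {
  a <- annotDF(paste0("cg", 1:4), "chr2", c(10, 110, 210, 310),
               c("G1;G2", "G1;G2", "G1;G2", "G1"))
  rs <- buildRegions(a, verbose = FALSE)
  expect_equal(length(rs), 2L)
  expect_setequal(mcols(regionRanges(rs))$gene, c("G1", "G2"))
  # collapsing genic duplicates by coordinates+probes keeps distinct sets
  rs2 <- buildRegions(a, collapseGenic = TRUE, verbose = FALSE)
  expect_equal(length(rs2), 2L)  # probe sets differ (G1 has cg4)
  a2 <- annotDF(paste0("cg", 1:3), "chr2", c(10, 110, 210), "G1;G2")
  expect_equal(length(buildRegions(a2, verbose = FALSE)), 2L)
  expect_equal(length(buildRegions(a2, collapseGenic = TRUE,
                                   verbose = FALSE)), 1L)
})

test_that("non-autosomal probes are excluded with a logged count", {
  a <- annotDF(paste0("cg", 1:6), c(rep("chr1", 3), "chrX", "chrY", "chrM"),
               c(100, 200, 300, 100, 100, 100), "G1")
  expect_message(rs <- buildRegions(a), "3 non-autosomal")
  expect_equal(length(rs), 1L)
})

test_that("probes at identical positions are kept with gap zero", {
  a <- annotDF(paste0("cg", 1:3), "chr1", c(500, 500, 600), "G1")
  rs <- buildRegions(a, verbose = FALSE)
  expect_equal(length(rs), 1L)
  expect_equal(mcols(regionRanges(rs))$n_probes, 3L)
})

test_that("construction is deterministic and raising maxGap never loses probes", {
  set.seed(11)
  n <- 300
  a <- annotDF(paste0("cg", seq_len(n)),
               sample(paste0("chr", 1:5), n, replace = TRUE),
               sample.int(50000, n),
               sample(c("", "GA", "GB", "GA;GB"), n, replace = TRUE))
  r1 <- buildRegions(a, verbose = FALSE)
  r2 <- buildRegions(a, verbose = FALSE)
  expect_identical(regionIds(r1), regionIds(r2))
  expect_identical(regionProbes(r1), regionProbes(r2))

  covered <- function(rs) length(unique(unlist(regionProbes(rs))))
  gaps <- c(100, 200, 400, 800)
  cov <- vapply(gaps,
                function(g) covered(buildRegions(a, maxGap = g,
                                                 verbose = FALSE)),
                numeric(1))
  expect_true(all(diff(cov) >= 0))

  # every region satisfies its invariants
  for (rs in list(r1)) {
    probes <- regionProbes(rs)
    posOf <- setNames(a$pos, a$probe_id)
    chromOf <- setNames(a$chrom, a$probe_id)
    for (i in seq_along(probes)) {
      pr <- probes[[i]]
      expect_gte(length(pr), 3L)
      expect_true(all(diff(posOf[pr]) >= 0))
      expect_true(all(diff(posOf[pr]) <= 200))
      expect_equal(length(unique(chromOf[pr])), 1L)
    }
  }
})

test_that("BED export/import round trip preserves regions and probes", {
  a <- annotDF(paste0("cg", 1:8), "chr3",
               c(100, 150, 220, 5000, 5100, 5150, 9000, 9050),
               c(rep("G1", 3), rep("", 3), "G2", "G2"))
  rs <- buildRegions(a, verbose = FALSE)
  expect_equal(length(rs), 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  exportRegionsBED(rs, path)
  bed <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(bed$start0, start(regionRanges(rs)) - 1L)  # 0-based export
  rs2 <- importRegionsBED(path, a)
  expect_identical(regionIds(rs2), regionIds(rs))
  expect_identical(unname(regionProbes(rs2)), unname(regionProbes(rs)))
})

test_that("generated genomes are recovered exactly by region building", {
  ds <- smallDataset(nSubjects = 8, nRegions = 50, seed = 5)
  rs <- buildRegions(ds, verbose = FALSE)
  truth <- S4Vectors::metadata(ds)$trueRegions
  expect_equal(length(rs), nrow(truth))
  m <- mcols(regionRanges(rs))
  key <- function(id, ...) sub("_.*$", "", id)
  expect_setequal(key(m$region_id), truth$region_id)
  got <- m$n_probes[match(truth$region_id, key(m$region_id))]
  expect_equal(got, truth$n_probes)
})
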