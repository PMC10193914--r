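#' Cluster CpG probes into candidate regions
#'
#' Autosomal probes are first split into genic and intergenic sets. Genic
#' probes are stratified per annotated gene (a probe annotated to several
#' genes can seed a region in each), intergenic probes per chromosome.
#' Within each stratum, probes sorted by position are grouped greedily:
#' consecutive probes no more than `maxGap` base pairs apart stay in one
#' cluster, and only clusters with at least `minProbes` probes are retained
#' as regions. Region coordinates span the first to the last probe
#' (1-based, inclusive).
#'
#' @param x a [MethylationDataset-class], a probe `GRanges` (named by probe
#'   id, with a `genes` `CharacterList` column) or an annotation data.frame
#'   as accepted by [MethylationDataset()].
#' @param maxGap maximum distance (bp) between consecutive probes within a
#'   region; the threshold is inclusive (a gap of exactly `maxGap` does not
#'   split). Default 200.
#' @param minProbes minimum number of probes for a region to be retained.
#'   Default 3.
#' @param collapseGenic merge genic regions that have identical coordinates
#'   and probe sets (arising from probes shared between genes) into one.
#' @param verbose log the number of non-autosomal probes removed.
#' @return a [CpGRegionSet-class], ordered by chromosome, start and context.
#' @examples
#' annot <- data.frame(probe_id = c("cg1", "cg2", "cg3"), chrom = "chr1",
#'                     pos = c(1000, 1100, 1250), genes = "GENE1")
#' buildRegions(annot)
#' @export
buildRegions <- function(x, maxGap = 200L, minProbes = 3L,
                         collapseGenic = FALSE, verbose = TRUE) {
  gr <- if (is(x, "MethylationDataset")) probeAnnotation(x)
        else .asProbeGRanges(x)
  maxGap <- as.integer(maxGap)
  minProbes <- as.integer(minProbes)

  auto <- .isAutosome(as.character(seqnames(gr)))
  if (any(!auto) && verbose)
    message(sum(!auto), " non-autosomal probe(s) excluded")
  gr <- gr[auto]

  out <- list()
  if (length(gr)) {
    nGenes <- lengths(mcols(gr)$genes)
    genic <- gr[nGenes > 0L]
    intergenic <- gr[nGenes == 0L]

    if (length(genic)) {
      geneOf <- mcols(genic)$genes
      idx <- rep(seq_along(genic), lengths(geneOf))
      gene <- unlist(geneOf, use.names = FALSE)
      for (g in unique(gene)) {
        sub <- genic[idx[gene == g]]
        for (ch in unique(as.character(seqnames(sub)))) {
          out <- c(out, .clusterStratum(
            sub[as.character(seqnames(sub)) == ch], maxGap, minProbes,
            context = "genic", gene = g))
        }
      }
    }
    if (length(intergenic)) {
      for (ch in unique(as.character(seqnames(intergenic)))) {
        sub <- intergenic[as.character(seqnames(intergenic)) == ch]
        out <- c(out, .clusterStratum(sub, maxGap, minProbes,
                                      context = "intergenic", gene = NA))
      }
    }
  }

  regions <- if (length(out)) {
    df <- do.call(rbind, out)
    g <- GRanges(df$chrom, IRanges(df$start, df$end),
                 region_id = df$region_id, context = df$context,
                 gene = df$gene,
                 probes = IRanges::CharacterList(df$probes),
                 n_probes = lengths(df$probes))
    g[order(as.character(seqnames(g)), start(g), mcols(g)$context,
            ifelse(is.na(mcols(g)$gene), "", mcols(g)$gene))]
  } else {
    GRanges(region_id = character(), context = character(),
            gene = character(),
            probes = IRanges::CharacterList(),
            n_probes = integer())
  }
  if (collapseGenic && length(regions)) {
    key <- paste(mcols(regions)$region_id,
                 vapply(mcols(regions)$probes, paste, "", collapse = ","))
    regions <- regions[!duplicated(key)]
  }
  mcols(regions)$region_id <- .uniquifyIds(mcols(regions)$region_id,
                                           mcols(regions)$gene)
  new("CpGRegionSet", regions = regions, maxGap = maxGap,
      minProbes = minProbes)
}

.isAutosome <- function(chrom) {
  ch <- sub("^chr", "", chrom, ignore.case = TRUE)
  ok <- grepl("^[0-9]+$", ch)
  n <- suppressWarnings(as.integer(ch))
  ok & !is.na(n) & n >= 1L & n <= 22L
}

.clusterStratum <- function(gr, maxGap, minProbes, context, gene) {
  o <- order(start(gr))
  gr <- gr[o]
  pos <- start(gr)
  grp <- cumsum(c(1L, as.integer(diff(pos) > maxGap)))
  res <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    if (sum(sel) < minProbes) next
    p <- pos[sel]
    res[[length(res) + 1L]] <- data.frame(
      chrom = as.character(seqnames(gr))[which(sel)[1L]],
      start = min(p), end = max(p),
      region_id = sprintf("%s:%d-%d",
                          as.character(seqnames(gr))[which(sel)[1L]],
                          min(p), max(p)),
      context = context, gene = gene,
      probes = I(list(names(gr)[sel])))
  }
  res
}

.uniquifyIds <- function(ids, gene) {
  dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
  if (any(dup)) {
    suffix <- ifelse(is.na(gene), "intergenic", gene)
    ids[dup] <- paste0(ids[dup], "_", suffix[dup])
    ids <- make.unique(ids, sep = "_")
  }
  ids
}

#' @describeIn CpGRegionSet-class number of regions
#' @param x a `CpGRegionSet`
#' @export
setMethod("length", "CpGRegionSet", function(x) length(x@regions))

#' @describeIn CpGRegionSet-class brief summary
#' @param object a `CpGRegionSet`
#' @export
setMethod("show", "CpGRegionSet", function(object) {
  m <- mcols(object@regions)
  cat(sprintf(
    "CpGRegionSet: %d regions (%d genic, %d intergenic), maxGap = %d bp, minProbes = %d\n",
    length(object), sum(m$context == "genic"),
    sum(m$context == "intergenic"), object@maxGap, object@minProbes))
})

#' @describeIn CpGRegionSet-class subset regions
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "CpGRegionSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, regions = x@regions[i])
})

#' Region accessors
#'
#' `regionRanges()` returns the underlying `GRanges`; `regionIds()` the
#' region identifiers; `regionProbes()` a named `CharacterList` of probe ids
#' per region (ordered by genomic position).
#'
#' @param x a [CpGRegionSet-class]
#' @name region-accessors
#' @export
regionRanges <- function(x) x@regions

#' @rdname region-accessors
#' @export
regionIds <- function(x) mcols(x@regions)$region_id

#' @rdname region-accessors
#' @export
regionProbes <- function(x) {
  p <- mcols(x@regions)$probes
  names(p) <- regionIds(x)
  p
}

#' Export/import regions as BED-like TSV
#'
#' The export writes `chrom, start0, end, region_id, context` with 0-based
#' half-open coordinates (the package is 1-based inclusive internally; the
#' conversion happens only here). The import re-derives probe membership
#' from a probe annotation: probes inside the interval whose genic status
#' matches the region's context.
#'
#' @param x a [CpGRegionSet-class]
#' @param path TSV path
#' @return `exportRegionsBED` invisibly returns `path`;
#'   `importRegionsBED` returns a [CpGRegionSet-class].
#' @export
exportRegionsBED <- function(x, path) {
  m <- mcols(x@regions)
  utils::write.table(
    data.frame(chrom = as.character(seqnames(x@regions)),
               start0 = start(x@regions) - 1L,
               end = end(x@regions),
               region_id = m$region_id,
               context = m$context),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportRegionsBED
#' @param annotation probe annotation (see [buildRegions()]) used to recover
#'   probe membership.
#' @param minProbes regions with fewer matching probes are dropped.
#' @export
importRegionsBED <- function(path, annotation, minProbes = 3L) {
  bed <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  gr <- .asProbeGRanges(annotation)
  genic <- lengths(mcols(gr)$genes) > 0L
  rows <- list()
  for (i in seq_len(nrow(bed))) {
    want <- as.character(seqnames(gr)) == bed$chrom[i] &
      start(gr) >= bed$start0[i] + 1L & start(gr) <= bed$end[i] &
      (genic == (bed$context[i] == "genic"))
    probes <- names(gr)[want][order(start(gr)[want])]
    if (length(probes) < minProbes) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = bed$chrom[i], start = bed$start0[i] + 1L, end = bed$end[i],
      region_id = bed$region_id[i], context = bed$context[i],
      gene = NA_character_, probes = I(list(probes)))
  }
  regions <- if (length(rows)) {
    df <- do.call(rbind, rows)
    GRanges(df$chrom, IRanges(df$start, df$end), region_id = df$region_id,
            context = df$context, gene = df$gene,
            probes = IRanges::CharacterList(df$probes),
            n_probes = lengths(df$probes))
  } else {
    GRanges(region_id = character(), context = character(),
            gene = character(), probes = IRanges::CharacterList(),
            n_probes = integer())
  }
  new("CpGRegionSet", regions = regions, maxGap = NA_integer_,
      minProbes = as.integer(minProbes))
}
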