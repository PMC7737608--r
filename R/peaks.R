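#' Read a peak set from BED
#'
#' Ingests a BED file (0-based half-open intervals) into a normalised
#' `PeakSet`: a data frame of `chrom`, `start`, `end` (0-based half-open)
#' and optional `score`, sorted within chromosome.
#'
#' @param path Path to a BED file.
#' @return A data frame of class `PeakSet`.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  as_peak_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    score = if (!is.null(gr$score)) gr$score else NA_real_
  ))
}

#' Validate and normalise a peak set
#'
#' @param peaks Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `score`.
#' @return The sorted, validated data frame with class `PeakSet`.
#' @export
as_peak_set <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$start >= peaks$end)) {
    ps_stop("peak intervals must satisfy start < end", "ps_peaks")
  }
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("PeakSet", "data.frame")
  peaks
}

# 0-based half-open intervals -> GRanges (1-based closed)
granges_0based <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1L, end = end),
                         strand = strand)
}

#' Map ChIP peaks to genes
#'
#' Assigns peaks to genes with the precedence promoter > gene body >
#' nearest gene: a peak overlapping the promoter window (1,000 bp upstream
#' to 200 bp downstream of a TSS, strand-aware) maps to that gene; a peak
#' overlapping a gene body maps to that gene; any remaining (intergenic)
#' peak within `max_distance` of a gene body is assigned to the single
#' closest gene. A peak can map to several genes via promoter or body
#' overlap but to exactly one via the nearest-gene rule.
#'
#' @param peaks A `PeakSet` (see [as_peak_set()]; coordinates 0-based
#'   half-open).
#' @param genes Data frame with columns `gene`, `chrom`, `strand`
#'   (`+`/`-`), `tss`, `body_start`, `body_end` (0-based half-open; `tss`
#'   is a 0-based position).
#' @param upstream,downstream Promoter window extents around the TSS
#'   (defaults 1,000 and 200 bp).
#' @param max_distance Maximum peak-to-gene distance for the nearest-gene
#'   rule (default 50,000 bp).
#' @return List with `bound` (named logical per gene), `assignments`
#'   (data frame: peak index, gene, rule in promoter/body/nearest) and
#'   `unmapped` (indices of unassigned peaks).
#' @export
map_peaks_to_genes <- function(peaks, genes, upstream = 1000, downstream = 200,
                               max_distance = 50000) {
  peaks <- as_peak_set(peaks)
  need <- c("gene", "chrom", "strand", "tss", "body_start", "body_end")
  stopifnot(all(need %in% names(genes)))
  if (!all(genes$strand %in% c("+", "-"))) {
    bad <- setdiff(unique(genes$strand), c("+", "-"))
    ps_stop(paste0("unknown strand symbol: ", paste(bad, collapse = ", ")),
            "ps_strand")
  }
  pk <- granges_0based(peaks$chrom, peaks$start, peaks$end)
  plus <- genes$strand == "+"
  prom_start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  prom_end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  prom <- granges_0based(genes$chrom, pmax(prom_start, 0), prom_end)
  body <- granges_0based(genes$chrom, genes$body_start, genes$body_end)

  hit_prom <- GenomicRanges::findOverlaps(pk, prom)
  hit_body <- GenomicRanges::findOverlaps(pk, body)
  hit_df <- function(hits, rule) {
    q <- S4Vectors::queryHits(hits)
    data.frame(peak = q, gene = genes$gene[S4Vectors::subjectHits(hits)],
               rule = rep(rule, length(q)))
  }
  asg <- rbind(hit_df(hit_prom, "promoter"), hit_df(hit_body, "body"))
  # promoter beats body for the same (peak, gene)
  asg <- asg[!duplicated(asg[, c("peak", "gene")]), , drop = FALSE]

  left <- setdiff(seq_along(pk), unique(asg$peak))
  if (length(left)) {
    nearest <- GenomicRanges::distanceToNearest(pk[left], body)
    qh <- S4Vectors::queryHits(nearest)
    dist <- S4Vectors::mcols(nearest)$distance
    ok <- dist <= max_distance
    if (any(ok)) {
      asg <- rbind(asg, data.frame(
        peak = left[qh[ok]],
        gene = genes$gene[S4Vectors::subjectHits(nearest)[ok]],
        rule = rep("nearest", sum(ok))))
    }
  }
  asg <- asg[order(asg$peak, asg$gene), , drop = FALSE]
  rownames(asg) <- NULL
  bound <- stats::setNames(genes$gene %in% asg$gene, genes$gene)
  list(bound = bound, assignments = asg,
       unmapped = setdiff(seq_along(pk), unique(asg$peak)))
}

#' Enrichment of TF binding among differentially expressed genes
#'
#' Tests, separately for up- and downregulated genes, whether a TF's bound
#' genes overlap its DE genes more than expected by chance: fold
#' enrichment is observed overlap over the expected overlap `nK/N`, and
#' the p-value is the hypergeometric upper tail.
#'
#' @param de_genes_up,de_genes_down Character vectors of up-/downregulated
#'   genes for the TF (either may be empty; empty sets are flagged as
#'   not computed).
#' @param bound_genes Character vector of genes with a mapped peak for the
#'   TF.
#' @param universe Character vector covering all genes under consideration
#'   (must contain both gene lists).
#' @return Data frame with one row per direction: direction, n_de,
#'   n_bound, overlap, expected, enrichment, p, computed.
#' @export
binding_expression_enrichment <- function(de_genes_up, de_genes_down,
                                          bound_genes, universe) {
  universe <- unique(universe)
  sets <- list(up = unique(de_genes_up), down = unique(de_genes_down))
  bound <- intersect(unique(bound_genes), universe)
  for (s in sets) {
    if (!all(s %in% universe)) {
      ps_stop("universe must cover the DE gene lists", "ps_universe")
    }
  }
  do.call(rbind, lapply(names(sets), function(dir) {
    de <- sets[[dir]]
    if (length(de) == 0) {
      return(data.frame(direction = dir, n_de = 0L, n_bound = length(bound),
                        overlap = NA_integer_, expected = NA_real_,
                        enrichment = NA_real_, p = NA_real_, computed = FALSE))
    }
    k <- length(intersect(de, bound))
    hg <- hypergeom_overlap(k, K = length(bound), n = length(de),
                            N = length(universe))
    data.frame(direction = dir, n_de = length(de), n_bound = length(bound),
               overlap = k, expected = hg$expected,
               enrichment = if (hg$expected > 0) k / hg$expected else NA_real_,
               p = hg$p, computed = TRUE)
  }))
}
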