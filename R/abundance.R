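#' Build a gene count table
#'
#' Wraps a genes-by-samples read-count matrix in a
#' \code{SummarizedExperiment} with the per-sample total-mapped-read
#' denominators (which may exceed the column sums: the catalog never
#' captures every mapped read) in \code{colData}, and optional gene
#' lengths / CAZyme family / taxon labels in \code{rowData}.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @param totalMapped numeric vector of total mapped reads per sample
#'   (recycled names from \code{colnames(counts)} if unnamed).
#' @param lengthBp optional gene lengths in bp (for RPKM).
#' @param family,taxon optional per-gene labels.
#' @param group optional per-sample group label (e.g. surface,
#'   bathypelagic, hadal).
#' @return A \code{SummarizedExperiment} with assay \code{"counts"}.
#' @export
countTable <- function(counts, totalMapped, lengthBp = NULL, family = NULL,
                       taxon = NULL, group = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(names(totalMapped))) names(totalMapped) <- colnames(counts)
  totalMapped <- totalMapped[colnames(counts)]
  if (anyNA(totalMapped)) stop("totalMapped must cover every sample")
  if (any(totalMapped < colSums(counts)))
    stop("total mapped reads must be >= the column sum of each sample")
  cd <- S4Vectors::DataFrame(total_mapped = as.numeric(totalMapped),
                             row.names = colnames(counts))
  if (!is.null(group)) cd$group <- as.character(group)
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(lengthBp)) rd$length_bp <- as.numeric(lengthBp)
  if (!is.null(family)) rd$family <- as.character(family)
  if (!is.null(taxon)) rd$taxon <- as.character(taxon)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
}

#' Depth and length normalization of gene counts
#'
#' \code{calcCPM} computes copies per million mapped reads,
#' \code{count / total_mapped * 1e6}, using each sample's total
#' mapped-read count (not the in-table column sum) as denominator.
#' \code{calcRPKM} computes reads per kilobase per million mapped reads,
#' \code{count / (length_kb * total_mapped / 1e6)}.
#'
#' @param se a \code{SummarizedExperiment} from [countTable()].
#' @return The input with an added assay \code{"cpm"} / \code{"rpkm"}.
#' @examples
#' se <- countTable(matrix(c(5, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1")),
#'                  totalMapped = c(s1 = 1e6), lengthBp = c(1000, 500))
#' SummarizedExperiment::assay(calcCPM(se), "cpm")
#' @export
calcCPM <- function(se) {
  tm <- SummarizedExperiment::colData(se)$total_mapped
  if (is.null(tm)) stop("colData must carry total_mapped")
  if (any(tm <= 0)) stop("total_mapped must be positive")
  cts <- SummarizedExperiment::assay(se, "counts")
  SummarizedExperiment::assay(se, "cpm") <-
    sweep(cts, 2, tm, "/") * 1e6
  se
}

#' @rdname calcCPM
#' @export
calcRPKM <- function(se) {
  tm <- SummarizedExperiment::colData(se)$total_mapped
  if (is.null(tm)) stop("colData must carry total_mapped")
  if (any(tm <= 0)) stop("total_mapped must be positive")
  len <- SummarizedExperiment::rowData(se)$length_bp
  if (is.null(len) || anyNA(len) || any(len <= 0))
    stop("rowData must carry positive length_bp for every gene")
  cts <- SummarizedExperiment::assay(se, "counts")
  SummarizedExperiment::assay(se, "rpkm") <-
    sweep(sweep(cts, 1, len / 1e3, "/"), 2, tm / 1e6, "/")
  se
}

#' CAZyme gene density of a genome
#'
#' Number of genes carrying at least one CAZyme family per megabase of
#' assembled sequence.
#'
#' @param genome a [GenomeAnnotation-class].
#' @return Genes per Mb.
#' @export
cazymeDensity <- function(genome) {
  tot <- sum(BiocGenerics::width(contigs(genome)))
  if (tot == 0) stop("genome has zero assembled length")
  n <- sum(lengths(genes(genome)$cazyme_families) > 0)
  n / (tot / 1e6)
}

#' Shannon diversity
#'
#' \eqn{H = -\sum p_i \ln p_i} over relative abundances (natural log,
#' zero entries omitted). Thin wrapper over \code{vegan::diversity} with
#' the input checks the pipeline relies on.
#'
#' @param x non-negative abundance vector with positive sum.
#' @return Shannon index (nats).
#' @export
shannonIndex <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) <= 0) stop("abundance vector must have positive sum")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{\sum |a_i - b_i| / \sum (a_i + b_i)} between two abundance
#' vectors (via \code{vegan::vegdist}); 0 for identical profiles, 1 for
#' disjoint supports.
#'
#' @param a,b non-negative vectors of equal length, not both all-zero.
#' @return Dissimilarity in [0, 1].
#' @export
brayCurtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  if (sum(a) + sum(b) <= 0) stop("vectors must not both be all-zero")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' @rdname brayCurtis
#' @param counts samples-by-features abundance matrix.
#' @return \code{brayCurtisMatrix}: a \code{dist} of pairwise sample
#'   dissimilarities (the input ordination methods like NMDS consume).
#' @export
brayCurtisMatrix <- function(counts) {
  vegan::vegdist(counts, method = "bray")
}

#' Two-group Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison with mid-ranks for
#' ties. For pooled sizes up to \code{exactMax} all group splits are
#' enumerated exactly; beyond that a seeded Monte-Carlo permutation null
#' is used. The p-value is the (add-one-smoothed, for permutations)
#' proportion of splits whose statistic is at least as far from its null
#' mean as observed.
#'
#' @param x,y numeric vectors, each with >= 2 observations.
#' @param nPerm permutations when enumeration is infeasible.
#' @param seed RNG seed for the permutation null.
#' @param exactMax largest pooled size for exhaustive enumeration.
#' @return list with \code{statistic} (Mann-Whitney U of \code{x}),
#'   \code{p.value} and \code{method}.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p.value  # exact: 0.1
#' @export
rankSumTest <- function(x, y, nPerm = 10000L, seed = 1L, exactMax = 12L) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs >= 2 observations")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))              # mid-ranks for ties
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  obs <- abs(U - mu)
  eps <- 1e-9
  if (n <= exactMax) {
    splits <- utils::combn(n, n1)
    Us <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= obs - eps)
    method <- "exact enumeration"
  } else {
    cnt <- withSeed(seed, {
      sum(vapply(seq_len(nPerm), function(k) {
        rs <- sum(sample(r, n1)) - n1 * (n1 + 1) / 2
        abs(rs - mu) >= obs - eps
      }, logical(1)))
    })
    p <- (1 + cnt) / (1 + nPerm)
    method <- sprintf("permutation (n=%d)", nPerm)
  }
  list(statistic = c(U = U), p.value = p, method = method)
}

#' Write / read a count table TSV
#'
#' Plain-text serialization of a [countTable()] object: a
#' \code{#total_mapped} header line carrying the per-sample denominators,
#' then a genes-by-samples table with optional \code{length_bp} and
#' \code{family} columns.
#'
#' @param se a \code{SummarizedExperiment} from [countTable()].
#' @param path TSV path.
#' @return \code{readCountTable}: the reconstructed
#'   \code{SummarizedExperiment}.
#' @export
writeCountTable <- function(se, path) {
  cts <- SummarizedExperiment::assay(se, "counts")
  rd <- SummarizedExperiment::rowData(se)
  cd <- SummarizedExperiment::colData(se)
  extra <- intersect(c("length_bp", "family"), colnames(rd))
  df <- cbind(data.frame(gene_id = rownames(cts)),
              as.data.frame(rd[, extra, drop = FALSE]),
              as.data.frame(cts, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#total_mapped", rep("", 1 + length(extra)),
                     cd$total_mapped), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#total_mapped"))
    stop("count table must start with a #total_mapped line")
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE)
  meta <- intersect(c("gene_id", "length_bp", "family"), colnames(df))
  samples <- setdiff(colnames(df), meta)
  cts <- as.matrix(df[, samples, drop = FALSE])
  rownames(cts) <- df$gene_id
  tm <- as.numeric(utils::tail(strsplit(first, "\t")[[1]], length(samples)))
  countTable(cts, stats::setNames(tm, samples),
             lengthBp = if ("length_bp" %in% meta) df$length_bp,
             family = if ("family" %in% meta) df$family)
}
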