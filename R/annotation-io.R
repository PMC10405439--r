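#' Read an annotated genome bundle
#'
#' Builds a [GenomeAnnotation-class] from the four files a typical
#' Prokka + dbCAN-style annotation run leaves behind: a GFF3 of CDS
#' features, the nucleotide contigs and protein sequences as FASTA, and a
#' per-gene feature table (TSV with columns \code{gene_id},
#' \code{domains}, \code{cazyme_families}; the last two comma-joined).
#' CDS \code{ID} attributes must match the protein FASTA headers and the
#' feature-table \code{gene_id} column. Genes absent from the feature
#' table get empty domain/CAZyme sets.
#'
#' @param gffPath path to a GFF3 file with CDS features.
#' @param contigFasta path to the nucleotide FASTA.
#' @param proteinFasta path to the protein FASTA.
#' @param featureTSV path to the per-gene feature table.
#' @param genomeID genome identifier; defaults to the GFF file stem.
#' @return A [GenomeAnnotation-class].
#' @examples
#' d <- tempfile(); dir.create(d)
#' g <- makeGenome(seed = 1, nGenes = 20,
#'                 plantedPULs = plantedPUL("arabinan", 3))$genome
#' writeGenomeBundle(g, d)
#' g2 <- readGenomeBundle(file.path(d, "synthetic-1.gff3"),
#'                        file.path(d, "synthetic-1.fna"),
#'                        file.path(d, "synthetic-1.faa"),
#'                        file.path(d, "synthetic-1_features.tsv"))
#' @export
readGenomeBundle <- function(gffPath, contigFasta, proteinFasta, featureTSV,
                             genomeID = NULL) {
  for (p in c(gffPath, contigFasta, proteinFasta, featureTSV))
    if (!file.exists(p)) stop("file not found: ", p)
  if (is.null(genomeID))
    genomeID <- sub("\\.gff3?$", "", basename(gffPath))

  ctg <- Biostrings::readDNAStringSet(contigFasta)
  names(ctg) <- sub("\\s.*", "", names(ctg))
  prot <- Biostrings::readAAStringSet(proteinFasta)
  names(prot) <- sub("\\s.*", "", names(prot))

  gff <- rtracklayer::import(gffPath, format = "gff3")
  gff <- gff[gff$type == "CDS"]
  ids <- as.character(gff$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("every CDS must carry an ID attribute")

  feat <- utils::read.delim(featureTSV, colClasses = "character")
  need <- c("gene_id", "domains", "cazyme_families")
  if (!all(need %in% colnames(feat)))
    stop("feature TSV must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(feat$gene_id, ids)
  if (length(unknown))
    stop("feature TSV gene_id not present in GFF3: ",
         paste(unknown, collapse = ", "))

  splitComma <- function(x) {
    out <- strsplit(x, ",", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  i <- match(ids, feat$gene_id)
  dom <- fam <- vector("list", length(ids))
  dom[!is.na(i)] <- splitComma(feat$domains[i[!is.na(i)]])
  fam[!is.na(i)] <- splitComma(feat$cazyme_families[i[!is.na(i)]])
  dom[is.na(i)] <- list(character(0))
  fam[is.na(i)] <- list(character(0))

  product <- if ("product" %in% colnames(S4Vectors::mcols(gff)))
    as.character(gff$product) else character(length(gff))
  product[is.na(product)] <- ""

  gr <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(gff)),
    ranges = IRanges::ranges(gff),
    strand = GenomicRanges::strand(gff),
    gene_id = ids,
    domains = IRanges::CharacterList(dom),
    cazyme_families = IRanges::CharacterList(fam),
    product = product)

  GenomeAnnotation(genomeID, ctg, gr, prot[names(prot) %in% ids])
}

#' Write a genome bundle
#'
#' Inverse of [readGenomeBundle()]: writes \code{<prefix>.gff3},
#' \code{<prefix>.fna}, \code{<prefix>.faa} and
#' \code{<prefix>_features.tsv} into \code{dir}. Reading the bundle back
#' reproduces the object (coordinates, ordering, annotation sets).
#'
#' @param genome a [GenomeAnnotation-class].
#' @param dir output directory (created if absent).
#' @param prefix file-name stem; defaults to the genome ID.
#' @return Invisibly, the four paths written.
#' @export
writeGenomeBundle <- function(genome, dir, prefix = genomeID(genome)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".gff3", ".fna", ".faa",
                                           "_features.tsv")))
  gr <- genes(genome)
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr))
  out$source <- "PULscope"
  out$type <- "CDS"
  out$phase <- 0L
  out$ID <- gr$gene_id
  out$product <- gr$product
  rtracklayer::export(out, paths[1], format = "gff3")
  Biostrings::writeXStringSet(contigs(genome), paths[2])
  Biostrings::writeXStringSet(proteins(genome), paths[3])
  feat <- data.frame(
    gene_id = gr$gene_id,
    domains = vapply(gr$domains, paste, character(1), collapse = ","),
    cazyme_families = vapply(gr$cazyme_families, paste, character(1),
                             collapse = ","))
  utils::write.table(feat, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write / read a PUL call table
#'
#' Flat TSV twin of the in-memory [PULSet-class]: one row per PUL with
#' columns \code{genome_id}, \code{contig}, \code{start}, \code{end},
#' \code{n_genes}, \code{sus_pairs} (\code{susC|susD}, semicolon-joined),
#' \code{degradative_families} (semicolon-joined), \code{substrate},
#' \code{confidence}.
#'
#' @param puls a [PULSet-class] or list of them.
#' @param out output TSV path.
#' @return \code{writePULTable}: invisibly, the data.frame written.
#'   \code{readPULTable}: the table as a data.frame.
#' @export
writePULTable <- function(puls, out) {
  if (is(puls, "PULSet")) puls <- list(puls)
  rows <- lapply(puls, function(p) {
    cl <- p@calls
    data.frame(
      genome_id = rep(genomeID(p), nrow(cl)),
      contig = as.character(cl$contig),
      start = cl$start, end = cl$end, n_genes = cl$n_genes,
      sus_pairs = vapply(seq_len(nrow(cl)), function(i)
        paste(paste0(cl$susC[[i]], "|", cl$susD[[i]]), collapse = ";"),
        character(1)),
      degradative_families = .joinSemi(cl$degradative_families),
      substrate = cl$substrate, confidence = cl$confidence)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), contig = character(),
               start = integer(), end = integer(), n_genes = integer(),
               sus_pairs = character(), degradative_families = character(),
               substrate = character(), confidence = character())
  utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname writePULTable
#' @param path TSV path to read.
#' @export
readPULTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, colClasses = c(
    genome_id = "character", contig = "character", start = "integer",
    end = "integer", n_genes = "integer", sus_pairs = "character",
    degradative_families = "character", substrate = "character",
    confidence = "character"))
}
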