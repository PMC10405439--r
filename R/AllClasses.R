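#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
NULL

CAZY_FAMILY_RE <- "^(GH|PL|CE|GT|AA|CBM)[0-9]+(_[0-9]+)?$"

## susC-like and susD-like Pfam domain sets (TonB-dependent transporter /
## surface glycan-binding lipoprotein of the starch utilization system).
SUSC_DOMAINS <- c("PF00593", "PF13715", "PF07715")
SUSD_DOMAINS <- c("PF07980", "PF12741", "PF12771", "PF14322")

#' GenomeAnnotation: an annotated genome
#'
#' One genome (or MAG) as the pipeline sees it: nucleotide contigs, an
#' ordered table of gene models carrying protein-domain accessions and
#' CAZyme family labels, and the corresponding protein sequences.
#'
#' Gene models are held in a \code{GRanges} (1-based inclusive coordinates,
#' the GFF3 convention) with metadata columns \code{gene_id},
#' \code{ordinal} (0-based rank of the gene along its contig, ordered by
#' start, ties broken by end then gene_id), \code{domains} and
#' \code{cazyme_families} (\code{CharacterList}s), and \code{product}.
#' CAZyme labels follow the CAZy classification
#' (\code{(GH|PL|CE|GT|AA|CBM)<n>}, optionally with a dbCAN subfamily
#' suffix such as \code{GH43_4}); subfamily labels are retained verbatim
#' but compared at family level throughout unless a substrate rule names
#' the subfamily explicitly.
#'
#' @slot genomeID single genome identifier.
#' @slot contigs named \code{DNAStringSet} of contig sequences.
#' @slot genes \code{GRanges} of gene models, sorted by (contig, start).
#' @slot proteins \code{AAStringSet} named by \code{gene_id}.
#'
#' @seealso [readGenomeBundle()], [makeGenome()], [callPULs()]
#' @export
setClass("GenomeAnnotation",
  slots = c(
    genomeID = "character",
    contigs = "DNAStringSet",
    genes = "GRanges",
    proteins = "AAStringSet"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  gr <- object@genes
  ctg <- object@contigs
  if (length(object@genomeID) != 1L || is.na(object@genomeID))
    msg <- c(msg, "genomeID must be a single non-NA string")
  if (is.null(names(ctg)) || anyDuplicated(names(ctg)))
    msg <- c(msg, "contigs must be uniquely named")
  need <- c("gene_id", "ordinal", "domains", "cazyme_families", "product")
  if (!all(need %in% colnames(S4Vectors::mcols(gr)))) {
    return(c(msg, paste("genes must carry metadata columns:",
                        paste(need, collapse = ", "))))
  }
  if (length(gr)) {
    sq <- as.character(GenomicRanges::seqnames(gr))
    if (!all(sq %in% names(ctg)))
      msg <- c(msg, "every gene's contig must exist in contigs")
    else {
      w <- stats::setNames(BiocGenerics::width(ctg), names(ctg))[sq]
      if (any(GenomicRanges::end(gr) > w) || any(GenomicRanges::start(gr) < 1L))
        msg <- c(msg, "gene spans must lie within their contig")
    }
    if (anyDuplicated(gr$gene_id))
      msg <- c(msg, "gene_id values must be unique")
    o <- order(match(sq, names(ctg)), GenomicRanges::start(gr),
               GenomicRanges::end(gr), gr$gene_id)
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "genes must be sorted by (contig, start, end, gene_id)")
    ord.ok <- unlist(lapply(split(gr$ordinal, sq), function(x)
      identical(as.integer(sort(x)), seq_along(x) - 1L)), use.names = FALSE)
    if (!all(ord.ok))
      msg <- c(msg, "ordinals must be 0-based and consecutive within a contig")
    fams <- unlist(gr$cazyme_families, use.names = FALSE)
    if (length(fams) && !all(grepl(CAZY_FAMILY_RE, fams)))
      msg <- c(msg, sprintf("malformed CAZyme family label(s): %s",
        paste(unique(fams[!grepl(CAZY_FAMILY_RE, fams)]), collapse = ", ")))
    if (length(object@proteins) &&
        !all(names(object@proteins) %in% gr$gene_id))
      msg <- c(msg, "protein names must be gene_ids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' Genes are re-sorted by (contig, start, end, gene_id) and 0-based
#' ordinals are (re)assigned per contig, so callers may pass genes in any
#' order and without an \code{ordinal} column.
#'
#' @param genomeID single genome identifier.
#' @param contigs named \code{DNAStringSet}.
#' @param genes \code{GRanges} with metadata columns \code{gene_id},
#'   \code{domains}, \code{cazyme_families}, \code{product}
#'   (\code{domains}/\code{cazyme_families} as \code{CharacterList}s).
#' @param proteins \code{AAStringSet} named by gene_id (may be empty).
#' @return A validated [GenomeAnnotation-class] object.
#' @export
GenomeAnnotation <- function(genomeID, contigs, genes,
                             proteins = Biostrings::AAStringSet()) {
  genes <- .orderGenes(genes, names(contigs))
  new("GenomeAnnotation", genomeID = as.character(genomeID),
      contigs = contigs, genes = genes, proteins = proteins)
}

.orderGenes <- function(gr, contigOrder) {
  sq <- as.character(GenomicRanges::seqnames(gr))
  o <- order(match(sq, contigOrder), GenomicRanges::start(gr),
             GenomicRanges::end(gr), gr$gene_id)
  gr <- gr[o]
  sq <- as.character(GenomicRanges::seqnames(gr))
  gr$ordinal <- stats::ave(seq_along(gr), sq, FUN = seq_along) - 1L
  gr
}

setMethod("show", "GenomeAnnotation", function(object) {
  nc <- sum(lengths(genes(object)$cazyme_families) > 0)
  cat("GenomeAnnotation '", object@genomeID, "': ",
      length(object@contigs), " contig(s), ",
      format(sum(BiocGenerics::width(object@contigs)), big.mark = ","),
      " bp, ", length(object@genes), " genes (", nc, " CAZyme)\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("genomeID", "GenomeAnnotation", function(x) x@genomeID)
#' @rdname accessors
#' @export
setMethod("contigs", "GenomeAnnotation", function(x) x@contigs)
#' @rdname accessors
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("proteins", "GenomeAnnotation", function(x) x@proteins)

#' PULSet: called polysaccharide utilization loci
#'
#' The PUL calls for one genome. Each row of the call table is one locus:
#' its member genes (consecutive along one contig), the tandem susCD
#' pair(s) anchoring it, the degradative GH/PL families it carries, its
#' nucleotide span, and the substrate assigned from the rule table.
#'
#' @slot genomeID the genome the calls belong to.
#' @slot calls \code{DataFrame} with columns \code{pul_id}, \code{contig},
#'   \code{start}, \code{end}, \code{n_genes}, \code{gene_ids},
#'   \code{susC}, \code{susD} (CharacterLists), \code{degradative_families}
#'   (CharacterList, one label per degradative gene-family record),
#'   \code{substrate}, \code{confidence}.
#' @seealso [callPULs()], [classifyPUL()], [writePULTable()]
#' @export
setClass("PULSet",
  slots = c(genomeID = "character", calls = "DataFrame"))

setValidity("PULSet", function(object) {
  need <- c("pul_id", "contig", "start", "end", "n_genes", "gene_ids",
            "susC", "susD", "degradative_families", "substrate", "confidence")
  if (!all(need %in% colnames(object@calls)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  cl <- object@calls
  if (nrow(cl)) {
    if (any(cl$start > cl$end)) return("start must be <= end")
    if (any(lengths(cl$susC) < 1L)) return("each PUL needs >= 1 susCD pair")
  }
  TRUE
})

setMethod("show", "PULSet", function(object) {
  cl <- object@calls
  cat("PULSet for '", object@genomeID, "': ", nrow(cl), " PUL(s)\n", sep = "")
  if (nrow(cl))
    print(as.data.frame(cl[, c("pul_id", "contig", "start", "end",
                               "n_genes", "substrate")]))
})

setMethod("length", "PULSet", function(x) nrow(x@calls))

#' @rdname accessors
#' @export
setMethod("genomeID", "PULSet", function(x) x@genomeID)
#' @rdname accessors
#' @export
setMethod("puls", "PULSet", function(x) x@calls)

#' SubstrateRules: substrate-diagnostic CAZyme family table
#'
#' Ordered mapping from glycan substrate types to their diagnostic
#' degradative (GH/PL) CAZyme families, with a minimum-evidence threshold
#' per substrate. See [substrateRules()] for the built-in default table.
#'
#' @slot rules \code{DataFrame} with columns \code{substrate},
#'   \code{families} (CharacterList) and \code{min_hits} (integer).
#' @export
setClass("SubstrateRules", slots = c(rules = "DataFrame"))

setValidity("SubstrateRules", function(object) {
  r <- object@rules
  msg <- character()
  if (!all(c("substrate", "families", "min_hits") %in% colnames(r)))
    return("rules must have columns substrate, families, min_hits")
  if (anyDuplicated(r$substrate))
    msg <- c(msg, "substrate names must be unique")
  fams <- unlist(r$families, use.names = FALSE)
  bad <- fams[!grepl("^(GH|PL)[0-9]+(_[0-9]+)?$", fams)]
  if (length(bad))
    msg <- c(msg, sprintf("diagnostic families must be GH/PL labels; bad: %s",
                          paste(unique(bad), collapse = ", ")))
  if (any(r$min_hits < 1L)) msg <- c(msg, "min_hits must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubstrateRules", function(object) {
  r <- object@rules
  cat("SubstrateRules:", nrow(r), "substrate type(s)\n")
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-28s %s (min_hits=%d)\n", r$substrate[i],
                paste(r$families[[i]], collapse = "/"), r$min_hits[i]))
})

setMethod("length", "SubstrateRules", function(x) nrow(x@rules))

#' @rdname accessors
#' @export
setMethod("ruleTable", "SubstrateRules", function(x) x@rules)

#' GCProfile: non-overlapping GC-content windows
#'
#' Per-window GC fractions along one contig, computed over non-overlapping
#' windows (trailing partial window dropped). Ambiguous bases are excluded
#' from both numerator and denominator; \code{informativeBases} records the
#' number of unambiguous bases per window so that the base-weighted mean of
#' the window values reconstructs the GC of the covered prefix exactly.
#'
#' @slot contigID contig identifier.
#' @slot windowBp window size in bp.
#' @slot gc per-window GC fractions in [0, 1].
#' @slot informativeBases unambiguous (A/C/G/T) base count per window.
#' @slot overallGC GC fraction of the whole input sequence.
#' @seealso [gcProfile()]
#' @export
setClass("GCProfile",
  slots = c(contigID = "character", windowBp = "integer",
            gc = "numeric", informativeBases = "integer",
            overallGC = "numeric"))

setValidity("GCProfile", function(object) {
  if (length(object@gc) &&
      (any(object@gc < 0) || any(object@gc > 1)))
    return("window GC values must lie in [0, 1]")
  if (length(object@gc) != length(object@informativeBases))
    return("gc and informativeBases must be parallel")
  TRUE
})

setMethod("show", "GCProfile", function(object) {
  cat("GCProfile '", object@contigID, "': ", length(object@gc),
      " windows of ", object@windowBp, " bp; overall GC ",
      sprintf("%.1f%%", 100 * object@overallGC), "\n", sep = "")
})

setMethod("length", "GCProfile", function(x) length(x@gc))

#' @rdname accessors
#' @export
setMethod("gcValues", "GCProfile", function(x) x@gc)
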