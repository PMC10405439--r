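## Built-in substrate rule table. Each substrate type maps to the GH/PL
## families commonly diagnostic for degrading that glycan; GH2 and GH5 are
## functionally broad families and require two independent hits before a
## call is made on their evidence alone.
.DEFAULT_RULES <- list(
  "alpha-1,4-glucan"           = list(families = "GH13", min_hits = 1L),
  "beta-1,3-glucan/laminarin"  = list(families = "GH16", min_hits = 1L),
  "beta-1,4-glucan/cellulose"  = list(families = "GH5", min_hits = 2L),
  "alpha-mannan"               = list(families = "GH92", min_hits = 1L),
  "fucose-containing glycan"   = list(families = "GH29", min_hits = 1L),
  "sialic-acid oligosaccharides" = list(families = "GH33", min_hits = 1L),
  "beta-galactan"              = list(families = "GH2", min_hits = 2L),
  "beta-1,2-glucan"            = list(families = "GH144", min_hits = 1L),
  "xylan"                      = list(families = c("GH10", "GH115"),
                                      min_hits = 1L),
  "arabinan"                   = list(families = c("GH43", "GH51", "GH127"),
                                      min_hits = 1L),
  "alginate"                   = list(families = c("PL6", "PL7", "PL17"),
                                      min_hits = 1L),
  "xyloglucan"                 = list(families = c("GH74", "GH31"),
                                      min_hits = 1L),
  "beta-mannan"                = list(families = c("GH26", "GH130"),
                                      min_hits = 1L),
  "pectic main chain"          = list(families = c("GH28", "PL1", "PL11"),
                                      min_hits = 1L)
)

#' Substrate rule tables
#'
#' \code{substrateRules()} returns the rule table mapping glycan substrate
#' types to their diagnostic degradative CAZyme families.
#' \code{"default"} gives the built-in 14-substrate table (storage
#' glucans, hemicelluloses, pectins, algal polysaccharides); a JSON path
#' gives a user table with schema
#' \code{{"substrate": {"families": [...], "min_hits": n}}} (bare family
#' arrays are accepted, implying \code{min_hits = 1}).
#' \code{writeSubstrateRules()} dumps a table back to that JSON schema, so
#' \code{substrateRules(writeSubstrateRules(x, f))} reproduces \code{x}.
#'
#' @param config \code{"default"} or a JSON file path.
#' @return A [SubstrateRules-class].
#' @examples
#' substrateRules()
#' @export
substrateRules <- function(config = "default") {
  if (identical(config, "default")) {
    raw <- .DEFAULT_RULES
  } else {
    if (!file.exists(config)) stop("rule config not found: ", config)
    raw <- jsonlite::read_json(config, simplifyVector = FALSE)
    if (anyDuplicated(names(raw)))
      stop("duplicate substrate name(s): ",
           paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
    raw <- lapply(raw, function(r) {
      if (is.null(names(r)))  # bare family array
        list(families = unlist(r), min_hits = 1L)
      else
        list(families = unlist(r$families),
             min_hits = as.integer(if (is.null(r$min_hits)) 1L else r$min_hits))
    })
  }
  df <- S4Vectors::DataFrame(
    substrate = names(raw),
    families = IRanges::CharacterList(lapply(raw, `[[`, "families")),
    min_hits = unname(vapply(raw, `[[`, integer(1), "min_hits")))
  rownames(df) <- NULL
  new("SubstrateRules", rules = df)
}

#' @rdname substrateRules
#' @param rules a [SubstrateRules-class].
#' @param path output JSON path.
#' @export
writeSubstrateRules <- function(rules, path) {
  r <- ruleTable(rules)
  out <- stats::setNames(lapply(seq_len(nrow(r)), function(i)
    list(families = as.character(r$families[[i]]),
         min_hits = r$min_hits[i])), r$substrate)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Assign a PUL to a substrate by diagnostic-family voting
#'
#' Every (gene, GH/PL family) record in the PUL votes for each substrate
#' whose diagnostic set contains the family (family-level comparison; a
#' rule naming a dbCAN subfamily matches only that subfamily). The winner
#' is the substrate with the most votes among those meeting their
#' \code{min_hits}; a tie between distinct winners yields \code{"mixed"},
#' and no qualifying votes yields \code{"unclassified"}. Families matching
#' no rule contribute no votes.
#'
#' @param puls a [PULSet-class].
#' @param i row index of the PUL to classify.
#' @param rules a [SubstrateRules-class].
#' @return list with elements \code{substrate}, \code{votes} (named
#'   integer) and \code{evidence} (data.frame gene_id, family, substrate).
#' @export
classifyPUL <- function(puls, i = 1L, rules = substrateRules()) {
  cl <- puls@calls
  stopifnot(i >= 1L, i <= nrow(cl))
  fams <- cl$degradative_families[[i]]
  gids <- if ("degradative_genes" %in% colnames(cl))
    cl$degradative_genes[[i]] else rep(NA_character_, length(fams))
  classifyFamilySet(fams, rules, geneIDs = gids)
}

#' @rdname classifyPUL
#' @param families character vector of GH/PL family labels, one record
#'   per (gene, family) evidence unit.
#' @param geneIDs optional gene ids parallel to \code{families}.
#' @export
classifyFamilySet <- function(families, rules = substrateRules(),
                              geneIDs = NULL) {
  fams <- families
  gids <- if (is.null(geneIDs)) rep(NA_character_, length(fams)) else geneIDs
  r <- ruleTable(rules)
  ev <- list()
  votes <- stats::setNames(integer(nrow(r)), r$substrate)
  for (j in seq_len(nrow(r))) {
    hit <- matchesRuleFamily(fams, r$families[[j]])
    votes[j] <- sum(hit)
    if (any(hit))
      ev[[length(ev) + 1L]] <- data.frame(
        gene_id = gids[hit], family = fams[hit],
        substrate = r$substrate[j])
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(gene_id = character(), family = character(),
               substrate = character())
  eligible <- votes[votes >= r$min_hits & votes > 0L]
  substrate <- if (!length(eligible)) "unclassified"
  else {
    win <- names(eligible)[eligible == max(eligible)]
    if (length(win) > 1L) "mixed" else win
  }
  list(substrate = substrate, votes = votes, evidence = evidence)
}

#' Per-genome substrate profile of called PULs
#'
#' Calls PULs in each genome and tabulates counts per substrate type: an
#' integer matrix of genomes by substrates. \code{"mixed"} and
#' \code{"unclassified"} calls are reported in separate final columns, so
#' the row sum over substrate columns equals the per-genome count of
#' substrate-assigned PULs.
#'
#' @param genomes list of [GenomeAnnotation-class] objects.
#' @param rules a [SubstrateRules-class].
#' @param ... passed to [callPULs()] (window, minDegradative, ...).
#' @return Integer matrix, rownames = genome IDs, colnames = substrate
#'   names plus \code{"mixed"} and \code{"unclassified"}.
#' @export
substrateProfile <- function(genomes, rules = substrateRules(), ...) {
  subs <- c(ruleTable(rules)$substrate, "mixed", "unclassified")
  m <- matrix(0L, nrow = length(genomes), ncol = length(subs),
              dimnames = list(
                vapply(genomes, genomeID, character(1)), subs))
  for (g in seq_along(genomes)) {
    p <- callPULs(genomes[[g]], rules = rules, ...)
    if (length(p)) {
      tab <- table(factor(puls(p)$substrate, levels = subs))
      m[g, ] <- as.integer(tab)
    }
  }
  m
}
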