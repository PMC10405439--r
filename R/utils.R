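## Internal helpers shared across modules.

## dbCAN subfamily labels (GH43_4) are compared at family level (GH43)
## unless a rule names the subfamily explicitly.
familyLevel <- function(x) sub("_[0-9]+$", "", x)

## A gene is "degradative" iff it carries >= 1 GH or PL family.
.isDegradative <- function(famList) {
  vapply(famList, function(f) any(grepl("^(GH|PL)[0-9]", f)), logical(1))
}

## Evaluate expr under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

.joinSemi <- function(x) vapply(x, paste, character(1), collapse = ";")

.splitSemi <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

## A match(family-set, rule-families) that honours the family-level
## convention: a rule family without subfamily suffix matches any
## subfamily; a rule naming a subfamily matches only that subfamily.
matchesRuleFamily <- function(geneFams, ruleFams) {
  hasSub <- grepl("_", ruleFams, fixed = TRUE)
  geneFams %in% ruleFams[hasSub] |
    familyLevel(geneFams) %in% ruleFams[!hasSub]
}
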