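# Independent brute-force restatement of the classification rules,
# written directly from the set conditions (no shared code with
# classify_sets): used to prove the classifier over all ordered triples
# of non-empty subsets of {A,C,G,T,-}.

symbol_subsets <- local({
  syms <- c("A", "C", "G", "T", "-")
  lapply(1:31, function(b) syms[bitwAnd(b, 2L^(0:4)) > 0L])
})

oracle_classify3 <- function(sets) {
  labs <- names(sets)
  single <- function(s) length(s) == 1L
  disjoint <- function(p, q) length(intersect(p, q)) == 0L
  s1 <- sets[[1]]; s2 <- sets[[2]]; s3 <- sets[[3]]
  if (single(s1) && single(s2) && single(s3) &&
      s1 == s2 && s2 == s3 && s1 != "-") {
    return(list(category = "UNIVERSAL", groups = character(0),
                subtype = NA_character_))
  }
  for (p in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
    X <- sets[[p[1]]]; Y <- sets[[p[2]]]
    Z <- sets[[setdiff(1:3, p)]]
    if (disjoint(Z, union(X, Y)) && !disjoint(X, Y)) {
      return(list(category = "PAIR", groups = sort(labs[p]),
                  subtype = if ("-" %in% intersect(X, Y)) "INDEL"
                            else "SUBSTITUTION"))
    }
  }
  for (i in 1:3) {
    X <- sets[[i]]
    others <- unlist(sets[setdiff(1:3, i)])
    if (single(X) && disjoint(X, others)) {
      return(list(category = "ONLY", groups = labs[i],
                  subtype = if (X == "-") "INDEL" else "SUBSTITUTION"))
    }
  }
  list(category = "UNCLASSIFIED", groups = character(0),
       subtype = NA_character_)
}

# how many of the three pair patterns hold (for mutual-exclusivity)
n_qualifying_pairs <- function(sets) {
  disjoint <- function(p, q) length(intersect(p, q)) == 0L
  n <- 0L
  for (p in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
    X <- sets[[p[1]]]; Y <- sets[[p[2]]]
    Z <- sets[[setdiff(1:3, p)]]
    if (disjoint(Z, union(X, Y)) && !disjoint(X, Y)) n <- n + 1L
  }
  n
}
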