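# Fixtures built in code: tiny references and an enumeration-based
# classification oracle independent of the package's matching path.

# Mature used in the classification examples (21 nt).
T21 <- "AUCGAUCGAUCGAUCGAUCGA"

# Two-group reference: T21 plus an unrelated mature, each inside a hairpin
# whose first downstream base is G (so U-tails are never templated).
write_mini_ref <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("miniref")
    dir.create(dir)
  }
  m2 <- "GGCAUUCAGGCAUUCAGGCAU"
  mat <- file.path(dir, "mature.fa")
  hp <- file.path(dir, "hairpin.fa")
  writeLines(c(">miR900a", T21, ">miR901a", m2), mat)
  writeLines(c(">miR900a", paste0("CCAAGG", T21, "GGAUCCAAGG"),
               ">miR901a", paste0("AAUUGG", m2, "GCCAUUGGAA")), hp)
  list(mature = mat, hairpin = hp)
}

mini_refset <- function() {
  f <- write_mini_ref()
  load_references(f$mature, f$hairpin)
}

# Exhaustive decomposition oracle: for every reference and every split of
# the read into (matched mature prefix, suffix), collect the valid
# decompositions, take the maximal matched prefix per reference, then the
# minimal truncation across references; exact ties are ambiguous.
oracle_classify <- function(s, refset, params = classify_params()) {
  n <- nchar(s)
  if (n < params$min_len || n > params$max_len) {
    return(list(status = "filtered"))
  }
  cands <- list()
  for (i in seq_len(nrow(refset$groups))) {
    g <- refset$groups[i, ]
    L <- g$mature_len
    valid <- list()
    for (m in params$min_match:min(L, n)) {
      if (substr(s, 1, m) != substr(g$mature, 1, m)) next
      # m must be the full shared prefix: a longer agreeing split exists
      # unless the next characters differ (or one string ends)
      maximal <- (m == min(L, n)) ||
        substr(s, m + 1, m + 1) != substr(g$mature, m + 1, m + 1)
      if (!maximal) next
      tr <- L - m
      tail <- substring(s, m + 1)
      if (tr <= params$max_tr && nchar(tail) <= params$max_ta) {
        valid[[length(valid) + 1]] <- list(group = g$group_name, tr = tr,
                                           tail = tail)
      }
    }
    if (length(valid)) {
      trs <- vapply(valid, `[[`, numeric(1), "tr")
      cands[[length(cands) + 1]] <- valid[[which.min(trs)]]
    }
  }
  if (!length(cands)) return(list(status = "unassigned"))
  trs <- vapply(cands, `[[`, numeric(1), "tr")
  best <- which(trs == min(trs))
  if (length(best) > 1) return(list(status = "ambiguous"))
  c(list(status = "assigned"), cands[[best]])
}

# Random calls tibble for marginalisation/matrix properties.
random_calls <- function(n = 50, max_tr = 8, max_ta = 8) {
  tr <- sample(0:max_tr, n, replace = TRUE)
  ta <- sample(0:max_ta, n, replace = TRUE)
  tibble::tibble(
    library = "lib", group = "g1", tr = tr, ta = ta,
    tail_seq = vapply(ta, function(k) {
      paste(sample(c("A", "C", "G", "U"), k, replace = TRUE), collapse = "")
    }, character(1)),
    category = ifelse(tr == 0 & ta == 0, "FL",
                 ifelse(tr > 0 & ta == 0, "TR_ONLY",
                   ifelse(tr == 0 & ta > 0, "TA_ONLY", "TR_TA"))),
    count = sample(1:20, n, replace = TRUE)
  )
}
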