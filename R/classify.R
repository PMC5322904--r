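# Read classification. A read is assigned to a miRNA group when its 5' end
# exactly matches the mature 5' end over at least `min_match` bases; the
# matched length is the longest common prefix of read and mature. Whatever
# the read carries past the matched prefix is the 3' tail, and the distance
# from the matched prefix to the mature 3' end is the truncation length:
#
#   tr = mature_length - matched,  tail = read[matched+1 ...],  ta = nchar(tail)
#   (tr, ta) = (0,0) FL | (>0,0) TR-only | (0,>0) TA-only | (>0,>0) TR+TA
#
# No internal mismatches and no 5' isomiR offsets are allowed: the
# quantities of interest here are purely 3'-end phenomena.

CATEGORY_LEVELS <- c("FL", "TR_ONLY", "TA_ONLY", "TR_TA")

#' Classification parameters
#'
#' @param max_tr maximum 3' truncation length accepted (nt, default 8).
#' @param max_ta maximum tail length accepted (nt, default 8).
#' @param min_match minimum exactly matched 5' prefix (nt, default 12; kept
#'   >= 10 so that spurious matches at genome scale are improbable).
#' @param tail_dialect `"mature_anchored"` (default: every base past the
#'   matched mature prefix counts as tail, even if hairpin-templated) or
#'   `"template_extended"` (matching may continue past the mature 3' end
#'   along the hairpin; the templated extension length is reported in
#'   `templated_ext`, and the category is called on tr = 0 with the full
#'   suffix as tail).
#' @param ambiguous_policy `"drop"` (default) or `"fractional"` for reads
#'   tying between groups at equal truncation.
#' @param min_len,max_len read length filter applied before matching
#'   (defaults 15 and 30 nt; adapter trimming is assumed upstream).
#' @return a `classify_params` list.
#' @export
classify_params <- function(max_tr = 8, max_ta = 8, min_match = 12,
                            tail_dialect = c("mature_anchored",
                                             "template_extended"),
                            ambiguous_policy = c("drop", "fractional"),
                            min_len = 15, max_len = 30) {
  tail_dialect <- match.arg(tail_dialect)
  ambiguous_policy <- match.arg(ambiguous_policy)
  stopifnot(max_tr >= 0, max_ta >= 0, min_match >= 1, min_len <= max_len)
  if (min_match < 10) {
    warning("min_match < 10 risks spurious assignments; proceeding anyway")
  }
  structure(list(max_tr = as.integer(max_tr), max_ta = as.integer(max_ta),
                 min_match = as.integer(min_match),
                 tail_dialect = tail_dialect,
                 ambiguous_policy = ambiguous_policy,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "classify_params")
}

# 5' k-mer index: named list mapping the first min_match bases of each
# mature to the row indices of candidate groups.
prefix_index <- function(refset, k) {
  g <- refset$groups
  if (any(g$mature_len < k)) {
    stop("min_match (", k, ") exceeds the shortest mature length (",
         min(g$mature_len), ")", call. = FALSE)
  }
  split(seq_len(nrow(g)), substr(g$mature, 1, k))
}

#' Classify reads, one row per input read
#'
#' Vectorised over a tibble of reads. Returns a per-read table carrying the
#' assignment (or the reason there is none); [classify_library()] wraps
#' this with aggregation and summary statistics.
#'
#' @param reads tibble with columns `seq` and optionally `count`
#'   (collapsed multiplicity, default 1) and `id`.
#' @param refset a [load_references()] result.
#' @param params a [classify_params()] list.
#' @return tibble with columns `id`, `seq`, `count`, `status` (one of
#'   `assigned`, `unassigned`, `ambiguous`, `filtered`), `group`, `tr`,
#'   `tail_seq`, `ta`, `category`, `templated_ext`. Under the fractional
#'   policy an ambiguous read yields one `assigned` row per tied group with
#'   its count split equally.
#' @export
classify_reads <- function(reads, refset, params = classify_params()) {
  stopifnot(inherits(refset, "mirna_refset"))
  if (!inherits(params, "classify_params")) {
    params <- do.call(classify_params, params)
  }
  reads <- tibble::as_tibble(reads)
  if (!"count" %in% names(reads)) reads$count <- 1
  if (!"id" %in% names(reads)) {
    reads$id <- sprintf("read_%06d", seq_len(nrow(reads)))
  }
  g <- refset$groups
  if (params$max_tr >= min(g$mature_len) - 1) {
    stop("max_tr (", params$max_tr, ") must be smaller than the shortest ",
         "mature length - 1 (", min(g$mature_len) - 1, ")", call. = FALSE)
  }
  if (nrow(reads) == 0) {
    return(empty_read_calls())
  }

  reads$seq <- normalize_rna(reads$seq, ids = reads$id)
  idx <- prefix_index(refset, params$min_match)

  # work on unique sequences, then fan back out to reads
  useq <- unique(reads$seq)
  ulen <- nchar(useq)
  ukey <- substr(useq, 1, params$min_match)
  ures <- vector("list", length(useq))

  for (u in seq_along(useq)) {
    s <- useq[u]
    if (ulen[u] < params$min_len || ulen[u] > params$max_len) {
      ures[[u]] <- list(status = "filtered")
      next
    }
    cand <- idx[[ukey[u]]]
    if (is.null(cand)) {
      ures[[u]] <- list(status = "unassigned")
      next
    }
    best <- classify_against(s, g, cand, params)
    ures[[u]] <- best
  }

  # unique-level result table, one row per (sequence x tied group), then a
  # vectorised join back onto the reads
  reps <- vapply(ures, function(r) {
    if (r$status == "assigned") length(r$group) else 1L
  }, integer(1))
  ut <- tibble::tibble(
    .uidx = rep(seq_along(useq), reps),
    status = rep(vapply(ures, `[[`, character(1), "status"), reps),
    group = unlist(lapply(ures, function(r) {
      if (r$status == "assigned") r$group else NA_character_
    })),
    tr = unlist(lapply(ures, function(r) {
      if (r$status == "assigned") r$tr else NA_integer_
    })),
    tail_seq = unlist(lapply(ures, function(r) {
      if (r$status == "assigned") r$tail else NA_character_
    })),
    templated_ext = unlist(lapply(ures, function(r) {
      if (r$status == "assigned") r$templated_ext else NA_integer_
    })),
    .nties = rep(reps, reps)
  )
  reads$.uidx <- match(reads$seq, useq)
  out <- dplyr::inner_join(reads[, c("id", "seq", "count", ".uidx")], ut,
                           by = ".uidx", relationship = "many-to-many")
  out |>
    dplyr::mutate(
      count = .data$count / .data$.nties,
      ta = ifelse(is.na(.data$tail_seq), NA_integer_, nchar(.data$tail_seq)),
      category = ifelse(.data$status == "assigned",
                        call_category(.data$tr, .data$ta), NA_character_)
    ) |>
    dplyr::select("id", "seq", "count", "status", "group", "tr", "tail_seq",
                  "ta", "category", "templated_ext")
}

# Core per-sequence decision over candidate groups.
classify_against <- function(s, groups, cand, params) {
  hits <- list()
  for (ci in cand) {
    L <- groups$mature_len[ci]
    matched <- min(lcp_len(s, groups$mature[ci]), L)
    if (matched < params$min_match) next
    tr <- as.integer(L - matched)
    tail <- substring(s, matched + 1)
    text <- 0L
    if (params$tail_dialect == "template_extended" && tr == 0L &&
        nchar(tail) > 0) {
      text <- lcp_len(tail, groups$downstream[ci])
    }
    if (tr <= params$max_tr && nchar(tail) <= params$max_ta) {
      hits[[length(hits) + 1]] <- list(group = groups$group_name[ci],
                                       tr = tr, tail = tail,
                                       templated_ext = text)
    }
  }
  if (!length(hits)) return(list(status = "unassigned"))
  trs <- vapply(hits, `[[`, integer(1), "tr")
  best <- which(trs == min(trs))
  if (length(best) == 1) {
    h <- hits[[best]]
    return(list(status = "assigned", group = h$group, tr = h$tr,
                tail = h$tail, templated_ext = h$templated_ext))
  }
  if (params$ambiguous_policy == "drop") {
    return(list(status = "ambiguous"))
  }
  # fractional: keep all tied groups; caller splits the count
  list(status = "assigned",
       group = vapply(hits[best], `[[`, character(1), "group"),
       tr = vapply(hits[best], `[[`, integer(1), "tr"),
       tail = vapply(hits[best], `[[`, character(1), "tail"),
       templated_ext = vapply(hits[best], `[[`, integer(1), "templated_ext"))
}

call_category <- function(tr, ta) {
  ifelse(tr == 0 & ta == 0, "FL",
    ifelse(tr > 0 & ta == 0, "TR_ONLY",
      ifelse(tr == 0 & ta > 0, "TA_ONLY", "TR_TA")))
}

empty_read_calls <- function() {
  tibble::tibble(id = character(), seq = character(), count = numeric(),
                 status = character(), group = character(), tr = integer(),
                 tail_seq = character(), ta = integer(),
                 category = character(), templated_ext = integer())
}

#' Classify a single read
#'
#' Convenience wrapper around [classify_reads()] for one sequence.
#'
#' @param seq an RNA/DNA string (or a list/tibble row with `seq`, `count`).
#' @param refset,params see [classify_reads()].
#' @param count read multiplicity (default 1).
#' @return one-row tibble (possibly more under the fractional policy); the
#'   `status` column is `"assigned"`, `"unassigned"`, `"ambiguous"` or
#'   `"filtered"` — none of these is an error.
#' @export
classify_read <- function(seq, refset, params = classify_params(),
                          count = 1) {
  if (is.list(seq)) {
    count <- if (!is.null(seq$count)) seq$count else count
    seq <- seq$seq
  }
  classify_reads(tibble::tibble(seq = seq, count = count), refset, params)
}

#' Classify a library and aggregate isoform calls
#'
#' Runs [classify_reads()], aggregates assigned reads by
#' (group, tr, tail_seq) with summed counts, and reports library statistics.
#' Reads failing the 15–30 nt length filter are counted inside
#' `unassigned` (and reported separately as `length_filtered`), so
#' `assigned + unassigned + ambiguous_dropped == total_count` always holds.
#'
#' @inheritParams classify_reads
#' @param library_id label stored with the calls (default `"library"`).
#' @return an `isotrim_library`: list with `library_id`, `calls` (tibble:
#'   `library`, `group`, `tr`, `tail_seq`, `ta`, `category`,
#'   `templated_ext`, `count`), `reads` (the per-read table) and `stats`
#'   (one-row tibble: `total_count`, `assigned`, `unassigned`,
#'   `ambiguous_dropped`, `length_filtered`).
#' @export
classify_library <- function(reads, refset, params = classify_params(),
                             library_id = "library") {
  by_read <- classify_reads(reads, refset, params)

  calls <- by_read |>
    dplyr::filter(.data$status == "assigned") |>
    dplyr::group_by(.data$group, .data$tr, .data$tail_seq, .data$ta,
                    .data$category) |>
    dplyr::summarise(count = sum(.data$count),
                     templated_ext = max(.data$templated_ext, 0L),
                     .groups = "drop") |>
    dplyr::mutate(library = library_id, .before = 1) |>
    dplyr::arrange(.data$group, .data$tr, .data$tail_seq)

  # per-read status counts weighted by multiplicity; fractional rows of one
  # read sum back to its original count
  per_read <- by_read |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(status = .data$status[1], count = sum(.data$count),
                     .groups = "drop")
  n_of <- function(st) sum(per_read$count[per_read$status %in% st])
  stats <- tibble::tibble(
    library = library_id,
    total_count = sum(per_read$count),
    assigned = n_of("assigned"),
    unassigned = n_of(c("unassigned", "filtered")),
    ambiguous_dropped = n_of("ambiguous"),
    length_filtered = n_of("filtered")
  )

  structure(list(library_id = library_id, calls = calls, reads = by_read,
                 stats = stats, params = params),
            class = "isotrim_library")
}

#' @export
print.isotrim_library <- function(x, ...) {
  s <- x$stats
  cat("<isotrim_library> ", x$library_id, ": ", s$total_count,
      " reads; assigned ", s$assigned, ", unassigned ", s$unassigned,
      " (", s$length_filtered, " length-filtered), ambiguous ",
      s$ambiguous_dropped, "\n", sep = "")
  invisible(x)
}
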